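#' Total-variation solver configuration
#'
#' @param lambda_tv regularization weight on unit-normalized intensities
#'   (default 1e-2; 0 gives pure least squares).
#' @param step_size gradient-descent step; `NULL` (default) estimates
#'   `1/L` by power iteration on the normal operator.
#' @param max_iterations iteration cap.
#' @param tv_epsilon smoothing constant of the isotropic TV semi-norm.
#' @param tolerance relative objective-change stopping threshold.
#' @return An object of class `srmri_tvconfig`.
#' @export
tv_config <- function(lambda_tv = 1e-2, step_size = NULL,
                      max_iterations = 200L, tv_epsilon = 1e-3,
                      tolerance = 1e-6) {
  if (lambda_tv < 0) stop("lambda_tv must be nonnegative")
  if (tv_epsilon <= 0) stop("tv_epsilon must be positive")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(lambda_tv = lambda_tv, step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 tv_epsilon = tv_epsilon, tolerance = tolerance),
            class = "srmri_tvconfig")
}

# HR lattice implied by a set of stacks: in-plane axes carry the true extent,
# the slice axis of each stack is upsampled by its factor (symmetric padding
# introduced by the decimation is undone via the recorded geometry)
derive_hr_lattice <- function(stacks, geoms) {
  sp <- geoms[[1]]$inplane_spacing
  shape <- integer(3)
  for (a in 1:3) {
    inplane <- unlist(lapply(seq_along(stacks), function(i)
      if (geoms[[i]]$slice_axis != a) dim(stacks[[i]]$data)[a] else NULL))
    shape[a] <- if (length(inplane)) max(inplane) else
      max(vapply(seq_along(stacks), function(i)
        dim(stacks[[i]]$data)[a] * geoms[[i]]$factor, numeric(1)))
  }
  aff <- stacks[[1]]$affine
  ax <- geoms[[1]]$slice_axis
  f <- geoms[[1]]$factor
  aff[1:3, ax] <- aff[1:3, ax] / f
  np <- dim(stacks[[1]]$data)[ax] * f
  padl <- (np - shape[ax]) %/% 2L
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, ax] * padl
  list(shape = shape, affine = aff, spacing = rep(sp, 3))
}

build_stack_ops <- function(stacks, geoms, transforms, hr_shape, hr_affine,
                            truncate = 4) {
  if (is.null(transforms)) transforms <- rep(list(rigid_transform()),
                                             length(stacks))
  ops <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    ops[[i]] <- make_degrade_op(hr_shape, hr_affine, geoms[[i]],
                                transforms[[i]], truncate = truncate)
    if (!identical(as.integer(ops[[i]]$out_shape),
                   as.integer(dim(stacks[[i]]$data))))
      stop(sprintf("stack %d lattice (%s) inconsistent with operator output (%s)",
                   i, paste(dim(stacks[[i]]$data), collapse = "x"),
                   paste(ops[[i]]$out_shape, collapse = "x")))
  }
  ops
}

#' Data-consistency objective
#'
#' `sum_i || y_i - A_i x ||^2` with `A_i` the noise-free degradation operator
#' of stack `i`.
#'
#' @param x HR `srmri_volume`.
#' @param stacks list of LR `srmri_volume`s.
#' @param geoms list of `srmri_geometry`s.
#' @param transforms list of `srmri_rigid`s (or `NULL` for identity poses).
#' @return Nonnegative scalar.
#' @export
data_objective <- function(x, stacks, geoms, transforms = NULL) {
  stopifnot_volume(x)
  ops <- build_stack_ops(stacks, geoms, transforms, dim(x$data), x$affine)
  sum(vapply(seq_along(stacks), function(i)
    sum((stacks[[i]]$data - ops[[i]]$forward(x$data))^2), numeric(1)))
}

tv_value <- function(arr, eps) {
  n <- dim(arr)
  gx <- arr[c(2:n[1], n[1]), , ] - arr
  gy <- arr[, c(2:n[2], n[2]), ] - arr
  gz <- arr[, , c(2:n[3], n[3])] - arr
  sum(sqrt(gx^2 + gy^2 + gz^2 + eps^2))
}

tv_gradient <- function(arr, eps) {
  n <- dim(arr)
  gx <- arr[c(2:n[1], n[1]), , ] - arr
  gy <- arr[, c(2:n[2], n[2]), ] - arr
  gz <- arr[, , c(2:n[3], n[3])] - arr
  d <- sqrt(gx^2 + gy^2 + gz^2 + eps^2)
  px <- gx / d; py <- gy / d; pz <- gz / d
  shift_back <- function(p, axis) {
    z <- array(0, n)
    if (axis == 1) z[2:n[1], , ] <- p[1:(n[1] - 1), , ]
    if (axis == 2) z[, 2:n[2], ] <- p[, 1:(n[2] - 1), ]
    if (axis == 3) z[, , 2:n[3]] <- p[, , 1:(n[3] - 1)]
    z
  }
  (shift_back(px, 1) - px) + (shift_back(py, 2) - py) + (shift_back(pz, 3) - pz)
}

# largest eigenvalue of 2*sum_i A_i^T A_i by deterministic power iteration
normal_operator_lipschitz <- function(ops, hr_shape, iters = 12) {
  v <- array(1, hr_shape) + array(sin(seq_len(prod(hr_shape))), hr_shape)
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(iters)) {
    w <- Reduce(`+`, lapply(ops, function(op) op$adjoint(op$forward(v))))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1e-12)
    v <- w / lam
  }
  2 * lam
}

#' Total-variation-regularized super-resolution
#'
#' Minimizes `sum_i ||y_i - A_i x||^2 + lambda_tv * TV_eps(x)` by monotone
#' gradient descent with backtracking, initialized from the adjoint-based
#' average of the upsampled stacks. `TV_eps` is the smoothed isotropic total
#' variation `sum sqrt(|grad x|^2 + eps^2)`. The objective trace is
#' non-increasing by construction.
#'
#' @param stacks list of LR `srmri_volume`s (>= 1).
#' @param geoms list of `srmri_geometry`s.
#' @param transforms list of `srmri_rigid`s or `NULL` for identity poses.
#' @param cfg an `srmri_tvconfig`.
#' @param hr_shape,hr_affine optional HR lattice override; derived from the
#'   stack geometry when `NULL`.
#' @return List with `volume` (the HR `srmri_volume`), `trace` (data frame of
#'   per-iteration objective, data and TV terms), and `converged`.
#' @export
tv_reconstruct <- function(stacks, geoms, transforms = NULL,
                           cfg = tv_config(), hr_shape = NULL,
                           hr_affine = NULL) {
  if (length(stacks) < 1) stop("need at least one stack")
  lapply(stacks, stopifnot_volume)
  if (is.null(hr_shape)) {
    lat <- derive_hr_lattice(stacks, geoms)
    hr_shape <- lat$shape
    if (is.null(hr_affine)) hr_affine <- lat$affine
  } else if (is.null(hr_affine)) {
    hr_affine <- diag(c(rep(geoms[[1]]$inplane_spacing, 3), 1))
  }
  ops <- build_stack_ops(stacks, geoms, transforms, hr_shape, hr_affine)
  ys <- lapply(stacks, function(s) s$data)
  # lambda_tv is stated for unit-normalized intensities; the TV term scales
  # linearly and the data term quadratically with intensity, so rescale
  lambda_eff <- cfg$lambda_tv * max(abs(unlist(lapply(ys, range))))
  cfg$lambda_tv <- lambda_eff
  # adjoint back-projection average (A^T of the decimation scales by 1/f)
  x <- Reduce(`+`, lapply(seq_along(ops), function(i)
    geoms[[i]]$factor * ops[[i]]$adjoint(ys[[i]]))) / length(ops)
  objective <- function(arr) {
    dt <- sum(vapply(seq_along(ops), function(i)
      sum((ys[[i]] - ops[[i]]$forward(arr))^2), numeric(1)))
    tv <- if (cfg$lambda_tv > 0) tv_value(arr, cfg$tv_epsilon) else 0
    c(dt + cfg$lambda_tv * tv, dt, tv)
  }
  gradient <- function(arr) {
    g <- Reduce(`+`, lapply(seq_along(ops), function(i)
      2 * ops[[i]]$adjoint(ops[[i]]$forward(arr) - ys[[i]])))
    if (cfg$lambda_tv > 0)
      g <- g + cfg$lambda_tv * tv_gradient(arr, cfg$tv_epsilon)
    g
  }
  step0 <- if (is.null(cfg$step_size))
    1 / normal_operator_lipschitz(ops, hr_shape) else cfg$step_size
  step <- step0
  ob <- objective(x)
  trace <- matrix(NA_real_, cfg$max_iterations + 1L, 3L)
  trace[1L, ] <- ob
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_iterations)) {
    g <- gradient(x)
    accepted <- FALSE
    s <- step
    for (try in 1:25) {
      xt <- x - s * g
      obt <- objective(xt)
      if (obt[1] <= ob[1]) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) { converged <- TRUE; it <- it - 1L; break }
    rel <- (ob[1] - obt[1]) / max(ob[1], 1e-300)
    x <- xt; ob <- obt
    trace[it + 1L, ] <- ob
    step <- min(s * 1.2, 4 * step0)
    if (rel < cfg$tolerance) { converged <- TRUE; break }
  }
  trace <- trace[seq_len(it + 1L), , drop = FALSE]
  vol <- new_volume(x, rep(geoms[[1]]$inplane_spacing, 3), hr_affine)
  list(volume = vol,
       trace = data.frame(iteration = seq_len(nrow(trace)) - 1L,
                          objective = trace[, 1], data_term = trace[, 2],
                          tv_term = trace[, 3]),
       converged = converged)
}
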