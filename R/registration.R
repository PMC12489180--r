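#' Registration configuration
#'
#' @param histogram_bins joint-histogram bins for mutual information (>= 8).
#' @param max_iterations Powell iteration cap per resolution level.
#' @param parameter_tolerance convergence threshold on the relative objective
#'   change and on transform parameters.
#' @param multiresolution_levels coarse-to-fine downsampling factors.
#' @param max_voxels cap on the number of voxels sampled per MI evaluation
#'   (finest levels are strided deterministically beyond this).
#' @return An object of class `srmri_regconfig`.
#' @export
registration_config <- function(histogram_bins = 32L, max_iterations = 20L,
                                parameter_tolerance = 1e-6,
                                multiresolution_levels = c(4, 2, 1),
                                max_voxels = 150000L) {
  if (histogram_bins < 8) stop("histogram_bins must be >= 8")
  if (parameter_tolerance <= 0) stop("tolerances must be positive")
  structure(list(histogram_bins = as.integer(histogram_bins),
                 max_iterations = as.integer(max_iterations),
                 parameter_tolerance = parameter_tolerance,
                 multiresolution_levels = as.numeric(multiresolution_levels),
                 max_voxels = as.integer(max_voxels)),
            class = "srmri_regconfig")
}

mi_from_values <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2])
    stop("degenerate input: constant image has zero marginal entropy")
  ia <- pmin(bins, floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L)
  ib <- pmin(bins, floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L)
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins)
  p <- joint / length(a)
  pj <- matrix(p, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(pa, pb)[nz]))
}

#' Mutual information between two volumes
#'
#' MI in bits from a dense `bins x bins` joint intensity histogram of paired
#' voxels; the volumes must already live on a common lattice.
#'
#' @param a,b `srmri_volume`s with identical dimensions.
#' @param bins histogram bins per image.
#' @return Nonnegative MI in bits.
#' @export
mutual_information <- function(a, b, bins = 32L) {
  stopifnot_volume(a); stopifnot_volume(b)
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes must share a lattice; resample first")
  mi_from_values(as.numeric(a$data), as.numeric(b$data), as.integer(bins))
}

# Powell's direction-set minimizer (no derivatives, deterministic).
# Directions start as the scaled coordinate axes; each cycle line-minimizes
# along every direction (Brent via stats::optimize) and may replace the
# direction of largest decrease by the cycle's net displacement.
powell_minimize <- function(fn, p0, scales, max_iterations = 20,
                            tolerance = 1e-6, span = 2, line_tol = 0.01) {
  n <- length(p0)
  dirs <- diag(scales, n)
  p <- p0
  fval <- fn(p)
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    fbegin <- fval; pbegin <- p
    dmax <- 0; imax <- 1L
    for (i in seq_len(n)) {
      d <- dirs[, i]
      ls <- optimize(function(t) fn(p + t * d), c(-span, span),
                     tol = line_tol)
      if (ls$objective < fval) {
        dec <- fval - ls$objective
        if (dec > dmax) { dmax <- dec; imax <- i }
        fval <- ls$objective
        p <- p + ls$minimum * d
      }
    }
    if (2 * (fbegin - fval) <= tolerance * (abs(fbegin) + abs(fval)) + 1e-14) {
      converged <- TRUE
      break
    }
    pe <- p - pbegin
    if (sqrt(sum(pe^2)) > 1e-14) {
      fext <- fn(p + pe)
      if (fext < fbegin) {
        t1 <- 2 * (fbegin - 2 * fval + fext) * ((fbegin - fval) - dmax)^2
        t2 <- (fbegin - fext)^2 * dmax
        if (t1 < t2) {
          ls <- optimize(function(t) fn(p + t * pe), c(-span, span),
                         tol = line_tol)
          if (ls$objective < fval) {
            fval <- ls$objective
            p <- p + ls$minimum * pe
          }
          dirs[, imax] <- pe
        }
      }
    }
  }
  list(par = p, value = fval, converged = converged)
}

# deterministic strided voxel subset keeping at most max_voxels samples
stride_subset <- function(shape, max_voxels) {
  s <- max(1L, as.integer(ceiling((prod(shape) / max_voxels)^(1 / 3))))
  list(i = seq(1L, shape[1], by = s), j = seq(1L, shape[2], by = s),
       k = seq(1L, shape[3], by = s))
}

#' Rigid registration by mutual information and Powell search
#'
#' Estimates the 6-DOF transform maximizing the mutual information between
#' `fixed` and the transformed `moving` image, coarse-to-fine over the
#' configured multiresolution levels, with third-order B-spline interpolation
#' during resampling and Powell's derivative-free optimizer. Deterministic for
#' a fixed configuration.
#'
#' @param fixed,moving `srmri_volume`s with overlapping fields of view.
#' @param cfg an `srmri_regconfig`.
#' @param initial optional initial `srmri_rigid` guess.
#' @return An `srmri_rigid` `t` such that `apply_transform(moving, t)` aligns
#'   with `fixed` — i.e. the inverse of the pose that moved the object.
#'   Rotation centre is the fixed volume's world centre; attributes `mi`
#'   (bits, at the optimum) and `converged` are attached.
#' @export
register_rigid <- function(fixed, moving, cfg = registration_config(),
                           initial = NULL) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  centre <- as.numeric(fixed$affine[1:3, 1:3] %*% ((dim(fixed$data) - 1) / 2) +
                         fixed$affine[1:3, 4])
  par <- if (is.null(initial)) rep(0, 6) else
    c(initial$rotation, initial$translation)
  scales <- c(rep(0.05, 3), rep(2.5, 3))  # rad, mm per unit line-search step
  mov_inv <- solve(moving$affine[1:3, 1:3])
  mov_org <- moving$affine[1:3, 4]
  converged <- TRUE
  mi_opt <- NA_real_
  for (lev in cfg$multiresolution_levels) {
    if (lev > 1) {
      sp <- fixed$spacing * lev
      shp <- pmax(8L, as.integer(ceiling(dim(fixed$data) / lev)))
      fx <- resample_to_lattice(smooth_for_level(fixed, lev), sp, shp)
    } else fx <- fixed
    sub <- stride_subset(dim(fx$data), cfg$max_voxels)
    vox <- as.matrix(expand.grid(sub$i - 1, sub$j - 1, sub$k - 1))
    wf <- fx$affine[1:3, 1:3] %*% t(vox) + fx$affine[1:3, 4]
    fv <- as.numeric(fx$data[as.matrix(expand.grid(sub$i, sub$j, sub$k))])
    mv_arr <- moving$data
    coeff <- bspline3_coefficients(mv_arr)
    nmov <- dim(mv_arr)
    cost <- function(p) {
      R <- rot_matrix_xyz(p[1:3])
      srcw <- t(R) %*% (wf - centre - p[4:6]) + centre
      srcv <- mov_inv %*% (srcw - mov_org)
      inside <- srcv[1, ] >= 0 & srcv[1, ] <= nmov[1] - 1 &
                srcv[2, ] >= 0 & srcv[2, ] <= nmov[2] - 1 &
                srcv[3, ] >= 0 & srcv[3, ] <= nmov[3] - 1
      if (sum(inside) < 100) return(0)
      mvv <- sample_bspline3(mv_arr, srcv[, inside, drop = FALSE], coeff = coeff)
      -mi_from_values(fv[inside], mvv, cfg$histogram_bins)
    }
    res <- powell_minimize(cost, par, scales,
                           max_iterations = cfg$max_iterations,
                           tolerance = cfg$parameter_tolerance)
    par <- res$par
    converged <- res$converged
    mi_opt <- -res$value
    scales <- scales / 2
  }
  out <- rigid_transform(par[1:3], par[4:6], centre)
  attr(out, "mi") <- mi_opt
  attr(out, "converged") <- converged
  out
}

# light Gaussian smoothing before decimating to a coarser level
smooth_for_level <- function(vol, lev) {
  sig <- 0.5 * lev
  r <- max(1L, ceiling(2 * sig))
  taps <- dnorm(-r:r, sd = sig); taps <- taps / sum(taps)
  arr <- vol$data
  for (ax in 1:3) {
    if (length(taps) <= dim(arr)[ax])
      arr <- apply_axis_matrix(arr, blur_matrix(dim(arr)[ax], taps), ax)
  }
  new_volume(arr, vol$spacing, vol$affine)
}

#' Register a group of stacks into a common frame
#'
#' The reference stack (first by default) defines the frame and receives the
#' identity transform; every other stack is registered to it after both are
#' resampled to the coarsest common isotropic lattice.
#'
#' @param stacks list of `srmri_volume`s (>= 1).
#' @param geoms list of `srmri_geometry`s, parallel to `stacks`.
#' @param cfg an `srmri_regconfig`.
#' @param reference index of the reference stack.
#' @return List of `srmri_rigid` transforms, parallel to `stacks`.
#' @export
register_group <- function(stacks, geoms, cfg = registration_config(),
                           reference = 1L) {
  if (length(stacks) < 1) stop("need at least one stack")
  lapply(stacks, stopifnot_volume)
  common_sp <- max(vapply(stacks, function(s) max(s$spacing), numeric(1)))
  ref <- stacks[[reference]]
  shp <- pmax(8L, as.integer(round(dim(ref$data) * ref$spacing / common_sp)))
  ref_iso <- resample_to_lattice(ref, rep(common_sp, 3), shp, "bspline3")
  out <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    if (i == reference) {
      out[[i]] <- rigid_transform()
      attr(out[[i]], "converged") <- TRUE
      next
    }
    shp_i <- pmax(8L, as.integer(round(dim(stacks[[i]]$data) *
                                         stacks[[i]]$spacing / common_sp)))
    mov_iso <- resample_to_lattice(stacks[[i]], rep(common_sp, 3), shp_i,
                                   "bspline3")
    out[[i]] <- register_rigid(ref_iso, mov_iso, cfg)
  }
  out
}

#' Serialize a rigid transform to a plain-text file
#'
#' Writes the parameter six-vector (radians, mm), the rotation centre, and the
#' homogeneous 4x4 matrix.
#' @param t an `srmri_rigid`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  lines <- c(paste("params:", paste(format(c(t$rotation, t$translation),
                                           digits = 17), collapse = " ")),
             paste("center:", paste(format(t$center, digits = 17),
                                    collapse = " ")),
             "matrix:",
             apply(rt_matrix(t), 1, function(r)
               paste(format(r, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rigid transform written by [write_transform()]
#' @param path text file path.
#' @return An `srmri_rigid`.
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  p <- as.numeric(strsplit(sub("params: *", "", lines[1]), " +")[[1]])
  ctr <- as.numeric(strsplit(sub("center: *", "", lines[2]), " +")[[1]])
  rigid_transform(p[1:3], p[4:6], ctr)
}
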