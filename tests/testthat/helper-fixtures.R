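# Shared fixtures, all generated in code.

# smooth structured test volume (sum of Gaussian blobs), deterministic
structured_volume <- function(n = 16L, spacing = 1, seed = 101L) {
  centers <- matrix(c(0.35, 0.4, 0.5,
                      0.65, 0.6, 0.45,
                      0.5, 0.5, 0.7), 3, byrow = TRUE)
  amps <- c(1, 0.7, 0.5)
  widths <- c(0.12, 0.18, 0.1)
  u <- (seq_len(n) - 0.5) / n
  arr <- array(0, c(n, n, n))
  for (b in seq_along(amps)) {
    d2 <- outer(outer((u - centers[b, 1])^2, (u - centers[b, 2])^2, `+`),
                (u - centers[b, 3])^2, `+`)
    arr <- arr + amps[b] * exp(-d2 / (2 * widths[b]^2))
  }
  if (!is.null(seed))
    arr <- arr + with_seed_test(seed, array(rnorm(n^3, sd = 1e-3), c(n, n, n)))
  new_volume(arr, rep(spacing, 3))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small simulated study used by several test files
tiny_study <- function(n = 32L, thicknesses = 1, planes = c("axial", "coronal"),
                       sigma_fraction = 0, seed = 7L) {
  ph <- make_phantom(phantom_spec(shape = rep(n, 3), spacing = 0.5, seed = seed))
  simulate_study(ph$volume, ph$masks, thicknesses = thicknesses,
                 planes = planes, sigma_fraction = sigma_fraction, seed = seed)
}

study_stacks <- function(study) lapply(study$stacks, `[[`, "volume")
study_geoms <- function(study) lapply(study$stacks, `[[`, "geom")

# dense matrix of a linear operator, built by probing with basis vectors
operator_matrix <- function(fun, in_shape, out_len) {
  N <- prod(in_shape)
  M <- matrix(0, out_len, N)
  for (j in seq_len(N)) {
    e <- numeric(N); e[j] <- 1
    M[, j] <- as.numeric(fun(array(e, in_shape)))
  }
  M
}

# independently assembled dense degradation matrix for identity poses:
# explicit DFT matrices and an explicitly assembled blur matrix, combined by
# Kronecker products (fastest index first in R's column-major order)
dense_degrade_matrix <- function(shape, geom, truncate = 4) {
  n <- shape[geom$slice_axis]
  f <- geom$factor
  stopifnot(n %% f == 0)
  k <- make_slice_kernel(geom, truncate = truncate)
  taps <- k$taps
  h <- (length(taps) - 1L) / 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -h:h) {
      jj <- i + o
      while (jj < 1 || jj > n) {           # mirror reflection about edges
        if (jj < 1) jj <- 2 - jj
        if (jj > n) jj <- 2 * n - jj
      }
      B[i, jj] <- B[i, jj] + taps[o + h + 1]
    }
  }
  m <- n / f
  FN <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  GM <- exp(2i * pi * outer(0:(m - 1), 0:(m - 1)) / m)
  j <- 0:(m - 1)
  kfreq <- ifelse(j <= m / 2, j, j - m)
  P <- matrix(0, m, n)
  P[cbind(seq_len(m), (kfreq %% n) + 1)] <- 1
  D <- Re(GM %*% P %*% FN) / (m * f)
  DB <- D %*% B
  ax <- geom$slice_axis
  eye <- function(d) diag(1, d)
  if (ax == 1) kronecker(eye(shape[3]), kronecker(eye(shape[2]), DB))
  else if (ax == 2) kronecker(eye(shape[3]), kronecker(DB, eye(shape[1])))
  else kronecker(DB, kronecker(eye(shape[2]), eye(shape[1])))
}
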