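# Interpolated sampling of a 3-D array at continuous voxel coordinates.
#
# `coords` is a 3 x N matrix of 0-based voxel positions. Samples falling
# entirely outside the grid evaluate to 0 (out-of-field convention shared by
# apply_transform and resample_to_lattice). The cubic B-spline path applies
# the standard recursive prefilter so that the spline interpolates (rather
# than smooths) the samples.

sample_volume <- function(arr, coords, interpolation) {
  switch(interpolation,
         nearest   = sample_nearest(arr, coords),
         trilinear = sample_trilinear(arr, coords),
         bspline3  = sample_bspline3(arr, coords),
         stop("unknown interpolation: ", interpolation))
}

sample_nearest <- function(arr, coords) {
  n <- dim(arr)
  idx <- round(coords) + 1
  ok <- idx[1, ] >= 1 & idx[1, ] <= n[1] &
        idx[2, ] >= 1 & idx[2, ] <= n[2] &
        idx[3, ] >= 1 & idx[3, ] <= n[3]
  out <- numeric(ncol(coords))
  lin <- idx[1, ok] + (idx[2, ok] - 1) * n[1] + (idx[3, ok] - 1) * n[1] * n[2]
  out[ok] <- arr[lin]
  out
}

sample_trilinear <- function(arr, coords) {
  n <- dim(arr)
  i0 <- floor(coords)
  f <- coords - i0
  out <- numeric(ncol(coords))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- i0[1, ] + dx; iy <- i0[2, ] + dy; iz <- i0[3, ] + dz
    w <- (if (dx) f[1, ] else 1 - f[1, ]) *
         (if (dy) f[2, ] else 1 - f[2, ]) *
         (if (dz) f[3, ] else 1 - f[3, ])
    ok <- ix >= 0 & ix < n[1] & iy >= 0 & iy < n[2] & iz >= 0 & iz < n[3] & w > 0
    if (any(ok)) {
      lin <- ix[ok] + iy[ok] * n[1] + iz[ok] * n[1] * n[2] + 1
      out[ok] <- out[ok] + w[ok] * arr[lin]
    }
  }
  out
}

# weight/index triplet representation of the trilinear pull-back, used to
# assemble the sparse matrix whose transpose is the exact adjoint
trilinear_triplets <- function(shape, coords) {
  n <- shape
  i0 <- floor(coords)
  f <- coords - i0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- i0[1, ] + dx; iy <- i0[2, ] + dy; iz <- i0[3, ] + dz
    w <- (if (dx) f[1, ] else 1 - f[1, ]) *
         (if (dy) f[2, ] else 1 - f[2, ]) *
         (if (dz) f[3, ] else 1 - f[3, ])
    ok <- which(ix >= 0 & ix < n[1] & iy >= 0 & iy < n[2] &
                iz >= 0 & iz < n[3] & w > 0)
    if (length(ok)) {
      rows <- c(rows, ok)
      cols <- c(cols, ix[ok] + iy[ok] * n[1] + iz[ok] * n[1] * n[2] + 1L)
      vals <- c(vals, w[ok])
    }
  }
  list(i = rows, j = cols, x = vals)
}

# --- cubic B-spline interpolation ------------------------------------------

# recursive prefilter along the first array dimension (pole sqrt(3) - 2),
# mirror boundary; vectorized over the remaining dimensions
bspline3_prefilter_axis1 <- function(m) {
  z <- sqrt(3) - 2
  n <- nrow(m)
  if (n == 1L) return(m)
  gain <- (1 - z) * (1 - 1 / z)
  m <- m * gain
  # causal init: truncated mirror sum
  horiz <- min(n, ceiling(log(1e-12) / log(abs(z))))
  zp <- z^(seq_len(horiz) - 1)
  cp <- m
  cp[1, ] <- as.numeric(zp %*% m[seq_len(horiz), , drop = FALSE])
  for (i in 2:n) cp[i, ] <- m[i, ] + z * cp[i - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}

bspline3_coefficients <- function(arr) {
  n <- dim(arr)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = n[ax])
    m <- bspline3_prefilter_axis1(m)
    arr <- aperm(array(m, dim(arr)[perm]), order(perm))
  }
  arr
}

bspline3_weights <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  list(w0 = (1 - 3 * f + 3 * f2 - f3) / 6,
       w1 = (4 - 6 * f2 + 3 * f3) / 6,
       w2 = (1 + 3 * f + 3 * f2 - 3 * f3) / 6,
       w3 = f3 / 6)
}

mirror_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

sample_bspline3 <- function(arr, coords, coeff = NULL) {
  n <- dim(arr)
  if (is.null(coeff)) coeff <- bspline3_coefficients(arr)
  i0 <- floor(coords)
  f <- coords - i0
  inside <- coords[1, ] >= 0 & coords[1, ] <= n[1] - 1 &
            coords[2, ] >= 0 & coords[2, ] <= n[2] - 1 &
            coords[3, ] >= 0 & coords[3, ] <= n[3] - 1
  wx <- bspline3_weights(f[1, ]); wy <- bspline3_weights(f[2, ])
  wz <- bspline3_weights(f[3, ])
  wl <- function(w, d) switch(d + 2L, w$w0, w$w1, w$w2, w$w3)
  out <- numeric(ncol(coords))
  for (dz in -1:2) {
    iz <- mirror_index(i0[3, ] + dz, n[3])
    wzd <- wl(wz, dz)
    for (dy in -1:2) {
      iy <- mirror_index(i0[2, ] + dy, n[2])
      wyz <- wl(wy, dy) * wzd
      for (dx in -1:2) {
        ix <- mirror_index(i0[1, ] + dx, n[1])
        lin <- ix + iy * n[1] + iz * n[1] * n[2] + 1
        out <- out + wl(wx, dx) * wyz * coeff[lin]
      }
    }
  }
  out[!inside] <- 0
  out
}
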