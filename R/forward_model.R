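#' Rigid (6-DOF) transform
#'
#' Rotation is parameterized by three Euler angles about the fixed X, Y, Z
#' axes (applied in that order, `R = Rz Ry Rx`), followed by a translation;
#' rotation acts about `center` (world mm). The map is
#' `m(p) = R (p - center) + center + translation`.
#'
#' @param rotation length-3 Euler angles in radians (about fixed X, Y, Z).
#' @param translation length-3 translation in mm.
#' @param center length-3 world point the rotation pivots about.
#' @return An object of class `srmri_rigid`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3, length(center) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "srmri_rigid")
}

#' @export
print.srmri_rigid <- function(x, ...) {
  cat(sprintf("srmri rigid transform: rot (%s) deg, trans (%s) mm\n",
              paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

rot_matrix_xyz <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

euler_from_rot <- function(R) {
  c(atan2(R[3, 2], R[3, 3]),
    asin(max(-1, min(1, -R[3, 1]))),
    atan2(R[2, 1], R[1, 1]))
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param t an `srmri_rigid`.
#' @return 4x4 matrix acting on world-mm column vectors.
#' @export
rt_matrix <- function(t) {
  R <- rot_matrix_xyz(t$rotation)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t$center + t$translation - R %*% t$center
  m
}

#' Invert a rigid transform
#' @param t an `srmri_rigid`.
#' @return The inverse transform (same rotation center).
#' @export
rt_invert <- function(t) {
  R <- rot_matrix_xyz(t$rotation)
  rigid_transform(euler_from_rot(t(R)),
                  as.numeric(-t(R) %*% t$translation),
                  t$center)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `srmri_rigid` objects.
#' @return The composed transform, expressed about `b`'s center.
#' @export
rt_compose <- function(a, b) {
  m <- rt_matrix(a) %*% rt_matrix(b)
  R <- m[1:3, 1:3]
  c0 <- b$center
  rigid_transform(euler_from_rot(R),
                  as.numeric(m[1:3, 4] + R %*% c0 - c0),
                  c0)
}

rt_is_identity <- function(t, tol = 0) {
  all(abs(t$rotation) <= tol) && all(abs(t$translation) <= tol)
}

#' Gaussian slice-profile kernel
#'
#' The slice-excitation profile is modelled as a 1-D Gaussian whose FWHM
#' equals the slice thickness, so `sigma_mm = thickness / (2 sqrt(2 ln 2))`.
#' The kernel lives on the HR lattice (`sigma_voxels = sigma_mm /
#' inplane_spacing`), is truncated at `truncate` sigma (rounded up to an odd
#' length) and renormalized to unit sum, and acts along the slice-select axis
#' only.
#'
#' @param geom an `srmri_geometry`.
#' @param truncate truncation radius in units of sigma (default 4).
#' @return An object of class `srmri_kernel` with `taps`, `axis`,
#'   `sigma_voxels`.
#' @export
make_slice_kernel <- function(geom, truncate = 4) {
  sigma_mm <- geom$slice_thickness / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / geom$inplane_spacing
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  taps <- dnorm(-r:r, sd = sigma_vox)
  taps <- taps / sum(taps)
  structure(list(taps = taps, axis = geom$slice_axis, sigma_voxels = sigma_vox),
            class = "srmri_kernel")
}

# banded blur matrix along one axis with mirror boundary; its transpose is
# the exact adjoint used by the reconstruction solvers
blur_matrix <- function(n, taps) {
  L <- length(taps)
  h <- (L - 1L) %/% 2L
  B <- matrix(0, n, n)
  rows <- seq_len(n)
  for (o in -h:h) {
    cols <- mirror_index(rows - 1L + o, n) + 1L
    idx <- cbind(rows, cols)
    B[idx] <- B[idx] + taps[o + h + 1L]
  }
  B
}

apply_axis_matrix <- function(arr, M, axis) {
  n <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n[axis])
  y <- M %*% m
  newdim <- c(nrow(M), n[perm[2]], n[perm[3]])
  aperm(array(y, newdim), order(perm))
}

#' Apply a rigid transform to a volume
#'
#' Resamples the volume on its own lattice after moving it by `t` (pull-back
#' through the inverse map); out-of-field voxels are set to 0.
#'
#' @param vol an `srmri_volume`.
#' @param t an `srmri_rigid`.
#' @param interpolation `"trilinear"` (default) or `"bspline3"`.
#' @return The transformed volume on the same lattice.
#' @export
apply_transform <- function(vol, t, interpolation = c("trilinear", "bspline3")) {
  stopifnot_volume(vol)
  interpolation <- match.arg(interpolation)
  if (rt_is_identity(t)) return(vol)
  src <- transform_source_coords(dim(vol$data), vol$affine, t)
  out <- sample_volume(vol$data, src, interpolation)
  new_volume(array(out, dim(vol$data)), vol$spacing, vol$affine,
             intensity_range = vol$intensity_range)
}

# continuous source voxel coordinates (3 x N) of the pull-back resampling
transform_source_coords <- function(shape, affine, t) {
  vox <- voxel_grid(shape)
  world <- affine[1:3, 1:3] %*% vox + affine[1:3, 4]
  R <- rot_matrix_xyz(t$rotation)
  src_world <- t(R) %*% (world - t$center - t$translation) + t$center
  solve(affine[1:3, 1:3]) %*% (src_world - affine[1:3, 4])
}

#' Blur a volume along one axis
#'
#' 1-D convolution with the kernel taps along `k$axis`, mirror boundary
#' handling; the other axes are untouched. A constant volume maps to itself
#' (unit-sum kernel).
#'
#' @param vol an `srmri_volume`.
#' @param k an `srmri_kernel`.
#' @return The blurred volume.
#' @export
blur_along_axis <- function(vol, k) {
  stopifnot_volume(vol)
  n <- dim(vol$data)[k$axis]
  if (length(k$taps) > n)
    stop("kernel length ", length(k$taps), " exceeds axis extent ", n)
  B <- blur_matrix(n, k$taps)
  new_volume(apply_axis_matrix(vol$data, B, k$axis), vol$spacing, vol$affine,
             intensity_range = vol$intensity_range)
}

# retained-band row indices (1-based, in the length-np spectrum) for output
# length m; at the even-m Nyquist tie the positive-frequency bin is kept
band_rows <- function(np, m) {
  j <- 0:(m - 1)
  k <- ifelse(j <= m / 2, j, j - m)
  (k %% np) + 1
}

fft_decimate <- function(mat, f) {
  np <- nrow(mat)
  m <- np %/% f
  if (f == 1L) return(mat)
  Y <- mvfft(mat + 0i)
  Re(mvfft(Y[band_rows(np, m), , drop = FALSE], inverse = TRUE)) / (m * f)
}

fft_decimate_adjoint <- function(mat, f, np) {
  m <- nrow(mat)
  if (f == 1L) return(mat)
  Z <- mvfft(mat + 0i)
  Zp <- matrix(0i, np, ncol(mat))
  Zp[band_rows(np, m), ] <- Z
  Re(mvfft(Zp, inverse = TRUE)) / (m * f)
}

#' Frequency-domain downsampling along the slice axis
#'
#' Takes the 1-D FFT along the slice-select axis, retains the central
#' `1/factor` band of frequencies, and inverse-transforms onto a grid of
#' length `N/factor`, scaled so a constant maps to the same constant. Axis
#' extents not divisible by the factor are zero-padded symmetrically to the
#' next multiple first (the padding is recorded in the `pad` attribute).
#'
#' @param vol an `srmri_volume` (HR lattice).
#' @param geom an `srmri_geometry`; `geom$factor` is the decimation ratio.
#' @return The decimated volume; spacing along the slice axis is multiplied
#'   by the factor.
#' @export
downsample_freq <- function(vol, geom) {
  stopifnot_volume(vol)
  axis <- geom$slice_axis
  f <- geom$factor
  n <- dim(vol$data)[axis]
  if (f > n) stop("factor ", f, " exceeds axis extent ", n)
  if (f == 1L) return(vol)
  np <- as.integer(ceiling(n / f) * f)
  padl <- (np - n) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(vol$data, perm), nrow = n)
  if (np > n) m <- rbind(matrix(0, padl, ncol(m)), m,
                         matrix(0, np - n - padl, ncol(m)))
  y <- fft_decimate(m, f)
  newdim <- c(np %/% f, dim(vol$data)[perm[2]], dim(vol$data)[perm[3]])
  out <- aperm(array(y, newdim), order(perm))
  sp <- vol$spacing; sp[axis] <- sp[axis] * f
  aff <- vol$affine
  aff[1:3, axis] <- aff[1:3, axis] * f
  aff[1:3, 4] <- aff[1:3, 4] - (vol$affine[1:3, axis]) * padl
  v <- new_volume(out, sp, aff, intensity_range = vol$intensity_range)
  attr(v, "pad") <- c(left = padl, right = np - n - padl)
  v
}

#' Add i.i.d. Gaussian noise
#'
#' Noise standard deviation is `sigma_fraction` times the maximum voxel
#' intensity of the input, per stack. Reproducible under a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param vol an `srmri_volume`.
#' @param sigma_fraction nonnegative fraction of the per-volume maximum.
#' @param seed integer RNG seed.
#' @return The noisy volume.
#' @export
add_noise <- function(vol, sigma_fraction, seed = 0L) {
  stopifnot_volume(vol)
  if (sigma_fraction < 0) stop("sigma_fraction must be nonnegative")
  if (sigma_fraction == 0) return(vol)
  sigma <- sigma_fraction * max(vol$data)
  noise <- with_seed(seed, rnorm(length(vol$data), sd = sigma))
  new_volume(vol$data + array(noise, dim(vol$data)), vol$spacing, vol$affine,
             intensity_range = vol$intensity_range)
}

#' Simulate one thick-slice acquisition from an HR volume
#'
#' The full forward model: rigid transform, Gaussian slice-profile blur along
#' the slice axis, frequency-domain decimation, then additive Gaussian noise.
#' With `sigma_fraction = 0` the map is linear in `x`.
#'
#' @param x HR `srmri_volume` on the lattice implied by
#'   `geom$inplane_spacing`.
#' @param geom an `srmri_geometry`.
#' @param t optional `srmri_rigid` pose (default identity).
#' @param sigma_fraction noise level as a fraction of the stack maximum.
#' @param seed noise RNG seed.
#' @param truncate slice-kernel truncation radius in sigmas.
#' @return The simulated low-resolution stack.
#' @export
degrade <- function(x, geom, t = rigid_transform(), sigma_fraction = 0,
                    seed = 0L, truncate = 4) {
  stopifnot_volume(x)
  k <- make_slice_kernel(geom, truncate = truncate)
  y <- apply_transform(x, t)
  y <- blur_along_axis(y, k)
  y <- downsample_freq(y, geom)
  add_noise(y, sigma_fraction, seed)
}

#' Matrix-free degradation operator with exact adjoint
#'
#' Packages the noise-free forward model for one stack as a pair of closures
#' `forward(arr)` / `adjoint(arr)` operating on plain arrays. The adjoint is
#' exact: transpose of the sparse trilinear warp matrix, transpose of the
#' banded blur matrix, and the analytic adjoint of the FFT band decimation.
#' Used by the TV solver and the network training loss.
#'
#' @param hr_shape voxel triple of the HR lattice.
#' @param hr_affine 4x4 affine of the HR lattice.
#' @param geom an `srmri_geometry`.
#' @param t an `srmri_rigid` pose (identity poses skip the warp entirely).
#' @param truncate slice-kernel truncation radius in sigmas.
#' @return List with `forward`, `adjoint`, `out_shape`, `geom`.
#' @export
make_degrade_op <- function(hr_shape, hr_affine, geom, t = rigid_transform(),
                            truncate = 4) {
  hr_shape <- as.integer(hr_shape)
  axis <- geom$slice_axis
  f <- geom$factor
  k <- make_slice_kernel(geom, truncate = truncate)
  n <- hr_shape[axis]
  if (length(k$taps) > n)
    stop("kernel length exceeds axis extent ", n)
  B <- blur_matrix(n, k$taps)
  tB <- t(B)
  W <- NULL
  if (!rt_is_identity(t)) {
    src <- transform_source_coords(hr_shape, hr_affine, t)
    tr <- trilinear_triplets(hr_shape, src)
    N <- prod(hr_shape)
    W <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(N, N))
  }
  np <- as.integer(ceiling(n / f) * f)
  padl <- (np - n) %/% 2L
  out_shape <- hr_shape
  out_shape[axis] <- np %/% f
  perm <- c(axis, setdiff(1:3, axis))
  forward <- function(arr) {
    if (!is.null(W))
      arr <- array(as.numeric(W %*% as.numeric(arr)), hr_shape)
    arr <- apply_axis_matrix(arr, B, axis)
    if (f > 1L) {
      m <- matrix(aperm(arr, perm), nrow = n)
      if (np > n) m <- rbind(matrix(0, padl, ncol(m)), m,
                             matrix(0, np - n - padl, ncol(m)))
      y <- fft_decimate(m, f)
      arr <- aperm(array(y, c(np %/% f, hr_shape[perm[2]], hr_shape[perm[3]])),
                   order(perm))
    }
    arr
  }
  adjoint <- function(arr) {
    if (f > 1L) {
      m <- matrix(aperm(arr, perm), nrow = out_shape[axis])
      yp <- fft_decimate_adjoint(m, f, np)
      if (np > n) yp <- yp[(padl + 1):(padl + n), , drop = FALSE]
      arr <- aperm(array(yp, c(n, hr_shape[perm[2]], hr_shape[perm[3]])),
                   order(perm))
    }
    arr <- apply_axis_matrix(arr, tB, axis)
    if (!is.null(W))
      arr <- array(as.numeric(Matrix::crossprod(W, as.numeric(arr))), hr_shape)
    arr
  }
  list(forward = forward, adjoint = adjoint, out_shape = out_shape,
       geom = geom, transform = t)
}
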