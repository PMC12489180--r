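#' @importFrom stats rnorm dnorm pnorm fft mvfft optimize kmeans quantile sd setNames
#' @importFrom utils write.csv head tail
NULL

#' 3-D image volume
#'
#' The canonical in-memory image object shared by every operation in the
#' package: a 3-D intensity array together with per-axis voxel spacing (mm) and
#' a 4x4 voxel-to-world affine. Volumes are held in canonical RAS axis order;
#' world/voxel conversions happen only at the NIfTI I/O edges.
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing numeric length-3, voxel size in mm along each axis (all > 0).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). Defaults to
#'   a diagonal affine built from `spacing` with the origin at 0.
#' @param intensity_range optional length-2 `(min, max)` recorded by
#'   [normalize_unit()] so the scaling can be inverted exactly.
#' @return An object of class `srmri_volume`.
#' @export
new_volume <- function(data, spacing, affine = NULL, intensity_range = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got ", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- unclass(affine)[1:4, 1:4]
  cn <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(cn - spacing) > 1e-6 * pmax(1, spacing)))
    stop("affine column norms are inconsistent with spacing")
  structure(list(data = data, spacing = spacing, affine = affine,
                 intensity_range = intensity_range),
            class = "srmri_volume")
}

#' @export
print.srmri_volume <- function(x, ...) {
  cat(sprintf("srmri volume: %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.srmri_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "srmri_volume")

stopifnot_volume <- function(x) {
  if (!is_volume(x)) stop("expected an srmri_volume")
  invisible(x)
}

#' Acquisition geometry of a thick-slice stack
#'
#' Describes how one low-resolution stack was acquired: which axis is the
#' slice-select axis, the slice thickness, and the in-plane spacing. The
#' through-plane downsampling factor is derived as
#' `slice_thickness / inplane_spacing` and must be an integer: frequency-domain
#' decimation is defined for integer factors, and non-integer ratios are
#' rejected rather than rounded.
#'
#' @param slice_axis integer 1, 2 or 3: the slice-select axis in canonical
#'   (RAS) axis order. Axial stacks select along axis 3, coronal along 2,
#'   sagittal along 1.
#' @param slice_thickness slice thickness in mm.
#' @param inplane_spacing in-plane voxel size in mm (the HR lattice spacing).
#' @return An object of class `srmri_geometry` with fields `slice_axis`,
#'   `slice_thickness`, `inplane_spacing`, `factor`.
#' @export
acq_geometry <- function(slice_axis, slice_thickness, inplane_spacing) {
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  if (slice_thickness <= 0 || inplane_spacing <= 0)
    stop("thickness and spacing must be positive")
  ratio <- slice_thickness / inplane_spacing
  factor <- round(ratio)
  if (factor < 1 || abs(factor * inplane_spacing - slice_thickness) > 1e-9)
    stop(sprintf("slice_thickness/inplane_spacing = %.6g is not an integer; ",
                 ratio), "non-integer downsampling factors are not supported")
  structure(list(slice_axis = slice_axis,
                 slice_thickness = slice_thickness,
                 inplane_spacing = inplane_spacing,
                 factor = as.integer(factor)),
            class = "srmri_geometry")
}

#' @export
print.srmri_geometry <- function(x, ...) {
  cat(sprintf("srmri geometry: axis %d, thickness %g mm, in-plane %g mm, factor %d\n",
              x$slice_axis, x$slice_thickness, x$inplane_spacing, x$factor))
  invisible(x)
}

#' Read a NIfTI file as a canonical RAS volume
#'
#' Loads a single-image NIfTI-1/2 file, reorients the array to canonical RAS
#' axis order, and returns it with the header spacing and affine. The original
#' on-disk orientation string is recorded in the `orientation` attribute so a
#' round trip can restore it.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `srmri_volume`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3-D image; file has ", length(d),
         " dimensions (dim = ", paste(d, collapse = "x"), ")")
  orig <- RNifti::orientation(img)
  if (!identical(orig, "RAS")) {
    ok <- tryCatch({ RNifti::orientation(img) <- "RAS"; TRUE },
                   warning = function(w) FALSE)
    if (!ok) orig <- "RAS"  # no xform codes: take storage order as canonical
  }
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(sp <= 0) || any(!is.finite(sp))) sp <- rep(1, 3)
  v <- new_volume(array(as.numeric(img), dim(img)), spacing = sp, affine = aff)
  attr(v, "orientation") <- orig
  v
}

#' Write a volume to a NIfTI file
#'
#' Intensities are stored as float32 (denormalized if an intensity range is
#' recorded the data are written as they are held — normalization is the
#' caller's bookkeeping); header spacing and affine are taken from the volume.
#'
#' @param vol an `srmri_volume`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot_volume(vol)
  if (!dir.exists(dirname(path))) stop("no such directory: ", dirname(path))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  aff <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Map intensities affinely onto [0, 1]
#'
#' Records the original `(min, max)` in `intensity_range` so that
#' [denormalize_unit()] inverts the scaling exactly. Needed because the
#' reconstruction network ends in a sigmoid and therefore emits values in
#' (0, 1).
#'
#' @param vol an `srmri_volume` with non-constant, finite intensities.
#' @return The rescaled volume.
#' @export
normalize_unit <- function(vol) {
  stopifnot_volume(vol)
  r <- range(vol$data)
  if (any(!is.finite(r))) stop("volume has non-finite intensities")
  if (r[1] == r[2]) stop("degenerate input: constant volume cannot be unit-normalized")
  new_volume((vol$data - r[1]) / (r[2] - r[1]), vol$spacing, vol$affine,
             intensity_range = r)
}

#' Invert [normalize_unit()]
#' @param vol a volume carrying an `intensity_range`.
#' @return The volume on its original intensity scale.
#' @export
denormalize_unit <- function(vol) {
  stopifnot_volume(vol)
  r <- vol$intensity_range
  if (is.null(r)) stop("volume carries no recorded intensity range")
  new_volume(vol$data * (r[2] - r[1]) + r[1], vol$spacing, vol$affine)
}

#' Resample a volume onto a new lattice
#'
#' The target lattice is centred on the same world extent as the input (field
#' of view centres coincide); intensities are interpolated by the named scheme.
#'
#' @param vol an `srmri_volume`.
#' @param target_spacing mm triple for the output lattice.
#' @param target_shape voxel-count triple for the output lattice.
#' @param interpolation one of `"nearest"`, `"trilinear"`, `"bspline3"`.
#' @return The resampled `srmri_volume`.
#' @export
resample_to_lattice <- function(vol, target_spacing, target_shape,
                                interpolation = c("trilinear", "nearest", "bspline3")) {
  stopifnot_volume(vol)
  interpolation <- match.arg(interpolation)
  target_spacing <- as.numeric(target_spacing)
  target_shape <- as.integer(target_shape)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  if (any(target_shape < 1)) stop("target shape must be positive")
  n_in <- dim(vol$data)
  # centre-aligned axis-parallel lattice in the input's world frame
  aff_out <- vol$affine
  aff_out[1:3, 1:3] <- vol$affine[1:3, 1:3] %*%
    diag(target_spacing / vol$spacing, 3)
  centre_shift <- (vol$spacing * (n_in - 1) - target_spacing * (target_shape - 1)) / 2
  aff_out[1:3, 4] <- vol$affine[1:3, 4] +
    (vol$affine[1:3, 1:3] / rep(vol$spacing, each = 3)) %*% centre_shift
  vox <- voxel_grid(target_shape)                    # 3 x N, 0-based
  world <- aff_out[1:3, 1:3] %*% vox + aff_out[1:3, 4]
  src <- solve(vol$affine[1:3, 1:3]) %*% (world - vol$affine[1:3, 4])
  out <- sample_volume(vol$data, src, interpolation)
  new_volume(array(out, target_shape), target_spacing, aff_out,
             intensity_range = vol$intensity_range)
}

# 3 x prod(shape) matrix of 0-based voxel indices, column-major order
voxel_grid <- function(shape) {
  i <- seq_len(shape[1]) - 1
  j <- seq_len(shape[2]) - 1
  k <- seq_len(shape[3]) - 1
  rbind(rep(i, times = shape[2] * shape[3]),
        rep(rep(j, each = shape[1]), times = shape[3]),
        rep(k, each = shape[1] * shape[2]))
}

# evaluate code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
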