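#' Phantom specification
#'
#' Parameters of the procedural brain-like digital phantom: nested,
#' lobularly-perturbed ellipsoidal shells (background / peripheral CSF / GM
#' band / WM core / ventricular CSF) with exact tissue-mean intensities. The
#' default contrast is T2-like (CSF brightest, GM above WM), matching the
#' T2 TSE acquisitions the reconstruction pipeline targets.
#'
#' @param shape voxel triple (each >= 32).
#' @param spacing isotropic voxel size in mm.
#' @param means named intensities for `background`, `csf`, `gm`, `wm` (all
#'   distinct).
#' @param contrast `"T2"` or `"T1"` (checked against the ordering of
#'   `means`).
#' @param n_modes number of random cosine modes perturbing the shell radii.
#' @param mode_amp amplitude of each radial perturbation mode.
#' @param seed RNG seed for the perturbation modes.
#' @return An object of class `srmri_phantomspec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing = 0.5,
                         means = c(background = 0, csf = 200, gm = 120, wm = 80),
                         contrast = c("T2", "T1"), n_modes = 4L,
                         mode_amp = 0.04, seed = 0L) {
  contrast <- match.arg(contrast)
  shape <- as.integer(shape)
  if (any(shape < 32)) stop("phantom shape must be >= 32 voxels per axis")
  req <- c("background", "csf", "gm", "wm")
  if (!all(req %in% names(means))) stop("means must name ", paste(req, collapse = ", "))
  if (length(unique(means[req])) != 4) stop("tissue means must be distinct")
  structure(list(shape = shape, spacing = spacing, means = means[req],
                 contrast = contrast, n_modes = as.integer(n_modes),
                 mode_amp = mode_amp, seed = as.integer(seed)),
            class = "srmri_phantomspec")
}

#' Generate a brain-like digital phantom
#'
#' Builds the label geometry of `spec` (head boundary, peripheral CSF shell,
#' cortical GM band, WM core, central CSF ventricle, each radius modulated by
#' seeded low-frequency cosine modes for lobular variation), assigns each
#' tissue its exact specified mean intensity, and returns the volume together
#' with the matching membership masks. Identical seeds reproduce the phantom
#' bit-exactly.
#'
#' @param spec an `srmri_phantomspec`.
#' @return List with `volume` (an `srmri_volume`) and `masks` (an
#'   `srmri_masks`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  n <- spec$shape
  u1 <- (seq_len(n[1]) - (n[1] + 1) / 2) / (n[1] / 2)
  u2 <- (seq_len(n[2]) - (n[2] + 1) / 2) / (n[2] / 2)
  u3 <- (seq_len(n[3]) - (n[3] + 1) / 2) / (n[3] / 2)
  radii <- c(0.92, 0.88, 0.80)  # mild head anisotropy
  U1 <- array(u1 / radii[1], n)
  U2 <- array(rep(u2, each = n[1]) / radii[2], n)
  U3 <- array(rep(u3, each = n[1] * n[2]) / radii[3], n)
  R <- sqrt(U1^2 + U2^2 + U3^2)
  modes <- with_seed(spec$seed, {
    lapply(seq_len(2L), function(m) {
      list(k = matrix(sample(-2:2, 3L * spec$n_modes, replace = TRUE), 3L),
           phase = runif(spec$n_modes, 0, 2 * pi),
           amp = rep(spec$mode_amp, spec$n_modes))
    })
  })
  mod_field <- function(md) {
    f <- array(0, n)
    for (j in seq_len(ncol(md$k))) {
      f <- f + md$amp[j] * cos(2 * pi * (md$k[1, j] * U1 + md$k[2, j] * U2 +
                                           md$k[3, j] * U3) + md$phase[j])
    }
    f
  }
  m1 <- mod_field(modes[[1]])
  m2 <- mod_field(modes[[2]])
  lab <- array(0L, n)                      # 0 background
  lab[R < 0.95 * (1 + m1)] <- 1L           # peripheral CSF
  lab[R < 0.85 * (1 + m1)] <- 2L           # cortical GM band
  lab[R < 0.62 * (1 + m2)] <- 3L           # WM core
  lab[R < 0.18 * (1 + m2)] <- 1L           # ventricular CSF
  mk <- spec$means
  arr <- array(mk[["background"]], n)
  arr[lab == 1L] <- mk[["csf"]]
  arr[lab == 2L] <- mk[["gm"]]
  arr[lab == 3L] <- mk[["wm"]]
  vol <- new_volume(arr, rep(spec$spacing, 3))
  masks <- tissue_masks(gm = array(as.numeric(lab == 2L), n),
                        wm = array(as.numeric(lab == 3L), n),
                        csf = array(as.numeric(lab == 1L), n),
                        background = lab == 0L)
  attr(vol, "labels") <- lab
  list(volume = vol, masks = masks, spec = spec)
}

plane_axis <- function(plane) {
  switch(plane, axial = 3L, coronal = 2L, sagittal = 1L,
         stop("unknown plane: ", plane))
}

#' Simulate a multi-stack low-resolution study
#'
#' For every combination of slice thickness and imaging plane, degrades the
#' HR phantom through the forward acquisition model (optional rigid pose,
#' slice-profile blur, frequency-domain decimation, additive Gaussian noise
#' whose sigma is `sigma_fraction` of that stack's maximum). Per-stack noise
#' seeds are derived deterministically from the master seed, so an identical
#' master seed regenerates the study bit-exactly.
#'
#' @param phantom HR ground-truth `srmri_volume` (isotropic spacing).
#' @param masks optional `srmri_masks` carried along for evaluation.
#' @param thicknesses slice thicknesses in mm (integer multiples of the
#'   phantom spacing).
#' @param planes subset of `c("axial", "coronal", "sagittal")`.
#' @param sigma_fraction noise sigma as a fraction of each stack's maximum.
#' @param transforms optional list of `srmri_rigid` poses, one per stack (in
#'   stack order: plane varies fastest); default identity poses.
#' @param seed master seed.
#' @return An object of class `srmri_study`: `truth`, `masks`, `stacks`
#'   (each with `volume`, `geom`, `transform`, `seed`, `plane`,
#'   `thickness`), and a `manifest` list.
#' @export
simulate_study <- function(phantom, masks = NULL,
                           thicknesses = 2,
                           planes = c("axial", "coronal", "sagittal"),
                           sigma_fraction = 0.1, transforms = NULL,
                           seed = 0L) {
  stopifnot_volume(phantom)
  sp <- phantom$spacing[1]
  if (max(abs(phantom$spacing - sp)) > 1e-9)
    stop("phantom must have isotropic spacing")
  combos <- expand.grid(plane = planes, thickness = thicknesses,
                        stringsAsFactors = FALSE)
  n_stacks <- nrow(combos)
  if (!is.null(transforms) && length(transforms) != n_stacks)
    stop("need one transform per stack (", n_stacks, ")")
  stacks <- vector("list", n_stacks)
  for (i in seq_len(n_stacks)) {
    geom <- acq_geometry(plane_axis(combos$plane[i]), combos$thickness[i], sp)
    tr <- if (is.null(transforms)) rigid_transform() else transforms[[i]]
    stack_seed <- (as.integer(seed) + 1009L * i) %% 2147483647L
    vol <- degrade(phantom, geom, tr, sigma_fraction, stack_seed)
    stacks[[i]] <- list(volume = vol, geom = geom, transform = tr,
                        seed = stack_seed, plane = combos$plane[i],
                        thickness = combos$thickness[i],
                        sigma_fraction = sigma_fraction)
  }
  manifest <- list(
    seed = as.integer(seed), sigma_fraction = sigma_fraction,
    hr_spacing = sp, hr_shape = dim(phantom$data),
    stacks = lapply(stacks, function(s) list(
      plane = s$plane, thickness = s$thickness, slice_axis = s$geom$slice_axis,
      factor = s$geom$factor, seed = s$seed,
      rotation = s$transform$rotation, translation = s$transform$translation,
      center = s$transform$center)))
  structure(list(truth = phantom, masks = masks, stacks = stacks,
                 manifest = manifest),
            class = "srmri_study")
}

#' @export
print.srmri_study <- function(x, ...) {
  cat(sprintf("srmri simulated study: %d stacks from a %s phantom\n",
              length(x$stacks), paste(dim(x$truth$data), collapse = "x")))
  for (s in x$stacks)
    cat(sprintf("  %-8s thickness %g mm (factor %d), noise seed %d\n",
                s$plane, s$thickness, s$geom$factor, s$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits one NIfTI per stack, the ground truth and mask NIfTIs, and a YAML
#' manifest (geometries, poses, seeds) sufficient to regenerate the study.
#'
#' @param study an `srmri_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(study$truth, file.path(dir, "ground_truth.nii.gz"))
  if (!is.null(study$masks)) {
    for (nm in c("gm", "wm", "csf")) {
      write_nifti(new_volume(study$masks[[nm]], study$truth$spacing,
                             study$truth$affine),
                  file.path(dir, paste0("mask_", nm, ".nii.gz")))
    }
    write_nifti(new_volume(array(as.numeric(study$masks$background),
                                 dim(study$truth$data)),
                           study$truth$spacing, study$truth$affine),
                file.path(dir, "mask_background.nii.gz"))
  }
  for (i in seq_along(study$stacks)) {
    s <- study$stacks[[i]]
    write_nifti(s$volume, file.path(dir, sprintf("stack_%02d_%s_%gmm.nii.gz",
                                                 i, s$plane, s$thickness)))
  }
  yaml::write_yaml(study$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Canned acquisition recipes
#'
#' Two study recipes: (a) the simulation protocol — isotropic HR ground
#' truth, slice thicknesses 1/1.5/2/2.5/3 mm, three orthogonal planes, 10%
#' noise; (b) the clinical protocol — two stacks (axial + coronal), 0.5 mm
#' in-plane, 2 mm slices (factor 4). At `scale = "desk"` the grids are
#' shrunk to a 64^3 lattice (HR spacing kept at 0.5 mm) so the recipes run
#' in minutes on one CPU; at `scale = "full"` the HR grid matches a
#' whole-brain matrix at 0.5 mm and expects a user-supplied ground-truth
#' volume.
#'
#' @param scale `"desk"` or `"full"`.
#' @return List with `simulation` and `clinical` recipe lists.
#' @export
reference_protocols <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  shape <- if (scale == "desk") c(64L, 64L, 64L) else c(384L, 384L, 288L)
  list(
    simulation = list(hr_spacing = 0.5, hr_shape = shape,
                      thicknesses = c(1, 1.5, 2, 2.5, 3),
                      planes = c("axial", "coronal", "sagittal"),
                      sigma_fraction = 0.1),
    clinical = list(hr_spacing = 0.5, hr_shape = shape,
                    thicknesses = 2,
                    planes = c("axial", "coronal"),
                    sigma_fraction = 0.1,
                    factor = as.integer(2 / 0.5)))
}
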