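#' Evaluate a reconstruction with the full metric suite
#'
#' Computes SSIM, NMI and JSD against a reference (when given), normalized
#' sharpness against the reference, and SNR/CNR from tissue masks (segmented
#' with [segment_simple()] when no masks are supplied).
#'
#' @param recon reconstructed `srmri_volume`.
#' @param reference optional reference/ground-truth `srmri_volume`.
#' @param masks optional `srmri_masks` for SNR/CNR.
#' @param bins histogram bins for NMI/JSD.
#' @param contrast contrast ordering passed to [segment_simple()].
#' @return One-row data frame of metric values.
#' @export
evaluate_reconstruction <- function(recon, reference = NULL, masks = NULL,
                                    bins = 256L, contrast = "T2") {
  stopifnot_volume(recon)
  out <- list()
  if (!is.null(reference)) {
    out$ssim <- ssim_volume(recon, reference)
    out$nmi <- nmi_volume(recon, reference, bins)
    out$jsd <- jsd_volume(recon, reference, bins)
    out$sharpness <- normalized_sharpness(recon, reference)
  } else {
    out$aes <- aes_sharpness(recon)
  }
  if (is.null(masks)) {
    masks <- tryCatch(segment_simple(recon, contrast), error = function(e) NULL)
  }
  if (!is.null(masks)) {
    out$snr <- tryCatch(snr(recon, masks), error = function(e) NA_real_)
    out$cnr <- tryCatch(cnr(recon, masks), error = function(e) NA_real_)
  }
  as.data.frame(out)
}

default_pipeline_config <- function() {
  list(
    output_dir = "srmri_run",
    seed = 0L,
    simulate = list(enabled = TRUE, shape = c(64L, 64L, 64L), spacing = 0.5,
                    thicknesses = 2, planes = c("axial", "coronal"),
                    sigma_fraction = 0.1, contrast = "T2"),
    register = list(enabled = FALSE, histogram_bins = 32L,
                    multiresolution_levels = c(4, 2)),
    reconstruct_tv = list(enabled = TRUE, lambda_tv = 1e-2,
                          max_iterations = 200L),
    reconstruct = list(enabled = TRUE, preset = "reduced", patch_size = 8L,
                       iterations = 300L, learning_rate = NULL),
    evaluate = list(enabled = TRUE, bins = 256L))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  known <- names(default_pipeline_config())
  bad <- setdiff(names(cfg), c(known, "stacks"))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}

resolve_recon_config <- function(rc, seed) {
  preset <- if (is.null(rc$preset)) "reduced" else rc$preset
  cfg <- if (preset == "paper") recon_config(seed = seed) else
    recon_config_reduced(seed = seed)
  if (!is.null(rc$patch_size)) cfg$patch_size <- as.integer(rc$patch_size)
  if (!is.null(rc$iterations)) cfg$iterations <- as.integer(rc$iterations)
  if (!is.null(rc$learning_rate)) cfg$learning_rate <- rc$learning_rate
  cfg
}

#' Run the full reconstruction pipeline
#'
#' Executes the requested stages in order — simulate (or load stacks),
#' register (optional; simulated studies can use their known ground-truth
#' poses), TV reconstruction, transformer reconstruction, evaluation — and
#' writes each stage's outputs plus a YAML manifest (resolved configuration,
#' seeds, input digests, timings) into the output directory.
#'
#' @param config path to a YAML configuration file, or a configuration list;
#'   unknown keys raise a schema error. See `default_pipeline_config` in the
#'   package source for the recognized structure.
#' @return Invisibly, a list with the reconstructions, the metric report
#'   (data frame with one row per method), and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(merge_config(default_pipeline_config(), user))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  seed <- as.integer(cfg$seed)

  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (isTRUE(cfg$simulate$enabled)) {
    ph <- make_phantom(phantom_spec(shape = cfg$simulate$shape,
                                    spacing = cfg$simulate$spacing,
                                    contrast = cfg$simulate$contrast,
                                    seed = seed))
    study <- simulate_study(ph$volume, ph$masks,
                            thicknesses = cfg$simulate$thicknesses,
                            planes = cfg$simulate$planes,
                            sigma_fraction = cfg$simulate$sigma_fraction,
                            seed = seed)
    stacks <- lapply(study$stacks, `[[`, "volume")
    geoms <- lapply(study$stacks, `[[`, "geom")
    transforms <- lapply(study$stacks, `[[`, "transform")
    truth <- ph$volume
    masks <- ph$masks
    write_study(study, file.path(cfg$output_dir, "study"))
  } else {
    if (is.null(cfg$stacks)) stop("no simulation requested and no stacks given")
    stacks <- list(); geoms <- list(); transforms <- NULL
    for (s in cfg$stacks) {
      if (!file.exists(s$path)) stop("missing stack file: ", s$path)
      v <- read_nifti(s$path)
      g <- acq_geometry(s$slice_axis, s$slice_thickness, s$inplane_spacing)
      stacks <- c(stacks, list(v)); geoms <- c(geoms, list(g))
    }
    truth <- NULL; masks <- NULL
  }
  timings$simulate <- tic() - t0

  t0 <- tic()
  if (isTRUE(cfg$register$enabled)) {
    rcfg <- registration_config(
      histogram_bins = cfg$register$histogram_bins,
      multiresolution_levels = cfg$register$multiresolution_levels)
    transforms <- register_group(stacks, geoms, rcfg)
    for (i in seq_along(transforms))
      write_transform(transforms[[i]],
                      file.path(cfg$output_dir, sprintf("transform_%02d.txt", i)))
  }
  timings$register <- tic() - t0

  report <- NULL
  recon_tv <- NULL
  t0 <- tic()
  if (isTRUE(cfg$reconstruct_tv$enabled)) {
    tvres <- tv_reconstruct(stacks, geoms, transforms,
                            cfg = tv_config(
                              lambda_tv = cfg$reconstruct_tv$lambda_tv,
                              max_iterations = cfg$reconstruct_tv$max_iterations))
    recon_tv <- tvres$volume
    write_nifti(recon_tv, file.path(cfg$output_dir, "recon_tv.nii.gz"))
    write.csv(tvres$trace, file.path(cfg$output_dir, "tv_trace.csv"),
              row.names = FALSE)
  }
  timings$reconstruct_tv <- tic() - t0

  recon_net <- NULL
  t0 <- tic()
  if (isTRUE(cfg$reconstruct$enabled)) {
    ncfg <- resolve_recon_config(cfg$reconstruct, seed)
    dres <- dip_train(stacks, geoms, transforms, cfg = ncfg)
    recon_net <- dres$volume
    write_nifti(recon_net, file.path(cfg$output_dir, "recon_transformer.nii.gz"))
    write.csv(dres$trace, file.path(cfg$output_dir, "loss_trace.csv"),
              row.names = FALSE)
    yaml::write_yaml(unclass(ncfg), file.path(cfg$output_dir, "recon_config.yaml"))
  }
  timings$reconstruct <- tic() - t0

  t0 <- tic()
  if (isTRUE(cfg$evaluate$enabled)) {
    rows <- list()
    for (nm in c("tv", "transformer")) {
      vol <- if (nm == "tv") recon_tv else recon_net
      if (is.null(vol)) next
      r <- evaluate_reconstruction(vol, reference = truth, masks = masks,
                                   bins = cfg$evaluate$bins)
      r <- cbind(method = nm, r)
      rows[[nm]] <- r
    }
    if (length(rows)) {
      report <- do.call(rbind, rows)
      rownames(report) <- NULL
      write.csv(report, file.path(cfg$output_dir, "metrics.csv"),
                row.names = FALSE)
      jsonlite::write_json(report, file.path(cfg$output_dir, "metrics.json"),
                           dataframe = "rows", digits = NA)
    }
  }
  timings$evaluate <- tic() - t0

  manifest <- list(config = cfg, seed = seed, timings = timings,
                   package_version = as.character(utils::packageVersion("srmri")),
                   outputs = list.files(cfg$output_dir, recursive = TRUE))
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  invisible(list(recon_tv = recon_tv, recon_transformer = recon_net,
                 report = report, manifest = manifest,
                 stacks = stacks, geoms = geoms, truth = truth, masks = masks))
}

#' Patch-size sweep
#'
#' Reruns the transformer reconstruction over a list of tokenization patch
#' sizes on fixed inputs and seed and tabulates NMI, JSD, normalized
#' sharpness and SNR per size.
#'
#' @param config pipeline configuration (path or list), as in
#'   [run_pipeline()]; its `reconstruct$patch_size` entry is overridden.
#' @param sizes integer patch sizes (each a power of two dividing the padded
#'   HR grid).
#' @return Data frame with one row per patch size.
#' @export
sweep_patch_size <- function(config = list(), sizes = c(8L, 16L, 32L)) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  rows <- list()
  for (p in sizes) {
    cfgp <- merge_config(user, list(reconstruct = list(patch_size = as.integer(p)),
                                    output_dir = file.path(
                                      if (is.null(user$output_dir)) "srmri_run"
                                      else user$output_dir,
                                      paste0("patch_", p))))
    res <- run_pipeline(cfgp)
    r <- res$report[res$report$method == "transformer", , drop = FALSE]
    r$patch_size <- p
    rows[[as.character(p)]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("patch_size", setdiff(names(out), "patch_size"))]
}
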