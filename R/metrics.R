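#' Intensity histogram
#'
#' Normalized intensity histogram (mass sums to 1) over `bins` equal-width
#' bins spanning `limits`.
#'
#' @param vol an `srmri_volume` or numeric vector.
#' @param bins bin count.
#' @param limits length-2 intensity range; defaults to the data range.
#' @return An object of class `srmri_histogram` with `edges` and `mass`.
#' @export
intensity_histogram <- function(vol, bins = 256L, limits = NULL) {
  x <- if (is_volume(vol)) as.numeric(vol$data) else as.numeric(vol)
  if (length(x) == 0) stop("empty histogram input")
  if (is.null(limits)) limits <- range(x)
  if (limits[1] == limits[2]) limits <- limits + c(-0.5, 0.5)
  idx <- pmin(bins, pmax(1L, floor((x - limits[1]) /
                                     (limits[2] - limits[1]) * bins) + 1L))
  mass <- tabulate(idx, nbins = bins) / length(x)
  structure(list(edges = seq(limits[1], limits[2], length.out = bins + 1L),
                 mass = mass),
            class = "srmri_histogram")
}

# replicate-edge Gaussian filter matrix matching the SSIM window convention
# (sigma 1.5, radius round(3.5*sigma), nearest-edge padding)
gauss_filter_matrix <- function(n, sigma, radius) {
  taps <- exp(-0.5 * ((-radius):radius / sigma)^2)
  taps <- taps / sum(taps)
  B <- matrix(0, n, n)
  rows <- seq_len(n)
  for (o in -radius:radius) {
    cols <- pmin(pmax(rows + o, 1L), n)
    idx <- cbind(rows, cols)
    B[idx] <- B[idx] + taps[o + radius + 1L]
  }
  B
}

gauss_filter3 <- function(arr, sigma, radius) {
  for (ax in 1:3)
    arr <- apply_axis_matrix(arr, gauss_filter_matrix(dim(arr)[ax], sigma, radius), ax)
  arr
}

#' Structural similarity index between two volumes
#'
#' Mean local SSIM with a Gaussian window (sigma 1.5, radius
#' `round(3.5*sigma)`), constants `K1 = 0.01`, `K2 = 0.03`, and the dynamic
#' range taken from the reference. If the lattices differ the evaluated image
#' is resampled onto the reference lattice first. The mean is taken over the
#' window-interior region (edge crop of one window radius).
#'
#' @param x evaluated `srmri_volume`.
#' @param ref reference `srmri_volume`.
#' @param sigma Gaussian window sigma in voxels.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim_volume <- function(x, ref, sigma = 1.5) {
  stopifnot_volume(x); stopifnot_volume(ref)
  if (!identical(dim(x$data), dim(ref$data)))
    x <- resample_to_lattice(x, ref$spacing, dim(ref$data))
  a <- x$data; b <- ref$data
  radius <- as.integer(round(3.5 * sigma))
  L <- diff(range(b))
  if (L <= 0) stop("reference has zero dynamic range")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  ux <- gauss_filter3(a, sigma, radius)
  uy <- gauss_filter3(b, sigma, radius)
  vx <- gauss_filter3(a * a, sigma, radius) - ux^2
  vy <- gauss_filter3(b * b, sigma, radius) - uy^2
  cxy <- gauss_filter3(a * b, sigma, radius) - ux * uy
  S <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  n <- dim(S)
  if (all(n > 2 * radius)) {
    S <- S[(radius + 1):(n[1] - radius), (radius + 1):(n[2] - radius),
           (radius + 1):(n[3] - radius)]
  }
  mean(S)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized mutual information
#'
#' `(H(x) + H(ref)) / H(x, ref)` from a `bins x bins` joint histogram of
#' paired voxels, each image binned over its own range: 2 for identical
#' images, near 1 for independent ones. Unequal lattices are paired by
#' resampling the evaluated image onto the reference lattice.
#'
#' @param x,ref `srmri_volume`s (non-constant).
#' @param bins histogram bins per image.
#' @return NMI `>= 1`.
#' @export
nmi_volume <- function(x, ref, bins = 256L) {
  stopifnot_volume(x); stopifnot_volume(ref)
  if (!identical(dim(x$data), dim(ref$data)))
    x <- resample_to_lattice(x, ref$spacing, dim(ref$data))
  a <- as.numeric(x$data); b <- as.numeric(ref$data)
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) stop("constant image in NMI")
  ia <- pmin(bins, floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L)
  ib <- pmin(bins, floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L)
  pj <- matrix(tabulate(ia + (ib - 1L) * bins, nbins = bins * bins) /
                 length(a), bins, bins)
  (entropy_bits(rowSums(pj)) + entropy_bits(colSums(pj))) / entropy_bits(pj)
}

#' Jensen-Shannon divergence between two histograms
#'
#' Standard bounded form in bits: `JSD(p,q) = KL(p||m)/2 + KL(q||m)/2` with
#' `m = (p+q)/2` and `0 log 0 = 0`; symmetric, 0 iff `p == q`, 1 for
#' disjoint supports.
#'
#' @param p,q `srmri_histogram`s or nonnegative mass vectors of equal length
#'   (normalized to sum 1 internally).
#' @return JSD in `[0, 1]`.
#' @export
jsd_hist <- function(p, q) {
  pm <- if (inherits(p, "srmri_histogram")) p$mass else as.numeric(p)
  qm <- if (inherits(q, "srmri_histogram")) q$mass else as.numeric(q)
  if (length(pm) != length(qm)) stop("histograms must have equal length")
  if (sum(pm) <= 0 || sum(qm) <= 0) stop("empty histogram")
  pm <- pm / sum(pm); qm <- qm / sum(qm)
  m <- (pm + qm) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(pm, m) + kl(qm, m)) / 2
}

#' Jensen-Shannon divergence between two volumes
#'
#' Marginal intensity histograms over the shared min-max range; requires no
#' lattice agreement (distribution-level comparison only).
#'
#' @param x,ref `srmri_volume`s.
#' @param bins histogram bins.
#' @return JSD in `[0, 1]` (bits).
#' @export
jsd_volume <- function(x, ref, bins = 256L) {
  stopifnot_volume(x); stopifnot_volume(ref)
  lim <- range(c(range(x$data), range(ref$data)))
  jsd_hist(intensity_histogram(x, bins, lim), intensity_histogram(ref, bins, lim))
}

# --- average edge strength ---------------------------------------------------

otsu_threshold <- function(x, bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(bins, floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L),
                nbins = bins)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  mt <- mu[bins]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  r[1] + k / bins * (r[2] - r[1])
}

shift2 <- function(m, di, dj) {
  n <- dim(m)
  i <- pmin(pmax(seq_len(n[1]) + di, 1L), n[1])
  j <- pmin(pmax(seq_len(n[2]) + dj, 1L), n[2])
  m[i, j, drop = FALSE]
}

conv3x3 <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1)
    if (k[di + 2, dj + 2] != 0)
      out <- out + k[di + 2, dj + 2] * shift2(m, di, dj)
  out
}

sobel_gradients <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  list(gx = conv3x3(m, kx), gy = conv3x3(m, t(kx)))
}

prewitt_gradients <- function(m) {
  kx <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, byrow = TRUE)
  list(gx = conv3x3(m, kx), gy = conv3x3(m, t(kx)))
}

#' Canny edge mask of a 2-D slice
#'
#' Gaussian smoothing, Sobel gradients, four-direction non-maximum
#' suppression, and hysteresis thresholding. The high threshold defaults to
#' Otsu's threshold of the nonzero gradient magnitudes and the low threshold
#' to `low_frac` times the high one.
#'
#' @param m numeric matrix (one slice).
#' @param sigma smoothing sigma in pixels.
#' @param low_frac low/high hysteresis threshold ratio.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(m, sigma = 1.4, low_frac = 0.4) {
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  Bx <- gauss_filter_matrix(nrow(m), sigma, radius)
  By <- gauss_filter_matrix(ncol(m), sigma, radius)
  sm <- Bx %*% m %*% t(By)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  # quantize gradient direction to 0/45/90/135 degrees and suppress non-maxima
  # (gx differentiates along columns, gy along rows: sector 0 compares column
  # neighbours, sector 2 row neighbours)
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(m), ncol(m))
  for (s in 0:3) {
    o <- offs[[s + 1]]
    nb1 <- shift2(mag, o[1], o[2])
    nb2 <- shift2(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag >= nb1 & mag >= nb2)
  }
  mag_nms <- ifelse(keep, mag, 0)
  pos <- mag_nms[mag_nms > 0]
  if (length(pos) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  high <- otsu_threshold(pos)
  low <- low_frac * high
  strong <- mag_nms >= high
  cand <- mag_nms >= low
  # hysteresis: grow strong edges through connected weak candidates
  repeat {
    grown <- strong
    for (di in -1:1) for (dj in -1:1)
      if (di != 0 || dj != 0) grown <- grown | shift2(strong, di, dj)
    grown <- grown & cand
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

#' Average edge strength (sharpness)
#'
#' Slice-wise 2-D sharpness: on each slice along `axis`, a Canny edge mask
#' selects edge pixels and the Prewitt gradient is evaluated there; the
#' per-slice score is the mean (over edge pixels) of the squared gradient
#' norm (`power = "squared"`, as specified) or of the gradient magnitude
#' (`power = "magnitude"`). Slice scores are averaged over all slices that
#' contain edges. Relative comparisons between images are unaffected by the
#' choice, which is a monotone transform.
#'
#' @param vol an `srmri_volume` (non-constant).
#' @param axis slice axis (default 3, axial planes).
#' @param power `"squared"` or `"magnitude"`.
#' @param canny_sigma,canny_low_frac Canny detector settings.
#' @return Nonnegative sharpness score.
#' @export
aes_sharpness <- function(vol, axis = 3L, power = c("squared", "magnitude"),
                          canny_sigma = 1.4, canny_low_frac = 0.4) {
  stopifnot_volume(vol)
  power <- match.arg(power)
  n <- dim(vol$data)
  scores <- numeric(0)
  perm <- c(setdiff(1:3, axis), axis)
  arr <- aperm(vol$data, perm)
  for (k in seq_len(n[axis])) {
    sl <- arr[, , k]
    if (max(sl) == min(sl)) next
    E <- canny_edges(sl, canny_sigma, canny_low_frac)
    if (!any(E)) next
    g <- prewitt_gradients(sl)
    g2 <- g$gx[E]^2 + g$gy[E]^2
    scores <- c(scores, mean(if (power == "squared") g2 else sqrt(g2)))
  }
  if (length(scores) == 0)
    stop("no edges detected in any slice; sharpness undefined")
  mean(scores)
}

#' Normalized sharpness of a reconstruction against a reference
#'
#' `aes_sharpness(recon) / aes_sharpness(ref)`; values above 1 mean the
#' reconstruction is sharper than the reference.
#'
#' @param recon,ref `srmri_volume`s.
#' @param ... passed to [aes_sharpness()].
#' @return Dimensionless sharpness ratio.
#' @export
normalized_sharpness <- function(recon, ref, ...) {
  aes_sharpness(recon, ...) / aes_sharpness(ref, ...)
}

# --- SNR / CNR ---------------------------------------------------------------

#' Tissue membership masks
#'
#' @param gm,wm,csf per-voxel membership probability arrays in `[0, 1]`.
#' @param background logical array of background voxels, disjoint from the
#'   tissue support.
#' @return An object of class `srmri_masks`.
#' @export
tissue_masks <- function(gm, wm, csf, background) {
  for (m in list(gm, wm, csf))
    if (min(m) < 0 || max(m) > 1) stop("membership probabilities must be in [0,1]")
  if (any(background & (gm + wm + csf > 0)))
    stop("background overlaps tissue support")
  structure(list(gm = gm, wm = wm, csf = csf, background = background),
            class = "srmri_masks")
}

#' Tissue signal and noise statistics
#'
#' `s` is the gray+white mean signal weighted by voxel counts (membership
#' mass), `s_gm`/`s_wm` the per-tissue means, and `sigma_noise` the standard
#' deviation of the background voxel intensities.
#'
#' @param vol an `srmri_volume`.
#' @param masks an `srmri_masks`.
#' @return List with `s`, `s_gm`, `s_wm`, `sigma_noise`, `n_gm`, `n_wm`,
#'   `n_background`.
#' @export
tissue_stats <- function(vol, masks) {
  stopifnot_volume(vol)
  x <- vol$data
  n_gm <- sum(masks$gm); n_wm <- sum(masks$wm)
  if (n_gm == 0 || n_wm == 0) stop("empty gray/white masks")
  s_gm <- sum(masks$gm * x) / n_gm
  s_wm <- sum(masks$wm * x) / n_wm
  s <- (s_gm * n_gm + s_wm * n_wm) / (n_gm + n_wm)
  bgv <- x[masks$background]
  if (length(bgv) < 2) stop("background region is empty")
  list(s = s, s_gm = s_gm, s_wm = s_wm, sigma_noise = sd(bgv),
       n_gm = n_gm, n_wm = n_wm, n_background = length(bgv))
}

#' Signal-to-noise ratio
#'
#' Mean gray+white signal (weighted by voxel counts) over the standard
#' deviation of background intensities.
#'
#' @param vol an `srmri_volume`.
#' @param masks an `srmri_masks`.
#' @return SNR (dimensionless).
#' @export
snr <- function(vol, masks) {
  st <- tissue_stats(vol, masks)
  if (st$sigma_noise == 0) stop("degenerate noise: background sd is zero")
  st$s / st$sigma_noise
}

#' Contrast-to-noise ratio between gray and white matter
#'
#' `|s_GM - s_WM| / sigma` with `sigma` the background noise standard
#' deviation.
#'
#' @param vol an `srmri_volume`.
#' @param masks an `srmri_masks`.
#' @return CNR (dimensionless).
#' @export
cnr <- function(vol, masks) {
  st <- tissue_stats(vol, masks)
  if (st$sigma_noise == 0) stop("degenerate noise: background sd is zero")
  abs(st$s_gm - st$s_wm) / st$sigma_noise
}

# grow the connected component containing `seed_idx` inside `mask` by
# repeated 6-neighbour dilation (vectorized flood fill)
largest_component_from <- function(mask, seed_idx) {
  comp <- array(FALSE, dim(mask))
  comp[seed_idx] <- TRUE
  n <- dim(mask)
  repeat {
    grown <- comp
    grown[c(2:n[1], n[1]), , ] <- grown[c(2:n[1], n[1]), , ] | comp
    grown[c(1, 1:(n[1] - 1)), , ] <- grown[c(1, 1:(n[1] - 1)), , ] | comp
    grown[, c(2:n[2], n[2]), ] <- grown[, c(2:n[2], n[2]), ] | comp
    grown[, c(1, 1:(n[2] - 1)), ] <- grown[, c(1, 1:(n[2] - 1)), ] | comp
    grown[, , c(2:n[3], n[3])] <- grown[, , c(2:n[3], n[3])] | comp
    grown[, , c(1, 1:(n[3] - 1))] <- grown[, , c(1, 1:(n[3] - 1))] | comp
    grown <- grown & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

#' Stand-in tissue segmentation
#'
#' A deliberately simple three-class segmenter whose only purpose is to feed
#' the SNR/CNR computations: Otsu thresholding plus a largest-component head
#' mask, then 3-class k-means on the in-mask intensities (deterministic
#' quantile-initialized centers), with classes mapped to CSF/GM/WM by mean
#' rank under the stated contrast (T2-like: CSF > GM > WM; T1-like:
#' WM > GM > CSF).
#'
#' @param vol an `srmri_volume` with background near zero.
#' @param contrast `"T2"` or `"T1"` intensity ordering.
#' @return An `srmri_masks`.
#' @export
segment_simple <- function(vol, contrast = c("T2", "T1")) {
  stopifnot_volume(vol)
  contrast <- match.arg(contrast)
  x <- vol$data
  if (max(x) == min(x)) stop("constant image cannot be segmented")
  thr <- otsu_threshold(as.numeric(x))
  fg <- x > thr
  if (!any(fg)) stop("no foreground above the Otsu threshold")
  head_mask <- largest_component_from(fg, which.max(x * fg))
  vals <- x[head_mask]
  ctrs <- quantile(vals, c(0.2, 0.5, 0.8), names = FALSE)
  if (length(unique(ctrs)) < 3)
    stop("fewer than 3 separable intensity classes in the head mask")
  km <- kmeans(vals, centers = matrix(ctrs, 3, 1), iter.max = 100L)
  ord <- order(km$centers)  # ascending mean intensity
  lab <- match(km$cluster, ord)  # 1 = darkest, 3 = brightest
  head_idx <- which(head_mask)
  assign_mask <- function(rank) {
    m <- array(0, dim(x))
    m[head_idx[lab == rank]] <- 1
    m
  }
  if (contrast == "T2") {
    masks <- tissue_masks(gm = assign_mask(2), wm = assign_mask(1),
                          csf = assign_mask(3), background = !head_mask & !fg)
  } else {
    masks <- tissue_masks(gm = assign_mask(2), wm = assign_mask(3),
                          csf = assign_mask(1), background = !head_mask & !fg)
  }
  masks
}
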