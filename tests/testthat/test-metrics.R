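test_that("SSIM identities and cross-implementation oracle values", {
  v <- structured_volume(16)
  expect_equal(ssim_volume(v, v), 1, tolerance = 1e-12)
  # frozen oracle: scikit-image 0.26 structural_similarity with
  # gaussian_weights, sigma = 1.5, use_sample_covariance = FALSE, on this
  # exact deterministically generated pair
  set.seed(424242)
  a <- array(runif(24^3), c(24, 24, 24))
  b <- 0.6 * a + 0.4 * array(runif(24^3), c(24, 24, 24))
  va <- new_volume(a, rep(1, 3)); vb <- new_volume(b, rep(1, 3))
  expect_equal(ssim_volume(va, vb), 0.7931063386, tolerance = 1e-6)
  bin <- array(as.numeric(a > 0.5), c(24, 24, 24))
  expect_equal(ssim_volume(new_volume(bin, rep(1, 3)),
                           new_volume(1 - bin, rep(1, 3))),
               -0.9820470224, tolerance = 1e-6)
  expect_lt(ssim_volume(new_volume(bin, rep(1, 3)),
                        new_volume(1 - bin, rep(1, 3))), 0)
})

test_that("NMI is 2 for identical images and near 1 for independent noise", {
  v <- structured_volume(16)
  expect_equal(nmi_volume(v, v, 64), 2, tolerance = 1e-9)
  n1 <- new_volume(with_seed_test(1, array(runif(64^3), c(64, 64, 64))), rep(1, 3))
  n2 <- new_volume(with_seed_test(2, array(runif(64^3), c(64, 64, 64))), rep(1, 3))
  expect_lt(nmi_volume(n1, n2, 32), 1.02)
  expect_gte(nmi_volume(n1, n2, 32), 1)
  expect_error(nmi_volume(new_volume(array(1, c(16, 16, 16)), rep(1, 3)), v),
               "constant")
})

test_that("NMI is invariant to relabeling the intensity bins of one image", {
  set.seed(9)
  lab <- array(sample(0:7, 16^3, replace = TRUE), c(16, 16, 16))
  ref <- structured_volume(16)
  perm <- c(5, 2, 7, 0, 6, 1, 4, 3)
  relab <- array(perm[lab + 1], c(16, 16, 16))
  v1 <- new_volume(lab, rep(1, 3)); v2 <- new_volume(relab, rep(1, 3))
  expect_equal(nmi_volume(v1, ref, 8), nmi_volume(v2, ref, 8), tolerance = 1e-9)
})

test_that("mutual information identities hold", {
  v <- structured_volume(16)
  entropy_of <- function(x, bins) {
    p <- tabulate(pmin(bins, floor((x - min(x)) / diff(range(x)) * bins) + 1L),
                  nbins = bins)
    p <- p / sum(p); p <- p[p > 0]; -sum(p * log2(p))
  }
  mi_self <- mutual_information(v, v, 32)
  expect_equal(mi_self, entropy_of(as.numeric(v$data), 32), tolerance = 1e-9)
  expect_gt(mi_self, 0)
  # invariance under a monotone affine rescale of one argument
  w <- new_volume(3.5 * v$data - 2, v$spacing)
  expect_equal(mutual_information(v, w, 32), mi_self, tolerance = 1e-9)
  n1 <- new_volume(with_seed_test(3, array(runif(64^3), c(64, 64, 64))), rep(1, 3))
  n2 <- new_volume(with_seed_test(4, array(runif(64^3), c(64, 64, 64))), rep(1, 3))
  expect_lt(mutual_information(n1, n2, 32), 0.05)
})

test_that("JSD identities, hand value, symmetry and bounds", {
  expect_equal(jsd_hist(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(jsd_hist(c(1, 0), c(0, 1)), 1)
  expect_equal(jsd_hist(c(1, 0), c(0.5, 0.5)), 0.3113, tolerance = 1e-4)
  set.seed(20)
  for (i in 1:10) {
    p <- runif(16); q <- runif(16)
    j1 <- jsd_hist(p, q); j2 <- jsd_hist(q, p)
    expect_equal(j1, j2, tolerance = 1e-12)
    expect_gte(j1, 0); expect_lte(j1, 1)
  }
  v <- structured_volume(16)
  expect_equal(jsd_volume(v, v), 0)
  expect_error(jsd_hist(c(0, 0), c(1, 0)), "empty")
})

test_that("AES matches the closed-form Prewitt response on an ideal step", {
  h <- 3.7
  img <- array(0, c(32, 32, 4))
  img[, 17:32, ] <- h     # vertical step of height h in each slice
  v <- new_volume(img, rep(1, 3))
  # Prewitt response at the step columns is 3h; squared-norm form gives 9h^2
  expect_equal(aes_sharpness(v), 9 * h^2, tolerance = 1e-9)
  # intensity scaling by c scales the squared-gradient AES by c^2
  v2 <- new_volume(2 * img, rep(1, 3))
  expect_equal(aes_sharpness(v2), 4 * aes_sharpness(v), tolerance = 1e-9)
  expect_equal(aes_sharpness(v2, power = "magnitude"),
               2 * aes_sharpness(v, power = "magnitude"), tolerance = 1e-9)
  expect_error(aes_sharpness(new_volume(array(1, c(8, 8, 8)), rep(1, 3))),
               "no edges")
})

test_that("AES decreases monotonically under increasing Gaussian blur", {
  v <- structured_volume(32, seed = NULL)
  v <- new_volume(v$data + make_phantom(phantom_spec(seed = 3))$volume$data[1:32, 1:32, 1:32] / 100,
                  rep(1, 3))
  sigmas <- c(0.5, 1, 1.5, 2)
  vals <- vapply(sigmas, function(s) {
    arr <- srmri:::gauss_filter3(v$data, s, ceiling(3 * s))
    aes_sharpness(new_volume(arr, v$spacing))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("normalized sharpness is 1 for identical pairs and <1 under blur", {
  v <- make_phantom(phantom_spec(seed = 2))$volume
  v <- add_noise(v, 0.02, seed = 5)
  expect_equal(normalized_sharpness(v, v), 1, tolerance = 1e-12)
  blurred <- new_volume(srmri:::gauss_filter3(v$data, 1.5, 5), v$spacing)
  expect_lt(normalized_sharpness(blurred, v), 1)
  expect_gt(normalized_sharpness(v, blurred), 1)
})

test_that("SNR and CNR arithmetic on constructed masks", {
  n <- c(10, 10, 10)
  gm <- array(0, n); wm <- array(0, n); csf <- array(0, n)
  gm[1:3, , ] <- 1       # 300 voxels
  wm[4, , ] <- 1         # 100 voxels
  bg <- array(FALSE, n); bg[6:10, , ] <- TRUE
  x <- array(0, n)
  x[gm == 1] <- 120; x[wm == 1] <- 80
  set.seed(77)
  x[bg] <- rnorm(sum(bg), mean = 0, sd = 5)
  # force the sample sd of the background to exactly 5
  x[bg] <- (x[bg] - mean(x[bg])) / sd(x[bg]) * 5
  masks <- tissue_masks(gm, wm, csf, bg)
  st <- tissue_stats(new_volume(x, rep(1, 3)), masks)
  expect_equal(st$s, (120 * 300 + 80 * 100) / 400)
  expect_equal(snr(new_volume(x, rep(1, 3)), masks), 110 / 5, tolerance = 1e-12)
  expect_equal(cnr(new_volume(x, rep(1, 3)), masks), 40 / 5, tolerance = 1e-12)
  # s = 100, sigma = 5 -> SNR 20
  x2 <- x; x2[gm == 1] <- 100; x2[wm == 1] <- 100
  expect_equal(snr(new_volume(x2, rep(1, 3)), masks), 20, tolerance = 1e-12)
  # global intensity scaling leaves both invariant
  expect_equal(snr(new_volume(2 * x, rep(1, 3)), masks),
               snr(new_volume(x, rep(1, 3)), masks), tolerance = 1e-12)
  expect_equal(cnr(new_volume(2 * x, rep(1, 3)), masks),
               cnr(new_volume(x, rep(1, 3)), masks), tolerance = 1e-12)
  # swapping GM and WM leaves CNR unchanged
  masks_sw <- tissue_masks(wm, gm, csf, bg)
  expect_equal(cnr(new_volume(x, rep(1, 3)), masks_sw),
               cnr(new_volume(x, rep(1, 3)), masks), tolerance = 1e-12)
  # degenerate noise
  x3 <- x; x3[bg] <- 0
  expect_error(snr(new_volume(x3, rep(1, 3)), masks), "degenerate")
})

test_that("the stand-in segmenter recovers phantom tissues with Dice >= 0.9", {
  ph <- make_phantom(phantom_spec(seed = 5))
  vn <- add_noise(ph$volume, 0.05, seed = 9)
  seg <- segment_simple(vn, "T2")
  dice <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))
  expect_gte(dice(seg$gm, ph$masks$gm), 0.9)
  expect_gte(dice(seg$wm, ph$masks$wm), 0.9)
  expect_gte(dice(seg$csf, ph$masks$csf), 0.9)
  # masks contract: probabilities in [0,1], background disjoint
  for (m in list(seg$gm, seg$wm, seg$csf)) {
    expect_gte(min(m), 0); expect_lte(max(m), 1)
  }
  expect_false(any(seg$background & (seg$gm + seg$wm + seg$csf > 0)))
  expect_error(segment_simple(new_volume(array(0, c(8, 8, 8)), rep(1, 3))),
               "constant|segmented")
})
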