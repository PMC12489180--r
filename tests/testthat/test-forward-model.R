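test_that("slice kernel follows the FWHM = thickness rule", {
  g <- acq_geometry(3, 2, 0.5)
  k <- make_slice_kernel(g)
  expect_equal(k$sigma_voxels, (2 / (2 * sqrt(2 * log(2)))) / 0.5,
               tolerance = 1e-12)
  expect_equal(k$sigma_voxels, 1.6986, tolerance = 1e-4)
  expect_equal(sum(k$taps), 1, tolerance = 1e-12)
  expect_true(length(k$taps) %% 2 == 1)
  expect_equal(k$taps, rev(k$taps))
  # factor-1 geometry: near-delta kernel
  k1 <- make_slice_kernel(acq_geometry(1, 0.5, 0.5))
  expect_equal(k1$sigma_voxels, 1 / (2 * sqrt(2 * log(2))), tolerance = 1e-12)
  expect_equal(k1$sigma_voxels, 0.4247, tolerance = 1e-4)
})

test_that("rigid transforms compose and invert to identity", {
  t1 <- rigid_transform(c(0.03, -0.02, 0.05), c(1.5, -1, 2), c(4, 4, 4))
  tc <- rt_compose(t1, rt_invert(t1))
  expect_lt(max(abs(c(tc$rotation, tc$translation))), 1e-9)
  # matrix of the composition is the identity
  expect_equal(rt_matrix(t1) %*% rt_matrix(rt_invert(t1)), diag(4),
               tolerance = 1e-12)
})

test_that("identity transform leaves the volume untouched", {
  v <- structured_volume(12)
  out <- apply_transform(v, rigid_transform())
  expect_equal(out$data, v$data, tolerance = 1e-9)
})

test_that("a one-voxel translation matches an index shift in the interior", {
  v <- structured_volume(12)
  t <- rigid_transform(translation = c(1, 0, 0) * v$spacing[1])
  out <- apply_transform(v, t, "trilinear")
  # moving the object +1 voxel along axis 1: out[i] = in[i-1]
  expect_equal(out$data[2:12, , ], v$data[1:11, , ], tolerance = 1e-12)
})

test_that("transforming there and back recovers a smooth volume", {
  v <- structured_volume(24, seed = NULL)
  t <- rigid_transform(c(0.05, -0.04, 0.06), c(1.2, -0.8, 0.9), c(12, 12, 12))
  back <- apply_transform(apply_transform(v, t, "bspline3"), rt_invert(t),
                          "bspline3")
  interior <- back$data[5:20, 5:20, 5:20]
  expect_lt(max(abs(interior - v$data[5:20, 5:20, 5:20])) / diff(range(v$data)),
            1e-2)
})

test_that("unit-sum blur preserves constants and delta kernels are identities", {
  v <- new_volume(array(4.2, c(16, 16, 16)), rep(1, 3))
  g <- acq_geometry(2, 3, 1)
  expect_equal(blur_along_axis(v, make_slice_kernel(g))$data, v$data,
               tolerance = 1e-12)
  kd <- structure(list(taps = 1, axis = 2L, sigma_voxels = 0),
                  class = "srmri_kernel")
  w <- structured_volume(8)
  expect_equal(blur_along_axis(w, kd)$data, w$data)
})

test_that("blurring an impulse reproduces the kernel taps along the axis", {
  g <- acq_geometry(3, 2, 0.5)
  k <- make_slice_kernel(g)
  n <- 32L
  arr <- array(0, c(5, 5, n)); arr[3, 3, 16] <- 1
  out <- blur_along_axis(new_volume(arr, rep(0.5, 3)), k)
  h <- (length(k$taps) - 1) / 2
  expect_equal(out$data[3, 3, (16 - h):(16 + h)], k$taps, tolerance = 1e-12)
  expect_equal(sum(out$data), 1, tolerance = 1e-12)  # off-axis untouched
  expect_error(blur_along_axis(new_volume(array(0, c(4, 4, 4)), rep(1, 3)), k),
               "exceeds")
})

test_that("frequency decimation preserves constants and is exact on band-limited cosines", {
  g <- acq_geometry(3, 2, 0.5)      # factor 4
  cv <- new_volume(array(7.25, c(8, 8, 32)), rep(0.5, 3))
  dc <- downsample_freq(cv, g)
  expect_equal(dim(dc$data), c(8L, 8L, 8L))
  expect_equal(range(dc$data), c(7.25, 7.25), tolerance = 1e-12)
  expect_equal(dc$spacing, c(0.5, 0.5, 2))
  # factor 1 is the identity
  v <- structured_volume(8)
  expect_equal(downsample_freq(v, acq_geometry(3, 1, 1))$data, v$data,
               tolerance = 1e-12)
  # cosine strictly inside the retained band decimates to its analytic samples
  N <- 32L; f <- 4L
  x <- cos(2 * pi * 3 * (0:(N - 1)) / N + 0.3)
  vol <- new_volume(aperm(array(x, c(N, 8, 8)), c(2, 3, 1)), rep(0.5, 3))
  got <- downsample_freq(vol, g)$data[4, 4, ]
  expected <- cos(2 * pi * 3 * (0:(N / f - 1)) * f / N + 0.3)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("output axis length is N/f exactly, padding when needed", {
  g5 <- acq_geometry(3, 2.5, 0.5)   # factor 5
  v <- structured_volume(16)        # 16 not divisible by 5 -> pad to 20
  d <- downsample_freq(v, g5)
  expect_equal(dim(d$data)[3], 4L)
  expect_equal(attr(d, "pad"), c(left = 2L, right = 2L))
})

test_that("added noise matches the requested sigma and is seed-reproducible", {
  v <- new_volume(array(100, c(100, 100, 100)), rep(1, 3))
  expect_identical(add_noise(v, 0, 1)$data, v$data)
  n1 <- add_noise(v, 0.1, seed = 42)
  n2 <- add_noise(v, 0.1, seed = 42)
  expect_identical(n1$data, n2$data)
  s <- sd(n1$data - v$data)      # 1e6 voxels: sd of noise must be 10 +- 0.1
  expect_gt(s, 9.9); expect_lt(s, 10.1)
  expect_error(add_noise(v, -0.1), "nonnegative")
})

test_that("the noise-free degradation is linear", {
  g <- acq_geometry(2, 2, 1)
  v1 <- structured_volume(12, seed = 11)
  v2 <- structured_volume(12, seed = 12)
  lhs <- degrade(new_volume(2 * v1$data - 3 * v2$data, v1$spacing), g)
  rhs1 <- degrade(v1, g); rhs2 <- degrade(v2, g)
  expect_equal(lhs$data, 2 * rhs1$data - 3 * rhs2$data, tolerance = 1e-9)
})

test_that("degenerate pipeline (factor 1, identity pose, no noise) is near-identity", {
  v <- structured_volume(16, seed = NULL)   # smooth
  g <- acq_geometry(3, 1, 1)                # factor 1, near-delta-free sigma
  out <- degrade(v, g)
  # only the slice-profile blur remains; smooth input changes little
  expect_lt(max(abs(out$data - v$data)) / diff(range(v$data)), 0.2)
  expect_equal(dim(out$data), dim(v$data))
})

test_that("the matrix-free operator passes the adjoint test, with and without a pose", {
  shp <- c(15L, 15L, 15L)
  g <- acq_geometry(1, 3, 1)
  poses <- list(rigid_transform(),
                rigid_transform(c(0.04, -0.03, 0.02), c(1, -0.5, 0.7),
                                c(7, 7, 7)))
  for (t in poses) {
    op <- make_degrade_op(shp, diag(c(1, 1, 1, 1)), g, t)
    x <- with_seed_test(21, array(rnorm(prod(shp)), shp))
    y <- with_seed_test(22, array(rnorm(prod(op$out_shape)), op$out_shape))
    lhs <- sum(op$forward(x) * y)
    rhs <- sum(x * op$adjoint(y))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("matrix-free decimation agrees with a brute-force DFT oracle", {
  # oracle: dense DFT matrices assembled from first principles
  shp <- c(6L, 6L, 12L)
  g <- acq_geometry(3, 2, 1)
  A_dense <- dense_degrade_matrix(shp, g)
  op <- make_degrade_op(shp, diag(c(1, 1, 1, 1)), g)
  x <- with_seed_test(31, array(rnorm(prod(shp)), shp))
  expect_equal(as.numeric(op$forward(x)), as.numeric(A_dense %*% as.numeric(x)),
               tolerance = 1e-6)
})
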