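test_that("phantom generation is seeded and hits its tissue means exactly", {
  sp <- phantom_spec(seed = 4)
  p1 <- make_phantom(sp)
  p2 <- make_phantom(sp)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_equal(mean(p1$volume$data[p1$masks$gm == 1]), 120)
  expect_equal(mean(p1$volume$data[p1$masks$wm == 1]), 80)
  expect_equal(mean(p1$volume$data[p1$masks$csf == 1]), 200)
  # different seeds: voxelwise different geometry, same tissue means
  p3 <- make_phantom(phantom_spec(seed = 5))
  expect_false(identical(p1$volume$data, p3$volume$data))
  expect_lt(abs(mean(p3$volume$data[p3$masks$gm == 1]) - 120) / 120, 0.01)
  expect_error(phantom_spec(shape = c(16, 64, 64)), ">= 32")
  expect_error(phantom_spec(means = c(background = 0, csf = 100, gm = 100, wm = 80)),
               "distinct")
})

test_that("a study emits one stack per thickness/plane combination", {
  ph <- make_phantom(phantom_spec(seed = 1))
  st <- simulate_study(ph$volume, ph$masks, thicknesses = c(1, 1.5, 2, 2.5, 3),
                       planes = c("axial", "coronal", "sagittal"),
                       sigma_fraction = 0, seed = 2)
  expect_length(st$stacks, 15L)
  st3 <- simulate_study(ph$volume, ph$masks, thicknesses = 2,
                        planes = c("axial", "coronal", "sagittal"),
                        sigma_fraction = 0, seed = 2)
  expect_length(st3$stacks, 3L)
  # stack geometry: the slice axis shrinks by the factor, others unchanged
  ax <- st3$stacks[[which(vapply(st3$stacks, `[[`, "", "plane") == "axial")]]
  expect_equal(dim(ax$volume$data), c(64L, 64L, 16L))
  expect_identical(ax$geom$factor, 4L)
  co <- st3$stacks[[which(vapply(st3$stacks, `[[`, "", "plane") == "coronal")]]
  expect_equal(dim(co$volume$data), c(64L, 16L, 64L))
})

test_that("identical master seeds regenerate a study bit-exactly", {
  ph <- make_phantom(phantom_spec(seed = 1))
  s1 <- simulate_study(ph$volume, ph$masks, thicknesses = 2,
                       planes = c("axial", "coronal"), sigma_fraction = 0.1,
                       seed = 33)
  s2 <- simulate_study(ph$volume, ph$masks, thicknesses = 2,
                       planes = c("axial", "coronal"), sigma_fraction = 0.1,
                       seed = 33)
  for (i in seq_along(s1$stacks))
    expect_identical(s1$stacks[[i]]$volume$data, s2$stacks[[i]]$volume$data)
  expect_identical(s1$manifest, s2$manifest)
  # a different master seed changes the noise
  s3 <- simulate_study(ph$volume, ph$masks, thicknesses = 2,
                       planes = c("axial", "coronal"), sigma_fraction = 0.1,
                       seed = 34)
  expect_false(identical(s1$stacks[[1]]$volume$data, s3$stacks[[1]]$volume$data))
})

test_that("emitted stack noise matches the requested fraction of the stack max", {
  ph <- make_phantom(phantom_spec(shape = c(96, 96, 96), seed = 6))
  clean <- simulate_study(ph$volume, ph$masks, thicknesses = 1,
                          planes = "axial", sigma_fraction = 0, seed = 3)
  noisy <- simulate_study(ph$volume, ph$masks, thicknesses = 1,
                          planes = "axial", sigma_fraction = 0.1, seed = 3)
  resid <- noisy$stacks[[1]]$volume$data - clean$stacks[[1]]$volume$data
  sigma_req <- 0.1 * max(clean$stacks[[1]]$volume$data)
  expect_lt(abs(sd(resid) - sigma_req) / sigma_req, 0.01)
})

test_that("round-trip closure: factor-1 degradation then TV recovers the phantom", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), seed = 7))
  st <- simulate_study(ph$volume, ph$masks, thicknesses = 0.5,
                       planes = "axial", sigma_fraction = 0, seed = 1)
  rec <- tv_reconstruct(study_stacks(st), study_geoms(st),
                        cfg = tv_config(lambda_tv = 0, max_iterations = 300,
                                        tolerance = 0))
  rel <- sqrt(sum((rec$volume$data - ph$volume$data)^2)) /
    sqrt(sum(ph$volume$data^2))
  expect_lt(rel, 0.05)
})

test_that("canned protocol recipes match the acquisition design", {
  rp <- reference_protocols("desk")
  expect_equal(sort(rp$simulation$thicknesses), c(1, 1.5, 2, 2.5, 3))
  expect_setequal(rp$simulation$planes, c("axial", "coronal", "sagittal"))
  expect_equal(rp$simulation$sigma_fraction, 0.1)
  expect_length(rp$clinical$planes, 2L)
  expect_setequal(rp$clinical$planes, c("axial", "coronal"))
  expect_identical(rp$clinical$factor, 4L)
  expect_equal(rp$clinical$thicknesses / rp$clinical$hr_spacing, 4)
})

test_that("a study writes to disk with a manifest and readable stacks", {
  td <- withr::local_tempdir()
  ph <- make_phantom(phantom_spec(seed = 1))
  st <- simulate_study(ph$volume, ph$masks, thicknesses = 2,
                       planes = "axial", sigma_fraction = 0.05, seed = 9)
  write_study(st, td)
  expect_true(file.exists(file.path(td, "manifest.yaml")))
  man <- yaml::read_yaml(file.path(td, "manifest.yaml"))
  expect_equal(man$seed, 9L)
  expect_length(man$stacks, 1L)
  back <- read_nifti(file.path(td, "stack_01_axial_2mm.nii.gz"))
  expect_equal(back$data, st$stacks[[1]]$volume$data, tolerance = 1e-4)
  expect_equal(back$spacing, c(0.5, 0.5, 2))
})
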