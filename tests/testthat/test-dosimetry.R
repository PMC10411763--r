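test_that("bone segmentation thresholds inclusively at the cutoff", {
  ct <- volume3d(array(c(-100, 299, 300, 1000, -1000, 500, 0, 80),
                       c(2, 2, 2)), value_kind = "HU")
  m <- segment_bone(ct)
  expect_equal(as.logical(m)[1:4], c(FALSE, FALSE, TRUE, TRUE))
  air <- volume3d(array(-1000, c(3, 3, 3)), value_kind = "HU")
  expect_equal(sum(segment_bone(air)), 0)
  expect_equal(sum(segment_bone(air, cutoff_hu = -2000)), 27)
  notct <- volume3d(array(1, c(2, 2, 2)), value_kind = "counts")
  expect_error(segment_bone(notct), "Hounsfield")
})

test_that("toy kernels have the documented structure", {
  expect_error(generate_toy_kernel("Lu177", 4, table_side = 4), "odd")
  k1 <- generate_toy_kernel("Lu177", 4, table_side = 1)
  expect_equal(dim(k1$values), c(1, 1, 1))
  expect_gt(k1$values[1, 1, 1], 0)

  ks <- generate_toy_kernel("Lu177", 4, 7)
  kb <- generate_toy_kernel("Lu177", 4, 7, medium = "bone")
  ctr <- c(4, 4, 4)
  expect_equal(max(ks$values), ks$values[ctr[1], ctr[2], ctr[3]])
  off <- ks$values; off[4, 4, 4] <- NA
  offb <- kb$values; offb[4, 4, 4] <- NA
  expect_true(all(offb <= off, na.rm = TRUE))
  # values decay monotonically along the axes from the centre
  expect_true(all(diff(ks$values[4:7, 4, 4]) < 0))
  expect_identical(ks$values,
                   generate_toy_kernel("Lu177", 4, 7)$values)
  expect_match(ks$provenance, "not for clinical use")
})

test_that("kernel files round-trip through JSON and are validated on read", {
  k <- generate_toy_kernel("Y90", 4.5, 5, medium = "bone")
  f <- withr::local_tempfile(fileext = ".json")
  write_dose_kernel(k, f)
  k2 <- read_dose_kernel(f)
  expect_equal(k2$values, k$values)
  expect_equal(k2$voxel_spacing, k$voxel_spacing)
  expect_identical(k2$medium, "bone")

  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$values[1] <- max(bad$values) * 2   # corner exceeds the centre
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_dose_kernel(f2), "centre|maximum")
})

test_that("a pure self-dose kernel scales the TIA map exactly", {
  tia <- random_volume(c(6, 6, 6), seed = 14)
  tia$value_kind <- "tia_MBq_s"
  k <- generate_toy_kernel("Lu177", 4, 1)
  s0 <- k$values[1, 1, 1]
  dose <- convolve_dose(tia, k)
  expect_equal(dose$values, tia$values * s0, tolerance = 1e-12)
  expect_identical(dose$value_kind, "dose_mGy")
})

test_that("a single-voxel source reproduces the kernel as its impulse response", {
  tia <- volume3d(array(0, c(15, 15, 15)), spacing = c(4, 4, 4),
                  value_kind = "tia_MBq_s")
  tia$values[8, 8, 8] <- 3
  k <- generate_toy_kernel("I131", 4, 7)
  dose <- convolve_dose(tia, k)
  expect_equal(dose$values[5:11, 5:11, 5:11], 3 * k$values,
               tolerance = 1e-9 * max(k$values))
})

test_that("FFT convolution equals the direct sum and is linear", {
  for (i in 1:5) {
    tia <- random_volume(c(8, 8, 8), seed = 300 + i)
    tia$value_kind <- "tia_MBq_s"
    set.seed(400 + i)
    k <- generate_toy_kernel("Lu177", 4, 5)
    k$values <- array(runif(125), c(5, 5, 5))
    k$values[3, 3, 3] <- max(k$values) + 1
    fftd <- convolve_dose(tia, k)
    direct <- brute_force_dose(tia, k)
    expect_lt(max(abs(fftd$values - direct$values)) / max(direct$values),
              1e-10)
    tia2 <- tia; tia2$values <- tia$values * 4
    expect_equal(convolve_dose(tia2, k)$values, fftd$values * 4,
                 tolerance = 1e-9)
  }
})

test_that("two-media convolution requires matching grids and masks", {
  tia <- random_volume(c(6, 6, 6), seed = 15)
  tia$value_kind <- "tia_MBq_s"
  ks <- generate_toy_kernel("Lu177", 4, 3)
  kwrong <- generate_toy_kernel("Lu177", 5, 3)
  expect_error(convolve_dose(tia, kwrong), "spacing")
  kb <- generate_toy_kernel("Lu177", 4, 3, medium = "bone")
  expect_error(convolve_dose(tia, list(soft_tissue = ks, bone = kb)),
               "tissue mask")
  ct <- volume3d(array(rep(c(0, 800), each = 108), c(6, 6, 6)),
                 value_kind = "HU")
  mask <- segment_bone(ct)
  dose <- convolve_dose(tia, list(soft_tissue = ks, bone = kb), mask)
  # bone + soft contributions sum to the whole
  soft_only <- convolve_dose(
    volume3d(tia$values * !mask, spacing = tia$spacing,
             value_kind = "tia_MBq_s"), ks)
  bone_only <- convolve_dose(
    volume3d(tia$values * mask, spacing = tia$spacing,
             value_kind = "tia_MBq_s"), kb)
  expect_equal(dose$values, soft_only$values + bone_only$values,
               tolerance = 1e-10)
})

test_that("interior sources conserve dose: sum(dose) = sum(TIA) x sum(kernel)", {
  tia <- volume3d(array(0, c(20, 20, 20)), spacing = c(4, 4, 4),
                  value_kind = "tia_MBq_s")
  set.seed(16)
  tia$values[9:12, 9:12, 9:12] <- runif(64) * 10
  k <- generate_toy_kernel("Lu177", 4, 7)
  dose <- convolve_dose(tia, k)
  expect_lt(abs(sum(dose$values) / (sum(tia$values) * sum(k$values)) - 1),
            1e-9)
})

test_that("the cutoff VOI keeps the connected supra-threshold component", {
  dose <- volume3d(array(0, c(12, 12, 12)), spacing = c(4, 4, 4),
                   value_kind = "dose_mGy")
  region <- array(FALSE, c(12, 12, 12)); region[2:11, 2:11, 2:11] <- TRUE
  dose$values[region] <- 50
  v <- voi_by_cutoff(dose, region)
  expect_equal(v$n_voxels, sum(region))
  expect_equal(v$mean_dose, 50)
  expect_equal(v$max_dose, 50)

  dose$values[region] <- 39
  dose$values[5:7, 5:7, 5:7] <- 100
  v2 <- voi_by_cutoff(dose, region, cutoff_fraction = 0.40)
  expect_equal(v2$n_voxels, 27)         # the 39s fall below 40 = 0.4 x 100
  expect_equal(v2$mean_dose, 100)

  # a supra-threshold blob disconnected from the max is excluded
  dose$values[10, 10, 10] <- 45
  v3 <- voi_by_cutoff(dose, region, cutoff_fraction = 0.40)
  expect_equal(v3$n_voxels, 27)
  expect_error(voi_by_cutoff(dose, array(FALSE, c(12, 12, 12))), "empty")
})

test_that("method-comparison utilities match their closed forms", {
  a <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a), -1)
  set.seed(17)
  x <- rnorm(30); y <- rnorm(30)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), hand, tolerance = 1e-12)
  expect_error(pearson_correlation(a, rep(1, 5)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "3 pairs")

  ba <- bland_altman(a, a)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$loa_upper, 0)
  ba2 <- bland_altman(a, a + 2)
  expect_equal(ba2$mean_difference, -2)
  expect_equal(ba2$sd_difference, 0)
  ba3 <- bland_altman(x, y)
  expect_equal(ba3$loa_upper, mean(x - y) + 1.96 * sd(x - y))
  expect_equal(nrow(ba3$table), 30)
  expect_error(bland_altman(1:3, 1:4), "mismatch")
})
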