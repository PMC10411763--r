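test_that("volume3d validates its geometry and values", {
  expect_error(volume3d(matrix(1, 2, 2)), "3-D")
  expect_error(volume3d(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)), "positive")
  expect_error(volume3d(array(-1, c(2, 2, 2)), value_kind = "counts"),
               "negative")
  expect_silent(volume3d(array(-1000, c(2, 2, 2)), value_kind = "HU"))
  expect_error(volume3d(array(NA_real_, c(2, 2, 2))), "finite")
})

test_that("index/world mapping round-trips exactly on integer indices", {
  v <- volume3d(array(0, c(5, 6, 7)), spacing = c(2, 3, 4),
                origin = c(-10, 4, 2.5))
  idx <- as.matrix(expand.grid(0:4, 0:5, 0:6))
  expect_equal(world_to_index(v, index_to_world(v, idx)), idx,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(voxel_volume_ml(v), 24 / 1000)
})

test_that("resampling onto an identical grid is exact; constants survive downsampling", {
  v <- random_volume(c(10, 10, 10), seed = 3)
  out <- resample_to_grid(v, v)
  expect_identical(out$values, v$values)
  expect_true(all(attr(out, "valid")))

  cv <- volume3d(array(7, c(16, 16, 16)), spacing = c(2, 2, 2))
  coarse <- volume3d(array(0, c(7, 7, 7)), spacing = c(4, 4, 4),
                     origin = c(2, 2, 2))
  out2 <- resample_to_grid(cv, coarse)
  expect_equal(out2$values[attr(out2, "valid")],
               rep(7, sum(attr(out2, "valid"))))
})

test_that("trilinear interpolation is exact on a linear ramp", {
  n <- c(9, 9, 9)
  idx <- as.matrix(expand.grid(0:8, 0:8, 0:8))
  ramp <- 2 + 0.5 * idx[, 1] + 0.25 * idx[, 2] + 0.125 * idx[, 3]
  v <- volume3d(array(ramp, n), spacing = c(2, 2, 2))
  fine <- volume3d(array(0, c(5, 5, 5)), spacing = c(3, 3, 3),
                   origin = c(1, 1, 1))
  out <- resample_to_grid(v, fine)
  iw <- world_to_index(v, index_to_world(fine, as.matrix(
    expand.grid(0:4, 0:4, 0:4))))
  expected <- 2 + 0.5 * iw[, 1] + 0.25 * iw[, 2] + 0.125 * iw[, 3]
  expect_equal(as.numeric(out$values), expected, tolerance = 1e-12)
})

test_that("disjoint fields of view are an error, not silence", {
  a <- random_volume(c(6, 6, 6), seed = 1)
  far <- volume3d(array(0, c(6, 6, 6)), spacing = c(4, 4, 4),
                  origin = c(1000, 1000, 1000))
  expect_error(resample_to_grid(a, far), "disjoint")
})

test_that("DICOM series round-trip preserves values and geometry", {
  set.seed(9)
  v <- volume3d(array(runif(16 * 12 * 6) * 800, c(16, 12, 6)),
                spacing = c(2, 3, 4), origin = c(-12, 6, 3))
  d <- withr::local_tempdir()
  write_dicom_series(v, d, "round trip test")
  v2 <- read_dicom_series(d)
  quant <- (max(v$values) - min(v$values)) / 65535
  expect_lt(max(abs(v2$values - v$values)), quant)
  expect_lt(abs(sum(v2$values) / sum(v$values) - 1), 1e-3)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-7)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
})

test_that("a constant volume is encoded exactly in DICOM", {
  v <- volume3d(array(123.456, c(4, 4, 3)), spacing = c(4, 4, 4))
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  expect_equal(read_dicom_series(d)$values, v$values, tolerance = 1e-7)
})

test_that("inconsistent slice spacing and mixed series are rejected", {
  v <- random_volume(c(6, 6, 5), seed = 2)
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  file.remove(file.path(d, "slice0003.dcm"))   # creates a double-width gap
  expect_error(read_dicom_series(d), "inconsistent slice spacing")

  d2 <- withr::local_tempdir()
  write_dicom_series(v, d2)
  write_dicom_series(random_volume(c(6, 6, 2), seed = 3),
                     file.path(d2, "other"))
  file.copy(file.path(d2, "other", "slice0001.dcm"),
            file.path(d2, "extra.dcm"))
  unlink(file.path(d2, "other"), recursive = TRUE)
  expect_error(read_dicom_series(d2), "mixed series")
})

test_that("an independent DICOM reader agrees with ours", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # part of the supported toolchain
  set.seed(21)
  v <- volume3d(array(runif(8 * 6 * 3) * 500, c(8, 6, 3)),
                spacing = c(2, 2, 4), value_kind = "counts")
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  script <- paste(
    "import pydicom, glob, sys",
    sprintf("fs = sorted(glob.glob(r'%s/*.dcm'))", d),
    "tot = 0.0",
    "for f in fs:",
    "    ds = pydicom.dcmread(f)",
    "    tot += float((ds.pixel_array * float(ds.RescaleSlope) +",
    "                  float(ds.RescaleIntercept)).sum())",
    "print(repr(tot))", sep = "\n")
  out <- system2(py, "-", input = script, stdout = TRUE)
  expect_equal(as.numeric(out[length(out)]), sum(v$values),
               tolerance = 1e-6)
})

test_that("NIfTI round-trip is lossless and honours scale factors", {
  v <- random_volume(c(10, 8, 6), seed = 5, spacing = c(2, 3, 4))
  v$origin <- c(-5, 2, 8)
  f <- withr::local_tempfile(fileext = ".nii")
  write_nifti_volume(v, f)
  v2 <- suppressMessages(read_nifti_volume(f))
  expect_equal(v2$values, v$values)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
  expect_equal(v2$orientation, v$orientation, tolerance = 1e-6)

  # a slope of 2 in the header must double the values on read
  raw <- readBin(f, "raw", file.info(f)$size)
  con <- file(f, "r+b")
  seek(con, 112, rw = "write")                 # scl_slope field, float32
  writeBin(c(2, 1), con, size = 4)             # slope 2, intercept 1
  close(con)
  v3 <- read_nifti_volume(f)
  expect_equal(v3$values, v$values * 2 + 1, tolerance = 1e-6)
})

test_that("DICOM and NIfTI copies index the same anatomy at the same world point", {
  set.seed(13)
  v <- volume3d(array(runif(12^3) * 100, c(12, 12, 12)),
                spacing = c(3, 3, 3), origin = c(-16.5, -16.5, -16.5))
  d <- withr::local_tempdir()
  f <- withr::local_tempfile(fileext = ".nii")
  write_dicom_series(v, d)
  write_nifti_volume(v, f)
  vd <- read_dicom_series(d)
  vn <- suppressMessages(read_nifti_volume(f))
  for (i in 1:10) {
    p <- runif(3, -14, 14)
    id <- round(world_to_index(vd, p))
    nn <- round(world_to_index(vn, p))
    # the DICOM copy is quantized to 16 bits over the value range
    expect_equal(vd$values[id[1] + 1, id[2] + 1, id[3] + 1],
                 vn$values[nn[1] + 1, nn[2] + 1, nn[3] + 1],
                 tolerance = 1e-3)
  }
})
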