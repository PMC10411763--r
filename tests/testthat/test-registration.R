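brute_force_mse <- function(ref, g, valid) {
  # independent double-loop evaluation on identical grids
  s <- 0; n <- 0
  d <- dim(ref)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (valid[i, j, k]) {
      s <- s + (ref[i, j, k] - g[i, j, k])^2
      n <- n + 1
    }
  }
  s / n
}

test_that("mse cost matches closed forms and a brute-force oracle", {
  v <- random_volume(c(8, 8, 8), seed = 1)
  expect_equal(as.numeric(mse_cost(v, v)), 0)

  a <- volume3d(array(3, c(6, 6, 6)), spacing = c(4, 4, 4))
  b <- volume3d(array(3 + 1.5, c(6, 6, 6)), spacing = c(4, 4, 4))
  expect_equal(as.numeric(mse_cost(a, b)), 1.5^2, tolerance = 1e-12)

  set.seed(2)
  w <- random_volume(c(8, 8, 8), seed = 99)
  tr <- rigid_transform(1.2, -0.7, 0.4, rz = 3)
  g <- reslice(w, tr, v)
  expect_equal(as.numeric(mse_cost(v, w, tr)),
               brute_force_mse(v$values, g$values, attr(g, "valid")),
               tolerance = 1e-10)
})

test_that("ncc cost is -1 for identical and affinely related volumes", {
  v <- random_volume(c(12, 12, 12), seed = 4)
  cfg <- registration_config("ncc", smoothing_fwhm_mm = 0,
                             sample_spacing_mm = NULL)
  expect_equal(ncc_cost(v, v, config = cfg), -1, tolerance = 1e-12)
  w <- v; w$values <- 2.5 * v$values + 3
  expect_equal(ncc_cost(v, w, config = cfg), -1, tolerance = 1e-12)
  z <- v; z$values[] <- 1
  expect_error(ncc_cost(v, z, config = cfg), "variance")
})

test_that("ncc cost equals brute-force Pearson over sampled voxels", {
  v <- random_volume(c(8, 8, 8), seed = 5)
  w <- random_volume(c(8, 8, 8), seed = 6)
  cfg <- registration_config("ncc", smoothing_fwhm_mm = 0,
                             sample_spacing_mm = NULL)
  got <- ncc_cost(v, w, config = cfg)
  a <- as.numeric(v$values); b <- as.numeric(w$values)
  hand <- -sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got, hand, tolerance = 1e-10)
})

test_that("registering a volume to itself recovers the identity", {
  v <- small_phantom_noiseless()
  rr <- register_rigid(v, v)
  expect_lt(max(abs(rr$transform$translation)), 0.1)
  expect_lt(max(abs(rr$transform$rotation_deg)), 0.1)
  expect_true(rr$converged)
  expect_lte(rr$iterations, 100)
})

test_that("a noiseless 5-degree bed-axis rotation is recovered", {
  spec <- small_spec()
  ref <- small_phantom_noiseless()
  tr <- rigid_transform(rz = -5)
  tgt <- simulate_acquisition(make_phantom(spec, transform = tr)$activity,
                              poisson = FALSE)
  rr <- register_rigid(ref, tgt)
  # voxelization of the rotated phantom leaves ~0.3 degree of bias at 4 mm
  # voxels; the accuracy budget is 0.5 degree / half a voxel
  expect_lt(abs(rr$transform$rotation_deg["rz"] - (-5)), 0.5)
  expect_lt(sqrt(sum(rr$transform$translation^2)), 0.5)
  # recovered optimum is no worse than the identity cost
  expect_lte(rr$final_cost, as.numeric(mse_cost(ref, tgt)))
  # %RMSE strictly improves after reslice
  resl <- reslice(tgt, rr$transform, ref)
  expect_lt(percent_rmse(ref, resl), percent_rmse(ref, tgt))
})

test_that("randomized rigid perturbations are recovered on the noisy phantom", {
  spec <- small_spec()
  ref <- simulate_acquisition(make_phantom(spec)$activity, seed = 50)
  set.seed(77)
  errs <- t(vapply(1:20, function(i) {
    tr <- rigid_transform(runif(1, -10, 10), runif(1, -10, 10),
                          runif(1, -10, 10), runif(1, -10, 10),
                          runif(1, -10, 10), runif(1, -10, 10))
    tgt <- simulate_acquisition(make_phantom(spec, transform = tr)$activity,
                                seed = 1000 + i)
    rr <- register_rigid(ref, tgt)
    resid <- compose_transforms(rr$transform, invert_transform(tr))
    Rm <- transform_matrix(resid)[1:3, 1:3]
    c(rot = acos(max(-1, min(1, (sum(diag(Rm)) - 1) / 2))) * 180 / pi,
      trans = sqrt(sum(transform_matrix(resid)[1:3, 4]^2)))
  }, c(rot = 0, trans = 0)))
  expect_lte(median(errs[, "rot"]), 0.5)
  expect_lte(median(errs[, "trans"]), 2)   # half of the 4 mm voxel
})

test_that("reslicing through a transform and its inverse is near-lossless and mass-preserving", {
  v <- small_phantom_noiseless()
  expect_identical(reslice(v, rigid_transform(), v)$values, v$values)
  # band-limited volume (PSF 4 voxels FWHM) so the round trip measures
  # interpolation error, not undersampling
  v <- simulate_acquisition(make_phantom(small_spec())$activity,
                            psf_fwhm_mm = 16, poisson = FALSE)
  tr <- rigid_transform(2.5, -1.5, 3, rx = 2, rz = -7, center = c(0, 0, 0))
  fwd <- reslice(v, tr, v)
  back <- reslice(fwd, invert_transform(tr), v)
  ok <- attr(back, "valid")
  expect_lt(sqrt(mean((back$values[ok] - v$values[ok])^2)),
            0.01 * max(v$values))
  # interior-supported object: totals preserved within 2%
  expect_lt(abs(sum(fwd$values) / sum(v$values) - 1), 0.02)
})

test_that("the fiducial is found and becomes the origin", {
  spec <- small_spec()
  vol <- simulate_acquisition(make_phantom(spec)$activity, seed = 3)
  shifted <- set_origin_on_fiducial(vol)
  # world (0,0,0) must now sit at the fiducial centre (93, 93, 0) of the
  # original frame: the origin moved by about that much
  expect_equal(vol$origin - shifted$origin, spec$fiducial$position,
               tolerance = 0.05)  # relative; ~4 mm absolute on 93 mm

  manual <- set_origin_on_fiducial(vol, "manual_point", point = c(10, -5, 2))
  expect_equal(vol$origin - manual$origin, c(10, -5, 2))

  bare <- simulate_acquisition(
    make_phantom(spec, with_fiducial = FALSE)$activity, seed = 3)
  expect_error(set_origin_on_fiducial(bare), "no fiducial candidate")
})

test_that("equal fiducial candidates tie-break deterministically with a warning", {
  v <- array(0, c(24, 24, 24))
  v[10:14, 10:14, 10:14] <- 100          # main object
  v[2:3, 2, 2] <- 50                     # candidate A: 2 voxels
  v[20, 20, 20] <- 50                    # candidate B: 1 voxel
  vol <- volume3d(v, spacing = c(4, 4, 4))
  expect_warning(out <- set_origin_on_fiducial(vol), "equal peak")
  centroid <- vol$origin - out$origin
  expect_equal(centroid, drop(index_to_world(vol, c(1.5, 1, 1))),
               tolerance = 1e-9)
})

test_that("registering with and without the fiducial gives matching transforms", {
  spec <- small_spec()
  tr <- rigid_transform(rz = -10)
  res <- lapply(c(TRUE, FALSE), function(fid) {
    ref <- simulate_acquisition(
      make_phantom(spec, with_fiducial = fid)$activity, seed = 60 + fid)
    tgt <- simulate_acquisition(
      make_phantom(spec, with_fiducial = fid, transform = tr)$activity,
      seed = 70 + fid)
    register_rigid(ref, tgt)$transform
  })
  expect_lt(max(abs(res[[1]]$rotation_deg - res[[2]]$rotation_deg)), 0.5)
  expect_lt(max(abs(res[[1]]$translation - res[[2]]$translation)), 2)
})
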