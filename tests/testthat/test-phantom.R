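test_that("a phantom without cold inserts is a uniform fill", {
  spec <- phantom_spec(sphere_radii = numeric(),
                       rod_sector_diameters = numeric(),
                       fiducial = NULL, grid_shape = c(48, 48, 48),
                       cylinder_radius = 80, cylinder_height = 150,
                       activity_concentration = 0.2)
  ph <- make_phantom(spec)
  vals <- unique(as.numeric(ph$activity$values))
  expect_setequal(round(vals, 12), round(c(0, 0.2 * 64 / 1000), 12))
  expect_equal(ph$ct$value_kind, "HU")
  expect_setequal(unique(as.numeric(ph$ct$values)), c(-1000, 0, 120))
})

test_that("the default phantom holds 740 MBq and its cold spheres are empty", {
  ph <- make_phantom(default_spec())
  expect_lt(abs(sum(ph$activity$values) - 740) / 740, 0.02)
  ss <- phantom_sphere_specs(default_spec())
  d <- dim(ph$activity$values)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  pts <- index_to_world(ph$activity, idx)
  for (s in seq_len(nrow(ss))) {
    m <- (pts[, 1] - ss$x[s])^2 + (pts[, 2] - ss$y[s])^2 +
      (pts[, 3] - ss$z[s])^2 <= ss$radius[s]^2
    expect_equal(sum(ph$activity$values[m]), 0)
  }
})

test_that("geometry violations are configuration errors naming the element", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 16)), "grid_shape")
  expect_error(phantom_spec(sphere_ring_radius = 105), "spheres")
  expect_error(phantom_spec(fiducial = list(volume_ml = 3, position = c(0, 0, 0))),
               "fiducial")
  expect_error(phantom_spec(fiducial = list(volume_ml = 3,
                                            position = c(260, 0, 0))),
               "fiducial")
  expect_error(phantom_spec(cylinder_radius = -3), "positive")
})

test_that("phantom specs and kinetics round-trip through JSON and YAML", {
  spec <- small_spec()
  fj <- withr::local_tempfile(fileext = ".json")
  write_phantom_spec(spec, fj)
  spec2 <- read_phantom_spec(fj)
  expect_equal(spec2$cylinder_height, spec$cylinder_height)
  expect_equal(spec2$rods, spec$rods)
  expect_equal(spec2$fiducial[names(spec$fiducial)], spec$fiducial)

  fy <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, fy)
  expect_equal(read_phantom_spec(fy)$sphere_radii, spec$sphere_radii)

  k <- kinetic_ground_truth(A1 = 7.5, lambda1 = 0.2, ramp_peak_h = 2)
  fk <- withr::local_tempfile(fileext = ".json")
  write_kinetic_ground_truth(k, fk)
  expect_equal(read_kinetic_ground_truth(fk), k)
})

test_that("acquisition with no PSF and no noise is the scaled truth", {
  truth <- make_phantom(small_spec())$activity
  tot <- sum(truth$values)
  out <- simulate_acquisition(truth, psf_fwhm_mm = 0, total_counts = tot * 5,
                              poisson = FALSE)
  expect_equal(out$values, truth$values * 5, tolerance = 1e-12)
  expect_identical(out$value_kind, "counts")
})

test_that("acquisition is seed-deterministic and Poisson-consistent", {
  truth <- volume3d(array(rep(c(0, 2), each = 2048), c(16, 16, 16)),
                    spacing = c(4, 4, 4), value_kind = "activity_MBq")
  a <- simulate_acquisition(truth, 8, 5e4, seed = 123)
  b <- simulate_acquisition(truth, 8, 5e4, seed = 123)
  expect_identical(a$values, b$values)
  expect_error(simulate_acquisition(truth, 8, -1), "positive")

  totals <- vapply(1:100, function(s)
    sum(simulate_acquisition(truth, 8, 5e4, seed = s)$values), 0)
  # Poisson: mean of totals ~ N(5e4, sqrt(5e4/100)); variance ~ mean
  expect_lt(abs(mean(totals) - 5e4), 3 * sqrt(5e4 / 100))
  expect_lt(abs(var(totals) / 5e4 - 1), 0.5)
})

test_that("the default rotation study yields 18 studies with exact ground truth", {
  spec <- small_spec()
  sim <- make_rotation_study(spec, psf_fwhm_mm = 0, total_counts = 1e6,
                             poisson = FALSE, replicates = 3)
  expect_length(sim$studies, 18)
  expect_named(sim$references, c("with_fiducial", "without_fiducial"))
  zero <- Filter(function(s) s$angle_deg == 0, sim$studies)
  for (s in zero)
    expect_equal(transform_matrix(s$truth_transform), diag(4))
  five <- Filter(function(s) s$angle_deg == 5, sim$studies)[[1]]
  expect_equal(unname(five$truth_transform$rotation_deg["rz"]), -5)
})

test_that("applying a rotation and then its inverse restores the volume", {
  spec <- small_spec()
  # a 16 mm PSF on 4 mm voxels gives an adequately sampled (band-limited)
  # volume, where trilinear round-trip error reflects interpolation alone
  base <- simulate_acquisition(make_phantom(spec)$activity,
                               psf_fwhm_mm = 16, poisson = FALSE)
  tr <- rigid_transform(rz = -5)
  fwd <- reslice(base, tr, base)
  back <- reslice(fwd, invert_transform(tr), base)
  ok <- attr(back, "valid") & attr(fwd, "valid")
  rms <- sqrt(mean((back$values[ok] - base$values[ok])^2))
  expect_lt(rms, 0.01 * max(base$values))
})

test_that("clockwise rotation about the bed axis moves a marker as documented", {
  # marker on the +x axis; clockwise (viewed from +z) sends +x towards -y
  spec <- phantom_spec(sphere_radii = numeric(),
                       rod_sector_diameters = numeric(),
                       fiducial = list(volume_ml = 15, position = c(100, 0, 0)),
                       cylinder_radius = 60, cylinder_height = 100,
                       grid_shape = c(64, 64, 64))
  rot <- make_phantom(spec, transform = rigid_transform(rz = -90))$activity
  d <- dim(rot$values)
  # locate the fiducial as the activity centroid outside the cylinder radius
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  pts <- index_to_world(rot, idx)
  out_cyl <- pts[, 1]^2 + pts[, 2]^2 > 70^2
  w <- as.numeric(rot$values)[out_cyl]
  cen <- colSums(pts[out_cyl, ] * w) / sum(w)
  expect_equal(cen, c(0, -100, 0), tolerance = 2)
})

test_that("patient-series kinetics match an independent quadrature", {
  k <- kinetic_ground_truth(A1 = 10, lambda1 = 0.1, A2 = 5, lambda2 = 0.01,
                            ramp_peak_h = 1.5)
  closed <- voxdose:::kinetics_tia_h(k, 1.5)
  hand <- 0.5 * 1.5 * (10 * exp(-0.15) + 5 * exp(-0.015)) +
    10 / 0.1 * exp(-0.1 * 1.5) + 5 / 0.01 * exp(-0.01 * 1.5)
  expect_equal(closed, hand, tolerance = 1e-12)
  quad <- stats::integrate(function(t)
    voxdose:::kinetics_activity(k, t, 1.5), 0, 5000,
    rel.tol = 1e-10, subdivisions = 1000L)$value
  tail_beyond <- 5 / 0.01 * exp(-0.01 * 5000)  # negligible fast component
  expect_equal(closed, quad + tail_beyond, tolerance = 1e-6)
})

test_that("degenerate kinetics behave: mono-exponential and all-zero cases", {
  km <- kinetic_ground_truth(A1 = 8, lambda1 = 0.05, A2 = 0, lambda2 = 0.05)
  t <- seq(2, 100, by = 1)
  a <- voxdose:::kinetics_activity(km, t, 2)
  expect_equal(a, 8 * exp(-0.05 * t), tolerance = 1e-12)

  orgs <- default_patient_organs()
  for (i in seq_along(orgs))
    if (!is.null(orgs[[i]]$kinetics))
      orgs[[i]]$kinetics <- kinetic_ground_truth(A1 = 0, A2 = 0)
  ps <- make_patient_series(organs = orgs, grid_shape = c(32, 32, 32),
                            voxel_spacing = 8)
  expect_true(all(vapply(ps$series, function(v) sum(v$values), 0) == 0))
  expect_equal(sum(ps$analytic_tia$values), 0)
})

test_that("patient series validates its time grid and contains bone", {
  expect_error(make_patient_series(times_h = c(1.5, 5, 24)), "4 time points")
  expect_error(make_patient_series(times_h = c(1.5, 5, 5, 24)),
               "strictly increasing")
  ps <- patient_fixture()$ps
  expect_true(any(ps$ct$values >= 300))
  expect_true(any(ps$ct$values < 300 & ps$ct$values > -500))
  expect_equal(vapply(ps$series, function(v) v$acquisition_time_h, 0),
               c(1.5, 5, 24, 240))
})
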