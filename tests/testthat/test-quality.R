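vol_1x2 <- function(vals) volume3d(array(vals, c(2, 1, 1)),
                                   spacing = c(4, 4, 4))

test_that("rmse and %RMSE match hand-computed values on printed toy grids", {
  r <- vol_1x2(c(2, 4)); g <- vol_1x2(c(0, 4))
  expect_equal(rmse(r, r), 0)
  expect_equal(as.numeric(rmse(r, g)), sqrt((4 + 0) / 2), tolerance = 1e-12)
  expect_equal(percent_rmse(r, g), 100 * sqrt(2) / 6, tolerance = 1e-12)
  expect_equal(percent_rmse(r, r), 0)

  # constant offset: rmse is the offset
  a <- random_volume(c(6, 6, 6), seed = 8)
  b <- a; b$values <- a$values + 0.75
  expect_equal(as.numeric(rmse(a, b)), 0.75, tolerance = 1e-12)

  expect_error(percent_rmse(volume3d(array(0, c(2, 2, 2))), r), "zero total")
  expect_error(rmse(a, random_volume(c(5, 5, 5))), "same grid")
})

test_that("%RMSE is invariant under joint rescaling, and per-slice values average", {
  a <- random_volume(c(6, 6, 4), seed = 9)
  b <- random_volume(c(6, 6, 4), seed = 10)
  k <- 3.7
  ak <- a; ak$values <- a$values * k
  bk <- b; bk$values <- b$values * k
  expect_equal(percent_rmse(ak, bk), percent_rmse(a, b), tolerance = 1e-12)

  ps <- rmse(a, b, per_slice = TRUE)
  expect_length(attr(ps, "per_slice"), 4)
  expect_equal(as.numeric(ps), mean(attr(ps, "per_slice")))
})

test_that("rmse behaves as a metric on random volume triples", {
  set.seed(31)
  for (i in 1:5) {
    a <- random_volume(c(5, 5, 5), seed = i)
    b <- random_volume(c(5, 5, 5), seed = i + 100)
    c3 <- random_volume(c(5, 5, 5), seed = i + 200)
    expect_equal(as.numeric(rmse(a, b)), as.numeric(rmse(b, a)))
    expect_lte(as.numeric(rmse(a, c3)),
               as.numeric(rmse(a, b)) + as.numeric(rmse(b, c3)) + 1e-12)
    expect_gt(as.numeric(rmse(a, b)), 0)
  }
})

test_that("integral uniformity: constant region scores 0, a 90/110 split scores 10", {
  v <- volume3d(array(50, c(20, 20, 8)), spacing = c(4, 4, 4),
                origin = c(-38, -38, -14))
  region <- list(radius = 30, z_range = c(-10, 10))
  expect_equal(as.numeric(uniformity(v, region)), 0)

  # wide blocks survive 3x3 smoothing in their interiors
  w <- v
  w$values[1:10, , ] <- 90
  w$values[11:20, , ] <- 110
  expect_equal(as.numeric(uniformity(w, region)), 100 * 20 / 200,
               tolerance = 1e-12)
  expect_error(uniformity(v, list(radius = 30, z_range = c(500, 600))),
               "empty")
})

test_that("cold-sphere contrast hits its closed-form extremes", {
  spec <- small_spec()
  vol <- simulate_acquisition(make_phantom(spec)$activity, psf_fwhm_mm = 0,
                              poisson = FALSE)
  co <- contrast(vol, phantom_sphere_specs(spec), phantom_background_roi(spec))
  # unblurred cold spheres: every sphere perfectly cold
  expect_true(all(abs(co$max_contrast - 100) < 1e-9))
  expect_true(all(co$mean_contrast > 95))

  # sphere filled at background level scores ~0
  filled <- vol
  ss <- phantom_sphere_specs(spec)[5, ]
  d <- dim(filled$values)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  pts <- index_to_world(filled, idx)
  m <- (pts[, 1] - ss$x)^2 + (pts[, 2] - ss$y)^2 + (pts[, 3] - ss$z)^2 <=
    ss$radius^2
  filled$values[array(m, d)] <- mean(vol$values[vol$values > 0])
  co2 <- contrast(filled, ss, phantom_background_roi(spec))
  expect_lt(abs(co2$mean_contrast), 2)
})

test_that("measured contrast decreases monotonically with PSF width", {
  spec <- small_spec()
  truth <- make_phantom(spec)$activity
  widths <- c(6, 10, 16)
  mc <- vapply(widths, function(w) {
    v <- simulate_acquisition(truth, psf_fwhm_mm = w, poisson = FALSE)
    co <- contrast(v, phantom_sphere_specs(spec), phantom_background_roi(spec))
    co$mean_contrast[co$radius_mm == 15.9]
  }, 0)
  expect_true(all(diff(mc) < 0))
  expect_true(all(mc > 0 & mc < 100))
})

test_that("gaussian profiles are recovered with the analytic FWHM", {
  x <- seq(0, 120, by = 2)
  prof <- 100 * exp(-(x - 60)^2 / (2 * 16))     # sigma 4 mm
  v <- volume3d(array(rep(prof, 4), c(length(x), 2, 2)), spacing = c(2, 5, 5))
  line <- list(start = c(0, 0, 0), direction = c(1, 0, 0), length = 120,
               step = 2)
  fit <- resolution_fwhm(v, line)
  expect_equal(nrow(fit), 1)
  expect_equal(fit$fwhm_mm, 2 * sqrt(2 * log(2)) * 4, tolerance = 0.05)

  two <- 80 * exp(-(x - 35)^2 / (2 * 9)) + 60 * exp(-(x - 90)^2 / (2 * 25))
  v2 <- volume3d(array(rep(two, 4), c(length(x), 2, 2)), spacing = c(2, 5, 5))
  fit2 <- resolution_fwhm(v2, line)
  expect_equal(nrow(fit2), 2)
  expect_equal(sort(fit2$fwhm_mm),
               2 * sqrt(2 * log(2)) * c(3, 5), tolerance = 0.02 * 11.8)

  flat <- volume3d(array(5, c(40, 2, 2)), spacing = c(2, 5, 5))
  expect_equal(nrow(resolution_fwhm(flat, list(start = c(0, 0, 0),
                                               direction = c(1, 0, 0),
                                               length = 70, step = 2))), 0)
})

test_that("qc reports compare metric-by-metric and reject mismatches", {
  spec <- small_spec()
  vol <- simulate_acquisition(make_phantom(spec)$activity, poisson = FALSE)
  q <- qc_report(vol, spec)
  cmp <- qc_compare(q, q)
  expect_true(all(cmp$delta == 0))

  q2 <- q
  q2$uniformity <- q$uniformity + 1
  cmp2 <- qc_compare(q, q2)
  expect_equal(cmp2$delta[cmp2$metric == "uniformity"], 1)

  q3 <- q
  q3$contrast <- q$contrast[-1, ]
  expect_error(qc_compare(q, q3), "mismatched")
})
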