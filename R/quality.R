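#' Root-mean-square error between two same-grid volumes
#'
#' `rmse` is the square root of the mean over all voxels of the squared
#' count difference between the reference and the registered volume;
#' `mse` is the un-rooted mean. With `per_slice = TRUE` the value is computed
#' per transverse (third-axis) slice and the mean of the slice values is
#' returned, with the slice values in the `"per_slice"` attribute.
#'
#' @param reference,registered [volume3d()]s on the same grid and of the same
#'   value kind.
#' @param per_slice compute slice-wise and average.
#' @return the (root) mean squared error in count units.
#' @export
rmse <- function(reference, registered, per_slice = FALSE) {
  m <- mse(reference, registered, per_slice = per_slice)
  if (!per_slice) return(sqrt(as.numeric(m)))
  sl <- sqrt(attr(m, "per_slice"))
  structure(mean(sl), per_slice = sl)
}

#' @rdname rmse
#' @export
mse <- function(reference, registered, per_slice = FALSE) {
  stopifnot_same_grid(reference, registered)
  if (!identical(reference$value_kind, registered$value_kind))
    stop("value kinds differ", call. = FALSE)
  d2 <- (reference$values - registered$values)^2
  if (!per_slice) return(sum(d2) / length(d2))
  sl <- apply(d2, 3, mean)
  structure(mean(sl), per_slice = sl)
}

#' Percent root-mean-square error (%RMSE)
#'
#' The registration-quality metric: the RMSE between reference and
#' registered volume expressed relative to the total counts of the
#' reference, `100 * rmse / sum(reference)`. An alternative normalization by
#' the per-voxel mean of the reference is available via
#' `normalization = "mean"` (excluded from default reports).
#'
#' @inheritParams rmse
#' @param normalization `"total"` (default) or `"mean"` counts of the
#'   reference.
#' @return %RMSE (dimensionless, percent).
#' @export
percent_rmse <- function(reference, registered,
                         normalization = c("total", "mean")) {
  normalization <- match.arg(normalization)
  tot <- sum(reference$values)
  if (tot <= 0) stop("reference volume has zero total counts", call. = FALSE)
  denom <- if (normalization == "total") tot else tot / length(reference$values)
  100 * rmse(reference, registered) / denom
}

#' Integral uniformity over a cylindrical region
#'
#' IAEA/NEMA-style integral uniformity: each transverse slice intersecting
#' the region is smoothed with a 3x3 mean filter, and
#' `100 * (max - min) / (max + min)` is computed over the in-region voxels;
#' the mean over slices is returned, slice values in the `"per_slice"`
#' attribute.
#'
#' @param volume a [volume3d()].
#' @param region list with `radius` (mm), `z_range` (length-2, world mm) and
#'   optionally `center` (x,y world mm, default c(0,0)); see
#'   [phantom_uniform_region()].
#' @return mean integral uniformity in percent.
#' @export
uniformity <- function(volume, region) {
  d <- dim(volume$values)
  ctr <- region$center %||% c(0, 0)
  zs <- index_to_world(volume, cbind(0, 0, 0:(d[3] - 1)))[, 3]
  ksel <- which(zs >= region$z_range[1] & zs <= region$z_range[2])
  if (length(ksel) == 0) stop("uniformity region is empty", call. = FALSE)
  xw <- index_to_world(volume, cbind(0:(d[1] - 1), 0, 0))[, 1]
  yw <- index_to_world(volume, cbind(0, 0:(d[2] - 1), 0))[, 2]
  inroi <- outer(xw - ctr[1], yw - ctr[2],
                 function(a, b) a^2 + b^2) <= region$radius^2
  if (!any(inroi)) stop("uniformity region is empty", call. = FALSE)
  sm <- smooth_slices_3x3(volume$values[, , ksel, drop = FALSE])
  per_slice <- vapply(seq_along(ksel), function(i) {
    v <- sm[, , i][inroi]
    mx <- max(v); mn <- min(v)
    if (mx + mn == 0) return(0)
    100 * (mx - mn) / (mx + mn)
  }, 0)
  structure(mean(per_slice), per_slice = per_slice, n_slices = length(ksel))
}

#' Cold-sphere contrast against a uniform background
#'
#' For each sphere, the minimum and mean counts inside the sphere mask are
#' compared against the mean counts `B` of a user-defined uniform background
#' region: `max_contrast = 100 (B - min) / B` and
#' `mean_contrast = 100 (B - mean) / B`. Perfectly cold spheres score 100.
#'
#' @param volume a [volume3d()].
#' @param sphere_specs data frame with columns `x`, `y`, `z`, `radius` (world
#'   mm); see [phantom_sphere_specs()].
#' @param background_roi list with `center` (x,y,z mm), `radius` (mm) and
#'   `half_thickness` (mm): a disk-shaped slab of uniform activity.
#' @return tibble with one row per sphere: `sphere`, `radius_mm`,
#'   `max_contrast`, `mean_contrast`.
#' @export
contrast <- function(volume, sphere_specs, background_roi) {
  d <- dim(volume$values)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  pts <- index_to_world(volume, idx)
  b <- background_roi
  bg <- (pts[, 1] - b$center[1])^2 + (pts[, 2] - b$center[2])^2 <= b$radius^2 &
    abs(pts[, 3] - b$center[3]) <= b$half_thickness
  B <- mean(volume$values[bg])
  if (!is.finite(B) || B <= 0)
    stop("background ROI mean is zero or empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(sphere_specs)), function(s) {
    sp <- sphere_specs[s, ]
    m <- (pts[, 1] - sp$x)^2 + (pts[, 2] - sp$y)^2 + (pts[, 3] - sp$z)^2 <=
      sp$radius^2
    if (!any(m)) return(NULL)
    v <- volume$values[m]
    tibble::tibble(sphere = s, radius_mm = sp$radius,
                   max_contrast = 100 * (B - min(v)) / B,
                   mean_contrast = 100 * (B - mean(v)) / B)
  })
  do.call(rbind, rows)
}

#' Sample a straight-line count profile through a volume
#'
#' @param volume a [volume3d()].
#' @param line list with `start` (world mm), `direction` (mm vector, will be
#'   normalized), `length` (mm) and optionally `step` (mm, default the
#'   smallest voxel spacing).
#' @return tibble with `distance_mm` and `value` (trilinear samples; samples
#'   outside the field of view are dropped).
#' @export
sample_profile <- function(volume, line) {
  step <- line$step %||% min(volume$spacing)
  u <- line$direction / sqrt(sum(line$direction^2))
  s <- seq(0, line$length, by = step)
  pts <- outer(s, u) + matrix(line$start, length(s), 3, byrow = TRUE)
  idx <- world_to_index(volume, pts)
  d <- dim(volume$values)
  # trilinear via the resampler on an n x 1 x 1 synthetic grid
  M <- matrix(0, 3, 4)
  M[, 4] <- idx[1, ]
  M[, 1] <- idx[2, ] - idx[1, ]
  res <- cpp_affine_resample(as.numeric(volume$values), d,
                             c(length(s), 1L, 1L), M, 0L)
  tibble::tibble(distance_mm = s[res$valid], value = res$values[res$valid])
}

#' Resolution from a rod-profile multi-Gaussian fit
#'
#' Samples a line profile and fits it as a constant baseline plus k upright
#' or inverted Gaussians, one per detected peak. Peaks are local extrema of
#' the baseline-subtracted profile exceeding 3 times the robust noise level
#' (MAD of first differences), separated by at least `min_separation_mm`.
#' The FWHM of each fitted Gaussian, `2 sqrt(2 ln 2) sigma`, is reported in
#' mm. Non-converging fits are reported with `converged = FALSE`, never as
#' an error.
#'
#' @param volume a [volume3d()].
#' @param line profile specification as for [sample_profile()].
#' @param min_separation_mm minimum separation between detected peaks
#'   (typically one rod diameter).
#' @param expected_centers_mm optional known peak positions (mm from the
#'   profile start): skips detection and anchors one Gaussian per centre.
#'   Used by [qc_report()], where the rod positions follow from the phantom
#'   geometry; automatic detection assumes the profile has a visible
#'   baseline between peaks, which densely packed blurred rods do not.
#' @return tibble with `center_mm`, `fwhm_mm`, `amplitude`, `converged`; zero
#'   rows when no peak is detected.
#' @export
resolution_fwhm <- function(volume, line, min_separation_mm = 8,
                            expected_centers_mm = NULL) {
  prof <- sample_profile(volume, line)
  x <- prof$distance_mm; y <- prof$value
  empty <- tibble::tibble(center_mm = numeric(), fwhm_mm = numeric(),
                          amplitude = numeric(), converged = logical())
  if (length(y) < 7) return(empty)
  if (!is.null(expected_centers_mm)) {
    inverted <- TRUE
    base <- stats::quantile(y, 0.9, names = FALSE)
    r <- y - base
    keep <- vapply(expected_centers_mm, function(cm) which.min(abs(x - cm)),
                   0L)
  } else {
    # polarity: cold rods are dips from a hot baseline, point sources are
    # upright peaks from a cold baseline; anchor the baseline on the quiet
    # side
    med <- stats::median(y)
    inverted <- (med - min(y)) > (max(y) - med)
    base <- stats::quantile(y, if (inverted) 0.9 else 0.1, names = FALSE)
    r <- y - base
    # diff-based noise floors near zero on noiseless profiles; the
    # prominence term keeps structured baselines from drowning real extrema
    noise <- stats::mad(diff(y)) / sqrt(2)
    thr <- max(3 * noise, 0.3 * max(abs(r)), 1e-12)
    n <- length(r)
    is_ext <- abs(r) >= thr &
      c(FALSE, abs(r[2:(n - 1)]) >= abs(r[1:(n - 2)]) &
          abs(r[2:(n - 1)]) >= abs(r[3:n]), FALSE)
    cand <- which(is_ext)
    if (length(cand) == 0) return(empty)
    # greedy: strongest first, enforce separation
    cand <- cand[order(-abs(r[cand]))]
    keep <- integer()
    for (i in cand)
      if (all(abs(x[i] - x[keep]) >= min_separation_mm)) keep <- c(keep, i)
    keep <- sort(keep)
  }
  k <- length(keep)
  step <- stats::median(diff(x))
  start <- c(b0 = base)
  lower <- c(-Inf)
  upper <- c(Inf)
  form <- "y ~ b0"
  for (j in seq_len(k)) {
    form <- paste0(form, sprintf(
      " + a%d * exp(-(x - m%d)^2 / (2 * s%d^2))", j, j, j))
    start <- c(start, stats::setNames(r[keep[j]], paste0("a", j)),
               stats::setNames(x[keep[j]], paste0("m", j)),
               stats::setNames(2 * step, paste0("s", j)))
    lower <- c(lower, -Inf, x[keep[j]] - min_separation_mm, step / 4)
    upper <- c(upper, Inf, x[keep[j]] + min_separation_mm, diff(range(x)) / 2)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form),
                      data = data.frame(x = x, y = y),
                      start = as.list(start), lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble::tibble(center_mm = x[keep], fwhm_mm = NA_real_,
                          amplitude = r[keep], converged = FALSE))
  }
  cf <- stats::coef(fit)
  tibble::tibble(
    center_mm = unname(cf[paste0("m", seq_len(k))]),
    fwhm_mm = 2 * sqrt(2 * log(2)) * abs(unname(cf[paste0("s", seq_len(k))])),
    amplitude = unname(cf[paste0("a", seq_len(k))]),
    converged = TRUE)
}

#' Phantom-derived regions for quality-control metrics
#'
#' Helpers mapping a [phantom_spec()] to the regions the QC metrics need:
#' the uniform-compartment cylinder (eroded to 75% of the phantom radius, in
#' the band between the rod sectors and the sphere plane), the cold-sphere
#' positions, a central background disk in the sphere plane, and a profile
#' line along a rod row of the widest rod sector.
#'
#' @param spec a [phantom_spec()].
#' @param radius_fraction fraction of the cylinder radius kept in the
#'   uniformity region (central field of view).
#' @return `phantom_uniform_region`: a region list for [uniformity()].
#' @export
phantom_uniform_region <- function(spec, radius_fraction = 0.75) {
  hz <- spec$cylinder_height / 2
  zlo <- -hz + spec$rod_length + 12
  zhi <- spec$sphere_plane_z - max(spec$sphere_radii) - 12
  list(radius = radius_fraction * spec$cylinder_radius,
       z_range = c(zlo, zhi), center = c(0, 0))
}

#' @rdname phantom_uniform_region
#' @return `phantom_sphere_specs`: data frame of sphere centres and radii.
#' @export
phantom_sphere_specs <- function(spec) {
  ns <- length(spec$sphere_radii)
  th <- (seq_len(ns) - 1) * 2 * pi / ns
  data.frame(x = spec$sphere_ring_radius * cos(th),
             y = spec$sphere_ring_radius * sin(th),
             z = spec$sphere_plane_z, radius = spec$sphere_radii)
}

#' @rdname phantom_uniform_region
#' @return `phantom_background_roi`: background region list for [contrast()].
#' @export
phantom_background_roi <- function(spec) {
  list(center = c(0, 0, spec$sphere_plane_z), radius = 25, half_thickness = 10)
}

#' @rdname phantom_uniform_region
#' @param sector rod sector to profile (default the widest rods).
#' @return `phantom_rod_profile_line`: line specification for
#'   [resolution_fwhm()], following a lattice row of rod centres.
#' @export
phantom_rod_profile_line <- function(spec, sector = NULL) {
  rods <- spec$rods
  sector <- sector %||% rods$sector[which.max(rods$diameter)]
  rs <- rods[rods$sector == sector, ]
  # lattice rows have constant y; profile the row with the most rods
  yr <- as.numeric(names(sort(table(round(rs$y, 6)), decreasing = TRUE))[1])
  row <- rs[abs(rs$y - yr) < 1e-6, ]
  row <- row[order(row$x), ]
  d <- row$diameter[1]
  zmid <- -spec$cylinder_height / 2 + spec$rod_length / 2
  # pad by one diameter but stay clear of the cylinder edge falloff
  xmax_in <- sqrt(spec$cylinder_radius^2 - yr^2) - 1.5 * d
  x0 <- max(min(row$x) - d, -xmax_in)
  x1 <- min(max(row$x) + d, xmax_in)
  list(start = c(x0, yr, zmid), direction = c(1, 0, 0), length = x1 - x0,
       rod_diameter = d, n_rods = nrow(row), centers_mm = row$x - x0)
}

#' Phantom quality-control report
#'
#' Computes uniformity, cold-sphere contrast and rod-resolution FWHM for one
#' volume using the regions derived from the phantom specification.
#'
#' @param volume a [volume3d()] (counts).
#' @param spec the [phantom_spec()] describing the imaged phantom.
#' @param metadata named list stored with the report (study id, angle, ...).
#' @return object of class `qc_report`: `uniformity`, `contrast` (tibble),
#'   `resolution` (tibble), `metadata`.
#' @export
qc_report <- function(volume, spec, metadata = list()) {
  line <- phantom_rod_profile_line(spec)
  structure(list(
    uniformity = as.numeric(uniformity(volume, phantom_uniform_region(spec))),
    contrast = contrast(volume, phantom_sphere_specs(spec),
                        phantom_background_roi(spec)),
    resolution = resolution_fwhm(volume, line,
                                 min_separation_mm = line$rod_diameter * 2,
                                 expected_centers_mm = line$centers_mm),
    metadata = metadata), class = "qc_report")
}

#' Compare two quality-control reports
#'
#' @param before,after `qc_report` objects with matching metric sets.
#' @return tibble with `metric`, `before`, `after`, `delta`,
#'   `relative_change` (fraction of `before`).
#' @export
qc_compare <- function(before, after) {
  flat <- function(q) {
    v <- c(uniformity = q$uniformity)
    if (!is.null(q$contrast)) {
      v <- c(v,
             stats::setNames(q$contrast$max_contrast,
                             paste0("max_contrast_sphere", q$contrast$sphere)),
             stats::setNames(q$contrast$mean_contrast,
                             paste0("mean_contrast_sphere", q$contrast$sphere)))
    }
    res <- q$resolution
    if (!is.null(res) && nrow(res) > 0)
      v <- c(v, stats::setNames(res$fwhm_mm,
                                sprintf("fwhm_rod%d", seq_len(nrow(res)))))
    v
  }
  a <- flat(before); b <- flat(after)
  if (!identical(names(a), names(b)))
    stop("QC reports have mismatched metric sets", call. = FALSE)
  tibble::tibble(metric = names(a), before = unname(a), after = unname(b),
                 delta = unname(b - a),
                 relative_change = unname(ifelse(a == 0, NA_real_,
                                                 (b - a) / a)))
}
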