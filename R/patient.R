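#' Ground-truth double-exponential kinetics for a simulated region
#'
#' Describes an organ's activity over time: a linear uptake ramp from zero at
#' injection (t = 0) to the peak at `ramp_peak_h`, followed by
#' `A1 exp(-lambda1 t) + A2 exp(-lambda2 t)` (absolute time). Amplitudes are
#' the organ totals in MBq; the simulator distributes them uniformly over the
#' organ volume.
#'
#' @param A1,A2 amplitudes, MBq (>= 0).
#' @param lambda1,lambda2 decay constants, 1/h (> 0).
#' @param ramp_peak_h end of the uptake ramp, hours; `NULL` means the first
#'   acquisition time of the series being simulated.
#' @return an object of class `kinetic_ground_truth`.
#' @export
kinetic_ground_truth <- function(A1 = 10, lambda1 = 0.1, A2 = 5,
                                 lambda2 = 0.01, ramp_peak_h = NULL) {
  if (lambda1 <= 0 || lambda2 <= 0)
    stop("decay constants must be positive", call. = FALSE)
  if (A1 < 0 || A2 < 0) stop("amplitudes must be non-negative", call. = FALSE)
  structure(list(A1 = A1, lambda1 = lambda1, A2 = A2, lambda2 = lambda2,
                 ramp_peak_h = ramp_peak_h),
            class = "kinetic_ground_truth")
}

#' Serialize ground-truth kinetics to JSON or YAML
#'
#' @param kinetics a [kinetic_ground_truth()].
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @return `write_kinetic_ground_truth`: `path`, invisibly;
#'   `read_kinetic_ground_truth`: a [kinetic_ground_truth()].
#' @export
write_kinetic_ground_truth <- function(kinetics, path) {
  fields <- unclass(kinetics)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output", call. = FALSE)
    yaml::write_yaml(fields, path)
  } else {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_kinetic_ground_truth
#' @export
read_kinetic_ground_truth <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(kinetic_ground_truth, fields[!vapply(fields, is.null, TRUE)])
}

# Organ activity (MBq) at time t (vectorized over t).
kinetics_activity <- function(k, t, peak_h) {
  decayed <- k$A1 * exp(-k$lambda1 * t) + k$A2 * exp(-k$lambda2 * t)
  peak_val <- k$A1 * exp(-k$lambda1 * peak_h) + k$A2 * exp(-k$lambda2 * peak_h)
  ifelse(t < peak_h, peak_val * t / peak_h, decayed)
}

# Closed-form time-integrated activity (MBq h): triangular uptake plus the
# analytic exponential tail from the peak to infinity.
kinetics_tia_h <- function(k, peak_h) {
  peak_val <- k$A1 * exp(-k$lambda1 * peak_h) + k$A2 * exp(-k$lambda2 * peak_h)
  0.5 * peak_h * peak_val +
    k$A1 / k$lambda1 * exp(-k$lambda1 * peak_h) +
    k$A2 / k$lambda2 * exp(-k$lambda2 * peak_h)
}

#' Default organ geometry for the simulated patient
#'
#' Two kidney ellipsoids, a liver sphere with slower washout, a water body
#' cylinder and a bone (spine) cylinder for the CT. Geometry is in world mm
#' on a grid centred at the origin.
#'
#' @return list of organ descriptors (`name`, `type`, geometry, `kinetics`
#'   where radioactive, `hu`).
#' @export
default_patient_organs <- function() {
  list(
    list(name = "kidney_left", type = "ellipsoid",
         center = c(-45, 20, -10), semiaxes = c(15, 15, 25),
         kinetics = kinetic_ground_truth(), hu = 30),
    list(name = "kidney_right", type = "ellipsoid",
         center = c(45, 20, -10), semiaxes = c(15, 15, 25),
         kinetics = kinetic_ground_truth(), hu = 30),
    list(name = "liver", type = "ellipsoid",
         center = c(55, -25, 35), semiaxes = c(32, 28, 30),
         kinetics = kinetic_ground_truth(A1 = 8, lambda1 = 0.08,
                                         A2 = 4, lambda2 = 0.012),
         hu = 50),
    list(name = "body", type = "cylinder", radius = 100, height = 220,
         center = c(0, 0, 0), hu = 0),
    list(name = "spine", type = "cylinder", radius = 12, height = 220,
         center = c(0, -60, 0), hu = 800))
}

organ_mask <- function(organ, pts) {
  if (organ$type == "ellipsoid") {
    d <- sweep(pts, 2, organ$center)
    rowSums(sweep(d, 2, organ$semiaxes, "/")^2) <= 1
  } else {
    d <- sweep(pts, 2, organ$center)
    d[, 1]^2 + d[, 2]^2 <= organ$radius^2 & abs(d[, 3]) <= organ$height / 2
  }
}

#' Simulate a serial patient-like SPECT/CT study with known kinetics
#'
#' Builds a four-plus-time-point SPECT series in which each radioactive organ
#' follows its ground-truth ramp-plus-double-exponential kinetics, together
#' with a CT containing at least one bone region (HU >= 300), the closed-form
#' per-voxel time-integrated activity map, and the organ masks. The analytic
#' TIA map is blurred with the same point-spread function as the simulated
#' acquisitions (blurring commutes with time integration), so it remains an
#' exact reference for the noiseless pipeline.
#'
#' Counts are derived from activity through `calibration` (MBq per count);
#' optional Poisson noise is applied per time point.
#'
#' @param organs organ list as from [default_patient_organs()].
#' @param times_h acquisition times, hours post-injection, strictly
#'   increasing, at least 4 (default the typical 1.5 / 5 / 24 / 240 h
#'   schedule).
#' @param grid_shape,voxel_spacing output grid (default 64^3 at 4 mm).
#' @param psf_fwhm_mm acquisition PSF (mm); 0 disables blurring.
#' @param calibration a [calibration_factor()] (MBq per count).
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed used when `noise = "poisson"`.
#' @return list with `series` (list of counts [volume3d()]s with acquisition
#'   times), `ct`, `analytic_tia` ([volume3d()], MBq s), `organ_masks`
#'   (named list of logical arrays), `organs`, `calibration`, `times_h`.
#' @export
make_patient_series <- function(organs = default_patient_organs(),
                                times_h = c(1.5, 5, 24, 240),
                                grid_shape = c(64, 64, 64),
                                voxel_spacing = 4.0,
                                psf_fwhm_mm = 10,
                                calibration = calibration_factor(5e-5),
                                noise = c("none", "poisson"),
                                seed = 1L) {
  noise <- match.arg(noise)
  if (length(times_h) < 4) stop("need at least 4 time points", call. = FALSE)
  if (any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing", call. = FALSE)
  if (length(voxel_spacing) == 1) voxel_spacing <- rep(voxel_spacing, 3)
  n <- as.integer(grid_shape)
  origin <- -(n - 1) / 2 * voxel_spacing
  ax <- lapply(1:3, function(a) origin[a] + voxel_spacing[a] * (seq_len(n[a]) - 1))
  pts <- cbind(rep(ax[[1]], times = n[2] * n[3]),
               rep(rep(ax[[2]], each = n[1]), times = n[3]),
               rep(ax[[3]], each = n[1] * n[2]))
  vvol_ml <- prod(voxel_spacing) / 1000

  hu <- rep(-1000, nrow(pts))
  masks <- list()
  hot <- list()
  for (org in organs) {
    m <- organ_mask(org, pts)
    hu[m] <- org$hu  # later organs overwrite earlier ones (body first in list order is not assumed)
    masks[[org$name]] <- m
    if (!is.null(org$kinetics)) hot[[org$name]] <- org
  }
  # body/background must not overwrite organs: reapply radioactive organs' HU
  for (org in organs) if (!is.null(org$kinetics)) hu[masks[[org$name]]] <- org$hu

  sigma_vox <- if (psf_fwhm_mm > 0) psf_fwhm_mm * FWHM_TO_SIGMA / voxel_spacing
               else rep(0, 3)
  blur <- function(v) {
    if (all(sigma_vox <= 0)) return(v)
    gaussian_blur_fft(array(v, n), sigma_vox)
  }

  conc <- function(org, t) {
    k <- org$kinetics
    peak <- k$ramp_peak_h %||% times_h[1]
    vol_ml <- sum(masks[[org$name]]) * vvol_ml
    kinetics_activity(k, t, peak) / vol_ml
  }

  series <- lapply(times_h, function(t) {
    act <- numeric(nrow(pts))
    for (org in hot) act[masks[[org$name]]] <- conc(org, t) * vvol_ml
    counts <- blur(act) / calibration$mbq_per_count
    if (noise == "poisson")
      counts <- with_seed(seed * 1000L + round(t * 10),
                          array(stats::rpois(length(counts), counts), n))
    volume3d(array(counts, n), spacing = voxel_spacing, origin = origin,
             value_kind = "counts", acquisition_time_h = t)
  })

  tia_h <- numeric(nrow(pts))
  for (org in hot) {
    k <- org$kinetics
    peak <- k$ramp_peak_h %||% times_h[1]
    vol_ml <- sum(masks[[org$name]]) * vvol_ml
    tia_h[masks[[org$name]]] <- kinetics_tia_h(k, peak) / vol_ml * vvol_ml
  }
  analytic_tia <- volume3d(blur(tia_h) * 3600, spacing = voxel_spacing,
                           origin = origin, value_kind = "tia_MBq_s")
  ct <- volume3d(array(hu, n), spacing = voxel_spacing, origin = origin,
                 value_kind = "HU")
  list(series = series, ct = ct, analytic_tia = analytic_tia,
       organ_masks = lapply(masks, function(m) array(m, n)),
       organs = organs, calibration = calibration, times_h = times_h)
}
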