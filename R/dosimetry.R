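RADIONUCLIDES <- c("I131", "Lu177", "Y90")

# Physical half-lives in hours, used for the last-resort decay fallback.
RADIONUCLIDE_HALF_LIFE_H <- c(I131 = 192.5, Lu177 = 159.5, Y90 = 64.05)

#' Segment bone from a CT volume
#'
#' Thresholds the CT at `cutoff_hu` (inclusive: a voxel exactly at the
#' cutoff is bone). The default of 300 HU separates bone from soft tissue
#' for kernel selection.
#'
#' @param ct a [volume3d()] of kind `"HU"`, already on the dose grid.
#' @param cutoff_hu threshold in Hounsfield units.
#' @return logical array the shape of the CT (`TRUE` = bone), class
#'   `tissue_mask` with the grid geometry in attributes.
#' @export
segment_bone <- function(ct, cutoff_hu = 300) {
  if (!identical(ct$value_kind, "HU"))
    stop("segment_bone expects a CT volume in Hounsfield units", call. = FALSE)
  m <- ct$values >= cutoff_hu
  attr(m, "spacing") <- ct$spacing
  attr(m, "cutoff_hu") <- cutoff_hu
  class(m) <- c("tissue_mask", class(m))
  m
}

#' Generate a synthetic voxel S-value kernel
#'
#' Builds an analytic stand-in dose-point kernel: a central self-dose term
#' (local deposition of the mean beta energy in the source voxel mass) plus
#' an exponential radial fall-off with inverse-square geometry for the
#' cross-dose, attenuated more strongly — and scaled down by density — in
#' bone. Values are mGy per MBq s in the source voxel. These kernels have
#' the right shape, ordering and rough magnitude for testing the dosimetry
#' chain; they are synthetic and explicitly not for clinical use
#' (provenance field says so).
#'
#' @param radionuclide `"I131"`, `"Lu177"` or `"Y90"`.
#' @param spacing_mm isotropic voxel spacing of the target grid, mm.
#' @param table_side odd number of voxels per kernel axis.
#' @param medium `"soft_tissue"` or `"bone"`.
#' @param params optional overrides: `mean_beta_MeV`, `local_fraction`,
#'   `cross_fraction`, `mu_soft_mm`, `mu_bone_mm`, `bone_density`.
#' @return object of class `dose_kernel`.
#' @export
generate_toy_kernel <- function(radionuclide = RADIONUCLIDES,
                                spacing_mm = 4, table_side = 9,
                                medium = c("soft_tissue", "bone"),
                                params = list()) {
  radionuclide <- match.arg(radionuclide)
  medium <- match.arg(medium)
  if (table_side %% 2 == 0) stop("table_side must be odd", call. = FALSE)
  defaults <- list(
    mean_beta_MeV = c(I131 = 0.182, Lu177 = 0.133, Y90 = 0.935)[[radionuclide]],
    local_fraction = 0.90, cross_fraction = 0.04,
    mu_soft_mm = c(I131 = 0.35, Lu177 = 0.45, Y90 = 0.15)[[radionuclide]],
    mu_bone_mm = NULL, bone_density = 1.3)
  p <- utils::modifyList(defaults, params)
  p$mu_bone_mm <- p$mu_bone_mm %||% (p$mu_soft_mm * p$bone_density)
  density <- if (medium == "bone") p$bone_density else 1.0
  mu <- if (medium == "bone") p$mu_bone_mm else p$mu_soft_mm
  mass_kg <- density * spacing_mm^3 * 1e-6          # 1 mm^3 water = 1e-6 kg
  joule_per_decay <- p$mean_beta_MeV * 1.602176634e-13
  s0 <- 1e6 * joule_per_decay * p$local_fraction / mass_kg * 1e3  # mGy/(MBq s)
  half <- (table_side - 1) / 2
  off <- (-half:half) * spacing_mm
  dist <- sqrt(outer(outer(off^2, off^2, "+"), off^2, "+"))
  dim(dist) <- rep(table_side, 3)
  k <- array(0, rep(table_side, 3))
  nz <- dist > 0
  k[nz] <- s0 * p$cross_fraction * exp(-mu * (dist[nz] - spacing_mm)) *
    (spacing_mm / dist[nz])^2
  k[!nz] <- s0
  structure(list(radionuclide = radionuclide,
                 voxel_spacing = rep(spacing_mm, 3), medium = medium,
                 values = k,
                 provenance = "synthetic toy kernel - not for clinical use"),
            class = "dose_kernel")
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat(sprintf("<dose_kernel> %s / %s, %d^3 at %.3g mm, S0 = %.4g mGy/(MBq s)\n",
              x$radionuclide, x$medium, dim(x$values)[1], x$voxel_spacing[1],
              max(x$values)))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read / write a dose kernel as JSON
#'
#' The kernel file is a JSON object with the radionuclide, voxel spacing,
#' medium, provenance, array dimensions and the flattened (column-major)
#' values — plain text, self-describing, diff-able.
#'
#' @param kernel a `dose_kernel`.
#' @param path file path.
#' @return `write_dose_kernel` the path, invisibly; `read_dose_kernel` a
#'   `dose_kernel`.
#' @export
write_dose_kernel <- function(kernel, path) {
  jsonlite::write_json(list(
    radionuclide = kernel$radionuclide,
    voxel_spacing_mm = kernel$voxel_spacing,
    medium = kernel$medium, provenance = kernel$provenance,
    dim = dim(kernel$values), values = as.numeric(kernel$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_kernel
#' @export
read_dose_kernel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- array(x$values, x$dim)
  if (any(x$dim %% 2 == 0)) stop("kernel table sides must be odd", call. = FALSE)
  if (any(v < 0)) stop("kernel values must be non-negative", call. = FALSE)
  ctr <- (x$dim + 1) / 2
  if (v[ctr[1], ctr[2], ctr[3]] < max(v))
    stop("kernel centre (self-dose) must be the maximum", call. = FALSE)
  structure(list(radionuclide = x$radionuclide,
                 voxel_spacing = x$voxel_spacing_mm, medium = x$medium,
                 values = v, provenance = x$provenance),
            class = "dose_kernel")
}

#' Dose map by voxel S-value kernel convolution
#'
#' Computes `dose(v) = sum_s TIA(s) K_medium(s)(v - s)`: source voxels are
#' split by their tissue (bone vs soft, from the mask), each group is
#' convolved with its medium's kernel by zero-padded FFT, and the results
#' are summed. The operation is linear in TIA; boundary handling is zero
#' padding (no wrap-around). Kernel spacing must match the TIA grid —
#' mismatches are an error, never silently resampled.
#'
#' @param tia a [volume3d()] of kind `"tia_MBq_s"`.
#' @param kernels a single `dose_kernel` (single-medium case) or a named
#'   list with elements `soft_tissue` and `bone`.
#' @param tissue a [segment_bone()] mask (required with two kernels).
#' @return a [volume3d()] of kind `"dose_mGy"`.
#' @export
convolve_dose <- function(tia, kernels, tissue = NULL) {
  if (inherits(kernels, "dose_kernel")) kernels <- list(soft_tissue = kernels)
  for (k in kernels)
    if (max(abs(k$voxel_spacing - tia$spacing)) > 1e-6)
      stop(sprintf(
        "kernel spacing (%s mm) does not match the TIA grid (%s mm)",
        paste(signif(k$voxel_spacing, 4), collapse = "x"),
        paste(signif(tia$spacing, 4), collapse = "x")), call. = FALSE)
  two_media <- length(kernels) > 1
  if (two_media) {
    if (is.null(tissue))
      stop("a tissue mask is required with separate bone and soft-tissue kernels",
           call. = FALSE)
    if (!identical(dim(tissue), dim(tia$values)))
      stop("tissue mask shape does not match the TIA grid", call. = FALSE)
    if (!all(c("soft_tissue", "bone") %in% names(kernels)))
      stop("kernels must be named soft_tissue and bone", call. = FALSE)
  }
  d <- dim(tia$values)
  groups <- if (two_media) {
    list(list(src = tia$values * !tissue, k = kernels$soft_tissue),
         list(src = tia$values * tissue, k = kernels$bone))
  } else list(list(src = tia$values, k = kernels[[1]]))
  dose <- array(0, d)
  for (g in groups) {
    if (all(g$src == 0)) next
    dose <- dose + fft_convolve3(g$src, g$k$values)
  }
  new_volume_like(tia, pmax(dose, 0), value_kind = "dose_mGy",
                  acquisition_time_h = NA_real_)
}

# Zero-padded linear convolution with an odd-sided centred kernel via FFT,
# cropped to the input size. Pad sizes are rounded up to 2-3-5-smooth
# lengths for FFT speed.
fft_convolve3 <- function(x, k) {
  d <- dim(x); kd <- dim(k)
  P <- vapply(seq_len(3), function(a) stats::nextn(d[a] + kd[a] - 1, c(2, 3, 5)),
              0L)
  X <- array(0, P); X[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  K <- array(0, P)
  ctr <- (kd - 1) / 2
  ix <- ((seq_len(kd[1]) - 1 - ctr[1]) %% P[1]) + 1
  iy <- ((seq_len(kd[2]) - 1 - ctr[2]) %% P[2]) + 1
  iz <- ((seq_len(kd[3]) - 1 - ctr[3]) %% P[3]) + 1
  K[ix, iy, iz] <- k
  out <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / prod(P)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

#' Brute-force dose reference by direct triple-loop convolution
#'
#' The independent oracle for [convolve_dose()]: the same sum evaluated
#' directly in the spatial domain. Used for validation and for analytic dose
#' references on synthetic studies.
#'
#' @inheritParams convolve_dose
#' @return a [volume3d()] of kind `"dose_mGy"`.
#' @export
brute_force_dose <- function(tia, kernels, tissue = NULL) {
  if (inherits(kernels, "dose_kernel")) kernels <- list(soft_tissue = kernels)
  d <- dim(tia$values)
  groups <- if (length(kernels) > 1) {
    list(list(src = tia$values * !tissue, k = kernels$soft_tissue),
         list(src = tia$values * tissue, k = kernels$bone))
  } else list(list(src = tia$values, k = kernels[[1]]))
  dose <- array(0, d)
  for (g in groups)
    dose <- dose + array(cpp_conv3_direct(as.numeric(g$src), d,
                                          as.numeric(g$k$values),
                                          dim(g$k$values)), d)
  new_volume_like(tia, dose, value_kind = "dose_mGy",
                  acquisition_time_h = NA_real_)
}

#' Volume of interest at a fraction of the maximum dose
#'
#' Finds the maximum dose within the organ region, keeps the voxels at or
#' above `cutoff_fraction` of it (inclusive at the boundary), and takes the
#' 26-connected component containing the maximum voxel as the VOI.
#'
#' @param dose a [volume3d()] of kind `"dose_mGy"`.
#' @param organ_region logical array (coarse organ mask) or a world point
#'   (mm), in which case a ball of `seed_radius_mm` around it is used.
#' @param cutoff_fraction fraction of the regional maximum (default 0.40).
#' @param seed_radius_mm radius of the ball built around a seed point.
#' @return object of class `voi_stats`: `mask`, `mean_dose`, `max_dose`
#'   (mGy), `volume_ml`, `n_voxels`, `cutoff_fraction`.
#' @export
voi_by_cutoff <- function(dose, organ_region, cutoff_fraction = 0.40,
                          seed_radius_mm = 40) {
  d <- dim(dose$values)
  if (is.numeric(organ_region) && length(organ_region) == 3) {
    idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                 k = 0:(d[3] - 1)))
    pts <- index_to_world(dose, idx)
    organ_region <- array(
      rowSums(sweep(pts, 2, organ_region)^2) <= seed_radius_mm^2, d)
  }
  if (!any(organ_region)) stop("organ region is empty", call. = FALSE)
  v <- dose$values
  mx <- max(v[organ_region])
  if (mx <= 0) stop("no dose inside the organ region", call. = FALSE)
  thr <- cutoff_fraction * mx
  supra <- organ_region & v >= thr
  lab <- array(cpp_label26(supra, d), d)
  peak_idx <- which(organ_region & v == mx)[1]
  voi <- lab == lab[peak_idx]
  structure(list(mask = voi, mean_dose = mean(v[voi]), max_dose = mx,
                 volume_ml = sum(voi) * prod(dose$spacing) / 1000,
                 n_voxels = sum(voi), cutoff_fraction = cutoff_fraction),
            class = "voi_stats")
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf(
    "<voi_stats> %d voxels (%.2f mL) at >= %.0f%% of max: mean %.4g mGy, max %.4g mGy\n",
    x$n_voxels, x$volume_ml, 100 * x$cutoff_fraction, x$mean_dose, x$max_dose))
  invisible(x)
}

#' Pearson correlation between paired dose estimates
#'
#' @param a,b paired numeric vectors (n >= 3, finite).
#' @return the product-moment correlation coefficient.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance input", call. = FALSE)
  stats::cor(a, b)
}

#' Bland-Altman agreement analysis for paired dose estimates
#'
#' Differences are `a - b`. Limits of agreement are the mean difference
#' plus/minus 1.96 standard deviations.
#'
#' @param a,b paired numeric vectors (n >= 2).
#' @return object of class `bland_altman`: `table` (tibble with `mean` and
#'   `difference` per pair), `mean_difference`, `sd_difference`,
#'   `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(
    table = tibble::tibble(mean = (a + b) / 2, difference = d),
    mean_difference = md, sd_difference = sdd,
    loa_lower = md - 1.96 * sdd, loa_upper = md + 1.96 * sdd),
    class = "bland_altman")
}

#' Plot a Bland-Altman analysis
#'
#' @param x a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(x$table, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = x$mean_difference, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(x$loa_lower, x$loa_upper),
                        linetype = 3) +
    ggplot2::labs(x = "Mean of methods (mGy)",
                  y = "Difference (mGy)",
                  title = "Bland-Altman agreement")
}
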