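#' Specify a Jaszczak-style cylindrical phantom
#'
#' Defines the geometry and fill of a digital quality-control phantom: a
#' uniform cylindrical compartment of radioactive solution, cold (inactive)
#' spheres on a ring near the top, cold rod sectors near the bottom, and an
#' optional external fiducial source. All geometry is in mm, world
#' coordinates, with the cylinder axis along +z (the bed axis) and the
#' cylinder centred at the world origin.
#'
#' The default fill emulates 740.0 MBq of Tc-99m pertechnetate diluted in
#' 6.1 L of water (concentration 740/6100 MBq/mL). When `cylinder_height` is
#' `NULL` it is derived so that the fillable (hot) volume — cylinder minus
#' cold inserts — equals `fill_volume_ml`, making the default total activity
#' 740 MBq by construction. Sphere and rod diameters are nominal
#' Jaszczak-class values and fully configurable; they are not calibrated to
#' any particular physical insert.
#'
#' @param cylinder_radius cylinder interior radius, mm.
#' @param cylinder_height cylinder interior height, mm, or `NULL` to derive
#'   from `fill_volume_ml`.
#' @param fill_volume_ml target fillable volume (mL) used when
#'   `cylinder_height` is `NULL`.
#' @param activity_concentration activity concentration of the fill, MBq/mL.
#' @param sphere_radii radii (mm) of the cold spheres, placed on a ring of
#'   radius `sphere_ring_radius` at `sphere_plane_z` (defaults 40 mm below the
#'   cylinder top).
#' @param rod_sector_diameters rod diameters (mm), one fan sector per entry;
#'   rods are cold, packed on a triangular lattice at twice their diameter,
#'   spanning `rod_length` mm from the cylinder bottom.
#' @param fiducial `NULL`, or a list with `volume_ml`, `position` (mm, must be
#'   outside the cylinder), and optionally `concentration` (MBq/mL, default
#'   the fill concentration: the marker is filled from the same solution).
#' @param grid_shape voxels per axis (>= 32 each).
#' @param voxel_spacing mm per axis (scalar or length 3).
#' @param sphere_ring_radius,sphere_plane_z,rod_length geometry details, mm.
#' @param shell_thickness acrylic shell thickness (mm) used for the CT volume.
#' @param hu HU values used for the companion CT: named list with `air`,
#'   `water`, `acrylic`, `bone`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(cylinder_radius = 108,
                         cylinder_height = NULL,
                         fill_volume_ml = 6100,
                         activity_concentration = 740 / 6100,
                         sphere_radii = c(6.35, 7.95, 9.55, 12.7, 15.9),
                         rod_sector_diameters = c(6.4, 7.9, 9.5, 11.1),
                         fiducial = list(volume_ml = 3.0,
                                         position = c(138, 0, 0)),
                         grid_shape = c(128, 128, 128),
                         voxel_spacing = 4.0,
                         sphere_ring_radius = 60,
                         sphere_plane_z = NULL,
                         rod_length = 70,
                         shell_thickness = 10,
                         hu = list(air = -1000, water = 0, acrylic = 120,
                                   bone = 800)) {
  if (length(voxel_spacing) == 1) voxel_spacing <- rep(voxel_spacing, 3)
  if (any(grid_shape < 32))
    stop("phantom_spec: grid_shape must be at least 32 voxels per axis",
         call. = FALSE)
  if (cylinder_radius <= 0 || any(sphere_radii <= 0) ||
      any(rod_sector_diameters <= 0))
    stop("phantom_spec: all radii and diameters must be positive", call. = FALSE)
  spec <- list(cylinder_radius = cylinder_radius,
               activity_concentration = activity_concentration,
               sphere_radii = sphere_radii,
               rod_sector_diameters = rod_sector_diameters,
               fiducial = fiducial, grid_shape = as.integer(grid_shape),
               voxel_spacing = voxel_spacing,
               sphere_ring_radius = sphere_ring_radius,
               rod_length = rod_length, shell_thickness = shell_thickness,
               hu = hu)
  # Cold-insert volumes (analytic) let us derive the height giving the target
  # fill volume.
  v_spheres <- sum(4 / 3 * pi * sphere_radii^3)
  rods <- rod_layout(cylinder_radius, rod_sector_diameters)
  v_rods <- sum(pi * (rods$diameter / 2)^2) * rod_length
  if (is.null(cylinder_height))
    cylinder_height <- (fill_volume_ml * 1000 + v_spheres + v_rods) /
      (pi * cylinder_radius^2)
  spec$cylinder_height <- cylinder_height
  spec$sphere_plane_z <- sphere_plane_z %||% (cylinder_height / 2 - 40)
  spec$rods <- rods

  half_extent <- (spec$grid_shape - 1) / 2 * voxel_spacing
  if (cylinder_radius >= min(half_extent[1:2]) ||
      cylinder_height / 2 >= half_extent[3])
    stop("phantom_spec: cylinder does not fit inside the grid", call. = FALSE)
  if (length(sphere_radii) > 0 &&
      (sphere_ring_radius + max(sphere_radii) > cylinder_radius ||
       abs(spec$sphere_plane_z) + max(sphere_radii) > cylinder_height / 2))
    stop("phantom_spec: cold spheres extend outside the cylinder", call. = FALSE)
  if (rod_length > cylinder_height)
    stop("phantom_spec: rod sectors longer than the cylinder", call. = FALSE)
  if (!is.null(fiducial)) {
    p <- fiducial$position
    if (sqrt(sum(p[1:2]^2)) <= cylinder_radius + shell_thickness &&
        abs(p[3]) <= cylinder_height / 2 + shell_thickness)
      stop("phantom_spec: fiducial must lie outside the cylinder body",
           call. = FALSE)
    r_fid <- (3 * fiducial$volume_ml * 1000 / (4 * pi))^(1 / 3)
    if (any(abs(p) + r_fid > half_extent))
      stop("phantom_spec: fiducial extends outside the grid", call. = FALSE)
    spec$fiducial$radius <- r_fid
    spec$fiducial$concentration <- fiducial$concentration %||%
      activity_concentration
  }
  structure(spec, class = "phantom_spec")
}

# Cold-rod centres: one fan sector per diameter, rods on a triangular lattice
# with pitch twice the diameter, kept clear of the cylinder wall, the centre
# and the sector boundary lines.
rod_layout <- function(cylinder_radius, diameters) {
  k <- length(diameters)
  out <- NULL
  for (s in seq_len(k)) {
    d <- diameters[s]
    pitch <- 2 * d
    rmax <- cylinder_radius - 12 - d / 2
    xs <- seq(-rmax, rmax, by = pitch)
    ys <- seq(-rmax, rmax, by = pitch * sqrt(3) / 2)
    pts <- expand.grid(ix = seq_along(xs), iy = seq_along(ys))
    x <- xs[pts$ix] + ifelse(pts$iy %% 2 == 0, d, 0)
    y <- ys[pts$iy]
    r <- sqrt(x^2 + y^2)
    th <- atan2(y, x) %% (2 * pi)
    th0 <- (s - 1) * 2 * pi / k
    th1 <- s * 2 * pi / k
    in_sector <- th >= th0 & th < th1
    # clearance >= one diameter from both radial boundary lines of the sector
    clear <- r * abs(sin(th - th0)) >= d & r * abs(sin(th - th1)) >= d
    keep <- in_sector & clear & r >= 18 & r <= rmax
    if (any(keep))
      out <- rbind(out, data.frame(x = x[keep], y = y[keep],
                                   diameter = d, sector = s))
  }
  out
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> cylinder r=%.1f mm h=%.1f mm, %.4g MBq/mL\n",
              x$cylinder_radius, x$cylinder_height, x$activity_concentration))
  cat(sprintf("  %d cold spheres, %d rod sectors (%d rods), fiducial: %s\n",
              length(x$sphere_radii), length(x$rod_sector_diameters),
              if (is.null(x$rods)) 0L else nrow(x$rods), if (is.null(x$fiducial)) "none" else
                sprintf("%.1f mL at (%.0f, %.0f, %.0f)", x$fiducial$volume_ml,
                        x$fiducial$position[1], x$fiducial$position[2],
                        x$fiducial$position[3])))
  cat(sprintf("  grid %d x %d x %d at %.2f x %.2f x %.2f mm\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  invisible(x)
}

# Classify world points against the phantom geometry.
# Returns integer: 0 air, 1 hot fill, 2 cold insert, 3 acrylic shell,
# 4 fiducial interior.
phantom_membership <- function(spec, pts, with_fiducial = TRUE) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  r2 <- x^2 + y^2
  R <- spec$cylinder_radius
  hz <- spec$cylinder_height / 2
  cls <- integer(length(x))
  inside <- r2 <= R^2 & abs(z) <= hz
  shell <- !inside & r2 <= (R + spec$shell_thickness)^2 &
    abs(z) <= hz + spec$shell_thickness
  cls[shell] <- 3L
  cls[inside] <- 1L
  # cold spheres on the ring
  ns <- length(spec$sphere_radii)
  for (i in seq_len(ns)) {
    th <- (i - 1) * 2 * pi / ns
    cx <- spec$sphere_ring_radius * cos(th)
    cy <- spec$sphere_ring_radius * sin(th)
    d2 <- (x - cx)^2 + (y - cy)^2 + (z - spec$sphere_plane_z)^2
    cls[inside & d2 <= spec$sphere_radii[i]^2] <- 2L
  }
  # cold rods (z span from the cylinder bottom)
  zr <- z >= -hz & z <= -hz + spec$rod_length
  if (any(zr) && !is.null(spec$rods) && nrow(spec$rods) > 0) {
    idx <- which(inside & zr)
    if (length(idx)) {
      for (j in seq_len(nrow(spec$rods))) {
        rr <- spec$rods$diameter[j] / 2
        hit <- (x[idx] - spec$rods$x[j])^2 + (y[idx] - spec$rods$y[j])^2 <= rr^2
        cls[idx[hit]] <- 2L
      }
    }
  }
  if (with_fiducial && !is.null(spec$fiducial)) {
    p <- spec$fiducial$position
    d2 <- (x - p[1])^2 + (y - p[2])^2 + (z - p[3])^2
    cls[d2 <= spec$fiducial$radius^2] <- 4L
  }
  cls
}

phantom_grid_points <- function(spec, transform = NULL) {
  n <- spec$grid_shape
  sp <- spec$voxel_spacing
  origin <- -(n - 1) / 2 * sp
  ax <- lapply(1:3, function(a) origin[a] + sp[a] * (seq_len(n[a]) - 1))
  pts <- cbind(rep(ax[[1]], times = n[2] * n[3]),
               rep(rep(ax[[2]], each = n[1]), times = n[3]),
               rep(ax[[3]], each = n[1] * n[2]))
  if (!is.null(transform)) {
    inv <- invert_transform(transform)
    pts <- apply_transform(inv, pts)
  }
  list(points = pts, origin = origin)
}

#' Serialize a phantom specification to JSON or YAML
#'
#' Writes the constructor arguments (not the derived rod layout), so the
#' file re-validates through [phantom_spec()] on reading. The format follows
#' the file extension: `.json` (default) or `.yaml`/`.yml` (requires the
#' yaml package).
#'
#' @param spec a [phantom_spec()].
#' @param path output path.
#' @return `write_phantom_spec`: `path`, invisibly; `read_phantom_spec`: a
#'   [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  fields <- list(
    cylinder_radius = spec$cylinder_radius,
    cylinder_height = spec$cylinder_height,
    activity_concentration = spec$activity_concentration,
    sphere_radii = spec$sphere_radii,
    rod_sector_diameters = spec$rod_sector_diameters,
    fiducial = if (is.null(spec$fiducial)) NULL else
      spec$fiducial[c("volume_ml", "position", "concentration")],
    grid_shape = spec$grid_shape, voxel_spacing = spec$voxel_spacing,
    sphere_ring_radius = spec$sphere_ring_radius,
    sphere_plane_z = spec$sphere_plane_z, rod_length = spec$rod_length,
    shell_thickness = spec$shell_thickness, hu = spec$hu)
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

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(fields$fiducial)) fields$fiducial <- as.list(fields$fiducial)
  do.call(phantom_spec, fields)
}

#' Generate phantom activity and CT volumes
#'
#' Voxels are classified by the membership of their centre point (no
#' anti-aliasing): exact, testable geometry. Partial-volume effects are
#' introduced later by the acquisition point-spread function. The activity
#' volume holds MBq per voxel; the CT holds Hounsfield units (air -1000,
#' water 0 inside, configurable acrylic shell).
#'
#' @param spec a [phantom_spec()].
#' @param with_fiducial include the fiducial source (if the spec has one).
#' @param transform optional [rigid_transform()]: the returned volumes show
#'   the phantom *moved* by this transform (used for rotation studies; the
#'   geometry is classified analytically at inverse-transformed voxel
#'   centres, so no interpolation is involved).
#' @return list with elements `activity` and `ct`, both [volume3d()].
#' @export
make_phantom <- function(spec, with_fiducial = TRUE, transform = NULL) {
  g <- phantom_grid_points(spec, transform)
  cls <- phantom_membership(spec, g$points, with_fiducial)
  vvol <- prod(spec$voxel_spacing) / 1000
  act <- numeric(length(cls))
  act[cls == 1L] <- spec$activity_concentration * vvol
  if (any(cls == 4L))
    act[cls == 4L] <- spec$fiducial$concentration * vvol
  hu <- rep(spec$hu$air, length(cls))
  hu[cls %in% c(1L, 2L, 4L)] <- spec$hu$water
  hu[cls == 3L] <- spec$hu$acrylic
  n <- spec$grid_shape
  list(activity = volume3d(array(act, n), spacing = spec$voxel_spacing,
                           origin = g$origin, value_kind = "activity_MBq"),
       ct = volume3d(array(hu, n), spacing = spec$voxel_spacing,
                     origin = g$origin, value_kind = "HU"))
}

#' Simulate a SPECT acquisition of a known activity distribution
#'
#' The ground-truth volume is blurred with an isotropic Gaussian point-spread
#' function, scaled so that the expected total equals `total_counts`, and
#' Poisson-sampled. This emulates a reconstructed SPECT image directly — no
#' projection, reconstruction or attenuation model — which is sufficient to
#' exercise registration, quality control and dosimetry.
#'
#' @param truth a [volume3d()] (any non-negative kind).
#' @param psf_fwhm_mm full width at half maximum of the system PSF, mm
#'   (default 10, a typical SPECT reconstructed resolution).
#' @param total_counts expected total counts in the volume.
#' @param seed RNG seed for the Poisson draw.
#' @param poisson set `FALSE` for a noiseless (expected-value) image.
#' @return a [volume3d()] of kind `"counts"`.
#' @export
simulate_acquisition <- function(truth, psf_fwhm_mm = 10,
                                 total_counts = 6e7, seed = 1L,
                                 poisson = TRUE) {
  if (!is.finite(total_counts) || total_counts <= 0)
    stop("total_counts must be positive", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  v <- truth$values
  if (psf_fwhm_mm > 0)
    v <- gaussian_blur_fft(v, psf_fwhm_mm * FWHM_TO_SIGMA / truth$spacing)
  tot <- sum(v)
  if (tot <= 0) stop("truth volume has no signal", call. = FALSE)
  v <- v * (total_counts / tot)
  if (poisson)
    v <- with_seed(seed, array(stats::rpois(length(v), v), dim(v)))
  new_volume_like(truth, v, value_kind = "counts")
}

#' Simulate the phantom rotation experiment
#'
#' Generates the full rotation study set: for each rotation angle (clockwise
#' about the bed/z axis through the volume centre), each fiducial state and
#' each replicate, one noisy acquisition paired with the exact ground-truth
#' transform that was applied. One extra acquisition at 0 degrees per
#' fiducial state serves as the registration reference. With the defaults
#' (angles 0/5/10, 3 replicates, both fiducial states) this yields 18
#' studies.
#'
#' Clockwise rotation viewed from the head end (+z towards the viewer) is a
#' negative right-handed rotation about +z, so the stored ground truth for a
#' clockwise angle `a` has `rz = -a`.
#'
#' @param spec a [phantom_spec()].
#' @param angles_deg clockwise rotation angles, degrees.
#' @param fiducial_states logical vector of fiducial states to simulate.
#' @param replicates acquisitions per angle and state.
#' @param seed top-level RNG seed; per-study seeds are derived from it.
#' @param psf_fwhm_mm,total_counts,poisson passed to [simulate_acquisition()].
#' @return list with `studies` (list of records with `volume`,
#'   `truth_transform`, `angle_deg`, `fiducial`, `replicate`, `study_id`) and
#'   `references` (named list of reference volumes, one per fiducial state).
#' @export
make_rotation_study <- function(spec, angles_deg = c(0, 5, 10),
                                fiducial_states = c(TRUE, FALSE),
                                replicates = 3, seed = 1L,
                                psf_fwhm_mm = 10, total_counts = 6e7,
                                poisson = TRUE) {
  if (any(!is.finite(angles_deg)))
    stop("angles_deg must be finite", call. = FALSE)
  center <- c(0, 0, 0)  # phantom grid is centred on the world origin
  studies <- list()
  references <- list()
  sid <- 0L
  for (fid in fiducial_states) {
    fkey <- if (fid) "with_fiducial" else "without_fiducial"
    ref_truth <- make_phantom(spec, with_fiducial = fid)$activity
    references[[fkey]] <- simulate_acquisition(
      ref_truth, psf_fwhm_mm, total_counts,
      seed = seed * 100000L + sid, poisson = poisson)
    for (a in angles_deg) {
      tr <- rigid_transform(rz = -a, center = center)
      truth <- if (a == 0) ref_truth else
        make_phantom(spec, with_fiducial = fid, transform = tr)$activity
      for (rep_i in seq_len(replicates)) {
        sid <- sid + 1L
        studies[[sid]] <- list(
          volume = simulate_acquisition(truth, psf_fwhm_mm, total_counts,
                                        seed = seed * 100000L + sid,
                                        poisson = poisson),
          truth_transform = tr, angle_deg = a, fiducial = fid,
          replicate = rep_i,
          study_id = sprintf("rot%02d_%s_rep%d", a, fkey, rep_i))
      }
    }
  }
  list(studies = studies, references = references, spec = spec)
}
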