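#' @useDynLib voxdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALUE_KINDS <- c("counts", "HU", "activity_MBq", "tia_MBq_s", "dose_mGy")

#' Construct a 3-D image volume with physical geometry
#'
#' `volume3d` is the package's core container: a 3-D scalar grid together with
#' voxel spacing (mm), the world position of the centre of voxel `(0,0,0)`,
#' axis direction cosines, the physical meaning of the values and, optionally,
#' the acquisition time in hours post-injection. World coordinates follow the
#' scanner (DICOM/LPS) convention; voxels are node-centred and indices are
#' 0-based, so voxel `(i,j,k)` sits at
#' `origin + orientation %*% (spacing * c(i,j,k))`.
#'
#' @param values numeric 3-D array.
#' @param spacing voxel spacing in mm, length 3, all positive.
#' @param origin world coordinates (mm) of the centre of voxel `(0,0,0)`.
#' @param orientation 3x3 orthonormal direction-cosine matrix (columns are the
#'   world directions of the grid axes).
#' @param value_kind one of `"counts"`, `"HU"`, `"activity_MBq"`,
#'   `"tia_MBq_s"`, `"dose_mGy"`.
#' @param acquisition_time_h acquisition time in hours post-injection, or `NA`.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     orientation = diag(3), value_kind = "counts",
                     acquisition_time_h = NA_real_) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  storage.mode(values) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("`orientation` must be a 3x3 orthonormal matrix", call. = FALSE)
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (value_kind != "HU" && min(values) < 0)
    stop(sprintf("negative values not allowed for value_kind '%s'", value_kind),
         call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         orientation = orientation, value_kind = value_kind,
         acquisition_time_h = as.numeric(acquisition_time_h)[1]),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  kind: %s | range: [%.4g, %.4g] | total: %.6g\n",
              x$value_kind, min(x$values), max(x$values), sum(x$values)))
  if (is.finite(x$acquisition_time_h))
    cat(sprintf("  acquired at %.3g h post-injection\n", x$acquisition_time_h))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' @export
as.array.volume3d <- function(x, ...) x$values

#' Voxel volume in millilitres
#' @param volume a [volume3d()].
#' @return voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(volume) prod(volume$spacing) / 1000

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param volume a [volume3d()].
#' @param index numeric matrix (n x 3) or vector of 0-based indices.
#' @return n x 3 matrix of world coordinates.
#' @export
index_to_world <- function(volume, index) {
  index <- rbind_pts(index)
  t(volume$orientation %*% (t(index) * volume$spacing) + volume$origin)
}

#' Map world coordinates (mm) to fractional 0-based voxel indices
#' @rdname index_to_world
#' @param world numeric matrix (n x 3) of world points.
#' @export
world_to_index <- function(volume, world) {
  world <- rbind_pts(world)
  t((t(volume$orientation) %*% (t(world) - volume$origin)) / volume$spacing)
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3)
  storage.mode(p) <- "double"
  p
}

# World coordinates of the geometric centre of the grid.
volume_center <- function(volume) {
  drop(index_to_world(volume, (dim(volume$values) - 1) / 2))
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-3 ||
      max(abs(a$orientation - b$orientation)) > 1e-6)
    stop("volumes are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

new_volume_like <- function(template, values, value_kind = template$value_kind,
                            acquisition_time_h = template$acquisition_time_h) {
  if (is.null(dim(values))) dim(values) <- dim(template$values)
  volume3d(values, spacing = template$spacing, origin = template$origin,
           orientation = template$orientation, value_kind = value_kind,
           acquisition_time_h = acquisition_time_h)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Values are interpolated at the world positions of the reference grid's
#' voxel centres. Voxels of the reference grid that fall outside the source
#' volume's field of view are set to 0 and flagged invalid in the
#' `"valid"` attribute (a logical array) rather than silently zero-filled:
#' downstream consumers must consult the mask.
#'
#' @param volume source [volume3d()].
#' @param reference [volume3d()] defining the output grid.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return a [volume3d()] on the reference grid, with attribute `"valid"`.
#' @export
resample_to_grid <- function(volume, reference, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  M <- index_affine(reference, volume, transform = NULL)
  res <- cpp_affine_resample(as.numeric(volume$values), dim(volume$values),
                             dim(reference$values), M,
                             if (interp == "trilinear") 0L else 1L)
  if (!any(res$valid))
    stop("fields of view are disjoint: no reference voxel falls inside the source volume",
         call. = FALSE)
  vals <- array(res$values, dim(reference$values))
  out <- volume3d(pmax(vals, if (volume$value_kind == "HU") -Inf else 0),
                  spacing = reference$spacing, origin = reference$origin,
                  orientation = reference$orientation,
                  value_kind = volume$value_kind,
                  acquisition_time_h = volume$acquisition_time_h)
  attr(out, "valid") <- array(res$valid, dim(reference$values))
  out
}

# 3x4 affine taking a 0-based index of `out_grid` to a fractional 0-based
# index of `src`, optionally through a rigid transform t mapping out_grid
# world coordinates into src world coordinates.
index_affine <- function(out_grid, src, transform = NULL) {
  A <- out_grid$orientation %*% diag(out_grid$spacing)
  b <- out_grid$origin
  if (!is.null(transform)) {
    Tm <- transform_matrix(transform)
    A <- Tm[1:3, 1:3] %*% A
    b <- drop(Tm[1:3, 1:3] %*% b) + Tm[1:3, 4]
  }
  Sinv <- diag(1 / src$spacing) %*% t(src$orientation)
  cbind(Sinv %*% A, drop(Sinv %*% (b - src$origin)))
}
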