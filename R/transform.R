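#' 6-degree-of-freedom rigid transform
#'
#' Translations are in mm, rotations in degrees as fixed-axis Euler angles
#' applied z, then y, then x (so the rotation matrix is
#' `Rx(rx) %*% Ry(ry) %*% Rz(rz)`). The transform maps a point `x` in the
#' reference frame to `R (x - center) + center + t` in the target frame.
#'
#' @param tx,ty,tz translations in mm.
#' @param rx,ry,rz rotations in degrees about the world x, y, z axes.
#' @param center rotation centre in world mm (default the origin; registration
#'   routines default it to the volume centre).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                            center = c(0, 0, 0)) {
  stopifnot(length(center) == 3)
  structure(list(translation = c(tx = tx, ty = ty, tz = tz),
                 rotation_deg = c(rx = rx, ry = ry, rz = rz),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3]))
  cat(sprintf("  center = (%.2f, %.2f, %.2f) mm, convention zyx-fixed\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

rot_matrix_zyx <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# Euler angles (degrees, zyx-fixed convention) from a rotation matrix.
euler_from_matrix <- function(R) {
  ry <- asin(max(-1, min(1, R[1, 3])))
  rx <- atan2(-R[2, 3], R[3, 3])
  rz <- atan2(-R[1, 2], R[1, 1])
  c(rx = rx, ry = ry, rz = rz) * 180 / pi
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param transform a [rigid_transform()].
#' @return 4x4 matrix mapping homogeneous reference coordinates to target
#'   coordinates.
#' @export
transform_matrix <- function(transform) {
  R <- rot_matrix_zyx(transform$rotation_deg[1], transform$rotation_deg[2],
                      transform$rotation_deg[3])
  c0 <- transform$center
  b <- c0 + unname(transform$translation) - drop(R %*% c0)
  unname(rbind(cbind(R, b), c(0, 0, 0, 1)))
}

#' Apply a rigid transform to world points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  points <- rbind_pts(points)
  M <- transform_matrix(transform)
  out <- t(M[1:3, 1:3] %*% t(points) + M[1:3, 4])
  dimnames(out) <- NULL
  out
}

#' Invert a rigid transform
#'
#' The inverse keeps the same rotation centre; its parameters are recovered
#' from the transposed rotation matrix.
#'
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  R <- rot_matrix_zyx(transform$rotation_deg[1], transform$rotation_deg[2],
                      transform$rotation_deg[3])
  ang <- euler_from_matrix(t(R))
  tr <- -drop(t(R) %*% transform$translation)
  rigid_transform(tr[1], tr[2], tr[3], ang[1], ang[2], ang[3],
                  center = transform$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#' The composite keeps the rotation centre of `first`.
#'
#' @param second,first [rigid_transform()]s.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  M <- transform_matrix(second) %*% transform_matrix(first)
  ang <- euler_from_matrix(M[1:3, 1:3])
  c0 <- first$center
  # solve R(x - c0) + c0 + t = M x  =>  t = M[,4] + R c0 - c0
  tr <- M[1:3, 4] + drop(M[1:3, 1:3] %*% c0) - c0
  rigid_transform(tr[1], tr[2], tr[3], ang[1], ang[2], ang[3], center = c0)
}

#' Serialize / deserialize a rigid transform as JSON
#' @param transform a [rigid_transform()].
#' @param path file path; for `transform_from_json`, a path or JSON string.
#' @return `transform_to_json` returns `path` invisibly; `transform_from_json`
#'   a [rigid_transform()].
#' @export
transform_to_json <- function(transform, path) {
  jsonlite::write_json(
    list(translations_mm = unname(transform$translation),
         rotations_deg = unname(transform$rotation_deg),
         center_mm = unname(transform$center),
         convention = "zyx-fixed"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$convention, "zyx-fixed"))
    stop("unsupported rotation convention: ", x$convention, call. = FALSE)
  rigid_transform(x$translations_mm[1], x$translations_mm[2], x$translations_mm[3],
                  x$rotations_deg[1], x$rotations_deg[2], x$rotations_deg[3],
                  center = x$center_mm)
}
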