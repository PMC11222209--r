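#' Rigid transforms in world (mm) coordinates
#'
#' A rigid transform is a proper rotation plus a translation, mapping
#' preoperative world coordinates to postoperative world coordinates (or more
#' generally, source world to target world). Rotations are stored as 3x3
#' orthonormal matrices with determinant +1; translations in millimetres.
#'
#' @param rotation 3x3 orthonormal matrix, determinant +1.
#' @param translation numeric length-3, millimetres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  angle", sprintf("%.3f deg,", rotation_angle_deg(x$rotation)),
      "translation [", paste(sprintf("%.3f", x$translation), collapse = ", "),
      "] mm\n")
  invisible(x)
}

#' Apply a rigid transform to world points
#'
#' @param transform A [rigid_transform()].
#' @param points Numeric length-3 vector or n x 3 matrix of world points (mm).
#' @return Points of the same shape, transformed.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) {
    as.numeric(transform$rotation %*% points + transform$translation)
  } else {
    p <- as.matrix(points)
    sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
  }
}

#' Compose rigid transforms
#'
#' `compose_transform(a, b)` returns the transform applying `b` first, then
#' `a` (i.e. `x -> a(b(x))`).
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Rotation matrix from axis and angle
#'
#' @param axis Numeric length-3 rotation axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("axis must be nonzero")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform rotating about a point
#'
#' Rotates by `angle_deg` about `axis` through the point `center`, then
#' translates by `translation`.
#' @inheritParams rotation_about_axis
#' @param center World point the rotation axis passes through (mm).
#' @param translation Additional translation (mm).
#' @return A [rigid_transform()].
#' @export
transform_about_point <- function(axis, angle_deg, center = c(0, 0, 0),
                                  translation = c(0, 0, 0)) {
  R <- rotation_about_axis(axis, angle_deg)
  center <- as.numeric(center)
  rigid_transform(R, center - as.numeric(R %*% center) + as.numeric(translation))
}

#' Rotation angle of a rotation matrix
#' @param rotation 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(rotation) {
  ctheta <- (sum(diag(rotation)) - 1) / 2
  acos(max(-1, min(1, ctheta))) * 180 / pi
}

# rotation vector (axis * angle, radians) <-> matrix; used as the 3-parameter
# rotation chart by the optimizers
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + matrix(c(0, w[3], -w[2], -w[3], 0, w[1],
                                            w[2], -w[1], 0), 3, 3))
  rotation_about_axis(w, th * 180 / pi)
}

matrix_to_rotvec <- function(R) {
  th <- rotation_angle_deg(R) * pi / 180
  if (th < 1e-9) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near 180 deg: extract axis from R + I
    B <- (R + diag(3)) / 2
    u <- sqrt(pmax(diag(B), 0))
    i <- which.max(u)
    u <- B[, i] / u[i]
    u <- u / sqrt(sum(u^2))
    return(u * th)
  }
  u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  u * th
}

#' Discrepancy between two rigid transforms
#'
#' Forms the difference transform `delta = T1 o inverse(T2)` and reports its
#' rotation angle and the displacement it induces at a reference world point
#' (typically the vertebra centroid, so the translation component is measured
#' where the anatomy actually sits).
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @param reference World point (mm) at which displacement is measured.
#' @return Named numeric: `translation_mm`, `rotation_deg`.
#' @export
transform_discrepancy <- function(t1, t2, reference = c(0, 0, 0)) {
  delta <- compose_transform(t1, invert_transform(t2))
  moved <- apply_transform(delta, as.numeric(reference))
  c(translation_mm = sqrt(sum((moved - reference)^2)),
    rotation_deg = rotation_angle_deg(delta$rotation))
}

#' Random rigid transform of fixed magnitude
#'
#' Draws a rotation of exactly `angle_deg` about a uniformly random axis and a
#' translation of exactly `trans_mm` in a uniformly random direction; the
#' rotation axis passes through `center`. Used by the perturbation analysis
#' and the phantom's inter-scan motion model (with magnitudes drawn upstream).
#'
#' @param angle_deg Rotation magnitude, degrees.
#' @param trans_mm Translation magnitude, mm.
#' @param center Point the rotation axis passes through.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(angle_deg, trans_mm, center = c(0, 0, 0)) {
  axis <- rnorm(3)
  dirn <- rnorm(3)
  dirn <- dirn / sqrt(sum(dirn^2))
  transform_about_point(axis, angle_deg, center, dirn * trans_mm)
}

#' @export
tidy.rigid_transform <- function(x, ...) {
  w <- matrix_to_rotvec(x$rotation)
  tibble::tibble(
    term = c("rx", "ry", "rz", "tx", "ty", "tz"),
    estimate = c(w * 180 / pi, x$translation),
    unit = c(rep("deg", 3), rep("mm", 3))
  )
}
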