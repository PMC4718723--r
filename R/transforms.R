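#' Rigid-body transform
#'
#' A proper rigid motion `x -> R x + t` in Angstrom coordinates. The rotation
#' must be proper orthogonal (determinant +1); reflections are rejected.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3 translation vector (Angstrom).
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation matrix is not orthogonal within 1e-6")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation matrix is not proper (det != +1): reflections are not rigid motions")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ra <- rotation_angle_axis(x)
  cat("<rigid_transform>\n")
  cat(sprintf("  rotation angle: %.3f deg\n", ra$angle))
  if (isTRUE(ra$axis_defined)) {
    cat(sprintf("  axis: [%.3f, %.3f, %.3f]\n", ra$axis[1], ra$axis[2], ra$axis[3]))
  }
  cat(sprintf("  translation: [%.3f, %.3f, %.3f] A\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param transform a [rigid_transform()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- rbind(xyz)
  sweep(xyz %*% t(transform$rotation), 2, -transform$translation)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  as.numeric(-t(transform$rotation) %*% transform$translation))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the direction `axis`.
#'
#' @param axis length-3 direction (normalised internally).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- as.numeric(axis)
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("axis has zero length")
  u <- u / nu
  th <- angle * pi / 180
  kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

#' Rigid rotation about an axis through a point
#'
#' Convenience constructor for the screw-free rotation `x -> R (x - p) + p`.
#'
#' @inheritParams rotation_about_axis
#' @param point a point on the rotation axis (Angstrom).
#' @return A [rigid_transform()].
#' @export
rotation_about_line <- function(axis, angle, point = c(0, 0, 0)) {
  R <- rotation_about_axis(axis, angle)
  rigid_transform(R, as.numeric(point - R %*% point))
}

# rotation-vector (axis * angle in degrees) -> rotation matrix; zero vector -> identity
rotvec_to_matrix <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(diag(3))
  rotation_about_axis(v / ang, ang)
}
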