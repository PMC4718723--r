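#' Least-squares superposition of matched point sets
#'
#' Kabsch/SVD superposition of `model_a` onto `model_b` over matched CA
#' coordinates, restricted to proper rotations (reflections excluded). This
#' is the primitive underlying all rigid-body state comparisons: the returned
#' transform's rotation part is what the angle/axis decomposition reports.
#'
#' @param model_a,model_b [backbone_model()] objects (matched residues) or
#'   n x 3 coordinate matrices with matched rows (n >= 3, non-collinear).
#' @return An object of class `superposition`: `transform` (the
#'   [rigid_transform()] taking `model_a` coordinates onto `model_b`),
#'   `rmsd_before`, `rmsd_after`, `centroid` (of the moving set).
#' @export
superpose <- function(model_a, model_b) {
  xa <- if (inherits(model_a, "backbone_model")) ca_coords(model_a) else rbind(model_a)
  xb <- if (inherits(model_b, "backbone_model")) ca_coords(model_b) else rbind(model_b)
  if (nrow(xa) != nrow(xb)) stop("point sets must have equal counts")
  if (nrow(xa) < 3) stop("superposition needs at least 3 points")
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  sv <- svd(crossprod(A, B))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate (collinear or coincident) point set: rotation is underdetermined")
  }
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  t <- as.numeric(cb - R %*% ca)
  tr <- rigid_transform(R, t)
  structure(list(
    transform = tr,
    rmsd_before = sqrt(mean(rowSums((xa - xb)^2))),
    rmsd_after = sqrt(mean(rowSums((apply_transform(xa, tr) - xb)^2))),
    centroid = ca
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  ra <- rotation_angle_axis(x)
  cat(sprintf("<superposition> rotation %.3f deg, RMSD %.3f -> %.3f A\n",
              ra$angle, x$rmsd_before, x$rmsd_after))
  invisible(x)
}

#' Rotation angle, axis and screw-axis point of a rigid motion
#'
#' The rotation angle comes from the rotation-matrix trace; the axis is the
#' invariant direction. The axis point is the point on the screw axis closest
#' to `center` (for a [superpose()] result, the moving set's centroid), since
#' physically meaningful rotation axes live in space, not through the origin.
#' Rotations below 0.1 degree have no well-defined axis and are flagged
#' rather than fabricated.
#'
#' @param transform a [rigid_transform()] or [superpose()] result.
#' @param center reference point for placing the screw axis (overridden by a
#'   superposition's centroid).
#' @return An object of class `state_rotation`: `angle` (degrees, in
#'   `[0, 180]`), `axis` (unit vector or `NA`), `axis_defined`, `axis_point`,
#'   and `rmsd_before` / `rmsd_after` when available.
#' @export
rotation_angle_axis <- function(transform, center = c(0, 0, 0)) {
  rb <- ra <- NA_real_
  if (inherits(transform, "superposition")) {
    center <- transform$centroid
    rb <- transform$rmsd_before; ra <- transform$rmsd_after
    transform <- transform$transform
  }
  R <- transform$rotation
  tvec <- transform$translation
  cosang <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  angle <- acos(cosang) * 180 / pi
  if (angle < 0.1) {
    return(structure(list(angle = angle, axis = c(NA, NA, NA),
                          axis_defined = FALSE, axis_point = c(NA, NA, NA),
                          rmsd_before = rb, rmsd_after = ra),
                     class = "state_rotation"))
  }
  if (angle < 179.9) {
    u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  } else {
    # near 180 deg: axis from the symmetric part's dominant eigenvector
    u <- Re(eigen((R + t(R)) / 2)$vectors[, 1])
  }
  u <- u / sqrt(sum(u^2))
  # screw decomposition: solve (I - R) p = t_perp in the plane normal to u
  t_perp <- tvec - sum(tvec * u) * u
  M <- diag(3) - R
  p <- as.numeric(qr.solve(rbind(M, u), c(t_perp, 0)))
  # slide p to the closest point to `center` along the axis
  p <- p + sum((center - p) * u) * u
  structure(list(angle = angle, axis = u, axis_defined = TRUE,
                 axis_point = p, rmsd_before = rb, rmsd_after = ra),
            class = "state_rotation")
}

#' @export
print.state_rotation <- function(x, ...) {
  cat(sprintf("<state_rotation> angle %.3f deg", x$angle))
  if (isTRUE(x$axis_defined)) {
    cat(sprintf(", axis [%.3f, %.3f, %.3f] through [%.1f, %.1f, %.1f]",
                x$axis[1], x$axis[2], x$axis[3],
                x$axis_point[1], x$axis_point[2], x$axis_point[3]))
  } else {
    cat(" (axis undefined)")
  }
  cat("\n")
  invisible(x)
}

#' One-row tibble of a state rotation
#' @param x a `state_rotation`.
#' @param ... unused.
#' @return One-row tibble with angle, axis components, axis point and RMSDs.
#' @export
tidy.state_rotation <- function(x, ...) {
  tibble::tibble(angle = x$angle, axis_defined = x$axis_defined,
                 axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
                 point_x = x$axis_point[1], point_y = x$axis_point[2],
                 point_z = x$axis_point[3],
                 rmsd_before = x$rmsd_before, rmsd_after = x$rmsd_after)
}

#' Write state-rotation records as JSON
#' @param rotations a `state_rotation` or list of them (optionally named).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rotations_json <- function(rotations, path) {
  if (inherits(rotations, "state_rotation")) rotations <- list(rotations)
  jsonlite::write_json(lapply(rotations, function(r) {
    list(angle = r$angle, axis = r$axis, axis_defined = r$axis_defined,
         axis_point = r$axis_point, rmsd_before = r$rmsd_before,
         rmsd_after = r$rmsd_after)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rotational offset between two states of a symmetric ring
#'
#' Rotation of `ring_b` relative to `ring_a` about the ring axis, reported
#' modulo the symmetry step (e.g. the 45 degree step of an 8-fold ring) in
#' `(-180/order, +180/order]`. An n-fold ring has n equivalent subunit
#' labellings, so only the residual within one symmetry step is meaningful;
#' the offset is computed from the circular mean of per-atom azimuthal
#' differences, which matches subunits by optimal circular shift implicitly.
#'
#' @param ring_a,ring_b [backbone_model()] objects with matched atom counts.
#' @param symmetry_order rotational symmetry of the ring (default 8).
#' @param axis optional list with `point` and `direction`; fitted from
#'   `ring_a` when `NULL` (subunit centroids define the ring plane).
#' @return Offset in degrees, in `(-180/symmetry_order, +180/symmetry_order]`.
#' @export
ring_offset <- function(ring_a, ring_b, symmetry_order = 8, axis = NULL) {
  if (symmetry_order < 1) stop("symmetry_order must be >= 1")
  xa <- ca_coords(ring_a); xb <- ca_coords(ring_b)
  if (nrow(xa) != nrow(xb)) {
    stop("rings have incompatible atom counts")
  }
  if (is.null(axis)) {
    per <- nrow(xa) / symmetry_order
    if (per != round(per)) {
      stop("atom count is not a multiple of symmetry_order; supply `axis`")
    }
    subctr <- t(vapply(seq_len(symmetry_order), function(s) {
      colMeans(xa[((s - 1) * per + 1):(s * per), , drop = FALSE])
    }, numeric(3)))
    ctr <- colMeans(subctr)
    sv <- svd(sweep(subctr, 2, ctr), nu = 0, nv = 3)
    u <- as.numeric(sv$v[, 3])
    # deterministic sign: point along the dominant coordinate axis
    u <- u * sign(u[which.max(abs(u))])
    axis <- list(point = ctr, direction = u)
  }
  u <- axis$direction / sqrt(sum(axis$direction^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  az <- function(x) {
    rel <- sweep(x, 2, axis$point)
    atan2(rel %*% e2, rel %*% e1)[, 1]
  }
  dth <- az(xb) - az(xa)
  delta <- atan2(mean(sin(dth)), mean(cos(dth))) * 180 / pi
  step <- 360 / symmetry_order
  off <- delta %% step
  if (off > step / 2 + 1e-12) off <- off - step
  off
}

#' Linear interpolation between two conformational states
#'
#' Per-atom linear interpolation in Cartesian coordinates, for visualising
#' transitions. Endpoints are reproduced exactly. The frames are geometric
#' illustrations only -- linear interpolation shortens rotating arms along
#' the chord and is not a physical trajectory; the result carries a
#' `non_physical` attribute and [write_frames_pdb()] records the caveat.
#'
#' @param model_a,model_b matched [backbone_model()] objects.
#' @param n_frames number of frames including both endpoints (>= 2).
#' @return A list of `n_frames` [backbone_model()] objects with attribute
#'   `non_physical = TRUE`.
#' @export
interpolate_states <- function(model_a, model_b, n_frames = 10) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (!identical(model_a$resno, model_b$resno)) {
    stop("models must have matched residues")
  }
  w <- seq(0, 1, length.out = n_frames)
  frames <- lapply(w, function(t) {
    backbone_model(model_a$resno,
                   (1 - t) * model_a$n + t * model_b$n,
                   (1 - t) * model_a$ca + t * model_b$ca,
                   (1 - t) * model_a$c + t * model_b$c,
                   (1 - t) * model_a$o + t * model_b$o)
  })
  attr(frames, "non_physical") <- TRUE
  frames
}
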