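#' Ideal helix build parameters
#'
#' Backbone dihedrals and peptide geometry used by [build_ideal_helix()].
#' Defaults are the canonical straight alpha-helix dihedrals phi = -57 deg,
#' psi = -47 deg with a trans peptide bond (omega = 180 deg) and standard
#' peptide bond lengths/angles (Engh-Huber-type values). The dihedrals alone
#' do not fix absolute coordinates: the bond geometry set is recorded here so
#' that tests can pin exact numbers.
#'
#' @param phi,psi,omega backbone dihedral angles in degrees.
#' @param b_n_ca,b_ca_c,b_c_n,b_c_o bond lengths in Angstrom (N-CA, CA-C,
#'   C-N peptide bond, C=O carbonyl).
#' @param ang_n_ca_c,ang_ca_c_n,ang_c_n_ca,ang_ca_c_o bond angles in degrees.
#' @return An object of class `helix_params` (a named list).
#' @export
helix_params <- function(phi = -57, psi = -47, omega = 180,
                         b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                         b_c_o = 1.231,
                         ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                         ang_c_n_ca = 121.7, ang_ca_c_o = 120.8) {
  structure(list(phi = phi, psi = psi, omega = omega,
                 b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n,
                 b_c_o = b_c_o,
                 ang_n_ca_c = ang_n_ca_c, ang_ca_c_n = ang_ca_c_n,
                 ang_c_n_ca = ang_c_n_ca, ang_ca_c_o = ang_ca_c_o),
            class = "helix_params")
}

# Natural-extension reference frame (NeRF) placement: position atom d given
# the three preceding atoms a-b-c, the c-d bond length, the b-c-d angle and
# the a-b-c-d dihedral (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- cbind(bc, c(nrm[2] * bc[3] - nrm[3] * bc[2],
                   nrm[3] * bc[1] - nrm[1] * bc[3],
                   nrm[1] * bc[2] - nrm[2] * bc[1]), nrm)
  as.numeric(m %*% d_local) + c
}

#' Build an ideal alpha-helix backbone
#'
#' Constructs an N-residue backbone residue-by-residue from internal
#' coordinates (bond length, bond angle, dihedral), i.e. a straight helix at
#' the dihedrals in `params`. The first residue is placed in a canonical
#' frame: N1 at the origin, CA1 on the +x axis, C1 in the xy plane.
#'
#' @param n_residues number of residues (>= 1).
#' @param params a [helix_params()] object.
#' @param first_resno sequence number of the first residue (1-based).
#' @return A [backbone_model()].
#' @export
build_ideal_helix <- function(n_residues, params = helix_params(),
                              first_resno = 1L) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  p <- params
  nrs <- as.integer(n_residues)
  N <- CA <- C <- O <- matrix(NA_real_, nrs, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(p$b_n_ca, 0, 0)
  th <- p$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + p$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(nrs - 1L) + 1L) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         p$b_c_n, p$ang_ca_c_n, p$psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          p$b_n_ca, p$ang_c_n_ca, p$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         p$b_ca_c, p$ang_n_ca_c, p$phi)
  }
  # carbonyl O in the peptide plane, trans to the next amide N
  for (i in seq_len(nrs)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         p$b_c_o, p$ang_ca_c_o, p$psi + 180)
  }
  backbone_model(seq.int(first_resno, length.out = nrs), N, CA, C, O)
}

#' Straight axis segment (density rod / helix axis)
#'
#' A rod abstracts an elongated feature: either the fitted axis of a helix or
#' an elongated above-threshold density component in a map. Its direction is
#' the unit vector from `endpoint_a` to `endpoint_b`.
#'
#' @param endpoint_a,endpoint_b length-3 points in Angstrom.
#' @return An object of class `rod_axis`.
#' @export
rod_axis <- function(endpoint_a, endpoint_b) {
  a <- as.numeric(endpoint_a); b <- as.numeric(endpoint_b)
  stopifnot(length(a) == 3, length(b) == 3)
  if (sqrt(sum((b - a)^2)) <= 0) stop("rod must have positive length")
  structure(list(endpoint_a = a, endpoint_b = b), class = "rod_axis")
}

#' @export
print.rod_axis <- function(x, ...) {
  cat(sprintf("<rod_axis> length %.2f A, direction [%.3f, %.3f, %.3f]\n",
              rod_length(x), rod_direction(x)[1], rod_direction(x)[2],
              rod_direction(x)[3]))
  invisible(x)
}

#' @rdname rod_axis
#' @param rod a `rod_axis`.
#' @export
rod_length <- function(rod) sqrt(sum((rod$endpoint_b - rod$endpoint_a)^2))

#' @rdname rod_axis
#' @export
rod_direction <- function(rod) {
  d <- rod$endpoint_b - rod$endpoint_a
  d / sqrt(sum(d^2))
}

#' @rdname rod_axis
#' @export
rod_midpoint <- function(rod) (rod$endpoint_a + rod$endpoint_b) / 2

#' Fit a straight axis through a helix backbone
#'
#' Total-least-squares line through the CA coordinates (first principal
#' component of the centred CA cloud). Endpoints are the projections of the
#' first and last CA onto the line, so the direction runs from the first
#' residue towards the last.
#'
#' @param model a [backbone_model()] with at least 3 residues.
#' @return A [rod_axis()].
#' @export
fit_axis <- function(model) {
  ca <- ca_coords(model)
  if (nrow(ca) < 3) stop("axis fitting needs at least 3 residues")
  ctr <- colMeans(ca)
  x <- sweep(ca, 2, ctr)
  sv <- svd(x, nu = 0, nv = 1)
  if (sv$d[1] < 1e-8) stop("all CA coordinates coincide; axis undefined")
  u <- as.numeric(sv$v[, 1])
  proj <- as.numeric(x %*% u)
  if (proj[length(proj)] < proj[1]) { u <- -u; proj <- -proj }
  rod_axis(ctr + proj[1] * u, ctr + proj[length(proj)] * u)
}

#' Helix geometry statistics
#'
#' Rise per residue, residues per turn and radius, measured from the CA trace
#' relative to the fitted axis: axial rise from a linear fit of axial
#' position against residue index, turn from the mean unwrapped azimuthal
#' step, radius as the mean radial distance from the axis.
#'
#' @param model a [backbone_model()].
#' @return A one-row [tibble::tibble()] with columns `rise`, `residues_per_turn`,
#'   `radius`, `ca_ca_mean` (mean consecutive CA-CA distance, Angstrom).
#' @export
helix_stats <- function(model) {
  ca <- ca_coords(model)
  ax <- fit_axis(model)
  u <- rod_direction(ax)
  ctr <- rod_midpoint(ax)
  rel <- sweep(ca, 2, ctr)
  s <- as.numeric(rel %*% u)
  radial <- rel - outer(s, u)
  # orthonormal frame in the plane normal to the axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  theta <- atan2(radial %*% e2, radial %*% e1)
  dth <- diff(theta[, 1])
  dth <- (dth + pi) %% (2 * pi) - pi  # unwrap
  idx <- seq_len(nrow(ca))
  rise <- unname(stats::coef(stats::lm(s ~ idx))[2])
  tibble::tibble(
    rise = rise,
    residues_per_turn = 2 * pi / abs(mean(dth)),
    radius = mean(sqrt(rowSums(radial^2))),
    ca_ca_mean = mean(sqrt(rowSums(diff(ca)^2)))
  )
}

#' Place an ideal helix onto a rod
#'
#' Builds an ideal helix of `segment_length` residues and rigidly transforms
#' it so that its fitted axis lies on the rod's line. This is the reproducible
#' counterpart of fitting a helix into an elongated density feature by hand.
#'
#' The helix axis midpoint is placed at the rod midpoint, so helices longer
#' than their rod overhang symmetrically. `direction = "forward"` puts
#' residue 1 nearest `endpoint_a`, `"reverse"` nearest `endpoint_b`.
#' `register_shift` slides the helix along the rod direction in whole-residue
#' rise increments; `roll` rotates it about the rod axis (degrees).
#'
#' @param segment_length number of residues.
#' @param rod a [rod_axis()].
#' @param direction `"forward"` or `"reverse"`.
#' @param register_shift axial shift in residues; |shift| <= segment_length.
#' @param roll rotation about the axis, degrees.
#' @param params a [helix_params()].
#' @param first_resno sequence number of the first residue.
#' @return A [backbone_model()] of the placed helix.
#' @export
place_helix <- function(segment_length, rod, direction = c("forward", "reverse"),
                        register_shift = 0, roll = 0,
                        params = helix_params(), first_resno = 1L) {
  direction <- match.arg(direction)
  if (abs(register_shift) > segment_length) {
    stop("|register_shift| must not exceed segment_length")
  }
  helix <- build_ideal_helix(segment_length, params, first_resno)
  place_built_helix(helix, rod, direction, register_shift, roll)
}

# place an already-built ideal helix (allows callers to cache the build)
place_built_helix <- function(helix, rod, direction, register_shift, roll) {
  hax <- fit_axis(helix)
  u <- rod_direction(hax)              # helix axis, residue 1 -> last
  d <- rod_direction(rod)
  target <- if (direction == "forward") d else -d
  R1 <- minimal_rotation(u, target)
  rise <- rod_length(hax) / (n_residues(helix) - 1)
  # rotate about helix axis midpoint, then translate midpoint onto rod midpoint
  hm <- rod_midpoint(hax)
  t1 <- rigid_transform(R1, as.numeric(rod_midpoint(rod) - R1 %*% hm))
  shift_vec <- register_shift * rise * d
  t2 <- rigid_transform(diag(3), shift_vec)
  tr <- compose_transforms(t2, t1)
  if (roll != 0) {
    tr <- compose_transforms(
      rotation_about_line(d, roll, rod_midpoint(rod) + shift_vec), tr)
  }
  transform_model(helix, tr)
}

# minimal-angle rotation taking unit vector u onto unit vector v
minimal_rotation <- function(u, v) {
  cang <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (cang > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any axis perpendicular to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- ref - sum(ref * u) * u
    return(rotation_about_axis(perp, 180))
  }
  rotation_about_axis(ax / s, atan2(s, cang) * 180 / pi)
}
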