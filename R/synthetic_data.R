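#' Simulated map specification
#'
#' Grid and imaging parameters for [render_map()]. Defaults emulate the
#' medium-resolution single-particle setting this package targets: 1.64
#' Angstrom voxels and ~7 Angstrom resolution features.
#'
#' @param voxel_size Angstrom per voxel (> 0).
#' @param resolution nominal resolution in Angstrom (>= 2 * voxel_size).
#' @param box_edge box size in voxels; `NULL` sizes the box to the model
#'   plus `margin`.
#' @param noise_sigma standard deviation of added i.i.d. Gaussian noise, in
#'   density units (kernel peak height is 1).
#' @param margin padding around the model when `box_edge` is `NULL`, Angstrom.
#' @return An object of class `map_spec`.
#' @export
map_spec <- function(voxel_size = 1.64, resolution = 7, box_edge = NULL,
                     noise_sigma = 0, margin = 10) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (resolution < 2 * voxel_size) {
    stop("resolution must be >= 2 * voxel_size (Nyquist)")
  }
  structure(list(voxel_size = voxel_size, resolution = resolution,
                 box_edge = box_edge, noise_sigma = noise_sigma,
                 margin = margin),
            class = "map_spec")
}

#' Generate a synthetic helical-bundle ground truth
#'
#' Builds a bundle of ideal alpha-helices packed on near-parallel axes with
#' alternating N-to-C direction, emulating the membrane-helix rows this
#' package is designed to trace. Axis base positions sit on a single row at
#' nearest-neighbour spacing `spacing` with random axial (membrane-depth)
#' stagger; each axis is tilted by a small random angle (uniform in
#' `[0, max_tilt]` about its midpoint, random azimuth) and each helix is
#' given a random roll. With `surface_helix`, the last helix instead lies
#' near-horizontally along the membrane plane against the side of the row.
#' The generating placement is recorded so recovery can be scored against it.
#'
#' @param n_helices number of helices (>= 1).
#' @param lengths residues per helix (recycled to `n_helices`); `NULL` uses a
#'   varied default (24, 30, 22, 28, 20, 26, ...) emulating the unequal
#'   helix lengths of natural membrane bundles.
#' @param spacing nominal inter-axis spacing in Angstrom.
#' @param rng_seed integer seed; the same seed reproduces coordinates
#'   bit-identically.
#' @param max_tilt maximum axis tilt from the bundle direction, degrees
#'   (<= 15).
#' @param z_stagger axial midpoint offsets drawn uniformly from
#'   `[-z_stagger, z_stagger]` Angstrom (membrane helices sit at different
#'   depths).
#' @param gap unmodelled residues between consecutive segments (loops).
#' @param surface_helix make the last helix run along the membrane plane,
#'   packed against the side of the row, instead of inserting it -- the
#'   arrangement of the archetypal proton-channel subunit (five
#'   membrane-inserted helices plus one helix along the membrane plane).
#' @param params a [helix_params()].
#' @return An object of class `bundle_truth`: list with `model` (combined
#'   [backbone_model()]), `segments` (tibble: helix_id, first, last),
#'   `axes` (list of true [rod_axis()] per helix), `true_assignment` (tibble:
#'   helix_id, rod, direction, roll), and `rng_seed`.
#' @export
make_bundle <- function(n_helices = 6, lengths = NULL, spacing = 10,
                        rng_seed = 1, max_tilt = 3, z_stagger = 8, gap = 3,
                        surface_helix = FALSE, params = helix_params()) {
  if (n_helices < 1) stop("n_helices must be >= 1")
  if (is.null(lengths)) lengths <- c(30, 34, 28, 36, 26, 32)
  lengths <- rep_len(lengths, n_helices)
  if (any(lengths < 6)) stop("each helix must have >= 6 residues")
  if (max_tilt > 15) stop("max_tilt is capped at 15 degrees")
  if (surface_helix && n_helices < 3) {
    stop("surface_helix needs at least 3 helices")
  }
  set.seed(as.integer(rng_seed))

  n_tm <- n_helices - as.integer(surface_helix)
  rise <- helix_stats(build_ideal_helix(max(12, max(lengths)), params))$rise
  base <- bundle_positions(n_tm) * spacing

  # axial stagger: membrane helices sit at different depths; this also keeps
  # the bundle from being mirror-symmetric about the membrane mid-plane
  # (under such a mirror, reversing every helix would be indistinguishable
  # from the generating placement)
  z_off <- stats::runif(n_tm, -z_stagger, z_stagger)
  axes <- vector("list", n_helices)
  for (h in seq_len(n_tm)) {
    half <- (lengths[h] - 1) * rise / 2
    tilt <- stats::runif(1, 0, max_tilt) * pi / 180
    azim <- stats::runif(1, 0, 2 * pi)
    u <- c(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt))
    mid <- c(base[h, ], z_off[h])
    axes[[h]] <- rod_axis(mid - half * u, mid + half * u)
  }
  if (surface_helix) {
    # one near-horizontal helix lying along the membrane plane, packed
    # against the side of the row at the nominal spacing -- every inserted
    # helix crosses it at the same distance, as the strongly tilted
    # membrane-intrinsic helices of proton-channel subunits do
    half <- (lengths[n_helices] - 1) * rise / 2
    tilt <- stats::runif(1, 0, max_tilt) * pi / 180
    azim <- stats::runif(1, 0, 2 * pi)
    u <- c(cos(tilt), sin(tilt) * cos(azim), sin(tilt) * sin(azim))
    # off-centre along the row: a centred horizontal helix would make a
    # mirror image of the row (reflect the inserted helices, flip this one)
    # satisfy almost the same constraints
    mid <- c(mean(range(base[, 1])) - 0.8 * spacing, -spacing, 0)
    axes[[n_helices]] <- rod_axis(mid - half * u, mid + half * u)
  }
  if (n_helices > 1) {
    mind <- min_axis_distance(axes)
    if (mind < 4) {
      stop(sprintf("unphysical bundle: axes approach to %.2f A (< 4 A)", mind))
    }
  }

  dirs <- ifelse(seq_len(n_helices) %% 2 == 1, "forward", "reverse")
  rolls <- stats::runif(n_helices, 0, 360)
  first <- cumsum(c(1, utils::head(lengths, -1) + gap))
  pieces <- vector("list", n_helices)
  for (h in seq_len(n_helices)) {
    pieces[[h]] <- place_helix(lengths[h], axes[[h]], dirs[h],
                               register_shift = 0, roll = rolls[h],
                               params = params, first_resno = first[h])
  }
  structure(list(
    model = bind_models(pieces),
    segments = tibble::tibble(helix_id = seq_len(n_helices),
                              first = as.integer(first),
                              last = as.integer(first + lengths - 1L)),
    axes = axes,
    true_assignment = tibble::tibble(helix_id = seq_len(n_helices),
                                     rod = seq_len(n_helices),
                                     direction = dirs, roll = rolls),
    rng_seed = as.integer(rng_seed)
  ), class = "bundle_truth")
}

#' @export
print.bundle_truth <- function(x, ...) {
  cat(sprintf("<bundle_truth> %d helices, %d residues, seed %d\n",
              nrow(x$segments), length(x$model$resno), x$rng_seed))
  invisible(x)
}

# Axis base positions (units of the nominal spacing): a single row. Membrane
# subunits traced at medium resolution look like curved rows or sheets of
# helices rather than symmetric globular bundles, and a row keeps every
# non-consecutive axis pair about two spacings apart, so a contact pair
# placed across non-neighbouring rods clearly violates the 15 A satisfaction
# check. In a compact ring or triangular packing, second-neighbour axes are
# close enough that permuted placements satisfy the same constraints and the
# generating assignment is unidentifiable in principle.
bundle_positions <- function(n) {
  cbind(seq_len(n) - 1, 0)
}

#' Minimum distance between axis segments of a bundle
#' @param axes list of [rod_axis()] objects.
#' @return Minimum pairwise segment-segment distance (Angstrom).
#' @export
min_axis_distance <- function(axes) {
  k <- length(axes)
  mind <- Inf
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    mind <- min(mind, segment_distance(axes[[i]], axes[[j]]))
  }
  mind
}

# minimum distance between two finite segments (dense parametric sampling is
# avoided: closed-form clamped quadratic minimisation)
segment_distance <- function(r1, r2) {
  p1 <- r1$endpoint_a; d1 <- r1$endpoint_b - p1
  p2 <- r2$endpoint_a; d2 <- r2$endpoint_b - p2
  r <- p1 - p2
  a <- sum(d1 * d1); b <- sum(d1 * d2); c <- sum(d2 * d2)
  d <- sum(d1 * r); e <- sum(d2 * r)
  den <- a * c - b * b
  s <- if (den > 1e-12) max(0, min(1, (b * e - c * d) / den)) else 0
  t <- if (c > 1e-12) max(0, min(1, (b * s + e) / c)) else 0
  s <- max(0, min(1, (b * t - d) / a))
  sqrt(sum((p1 + s * d1 - p2 - t * d2)^2))
}

#' Generate a contact list with a controlled false-positive rate
#'
#' Emulates the top-N output of an evolutionary-coupling pipeline against a
#' known ground-truth structure. True pairs are drawn without replacement
#' from residue pairs with CA-CA distance <= `true_threshold` and sequence
#' separation >= `min_separation`; false pairs from pairs with CA-CA
#' distance > `false_floor`. `round(n_pairs * (1 - fp_rate))` pairs are true.
#' Scores are distinct and deterministically assigned so ordering is
#' reproducible under the seed.
#'
#' @param truth a [make_bundle()] result (or any object with a `model`
#'   [backbone_model()]).
#' @param n_pairs total pairs to generate.
#' @param fp_rate fraction of false pairs in `[0, 1)`.
#' @param true_threshold CA-CA distance defining a true contact, Angstrom.
#' @param rng_seed integer seed.
#' @param min_separation minimum |i - j| for generated same-chain pairs.
#' @param false_floor minimum CA-CA distance of generated false pairs,
#'   Angstrom.
#' @param partner optional partner-chain [backbone_model()] (e.g. a c-ring
#'   stand-in, chain "C"); when given, `n_inter` inter-chain true pairs are
#'   generated in addition to `n_pairs` same-chain pairs.
#' @param n_inter number of inter-chain pairs when `partner` is supplied.
#' @param inter_threshold CA-CA distance defining an inter-chain contact.
#' @return A contacts [tibble::tibble()] with columns `res_i`, `res_j`,
#'   `score`, `chain_i`, `chain_j`, sorted by score descending.
#' @export
make_contacts <- function(truth, n_pairs = 90, fp_rate = 0.06,
                          true_threshold = 8, rng_seed = 1,
                          min_separation = 5, false_floor = 20,
                          partner = NULL, n_inter = 0, inter_threshold = 10) {
  if (fp_rate < 0 || fp_rate >= 1) stop("fp_rate must be in [0, 1)")
  model <- if (inherits(truth, "bundle_truth")) truth$model else truth
  set.seed(as.integer(rng_seed))
  ca <- ca_coords(model)
  res <- model$resno
  nr <- length(res)
  ij <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
  sep_ok <- abs(res[ij[, 2]] - res[ij[, 1]]) >= min_separation
  ij <- ij[sep_ok, , drop = FALSE]
  d <- sqrt(rowSums((ca[ij[, 1], , drop = FALSE] - ca[ij[, 2], , drop = FALSE])^2))

  n_true <- round(n_pairs * (1 - fp_rate))
  n_false <- n_pairs - n_true
  true_pool <- which(d <= true_threshold)
  false_pool <- which(d > false_floor)
  if (length(true_pool) < n_true) {
    stop(sprintf("insufficient true pairs: need %d, only %d pairs under %.1f A",
                 n_true, length(true_pool), true_threshold))
  }
  if (length(false_pool) < n_false) {
    stop(sprintf("insufficient false pairs: need %d, only %d pairs over %.1f A",
                 n_false, length(false_pool), false_floor))
  }
  pick_t <- sample(true_pool, n_true)
  pick_f <- sample(false_pool, n_false)
  sel <- c(pick_t, pick_f)
  out <- tibble::tibble(
    res_i = res[ij[sel, 1]], res_j = res[ij[sel, 2]],
    score = NA_real_, chain_i = "A", chain_j = "A"
  )
  # distinct scores over a random permutation: rank order carries no signal
  # about truth status, only reproducibility
  out$score <- round(seq(2, 1, length.out = nrow(out)), 6)[order(sample.int(nrow(out)))]

  if (!is.null(partner) && n_inter > 0) {
    pca <- ca_coords(partner)
    cross <- as.matrix(stats::dist(rbind(ca, pca)))[seq_len(nr),
                                                    nr + seq_len(nrow(pca)),
                                                    drop = FALSE]
    cand <- which(cross <= inter_threshold, arr.ind = TRUE)
    if (nrow(cand) < n_inter) {
      stop(sprintf("insufficient inter-chain pairs: need %d, found %d under %.1f A",
                   n_inter, nrow(cand), inter_threshold))
    }
    pick <- cand[sample.int(nrow(cand), n_inter), , drop = FALSE]
    inter <- tibble::tibble(
      res_i = res[pick[, 1]], res_j = partner$resno[pick[, 2]],
      score = round(seq(0.99, 0.9, length.out = n_inter), 6),
      chain_i = "A", chain_j = "C"
    )
    out <- rbind(out, inter)
  }
  out[order(-out$score, out$res_i, out$res_j), ]
}

#' Render a backbone model into a simulated density map
#'
#' Each CA contributes an isotropic Gaussian kernel of width
#' `sigma = resolution / (pi * sqrt(2))` (a standard resolution-to-sigma
#' convention) and unit peak height; optional i.i.d. Gaussian noise is added.
#' The box is centred on the model unless `spec$box_edge` fixes its size.
#'
#' @param model a [backbone_model()].
#' @param spec a [map_spec()].
#' @param rng_seed integer seed for the noise (ignored when
#'   `noise_sigma = 0`).
#' @return A [density_map()].
#' @export
render_map <- function(model, spec = map_spec(), rng_seed = 1) {
  ca <- ca_coords(model)
  vx <- spec$voxel_size
  ctr <- (apply(ca, 2, max) + apply(ca, 2, min)) / 2
  if (is.null(spec$box_edge)) {
    extent <- max(apply(ca, 2, max) - apply(ca, 2, min)) + 2 * spec$margin
    nvox <- as.integer(ceiling(extent / vx))
  } else {
    nvox <- as.integer(spec$box_edge)
  }
  origin <- ctr - (nvox - 1) * vx / 2
  lim_lo <- origin - vx / 2
  lim_hi <- origin + (nvox - 0.5) * vx
  if (any(sweep(ca, 2, lim_lo) < 0) || any(sweep(ca, 2, lim_hi) > 0)) {
    stop("model does not fit in the requested box")
  }
  sigma <- spec$resolution / (pi * sqrt(2))
  grid <- array(0, dim = rep(nvox, 3))
  axes_ang <- lapply(1:3, function(k) origin[k] + (seq_len(nvox) - 1) * vx)
  reach <- ceiling(4 * sigma / vx)
  for (a in seq_len(nrow(ca))) {
    idx0 <- round((ca[a, ] - origin) / vx) + 1
    rng <- lapply(1:3, function(k) {
      max(1, idx0[k] - reach):min(nvox, idx0[k] + reach)
    })
    gx <- exp(-(axes_ang[[1]][rng[[1]]] - ca[a, 1])^2 / (2 * sigma^2))
    gy <- exp(-(axes_ang[[2]][rng[[2]]] - ca[a, 2])^2 / (2 * sigma^2))
    gz <- exp(-(axes_ang[[3]][rng[[3]]] - ca[a, 3])^2 / (2 * sigma^2))
    grid[rng[[1]], rng[[2]], rng[[3]]] <-
      grid[rng[[1]], rng[[2]], rng[[3]]] + outer(gx, outer(gy, gz))
  }
  if (spec$noise_sigma > 0) {
    set.seed(as.integer(rng_seed))
    grid <- grid + array(stats::rnorm(length(grid), 0, spec$noise_sigma),
                         dim = dim(grid))
  }
  density_map(grid, vx, origin)
}

#' Generate an ensemble of conformational-state maps
#'
#' One map per rotation angle, in which only the mobile sub-structure is
#' rotated about the supplied axis; the rest of the model stays fixed.
#' Emulates a set of single-particle maps of distinct rotational sub-states.
#' Noise is drawn independently per map (deterministically under the seed).
#'
#' @param truth a [make_bundle()] result.
#' @param mobile_part helix ids (integers, subset of `truth$segments$helix_id`)
#'   or a separate [backbone_model()] (e.g. a rotating ring) appended to the
#'   static model.
#' @param angles rotation angles in degrees, one map per angle.
#' @param axis list with `point` and `direction` (length-3 each) defining the
#'   rotation axis.
#' @param spec a [map_spec()]; all maps share its grid (a common `box_edge`
#'   is computed if unset).
#' @param rng_seed integer seed.
#' @return A list of [density_map()] objects, one per angle.
#' @export
make_state_ensemble <- function(truth, mobile_part, angles,
                                axis = list(point = c(0, 0, 0),
                                            direction = c(0, 0, 1)),
                                spec = map_spec(), rng_seed = 1) {
  if (length(angles) < 1) stop("angles must be non-empty")
  static <- truth$model
  if (inherits(mobile_part, "backbone_model")) {
    mobile <- mobile_part
  } else {
    if (length(mobile_part) == 0) stop("mobile_part must not be empty")
    if (!all(mobile_part %in% truth$segments$helix_id)) {
      stop("mobile_part contains unknown helix ids")
    }
    segs <- truth$segments[truth$segments$helix_id %in% mobile_part, ]
    mobile <- bind_models(lapply(seq_len(nrow(segs)), function(k) {
      slice_model(truth$model, segs$first[k], segs$last[k])
    }))
    keep <- !(static$resno %in% mobile$resno)
    static <- backbone_model(static$resno[keep], static$n[keep, , drop = FALSE],
                             static$ca[keep, , drop = FALSE],
                             static$c[keep, , drop = FALSE],
                             static$o[keep, , drop = FALSE])
  }
  if (is.null(spec$box_edge)) {
    allca <- rbind(ca_coords(static), ca_coords(mobile))
    extent <- max(apply(allca, 2, max) - apply(allca, 2, min)) +
      2 * spec$margin + 2 * max(abs(angles)) * pi / 180 *
      max(sqrt(rowSums(sweep(ca_coords(mobile), 2, axis$point)^2)))
    spec$box_edge <- as.integer(ceiling(extent / spec$voxel_size))
  }
  combined0 <- merge_chain_models(static, mobile)
  # one shared grid frame for all states, centred on the base combined model
  ca0 <- ca_coords(combined0)
  nvox <- as.integer(spec$box_edge)
  ctr <- (apply(ca0, 2, max) + apply(ca0, 2, min)) / 2
  template <- density_map(array(0, dim = rep(2, 3)), spec$voxel_size,
                          ctr - (nvox - 1) * spec$voxel_size / 2)
  template$grid <- array(0, dim = rep(nvox, 3))
  set.seed(as.integer(rng_seed))
  seeds <- sample.int(2^30, length(angles))
  lapply(seq_along(angles), function(k) {
    tr <- rotation_about_line(axis$direction, angles[k], axis$point)
    moved <- transform_model(mobile, tr)
    m <- merge_chain_models(static, moved)
    map <- render_on_grid(m, template, spec$resolution)
    if (spec$noise_sigma > 0) {
      set.seed(seeds[k])
      map$grid <- map$grid + array(stats::rnorm(length(map$grid), 0,
                                                spec$noise_sigma),
                                   dim = dim(map$grid))
    }
    map
  })
}

# combine two backbone models that may share residue numbering (different
# conceptual chains) into one coordinate set for rendering
merge_chain_models <- function(a, b) {
  if (length(a$resno) == 0) return(b)
  if (length(b$resno) == 0) return(a)
  if (length(intersect(a$resno, b$resno)) == 0) {
    return(bind_models(list(a, b)[order(c(min(a$resno), min(b$resno)))]))
  }
  # renumber b past a to keep the container valid; rendering only uses CA xyz
  off <- max(a$resno) + 10L
  b2 <- backbone_model(b$resno + off, b$n, b$ca, b$c, b$o)
  bind_models(list(a, b2))
}

# render a model onto the grid of an existing map (same origin / voxel / dims)
render_on_grid <- function(model, template, resolution) {
  ca <- ca_coords(model)
  vx <- template$voxel_size
  origin <- template$origin
  nv <- dim(template$grid)
  sigma <- resolution / (pi * sqrt(2))
  grid <- array(0, dim = nv)
  axes_ang <- lapply(1:3, function(k) origin[k] + (seq_len(nv[k]) - 1) * vx)
  reach <- ceiling(4 * sigma / vx)
  for (a in seq_len(nrow(ca))) {
    idx0 <- round((ca[a, ] - origin) / vx) + 1
    rng <- lapply(1:3, function(k) {
      lo <- max(1, idx0[k] - reach); hi <- min(nv[k], idx0[k] + reach)
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) next
    gx <- exp(-(axes_ang[[1]][rng[[1]]] - ca[a, 1])^2 / (2 * sigma^2))
    gy <- exp(-(axes_ang[[2]][rng[[2]]] - ca[a, 2])^2 / (2 * sigma^2))
    gz <- exp(-(axes_ang[[3]][rng[[3]]] - ca[a, 3])^2 / (2 * sigma^2))
    grid[rng[[1]], rng[[2]], rng[[3]]] <-
      grid[rng[[1]], rng[[2]], rng[[3]]] + outer(gx, outer(gy, gz))
  }
  density_map(grid, vx, origin)
}

#' Generate a symmetric ring of helices (c-ring stand-in)
#'
#' `n_subunits` copies of a single ideal helix arranged with rotational
#' symmetry about the z axis through `center`. Used as a partner chain for
#' inter-chain constraint scoring and as the mobile part of rotational
#' state ensembles.
#'
#' @param n_subunits ring symmetry order (default 8, as in a c8 rotor ring).
#' @param helix_length residues per subunit helix.
#' @param radius ring radius in Angstrom.
#' @param center ring centre.
#' @param first_resno numbering of the first subunit's first residue.
#' @param params a [helix_params()].
#' @return A [backbone_model()] with `n_subunits * helix_length` residues,
#'   numbered consecutively subunit by subunit.
#' @export
make_ring <- function(n_subunits = 8, helix_length = 20, radius = 20,
                      center = c(0, 0, 0), first_resno = 1L,
                      params = helix_params()) {
  if (n_subunits < 1) stop("n_subunits must be >= 1")
  half <- (helix_length - 1) * 1.5 / 2
  sub <- vector("list", n_subunits)
  for (s in seq_len(n_subunits)) {
    th <- 2 * pi * (s - 1) / n_subunits
    mid <- center + c(radius * cos(th), radius * sin(th), 0)
    rod <- rod_axis(mid - c(0, 0, half), mid + c(0, 0, half))
    sub[[s]] <- place_helix(helix_length, rod, "forward", 0,
                            roll = th * 180 / pi, params = params,
                            first_resno = first_resno +
                              (s - 1L) * as.integer(helix_length))
  }
  bind_models(sub)
}

#' Write a bundle truth to disk
#'
#' The model goes to PDB (chain A; an optional partner ring as chain C),
#' segments and the generating assignment to JSON.
#'
#' @param truth a [make_bundle()] result.
#' @param dir output directory (created if needed).
#' @param partner optional partner [backbone_model()] written as chain C.
#' @return Named character vector of the files written, invisibly.
#' @export
write_bundle <- function(truth, dir, partner = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, "truth_model.pdb")
  models <- list(A = truth$model)
  if (!is.null(partner)) models$C <- partner
  write_model_pdb(models, pdb)
  meta <- file.path(dir, "truth_meta.json")
  jsonlite::write_json(list(
    segments = truth$segments,
    true_assignment = truth$true_assignment,
    rng_seed = truth$rng_seed
  ), meta, auto_unbox = TRUE, digits = NA)
  invisible(c(model = pdb, metadata = meta))
}
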