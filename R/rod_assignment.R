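#' Detect rod-like (helical) features in a density map
#'
#' Voxels above `density_threshold` are grouped into 26-connected components;
#' each component elongated enough to be a trans-membrane helix is summarised
#' by its principal axis. A component is kept when its axial extent is at
#' least `min_length` and the anisotropy of its voxel cloud (largest /
#' second singular value) is at least `anisotropy_min`.
#'
#' @param map a [density_map()].
#' @param density_threshold density cutoff; must lie within the map's value
#'   range.
#' @param min_length minimum axial extent in Angstrom.
#' @param anisotropy_min minimum elongation ratio.
#' @param min_voxels components smaller than this are ignored as speckle.
#' @param smooth_sigma optional Gaussian pre-smoothing (Angstrom, see
#'   [smooth_map()]); 0 disables. Smoothing before thresholding is standard
#'   for noisy maps; the threshold is applied on the smoothed density scale.
#' @param stitch merge nearly collinear fragments of one rod? At thresholds
#'   high enough to separate adjacent helices the thresholded tube is only
#'   one or two voxels thick, so noise routinely splits a helix into
#'   collinear fragments; stitching joins fragments whose combined voxel
#'   cloud is still rod-like (gap below `stitch_gap` Angstrom, lateral RMS
#'   residual below `stitch_residual` Angstrom).
#' @param stitch_gap,stitch_residual stitching tolerances in Angstrom.
#' @param split_residual components whose lateral RMS spread about their own
#'   axis exceeds this (Angstrom) are treated as two tubes fused by a
#'   density bridge -- common where helices touch at contact points -- and
#'   are split across their second principal axis, recursively.
#' @return A list of [rod_axis()] objects (possibly empty), ordered by
#'   decreasing length.
#' @export
rod_detect <- function(map, density_threshold, min_length = 15,
                       anisotropy_min = 2, min_voxels = 5,
                       smooth_sigma = 0, stitch = TRUE, stitch_gap = 4,
                       stitch_residual = 2.5, split_residual = 3) {
  if (smooth_sigma > 0) map <- smooth_map(map, smooth_sigma)
  if (density_threshold < min(map$grid) || density_threshold > max(map$grid)) {
    stop("density_threshold outside the map's value range")
  }
  sel <- which(map$grid > density_threshold)
  if (length(sel) == 0) return(list())
  dims <- dim(map$grid)
  id <- seq_along(sel)
  pos <- arrayInd(sel, dims)
  lookup <- array(0L, dims)
  lookup[sel] <- id
  # 13 positive neighbour offsets of the 26-neighbourhood
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[(offs[, 3] > 0) | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, -offs[k, ])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_id <- rep(0L, length(id))
    nb_id[ok] <- lookup[nb[ok, , drop = FALSE]]
    hit <- nb_id > 0L
    if (any(hit)) edges[[k]] <- cbind(id[hit], nb_id[hit])
  }
  el <- do.call(rbind, edges)
  if (is.null(el)) {
    comp <- id
  } else {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(id) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  clouds <- list()
  for (cid in seq_len(max(comp))) {
    members <- which(comp == cid)
    if (length(members) < min_voxels) next
    xyz <- sweep(pos[members, , drop = FALSE] - 1, 2, -map$origin / map$voxel_size)
    clouds[[length(clouds) + 1]] <- xyz * map$voxel_size
  }
  clouds <- unlist(lapply(clouds, split_cloud, max_residual = split_residual,
                          min_voxels = min_voxels), recursive = FALSE)
  if (stitch) clouds <- stitch_clouds(clouds, stitch_gap, stitch_residual)
  rods <- list()
  for (xyz in clouds) {
    st <- cloud_axis(xyz)
    if (st$extent >= min_length && st$aniso >= anisotropy_min) {
      rods[[length(rods) + 1]] <- st$rod
    }
  }
  rods[order(-vapply(rods, rod_length, 1))]
}

# principal-axis summary of a voxel cloud
cloud_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 2)
  aniso <- if (sv$d[2] < 1e-9) Inf else sv$d[1] / sv$d[2]
  u <- as.numeric(sv$v[, 1])
  proj <- as.numeric(xc %*% u)
  lateral <- xc - outer(proj, u)
  list(rod = rod_axis(ctr + min(proj) * u, ctr + max(proj) * u),
       extent = max(proj) - min(proj), aniso = aniso,
       residual = sqrt(mean(rowSums(lateral^2))))
}

# recursively split clouds that are too wide to be one tube: assign voxels
# by the sign of their projection on the second principal axis
split_cloud <- function(xyz, max_residual, min_voxels, min_sep = 5) {
  st <- cloud_axis(xyz)
  if (st$residual <= max_residual || nrow(xyz) < 2 * min_voxels) {
    return(list(xyz))
  }
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  u <- rod_direction(st$rod)
  lat <- xc - outer(as.numeric(xc %*% u), u)
  # deterministic 2-means on the lateral coordinates: seed with the most
  # off-axis voxel and the voxel farthest from it
  i1 <- which.max(rowSums(lat^2))
  i2 <- which.max(rowSums(sweep(lat, 2, lat[i1, ])^2))
  c1 <- lat[i1, ]; c2 <- lat[i2, ]
  side <- logical(nrow(lat))
  for (it in 1:15) {
    d1 <- rowSums(sweep(lat, 2, c1)^2)
    d2 <- rowSums(sweep(lat, 2, c2)^2)
    new_side <- d1 <= d2
    if (it > 1 && all(new_side == side)) break
    side <- new_side
    if (all(side) || !any(side)) return(list(xyz))
    c1 <- colMeans(lat[side, , drop = FALSE])
    c2 <- colMeans(lat[!side, , drop = FALSE])
  }
  a <- xyz[side, , drop = FALSE]
  b <- xyz[!side, , drop = FALSE]
  # a genuine two-tube component separates into laterally distinct halves;
  # a single thick tube does not, and is kept whole
  dc <- colMeans(a) - colMeans(b)
  sep <- sqrt(sum((dc - sum(dc * u) * u)^2))
  if (sep < min_sep) return(list(xyz))
  c(split_cloud(a, max_residual, min_voxels, min_sep),
    split_cloud(b, max_residual, min_voxels, min_sep))
}

# greedy merging of voxel clouds that remain rod-like when combined
stitch_clouds <- function(clouds, gap, residual) {
  repeat {
    n <- length(clouds)
    if (n < 2) return(clouds)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- clouds[[i]]; b <- clouds[[j]]
        # nearest approach between the two clouds
        mind <- min(vapply(seq_len(nrow(a)), function(k) {
          min(sqrt(rowSums(sweep(b, 2, a[k, ])^2)))
        }, 1))
        if (mind > gap) next
        st <- cloud_axis(rbind(a, b))
        if (st$residual <= residual) {
          clouds[[i]] <- rbind(a, b)
          clouds[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(clouds)
  }
}

#' Helix-to-rod assignment problem
#'
#' Bundles everything the combinatorial search needs: the helix segments of
#' the sequence, the density rods, the contact constraints, and the discrete
#' register/roll grids over which each placement is refined.
#'
#' @param segments tibble/data frame with columns `helix_id`, `first`,
#'   `last` (1-based inclusive residue numbering).
#' @param rods list of [rod_axis()] objects (at least as many as segments).
#' @param pairs contacts tibble (see [read_contacts()]).
#' @param threshold satisfaction distance, Angstrom.
#' @param register_range register searched over `-register_range ..
#'   +register_range` residues.
#' @param roll_samples number of equally spaced roll angles in `[0, 360)`.
#' @param partner optional partner-chain [backbone_model()] (chain "C") for
#'   inter-chain pairs.
#' @param params a [helix_params()].
#' @return An object of class `assignment_problem`.
#' @export
assignment_problem <- function(segments, rods, pairs, threshold = 15,
                               register_range = 4, roll_samples = 8,
                               partner = NULL, params = helix_params()) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("helix_id", "first", "last") %in% names(segments)))
  if (nrow(segments) > length(rods)) {
    stop("more segments than rods: every helix needs a rod")
  }
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(segments = segments, rods = rods, pairs = pairs,
                 threshold = threshold, register_range = register_range,
                 roll_samples = roll_samples, partner = partner,
                 params = params),
            class = "assignment_problem")
}

#' Enumerate geometric assignments (rod choice and direction)
#'
#' Yields every injective mapping of the K segments onto the rods combined
#' with every per-helix direction, `P(n_rods, K) * 2^K` assignments in a
#' deterministic order: injective rod tuples in lexicographic order, and for
#' each tuple the direction words `0 .. 2^K - 1` in ascending order (bit
#' `h - 1` set means helix `h` is reversed).
#'
#' @param problem an [assignment_problem()] (or anything with `segments` and
#'   `rods`).
#' @param max_exhaustive hard cap on K for exhaustive enumeration.
#' @return A list with `rods` (matrix, one row per assignment, column per
#'   helix) and `reversed` (logical matrix of the same shape).
#' @export
enumerate_assignments <- function(problem, max_exhaustive = 8) {
  K <- nrow(problem$segments)
  n_rods <- length(problem$rods)
  if (K > max_exhaustive) {
    stop(sprintf(
      "K = %d segments exceeds the exhaustive cap (%d): use search_best(mode = 'greedy')",
      K, max_exhaustive))
  }
  tuples <- injective_tuples(n_rods, K)
  n_dir <- 2L^K
  dir_words <- 0:(n_dir - 1L)
  rods <- tuples[rep(seq_len(nrow(tuples)), each = n_dir), , drop = FALSE]
  rev_mat <- t(vapply(dir_words, function(m) bitwAnd(m, 2L^(seq_len(K) - 1L)) > 0L,
                      logical(K)))
  if (K == 1) rev_mat <- matrix(rev_mat, ncol = 1)
  reversed <- rev_mat[rep(seq_len(n_dir), times = nrow(tuples)), , drop = FALSE]
  list(rods = rods, reversed = reversed)
}

# all injective K-tuples from 1..n in lexicographic order
injective_tuples <- function(n, k) {
  if (k == 0) return(matrix(integer(), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (d in seq_len(k - 1)) {
    pieces <- lapply(seq_len(nrow(out)), function(r) {
      nxt <- setdiff(seq_len(n), out[r, ])
      cbind(matrix(out[r, ], length(nxt), d, byrow = TRUE), nxt)
    })
    out <- do.call(rbind, pieces)
  }
  unname(out)
}

# register values and roll grid for a problem
register_grid <- function(problem) seq(-problem$register_range, problem$register_range)
roll_grid <- function(problem) seq(0, 360, length.out = problem$roll_samples + 1)[seq_len(problem$roll_samples)]

#' Score one assignment by constraint satisfaction
#'
#' Places each helix on its assigned rod and direction, refines register and
#' roll over the problem's discrete grids, and scores the combined model with
#' [satisfaction()]. Refinement is a deterministic forward sweep: helices
#' start at register 0 / roll 0 and are optimised one at a time in segment
#' order (maximising satisfied pairs, then minimising total distance; ties
#' resolved towards the smaller register, then the smaller roll).
#'
#' @param problem an [assignment_problem()].
#' @param assignment list/tibble with per-helix `rod` (1-based rod index) and
#'   `direction` (`"forward"`/`"reverse"`), in segment order.
#' @param models_cache optional environment used to memoise built helices
#'   across calls.
#' @return A list of class `scored_assignment`: `report` (the
#'   [satisfaction()] result), `placements` (tibble with the refined
#'   register/roll per helix), and `model` (the combined [backbone_model()]).
#' @export
score_assignment <- function(problem, assignment, models_cache = NULL) {
  segs <- problem$segments
  K <- nrow(segs)
  rod_idx <- assignment$rod
  dirs <- assignment$direction
  if (anyDuplicated(rod_idx)) stop("assignment must map helices to distinct rods")
  regs <- register_grid(problem)
  rolls <- roll_grid(problem)
  if (is.null(models_cache)) models_cache <- new.env(parent = emptyenv())

  place_seg <- function(h, reg, roll) {
    key <- sprintf("%d_%d_%s_%d_%g", h, rod_idx[h], dirs[h], reg, roll)
    if (!is.null(models_cache[[key]])) return(models_cache[[key]])
    m <- place_helix(segs$last[h] - segs$first[h] + 1L,
                     problem$rods[[rod_idx[h]]], dirs[h], reg, roll,
                     params = problem$params, first_resno = segs$first[h])
    models_cache[[key]] <- m
    m
  }
  combined <- function(pieces) {
    mods <- list(A = bind_models(pieces[order(segs$first)]))
    if (!is.null(problem$partner)) mods$C <- problem$partner
    mods
  }
  # resolve each pair endpoint once: (segment index, row within segment) for
  # chain-A residues inside segments, fixed partner coordinates otherwise
  locate <- function(res, chain) {
    if (chain != "C") {
      h <- which(segs$first <= res & segs$last >= res)
      if (length(h) == 1) return(c(h, res - segs$first[h] + 1L))
      return(NULL)
    }
    if (is.null(problem$partner)) return(NULL)
    k <- match(res, problem$partner$resno)
    if (is.na(k)) return(NULL) else return(c(0L, k))
  }
  pr <- problem$pairs
  loc_i <- lapply(seq_len(nrow(pr)), function(p) locate(pr$res_i[p], pr$chain_i[p]))
  loc_j <- lapply(seq_len(nrow(pr)), function(p) locate(pr$res_j[p], pr$chain_j[p]))
  resolvable <- !vapply(loc_i, is.null, TRUE) & !vapply(loc_j, is.null, TRUE)
  if (!any(resolvable)) {
    stop("no resolvable pairs: satisfaction fraction is undefined")
  }
  li <- do.call(rbind, loc_i[resolvable])
  lj <- do.call(rbind, loc_j[resolvable])
  pca <- if (is.null(problem$partner)) matrix(0, 0, 3) else ca_coords(problem$partner)
  end_coords <- function(loc, pieces) {
    out <- matrix(NA_real_, nrow(loc), 3)
    part <- loc[, 1] == 0L
    if (any(part)) out[part, ] <- pca[loc[part, 2], , drop = FALSE]
    for (h in unique(loc[!part, 1])) {
      sel <- loc[, 1] == h
      out[sel, ] <- pieces[[h]]$ca[loc[sel, 2], , drop = FALSE]
    }
    out
  }
  eval_counts <- function(pieces) {
    d <- sqrt(rowSums((end_coords(li, pieces) - end_coords(lj, pieces))^2))
    c(sum(d <= problem$threshold), sum(d))
  }

  cur_reg <- rep(0, K); cur_roll <- rep(0, K)
  pieces <- lapply(seq_len(K), function(h) place_seg(h, 0, 0))
  for (h in seq_len(K)) {
    best <- NULL
    for (reg in regs) for (roll in rolls) {
      cand <- pieces
      cand[[h]] <- place_seg(h, reg, roll)
      sc <- eval_counts(cand)
      if (is.null(best) || sc[1] > best$sc[1] ||
          (sc[1] == best$sc[1] && sc[2] < best$sc[2] - 1e-9)) {
        best <- list(sc = sc, reg = reg, roll = roll)
      }
    }
    cur_reg[h] <- best$reg; cur_roll[h] <- best$roll
    pieces[[h]] <- place_seg(h, best$reg, best$roll)
  }
  report <- satisfaction(combined(pieces), problem$pairs, problem$threshold)
  structure(list(
    report = report,
    placements = tibble::tibble(helix_id = segs$helix_id, rod = rod_idx,
                                direction = dirs, register = cur_reg,
                                roll = cur_roll),
    model = bind_models(pieces[order(segs$first)])
  ), class = "scored_assignment")
}

#' @export
print.scored_assignment <- function(x, ...) {
  cat("<scored_assignment>\n")
  print(x$placements)
  print(x$report)
  invisible(x)
}

#' Match detected rods to ground-truth axes
#'
#' Pairs each true axis with the nearest detected rod (greedy on midpoint
#' distance), recording whether the detected rod's arbitrary endpoint order
#' runs opposite to the true axis direction. Used to express a generating
#' placement in terms of detected rods when scoring recovery.
#'
#' @param rods list of detected [rod_axis()] objects.
#' @param axes list of true [rod_axis()] objects (one per helix, in helix
#'   order).
#' @return Tibble with one row per true axis: `helix_id`, `rod` (index into
#'   `rods`), `flipped` (detected direction opposes the true one),
#'   `midpoint_distance`, `angle` (degrees between axis lines).
#' @export
match_rods_to_axes <- function(rods, axes) {
  if (length(rods) < length(axes)) {
    stop("fewer detected rods than true axes")
  }
  dmat <- outer(seq_along(axes), seq_along(rods), Vectorize(function(i, j) {
    sqrt(sum((rod_midpoint(axes[[i]]) - rod_midpoint(rods[[j]]))^2))
  }))
  match_rod <- integer(length(axes))
  free <- rep(TRUE, length(rods))
  dm <- dmat
  for (k in seq_along(axes)) {
    best <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    match_rod[best[1]] <- best[2]
    dm[best[1], ] <- Inf
    dm[, best[2]] <- Inf
    free[best[2]] <- FALSE
  }
  ang <- vapply(seq_along(axes), function(i) {
    cs <- sum(rod_direction(axes[[i]]) * rod_direction(rods[[match_rod[i]]]))
    acos(pmin(1, abs(cs))) * 180 / pi
  }, 1)
  flipped <- vapply(seq_along(axes), function(i) {
    sum(rod_direction(axes[[i]]) * rod_direction(rods[[match_rod[i]]])) < 0
  }, TRUE)
  tibble::tibble(helix_id = seq_along(axes), rod = match_rod,
                 flipped = flipped,
                 midpoint_distance = dmat[cbind(seq_along(axes), match_rod)],
                 angle = ang)
}

#' Express the generating assignment in terms of detected rods
#'
#' Translates a bundle truth's generating placement into the (rod, direction)
#' labels of a detected rod set, so a search result can be compared against
#' the ground truth directly.
#'
#' @param truth a [make_bundle()] result.
#' @param rods list of detected [rod_axis()] objects.
#' @return A list with `rod` and `direction` vectors in helix order.
#' @export
true_assignment_on_rods <- function(truth, rods) {
  mm <- match_rods_to_axes(rods, truth$axes)
  dirs <- truth$true_assignment$direction
  flip <- function(d) ifelse(d == "forward", "reverse", "forward")
  list(rod = mm$rod,
       direction = ifelse(mm$flipped, flip(dirs), dirs))
}
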