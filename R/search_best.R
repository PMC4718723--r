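# Precompute CA coordinates for every (segment, rod, direction, register,
# roll) placement. Register shifts and rolls are applied analytically to the
# register-0 / roll-0 placement (the algebra is identical to place_helix:
# roll about the rod axis through the shifted midpoint commutes into
# a rotation of the centred coordinates plus the axial shift).
precompute_placements <- function(problem) {
  segs <- problem$segments
  K <- nrow(segs)
  n_rods <- length(problem$rods)
  regs <- register_grid(problem)
  rolls <- roll_grid(problem)
  n_reg <- length(regs); n_roll <- length(rolls)
  lens <- segs$last - segs$first + 1L
  built <- lapply(lens, function(L) build_ideal_helix(L, problem$params))
  rises <- vapply(built, function(b) rod_length(fit_axis(b)) / (n_residues(b) - 1), 1)

  blocks <- vector("list", K * n_rods * 2L)
  off <- integer(K * n_rods * 2L)
  pos <- 0L
  for (d in 0:1) for (r in seq_len(n_rods)) for (h in seq_len(K)) {
    dir <- if (d == 0) "forward" else "reverse"
    base <- place_built_helix(built[[h]], problem$rods[[r]], dir, 0, 0)
    ca0 <- ca_coords(base)
    rodv <- rod_direction(problem$rods[[r]])
    mid <- rod_midpoint(problem$rods[[r]])
    xc <- sweep(ca0, 2, mid)
    block <- numeric(n_reg * n_roll * lens[h] * 3L)
    bi <- 1L
    for (rg in regs) {
      shift <- mid + rg * rises[h] * rodv
      for (rl in rolls) {
        R <- rotation_about_axis(rodv, rl)
        cc <- xc %*% t(R)
        cc <- sweep(cc, 2, -shift)
        block[bi:(bi + lens[h] * 3L - 1L)] <- as.vector(t(cc))
        bi <- bi + lens[h] * 3L
      }
    }
    key <- h + K * ((r - 1L) + n_rods * d)
    blocks[[key]] <- block
    off[key] <- pos
    pos <- pos + length(block)
  }
  list(coords = unlist(blocks), off = off, lens = lens,
       n_reg = n_reg, n_roll = n_roll,
       zero_reg = which(regs == 0) - 1L, zero_roll = 0L)
}

# classify pairs for the compiled scorer: seg/atom indices, partner rows,
# constants, and unresolved pairs
index_pairs <- function(problem) {
  segs <- problem$segments
  pairs <- problem$pairs
  locate <- function(res, chain) {
    if (chain != "C") {
      h <- which(segs$first <= res & segs$last >= res)
      if (length(h) == 1) return(c(h - 1L, res - segs$first[h]))
      return(NULL)
    }
    if (is.null(problem$partner)) return(NULL)
    k <- match(res, problem$partner$resno)
    if (is.na(k)) return(NULL)
    c(-1L, k - 1L)
  }
  lens <- segs$last - segs$first + 1L
  built_ca <- lapply(lens, function(L) ca_coords(build_ideal_helix(L, problem$params)))
  rows <- list(); unresolved <- list()
  const_nsat <- 0; const_dist <- 0
  add_const <- function(d) {
    const_dist <<- const_dist + d
    if (d <= problem$threshold) const_nsat <<- const_nsat + 1
  }
  for (p in seq_len(nrow(pairs))) {
    a <- locate(pairs$res_i[p], pairs$chain_i[p])
    b <- locate(pairs$res_j[p], pairs$chain_j[p])
    if (is.null(a) || is.null(b)) {
      unresolved[[length(unresolved) + 1L]] <- p
    } else if (a[1] < 0 && b[1] < 0) {
      # partner-partner: fixed geometry
      pca <- ca_coords(problem$partner)
      add_const(sqrt(sum((pca[a[2] + 1, ] - pca[b[2] + 1, ])^2)))
    } else if (a[1] >= 0 && a[1] == b[1]) {
      # intra-segment: invariant under rigid placement
      ca <- built_ca[[a[1] + 1]]
      add_const(sqrt(sum((ca[a[2] + 1, ] - ca[b[2] + 1, ])^2)))
    } else {
      if (a[1] < 0) { tmp <- a; a <- b; b <- tmp }
      rows[[length(rows) + 1L]] <- c(a, b)
    }
  }
  mat <- if (length(rows)) do.call(rbind, rows) else matrix(0L, 0, 4)
  storage.mode(mat) <- "integer"
  n_const <- nrow(pairs) - length(unresolved) - nrow(mat)
  list(pairs = mat, const_nsat = const_nsat, const_dist = const_dist,
       n_resolvable = nrow(mat) + n_const,
       n_unresolved = length(unresolved))
}

#' Exhaustively search helix-to-rod assignments
#'
#' Evaluates every injective rod choice and direction combination (see
#' [enumerate_assignments()]), refining register and roll for each by the
#' same deterministic sweep as [score_assignment()], and ranks solutions by
#' satisfied pairs (descending), mean pair distance (ascending), and
#' enumeration order for full determinism. A unique-maximiser flag records
#' whether the top solution is the only one attaining the maximal number of
#' satisfied pairs -- the formal version of "the only orientation satisfying
#' the constraints".
#'
#' For more than `max_exhaustive` segments a greedy construction with 2-swap
#' refinement is available (`mode = "greedy"`), clearly flagged as heuristic
#' in the result.
#'
#' @param problem an [assignment_problem()].
#' @param mode `"exhaustive"` (default, K <= `max_exhaustive`) or `"greedy"`.
#' @param max_exhaustive cap on K for exhaustive search.
#' @return An object of class `ranked_solutions`: list with `solutions` (a
#'   tibble, one row per assignment, best first: rod/direction/register/roll
#'   list-columns plus `n_satisfied`, `fraction_satisfied`,
#'   `mean_distance`), `n_evaluated`, `exhaustive`, `unique_maximizer`.
#' @export
search_best <- function(problem, mode = c("exhaustive", "greedy"),
                        max_exhaustive = 8) {
  mode <- match.arg(mode)
  if (length(problem$rods) == 0) stop("no rods to assign helices to")
  K <- nrow(problem$segments)
  if (mode == "greedy") return(search_greedy(problem))
  if (K > max_exhaustive) {
    stop(sprintf(
      "K = %d segments exceeds the exhaustive cap (%d): use search_best(mode = 'greedy')",
      K, max_exhaustive))
  }
  pre <- precompute_placements(problem)
  idx <- index_pairs(problem)
  if (idx$n_resolvable == 0) {
    stop("no resolvable pairs: satisfaction fraction is undefined")
  }
  partner_xyz <- if (is.null(problem$partner)) matrix(0, 1, 3) else
    ca_coords(problem$partner)
  res <- cpp_search_exhaustive(pre$coords, pre$off, pre$lens,
                               length(problem$rods), pre$n_reg, pre$n_roll,
                               idx$pairs, partner_xyz, problem$threshold,
                               idx$const_nsat, idx$const_dist,
                               pre$zero_reg, pre$zero_roll)
  enum <- enumerate_assignments(problem, max_exhaustive)
  n_sat <- res[, 1]
  mean_dist <- res[, 2] / idx$n_resolvable
  ord <- order(-n_sat, mean_dist, seq_along(n_sat))
  regs <- register_grid(problem); rolls <- roll_grid(problem)
  sol <- tibble::tibble(
    rank = seq_along(ord),
    rods = lapply(ord, function(i) enum$rods[i, ]),
    directions = lapply(ord, function(i)
      ifelse(enum$reversed[i, ], "reverse", "forward")),
    registers = lapply(ord, function(i) regs[res[i, 2 + seq_len(K)] + 1]),
    rolls = lapply(ord, function(i) rolls[res[i, 2 + K + seq_len(K)] + 1]),
    n_satisfied = as.integer(n_sat[ord]),
    fraction_satisfied = n_sat[ord] / idx$n_resolvable,
    mean_distance = mean_dist[ord]
  )
  top <- sol$n_satisfied[1]
  structure(list(solutions = sol, n_evaluated = nrow(res), exhaustive = TRUE,
                 unique_maximizer = sum(n_sat == top) == 1,
                 n_resolvable = idx$n_resolvable,
                 n_unresolved = idx$n_unresolved),
            class = "ranked_solutions")
}

#' @export
print.ranked_solutions <- function(x, ...) {
  cat(sprintf("<ranked_solutions> %d assignments evaluated (%s)\n",
              x$n_evaluated,
              if (x$exhaustive) "exhaustive" else "greedy heuristic"))
  cat(sprintf("  top solution: %d/%d pairs satisfied (mean %.2f A); unique maximizer: %s\n",
              x$solutions$n_satisfied[1], x$n_resolvable,
              x$solutions$mean_distance[1], x$unique_maximizer))
  invisible(x)
}

#' Assignment tibble of ranked solutions
#' @param x a `ranked_solutions` object.
#' @param ... unused.
#' @return The `solutions` tibble (best first).
#' @export
tidy.ranked_solutions <- function(x, ...) x$solutions

#' One-row summary of a search
#' @param x a `ranked_solutions` object.
#' @param ... unused.
#' @return One-row tibble with search metadata and the top score.
#' @export
glance.ranked_solutions <- function(x, ...) {
  tibble::tibble(n_evaluated = x$n_evaluated, exhaustive = x$exhaustive,
                 unique_maximizer = x$unique_maximizer,
                 top_n_satisfied = x$solutions$n_satisfied[1],
                 top_fraction = x$solutions$fraction_satisfied[1],
                 top_mean_distance = x$solutions$mean_distance[1])
}

#' Extract an assignment from ranked solutions
#' @param solutions a `ranked_solutions` object.
#' @param rank which solution (1 = best).
#' @return A list with `rod` and `direction` vectors usable by
#'   [score_assignment()].
#' @export
get_assignment <- function(solutions, rank = 1) {
  s <- solutions$solutions
  list(rod = s$rods[[rank]], direction = s$directions[[rank]])
}

# Greedy construction + 2-swap refinement for K beyond the exhaustive cap.
# Heuristic: no optimality guarantee; flagged in the result.
search_greedy <- function(problem) {
  segs <- problem$segments
  K <- nrow(segs)
  n_rods <- length(problem$rods)
  cache <- new.env(parent = emptyenv())
  score_of <- function(rod, dir) {
    sc <- score_assignment(problem, list(rod = rod, direction = dir), cache)
    c(sc$report$n_satisfied, -sc$report$mean_distance)
  }
  # start from the identity-order assignment, all forward
  rod <- seq_len(K); dir <- rep("forward", K)
  best <- score_of(rod, dir)
  improved <- TRUE
  n_eval <- 1L
  while (improved) {
    improved <- FALSE
    for (h in seq_len(K)) {
      for (r in seq_len(n_rods)) for (dd in c("forward", "reverse")) {
        if (r %in% rod[-h] || (r == rod[h] && dd == dir[h])) next
        cand_rod <- rod; cand_dir <- dir
        if (r %in% rod) { # swap with the helix currently on rod r
          other <- which(rod == r)
          cand_rod[other] <- rod[h]
        }
        cand_rod[h] <- r; cand_dir[h] <- dd
        sc <- score_of(cand_rod, cand_dir)
        n_eval <- n_eval + 1L
        if (sc[1] > best[1] || (sc[1] == best[1] && sc[2] > best[2] + 1e-9)) {
          rod <- cand_rod; dir <- cand_dir; best <- sc; improved <- TRUE
        }
      }
    }
  }
  final <- score_assignment(problem, list(rod = rod, direction = dir), cache)
  sol <- tibble::tibble(
    rank = 1L, rods = list(rod), directions = list(dir),
    registers = list(final$placements$register),
    rolls = list(final$placements$roll),
    n_satisfied = final$report$n_satisfied,
    fraction_satisfied = final$report$fraction_satisfied,
    mean_distance = final$report$mean_distance
  )
  structure(list(solutions = sol, n_evaluated = n_eval, exhaustive = FALSE,
                 unique_maximizer = NA, n_resolvable = final$report$n_pairs,
                 n_unresolved = nrow(final$report$unresolved)),
            class = "ranked_solutions")
}
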