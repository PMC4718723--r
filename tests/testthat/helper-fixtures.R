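# shared fixtures and an independent brute-force re-scorer used as the
# oracle for the assignment search

# a small assignment problem built from a synthetic bundle truth
tiny_problem <- function(n_helices = 3, n_pairs = 30, fp_rate = 0,
                         seed = 1, lengths = NULL, spacing = 10, ...) {
  b <- make_bundle(n_helices, lengths, spacing, rng_seed = seed)
  contacts <- make_contacts(b, n_pairs, fp_rate, rng_seed = seed)
  list(truth = b,
       problem = assignment_problem(b$segments, b$axes, contacts, ...))
}

# random rigid motion (seeded by the caller)
random_rigid <- function() {
  v <- stats::runif(3, -1, 1)
  rigid_transform(rotation_about_axis(v, stats::runif(1, 0, 180)),
                  stats::runif(3, -20, 20))
}

# Naive brute-force re-scorer: enumerates every injective rod tuple and
# direction word itself, rebuilds every candidate model from scratch through
# place_helix, and scores with satisfaction(). Independent of the compiled
# search path and of score_assignment's caching.
naive_rank <- function(problem) {
  segs <- problem$segments
  K <- nrow(segs)
  n_rods <- length(problem$rods)
  regs <- seq(-problem$register_range, problem$register_range)
  rolls <- seq(0, 360, length.out = problem$roll_samples + 1)[
    seq_len(problem$roll_samples)]
  place <- function(h, rod, dir, reg, roll) {
    place_helix(segs$last[h] - segs$first[h] + 1L, problem$rods[[rod]],
                dir, reg, roll, first_resno = segs$first[h])
  }
  eval_full <- function(pieces) {
    mods <- list(A = bind_models(pieces[order(segs$first)]))
    if (!is.null(problem$partner)) mods$C <- problem$partner
    rep <- satisfaction(mods, problem$pairs, problem$threshold)
    dd <- rep$distances$distance
    c(rep$n_satisfied, sum(dd[!is.na(dd)]), rep$n_pairs)
  }
  score_one <- function(rod_tuple, dirs) {
    pieces <- lapply(seq_len(K), function(h)
      place(h, rod_tuple[h], dirs[h], 0, 0))
    for (h in seq_len(K)) {
      best <- NULL
      for (reg in regs) for (roll in rolls) {
        cand <- pieces
        cand[[h]] <- place(h, rod_tuple[h], dirs[h], reg, roll)
        sc <- eval_full(cand)
        if (is.null(best) || sc[1] > best$sc[1] ||
            (sc[1] == best$sc[1] && sc[2] < best$sc[2] - 1e-9)) {
          best <- list(sc = sc, reg = reg, roll = roll)
        }
      }
      pieces[[h]] <- place(h, rod_tuple[h], dirs[h], best$reg, best$roll)
    }
    eval_full(pieces)
  }
  rows <- list()
  tuples <- utils::combn(seq_len(n_rods), K, simplify = FALSE)
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  for (tp in tuples) for (pm in perm_all(tp)) {
    for (m in 0:(2^K - 1)) {
      dirs <- ifelse(bitwAnd(m, 2^(seq_len(K) - 1)) > 0, "reverse", "forward")
      sc <- score_one(pm, dirs)
      rows[[length(rows) + 1]] <- data.frame(
        rods = paste(pm, collapse = ","),
        dirs = paste(substr(dirs, 1, 1), collapse = ","),
        n_satisfied = sc[1], mean_distance = sc[2] / sc[3])
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$n_satisfied, out$mean_distance), ]
}

# key string for comparing assignments
assignment_key <- function(rods, dirs) {
  paste(paste(rods, collapse = ","),
        paste(substr(dirs, 1, 1), collapse = ","), sep = "|")
}
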