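test_that("rod detection handles empty and single-feature maps", {
  zero <- density_map(array(0, dim = c(12, 12, 12)), 1.64)
  expect_equal(rod_detect(zero, 0), list())
  expect_error(rod_detect(zero, 5), "range")

  h <- build_ideal_helix(20)
  m <- render_map(h, map_spec(resolution = 7), rng_seed = 1)
  rods <- rod_detect(m, max(m$grid) / 2, min_length = 15)
  expect_length(rods, 1)
  true_ax <- fit_axis(h)
  cosang <- abs(sum(rod_direction(rods[[1]]) * rod_direction(true_ax)))
  expect_lt(acos(pmin(1, cosang)) * 180 / pi, 5)
  rise <- helix_stats(h)$rise
  expect_equal(rod_length(rods[[1]]), 19 * rise, tolerance = 0.2)
})

test_that("a rendered bundle yields one rod per helix", {
  b <- make_bundle(6, NULL, 10, rng_seed = 7)
  m <- render_map(b$model, map_spec(resolution = 7, noise_sigma = 0.1),
                  rng_seed = 7)
  m <- smooth_map(m, 0.8)
  rods <- rod_detect(m, 0.75 * max(m$grid), min_length = 15)
  expect_length(rods, 6)
  mm <- match_rods_to_axes(rods, b$axes)
  expect_equal(sort(mm$rod), 1:6)  # one-to-one
  expect_true(all(mm$angle < 15))
  expect_true(all(mm$midpoint_distance < 5))
})

test_that("assignment enumeration counts and order are deterministic", {
  dummy <- tibble::tibble(res_i = 1L, res_j = 20L, score = 1,
                          chain_i = "A", chain_j = "A")
  for (k in 1:4) {
    b <- make_bundle(k, rng_seed = 1)
    prob <- assignment_problem(b$segments, b$axes, dummy)
    enum <- enumerate_assignments(prob)
    expect_equal(nrow(enum$rods), factorial(k) * 2^k)
    expect_equal(anyDuplicated(cbind(enum$rods, enum$reversed)), 0)
  }
  # injective when more rods than segments: P(4, 2) * 2^2
  b2 <- make_bundle(2, rng_seed = 1)
  rods4 <- c(b2$axes, list(rod_axis(c(50, 0, 0), c(50, 0, 20)),
                           rod_axis(c(0, 50, 0), c(0, 50, 20))))
  prob2 <- assignment_problem(b2$segments, rods4, dummy)
  expect_equal(nrow(enumerate_assignments(prob2)$rods), 4 * 3 * 4)
  expect_error(enumerate_assignments(prob2, max_exhaustive = 1), "cap")
})

test_that("the generating assignment of a clean problem scores perfectly", {
  b <- make_bundle(3, lengths = 20, rng_seed = 2)
  contacts <- make_contacts(b, 25, 0, rng_seed = 2)
  prob <- assignment_problem(b$segments, b$axes, contacts)
  ta <- true_assignment_on_rods(b, b$axes)
  sc <- score_assignment(prob, ta)
  expect_equal(sc$report$fraction_satisfied, 1)
  expect_error(score_assignment(prob, list(rod = c(1, 1, 2),
                                           direction = rep("forward", 3))),
               "distinct")
  zero <- prob
  zero$pairs <- contacts[0, ]
  expect_error(score_assignment(zero, ta), "resolvable")
})

test_that("direction flips lose satisfied pairs on the true rods", {
  wins <- 0
  for (seed in 1:10) {
    b <- make_bundle(4, rng_seed = seed)
    contacts <- make_contacts(b, 30, 0, rng_seed = seed)
    prob <- assignment_problem(b$segments, b$axes, contacts)
    ta <- true_assignment_on_rods(b, b$axes)
    flipped <- ta
    flipped$direction[2] <- setdiff(c("forward", "reverse"),
                                    flipped$direction[2])
    s_true <- score_assignment(prob, ta)$report$n_satisfied
    s_flip <- score_assignment(prob, flipped)$report$n_satisfied
    wins <- wins + (s_true > s_flip)
  }
  expect_gte(wins, 9)
})

test_that("search ranking matches the naive brute-force re-scorer", {
  fx <- tiny_problem(n_helices = 2, n_pairs = 20, fp_rate = 0.1, seed = 5)
  s <- search_best(fx$problem)
  oracle <- naive_rank(fx$problem)
  expect_equal(s$n_evaluated, nrow(oracle))
  got <- tidy(s)
  keys_got <- mapply(assignment_key, got$rods, got$directions)
  key_oracle <- paste(oracle$rods, oracle$dirs, sep = "|")
  lookup <- match(keys_got, key_oracle)
  expect_false(anyNA(lookup))
  expect_equal(got$n_satisfied, oracle$n_satisfied[lookup])
  expect_equal(got$mean_distance, oracle$mean_distance[lookup],
               tolerance = 1e-9)
  # the package ranking is a valid sort under the oracle's scores
  expect_true(all(diff(got$n_satisfied) <= 0))
  ties <- which(diff(got$n_satisfied) == 0)
  expect_true(all(got$mean_distance[ties + 1] >= got$mean_distance[ties] - 1e-9))
  expect_equal(assignment_key(got$rods[[1]], got$directions[[1]]),
               key_oracle[1])
})

test_that("search results are deterministic and consistent with score_assignment", {
  fx <- tiny_problem(n_helices = 3, n_pairs = 30, fp_rate = 0.1, seed = 9)
  s1 <- search_best(fx$problem)
  s2 <- search_best(fx$problem)
  expect_identical(tidy(s1), tidy(s2))
  expect_true(s1$exhaustive)
  expect_equal(s1$n_evaluated, factorial(3) * 2^3)

  top <- get_assignment(s1, 1)
  rescored <- score_assignment(fx$problem, top)
  expect_equal(rescored$report$n_satisfied, tidy(s1)$n_satisfied[1])
  expect_equal(rescored$report$mean_distance, tidy(s1)$mean_distance[1],
               tolerance = 1e-9)
  expect_equal(rescored$placements$register, tidy(s1)$registers[[1]])
  expect_equal(rescored$placements$roll, tidy(s1)$rolls[[1]])
})

test_that("forward and reverse are distinguished through partner contacts", {
  b <- make_bundle(1, lengths = 20, rng_seed = 3)
  ring <- make_ring(4, 14, radius = 14, center = c(0, 2, 0),
                    first_resno = 200L)
  contacts <- make_contacts(b, 0, 0, rng_seed = 3, partner = ring,
                            n_inter = 5)
  prob <- assignment_problem(b$segments, b$axes, contacts, partner = ring)
  s <- search_best(prob)
  expect_equal(s$n_evaluated, 2L)
  expect_equal(tidy(s)$directions[[1]], b$true_assignment$direction[1])
  expect_gte(tidy(s)$n_satisfied[1], tidy(s)$n_satisfied[2])
})

test_that("greedy mode returns a labelled heuristic result", {
  fx <- tiny_problem(n_helices = 3, n_pairs = 30, fp_rate = 0, seed = 4)
  g <- search_best(fx$problem, mode = "greedy")
  expect_false(g$exhaustive)
  expect_equal(nrow(tidy(g)), 1)
  expect_true(tidy(g)$fraction_satisfied >= 0.9)  # greedy finds a good fit here
  expect_error(search_best(fx$problem, max_exhaustive = 2), "cap")
})
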