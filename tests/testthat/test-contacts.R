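test_that("contact files round-trip through both dialects", {
  pairs <- tibble::tibble(res_i = c(5L, 12L, 40L), res_j = c(41L, 80L, 90L),
                          score = c(1.27, 0.9, 2.5),
                          chain_i = "A", chain_j = "A")
  f <- withr::local_tempfile(fileext = ".txt")
  write_contacts(pairs, f)
  expect_equal(as.data.frame(read_contacts(f)), as.data.frame(pairs))

  # minimal 3-column record without header
  writeLines("5 41 1.27", f)
  one <- read_contacts(f)
  expect_equal(nrow(one), 1)
  expect_equal(one$res_i, 5L)
  expect_equal(one$res_j, 41L)
  expect_equal(one$score, 1.27)
  expect_equal(one$chain_i, "A")

  # tagged dialect with mixed chains survives a round trip
  inter <- tibble::tibble(res_i = c(3L, 7L), res_j = c(100L, 110L),
                          score = c(2, 1), chain_i = "A",
                          chain_j = c("C", "A"))
  write_contacts(inter, f)
  expect_equal(as.data.frame(read_contacts(f)), as.data.frame(inter))

  # comma-delimited input is accepted
  writeLines(c("i,j,score", "5,41,1.27"), f)
  expect_equal(read_contacts(f)$score, 1.27)
})

test_that("malformed and empty contact files are reported, not crashed on", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), f)
  expect_warning(empty <- read_contacts(f), "empty")
  expect_equal(nrow(empty), 0)

  writeLines(c("5 41 1.27", "oops bad line", "6 50 0.9"), f)
  expect_warning(got <- read_contacts(f), "line")
  expect_equal(nrow(got), 2)

  writeLines(c("1 2", "3 4"), f)
  expect_error(read_contacts(f), "layout")
})

test_that("top_n_contacts ranks by score with deterministic ties", {
  pairs <- tibble::tibble(res_i = c(10L, 2L, 2L, 30L, 7L),
                          res_j = c(20L, 50L, 40L, 33L, 90L),
                          score = c(1, 2, 2, 5, 0.5),
                          chain_i = "A", chain_j = "A")
  top <- top_n_contacts(pairs, n = 4, min_separation = 5)
  # (30,33) removed: |30-33| < 5; equal scores ordered by (res_i, res_j)
  expect_equal(top$res_i, c(2L, 2L, 10L, 7L))
  expect_equal(top$res_j, c(40L, 50L, 20L, 90L))
  expect_true(all(diff(top$score) <= 0))
  # truncation to what is available
  expect_equal(nrow(top_n_contacts(pairs, n = 90)), 4)

  # inter-chain restriction keeps only cross-chain pairs
  pairs$chain_j <- c("A", "C", "A", "A", "C")
  expect_equal(nrow(top_n_contacts(pairs, n = 6, chains = "inter")), 2)
})

test_that("satisfaction computes the documented arithmetic", {
  ca <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(20, 0, 0))
  m <- backbone_model(c(1L, 2L, 3L, 4L), ca, ca, ca, ca)
  pairs <- tibble::tibble(res_i = c(1L, 1L, 1L), res_j = c(2L, 3L, 4L),
                          score = c(3, 2, 1), chain_i = "A", chain_j = "A")
  rep <- satisfaction(m, pairs, threshold = 15)
  expect_equal(rep$n_pairs, 3)
  expect_equal(rep$n_satisfied, 2)
  expect_equal(rep$fraction_satisfied, 2 / 3)
  expect_equal(rep$mean_distance, 35 / 3)
  expect_equal(nrow(rep$violations), 1)
  expect_equal(rep$violations$distance, 20)
  g <- glance(rep)
  expect_equal(g$fraction_satisfied, 2 / 3)
  expect_equal(nrow(tidy(rep)), 3)
})

test_that("a zero-false-positive contact list is fully satisfied", {
  b <- make_bundle(4, rng_seed = 3)
  contacts <- make_contacts(b, n_pairs = 40, fp_rate = 0, rng_seed = 3)
  rep <- satisfaction(b$model, contacts, threshold = 15)
  expect_equal(rep$fraction_satisfied, 1)
})

test_that("fraction satisfied is monotone in the threshold", {
  b <- make_bundle(4, rng_seed = 11)
  contacts <- make_contacts(b, 40, 0.1, rng_seed = 11)
  fr <- vapply(c(5, 8, 12, 15, 20, 30),
               function(th) satisfaction(b$model, contacts, th)$fraction_satisfied,
               1)
  expect_true(all(diff(fr) >= 0))
})

test_that("satisfaction is invariant under a common rigid motion", {
  set.seed(5)
  b <- make_bundle(3, rng_seed = 5)
  ring <- make_ring(4, 12, radius = 14,
                    center = c(10, 5, 0), first_resno = 500L)
  contacts <- make_contacts(b, 30, 0.1, rng_seed = 5,
                            partner = ring, n_inter = 4)
  r0 <- satisfaction(list(A = b$model, C = ring), contacts, 15)
  for (k in 1:3) {
    tr <- random_rigid()
    r1 <- satisfaction(list(A = transform_model(b$model, tr),
                            C = transform_model(ring, tr)), contacts, 15)
    expect_equal(r1$n_satisfied, r0$n_satisfied)
    expect_equal(r1$mean_distance, r0$mean_distance, tolerance = 1e-9)
  }
})

test_that("pairs with residues missing from the model are unresolved", {
  b <- make_bundle(3, rng_seed = 2)
  contacts <- make_contacts(b, 20, 0, rng_seed = 2)
  contacts$res_j[1:3] <- max(b$model$resno) + 50L  # outside the model
  rep <- satisfaction(b$model, contacts, 15)
  expect_equal(nrow(rep$unresolved), 3)
  expect_equal(rep$n_pairs, 17)
  # partition: every resolvable pair is satisfied or violated
  expect_equal(rep$n_pairs, rep$n_satisfied + nrow(rep$violations))

  contacts$res_j <- max(b$model$resno) + 50L
  expect_error(satisfaction(b$model, contacts, 15), "resolvable")
})
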