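test_that("single-helix bundle is the trivial case", {
  b <- make_bundle(1, lengths = 10, rng_seed = 1)
  expect_equal(nrow(b$segments), 1)
  expect_equal(b$segments$first, 1L)
  expect_equal(b$segments$last, 10L)
  expect_equal(b$true_assignment$rod, 1L)
  expect_equal(b$true_assignment$direction, "forward")
})

test_that("generators are bit-identical under a repeated seed", {
  b1 <- make_bundle(6, rng_seed = 42)
  b2 <- make_bundle(6, rng_seed = 42)
  expect_identical(b1$model, b2$model)
  expect_identical(b1$true_assignment, b2$true_assignment)

  c1 <- make_contacts(b1, 90, 0.06, rng_seed = 9)
  c2 <- make_contacts(b2, 90, 0.06, rng_seed = 9)
  expect_identical(c1, c2)

  spec <- map_spec(box_edge = 32, noise_sigma = 0.05)
  m1 <- render_map(slice_model(b1$model, 1, 30), spec, rng_seed = 5)
  m2 <- render_map(slice_model(b2$model, 1, 30), spec, rng_seed = 5)
  expect_identical(m1$grid, m2$grid)
})

test_that("segments are non-overlapping, ascending, and cover the assignment", {
  b <- make_bundle(5, rng_seed = 8)
  expect_true(all(b$segments$last >= b$segments$first))
  expect_true(all(diff(b$segments$first) > 0))
  expect_true(all(utils::head(b$segments$last, -1) < utils::tail(b$segments$first, -1)))
  expect_setequal(b$true_assignment$helix_id, b$segments$helix_id)
})

test_that("axis spacing is respected after tilts", {
  mins <- vapply(1:25, function(seed) {
    min_axis_distance(make_bundle(4, lengths = 20, spacing = 10,
                                  rng_seed = seed)$axes)
  }, 1)
  # tilts about pinned midpoints can only bring near-parallel axes closer,
  # never push them beyond the nominal spacing
  expect_true(all(mins >= 7))
  expect_true(all(mins <= 10 + 1e-6))
  expect_error(make_bundle(4, spacing = 3, rng_seed = 1), "unphysical")
})

test_that("contact lists have the exact specified composition", {
  b <- make_bundle(6, rng_seed = 4)
  contacts <- make_contacts(b, n_pairs = 90, fp_rate = 0.06, rng_seed = 4)
  expect_equal(nrow(contacts), 90)
  d <- tidy(satisfaction(b$model, contacts, threshold = 1e6))$distance
  expect_equal(sum(d <= 8), 85)   # round(90 * 0.94)
  expect_equal(sum(d > 20), 5)
  expect_true(all(abs(contacts$res_i - contacts$res_j) >= 5))
  # scores are distinct so top-N selection is reproducible
  expect_equal(anyDuplicated(contacts$score), 0)

  expect_error(make_contacts(b, n_pairs = 5000, fp_rate = 0, rng_seed = 1),
               "insufficient true pairs")
  expect_error(make_contacts(b, 90, fp_rate = 1, rng_seed = 1), "fp_rate")
})

test_that("satisfaction of the generating model tracks the false-pair count", {
  fr <- vapply(1:20, function(seed) {
    b <- make_bundle(6, rng_seed = seed)
    contacts <- make_contacts(b, 90, 0.06, rng_seed = seed)
    satisfaction(b$model, contacts, 15)$fraction_satisfied
  }, 1)
  expect_true(all(fr >= 85 / 90))
  expect_equal(mean(fr), 0.94, tolerance = 0.02)
})

test_that("rendered density peaks at the atom and integrates per atom", {
  one <- backbone_model(1L, c(0, 0, 0), c(0.2, 0.1, -0.3),
                        c(1, 1, 1), c(2, 2, 2))
  m <- render_map(one, map_spec(box_edge = 21), rng_seed = 1)
  peak <- arrayInd(which.max(m$grid), dim(m$grid))
  world <- m$origin + (peak - 1) * m$voxel_size
  expect_true(all(abs(world - c(0.2, 0.1, -0.3)) <= m$voxel_size / 2 + 1e-9))

  h5 <- build_ideal_helix(5)
  h15 <- build_ideal_helix(15)
  m5 <- render_map(h5, map_spec(box_edge = 41), rng_seed = 1)
  m15 <- render_map(h15, map_spec(box_edge = 41), rng_seed = 1)
  expect_equal(sum(m15$grid) / sum(m5$grid), 3, tolerance = 0.01)

  expect_error(render_map(h15, map_spec(box_edge = 8)), "fit")
})

test_that("state ensembles rotate only the mobile part", {
  b <- make_bundle(3, lengths = 14, spacing = 10, rng_seed = 6)
  expect_error(make_state_ensemble(b, integer(), angles = c(0, 5)),
               "mobile_part")
  expect_error(make_state_ensemble(b, 1L, angles = numeric()), "angles")

  ax <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  maps <- make_state_ensemble(b, 1L, angles = c(0, 0), axis = ax,
                              spec = map_spec(), rng_seed = 3)
  expect_identical(maps[[1]]$grid, maps[[2]]$grid)  # zero rotation twice

  maps2 <- make_state_ensemble(b, 1L, angles = c(0, 25), axis = ax,
                               spec = map_spec(), rng_seed = 3)
  expect_gt(max(abs(maps2[[2]]$grid - maps2[[1]]$grid)), 0.2)
})

test_that("voxel variance is higher where the structure moves", {
  b <- make_bundle(3, lengths = 14, spacing = 10, rng_seed = 9)
  ring <- make_ring(8, 10, radius = 16, center = c(10, -16, 0))
  ax <- list(point = c(10, -16, 0), direction = c(0, 0, 1))
  maps <- make_state_ensemble(b, ring, angles = seq(0, 30, by = 5),
                              axis = ax, spec = map_spec(noise_sigma = 0.02),
                              rng_seed = 2)
  va <- average_maps(maps)$variance
  axes <- lapply(1:3, function(k) {
    va$origin[k] + (seq_len(dim(va$grid)[k]) - 1) * va$voxel_size
  })
  near <- function(model, cutoff = 4) {
    ca <- ca_coords(model)
    arr <- array(FALSE, dim(va$grid))
    for (a in seq_len(nrow(ca))) {
      rng <- lapply(1:3, function(k) {
        which(abs(axes[[k]] - ca[a, k]) <= cutoff)
      })
      arr[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
    }
    arr
  }
  mobile_mask <- near(ring)
  static_mask <- near(b$model) & !mobile_mask
  expect_gt(median(va$grid[mobile_mask]), median(va$grid[static_mask]))
})

test_that("map_spec validates its physical constraints", {
  expect_error(map_spec(voxel_size = 0), "positive")
  expect_error(map_spec(voxel_size = 2, resolution = 3), "Nyquist")
})

test_that("bundle truths round-trip through PDB and JSON", {
  b <- make_bundle(3, lengths = 12, rng_seed = 10)
  dir <- withr::local_tempdir()
  files <- write_bundle(b, dir, partner = make_ring(4, 8, radius = 14))
  models <- read_model_pdb(files[["model"]])
  expect_setequal(names(models), c("A", "C"))
  expect_equal(ca_coords(models$A), ca_coords(b$model), tolerance = 1e-3)
  meta <- jsonlite::read_json(files[["metadata"]], simplifyVector = TRUE)
  expect_equal(meta$rng_seed, b$rng_seed)
  expect_equal(nrow(meta$segments), 3)
})
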