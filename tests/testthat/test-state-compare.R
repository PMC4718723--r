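test_that("superposition recovers exact rigid motions", {
  h <- build_ideal_helix(20)
  sup <- superpose(h, h)
  expect_equal(sup$rmsd_after, 0, tolerance = 1e-9)
  ra <- rotation_angle_axis(sup)
  expect_lt(ra$angle, 1e-3)
  expect_false(ra$axis_defined)

  tr <- rotation_about_line(c(0, 0, 1), 16, c(3, -2, 5))
  sup16 <- superpose(h, transform_model(h, tr))
  ra16 <- rotation_angle_axis(sup16)
  expect_equal(ra16$angle, 16, tolerance = 1e-6)
  expect_gt(abs(sum(ra16$axis * c(0, 0, 1))), 0.9999)
  expect_lt(sup16$rmsd_after, 1e-9)

  expect_error(superpose(ca_coords(h)[1:5, ], ca_coords(h)[1:4, ]), "equal")
  line <- cbind(0, 0, 1:5)
  expect_error(superpose(line, line), "degenerate|collinear")
})

test_that("superposition matches an independent least-squares fit", {
  set.seed(31)
  a <- matrix(rnorm(60, sd = 5), 20, 3)
  tr <- random_rigid()
  b <- apply_transform(a, tr) + matrix(rnorm(60, sd = 0.3), 20, 3)
  sup <- superpose(a, b)
  # cross-check against the reference superposition in bio3d
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(b)), mobile = as.numeric(t(a))))
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(sup$rmsd_after, rmsd_bio3d, tolerance = 1e-6)
  # rmsd_after never exceeds rmsd_before and matches the closed form
  expect_lte(sup$rmsd_after, sup$rmsd_before)
  direct <- sqrt(mean(rowSums((apply_transform(a, sup$transform) - b)^2)))
  expect_equal(sup$rmsd_after, direct, tolerance = 1e-9)
})

test_that("noisy superposition RMSD follows the two-sided jitter law", {
  h <- build_ideal_helix(30)
  ca <- ca_coords(h)
  n <- nrow(ca)
  sigma <- 0.5
  rmsds <- vapply(1:100, function(k) {
    set.seed(k)
    a <- ca + matrix(rnorm(length(ca), sd = sigma), ncol = 3)
    b <- ca + matrix(rnorm(length(ca), sd = sigma), ncol = 3)
    superpose(a, b)$rmsd_after
  }, 1)
  # each atom-atom difference is N(0, 2 sigma^2) per coordinate and the fit
  # absorbs 6 of the 3n degrees of freedom
  expected <- sigma * sqrt((6 * n - 12) / n)
  expect_equal(mean(rmsds), expected, tolerance = 0.15 * expected)
})

test_that("angle/axis decomposition handles screw motions and degeneracy", {
  ra <- rotation_angle_axis(rigid_transform(diag(3), c(1, 2, 3)))
  expect_equal(ra$angle, 0)
  expect_false(ra$axis_defined)

  r10 <- rotation_angle_axis(rotation_about_line(c(1, 1, 0), 10, c(5, 0, 0)))
  expect_equal(r10$angle, 10, tolerance = 1e-9)
  expect_gt(abs(sum(r10$axis * c(1, 1, 0) / sqrt(2))), 0.9999)

  # adding a translation along the axis (screw) leaves angle and axis alone
  base <- rotation_about_line(c(0, 0, 1), 12, c(2, 2, 0))
  screw <- compose_transforms(rigid_transform(diag(3), c(0, 0, 7)), base)
  rs <- rotation_angle_axis(screw, center = c(0, 0, 0))
  expect_equal(rs$angle, 12, tolerance = 1e-9)
  expect_gt(abs(sum(rs$axis * c(0, 0, 1))), 0.9999)
  # screw axis passes through (2, 2, *): the axis point lies on that line
  expect_equal(rs$axis_point[1:2], c(2, 2), tolerance = 1e-6)
})

test_that("ring offsets are reported modulo the symmetry step", {
  ring <- make_ring(8, helix_length = 12, radius = 20)
  expect_equal(ring_offset(ring, ring, 8), 0, tolerance = 1e-9)

  rot <- function(deg) transform_model(ring, rotation_about_line(c(0, 0, 1), deg))
  expect_equal(ring_offset(ring, rot(5), 8), 5, tolerance = 1e-6)
  expect_equal(ring_offset(ring, rot(47), 8), 2, tolerance = 1e-6)
  expect_equal(ring_offset(ring, rot(-20), 8), -20, tolerance = 1e-6)

  # invariant under relabelling by one symmetry step (45 deg here)
  expect_equal(ring_offset(ring, rot(45 + 3), 8), 3, tolerance = 1e-6)

  # equivariant under a whole-scene rigid motion
  set.seed(77)
  tr <- random_rigid()
  expect_equal(ring_offset(transform_model(ring, tr),
                           transform_model(rot(5), tr), 8),
               5, tolerance = 1e-6)

  small <- make_ring(4, helix_length = 6, radius = 10)
  expect_error(ring_offset(ring, small, 8), "atom counts")
})

test_that("state interpolation is linear with exact endpoints", {
  a <- build_ideal_helix(15)
  expect_error(interpolate_states(a, build_ideal_helix(14)), "matched")

  b <- transform_model(a, rigid_transform(diag(3), c(4, 0, 0)))
  two <- interpolate_states(a, b, n_frames = 2)
  expect_equal(ca_coords(two[[1]]), ca_coords(a))
  expect_equal(ca_coords(two[[2]]), ca_coords(b))
  expect_true(attr(two, "non_physical"))

  # translation midpoint: every atom moves exactly half way
  mid <- interpolate_states(a, b, 3)[[2]]
  expect_equal(ca_coords(mid) - ca_coords(a), matrix(c(2, 0, 0), 15, 3,
                                                     byrow = TRUE))
})

test_that("rotation midpoints interpolate the chord, not the arc", {
  a <- build_ideal_helix(15)
  tr16 <- rotation_about_line(c(0, 0, 1), 16, c(30, 0, 0))
  b <- transform_model(a, tr16)
  mid <- interpolate_states(a, b, 3)[[2]]
  half <- transform_model(a, rotation_about_line(c(0, 0, 1), 8, c(30, 0, 0)))
  # chord shortening: linear midpoint lies inside the arc by r (1 - cos(8 deg))
  ca_m <- ca_coords(mid); ca_h <- ca_coords(half)
  r <- sqrt(rowSums(sweep(ca_coords(a)[, 1:2, drop = FALSE], 2,
                          c(30, 0))^2))
  expected <- r * (1 - cos(8 * pi / 180))
  got <- sqrt(rowSums((ca_m - ca_h)^2))
  expect_equal(got, expected, tolerance = 1e-6)

  frames <- interpolate_states(a, b, 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_frames_pdb(frames, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 5)
  expect_true(any(grepl("non-physical", txt)))
})
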