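test_that("builder places the first residue in the canonical frame", {
  h <- build_ideal_helix(10)
  expect_equal(n_residues(h), 10)
  expect_equal(nrow(as_tibble(h)), 40)  # 4 backbone atoms per residue
  p <- helix_params()
  # hand-computed from the internal-coordinate rules
  expect_equal(h$n[1, ], c(0, 0, 0))
  expect_equal(h$ca[1, ], c(p$b_n_ca, 0, 0))
  th <- p$ang_n_ca_c * pi / 180
  expect_equal(h$c[1, ],
               c(p$b_n_ca - p$b_ca_c * cos(th), p$b_ca_c * sin(th), 0),
               tolerance = 1e-12)
  expect_error(build_ideal_helix(0), "n_residues")
})

test_that("built helix has canonical alpha-helix geometry", {
  h <- build_ideal_helix(36)
  ca <- ca_coords(h)
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  # independent measurement: principal axis via prcomp, rise via lm,
  # azimuth unwrapping by hand
  pc <- stats::prcomp(ca)
  u <- pc$rotation[, 1]
  s <- as.numeric(scale(ca, scale = FALSE) %*% u)
  rise <- abs(unname(coef(lm(s ~ seq_along(s)))[2]))
  expect_equal(rise, 1.5, tolerance = 0.1)
  rad_vec <- scale(ca, scale = FALSE) - outer(s, u)
  expect_equal(mean(sqrt(rowSums(rad_vec^2))), 2.3, tolerance = 0.2)
  e1 <- rad_vec[1, ] / sqrt(sum(rad_vec[1, ]^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  theta <- atan2(rad_vec %*% e2, rad_vec %*% e1)
  dth <- diff(theta[, 1])
  dth <- (dth + pi) %% (2 * pi) - pi
  expect_equal(2 * pi / abs(mean(dth)), 3.6, tolerance = 0.2)
  # the packaged summary agrees with the independent measurement
  st <- helix_stats(h)
  expect_equal(st$rise, rise, tolerance = 1e-6)
})

test_that("fit_axis recovers exact and helical axes", {
  # exactly collinear CA positions along z
  z <- seq(0, 30, length.out = 11)
  fake <- backbone_model(1:11, cbind(0, 0, z), cbind(0, 0, z),
                         cbind(0, 0, z), cbind(0, 0, z))
  ax <- fit_axis(fake)
  expect_equal(abs(sum(rod_direction(ax) * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_equal(ax$endpoint_a, c(0, 0, 0), tolerance = 1e-9)

  coinc <- backbone_model(1:3, matrix(1, 3, 3), matrix(1, 3, 3),
                          matrix(1, 3, 3), matrix(1, 3, 3))
  expect_error(fit_axis(coinc), "coincide")

  h <- build_ideal_helix(20)
  ax <- fit_axis(h)
  ca <- ca_coords(h)
  rel <- sweep(ca, 2, rod_midpoint(ax))
  u <- rod_direction(ax)
  radial <- rel - outer(as.numeric(rel %*% u), u)
  expect_equal(mean(sqrt(rowSums(radial^2))), 2.3, tolerance = 0.2)
})

test_that("axis length matches residues times rise", {
  for (n in c(12, 20, 36)) {
    h <- build_ideal_helix(n)
    rise <- helix_stats(h)$rise
    expect_equal(rod_length(fit_axis(h)), (n - 1) * rise,
                 tolerance = 0.05 * (n - 1) * rise)
  }
})

test_that("fit_axis is equivariant under rigid motions", {
  set.seed(42)
  h <- build_ideal_helix(18)
  ax <- fit_axis(h)
  for (k in 1:5) {
    tr <- random_rigid()
    ax2 <- fit_axis(transform_model(h, tr))
    expect_equal(ax2$endpoint_a, as.numeric(apply_transform(ax$endpoint_a, tr)),
                 tolerance = 1e-6)
    expect_equal(ax2$endpoint_b, as.numeric(apply_transform(ax$endpoint_b, tr)),
                 tolerance = 1e-6)
  }
})

test_that("place_helix honours direction, register, roll and rigidity", {
  rod <- rod_axis(c(5, -3, 0), c(5, -3, 28))
  fwd <- place_helix(18, rod, "forward")
  rev <- place_helix(18, rod, "reverse")
  d_first_a <- sqrt(sum((ca_coords(fwd)[1, ] - rod$endpoint_a)^2))
  d_first_b <- sqrt(sum((ca_coords(rev)[1, ] - rod$endpoint_b)^2))
  expect_equal(d_first_a, d_first_b, tolerance = 0.5)
  d_last_b <- sqrt(sum((ca_coords(fwd)[18, ] - rod$endpoint_b)^2))
  d_last_a <- sqrt(sum((ca_coords(rev)[18, ] - rod$endpoint_a)^2))
  expect_equal(d_last_b, d_last_a, tolerance = 0.5)

  # register shift slides every CA by one rise along the axis
  sh <- place_helix(18, rod, "forward", register_shift = 1)
  disp <- ca_coords(sh) - ca_coords(fwd)
  expect_true(all(abs(sqrt(rowSums(disp^2)) - 1.5) < 0.1))
  expect_true(all(abs(disp %*% rod_direction(rod) -
                        sqrt(rowSums(disp^2))) < 1e-6))

  # full roll turn is the identity
  r360 <- place_helix(18, rod, "forward", roll = 360)
  expect_lt(max(abs(ca_coords(r360) - ca_coords(fwd))), 1e-6)

  # rigid placement preserves intra-helix distances
  h0 <- build_ideal_helix(18)
  placed <- place_helix(18, rod, "reverse", register_shift = 2, roll = 135)
  expect_lt(max(abs(dist(ca_coords(h0)) - dist(ca_coords(placed)))), 1e-6)

  expect_error(place_helix(10, rod, register_shift = 11), "register")
})

test_that("build -> fit_axis -> place round-trips the coordinates", {
  h <- build_ideal_helix(25)
  placed <- place_helix(25, fit_axis(h), "forward", 0, 0)
  rmsd <- sqrt(mean(rowSums((ca_coords(placed) - ca_coords(h))^2)))
  expect_lt(rmsd, 0.1)
})
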