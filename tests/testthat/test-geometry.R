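test_that("half-aperture angle follows the chord relation", {
  expect_equal(phi_star(7.8, 11.46), asin(11.46 / 15.6), tolerance = 1e-14)
  expect_equal(round(phi_star(7.8, 11.46), 2), 0.83)
  # limits: flat cornea and hemispherical cap
  expect_lt(phi_star(7.8, 1e-8), 1e-8)
  expect_gt(phi_star(7.8, 2 * 7.8 - 1e-9), pi / 2 - 1e-3)
  expect_error(phi_star(7.8, 15.6), "invalid geometry")
  expect_error(phi_star(-1, 3), "invalid geometry")
})

test_that("reference nodes lie exactly on concentric arcs", {
  geom <- cornea_geometry()
  disc <- discretization(4, 20)
  ng <- build_nodes(geom, disc)
  expect_equal(dim(ng$X), c(5, 81))
  # apex node on the anterior arc
  expect_equal(ng$X[5, 41], 7.8, tolerance = 1e-14)
  expect_equal(ng$Y[5, 41], 0, tolerance = 1e-14)
  # hand polar-to-Cartesian at the first limbus node (R_P, -Phi*)
  expect_equal(ng$X[1, 1], 4.871514, tolerance = 1e-6)
  expect_equal(ng$Y[1, 1], -5.274538, tolerance = 1e-6)
  # circle residual to machine precision
  rad <- sqrt(ng$X^2 + ng$Y^2)
  expect_lt(max(abs(rad - matrix(ng$R_i, 5, 81))), 1e-12 * geom$R_A)
  # mirror symmetry
  expect_equal(ng$Y, -ng$Y[, 81:1], tolerance = 1e-14)
  expect_equal(ng$X, ng$X[, 81:1], tolerance = 1e-14)
})

test_that("rest lengths obey the lattice identities", {
  geom <- cornea_geometry()
  disc <- discretization(4, 20)
  rl <- rest_lengths(geom, disc)
  expect_equal(rl$L2, 0.155)
  expect_equal(rl$L1[5], 0.1608916, tolerance = 1e-6)
  # diagonal identity L3^2 = L1_i L1_{i+1} + L2^2
  expect_equal(rl$L3^2, rl$L1[1:4] * rl$L1[2:5] + rl$L2^2, tolerance = 1e-14)
  expect_equal(rl$q_i, rl$L2 / rl$L1)
  # all rest lengths scale as O(1/N) at fixed gamma
  rl2 <- rest_lengths(geom, discretization(8, 20))
  expect_equal(8 * rl2$L2, 4 * rl$L2, tolerance = 1e-12)
  expect_equal(8 * rl2$L1[c(1, 9)], 4 * rl$L1[c(1, 5)], tolerance = 1e-3)
})

test_that("microstructure functions satisfy the trigonometric identities", {
  geom <- cornea_geometry()
  disc <- discretization(4, 20)
  ms <- microstructure(geom, disc)
  expect_equal(ms$kappa, 2 * geom$Phi_star / 20)
  expect_equal(ms$q(7.8 / 0.62), 0.9633646, tolerance = 1e-6)
  R <- seq(ms$R_range[1], ms$R_range[2], length.out = 7)
  expect_equal(ms$w(R), sin(ms$beta(R)), tolerance = 1e-14)
  expect_equal(ms$kappa * R * ms$w(R), cos(ms$beta(R)), tolerance = 1e-14)
  expect_equal(ms$w(R), ms$q(R) / sqrt(1 + ms$q(R)^2), tolerance = 1e-14)
  expect_error(ms$q(-1), "R > 0")
})

test_that("discrete length ratios converge to the continuum ones at O(N^-2)", {
  geom <- cornea_geometry()
  Ns <- c(4, 8, 16, 32)
  err_q <- err_w <- numeric(length(Ns))
  for (k in seq_along(Ns)) {
    disc <- discretization(Ns[k], 20)
    rl <- rest_lengths(geom, disc)
    ms <- microstructure(geom, disc)
    err_q[k] <- max(abs(rl$q_i - ms$q(rl$R_i / geom$T)))
    Rhalf <- (rl$R_i[-1] + rl$R_i[-length(rl$R_i)]) / 2 / geom$T
    err_w[k] <- max(abs(rl$w_iphalf - ms$w(Rhalf)))
  }
  slope_q <- stats::coef(stats::lm(log(err_q) ~ log(Ns)))[2]
  slope_w <- stats::coef(stats::lm(log(err_w) ~ log(Ns)))[2]
  expect_equal(unname(slope_q), -2, tolerance = 0.05)
  expect_equal(unname(slope_w), -2, tolerance = 0.15)
})

test_that("discretization validates its invariants", {
  expect_error(discretization(3, 7), "even")
  expect_error(discretization(0, 20), "positive integer")
  expect_error(discretization(4, 20.3), "integer")
  d <- discretization(4, 20)
  expect_identical(d$M, 80L)
})

test_that("fiber directions are unit vectors with the stated geometry", {
  ff <- fiber_frame(12.5, 0.0825)
  expect_equal(sum(ff$e_plus^2), 1, tolerance = 1e-14)
  expect_equal(sum(ff$e_minus^2), 1, tolerance = 1e-14)
  # e+ . e- = sin^2 beta - cos^2 beta
  b <- ff$beta
  expect_equal(sum(ff$e_plus * ff$e_minus), sin(b)^2 - cos(b)^2, tolerance = 1e-14)
})
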