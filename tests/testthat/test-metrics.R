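circle_curve <- function(rho, n, half_angle = 0.8) {
  th <- seq(-half_angle, half_angle, length.out = n)
  data.frame(x = rho * cos(th), y = rho * sin(th))
}

test_that("curvature operator reproduces analytic circles and lines", {
  prof <- surface_curvature(circle_curve(7.8, 200))
  expect_lt(max(abs(prof$curvature - 1 / 7.8)) * 7.8, 1e-4)
  expect_true(all(prof$curvature > 0))          # sign convention
  # straight line
  lin <- surface_curvature(data.frame(x = seq(1, 2, length.out = 50),
                                      y = seq(-1, 1, length.out = 50)))
  expect_lt(max(abs(lin$curvature)), 1e-12)
  # second-order convergence in sample count (interior points)
  err <- vapply(c(100, 200, 400), function(n) {
    pr <- surface_curvature(circle_curve(7.18, n))
    max(abs(pr$curvature[3:(n - 2)] - 1 / 7.18))
  }, 0)
  slope <- stats::coef(stats::lm(log(err) ~ log(c(100, 200, 400))))[2]
  expect_equal(unname(slope), -2, tolerance = 0.2)
  # ordering handled, fold-over rejected
  rev_prof <- surface_curvature(circle_curve(7.8, 100)[100:1, ])
  expect_equal(max(rev_prof$curvature), max(prof$curvature), tolerance = 1e-4)
  expect_error(surface_curvature(data.frame(x = c(0, 1, 2), y = c(0, 1, 0.5))),
               "parametrization")
})

test_that("maximum curvature excludes the outer ends", {
  k <- c(100, rep(1, 98), 100)        # spikes at both ends
  expect_equal(max_curvature(k), 1)
  expect_equal(max_curvature(rep(0.128, 200)), 0.128)
  # spike just inside the retained window is kept
  k2 <- rep(1, 100); k2[50] <- 3
  expect_equal(max_curvature(k2), 3)
})

test_that("unloaded reference metrics equal the analytic values", {
  cfg0 <- modify_config(cornea_config(Dmax = 0), p_kPa = 0)
  sol <- solve_discrete(cfg0, N = 4)
  mr <- metrics_report(sol)
  expect_equal(mr$AD_mm, 0)
  expect_equal(mr$CCT_mm, 0.62, tolerance = 1e-12)
  # curvature of the unloaded arcs: 1/R_A and 1/R_P (M = 80 chords)
  expect_equal(mr$MAC_per_mm, 1 / 7.8, tolerance = 1e-3)
  expect_equal(mr$MPC_per_mm, 1 / 7.18, tolerance = 1e-3)
  # printed precision of the reference values
  expect_equal(round(mr$MAC_per_mm, 3), 0.128)
  expect_equal(round(mr$MPC_per_mm, 3), 0.139)
})

test_that("loaded solutions thin the slice and steepen the surfaces", {
  sol <- healthy_coarse()
  mr <- metrics_report(sol)
  expect_lt(mr$CCT_mm, 0.62)
  expect_gt(mr$MAC_per_mm, 1 / 7.8)
  expect_gt(mr$MPC_per_mm, 1 / 7.18)
  # anterior and posterior apex displacements agree to the printed precision
  expect_equal(round(mr$AD_mm, 2), round(mr$AD_posterior_mm, 2))
})

test_that("metrics report serializes losslessly to JSON", {
  sol <- discrete_healthy(4)
  mr <- metrics_report(sol)
  mr2 <- metrics_from_json(metrics_to_json(mr))
  for (f in c("AD_mm", "CCT_mm", "MAC_per_mm", "MPC_per_mm", "AD_posterior_mm")) {
    expect_identical(mr[[f]], mr2[[f]])
  }
  expect_identical(mr$config_hash, mr2$config_hash)
})
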