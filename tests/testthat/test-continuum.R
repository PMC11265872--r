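baseline_nd <- nondimensional(cornea_config(Dmax = 0))

test_that("right Cauchy-Green tensor recovers manufactured fields", {
  R0 <- 12.2; P0 <- 0.3
  expect_equal(right_cauchy_green(identity_field(), R0, P0), diag(2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # uniform inflation r = c R
  c0 <- 1.02
  infl <- deformation_field(function(R, Phi) c0 * R, function(R, Phi) Phi)
  expect_equal(right_cauchy_green(infl, R0, P0), diag(c0^2, 2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # shear-like field r = R, phi = Phi + a R (closed form by hand)
  mf <- make_fixture("manufactured_field")
  a <- mf$a
  C <- right_cauchy_green(mf, R0, P0)
  expect_equal(C[1, 1], 1 + a^2 * R0^2, tolerance = 1e-7)
  expect_equal(C[1, 2], a * R0, tolerance = 1e-7)
  expect_equal(C[2, 2], 1, tolerance = 1e-7)
  # e_R stretch is sqrt(1 + a^2 R^2), e_Phi stretch is 1
  expect_equal(sqrt(C[1, 1]), sqrt(1 + a^2 * R0^2), tolerance = 1e-7)
})

test_that("strain energy density vanishes at identity and matches a hand case", {
  kap <- baseline_nd$kappa
  expect_equal(strain_energy_density(diag(2), 12, kap, 1, baseline_nd$K2,
                                     baseline_nd$K3, baseline_nd$D), 0)
  # pure azimuthal stretch: lam_pm = sqrt(sin^2 b + lam^2 cos^2 b)
  lam <- 1.01; R <- baseline_nd$RA
  C <- diag(c(1, lam^2))
  W <- strain_energy_density(C, R, kap, 1, baseline_nd$K2, baseline_nd$K3,
                             baseline_nd$D)
  b <- atan(1 / (kap * R))
  lpm <- sqrt(sin(b)^2 + lam^2 * cos(b)^2)
  Whand <- ((kap * R)^2 * (lam - 1)^2 +
              (1 + (kap * R)^2) * baseline_nd$K3 * 2 * (lpm - 1)^2) /
    (2 * kap * R * baseline_nd$D)
  expect_equal(W, Whand, tolerance = 1e-12)
  expect_equal(W, 3.452664e-05, tolerance = 1e-6)
  expect_error(strain_energy_density(diag(c(1, -1)), 12, kap, 1, 0.001, 0.07),
               "positive definite")
})

test_that("stress is twice the energy gradient in C", {
  set.seed(42)
  kap <- baseline_nd$kappa
  for (trial in 1:5) {
    A <- matrix(rnorm(4), 2, 2)
    C <- crossprod(A) + 0.5 * diag(2)
    R <- runif(1, baseline_nd$RP, baseline_nd$RA)
    K1 <- runif(1, 0.1, 1)
    K3 <- K1 * 0.07
    W <- function(Cm) strain_energy_density(Cm, R, kap, K1, baseline_nd$K2, K3,
                                            baseline_nd$D)
    S <- second_pk_stress(C, R, kap, K1, baseline_nd$K2, K3, baseline_nd$D)
    h <- 1e-6
    Sfd <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      dC <- matrix(0, 2, 2)
      if (i == j) dC[i, j] <- 1 else dC[i, j] <- dC[j, i] <- 0.5
      Sfd[i, j] <- (W(C + h * dC) - W(C - h * dC)) / h
    }
    expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-6)
  }
  # identity gives zero stress; diagonal shear asymmetry gives T_RPhi > 0
  S0 <- second_pk_stress(diag(2), 12, kap, 1, 0.001, 0.07)
  expect_equal(max(abs(S0)), 0)
  Cs <- matrix(c(1, 0.05, 0.05, 1), 2, 2)   # lam_+ > lam_-
  Ss <- second_pk_stress(Cs, 12, kap, 1, 0.001, 0.07)
  expect_gt(Ss[1, 2], 0)
})

test_that("energy is frame indifferent and zero for the identity", {
  cfg <- cornea_config(Dmax = 0)
  expect_equal(total_potential(identity_field(), cfg, n_R = 4, n_Phi = 40, p = 0), 0)
  # rigid rotation about the arc centre leaves the strain energy at zero
  rot <- deformation_field(function(R, Phi) R, function(R, Phi) Phi + 0.1)
  expect_equal(total_potential(rot, cfg, n_R = 4, n_Phi = 40, p = 0), 0,
               tolerance = 1e-15)
  # damage fields do not change either conclusion
  cfgd <- cornea_config(Dmax = 0.99, xi = 4)
  expect_equal(total_potential(identity_field(), cfgd, n_R = 4, n_Phi = 40, p = 0), 0)
})

test_that("assembled gradient and Hessian match finite differences", {
  set.seed(5)
  cfg <- cornea_config(Dmax = 0)
  model <- corneamech:::build_continuum_model(cfg, n_R = 3, n_Phi = 8, Dmax = 0.4)
  ref <- corneamech:::cont_reference_state(model)
  r <- ref$r; phi <- ref$phi
  fn <- which(model$free)
  r[fn] <- r[fn] + 0.02 * rnorm(length(fn))
  phi[fn] <- phi[fn] + 0.002 * rnorm(length(fn))
  p <- model$p * 50
  ev <- corneamech:::cont_eval(model, r, phi, p, what = 2)
  u0 <- corneamech:::cont_pack(model, r, phi)
  En <- function(u) {
    st <- corneamech:::cont_unpack(model, u, ref)
    corneamech:::cont_eval(model, st$r, st$phi, p, what = 0)$energy
  }
  h <- 1e-6
  gfd <- vapply(seq_along(u0), function(k) {
    up <- u0; um <- u0; up[k] <- up[k] + h; um[k] <- um[k] - h
    (En(up) - En(um)) / (2 * h)
  }, 0)
  expect_lt(max(abs(ev$grad - gfd)) / max(abs(ev$grad)), 1e-5)
  G <- function(u) {
    st <- corneamech:::cont_unpack(model, u, ref)
    corneamech:::cont_eval(model, st$r, st$phi, p, what = 1)$grad
  }
  H <- as.matrix(ev$H)
  Hfd <- sapply(seq_along(u0), function(k) {
    up <- u0; um <- u0; up[k] <- up[k] + h; um[k] <- um[k] - h
    (G(up) - G(um)) / (2 * h)
  })
  expect_lt(max(abs(H - Hfd)) / max(abs(H)), 1e-5)
  expect_lt(max(abs(H - t(H))), 1e-12)
})

test_that("zero-pressure continuum solution is exactly the identity", {
  cfg <- modify_config(cornea_config(Dmax = 0), p_kPa = 0)
  sol <- solve_continuum(cfg, n_R = 4, n_Phi = 80)
  expect_equal(sol$r, matrix(sol$Rnodes, 5, 81), tolerance = 1e-14)
  expect_equal(sol$phi, matrix(sol$Phinodes, 5, 81, byrow = TRUE), tolerance = 1e-14)
  expect_equal(apex_displacement(sol), 0)
  expect_equal(central_thickness(sol), 0.62, tolerance = 1e-12)
})

test_that("healthy continuum solution has the expected shape response", {
  sol <- healthy_coarse()
  expect_lt(sol$grad_norm, 1e-10)
  # physiological response: outward apex motion of a few hundredths of a mm
  expect_gt(apex_displacement(sol), 0.03)
  expect_lt(apex_displacement(sol), 0.05)
  expect_lt(central_thickness(sol), 0.62)
  # mirror symmetry of the converged fields
  nP <- sol$n_Phi
  expect_lt(max(abs(sol$r - sol$r[, (nP + 1):1])), 1e-8 * sol$nd$RA)
  expect_lt(max(abs(sol$phi + sol$phi[, (nP + 1):1])), 1e-8)
  # pressure trajectory is monotone in apex displacement
  pr <- sol$trajectory[sol$trajectory$phase == "pressure", ]
  expect_true(all(diff(pr$AD_mm) > 0))
  # energy of the loaded state is below zero (pressure work dominates)
  expect_lt(sol$energy, 0)
})

test_that("strong-form residual vanishes on the identity and refines", {
  cfg0 <- modify_config(cornea_config(Dmax = 0), p_kPa = 0)
  s0 <- solve_continuum(cfg0, n_R = 4, n_Phi = 80)
  sf0 <- strong_form_residual(s0)
  expect_lt(max(abs(sf0$res_r)), 1e-12)
  expect_lt(max(abs(sf0$res_phi)), 1e-12)

  rms_ratio <- function(s) {
    sf <- strong_form_residual(s)
    cen <- abs(sf$Phi) < 0.8 * s$nd$Phi_star
    sqrt(mean(sf$res_r[cen]^2 + sf$res_phi[cen]^2)) / sqrt(mean(sf$scale[cen]^2))
  }
  s8 <- solve_continuum(cornea_config(Dmax = 0), n_R = 8, n_Phi = 160)
  r8 <- rms_ratio(s8)
  r16 <- rms_ratio(healthy_coarse())
  expect_lt(r16, 0.02)        # central interior balance satisfied to ~1%
  expect_lt(r16, r8)          # and improving under refinement
  # symmetry: radial residual even, azimuthal residual odd in Phi
  sf <- strong_form_residual(healthy_coarse())
  mphi <- matrix(sf$res_phi, nrow = healthy_coarse()$n_R - 1)
  mr <- matrix(sf$res_r, nrow = healthy_coarse()$n_R - 1)
  expect_lt(max(abs(mphi + mphi[, ncol(mphi):1])), 1e-6 * max(abs(mphi)))
  expect_lt(max(abs(mr - mr[, ncol(mr):1])), 1e-6 * max(abs(mr)))
})
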