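# independent oracle: total potential assembled directly from the element
# table and a shoelace area, used to cross-check residual and tangent
oracle_energy <- function(net, x, y, p) {
  e <- net$el
  l <- sqrt((x[e$n2] - x[e$n1])^2 + (y[e$n2] - y[e$n1])^2)
  Es <- sum(e$K / 2 * (l - e$L)^2)
  px <- x[net$posterior]; py <- y[net$posterior]
  n <- length(px); nxt <- c(2:n, 1)
  Es - p * net$nd$D * sum(px * py[nxt] - px[nxt] * py) / 2
}

tiny_net <- function() build_network(modify_config(cornea_config(Dmax = 0), gamma = 2), N = 2)

perturbed_state <- function(net, scale = 0.01, seed = 7) {
  set.seed(seed)
  x <- net$X; y <- net$Y
  ix <- which(net$free)
  x[ix] <- x[ix] + scale * rnorm(length(ix))
  y[ix] <- y[ix] + scale * rnorm(length(ix))
  list(x = x, y = y)
}

test_that("force per unit length follows the linear spring law", {
  expect_equal(force_per_length(1, 7.2), 0)
  expect_equal(force_per_length(1.01, 7.2), 0.07128713, tolerance = 1e-7)
  expect_equal(force_per_length(1e9, 7.2), 7.2, tolerance = 1e-8)
  expect_lt(force_per_length(0.9, 1), 0)   # compression
  expect_error(force_per_length(0, 1), "degenerate")
  expect_error(force_per_length(-1, 1), "degenerate")
})

test_that("pressure nodal forces lump the segment resultants", {
  net <- tiny_net()
  pts <- cbind(net$X[net$posterior], net$Y[net$posterior])
  expect_equal(iop_nodal_forces(pts, 0, net$nd$D), matrix(0, 5, 2))
  p <- 0.03
  F <- iop_nodal_forces(pts, p, net$nd$D)
  # apex force points along +x (into the tissue) with the half-segment sum
  L1 <- 2 * net$nd$RP * sin(net$nd$Phi_star / net$M)
  apex <- net$M / 2 + 1
  expect_equal(F[apex, 2], 0, tolerance = 1e-14)
  expect_equal(F[apex, 1], p * net$nd$D * L1 * cos(net$nd$Phi_star * 2 / net$M / 2),
               tolerance = 1e-12)
  # interior forces equal the gradient of p*D*(enclosed area), by central FD
  area <- function(px, py) {
    n <- length(px); nxt <- c(2:n, 1)
    sum(px * py[nxt] - px[nxt] * py) / 2
  }
  h <- 1e-7
  for (k in 2:4) {
    for (co in 1:2) {
      pp <- pts; pm <- pts
      pp[k, co] <- pp[k, co] + h; pm[k, co] <- pm[k, co] - h
      fd <- p * net$nd$D * (area(pp[, 1], pp[, 2]) - area(pm[, 1], pm[, 2])) / (2 * h)
      expect_equal(F[k, co], fd, tolerance = 1e-6)
    }
  }
  expect_error(iop_nodal_forces(pts[c(1, 1), ], 1, 1), "degenerate")
})

test_that("reference configuration is an exact equilibrium at zero pressure", {
  net <- tiny_net()
  expect_lt(max(abs(discrete_residual(net, p = 0))), 1e-13)
  net2 <- build_network(cornea_config(Dmax = 0), N = 4)
  expect_lt(max(abs(discrete_residual(net2, p = 0))), 1e-13)
})

test_that("residual equals the negative gradient of the assembled potential", {
  net <- tiny_net()
  st <- perturbed_state(net)
  p <- 0.05
  res <- discrete_residual(net, st$x, st$y, p)
  h <- 1e-7
  ix <- which(net$free)
  k <- 0
  fd <- numeric(2 * net$nfree)
  for (nid in ix) for (co in 1:2) {
    k <- k + 1
    xp <- st$x; yp <- st$y; xm <- st$x; ym <- st$y
    if (co == 1) { xp[nid] <- xp[nid] + h; xm[nid] <- xm[nid] - h }
    else { yp[nid] <- yp[nid] + h; ym[nid] <- ym[nid] - h }
    fd[k] <- (oracle_energy(net, xp, yp, p) - oracle_energy(net, xm, ym, p)) / (2 * h)
  }
  expect_lt(max(abs(res + fd)) / max(abs(res)), 1e-6)
})

test_that("analytic tangent matches the finite-difference Jacobian", {
  net <- tiny_net()
  st <- perturbed_state(net, seed = 11)
  p <- 0.04
  J <- as.matrix(discrete_jacobian(net, st$x, st$y, p))
  h <- 1e-7
  ix <- which(net$free)
  k <- 0
  Jfd <- matrix(0, nrow(J), ncol(J))
  for (nid in ix) for (co in 1:2) {
    k <- k + 1
    xp <- st$x; yp <- st$y; xm <- st$x; ym <- st$y
    if (co == 1) { xp[nid] <- xp[nid] + h; xm[nid] <- xm[nid] - h }
    else { yp[nid] <- yp[nid] + h; ym[nid] <- ym[nid] - h }
    Jfd[, k] <- (discrete_residual(net, xp, yp, p) -
                   discrete_residual(net, xm, ym, p)) / (2 * h)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  # conservative springs: symmetric tangent at zero pressure
  J0 <- discrete_jacobian(net, st$x, st$y, 0)
  expect_lt(max(abs(J0 - Matrix::t(J0))), 1e-12)
  # 9-node stencil: at most 18 nonzero columns per row
  big <- build_network(cornea_config(Dmax = 0), N = 4)
  Jb <- discrete_jacobian(big)
  nnz_per_row <- tabulate(Jb@i + 1L, nbins = nrow(Jb))
  expect_lte(max(nnz_per_row), 18)
})

test_that("reflection symmetry of the lattice maps the residual accordingly", {
  net <- tiny_net()
  st <- perturbed_state(net, seed = 3)
  p <- 0.02
  res <- discrete_residual(net, st$x, st$y, p)
  # reflect y -> -y and reverse the azimuthal ordering
  Np1 <- net$N + 1L
  flip <- function(v, sgn) {
    m <- matrix(v, Np1, net$M + 1L)
    as.vector(sgn * m[, (net$M + 1L):1])
  }
  res2 <- discrete_residual(net, flip(st$x, 1), flip(st$y, -1), p)
  rx <- res[seq(1, length(res), 2)]; ry <- res[seq(2, length(res), 2)]
  r2x <- res2[seq(1, length(res2), 2)]; r2y <- res2[seq(2, length(res2), 2)]
  fm <- function(v, sgn) {
    m <- matrix(v, Np1, net$M - 1L)
    as.vector(sgn * m[, (net$M - 1L):1])
  }
  expect_equal(r2x, fm(rx, 1), tolerance = 1e-12)
  expect_equal(r2y, fm(ry, -1), tolerance = 1e-12)
})

test_that("zero pressure solve returns the reference configuration", {
  cfg <- modify_config(cornea_config(Dmax = 0), p_kPa = 0)
  sol <- solve_discrete(cfg, N = 2)
  expect_equal(sol$x, sol$network$X, tolerance = 1e-14)
  expect_equal(sol$y, sol$network$Y, tolerance = 1e-14)
  expect_equal(apex_displacement(sol), 0)
  expect_equal(central_thickness(sol), 0.62, tolerance = 1e-12)
})

test_that("healthy solve is mirror symmetric with monotone load response", {
  sol <- discrete_healthy(4)
  net <- sol$network
  expect_lt(sol$residual_norm, 1e-10)
  expect_true(all(sol$stretch > 0))
  # element force law f = K L (lambda - 1)
  expect_equal(sol$force, net$el$K * net$el$L * (sol$stretch - 1), tolerance = 1e-12)
  ym <- matrix(sol$y, net$N + 1, net$M + 1)
  xm <- matrix(sol$x, net$N + 1, net$M + 1)
  expect_lt(max(abs(ym + ym[, (net$M + 1):1])), 1e-8 * net$nd$RA)
  expect_lt(max(abs(xm - xm[, (net$M + 1):1])), 1e-8 * net$nd$RA)
  expect_true(all(diff(sol$trajectory$AD_mm) > 0))   # AD monotone in p
  expect_gt(apex_displacement(sol), 0)
  expect_lt(central_thickness(sol), 0.62)            # tension thins the slice
})

test_that("lamellar force carried by a cross-section is N-independent", {
  tots <- vapply(c(4, 8), function(N) {
    sol <- discrete_healthy(N)
    net <- sol$network
    e <- net$el
    lam <- which(e$family == 1L)
    jj <- (e$n1[lam] - 1L) %/% (net$N + 1L)
    sum(sol$force_N[lam[jj == net$M / 2]])
  }, 0)
  expect_lt(abs(diff(tots)) / mean(tots), 0.01)
})

test_that("lamellar stress equals segment force over reference area", {
  sol <- discrete_healthy(4)
  ls <- lamellar_stress(sol)
  net <- sol$network
  expect_equal(nrow(ls), (net$N + 1) * net$M)
  # direct arithmetic: T = K1 L1 (lambda - 1) / (L2 D), in kPa
  e <- net$el; lam <- e$family == 1L
  expected <- sol$force_N[lam] / (0.62 / net$N * 1) * 1000
  expect_equal(ls$stress_kPa, expected, tolerance = 1e-12)
  expect_true(all(ls$stress_kPa[abs(ls$Y_mm) < 2] > 0))  # central lamellae in tension
  # unloaded: zero stress
  s0 <- solve_discrete(modify_config(cornea_config(Dmax = 0), p_kPa = 0), N = 2)
  expect_true(all(abs(lamellar_stress(s0)$stress_kPa) < 1e-9))
})
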