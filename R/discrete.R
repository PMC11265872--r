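#' Force per unit current length in a linear strut
#'
#' For a linearly elastic strut of axial stiffness `K`, the nodal force
#' contribution per unit current length is `g(lambda) = K (1 - 1/lambda)`:
#' negative in compression (`lambda < 1`), saturating at `K` for large
#' stretch.
#'
#' @param lam Element stretch(es), `> 0`.
#' @param K Axial stiffness.
#' @return `K * (1 - 1/lam)`.
#' @export
force_per_length <- function(lam, K) {
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("degenerate element: stretch must be positive", call. = FALSE)
  }
  K * (1 - 1 / lam)
}

# ---- signed-area helpers (pressure potential) -------------------------------
# A(px, py): shoelace signed area of the closed polygon through the vertices
# in order (the chord between the last and first vertex closes it). For the
# posterior boundary traversed from Phi = -Phi* to +Phi* this is positive and
# grows as the cornea bulges outward, so the pressure potential is -p*D*A.
poly_area <- function(px, py) {
  nxt <- c(seq_along(px)[-1], 1L)
  sum(px * py[nxt] - px[nxt] * py) / 2
}

poly_area_grad <- function(px, py) {
  n <- length(px)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1))
  list(x = (py[nxt] - py[prv]) / 2, y = (px[prv] - px[nxt]) / 2)
}

# constant Hessian of the shoelace area: d2A/dx_k dy_{k+1} = 1/2,
# d2A/dx_{k+1} dy_k = -1/2 (plus transposes). Returned as triplets in the
# 2n-dof ordering (x_k, y_k) interleaved.
poly_area_hess_triplets <- function(n) {
  k <- 1:n
  nxt <- c(2:n, 1L)
  xi <- 2 * k - 1; ynxt <- 2 * nxt; yi <- 2 * k; xnxt <- 2 * nxt - 1
  list(
    i = c(xi, ynxt, yi, xnxt),
    j = c(ynxt, xi, xnxt, yi),
    x = c(rep(0.5, n), rep(0.5, n), rep(-0.5, n), rep(-0.5, n))
  )
}

#' Equivalent nodal forces of the intraocular pressure
#'
#' Integrates the pressure over each posterior lamellar segment and lumps
#' half of each segment resultant onto its two end nodes: the force on
#' node `j` is `p D / 2 * (l_{j-1/2} n_{j-1/2} + l_{j+1/2} n_{j+1/2})`,
#' with `n` the unit normal pointing from the posterior surface into the
#' tissue. These nodal forces are exactly the gradient of `p D A`, where
#' `A` is the signed area enclosed by the posterior polyline and the chord
#' between its pinned endpoints.
#'
#' @param polyline Two-column matrix (or data frame) of the `M+1` posterior
#'   node positions in the current configuration, ordered from one limbus
#'   to the other.
#' @param p Pressure (consistent units).
#' @param D Slice depth (consistent units).
#' @return `(M+1) x 2` matrix of nodal force vectors (end nodes carry only
#'   their single adjacent half-segment).
#' @export
iop_nodal_forces <- function(polyline, p, D) {
  pts <- as.matrix(polyline)
  n <- nrow(pts)
  if (n < 2) stop("polyline needs at least two points", call. = FALSE)
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("degenerate geometry: zero-length segment", call. = FALSE)
  # l * nhat = segment rotated by -90 degrees: (dy, -dx)
  ln <- cbind(seg[, 2], -seg[, 1])
  F <- matrix(0, n, 2)
  F[-n, ] <- F[-n, ] + ln / 2
  F[-1, ] <- F[-1, ] + ln / 2
  p * D * F
}

# ---- network construction ---------------------------------------------------

#' Assemble the discrete spring network
#'
#' Builds the dimensionless lattice for a configuration: reference node
#' positions, element connectivity for the three families (lamellar,
#' radial, diagonal), rest lengths, and per-element stiffness with the
#' damage profile (if any) applied to the lamellar and diagonal families at
#' the element midpoint reference `Y`.
#'
#' @param config A [cornea_config()].
#' @param N Number of radial layers; defaults to `config$N`.
#' @return Object of class `cornea_network`.
#' @export
build_network <- function(config, N = config$N) {
  nd <- nondimensional(config)
  disc <- discretization(N, config$gamma)
  N <- disc$N; M <- disc$M
  nid <- function(i, j) j * (N + 1L) + i + 1L  # i = 0..N, j = 0..M
  R_i <- nd$RP + (0:N) / N
  Phi_j <- ((0:M) - M / 2) * 2 * nd$Phi_star / M
  X <- as.vector(outer(R_i, cos(Phi_j)))
  Y <- as.vector(outer(R_i, sin(Phi_j)))
  L2 <- 1 / N
  L1 <- 2 * R_i * sin(nd$Phi_star / M)
  L3 <- sqrt(L1[1:N] * L1[2:(N + 1)] + L2^2)

  ii <- 0:N; jj <- 0:(M - 1)
  lam_n1 <- as.vector(outer(ii, jj, function(i, j) nid(i, j)))
  lam_n2 <- as.vector(outer(ii, jj, function(i, j) nid(i, j + 1L)))
  lam_L <- rep(L1, times = M)
  ii2 <- 0:(N - 1); jj2 <- 0:M
  rad_n1 <- as.vector(outer(ii2, jj2, function(i, j) nid(i, j)))
  rad_n2 <- as.vector(outer(ii2, jj2, function(i, j) nid(i + 1L, j)))
  dia_n1 <- c(as.vector(outer(ii2, jj, function(i, j) nid(i, j))),
              as.vector(outer(ii2, jj, function(i, j) nid(i, j + 1L))))
  dia_n2 <- c(as.vector(outer(ii2, jj, function(i, j) nid(i + 1L, j + 1L))),
              as.vector(outer(ii2, jj, function(i, j) nid(i + 1L, j))))
  dia_L <- rep(rep(L3, times = M), 2)

  n1 <- c(lam_n1, rad_n1, dia_n1)
  n2 <- c(lam_n2, rad_n2, dia_n2)
  L <- c(lam_L, rep(L2, length(rad_n1)), dia_L)
  family <- rep(c(1L, 2L, 3L), c(length(lam_n1), length(rad_n1), length(dia_n1)))
  Kfam <- c(1, nd$K2, nd$K3)[family]
  # damage at element midpoint reference Y (converted to mm for the profile)
  Ymid_mm <- (Y[n1] + Y[n2]) / 2 * nd$length_mm
  dmg <- damage_at(Ymid_mm, config)
  Kel <- ifelse(family == 2L, Kfam, (1 - dmg) * Kfam)

  jnode <- rep(0:M, each = N + 1L)
  free <- jnode != 0L & jnode != M
  fpos <- integer(length(free)); fpos[] <- NA_integer_
  fpos[free] <- seq_len(sum(free))

  structure(list(
    N = N, M = M, nn = (N + 1L) * (M + 1L),
    X = X, Y = Y, R_i = R_i, Phi_j = Phi_j,
    el = list(n1 = n1, n2 = n2, L = L, K = Kel, family = family,
              damage = dmg),
    free = free, fpos = fpos, nfree = sum(free),
    posterior = nid(0L, 0:M), anterior = nid(N, 0:M),
    nd = nd, config = config
  ), class = "cornea_network")
}

# ---- energy / residual / tangent -------------------------------------------

# total potential: spring energy minus p*D*(enclosed posterior area);
# x, y full-length coordinate vectors (dimensionless)
net_energy <- function(net, x, y, p) {
  e <- net$el
  dx <- x[e$n2] - x[e$n1]; dy <- y[e$n2] - y[e$n1]
  l <- sqrt(dx^2 + dy^2)
  E <- sum(e$K / 2 * (l - e$L)^2)
  if (p != 0) {
    E <- E - p * net$nd$D * poly_area(x[net$posterior], y[net$posterior])
  }
  E
}

# gradient of net_energy w.r.t. all nodal coordinates; returns list(x=, y=)
net_energy_grad <- function(net, x, y, p) {
  e <- net$el
  dx <- x[e$n2] - x[e$n1]; dy <- y[e$n2] - y[e$n1]
  l <- sqrt(dx^2 + dy^2)
  if (any(l == 0)) stop("degenerate element: coincident nodes", call. = FALSE)
  f <- e$K * (l - e$L) / l   # force magnitude over length
  gx <- rowsum(c(-f * dx, f * dx), c(e$n1, e$n2))
  gy <- rowsum(c(-f * dy, f * dy), c(e$n1, e$n2))
  # rowsum groups come back sorted by node id; all nodes appear
  Gx <- numeric(net$nn); Gy <- numeric(net$nn)
  Gx[as.integer(rownames(gx))] <- gx
  Gy[as.integer(rownames(gy))] <- gy
  if (p != 0) {
    ga <- poly_area_grad(x[net$posterior], y[net$posterior])
    Gx[net$posterior] <- Gx[net$posterior] - p * net$nd$D * ga$x
    Gy[net$posterior] <- Gy[net$posterior] - p * net$nd$D * ga$y
  }
  list(x = Gx, y = Gy)
}

#' Nodal force imbalance of the discrete network
#'
#' Evaluates the out-of-balance force at every free node: the sum of the
#' axial forces of the connected struts plus (on the posterior surface) the
#' equivalent pressure forces. This equals the negative gradient of the
#' total potential (spring energy minus `p D` times the enclosed posterior
#' area), and vanishes at equilibrium.
#'
#' @param net A [build_network()] object.
#' @param x,y Current nodal coordinates (dimensionless, full grid including
#'   pinned nodes). Default: reference configuration.
#' @param p Dimensionless pressure (`p_tilde * T / K1`); defaults to the
#'   configuration value.
#' @return Numeric vector of length `2 * nfree`, interleaved
#'   `(Fx, Fy)` per free node (nodes ordered radial-index fastest).
#' @export
discrete_residual <- function(net, x = net$X, y = net$Y, p = net$nd$p) {
  g <- net_energy_grad(net, x, y, p)
  res <- numeric(2 * net$nfree)
  res[seq(1, by = 2, length.out = net$nfree)] <- -g$x[net$free]
  res[seq(2, by = 2, length.out = net$nfree)] <- -g$y[net$free]
  res
}

# sparse Hessian of the total potential restricted to free dof
net_hessian <- function(net, x, y, p) {
  e <- net$el
  dx <- x[e$n2] - x[e$n1]; dy <- y[e$n2] - y[e$n1]
  l <- sqrt(dx^2 + dy^2)
  tx <- dx / l; ty <- dy / l
  a <- e$K * (1 - e$L / l)      # coefficient of identity
  b <- e$K * (e$L / l)          # coefficient of t t^T
  kxx <- a + b * tx * tx
  kxy <- b * tx * ty
  kyy <- a + b * ty * ty

  dofx <- function(nid) 2 * net$fpos[nid] - 1
  dofy <- function(nid) 2 * net$fpos[nid]
  n1 <- e$n1; n2 <- e$n2
  blocks <- list(list(n1, n1, 1), list(n2, n2, 1), list(n1, n2, -1), list(n2, n1, -1))
  ti <- tj <- integer(0); tv <- numeric(0)
  for (blk in blocks) {
    a1 <- blk[[1]]; a2 <- blk[[2]]; sg <- blk[[3]]
    keep <- net$free[a1] & net$free[a2]
    if (!any(keep)) next
    i1 <- a1[keep]; i2 <- a2[keep]
    ti <- c(ti, dofx(i1), dofx(i1), dofy(i1), dofy(i1))
    tj <- c(tj, dofx(i2), dofy(i2), dofx(i2), dofy(i2))
    tv <- c(tv, sg * kxx[keep], sg * kxy[keep], sg * kxy[keep], sg * kyy[keep])
  }
  if (p != 0) {
    ph <- poly_area_hess_triplets(length(net$posterior))
    # map polygon dof (interleaved over posterior vertices) to free dof
    vert <- net$posterior[(ph$i + 1) %/% 2]
    vertj <- net$posterior[(ph$j + 1) %/% 2]
    isx_i <- ph$i %% 2 == 1; isx_j <- ph$j %% 2 == 1
    keep <- net$free[vert] & net$free[vertj]
    if (any(keep)) {
      di <- ifelse(isx_i, 2 * net$fpos[vert] - 1, 2 * net$fpos[vert])
      dj <- ifelse(isx_j, 2 * net$fpos[vertj] - 1, 2 * net$fpos[vertj])
      ti <- c(ti, di[keep]); tj <- c(tj, dj[keep])
      tv <- c(tv, -p * net$nd$D * ph$x[keep])
    }
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                       dims = c(2 * net$nfree, 2 * net$nfree))
}

#' Tangent (Jacobian) of the discrete residual
#'
#' Analytic sparse derivative of [discrete_residual()] with respect to the
#' free nodal coordinates, including the configuration dependence of the
#' pressure (follower) forces. Because the residual is the negative
#' gradient of a potential, the Jacobian is the negative Hessian and is
#' symmetric.
#'
#' @inheritParams discrete_residual
#' @return Sparse `2 nfree x 2 nfree` matrix.
#' @export
discrete_jacobian <- function(net, x = net$X, y = net$Y, p = net$nd$p) {
  -net_hessian(net, x, y, p)
}

# ---- solver -----------------------------------------------------------------

solve_newton <- function(u0, energy_fn, grad_fn, hess_fn, tol, max_iter,
                         label = "newton") {
  u <- u0
  g <- grad_fn(u)
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) <= tol) break
    H <- hess_fn(u)
    d <- NULL
    tau <- 0
    for (k in 0:8) {
      Hk <- if (tau > 0) H + Matrix::Diagonal(nrow(H), tau) else H
      d <- tryCatch({
        ch <- Matrix::Cholesky(Matrix::forceSymmetric(Hk), LDL = FALSE, perm = TRUE)
        as.numeric(Matrix::solve(ch, -g))
      }, error = function(e) NULL)
      if (!is.null(d) && sum(d * g) < 0) break
      tau <- if (tau == 0) 1e-8 * max(abs(H@x)) else tau * 100
      d <- NULL
    }
    if (is.null(d)) stop(label, ": could not obtain a descent direction", call. = FALSE)
    E0 <- energy_fn(u)
    slope <- sum(g * d)
    alpha <- 1
    repeat {
      Et <- energy_fn(u + alpha * d)
      if (is.finite(Et) && Et <= E0 + 1e-4 * alpha * slope) break
      alpha <- alpha / 2
      if (alpha < 2^-30) stop(label, ": line search failed", call. = FALSE)
    }
    u <- u + alpha * d
    g <- grad_fn(u)
  }
  if (max(abs(g)) > tol) {
    stop(sprintf("%s: no convergence in %d iterations (residual %.3e)",
                 label, max_iter, max(abs(g))), call. = FALSE)
  }
  list(u = u, resid = max(abs(g)), iter = it)
}

#' Solve the discrete lattice equilibrium
#'
#' Finds the finite-kinematics equilibrium of the spring lattice under the
#' intraocular pressure with pinned limbus nodes, by Newton's method with
#' backtracking line search on the total potential and incremental pressure
#' continuation (the continuation selects the stable branch connected to
#' the stress-free reference state).
#'
#' @param config A [cornea_config()]. Use `Dmax = 0` for a healthy cornea.
#' @param N Number of radial layers (default `config$N`).
#' @param n_steps Number of equal pressure increments (default from
#'   `config$solver`).
#' @param tol Residual infinity-norm tolerance (dimensionless).
#' @param max_iter Maximum Newton iterations per load step.
#' @return Object of class `cornea_discrete`: the converged nodal positions
#'   (`x`, `y`, dimensionless; `x_mm`, `y_mm` in mm), per-element stretches
#'   and axial forces, the residual norm achieved, and a `trajectory`
#'   tibble with the apex displacement after each load step.
#' @export
solve_discrete <- function(config, N = config$N,
                           n_steps = config$solver$n_load_steps,
                           tol = config$solver$tol,
                           max_iter = config$solver$max_iter) {
  net <- build_network(config, N = N)
  nf <- net$nfree
  ixf <- which(net$free)
  x <- net$X; y <- net$Y
  pack <- function(x, y) {
    u <- numeric(2 * nf)
    u[seq(1, by = 2, length.out = nf)] <- x[ixf]
    u[seq(2, by = 2, length.out = nf)] <- y[ixf]
    u
  }
  unpack <- function(u) {
    x2 <- net$X; y2 <- net$Y
    x2[ixf] <- u[seq(1, by = 2, length.out = nf)]
    y2[ixf] <- u[seq(2, by = 2, length.out = nf)]
    list(x = x2, y = y2)
  }
  u <- pack(x, y)
  traj <- list()
  p_target <- net$nd$p
  steps <- if (p_target == 0) numeric(0) else p_target * seq_len(n_steps) / n_steps
  resid <- 0; iters <- 0L
  for (s in seq_along(steps)) {
    pk <- steps[s]
    fit <- solve_newton(
      u,
      energy_fn = function(uu) { st <- unpack(uu); net_energy(net, st$x, st$y, pk) },
      grad_fn = function(uu) {
        st <- unpack(uu)
        g <- net_energy_grad(net, st$x, st$y, pk)
        pack(g$x, g$y)
      },
      hess_fn = function(uu) { st <- unpack(uu); net_hessian(net, st$x, st$y, pk) },
      tol = tol, max_iter = max_iter,
      label = sprintf("discrete solve (step %d/%d)", s, length(steps))
    )
    u <- fit$u; resid <- fit$resid; iters <- iters + fit$iter
    st <- unpack(u)
    disp <- sqrt((st$x - net$X)^2 + (st$y - net$Y)^2) * net$nd$length_mm
    apex <- net$anterior[net$M / 2 + 1]
    traj[[s]] <- tibble::tibble(
      step = s, p_kPa = pk / (1e-3 * net$nd$length_mm / config$K1),
      max_disp_mm = max(disp),
      AD_mm = (sqrt(st$x[apex]^2 + st$y[apex]^2) - net$nd$RA) * net$nd$length_mm
    )
  }
  st <- unpack(u)
  e <- net$el
  dx <- st$x[e$n2] - st$x[e$n1]; dy <- st$y[e$n2] - st$y[e$n1]
  l <- sqrt(dx^2 + dy^2)
  structure(list(
    network = net,
    x = st$x, y = st$y,
    x_mm = st$x * net$nd$length_mm, y_mm = st$y * net$nd$length_mm,
    stretch = l / e$L,
    force = e$K * (l - e$L),            # dimensionless (units of K1*T)
    force_N = e$K * (l - e$L) * net$nd$force_N,
    residual_norm = resid, newton_iterations = iters,
    p_kPa = config$p,
    trajectory = dplyr::bind_rows(traj),
    config = config
  ), class = "cornea_discrete")
}

#' @export
print.cornea_discrete <- function(x, ...) {
  net <- x$network
  cat(sprintf("<cornea_discrete> N = %d, M = %d, p = %g kPa\n", net$N, net$M, x$p_kPa))
  cat(sprintf("  residual norm %.2e after %d Newton iterations\n",
              x$residual_norm, x$newton_iterations))
  cat(sprintf("  apex displacement %.4f mm, max displacement %.4f mm\n",
              apex_displacement(x), max_displacement(x)))
  invisible(x)
}

#' Maximum nodal displacement magnitude
#'
#' @param sol A `cornea_discrete` solution.
#' @return Maximum over all nodes of the displacement magnitude, in mm.
#' @export
max_displacement <- function(sol) {
  stopifnot(inherits(sol, "cornea_discrete"))
  net <- sol$network
  max(sqrt((sol$x - net$X)^2 + (sol$y - net$Y)^2)) * net$nd$length_mm
}

#' Azimuthal lamellar stress per segment
#'
#' Estimates the azimuthal normal stress carried by each lamellar segment
#' as its axial force divided by the reference cross-sectional area
#' `L2 * D` of the tributary region: `T = K1 (l - L1) / (L2 D)`.
#'
#' @param sol A converged `cornea_discrete` solution.
#' @return Tibble with one row per lamellar segment: layer index `i`,
#'   azimuthal interval `j` (element between nodes `j` and `j+1`), midpoint
#'   reference coordinates (mm), stretch, and stress in kPa.
#' @export
lamellar_stress <- function(sol) {
  stopifnot(inherits(sol, "cornea_discrete"))
  net <- sol$network
  e <- net$el
  lam <- e$family == 1L
  nd <- net$nd
  # dimensionless force / (L2 * D) -> stress scale K1/T (MPa) -> kPa
  stress <- sol$force[lam] / ((1 / net$N) * nd$D) * nd$stress_kPa
  n1 <- e$n1[lam]; n2 <- e$n2[lam]
  i <- (n1 - 1L) %% (net$N + 1L)
  j <- (n1 - 1L) %/% (net$N + 1L)
  tibble::tibble(
    i = i, j = j,
    X_mm = (net$X[n1] + net$X[n2]) / 2 * nd$length_mm,
    Y_mm = (net$Y[n1] + net$Y[n2]) / 2 * nd$length_mm,
    stretch = sol$stretch[lam],
    stress_kPa = stress
  )
}
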