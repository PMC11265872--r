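#' @useDynLib corneamech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- model construction -----------------------------------------------------

# Build the structured-grid continuum model: node coordinates, quadrature
# stiffness fields (with damage), dof maps for the Dirichlet-constrained
# minimization. All quantities dimensionless (lengths / T, stiffness / K1).
build_continuum_model <- function(config, n_R, n_Phi, Dmax = 0) {
  nd <- nondimensional(config)
  if (n_Phi %% 2 != 0) stop("n_Phi must be even (apex node required)", call. = FALSE)
  Rnodes <- nd$RP + (0:n_R) / n_R          # thickness is 1 dimensionless
  dR <- 1 / n_R
  Phinodes <- ((0:n_Phi) - n_Phi / 2) * 2 * nd$Phi_star / n_Phi
  dPhi <- 2 * nd$Phi_star / n_Phi
  nn <- (n_R + 1) * (n_Phi + 1)
  node_id <- function(i, j) j * (n_R + 1L) + i + 1L   # i=0..n_R, j=0..n_Phi

  # quadrature point reference coordinates, ordering must match the C++ loop:
  # qp = (eJ*nR + eI)*4 + g, g = gj*2 + gi, gauss points (-,+)/sqrt(3)
  gs <- c(-1, 1) / sqrt(3)
  eI <- rep(0:(n_R - 1), times = n_Phi)
  eJ <- rep(0:(n_Phi - 1), each = n_R)
  qpR <- qpPhi <- numeric(4 * n_R * n_Phi)
  for (g in 0:3) {
    gi <- g %% 2; gj <- g %/% 2
    idx <- (eJ * n_R + eI) * 4 + g + 1
    qpR[idx] <- Rnodes[eI + 1] + 0.5 * (1 + gs[gi + 1]) * dR
    qpPhi[idx] <- Phinodes[eJ + 1] + 0.5 * (1 + gs[gj + 1]) * dPhi
  }
  qpY_mm <- qpR * sin(qpPhi) * nd$length_mm

  jnode <- rep(0:n_Phi, each = n_R + 1)
  free <- jnode != 0 & jnode != n_Phi
  ford <- integer(nn); ford[] <- -1L
  ford[free] <- seq_len(sum(free)) - 1L        # 0-based free node ordinal
  dofR <- ifelse(ford >= 0, 2L * ford, -1L)
  dofPhi <- ifelse(ford >= 0, 2L * ford + 1L, -1L)

  m <- list(
    n_R = n_R, n_Phi = n_Phi, nn = nn,
    Rnodes = Rnodes, Phinodes = Phinodes, dR = dR, dPhi = dPhi,
    kappa = nd$kappa, K2 = nd$K2, K3 = nd$K3, D = nd$D, p = nd$p,
    qpY_mm = qpY_mm,
    free = free, dofR = dofR, dofPhi = dofPhi, nfree = 2L * sum(free),
    posterior = node_id(0L, 0:n_Phi), anterior = node_id(n_R, 0:n_Phi),
    nd = nd, config = config
  )
  cont_set_damage(m, Dmax)
}

cont_set_damage <- function(model, Dmax) {
  d <- damage_at(model$qpY_mm, model$config, Dmax = Dmax)
  model$K1qp <- 1 - d
  model$K3qp <- model$K3 * (1 - d)
  model$Dmax_current <- Dmax
  model
}

# reference (identity) state
cont_reference_state <- function(model) {
  list(r = rep(model$Rnodes, times = model$n_Phi + 1),
       phi = rep(model$Phinodes, each = model$n_R + 1))
}

# ---- pressure (enclosed-area) term in polar unknowns ------------------------

# E_p = -p * D * A(x(r,phi), y(r,phi)) over the posterior boundary row.
cont_pressure <- function(model, r, phi, p, what = 0) {
  post <- model$posterior
  rb <- r[post]; pb <- phi[post]
  xb <- rb * cos(pb); yb <- rb * sin(pb)
  A <- poly_area(xb, yb)
  E <- -p * model$D * A
  if (what == 0) return(list(energy = E))
  ga <- poly_area_grad(xb, yb)
  gx <- -p * model$D * ga$x
  gy <- -p * model$D * ga$y
  cosb <- cos(pb); sinb <- sin(pb)
  gr <- gx * cosb + gy * sinb
  gp <- gx * (-rb * sinb) + gy * (rb * cosb)
  if (what == 1) return(list(energy = E, post = post, gr = gr, gp = gp))

  # Hessian: neighbour coupling through the area form + same-node curvature
  # of the polar-to-Cartesian map.
  n <- length(post)
  c12 <- -p * model$D * 0.5   # d2E/dx_k dy_{k+1} etc. (area Hessian scaled)
  k <- 1:(n - 1); k2 <- k + 1
  # J_k columns (d/dr, d/dphi) of (x, y)
  Jx_r <- cosb; Jx_p <- -rb * sinb
  Jy_r <- sinb; Jy_p <- rb * cosb
  # block between vertex k and k+1 in (x,y): [[0, c12], [-c12, 0]]
  # transformed: H_ab = Jk^T B J_{k+1}
  B_rr <- c12 * (Jx_r[k] * Jy_r[k2] - Jy_r[k] * Jx_r[k2])
  B_rp <- c12 * (Jx_r[k] * Jy_p[k2] - Jy_r[k] * Jx_p[k2])
  B_pr <- c12 * (Jx_p[k] * Jy_r[k2] - Jy_p[k] * Jx_r[k2])
  B_pp <- c12 * (Jx_p[k] * Jy_p[k2] - Jy_p[k] * Jx_p[k2])
  # same-node terms: g . d2(x,y)/d(r,phi)2
  d_rp <- gx * (-sinb) + gy * cosb
  d_pp <- gx * (-xb) + gy * (-yb)
  list(energy = E, post = post, gr = gr, gp = gp,
       pair = list(k = k, k2 = k2, B_rr = B_rr, B_rp = B_rp,
                   B_pr = B_pr, B_pp = B_pp),
       diag = list(d_rp = d_rp, d_pp = d_pp))
}

# ---- assembled energy / gradient / Hessian ----------------------------------

cont_eval <- function(model, r, phi, p, what = 2) {
  out <- cm_assemble(model$n_R, model$n_Phi, model$Rnodes, model$dR, model$dPhi,
                     r, phi, model$kappa, model$K1qp, model$K3qp, model$K2,
                     model$D, model$dofR, model$dofPhi, model$nfree, what)
  pr <- if (p != 0) cont_pressure(model, r, phi, p, what = what) else NULL
  E <- out$energy + if (is.null(pr)) 0 else pr$energy
  res <- list(energy = E, mindet = out$mindet)
  if (what >= 1) {
    grad <- out$grad            # length 2*nn, [2*node] = r-dof (0-based C++)
    if (!is.null(pr)) {
      ir <- 2 * (pr$post - 1) + 1
      grad[ir] <- grad[ir] + pr$gr
      grad[ir + 1] <- grad[ir + 1] + pr$gp
    }
    g <- numeric(model$nfree)
    fn <- which(model$free)
    g[model$dofR[fn] + 1] <- grad[2 * (fn - 1) + 1]
    g[model$dofPhi[fn] + 1] <- grad[2 * (fn - 1) + 2]
    res$grad <- g
  }
  if (what >= 2) {
    ti <- out$ti + 1L; tj <- out$tj + 1L; tx <- out$tx
    if (!is.null(pr)) {
      pk <- pr$pair
      n1 <- pr$post[pk$k]; n2 <- pr$post[pk$k2]
      dr1 <- model$dofR[n1] + 1L; dp1 <- model$dofPhi[n1] + 1L
      dr2 <- model$dofR[n2] + 1L; dp2 <- model$dofPhi[n2] + 1L
      keep <- function(a, b) a > 0 & b > 0
      addt <- function(ia, ja, xa) {
        k <- keep(ia, ja)
        if (any(k)) {
          ti <<- c(ti, ia[k], ja[k]); tj <<- c(tj, ja[k], ia[k])
          tx <<- c(tx, xa[k], xa[k])
        }
      }
      addt(dr1, dr2, pk$B_rr); addt(dr1, dp2, pk$B_rp)
      addt(dp1, dr2, pk$B_pr); addt(dp1, dp2, pk$B_pp)
      dd <- pr$diag
      drr <- model$dofR[pr$post] + 1L; dpp <- model$dofPhi[pr$post] + 1L
      k <- drr > 0
      if (any(k)) {
        ti <- c(ti, drr[k], dpp[k], dpp[k])
        tj <- c(tj, dpp[k], drr[k], dpp[k])
        tx <- c(tx, dd$d_rp[k], dd$d_rp[k], dd$d_pp[k])
      }
    }
    res$H <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                  dims = c(model$nfree, model$nfree))
  }
  res
}

# separable linear interpolation of a structured-grid field onto new axes
grid_interp <- function(mat, R0, P0, R1, P1) {
  tmp <- apply(mat, 2, function(col) stats::approx(R0, col, xout = R1,
                                                   rule = 2)$y)
  t(apply(tmp, 1, function(row) stats::approx(P0, row, xout = P1,
                                              rule = 2)$y))
}

# scatter/gather between full fields and the free-dof vector
cont_pack <- function(model, r, phi) {
  fn <- which(model$free)
  u <- numeric(model$nfree)
  u[model$dofR[fn] + 1] <- r[fn]
  u[model$dofPhi[fn] + 1] <- phi[fn]
  u
}
cont_unpack <- function(model, u, ref) {
  fn <- which(model$free)
  r <- ref$r; phi <- ref$phi
  r[fn] <- u[model$dofR[fn] + 1]
  phi[fn] <- u[model$dofPhi[fn] + 1]
  list(r = r, phi = phi)
}

# Newton with backtracking line search. States with non-positive det F are
# rejected as infeasible. `senv` (an environment) carries the symbolic
# Cholesky factorization across iterations and continuation steps.
cont_newton <- function(model, u0, ref, p, tol, max_iter, label,
                        senv = new.env(parent = emptyenv())) {
  chol_solve <- function(H, g, tau) {
    Hs <- Matrix::forceSymmetric(H)
    ch <- NULL
    if (!is.null(senv$ch)) {
      ch <- tryCatch(Matrix::update(senv$ch, Hs, mult = tau),
                     error = function(e) NULL)
    }
    if (is.null(ch)) {
      ch <- tryCatch(Matrix::Cholesky(Hs, LDL = FALSE, perm = TRUE, Imult = tau),
                     error = function(e) NULL)
    }
    if (is.null(ch)) return(NULL)
    senv$ch <- ch
    as.numeric(Matrix::solve(ch, -g))
  }
  u <- u0
  for (it in seq_len(max_iter)) {
    st <- cont_unpack(model, u, ref)
    ev <- cont_eval(model, st$r, st$phi, p, what = 2)
    g <- ev$grad
    if (max(abs(g)) <= tol) {
      return(list(u = u, resid = max(abs(g)), energy = ev$energy, iter = it))
    }
    H <- ev$H
    d <- NULL; tau <- 0
    for (k in 0:8) {
      d <- chol_solve(H, g, tau)
      if (!is.null(d) && sum(d * g) < 0) break
      tau <- if (tau == 0) 1e-8 * max(abs(H@x)) else tau * 100
      d <- NULL
    }
    if (is.null(d)) stop(label, ": could not obtain a descent direction", call. = FALSE)
    E0 <- ev$energy
    slope <- sum(g * d)
    alpha <- 1
    repeat {
      st2 <- cont_unpack(model, u + alpha * d, ref)
      et <- cont_eval(model, st2$r, st2$phi, p, what = 0)
      ok <- is.finite(et$energy) && et$mindet > 0 &&
        et$energy <= E0 + 1e-4 * alpha * slope
      if (ok) break
      alpha <- alpha / 2
      if (alpha < 2^-30) stop(label, ": line search failed", call. = FALSE)
    }
    u <- u + alpha * d
  }
  st <- cont_unpack(model, u, ref)
  ev <- cont_eval(model, st$r, st$phi, p, what = 1)
  if (max(abs(ev$grad)) > tol) {
    stop(sprintf("%s: no convergence in %d iterations (gradient %.3e)",
                 label, max_iter, max(abs(ev$grad))), call. = FALSE)
  }
  list(u = u, resid = max(abs(ev$grad)), energy = ev$energy, iter = max_iter)
}

#' Solve the continuum corneal model
#'
#' Minimizes the total potential (upscaled anisotropic strain energy stored
#' in the annular sector minus the pressure work, expressed as `p D` times
#' the area enclosed by the deformed posterior boundary and the limbus
#' chord) over deformation fields `(r, phi)(R, Phi)` pinned to the identity
#' at the limbus. Discretization: structured bilinear elements on the
#' `(R, Phi)` rectangle with 2x2 Gauss quadrature; solution by Newton's
#' method with backtracking line search, continuation first in pressure
#' and then (for a damaged cornea) in the maximum damage.
#'
#' @param config A [cornea_config()]; `config$Dmax` sets the damage level
#'   (0 = healthy).
#' @param n_R Radial element count (default from `config$solver`).
#' @param n_Phi Azimuthal element count (default `n_R * n_Phi_per_R`,
#'   matching the lattice aspect ratio); must be even.
#' @param tol Gradient infinity-norm tolerance (dimensionless).
#' @param max_iter Newton iteration cap per continuation step.
#' @param n_load_steps Pressure increments.
#' @param n_damage_steps Damage increments after the pressure ramp.
#' @param warm_start Optional converged `cornea_continuum` (typically the
#'   healthy solution at full pressure) used as the starting state; the
#'   pressure ramp is then skipped. A solution on a different grid is
#'   transferred by bilinear interpolation; if the direct solve from a
#'   warm start does not converge, the full pressure continuation is rerun
#'   from the reference state.
#' @return Object of class `cornea_continuum`: deformed field matrices
#'   `r`, `phi` (`(n_R+1) x (n_Phi+1)`, dimensionless), grid vectors,
#'   converged energy and gradient norm, and a `trajectory` tibble with one
#'   row per continuation step (pressure and damage phases).
#' @export
solve_continuum <- function(config,
                            n_R = config$solver$n_R,
                            n_Phi = n_R * config$solver$n_Phi_per_R,
                            tol = config$solver$tol,
                            max_iter = config$solver$max_iter,
                            n_load_steps = config$solver$n_load_steps,
                            n_damage_steps = config$solver$n_damage_steps,
                            warm_start = NULL) {
  n_Phi <- as.integer(round(n_Phi))
  model <- build_continuum_model(config, n_R, n_Phi, Dmax = 0)
  ref <- cont_reference_state(model)
  p_target <- model$p
  traj <- list(); ti <- 0L
  note <- function(phase, p, Dmax, st, resid) {
    ti <<- ti + 1L
    ad <- (st$r[model$anterior[n_Phi / 2 + 1]] - model$nd$RA) * model$nd$length_mm
    ax <- model$anterior[n_Phi / 2 + 1]; px <- model$posterior[n_Phi / 2 + 1]
    xa <- st$r[ax] * cos(st$phi[ax]); ya <- st$r[ax] * sin(st$phi[ax])
    xp <- st$r[px] * cos(st$phi[px]); yp <- st$r[px] * sin(st$phi[px])
    cct <- sqrt((xa - xp)^2 + (ya - yp)^2) * model$nd$length_mm
    traj[[ti]] <<- tibble::tibble(
      phase = phase, p_kPa = p / (1e-3 * model$nd$length_mm / config$K1),
      Dmax = Dmax, AD_mm = ad, CCT_mm = cct, residual = resid)
  }

  senv <- new.env(parent = emptyenv())
  u_prev <- NULL
  # linear predictor across equal continuation steps (kept only if feasible)
  predict_u <- function(u, u_prev, p) {
    if (is.null(u_prev)) return(u)
    ug <- u + (u - u_prev)
    st <- cont_unpack(model, ug, ref)
    et <- cont_eval(model, st$r, st$phi, p, what = 0)
    if (is.finite(et$energy) && et$mindet > 0) ug else u
  }

  if (!is.null(warm_start)) {
    stopifnot(inherits(warm_start, "cornea_continuum"))
    if (warm_start$n_R != n_R || warm_start$n_Phi != n_Phi) {
      # transfer the converged field to this grid by bilinear interpolation
      # (both grids are uniform over the same sector, so the Dirichlet
      # columns interpolate exactly)
      rw <- grid_interp(warm_start$r, warm_start$Rnodes, warm_start$Phinodes,
                        model$Rnodes, model$Phinodes)
      pw <- grid_interp(warm_start$phi, warm_start$Rnodes, warm_start$Phinodes,
                        model$Rnodes, model$Phinodes)
      u <- cont_pack(model, as.vector(rw), as.vector(pw))
    } else {
      u <- cont_pack(model, as.vector(warm_start$r), as.vector(warm_start$phi))
    }
    p_now <- p_target
  } else {
    u <- cont_pack(model, ref$r, ref$phi)
    p_now <- 0
    if (p_target > 0) {
      for (s in seq_len(n_load_steps)) {
        pk <- p_target * s / n_load_steps
        fit <- cont_newton(model, predict_u(u, u_prev, pk), ref, pk, tol, max_iter,
                           sprintf("continuum pressure step %d/%d", s, n_load_steps),
                           senv = senv)
        u_prev <- u; u <- fit$u
        note("pressure", pk, 0, cont_unpack(model, u, ref), fit$resid)
      }
      p_now <- p_target
    }
  }

  resid <- NA_real_; energy <- NA_real_
  if (config$Dmax > 0) {
    u_prev <- NULL
    for (s in seq_len(n_damage_steps)) {
      dk <- config$Dmax * s / n_damage_steps
      model <- cont_set_damage(model, dk)
      fit <- cont_newton(model, predict_u(u, u_prev, p_now), ref, p_now, tol,
                         max_iter,
                         sprintf("continuum damage step %d/%d", s, n_damage_steps),
                         senv = senv)
      u_prev <- u; u <- fit$u; resid <- fit$resid; energy <- fit$energy
      note("damage", p_now, dk, cont_unpack(model, u, ref), fit$resid)
    }
  } else if (p_target > 0 && is.null(warm_start)) {
    # already solved in the pressure loop
    last <- cont_eval(model, cont_unpack(model, u, ref)$r,
                      cont_unpack(model, u, ref)$phi, p_now, what = 1)
    resid <- max(abs(last$grad)); energy <- last$energy
  } else {
    fit <- tryCatch(
      cont_newton(model, u, ref, p_now, tol, max_iter, "continuum solve",
                  senv = senv),
      error = function(e) NULL)
    if (is.null(fit)) {
      # warm start failed to converge directly: fall back to the full
      # pressure continuation from the reference state
      u <- cont_pack(model, ref$r, ref$phi)
      u_prev <- NULL
      for (s in seq_len(n_load_steps)) {
        pk <- p_target * s / n_load_steps
        fit <- cont_newton(model, predict_u(u, u_prev, pk), ref, pk, tol,
                           max_iter,
                           sprintf("continuum pressure step %d/%d", s, n_load_steps),
                           senv = senv)
        u_prev <- u; u <- fit$u
      }
    }
    u <- fit$u; resid <- fit$resid; energy <- fit$energy
    note("pressure", p_now, config$Dmax, cont_unpack(model, u, ref), resid)
  }

  st <- cont_unpack(model, u, ref)
  structure(list(
    r = matrix(st$r, n_R + 1, n_Phi + 1),
    phi = matrix(st$phi, n_R + 1, n_Phi + 1),
    Rnodes = model$Rnodes, Phinodes = model$Phinodes,
    n_R = n_R, n_Phi = n_Phi,
    energy = energy, grad_norm = resid,
    p_kPa = config$p, Dmax = config$Dmax,
    trajectory = dplyr::bind_rows(traj),
    nd = model$nd, config = config
  ), class = "cornea_continuum")
}

#' @export
print.cornea_continuum <- function(x, ...) {
  cat(sprintf("<cornea_continuum> grid %d x %d, p = %g kPa, Dmax = %g\n",
              x$n_R, x$n_Phi, x$p_kPa, x$Dmax))
  cat(sprintf("  energy %.6e, gradient norm %.2e\n", x$energy, x$grad_norm))
  cat(sprintf("  apex displacement %.4f mm, central thickness %.4f mm\n",
              apex_displacement(x), central_thickness(x)))
  invisible(x)
}

#' Total potential of a deformation field
#'
#' Evaluates the total potential `Pi = integral of W * D R dR dPhi` minus
#' `p D` times the enclosed posterior area, for an analytically specified
#' deformation field sampled on the structured grid. Mainly useful for
#' verification (the identity field at zero pressure has `Pi = 0`).
#'
#' @param field A [deformation_field()].
#' @param config A [cornea_config()].
#' @param n_R,n_Phi Grid resolution.
#' @param p Dimensionless pressure; defaults to the configuration value.
#' @param Dmax Damage amplitude used for the stiffness fields.
#' @return Scalar energy (dimensionless). Fields with non-positive `det F`
#'   at a quadrature point raise an error.
#' @export
total_potential <- function(field, config, n_R = 16, n_Phi = 20 * n_R,
                            p = NULL, Dmax = config$Dmax) {
  stopifnot(inherits(field, "deformation_field"))
  model <- build_continuum_model(config, n_R, as.integer(n_Phi), Dmax = Dmax)
  if (is.null(p)) p <- model$p
  RR <- rep(model$Rnodes, times = model$n_Phi + 1)
  PP <- rep(model$Phinodes, each = model$n_R + 1)
  r <- field$r(RR, PP); phi <- field$phi(RR, PP)
  ev <- cont_eval(model, r, phi, p, what = 0)
  if (ev$mindet <= 0) {
    stop("total_potential: det F <= 0 at a quadrature point", call. = FALSE)
  }
  ev$energy
}
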