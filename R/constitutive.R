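#' Analytic deformation field
#'
#' Wraps a pair of functions `(R, Phi) -> (r, phi)` mapping the reference
#' annular sector (dimensionless polar coordinates) to deformed polar
#' positions. Used for manufactured-solution verification and for
#' [total_potential()].
#'
#' @param r_fun,phi_fun Vectorized functions of `(R, Phi)`.
#' @return Object of class `deformation_field`.
#' @export
deformation_field <- function(r_fun, phi_fun) {
  structure(list(r = r_fun, phi = phi_fun), class = "deformation_field")
}

#' Identity deformation field
#' @return The identity [deformation_field()] `r = R`, `phi = Phi`.
#' @export
identity_field <- function() {
  deformation_field(function(R, Phi) R, function(R, Phi) Phi)
}

# derivatives of a field at a point: central differences
field_derivs <- function(field, R, Phi, h = 1e-6) {
  list(
    r = field$r(R, Phi), phi = field$phi(R, Phi),
    r_R = (field$r(R + h, Phi) - field$r(R - h, Phi)) / (2 * h),
    r_P = (field$r(R, Phi + h) - field$r(R, Phi - h)) / (2 * h),
    p_R = (field$phi(R + h, Phi) - field$phi(R - h, Phi)) / (2 * h),
    p_P = (field$phi(R, Phi + h) - field$phi(R, Phi - h)) / (2 * h)
  )
}

C_from_derivs <- function(d, R) {
  C_RR <- d$r_R^2 + d$r^2 * d$p_R^2
  C_RP <- (d$r_R * d$r_P + d$r^2 * d$p_R * d$p_P) / R
  C_PP <- (d$r_P^2 + d$r^2 * d$p_P^2) / R^2
  matrix(c(C_RR, C_RP, C_RP, C_PP), 2, 2,
         dimnames = list(c("R", "Phi"), c("R", "Phi")))
}

#' Right Cauchy-Green tensor in the polar frame
#'
#' Computes `C = F^T F` at a reference point, expressed in the orthonormal
#' polar frame `(e_R, e_Phi)`: the squared stretch along `e_Phi` is
#' `(r_Phi^2 + r^2 phi_Phi^2)/R^2`, along `e_R` it is
#' `r_R^2 + r^2 phi_R^2`, and the off-diagonal component is
#' `(r_R r_Phi + r^2 phi_R phi_Phi)/R`.
#'
#' @param field A [deformation_field()] (derivatives via central
#'   differences) or a `cornea_continuum` solution (derivatives via grid
#'   finite differences).
#' @param R,Phi Reference point (dimensionless polar coordinates). For a
#'   solution object these must be grid node coordinates.
#' @param ... Unused.
#' @return Symmetric `2 x 2` matrix `C` with rows/columns `(R, Phi)`.
#' @export
right_cauchy_green <- function(field, R, Phi, ...) UseMethod("right_cauchy_green")

#' @export
right_cauchy_green.deformation_field <- function(field, R, Phi, ...) {
  d <- field_derivs(field, R, Phi)
  if (!all(is.finite(unlist(d)))) stop("non-finite field derivatives", call. = FALSE)
  C_from_derivs(d, R)
}

#' @export
right_cauchy_green.cornea_continuum <- function(field, R, Phi, ...) {
  i <- which.min(abs(field$Rnodes - R))
  j <- which.min(abs(field$Phinodes - Phi))
  d <- solution_derivs(field)
  dd <- list(r = field$r[i, j], phi = field$phi[i, j],
             r_R = d$r_R[i, j], r_P = d$r_P[i, j],
             p_R = d$p_R[i, j], p_P = d$p_P[i, j])
  C_from_derivs(dd, field$Rnodes[i])
}

# grid finite differences (central interior, one-sided at edges) of the
# solution fields; returns matrices matching sol$r
solution_derivs <- function(sol) {
  list(r_R = fd_rows(sol$r, sol$Rnodes[2] - sol$Rnodes[1]),
       r_P = fd_cols(sol$r, sol$Phinodes[2] - sol$Phinodes[1]),
       p_R = fd_rows(sol$phi, sol$Rnodes[2] - sol$Rnodes[1]),
       p_P = fd_cols(sol$phi, sol$Phinodes[2] - sol$Phinodes[1]))
}

fd_rows <- function(m, h) {
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
  d[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * h)
  d[n, ] <- (3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / (2 * h)
  d
}
fd_cols <- function(m, h) t(fd_rows(t(m), h))

# stretches along the four families from C (orthonormal polar frame)
family_stretches <- function(C, R, kappa) {
  kR <- kappa * R
  w2 <- 1 / (1 + kR^2)
  sb2 <- w2; cb2 <- kR^2 * w2; sc <- kR * w2
  lamPhi <- sqrt(C[2, 2])
  lamR <- sqrt(C[1, 1])
  lamP <- sqrt(sb2 * C[1, 1] + 2 * sc * C[1, 2] + cb2 * C[2, 2])
  lamM <- sqrt(sb2 * C[1, 1] - 2 * sc * C[1, 2] + cb2 * C[2, 2])
  list(Phi = lamPhi, R = lamR, plus = lamP, minus = lamM)
}

check_spd <- function(C) {
  if (!isTRUE(all.equal(C[1, 2], C[2, 1], tolerance = 1e-8))) {
    stop("C must be symmetric", call. = FALSE)
  }
  if (C[1, 1] <= 0 || C[1, 1] * C[2, 2] - C[1, 2] * C[2, 1] <= 0) {
    stop("C must be symmetric positive definite", call. = FALSE)
  }
}

#' Upscaled strain-energy density
#'
#' The strain energy of the micro-structured corneal tissue per unit
#' reference area measure (`D R dR dPhi`):
#' `W = 1/(2 kappa R D) * [(kappa R)^2 K1 (lam_Phi - 1)^2 +
#' K2 (lam_R - 1)^2 + (1 + (kappa R)^2) K3 ((lam_+ - 1)^2 +
#' (lam_- - 1)^2)]`, with `lam_a = sqrt(e_a . C e_a)` the stretch of the
#' fibre family along unit direction `e_a`.
#'
#' @param C Symmetric positive-definite `2 x 2` right Cauchy-Green tensor
#'   in the orthonormal polar frame.
#' @param R Dimensionless reference radius.
#' @param kappa Microstructural ratio `2 Phi_star / gamma`.
#' @param K1,K2,K3 Dimensionless stiffnesses (possibly damage-reduced for
#'   `K1`, `K3`).
#' @param D Dimensionless slice depth.
#' @return Energy density (dimensionless).
#' @export
strain_energy_density <- function(C, R, kappa, K1 = 1, K2, K3, D = 1) {
  check_spd(C)
  lam <- family_stretches(C, R, kappa)
  kR <- kappa * R
  (kR^2 * K1 * (lam$Phi - 1)^2 + K2 * (lam$R - 1)^2 +
      (1 + kR^2) * K3 * ((lam$plus - 1)^2 + (lam$minus - 1)^2)) / (2 * kR * D)
}

#' Second Piola-Kirchhoff stress of the upscaled material
#'
#' `T = 2 dW/dC`: the sum of rank-one contributions of the four fibre
#' families, each proportional to `(1 - 1/lam_a)`. In components,
#' `T_RR = (K2 (1 - lam_R^-1) + K3 (2 - lam_+^-1 - lam_-^-1)) / (kappa R D)`,
#' `T_RPhi = K3 (lam_-^-1 - lam_+^-1) / D`, and
#' `T_PhiPhi = kappa R (K1 (1 - lam_Phi^-1) + K3 (2 - lam_+^-1 - lam_-^-1)) / D`.
#'
#' @inheritParams strain_energy_density
#' @return Symmetric `2 x 2` stress matrix (dimensionless; multiply by
#'   `K1_N_mm / T_mm` for N/mm^2).
#' @export
second_pk_stress <- function(C, R, kappa, K1 = 1, K2, K3, D = 1) {
  check_spd(C)
  lam <- family_stretches(C, R, kappa)
  kR <- kappa * R
  T_RR <- (K2 * (1 - 1 / lam$R) + K3 * (2 - 1 / lam$plus - 1 / lam$minus)) / (kR * D)
  T_RP <- K3 * (1 / lam$minus - 1 / lam$plus) / D
  T_PP <- kR * (K1 * (1 - 1 / lam$Phi) + K3 * (2 - 1 / lam$plus - 1 / lam$minus)) / D
  matrix(c(T_RR, T_RP, T_RP, T_PP), 2, 2,
         dimnames = list(c("R", "Phi"), c("R", "Phi")))
}

#' Derived field quantities of a continuum solution
#'
#' Evaluates the deformation, stress components and strain-energy density
#' at every grid node of a converged continuum solution (derivatives by
#' grid finite differences; one-sided at the boundaries).
#'
#' @param sol A `cornea_continuum` solution.
#' @return Tibble with columns `R_mm`, `Phi_rad`, `x_mm`, `y_mm`,
#'   `T_RR_kPa`, `T_RPhi_kPa`, `T_PhiPhi_kPa` and `W` (dimensionless
#'   energy density).
#' @export
continuum_fields <- function(sol) {
  stopifnot(inherits(sol, "cornea_continuum"))
  nd <- sol$nd
  d <- solution_derivs(sol)
  R <- matrix(sol$Rnodes, sol$n_R + 1, sol$n_Phi + 1)
  Phi <- matrix(sol$Phinodes, sol$n_R + 1, sol$n_Phi + 1, byrow = TRUE)
  r <- sol$r
  C_RR <- d$r_R^2 + r^2 * d$p_R^2
  C_RP <- (d$r_R * d$r_P + r^2 * d$p_R * d$p_P) / R
  C_PP <- (d$r_P^2 + r^2 * d$p_P^2) / R^2
  kR <- nd$kappa * R
  w2 <- 1 / (1 + kR^2)
  lamPhi <- sqrt(C_PP)
  lamR <- sqrt(C_RR)
  lamP <- sqrt(w2 * C_RR + 2 * kR * w2 * C_RP + kR^2 * w2 * C_PP)
  lamM <- sqrt(w2 * C_RR - 2 * kR * w2 * C_RP + kR^2 * w2 * C_PP)
  dmg <- damage_at(R * sin(Phi) * nd$length_mm, sol$config,
                   Dmax = sol$Dmax)
  K1 <- 1 - dmg
  K3 <- nd$K3 * (1 - dmg)
  K2 <- nd$K2; D <- nd$D
  T_RR <- (K2 * (1 - 1 / lamR) + K3 * (2 - 1 / lamP - 1 / lamM)) / (kR * D)
  T_RP <- K3 * (1 / lamM - 1 / lamP) / D
  T_PP <- kR * (K1 * (1 - 1 / lamPhi) + K3 * (2 - 1 / lamP - 1 / lamM)) / D
  W <- (kR^2 * K1 * (lamPhi - 1)^2 + K2 * (lamR - 1)^2 +
          (1 + kR^2) * K3 * ((lamP - 1)^2 + (lamM - 1)^2)) / (2 * kR * D)
  tibble::tibble(
    R_mm = as.vector(R) * nd$length_mm,
    Phi_rad = as.vector(Phi),
    x_mm = as.vector(r * cos(sol$phi)) * nd$length_mm,
    y_mm = as.vector(r * sin(sol$phi)) * nd$length_mm,
    T_RR_kPa = as.vector(T_RR) * nd$stress_kPa,
    T_RPhi_kPa = as.vector(T_RP) * nd$stress_kPa,
    T_PhiPhi_kPa = as.vector(T_PP) * nd$stress_kPa,
    W = as.vector(W)
  )
}

#' Strong-form residual of the upscaled balance
#'
#' Independent verification of a converged continuum solution: evaluates
#' the strong-form (Euler-Lagrange) balance operators of the upscaled
#' model at interior grid nodes by finite differences. The operators
#' involve the force-per-length functions `G1`, `G2`, `G3+-` of the
#' azimuthal, radial and diagonal stretches; for a converged minimizer the
#' interior residual should be small compared to the individual terms and
#' decrease under grid refinement.
#'
#' @param sol A `cornea_continuum` solution.
#' @return Tibble with interior node coordinates and residual components
#'   `res_r`, `res_phi` (dimensionless), plus `scale`, the magnitude of the
#'   dominant contributing term, for normalisation.
#' @export
strong_form_residual <- function(sol) {
  stopifnot(inherits(sol, "cornea_continuum"))
  nd <- sol$nd
  kap <- nd$kappa
  dR <- sol$Rnodes[2] - sol$Rnodes[1]
  dP <- sol$Phinodes[2] - sol$Phinodes[1]
  R <- matrix(sol$Rnodes, sol$n_R + 1, sol$n_Phi + 1)
  Phi <- matrix(sol$Phinodes, sol$n_R + 1, sol$n_Phi + 1, byrow = TRUE)
  r <- sol$r
  d <- solution_derivs(sol)
  rR <- d$r_R; rP <- d$r_P; pR <- d$p_R; pP <- d$p_P

  dmg <- damage_at(R * sin(Phi) * nd$length_mm, sol$config, Dmax = sol$Dmax)
  K1 <- 1 - dmg
  K3 <- nd$K3 * (1 - dmg)

  q <- 1 / (kap * R)
  w <- 1 / sqrt(1 + (kap * R)^2)
  g <- function(K, lam) K * (1 - 1 / lam)
  G1 <- g(K1, q * kap * sqrt(rP^2 + (r * pP)^2))
  G2 <- g(nd$K2, sqrt(rR^2 + (r * pR)^2))
  G3p <- g(K3, w * sqrt((rR + kap * rP)^2 + (r * pR + kap * r * pP)^2))
  G3m <- g(K3, w * sqrt((rR - kap * rP)^2 + (r * pR - kap * r * pP)^2))

  res_r <- kap^2 * (fd_cols(rP * G1, dP) - r * pP^2 * G1) +
    (fd_rows(rR * G2, dR) - r * pR^2 * G2) +
    fd_rows((rR + kap * rP) * G3p + (rR - kap * rP) * G3m, dR) +
    kap * fd_cols((rR + kap * rP) * G3p - (rR - kap * rP) * G3m, dP) -
    (pR + kap * pP) * (r * pR + kap * r * pP) * G3p -
    (pR - kap * pP) * (r * pR - kap * r * pP) * G3m
  res_phi <- kap^2 * (fd_cols(r * pP * G1, dP) + rP * pP * G1) +
    (fd_rows(r * pR * G2, dR) + rR * pR * G2) +
    fd_rows((r * pR + kap * r * pP) * G3p + (r * pR - kap * r * pP) * G3m, dR) +
    kap * fd_cols((r * pR + kap * r * pP) * G3p - (r * pR - kap * r * pP) * G3m, dP) +
    (pR + kap * pP) * (rR + kap * rP) * G3p +
    (pR - kap * pP) * (rR - kap * rP) * G3m

  # dominant term magnitude for normalisation
  scale <- pmax(abs(fd_rows(rR * G2, dR)),
                abs(fd_rows((rR + kap * rP) * G3p + (rR - kap * rP) * G3m, dR)),
                abs(kap^2 * fd_cols(rP * G1, dP)))
  ii <- 2:sol$n_R; jj <- 2:sol$n_Phi
  tibble::tibble(
    R = as.vector(R[ii, jj]), Phi = as.vector(Phi[ii, jj]),
    res_r = as.vector(res_r[ii, jj]), res_phi = as.vector(res_phi[ii, jj]),
    scale = as.vector(scale[ii, jj])
  )
}
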