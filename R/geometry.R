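#' Half-aperture angle of the corneal arc
#'
#' The unloaded anterior and posterior surfaces are modelled as concentric
#' circular arcs spanning an angle `2 * Phi_star`. The half-aperture follows
#' from the chord relation `D_A = 2 * R_A * sin(Phi_star)` between the
#' anterior radius and the anterior in-plane diameter.
#'
#' @param R_A Anterior radius of curvature (mm).
#' @param D_A Anterior in-plane diameter (mm).
#' @return Half-aperture angle in radians, in `(0, pi/2)`.
#' @examples
#' phi_star(7.8, 11.46) # approximately 0.83 rad
#' @export
phi_star <- function(R_A, D_A) {
  if (!is.numeric(R_A) || !is.numeric(D_A) || R_A <= 0 || D_A <= 0) {
    stop("invalid geometry: R_A and D_A must be positive", call. = FALSE)
  }
  if (D_A >= 2 * R_A) {
    stop("invalid geometry: D_A must be smaller than 2*R_A", call. = FALSE)
  }
  asin(D_A / (2 * R_A))
}

#' Reference (unloaded) corneal geometry
#'
#' Collects the macroscale geometric parameters of the planar corneal slice:
#' concentric anterior/posterior arcs of radii `R_A` and `R_P = R_A - T`,
#' uniform thickness `T`, slice depth `D` (plane strain) and the
#' half-aperture angle derived from the in-plane diameter.
#'
#' @param R_A Anterior radius of curvature (mm).
#' @param T Corneal thickness (mm), `0 < T < R_A`.
#' @param D_A Anterior in-plane diameter (mm), `0 < D_A < 2*R_A`.
#' @param depth Slice depth (mm); the plane-strain model uses one unit.
#' @return An object of class `cornea_geometry`: a list with fields `R_A`,
#'   `T`, `D_A`, `D`, `R_P` and `Phi_star` (rad). All lengths in mm.
#' @export
cornea_geometry <- function(R_A = 7.8, T = 0.62, D_A = 11.46, depth = 1) {
  if (!(T > 0 && T < R_A)) stop("invalid geometry: need 0 < T < R_A", call. = FALSE)
  if (!(depth > 0)) stop("invalid geometry: depth must be positive", call. = FALSE)
  ps <- phi_star(R_A, D_A)
  structure(
    list(R_A = R_A, T = T, D_A = D_A, D = depth, R_P = R_A - T, Phi_star = ps),
    class = "cornea_geometry"
  )
}

#' Lattice discretization
#'
#' The slice is discretized into `N` radial layers (so `N + 1` lamellar
#' arcs) and `M = gamma * N` azimuthal segments per arc; the mesh aspect
#' ratio `gamma` is held fixed as `N` grows, which is what makes the
#' continuum limit well defined.
#'
#' @param N Number of radial layers (positive integer).
#' @param gamma Mesh aspect ratio `M / N`; `gamma * N` must be an even
#'   integer.
#' @return An object of class `cornea_discretization` with fields `N`, `M`,
#'   `gamma`.
#' @export
discretization <- function(N, gamma = 20) {
  if (!is.numeric(N) || N < 1 || N != round(N)) {
    stop("N must be a positive integer", call. = FALSE)
  }
  M <- gamma * N
  if (abs(M - round(M)) > 1e-9) stop("gamma * N must be an integer", call. = FALSE)
  M <- as.integer(round(M))
  if (M %% 2L != 0L) stop("M = gamma * N must be even", call. = FALSE)
  structure(list(N = as.integer(N), M = M, gamma = gamma),
            class = "cornea_discretization")
}

#' Reference node lattice
#'
#' Places the `(N+1) * (M+1)` reference nodes on concentric arcs of radii
#' `R_i = R_P + i * T / N` at angles `Phi_j = (j - M/2) * 2 * Phi_star / M`,
#' measured from the symmetry axis (the X-axis through the apex).
#'
#' @param geom A [cornea_geometry()].
#' @param disc A [discretization()].
#' @return An object of class `cornea_nodes`: list with `(N+1) x (M+1)`
#'   matrices `X`, `Y` (mm; rows index `i = 0..N`, columns `j = 0..M`),
#'   the radii `R_i` and angles `Phi_j`.
#' @export
build_nodes <- function(geom, disc) {
  stopifnot(inherits(geom, "cornea_geometry"), inherits(disc, "cornea_discretization"))
  N <- disc$N; M <- disc$M
  R_i <- geom$R_P + (0:N) * geom$T / N
  Phi_j <- ((0:M) - M / 2) * 2 * geom$Phi_star / M
  X <- outer(R_i, cos(Phi_j))
  Y <- outer(R_i, sin(Phi_j))
  structure(list(X = X, Y = Y, R_i = R_i, Phi_j = Phi_j, N = N, M = M),
            class = "cornea_nodes")
}

#' Rest lengths of the three element families
#'
#' Lamellar segments are chords of the arcs, `L1_i = 2 R_i sin(Phi_star/M)`;
#' radial crosslinks have uniform length `L2 = T/N`; diagonal crosslinks
#' connect adjacent layers one azimuthal step apart with
#' `L3_{i+1/2}^2 = L1_i * L1_{i+1} + L2^2`.
#'
#' @inheritParams build_nodes
#' @return An object of class `cornea_rest_lengths`: list with `L1` (length
#'   `N+1`, mm), `L2` (scalar, mm), `L3` (length `N`, mm) and the
#'   dimensionless ratios `q_i = L2/L1_i` (length `N+1`) and
#'   `w_iphalf = L2/L3_{i+1/2}` (length `N`).
#' @export
rest_lengths <- function(geom, disc) {
  stopifnot(inherits(geom, "cornea_geometry"), inherits(disc, "cornea_discretization"))
  N <- disc$N; M <- disc$M
  R_i <- geom$R_P + (0:N) * geom$T / N
  L2 <- geom$T / N
  L1 <- 2 * R_i * sin(geom$Phi_star / M)
  L3 <- sqrt(L1[1:N] * L1[2:(N + 1)] + L2^2)
  structure(list(L1 = L1, L2 = L2, L3 = L3,
                 q_i = L2 / L1, w_iphalf = L2 / L3, R_i = R_i),
            class = "cornea_rest_lengths")
}

#' Continuum microstructure ratio functions
#'
#' In the continuum limit (`N -> Inf` at fixed aspect ratio `gamma`) the
#' discrete length ratios become smooth functions of the dimensionless
#' radial coordinate `R` (lengths scaled by the thickness `T`):
#' `q(R) = 1/(kappa R)` with `kappa = 2 Phi_star / gamma`,
#' `w(R) = 1/sqrt(1 + (kappa R)^2)`, and the diagonal inclination angle
#' `beta(R) = atan(q(R))`, so that `sin(beta) = w` and
#' `cos(beta) = kappa R w`.
#'
#' @inheritParams build_nodes
#' @return An object of class `cornea_microstructure`: list with scalar
#'   `kappa` and vectorized functions `q`, `w`, `beta` of the dimensionless
#'   radius, plus the dimensionless domain `R_range = c(R_P, R_A)/T`.
#' @export
microstructure <- function(geom, disc) {
  stopifnot(inherits(geom, "cornea_geometry"), inherits(disc, "cornea_discretization"))
  kappa <- 2 * geom$Phi_star / disc$gamma
  chk <- function(R) {
    if (any(!is.finite(R)) || any(R <= 0)) {
      stop("microstructure functions require R > 0", call. = FALSE)
    }
    R
  }
  structure(list(
    kappa = kappa,
    q = function(R) 1 / (kappa * chk(R)),
    w = function(R) 1 / sqrt(1 + (kappa * chk(R))^2),
    beta = function(R) atan(1 / (kappa * chk(R))),
    R_range = c(geom$R_P, geom$R_A) / geom$T
  ), class = "cornea_microstructure")
}

#' Fibre directions of the upscaled material
#'
#' Unit vectors of the four fibre families at dimensionless radius `R`,
#' expressed in the orthonormal polar frame `(e_R, e_Phi)`: the radial and
#' azimuthal directions plus the two diagonal directions
#' `e_pm = sin(beta) e_R +- cos(beta) e_Phi`.
#'
#' @param R Dimensionless radial coordinate (lengths scaled by thickness).
#' @param kappa Microstructural ratio `2 Phi_star / gamma`.
#' @return List with unit 2-vectors `e_R`, `e_Phi`, `e_plus`, `e_minus`
#'   (components in the `(e_R, e_Phi)` frame) and the angle `beta`.
#' @export
fiber_frame <- function(R, kappa) {
  if (R <= 0) stop("fiber_frame requires R > 0", call. = FALSE)
  w <- 1 / sqrt(1 + (kappa * R)^2)
  sb <- w
  cb <- kappa * R * w
  list(e_R = c(1, 0), e_Phi = c(0, 1),
       e_plus = c(sb, cb), e_minus = c(sb, -cb),
       beta = atan2(sb, cb))
}
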