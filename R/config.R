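#' Full model configuration
#'
#' Bundles geometry, discretization, material stiffness, pressure, damage
#' and solver options. Defaults are the baseline parameter set of the
#' corneal slice model: thickness 0.62 mm, anterior radius 7.8 mm,
#' anterior diameter 11.46 mm, `N = 32` layers at aspect ratio
#' `gamma = 20`, axial stiffnesses `K1 = 7.2`, `K2 = 0.0072`,
#' `K3 = 0.504` N/mm, physiological intraocular pressure 2 kPa and a
#' quartic damage profile with maximum damage 0.99. Pass `Dmax = 0` for a
#' healthy cornea.
#'
#' @param R_A_mm Anterior radius of curvature (mm).
#' @param T_mm Corneal thickness (mm).
#' @param D_A_mm Anterior in-plane diameter (mm).
#' @param depth_mm Slice depth (mm); plane strain uses one unit of length.
#' @param N Number of radial layers of the discrete lattice.
#' @param gamma Mesh aspect ratio `M/N` (azimuthal segments per layer,
#'   divided by the layer count). `M` is always derived, never set.
#' @param K1_N_mm,K2_N_mm,K3_N_mm Axial stiffness of the lamellar, radial
#'   and diagonal elements (N/mm).
#' @param p_kPa Intraocular pressure (kPa).
#' @param Dmax Maximum damage in `[0, 1)` at the corneal centre.
#' @param xi Even damage-localization exponent (2, 4, 6, ...).
#' @param solver Named list of solver options; missing entries take
#'   defaults: `tol` (residual infinity-norm, dimensionless, 1e-10),
#'   `max_iter` (Newton iterations per continuation step, 50),
#'   `n_load_steps` (pressure increments, 10), `n_damage_steps` (damage
#'   increments once the pressure ramp is complete; 20 when `Dmax >= 0.9`,
#'   otherwise 8), `n_R` (continuum radial elements, 64), `n_Phi_per_R`
#'   (continuum azimuthal elements per radial element, `gamma`).
#' @return Object of class `cornea_config`.
#' @export
cornea_config <- function(R_A_mm = 7.8, T_mm = 0.62, D_A_mm = 11.46,
                          depth_mm = 1, N = 32, gamma = 20,
                          K1_N_mm = 7.2, K2_N_mm = 0.0072, K3_N_mm = 0.504,
                          p_kPa = 2, Dmax = 0.99, xi = 4, solver = list()) {
  geom <- cornea_geometry(R_A = R_A_mm, T = T_mm, D_A = D_A_mm, depth = depth_mm)
  if (!(K1_N_mm > 0 && K2_N_mm > 0 && K3_N_mm > 0)) {
    stop("stiffnesses must be positive", call. = FALSE)
  }
  if (!(Dmax >= 0 && Dmax < 1)) stop("Dmax must lie in [0, 1)", call. = FALSE)
  if (!(xi >= 2 && xi %% 2 == 0)) stop("xi must be an even integer >= 2", call. = FALSE)
  if (p_kPa < 0) stop("pressure must be non-negative", call. = FALSE)
  sdef <- list(tol = 1e-10, max_iter = 50L, n_load_steps = 10L,
               n_damage_steps = if (Dmax >= 0.9) 20L else 8L,
               n_R = 64L, n_Phi_per_R = gamma)
  unknown <- setdiff(names(solver), names(sdef))
  if (length(unknown)) {
    stop("unknown solver option(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sdef[names(solver)] <- solver
  cfg <- structure(list(
    geometry = geom,
    N = as.integer(N), gamma = gamma,
    K1 = K1_N_mm, K2 = K2_N_mm, K3 = K3_N_mm,
    p = p_kPa, Dmax = Dmax, xi = xi,
    solver = sdef
  ), class = "cornea_config")
  # sanity-check the derived discretization (M even etc.)
  discretization(N, gamma)
  cfg
}

#' @export
print.cornea_config <- function(x, ...) {
  g <- x$geometry
  nd <- nondimensional(x)
  cat("<cornea_config>\n")
  cat(sprintf("  geometry: R_A = %.3g mm, T = %.3g mm, D_A = %.3g mm, depth = %.3g mm\n",
              g$R_A, g$T, g$D_A, g$D))
  cat(sprintf("  Phi_star = %.4f rad, N = %d, gamma = %g (M = %d)\n",
              g$Phi_star, x$N, x$gamma, as.integer(x$gamma * x$N)))
  cat(sprintf("  stiffness: K1 = %.4g, K2 = %.4g, K3 = %.4g N/mm; p = %.3g kPa\n",
              x$K1, x$K2, x$K3, x$p))
  cat(sprintf("  dimensionless: K2/K1 = %.4g, K3/K1 = %.4g, p*T/K1 = %.4g\n",
              nd$K2, nd$K3, nd$p))
  cat(sprintf("  damage: Dmax = %.3g, xi = %d\n", x$Dmax, as.integer(x$xi)))
  invisible(x)
}

#' Dimensionless parameter block
#'
#' Internally all lengths are scaled by the thickness `T` and all forces by
#' the lamellar reference force `K1 * T`, so the model is governed by the
#' seven dimensionless groups `gamma`, `Phi_star`, `R_A/T`, `D/T`,
#' `K2/K1`, `K3/K1` and `p*T/K1`.
#'
#' @param config A [cornea_config()].
#' @return List with fields `RA`, `RP`, `D` (lengths over `T`), `Phi_star`,
#'   `gamma`, `kappa`, `K2`, `K3` (over `K1`), `p` (`p*T/K1`), `Ymax`
#'   (dimensionless anterior-limbus height), plus scales `length_mm = T`,
#'   `force_N = K1*T` and `stress_kPa = 1000 * K1/T`.
#' @export
nondimensional <- function(config) {
  g <- config$geometry
  T <- g$T
  list(RA = g$R_A / T, RP = g$R_P / T, D = g$D / T,
       Phi_star = g$Phi_star, gamma = config$gamma,
       kappa = 2 * g$Phi_star / config$gamma,
       K2 = config$K2 / config$K1, K3 = config$K3 / config$K1,
       # p in kPa = 1e-3 N/mm^2; K1 in N/mm; p*T/K1 dimensionless
       p = config$p * 1e-3 * T / config$K1,
       Ymax = g$R_A * sin(g$Phi_star) / T,
       length_mm = T, force_N = config$K1 * T,
       stress_kPa = 1000 * config$K1 / T)
}

#' Read a configuration file
#'
#' Reads a YAML or JSON configuration. Recognized keys (all optional;
#' missing keys take the baseline defaults): `R_A_mm`, `T_mm`, `D_A_mm`,
#' `depth_mm`, `N`, `gamma`, `K1_N_mm`, `K2_N_mm`, `K3_N_mm`, `p_kPa`,
#' and nested blocks `damage: {Dmax, xi}` and `solver: {...}`. Unknown
#' keys are rejected with their key path.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [cornea_config()].
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  top <- c("R_A_mm", "T_mm", "D_A_mm", "depth_mm", "N", "gamma",
           "K1_N_mm", "K2_N_mm", "K3_N_mm", "p_kPa", "damage", "solver")
  unknown <- setdiff(names(raw), top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$damage)) {
    bad <- setdiff(names(raw$damage), c("Dmax", "xi"))
    if (length(bad)) {
      stop("unknown config key(s): ", paste0("damage.", bad, collapse = ", "),
           call. = FALSE)
    }
  }
  args <- raw[setdiff(names(raw), c("damage", "solver"))]
  if (!is.null(raw$damage$Dmax)) args$Dmax <- raw$damage$Dmax
  if (!is.null(raw$damage$xi)) args$xi <- raw$damage$xi
  if (!is.null(raw$solver)) args$solver <- raw$solver
  do.call(cornea_config, args)
}

#' Stable hash of a configuration
#'
#' Used to stamp output files so that results can be traced back to the
#' exact parameter set that produced them.
#'
#' @param config A [cornea_config()].
#' @return A short character hash.
#' @export
config_hash <- function(config) {
  key <- list(
    geometry = unclass(config$geometry),
    N = config$N, gamma = config$gamma,
    K = c(config$K1, config$K2, config$K3),
    p = config$p, Dmax = config$Dmax, xi = config$xi
  )
  rlang::hash(key)
}
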