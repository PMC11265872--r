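#' Discrete-to-continuum convergence study
#'
#' Solves the discrete lattice for an ascending sequence of layer counts
#' `N` (at fixed aspect ratio) and one continuum problem, and fits the
#' convergence order of the apex-displacement error by least squares of
#' `log(error)` against `log(N)`. The error decays as `O(1/N)`, i.e. a
#' fitted slope near -1.
#'
#' @param N_list Ascending integer vector of layer counts.
#' @param config A [cornea_config()].
#' @param n_R,n_Phi Continuum grid (defaults from `config$solver`).
#' @param continuum Optionally, an already converged `cornea_continuum`
#'   solution to compare against (must match `config`).
#' @return List with `table` (tibble: `N`, `AD_discrete_mm`,
#'   `AD_continuum_mm`, `abs_error_mm`, `runtime_s`), the fitted `slope`,
#'   and the continuum solution used.
#' @export
convergence_study <- function(N_list, config,
                              n_R = config$solver$n_R,
                              n_Phi = n_R * config$solver$n_Phi_per_R,
                              continuum = NULL) {
  stopifnot(all(diff(N_list) > 0))
  if (is.null(continuum)) {
    continuum <- solve_continuum(config, n_R = n_R, n_Phi = n_Phi)
  }
  ad_c <- apex_displacement(continuum)
  rows <- purrr::map(N_list, function(N) {
    t0 <- proc.time()[["elapsed"]]
    sol <- solve_discrete(config, N = N)
    tibble::tibble(
      N = N,
      AD_discrete_mm = apex_displacement(sol),
      AD_continuum_mm = ad_c,
      abs_error_mm = abs(apex_displacement(sol) - ad_c),
      runtime_s = proc.time()[["elapsed"]] - t0
    )
  })
  tab <- dplyr::bind_rows(rows)
  slope <- unname(stats::coef(stats::lm(log(abs_error_mm) ~ log(N), data = tab))[2])
  list(table = tab, slope = slope, continuum = continuum)
}

#' Damage parameter sweep
#'
#' Continuum solves over a grid of maximum damage and localization
#' exponents, with warm starts from the nearest previously converged cell
#' (the healthy solution seeds the smallest damage in each exponent
#' series).
#'
#' @param Dmax_list Maximum damage values (each `< 1`), ascending.
#' @param xi_list Even localization exponents.
#' @param config Base [cornea_config()] (its own `Dmax`, `xi` are ignored).
#' @param n_R,n_Phi Continuum grid.
#' @return Tibble with one row per cell: `Dmax`, `xi`, metrics columns from
#'   [metrics_report()] and `converged`.
#' @export
damage_sweep <- function(Dmax_list, xi_list, config,
                         n_R = config$solver$n_R,
                         n_Phi = n_R * config$solver$n_Phi_per_R) {
  stopifnot(all(Dmax_list < 1), all(diff(Dmax_list) > 0))
  healthy_cfg <- modify_config(config, Dmax = 0)
  healthy <- solve_continuum(healthy_cfg, n_R = n_R, n_Phi = n_Phi)
  rows <- list()
  for (xi in xi_list) {
    warm <- healthy
    for (Dm in Dmax_list) {
      cfg <- modify_config(config, Dmax = Dm, xi = xi)
      row <- tibble::tibble(Dmax = Dm, xi = xi, converged = FALSE,
                            AD_mm = NA_real_, CCT_mm = NA_real_,
                            MAC_per_mm = NA_real_, MPC_per_mm = NA_real_)
      sol <- tryCatch(
        solve_continuum(cfg, n_R = n_R, n_Phi = n_Phi, warm_start = warm),
        error = function(e) NULL)
      if (!is.null(sol)) {
        mr <- metrics_report(sol)
        row$converged <- TRUE
        row$AD_mm <- mr$AD_mm; row$CCT_mm <- mr$CCT_mm
        row$MAC_per_mm <- mr$MAC_per_mm; row$MPC_per_mm <- mr$MPC_per_mm
        warm <- structure(list(r = sol$r, phi = sol$phi, n_R = sol$n_R,
                               n_Phi = sol$n_Phi), class = "cornea_continuum")
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Sensitivity sweep of the damaged cornea
#'
#' One-at-a-time sweeps of the mesh aspect ratio `gamma` and the
#' dimensionless crosslink stiffnesses `K2/K1`, `K3/K1` around the
#' damaged baseline (`Dmax`, `xi` fixed from `config`).
#'
#' @param gamma_list,K2_list,K3_list Values to sweep (dimensionless; `K2`
#'   and `K3` as ratios to `K1`). Any may be `NULL` to skip.
#' @param config Damaged base configuration.
#' @param n_R,n_Phi Continuum grid.
#' @return Tibble: `parameter`, `value`, metrics columns, `converged`.
#' @export
sensitivity_sweep <- function(gamma_list = NULL, K2_list = NULL, K3_list = NULL,
                              config,
                              n_R = config$solver$n_R,
                              n_Phi = n_R * config$solver$n_Phi_per_R) {
  one <- function(parameter, value) {
    cfg <- switch(parameter,
      gamma = modify_config(config, gamma = value),
      K2 = modify_config(config, K2_N_mm = value * config$K1),
      K3 = modify_config(config, K3_N_mm = value * config$K1))
    row <- tibble::tibble(parameter = parameter, value = value, converged = FALSE,
                          AD_mm = NA_real_, CCT_mm = NA_real_,
                          MAC_per_mm = NA_real_, MPC_per_mm = NA_real_)
    sol <- tryCatch(solve_continuum(cfg, n_R = n_R, n_Phi = n_Phi),
                    error = function(e) NULL)
    if (!is.null(sol)) {
      mr <- metrics_report(sol)
      row$converged <- TRUE
      row$AD_mm <- mr$AD_mm; row$CCT_mm <- mr$CCT_mm
      row$MAC_per_mm <- mr$MAC_per_mm; row$MPC_per_mm <- mr$MPC_per_mm
    }
    row
  }
  grid <- dplyr::bind_rows(
    if (length(gamma_list)) tibble::tibble(parameter = "gamma", value = gamma_list),
    if (length(K2_list)) tibble::tibble(parameter = "K2", value = K2_list),
    if (length(K3_list)) tibble::tibble(parameter = "K3", value = K3_list)
  )
  dplyr::bind_rows(purrr::map2(grid$parameter, grid$value, one))
}

#' Modify a configuration
#'
#' Returns a copy of a [cornea_config()] with the given construction
#' arguments replaced (re-validated).
#'
#' @param config A [cornea_config()].
#' @param ... Named arguments of [cornea_config()] to override.
#' @return A new `cornea_config`.
#' @export
modify_config <- function(config, ...) {
  g <- config$geometry
  args <- list(R_A_mm = g$R_A, T_mm = g$T, D_A_mm = g$D_A, depth_mm = g$D,
               N = config$N, gamma = config$gamma,
               K1_N_mm = config$K1, K2_N_mm = config$K2, K3_N_mm = config$K3,
               p_kPa = config$p, Dmax = config$Dmax, xi = config$xi,
               solver = config$solver)
  over <- list(...)
  args[names(over)] <- over
  do.call(cornea_config, args)
}
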