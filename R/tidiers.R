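#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a discrete solution
#'
#' @param x A `cornea_discrete` solution.
#' @param ... Unused.
#' @return Tibble with one row per node: indices, reference and deformed
#'   positions (mm) and displacement magnitude.
#' @export
tidy.cornea_discrete <- function(x, ...) {
  net <- x$network
  nid <- seq_len(net$nn)
  tibble::tibble(
    i = (nid - 1L) %% (net$N + 1L),
    j = (nid - 1L) %/% (net$N + 1L),
    X_mm = net$X * net$nd$length_mm, Y_mm = net$Y * net$nd$length_mm,
    x_mm = x$x_mm, y_mm = x$y_mm,
    disp_mm = sqrt((x$x_mm - net$X * net$nd$length_mm)^2 +
                     (x$y_mm - net$Y * net$nd$length_mm)^2)
  )
}

#' Tidy a continuum solution
#'
#' @param x A `cornea_continuum` solution.
#' @param ... Unused.
#' @return The node-wise field table of [continuum_fields()].
#' @export
tidy.cornea_continuum <- function(x, ...) continuum_fields(x)

#' One-row summary of a discrete solution
#' @param x A `cornea_discrete` solution.
#' @param ... Unused.
#' @return One-row tibble with grid sizes, pressure, residual norm and the
#'   headline metrics.
#' @export
glance.cornea_discrete <- function(x, ...) {
  tibble::tibble(
    N = x$network$N, M = x$network$M, p_kPa = x$p_kPa,
    residual_norm = x$residual_norm,
    AD_mm = apex_displacement(x), CCT_mm = central_thickness(x),
    max_disp_mm = max_displacement(x)
  )
}

#' One-row summary of a continuum solution
#' @param x A `cornea_continuum` solution.
#' @param ... Unused.
#' @return One-row tibble with grid sizes, pressure, damage, energy and
#'   the headline metrics.
#' @export
glance.cornea_continuum <- function(x, ...) {
  tibble::tibble(
    n_R = x$n_R, n_Phi = x$n_Phi, p_kPa = x$p_kPa, Dmax = x$Dmax,
    energy = x$energy, grad_norm = x$grad_norm,
    AD_mm = apex_displacement(x), CCT_mm = central_thickness(x)
  )
}

#' Plot the deformed corneal interfaces
#'
#' @param object A solution (either scale).
#' @param ... Unused.
#' @return A ggplot showing the reference and deformed anterior/posterior
#'   surfaces (mm).
#' @export
autoplot.cornea_discrete <- function(object, ...) plot_interfaces(object)

#' @rdname autoplot.cornea_discrete
#' @export
autoplot.cornea_continuum <- function(object, ...) plot_interfaces(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

plot_interfaces <- function(sol) {
  nd <- if (inherits(sol, "cornea_discrete")) sol$network$nd else sol$nd
  ref <- function(R0, label) {
    ph <- seq(-nd$Phi_star, nd$Phi_star, length.out = 241)
    tibble::tibble(x_mm = R0 * cos(ph) * nd$length_mm,
                   y_mm = R0 * sin(ph) * nd$length_mm,
                   surface = label, state = "reference")
  }
  cur <- dplyr::bind_rows(
    dplyr::mutate(interface_curve(sol, "anterior"), surface = "anterior"),
    dplyr::mutate(interface_curve(sol, "posterior"), surface = "posterior"))
  cur$state <- "deformed"
  dat <- dplyr::bind_rows(ref(nd$RA, "anterior"), ref(nd$RP, "posterior"), cur)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$y_mm, y = .data$x_mm,
                                    colour = .data$surface,
                                    linetype = .data$state)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Y (mm)", y = "X (mm)",
                  title = "Corneal interfaces (reference vs deformed)") +
    ggplot2::theme_minimal()
}

#' Plot interface curvature profiles
#'
#' @param sol A solution (either scale).
#' @return A ggplot of anterior and posterior curvature (1/mm) against the
#'   transverse coordinate `y` (mm).
#' @export
plot_curvature <- function(sol) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(surface_curvature(interface_curve(sol, "anterior")),
                  surface = "anterior"),
    dplyr::mutate(surface_curvature(interface_curve(sol, "posterior")),
                  surface = "posterior"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$y, y = .data$curvature,
                                    colour = .data$surface)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "y (mm)", y = "curvature (1/mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
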