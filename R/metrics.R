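#' Deformed interface curve
#'
#' Extracts the deformed anterior or posterior surface of a solution as an
#' ordered point sequence, from limbus to limbus.
#'
#' @param sol A `cornea_discrete` or `cornea_continuum` solution.
#' @param which `"anterior"` or `"posterior"`.
#' @return Tibble with columns `x_mm`, `y_mm` ordered by increasing `y`.
#' @export
interface_curve <- function(sol, which = c("anterior", "posterior")) {
  which <- match.arg(which)
  if (inherits(sol, "cornea_discrete")) {
    net <- sol$network
    ids <- if (which == "anterior") net$anterior else net$posterior
    tibble::tibble(x_mm = sol$x[ids] * net$nd$length_mm,
                   y_mm = sol$y[ids] * net$nd$length_mm)
  } else if (inherits(sol, "cornea_continuum")) {
    i <- if (which == "anterior") sol$n_R + 1 else 1
    r <- sol$r[i, ]; ph <- sol$phi[i, ]
    tibble::tibble(x_mm = r * cos(ph) * sol$nd$length_mm,
                   y_mm = r * sin(ph) * sol$nd$length_mm)
  } else {
    stop("unsupported solution type", call. = FALSE)
  }
}

#' Apex displacement
#'
#' Radial displacement of the anterior surface point on the symmetry axis
#' (`Phi = 0`). The posterior apex displacement is available via
#' `posterior = TRUE`.
#'
#' @param sol A converged solution (either scale).
#' @param posterior If `TRUE`, report the posterior apex instead.
#' @return Displacement in mm (positive = outward bulging).
#' @export
apex_displacement <- function(sol, posterior = FALSE) {
  if (inherits(sol, "cornea_discrete")) {
    net <- sol$network
    ids <- if (posterior) net$posterior else net$anterior
    apex <- ids[net$M / 2 + 1]
    R0 <- if (posterior) net$nd$RP else net$nd$RA
    (sqrt(sol$x[apex]^2 + sol$y[apex]^2) - R0) * net$nd$length_mm
  } else if (inherits(sol, "cornea_continuum")) {
    i <- if (posterior) 1 else sol$n_R + 1
    j <- sol$n_Phi / 2 + 1
    R0 <- if (posterior) sol$nd$RP else sol$nd$RA
    (sol$r[i, j] - R0) * sol$nd$length_mm
  } else {
    stop("unsupported solution type", call. = FALSE)
  }
}

#' Central corneal thickness
#'
#' Euclidean distance between the deformed anterior and posterior apex
#' points (`Phi = 0`).
#'
#' @param sol A converged solution (either scale).
#' @return Thickness in mm.
#' @export
central_thickness <- function(sol) {
  if (inherits(sol, "cornea_discrete")) {
    net <- sol$network
    a <- net$anterior[net$M / 2 + 1]; p <- net$posterior[net$M / 2 + 1]
    sqrt((sol$x[a] - sol$x[p])^2 + (sol$y[a] - sol$y[p])^2) * net$nd$length_mm
  } else if (inherits(sol, "cornea_continuum")) {
    j <- sol$n_Phi / 2 + 1
    ia <- sol$n_R + 1
    xa <- sol$r[ia, j] * cos(sol$phi[ia, j]); ya <- sol$r[ia, j] * sin(sol$phi[ia, j])
    xp <- sol$r[1, j] * cos(sol$phi[1, j]); yp <- sol$r[1, j] * sin(sol$phi[1, j])
    sqrt((xa - xp)^2 + (ya - yp)^2) * sol$nd$length_mm
  } else {
    stop("unsupported solution type", call. = FALSE)
  }
}

#' Curvature profile of an interface
#'
#' Describes the surface as a graph `x = F(y)` and computes the curvature
#' `K = F'' / (1 + F'^2)^(3/2)` with three-point finite differences on the
#' (possibly non-uniform) `y` grid (one-sided at the ends). The sign is
#' chosen so that the unloaded cornea has positive curvature.
#'
#' @param curve Two-column object with the ordered point sequence; columns
#'   `x` (or `x_mm`) and `y` (or `y_mm`).
#' @return Tibble with `y`, `x`, and `curvature` (1/length-unit of the
#'   input).
#' @export
surface_curvature <- function(curve) {
  m <- as.data.frame(curve)
  xc <- if ("x_mm" %in% names(m)) m$x_mm else m$x
  yc <- if ("y_mm" %in% names(m)) m$y_mm else m$y
  if (is.null(xc) || is.null(yc)) stop("curve needs x and y columns", call. = FALSE)
  n <- length(yc)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  dy <- diff(yc)
  if (any(dy <= 0)) {
    if (all(dy < 0)) { xc <- rev(xc); yc <- rev(yc); dy <- diff(yc) }
    else stop("parametrization error: y must be strictly monotone", call. = FALSE)
  }
  F1 <- F2 <- numeric(n)
  h1 <- dy[1:(n - 2)]; h2 <- dy[2:(n - 1)]
  xm <- xc[1:(n - 2)]; x0 <- xc[2:(n - 1)]; xp <- xc[3:n]
  den <- h1 * h2 * (h1 + h2)
  F1[2:(n - 1)] <- (h1^2 * xp - h2^2 * xm + (h2^2 - h1^2) * x0) / den
  F2[2:(n - 1)] <- 2 * (h1 * xp + h2 * xm - (h1 + h2) * x0) / den
  # ends: one-sided derivatives from the interpolating cubic through the
  # nearest four points (second-order accurate like the interior stencil)
  end4 <- function(ys, xs, y0) {
    t <- ys - y0
    m <- length(ys)
    cf <- solve(outer(t, 0:(m - 1), "^"), xs)
    list(F1 = cf[2], F2 = 2 * cf[3])
  }
  np <- min(n, 5)
  e1 <- end4(yc[1:np], xc[1:np], yc[1])
  e2 <- end4(yc[(n - np + 1):n], xc[(n - np + 1):n], yc[n])
  F1[1] <- e1$F1; F2[1] <- e1$F2
  F1[n] <- e2$F1; F2[n] <- e2$F2
  tibble::tibble(y = yc, x = xc, curvature = -F2 / (1 + F1^2)^1.5)
}

#' Maximum curvature over the central region
#'
#' Takes the maximum of a curvature profile over the central part of the
#' arc, excluding a fraction of the points at both ends to avoid the
#' boundary effects of the rigidly pinned limbus.
#'
#' @param profile A tibble from [surface_curvature()] or a numeric vector
#'   of curvature samples ordered along the arc.
#' @param exclusion_fraction Fraction of points excluded at each end
#'   (default 0.10).
#' @return Maximum curvature over the retained points.
#' @export
max_curvature <- function(profile, exclusion_fraction = 0.10) {
  k <- if (is.numeric(profile)) profile else profile$curvature
  n <- length(k)
  idx <- 0:(n - 1)
  keep <- idx >= exclusion_fraction * (n - 1) & idx <= (1 - exclusion_fraction) * (n - 1)
  max(k[keep])
}

#' Headline metrics of a solution
#'
#' Collects the four shape metrics used to quantify disease progression:
#' apex displacement (AD), central corneal thickness (CCT) and the maximum
#' curvature of the anterior (MAC) and posterior (MPC) surfaces over the
#' central 80% of the arc. For the unloaded reference these are exactly
#' `(0, T, 1/R_A, 1/R_P)`.
#'
#' @param sol A converged solution (either scale).
#' @return Object of class `metrics_report` (also a list): `AD_mm`,
#'   `CCT_mm`, `MAC_per_mm`, `MPC_per_mm`, `AD_posterior_mm`, plus
#'   provenance (`config_hash`, grid description).
#' @export
metrics_report <- function(sol) {
  ant <- surface_curvature(interface_curve(sol, "anterior"))
  post <- surface_curvature(interface_curve(sol, "posterior"))
  grid <- if (inherits(sol, "cornea_discrete")) {
    sprintf("discrete N=%d M=%d", sol$network$N, sol$network$M)
  } else {
    sprintf("continuum %dx%d", sol$n_R, sol$n_Phi)
  }
  structure(list(
    AD_mm = apex_displacement(sol),
    CCT_mm = central_thickness(sol),
    MAC_per_mm = max_curvature(ant),
    MPC_per_mm = max_curvature(post),
    AD_posterior_mm = apex_displacement(sol, posterior = TRUE),
    config_hash = config_hash(sol$config),
    grid = grid
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", x$grid, "\n")
  cat(sprintf("  AD  = %.4f mm (posterior %.4f mm)\n", x$AD_mm, x$AD_posterior_mm))
  cat(sprintf("  CCT = %.4f mm\n", x$CCT_mm))
  cat(sprintf("  MAC = %.4f /mm, MPC = %.4f /mm\n", x$MAC_per_mm, x$MPC_per_mm))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report A [metrics_report()].
#' @return JSON string.
#' @export
metrics_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(17))
}

#' Deserialize a metrics report from JSON
#' @param txt JSON string from [metrics_to_json()].
#' @return A `metrics_report` object.
#' @export
metrics_from_json <- function(txt) {
  structure(jsonlite::fromJSON(txt), class = "metrics_report")
}
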