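#' Keratoconus damage specification
#'
#' Damage is modelled as a smooth, even reduction of element stiffness,
#' maximal at the corneal centre and vanishing where the anterior surface
#' meets the limbus: `D(Y) = Dmax * (1 - (Y/Ymax)^xi)` with an even
#' localization exponent `xi`. Larger `xi` concentrates the average damage
#' closer to its maximum.
#'
#' @param Dmax Maximum damage in `[0, 1)`.
#' @param xi Even integer exponent `>= 2`.
#' @param Ymax Reference `Y` where the anterior surface meets the limbus
#'   (`R_A * sin(Phi_star)`); same length unit as the `Y` values the
#'   profile will be evaluated at.
#' @return Object of class `damage_spec`.
#' @export
damage_spec <- function(Dmax, xi, Ymax) {
  if (!(Dmax >= 0 && Dmax < 1)) stop("invalid damage: Dmax must be in [0, 1)", call. = FALSE)
  if (!(xi >= 2 && xi %% 2 == 0)) stop("invalid damage: xi must be an even integer >= 2", call. = FALSE)
  if (!(Ymax > 0)) stop("invalid damage: Ymax must be positive", call. = FALSE)
  structure(list(Dmax = Dmax, xi = as.integer(xi), Ymax = Ymax),
            class = "damage_spec")
}

#' Damage profile across the cornea
#'
#' @param Y Reference transverse coordinate(s), same unit as `spec$Ymax`.
#' @param spec A [damage_spec()].
#' @return Damage fraction(s) in `[0, Dmax]`. Values with `|Y| > Ymax`
#'   (nodes outside the anterior chord) are clamped to zero with a warning.
#' @export
damage_profile <- function(Y, spec) {
  stopifnot(inherits(spec, "damage_spec"))
  d <- spec$Dmax * (1 - (Y / spec$Ymax)^spec$xi)
  out <- abs(Y) > spec$Ymax
  if (any(out)) {
    warning("damage_profile: |Y| > Ymax for ", sum(out),
            " point(s); clamped to zero damage", call. = FALSE)
    d[out] <- 0
  }
  pmax(d, 0)
}

#' Apply damage to element stiffness
#'
#' Damage reduces the stiffness of the lamellar segments (`K1`) and the
#' diagonal crosslinks (`K3`) linearly, `K -> (1 - d) K`. The radial
#' crosslinks (`K2`) are never modified: their role is to keep the lamellae
#' spaced, and they are held intact as the disease progresses.
#'
#' @param K1,K3 Undamaged stiffnesses (any consistent unit).
#' @param d Damage fraction(s) in `[0, 1)`.
#' @return List with damaged `K1` and `K3`.
#' @export
apply_damage <- function(K1, K3, d) {
  if (any(d < 0) || any(d >= 1)) {
    stop("invalid damage: fractions must lie in [0, 1)", call. = FALSE)
  }
  list(K1 = (1 - d) * K1, K3 = (1 - d) * K3)
}

# internal: damage fraction at reference Y for a config (dimensionless or mm,
# as long as Y and Ymax use the same unit); Dmax may be overridden during
# continuation
damage_at <- function(Y, config, Dmax = config$Dmax, clamp_quietly = TRUE) {
  if (Dmax == 0) return(rep(0, length(Y)))
  g <- config$geometry
  Ymax <- g$R_A * sin(g$Phi_star)
  d <- Dmax * (1 - (Y / Ymax)^config$xi)
  pmax(d, 0)
}
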