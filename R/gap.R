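# Enclosed air-gap physics: Rayleigh number, rectangular-enclosure Nusselt
# correlation, and the lumped liner<->skin interface fluxes.

#' Construct an air-gap description
#'
#' The enclosed air layer between the thermal liner and the skin. Convection
#' is gated on the Rayleigh number: above 1000 for a vertical gap (1708
#' horizontal) the enclosure Nusselt correlation multiplies the conductive
#' exchange. The cavity height `H` is the characteristic height of one
#' convection cell: garment air layers are pinched into closed cells by
#' fabric-skin contact points, and by default the cells are taken as roughly
#' cubical (`H` equal to the gap size); a fixed height can be supplied
#' instead.
#'
#' @param size_mm gap thickness in mm (>= 0; 0 means liner in perfect
#'   thermal contact with the skin).
#' @param height_m cavity height H in m; `NULL` (default) uses the gap size.
#' @param kappa_air_m1 extinction coefficient of the gap air, 1/m.
#' @param orientation `"vertical"` or `"horizontal"` (sets the convection
#'   onset threshold: Ra > 1000 vs Ra > 1708).
#' @return object of class `air_gap`.
#' @export
air_gap <- function(size_mm = 6.4, height_m = NULL, kappa_air_m1 = 5,
                    orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  stopifnot(size_mm >= 0, is.null(height_m) || height_m > 0, kappa_air_m1 >= 0)
  structure(list(
    size_m = size_mm / 1000,
    height_m = if (is.null(height_m)) max(size_mm / 1000, 1e-3) else height_m,
    kappa_air_m1 = kappa_air_m1,
    orientation = orientation,
    ra_threshold = if (orientation == "vertical") 1000 else 1708
  ), class = "air_gap")
}

#' Rayleigh number of the enclosed gap
#'
#' `Ra = g beta |T_hot - T_cold| L^3 / (alpha nu)`. By default the air
#' properties (and the ideal-gas `beta = 1/T`) are evaluated at the film
#' temperature (arithmetic mean of the bounding surfaces); passing
#' `T_props_K` evaluates them at a fixed reference state instead — the gap
#' solver uses the ambient state, which reproduces the reported convection
#' onset (Ra above 1000 in a ~6 mm gap under nominal exposure; film-state
#' properties suppress it to ~9 mm). Zero when the gap is absent or
#' isothermal.
#'
#' @param T_hot,T_cold bounding surface temperatures, K.
#' @param L_air gap thickness, m (>= 0).
#' @param T_props_K optional property-evaluation temperature, K.
#' @return dimensionless Rayleigh number.
#' @export
rayleigh_number <- function(T_hot, T_cold, L_air, T_props_K = NULL) {
  stopifnot(L_air >= 0)
  dT <- abs(T_hot - T_cold)
  if (L_air == 0 || dT == 0) return(0)
  Tp <- if (is.null(T_props_K)) (T_hot + T_cold) / 2 else T_props_K
  a <- air_properties(min(max(Tp, 250), 800))
  G_ACCEL * a$beta_1_K * dT * L_air^3 / (a$alpha_m2_s * a$nu_m2_s)
}

#' Rectangular-enclosure Nusselt number
#'
#' Two-branch correlation for a tall rectangular cavity:
#' `Nu = 1` for `Ra <= 1e3` (pure conduction), and
#' `Nu = 0.22 (Pr Ra / (0.2 + Pr))^0.28 (H / L)^(-0.25)` for
#' `1e3 < Ra <= 1e10`, reported with the physical floor `max(Nu, 1)`.
#' Ties at exactly `Ra = 1e3` take the conduction branch.
#'
#' @param Ra Rayleigh number (>= 0; error above 1e10, outside the
#'   correlation).
#' @param Pr Prandtl number.
#' @param H cavity height, m.
#' @param L_air gap thickness, m (> 0).
#' @return Nusselt number (>= 1).
#' @export
enclosure_nusselt <- function(Ra, Pr, H, L_air) {
  stopifnot(Ra >= 0, Pr > 0, H > 0, L_air > 0)
  if (Ra > 1e10) stop("Ra > 1e10: outside the enclosure correlation", call. = FALSE)
  if (Ra <= 1e3) return(1.0)
  max(1.0, 0.22 * (Pr / (0.2 + Pr) * Ra)^0.28 * (H / L_air)^(-0.25))
}

#' Lumped interface fluxes across the air gap
#'
#' The lumped (film-coefficient) view of the gap exchange: the liner inner
#' surface loses the liner-to-skin radiation `q_transmitted` plus the
#' convective/conductive film exchange `h_gap (T_liner - T_skin)` with
#' `h_gap = Nu k_air(T_film) / L_air` (`Nu = 1` means pure conduction); the
#' skin surface gains the radiation attenuated over the gap by Beer's law,
#' `q_transmitted exp(-kappa_air L_air)`, plus the same film exchange. The
#' difference, `q_transmitted (1 - exp(-kappa_air L_air))`, is deposited in
#' the gap air.
#'
#' @param gap an [air_gap()].
#' @param T_liner liner inner-surface temperature, K.
#' @param T_skin skin surface temperature, K.
#' @param q_transmitted radiation leaving the liner toward the skin, W/m^2.
#' @param Nu Nusselt number of the gap (default: recomputed from the current
#'   Ra at the film temperature).
#' @return list with `liner_W_m2` (leaving the liner), `skin_W_m2` (arriving
#'   at the skin), `absorbed_W_m2` (deposited in the gap air), `h_gap_W_m2K`,
#'   `Ra` and `Nu`.
#' @export
gap_interface_fluxes <- function(gap, T_liner, T_skin, q_transmitted, Nu = NULL) {
  stopifnot(inherits(gap, "air_gap"))
  if (gap$size_m == 0) {
    stop("gap size is 0: liner and skin are in perfect thermal contact; no gap interface",
         call. = FALSE)
  }
  T_film <- min(max((T_liner + T_skin) / 2, 250), 800)
  Ra <- rayleigh_number(T_liner, T_skin, gap$size_m)
  if (is.null(Nu)) {
    Nu <- enclosure_nusselt(Ra, air_properties(T_film)$Pr, gap$height_m, gap$size_m)
  }
  h_gap <- Nu * air_conductivity(T_film) / gap$size_m
  conv <- h_gap * (T_liner - T_skin)
  trans <- exp(-gap$kappa_air_m1 * gap$size_m)
  list(
    liner_W_m2 = q_transmitted + conv,
    skin_W_m2 = q_transmitted * trans + conv,
    absorbed_W_m2 = q_transmitted * (1 - trans),
    h_gap_W_m2K = h_gap,
    Ra = Ra,
    Nu = Nu
  )
}

#' Liner-to-skin radiative exchange
#'
#' Net radiation leaving the liner inner surface toward the skin, treated as
#' infinite parallel plates:
#' `q = sigma (T_liner^4 - T_skin^4) / (1/eps_liner + 1/eps_skin - 1)`.
#'
#' @param T_liner,T_skin surface temperatures, K.
#' @param eps_liner,eps_skin surface emissivities.
#' @return flux in W/m^2 (positive toward the skin).
#' @export
liner_skin_radiation <- function(T_liner, T_skin, eps_liner = 0.9, eps_skin = 0.9) {
  SIGMA_SB * (T_liner^4 - T_skin^4) / (1 / eps_liner + 1 / eps_skin - 1)
}
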