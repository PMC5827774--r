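# Transport properties of dry air at atmospheric pressure, 250-800 K.
# Standard engineering property table (kinematic viscosity, thermal
# diffusivity, Prandtl number, density, specific heat); linear interpolation
# between tabulated points. Conduction uses the linear k_air(T) model in
# materials.R; the expansion coefficient is the ideal-gas 1/T_film.

.AIR_TAB <- data.frame(
  T_K  = c(250, 300, 350, 400, 450, 500, 550, 600, 650, 700, 750, 800),
  nu   = 1e-6 * c(11.44, 15.89, 20.92, 26.41, 32.39, 38.79, 45.57, 52.69,
                  60.21, 68.10, 76.37, 84.93), # m^2/s
  alpha = 1e-6 * c(15.9, 22.5, 29.9, 38.3, 47.2, 56.7, 66.7, 76.9,
                   87.3, 98.0, 109.0, 120.0), # m^2/s
  Pr   = c(0.720, 0.707, 0.700, 0.690, 0.686, 0.684, 0.683, 0.685,
           0.690, 0.695, 0.702, 0.709),
  rho  = c(1.3947, 1.1614, 0.9950, 0.8711, 0.7740, 0.6964, 0.6329, 0.5804,
           0.5356, 0.4975, 0.4643, 0.4354), # kg/m^3
  cp   = c(1006, 1007, 1009, 1014, 1021, 1030, 1040, 1051, 1063, 1075,
           1087, 1099) # J/(kg K)
)

#' Dry-air transport properties at a film temperature
#'
#' Linearly interpolated kinematic viscosity, thermal diffusivity, Prandtl
#' number, density and specific heat of dry air at 1 atm, plus the ideal-gas
#' expansion coefficient `beta = 1/T` and the package's linear conductivity
#' model evaluated at `T`.
#'
#' @param T film temperature in kelvin, in `[250, 800]`.
#' @return named list: `nu_m2_s`, `alpha_m2_s`, `Pr`, `rho_kg_m3`,
#'   `cp_J_kgK`, `beta_1_K`, `k_W_mK`.
#' @export
air_properties <- function(T) {
  .check_T_range(T, 250, 800, "air film temperature")
  list(
    nu_m2_s = approx(.AIR_TAB$T_K, .AIR_TAB$nu, T)$y,
    alpha_m2_s = approx(.AIR_TAB$T_K, .AIR_TAB$alpha, T)$y,
    Pr = approx(.AIR_TAB$T_K, .AIR_TAB$Pr, T)$y,
    rho_kg_m3 = approx(.AIR_TAB$T_K, .AIR_TAB$rho, T)$y,
    cp_J_kgK = approx(.AIR_TAB$T_K, .AIR_TAB$cp, T)$y,
    beta_1_K = 1 / T,
    k_W_mK = air_conductivity(T)
  )
}
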