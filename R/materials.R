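# Temperature-dependent thermo-physical and optical property models for the
# fabric layers of a turnout ensemble, plus the packaged three-layer default.

.check_T_range <- function(T, lo = 200, hi = 1000, what = "temperature") {
  if (any(!is.finite(T)) || any(T < lo) || any(T > hi)) {
    stop(sprintf("%s out of range: valid interval is [%g, %g] K", what, lo, hi),
         call. = FALSE)
  }
  invisible(T)
}

#' Fiber thermal conductivity as a function of temperature
#'
#' Linear model for the conductivity of aramid fiber,
#' `k_fiber(T) = 0.13 + 0.0018 (T - 300)` W/(m K).
#'
#' @param T temperature in kelvin, in `[200, 1000]`.
#' @return conductivity in W/(m K).
#' @export
#' @examples
#' fiber_conductivity(300) # 0.13
fiber_conductivity <- function(T) {
  .check_T_range(T)
  0.13 + 0.0018 * (T - 300)
}

#' Air thermal conductivity as a function of temperature
#'
#' Linear model `k_air(T) = 0.026 + 0.000068 (T - 300)` W/(m K), used both for
#' the air trapped in fabric pores and for the enclosed air gap.
#'
#' @inheritParams fiber_conductivity
#' @return conductivity in W/(m K).
#' @export
air_conductivity <- function(T) {
  .check_T_range(T)
  0.026 + 0.000068 * (T - 300)
}

#' Construct a fabric layer description
#'
#' A `fabric_layer` holds the thermo-physical and optical description of one
#' clothing layer: thickness, density, specific heat, measured reference
#' conductivity (at 300 K), surface emissivity, reflectivity `r`,
#' transmissivity `tau`, and the Beer-Lambert extinction coefficient derived
#' from `r`, `tau` and the thickness.
#'
#' @param name layer name.
#' @param thickness_m thickness in m (> 0).
#' @param density_kg_m3 bulk density in kg/m^3 (> 0).
#' @param specific_heat_J_kgK specific heat in J/(kg K) (> 0).
#' @param conductivity_ref_W_mK measured conductivity at the 300 K reference
#'   temperature, W/(m K).
#' @param emissivity surface emissivity in `[0, 1]`.
#' @param reflectivity reflectivity `r` in `[0, 1)`.
#' @param transmissivity transmissivity `tau` in `(0, 1 - r]`. Together with
#'   `reflectivity` this fixes the extinction coefficient; both are calibration
#'   knobs (they are rarely measured for turnout fabrics).
#' @return an object of class `fabric_layer` (a named list with an added
#'   `extinction_m1` field).
#' @export
fabric_layer <- function(name, thickness_m, density_kg_m3, specific_heat_J_kgK,
                         conductivity_ref_W_mK, emissivity = 0.9,
                         reflectivity = 0.09, transmissivity = 0.044) {
  stopifnot(is.character(name), length(name) == 1L)
  if (thickness_m <= 0) stop("thickness must be > 0", call. = FALSE)
  if (density_kg_m3 <= 0) stop("density must be > 0", call. = FALSE)
  if (specific_heat_J_kgK <= 0) stop("specific heat must be > 0", call. = FALSE)
  if (conductivity_ref_W_mK <= 0) stop("reference conductivity must be > 0", call. = FALSE)
  if (emissivity < 0 || emissivity > 1) stop("emissivity must lie in [0, 1]", call. = FALSE)
  if (reflectivity < 0 || reflectivity >= 1) stop("reflectivity must lie in [0, 1)", call. = FALSE)
  if (reflectivity + transmissivity > 1 + 1e-12) {
    stop("reflectivity + transmissivity must be <= 1", call. = FALSE)
  }
  layer <- list(
    name = name,
    thickness_m = thickness_m,
    density_kg_m3 = density_kg_m3,
    specific_heat_J_kgK = specific_heat_J_kgK,
    conductivity_ref_W_mK = conductivity_ref_W_mK,
    emissivity = emissivity,
    reflectivity = reflectivity,
    transmissivity = transmissivity,
    extinction_m1 = extinction_coefficient(reflectivity, transmissivity, thickness_m)
  )
  class(layer) <- "fabric_layer"
  layer
}

#' @export
print.fabric_layer <- function(x, ...) {
  cat(sprintf(
    "<fabric_layer> %s: L=%.3g mm, rho=%g kg/m3, cp=%g J/(kg K), k_ref=%g W/(m K), kappa=%.3g 1/m\n",
    x$name, 1e3 * x$thickness_m, x$density_kg_m3, x$specific_heat_J_kgK,
    x$conductivity_ref_W_mK, x$extinction_m1))
  invisible(x)
}

#' Beer-Lambert extinction coefficient of a fabric layer
#'
#' `kappa = ln((1 - r) / tau) / L`: the extinction coefficient consistent with
#' a layer of thickness `L` reflecting a fraction `r` and transmitting a
#' fraction `tau` of normally incident radiation.
#'
#' @param r reflectivity in `[0, 1)`.
#' @param tau transmissivity in `(0, 1 - r]`.
#' @param L layer thickness in m (> 0).
#' @return extinction coefficient in 1/m (>= 0).
#' @export
#' @examples
#' extinction_coefficient(0.09, 0.044, 0.00063) # ~4.8e3 1/m for the outer shell
extinction_coefficient <- function(r, tau, L) {
  if (r < 0 || r >= 1) stop("reflectivity must lie in [0, 1)", call. = FALSE)
  if (tau <= 0) {
    stop("transmissivity = 0: opaque layer; treat absorption as a surface term instead",
         call. = FALSE)
  }
  if (tau > 1 - r + 1e-12) stop("transmissivity must be <= 1 - reflectivity", call. = FALSE)
  if (L <= 0) stop("thickness must be > 0", call. = FALSE)
  log((1 - r) / tau) / L
}

# Unscaled 0.8/0.2 air/fiber mixture conductivity (the porous-fabric mixing
# rule); 0.0468 W/(m K) at 300 K.
.mixture_conductivity <- function(T) {
  0.8 * air_conductivity(T) + 0.2 * fiber_conductivity(T)
}

#' Fabric conductivity of a layer at temperature T
#'
#' The porous-fabric mixing rule `0.8 k_air(T) + 0.2 k_fiber(T)` carries the
#' temperature dependence, but its room-temperature value (0.0468 W/(m K))
#' disagrees with the measured conductivities of the inner layers. Each layer
#' is therefore anchored to its measured `conductivity_ref` at 300 K and the
#' mixture's temperature slope is applied multiplicatively:
#' `k(T) = k_ref * mix(T) / mix(300)`. The result is strictly increasing in T
#' and equals the measured value at the reference temperature.
#'
#' @param layer a [fabric_layer()].
#' @inheritParams fiber_conductivity
#' @return conductivity in W/(m K).
#' @export
fabric_conductivity <- function(layer, T) {
  stopifnot(inherits(layer, "fabric_layer"))
  layer$conductivity_ref_W_mK * .mixture_conductivity(T) / .mixture_conductivity(300)
}

#' The packaged three-layer turnout ensemble
#'
#' Measured properties of a typical firefighter turnout system: a Nomex outer
#' shell, a Nomex/Kevlar (PTFE) moisture barrier and an M-aramid thermal
#' liner. Optical properties (`r`, `tau`) are configuration defaults, not
#' measurements: the outer shell defaults give an extinction coefficient of
#' about 4.8e3 1/m; the inner layers default to near-opaque
#' (`tau = 0.01`). Treat them as calibration knobs.
#'
#' @param shell_reflectivity,shell_transmissivity optical defaults for the
#'   outer shell.
#' @param inner_transmissivity transmissivity default shared by moisture
#'   barrier and thermal liner.
#' @return list of three [fabric_layer()] objects, outermost first.
#' @export
turnout_ensemble <- function(shell_reflectivity = 0.09,
                             shell_transmissivity = 0.044,
                             inner_transmissivity = 0.01) {
  list(
    fabric_layer("outer_shell", 0.63e-3, 421, 1570, 0.047,
                 emissivity = 0.9, reflectivity = shell_reflectivity,
                 transmissivity = shell_transmissivity),
    fabric_layer("moisture_barrier", 0.91e-3, 221, 1160, 0.034,
                 emissivity = 0.9, reflectivity = 0.09,
                 transmissivity = inner_transmissivity),
    fabric_layer("thermal_liner", 2.21e-3, 231, 1350, 0.035,
                 emissivity = 0.9, reflectivity = 0.09,
                 transmissivity = inner_transmissivity)
  )
}

#' Write / read a material registry file
#'
#' The registry is a YAML document with one record per layer carrying exactly
#' the [fabric_layer()] fields; round-tripping reproduces every numeric field
#' bit-exactly (values are serialized at full precision).
#'
#' @param layers list of [fabric_layer()] objects.
#' @param path file path.
#' @return `write_material_registry` returns `path` invisibly;
#'   `read_material_registry` returns a list of [fabric_layer()].
#' @export
write_material_registry <- function(layers, path) {
  recs <- lapply(layers, function(l) {
    lapply(unclass(l)[c("name", "thickness_m", "density_kg_m3",
                        "specific_heat_J_kgK", "conductivity_ref_W_mK",
                        "emissivity", "reflectivity", "transmissivity")],
           function(v) if (is.numeric(v)) sprintf("%.17g", v) else v)
  })
  yaml::write_yaml(list(layers = recs), path)
  invisible(path)
}

#' @rdname write_material_registry
#' @export
read_material_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$layers)) stop("registry file has no 'layers' block", call. = FALSE)
  lapply(doc$layers, function(r) {
    fabric_layer(r$name,
                 as.numeric(r$thickness_m), as.numeric(r$density_kg_m3),
                 as.numeric(r$specific_heat_J_kgK), as.numeric(r$conductivity_ref_W_mK),
                 emissivity = as.numeric(r$emissivity),
                 reflectivity = as.numeric(r$reflectivity),
                 transmissivity = as.numeric(r$transmissivity))
  })
}
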