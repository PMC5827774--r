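# Reconstruction of a Stolwijk/Tanabe-type 81-node body dataset on the
# 20-segment division of a 20-zone thermal manikin (face, head, chest,
# stomach, back, hips, and left/right shoulder, upper arm, forearm, hand,
# thigh, calf, foot), four tissue layers per segment (core, muscle, fat,
# skin) plus a central blood compartment. The published multi-node datasets
# use 16 segments; this table re-aggregates by surface-area and mass
# proportionality. Segment capacities, basal rates and perfusions are
# physiologically plausible reconstructions, and the inter-layer
# conductances (and, where required for consistency, basal perfusion) are
# calibrated in code so that the set-point state is an exact thermoneutral
# steady state -- the calibration principle of the original models.

.SEG_NAMES <- c("face", "head", "chest", "stomach", "back", "hips",
                "l_shoulder", "r_shoulder", "l_upper_arm", "r_upper_arm",
                "l_forearm", "r_forearm", "l_hand", "r_hand",
                "l_thigh", "r_thigh", "l_calf", "r_calf", "l_foot", "r_foot")

#' Build the 81-node thermoregulation dataset
#'
#' Assembles the full parameter set of the body model: segment areas and
#' masses, per-layer heat capacities, set points, basal heat production,
#' basal perfusion, inter-layer conductances, signal-distribution weights,
#' and the canonical control coefficients of the vasodilatation /
#' vasoconstriction / sweating / shivering laws (Cdl = 117, Sdl = 7.5;
#' Cst = 5, Sst = 0.5; Csw = 371.2, Ssw = 33.6; Pch = 24.4). The set-point
#' state is calibrated to be an exact steady state (see the package
#' vignette); `basal_skin_loss_W` records the reference environmental loss
#' that balances each skin node there.
#'
#' @param total_area_m2 body surface area (default 1.87 m^2).
#' @param total_mass_kg body mass (default 74.43 kg).
#' @param res_frac fraction of total metabolic rate lost by respiration
#'   (assigned to the chest core).
#' @param eta_evap clothing evaporative efficiency in `[0, 1]`: the fraction
#'   of the free-surface maximum evaporative capacity available through the
#'   (dry) clothing model. The default 1 treats sweat evaporation at the
#'   free-surface rate, as the source model family does; lower values model
#'   the vapour resistance of the ensemble (with values around 0.3 the body
#'   cannot recover below the strain threshold within the simulated cooling
#'   at moderate fluxes).
#' @param h_e_W_m2kPa evaporative coefficient of the free skin surface.
#' @param bf_skin_basal_L_h whole-body basal skin perfusion, L/h,
#'   distributed by surface area.
#' @param bf_skin_max_L_h whole-body skin perfusion ceiling, L/h: with a
#'   single well-mixed blood pool and no countercurrent exchange, an
#'   unbounded vasodilated skin loop would slave the blood node to the skin
#'   temperature; the ceiling keeps the skin-core partition of stored heat
#'   in the physiological range.
#' @return object of class `body_model`.
#' @export
build_body <- function(total_area_m2 = 1.87, total_mass_kg = 74.43,
                       res_frac = 0.08, eta_evap = 1.0, h_e_W_m2kPa = 49.5,
                       bf_skin_basal_L_h = 7, bf_skin_max_L_h = 40) {
  n <- 20L
  central <- c(0.025, 0.050, 0.085, 0.085, 0.085, 0.090) # face..hips
  lateral <- c(0.030, 0.040, 0.030, 0.025, 0.080, 0.055, 0.030) # shoulder..foot, per side
  area_frac <- c(central, rep(lateral, each = 2))
  stopifnot(abs(sum(area_frac) - 1) < 1e-12)
  area <- area_frac * total_area_m2

  mass_central <- c(0.018, 0.052, 0.125, 0.105, 0.125, 0.125)
  mass_lateral <- c(0.012, 0.030, 0.018, 0.006, 0.095, 0.048, 0.016)
  mass_frac <- c(mass_central, rep(mass_lateral, each = 2))
  stopifnot(abs(sum(mass_frac) - 1) < 1e-12)
  blood_mass <- 2.5
  mass <- mass_frac * (total_mass_kg - blood_mass)

  # per-segment tissue split (core/muscle/fat/skin mass fractions)
  split_head <- c(0.78, 0.08, 0.06, 0.08)
  split_trunk <- c(0.42, 0.38, 0.13, 0.07)
  split_shoulder <- c(0.30, 0.50, 0.10, 0.10)
  split_arm <- c(0.25, 0.55, 0.10, 0.10)
  split_hand <- c(0.45, 0.20, 0.10, 0.25)
  split_leg <- c(0.25, 0.55, 0.12, 0.08)
  splits <- rbind(split_head, split_head, split_trunk, split_trunk,
                  split_trunk, split_trunk,
                  split_shoulder, split_shoulder, split_arm, split_arm,
                  split_arm, split_arm, split_hand, split_hand,
                  split_leg, split_leg, split_leg, split_leg,
                  split_hand, split_hand)
  layer_mass <- splits * mass # 20 x 4, kg
  cp_layer <- c(3700, 3800, 2300, 3680) # J/(kg K): core, muscle, fat, skin
  cap <- sweep(layer_mass, 2, cp_layer, "*") # J/K

  # set points, degC
  T_set <- cbind(
    core = c(37.0, 37.0, rep(36.9, 18)),
    muscle = rep(36.4, n),
    fat = rep(36.0, n),
    skin = c(35.6, 35.6, 35.0, 35.0, 35.0, 34.8,
             rep(c(34.5, 34.2, 34.0, 34.4, 34.3, 33.9, 33.9), each = 2))
  )

  # basal heat production, W
  Q_core_central <- c(1.0, 15.0, 19.0, 17.0, 6.0, 5.0)
  Q_core_lateral <- c(0.35, 0.60, 0.40, 0.20, 1.20, 0.60, 0.25)
  Q_basal <- cbind(
    core = c(Q_core_central, rep(Q_core_lateral, each = 2)),
    muscle = 0.20 * layer_mass[, 2],
    fat = 0.05 * layer_mass[, 3],
    skin = 0.10 * layer_mass[, 4]
  )
  M_basal <- sum(Q_basal)
  Res_basal <- res_frac * M_basal

  # basal perfusion, L/h (initial guesses; calibrated below)
  BF_core_central <- c(2.0, 40.0, 95.0, 65.0, 14.0, 10.0)
  BF_core_lateral <- c(0.6, 1.2, 0.8, 0.6, 2.2, 1.2, 0.6)
  BF <- cbind(
    core = c(BF_core_central, rep(BF_core_lateral, each = 2)),
    muscle = 0.9 * layer_mass[, 2],
    fat = 0.25 * layer_mass[, 3],
    skin = bf_skin_basal_L_h * area_frac
  )

  idx_chest <- 3L
  idx_head <- 2L
  Res_vec <- numeric(n); Res_vec[idx_chest] <- Res_basal

  # calibrate: set-point state must be an exact steady state. The central
  # blood set point is the perfusion-weighted mean of the node set points
  # (so the blood balance closes); inter-layer conductances follow from the
  # layer balances; where a balance would demand heat to flow inward
  # (D < D_min) the basal perfusion of that node is reduced instead.
  D_min <- 0.05
  for (pass in 1:8) {
    T81 <- sum(BF * T_set) / sum(BF)
    B <- BLOOD_HEAT_EQ * BF * (T_set - T81)
    D1 <- Q_basal[, 1] - B[, 1] - Res_vec
    fix <- D1 < D_min & (T_set[, 1] - T81) > 1e-3
    BF[fix, 1] <- (Q_basal[fix, 1] - Res_vec[fix] - D_min) /
      (BLOOD_HEAT_EQ * (T_set[fix, 1] - T81))
  }
  T81_set <- sum(BF * T_set) / sum(BF)
  B <- BLOOD_HEAT_EQ * BF * (T_set - T81_set)
  D1 <- Q_basal[, 1] - B[, 1] - Res_vec
  D2 <- Q_basal[, 2] - B[, 2] + D1
  D3 <- Q_basal[, 3] - B[, 3] + D2
  stopifnot(all(D1 > 0), all(D2 > 0), all(D3 > 0))
  K_cond <- cbind(
    D1 / (T_set[, 1] - T_set[, 2]),
    D2 / (T_set[, 2] - T_set[, 3]),
    D3 / (T_set[, 3] - T_set[, 4])
  ) # W/K
  basal_skin_loss <- Q_basal[, 4] - B[, 4] + D3 # W; reference (R+C+E) at set point

  # signal distribution weights (area-proportional re-aggregation)
  w_area <- area_frac
  muscle_mass <- layer_mass[, 2]
  w_shiver <- muscle_mass / sum(muscle_mass)
  # exercise work distribution: dominated by the legs, trunk assists
  work_central <- c(0, 0, 0.02, 0.02, 0.02, 0.02)
  work_lateral <- c(0.02, 0.05, 0.03, 0.01, 0.22, 0.12, 0.01)
  w_work <- c(work_central, rep(work_lateral, each = 2))
  stopifnot(abs(sum(w_work) - 1) < 1e-12)

  E_basal <- 0.06 * M_basal * w_area # basal skin diffusion, W

  structure(list(
    n_seg = n, names = .SEG_NAMES,
    total_area_m2 = total_area_m2, total_mass_kg = total_mass_kg,
    area_m2 = area, area_frac = area_frac, mass_kg = mass,
    cap_J_K = cap, T_set_C = T_set, Q_basal_W = Q_basal,
    BF_basal_L_h = BF, K_cond_W_K = K_cond,
    basal_skin_loss_W = basal_skin_loss,
    c81_J_K = blood_mass * 3850, T81_set_C = T81_set,
    M_basal_W = M_basal, res_frac = res_frac,
    idx_chest = idx_chest, idx_head = idx_head,
    w_skin_sensor = w_area, w_sweat = w_area, w_dilat = w_area,
    w_constrict = w_area, w_shiver = w_shiver, w_work = w_work,
    eta_evap = eta_evap, h_e_W_m2kPa = h_e_W_m2kPa, E_basal_W = E_basal,
    BF_skin_max_L_h = bf_skin_max_L_h * area_frac,
    SW_max_W = 670, # max sweat rate ~1 L/h water equivalent
    coeffs = list(
      C_dl = 117, S_dl = 7.5, P_dl = 0,   # vasodilatation, L/(h K)
      C_st = 5, S_st = 0.5, P_st = 0,     # vasoconstriction, 1/K
      C_sw = 371.2, S_sw = 33.6, P_sw = 0, # sweating, W/K
      C_ch = 0, S_ch = 0, P_ch = 24.4     # shivering, W/K^2
    )
  ), class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf(
    "<body_model> 20 segments x 4 layers + central blood (81 nodes)\n  area %.2f m2, mass %.1f kg, basal metabolism %.1f W, blood set point %.2f degC\n",
    x$total_area_m2, x$total_mass_kg, x$M_basal_W, x$T81_set_C))
  invisible(x)
}

#' Saturated water-vapour pressure over skin
#'
#' Magnus-type formula, kPa, `T` in degrees Celsius.
#'
#' @param T_C temperature in degC.
#' @return saturation pressure in kPa.
#' @export
p_sat_kPa <- function(T_C) 0.6105 * exp(17.27 * T_C / (237.3 + T_C))
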