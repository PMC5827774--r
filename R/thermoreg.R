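# Passive and active thermoregulation of the 81-node body model: warm/cold
# error signals, the four control laws, their application to perfusion,
# sweating and shivering, and the explicit heat-balance step.

#' Initialize the body state at its set points
#'
#' @param body a [build_body()] model.
#' @return object of class `body_state`: `T_C` (20 x 4 matrix, degC),
#'   `T81_C` (central blood) and the last control outputs.
#' @export
make_body_state <- function(body) {
  structure(list(
    T_C = body$T_set_C, T81_C = body$T81_set_C, time_s = 0,
    DL = 0, ST = 0, SW = 0, CH = 0
  ), class = "body_state")
}

#' Warm and cold error signals of every node
#'
#' `Err = T - T_set`; `Wrm = max(Err, 0)`, `Cld = max(-Err, 0)`. At most one
#' of `Wrm`, `Cld` is positive per node.
#'
#' @param T_C node temperatures (20 x 4 matrix, degC).
#' @param T_set_C set points, same shape.
#' @return list with matrices `Err`, `Wrm`, `Cld`.
#' @export
error_signals <- function(T_C, T_set_C) {
  stopifnot(all(dim(T_C) == dim(T_set_C)))
  Err <- T_C - T_set_C
  list(Err = Err, Wrm = pmax(Err, 0), Cld = pmax(-Err, 0))
}

#' Integrated (weighted) skin signals
#'
#' `Wrms = sum w_i Wrm_i,skin`; `Clds = sum w_i Cld_i,skin`, with
#' skin-sensor weights summing to 1.
#'
#' @param sig output of [error_signals()].
#' @param w skin-sensor weights (length 20, sum 1).
#' @return list with `Wrms` and `Clds`, K.
#' @export
integrated_skin_signals <- function(sig, w) {
  if (abs(sum(w) - 1) > 1e-8) stop("skin-sensor weights must sum to 1", call. = FALSE)
  list(Wrms = sum(w * sig$Wrm[, 4]), Clds = sum(w * sig$Cld[, 4]))
}

#' Control outputs: vasodilatation, vasoconstriction, sweating, shivering
#'
#' The four control laws driven by the head-core (hypothalamic) signals
#' `Err(1), Wrm(1), Cld(1)` and the integrated skin signals:
#' \deqn{DL = C_{dl} Err(1) + S_{dl}(Wrms - Clds) + P_{dl} Wrm(1) Wrms}
#' \deqn{ST = -C_{st} Err(1) - S_{st}(Wrms - Clds) + P_{st} Cld(1) Clds}
#' \deqn{SW = C_{sw} Err(1) + S_{sw}(Wrms - Clds) + P_{sw} Wrm(1) Wrms}
#' \deqn{CH = -C_{ch} Err(1) - S_{ch}(Wrms - Clds) + P_{ch} Cld(1) Clds}
#' all clamped at >= 0.
#'
#' @param sig output of [error_signals()].
#' @param skin output of [integrated_skin_signals()].
#' @param coeffs the `coeffs` list of a [build_body()] model.
#' @param idx_head row index of the head segment.
#' @return list with `DL` (L/h), `ST` (dimensionless), `SW` (W), `CH` (W).
#' @export
control_outputs <- function(sig, skin, coeffs, idx_head = 2L) {
  e1 <- sig$Err[idx_head, 1]
  w1 <- sig$Wrm[idx_head, 1]
  c1 <- sig$Cld[idx_head, 1]
  ds <- skin$Wrms - skin$Clds
  with(coeffs, list(
    DL = max(0, C_dl * e1 + S_dl * ds + P_dl * w1 * skin$Wrms),
    ST = max(0, -C_st * e1 - S_st * ds + P_st * c1 * skin$Clds),
    SW = max(0, C_sw * e1 + S_sw * ds + P_sw * w1 * skin$Wrms),
    CH = max(0, -C_ch * e1 - S_ch * ds + P_ch * c1 * skin$Clds)
  ))
}

#' Apply the control outputs to the passive system
#'
#' Skin perfusion scales with vasodilatation/vasoconstriction,
#' `BF_skin = (BF_basal + w_dl DL) / (1 + w_st ST) * 2^(Err_skin/10)`;
#' muscle perfusion rises with the local work and shivering load (1 L/h per
#' 1.16 W); sweat evaporation is distributed by the sweating weights, also
#' carrying the local `2^(Err/10)` factor, and is capped by the
#' environmental maximum evaporative capacity times the clothing
#' evaporative efficiency; shivering heat is distributed to the muscle
#' nodes by the shivering weights.
#'
#' @param body a [build_body()] model.
#' @param sig output of [error_signals()].
#' @param ctl output of [control_outputs()].
#' @param work_W per-segment exercise heat deposited in muscle, W.
#' @param T_amb_C,rh_pct ambient temperature and relative humidity (set the
#'   evaporative cap).
#' @return list with `BF_L_h` (20 x 4), `E_W` (length 20, capped), `E_max_W`,
#'   `shiver_W` (length 20).
#' @export
apply_controls <- function(body, sig, ctl, work_W = numeric(body$n_seg),
                           T_amb_C = 30, rh_pct = 65) {
  loc <- 2^(sig$Err[, 4] / 10)
  shiver <- body$w_shiver * ctl$CH
  BF <- body$BF_basal_L_h
  BF[, 2] <- BF[, 2] + (work_W + shiver) / 1.16
  BF[, 4] <- pmin((BF[, 4] + body$w_dilat * ctl$DL) /
                    (1 + body$w_constrict * ctl$ST) * loc,
                  body$BF_skin_max_L_h)
  P_air <- rh_pct / 100 * p_sat_kPa(T_amb_C)
  E_max <- pmax(0, body$eta_evap * body$h_e_W_m2kPa *
                  (p_sat_kPa(sig$Err[, 4] + body$T_set_C[, 4]) - P_air) *
                  body$area_m2)
  E <- pmin(body$E_basal_W + body$w_sweat * min(ctl$SW, body$SW_max_W) * loc,
            E_max)
  list(BF_L_h = BF, E_W = E, E_max_W = E_max, shiver_W = shiver)
}

#' Advance the body model one time step
#'
#' Explicit heat-balance step of the 81 node equations: core, muscle and fat
#' balance production, blood exchange and inter-layer conduction; the skin
#' balance replaces the free-surface (R + C) loss with the prescribed
#' clothing boundary flux and keeps the (capped) evaporative loss; the
#' central blood integrates the sum of all blood exchanges, so its
#' discretized balance is conservative to rounding. Respiration is
#' proportional to the total metabolic rate and charged to the chest core;
#' the exercise load above basal goes 85% to muscle by the work-distribution
#' weights and 15% to the cores.
#'
#' @param body a [build_body()] model.
#' @param state a [make_body_state()] state.
#' @param q_skin_W_m2 inward heat flux at the skin surface: scalar or
#'   per-segment vector, W/m^2.
#' @param met_W_m2 total metabolic rate per unit body area (>= basal).
#' @param dt_s time step, s.
#' @param T_amb_C,rh_pct ambient condition for the evaporative cap.
#' @return the advanced `body_state`.
#' @export
step_body <- function(body, state, q_skin_W_m2 = 0, met_W_m2 = 58.2,
                      dt_s = 0.1, T_amb_C = 30, rh_pct = 65) {
  stopifnot(inherits(body, "body_model"), inherits(state, "body_state"), dt_s > 0)
  sig <- error_signals(state$T_C, body$T_set_C)
  skin <- integrated_skin_signals(sig, body$w_skin_sensor)
  ctl <- control_outputs(sig, skin, body$coeffs, body$idx_head)
  M_total <- met_W_m2 * body$total_area_m2
  extra <- max(0, M_total - body$M_basal_W)
  work <- 0.85 * extra * body$w_work
  core_extra <- 0.15 * extra * body$Q_basal_W[, 1] / sum(body$Q_basal_W[, 1])
  act <- apply_controls(body, sig, ctl, work, T_amb_C, rh_pct)

  Res <- numeric(body$n_seg)
  Res[body$idx_chest] <- body$res_frac * M_total

  T <- state$T_C
  B <- BLOOD_HEAT_EQ * act$BF_L_h * (T - state$T81_C)
  D1 <- body$K_cond_W_K[, 1] * (T[, 1] - T[, 2])
  D2 <- body$K_cond_W_K[, 2] * (T[, 2] - T[, 3])
  D3 <- body$K_cond_W_K[, 3] * (T[, 3] - T[, 4])
  Q <- body$Q_basal_W
  Q[, 1] <- Q[, 1] + core_extra
  Q[, 2] <- Q[, 2] + work + act$shiver_W

  dT <- cbind(
    (Q[, 1] - B[, 1] - D1 - Res) / body$cap_J_K[, 1],
    (Q[, 2] - B[, 2] + D1 - D2) / body$cap_J_K[, 2],
    (Q[, 3] - B[, 3] + D2 - D3) / body$cap_J_K[, 3],
    (Q[, 4] - B[, 4] + D3 + q_skin_W_m2 * body$area_m2 - act$E_W) /
      body$cap_J_K[, 4]
  )
  if (any(abs(dT) * dt_s > 5)) {
    stop(sprintf("body model unstable at t = %.1f s: max |dT| = %.2f K in one step",
                 state$time_s, max(abs(dT)) * dt_s), call. = FALSE)
  }
  state$T_C <- T + dT * dt_s
  state$T81_C <- state$T81_C + sum(B) / body$c81_J_K * dt_s
  state$time_s <- state$time_s + dt_s
  state$DL <- ctl$DL; state$ST <- ctl$ST; state$SW <- ctl$SW; state$CH <- ctl$CH
  state
}

#' Area-weighted mean skin temperature
#'
#' @param body a [build_body()] model.
#' @param state a [make_body_state()] state.
#' @return mean skin temperature, degC.
#' @export
mean_skin_temperature <- function(body, state) {
  unname(sum(body$area_frac * state$T_C[, 4]))
}

#' Deep-core reporting temperature
#'
#' The model's core-temperature endpoint. By default the central blood
#' temperature (the convective pool every node exchanges with); the head
#' core is exposed as an alternative reporting node.
#'
#' @param body a [build_body()] model.
#' @param state a [make_body_state()] state.
#' @param which `"blood"` (default) or `"head_core"`.
#' @return core temperature, degC.
#' @export
core_temperature <- function(body, state, which = c("blood", "head_core")) {
  which <- match.arg(which)
  if (which == "blood") unname(state$T81_C)
  else unname(state$T_C[body$idx_head, 1])
}
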