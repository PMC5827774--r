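# Couples the clothing/air-gap solver to the body model over the exposure
# and cooling phases, computes the heat-strain endpoints, and runs the
# parametric sweeps over radiant intensity and gap size.

#' Build a fully resolved scenario configuration
#'
#' All knobs of a coupled run with their defaults: the bench configuration
#' (nominal 8.5 kW/m^2, 300 s exposure + 2500 s cooling, 30 degC / 65% RH
#' ambient, 6.4 mm vertical gap), a working metabolic rate of 290 W/m^2 and
#' the 38.5 degC core / 44 degC skin thresholds.
#'
#' @param nominal_flux_kW_m2 nominal incident flux.
#' @param exposure_s,cooling_s phase durations, s.
#' @param ambient_C,rh_pct ambient temperature (degC) and relative humidity.
#' @param gap_mm air-gap size.
#' @param metabolic_W_m2 total metabolic rate during the exposure (work)
#'   phase.
#' @param metabolic_cooling_W_m2 metabolic rate during the cooling phase:
#'   the subject recovers at rest (default 58.2 W/m^2, 1 met).
#' @param safe_core_C,burn_skin_C strain and skin-burn thresholds, degC.
#' @param source_temp_K,source_emissivity,source_area_m2,sample_area_m2,gas_emissivity,shell_ambient_viewfactor,char_length_m
#'   heat-source / surroundings parameters (see [radiant_scenario()]).
#' @param cavity_height_m,gap_kappa_m1,orientation air-gap parameters (see
#'   [air_gap()]; the default `NULL` cavity height uses the gap size).
#' @param skin_emissivity skin/sensor emissivity.
#' @param evap_efficiency clothing evaporative efficiency (see
#'   [build_body()]).
#' @param dx_fabric_m,dx_gap_m,dt_s,tol_K,max_iter numerics block.
#' @param layers clothing ensemble (default [turnout_ensemble()]).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(nominal_flux_kW_m2 = 8.5, exposure_s = 300,
                            cooling_s = 2500, ambient_C = 30, rh_pct = 65,
                            gap_mm = 6.4, metabolic_W_m2 = 290,
                            metabolic_cooling_W_m2 = 58.2,
                            safe_core_C = 38.5, burn_skin_C = 44,
                            source_temp_K = 733.15, source_emissivity = 0.98,
                            source_area_m2 = 0.0144, sample_area_m2 = 0.01,
                            gas_emissivity = 0.02,
                            shell_ambient_viewfactor = 1.0,
                            char_length_m = 0.1, cavity_height_m = NULL,
                            gap_kappa_m1 = 5, orientation = "vertical",
                            skin_emissivity = 0.9, evap_efficiency = 1.0,
                            dx_fabric_m = 5e-6,
                            dx_gap_m = 1e-4, dt_s = 0.1, tol_K = 1e-6,
                            max_iter = 100L, layers = turnout_ensemble()) {
  stopifnot(exposure_s > 0, cooling_s > 0, gap_mm >= 0,
            safe_core_C > 35, burn_skin_C > 35, dt_s > 0)
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

.cfg_scenario <- function(cfg) {
  radiant_scenario(
    T_hs_K = cfg$source_temp_K, eps_hs = cfg$source_emissivity,
    A_hs_m2 = cfg$source_area_m2, A_fab_m2 = cfg$sample_area_m2,
    eps_shell = cfg$layers[[1]]$emissivity, eps_g = cfg$gas_emissivity,
    F_shell_amb = cfg$shell_ambient_viewfactor,
    T_amb_K = C_to_K(cfg$ambient_C), t_exp_s = cfg$exposure_s,
    nominal_flux_W_m2 = cfg$nominal_flux_kW_m2 * 1000,
    char_length_m = cfg$char_length_m)
}

#' Run a coupled clothing + body simulation
#'
#' Lock-step coupling at the solver time step: each step the clothing solver
#' receives the current area-weighted mean skin temperature as its inner
#' boundary, and the body model receives the resulting skin surface flux on
#' every (covered) segment. The phase switches from exposure to cooling at
#' `exposure_s`. The run is fully deterministic.
#'
#' @param cfg a [scenario_config()].
#' @param progress print a line at phase switches and threshold crossings.
#' @param body optional [build_body()] model (default: built from the
#'   config's evaporative efficiency).
#' @return list of class `strain_run`: `series` (data.frame sampled every
#'   step: time_s, T_core_C, T_skin_mean_C, T_blood_C, T_shell_surface_K,
#'   T_liner_inner_K, Ra_gap, Nu_gap, q_skin_W_m2, SW_W, CH_W), `metrics`
#'   (see [strain_metrics()]), `config` and the calibrated scenario.
#' @export
run_scenario <- function(cfg, progress = FALSE, body = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  scen <- .cfg_scenario(cfg)
  gap <- air_gap(cfg$gap_mm, cfg$cavity_height_m, cfg$gap_kappa_m1,
                 cfg$orientation)
  grid <- build_grid(cfg$layers, gap, cfg$dx_fabric_m, cfg$dx_gap_m)
  if (is.null(body)) body <- build_body(eta_evap = cfg$evap_efficiency)
  cstate <- make_clothing_state(grid, scen$T_amb_K)
  bstate <- make_body_state(body)
  eps_liner <- cfg$layers[[length(cfg$layers)]]$emissivity

  nt <- as.integer(round((cfg$exposure_s + cfg$cooling_s) / cfg$dt_s))
  out <- matrix(NA_real_, nt + 1L, 11)
  colnames(out) <- c("time_s", "T_core_C", "T_skin_mean_C", "T_blood_C",
                     "T_shell_surface_K", "T_liner_inner_K", "Ra_gap",
                     "Nu_gap", "q_skin_W_m2", "SW_W", "CH_W")
  record <- function(k) {
    out[k, ] <<- c(bstate$time_s, core_temperature(body, bstate),
                   mean_skin_temperature(body, bstate), bstate$T81_C,
                   cstate$T_K[1], cstate$T_K[grid$idx_liner], cstate$Ra,
                   cstate$Nu, cstate$q_skin_W_m2, bstate$SW, bstate$CH)
  }
  record(1L)
  conv_prev <- FALSE
  core_above <- FALSE
  skin_above <- FALSE
  for (k in seq_len(nt)) {
    T_skin_K <- C_to_K(mean_skin_temperature(body, bstate))
    cstate <- clothing_step(cstate, grid, scen, gap, T_skin_K, cfg$dt_s,
                            eps_skin = cfg$skin_emissivity,
                            eps_liner = eps_liner, tol_K = cfg$tol_K,
                            maxit = cfg$max_iter)
    met <- if (cstate$time_s <= cfg$exposure_s) cfg$metabolic_W_m2
           else cfg$metabolic_cooling_W_m2
    bstate <- step_body(body, bstate, cstate$q_skin_W_m2, met,
                        cfg$dt_s, cfg$ambient_C, cfg$rh_pct)
    record(k + 1L)
    if (progress) {
      if (cstate$convection_active != conv_prev) {
        message(sprintf("t = %.1f s: gap convection %s (Ra = %.0f)",
                        cstate$time_s,
                        if (cstate$convection_active) "on" else "off", cstate$Ra))
        conv_prev <- cstate$convection_active
      }
      if (abs(cstate$time_s - cfg$exposure_s) < cfg$dt_s / 2) {
        message(sprintf("t = %.1f s: cooling phase begins", cstate$time_s))
      }
      core_now <- core_temperature(body, bstate)
      if ((core_now >= cfg$safe_core_C) != core_above) {
        core_above <- core_now >= cfg$safe_core_C
        message(sprintf("t = %.1f s: core %s the %.1f degC strain threshold",
                        cstate$time_s, if (core_above) "crosses" else "recovers below",
                        cfg$safe_core_C))
      }
      skin_now <- mean_skin_temperature(body, bstate)
      if ((skin_now >= cfg$burn_skin_C) != skin_above) {
        skin_above <- skin_now >= cfg$burn_skin_C
        message(sprintf("t = %.1f s: mean skin %s the %.1f degC burn threshold",
                        cstate$time_s, if (skin_above) "crosses" else "falls below",
                        cfg$burn_skin_C))
      }
    }
  }
  series <- as.data.frame(out)
  series$time_s <- seq(0L, nt) * cfg$dt_s # exact grid, no accumulation drift
  metrics <- strain_metrics(series$time_s, series$T_core_C,
                            series$T_skin_mean_C, cfg$exposure_s,
                            cfg$safe_core_C, cfg$burn_skin_C)
  structure(list(series = series, metrics = metrics, config = cfg,
                 scenario = scen, grid_nodes = grid$n_nodes), class = "strain_run")
}

#' Safe exposure time: first upward crossing of the core threshold
#'
#' Linearly interpolated between samples; `NA` when the threshold is never
#' exceeded.
#'
#' @param time_s sample times (ascending from 0).
#' @param core_C core-temperature series, degC.
#' @param threshold_C core threshold (default 38.5 degC).
#' @return crossing time in s, or `NA`.
#' @export
safe_exposure_time <- function(time_s, core_C, threshold_C = 38.5) {
  stopifnot(length(time_s) == length(core_C), length(time_s) > 0)
  above <- core_C >= threshold_C
  if (above[1]) return(time_s[1])
  i <- which(!above[-length(above)] & above[-1])
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  f <- (threshold_C - core_C[i]) / (core_C[i + 1] - core_C[i])
  time_s[i] + f * (time_s[i + 1] - time_s[i])
}

#' Effective cooling time: recovery below the core threshold
#'
#' Time elapsed after the end of exposure until the last downward crossing
#' of the threshold (linearly interpolated). `NA` when the core never
#' exceeded the threshold; `Inf` (a "longer than the simulated cooling"
#' sentinel) when it is still above the threshold at the end of the series.
#'
#' @inheritParams safe_exposure_time
#' @param t_exp_s end of the exposure phase, s.
#' @return elapsed time in s, `NA`, or `Inf`.
#' @export
effective_cooling_time <- function(time_s, core_C, threshold_C = 38.5, t_exp_s = 300) {
  stopifnot(length(time_s) == length(core_C), length(time_s) > 0)
  above <- core_C >= threshold_C
  if (!any(above)) return(NA_real_)
  n <- length(core_C)
  if (above[n]) return(Inf)
  i <- which(above[-n] & !above[-1])
  i <- i[length(i)]
  f <- (core_C[i] - threshold_C) / (core_C[i] - core_C[i + 1])
  max(0, time_s[i] + f * (time_s[i + 1] - time_s[i]) - t_exp_s)
}

#' Skin-burn monitor against the 44 degC threshold
#'
#' @param time_s sample times.
#' @param skin_C mean-skin-temperature series, degC.
#' @param threshold_C burn threshold (default 44 degC, boundary inclusive).
#' @return list: `flag` (any sample >= threshold), `first_crossing_s`,
#'   `supra_duration_s` (time spent at or above the threshold).
#' @export
burn_monitor <- function(time_s, skin_C, threshold_C = 44) {
  above <- skin_C >= threshold_C
  if (!any(above)) {
    return(list(flag = FALSE, first_crossing_s = NA_real_, supra_duration_s = 0))
  }
  dt <- diff(time_s)
  list(flag = TRUE,
       first_crossing_s = time_s[which(above)[1]],
       supra_duration_s = sum(dt[above[-length(above)]]))
}

#' Heat-strain endpoint summary of a run
#'
#' @inheritParams safe_exposure_time
#' @param skin_C mean-skin series, degC.
#' @param t_exp_s end of exposure, s.
#' @param safe_core_C,burn_skin_C thresholds.
#' @return list: `safe_exposure_time_s`, `effective_cooling_time_s`,
#'   `dangerous_zone_s` (start/end or `NULL`), `peak_core_C` (+ time),
#'   `peak_skin_C` (+ time), `burn` (see [burn_monitor()]).
#' @export
strain_metrics <- function(time_s, core_C, skin_C, t_exp_s = 300,
                           safe_core_C = 38.5, burn_skin_C = 44) {
  set_t <- safe_exposure_time(time_s, core_C, safe_core_C)
  ect <- effective_cooling_time(time_s, core_C, safe_core_C, t_exp_s)
  zone <- NULL
  if (!is.na(set_t) && is.finite(ect)) zone <- c(start = set_t, end = t_exp_s + ect)
  if (!is.na(set_t) && is.infinite(ect)) zone <- c(start = set_t, end = Inf)
  ic <- which.max(core_C); is <- which.max(skin_C)
  list(
    safe_exposure_time_s = set_t,
    effective_cooling_time_s = ect,
    dangerous_zone_s = zone,
    peak_core_C = core_C[ic], peak_core_time_s = time_s[ic],
    peak_skin_C = skin_C[is], peak_skin_time_s = time_s[is],
    burn = burn_monitor(time_s, skin_C, burn_skin_C)
  )
}

#' Parametric sweep over radiant flux or gap size
#'
#' Runs one coupled simulation per axis value (serial, deterministic order)
#' and collects the strain endpoints. A failed run is recorded with its
#' error message and the sweep continues.
#'
#' @param cfg base [scenario_config()].
#' @param axis `"flux"` (values in kW/m^2) or `"gap"` (values in mm).
#' @param values axis values; defaults: 5, 8.5, 11, 14, 17, 20, 23 kW/m^2
#'   for flux, 0, 3, 6, 9, 12, 15, 18, 21, 24 mm for gap.
#' @param keep_series keep each run's full time series (in a `runs` attr).
#' @return data.frame, one row per value: axis value, safe exposure time,
#'   effective cooling time, peak core and skin temperatures (+ times), burn
#'   flag, convection flags (`conv_exposure`: gap Ra exceeded 1000 at any
#'   time during exposure; `conv_cooling`: it still did beyond the first
#'   60 s of cooling, i.e. convection persisted rather than merely decaying
#'   across the phase switch), and the error message (NA when the run
#'   succeeded).
#' @export
sweep_scenarios <- function(cfg, axis = c("flux", "gap"), values = NULL,
                            keep_series = FALSE) {
  axis <- match.arg(axis)
  if (is.null(values)) {
    values <- if (axis == "flux") c(5, 8.5, 11, 14, 17, 20, 23)
              else c(0, 3, 6, 9, 12, 15, 18, 21, 24)
  }
  rows <- vector("list", length(values))
  runs <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfg_i <- cfg
    if (axis == "flux") cfg_i$nominal_flux_kW_m2 <- values[i]
    else cfg_i$gap_mm <- values[i]
    rows[[i]] <- tryCatch({
      r <- run_scenario(cfg_i)
      if (keep_series) runs[[i]] <- r
      m <- r$metrics
      s <- r$series
      exp_rows <- s$time_s <= cfg$exposure_s
      data.frame(
        value = values[i],
        safe_exposure_time_s = m$safe_exposure_time_s,
        effective_cooling_time_s = m$effective_cooling_time_s,
        peak_core_C = m$peak_core_C, peak_core_time_s = m$peak_core_time_s,
        peak_skin_C = m$peak_skin_C, peak_skin_time_s = m$peak_skin_time_s,
        burn_flag = m$burn$flag,
        conv_exposure = any(s$Ra_gap[exp_rows] > 1000),
        conv_cooling = any(s$Ra_gap[s$time_s > cfg$exposure_s + 60] > 1000),
        error = NA_character_)
    }, error = function(e) {
      data.frame(value = values[i], safe_exposure_time_s = NA_real_,
                 effective_cooling_time_s = NA_real_, peak_core_C = NA_real_,
                 peak_core_time_s = NA_real_, peak_skin_C = NA_real_,
                 peak_skin_time_s = NA_real_, burn_flag = NA,
                 conv_exposure = NA, conv_cooling = NA,
                 error = conditionMessage(e))
    })
  }
  res <- do.call(rbind, rows)
  names(res)[1] <- if (axis == "flux") "flux_kW_m2" else "gap_mm"
  if (keep_series) attr(res, "runs") <- runs
  res
}
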