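# Driver for the Crank-Nicolson clothing/air-gap step (compiled kernel) and
# the solver state it advances.

#' Initialize the clothing solver state
#'
#' All clothing and gap nodes start uniform at the ambient temperature.
#'
#' @param grid a [build_grid()] grid.
#' @param T_init_K initial (ambient) temperature, K.
#' @return object of class `clothing_state`.
#' @export
make_clothing_state <- function(grid, T_init_K) {
  structure(list(
    T_K = rep(T_init_K, grid$n_nodes), time_s = 0, phase = "exposure",
    iters = 0L, max_change_K = 0, Ra = 0, Nu = 1, convection_active = FALSE,
    q_skin_W_m2 = 0, diag = NULL
  ), class = "clothing_state")
}

#' Advance the clothing/air-gap solver one time step
#'
#' One Crank-Nicolson step of the transient conduction-radiation problem:
#' temperature-dependent conductivities, in-depth Beer absorption of the
#' incident source radiation (exposure phase), the convective + radiative
#' outer boundary for the current phase, liner-to-skin radiation attenuated
#' across the gap, and Rayleigh-gated gap convection (the gap air
#' conductivity is multiplied by the enclosure Nusselt number, which in
#' quasi-steady state equals the film-coefficient exchange
#' `h_gap = Nu k_air / L`). Nonlinear terms are lagged and swept until the
#' largest temperature change is below `tol_K`.
#'
#' @param state a [make_clothing_state()] state.
#' @param grid a [build_grid()] grid.
#' @param scenario a [radiant_scenario()].
#' @param gap an [air_gap()].
#' @param T_skin_K skin surface temperature (Dirichlet boundary), K.
#' @param dt_s time step, s.
#' @param eps_skin skin/sensor emissivity for the gap radiation.
#' @param eps_liner liner inner-surface emissivity.
#' @param tol_K sweep convergence tolerance, K.
#' @param maxit sweep cap (warning when hit).
#' @param h_conv_override fixed outer convection coefficient, W/(m^2 K),
#'   bypassing the plate correlation (used for verification against analytic
#'   solutions; a very large value clamps the outer surface to ambient).
#' @return the advanced `clothing_state`; `q_skin_W_m2` holds the net flux
#'   crossing the skin surface (positive inward).
#' @export
clothing_step <- function(state, grid, scenario, gap, T_skin_K, dt_s = 0.1,
                          eps_skin = 0.9, eps_liner = 0.9,
                          tol_K = 1e-6, maxit = 100L, h_conv_override = NULL) {
  stopifnot(inherits(state, "clothing_state"), dt_s > 0)
  exposure <- state$time_s < scenario$t_exp_s
  T_shell <- state$T_K[1]
  h_conv <- if (is.null(h_conv_override)) {
    free_convection_h(T_shell, scenario$T_amb_K, scenario$char_length_m)
  } else h_conv_override
  # gap convection state from the start-of-step temperatures
  Ra <- 0; Nu <- 1; active <- FALSE
  sigma_eff <- 0
  if (grid$has_gap) {
    T_liner <- state$T_K[grid$idx_liner]
    L_air <- grid$L_total_m - grid$L_fab_m
    Ra <- rayleigh_number(T_liner, T_skin_K, L_air,
                          T_props_K = scenario$T_amb_K)
    active <- Ra > gap$ra_threshold
    if (active) {
      T_film <- min(max((T_liner + T_skin_K) / 2, 250), 800)
      Nu <- enclosure_nusselt(min(Ra, 1e10), air_properties(T_film)$Pr,
                              gap$height_m, L_air)
    }
    sigma_eff <- SIGMA_SB / (1 / eps_liner + 1 / eps_skin - 1)
  }
  out <- .cn_clothing_step(
    state$T_K, grid$dx_m, grid$mat, grid$k_scale, grid$cv_J_m2K,
    grid$frac_src, grid$frac_src_skin, grid$frac_gap, grid$frac_gap_skin,
    grid$idx_liner, grid$has_gap, T_skin_K, dt_s, exposure, h_conv,
    scenario$T_amb_K, scenario$eps_shell, scenario$F_shell_amb, scenario$eps_g,
    scenario$F_hs_shell, scenario$eps_hs, scenario$T_hs_K,
    scenario$A_hs_m2 / scenario$A_fab_m2, sigma_eff, Nu, tol_K, maxit)
  if (out$diverged) {
    stop(sprintf(
      "clothing solver diverged at t = %.1f s (phase %s): temperature outside (200, 1500) K; T range [%.1f, %.1f] K",
      state$time_s, if (exposure) "exposure" else "cooling",
      min(out$T), max(out$T)), call. = FALSE)
  }
  if (!out$converged) {
    warning(sprintf("sweep cap %d hit at t = %.1f s (max change %.2e K)",
                    maxit, state$time_s, out$max_change), call. = FALSE)
  }
  state$T_K <- out$T
  state$time_s <- state$time_s + dt_s
  state$phase <- if (exposure) "exposure" else "cooling"
  state$iters <- out$iters
  state$max_change_K <- out$max_change
  state$Ra <- Ra; state$Nu <- Nu; state$convection_active <- active
  state$q_skin_W_m2 <- out$q_skin
  state$diag <- out[c("q_rad", "q_gap", "surf_loss", "conv_loss", "rad_loss",
                      "absorbed_src", "absorbed_gap", "q_cond_skin")]
  state
}

#' Net flux crossing the skin surface
#'
#' The quantity a skin-simulant sensor records: conduction across the
#' innermost interval plus the gap radiation attenuated by Beer's law (plus
#' any source radiation transmitted through the whole stack), positive
#' inward. Evaluated at the Crank-Nicolson mid-point of the last step.
#'
#' @param state a [clothing_state][make_clothing_state()] after at least one
#'   [clothing_step()].
#' @return flux in W/m^2.
#' @export
skin_surface_flux <- function(state) {
  stopifnot(inherits(state, "clothing_state"))
  state$q_skin_W_m2
}
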