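# Shared fixtures. Heavy coupled runs are memoized so the acceptance blocks
# can share the same sweeps instead of recomputing them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a fast, coarse configuration for behavioural tests (not for acceptance)
quick_config <- function(...) {
  defaults <- list(exposure_s = 60, cooling_s = 60, dx_fabric_m = 2e-5,
                   dx_gap_m = 4e-4, dt_s = 0.1)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

nominal_run <- function() memo("nominal", run_scenario(scenario_config()))
flux_sweep <- function() memo("flux", sweep_scenarios(scenario_config(), axis = "flux",
                                                      keep_series = TRUE))
gap_sweep <- function() memo("gap", sweep_scenarios(scenario_config(), axis = "gap"))

# independent steady-state oracle for a slab with a convective outer boundary
# and a fixed inner temperature: shooting on the flux with dT/dx = -q/k(T)
steady_slab_oracle <- function(layer, h, T_amb, T_skin, n = 4000) {
  profile_end <- function(q) {
    T0 <- T_amb + q / h # surface temperature consistent with the flux
    L <- layer$thickness_m
    dx <- L / n
    T <- T0
    for (i in seq_len(n)) T <- T - q / fabric_conductivity(layer, T) * dx
    T
  }
  lo <- -5000; hi <- 5000
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (profile_end(mid) > T_skin) lo <- mid else hi <- mid
  }
  q <- (lo + hi) / 2
  list(q = q, T0 = T_amb + q / h)
}
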