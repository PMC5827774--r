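# Grid construction, gap correlations, and the Crank-Nicolson clothing/gap
# solver against analytic oracles and conservation checks.

test_that("grid discretizes the packaged ensemble at the default steps", {
  grid <- build_grid(turnout_ensemble(), air_gap(6.4))
  # 0.63/0.91/2.21 mm at 5 um -> 126 + 182 + 442 fabric intervals
  expect_equal(sum(grid$mat == 1), 126)
  expect_equal(sum(grid$mat == 2), 182)
  expect_equal(sum(grid$mat == 3), 442)
  expect_equal(grid$idx_liner, 751)
  expect_equal(sum(grid$mat == 0), 64) # 6.4 mm at 0.1 mm
  expect_equal(grid$n_nodes, 815)
  # zero gap ends at the liner inner surface
  g0 <- build_grid(turnout_ensemble(), air_gap(0))
  expect_equal(g0$n_nodes, 751)
  expect_false(g0$has_gap)
  expect_error(build_grid(turnout_ensemble(), air_gap(6.4), dx_fabric_m = 1e-3),
               "exceeds")
})

test_that("Rayleigh number follows g beta dT L^3 / (alpha nu)", {
  expect_equal(rayleigh_number(310, 310, 0.006), 0)
  expect_equal(rayleigh_number(350, 310, 0), 0)
  # direct evaluation with the packaged air properties at the film temp
  a <- air_properties(340)
  expect_equal(rayleigh_number(390, 290, 0.006),
               9.80665 / 340 * 100 * 0.006^3 / (a$alpha_m2_s * a$nu_m2_s))
  # exact 8x scaling when L doubles at fixed dT and property state
  r1 <- rayleigh_number(390, 290, 0.006, T_props_K = 340)
  r2 <- rayleigh_number(390, 290, 0.012, T_props_K = 340)
  expect_equal(r2 / r1, 8)
})

test_that("enclosure Nusselt correlation has the printed two-branch form", {
  expect_identical(enclosure_nusselt(500, 0.7, 0.12, 0.006), 1.0)
  expect_identical(enclosure_nusselt(1000, 0.7, 0.12, 0.006), 1.0) # tie -> conduction
  # direct evaluation of the convective branch
  expect_equal(enclosure_nusselt(1e4, 0.7, 0.12, 0.006),
               0.22 * (0.7 / 0.9 * 1e4)^0.28 * 20^(-0.25))
  expect_equal(enclosure_nusselt(1e4, 0.7, 0.12, 0.006), 1.28, tolerance = 1e-2)
  Ras <- c(2e3, 1e4, 1e5, 1e7, 1e9)
  Nus <- vapply(Ras, enclosure_nusselt, 0, Pr = 0.7, H = 0.12, L_air = 0.006)
  expect_true(all(diff(Nus) > 0))
  expect_true(all(Nus >= 1))
  expect_error(enclosure_nusselt(1e11, 0.7, 0.12, 0.006), "correlation")
})

test_that("lumped gap interface fluxes follow the Beer-attenuated exchange", {
  gap <- air_gap(6.4)
  fl <- gap_interface_fluxes(gap, 320, 320, 0)
  expect_equal(fl$liner_W_m2, 0); expect_equal(fl$skin_W_m2, 0)
  # kappa = 0: the skin receives exactly the radiation plus the film exchange
  gap0 <- air_gap(6.4, kappa_air_m1 = 0)
  fl0 <- gap_interface_fluxes(gap0, 400, 310, 500, Nu = 1)
  expect_equal(fl0$skin_W_m2 - fl0$h_gap_W_m2K * 90, 500)
  expect_equal(fl0$absorbed_W_m2, 0)
  # default gap: transmission factor exp(-5 * 0.0064)
  fl1 <- gap_interface_fluxes(gap, 400, 310, 500, Nu = 1)
  expect_equal((fl1$skin_W_m2 - fl1$h_gap_W_m2K * 90) / 500, exp(-0.032))
  expect_equal(fl1$absorbed_W_m2, 500 * (1 - exp(-0.032)))
  expect_error(gap_interface_fluxes(air_gap(0), 400, 310, 500), "perfect thermal contact")
})

test_that("an isothermal equilibrium state is a fixed point of the step", {
  scen <- radiant_scenario(T_amb_K = 310)
  gap <- air_gap(6.4)
  grid <- build_grid(turnout_ensemble(), gap, dx_fabric_m = 2e-5, dx_gap_m = 4e-4)
  st <- make_clothing_state(grid, 310)
  st$time_s <- scen$t_exp_s + 1 # cooling phase: no source
  st2 <- clothing_step(st, grid, scen, gap, T_skin_K = 310)
  expect_lt(max(abs(st2$T_K - 310)), 1e-12)
  expect_lt(abs(st2$q_skin_W_m2), 1e-12)
})

test_that("two-material slab relaxes to the series-resistance steady state", {
  # light, fast-diffusing synthetic layers; transparent (kappa = 0)
  A <- fabric_layer("A", 1e-3, 100, 100, 0.04, reflectivity = 0, transmissivity = 1)
  B <- fabric_layer("B", 2e-3, 100, 100, 0.08, reflectivity = 0, transmissivity = 1)
  scen <- radiant_scenario(T_amb_K = 300, eps_shell = 0)
  gap <- air_gap(0)
  grid <- build_grid(list(A, B), gap, dx_fabric_m = 5e-5)
  st <- make_clothing_state(grid, 300)
  st$time_s <- scen$t_exp_s + 1
  for (i in 1:400) {
    st$time_s <- scen$t_exp_s + 1
    st <- clothing_step(st, grid, scen, gap, T_skin_K = 302, dt_s = 0.05,
                        h_conv_override = 1e8)
  }
  # oracle: series resistance with conductivities at the local mean temps
  kA <- fabric_conductivity(A, 300.3); kB <- fabric_conductivity(B, 301.3)
  RA <- 1e-3 / kA; RB <- 2e-3 / kB
  q <- (302 - 300) / (RA + RB)
  T_iface <- 300 + q * RA
  i_iface <- which.min(abs(grid$x_m - 1e-3))
  expect_equal(st$T_K[i_iface], T_iface, tolerance = 2e-5)
  expect_equal(-st$q_skin_W_m2, q, tolerance = 5e-3) # heat flows outward
})

test_that("solver matches the analytic transient slab solution", {
  # both faces clamped at 302 K, uniform 300 K start, near-constant k
  L <- 2e-3
  A <- fabric_layer("slab", L, 421, 1570, 0.047, reflectivity = 0, transmissivity = 1)
  scen <- radiant_scenario(T_amb_K = 302, eps_shell = 0)
  gap <- air_gap(0)
  grid <- build_grid(list(A), gap, dx_fabric_m = 1e-5)
  st <- make_clothing_state(grid, 300)
  k_mid <- fabric_conductivity(A, 301)
  alpha <- k_mid / (421 * 1570)
  series_T <- function(x, t) {
    n <- seq(1, 399, by = 2)
    302 - 2 * sum(4 / (n * pi) * sin(n * pi * x / L) * exp(-n^2 * pi^2 * alpha * t / L^2))
  }
  dt <- 0.05
  for (step in seq_len(as.integer(30 / dt))) {
    st$time_s <- scen$t_exp_s + 1
    st <- clothing_step(st, grid, scen, gap, T_skin_K = 302, dt_s = dt,
                        h_conv_override = 1e8)
    t_now <- step * dt
    if (t_now %in% c(5, 10, 20, 30)) {
      for (xi in c(0.25, 0.5, 0.75) * L) {
        i <- which.min(abs(grid$x_m - xi))
        expect_equal(st$T_K[i], series_T(grid$x_m[i], t_now),
                     tolerance = 0.005 * 2 / 300, # 0.5% of the 2 K span
                     info = sprintf("t=%g x=%g", t_now, xi))
      }
    }
  }
})

test_that("each step closes the discrete energy budget to 0.1%", {
  scen <- radiant_scenario(nominal_flux_W_m2 = 8500)
  gap <- air_gap(6.4)
  grid <- build_grid(turnout_ensemble(), gap)
  st <- make_clothing_state(grid, scen$T_amb_K)
  N <- grid$n_nodes
  for (i in 1:200) {
    T_old <- st$T_K
    st <- clothing_step(st, grid, scen, gap, T_skin_K = 308.15)
    d <- st$diag
    stored <- sum(grid$cv_J_m2K[1:(N - 1)] * (st$T_K[1:(N - 1)] - T_old[1:(N - 1)]))
    budget <- 0.1 * (d$absorbed_src + d$absorbed_gap - d$q_gap - d$surf_loss -
                       d$q_cond_skin)
    throughput <- 0.1 * (abs(d$q_rad) + abs(d$surf_loss) + abs(d$q_cond_skin) + 1)
    expect_lt(abs(stored - budget) / throughput, 1e-3)
  }
})

test_that("halving both steps changes the 300 s skin flux by < 1%", {
  scen <- radiant_scenario(nominal_flux_W_m2 = 8500)
  gap <- air_gap(6.4)
  run_to_300 <- function(dxf, dxg, dt) {
    grid <- build_grid(turnout_ensemble(), gap, dx_fabric_m = dxf, dx_gap_m = dxg)
    st <- make_clothing_state(grid, scen$T_amb_K)
    for (i in seq_len(as.integer(300 / dt))) {
      st <- clothing_step(st, grid, scen, gap, T_skin_K = 308.15, dt_s = dt)
    }
    st$q_skin_W_m2
  }
  q_base <- run_to_300(5e-6, 1e-4, 0.1)
  q_fine <- run_to_300(2.5e-6, 5e-5, 0.05)
  expect_lt(abs(q_fine - q_base) / q_base, 0.01)
})

test_that("a hotter source raises the liner temperature trace pointwise", {
  gap <- air_gap(6.4)
  grid <- build_grid(turnout_ensemble(), gap, dx_fabric_m = 2e-5, dx_gap_m = 4e-4)
  trace_liner <- function(T_hs) {
    scen <- radiant_scenario(T_hs_K = T_hs, F_hs_shell = 0.4)
    st <- make_clothing_state(grid, scen$T_amb_K)
    out <- numeric(600)
    for (i in 1:600) {
      st <- clothing_step(st, grid, scen, gap, T_skin_K = 307)
      out[i] <- st$T_K[grid$idx_liner]
    }
    out
  }
  expect_true(all(trace_liner(800) >= trace_liner(733.15)))
})
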