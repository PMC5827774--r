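# Strain metrics against brute-force oracles, and the coupled driver's
# determinism on a coarse configuration.

test_that("safe exposure time interpolates the first upward crossing", {
  t <- seq(0, 600, by = 0.1)
  expect_true(is.na(safe_exposure_time(t, rep(37, length(t)))))
  ramp <- 37 + 3 * t / 600
  expect_equal(safe_exposure_time(t, ramp, 38.5), 300)
  # multi-crossing series: interpolation agrees with a dense re-sampled scan
  set.seed(7)
  for (rep in 1:10) {
    core <- 38.5 + 0.8 * sin(t / 60 + rnorm(1)) + 0.3 * sin(t / 17 + rnorm(1))
    found <- safe_exposure_time(t, core, 38.5)
    td <- seq(0, 600, by = 0.001)
    cd <- approx(t, core, td)$y
    brute <- if (cd[1] >= 38.5) 0 else td[which(cd >= 38.5)[1]]
    if (is.na(found)) {
      expect_true(all(cd < 38.5))
    } else {
      expect_lt(abs(found - brute), 0.05) # dt/2 of the dense grid scale
    }
  }
})

test_that("effective cooling time takes the last downward crossing after exposure", {
  t <- seq(0, 1000, by = 0.1)
  expect_true(is.na(effective_cooling_time(t, rep(37, length(t)), 38.5, 300)))
  # symmetric triangular excursion: up at 250, down at 800, t_exp 300 -> 500
  tri <- 38.5 + pmin(t - 250, 800 - t) * 0.01
  expect_equal(effective_cooling_time(t, tri, 38.5, 300), 500, tolerance = 0.06)
  # still above the threshold at the end -> sentinel
  expect_equal(effective_cooling_time(t, 37 + t / 100, 38.5, 300), Inf)
  # multi-crossing: exhaustive scan over all crossings picks the same one
  set.seed(11)
  for (rep in 1:10) {
    core <- 38.5 + 0.6 * sin(t / 90 + rnorm(1)) - 0.4 * (t / 1000)^2 + 0.2 * sin(t / 23)
    core[length(core)] <- 38.0 # force a finite answer
    found <- effective_cooling_time(t, core, 38.5, 300)
    above <- core >= 38.5
    if (!any(above)) { expect_true(is.na(found)); next }
    idx <- which(above[-length(above)] & !above[-1])
    last <- idx[length(idx)]
    f <- (core[last] - 38.5) / (core[last] - core[last + 1])
    expect_equal(found, max(0, t[last] + f * 0.1 - 300))
  }
})

test_that("burn monitor flags boundary-inclusive threshold contact", {
  t <- seq(0, 100, by = 0.1)
  expect_false(burn_monitor(t, rep(43.9, length(t)))$flag)
  bm <- burn_monitor(t, rep(44, length(t)))
  expect_true(bm$flag); expect_equal(bm$first_crossing_s, 0)
  # a pulse: supra-threshold duration equals the pulse width
  skin <- ifelse(t >= 20 & t < 50, 45, 40)
  bm <- burn_monitor(t, skin)
  expect_equal(bm$first_crossing_s, 20)
  expect_equal(bm$supra_duration_s, 30, tolerance = 0.2)
})

test_that("strain metrics tie the dangerous zone to its two crossings", {
  t <- seq(0, 1000, by = 0.1)
  core <- 37 + 2.5 * exp(-((t - 400) / 200)^2)
  skin <- 40 + 6 * exp(-((t - 300) / 150)^2)
  m <- strain_metrics(t, core, skin, t_exp_s = 300)
  expect_equal(unname(m$dangerous_zone_s["start"]), m$safe_exposure_time_s)
  expect_equal(unname(m$dangerous_zone_s["end"]), 300 + m$effective_cooling_time_s)
  expect_equal(m$peak_core_C, max(core))
  expect_true(m$burn$flag)
  # metrics invariant to down-sampling finer than 1 s
  keep <- seq(1, length(t), by = 5) # 0.5 s sampling
  m2 <- strain_metrics(t[keep], core[keep], skin[keep], t_exp_s = 300)
  expect_equal(m2$safe_exposure_time_s, m$safe_exposure_time_s, tolerance = 0.5)
  expect_equal(m2$effective_cooling_time_s, m$effective_cooling_time_s, tolerance = 0.5)
})

test_that("identical configurations give bit-identical coupled runs", {
  cfg <- quick_config()
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("a single-point sweep equals run_scenario plus metrics", {
  cfg <- quick_config()
  sw <- sweep_scenarios(cfg, axis = "gap", values = 6.4)
  r <- run_scenario(cfg)
  expect_equal(sw$peak_core_C, r$metrics$peak_core_C)
  expect_equal(sw$peak_skin_C, r$metrics$peak_skin_C)
  expect_true(is.na(sw$error))
})

test_that("a failed run is recorded and the sweep continues", {
  cfg <- quick_config()
  sw <- sweep_scenarios(cfg, axis = "gap", values = c(-5, 6.4))
  expect_false(is.na(sw$error[1]))
  expect_true(is.na(sw$error[2]))
  expect_false(is.na(sw$peak_core_C[2]))
})

test_that("zero-strength source at thermoneutral ambient keeps the core in band", {
  # near-zero nominal flux: the band is the normal 37.0 +/- 1.0 degC
  cfg <- scenario_config(nominal_flux_kW_m2 = 1e-6, exposure_s = 200,
                        cooling_s = 400, metabolic_W_m2 = 58.2,
                        dx_fabric_m = 2e-5, dx_gap_m = 4e-4)
  r <- run_scenario(cfg)
  expect_true(all(abs(r$series$T_core_C - 37.0) < 1.0))
})
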