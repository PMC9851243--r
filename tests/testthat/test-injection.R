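# Injection-stage driver and plume diagnostics.

test_that("with the source off, probes stay at physiological values", {
  grid <- build_grid(0.05, 0.05, 8, 8)
  cfg <- scenario_config(params = quiet_params(), grid = grid,
                         settings = solver_settings(dt = 0.05), t_end = 1)
  res <- run_injection(cfg)
  pr <- res$probes
  expect_lt(max(abs(pr$p_I)), 1e-9)
  expect_lt(max(abs(pr$p_B - 1000)), 1e-9)
  expect_lt(max(abs(pr$p_L + 1000)), 1e-9)
  expect_lt(max(abs(pr$u_z_surface)), 1e-12)
})

test_that("a short injection pressurizes the interstitium, dips the vessels and injects the right volume", {
  cfg <- small_scenario(t_end = 2, dt = 0.05)
  res <- suppressWarnings(run_injection(cfg))
  pr <- res$probes
  expect_gt(max(pr$p_I), 1e4)                    # strong pressurization
  expect_lt(min(pr$p_B), 1000)                   # early vessel dip
  expect_gt(pr$u_z_surface[nrow(pr)], 0)         # surface bulges upward
  # fluid audit tracks the analytic time integral of the source
  inj <- cfg$params$injection
  expected <- 4e-7 * stats::integrate(function(t)
    injection_time_profile(t, inj), 0, 2)$value /
    (inj$V_inj / inj$T_inj) * (inj$V_inj / inj$T_inj)
  expect_equal(res$audit$injected_volume, expected, tolerance = 5e-3)
  # pressure ordering far from the needle: blood > interstitium > lymph
  g <- res$grid; off <- pe_offsets(g$n_nodes)
  far <- nearest_node(g, 0.045, 0.005)
  y <- res$final$y
  expect_gt(y[off["pB"] + far], y[off["pI"] + far])
  expect_gt(y[off["pI"] + far], y[off["pL"] + far])
})

test_that("probe series extraction validates quantities and returns per-step series", {
  cfg <- small_scenario(t_end = 0.2, dt = 0.05)
  res <- suppressWarnings(run_injection(cfg))
  s <- probe_time_series(res, "p_I")
  expect_equal(nrow(s), 5)
  expect_equal(s$t, seq(0, 0.2, by = 0.05))
  expect_error(probe_time_series(res, "bogus"), "unknown")
})

test_that("plume radius recovers a synthetic top-hat field within one grid spacing", {
  cfg <- small_scenario(t_end = 0.1, dt = 0.05)
  res <- suppressWarnings(run_injection(cfg))
  g <- res$grid
  f <- extract_fields(res$fem, res$params, res$final$y, res$final$C)
  rho <- 0.012                      # 12 mm top-hat radius
  hat <- as.numeric(g$rc <= rho)
  # build a synthetic relative concentration = 0.5 inside the hat
  f$CR_I <- 0.5 * hat
  ext <- plume_radius(res, "I", threshold = 0.01, fields = f)
  hloc <- max(diff(g$r[g$r < 0.02]))
  expect_lt(abs(ext - rho), hloc + 1e-9)
  f$CR_I <- 0 * hat
  expect_equal(plume_radius(res, "I", fields = f), 0)
})

test_that("dominant-pressure radius finds a constructed crossover and is zero at rest", {
  cfg <- small_scenario(t_end = 0.1, dt = 0.05)
  res <- suppressWarnings(run_injection(cfg))
  g <- res$grid
  f <- extract_fields(res$fem, res$params, res$final$y, res$final$C)
  # rest state: blood pressure dominates everywhere
  f$p_I <- rep(0, g$n_nodes); f$p_B <- rep(1000, g$n_nodes)
  f$p_L <- rep(-1000, g$n_nodes)
  expect_equal(dominant_pressure_radius(res, fields = f), 0)
  # constructed crossover at r* = 15 mm
  rstar <- 0.015
  f$p_I <- 2000 * (1 - g$rc / rstar)
  expect_equal(dominant_pressure_radius(res, fields = f),
               rstar * 2000 / 3000, tolerance = 0.03)
})

test_that("surface displacement decays strongly after the injection ends", {
  cfg <- small_scenario(t_end = 9, dt = 0.15)
  res <- suppressWarnings(run_injection(cfg))
  pr <- res$probes
  u5 <- pr$u_z_surface[which.min(abs(pr$t - 5))]
  u9 <- pr$u_z_surface[nrow(pr)]
  expect_lt(u9, 0.5 * u5)
})
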