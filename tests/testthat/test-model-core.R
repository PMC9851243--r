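# Pointwise constitutive, exchange, source and post-processing formulas.

test_that("Lame conversion matches the isotropic closed form and rejects the incompressible limit", {
  lm <- lame_from_engineering(30e3, 0.45)
  expect_equal(lm$lambda, 93103.448, tolerance = 1e-6)
  expect_equal(lm$mu, 10344.828, tolerance = 1e-6)
  # nu = 0 decouples the Lame constants
  lm0 <- lame_from_engineering(12345, 1e-12)
  expect_equal(lm0$mu, 12345 / 2, tolerance = 1e-6)
  expect_equal(lm0$lambda, 0, tolerance = 1e-6)
  expect_error(lame_from_engineering(30e3, 0.5), "nu")
  expect_error(lame_from_engineering(-1, 0.3), "E")
})

test_that("Cauchy stress matches a brute-force elementwise evaluation", {
  set.seed(1)
  a <- matrix(rnorm(9), 3)
  eps <- (a + t(a)) / 2
  lam <- 2.3; mu <- 0.7
  sig <- cauchy_stress(eps, lam, mu)
  brute <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    brute[i, j] <- lam * sum(diag(eps)) * (i == j) + 2 * mu * eps[i, j]
  expect_equal(sig, brute, tolerance = 1e-14)
  expect_equal(cauchy_stress(diag(3), lam, mu), (3 * lam + 2 * mu) * diag(3))
  expect_equal(cauchy_stress(matrix(0, 2, 2), lam, mu), matrix(0, 2, 2))
  expect_error(cauchy_stress(matrix(c(0, 1, 0, 0), 2), lam, mu), "symmetric")
})

test_that("transmural exchange rates are linear in the pressure difference with the physiological magnitudes", {
  mix <- mixture_parameters()
  ex <- fluid_exchange_rates(0, 1000, -1000, mix)
  expect_equal(ex$s_BI, 2.5e-4)       # blood -> interstitium at rest
  expect_equal(ex$s_LI, -1.25e-4)     # interstitium -> lymph at rest
  expect_equal(fluid_exchange_rates(500, 500, 0, mix)$s_BI, 0)
})

test_that("equilibrium sources balance to zero identically and match the rest-state arithmetic", {
  fs <- equilibrium_sources(0, 1000, -1000, 2.5e-7, 1.25e-7)
  expect_equal(fs$f_B, 2.5e-4)
  expect_equal(fs$f_L, -1.25e-4)
  expect_equal(fs$f_I, -1.25e-4)
  set.seed(42)
  for (k in 1:25) {
    p <- rnorm(3, sd = 1e4)
    x <- runif(2, 0, 1e-6)
    fs <- equilibrium_sources(p[1], p[2], p[3], x[1], x[2])
    scale <- max(abs(c(fs$f_I, fs$f_B, fs$f_L)), 1e-300)
    expect_lt(abs(fs$f_I + fs$f_B + fs$f_L), 4 * .Machine$double.eps * scale)
  }
})

test_that("porosity update reproduces the rest state and the strain/pressure corrections", {
  # rest
  expect_equal(porosity_update(0.01, 0, 0, 0, 0, 0.99, 0.8415, 0.85,
                               0.125e6, 0.0235), 0.01)
  # 1% volumetric expansion of the interstitium at rest pressure
  phi <- porosity_update(0.01, 0.01, 0, 0, 0, 0.99, 0.8415, 0.85,
                         0.125e6, 0.0235)
  expect_equal(phi, 0.01 + (0.99 - 0.0235) * 0.01, tolerance = 1e-12)
  # volume-averaged porosity recovers phi_s0 at rest
  comps <- default_compartments()
  expect_equal(initial_mixture_porosity(comps), 0.0235)
  expect_error(porosity_update(0.01, -2, 0, 0, 0, 0.99, 0.8415, 0.85,
                               0.125e6, 0.0235, clamp = "error"), "porosity")
})

test_that("injection source has the nominal flow rate, sharp sphere and normalized volume", {
  inj <- injection_parameters()
  q0 <- injection_flow_rate(inj)
  expect_equal(q0, 2e-6 / (5 * (4 / 3) * pi * (1.5e-4)^3), tolerance = 1e-12)
  # nominal volumetric rate Q0 * (4/3) pi R^3 = V/T = 1440 mL/h
  expect_equal(q0 * (4 / 3) * pi * inj$R_inj^3 * 3600 * 1e6, 1440,
               tolerance = 1e-12)
  expect_equal(injection_space_profile(inj$R_inj, inj), 0.5)
  expect_lt(injection_time_profile(0, inj), 2e-3)
  expect_lt(injection_time_profile(15, inj), 1e-6)
  # space-time integral of Q recovers the injected volume (numeric oracle)
  sp <- stats::integrate(function(d) injection_space_profile(d, inj) *
                           4 * pi * d^2, 0, 3 * inj$R_inj,
                         rel.tol = 1e-10)$value
  tm <- stats::integrate(function(t) injection_time_profile(t, inj), 0, 15,
                         rel.tol = 1e-10)$value
  expect_equal(q0 * sp * tm, inj$V_inj, tolerance = 2e-3)
})

test_that("exchange direction indicator is a regularized upwind switch", {
  expect_lt(exchange_direction(1e-4), 1e-6)       # outflow from interstitium
  expect_gt(exchange_direction(-1e-4), 1 - 1e-6)  # inflow to interstitium
  expect_equal(exchange_direction(0), 0.5)
  expect_error(exchange_direction(1, eps_s = 0), "eps_s")
})

test_that("drug exchange terms match a term-by-term brute-force composition and conserve pairwise", {
  set.seed(7)
  for (k in 1:20) {
    C <- runif(3); s_BI <- rnorm(1, sd = 1e-4); s_LI <- rnorm(1, sd = 1e-4)
    phi <- runif(3, 0.05, 0.3); w <- c(0.7, 0.2, 0.1)
    phis <- sum(w * phi)
    g <- drug_exchange_terms(C[1], C[2], C[3], s_BI, s_LI,
                             phi[1], phi[2], phi[3], phis, w[1], w[2], w[3])
    d_BI <- 0.5 * (1 - (-s_BI) / (abs(s_BI) + 1e-12))
    G_ref <- (1 - d_BI) * s_BI * C[1] * w[1] * phi[1] / phis +
      d_BI * s_BI * C[2] * w[2] * phi[2] / phis
    expect_equal(g$G_BI, G_ref, tolerance = 1e-12)
    # all-zero concentrations give zero exchange
    g0 <- drug_exchange_terms(0, 0, 0, s_BI, s_LI, phi[1], phi[2], phi[3],
                              phis, w[1], w[2], w[3])
    expect_identical(c(g0$G_BI, g0$G_LI), c(0, 0))
  }
  # injection regime: p_I > p_B, drug leaves the interstitium into blood
  g <- drug_exchange_terms(1, 0, 0, s_BI = -1e-4, s_LI = -1e-4,
                           0.02, 0.1, 0.1, 0.0235, 0.85, 0.1, 0.05)
  expect_lt(g$G_BI, 0)
})

test_that("relative concentration follows C phi w / phi_s", {
  expect_equal(relative_concentration(1, 0.1, 0.1, 0.0235), 0.1 * 0.1 / 0.0235)
  expect_equal(relative_concentration(0, 0.1, 0.1, 0.0235), 0)
  # single-network consistency: w = 1, phi = phi_s
  expect_equal(relative_concentration(0.7, 0.3, 1, 0.3), 0.7)
  expect_error(relative_concentration(1, 0.1, 0.1, 0), "phi_s")
})

test_that("compartment drug mass integrates C w phi over the axisymmetric domain", {
  fem <- tiny_fem(8)
  nn <- fem$nn
  vol <- pi * 0.05^2 * 0.05
  expect_equal(compartment_drug_mass(fem, rep(1, nn), 0.1, 0.85),
               0.85 * 0.1 * vol, tolerance = 1e-12)
  expect_equal(compartment_drug_mass(fem, rep(0, nn), 0.1, 0.85), 0)
  # both forms of the mass integral agree: C^R phi_s vs C w phi
  set.seed(3)
  C <- runif(nn); phi <- runif(nn, 0.05, 0.2)
  w <- 0.6; phis <- w * phi          # single network
  m1 <- compartment_drug_mass(fem, C, phi, w)
  cr <- relative_concentration(C, phi, w, phis)
  m2 <- compartment_drug_mass(fem, cr * phis / phi / w, phi, w)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("parameter validation enforces the mixture constraints", {
  expect_s3_class(default_parameters(), "poroinject_params")
  p <- default_parameters()
  expect_equal(sum(vapply(p$comps, `[[`, 0, "alpha_i")), 0.99)
  expect_equal(p$phi_s0, 0.0235)
  comps <- default_compartments()
  comps$I$w <- 0.5; comps$B$w <- 0.5; comps$L$w <- 0.5
  expect_error(validate_parameters(mixture_parameters(), comps),
               "volume fractions")
  expect_error(mixture_parameters(alpha = 1.2), "Biot")
  comps <- default_compartments()
  comps$I$alpha_i <- 0.5
  expect_error(validate_parameters(mixture_parameters(), comps), "Biot")
})
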