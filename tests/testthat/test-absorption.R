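# Long-time transport-only stage and depot-clearance fit.

test_that("without exchange the compartment fractions stay constant", {
  fem <- tiny_fem(6)
  pr <- default_parameters()
  mix <- mixture_parameters(xi_BI = 0, xi_LI = 0)
  p <- validate_parameters(mix, pr$comps, pr$injection)
  nn <- fem$nn
  set.seed(2)
  C0 <- c(runif(nn), runif(nn) * 0.1, numeric(nn))
  ab <- run_absorption(C0, fem, p, duration = 1200, dt_long = 60)
  fr <- ab$fractions
  expect_lt(max(abs(fr$frac_I - fr$frac_I[1])), 1e-8)
  expect_lt(max(abs(fr$frac_B - fr$frac_B[1])), 1e-8)
})

test_that("uniform fields follow the pointwise matrix-exponential exchange oracle", {
  fem <- tiny_fem(6)
  p <- default_parameters()
  nn <- fem$nn
  C0v <- c(1, 0.3, 0)
  C0 <- rep(C0v, each = nn)
  dur <- 1800
  ab <- run_absorption(C0, fem, p, duration = dur, dt_long = 5, cadence = 300)
  # uniform fields: diffusion is inert, the FE stage must track the exact
  # 3x3 exponential at every node
  oracle <- absorption_pointwise_oracle(p, C0v, dur)
  w <- vapply(p$comps, `[[`, 0, "w")
  phi <- vapply(p$comps, `[[`, 0, "phi0")
  m_or <- oracle[1, ] * w * phi
  fr_or <- 100 * m_or / sum(m_or)
  fin <- ab$fractions[nrow(ab$fractions), ]
  expect_equal(c(fin$frac_I, fin$frac_B, fin$frac_L), unname(fr_or),
               tolerance = 1e-4)
})

test_that("fractions sum to 100, lymph is non-decreasing and blood non-increasing under physiological exchange", {
  fem <- tiny_fem(6)
  p <- default_parameters()
  nn <- fem$nn
  set.seed(9)
  C0 <- c(runif(nn), 0.05 * runif(nn), 0.01 * runif(nn))
  ab <- run_absorption(C0, fem, p, duration = 3600, dt_long = 10,
                       cadence = 300)
  fr <- ab$fractions
  expect_equal(fr$frac_I + fr$frac_B + fr$frac_L, rep(100, nrow(fr)),
               tolerance = 1e-9)
  expect_true(all(diff(fr$frac_L) > -1e-8))
  expect_true(all(diff(fr$frac_B) < 1e-8))
  expect_lt(ab$conservation_drift, 1e-6)
})

test_that("halving the long-stage step leaves the terminal fractions unchanged to <0.1 percentage point", {
  fem <- tiny_fem(5)
  p <- default_parameters()
  nn <- fem$nn
  C0 <- c(rep(1, nn), numeric(2 * nn))
  a1 <- run_absorption(C0, fem, p, duration = 1800, dt_long = 20)
  a2 <- run_absorption(C0, fem, p, duration = 1800, dt_long = 10)
  f1 <- a1$fractions[nrow(a1$fractions), ]
  f2 <- a2$fractions[nrow(a2$fractions), ]
  expect_lt(abs(f1$frac_I - f2$frac_I), 0.1)
  expect_lt(abs(f1$frac_L - f2$frac_L), 0.1)
})

test_that("decay-coefficient fit is exact on a clean exponential and robust to seeded noise", {
  t <- seq(0, 300, by = 10)
  expect_equal(fit_decay_coefficient(t, 100 * exp(-0.002 * t))$k, 0.002,
               tolerance = 1e-12)
  expect_equal(fit_decay_coefficient(t, rep(100, length(t)))$k, 0)
  set.seed(123)
  k_true <- 0.0035
  Mp <- 100 * exp(-k_true * t) * exp(rnorm(length(t), sd = 0.02))
  fit <- fit_decay_coefficient(t, Mp)
  # standard error of the slope from the log-linear regression
  se <- summary(stats::lm(log(Mp / 100) ~ t))$coefficients[2, 2]
  expect_lt(abs(fit$k - k_true), 2 * se)
  expect_error(fit_decay_coefficient(t[1:2], c(100, 90)), "3 points")
  expect_error(fit_decay_coefficient(t, 100 - t), "positive")
})

test_that("all drug in one compartment reports (100, 0, 0) up to permutation", {
  fem <- tiny_fem(4)
  p <- default_parameters()
  nn <- fem$nn
  ab <- run_absorption(c(numeric(nn), numeric(nn), rep(1, nn)), fem, p,
                       duration = 60, dt_long = 30)
  f0 <- ab$fractions[1, ]
  expect_equal(c(f0$frac_I, f0$frac_B, f0$frac_L), c(0, 0, 100))
})
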