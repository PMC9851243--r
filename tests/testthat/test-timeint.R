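# Generalized-alpha scheme, Newton driver, linear-solve contract.

# Closed-form generalized-alpha update for the scalar decay problem
# ydot = -k y, derived independently from the update relations.
ga_scalar_step <- function(y, ydot, k, dt, rho) {
  co <- generalized_alpha_coeffs(rho)
  am <- co$alpha_m; af <- co$alpha_f; g <- co$gamma
  # solve am*(ydot + am-part) + k*y_af = 0 for v = ydot_{n+1}
  v <- -((1 - am) * ydot + k * (y + af * dt * (1 - g) * ydot)) /
    (am + k * af * g * dt)
  c(y = y + dt * ((1 - g) * ydot + g * v), ydot = v)
}

test_that("generalized-alpha coefficients satisfy the second-order relation", {
  for (rho in c(0, 0.5, 1)) {
    co <- generalized_alpha_coeffs(rho)
    expect_equal(co$gamma, 0.5 + co$alpha_m - co$alpha_f)
    expect_equal(co$alpha_f, 1 / (1 + rho))
  }
  # rho = 1: midpoint member, no high-frequency damping on the scalar test
  co <- generalized_alpha_coeffs(1)
  expect_equal(co$alpha_m, 0.5)
  expect_equal(co$alpha_f, 0.5)
  expect_equal(co$gamma, 0.5)
  expect_error(generalized_alpha_coeffs(1.2), "rho_inf")
})

test_that("generalized_alpha_step matches the closed-form scalar amplification and is second order", {
  k <- 3
  st <- solver_settings(dt = 0.1)
  step_with <- function(dt, rho) {
    y <- 1; v <- -k   # consistent initial rate
    res <- function(vd, ya, ta) vd + k * ya
    sj <- function(r) {
      co <- generalized_alpha_coeffs(rho)
      r / (co$alpha_m + k * co$alpha_f * co$gamma * dt)
    }
    n <- round(1 / dt)
    co <- generalized_alpha_coeffs(rho)
    for (i in seq_len(n)) {
      stp <- generalized_alpha_step(y, v, (i - 1) * dt, dt, res, sj, st, co)
      # one step agrees with the independent closed form
      refc <- ga_scalar_step(y, v, k, dt, rho)
      expect_equal(stp$y, unname(refc["y"]), tolerance = 1e-12)
      y <- stp$y; v <- stp$ydot
    }
    y
  }
  for (rho in c(0.5, 1)) {
    errs <- vapply(c(0.1, 0.05, 0.025),
                   function(dt) abs(step_with(dt, rho) - exp(-k)), 0)
    orders <- log2(errs[-3] / errs[-1])
    expect_gt(min(orders), 1.9)
    expect_lt(max(orders), 2.15)
  }
})

test_that("an equilibrium state is a fixed point over many steps", {
  # scalar problem starting exactly at the fixed point y = 0
  st <- solver_settings(dt = 0.1)
  co <- generalized_alpha_coeffs(0.5)
  y <- 0; v <- 0
  for (i in 1:50) {
    stp <- generalized_alpha_step(y, v, 0, 0.1,
                                  function(vd, ya, ta) vd + 2 * ya,
                                  function(r) r / (co$alpha_m + 2 * co$alpha_f * co$gamma * 0.1),
                                  st, co, atol = 1e-14)
    y <- stp$y; v <- stp$ydot
  }
  expect_equal(y, 0)
})

test_that("Newton converges in one iteration on linear problems and quadratically on smooth ones", {
  A <- matrix(c(4, 1, 1, 3), 2)
  b <- c(1, 2)
  ns <- newton_solve(function(x) as.numeric(A %*% x) - b,
                     function(x, r) solve(A, r), c(0, 0))
  expect_true(ns$converged)
  expect_equal(ns$iterations, 1L)
  expect_equal(ns$x, solve(A, b), tolerance = 1e-12)
  # mildly nonlinear: x + x^3 = c, exact Jacobian -> quadratic tail
  f <- function(x) x + x^3 - 2
  ns <- newton_solve(f, function(x, r) r / (1 + 3 * x^2), 3,
                     tol = 1e-12, max_it = 20)
  expect_true(ns$converged)
  h <- ns$history
  h <- h[h > 1e-14]
  rate <- log(h[length(h)] / h[length(h) - 1]) /
    log(h[length(h) - 1] / h[length(h) - 2])
  expect_gt(rate, 1.7)
  # an inconsistent Jacobian degrades convergence to linear
  ns_bad <- newton_solve(f, function(x, r) r / (1 + 3.9 * x^2), 3,
                         tol = 1e-12, max_it = 30)
  expect_gt(ns_bad$iterations, ns$iterations)
})

test_that("linear_solve meets its residual contract on both backends", {
  st <- solver_settings(dt = 1, linear_tol = 1e-10)
  n <- 50
  set.seed(5)
  A <- Matrix::Diagonal(n, x = runif(n, 1, 2)) +
    Matrix::rsparsematrix(n, n, density = 0.1) * 0.05
  A <- methods::as(A, "generalMatrix")
  b <- rnorm(n)
  x1 <- linear_solve(A, b, st, backend = "direct")
  expect_lt(attr(x1, "residual"), 1e-10)
  # identity
  I <- methods::as(Matrix::Diagonal(4), "generalMatrix")
  expect_equal(as.numeric(linear_solve(I, 1:4, st)), as.numeric(1:4))
  # SPD 2x2 with known inverse
  A2 <- methods::as(Matrix::Matrix(c(2, 1, 1, 2), 2, sparse = TRUE),
                    "generalMatrix")
  expect_equal(as.numeric(linear_solve(A2, c(1, 0), st)),
               c(2, -1) / 3, tolerance = 1e-12)
  # recycled backend with a stale factorization still meets the tolerance
  cache <- new.env()
  x2 <- linear_solve(A, b, st, cache = cache, backend = "recycled")
  Ap <- A + Matrix::Diagonal(n, x = 0.01 * runif(n))
  x3 <- linear_solve(Ap, b, st, cache = cache, backend = "recycled")
  expect_lt(sqrt(sum((as.numeric(Ap %*% as.numeric(x3)) - b)^2)) / sqrt(sum(b^2)),
            1e-10)
  # both backends agree
  x4 <- linear_solve(Ap, b, st, backend = "direct")
  expect_equal(as.numeric(x3), as.numeric(x4), tolerance = 1e-8)
})
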