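# Weak-form assembly: equilibrium preservation, Jacobian consistency,
# exchange bookkeeping and conservation structure.

test_that("the physiological rest state is an exact zero of the assembled residual", {
  fem <- tiny_fem(8)
  p <- quiet_params()
  sys <- assemble_poroelastic_system(fem, p)
  r <- pe_residual(sys, numeric(sys$ndof), sys$y0, t = 3)
  expect_lt(max(abs(r)), 1e-12)
  # transport at zero concentration with no source is also at rest
  ts <- transport_structures(fem, p)
  co <- transport_coefficients(fem, p, sys$y0, numeric(sys$ndof), 0.05)
  tsys <- assemble_transport_system(ts, co, "injection")
  nn <- fem$nn
  r_c <- as.numeric(tsys$M %*% numeric(3 * nn) + tsys$K %*% numeric(3 * nn))
  expect_identical(max(abs(r_c)), 0)
})

test_that("the poroelastic iteration matrix is the exact derivative of the residual", {
  fem <- tiny_fem(5)
  p <- default_parameters()
  sys <- assemble_poroelastic_system(fem, p, bc = "none")
  set.seed(11)
  y <- sys$y0 + rnorm(sys$ndof, sd = 1e-3)
  v <- rnorm(sys$ndof, sd = 1e-4)
  dirn <- rnorm(sys$ndof); dirn <- dirn / sqrt(sum(dirn^2))
  dt <- 0.02
  ga <- generalized_alpha_coeffs(0.5)
  J <- ga$alpha_m * sys$M + ga$alpha_f * ga$gamma * dt * sys$K
  # directional derivative of the alpha-level residual wrt the rate unknown
  res_of <- function(vn) {
    v_am <- v + ga$alpha_m * (vn - v)
    y_af <- y + ga$alpha_f * dt * ((1 - ga$gamma) * v + ga$gamma * vn)
    pe_residual(sys, v_am, y_af, 0.5)
  }
  v1 <- v
  hs <- c(1e-3, 5e-4)
  err <- vapply(hs, function(h) {
    fd <- (res_of(v1 + h * dirn) - res_of(v1 - h * dirn)) / (2 * h)
    sqrt(sum((fd - as.numeric(J %*% dirn))^2)) / sqrt(sum(fd^2))
  }, 0)
  expect_lt(err[1], 1e-9)      # linear system: FD is exact up to roundoff
  # pure elasticity sub-block is state independent (linearity)
  expect_lt(max(abs((res_of(v1) - res_of(v1 + dirn)) +
                      as.numeric(J %*% dirn))), 1e-6 * max(abs(J %*% dirn)))
})

test_that("the transport iteration matrix is the exact derivative in the concentrations", {
  fem <- tiny_fem(5)
  p <- default_parameters()
  sys <- assemble_poroelastic_system(fem, p)
  set.seed(12)
  y <- sys$y0 + rnorm(sys$ndof, sd = 1)
  v <- rnorm(sys$ndof, sd = 1e-2)
  ts <- transport_structures(fem, p)
  dt <- 0.05
  co <- transport_coefficients(fem, p, y, v, dt)
  tsys <- assemble_transport_system(ts, co, "injection")
  nn <- fem$nn
  C <- runif(3 * nn); Cd <- rnorm(3 * nn, sd = 0.1)
  ga <- generalized_alpha_coeffs(0.5)
  J <- ga$alpha_m * tsys$M + ga$alpha_f * ga$gamma * dt * tsys$K
  res_of <- function(cn) {
    cd_am <- Cd + ga$alpha_m * (cn - Cd)
    c_af <- C + ga$alpha_f * dt * ((1 - ga$gamma) * Cd + ga$gamma * cn)
    as.numeric(tsys$M %*% cd_am + tsys$K %*% c_af) - tsys$F_shape
  }
  dirn <- rnorm(3 * nn); dirn <- dirn / sqrt(sum(dirn^2))
  h <- 1e-4
  fd <- (res_of(Cd + h * dirn) - res_of(Cd - h * dirn)) / (2 * h)
  expect_equal(as.numeric(J %*% dirn), fd, tolerance = 1e-9)
})

test_that("summing the three transport equations cancels the exchange terms exactly", {
  fem <- tiny_fem(6)
  p <- default_parameters()
  sys <- assemble_poroelastic_system(fem, p)
  set.seed(13)
  y <- sys$y0 + rnorm(sys$ndof, sd = 100)
  # zero rates: porosity-rate storage is a physical (non-cancelling) term,
  # so it is switched off to isolate the pairwise exchange bookkeeping
  ts <- transport_structures(fem, p)
  co <- transport_coefficients(fem, p, y, numeric(sys$ndof), 0.05)
  tsys <- assemble_transport_system(ts, co, "absorption")
  nn <- fem$nn
  # exchange-only stiffness (absorption stage: no advection, but diffusion
  # and storage are present; both conserve): row sums over the three blocks
  # annihilate the exchange contributions identically
  C <- runif(3 * nn)
  r <- as.numeric(tsys$K %*% C)
  tot <- r[seq_len(nn)] + r[nn + seq_len(nn)] + r[2 * nn + seq_len(nn)]
  # what remains is pure diffusion of each field; for a CONSTANT field even
  # that vanishes, so use constant concentrations to isolate the exchange
  Cc <- rep(runif(3), each = nn)
  rc <- as.numeric(tsys$K %*% Cc)
  totc <- rc[seq_len(nn)] + rc[nn + seq_len(nn)] + rc[2 * nn + seq_len(nn)]
  expect_lt(max(abs(totc)), 1e-18 + 1e-13 * max(abs(rc)))
})

test_that("discrete fluid bookkeeping: inter-network exchange cancels in the summed mass balances", {
  fem <- tiny_fem(6)
  p <- quiet_params()
  sys <- assemble_poroelastic_system(fem, p, bc = "none")
  set.seed(14)
  nn <- fem$nn; off <- sys$offsets
  y <- sys$y0
  # random constant pressure offsets: Darcy flux zero, only exchange acts
  dp <- rnorm(3, sd = 500)
  y[off["pI"] + seq_len(nn)] <- y[off["pI"] + seq_len(nn)] + dp[1]
  y[off["pB"] + seq_len(nn)] <- y[off["pB"] + seq_len(nn)] + dp[2]
  y[off["pL"] + seq_len(nn)] <- y[off["pL"] + seq_len(nn)] + dp[3]
  r <- pe_residual(sys, numeric(sys$ndof), y, t = 50)
  tot <- r[off["pI"] + seq_len(nn)] + r[off["pB"] + seq_len(nn)] +
    r[off["pL"] + seq_len(nn)]
  expect_lt(max(abs(tot)), 1e-12 * max(abs(r)))
})

test_that("Dirichlet rows hold exactly through a transient solve", {
  cfg <- small_scenario(t_end = 0.3, dt = 0.05)
  res <- suppressWarnings(run_injection(cfg))
  g <- res$grid; nn <- g$n_nodes
  off <- pe_offsets(nn)
  y <- res$final$y
  expect_equal(max(abs(y[off["ur"] + g$axis])), 0)
  expect_equal(max(abs(y[off["uz"] + g$bottom])), 0)
  pdir <- sort(unique(c(g$outer, g$bottom)))
  expect_equal(max(abs(y[off["pI"] + pdir] - 0)), 0)
  expect_equal(max(abs(y[off["pB"] + pdir] - 1000)), 0)
})

test_that("1-D constant-velocity advection tracks the analytic traveling front", {
  # linear interstitial pressure in z gives a constant Darcy velocity;
  # a smooth front must travel at the seepage speed v/phi with modest
  # stabilized-scheme smearing and near-zero over/undershoot
  p <- single_network_parameters(kappa = 1e-13, M = 1e12)
  g <- build_grid(0.002, 0.05, 1, 200)
  fem <- fem_setup(g)
  nn <- fem$nn
  off <- poroinject:::pe_offsets(nn)
  y <- numeric(5 * nn)
  y[off["pI"] + seq_len(nn)] <- 1e6 * (0.05 - g$zc)   # v_z = 1e-4 m/s
  ts <- transport_structures(fem, p)
  dt <- 0.5                                           # Courant 0.2 wrt v/phi
  co <- transport_coefficients(fem, p, y, numeric(5 * nn), dt)
  expect_equal(co$vz$I[[1]][1], 1e-4, tolerance = 1e-10)
  tsys <- assemble_transport_system(ts, co, "injection")
  ga <- generalized_alpha_coeffs(0.5)
  J <- ga$alpha_m * tsys$M + ga$alpha_f * ga$gamma * dt * tsys$K
  lt <- poroinject:::scaled_lu(J)
  front0 <- 0.01; width <- 1e-3
  C <- numeric(3 * nn)
  C[seq_len(nn)] <- 1 / (1 + exp((g$zc - front0) / width))
  Cd <- numeric(3 * nn)
  am <- ga$alpha_m; af <- ga$alpha_f; gam <- ga$gamma
  nsteps <- 60
  for (n in seq_len(nsteps)) {
    c0 <- Cd * (gam - 1) / gam
    Rc <- as.numeric(tsys$M %*% (Cd + am * (c0 - Cd)) +
                       tsys$K %*% (C + af * dt * ((1 - gam) * Cd + gam * c0)))
    Cd_new <- c0 - poroinject:::solve_scaled(lt, Rc)
    C <- C + dt * ((1 - gam) * Cd + gam * Cd_new)
    Cd <- Cd_new
  }
  CI <- C[g$axis]
  zax <- g$zc[g$axis]
  v_seep <- 1e-4 / p$comps$I$phi0                     # front speed v/phi
  z_front <- front0 + v_seep * dt * nsteps
  # leading-front crossing of C = 0.5 within a few cells of the exact one
  lead <- zax > z_front - 0.01
  i50 <- which(lead)[which(CI[lead] < 0.5)[1]]
  h <- 0.05 / 200
  expect_lt(abs(zax[i50] - z_front), 4 * h)
  # bounded over/undershoot of the stabilized scheme
  expect_lt(max(CI), 1.12)
  expect_gt(min(CI), -0.30)
})
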