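# Verification oracles: the classical Terzaghi consolidation column for the
# single-network (Biot) limit, steady manufactured solutions for the
# poroelastic and transport assemblies, and a mesh-refinement ladder with
# observed convergence orders.

#' Terzaghi consolidation series solution
#'
#' Excess pore pressure in a 1-D column of height `H`, loaded by a step
#' compression at the drained top surface, with an impermeable rigid bottom
#' (`z` measured upward from the bottom).
#'
#' @param z heights (m), in `[0, H]`.
#' @param t time since loading (s), > 0.
#' @param H column height (m).
#' @param cv consolidation coefficient (m^2/s).
#' @param p_init initial (undrained) excess pressure (Pa).
#' @param tol series truncation: terms are added until the additive change
#'   is below `tol * p_init`.
#' @return Excess pressure at `(z, t)` (Pa).
#' @export
terzaghi_solution <- function(z, t, H, cv, p_init, tol = 1e-12) {
  if (t <= 0) stop("t must be > 0")
  x <- H - z                      # depth below the drained surface
  p <- numeric(length(z))
  k <- 0
  repeat {
    m <- 2 * k + 1
    damp <- exp(-(m * pi / (2 * H))^2 * cv * t)
    p <- p + (4 / (m * pi)) * sin(m * pi * x / (2 * H)) * damp
    # truncate on the sine-free envelope (individual sines may vanish)
    if ((4 / (m * pi)) * damp < tol || k > 4000) break
    k <- k + 1
  }
  p_init * p
}

#' Single-network (Biot) degenerate parameter set
#'
#' The multi-network model with the vessel networks shrunk to a vanishing
#' volume fraction and zero exchange, leaving one Biot network; used to
#' compare against classical single-network solutions.  Volume fractions of
#' exactly zero would divide by zero in the porosity law, so the limit is
#' taken with a small positive fraction.
#'
#' @param E,nu,alpha,M,kappa,phi0,mu_f single-network material constants.
#' @param w_eps residual vessel volume fraction.
#' @return Validated `poroinject_params` (no injection).
#' @export
single_network_parameters <- function(E = 1e5, nu = 0.3, alpha = 0.95,
                                      M = 1e5, kappa = 1e-13, phi0 = 0.2,
                                      mu_f = 1e-3, w_eps = 1e-8) {
  mix <- mixture_parameters(E = E, nu = nu, alpha = alpha, mu_f = mu_f,
                            xi_BI = 0, xi_LI = 0)
  comps <- list(
    I = compartment_parameters("I", M = M, kappa = kappa, phi0 = phi0,
                               D = 1e-11, p0 = 0, w = 1 - 2 * w_eps,
                               alpha_i = alpha - 2 * w_eps * alpha),
    B = compartment_parameters("B", M = M, kappa = kappa, phi0 = phi0,
                               D = 1e-11, p0 = 0, w = w_eps,
                               alpha_i = w_eps * alpha),
    L = compartment_parameters("L", M = M, kappa = kappa, phi0 = phi0,
                               D = 1e-11, p0 = 0, w = w_eps,
                               alpha_i = w_eps * alpha))
  validate_parameters(mix, comps, NULL)
}

#' Simulate the Terzaghi column with the multi-network assembly
#'
#' Runs the degenerate single-network limit on a thin axisymmetric column,
#' laterally confined (`u_r = 0` everywhere), loaded by a step traction at
#' the drained top.
#'
#' @param n_z elements along the column.
#' @param t_out output time (s).
#' @param H column height (m).
#' @param load applied compression (Pa).
#' @param dt time step (s); default resolves the startup transient.
#' @param params degenerate parameter set.
#' @return List: `z` (node heights), `p_fem`, `p_exact`, relative L2 error
#'   `err_l2`, `cv`, `p_init`.
#' @export
terzaghi_column <- function(n_z = 32, t_out = NULL, H = 0.01, load = 1e4,
                            dt = NULL, params = single_network_parameters()) {
  mix <- params$mixture; cpI <- params$comps$I
  Kv <- mix$lambda + 2 * mix$mu
  w <- cpI$w
  cv <- (w * cpI$kappa / mix$mu_f) / (w / cpI$M + mix$alpha^2 / Kv)
  p_init <- load * (mix$alpha * cpI$M / w) / (Kv + mix$alpha^2 * cpI$M / w)
  if (is.null(t_out)) t_out <- 0.5 * H^2 / cv        # T_v = 0.5
  if (is.null(dt)) dt <- t_out / 3200   # temporal error well below spatial

  grid <- build_grid(H / 5, H, 2, n_z)
  fem <- fem_setup(grid)
  sys <- assemble_poroelastic_system(fem, params, bc = "none")
  nn <- fem$nn; off <- sys$offsets
  # constraints: laterally confined, bottom fixed, top drained, vessel
  # networks pinned at zero pressure
  all_nodes <- seq_len(nn)
  bc_idx <- c(off["ur"] + all_nodes, off["uz"] + grid$bottom,
              off["pI"] + grid$top, off["pB"] + all_nodes,
              off["pL"] + all_nodes)
  # step traction -load on the top surface (z = H): edge integral of N_a
  Fext <- numeric(sys$ndof)
  topel <- which(grid$el_j == grid$n_z)
  r1 <- grid$rc[grid$conn[topel, 4]]
  hr <- grid$hr[topel]
  # exact edge integrals of the two linear shape functions against 2 pi r
  f4 <- 2 * pi * (hr / 2 * r1 + hr^2 / 6)          # node at r1
  f3 <- 2 * pi * (hr / 2 * r1 + hr^2 / 3)          # node at r1 + hr
  idx4 <- off["uz"] + grid$conn[topel, 4]
  idx3 <- off["uz"] + grid$conn[topel, 3]
  for (k in seq_along(topel)) {
    Fext[idx4[k]] <- Fext[idx4[k]] - load * f4[k]
    Fext[idx3[k]] <- Fext[idx3[k]] - load * f3[k]
  }
  st <- solver_settings(dt = dt)
  ga <- generalized_alpha_coeffs(st$rho_inf)
  J <- apply_bc_matrix(ga$alpha_m * sys$M + ga$alpha_f * ga$gamma * dt * sys$K,
                       bc_idx)
  luJ <- scaled_lu(J)
  y <- numeric(sys$ndof); v <- numeric(sys$ndof)
  n_steps <- as.integer(round(t_out / dt))
  resfun <- function(vd, ya, ta) {
    r <- as.numeric(sys$M %*% vd + sys$K %*% ya) - Fext
    r[bc_idx] <- vd[bc_idx]
    r
  }
  atol <- 1e-12 * sqrt(sum(Fext^2))
  for (n in seq_len(n_steps)) {
    stp <- generalized_alpha_step(y, v, (n - 1) * dt, dt, resfun,
                                  function(r) solve_scaled(luJ, bc_zero(r, bc_idx)),
                                  st, ga, atol = atol)
    y <- stp$y; v <- stp$ydot
  }
  # axis column of interstitial pressure
  sel <- off["pI"] + grid$axis
  zax <- grid$zc[grid$axis]
  ord <- order(zax)
  p_fem <- y[sel][ord]; zax <- zax[ord]
  p_ex <- terzaghi_solution(zax, t_out, H, cv, p_init)
  err <- sqrt(sum((p_fem - p_ex)^2)) / sqrt(sum(p_ex^2))
  list(z = zax, p_fem = p_fem, p_exact = p_ex, err_l2 = err,
       cv = cv, p_init = p_init, t_out = t_out)
}

# ------------------------------------------------------------------------
# Steady manufactured solutions

mms_exact <- function() {
  list(
    ur = function(r, z) 1e-3 * r * (1 - r) * z * (1 - z),
    uz = function(r, z) 1e-3 * z * (1 - 0.5 * z) * (1 + 0.3 * cos(pi * r)),
    p = list(
      I = function(r, z) 1e3 * cos(0.5 * pi * r) * cos(0.5 * pi * z),
      B = function(r, z) 5e2 * (1 - r^2) * (1 + 0.5 * z),
      L = function(r, z) 2e2 * (1 + 0.2 * r^2) * cos(0.5 * pi * z)
    )
  )
}

num_d <- function(f, wrt, r, z, h = 1e-6) {
  if (wrt == "r") (f(r + h, z) - f(r - h, z)) / (2 * h)
  else (f(r, z + h) - f(r, z - h)) / (2 * h)
}
num_d2 <- function(f, wrt, r, z, h = 1e-4) {
  if (wrt == "rr") (f(r + h, z) - 2 * f(r, z) + f(r - h, z)) / h^2
  else if (wrt == "zz") (f(r, z + h) - 2 * f(r, z) + f(r, z - h)) / h^2
  else (f(r + h, z + h) - f(r + h, z - h) - f(r - h, z + h) + f(r - h, z - h)) /
    (4 * h^2)
}

# Strong-form residual operators of the steady poroelastic system evaluated
# on the exact fields; their values become the manufactured volume forcing.
mms_forcing <- function(ex, params, r, z) {
  mix <- params$mixture; comps <- params$comps
  lam <- mix$lambda; mu <- mix$mu
  ur <- ex$ur; uz <- ex$uz
  # strains and their derivatives (numerically; the exact fields are smooth)
  err_ <- function(r, z) num_d(ur, "r", r, z)
  ezz_ <- function(r, z) num_d(uz, "z", r, z)
  eth_ <- function(r, z) ur(r, z) / r
  erz_ <- function(r, z) 0.5 * (num_d(ur, "z", r, z) + num_d(uz, "r", r, z))
  ev_ <- function(r, z) err_(r, z) + ezz_(r, z) + eth_(r, z)
  srr <- function(r, z) lam * ev_(r, z) + 2 * mu * err_(r, z)
  szz <- function(r, z) lam * ev_(r, z) + 2 * mu * ezz_(r, z)
  sth <- function(r, z) lam * ev_(r, z) + 2 * mu * eth_(r, z)
  srz <- function(r, z) 2 * mu * erz_(r, z)
  h <- 1e-5
  divs_r <- (srr(r + h, z) - srr(r - h, z)) / (2 * h) +
    (srz(r, z + h) - srz(r, z - h)) / (2 * h) + (srr(r, z) - sth(r, z)) / r
  divs_z <- (srz(r + h, z) - srz(r - h, z)) / (2 * h) +
    (szz(r, z + h) - szz(r, z - h)) / (2 * h) + srz(r, z) / r
  gpr <- gpz <- 0
  for (nm in c("I", "B", "L")) {
    ai <- comps[[nm]]$alpha_i
    gpr <- gpr + ai * num_d(ex$p[[nm]], "r", r, z)
    gpz <- gpz + ai * num_d(ex$p[[nm]], "z", r, z)
  }
  f_ur <- -(divs_r - gpr)
  f_uz <- -(divs_z - gpz)
  fp <- list()
  pI <- ex$p$I(r, z); pB <- ex$p$B(r, z); pL <- ex$p$L(r, z)
  s_BI <- mix$xi_BI * (pB - pI); s_LI <- mix$xi_LI * (pL - pI)
  fs <- equilibrium_sources(comps$I$p0, comps$B$p0, comps$L$p0,
                            mix$xi_BI, mix$xi_LI)
  for (nm in c("I", "B", "L")) {
    cp <- comps[[nm]]
    f <- ex$p[[nm]]
    lap <- num_d2(f, "rr", r, z) + num_d(f, "r", r, z) / r +
      num_d2(f, "zz", r, z)
    sterm <- switch(nm, I = s_BI + s_LI + fs$f_I, B = -s_BI + fs$f_B,
                    L = -s_LI + fs$f_L)
    fp[[nm]] <- -cp$w * (cp$kappa / mix$mu_f) * lap - sterm
  }
  list(f_ur = f_ur, f_uz = f_uz, f_pI = fp$I, f_pB = fp$B, f_pL = fp$L)
}

#' Steady manufactured-solution solve of the poroelastic system
#'
#' Imposes the exact fields on the whole boundary, adds the manufactured
#' volume forcing, solves the steady system and reports relative L2 errors.
#'
#' @param n elements per direction (unit-square meridian domain, offset from
#'   the axis to keep the hoop terms generic).
#' @param params parameter set; defaults to an O(1) synthetic mixture.
#' @return List with `err_u`, `err_pI` (relative L2) and `h`.
#' @export
mms_poroelastic <- function(n = 8, params = NULL) {
  if (is.null(params)) {
    mix <- mixture_parameters(E = 1e4, nu = 0.3, alpha = 0.9, mu_f = 1e-3,
                              xi_BI = 1e-7, xi_LI = 5e-8)
    comps <- list(
      I = compartment_parameters("I", M = 1e5, kappa = 1e-10, phi0 = 0.1,
                                 D = 1e-11, p0 = 0, w = 0.6, alpha_i = 0.54),
      B = compartment_parameters("B", M = 1e5, kappa = 2e-10, phi0 = 0.2,
                                 D = 1e-11, p0 = 0, w = 0.25, alpha_i = 0.225),
      L = compartment_parameters("L", M = 1e5, kappa = 2e-10, phi0 = 0.2,
                                 D = 1e-11, p0 = 0, w = 0.15, alpha_i = 0.135))
    params <- validate_parameters(mix, comps, NULL)
  }
  ex <- mms_exact()
  grid <- build_grid(1, 1, n, n)
  # shift away from the axis to exercise the hoop terms without 1/r blow-up
  grid$r <- grid$r + 0.5; grid$rc <- grid$rc + 0.5
  grid$r_extent <- 1.5
  fem <- fem_setup(grid)
  sys <- assemble_poroelastic_system(fem, params, bc = "none")
  nn <- fem$nn; off <- sys$offsets
  # manufactured load vector
  F <- numeric(sys$ndof)
  for (g in 1:4) {
    fo <- mms_forcing(ex, params, fem$rg[[g]], fem$zg[[g]])
    for (a in 1:4) {
      wNa <- fem$W[[g]] * fem$N[[g]][a]
      F[off["ur"] + seq_len(nn)] <- F[off["ur"] + seq_len(nn)] +
        accumulate_nodal(fem, a, wNa * fo$f_ur, nn)
      F[off["uz"] + seq_len(nn)] <- F[off["uz"] + seq_len(nn)] +
        accumulate_nodal(fem, a, wNa * fo$f_uz, nn)
      F[off["pI"] + seq_len(nn)] <- F[off["pI"] + seq_len(nn)] +
        accumulate_nodal(fem, a, wNa * fo$f_pI, nn)
      F[off["pB"] + seq_len(nn)] <- F[off["pB"] + seq_len(nn)] +
        accumulate_nodal(fem, a, wNa * fo$f_pB, nn)
      F[off["pL"] + seq_len(nn)] <- F[off["pL"] + seq_len(nn)] +
        accumulate_nodal(fem, a, wNa * fo$f_pL, nn)
    }
  }
  bnodes <- sort(unique(c(grid$axis, grid$outer, grid$bottom, grid$top)))
  rc <- grid$rc; zc <- grid$zc
  y_ex <- numeric(sys$ndof)
  y_ex[off["ur"] + seq_len(nn)] <- ex$ur(rc, zc)
  y_ex[off["uz"] + seq_len(nn)] <- ex$uz(rc, zc)
  for (nm in c("I", "B", "L"))
    y_ex[off[paste0("p", nm)] + seq_len(nn)] <- ex$p[[nm]](rc, zc)
  bc_idx <- as.integer(outer(bnodes, off, `+`))
  K <- apply_bc_matrix(sys$K, bc_idx)
  rhs <- F
  rhs <- rhs - as.numeric(sys$K %*% (y_ex * (seq_len(sys$ndof) %in% bc_idx)))
  rhs[bc_idx] <- y_ex[bc_idx]
  y <- solve_scaled(scaled_lu(K), rhs)
  l2 <- function(blk, exact) {
    num <- den <- 0
    fe <- y[off[blk] + seq_len(nn)]
    exv <- exact(rc, zc)
    for (g in 1:4) {
      e <- gp_value(fem, fe - exv, g)
      x <- gp_value(fem, exv, g)
      num <- num + sum(fem$W[[g]] * e^2); den <- den + sum(fem$W[[g]] * x^2)
    }
    sqrt(num / den)
  }
  list(err_u = l2("uz", ex$uz), err_pI = l2("pI", ex$p$I), h = 1 / n)
}

#' Mesh-refinement benchmark ladder
#'
#' Runs one of the verification benchmarks over a ladder of uniform
#' refinements and reports errors and observed orders
#' (`log2(err[k-1]/err[k])`).
#'
#' @param benchmark `"terzaghi"` or `"manufactured_poroelastic"`.
#' @param resolutions integer vector of element counts (per direction or
#'   along the column).
#' @return Data frame of class `benchmark_result` with columns `n`, `h`,
#'   errors and observed `order`; a non-monotone error ladder is flagged
#'   with a warning.
#' @export
run_benchmark <- function(benchmark = c("terzaghi", "manufactured_poroelastic"),
                          resolutions = c(8, 16, 32)) {
  benchmark <- match.arg(benchmark)
  rows <- lapply(resolutions, function(n) {
    if (benchmark == "terzaghi") {
      tz <- terzaghi_column(n_z = n)
      data.frame(n = n, h = 1 / n, err = tz$err_l2)
    } else {
      mm <- mms_poroelastic(n = n)
      data.frame(n = n, h = mm$h, err = mm$err_pI, err_u = mm$err_u)
    }
  })
  out <- do.call(rbind, rows)
  out$order <- c(NA, log2(out$err[-nrow(out)] / out$err[-1]))
  if (any(diff(out$err) > 0))
    warning("non-monotone error ladder")
  class(out) <- c("benchmark_result", class(out))
  out
}
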