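# Driver for the fully coupled injection stage: the linear poroelastic
# subsystem (constant matrices, one factorization for the whole run) feeds
# frozen alpha-level coefficients to the transport subsystem (linear in C,
# solved with an exact Newton step whose linear solve recycles a lagged
# factorization).

#' Scenario configuration for the injection stage
#'
#' @param params validated `poroinject_params`.
#' @param grid `axi_grid`; the injection point must lie on the axis and the
#'   probe locations inside the domain.
#' @param settings `solver_settings`.
#' @param t_end total simulated time (s).
#' @param snapshot_times times at which full nodal fields are stored (s).
#' @param probe_offset depth offset of the secondary pressure probe below
#'   the injection point (m).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(params = default_parameters(),
                            grid = NULL,
                            settings = solver_settings(dt = 5e-3),
                            t_end = 15,
                            snapshot_times = c(2, 5, 15),
                            probe_offset = 0.010) {
  if (is.null(grid)) grid <- default_injection_grid()
  inj <- params$injection
  if (is.null(inj)) stop("scenario requires injection parameters")
  if (abs(inj$centre["r"]) > 1e-12)
    stop("injection point must lie on the symmetry axis")
  if (inj$centre["z"] <= 0 || inj$centre["z"] >= grid$z_extent)
    stop("injection point must lie inside the domain")
  structure(list(params = params, grid = grid, settings = settings,
                 t_end = t_end, snapshot_times = snapshot_times,
                 probe_offset = probe_offset),
            class = "scenario_config")
}

#' Default graded injection grid
#'
#' Tensor-product grid for the 50 mm x 50 mm meridian domain, geometrically
#' graded towards the needle (axis, 4 mm below the top surface) so the
#' needle-scale source region is resolved at near-reference spacing while the
#' far field stays coarse.
#'
#' @param h_min spacing at the injection point (m).
#' @param growth geometric growth factor.
#' @param r_extent,z_extent domain extents (m).
#' @param z_inj injection depth coordinate (m).
#' @return `axi_grid`.
#' @export
default_injection_grid <- function(h_min = 1.1e-4, growth = 1.06,
                                   r_extent = 0.05, z_extent = 0.05,
                                   z_inj = 0.046, h_max = 2e-3) {
  rn <- graded_nodes(r_extent, 0, h_min, growth, h_max = h_max)
  zn <- graded_nodes(z_extent, z_inj, h_min, growth, h_max = h_max)
  build_grid(r_extent, z_extent, length(rn) - 1L, length(zn) - 1L,
             r_nodes = rn, z_nodes = zn)
}

#' Run the coupled injection simulation
#'
#' Starts from the physiological rest state (`u = 0`, `p_i = p_i0`,
#' `C_i = 0`) and advances the coupled poroelastic + transport system with
#' the generalized-alpha scheme, recording probe series every step and full
#' field snapshots at the configured times.
#'
#' @param config `scenario_config`.
#' @param verbose print progress every ~10% of steps.
#' @return Object of class `injection_result`: probe data frame (`t`, `p_I`,
#'   `p_B`, `p_L` at the injection point, `p_I_deep` etc. at the offset
#'   probe, `u_z_surface`), snapshots, final state, mass audits and run
#'   metadata.
#' @export
run_injection <- function(config, verbose = FALSE) {
  params <- config$params; grid <- config$grid
  st <- config$settings
  fem <- fem_setup(grid)
  sys <- assemble_poroelastic_system(fem, params)
  ts <- transport_structures(fem, params)
  co_ga <- generalized_alpha_coeffs(st$rho_inf)
  dt <- st$dt
  n_steps <- as.integer(round(config$t_end / dt))

  # constant poroelastic iteration matrix, factorized once
  Jpe <- apply_bc_matrix(co_ga$alpha_m * sys$M +
                           co_ga$alpha_f * co_ga$gamma * dt * sys$K,
                         sys$bc_idx)
  lu_pe <- scaled_lu(Jpe)
  atol_pe <- 1e-12 * max(1, sqrt(sum(sys$F0^2)) + sqrt(sum(sys$LQ^2)))

  nn <- fem$nn; off <- sys$offsets; offC <- ts$off
  y <- sys$y0; v <- numeric(sys$ndof)
  C <- numeric(3L * nn); Cd <- numeric(3L * nn)

  inj <- params$injection
  node_inj <- nearest_node(grid, 0, inj$centre["z"])
  node_deep <- nearest_node(grid, 0, inj$centre["z"] - config$probe_offset)
  node_top <- nearest_node(grid, 0, grid$z_extent)

  probes <- matrix(NA_real_, n_steps + 1L, 9L)
  colnames(probes) <- c("t", "p_I", "p_B", "p_L", "p_I_deep", "p_B_deep",
                        "p_L_deep", "u_z_surface", "C_I")
  rec <- function(k, t) {
    probes[k, ] <<- c(t,
                      y[off["pI"] + node_inj], y[off["pB"] + node_inj],
                      y[off["pL"] + node_inj],
                      y[off["pI"] + node_deep], y[off["pB"] + node_deep],
                      y[off["pL"] + node_deep],
                      y[off["uz"] + node_top],
                      C[offC["I"] + node_inj])
  }
  rec(1L, 0)

  snaps <- list()
  snap_steps <- unique(pmin(pmax(round(config$snapshot_times / dt), 1L), n_steps))
  cache_tr <- new.env()
  warned_phi <- FALSE
  qt_int <- 0      # trapezoidal integral of Qt for the fluid audit

  am <- co_ga$alpha_m; af <- co_ga$alpha_f; gam <- co_ga$gamma
  check_every <- 25L
  for (n in seq_len(n_steps)) {
    t_n <- (n - 1L) * dt
    t_af <- t_n + af * dt
    # --- poroelastic step: linear, so one exact Newton update with the
    # cached factorization; residual re-verified periodically
    v0 <- v * (gam - 1) / gam
    v_am0 <- v + am * (v0 - v)
    y_af0 <- y + af * dt * ((1 - gam) * v + gam * v0)
    R0 <- pe_residual(sys, v_am0, y_af0, t_af)
    v_new <- v0 - solve_scaled(lu_pe, bc_zero(R0, sys$bc_idx))
    y_new <- y + dt * ((1 - gam) * v + gam * v_new)
    if (n %% check_every == 1L) {
      rchk <- pe_residual(sys, v + am * (v_new - v),
                          y + af * (y_new - y), t_af)
      if (sqrt(sum(rchk^2)) > max(st$newton_tol * sqrt(sum(R0^2)), atol_pe))
        stop(sprintf("poroelastic step lost accuracy at t = %.4g s", t_af))
    }

    # --- transport step with coefficients at the alpha-levels
    y_af <- y + af * (y_new - y)
    v_am <- v + am * (v_new - v)
    co_tr <- transport_coefficients(fem, params, y_af, v_am, dt, clamp = "clip")
    if (!warned_phi) {
      ph <- range(co_tr$phi$I[[1]])
      if (ph[1] <= 1e-6 || ph[2] >= 1 - 1e-6) {
        warning(sprintf("interstitial porosity left (0,1) near the needle: outside small-strain validity there (clipped)"))
        warned_phi <- TRUE
      }
    }
    tsys <- assemble_transport_system(ts, co_tr, stage = "injection")
    qt_af <- injection_time_profile(t_af, inj)
    Jtr <- tsys$M          # same sparsity pattern as K: combine value slots
    Jtr@x <- am * tsys$M@x + af * gam * dt * tsys$K@x
    c0 <- Cd * (gam - 1) / gam
    cd_am0 <- Cd + am * (c0 - Cd)
    ca0 <- C + af * dt * ((1 - gam) * Cd + gam * c0)
    Rc <- as.numeric(tsys$M %*% cd_am0 + tsys$K %*% ca0) - qt_af * tsys$F_shape
    Cd_new <- c0 - as.numeric(linear_solve(Jtr, Rc, st, cache = cache_tr,
                                           backend = "recycled"))
    C <- C + dt * ((1 - gam) * Cd + gam * Cd_new)
    Cd <- Cd_new
    y <- y_new; v <- v_new
    qt_int <- qt_int + dt * injection_time_profile(t_n + dt / 2, inj)

    rec(n + 1L, n * dt)
    if (n %in% snap_steps) {
      snaps[[sprintf("t%g", n * dt)]] <- extract_fields(fem, params, y, C)
    }
    if (verbose && n %% max(1L, n_steps %/% 10L) == 0L)
      message(sprintf("  t = %.3f s (%d/%d steps)", n * dt, n, n_steps))
  }

  masses <- drug_masses(fem, params, y, C)
  structure(list(
    probes = as.data.frame(probes), snapshots = snaps,
    final = list(y = y, ydot = v, C = C, Cdot = Cd),
    fem = fem, grid = grid, params = params, settings = st,
    nodes = list(inj = node_inj, deep = node_deep, top = node_top),
    audit = list(injected_volume = sum(ts$lq) * qt_int,
                 nominal_volume = inj$V_inj,
                 drug_mass = masses),
    meta = list(n_steps = n_steps, dt = dt, n_el = grid$n_el)
  ), class = "injection_result")
}

bc_zero <- function(r, idx) { if (length(idx)) r[idx] <- 0; r }

#' Derived nodal fields of a state
#'
#' Computes the snapshot field set from a poroelastic state vector and the
#' concentration vector: displacements, pressures, volumetric strain,
#' per-network porosities, the volume-averaged porosity, concentrations and
#' relative concentrations.
#'
#' @param fem `axi_fem`.
#' @param params validated `poroinject_params`.
#' @param y poroelastic state vector (`u_r | u_z | p_I | p_B | p_L`).
#' @param C concentration vector (`C_I | C_B | C_L`).
#' @return Named list of nodal fields.
#' @export
extract_fields <- function(fem, params, y, C) {
  nn <- fem$nn; off <- pe_offsets(nn); offC <- tr_offsets(nn)
  mix <- params$mixture; comps <- params$comps
  ur <- y[off["ur"] + seq_len(nn)]; uz <- y[off["uz"] + seq_len(nn)]
  ev <- nodal_volumetric_strain(fem, ur, uz)
  out <- list(u_r = ur, u_z = uz, eps_v = ev)
  phis <- 0
  for (nm in c("I", "B", "L")) {
    cp <- comps[[nm]]
    p <- y[off[paste0("p", nm)] + seq_len(nn)]
    phi <- porosity_update(cp$phi0, ev, 0, p, cp$p0, mix$alpha, cp$alpha_i,
                           cp$w, cp$M, params$phi_s0, clamp = "clip")
    out[[paste0("p_", nm)]] <- p
    out[[paste0("phi_", nm)]] <- phi
    out[[paste0("C_", nm)]] <- C[offC[nm] + seq_len(nn)]
    phis <- phis + cp$w * phi
  }
  out$phi_s <- phis
  for (nm in c("I", "B", "L"))
    out[[paste0("CR_", nm)]] <- relative_concentration(
      out[[paste0("C_", nm)]], out[[paste0("phi_", nm)]], comps[[nm]]$w, phis)
  out
}

# Per-network drug masses at the current state.
drug_masses <- function(fem, params, y, C) {
  f <- extract_fields(fem, params, y, C)
  vapply(c("I", "B", "L"), function(nm)
    compartment_drug_mass(fem, f[[paste0("C_", nm)]], f[[paste0("phi_", nm)]],
                          params$comps[[nm]]$w), 0)
}

#' Probe time series from an injection result
#'
#' @param result `injection_result`.
#' @param quantity one of the probe columns (`"p_I"`, `"p_B"`, `"p_L"`,
#'   `"p_I_deep"`, ..., `"u_z_surface"`, `"C_I"`).
#' @return Data frame with `t` and the requested series.
#' @export
probe_time_series <- function(result, quantity) {
  if (!quantity %in% names(result$probes))
    stop(sprintf("unknown probe quantity '%s'", quantity))
  result$probes[, c("t", quantity)]
}

#' Plume radius along the injection-depth line
#'
#' Radius (from the symmetry axis) of the region where the relative
#' concentration exceeds a threshold, measured along the horizontal line
#' through the injection point; the crossing is located by linear
#' interpolation between nodes.  The sharp front left by the tiny mAb
#' diffusivity makes the result insensitive to the threshold over a wide
#' range.
#'
#' @param result `injection_result` (its final state is used) or a field
#'   list from `extract_fields`.
#' @param compartment `"I"`, `"B"` or `"L"`.
#' @param threshold relative-concentration threshold (default 0.01, i.e. 1%
#'   of the injected normalized concentration).
#' @param fields optional precomputed field list (overrides `result$final`).
#' @return Radius (m); 0 when the field is nowhere above threshold; the
#'   domain radius when the plume reaches the outer boundary.
#' @export
plume_radius <- function(result, compartment = "I", threshold = 0.01,
                         fields = NULL) {
  stopifnot(threshold > 0)
  grid <- result$grid
  f <- if (!is.null(fields)) fields else
    extract_fields(result$fem, result$params, result$final$y, result$final$C)
  cr <- f[[paste0("CR_", compartment)]]
  j <- which.min(abs(grid$z - result$params$injection$centre["z"]))
  row <- cr[(j - 1L) * (grid$n_r + 1L) + seq_len(grid$n_r + 1L)]
  above <- row >= threshold
  if (!any(above)) return(0)
  k <- max(which(above))
  if (k == length(row)) return(grid$r[k])
  # interpolate the crossing between node k and k+1
  r1 <- grid$r[k]; r2 <- grid$r[k + 1]
  c1 <- row[k]; c2 <- row[k + 1]
  r1 + (c1 - threshold) / max(c1 - c2, 1e-300) * (r2 - r1)
}

#' Radius of interstitial pressure dominance
#'
#' Largest radius, along the horizontal line through the injection point,
#' within which the interstitial pressure exceeds both vessel pressures.
#' Inside this region transmural flow (and hence drug absorption) is
#' directed from the interstitium into both vessel networks.
#'
#' @param result `injection_result`.
#' @param fields field list (e.g. a snapshot); defaults to the final state.
#' @return Radius (m); 0 when interstitial pressure is nowhere dominant.
#' @export
dominant_pressure_radius <- function(result, fields = NULL) {
  grid <- result$grid
  f <- if (!is.null(fields)) fields else
    extract_fields(result$fem, result$params, result$final$y, result$final$C)
  j <- which.min(abs(grid$z - result$params$injection$centre["z"]))
  sel <- (j - 1L) * (grid$n_r + 1L) + seq_len(grid$n_r + 1L)
  gap <- f$p_I[sel] - pmax(f$p_B[sel], f$p_L[sel])
  if (gap[1] <= 0) return(0)
  below <- which(gap <= 0)
  if (!length(below)) return(grid$r_extent)
  k <- min(below) - 1L            # last dominant node
  r1 <- grid$r[k]; r2 <- grid$r[k + 1]
  g1 <- gap[k]; g2 <- gap[k + 1]
  r1 + g1 / max(g1 - g2, 1e-300) * (r2 - r1)
}
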