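# Configuration, serialization and output.  Configurations are YAML with
# clinical units stated in the key names (kPa, mm, mL, min where natural);
# everything is converted to SI at the boundary and validated through
# validate_parameters().

config_template <- function() {
  list(
    geometry = list(radius_mm = 50, height_mm = 50),
    mechanical = list(E_kPa = 30, nu = 0.45, alpha = 0.99, mu_f_Pa_s = 1e-3),
    exchange = list(xi_BI_per_Pa_s = 2.5e-7, xi_LI_per_Pa_s = 1.25e-7),
    interstitial = list(M_MPa = 0.125, kappa_m2 = 6e-13, phi0 = 0.01,
                        D_m2_s = 1e-11, p0_kPa = 0, w = 0.85, alpha_i = 0.8415),
    blood = list(M_MPa = 0.1, kappa_m2 = 1.2e-12, phi0 = 0.1,
                 D_m2_s = 1e-11, p0_kPa = 1, w = 0.1, alpha_i = 0.099),
    lymphatic = list(M_MPa = 0.1, kappa_m2 = 1.2e-12, phi0 = 0.1,
                     D_m2_s = 1e-11, p0_kPa = -1, w = 0.05, alpha_i = 0.0495),
    injection = list(alpha_T = 10 / 9, beta_per_s = 7, t_sh_s = 0.5,
                     Lambda_per_mm = 5000, R_inj_mm = 0.15, V_inj_mL = 2,
                     T_inj_s = 5, depth_below_top_mm = 4),
    solver = list(dt_s = 5e-3, rho_inf = 0.5, newton_tol = 1e-6,
                  linear_tol = 1e-8, t_end_s = 15,
                  snapshot_times_s = c(2, 5, 15)),
    grid = list(type = "graded", h_min_mm = 0.11, growth = 1.06,
                h_max_mm = 2, n_r = NULL, n_z = NULL)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a scenario configuration
#'
#' Reads a YAML configuration, fills unspecified keys with the default
#' parameter set, converts clinical units to SI and validates all
#' parameter constraints.  An empty (or missing) file yields the full
#' default scenario.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return `scenario_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_template()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop(sprintf("unknown config section(s): %s",
                     paste(unknown, collapse = ", ")))
      cfg <- merge_config(cfg, user)
    }
  }
  config_to_scenario(cfg)
}

config_to_scenario <- function(cfg) {
  me <- cfg$mechanical; xc <- cfg$exchange
  mix <- mixture_parameters(E = me$E_kPa * 1e3, nu = me$nu, alpha = me$alpha,
                            mu_f = me$mu_f_Pa_s,
                            xi_BI = xc$xi_BI_per_Pa_s,
                            xi_LI = xc$xi_LI_per_Pa_s)
  mk_comp <- function(nm, s) {
    compartment_parameters(nm, M = s$M_MPa * 1e6, kappa = s$kappa_m2,
                           phi0 = s$phi0, D = s$D_m2_s, p0 = s$p0_kPa * 1e3,
                           w = s$w, alpha_i = s$alpha_i)
  }
  comps <- list(I = mk_comp("I", cfg$interstitial),
                B = mk_comp("B", cfg$blood),
                L = mk_comp("L", cfg$lymphatic))
  gj <- cfg$geometry
  R <- gj$radius_mm * 1e-3; Z <- gj$height_mm * 1e-3
  ij <- cfg$injection
  inj <- injection_parameters(alpha_T = ij$alpha_T, beta = ij$beta_per_s,
                              t_sh = ij$t_sh_s,
                              Lambda = ij$Lambda_per_mm * 1e3,
                              R_inj = ij$R_inj_mm * 1e-3,
                              V_inj = ij$V_inj_mL * 1e-6,
                              T_inj = ij$T_inj_s,
                              centre = c(r = 0,
                                         z = Z - ij$depth_below_top_mm * 1e-3))
  params <- validate_parameters(mix, comps, inj)
  gr <- cfg$grid
  grid <- if (identical(gr$type, "uniform")) {
    build_grid(R, Z, gr$n_r, gr$n_z)
  } else {
    default_injection_grid(h_min = gr$h_min_mm * 1e-3, growth = gr$growth,
                           r_extent = R, z_extent = Z,
                           z_inj = inj$centre["z"],
                           h_max = gr$h_max_mm * 1e-3)
  }
  so <- cfg$solver
  scenario_config(params = params, grid = grid,
                  settings = solver_settings(dt = so$dt_s,
                                             rho_inf = so$rho_inf,
                                             newton_tol = so$newton_tol,
                                             linear_tol = so$linear_tol),
                  t_end = so$t_end_s,
                  snapshot_times = so$snapshot_times_s)
}

#' Save the configuration of a scenario back to YAML
#'
#' Writes the fully resolved configuration (defaults filled in) so that a
#' run can be reproduced from its output directory alone.
#'
#' @param cfg raw configuration list (as from [config_template()]) or a
#'   path written by a previous call.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write simulation outputs
#'
#' Emits the probe series as CSV, field snapshots as legacy-ASCII VTK
#' structured grids (readable by standard VTK tools), and a JSON run
#' manifest with the resolved parameters, grid, step sizes and summary
#' metrics.  File naming is deterministic.
#'
#' @param result `injection_result`.
#' @param outdir output directory (created if missing).
#' @param absorption optional `absorption_result` to include.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, outdir, absorption = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  f <- file.path(outdir, "probes.csv")
  utils::write.csv(result$probes, f, row.names = FALSE)
  files <- c(files, f)
  for (nm in names(result$snapshots)) {
    f <- file.path(outdir, sprintf("fields_%s.vtk", nm))
    write_vtk_snapshot(result$grid, result$snapshots[[nm]], f,
                       title = sprintf("poroinject snapshot %s", nm))
    files <- c(files, f)
  }
  if (!is.null(absorption)) {
    f <- file.path(outdir, "fractions.csv")
    utils::write.csv(absorption$fractions, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- run_manifest(result, absorption)
  f <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Run manifest
#'
#' @param result `injection_result`.
#' @param absorption optional `absorption_result`.
#' @return List with parameters, discretization and summary metrics.
#' @export
run_manifest <- function(result, absorption = NULL) {
  pr <- result$probes
  p <- result$params
  summary <- list(
    peak_interstitial_pressure_MPa = max(pr$p_I) / 1e6,
    surface_displacement_end_injection_mm =
      1e3 * pr$u_z_surface[which.min(abs(pr$t - p$injection$T_inj))],
    surface_displacement_final_mm = 1e3 * pr$u_z_surface[nrow(pr)],
    plume_extent_interstitial_mm = 1e3 * plume_radius(result),
    injected_volume_mL = 1e6 * result$audit$injected_volume,
    drug_mass_fractions_pct =
      as.list(100 * result$audit$drug_mass / sum(result$audit$drug_mass))
  )
  if (!is.null(absorption)) {
    fin <- absorption$fractions[nrow(absorption$fractions), ]
    summary$fractions_300min_pct <- list(I = fin$frac_I, B = fin$frac_B,
                                         L = fin$frac_L)
    summary$decay_coefficient_per_min <- absorption$k
  }
  list(
    package = "poroinject",
    version = as.character(utils::packageVersion("poroinject")),
    grid = list(n_r = result$grid$n_r, n_z = result$grid$n_z,
                n_el = result$grid$n_el,
                r_extent_mm = 1e3 * result$grid$r_extent,
                z_extent_mm = 1e3 * result$grid$z_extent),
    dt_s = result$meta$dt, n_steps = result$meta$n_steps,
    parameters = params_to_list(p),
    summary = summary
  )
}

params_to_list <- function(p) {
  mix <- p$mixture
  out <- list(mixture = mix[c("E", "nu", "alpha", "mu_f", "xi_BI", "xi_LI")])
  for (nm in c("I", "B", "L"))
    out[[nm]] <- p$comps[[nm]][c("M", "kappa", "phi0", "D", "p0", "w",
                                 "alpha_i")]
  if (!is.null(p$injection))
    out$injection <- p$injection[c("alpha_T", "beta", "t_sh", "Lambda",
                                   "R_inj", "V_inj", "T_inj")]
  out
}

#' Write one snapshot as a legacy-ASCII VTK structured grid
#'
#' @param grid `axi_grid`.
#' @param fields named list of nodal fields (from the snapshot machinery).
#' @param path output file.
#' @param title VTK header title.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(grid, fields, path, title = "poroinject") {
  nrp <- grid$n_r + 1L; nzp <- grid$n_z + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nrp, nzp),
               sprintf("POINTS %d double", grid$n_nodes)), con)
  pts <- cbind(grid$rc, grid$zc, 0)
  writeLines(apply(format(pts, digits = 9, trim = TRUE), 1, paste,
                   collapse = " "), con)
  writeLines(sprintf("POINT_DATA %d", grid$n_nodes), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) != grid$n_nodes) next
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(v, digits = 9, trim = TRUE), con)
  }
  invisible(path)
}
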