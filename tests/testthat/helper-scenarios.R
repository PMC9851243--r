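# Shared fixtures: tiny grids and scenario builders used across test files.

tiny_grid <- function(n = 6) build_grid(0.05, 0.05, n, n)

tiny_fem <- function(n = 6) fem_setup(tiny_grid(n))

# Parameter set with the injection switched off (vanishing injected volume)
# for equilibrium tests.
quiet_params <- function() {
  pr <- default_parameters()
  inj <- pr$injection
  inj$V_inj <- 1e-30
  validate_parameters(pr$mixture, pr$comps, inj)
}

# Small but physically meaningful injection scenario used by several tests:
# graded grid resolving the needle, short horizon.
small_scenario <- function(t_end = 1, dt = 0.05, n_coarse = 10) {
  grid <- default_injection_grid(h_min = 4e-4, growth = 1.25, h_max = 5e-3)
  scenario_config(params = default_parameters(), grid = grid,
                  settings = solver_settings(dt = dt), t_end = t_end,
                  snapshot_times = t_end)
}

# Memoized shared coarse reproduction run for the acceptance suite: one
# 15 s injection on the desk-scale graded grid, chained into the long
# absorption stage.  Built lazily on first use.
acceptance_env <- new.env()

acceptance_run <- function() {
  if (is.null(acceptance_env$res)) {
    cfg <- scenario_config(
      params = default_parameters(),
      grid = default_injection_grid(h_min = 1.2e-4, growth = 1.09,
                                    h_max = 3e-3),
      settings = solver_settings(dt = 0.02), t_end = 15,
      snapshot_times = c(2, 5, 15))
    acceptance_env$res <- suppressWarnings(run_injection(cfg))
  }
  acceptance_env$res
}

acceptance_absorption <- function() {
  if (is.null(acceptance_env$ab)) {
    acceptance_env$ab <- run_absorption(acceptance_run(),
                                        duration = 300 * 60, dt_long = 20,
                                        cadence = 300)
  }
  acceptance_env$ab
}
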