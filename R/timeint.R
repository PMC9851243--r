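# Generalized-alpha time integration for first-order (index-1 DAE) systems,
# Newton-Raphson per step, and a backend-agnostic linear-solve contract.

#' Generalized-alpha coefficients for first-order systems
#'
#' One-parameter family controlled by the spectral radius at infinity:
#' `alpha_m = (3 - rho)/(2 (1 + rho))`, `alpha_f = 1/(1 + rho)`,
#' `gamma = 1/2 + alpha_m - alpha_f`, which is second-order accurate and
#' unconditionally stable on the linear model problem; `rho_inf = 1` recovers
#' the undamped midpoint member.
#'
#' @param rho_inf spectral radius at infinity, in `[0, 1]`.
#' @return List with `alpha_m`, `alpha_f`, `gamma`.
#' @export
generalized_alpha_coeffs <- function(rho_inf) {
  if (rho_inf < 0 || rho_inf > 1) stop("rho_inf must lie in [0, 1]")
  am <- 0.5 * (3 - rho_inf) / (1 + rho_inf)
  af <- 1 / (1 + rho_inf)
  list(alpha_m = am, alpha_f = af, gamma = 0.5 + am - af)
}

#' Solver settings
#'
#' @param dt time step (s).
#' @param rho_inf generalized-alpha spectral radius (default 0.5: a standard
#'   compromise between accuracy and damping of spurious high frequencies in
#'   poroelasticity).
#' @param newton_tol relative residual tolerance of the Newton loop.
#' @param newton_max maximum Newton iterations per step.
#' @param linear_tol relative residual tolerance of the linear solver.
#' @param linear_max maximum inner iterations when a recycled factorization
#'   is used as the solver.
#' @param max_retries step-halving retries after a Newton failure.
#' @return List of class `solver_settings`.
#' @export
solver_settings <- function(dt, rho_inf = 0.5, newton_tol = 1e-6,
                            newton_max = 10L, linear_tol = 1e-8,
                            linear_max = 25L, max_retries = 3L) {
  stopifnot(dt > 0, newton_tol > 0, newton_tol < 1, linear_tol > 0, linear_tol < 1)
  structure(list(dt = dt, rho_inf = rho_inf, newton_tol = newton_tol,
                 newton_max = newton_max, linear_tol = linear_tol,
                 linear_max = linear_max, max_retries = max_retries),
            class = "solver_settings")
}

# Sparse LU with symmetric Jacobi (diagonal) equilibration.  The coupled
# poroelastic system mixes stress-scale and storage-scale entries over ~10
# orders of magnitude; scaling by 1/sqrt(|diag|) keeps the factorization
# well conditioned without changing the solution.
scaled_lu <- function(A) {
  d <- 1 / sqrt(pmax(abs(Matrix::diag(A)), 1e-300))
  D <- Matrix::Diagonal(x = d)
  list(lu = Matrix::lu(D %*% A %*% D), d = d)
}

solve_scaled <- function(S, b) {
  S$d * as.numeric(Matrix::solve(S$lu, S$d * b))
}

#' Linear solve contract
#'
#' Returns `x` with relative residual below `tol` independent of the backend:
#' a fresh sparse LU (`"direct"`), or iterative refinement preconditioned by
#' a previously stored factorization (`"recycled"`), falling back to a fresh
#' factorization when the recycled one has drifted too far.
#'
#' @param A sparse system matrix.
#' @param b right-hand side.
#' @param settings `solver_settings` (supplies tolerances).
#' @param cache optional environment holding `lu` (a recycled factorization);
#'   updated in place when a refactorization happens.
#' @param backend `"direct"` or `"recycled"`.
#' @return Solution vector, with attributes `iterations` and `residual`.
#' @export
linear_solve <- function(A, b, settings = solver_settings(1),
                         cache = NULL, backend = c("direct", "recycled")) {
  backend <- match.arg(backend)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(structure(numeric(length(b)), iterations = 0L, residual = 0))
  if (backend == "direct" || is.null(cache) || is.null(cache$lu)) {
    F <- scaled_lu(A)
    if (!is.null(cache)) cache$lu <- F
    x <- solve_scaled(F, b)
    res <- sqrt(sum((as.numeric(A %*% x) - b)^2)) / nb
    if (!is.finite(res) || res > settings$linear_tol)
      stop(sprintf("linear solve breakdown: achieved relative residual %.3g", res))
    return(structure(x, iterations = 1L, residual = res))
  }
  # recycled factorization as a BiCGSTAB preconditioner; the step-to-step
  # coefficient drift is localized (near the needle), i.e. a low-rank
  # perturbation that a Krylov method absorbs in a few iterations
  bi <- bicgstab(A, b, prec = function(r) solve_scaled(cache$lu, r),
                 tol = settings$linear_tol, maxit = settings$linear_max)
  if (bi$converged)
    return(structure(bi$x, iterations = bi$iterations, residual = bi$residual))
  cache$lu <- scaled_lu(A)
  x <- solve_scaled(cache$lu, b)
  res <- sqrt(sum((as.numeric(A %*% x) - b)^2)) / nb
  if (!is.finite(res) || res > settings$linear_tol)
    stop(sprintf("linear solve breakdown: achieved relative residual %.3g", res))
  structure(x, iterations = settings$linear_max + 1L, residual = res)
}

# Right-preconditioned BiCGSTAB (van der Vorst).
bicgstab <- function(A, b, prec, tol, maxit) {
  nb <- sqrt(sum(b^2))
  x <- prec(b)
  r <- b - as.numeric(A %*% x)
  res <- sqrt(sum(r^2)) / nb
  if (is.finite(res) && res <= tol)
    return(list(x = x, converged = TRUE, iterations = 0L, residual = res))
  rt <- r; rho0 <- 1; alpha <- 1; omega <- 1
  vv <- pp <- numeric(length(b))
  for (it in seq_len(maxit)) {
    rho <- sum(rt * r)
    if (!is.finite(rho) || abs(rho) < 1e-300) break
    beta <- (rho / rho0) * (alpha / omega)
    pp <- r + beta * (pp - omega * vv)
    ph <- prec(pp)
    vv <- as.numeric(A %*% ph)
    denom <- sum(rt * vv)
    if (!is.finite(denom) || abs(denom) < 1e-300) break
    alpha <- rho / denom
    s <- r - alpha * vv
    if (sqrt(sum(s^2)) / nb <= tol) {
      x <- x + alpha * ph
      return(list(x = x, converged = TRUE, iterations = it,
                  residual = sqrt(sum(s^2)) / nb))
    }
    sh <- prec(s)
    tv <- as.numeric(A %*% sh)
    tt <- sum(tv * tv)
    if (!is.finite(tt) || tt < 1e-300) break
    omega <- sum(tv * s) / tt
    x <- x + alpha * ph + omega * sh
    r <- s - omega * tv
    res <- sqrt(sum(r^2)) / nb
    if (is.finite(res) && res <= tol)
      return(list(x = x, converged = TRUE, iterations = it, residual = res))
    rho0 <- rho
  }
  list(x = x, converged = FALSE, iterations = maxit, residual = res)
}

#' Newton-Raphson driver
#'
#' Solves `residual(x) = 0` with an (optionally approximate) Jacobian solve
#' supplied by the caller.  Convergence is measured on the residual norm
#' relative to its initial value (absolute floor `atol`).
#'
#' @param residual function of `x` returning the residual vector.
#' @param solve_jac function of `(x, r)` returning the Newton increment
#'   solving `J dx = r` (exactly or approximately).
#' @param x0 initial guess.
#' @param tol relative tolerance; `atol` absolute floor on the residual norm.
#' @param max_it maximum iterations.
#' @param atol see above.
#' @return List with `x`, `converged`, `iterations`, `history` (residual
#'   norms).  On non-convergence `converged` is `FALSE` and the last iterate
#'   is returned for diagnosis.
#' @export
newton_solve <- function(residual, solve_jac, x0, tol = 1e-6, max_it = 10L,
                         atol = 0) {
  x <- x0
  r <- residual(x)
  n0 <- sqrt(sum(r^2))
  hist <- n0
  if (n0 <= atol) return(list(x = x, converged = TRUE, iterations = 0L, history = hist))
  for (it in seq_len(max_it)) {
    x <- x - solve_jac(x, r)
    r <- residual(x)
    nr <- sqrt(sum(r^2))
    hist <- c(hist, nr)
    if (!is.finite(nr)) break
    if (nr <= max(tol * n0, atol))
      return(list(x = x, converged = TRUE, iterations = it, history = hist))
    # stagnation at the linear-solver floor after a solid reduction: accept
    if (it >= 2L && nr >= 0.5 * hist[it] && nr <= sqrt(tol) * n0)
      return(list(x = x, converged = TRUE, iterations = it, history = hist))
  }
  list(x = x, converged = FALSE, iterations = length(hist) - 1L, history = hist)
}

#' One generalized-alpha step of a first-order system
#'
#' Advances `R(ydot, y, t) = 0` from `t` to `t + dt`.  The unknown is the
#' end-of-step rate; the residual is evaluated at the intermediate
#' alpha-levels.  The caller supplies the residual and an increment solver
#' for the iteration matrix `alpha_m dR/dydot + alpha_f gamma dt dR/dy`.
#'
#' @param y,ydot state and rate at time `t`.
#' @param t,dt current time and step size.
#' @param residual function `(ydot_am, y_af, t_af)` returning the residual.
#' @param solve_jac function `(r)` returning the increment in the rate
#'   unknown for residual `r` (exact or approximate Jacobian solve).
#' @param settings `solver_settings`.
#' @param co generalized-alpha coefficients (precomputed for speed).
#' @param atol absolute residual floor forwarded to [newton_solve()]; set it
#'   to the roundoff scale of the assembled residual so that an equilibrium
#'   state is recognized as converged.
#' @return List `y`, `ydot` at `t + dt`, plus `newton` diagnostics.
#' @export
generalized_alpha_step <- function(y, ydot, t, dt, residual, solve_jac,
                                   settings,
                                   co = generalized_alpha_coeffs(settings$rho_inf),
                                   atol = 0) {
  am <- co$alpha_m; af <- co$alpha_f; gam <- co$gamma
  t_af <- t + af * dt
  res_of <- function(v) {
    v_am <- ydot + am * (v - ydot)
    y_af <- y + af * dt * ((1 - gam) * ydot + gam * v)
    residual(v_am, y_af, t_af)
  }
  v0 <- ydot * (gam - 1) / gam          # constant-state predictor
  ns <- newton_solve(res_of, function(x, r) solve_jac(r), v0,
                     tol = settings$newton_tol, max_it = settings$newton_max,
                     atol = atol)
  if (!ns$converged)
    stop(structure(class = c("newton_failure", "error", "condition"),
                   list(message = sprintf(
                     "Newton failed at t = %.6g (residual history: %s)",
                     t, paste(signif(ns$history, 3), collapse = " -> ")),
                     call = NULL, history = ns$history)))
  v <- ns$x
  list(y = y + dt * ((1 - gam) * ydot + gam * v), ydot = v,
       newton = list(iterations = ns$iterations, history = ns$history))
}
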