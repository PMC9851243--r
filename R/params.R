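#' Lame constants from engineering moduli
#'
#' Converts Young's modulus and Poisson's ratio to the Lame parameters used by
#' the isotropic small-strain stress law.
#'
#' @param E Young's modulus (Pa), positive.
#' @param nu Poisson's ratio, in (0, 0.5) strictly; the incompressible limit
#'   `nu = 0.5` is rejected rather than returning an infinite `lambda`.
#' @return A list with elements `lambda` and `mu` (Pa).
#' @examples
#' lame_from_engineering(30e3, 0.45)
#' @export
lame_from_engineering <- function(E, nu) {
  if (!is.finite(E) || E <= 0) stop("invalid material: E must be > 0")
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5)
    stop("invalid material: nu must lie strictly in (0, 0.5)")
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu     = E / (2 * (1 + nu)))
}

#' Cauchy stress of the solid skeleton
#'
#' Linear isotropic law sigma = lambda tr(eps) I + 2 mu eps for a symmetric
#' strain tensor.
#'
#' @param eps symmetric strain matrix (any dimension).
#' @param lambda,mu Lame constants (Pa).
#' @return Stress matrix (Pa), symmetric.
#' @export
cauchy_stress <- function(eps, lambda, mu) {
  eps <- as.matrix(eps)
  if (!isTRUE(all.equal(eps, t(eps), tolerance = 1e-10)))
    stop("strain tensor must be symmetric")
  lambda * sum(diag(eps)) * diag(nrow(eps)) + 2 * mu * eps
}

#' Mixture-level material parameters
#'
#' Constants shared by the whole three-network mixture.  Defaults are the
#' reference subcutaneous-tissue values used throughout the package.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio.
#' @param alpha total Biot-Willis coefficient (sum over the three networks).
#' @param mu_f fluid dynamic viscosity (Pa s).
#' @param xi_BI,xi_LI transmural fluid-exchange coefficients between the
#'   interstitium and the blood / lymphatic networks (1/(Pa s)).
#' @return Object of class `mixture_parameters` (a list, with derived
#'   `lambda`, `mu`).
#' @export
mixture_parameters <- function(E = 30e3, nu = 0.45, alpha = 0.99,
                               mu_f = 1e-3, xi_BI = 2.5e-7, xi_LI = 1.25e-7) {
  lm <- lame_from_engineering(E, nu)
  if (mu_f <= 0) stop("invalid material: mu_f must be > 0")
  if (xi_BI < 0 || xi_LI < 0) stop("invalid material: exchange coefficients must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("invalid material: total Biot coefficient must lie in (0, 1]")
  structure(list(E = E, nu = nu, lambda = lm$lambda, mu = lm$mu,
                 alpha = alpha, mu_f = mu_f, xi_BI = xi_BI, xi_LI = xi_LI),
            class = "mixture_parameters")
}

#' Per-network compartment parameters
#'
#' One set per compartment: interstitium (`"I"`), blood (`"B"`), lymph (`"L"`).
#'
#' @param name one of `"I"`, `"B"`, `"L"`.
#' @param M Biot modulus (Pa).
#' @param kappa absolute permeability (m^2).
#' @param phi0 initial porosity (volume of network fluid per network volume).
#' @param D drug diffusion coefficient (m^2/s).
#' @param p0 physiological fluid pressure (Pa); may be negative (lymph).
#' @param w volume fraction of the network in the mixture.
#' @param alpha_i Biot-Willis coefficient of the network.
#' @return Object of class `compartment_parameters`.
#' @export
compartment_parameters <- function(name, M, kappa, phi0, D, p0, w, alpha_i) {
  stopifnot(name %in% c("I", "B", "L"))
  for (v in c("M", "kappa", "phi0", "D", "w", "alpha_i")) {
    x <- get(v)
    if (!is.finite(x) || x <= 0) stop(sprintf("compartment %s: %s must be > 0", name, v))
  }
  if (phi0 >= 1) stop(sprintf("compartment %s: phi0 must be < 1", name))
  if (w >= 1) stop(sprintf("compartment %s: w must be < 1", name))
  structure(list(name = name, M = M, kappa = kappa, phi0 = phi0, D = D,
                 p0 = p0, w = w, alpha_i = alpha_i),
            class = "compartment_parameters")
}

#' Default compartment parameter sets
#'
#' Reference values for human subcutaneous tissue: a low-porosity interstitium
#' and two stiffer, more permeable vessel networks at +1 kPa (blood) and
#' -1 kPa (lymph) physiological pressure.
#'
#' @return Named list of three `compartment_parameters` (`I`, `B`, `L`).
#' @export
default_compartments <- function() {
  list(
    I = compartment_parameters("I", M = 0.125e6, kappa = 6e-13,  phi0 = 0.01,
                               D = 1e-11, p0 = 0,     w = 0.85, alpha_i = 0.8415),
    B = compartment_parameters("B", M = 0.1e6,   kappa = 1.2e-12, phi0 = 0.10,
                               D = 1e-11, p0 = 1000,  w = 0.10, alpha_i = 0.099),
    L = compartment_parameters("L", M = 0.1e6,   kappa = 1.2e-12, phi0 = 0.10,
                               D = 1e-11, p0 = -1000, w = 0.05, alpha_i = 0.0495)
  )
}

#' Injection source parameters
#'
#' The needle source is a fixed-rate flow distributed over a small spherical
#' neighbourhood of the injection point, switched on and off smoothly in time.
#' Defaults describe a 2 mL / 5 s (1440 mL/h) injection through a 0.15 mm
#' radius needle.
#'
#' @param alpha_T dimensionless time-profile normalization factor.
#' @param beta ramp rate of the on/off switch (1/s).
#' @param t_sh time shift of the switch-on (s); must be < `T_inj`.
#' @param Lambda spatial sharpness of the source edge (1/m).
#' @param R_inj source-sphere (needle) radius (m).
#' @param V_inj total injected volume (m^3).
#' @param T_inj injection duration (s).
#' @param centre injection point `c(r, z)` in metres.
#' @param c_drug normalized concentration of the injected solution
#'   (dimensionless; the drug scale is set so this is 1).
#' @return Object of class `injection_parameters`.
#' @export
injection_parameters <- function(alpha_T = 10 / 9, beta = 7, t_sh = 0.5,
                                 Lambda = 5e6, R_inj = 1.5e-4, V_inj = 2e-6,
                                 T_inj = 5, centre = c(r = 0, z = 0.046),
                                 c_drug = 1) {
  for (v in c("alpha_T", "beta", "t_sh", "Lambda", "R_inj", "V_inj", "T_inj")) {
    x <- get(v)
    if (!is.finite(x) || x <= 0) stop(sprintf("injection: %s must be > 0", v))
  }
  if (t_sh >= T_inj) stop("injection: t_sh must be < T_inj")
  structure(list(alpha_T = alpha_T, beta = beta, t_sh = t_sh, Lambda = Lambda,
                 R_inj = R_inj, V_inj = V_inj, T_inj = T_inj,
                 centre = c(r = unname(centre[1]), z = unname(centre[2])),
                 c_drug = c_drug),
            class = "injection_parameters")
}

#' Initial volume-averaged porosity
#' @param comps list of the three `compartment_parameters`.
#' @return `sum_i w_i phi_i0` (dimensionless).
#' @export
initial_mixture_porosity <- function(comps) {
  sum(vapply(comps, function(cp) cp$w * cp$phi0, 0))
}

#' Validate a full parameter set
#'
#' Checks the algebraic constraints tying the mixture and compartment
#' parameters together: volume fractions sum to one, per-network Biot
#' coefficients sum to the mixture total, and the total satisfies
#' `phi_s0 <= alpha <= 1`.
#'
#' @param mixture `mixture_parameters`.
#' @param comps named list `I`, `B`, `L` of `compartment_parameters`.
#' @param injection optional `injection_parameters`.
#' @return Object of class `poroinject_params`: list with elements `mixture`,
#'   `comps`, `injection`, `phi_s0`.
#' @export
validate_parameters <- function(mixture, comps, injection = NULL) {
  stopifnot(inherits(mixture, "mixture_parameters"))
  if (!all(c("I", "B", "L") %in% names(comps)))
    stop("comps must contain compartments I, B and L")
  w_sum <- sum(vapply(comps, `[[`, 0, "w"))
  if (abs(w_sum - 1) > 1e-10)
    stop(sprintf("constraint violated: volume fractions must sum to 1 (got %.6g)", w_sum))
  a_sum <- sum(vapply(comps, `[[`, 0, "alpha_i"))
  if (abs(a_sum - mixture$alpha) > 1e-10)
    stop(sprintf("constraint violated: sum of network Biot coefficients (%.6g) must equal the mixture total (%.6g)",
                 a_sum, mixture$alpha))
  phi_s0 <- initial_mixture_porosity(comps)
  if (mixture$alpha < phi_s0 - 1e-12 || mixture$alpha > 1 + 1e-12)
    stop(sprintf("constraint violated: need phi_s0 <= alpha <= 1 (phi_s0 = %.6g, alpha = %.6g)",
                 phi_s0, mixture$alpha))
  if (!is.null(injection)) stopifnot(inherits(injection, "injection_parameters"))
  structure(list(mixture = mixture, comps = comps[c("I", "B", "L")],
                 injection = injection, phi_s0 = phi_s0),
            class = "poroinject_params")
}

#' Default full parameter set
#' @return Validated `poroinject_params` with all defaults.
#' @export
default_parameters <- function() {
  validate_parameters(mixture_parameters(), default_compartments(),
                      injection_parameters())
}

#' Transmural fluid-exchange rates
#'
#' Linear (Starling-like) closure: flow between communicating networks is
#' proportional to the pressure difference.  Positive `s_BI` means fluid
#' enters the interstitium from blood; `s_I->B = -s_BI` by construction.
#'
#' @param p_I,p_B,p_L fluid pressures (Pa).
#' @param mixture `mixture_parameters` (supplies `xi_BI`, `xi_LI`).
#' @return List with `s_BI` (= s_B->I) and `s_LI` (= s_L->I), units 1/s.
#' @export
fluid_exchange_rates <- function(p_I, p_B, p_L, mixture) {
  list(s_BI = mixture$xi_BI * (p_B - p_I),
       s_LI = mixture$xi_LI * (p_L - p_I))
}

#' Equilibrium mass sources
#'
#' Constant sources balancing the physiological inter-network exchange so that
#' the rest pressures are a steady state.  Their sum vanishes identically.
#'
#' @param p_I0,p_B0,p_L0 physiological pressures (Pa).
#' @param xi_BI,xi_LI exchange coefficients (1/(Pa s)).
#' @return List with `f_I`, `f_B`, `f_L` (1/s).
#' @export
equilibrium_sources <- function(p_I0, p_B0, p_L0, xi_BI, xi_LI) {
  list(f_I = xi_BI * (p_I0 - p_B0) + xi_LI * (p_I0 - p_L0),
       f_B = xi_BI * (p_B0 - p_I0),
       f_L = xi_LI * (p_L0 - p_I0))
}

#' Porosity update of one network
#'
#' Porosity responds to volumetric strain and to the network pressure:
#' `phi = phi0 + (alpha - phi_s0) (eps_v - eps_v0) +
#'  ((1 - alpha_i/w_i)/M_i) (p - p0)`.
#' Values leaving (0, 1) indicate the small-strain regime has been left; the
#' default policy warns and clamps, `clamp = "error"` hard-fails, and
#' `clamp = "none"` returns the raw value.
#'
#' @param phi0 initial porosity.
#' @param eps_v,eps_v0 current and reference volumetric strain.
#' @param p,p0 current and physiological pressure (Pa).
#' @param alpha total Biot coefficient; `alpha_i`, `w` per-network coefficient
#'   and volume fraction; `M` Biot modulus (Pa); `phi_s0` initial
#'   volume-averaged porosity.
#' @param alpha_i,w,M,phi_s0 see above.
#' @param clamp one of `"warn"` (warn and clip), `"error"`, `"clip"`
#'   (silent clip), `"none"` (raw value).
#' @return Porosity (vectorized over the state arguments).
#' @export
porosity_update <- function(phi0, eps_v, eps_v0, p, p0, alpha, alpha_i, w, M,
                            phi_s0, clamp = c("warn", "error", "clip", "none")) {
  clamp <- match.arg(clamp)
  phi <- phi0 + (alpha - phi_s0) * (eps_v - eps_v0) +
    ((1 - alpha_i / w) / M) * (p - p0)
  bad <- phi <= 0 | phi >= 1
  if (any(bad)) {
    if (clamp == "error")
      stop("porosity left (0, 1): outside small-deformation validity regime")
    if (clamp == "warn")
      warning(sprintf("porosity left (0, 1) at %d point(s); clamping", sum(bad)))
    if (clamp %in% c("warn", "clip")) phi <- pmin(pmax(phi, 1e-6), 1 - 1e-6)
  }
  phi
}

#' Injection flow-rate amplitude
#' @param inj `injection_parameters`.
#' @return `Q0 = V_inj / (T_inj * (4/3) pi R_inj^3)` (1/s).
#' @export
injection_flow_rate <- function(inj) {
  inj$V_inj / (inj$T_inj * (4 / 3) * pi * inj$R_inj^3)
}

#' Smooth time profile of the injection source
#' @param t time (s), vectorized.
#' @param inj `injection_parameters`.
#' @return Dimensionless profile `(alpha_T/2)[tanh(beta (t - t_sh)) -
#'   tanh(beta (t - T_inj))]`.
#' @export
injection_time_profile <- function(t, inj) {
  (inj$alpha_T / 2) * (tanh(inj$beta * (t - inj$t_sh)) -
                         tanh(inj$beta * (t - inj$T_inj)))
}

#' Spatial profile of the injection source
#' @param d distance from the injection point (m), vectorized.
#' @param inj `injection_parameters`.
#' @return Dimensionless profile `0.5 [1 - tanh(Lambda (d - R_inj))]`.
#' @export
injection_space_profile <- function(d, inj) {
  0.5 * (1 - tanh(inj$Lambda * (d - inj$R_inj)))
}

#' Injection source strength at a point
#'
#' Separable source `Q(x, t) = Q0 Q_D(x) Q_t(t)` distributed over a spherical
#' neighbourhood of the injection point.  Under axisymmetry with an on-axis
#' injection point, the meridian-plane Euclidean distance equals the 3-D
#' distance.
#'
#' @param r,z position (m), vectorized.
#' @param t time (s), scalar or vectorized consistently with `r`, `z`.
#' @param inj `injection_parameters`.
#' @return Source strength (1/s).
#' @export
injection_source <- function(r, z, t, inj) {
  if (any(t < 0)) stop("injection_source: t must be >= 0")
  d <- sqrt((r - inj$centre["r"])^2 + (z - inj$centre["z"])^2)
  injection_flow_rate(inj) * injection_space_profile(d, inj) *
    injection_time_profile(t, inj)
}

#' Upwind direction indicator of an inter-network exchange
#'
#' Regularized sign switch `d = 0.5 (1 - s/(|s| + eps_s))` applied to the
#' outgoing rate `s_I->j`: 0 when fluid leaves the interstitium into the
#' vessel, 1 when it enters the interstitium, and 1/2 at exact balance.
#'
#' @param s_Ij outgoing exchange rate `s_I->j` (1/s), vectorized.
#' @param eps_s regularization (1/s), strictly positive.
#' @return Direction indicator in `[0, 1]`.
#' @export
exchange_direction <- function(s_Ij, eps_s = 1e-12) {
  if (eps_s <= 0) stop("eps_s must be > 0")
  0.5 * (1 - s_Ij / (abs(s_Ij) + eps_s))
}

#' Upwinded drug-exchange terms
#'
#' Solute carried between networks by the transmural fluid exchange, always at
#' the upstream network's concentration.  `G_BI` enters the interstitial
#' transport equation with +1 and the blood equation with -1 (likewise
#' `G_LI` for lymph), so summing the three equations cancels them exactly.
#'
#' @param C_I,C_B,C_L normalized concentrations.
#' @param s_BI,s_LI exchange rates `s_B->I`, `s_L->I` (1/s).
#' @param phi_I,phi_B,phi_L current porosities.
#' @param phi_s current volume-averaged porosity (> 0).
#' @param w_I,w_B,w_L volume fractions.
#' @param eps_s sign regularization passed to [exchange_direction()].
#' @return List with `G_BI`, `G_LI` (1/s in normalized-concentration units)
#'   and the direction indicators `d_BI`, `d_LI`.
#' @export
drug_exchange_terms <- function(C_I, C_B, C_L, s_BI, s_LI,
                                phi_I, phi_B, phi_L, phi_s,
                                w_I, w_B, w_L, eps_s = 1e-12) {
  if (any(phi_s <= 0)) stop("invalid state: phi_s must be > 0")
  d_BI <- exchange_direction(-s_BI, eps_s)   # s_I->B = -s_B->I
  d_LI <- exchange_direction(-s_LI, eps_s)
  G_BI <- (1 - d_BI) * s_BI * C_I * w_I * phi_I / phi_s +
    d_BI * s_BI * C_B * w_B * phi_B / phi_s
  G_LI <- (1 - d_LI) * s_LI * C_I * w_I * phi_I / phi_s +
    d_LI * s_LI * C_L * w_L * phi_L / phi_s
  list(G_BI = G_BI, G_LI = G_LI, d_BI = d_BI, d_LI = d_LI)
}

#' Relative concentration of a network
#'
#' Drug mass in network i per unit total fluid volume of the mixture:
#' `C_i^R = C_i phi_i w_i / phi_s`.
#'
#' @param C_i normalized concentration.
#' @param phi_i network porosity.
#' @param w_i network volume fraction.
#' @param phi_s volume-averaged porosity (> 0).
#' @return Relative concentration (vectorized).
#' @export
relative_concentration <- function(C_i, phi_i, w_i, phi_s) {
  if (any(phi_s <= 0)) stop("invalid state: phi_s must be > 0")
  C_i * phi_i * w_i / phi_s
}
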