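# Assembly of the linear poroelastic subsystem: quasi-static momentum balance
# of the mixture plus the three network mass balances.  With small-strain
# elasticity, constant permeabilities and linear transmural exchange the
# system is M ydot + K y = F0 + Qt(t) LQ with constant M, K — both are built
# once per grid and reused for every time step.
#
# Unknown ordering (field-major blocks of length n_nodes):
#   u_r | u_z | p_I | p_B | p_L

pe_offsets <- function(nn) {
  c(ur = 0L, uz = nn, pI = 2L * nn, pB = 3L * nn, pL = 4L * nn)
}

block_triplets <- function(fem, vals, roff, coff) {
  conn <- fem$conn
  ii <- jj <- vector("list", 16L)
  k <- 0L
  for (b in 1:4) for (a in 1:4) {
    k <- k + 1L
    ii[[k]] <- conn[, a] + roff
    jj[[k]] <- conn[, b] + coff
  }
  list(i = unlist(ii), j = unlist(jj), x = as.numeric(vals))
}

# Elasticity blocks (axisymmetric, engineering shear).  which selects the
# (test-dof, trial-dof) direction pair.
vals_elastic <- function(fem, lambda, mu, which = c("rr", "rz", "zr", "zz")) {
  which <- match.arg(which)
  v <- vals_zero(fem)
  lp2m <- lambda + 2 * mu
  for (g in 1:4) {
    Wg <- fem$W[[g]]; Ng <- fem$N[[g]]
    dr <- fem$dNdr[[g]]; dz <- fem$dNdz[[g]]; rg <- fem$rg[[g]]
    k <- 0L
    for (b in 1:4) for (a in 1:4) {
      k <- k + 1L
      arr <- dr[, a]; ath <- Ng[a] / rg; az <- dz[, a]
      brr <- dr[, b]; bth <- Ng[b] / rg; bz <- dz[, b]
      v[, k] <- v[, k] + Wg * switch(which,
        rr = lp2m * (arr * brr + ath * bth) + lambda * (arr * bth + ath * brr) +
          mu * az * bz,
        rz = lambda * (arr + ath) * bz + mu * az * brr,
        zr = lambda * az * (brr + bth) + mu * arr * bz,
        zz = lp2m * az * bz + mu * arr * brr)
    }
  }
  v
}

# Strain-rate coupling into the mass balances: entries
# int N_a (div_axi N_b^u) with the axisymmetric divergence (includes hoop).
vals_div_coupling <- function(fem, dir = c("r", "z")) {
  dir <- match.arg(dir)
  v <- vals_zero(fem)
  for (g in 1:4) {
    Wg <- fem$W[[g]]; Ng <- fem$N[[g]]
    dr <- fem$dNdr[[g]]; dz <- fem$dNdz[[g]]; rg <- fem$rg[[g]]
    k <- 0L
    for (b in 1:4) for (a in 1:4) {
      k <- k + 1L
      db <- if (dir == "r") dr[, b] + Ng[b] / rg else dz[, b]
      v[, k] <- v[, k] + Wg * Ng[a] * db
    }
  }
  v
}

# Transpose a 16-stream vals matrix (swap test/trial node roles).
vals_T <- function(v) {
  perm <- integer(16L)
  k <- 0L
  for (b in 1:4) for (a in 1:4) {
    k <- k + 1L
    perm[k] <- (a - 1L) * 4L + b
  }
  v[, perm, drop = FALSE]
}

# Integral of the axisymmetric divergence of each shape function,
# int (dN_a/dr + N_a/r) resp. int dN_a/dz — the constant boundary-prestress
# load of the momentum equation.
div_load_vector <- function(fem, dir = c("r", "z")) {
  dir <- match.arg(dir)
  f <- numeric(fem$nn)
  for (g in 1:4) {
    Wg <- fem$W[[g]]; Ng <- fem$N[[g]]
    dr <- fem$dNdr[[g]]; dz <- fem$dNdz[[g]]; rg <- fem$rg[[g]]
    for (a in 1:4) {
      da <- if (dir == "r") dr[, a] + Ng[a] / rg else dz[, a]
      f <- f + accumulate_nodal(fem, a, Wg * da, fem$nn)
    }
  }
  f
}

#' Assemble the constant poroelastic system
#'
#' Builds the mass matrix `M` (multiplying rates), stiffness `K`
#' (multiplying the state), the constant equilibrium load `F0` and the
#' injection load shape `LQ` such that the semi-discrete system reads
#' `M ydot + K y = F0 + Qt(t) LQ`.
#'
#' @param fem `axi_fem`.
#' @param params validated `poroinject_params`.
#' @param bc `"standard"` applies the injection-scenario constraints
#'   (`u_r = 0` on the axis, `u_z = 0` on the bottom, `p_i = p_i0` on the
#'   outer and bottom boundaries); `"none"` leaves the system unconstrained
#'   (verification drivers build their own constraint sets).
#' @return List of class `pe_system` with `M`, `K`, `F0`, `LQ`, constrained
#'   dof indices/values, offsets, and the rest-state vector `y0`.
#' @export
assemble_poroelastic_system <- function(fem, params, bc = c("standard", "none")) {
  bc <- match.arg(bc)
  mix <- params$mixture; comps <- params$comps
  nn <- fem$nn; off <- pe_offsets(nn)
  ndof <- 5L * nn
  tr <- list()
  add <- function(t) tr[[length(tr) + 1L]] <<- t

  # momentum block
  add(block_triplets(fem, vals_elastic(fem, mix$lambda, mix$mu, "rr"), off["ur"], off["ur"]))
  add(block_triplets(fem, vals_elastic(fem, mix$lambda, mix$mu, "rz"), off["ur"], off["uz"]))
  add(block_triplets(fem, vals_elastic(fem, mix$lambda, mix$mu, "zr"), off["uz"], off["ur"]))
  add(block_triplets(fem, vals_elastic(fem, mix$lambda, mix$mu, "zz"), off["uz"], off["uz"]))
  # Pressure coupling integrated by parts on (p_i - p_i0):
  #   R_u = K_uu u - sum_i alpha_i int (p_i - p_i0) div(w)
  # so the natural traction condition on the free surfaces is total traction
  # equal to its physiological rest value; the constant p_i0 part goes into
  # the momentum load below.
  dvrT <- vals_T(vals_div_coupling(fem, "r"))
  dvzT <- vals_T(vals_div_coupling(fem, "z"))
  for (nm in c("I", "B", "L")) {
    ai <- comps[[nm]]$alpha_i
    po <- off[paste0("p", nm)]
    add(block_triplets(fem, -ai * dvrT, off["ur"], po))
    add(block_triplets(fem, -ai * dvzT, off["uz"], po))
  }

  # mass-balance stiffness: Darcy + exchange
  mass_v <- vals_mass(fem, 1)
  for (nm in c("I", "B", "L")) {
    cp <- comps[[nm]]
    po <- off[paste0("p", nm)]
    add(block_triplets(fem, vals_stiff(fem, cp$w * cp$kappa / mix$mu_f), po, po))
  }
  xBI <- mix$xi_BI; xLI <- mix$xi_LI
  add(block_triplets(fem, (xBI + xLI) * mass_v, off["pI"], off["pI"]))
  add(block_triplets(fem, -xBI * mass_v, off["pI"], off["pB"]))
  add(block_triplets(fem, -xLI * mass_v, off["pI"], off["pL"]))
  add(block_triplets(fem, xBI * mass_v, off["pB"], off["pB"]))
  add(block_triplets(fem, -xBI * mass_v, off["pB"], off["pI"]))
  add(block_triplets(fem, xLI * mass_v, off["pL"], off["pL"]))
  add(block_triplets(fem, -xLI * mass_v, off["pL"], off["pI"]))

  K <- Matrix::sparseMatrix(i = unlist(lapply(tr, `[[`, "i")),
                            j = unlist(lapply(tr, `[[`, "j")),
                            x = unlist(lapply(tr, `[[`, "x")),
                            dims = c(ndof, ndof))

  # mass matrix: storage + strain-rate coupling
  tr <- list()
  dvr <- vals_div_coupling(fem, "r")
  dvz <- vals_div_coupling(fem, "z")
  for (nm in c("I", "B", "L")) {
    cp <- comps[[nm]]
    po <- off[paste0("p", nm)]
    add(block_triplets(fem, cp$alpha_i * dvr, po, off["ur"]))
    add(block_triplets(fem, cp$alpha_i * dvz, po, off["uz"]))
    add(block_triplets(fem, (cp$w / cp$M) * mass_v, po, po))
  }
  M <- Matrix::sparseMatrix(i = unlist(lapply(tr, `[[`, "i")),
                            j = unlist(lapply(tr, `[[`, "j")),
                            x = unlist(lapply(tr, `[[`, "x")),
                            dims = c(ndof, ndof))

  # constant equilibrium sources and the momentum prestress load
  fs <- equilibrium_sources(comps$I$p0, comps$B$p0, comps$L$p0, xBI, xLI)
  one_load <- load_vector(fem, 1)
  F0 <- numeric(ndof)
  alpha_p0 <- sum(vapply(comps, function(cp) cp$alpha_i * cp$p0, 0))
  F0[off["ur"] + seq_len(nn)] <- -alpha_p0 * div_load_vector(fem, "r")
  F0[off["uz"] + seq_len(nn)] <- -alpha_p0 * div_load_vector(fem, "z")
  F0[off["pI"] + seq_len(nn)] <- fs$f_I * one_load
  F0[off["pB"] + seq_len(nn)] <- fs$f_B * one_load
  F0[off["pL"] + seq_len(nn)] <- fs$f_L * one_load

  # injection load shape (scaled by Qt(t) at run time)
  LQ <- numeric(ndof)
  lq <- if (!is.null(params$injection))
    injection_load_vector(fem, params$injection) else numeric(nn)
  LQ[off["pI"] + seq_len(nn)] <- lq

  # rest state
  y0 <- numeric(ndof)
  y0[off["pI"] + seq_len(nn)] <- comps$I$p0
  y0[off["pB"] + seq_len(nn)] <- comps$B$p0
  y0[off["pL"] + seq_len(nn)] <- comps$L$p0

  g <- fem$grid
  if (bc == "standard") {
    pdir <- sort(unique(c(g$outer, g$bottom)))
    bc_idx <- c(off["ur"] + g$axis, off["uz"] + g$bottom,
                off["pI"] + pdir, off["pB"] + pdir, off["pL"] + pdir)
    bc_val <- c(rep(0, length(g$axis)), rep(0, length(g$bottom)),
                rep(comps$I$p0, length(pdir)), rep(comps$B$p0, length(pdir)),
                rep(comps$L$p0, length(pdir)))
  } else {
    bc_idx <- integer(0); bc_val <- numeric(0)
  }

  structure(list(M = M, K = K, F0 = F0, LQ = LQ, y0 = y0,
                 bc_idx = as.integer(bc_idx), bc_val = bc_val,
                 offsets = off, nn = nn, ndof = ndof, params = params),
            class = "pe_system")
}

#' Apply Dirichlet constraints to a system matrix
#'
#' Zeroes constrained rows and columns and places a unit diagonal, the
#' standard symmetric elimination for constraints whose values are carried in
#' the state vector (rates of constrained dofs are zero).
#'
#' @param A sparse matrix.
#' @param idx constrained dof indices.
#' @return Constrained matrix.
#' @export
apply_bc_matrix <- function(A, idx) {
  if (length(idx) == 0L) return(A)
  mask <- rep(1, nrow(A)); mask[idx] <- 0
  Dm <- Matrix::Diagonal(x = mask)
  Dm %*% A %*% Dm + Matrix::Diagonal(x = 1 - mask)
}

#' Poroelastic residual
#'
#' Weak-form residual `M ydot + K y - F0 - Qt(t) LQ` with constrained rows
#' replaced by the rate components (which must stay zero for time-constant
#' Dirichlet data).
#'
#' @param sys `pe_system`.
#' @param ydot,y rate and state vectors at the evaluation levels.
#' @param t evaluation time (s).
#' @return Residual vector.
#' @export
pe_residual <- function(sys, ydot, y, t) {
  qt <- if (!is.null(sys$params$injection))
    injection_time_profile(t, sys$params$injection) else 0
  r <- as.numeric(sys$M %*% ydot + sys$K %*% y) - sys$F0 - qt * sys$LQ
  if (length(sys$bc_idx)) r[sys$bc_idx] <- ydot[sys$bc_idx]
  r
}

# Injection load vector int Q0 QD(x) N_a(x) 2 pi r dr dz, integrated in
# spherical coordinates about the injection point so that the needle-scale
# source is captured accurately on any mesh.  Composite Simpson in radius
# (split at the tanh edge), midpoint in polar angle.
injection_load_vector <- function(fem, inj, n_rho = 241L, n_theta = 256L) {
  grid <- fem$grid
  wq <- 15 / inj$Lambda
  rho_max <- inj$R_inj + 4 * wq
  simpson <- function(a, b, n) {     # n odd number of points
    x <- seq(a, b, length.out = n)
    h <- (b - a) / (n - 1)
    w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
    w[n] <- 1
    list(x = x, w = w * h / 3)
  }
  s1 <- simpson(1e-9, max(inj$R_inj - wq, 1e-8), n_rho)
  s2 <- simpson(max(inj$R_inj - wq, 1e-8), rho_max, n_rho)
  rho <- c(s1$x, s2$x); wrho <- c(s1$w, s2$w)
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  wth <- rep(pi / n_theta, n_theta)

  RR <- outer(rho, sin(th))                       # meridian radius
  ZZ <- inj$centre["z"] + outer(rho, cos(th))
  WW <- outer(wrho * rho^2 * injection_space_profile(rho, inj), wth * sin(th)) *
    2 * pi * injection_flow_rate(inj)

  keep <- RR <= grid$r_extent & ZZ >= 0 & ZZ <= grid$z_extent & WW > 0
  rr <- RR[keep]; zz <- ZZ[keep]; ww <- WW[keep]
  f <- numeric(grid$n_nodes)
  if (!length(rr)) return(f)
  i <- findInterval(rr, grid$r, all.inside = TRUE)
  j <- findInterval(zz, grid$z, all.inside = TRUE)
  xr <- (rr - grid$r[i]) / (grid$r[i + 1] - grid$r[i])
  xz <- (zz - grid$z[j]) / (grid$z[j + 1] - grid$z[j])
  nrp <- grid$n_r + 1L
  n00 <- i + (j - 1L) * nrp
  acc <- function(idx, w) {
    s <- rowsum(w, idx)
    f[as.integer(rownames(s))] <<- f[as.integer(rownames(s))] + s
  }
  acc(n00, ww * (1 - xr) * (1 - xz))
  acc(n00 + 1L, ww * xr * (1 - xz))
  acc(n00 + nrp + 1L, ww * xr * xz)
  acc(n00 + nrp, ww * (1 - xr) * xz)
  f
}
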