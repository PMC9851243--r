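# Assembly of the three-network drug-transport subsystem.  Given the
# poroelastic fields at the time-integration alpha-levels, the transport
# equations are linear in the concentrations:
#
#   w_i d(phi_i C_i)/dt + w_i div(v_i C_i) - w_i div(phi_i D_i grad C_i)
#     = [exchange] + Q (interstitium only),   v_i = -(kappa_i/mu_f) grad p_i
#
# discretized with SUPG streamline stabilization (the mAb diffusivity of
# 1e-11 m^2/s against injection-driven Darcy velocities gives extreme Peclet
# numbers; plain Galerkin oscillates at the plume front).  Unknown ordering:
# C_I | C_B | C_L, field-major.

tr_offsets <- function(nn) c(I = 0L, B = nn, L = 2L * nn)

# Block list of the coupled transport matrix (row compartment, column
# compartment); off-diagonal blocks carry only the exchange terms.
TR_BLOCKS <- list(c("I", "I"), c("B", "B"), c("L", "L"),
                  c("I", "B"), c("B", "I"), c("I", "L"), c("L", "I"))

#' Prepare reusable transport-assembly structures
#'
#' Builds the coupled sparsity pattern once; per-step assembly then reduces
#' to filling the numeric slot.
#'
#' @param fem `axi_fem`.
#' @param params validated `poroinject_params`.
#' @return List of class `transport_structures`.
#' @export
transport_structures <- function(fem, params) {
  nn <- fem$nn
  off <- tr_offsets(nn)
  tmpl <- fem$pattern$tmpl
  ts <- Matrix::summary(tmpl)      # CSC triplets of the scalar pattern
  nnz_s <- nrow(ts)
  ii <- jj <- vector("list", length(TR_BLOCKS))
  for (k in seq_along(TR_BLOCKS)) {
    ii[[k]] <- ts$i + off[TR_BLOCKS[[k]][1]]
    jj[[k]] <- ts$j + off[TR_BLOCKS[[k]][2]]
  }
  big <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = seq_len(nnz_s * length(TR_BLOCKS)),
                              dims = c(3L * nn, 3L * nn))
  perm <- as.integer(big@x)
  big@x[] <- 0
  lq <- if (!is.null(params$injection))
    injection_load_vector(fem, params$injection) else numeric(nn)
  # outflow edge data (outer r = R and bottom z = 0 boundaries)
  edges <- list(outer = edge_table(fem, "outer"),
                bottom = edge_table(fem, "bottom"))
  structure(list(fem = fem, params = params, nn = nn, off = off,
                 tmpl_big = big, perm = perm, nnz_s = nnz_s, lq = lq,
                 edges = edges),
            class = "transport_structures")
}

# Edge quadrature table: element id, local node indices of the edge, outward
# normal, edge length and the 2 pi r weights of its 2-point Gauss rule.
edge_table <- function(fem, which = c("outer", "bottom")) {
  which <- match.arg(which)
  g <- fem$grid
  if (which == "outer") {
    el <- which(g$el_i == g$n_r)
    if (!length(el)) return(NULL)
    a1 <- 2L; a2 <- 3L                       # local nodes on xi = +1
    len <- g$hz[el]
    rmid <- rep(g$r_extent, length(el))
    nrm <- c(1, 0)
  } else {
    el <- which(g$el_j == 1L)
    if (!length(el)) return(NULL)
    a1 <- 1L; a2 <- 2L                       # local nodes on eta = -1
    len <- g$hr[el]
    rmid <- g$rc[g$conn[el, 1]] + g$hr[el] / 2
    nrm <- c(0, -1)
  }
  data.frame(el = el, a1 = a1, a2 = a2, len = len, rmid = rmid,
             nr = nrm[1], nz = nrm[2])
}

#' Pointwise transport coefficients from the poroelastic state
#'
#' Evaluates, at every Gauss point, the porosities and their rates, the
#' volume-averaged porosity, the Darcy velocities, the transmural exchange
#' rates and upwind indicators, and the SUPG stabilization parameter.
#'
#' @param fem `axi_fem`.
#' @param params validated `poroinject_params`.
#' @param y,ydot poroelastic state and rate vectors at the evaluation levels
#'   (field-major `u_r | u_z | p_I | p_B | p_L`).
#' @param dt time-step size entering the SUPG transient scale (s).
#' @param clamp porosity clamp policy, see [porosity_update()].
#' @param dc discontinuity-capturing coefficient: isotropic artificial
#'   diffusion `dc * |v| * h / 2` added to the physical diffusivity.  The
#'   mAb diffusivity is so small that the plume front is grid-sharp; without
#'   capturing, the high-Courant core around the needle rings and the
#'   oscillations advect across the plume.  The front smearing this
#'   introduces is a few cells (first-order-upwind scale).
#' @return List of per-Gauss-point coefficient lists.
#' @export
transport_coefficients <- function(fem, params, y, ydot, dt,
                                   clamp = "clip", dc = 0.35) {
  nn <- fem$nn; off <- pe_offsets(nn)
  mix <- params$mixture; comps <- params$comps
  pick <- function(v, blk) v[off[blk] + seq_len(nn)]
  ur <- pick(y, "ur"); uz <- pick(y, "uz")
  urd <- pick(ydot, "ur"); uzd <- pick(ydot, "uz")
  out <- list(phi = list(), phid = list(), vr = list(), vz = list(),
              tau = list(), phis = vector("list", 4L),
              s = list(), dfac = list(),
              p_nodal = list(I = pick(y, "pI"), B = pick(y, "pB"),
                             L = pick(y, "pL")))
  out$nu_dc <- list()
  for (nm in c("I", "B", "L")) {
    out$phi[[nm]] <- vector("list", 4L); out$phid[[nm]] <- vector("list", 4L)
    out$vr[[nm]] <- vector("list", 4L); out$vz[[nm]] <- vector("list", 4L)
    out$tau[[nm]] <- vector("list", 4L); out$nu_dc[[nm]] <- vector("list", 4L)
  }
  for (pair in c("BI", "LI")) {
    out$s[[pair]] <- vector("list", 4L); out$dfac[[pair]] <- vector("list", 4L)
  }
  pn <- out$p_nodal
  pdn <- list(I = pick(ydot, "pI"), B = pick(ydot, "pB"), L = pick(ydot, "pL"))
  hr_el <- fem$grid$hr; hz_el <- fem$grid$hz
  for (g in 1:4) {
    ev <- gp_volumetric_strain(fem, ur, uz, g)
    evd <- gp_volumetric_strain(fem, urd, uzd, g)
    pg <- pdg <- grd <- list()
    for (nm in c("I", "B", "L")) {
      pg[[nm]] <- gp_value(fem, pn[[nm]], g)
      pdg[[nm]] <- gp_value(fem, pdn[[nm]], g)
      grd[[nm]] <- gp_grad(fem, pn[[nm]], g)
    }
    phis_g <- 0
    for (nm in c("I", "B", "L")) {
      cp <- comps[[nm]]
      phi <- porosity_update(cp$phi0, ev, 0, pg[[nm]], cp$p0, mix$alpha,
                             cp$alpha_i, cp$w, cp$M, params$phi_s0,
                             clamp = clamp)
      phid <- (mix$alpha - params$phi_s0) * evd +
        ((1 - cp$alpha_i / cp$w) / cp$M) * pdg[[nm]]
      vr <- -(cp$kappa / mix$mu_f) * grd[[nm]]$dr
      vz <- -(cp$kappa / mix$mu_f) * grd[[nm]]$dz
      vmag <- sqrt(vr * vr + vz * vz)
      hstr <- (abs(vr) * hr_el + abs(vz) * hz_el + 1e-300) / (vmag + 1e-300)
      tau <- 1 / sqrt((2 * phi / dt)^2 + (2 * vmag / hstr)^2 +
                        (4 * phi * cp$D / hstr^2)^2)
      out$phi[[nm]][[g]] <- phi; out$phid[[nm]][[g]] <- phid
      out$vr[[nm]][[g]] <- vr; out$vz[[nm]][[g]] <- vz
      out$tau[[nm]][[g]] <- tau
      out$nu_dc[[nm]][[g]] <- dc * vmag * hstr / 2
      phis_g <- phis_g + cp$w * phi
    }
    out$phis[[g]] <- phis_g
    out$s$BI[[g]] <- mix$xi_BI * (pg$B - pg$I)
    out$s$LI[[g]] <- mix$xi_LI * (pg$L - pg$I)
    out$dfac$BI[[g]] <- exchange_direction(-out$s$BI[[g]])
    out$dfac$LI[[g]] <- exchange_direction(-out$s$LI[[g]])
  }
  out
}

# Outflow edge contribution added into a vals matrix: for boundary edges with
# outward Darcy flux, + coef * max(v.n, 0) over the edge, lumped 2-node rule.
# The normal velocity is taken from the one-sided pressure difference across
# the boundary cell — adequate for a term that is inert while the plume stays
# inside the domain.
add_outflow_vals <- function(vals, fem, edges, p_nodal, kap_over_mu, w_i) {
  for (side in names(edges)) {
    ed <- edges[[side]]
    if (is.null(ed) || !nrow(ed)) next
    conn <- fem$conn
    n1 <- conn[cbind(ed$el, ed$a1)]
    n2 <- conn[cbind(ed$el, ed$a2)]
    # one-sided normal gradient from the nodes across the boundary cell
    if (side == "outer") {
      o1 <- conn[ed$el, 1L]; o2 <- conn[ed$el, 4L]
      h <- fem$grid$hr[ed$el]
    } else {
      o1 <- conn[ed$el, 4L]; o2 <- conn[ed$el, 3L]
      h <- fem$grid$hz[ed$el]
    }
    dpdn <- ((p_nodal[n1] + p_nodal[n2]) - (p_nodal[o1] + p_nodal[o2])) / (2 * h)
    vn <- pmax(-kap_over_mu * dpdn, 0)      # outward normal Darcy velocity
    wedge <- w_i * vn * ed$len * 2 * pi * ed$rmid / 2   # lumped per node
    s11 <- (ed$a1 - 1L) * 4L + ed$a1
    s22 <- (ed$a2 - 1L) * 4L + ed$a2
    for (k in seq_len(nrow(ed))) {
      vals[ed$el[k], s11[k]] <- vals[ed$el[k], s11[k]] + wedge[k]
      vals[ed$el[k], s22[k]] <- vals[ed$el[k], s22[k]] + wedge[k]
    }
  }
  vals
}

#' Assemble the transport system at frozen coefficients
#'
#' Returns the mass matrix `M` (multiplying Cdot), stiffness `K`
#' (multiplying C) and load `F_shape` such that the transport residual is
#' `M Cdot + K C - Qt(t) F_shape`.
#'
#' @param ts `transport_structures`.
#' @param co output of [transport_coefficients()] (or constant-coefficient
#'   analogue for the absorption stage).
#' @param stage `"injection"` (advection + SUPG + source + outflow) or
#'   `"absorption"` (exchange and diffusion only).
#' @return List with sparse `M`, `K` and numeric `F_shape`.
#' @export
assemble_transport_system <- function(ts, co, stage = c("injection", "absorption")) {
  stage <- match.arg(stage)
  fem <- ts$fem; params <- ts$params
  comps <- params$comps
  nn <- ts$nn
  zero <- rep(0, ts$nnz_s)
  Mx <- list(); Kx <- list()
  pat <- fem$pattern

  # exchange coefficient fields (Gauss-point lists)
  gcoef <- function(pair, side) {
    up <- if (pair == "BI") "B" else "L"
    lapply(1:4, function(g) {
      s <- co$s[[pair]][[g]]; d <- co$dfac[[pair]][[g]]
      if (side == "I")
        (1 - d) * s * comps$I$w * co$phi$I[[g]] / co$phis[[g]]
      else
        d * s * comps[[up]]$w * co$phi[[up]][[g]] / co$phis[[g]]
    })
  }
  gI_BI <- gcoef("BI", "I"); gB_BI <- gcoef("BI", "up")
  gI_LI <- gcoef("LI", "I"); gL_LI <- gcoef("LI", "up")

  supg_on <- stage == "injection"
  for (nm in c("I", "B", "L")) {
    cp <- comps[[nm]]
    wphi <- lapply(1:4, function(g) cp$w * co$phi[[nm]][[g]])
    wphid <- lapply(1:4, function(g) cp$w * co$phid[[nm]][[g]])
    wphiD <- lapply(1:4, function(g)
      cp$w * (co$phi[[nm]][[g]] * cp$D + co$nu_dc[[nm]][[g]]))
    mv <- vals_mass(fem, wphi)
    kv <- vals_mass(fem, wphid) + vals_stiff(fem, wphiD)
    if (stage == "injection") {
      vr <- co$vr[[nm]]; vz <- co$vz[[nm]]
      kv <- kv + vals_advection(fem, vr, vz, cp$w)
      if (supg_on) {
        tau_w <- lapply(1:4, function(g) cp$w * co$tau[[nm]][[g]])
        react <- lapply(1:4, function(g)
          co$phid[[nm]][[g]] + vr[[g]] / fem$rg[[g]])
        mv <- mv + vals_supg_mass(fem, vr, vz, tau_w,
                                  lapply(1:4, function(g) co$phi[[nm]][[g]]))
        kv <- kv + vals_supg_adv(fem, vr, vz, tau_w, react)
      }
      kv <- add_outflow_vals(kv, fem, ts$edges, co$p_nodal[[nm]],
                             cp$kappa / params$mixture$mu_f, cp$w)
    }
    # exchange, diagonal parts
    kv <- kv + switch(nm,
      I = -vals_mass(fem, lapply(1:4, function(g) gI_BI[[g]] + gI_LI[[g]])),
      B = vals_mass(fem, gB_BI),
      L = vals_mass(fem, gL_LI))
    Mx[[paste(nm, nm)]] <- pattern_reduce(pat, mv)
    Kx[[paste(nm, nm)]] <- pattern_reduce(pat, kv)
  }
  # exchange, off-diagonal parts
  Kx[["I B"]] <- pattern_reduce(pat, -vals_mass(fem, gB_BI))
  Kx[["B I"]] <- pattern_reduce(pat, vals_mass(fem, gI_BI))
  Kx[["I L"]] <- pattern_reduce(pat, -vals_mass(fem, gL_LI))
  Kx[["L I"]] <- pattern_reduce(pat, vals_mass(fem, gI_LI))
  for (k in seq_along(TR_BLOCKS)) {
    key <- paste(TR_BLOCKS[[k]][1], TR_BLOCKS[[k]][2])
    if (is.null(Mx[[key]])) Mx[[key]] <- zero
    if (is.null(Kx[[key]])) Kx[[key]] <- zero
  }
  blk_order <- vapply(TR_BLOCKS, paste, "", collapse = " ")
  Mbig <- ts$tmpl_big; Kbig <- ts$tmpl_big
  Mbig@x <- unlist(Mx[blk_order], use.names = FALSE)[ts$perm]
  Kbig@x <- unlist(Kx[blk_order], use.names = FALSE)[ts$perm]

  Fsh <- numeric(3L * nn)
  if (stage == "injection") {
    Fsh[ts$off["I"] + seq_len(nn)] <- ts$lq
    # SUPG counterpart of the source (Gauss-point evaluation of Q's shape)
    inj <- params$injection
    if (!is.null(inj)) {
      q0 <- injection_flow_rate(inj)
      fs <- numeric(nn)
      for (g in 1:4) {
        d <- sqrt((fem$rg[[g]] - inj$centre["r"])^2 +
                    (fem$zg[[g]] - inj$centre["z"])^2)
        qd <- q0 * injection_space_profile(d, inj)
        if (!any(qd > 0)) next
        cw <- fem$W[[g]] * comps$I$w * co$tau$I[[g]] * qd
        dr <- fem$dNdr[[g]]; dz <- fem$dNdz[[g]]
        for (a in 1:4) {
          ta <- co$vr$I[[g]] * dr[, a] + co$vz$I[[g]] * dz[, a]
          fs <- fs + accumulate_nodal(fem, a, cw * ta, nn)
        }
      }
      Fsh[ts$off["I"] + seq_len(nn)] <- Fsh[ts$off["I"] + seq_len(nn)] + fs
    }
  }
  list(M = Mbig, K = Kbig, F_shape = Fsh)
}
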