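# Finite-element plumbing for bilinear quadrilaterals on the axisymmetric
# meridian plane.  All volume integrals carry the 2*pi*r measure; 2x2 Gauss
# points are strictly interior, so r > 0 at every quadrature point and the
# hoop terms u_r / r are always well defined.

#' Precompute quadrature and shape-function data for a grid
#'
#' @param grid `axi_grid`.
#' @return Object of class `axi_fem`: per-Gauss-point shape values `N`
#'   (list of 4-vectors), derivative tables `dNdr`, `dNdz` (lists of
#'   `n_el x 4` matrices), weights `W` (lists of length-`n_el` vectors,
#'   including the `2 pi r` measure), Gauss-point radii `rg`, plus the scalar
#'   sparsity pattern used by the fast assemblers.
#' @export
fem_setup <- function(grid) {
  g1 <- 1 / sqrt(3)
  gp <- cbind(xi = c(-g1, g1, g1, -g1), eta = c(-g1, -g1, g1, g1))
  xa <- c(-1, 1, 1, -1); ya <- c(-1, -1, 1, 1)   # corner signs, conn order
  n_el <- grid$n_el
  hr <- grid$hr; hz <- grid$hz
  r1 <- grid$rc[grid$conn[, 1]]; z1 <- grid$zc[grid$conn[, 1]]
  N <- dNdr <- dNdz <- W <- rg <- zg <- vector("list", 4L)
  for (g in 1:4) {
    xi <- gp[g, 1]; eta <- gp[g, 2]
    Ng <- 0.25 * (1 + xa * xi) * (1 + ya * eta)
    dNxi <- 0.25 * xa * (1 + ya * eta)
    dNeta <- 0.25 * ya * (1 + xa * xi)
    rg[[g]] <- r1 + hr * (xi + 1) / 2
    zg[[g]] <- z1 + hz * (eta + 1) / 2
    dNdr[[g]] <- outer(2 / hr, dNxi)
    dNdz[[g]] <- outer(2 / hz, dNeta)
    W[[g]] <- (hr / 2) * (hz / 2) * 2 * pi * rg[[g]]   # unit Gauss weights
    N[[g]] <- Ng
  }
  # reference-element stream tables (16 = (a, b) node pairs, b-major) for
  # outer-product assembly: entry k of each table is the (a, b) product of
  # the reference shape values/derivatives at Gauss point g
  NN <- XX <- YY <- XY <- YX <- XN <- YN <- NX <- NY <- vector("list", 4L)
  for (g in 1:4) {
    xi <- gp[g, 1]; eta <- gp[g, 2]
    Ng <- 0.25 * (1 + xa * xi) * (1 + ya * eta)
    dX <- 0.25 * xa * (1 + ya * eta)      # dN/dxi
    dY <- 0.25 * ya * (1 + xa * xi)       # dN/deta
    st <- function(u, v) as.numeric(outer(u, v))   # stream k = (b-1)*4 + a
    NN[[g]] <- st(Ng, Ng)
    XX[[g]] <- st(dX, dX); YY[[g]] <- st(dY, dY)
    XY[[g]] <- st(dX, dY); YX[[g]] <- st(dY, dX)
    XN[[g]] <- st(dX, Ng); YN[[g]] <- st(dY, Ng)
    NX[[g]] <- st(Ng, dX); NY[[g]] <- st(Ng, dY)
  }
  fem <- list(grid = grid, n_el = n_el, nn = grid$n_nodes, conn = grid$conn,
              N = N, dNdr = dNdr, dNdz = dNdz, W = W, rg = rg, zg = zg,
              inv_hr = 2 / hr, inv_hz = 2 / hz,
              tab = list(NN = NN, XX = XX, YY = YY, XY = XY, YX = YX,
                         XN = XN, YN = YN, NX = NX, NY = NY))
  fem$pattern <- scalar_pattern(fem)
  class(fem) <- "axi_fem"
  fem
}

# Scalar sparsity pattern shared by every nodal-coupling matrix.  The 16
# (a, b) node-pair streams per element are reduced into unique CSC positions
# with a one-time sort; per-step assembly is then a cumsum over a fixed
# permutation.
scalar_pattern <- function(fem) {
  conn <- fem$conn; nn <- fem$nn
  ii <- jj <- vector("list", 16L)
  k <- 0L
  for (b in 1:4) for (a in 1:4) {
    k <- k + 1L
    ii[[k]] <- conn[, a]; jj[[k]] <- conn[, b]
  }
  i_all <- unlist(ii); j_all <- unlist(jj)
  key <- (as.numeric(j_all) - 1) * nn + as.numeric(i_all)
  ord <- order(key)
  key_s <- key[ord]
  new_grp <- c(TRUE, diff(key_s) > 0)
  grp_end <- c(which(new_grp[-1]) , length(key_s))
  tmpl <- Matrix::sparseMatrix(i = i_all[ord][new_grp], j = j_all[ord][new_grp],
                               x = 0, dims = c(nn, nn))
  list(i_all = i_all, j_all = j_all, ord = ord, grp_end = grp_end,
       nnz = sum(new_grp), tmpl = tmpl)
}

# Reduce a 16-stream value matrix (n_el x 16, columns in (a, b) stream order)
# to the nnz-long CSC value vector of the scalar pattern.
pattern_reduce <- function(pat, vals) {
  cs <- cumsum(as.numeric(vals)[pat$ord])
  x <- cs[pat$grp_end]
  x - c(0, x[-length(x)])
}

# vals builders ---------------------------------------------------------------
# Each returns an n_el x 16 matrix of element-block entries; `coef` arguments
# are lists over the 4 Gauss points of length-n_el vectors (or scalars).

vals_zero <- function(fem) matrix(0, fem$n_el, 16L)

# The builders collect one coefficient column per (Gauss point, table) pair
# and produce the element-block values with a single BLAS multiply
# CF (n_el x m) %*% TB (m x 16).

vals_gemm <- function(cols, tabs) {
  CF <- do.call(cbind, cols)
  TB <- do.call(rbind, tabs)
  CF %*% TB
}

vals_mass <- function(fem, coef) {
  cols <- tabs <- vector("list", 4L)
  for (g in 1:4) {
    cols[[g]] <- fem$W[[g]] * (if (is.list(coef)) coef[[g]] else coef)
    tabs[[g]] <- fem$tab$NN[[g]]
  }
  vals_gemm(cols, tabs)
}

vals_stiff <- function(fem, coef) {
  cols <- tabs <- vector("list", 8L)
  for (g in 1:4) {
    c_g <- fem$W[[g]] * (if (is.list(coef)) coef[[g]] else coef)
    cols[[g]] <- c_g * fem$inv_hr^2;     tabs[[g]] <- fem$tab$XX[[g]]
    cols[[g + 4]] <- c_g * fem$inv_hz^2; tabs[[g + 4]] <- fem$tab$YY[[g]]
  }
  vals_gemm(cols, tabs)
}

# Galerkin advection, integrated by parts: -(coef) (v . grad Na) Nb
vals_advection <- function(fem, vr, vz, coef = 1) {
  cols <- tabs <- vector("list", 8L)
  for (g in 1:4) {
    c_g <- fem$W[[g]] * (if (is.list(coef)) coef[[g]] else coef)
    cols[[g]] <- -c_g * vr[[g]] * fem$inv_hr;     tabs[[g]] <- fem$tab$XN[[g]]
    cols[[g + 4]] <- -c_g * vz[[g]] * fem$inv_hz; tabs[[g + 4]] <- fem$tab$YN[[g]]
  }
  vals_gemm(cols, tabs)
}

# SUPG terms: test function tau (v . grad Na) against either Nb ("mass") or
# (v . grad Nb + react Nb) ("advection + reaction").
vals_supg_mass <- function(fem, vr, vz, tau, coef) {
  cols <- tabs <- vector("list", 8L)
  for (g in 1:4) {
    c_g <- fem$W[[g]] * tau[[g]] * (if (is.list(coef)) coef[[g]] else coef)
    cols[[g]] <- c_g * vr[[g]] * fem$inv_hr;     tabs[[g]] <- fem$tab$XN[[g]]
    cols[[g + 4]] <- c_g * vz[[g]] * fem$inv_hz; tabs[[g + 4]] <- fem$tab$YN[[g]]
  }
  vals_gemm(cols, tabs)
}

vals_supg_adv <- function(fem, vr, vz, tau, react = NULL) {
  nr <- if (is.null(react)) 16L else 24L
  cols <- tabs <- vector("list", nr)
  for (g in 1:4) {
    c_g <- fem$W[[g]] * tau[[g]]
    ar <- vr[[g]] * fem$inv_hr; az <- vz[[g]] * fem$inv_hz
    cols[[g]] <- c_g * ar * ar;       tabs[[g]] <- fem$tab$XX[[g]]
    cols[[g + 4]] <- c_g * ar * az;   tabs[[g + 4]] <- fem$tab$XY[[g]]
    cols[[g + 8]] <- c_g * az * ar;   tabs[[g + 8]] <- fem$tab$YX[[g]]
    cols[[g + 12]] <- c_g * az * az;  tabs[[g + 12]] <- fem$tab$YY[[g]]
    if (!is.null(react)) {
      rg <- react[[g]]
      cols[[g + 16]] <- c_g * ar * rg; tabs[[g + 16]] <- fem$tab$XN[[g]]
      cols[[g + 20]] <- c_g * az * rg; tabs[[g + 20]] <- fem$tab$YN[[g]]
    }
  }
  vals_gemm(cols, tabs)
}

# Assemble a scalar matrix from a vals matrix.
asm_scalar <- function(fem, vals) {
  A <- fem$pattern$tmpl
  A@x <- pattern_reduce(fem$pattern, vals)
  A
}

# Load vector with a per-Gauss-point coefficient: F_a = sum_g W c N_a
load_vector <- function(fem, coef) {
  f <- numeric(fem$nn)
  for (g in 1:4) {
    c_g <- fem$W[[g]] * (if (is.list(coef)) coef[[g]] else coef)
    Ng <- fem$N[[g]]
    for (a in 1:4)
      f <- f + accumulate_nodal(fem, a, c_g * Ng[a], f_len = fem$nn)
  }
  f
}

# Fast scatter-add of per-element values to nodes via one of the 4 corners.
accumulate_nodal <- function(fem, a, vals, f_len) {
  out <- numeric(f_len)
  s <- rowsum(vals, fem$conn[, a])
  out[as.integer(rownames(s))] <- s
  out
}

#' Integrate a nodal field over the axisymmetric domain
#'
#' @param fem `axi_fem`.
#' @param field nodal values; alternatively a list of 4 per-Gauss-point
#'   vectors.
#' @return `integral of field * 2 pi r dr dz` (m^3 times field units).
#' @export
integrate_field <- function(fem, field) {
  tot <- 0
  if (is.list(field)) {
    for (g in 1:4) tot <- tot + sum(fem$W[[g]] * field[[g]])
  } else {
    for (g in 1:4) {
      fg <- gp_value(fem, field, g)
      tot <- tot + sum(fem$W[[g]] * fg)
    }
  }
  tot
}

# Field value / gradient at Gauss point g from nodal values.
gp_value <- function(fem, nodal, g) {
  Ng <- fem$N[[g]]; conn <- fem$conn
  Ng[1] * nodal[conn[, 1]] + Ng[2] * nodal[conn[, 2]] +
    Ng[3] * nodal[conn[, 3]] + Ng[4] * nodal[conn[, 4]]
}

gp_grad <- function(fem, nodal, g) {
  conn <- fem$conn; dr <- fem$dNdr[[g]]; dz <- fem$dNdz[[g]]
  list(
    dr = dr[, 1] * nodal[conn[, 1]] + dr[, 2] * nodal[conn[, 2]] +
      dr[, 3] * nodal[conn[, 3]] + dr[, 4] * nodal[conn[, 4]],
    dz = dz[, 1] * nodal[conn[, 1]] + dz[, 2] * nodal[conn[, 2]] +
      dz[, 3] * nodal[conn[, 3]] + dz[, 4] * nodal[conn[, 4]]
  )
}

# Axisymmetric volumetric strain at Gauss point g: du_r/dr + u_r/r + du_z/dz.
gp_volumetric_strain <- function(fem, ur, uz, g) {
  gu <- gp_grad(fem, ur, g)
  gw <- gp_grad(fem, uz, g)
  gu$dr + gp_value(fem, ur, g) / fem$rg[[g]] + gw$dz
}

# Lumped L2 projection of per-Gauss-point values to nodes.
project_to_nodes <- function(fem, gpvals) {
  num <- numeric(fem$nn); den <- numeric(fem$nn)
  for (g in 1:4) {
    Ng <- fem$N[[g]]
    for (a in 1:4) {
      w <- fem$W[[g]] * Ng[a]
      num <- num + accumulate_nodal(fem, a, w * gpvals[[g]], fem$nn)
      den <- den + accumulate_nodal(fem, a, w, fem$nn)
    }
  }
  num / den
}

#' Nodal volumetric strain field
#'
#' Lumped L2 projection of the axisymmetric volumetric strain (which includes
#' the hoop contribution `u_r / r`) from Gauss points to nodes.
#'
#' @param fem `axi_fem`.
#' @param ur,uz nodal displacement fields (m).
#' @return Nodal volumetric strain (dimensionless).
#' @export
nodal_volumetric_strain <- function(fem, ur, uz) {
  ev <- lapply(1:4, function(g) gp_volumetric_strain(fem, ur, uz, g))
  project_to_nodes(fem, ev)
}

#' Drug mass held by one network
#'
#' Volume integral `int C w phi 2 pi r dr dz` over the meridian plane, the
#' drug mass of a network in normalized-concentration units times m^3.
#'
#' @param fem `axi_fem`.
#' @param C nodal normalized concentration.
#' @param phi porosity: a scalar, a nodal vector, or a per-Gauss-point list.
#' @param w network volume fraction.
#' @return Mass (normalized units times m^3).
#' @export
compartment_drug_mass <- function(fem, C, phi, w) {
  tot <- 0
  for (g in 1:4) {
    Cg <- gp_value(fem, C, g)
    pg <- if (is.list(phi)) phi[[g]] else if (length(phi) == 1L) phi else
      gp_value(fem, phi, g)
    tot <- tot + sum(fem$W[[g]] * Cg * pg)
  }
  w * tot
}
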