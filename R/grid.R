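#' Build a structured axisymmetric grid
#'
#' Tensor-product quadrilateral grid on the meridian (r, z) plane of a
#' cylinder.  Nodes are uniform by default; explicit node coordinate vectors
#' allow graded spacing (see [graded_nodes()]) while keeping the tensor
#' structure.
#'
#' @param r_extent,z_extent radial and axial extent (m), positive.
#' @param n_r,n_z number of elements per direction (>= 1; >= 2 for anything
#'   resembling a field solve).
#' @param r_nodes,z_nodes optional strictly increasing node coordinate
#'   vectors overriding the uniform spacing; must start at 0 and end at the
#'   extent and have length `n + 1`.
#' @return Object of class `axi_grid`: node coordinates `rc`, `zc` (length
#'   `n_nodes`), element connectivity `conn` (`n_el x 4`, counterclockwise),
#'   per-element sizes `hr`, `hz`, and boundary node index sets `axis`
#'   (r = 0), `outer` (r = r_extent), `bottom` (z = 0), `top` (z = z_extent).
#' @export
build_grid <- function(r_extent, z_extent, n_r, n_z,
                       r_nodes = NULL, z_nodes = NULL) {
  if (r_extent <= 0 || z_extent <= 0) stop("grid extents must be positive")
  if (n_r < 1 || n_z < 1) stop("grid needs at least one element per direction")
  check_nodes <- function(x, n, ext, nm) {
    if (length(x) != n + 1 || any(diff(x) <= 0) ||
        abs(x[1]) > 1e-14 * ext || abs(x[length(x)] - ext) > 1e-9 * ext)
      stop(sprintf("%s must be increasing from 0 to the extent with n + 1 entries", nm))
    x[1] <- 0; x[length(x)] <- ext
    x
  }
  r <- if (is.null(r_nodes)) seq(0, r_extent, length.out = n_r + 1) else
    check_nodes(r_nodes, n_r, r_extent, "r_nodes")
  z <- if (is.null(z_nodes)) seq(0, z_extent, length.out = n_z + 1) else
    check_nodes(z_nodes, n_z, z_extent, "z_nodes")
  nrp <- n_r + 1L; nzp <- n_z + 1L
  nn <- nrp * nzp
  rc <- rep(r, times = nzp)
  zc <- rep(z, each = nrp)
  node_id <- function(i, j) i + (j - 1L) * nrp      # i in 1..nrp, j in 1..nzp
  ei <- rep(seq_len(n_r), times = n_z)
  ej <- rep(seq_len(n_z), each = n_r)
  conn <- cbind(node_id(ei, ej), node_id(ei + 1L, ej),
                node_id(ei + 1L, ej + 1L), node_id(ei, ej + 1L))
  structure(list(
    r_extent = r_extent, z_extent = z_extent, n_r = n_r, n_z = n_z,
    r = r, z = z, n_nodes = nn, n_el = n_r * n_z,
    rc = rc, zc = zc, conn = conn,
    hr = diff(r)[ei], hz = diff(z)[ej], el_i = ei, el_j = ej,
    axis   = which(abs(rc) < 1e-14),
    outer  = which(abs(rc - r_extent) < 1e-9 * r_extent),
    bottom = which(abs(zc) < 1e-14),
    top    = which(abs(zc - z_extent) < 1e-9 * z_extent)
  ), class = "axi_grid")
}

#' @export
print.axi_grid <- function(x, ...) {
  cat(sprintf("axisymmetric grid: %g mm x %g mm, %d x %d elements (%d nodes)\n",
              1e3 * x$r_extent, 1e3 * x$z_extent, x$n_r, x$n_z, x$n_nodes))
  invisible(x)
}

#' Graded 1-D node distribution
#'
#' Node coordinates on `[0, extent]` clustered around a focus point with a
#' minimum spacing there and geometric growth away from it, capped at
#' `h_max`.  A node is placed exactly at the focus.  Useful for resolving a
#' needle-scale source inside a centimetre-scale domain without a uniform
#' fine mesh.
#'
#' @param extent interval length (m).
#' @param focus location to cluster around, in `[0, extent]`.
#' @param h_min spacing at the focus (m).
#' @param growth geometric growth factor (> 1), e.g. 1.08.
#' @param h_max optional spacing cap (m); default `extent / 8`.
#' @return Strictly increasing node vector from 0 to `extent`.
#' @export
graded_nodes <- function(extent, focus, h_min, growth = 1.08, h_max = extent / 8) {
  if (focus < 0 || focus > extent) stop("focus must lie inside the interval")
  one_side <- function(len) {
    if (len <= 1e-14) return(numeric(0))
    h <- h_min; pos <- 0; out <- numeric(0)
    while (pos < len - 1e-14) {
      h <- min(h, h_max, len - pos)
      pos <- pos + h
      out <- c(out, pos)
      h <- h * growth
    }
    out[length(out)] <- len
    out
  }
  up <- focus + one_side(extent - focus)
  dn <- focus - rev(one_side(focus))
  nodes <- unique(c(rev(dn), focus, up))
  nodes <- nodes[nodes >= -1e-14 & nodes <= extent + 1e-12]
  nodes[1] <- max(nodes[1], 0)
  sort(nodes)
}

#' Locate the node nearest to a point
#' @param grid `axi_grid`.
#' @param r,z coordinates (m).
#' @return Node index (1-based).
#' @export
nearest_node <- function(grid, r, z) {
  i <- which.min(abs(grid$r - r))
  j <- which.min(abs(grid$z - z))
  i + (j - 1L) * (grid$n_r + 1L)
}

#' Interpolate a nodal field at a point
#'
#' Bilinear interpolation using the element shape functions; exact at nodes
#' and for fields linear in r and z.
#'
#' @param grid `axi_grid`.
#' @param field nodal values (length `n_nodes`).
#' @param r,z evaluation point (m), inside the domain.
#' @return Interpolated value.
#' @export
interp_at <- function(grid, field, r, z) {
  i <- findInterval(r, grid$r, all.inside = TRUE)
  j <- findInterval(z, grid$z, all.inside = TRUE)
  xr <- (r - grid$r[i]) / (grid$r[i + 1] - grid$r[i])
  xz <- (z - grid$z[j]) / (grid$z[j + 1] - grid$z[j])
  nrp <- grid$n_r + 1L
  n00 <- i + (j - 1L) * nrp
  (1 - xr) * (1 - xz) * field[n00] + xr * (1 - xz) * field[n00 + 1L] +
    xr * xz * field[n00 + nrp + 1L] + (1 - xr) * xz * field[n00 + nrp]
}
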