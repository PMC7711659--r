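#' Partition the simulation cell into subvolumes
#'
#' Divides the rotationally symmetric cell into nz axial slabs and, within
#' each slab, nr equal-area annular rings spanning the accessible radius at
#' that z (the cell radius in the baths, the wall profile R(z) inside the
#' membrane).  Slab edges are snapped to the membrane faces so that every
#' cell lies entirely in a bath or entirely in the pore.  The local
#' equilibrium assumption holds per cell: one electrochemical potential and
#' one sampled concentration per species per cell.
#'
#' @param system A [pore_system()].
#' @param nz,nr Number of axial slabs and radial rings (both >= 1; at least
#'   2 each for transport runs).
#' @return An object of class `subvolume_grid` with elements
#'   `z_edges` (length nz+1, after snapping), `nz`, `nr`,
#'   `r_edges2` (nz x (nr+1) matrix of squared ring radii),
#'   `volume` (nz x nr, nm^3), `z_center`, `r_center` (nz x nr),
#'   `Rmax` (accessible radius per slab) and `in_pore` (logical per slab).
#' @export
build_subvolume_grid <- function(system, nz, nr) {
  stopifnot(inherits(system, "pore_system"), nz >= 1, nr >= 1)
  L <- system$cell_half_length
  z_edges <- seq(-L, L, length.out = nz + 1)
  if (!is.null(system$membrane)) {
    z_edges <- sort(unique(c(z_edges, system$membrane)))
    # drop edges that collide with a membrane face within tolerance
    keep <- c(TRUE, diff(z_edges) > 1e-9)
    z_edges <- z_edges[keep]
  }
  nz_eff <- length(z_edges) - 1L
  z_center <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  Rmax <- accessible_radius(system, z_center)
  if (any(!is.finite(Rmax)) || any(Rmax <= 0)) {
    stop("degenerate geometry: nonpositive accessible radius in a slab")
  }
  r_edges2 <- t(vapply(Rmax, function(R) R^2 * (0:nr) / nr, numeric(nr + 1)))
  dz <- diff(z_edges)
  volume <- matrix(0, nz_eff, nr)
  r_center <- matrix(0, nz_eff, nr)
  for (i in seq_len(nz_eff)) {
    dA2 <- diff(r_edges2[i, ])
    volume[i, ] <- pi * dA2 * dz[i]
    # area-centroid radius of each annulus
    r_lo <- sqrt(r_edges2[i, -(nr + 1)])
    r_hi <- sqrt(r_edges2[i, -1])
    r_center[i, ] <- (2 / 3) * (r_hi^3 - r_lo^3) / (r_hi^2 - r_lo^2)
  }
  in_pore <- if (is.null(system$membrane)) rep(FALSE, nz_eff) else
    z_center > system$membrane[1] & z_center < system$membrane[2]
  structure(
    list(z_edges = z_edges, nz = nz_eff, nr = nr, r_edges2 = r_edges2,
         volume = volume, z_center = z_center, r_center = r_center,
         Rmax = Rmax, in_pore = in_pore),
    class = "subvolume_grid"
  )
}

#' @export
print.subvolume_grid <- function(x, ...) {
  cat(sprintf("<subvolume_grid> %d x %d cells, total volume %.3f nm^3\n",
              x$nz, x$nr, sum(x$volume)))
  invisible(x)
}

#' Map points to subvolumes
#'
#' @param grid A [build_subvolume_grid()] result.
#' @param z,r Cylindrical coordinates of points, nm (vectorized).
#' @return Integer cell indices (column-major over (iz, ir), i.e.
#'   `(ir - 1) * nz + iz`), or `NA` for points outside the grid.
#' @export
locate_subvolume <- function(grid, z, r) {
  iz <- findInterval(z, grid$z_edges, rightmost.closed = TRUE,
                     all.inside = FALSE)
  iz[z < grid$z_edges[1] | z > grid$z_edges[length(grid$z_edges)]] <- NA
  ir <- rep(NA_integer_, length(z))
  ok <- !is.na(iz)
  for (i in which(ok)) {
    k <- findInterval(r[i]^2, grid$r_edges2[iz[i], ],
                      rightmost.closed = TRUE)
    ir[i] <- if (k >= 1 && k <= grid$nr) k else NA_integer_
  }
  (ir - 1L) * grid$nz + iz
}

#' Total accessible volume of the cell
#'
#' @param grid A [build_subvolume_grid()] result.
#' @return Volume in nm^3.
#' @export
grid_total_volume <- function(grid) sum(grid$volume)
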