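# Nernst-Planck transport on the subvolume grid.
#
# The flux density of species i is j_i = -(1/kT) D_i c_i grad(mu_i); on the
# grid this becomes a face-centered finite-volume form with face
# conductance g = D_face * c_face * A_face / d_face (particles/ns per kT of
# potential difference), with arithmetic-mean face values.  Steady state
# requires the discrete continuity equation: the face flows out of every
# interior cell sum to zero, which is a sparse linear system for mu given
# c.  The same face network is used for flux evaluation and for the solve,
# so a solved field is divergence-free by construction.

#' Per-cell diffusion-coefficient profile
#'
#' `d_bulk` outside the membrane span, `d_pore` inside, with an optional
#' linear ramp over a transition zone of width `ramp` on each side of the
#' membrane faces (used for channel vestibules).
#'
#' @param electrolyte An [electrolyte()].
#' @param grid A [build_subvolume_grid()] result.
#' @param system The [pore_system()] the grid was built for.
#' @param ramp Transition-zone width in nm (0 for a sharp step).
#' @return Matrix (n_species x n_cells) of diffusion coefficients in
#'   nm^2/ns, strictly positive.
#' @export
diffusion_profile <- function(electrolyte, grid, system, ramp = 0) {
  ns <- length(electrolyte$species)
  ncell <- grid$nz * grid$nr
  d_bulk <- vapply(electrolyte$species, `[[`, 0, "d_bulk") * 1e9
  d_pore <- vapply(electrolyte$species, `[[`, 0, "d_pore") * 1e9
  wz <- rep(0, grid$nz)  # in-pore weight per slab
  if (!is.null(system$membrane)) {
    zc <- grid$z_center
    inside <- zc >= system$membrane[1] & zc <= system$membrane[2]
    wz[inside] <- 1
    if (ramp > 0) {
      dist <- pmin(abs(zc - system$membrane[1]),
                   abs(zc - system$membrane[2]))
      outside <- !inside & dist < ramp
      wz[outside] <- 1 - dist[outside] / ramp
    }
  }
  D <- matrix(0, ns, ncell)
  for (s in seq_len(ns)) {
    dcol <- d_bulk[s] + (d_pore[s] - d_bulk[s]) * wz
    D[s, ] <- rep(dcol, grid$nr)
  }
  D
}

# Face network of the grid: endpoints (cell indices), areas (nm^2) and
# center distances (nm) of all axial and radial faces.
.face_network <- function(grid) {
  nz <- grid$nz; nr <- grid$nr
  idx <- function(iz, ir) (ir - 1L) * nz + iz
  ann_area <- t(apply(grid$r_edges2, 1, diff)) * pi  # nz x nr
  if (nr == 1L) ann_area <- matrix(pi * apply(grid$r_edges2, 1, diff),
                                   nz, 1L)
  dz <- diff(grid$z_edges)
  a_from <- a_to <- a_area <- a_dist <- NULL
  if (nz > 1L) {
    iz <- rep(seq_len(nz - 1L), nr)
    ir <- rep(seq_len(nr), each = nz - 1L)
    a_from <- idx(iz, ir)
    a_to <- idx(iz + 1L, ir)
    a_area <- pmin(ann_area[cbind(iz, ir)], ann_area[cbind(iz + 1L, ir)])
    a_dist <- grid$z_center[iz + 1L] - grid$z_center[iz]
  }
  r_from <- r_to <- r_area <- r_dist <- NULL
  if (nr > 1L) {
    iz <- rep(seq_len(nz), nr - 1L)
    ir <- rep(seq_len(nr - 1L), each = nz)
    r_from <- idx(iz, ir)
    r_to <- idx(iz, ir + 1L)
    r_edge <- sqrt(grid$r_edges2[cbind(iz, ir + 1L)])
    r_area <- 2 * pi * r_edge * dz[iz]
    r_dist <- grid$r_center[cbind(iz, ir + 1L)] - grid$r_center[cbind(iz, ir)]
  }
  list(from = c(a_from, r_from), to = c(a_to, r_to),
       area = c(a_area, r_area), dist = c(a_dist, r_dist),
       n_axial = length(a_from),
       axial_iz = if (nz > 1L) rep(seq_len(nz - 1L), nr) else integer(0),
       axial_ir = if (nz > 1L) rep(seq_len(nr), each = nz - 1L) else
         integer(0))
}

# face conductances (particles/ns per kT) for one species
.face_conductance <- function(net, conc, D, conc_floor = 1e-8) {
  cf <- pmax((conc[net$from] + conc[net$to]) / 2, conc_floor) *
    molar_to_density()
  Df <- (D[net$from] + D[net$to]) / 2
  Df * cf * net$area / net$dist
}

#' Nernst-Planck flux field on the grid
#'
#' Evaluates the face flows -g * (mu_to - mu_from) for every face of the
#' grid and the resulting net outflow (divergence) per cell.
#'
#' @param conc Concentration matrix (n_species x n_cells), mol/L.
#' @param mu Electrochemical-potential matrix, same shape, kT.
#' @param D Diffusion-coefficient matrix from [diffusion_profile()],
#'   nm^2/ns.
#' @param grid The [build_subvolume_grid()] result.
#' @param conc_floor Concentration floor (mol/L) applied in the face
#'   coefficients.
#' @return An object of class `np_flux_field`: per species, face flows
#'   (particles/ns), face flux densities (particles/nm^2/ns), the axial
#'   face bookkeeping, and the per-cell divergence.
#' @export
np_flux <- function(conc, mu, D, grid, conc_floor = 1e-8) {
  stopifnot(nrow(conc) == nrow(mu), ncol(conc) == ncol(mu))
  net <- .face_network(grid)
  ns <- nrow(conc)
  ncell <- ncol(conc)
  flows <- flux_density <- vector("list", ns)
  divergence <- matrix(0, ns, ncell)
  for (s in seq_len(ns)) {
    g <- .face_conductance(net, conc[s, ], D[s, ], conc_floor)
    f <- -g * (mu[s, net$to] - mu[s, net$from])
    flows[[s]] <- f
    flux_density[[s]] <- f / net$area
    div <- numeric(ncell)
    for (k in seq_along(f)) {
      # f is the flow from `from` toward `to`: outflow of one, inflow of
      # the other
      div[net$from[k]] <- div[net$from[k]] + f[k]
      div[net$to[k]] <- div[net$to[k]] - f[k]
    }
    divergence[s, ] <- div  # net outflow per cell (particles/ns)
  }
  structure(list(flows = flows, flux_density = flux_density,
                 divergence = divergence, network = net, grid = grid),
            class = "np_flux_field")
}

#' Species and total current through a cross-section
#'
#' I_i(z) = z_i * e * (sum of axial face flows through the cross-section
#' at z), reported in pA.  Positive current flows toward positive z.
#'
#' @param flux An [np_flux()] result.
#' @param valence Vector of species valences.
#' @param z Axial position of the cross-section, nm; the nearest axial
#'   face plane is used.
#' @return List with `per_species` (pA), `total` (pA) and the face plane
#'   `z_face` actually used.
#' @export
total_current <- function(flux, valence, z = 0) {
  grid <- flux$grid
  if (grid$nz < 2L) stop("current needs at least two axial slabs")
  z_faces <- grid$z_edges[2:grid$nz]
  if (z < grid$z_edges[1] || z > grid$z_edges[grid$nz + 1L]) {
    stop("cross-section lies outside the cell")
  }
  plane <- which.min(abs(z_faces - z))
  net <- flux$network
  sel <- net$axial_iz == plane
  per <- vapply(seq_along(flux$flows), function(s) {
    valence[s] * .e_pA_ns * sum(flux$flows[[s]][seq_len(net$n_axial)][sel])
  }, 0)
  list(per_species = per, total = sum(per), z_face = z_faces[plane])
}

#' Axial current profile
#'
#' Species currents through every axial face plane; at a divergence-free
#' flux field the profile is constant in z.
#'
#' @inheritParams total_current
#' @return Matrix (n_species x n_planes) of currents in pA, with the face
#'   z positions as column names.
#' @export
current_profile <- function(flux, valence) {
  grid <- flux$grid
  net <- flux$network
  z_faces <- grid$z_edges[2:grid$nz]
  out <- matrix(0, length(flux$flows), length(z_faces))
  for (p in seq_along(z_faces)) {
    sel <- which(net$axial_iz == p)
    for (s in seq_along(flux$flows)) {
      out[s, p] <- valence[s] * .e_pA_ns * sum(flux$flows[[s]][sel])
    }
  }
  colnames(out) <- sprintf("%.3f", z_faces)
  out
}

#' Solve for the electrochemical potential at fixed concentrations
#'
#' Solves the discrete continuity equation div(D c grad mu) = 0 per species
#' with Dirichlet values on the two boundary slabs (the baths).  The
#' resulting mu field produces a divergence-free Nernst-Planck flux for the
#' given concentration field.
#'
#' @param conc Concentration matrix (n_species x n_cells), mol/L.
#' @param D Diffusion matrix (nm^2/ns), as [diffusion_profile()].
#' @param grid The subvolume grid.
#' @param boundary_mu Matrix (n_species x 2) with columns `left`, `right`:
#'   bath electrochemical potentials in kT (voltage included).
#' @param conc_floor Concentration floor (mol/L) in the coefficients,
#'   keeping the system nonsingular across depletion zones.
#' @return Matrix of mu values (n_species x n_cells, kT); boundary cells
#'   carry the bath values exactly.
#' @export
solve_mu_given_c <- function(conc, D, grid, boundary_mu,
                             conc_floor = 1e-8) {
  nz <- grid$nz; nr <- grid$nr
  ncell <- nz * nr
  stopifnot(ncol(conc) == ncell, nz >= 2L)
  net <- .face_network(grid)
  iz_of <- rep(seq_len(nz), nr)
  boundary <- which(iz_of == 1L | iz_of == nz)
  interior <- setdiff(seq_len(ncell), boundary)
  ns <- nrow(conc)
  mu <- matrix(0, ns, ncell)
  for (s in seq_len(ns)) {
    mu_b <- numeric(ncell)
    mu_b[iz_of == 1L] <- boundary_mu[s, 1]
    mu_b[iz_of == nz] <- boundary_mu[s, 2]
    g <- .face_conductance(net, conc[s, ], D[s, ], conc_floor)
    # assemble the interior Laplacian and the boundary source
    remap <- integer(ncell)
    remap[interior] <- seq_along(interior)
    ii <- jj <- integer(0)
    xx <- numeric(0)
    rhs <- numeric(length(interior))
    for (k in seq_along(g)) {
      a <- net$from[k]; b <- net$to[k]
      ia <- remap[a]; ib <- remap[b]
      a_int <- a %in% interior; b_int <- b %in% interior
      if (a_int) {
        ii <- c(ii, ia); jj <- c(jj, ia); xx <- c(xx, g[k])
        if (b_int) {
          ii <- c(ii, ia); jj <- c(jj, ib); xx <- c(xx, -g[k])
        } else rhs[ia] <- rhs[ia] + g[k] * mu_b[b]
      }
      if (b_int) {
        ii <- c(ii, ib); jj <- c(jj, ib); xx <- c(xx, g[k])
        if (a_int) {
          ii <- c(ii, ib); jj <- c(jj, ia); xx <- c(xx, -g[k])
        } else rhs[ib] <- rhs[ib] + g[k] * mu_b[a]
      }
    }
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = rep(length(interior), 2L))
    mu_s <- mu_b
    mu_s[interior] <- as.vector(Matrix::solve(A, rhs))
    mu[s, ] <- mu_s
  }
  mu
}

#' Bath boundary electrochemical potentials
#'
#' mu(boundary, side) = mu_bath + z * e * U(side) / kT with the applied
#' voltage split symmetrically, U(left) = +U/2 and U(right) = -U/2.  Only
#' the potential difference is physical; the symmetric split keeps the
#' finite cell's net charging antisymmetric in U, so reversing the voltage
#' of a mirror-symmetric system reverses the current exactly in
#' distribution (a single-sided split does not share this property in a
#' finite cell).
#'
#' @param mu_left,mu_right `chem_potential_table`s for the two baths (from
#'   [calibrate_chemical_potentials()]).
#' @param valence Species valences.
#' @param voltage_mV Applied voltage U, mV (left minus right).
#' @param temperature Temperature in K.
#' @return Matrix (n_species x 2) with columns `left`, `right` (kT).
#' @export
boundary_potentials <- function(mu_left, mu_right, valence, voltage_mV,
                                temperature = 298.15) {
  vt <- thermal_voltage_mV(temperature)
  cbind(left = mu_left$mu_total + valence * (voltage_mV / 2) / vt,
        right = mu_right$mu_total - valence * (voltage_mV / 2) / vt)
}

#' Self-consistent NP+LEMC iteration
#'
#' Alternates Local Equilibrium Monte Carlo sampling (concentrations given
#' the potential field) with the continuity solve (potential field given
#' concentrations), under-relaxing the potential update, until the species
#' currents are stationary.  The applied voltage enters only through the
#' boundary potentials; the electric field inside the cell emerges from the
#' sampled ion-ion and ion-charge interactions.
#'
#' @param system A [pore_system()] (its `applied_voltage` is used).
#' @param electrolyte An [electrolyte()].
#' @param grid A [build_subvolume_grid()] result.
#' @param mu_left,mu_right Calibration tables for the two baths.
#' @param run_spec [lemc_run_spec()] for the per-iteration sampling.
#' @param production [lemc_run_spec()] for the final averaging run
#'   (defaults to `run_spec` with twice the sweeps).
#' @param max_iter Maximum outer iterations.
#' @param min_iter Minimum outer iterations before convergence may be
#'   declared; guards against the small per-step changes produced by
#'   under-relaxation being mistaken for stationarity.
#' @param window Convergence is judged on the current drift across this
#'   many iterations, not on successive iterates.
#' @param tol Relative current change over the window defining
#'   convergence.
#' @param omega Under-relaxation factor for the potential update in (0, 1].
#' @param ramp Diffusion-profile transition width, nm.
#' @param conc_floor Concentration floor for the solve, mol/L.
#' @param seed Integer seed for the whole iteration (reproducible).
#' @return An object of class `npl_result`: final fieldset, potential
#'   field, flux, per-species currents with block standard errors, the
#'   iteration history and a convergence flag.
#' @export
npl_iterate <- function(system, electrolyte, grid, mu_left, mu_right,
                        run_spec = lemc_run_spec(), production = NULL,
                        max_iter = 24, min_iter = 8, window = 3,
                        tol = 0.05, omega = 0.5,
                        ramp = 0, conc_floor = 1e-8, seed = 1) {
  stopifnot(omega > 0, omega <= 1, max_iter >= 1, min_iter >= 1,
            window >= 1)
  z <- electrolyte$valence
  bmu <- boundary_potentials(mu_left, mu_right, z,
                             system$applied_voltage,
                             electrolyte$temperature)
  D <- diffusion_profile(electrolyte, grid, system, ramp)
  ncell <- grid$nz * grid$nr
  iz_of <- rep(seq_len(grid$nz), grid$nr)
  # initial field: linear interpolation between the bath values
  frac <- (grid$z_center[iz_of] - grid$z_center[1]) /
    (grid$z_center[grid$nz] - grid$z_center[1])
  mu <- matrix(0, length(z), ncell)
  for (s in seq_along(z)) {
    mu[s, ] <- bmu[s, 1] + frac * (bmu[s, 2] - bmu[s, 1])
  }
  set.seed(seed)
  history <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fs <- run_lemc(system, electrolyte, grid, mu, run_spec)
    mu_solved <- solve_mu_given_c(fs$conc, D, grid, bmu, conc_floor)
    flux <- np_flux(fs$conc, mu_solved, D, grid, conc_floor)
    I <- total_current(flux, z)$per_species
    history[[it]] <- I
    mu <- (1 - omega) * mu + omega * mu_solved
    if (it >= min_iter && it > window) {
      # drift across the window, against the combined block noise
      I_ref <- history[[it - window]]
      scale <- pmax(abs(I), abs(I_ref))
      dI <- abs(I - I_ref)
      se <- .block_current_se(fs, D, grid, bmu, z, conc_floor)
      if (all(dI <= tol * scale + 3 * sqrt(2) * se)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("NP+LEMC outer iteration did not meet the current tolerance ",
            "within ", max_iter, " iterations; returning the last state")
  }
  prod_spec <- production %||% lemc_run_spec(
    sweeps = 2L * run_spec$sweeps, equilibration = run_spec$equilibration,
    move_probs = stats::setNames(run_spec$move_probs,
                                 c("insert", "delete", "displace")),
    max_step = run_spec$max_step,
    moves_per_sweep = run_spec$moves_per_sweep,
    blocks = run_spec$blocks, interactions = run_spec$interactions)
  fs <- run_lemc(system, electrolyte, grid, mu, prod_spec)
  mu_final <- solve_mu_given_c(fs$conc, D, grid, bmu, conc_floor)
  flux <- np_flux(fs$conc, mu_final, D, grid, conc_floor)
  I <- total_current(flux, z)$per_species
  se <- .block_current_se(fs, D, grid, bmu, z, conc_floor)
  currents <- data.frame(species = electrolyte$names, current_pA = I,
                         se_pA = se, stringsAsFactors = FALSE)
  structure(
    list(fieldset = fs, mu = mu_final, flux = flux, currents = currents,
         total_current_pA = sum(I), total_se_pA = sqrt(sum(se^2)),
         history = do.call(rbind, history), converged = converged,
         iterations = length(history), boundary_mu = bmu,
         diffusion = D, voltage_mV = system$applied_voltage,
         grid = grid, species = electrolyte$names, valence = z,
         conc_floor = conc_floor),
    class = "npl_result"
  )
}

# standard error of the species currents from block-resampled
# concentrations: re-solve the potential for each block's concentration
# field and take the spread of the resulting currents
.block_current_se <- function(fs, D, grid, bmu, valence, conc_floor) {
  nb <- dim(fs$block_conc)[3]
  Ib <- matrix(0, nb, length(valence))
  for (b in seq_len(nb)) {
    cb <- fs$block_conc[, , b, drop = TRUE]
    if (is.null(dim(cb))) cb <- matrix(cb, nrow = length(valence))
    mu_b <- solve_mu_given_c(cb, D, grid, bmu, conc_floor)
    Ib[b, ] <- total_current(np_flux(cb, mu_b, D, grid, conc_floor),
                             valence)$per_species
  }
  apply(Ib, 2, stats::sd) / sqrt(nb)
}

#' @export
print.npl_result <- function(x, ...) {
  cat(sprintf("<npl_result> U = %+.1f mV, %s after %d outer iterations\n",
              x$voltage_mV,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  for (i in seq_len(nrow(x$currents))) {
    cat(sprintf("  I(%-5s) = %+10.4g pA  (se %.3g)\n",
                x$currents$species[i], x$currents$current_pA[i],
                x$currents$se_pA[i]))
  }
  cat(sprintf("  total     %+10.4g pA\n", x$total_current_pA))
  invisible(x)
}
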