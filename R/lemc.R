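#' Monte Carlo run settings
#'
#' @param sweeps Total number of sweeps; one sweep is `moves_per_sweep`
#'   attempted moves, and the configuration is sampled once per sweep after
#'   equilibration.
#' @param equilibration Sweeps discarded before sampling
#'   (`0 <= equilibration < sweeps`).
#' @param move_probs Probabilities of insertion, deletion and displacement
#'   attempts; must sum to 1.  Defaults to the symmetric 1/3 mix.
#' @param max_step Maximum displacement per Cartesian component, nm.
#' @param moves_per_sweep Attempted moves per sweep; `NULL` chooses a value
#'   automatically from the expected particle number.
#' @param blocks Number of blocks for block-averaged standard errors.
#' @param interactions `"full"` (hard spheres + Coulomb), `"hard"` (hard
#'   spheres only) or `"none"` (ideal gas); the reduced settings exist for
#'   validation against exactly solvable references.
#' @param widom_per_sweep Widom test insertions per sweep (0 disables);
#'   each insertion probes every species at one random point and
#'   accumulates the per-cell estimate of `exp(-mu_excess/kT)`.
#' @return An object of class `lemc_run_spec`.
#' @export
lemc_run_spec <- function(sweeps = 2000, equilibration = 500,
                          move_probs = c(insert = 1 / 3, delete = 1 / 3,
                                         displace = 1 / 3),
                          max_step = 0.3, moves_per_sweep = NULL,
                          blocks = 8,
                          interactions = c("full", "hard", "none"),
                          widom_per_sweep = 0) {
  stopifnot(sweeps > equilibration, equilibration >= 0,
            length(move_probs) == 3L, all(move_probs >= 0),
            abs(sum(move_probs) - 1) < 1e-12, max_step > 0, blocks >= 2,
            widom_per_sweep >= 0)
  interactions <- match.arg(interactions)
  structure(
    list(sweeps = as.integer(sweeps),
         equilibration = as.integer(equilibration),
         move_probs = unname(move_probs), max_step = max_step,
         moves_per_sweep = moves_per_sweep, blocks = as.integer(blocks),
         interactions = interactions,
         widom_per_sweep = as.integer(widom_per_sweep)),
    class = "lemc_run_spec"
  )
}

# --- marshalling helpers between R objects and the C++ engine -------------

.engine_geom <- function(system) {
  g <- list(cell_radius = system$cell_radius,
            cell_half_length = system$cell_half_length,
            has_membrane = !is.null(system$membrane))
  if (g$has_membrane) {
    g$zm_left <- system$membrane[1]
    g$zm_right <- system$membrane[2]
    g$wall_z <- system$wall_profile$z
    g$wall_R <- system$wall_profile$R
  }
  g
}

.engine_species <- function(electrolyte, interactions = "full") {
  lB <- if (interactions == "full")
    bjerrum_length(electrolyte$dielectric, electrolyte$temperature) else 0
  list(radius = vapply(electrolyte$species, `[[`, 0, "radius"),
       valence = as.numeric(electrolyte$valence),
       lB = lB, conc_unit = molar_to_density())
}

.engine_fixed <- function(system) {
  fc <- system$fixed_charges
  if (is.null(fc) || nrow(fc) == 0L) {
    matrix(numeric(0), 0L, 4L)
  } else {
    as.matrix(fc[, c("x", "y", "z", "q")])
  }
}

# deterministic initial placement of structural ions inside their
# confinement regions (uses the current R RNG stream).  Crowded regions --
# the whole point of the charge-space-competition filter -- defeat plain
# rejection sampling, so a golden-angle spiral lattice is used as a
# fallback before giving up.
.engine_structural <- function(system) {
  specs <- system$structural_ions
  n <- sum(vapply(specs, `[[`, 0L, "count"))
  pos <- matrix(0, n, 3L)
  rad <- chg <- numeric(n)
  conf <- matrix(0, n, 4L)
  ok_at <- function(i, p, s) {
    if (!is_accessible(system, s$radius, p[1], p[2], p[3],
                       c(s$z_range, s$r_range))) return(FALSE)
    if (i > 1L) {
      d <- sqrt(colSums((t(pos[seq_len(i - 1L), , drop = FALSE]) - p)^2))
      if (any(d < s$radius + rad[seq_len(i - 1L)])) return(FALSE)
    }
    TRUE
  }
  attempt <- function(use_lattice) {
    i <- 0L
    for (s in specs) {
      dz_grid <- (s$z_range[2] - s$z_range[1]) / s$count
      for (k in seq_len(s$count)) {
        i <- i + 1L
        placed <- FALSE
        if (use_lattice) {
          # golden-angle spiral: evenly spaced in z, rotated in azimuth
          for (rfrac in c(0.75, 0.5, 0.9, 0.25)) {
            r <- s$r_range[1] + rfrac * (s$r_range[2] - s$r_range[1])
            phi <- k * 2.399963
            z <- s$z_range[1] + (k - 0.5) * dz_grid
            p <- c(r * cos(phi), r * sin(phi), z)
            if (ok_at(i, p, s)) {
              pos[i, ] <<- p
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          # random search, confined to the slot's z slice in lattice mode
          zlo <- if (use_lattice) s$z_range[1] + (k - 1L) * dz_grid else
            s$z_range[1]
          zhi <- if (use_lattice) s$z_range[1] + k * dz_grid else
            s$z_range[2]
          for (try in 1:500) {
            z <- stats::runif(1, zlo, zhi)
            r <- sqrt(stats::runif(1, s$r_range[1]^2, s$r_range[2]^2))
            phi <- stats::runif(1, 0, 2 * pi)
            p <- c(r * cos(phi), r * sin(phi), z)
            if (ok_at(i, p, s)) {
              pos[i, ] <<- p
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) return(FALSE)
        rad[i] <<- s$radius
        chg[i] <<- s$charge
        conf[i, ] <<- c(s$z_range, s$r_range)
      }
    }
    TRUE
  }
  if (!attempt(FALSE) && !attempt(TRUE)) {
    stop("could not place the structural ions without overlap; ",
         "a confinement region is too crowded")
  }
  list(positions = pos, radius = rad, charge = chg, confinement = conf)
}

.engine_grid <- function(grid) {
  list(z_edges = grid$z_edges, nz = grid$nz, nr = grid$nr,
       r_edges2 = grid$r_edges2, volume = grid$volume)
}

.auto_moves_per_sweep <- function(electrolyte, grid) {
  cmax <- max(sum(electrolyte$conc_left), sum(electrolyte$conc_right))
  n_expect <- cmax * molar_to_density() * grid_total_volume(grid)
  as.integer(max(64, ceiling(2 * n_expect)))
}

#' Sample concentrations at a given electrochemical-potential field
#'
#' Runs the Local Equilibrium Monte Carlo engine: a grand-canonical-style
#' simulation in which each subvolume has its own electrochemical potential
#' mu_{i,alpha} per mobile species.  Insertion into subvolume alpha is
#' accepted with probability
#' min(1, c0*V_alpha/(N+1) * exp((mu - dU)/kT)), deletion with
#' min(1, N/(c0*V_alpha) * exp((-mu - dU)/kT)), and displacements with the
#' Metropolis rule including the mu difference of the cells involved.
#' Insertion points are drawn uniformly in the geometric subvolume; hard
#' walls act through infinite energy.  The output is the sampled
#' concentration per species per subvolume with block-averaged standard
#' errors.  Structural ions move by displacement only, so their number is
#' conserved exactly.
#'
#' @param system A [pore_system()].
#' @param electrolyte An [electrolyte()] (defines the mobile species).
#' @param grid A [build_subvolume_grid()] result.
#' @param mu Matrix (n_species x n_cells) of electrochemical potentials in
#'   kT, columns ordered as `(ir - 1) * nz + iz`.
#' @param run_spec A [lemc_run_spec()].
#' @param seed Optional integer seed (sets the R RNG; identical inputs and
#'   seed give identical output).
#' @return An object of class `lemc_fieldset`: list with `conc`, `conc_se`
#'   (mol/L matrices shaped like `mu`), `block_conc` (species x cells x
#'   blocks array), acceptance statistics, particle counts and the final
#'   structural-ion positions.
#' @export
run_lemc <- function(system, electrolyte, grid, mu, run_spec = lemc_run_spec(),
                     seed = NULL) {
  stopifnot(inherits(system, "pore_system"),
            inherits(electrolyte, "electrolyte"),
            inherits(grid, "subvolume_grid"),
            inherits(run_spec, "lemc_run_spec"))
  ncell <- grid$nz * grid$nr
  ns <- length(electrolyte$species)
  if (!is.matrix(mu) || nrow(mu) != ns || ncol(mu) != ncell) {
    stop("`mu` must be an n_species x n_cells matrix")
  }
  if (any(!is.finite(mu))) stop("`mu` must be finite everywhere")
  if (!is.null(seed)) set.seed(seed)
  mps <- run_spec$moves_per_sweep %||%
    .auto_moves_per_sweep(electrolyte, grid)
  run <- list(sweeps = run_spec$sweeps,
              equilibration = run_spec$equilibration,
              p_insert = run_spec$move_probs[1],
              p_delete = run_spec$move_probs[2],
              max_step = run_spec$max_step,
              moves_per_sweep = as.integer(mps),
              blocks = run_spec$blocks,
              interactions = match(run_spec$interactions,
                                   c("full", "hard", "none")) - 1L,
              widom_per_sweep = run_spec$widom_per_sweep %||% 0L)
  out <- lemc_engine(.engine_geom(system),
                     .engine_species(electrolyte, run_spec$interactions),
                     .engine_fixed(system),
                     .engine_structural(system),
                     .engine_grid(grid), mu, run)
  acc <- out$accepts / pmax(out$attempts, 1)
  if (any(out$attempts > 500 & (acc < 0.01))) {
    warning("very low Monte Carlo acceptance rate (",
            paste(sprintf("%.3f", acc), collapse = "/"),
            " for insert/delete/displace)")
  }
  structure(
    list(conc = out$conc, conc_se = out$conc_se,
         block_conc = array(out$block_conc, dim = c(ns, ncell,
                                                    out$n_blocks)),
         widom_mean = out$widom_mean, widom_n = out$widom_n,
         n_mobile = out$n_mobile, n_structural = out$n_structural,
         structural_positions = out$structural_positions,
         attempts = out$attempts, accepts = out$accepts,
         grid = grid, mu = mu, species = electrolyte$names),
    class = "lemc_fieldset"
  )
}

#' @export
print.lemc_fieldset <- function(x, ...) {
  cat(sprintf("<lemc_fieldset> %d species x %d cells; %d mobile ions at end\n",
              nrow(x$conc), ncol(x$conc), x$n_mobile))
  acc <- x$accepts / pmax(x$attempts, 1)
  cat(sprintf("  acceptance: insert %.2f, delete %.2f, displace %.2f\n",
              acc[1], acc[2], acc[3]))
  invisible(x)
}
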