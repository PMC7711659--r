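# Chemical-potential closure.  The transport boundary conditions are bath
# concentrations, but the sampler's input is an electrochemical potential
# per subvolume, so the two must be linked: the calibration finds the bulk
# chemical potential at which a grand-canonical simulation of the Primitive
# Model reproduces the prescribed bath composition.  Chemical potentials
# are measured in kT relative to an ideal gas at c0 = 1 mol/L, which
# removes the thermal wavelength; only differences and the mu <-> c closure
# matter anywhere in the method.

#' Debye screening length of a bath
#'
#' lambda_D = sqrt(eps*eps0*kT / (e^2 * sum_i rho_i z_i^2)) for the point-ion
#' electrolyte.
#'
#' @param electrolyte An [electrolyte()].
#' @param side `"left"` or `"right"` bath.
#' @return Debye length in nm.
#' @export
debye_length <- function(electrolyte, side = c("left", "right")) {
  side <- match.arg(side)
  conc <- if (side == "left") electrolyte$conc_left else
    electrolyte$conc_right
  rho <- conc * molar_to_density()
  s2 <- sum(rho * electrolyte$valence^2)
  if (s2 <= 0) stop("zero ionic strength: Debye length undefined")
  lB <- bjerrum_length(electrolyte$dielectric, electrolyte$temperature)
  1 / sqrt(4 * pi * lB * s2)
}

#' Mean Spherical Approximation screening length
#'
#' Screening length 1/(2*Gamma) of the restricted Primitive Model (equal
#' ion diameters d), with the MSA closure 2*Gamma*d = sqrt(1 + 2*kappa*d) - 1
#' where kappa is the inverse Debye length.  As d -> 0 this reduces to the
#' Debye length; at finite d the hard cores weaken the screening, so the
#' MSA length exceeds the Debye length and grows with d.
#'
#' @param electrolyte An [electrolyte()].
#' @param ion_diameter Common ion diameter d in nm (>= 0); defaults to the
#'   sum of the radii of the first cation and first anion (contact
#'   distance).
#' @param side `"left"` or `"right"` bath.
#' @return MSA screening length in nm.
#' @export
msa_screening_length <- function(electrolyte, ion_diameter = NULL,
                                 side = c("left", "right")) {
  side <- match.arg(side)
  if (is.null(ion_diameter)) {
    z <- electrolyte$valence
    rp <- electrolyte$species[[which(z > 0)[1]]]$radius
    rm <- electrolyte$species[[which(z < 0)[1]]]$radius
    ion_diameter <- rp + rm
  }
  stopifnot(ion_diameter >= 0)
  lam <- debye_length(electrolyte, side)
  if (ion_diameter == 0) return(lam)
  kappa <- 1 / lam
  two_gamma <- (sqrt(1 + 2 * kappa * ion_diameter) - 1) / ion_diameter
  1 / two_gamma
}

#' Double-layer-overlap scaling parameter
#'
#' xi = Rpore / (lambda * z_plus * |z_minus|): the pore radius in units of
#' the screening length, reduced by the valence product.  Small xi means
#' overlapping double layers (coion depletion, selectivity, rectification);
#' large xi means bulk-like electrolyte on the pore axis.
#'
#' @param pore_radius Pore radius, nm.
#' @param screening_length Screening length lambda, nm (Debye or MSA).
#' @param z_plus,z_minus Cation valence and anion valence magnitude.
#' @return The dimensionless scaling parameter.
#' @export
xi_scaling_parameter <- function(pore_radius, screening_length,
                                 z_plus, z_minus) {
  stopifnot(pore_radius > 0, z_plus > 0, z_minus != 0)
  if (screening_length <= 0) stop("screening length must be positive")
  pore_radius / (screening_length * z_plus * abs(z_minus))
}

#' Debye-Hueckel limiting-law excess chemical potential
#'
#' mu_ex = -z^2 * lB * kappa / 2 in kT: the dilute-electrolyte limit used
#' as an independent reference for the calibration.
#'
#' @param electrolyte An [electrolyte()].
#' @param side Bath side.
#' @return Named vector of excess chemical potentials (kT) per species.
#' @export
dh_limiting_excess <- function(electrolyte, side = c("left", "right")) {
  side <- match.arg(side)
  lB <- bjerrum_length(electrolyte$dielectric, electrolyte$temperature)
  kappa <- 1 / debye_length(electrolyte, side)
  mu <- -electrolyte$valence^2 * lB * kappa / 2
  names(mu) <- electrolyte$names
  mu
}

# cylindrical bulk box sized to hold several screening lengths and enough
# particles of the least-abundant species for stable statistics
.default_bulk_box <- function(electrolyte, side = "left") {
  lam <- tryCatch(debye_length(electrolyte, side), error = function(e) 1)
  conc <- if (side == "left") electrolyte$conc_left else
    electrolyte$conc_right
  cmin <- min(conc[conc > 0])
  s_part <- (15 / (cmin * molar_to_density() * pi))^(1 / 3)
  size <- max(2.5, 3 * lam, s_part)
  pore_system(cell_radius = size, cell_half_length = size)
}

#' Calibrate bulk chemical potentials to target concentrations
#'
#' Iterative grand-canonical closure: starting from the ideal-gas guess
#' mu_i = ln(c_i/c0), a bulk GCMC simulation (the LEMC engine with uniform
#' mu and no membrane) measures the excess chemical potential by Widom
#' test insertions, and mu is corrected by the damped per-species update
#' mu <- mu + omega * (ln(c_target/c0) + mu_excess - mu).  The Widom
#' estimator shares the exact grand-canonical fixed point with the
#' sampled-concentration closure (rho(r) = e^mu <exp(-dU/kT)> pointwise)
#' but has much smaller variance, especially in dilute systems.  Damping
#' is needed because the excess is strongly state-dependent for
#' multivalent salts, where the undamped fixed point oscillates.  After
#' the iterations the last few iterates are averaged (reducing the
#' stochastic wandering of the fixed point) and a longer validation run at
#' the averaged potentials records the concentrations actually reproduced.
#' Concentrations are measured in the interior subvolumes of the box to
#' avoid hard-wall artifacts.  With `interactions = "none"` the ideal
#' result mu_i = ln(c_i/c0) is returned exactly.
#'
#' @param electrolyte An [electrolyte()]; the bath selected by `side` is
#'   the calibration target and must be electroneutral.
#' @param side `"left"` or `"right"`.
#' @param iterations Number of fixed-point iterations (>= 1).
#' @param sweeps Sampling sweeps per iteration; the validation run uses
#'   `4 * sweeps`.
#' @param box Optional [pore_system()] bulk box (no membrane); default is a
#'   cylinder holding at least three screening lengths.
#' @param interactions Passed to [lemc_run_spec()].
#' @param omega Damping factor of the update in (0, 1].
#' @param average_last How many final iterates to average (>= 1).
#' @param seed Integer seed; the calibration is deterministic given the
#'   seed.
#' @param tol Relative concentration mismatch above which the validation
#'   run raises a warning.
#' @return A `chem_potential_table`: data.frame with columns `species`,
#'   `target_conc`, `mu_total`, `mu_ideal`, `mu_excess` (kT, reference
#'   c0 = 1 mol/L) plus attributes `validation` (sampled concentrations of
#'   the final run), `trace`, `temperature`, `dielectric`, `seed`.
#' @export
calibrate_chemical_potentials <- function(electrolyte,
                                          side = c("left", "right"),
                                          iterations = 8, sweeps = 3000,
                                          box = NULL,
                                          interactions = "full",
                                          omega = 0.5, average_last = 3,
                                          seed = 1, tol = 0.02) {
  side <- match.arg(side)
  stopifnot(iterations >= 1, omega > 0, omega <= 1, average_last >= 1)
  target <- if (side == "left") electrolyte$conc_left else
    electrolyte$conc_right
  if (any(target <= 0)) {
    stop("calibration requires strictly positive target concentrations")
  }
  mu_ideal <- log(target)
  if (interactions == "none") {
    return(.chem_table(electrolyte, target, mu_ideal, mu_ideal,
                       validation = target, trace = NULL, seed = seed))
  }
  if (is.null(box)) box <- .default_bulk_box(electrolyte, side)
  if (!is.null(box$membrane)) stop("calibration box must have no membrane")
  grid <- build_subvolume_grid(box, nz = 4, nr = 3)
  interior <- .interior_cells(grid)
  bulk_el <- electrolyte
  bulk_el$conc_left <- bulk_el$conc_right <- target
  set.seed(seed)
  mu <- mu_ideal
  iterates <- matrix(0, iterations, length(mu))
  trace <- list()
  w_int <- .cell_volumes(grid)[interior]
  sample_at <- function(mu, nswp) {
    spec <- lemc_run_spec(sweeps = nswp,
                          equilibration = max(200L, nswp %/% 5L),
                          interactions = interactions,
                          widom_per_sweep = 8L)
    mu_field <- matrix(mu, nrow = length(mu), ncol = grid$nz * grid$nr)
    fs <- run_lemc(box, bulk_el, grid, mu_field, spec)
    csamp <- .interior_conc(fs, grid, interior)
    if (any(csamp <= 0)) {
      stop("calibration sampled zero concentration; increase sweeps ",
           "or enlarge the box")
    }
    # interior-averaged Widom estimate of exp(-mu_excess) per species
    wm <- fs$widom_mean[, interior, drop = FALSE]
    wex <- as.vector(wm %*% w_int) / sum(w_int)
    list(conc = csamp, mu_excess = -log(wex))
  }
  for (it in seq_len(iterations)) {
    s <- sample_at(mu, sweeps)
    trace[[it]] <- data.frame(iteration = it, species = electrolyte$names,
                              sampled = unname(s$conc), mu = unname(mu))
    # damped Widom update: both closures share the exact grand-canonical
    # fixed point rho(r) = e^mu <exp(-dU)>, but the Widom estimator has
    # far smaller variance in dilute systems
    mu <- mu + omega * (log(target) + s$mu_excess - mu)
    iterates[it, ] <- mu
  }
  keep <- seq(max(1L, iterations - average_last + 1L), iterations)
  mu <- colMeans(iterates[keep, , drop = FALSE])
  s <- sample_at(mu, 4L * sweeps)
  csamp <- s$conc
  trace[[iterations + 1L]] <- data.frame(
    iteration = iterations + 1L, species = electrolyte$names,
    sampled = unname(csamp), mu = unname(mu))
  mismatch <- max(abs(csamp / target - 1))
  if (mismatch > tol) {
    warning(sprintf(paste0("calibration validation run misses the target ",
                           "by %.1f%% (tolerance %.1f%%); consider more ",
                           "sweeps or iterations"),
                    100 * mismatch, 100 * tol))
  }
  .chem_table(electrolyte, target, stats::setNames(mu, electrolyte$names),
              mu_ideal, validation = csamp,
              trace = do.call(rbind, trace), seed = seed)
}

.chem_table <- function(electrolyte, target, mu_total, mu_ideal,
                        validation, trace, seed) {
  tab <- data.frame(species = electrolyte$names,
                    target_conc = unname(target),
                    mu_total = unname(mu_total),
                    mu_ideal = unname(mu_ideal),
                    mu_excess = unname(mu_total - mu_ideal),
                    stringsAsFactors = FALSE)
  attr(tab, "validation") <- validation
  attr(tab, "trace") <- trace
  attr(tab, "temperature") <- electrolyte$temperature
  attr(tab, "dielectric") <- electrolyte$dielectric
  attr(tab, "seed") <- seed
  class(tab) <- c("chem_potential_table", "data.frame")
  tab
}

.interior_cells <- function(grid) {
  iz <- rep(seq_len(grid$nz), grid$nr)
  ir <- rep(seq_len(grid$nr), each = grid$nz)
  which(iz > 1 & iz < grid$nz & ir < grid$nr)
}

.cell_volumes <- function(grid) {
  # cell-ordered volumes, index (ir - 1) * nz + iz
  as.vector(grid$volume)
}

.interior_conc <- function(fieldset, grid, cells) {
  w <- .cell_volumes(grid)[cells]
  as.vector(fieldset$conc[, cells, drop = FALSE] %*% w) / sum(w)
}
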