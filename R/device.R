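# Device functions: the input-output characteristics of a pore summarized
# as scalars -- selectivity, rectification, conductance -- plus the axial
# profile and slope-conductance analyses that explain them.

#' Cation selectivity index
#'
#' |I+| / (|I+| + |I-|): 0.5 is non-selective, values above 0.5 mean the
#' pore prefers cations, below 0.5 anions.
#'
#' @param I_plus,I_minus Cation and anion currents (any consistent unit).
#' @return Selectivity in \[0, 1\], or `NA` with attribute
#'   `undefined = TRUE` when both currents are zero.
#' @export
cation_selectivity <- function(I_plus, I_minus) {
  a <- abs(I_plus); b <- abs(I_minus)
  if (a + b == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  a / (a + b)
}

#' Rectification ratio
#'
#' |I_on| / |I_off|: the asymmetry of the current magnitude between the two
#' voltage signs.  1 means no rectification.
#'
#' @param I_on,I_off Currents in the ON and OFF states.
#' @return Ratio >= 0, or `Inf` with attribute `infinite = TRUE` if
#'   `I_off` is zero.
#' @export
rectification <- function(I_on, I_off) {
  if (I_off == 0) {
    return(structure(Inf, infinite = TRUE))
  }
  abs(I_on) / abs(I_off)
}

#' Cross-section averaged axial concentration profiles
#'
#' Volume-weighted radial average of the concentration field in each axial
#' slab: cbar(z) = sum_r c(z,r) V(z,r) / sum_r V(z,r) over the accessible
#' cross-section.
#'
#' @param conc Concentration matrix (n_species x n_cells, mol/L) or an
#'   `lemc_fieldset`.
#' @param grid The [build_subvolume_grid()] result (ignored if `conc` is a
#'   fieldset).
#' @param species Optional species names for the output.
#' @return A data.frame with columns `z` (slab centers, nm), one column per
#'   species (mol/L).
#' @export
axial_profile <- function(conc, grid = NULL, species = NULL) {
  if (inherits(conc, "lemc_fieldset")) {
    grid <- conc$grid
    species <- species %||% conc$species
    conc <- conc$conc
  }
  stopifnot(inherits(grid, "subvolume_grid"))
  ns <- nrow(conc)
  species <- species %||% paste0("species", seq_len(ns))
  out <- data.frame(z = grid$z_center)
  for (s in seq_len(ns)) {
    cmat <- matrix(conc[s, ], grid$nz, grid$nr)
    out[[species[s]]] <- rowSums(cmat * grid$volume) / rowSums(grid$volume)
  }
  out
}

#' Slope-conductance resistance from the inverse-concentration integral
#'
#' In the small-voltage limit the resistance a pore offers to species i is
#' the series sum of its axial layers,
#' R_i = kT/(z_i^2 e^2) * integral dz / (D_i(z) A(z) cbar_i(z)),
#' so depletion zones (small cbar) dominate the integral exactly as high
#' resistors dominate a series circuit.  The kT/(z^2 e^2) prefactor makes
#' R_i the reciprocal of the species' slope conductance.
#'
#' @param profile Axial profile data.frame from [axial_profile()] (column
#'   `z` plus one column per species).
#' @param electrolyte The [electrolyte()] (valences, diffusion
#'   coefficients, temperature).
#' @param grid The subvolume grid (areas and slab widths).
#' @param system The [pore_system()]; sets the default integration domain
#'   (the membrane span) and the diffusion profile.
#' @param domain `"pore"` (membrane span only) or `"cell"` (the whole
#'   cell, i.e. including the bath access regions inside the cell).
#' @param ramp Diffusion transition width, nm (as in
#'   [diffusion_profile()]).
#' @param conc_floor Concentration floor, mol/L.
#' @return A data.frame with `species`, `resistance_Gohm` and
#'   `conductance_pS` (= 1/R).
#' @export
slope_resistance <- function(profile, electrolyte, grid, system,
                             domain = c("pore", "cell"), ramp = 0,
                             conc_floor = 1e-8) {
  domain <- match.arg(domain)
  if (domain == "pore" && is.null(system$membrane)) {
    stop("domain \"pore\" needs a membrane; use domain = \"cell\"")
  }
  dz <- diff(grid$z_edges)
  zc <- grid$z_center
  keep <- if (domain == "pore") {
    zc >= system$membrane[1] & zc <= system$membrane[2]
  } else rep(TRUE, grid$nz)
  if (!any(keep)) stop("empty integration domain")
  area <- pi * grid$Rmax^2  # accessible cross-section per slab, nm^2
  D <- diffusion_profile(electrolyte, grid, system, ramp)
  ns <- length(electrolyte$species)
  res <- numeric(ns)
  for (s in seq_len(ns)) {
    cbar <- pmax(profile[[electrolyte$names[s]]], conc_floor) *
      molar_to_density()
    Ds <- D[s, seq_len(grid$nz)]  # radially uniform by construction
    integ <- sum(dz[keep] / (Ds[keep] * area[keep] * cbar[keep]))
    # integ is in ns (flow per kT of driving); convert to electrical units
    z <- electrolyte$valence[s]
    g_pS <- z^2 * .e_pA_ns * 1000 /
      (thermal_voltage_mV(electrolyte$temperature) * integ)
    res[s] <- 1000 / g_pS  # G(pS) -> R(Gohm): R = 1e3/G
  }
  data.frame(species = electrolyte$names, resistance_Gohm = res,
             conductance_pS = 1000 / res, stringsAsFactors = FALSE)
}

#' Assemble the device-function summary of a run (or an ON/OFF pair)
#'
#' Collects species currents, chord conductance G = I/U, cation
#' selectivity, rectification (when both ON and OFF runs are given), the
#' dimensionless net charge Q of the pattern and the scaling parameter xi.
#'
#' @param on An `npl_result` (the ON state, or the only run).
#' @param off Optional `npl_result` for the OFF state (opposite voltage).
#' @param pattern Optional [charge_pattern()] for Q and xi.
#' @param electrolyte Optional [electrolyte()] for xi.
#' @param screening `"debye"` or `"msa"`: which screening length enters
#'   xi.
#' @return An object of class `device_result`.
#' @export
summarize_device <- function(on, off = NULL, pattern = NULL,
                             electrolyte = NULL,
                             screening = c("debye", "msa")) {
  screening <- match.arg(screening)
  stopifnot(inherits(on, "npl_result"))
  if (!is.null(off)) {
    stopifnot(inherits(off, "npl_result"))
    if (!identical(dim(on$mu), dim(off$mu)) ||
        !identical(on$species, off$species)) {
      stop("ON and OFF runs come from different systems")
    }
  }
  z <- on$valence
  I <- on$currents$current_pA
  Ip <- sum(I[z > 0]); Im <- sum(I[z < 0])
  sel <- cation_selectivity(Ip, Im)
  rect <- if (!is.null(off)) {
    rectification(on$total_current_pA, off$total_current_pA)
  } else NA_real_
  G <- if (on$voltage_mV != 0) {
    1000 * on$total_current_pA / on$voltage_mV  # pA/mV -> pS
  } else NA_real_
  Q <- if (!is.null(pattern)) net_charge_Q(pattern) else NA_real_
  xi <- if (!is.null(pattern) && !is.null(electrolyte)) {
    lam <- if (screening == "debye") debye_length(electrolyte) else
      msa_screening_length(electrolyte)
    zp <- max(electrolyte$valence)
    zm <- abs(min(electrolyte$valence))
    xi_scaling_parameter(pattern$pore_radius, lam, zp, zm)
  } else NA_real_
  structure(
    list(currents = on$currents, total_current_pA = on$total_current_pA,
         off_current_pA = if (!is.null(off)) off$total_current_pA else
           NA_real_,
         selectivity = sel, rectification = rect,
         chord_conductance_pS = G, Q = Q, xi = xi,
         voltage_mV = on$voltage_mV,
         converged = on$converged &&
           (is.null(off) || off$converged)),
    class = "device_result"
  )
}

#' @export
print.device_result <- function(x, ...) {
  cat("<device_result>\n")
  cat(sprintf("  U = %+.1f mV, I = %+.4g pA (G = %.4g pS)%s\n",
              x$voltage_mV, x$total_current_pA,
              x$chord_conductance_pS,
              if (x$converged) "" else "  [not converged]"))
  if (!is.na(x$selectivity)) {
    cat(sprintf("  cation selectivity  %.3f\n", x$selectivity))
  }
  if (!is.na(x$rectification)) {
    cat(sprintf("  rectification       %.3f  (|I_off| = %.4g pA)\n",
                x$rectification, abs(x$off_current_pA)))
  }
  if (!is.na(x$Q)) cat(sprintf("  net charge Q        %+.3f\n", x$Q))
  if (!is.na(x$xi)) cat(sprintf("  scaling xi          %.3f\n", x$xi))
  invisible(x)
}
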