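# Primitive Model configuration energies.  Ions are charged hard spheres in
# a uniform dielectric; there are no periodic boundaries and no Ewald sums:
# all Coulomb interactions are direct pairwise sums in the finite cell.
# Infinite energy (hard overlap or wall violation) is represented by `Inf`,
# which Monte Carlo acceptance treats as certain rejection.

#' Pair interaction energy of two ions
#'
#' Hard-sphere plus Coulomb energy in thermal units:
#' `Inf` for `distance < Ri + Rj`, otherwise `zi*zj*lB/r` kT where lB is the
#' Bjerrum length of the medium.
#'
#' @param species_i,species_j [ion_species()] objects.
#' @param distance Center-to-center distances in nm (vectorized, >= 0).
#' @param dielectric Relative permittivity.
#' @param temperature Temperature in K.
#' @return Energies in kT.
#' @export
pair_energy <- function(species_i, species_j, distance,
                        dielectric = 78.45, temperature = 298.15) {
  stopifnot(all(distance >= 0))
  lB <- bjerrum_length(dielectric, temperature)
  contact <- species_i$radius + species_j$radius
  u <- species_i$valence * species_j$valence * lB / distance
  u[distance < contact] <- Inf
  u
}

#' Energy of an ion in the external field of the system
#'
#' `Inf` if the ion center violates any hard wall (membrane, pore wall,
#' outer cylinder, or its confinement region for a structural ion);
#' otherwise the Coulomb sum over all fixed charges of the system.
#'
#' @param species An [ion_species()] (or any list with `radius` and
#'   `valence`).
#' @param position Numeric `c(x, y, z)` in nm.
#' @param system A [pore_system()].
#' @param dielectric,temperature Medium parameters.
#' @param confinement Optional confinement box `c(z1, z2, r1, r2)` for
#'   structural ions.
#' @return Energy in kT.
#' @export
external_energy <- function(species, position, system,
                            dielectric = 78.45, temperature = 298.15,
                            confinement = NULL) {
  if (!is_accessible(system, species$radius, position[1], position[2],
                     position[3], confinement)) {
    return(Inf)
  }
  fc <- system$fixed_charges
  if (is.null(fc) || nrow(fc) == 0L) return(0)
  lB <- bjerrum_length(dielectric, temperature)
  d <- sqrt((fc$x - position[1])^2 + (fc$y - position[2])^2 +
              (fc$z - position[3])^2)
  sum(species$valence * fc$q * lB / d)
}

#' Total energy of an ion configuration
#'
#' Sum over unordered ion pairs plus each ion's external energy (walls and
#' fixed charges).  A configuration is a data.frame with columns `species`
#' (names matching `species_table`), `x`, `y`, `z`; structural ions may
#' carry a `confinement` list-column.
#'
#' @param config Configuration data.frame.
#' @param system A [pore_system()].
#' @param species_table Named list of [ion_species()] (or species-like
#'   lists) keyed by the names used in `config$species`.
#' @param dielectric,temperature Medium parameters.
#' @return Total energy in kT (`Inf` if any overlap or wall violation).
#' @export
total_energy <- function(config, system, species_table,
                         dielectric = 78.45, temperature = 298.15) {
  n <- nrow(config)
  if (n == 0L) return(0)
  lB <- bjerrum_length(dielectric, temperature)
  sp <- species_table[config$species]
  zs <- vapply(sp, `[[`, 0, "valence")
  rs <- vapply(sp, `[[`, 0, "radius")
  conf <- config$confinement %||% vector("list", n)
  u <- 0
  for (i in seq_len(n)) {
    ue <- external_energy(sp[[i]], c(config$x[i], config$y[i], config$z[i]),
                          system, dielectric, temperature, conf[[i]])
    if (!is.finite(ue)) return(Inf)
    u <- u + ue
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      dx <- config$x[(i + 1L):n] - config$x[i]
      dy <- config$y[(i + 1L):n] - config$y[i]
      dz <- config$z[(i + 1L):n] - config$z[i]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      if (any(d < rs[i] + rs[(i + 1L):n])) return(Inf)
      u <- u + sum(zs[i] * zs[(i + 1L):n] * lB / d)
    }
  }
  u
}

#' Incremental energy change of a Monte Carlo move
#'
#' Energy difference produced by inserting, deleting or displacing a single
#' ion, computed from the interactions of that ion only.  Equals the full
#' recomputation `total_energy(after) - total_energy(before)` (to numerical
#' accuracy) at O(N) instead of O(N^2) cost.
#'
#' @param config Current configuration (see [total_energy()]).
#' @param move A list with `type` (`"insert"`, `"delete"` or
#'   `"displace"`), and for insert: `species`, `position`; for delete:
#'   `index`; for displace: `index`, `position` (the new position).
#' @inheritParams total_energy
#' @return Energy difference in kT (possibly `Inf` or `-Inf`).
#' @export
delta_energy <- function(config, move, system, species_table,
                         dielectric = 78.45, temperature = 298.15) {
  lB <- bjerrum_length(dielectric, temperature)
  conf <- config$confinement %||% vector("list", nrow(config))
  one_body <- function(sp, pos, exclude = 0L, confinement = NULL) {
    ue <- external_energy(sp, pos, system, dielectric, temperature,
                          confinement)
    if (!is.finite(ue)) return(Inf)
    idx <- setdiff(seq_len(nrow(config)), exclude)
    if (!length(idx)) return(ue)
    osp <- species_table[config$species[idx]]
    d <- sqrt((config$x[idx] - pos[1])^2 + (config$y[idx] - pos[2])^2 +
                (config$z[idx] - pos[3])^2)
    contact <- sp$radius + vapply(osp, `[[`, 0, "radius")
    if (any(d < contact)) return(Inf)
    ue + sum(sp$valence * vapply(osp, `[[`, 0, "valence") * lB / d)
  }
  switch(move$type,
    insert = one_body(species_table[[move$species]], move$position,
                      confinement = move$confinement %||% NULL),
    delete = {
      i <- move$index
      -one_body(species_table[[config$species[i]]],
                c(config$x[i], config$y[i], config$z[i]), exclude = i,
                confinement = conf[[i]])
    },
    displace = {
      i <- move$index
      u_new <- one_body(species_table[[config$species[i]]], move$position,
                        exclude = i, confinement = conf[[i]])
      u_old <- one_body(species_table[[config$species[i]]],
                        c(config$x[i], config$y[i], config$z[i]),
                        exclude = i, confinement = conf[[i]])
      u_new - u_old
    },
    stop("unknown move type: ", move$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
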