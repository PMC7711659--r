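#' Define an ion species
#'
#' An ion of the Primitive Model: a charged hard sphere with a valence, a
#' crystallographic (Pauling) radius and two diffusion coefficients -- one in
#' the bulk electrolyte and one inside the pore, where friction with the
#' confining geometry (and, implicitly, everything the reduced model leaves
#' out) slows the ion down.
#'
#' @param name Species label, e.g. `"Na+"`.
#' @param valence Signed integer charge number z.  Mobile electrolyte ions
#'   must have a nonzero integer valence; half-integer charges are reserved
#'   for structural ions (see [structural_ion_spec()]).
#' @param radius Hard-sphere radius in nm (> 0).
#' @param d_bulk Bulk diffusion coefficient in m^2/s (> 0).
#' @param d_pore Diffusion coefficient inside the pore in m^2/s (> 0);
#'   defaults to `d_bulk`.
#' @return An object of class `ion_species`.
#' @seealso [default_ion_table()] for the parameter set shipped with the
#'   package.
#' @export
ion_species <- function(name, valence, radius, d_bulk, d_pore = d_bulk) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(valence) || length(valence) != 1L ||
      valence != round(valence) || valence == 0) {
    stop("`valence` must be a nonzero integer for a mobile ion species")
  }
  stopifnot(radius > 0, d_bulk > 0, d_pore > 0)
  structure(
    list(name = name, valence = as.integer(valence), radius = radius,
         d_bulk = d_bulk, d_pore = d_pore),
    class = "ion_species"
  )
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s  z=%+d  R=%.3f nm  Dbulk=%.3g m2/s  Dpore=%.3g m2/s\n",
              x$name, x$valence, x$radius, x$d_bulk, x$d_pore))
  invisible(x)
}

#' Reference ion parameters
#'
#' Hard-sphere (Pauling) radii and diffusion coefficients for the ions used
#' in the channel and nanopore studies.  Radii are in nm; diffusion
#' coefficients in m^2/s.  `d_pore` values are the fitted in-pore diffusion
#' coefficients of the reduced channel model; for nanopore work they are
#' usually overridden per study.
#'
#' @return A data.frame with columns `name`, `valence`, `radius`, `d_bulk`,
#'   `d_pore`.
#' @export
default_ion_table <- function() {
  data.frame(
    name    = c("Na+", "Cs+", "Ca2+", "Cl-"),
    valence = c(1L, 1L, 2L, -1L),
    radius  = c(0.095, 0.169, 0.099, 0.181),
    d_bulk  = c(1.334e-9, 2.056e-9, 0.792e-9, 2.032e-9),
    d_pore  = c(0.141e-9, 0.193e-9, 0.0243e-9, 0.25e-9),
    stringsAsFactors = FALSE
  )
}

#' Look up a shipped ion species by name
#'
#' @param name One of the names in [default_ion_table()].
#' @param d_pore Optional override of the in-pore diffusion coefficient
#'   (m^2/s).
#' @return An [ion_species()] object.
#' @export
lookup_ion <- function(name, d_pore = NULL) {
  tab <- default_ion_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown ion: ", name,
                     " (available: ", paste(tab$name, collapse = ", "), ")")
  ion_species(tab$name[i], tab$valence[i], tab$radius[i], tab$d_bulk[i],
              if (is.null(d_pore)) tab$d_pore[i] else d_pore)
}

#' Define an electrolyte and its two baths
#'
#' Collects the ion species, the bath compositions on the two sides of the
#' membrane, and the two response functions of the implicit solvent: the
#' relative permittivity and the temperature.  Each bath must be
#' electroneutral.
#'
#' @param species List of [ion_species()] objects.
#' @param conc_left,conc_right Named numeric vectors of bath concentrations
#'   in mol/L, one entry per species (left bath is at z < 0).  `conc_right`
#'   defaults to `conc_left` (symmetric baths).
#' @param dielectric Relative permittivity of the implicit solvent (> 1).
#' @param temperature Absolute temperature in K.
#' @return An object of class `electrolyte`.
#' @examples
#' el <- electrolyte(list(lookup_ion("Na+"), lookup_ion("Cl-")),
#'                   c("Na+" = 1, "Cl-" = 1))
#' @export
electrolyte <- function(species, conc_left, conc_right = conc_left,
                        dielectric = 78.45, temperature = 298.15) {
  stopifnot(is.list(species), length(species) >= 1L,
            all(vapply(species, inherits, TRUE, "ion_species")),
            dielectric > 1, temperature > 0)
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate species names")
  z <- vapply(species, `[[`, 0L, "valence")
  check_bath <- function(conc, side) {
    if (is.null(names(conc)) || !setequal(names(conc), nm)) {
      stop(side, " bath concentrations must be named after every species")
    }
    conc <- conc[nm]
    if (any(conc < 0)) stop(side, " bath has a negative concentration")
    scale <- sum(abs(z) * conc)
    if (scale > 0 && abs(sum(z * conc)) > 1e-12 * scale) {
      stop(side, " bath is not electroneutral: sum(z*c) = ",
           format(sum(z * conc)))
    }
    conc
  }
  structure(
    list(species = species, names = nm, valence = z,
         conc_left = check_bath(conc_left, "left"),
         conc_right = check_bath(conc_right, "right"),
         dielectric = dielectric, temperature = temperature),
    class = "electrolyte"
  )
}

#' @export
print.electrolyte <- function(x, ...) {
  cat(sprintf("<electrolyte> %d species, eps=%.2f, T=%.2f K\n",
              length(x$species), x$dielectric, x$temperature))
  for (i in seq_along(x$species)) {
    cat(sprintf("  %-5s z=%+d  left %.4g M | right %.4g M\n", x$names[i],
                x$valence[i], x$conc_left[i], x$conc_right[i]))
  }
  invisible(x)
}

#' Build a z+:z- model electrolyte
#'
#' Convenience constructor for the salts used in the localized-charge
#' studies: equal-radius cations and anions (0.15 nm) with valences
#' `z_plus`:`z_minus` at a given salt concentration (concentration of the
#' formula unit; ion concentrations follow from stoichiometry).
#'
#' @param z_plus,z_minus Cation valence (> 0) and anion valence magnitude
#'   (> 0).
#' @param conc Salt concentration, mol/L (both sides).
#' @param radius Common ionic radius, nm.
#' @param d_bulk,d_pore Diffusion coefficients, m^2/s.
#' @param dielectric,temperature Passed to [electrolyte()].
#' @return An [electrolyte()] object with species `"C<z>+"` and `"A<z>-"`.
#' @export
model_salt <- function(z_plus, z_minus, conc, radius = 0.15,
                       d_bulk = 1.334e-9, d_pore = d_bulk,
                       dielectric = 78.45, temperature = 298.15) {
  stopifnot(z_plus >= 1, z_minus >= 1, conc >= 0)
  cat_name <- sprintf("C%d+", z_plus)
  an_name <- sprintf("A%d-", z_minus)
  sp <- list(ion_species(cat_name, z_plus, radius, d_bulk, d_pore),
             ion_species(an_name, -z_minus, radius, d_bulk, d_pore))
  conc_vec <- c(z_minus * conc, z_plus * conc)
  names(conc_vec) <- c(cat_name, an_name)
  electrolyte(sp, conc_vec, dielectric = dielectric,
              temperature = temperature)
}
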