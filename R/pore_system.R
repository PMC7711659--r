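#' Confined structural ions
#'
#' Structural ions represent the charged protein groups of the reduced
#' channel model: hard spheres (typically half-charged carboxylate oxygens,
#' O1/2-) that are mobile within a confinement region but can never leave it
#' and are never inserted or deleted.
#'
#' @param charge Charge in units of e (e.g. -0.5 for O1/2-).
#' @param radius Hard-sphere radius in nm.
#' @param count Number of such ions (> 0).
#' @param z_range Axial confinement interval, nm, length 2.
#' @param r_range Radial confinement interval, nm, length 2 (distances from
#'   the pore axis).
#' @return An object of class `structural_ion_spec`.
#' @export
structural_ion_spec <- function(charge, radius, count, z_range, r_range) {
  stopifnot(length(z_range) == 2L, length(r_range) == 2L,
            z_range[1] < z_range[2], r_range[1] < r_range[2],
            r_range[1] >= 0, radius > 0, count > 0, count == round(count))
  structure(list(charge = charge, radius = radius, count = as.integer(count),
                 z_range = as.numeric(z_range), r_range = as.numeric(r_range)),
            class = "structural_ion_spec")
}

#' Define the simulation cell, membrane and pore
#'
#' The simulation cell is a finite cylinder of radius `cell_radius` spanning
#' z in [-`cell_half_length`, +`cell_half_length`].  A hard membrane slab may
#' occupy the interval `membrane`; a pore through it is described by the
#' rotationally symmetric hard-wall profile R(z).  Fixed point charges (e.g.
#' wall charges of a charge pattern, or a ring of protein charges) and
#' confined structural ions complete the system.  All walls are hard: an ion
#' center may not come closer to any wall than its hard-sphere radius.
#'
#' @param cell_radius Cylinder radius, nm.
#' @param cell_half_length Half of the cylinder length, nm.
#' @param membrane `NULL` (no membrane, a bulk box) or the interval
#'   `c(z_left, z_right)` occupied by the membrane slab, nm.
#' @param wall_profile Pore wall radius: either a single number (cylindrical
#'   pore) or a data.frame with columns `z`, `R` describing a piecewise
#'   linear profile R(z) over the membrane span.
#' @param fixed_charges `NULL` or a data.frame/matrix with columns
#'   `x`, `y`, `z`, `q` (positions nm, charges in e).
#' @param structural_ions List of [structural_ion_spec()] objects.
#' @param applied_voltage Voltage U in mV, potential of the left bath minus
#'   the right bath.
#' @return An object of class `pore_system`.
#' @export
pore_system <- function(cell_radius, cell_half_length, membrane = NULL,
                        wall_profile = NULL, fixed_charges = NULL,
                        structural_ions = list(), applied_voltage = 0) {
  stopifnot(cell_radius > 0, cell_half_length > 0)
  if (!is.null(membrane)) {
    stopifnot(length(membrane) == 2L, membrane[1] < membrane[2],
              membrane[1] > -cell_half_length, membrane[2] < cell_half_length)
    if (is.null(wall_profile)) stop("a membrane needs a `wall_profile`")
    if (is.numeric(wall_profile) && length(wall_profile) == 1L) {
      wall_profile <- data.frame(z = membrane, R = rep(wall_profile, 2L))
    }
    stopifnot(is.data.frame(wall_profile),
              all(c("z", "R") %in% names(wall_profile)),
              all(wall_profile$R > 0))
    if (any(wall_profile$R >= cell_radius)) {
      stop("wall profile R(z) must stay below the cell radius")
    }
  }
  if (!is.null(fixed_charges)) {
    fixed_charges <- as.data.frame(fixed_charges)
    stopifnot(all(c("x", "y", "z", "q") %in% names(fixed_charges)))
  }
  stopifnot(all(vapply(structural_ions, inherits, TRUE,
                       "structural_ion_spec")))
  sys <- structure(
    list(cell_radius = cell_radius, cell_half_length = cell_half_length,
         membrane = membrane, wall_profile = wall_profile,
         fixed_charges = fixed_charges, structural_ions = structural_ions,
         applied_voltage = applied_voltage),
    class = "pore_system"
  )
  for (s in structural_ions) {
    zc <- mean(s$z_range)
    if (!is.null(membrane) &&
        (zc < membrane[1] || zc > membrane[2] ||
         s$r_range[2] > wall_radius(sys, zc))) {
      stop("structural-ion confinement region lies outside the pore")
    }
  }
  if (!is.null(fixed_charges) && !is.null(membrane)) {
    rfc <- sqrt(fixed_charges$x^2 + fixed_charges$y^2)
    inside <- fixed_charges$z >= membrane[1] & fixed_charges$z <= membrane[2]
    if (any(inside & rfc < wall_radius(sys, fixed_charges$z) - 1e-9)) {
      stop("fixed charges must lie on or outside the pore wall surface")
    }
  }
  sys
}

#' @export
print.pore_system <- function(x, ...) {
  cat(sprintf("<pore_system> cell R=%.2f nm, half-length %.2f nm\n",
              x$cell_radius, x$cell_half_length))
  if (is.null(x$membrane)) {
    cat("  no membrane (bulk box)\n")
  } else {
    cat(sprintf("  membrane z in [%.2f, %.2f] nm, pore R(0)=%.3f nm\n",
                x$membrane[1], x$membrane[2], wall_radius(x, 0)))
  }
  nfc <- if (is.null(x$fixed_charges)) 0L else nrow(x$fixed_charges)
  cat(sprintf("  %d fixed charges (total %+.4g e), %d structural-ion groups\n",
              nfc, if (nfc) sum(x$fixed_charges$q) else 0,
              length(x$structural_ions)))
  cat(sprintf("  applied voltage %+.1f mV (left minus right)\n",
              x$applied_voltage))
  invisible(x)
}

#' Pore wall radius at a given z
#'
#' Evaluates the piecewise linear hard-wall profile R(z).  Outside the
#' tabulated range the profile is extended with its end values.
#'
#' @param system A [pore_system()].
#' @param z Axial positions, nm (vectorized).
#' @return Wall radii in nm; `Inf` where there is no membrane.
#' @export
wall_radius <- function(system, z) {
  if (is.null(system$membrane)) return(rep(Inf, length(z)))
  wp <- system$wall_profile
  stats::approx(wp$z, wp$R, xout = z, rule = 2)$y
}

#' Accessible outer radius for ion centers at a given z
#'
#' The largest center radius available to a point ion: the wall profile
#' inside the membrane span, the cell radius outside it.
#'
#' @inheritParams wall_radius
#' @return Radii in nm.
#' @export
accessible_radius <- function(system, z) {
  r <- rep(system$cell_radius, length(z))
  if (!is.null(system$membrane)) {
    inside <- z >= system$membrane[1] & z <= system$membrane[2]
    r[inside] <- wall_radius(system, z[inside])
  }
  r
}

#' Hard-wall accessibility of an ion center
#'
#' Checks whether a hard sphere of radius `radius` centered at the given
#' position overlaps any hard wall: the outer cylinder, the membrane slab
#' (including its flat faces and the pore-mouth corner ring), the pore wall
#' R(z), and, for structural ions, the confinement region.  The cell end
#' planes at |z| = `cell_half_length` are the bath boundaries; ion centers
#' may reach them.
#'
#' @param system A [pore_system()].
#' @param radius Ion hard-sphere radius, nm.
#' @param x,y,z Position coordinates, nm (vectorized over positions).
#' @param confinement Optional `c(z1, z2, r1, r2)` confinement box for a
#'   structural ion (bounds apply to the ion center).
#' @return Logical vector: `TRUE` where the position is accessible.
#' @export
is_accessible <- function(system, radius, x, y, z, confinement = NULL) {
  r <- sqrt(x^2 + y^2)
  ok <- abs(z) <= system$cell_half_length & r <= system$cell_radius - radius
  if (!is.null(system$membrane)) {
    zmL <- system$membrane[1]; zmR <- system$membrane[2]
    inside <- z >= zmL & z <= zmR
    # inside the membrane span: must be in the pore, clear of the side wall
    ok[inside] <- ok[inside] &
      (r[inside] <= wall_radius(system, z[inside]) - radius)
    # near a membrane face: clear of the flat face and the corner ring
    for (face in c(zmL, zmR)) {
      near <- !inside & abs(z - face) < radius
      if (any(near)) {
        Rf <- wall_radius(system, face)
        dz <- abs(z[near] - face)
        rn <- r[near]
        face_ok <- ifelse(rn >= Rf, FALSE, (Rf - rn)^2 + dz^2 >= radius^2)
        ok[near] <- ok[near] & face_ok
      }
    }
  }
  if (!is.null(confinement)) {
    ok <- ok & z >= confinement[1] & z <= confinement[2] &
      r >= confinement[3] & r <= confinement[4]
  }
  ok
}
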