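#' Describe a two-region surface-charge pattern
#'
#' A cylindrical pore of radius `pore_radius` and length `pore_length` whose
#' wall carries areal charge density `sigma_left` on the left fraction
#' `x_left` of its length and `sigma_right` on the rest.  `sigma_ref` is the
#' reference density used to express the pattern as a dimensionless net
#' charge (see [net_charge_Q()]).  `grid_dz` sets the axial pitch of the
#' point charges that discretize the surface charge.
#'
#' @param sigma_left,sigma_right Surface charge densities, e/nm^2.
#' @param sigma_ref Reference density, e/nm^2 (> 0).
#' @param x_left Fraction of the pore length carrying `sigma_left`, in
#'   \[0, 1\].
#' @param pore_radius Pore radius, nm.
#' @param pore_length Pore length H, nm.
#' @param grid_dz Axial grid pitch for discretized charges, nm.
#' @return An object of class `charge_pattern`.
#' @examples
#' s0 <- 0.4835
#' charge_pattern(-s0, s0, s0, x_left = 0.5)   # bipolar 'np' pore
#' @export
charge_pattern <- function(sigma_left, sigma_right, sigma_ref,
                           x_left = 0.5, pore_radius = 0.97,
                           pore_length = 6.4, grid_dz = 0.2) {
  if (!is.numeric(sigma_ref) || sigma_ref == 0) {
    stop("`sigma_ref` must be nonzero")
  }
  stopifnot(sigma_ref > 0, x_left >= 0, x_left <= 1,
            pore_radius > 0, pore_length > 0, grid_dz > 0)
  structure(
    list(sigma_left = sigma_left, sigma_right = sigma_right,
         sigma_ref = sigma_ref, x_left = x_left, pore_radius = pore_radius,
         pore_length = pore_length, grid_dz = grid_dz),
    class = "charge_pattern"
  )
}

#' Dimensionless net charge Q of a two-region pattern
#'
#' Q = xL * sigmaL/sigma0 + (1 - xL) * sigmaR/sigma0.  Q runs from -1 (fully
#' negative pore, 'nn') through 0 (bipolar 'np' or neutral '00') to +1
#' (fully positive, 'pp'); the asymmetric unipolar 'n0' and '0p' pores at
#' xL = 1/2 have Q = -1/2 and +1/2.
#'
#' @param pattern A [charge_pattern()].
#' @return The dimensionless net charge.
#' @export
net_charge_Q <- function(pattern) {
  stopifnot(inherits(pattern, "charge_pattern"))
  with(pattern, x_left * sigma_left / sigma_ref +
         (1 - x_left) * sigma_right / sigma_ref)
}

# Surface grid shared by the wall-charge builders: axial rows of point sites
# on the cylinder r = Rpore, z in [-H/2, H/2].  `n_rows` rows at pitch
# H/n_rows, each with `n_phi` sites staggered by half a pitch between rows.
.surface_grid <- function(pore_radius, pore_length, n_rows, n_phi) {
  dz <- pore_length / n_rows
  zc <- -pore_length / 2 + (seq_len(n_rows) - 0.5) * dz
  grid <- expand.grid(row = seq_len(n_rows), k = seq_len(n_phi))
  phi <- 2 * pi * (grid$k - 1 + 0.5 * (grid$row %% 2)) / n_phi
  data.frame(x = pore_radius * cos(phi), y = pore_radius * sin(phi),
             z = zc[grid$row], row = grid$row)
}

#' Build a pore with two uniformly charged wall regions
#'
#' Discretizes the continuous surface charge of a [charge_pattern()] into
#' point charges on the pore wall.  Rows of sites are laid down at axial
#' pitch close to `grid_dz`; each site carries sigma times its share of the
#' wall area, so each fully interior row reproduces its region's surface
#' charge density exactly.  A row straddling the region boundary is split
#' site-by-site in proportion to the overlap, keeping the total placed
#' charge within one site charge of the analytic value
#' sigmaL*2*pi*R*H*xL + sigmaR*2*pi*R*H*(1-xL).
#'
#' @param pattern A [charge_pattern()].
#' @param cell_radius,cell_half_length Simulation-cell dimensions, nm;
#'   defaults leave about 2 nm of bath beyond the pore in each direction.
#' @param applied_voltage Voltage in mV (left minus right).
#' @return A [pore_system()] whose membrane spans `[-H/2, H/2]`.
#' @export
build_region_charge_pore <- function(pattern,
                                     cell_radius = pattern$pore_radius + 2,
                                     cell_half_length =
                                       pattern$pore_length / 2 + 2,
                                     applied_voltage = 0) {
  stopifnot(inherits(pattern, "charge_pattern"))
  H <- pattern$pore_length
  R <- pattern$pore_radius
  xL <- pattern$x_left
  if (xL > 0 && xL < 1 && pattern$grid_dz > xL * H) {
    warning("grid_dz exceeds the left-region length; the region boundary ",
            "is resolved by splitting the straddling row of sites")
  }
  n_rows <- max(1L, round(H / pattern$grid_dz))
  dz <- H / n_rows
  n_phi <- max(1L, round(2 * pi * R / dz))
  sites <- .surface_grid(R, H, n_rows, n_phi)
  site_area <- dz * 2 * pi * R / n_phi
  z_boundary <- -H / 2 + xL * H
  q <- numeric(nrow(sites))
  for (i in seq_len(n_rows)) {
    idx <- which(sites$row == i)
    z0 <- -H / 2 + (i - 1) * dz
    z1 <- z0 + dz
    if (z1 <= z_boundary) {
      q[idx] <- pattern$sigma_left * site_area
    } else if (z0 >= z_boundary) {
      q[idx] <- pattern$sigma_right * site_area
    } else {
      # straddling row: assign a matching fraction of its sites to the left
      f <- (z_boundary - z0) / dz
      nL <- round(f * length(idx))
      qrow <- rep(pattern$sigma_right * site_area, length(idx))
      if (nL > 0) qrow[seq_len(nL)] <- pattern$sigma_left * site_area
      q[idx] <- qrow
    }
  }
  fc <- data.frame(x = sites$x, y = sites$y, z = sites$z, q = q)
  fc <- fc[fc$q != 0, , drop = FALSE]
  pore_system(cell_radius, cell_half_length, membrane = c(-H / 2, H / 2),
              wall_profile = R,
              fixed_charges = if (nrow(fc)) fc else NULL,
              applied_voltage = applied_voltage)
}

#' Build a pore with localized wall charges on a square grid
#'
#' Places point charges of fixed strength sigma*dz^2 on a square surface
#' grid of pitch `grid_dz`: rows at axial pitch `grid_dz` and, within each
#' row, the integer number of sites whose arc pitch is nearest to `grid_dz`.
#' With `grid_dz` = 1 nm and sigma = -1 e/nm^2 every site carries exactly
#' -1 e, the localized-charge limit representing discrete chemical groups
#' (e.g. carboxylates) on the pore wall; small `grid_dz` approaches the
#' smeared surface charge.  The axial charge density per unit length is
#' exact; the total charge matches sigma*2*pi*R*H within one ring's
#' azimuthal rounding.
#'
#' @param pattern A [charge_pattern()] with equal region densities
#'   (`sigma_left == sigma_right`).
#' @inheritParams build_region_charge_pore
#' @return A [pore_system()].
#' @export
build_localized_charge_pore <- function(pattern,
                                        cell_radius = pattern$pore_radius + 2,
                                        cell_half_length =
                                          pattern$pore_length / 2 + 2,
                                        applied_voltage = 0) {
  stopifnot(inherits(pattern, "charge_pattern"))
  if (pattern$sigma_left != pattern$sigma_right) {
    stop("localized-charge builder needs a uniform pattern ",
         "(sigma_left == sigma_right)")
  }
  H <- pattern$pore_length
  R <- pattern$pore_radius
  dz <- pattern$grid_dz
  if (dz > H) stop("grid_dz exceeds the pore length")
  sigma <- pattern$sigma_left
  n_rows <- max(1L, round(H / dz))
  n_phi <- max(1L, round(2 * pi * R / dz))
  sites <- .surface_grid(R, H, n_rows, n_phi)
  fc <- data.frame(x = sites$x, y = sites$y, z = sites$z,
                   q = rep(sigma * dz^2, nrow(sites)))
  fc <- fc[fc$q != 0, , drop = FALSE]
  pore_system(cell_radius, cell_half_length, membrane = c(-H / 2, H / 2),
              wall_profile = R,
              fixed_charges = if (nrow(fc)) fc else NULL,
              applied_voltage = applied_voltage)
}

#' Default geometry of the reduced calcium-release-channel model
#'
#' Approximate dimensions for [build_ryr_model()]: the hard-wall profile
#' R(z), the four axial confinement regions of the half-charged oxygen
#' groups, and the luminal ring of fixed charges.  The numbers are an
#' approximate rendering of the published model geometry (which is available
#' only graphically) and are meant to be overridden where better dimensions
#' are known; the selectivity-filter radius is 0.35 nm.
#'
#' @return A list understood by [build_ryr_model()].
#' @export
ryr_default_config <- function() {
  list(
    # piecewise linear hard wall: cytosolic vestibule, selectivity filter,
    # luminal vestibule (z in nm, cytosolic side at z < 0). Approximate.
    wall_profile = data.frame(
      z = c(-3.0, -1.2, -1.0, 0.9, 1.1, 3.0),
      R = c(1.2,  0.6,  0.35, 0.35, 0.8, 1.2)
    ),
    membrane = c(-3.0, 3.0),
    cell_radius = 4.0,
    cell_half_length = 6.0,
    # axial confinement intervals of the 8 O1/2- ions per group; approximate
    confinements = list(
      D4945 = c(-2.8, -2.0),
      D4938 = c(-2.0, -1.1),
      D4899 = c(-1.0, 0.0),
      E4900 = c(0.0, 0.9)
    ),
    oxygen_charge = -0.5,
    oxygen_radius = 0.14,
    oxygen_count = 8L,
    # luminal ring of point charges (one carboxylate per subunit)
    ring_z = 2.5,
    ring_n = 8L,
    ring_charge = -0.5,
    dielectric = 78.5
  )
}

#' Build the reduced 3D model of the calcium release channel
#'
#' Constructs the pore system of the reduced ryanodine-receptor model: a
#' rotationally symmetric hard-wall pore whose charged protein groups are
#' represented by four groups of eight confined half-charged oxygen ions
#' (O1/2-, radius 0.14 nm) for the D4945, D4938, D4899 and E4900 residues,
#' plus a ring of eight fixed point charges at the luminal entrance for
#' E4902.  The default geometry ([ryr_default_config()]) is approximate.
#'
#' @param config A list as returned by [ryr_default_config()]; individual
#'   entries may be overridden.
#' @param applied_voltage Voltage in mV.
#' @return A [pore_system()] with four structural-ion groups and the fixed
#'   ring charges.
#' @export
build_ryr_model <- function(config = ryr_default_config(),
                            applied_voltage = 0) {
  cfg <- utils::modifyList(ryr_default_config(), config)
  wallR <- stats::approxfun(cfg$wall_profile$z, cfg$wall_profile$R, rule = 2)
  structural <- lapply(cfg$confinements, function(zr) {
    rmax <- min(wallR(seq(zr[1], zr[2], length.out = 21))) - cfg$oxygen_radius
    if (rmax <= 0) stop("confinement region lies outside the pore")
    structural_ion_spec(cfg$oxygen_charge, cfg$oxygen_radius,
                        cfg$oxygen_count, z_range = zr,
                        r_range = c(0, rmax))
  })
  phi <- 2 * pi * (seq_len(cfg$ring_n) - 1) / cfg$ring_n
  ring_r <- wallR(cfg$ring_z)
  ring <- data.frame(x = ring_r * cos(phi), y = ring_r * sin(phi),
                     z = cfg$ring_z, q = cfg$ring_charge)
  sys <- pore_system(cfg$cell_radius, cfg$cell_half_length,
                     membrane = cfg$membrane,
                     wall_profile = cfg$wall_profile,
                     fixed_charges = ring, structural_ions = structural,
                     applied_voltage = applied_voltage)
  attr(sys, "dielectric") <- cfg$dielectric
  sys
}
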