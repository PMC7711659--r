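test_that("net charge Q reproduces the canonical pattern values", {
  s0 <- 0.4835
  pat <- function(sL, sR, xL) charge_pattern(sL, sR, s0, x_left = xL)
  expect_equal(net_charge_Q(pat(-s0, -s0, 0.5)), -1)   # 'nn'
  expect_equal(net_charge_Q(pat(s0, s0, 0.25)), 1)     # 'pp', any xL
  expect_equal(net_charge_Q(pat(-s0, s0, 0.5)), 0)     # 'np'
  expect_equal(net_charge_Q(pat(-s0, 0, 0.5)), -0.5)   # 'n0'
  expect_equal(net_charge_Q(pat(0, s0, 0.5)), 0.5)     # '0p'
  expect_equal(net_charge_Q(pat(-s0, s0, 0.3)), 0.4)
})

test_that("Q is antisymmetric under a global sign flip of the pattern", {
  set.seed(4)
  for (i in 1:20) {
    sL <- runif(1, -1, 1); sR <- runif(1, -1, 1); xL <- runif(1)
    q1 <- net_charge_Q(charge_pattern(sL, sR, 1, x_left = xL))
    q2 <- net_charge_Q(charge_pattern(-sL, -sR, 1, x_left = xL))
    expect_equal(q2, -q1)
    expect_true(abs(q1) <= 1 + 1e-12)
  }
})

test_that("invalid charge patterns are rejected", {
  expect_error(charge_pattern(-1, 1, 0), "sigma_ref")
  expect_error(charge_pattern(-1, 1, 1, x_left = 1.2))
  expect_error(charge_pattern(-1, 1, 1, grid_dz = 0))
})

test_that("region builder places the analytic total charge", {
  s0 <- 0.4835
  for (xL in c(0, 0.3, 0.5, 1)) {
    pat <- charge_pattern(-s0, s0, s0, x_left = xL, pore_radius = 0.97,
                          pore_length = 6.4, grid_dz = 0.2)
    sys <- build_region_charge_pore(pat)
    total <- sum(sys$fixed_charges$q)
    analytic <- 2 * pi * 0.97 * 6.4 * (xL * -s0 + (1 - xL) * s0)
    site <- abs(sys$fixed_charges$q[1])
    expect_lt(abs(total - analytic), site + 1e-9)
    # summed charges vs the analytic surface integral, per site count
    expect_lt(abs(total - analytic) / (2 * pi * 0.97 * 6.4 * s0),
              1 / nrow(sys$fixed_charges) + 1e-9)
  }
})

test_that("region builder handles neutral patterns and coarse grids", {
  pat0 <- charge_pattern(0, 0, 1, x_left = 0.5)
  expect_null(build_region_charge_pore(pat0)$fixed_charges)
  pat_coarse <- charge_pattern(-1, 1, 1, x_left = 0.05, pore_length = 6.4,
                               grid_dz = 1)
  expect_warning(build_region_charge_pore(pat_coarse), "grid_dz")
})

test_that("region-builder sites sit on the pore wall surface", {
  pat <- charge_pattern(-0.4835, 0.4835, 0.4835, x_left = 0.4)
  sys <- build_region_charge_pore(pat)
  fc <- sys$fixed_charges
  expect_true(all(abs(sqrt(fc$x^2 + fc$y^2) - pat$pore_radius) < 1e-12))
  expect_true(all(abs(fc$z) <= pat$pore_length / 2))
})

test_that("localized builder produces sigma*dz^2 point charges", {
  pat1 <- charge_pattern(-1, -1, 1, pore_radius = 1, pore_length = 6,
                         grid_dz = 1)
  sys1 <- build_localized_charge_pore(pat1)
  expect_true(all(abs(sys1$fixed_charges$q - (-1)) < 1e-12))
  pat2 <- charge_pattern(-1, -1, 1, pore_radius = 1, pore_length = 6,
                         grid_dz = 0.2)
  sys2 <- build_localized_charge_pore(pat2)
  expect_true(all(abs(sys2$fixed_charges$q - (-0.04)) < 1e-12))
  # total charge equals the surface integral within one ring's rounding
  for (dz in c(0.2, 0.5, 1)) {
    pat <- charge_pattern(-1, -1, 1, pore_radius = 1, pore_length = 6,
                          grid_dz = dz)
    sys <- build_localized_charge_pore(pat)
    total <- sum(sys$fixed_charges$q)
    analytic <- -1 * 2 * pi * 1 * 6
    ring <- abs(2 * pi * 1 * dz)  # one ring's worth of charge
    expect_lt(abs(total - analytic), ring + 1e-9)
  }
  expect_error(build_localized_charge_pore(
    charge_pattern(-1, -1, 1, pore_length = 2, grid_dz = 3)), "grid_dz")
  expect_error(build_localized_charge_pore(
    charge_pattern(-1, 0, 1)), "uniform")
})

test_that("channel builder assembles the reduced-model structure", {
  sys <- build_ryr_model()
  specs <- sys$structural_ions
  expect_length(specs, 4L)
  expect_equal(sum(vapply(specs, `[[`, 0L, "count")), 32L)
  expect_true(all(vapply(specs, `[[`, 0, "radius") == 0.14))
  expect_true(all(vapply(specs, `[[`, 0, "charge") == -0.5))
  # luminal ring: 8 point charges totalling -4 e
  expect_equal(nrow(sys$fixed_charges), 8L)
  expect_equal(sum(sys$fixed_charges$q), -4)
  expect_equal(attr(sys, "dielectric"), 78.5)
  # confinement regions lie inside the pore
  for (s in specs) {
    zc <- mean(s$z_range)
    expect_lte(s$r_range[2], wall_radius(sys, zc))
  }
  # initial placement respects confinement and hard walls
  set.seed(2)
  st <- nplemc:::.engine_structural(sys)
  expect_equal(nrow(st$positions), 32L)
  for (i in seq_len(32)) {
    expect_true(is_accessible(sys, st$radius[i], st$positions[i, 1],
                              st$positions[i, 2], st$positions[i, 3],
                              st$confinement[i, ]))
  }
  expect_error(build_ryr_model(list(confinements = list(bad = c(5, 6)))))
})

test_that("pore system validates geometry and charge placement", {
  expect_error(pore_system(2, 3, membrane = c(-1, 1)), "wall_profile")
  expect_error(pore_system(2, 3, membrane = c(-4, 1), wall_profile = 1))
  expect_error(pore_system(2, 3, membrane = c(-1, 1), wall_profile = 2.5),
               "below the cell radius")
  # a fixed charge buried inside the pore lumen is rejected
  expect_error(
    pore_system(3, 4, membrane = c(-1, 1), wall_profile = 1,
                fixed_charges = data.frame(x = 0.2, y = 0, z = 0, q = -1)),
    "wall surface")
})
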