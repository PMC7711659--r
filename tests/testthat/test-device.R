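test_that("selectivity and rectification arithmetic and edge flags", {
  expect_equal(cation_selectivity(2, 2), 0.5)
  expect_equal(cation_selectivity(5, 0), 1)
  expect_equal(cation_selectivity(1, 3), 0.25)
  expect_equal(cation_selectivity(-1, 3), 0.25)  # magnitudes only
  und <- cation_selectivity(0, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_equal(rectification(3, 3), 1)
  expect_equal(rectification(2, 0.5), 4)
  expect_equal(rectification(-2, 0.5), 4)
  inf <- rectification(1, 0)
  expect_identical(as.numeric(inf), Inf)
  expect_true(attr(inf, "infinite"))
})

test_that("axial profile is the volume-weighted radial average", {
  # uniform field: the average is the value itself
  sys <- pore_system(1.0001, 2, membrane = c(-2 + 1e-9, 2 - 1e-9),
                     wall_profile = 1)
  grid <- build_subvolume_grid(sys, 4, 200)
  ncell <- grid$nz * grid$nr
  conc_u <- matrix(0.8, 1, ncell)
  pu <- axial_profile(conc_u, grid, species = "u")
  expect_equal(pu$u, rep(0.8, grid$nz))
  # synthetic field c(z, r) = r^2 on a unit-radius tube: mean = 1/2
  r_of <- as.vector(grid$r_center)  # cell-ordered centroid radii
  conc_r2 <- matrix(r_of^2, 1, ncell)
  pr <- axial_profile(conc_r2, grid, species = "r2")
  expect_equal(pr$r2, rep(0.5, grid$nz), tolerance = 1e-4)
})

test_that("slope resistance reproduces closed forms and the series law", {
  # uniform tube: R = kT L / (z^2 e^2 D A c)
  L <- 4; Rad <- 1
  sys <- pore_system(Rad + 1, L / 2,
                     membrane = c(-L / 2 + 1e-9, L / 2 - 1e-9),
                     wall_profile = Rad)
  grid <- build_subvolume_grid(sys, 8, 2)
  d_si <- 1.5e-9
  el <- electrolyte(list(ion_species("A+", 1, 0.1, d_si, d_si),
                         ion_species("B-", -1, 0.1, d_si, d_si)),
                    c("A+" = 0.5, "B-" = 0.5))
  prof <- data.frame(z = grid$z_center, "A+" = 0.5, "B-" = 0.5,
                     check.names = FALSE)
  sr <- slope_resistance(prof, el, grid, sys, domain = "pore")
  # independent evaluation of the closed form in SI units
  kT <- 1.380649e-23 * 298.15
  e <- 1.602176634e-19
  A_m2 <- pi * (Rad * 1e-9)^2
  c_m3 <- 0.5 * 6.02214076e23 * 1e3
  R_ohm <- kT * (L * 1e-9) / (e^2 * d_si * A_m2 * c_m3)
  expect_equal(sr$resistance_Gohm, rep(R_ohm / 1e9, 2), tolerance = 1e-6)
  # halving the concentration doubles the resistance
  prof2 <- prof; prof2$`A+` <- prof2$`A+` / 2; prof2$`B-` <- prof2$`B-` / 2
  sr2 <- slope_resistance(prof2, el, grid, sys, domain = "pore")
  expect_equal(sr2$resistance_Gohm, 2 * sr$resistance_Gohm,
               tolerance = 1e-9)
  # two-segment profile: series law R = R1 + R2 against a piecewise
  # integration oracle
  cseg <- ifelse(grid$z_center < 0, 0.2, 0.8)
  prof3 <- data.frame(z = grid$z_center, "A+" = cseg, "B-" = cseg,
                      check.names = FALSE)
  sr3 <- slope_resistance(prof3, el, grid, sys, domain = "pore")
  dz <- diff(grid$z_edges)
  integ <- sum(dz / (d_si * 1e9 * pi * Rad^2 * cseg *
                       molar_to_density()))
  g_pS <- nplemc:::.e_pA_ns * 1000 / (thermal_voltage_mV() * integ)
  expect_equal(sr3$resistance_Gohm, rep(1000 / g_pS, 2),
               tolerance = 1e-9)
})

test_that("an artificial depletion slab raises the resistance by its 1/c share", {
  L <- 4; Rad <- 1
  sys <- pore_system(Rad + 1, L / 2,
                     membrane = c(-L / 2 + 1e-9, L / 2 - 1e-9),
                     wall_profile = Rad)
  grid <- build_subvolume_grid(sys, 10, 2)
  d_si <- 1e-9
  el <- electrolyte(list(ion_species("A+", 1, 0.1, d_si, d_si),
                         ion_species("B-", -1, 0.1, d_si, d_si)),
                    c("A+" = 1, "B-" = 1))
  cvec <- rep(1, grid$nz)
  prof <- data.frame(z = grid$z_center, "A+" = cvec, "B-" = cvec,
                     check.names = FALSE)
  base <- slope_resistance(prof, el, grid, sys, domain = "pore")
  cdep <- cvec; cdep[5] <- 0.1
  profd <- data.frame(z = grid$z_center, "A+" = cdep, "B-" = cdep,
                      check.names = FALSE)
  dep <- slope_resistance(profd, el, grid, sys, domain = "pore")
  # analytic expectation: the slab's contribution scales by 1/0.1
  dz <- diff(grid$z_edges)
  slab_share <- dz[5] / (d_si * 1e9 * pi * Rad^2 * molar_to_density())
  delta_analytic <- slab_share * (1 / 0.1 - 1)  # in ns
  g_to_Gohm <- 1000 * thermal_voltage_mV() / (nplemc:::.e_pA_ns * 1000)
  expect_equal(dep$resistance_Gohm[1] - base$resistance_Gohm[1],
               delta_analytic * g_to_Gohm, tolerance = 0.05)
})

test_that("device summary wires the pieces together and checks pairing", {
  res <- g00_result()
  eq <- eq00_result()
  fx <- make_fixture("tiny-00", seed = 1)
  dev <- summarize_device(res, pattern = fx$pattern,
                          electrolyte = fx$electrolyte)
  expect_equal(dev$Q, 0)
  expect_equal(dev$chord_conductance_pS,
               1000 * res$total_current_pA / res$voltage_mV)
  expect_true(dev$selectivity >= 0 && dev$selectivity <= 1)
  expect_gt(dev$xi, 0)
  # an equilibrium-only summary flags the undefined selectivity
  dev_eq <- summarize_device(eq)
  expect_true(is.na(dev_eq$selectivity) || dev_eq$selectivity >= 0)
  # mismatched systems are rejected
  fx_loc <- make_fixture("tiny-localized", seed = 1)
  expect_error(summarize_device(res, structure(
    list(mu = matrix(0, 3, 4), species = c("a", "b", "c")),
    class = "npl_result")), "different systems")
})
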