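# Sampler correctness on exactly solvable toy systems, plus the structural
# invariants of the engine.

# a point-like species so wall-exclusion shells are negligible
tiny_ion <- function(name = "T+", z = 1) ion_species(name, z, 1e-4, 1e-9)

test_that("ideal-gas occupancy matches the grand-canonical closed form", {
  sys <- pore_system(2, 2)
  el <- electrolyte(list(tiny_ion("T+"), tiny_ion("T-", -1)),
                    c("T+" = 0.4, "T-" = 0.4))
  grid <- build_subvolume_grid(sys, 2, 2)
  mu <- matrix(log(0.4), 2, 4)
  fs <- run_lemc(sys, el, grid, mu,
                 lemc_run_spec(6000, 500, interactions = "none"),
                 seed = 11)
  # <c> = c0 e^mu = 0.4 M in every cell, within 3 block standard errors
  for (s in 1:2) {
    for (cl in 1:4) {
      expect_lt(abs(fs$conc[s, cl] - 0.4), 3 * fs$conc_se[s, cl] + 0.02)
    }
  }
})

test_that("two cells at different mu give the Boltzmann density ratio", {
  sys <- pore_system(2, 2)
  el <- electrolyte(list(tiny_ion("T+"), tiny_ion("T-", -1)),
                    c("T+" = 0.5, "T-" = 0.5))
  grid <- build_subvolume_grid(sys, 2, 1)
  dmu <- 0.7
  mu <- rbind(c(log(0.3), log(0.3) + dmu),
              c(log(0.3), log(0.3) + dmu))
  fs <- run_lemc(sys, el, grid, mu,
                 lemc_run_spec(8000, 500, interactions = "none"),
                 seed = 12)
  for (s in 1:2) {
    ratio <- fs$conc[s, 2] / fs$conc[s, 1]
    se <- ratio * sqrt((fs$conc_se[s, 1] / fs$conc[s, 1])^2 +
                         (fs$conc_se[s, 2] / fs$conc[s, 2])^2)
    expect_lt(abs(ratio - exp(dmu)), 3 * se + 0.08)
  }
})

test_that("hard-sphere occupancy matches the direct-summation oracle", {
  # a cell so small that only a few spheres fit; the oracle evaluates the
  # truncated grand-canonical sum with brute-force configuration integrals
  sys <- pore_system(0.5, 0.5)
  radius <- 0.15
  # a second species is needed for a neutral bath definition; its chemical
  # potential is set so low that it never enters the cell
  el <- electrolyte(list(ion_species("HS", 1, radius, 1e-9),
                         ion_species("X", -1, radius, 1e-9)),
                    c("HS" = 1, "X" = 1))
  grid <- build_subvolume_grid(sys, 1, 1)
  v_geom <- grid_total_volume(grid)
  mu <- log(4 / (v_geom * molar_to_density()))  # activity a = 4
  orc <- oracle_hs_mean_n(sys, radius, activity = 4, n_max = 8,
                          samples = 2e5, seed = 3)
  fs <- run_lemc(sys, el, grid, matrix(c(mu, -30), 2, 1),
                 lemc_run_spec(20000, 2000, interactions = "hard",
                               moves_per_sweep = 32, max_step = 0.15),
                 seed = 13)
  n_engine <- fs$conc[1, 1] * v_geom * molar_to_density()
  n_se <- fs$conc_se[1, 1] * v_geom * molar_to_density()
  expect_lt(abs(n_engine - orc$mean_n), 3 * sqrt(n_se^2 + orc$se^2) + 0.03)
})

test_that("sampling is bit-reproducible for a fixed seed", {
  fx <- make_fixture("bulk-box", seed = 2)
  mu <- matrix(log(0.5), 2, fx$grid$nz * fx$grid$nr)
  spec <- lemc_run_spec(300, 50)
  a <- run_lemc(fx$system, fx$electrolyte, fx$grid, mu, spec, seed = 99)
  b <- run_lemc(fx$system, fx$electrolyte, fx$grid, mu, spec, seed = 99)
  expect_identical(a$conc, b$conc)
  expect_identical(a$accepts, b$accepts)
  c_ <- run_lemc(fx$system, fx$electrolyte, fx$grid, mu, spec, seed = 98)
  expect_false(identical(a$conc, c_$conc))
})

test_that("structural ions are conserved and stay confined", {
  sys <- build_ryr_model()
  el <- electrolyte(list(lookup_ion("Na+"), lookup_ion("Cl-")),
                    c("Na+" = 0.1, "Cl-" = 0.1), dielectric = 78.5)
  grid <- build_subvolume_grid(sys, 10, 2)
  mu <- matrix(log(0.1), 2, grid$nz * grid$nr)
  fs <- run_lemc(sys, el, grid, mu, lemc_run_spec(400, 100), seed = 5)
  expect_equal(fs$n_structural, 32L)
  pos <- fs$structural_positions
  specs <- sys$structural_ions
  i <- 0L
  for (s in specs) {
    for (k in seq_len(s$count)) {
      i <- i + 1L
      r <- sqrt(pos[i, 1]^2 + pos[i, 2]^2)
      expect_gte(pos[i, 3], s$z_range[1])
      expect_lte(pos[i, 3], s$z_range[2])
      expect_gte(r, s$r_range[1])
      expect_lte(r, s$r_range[2] + 1e-12)
    }
  }
})

test_that("run_lemc validates its inputs", {
  fx <- make_fixture("bulk-box", seed = 1)
  bad_mu <- matrix(0, 3, fx$grid$nz * fx$grid$nr)
  expect_error(run_lemc(fx$system, fx$electrolyte, fx$grid, bad_mu,
                        lemc_run_spec(100, 10)), "n_species x n_cells")
  nan_mu <- matrix(NaN, 2, fx$grid$nz * fx$grid$nr)
  expect_error(run_lemc(fx$system, fx$electrolyte, fx$grid, nan_mu,
                        lemc_run_spec(100, 10)), "finite")
  expect_error(lemc_run_spec(100, 200), "sweeps")
  expect_error(lemc_run_spec(100, 10, move_probs = c(0.5, 0.5, 0.5)))
})

test_that("bath regions remain electroneutral on average at equilibrium", {
  res <- eq00_result()
  grid <- res$grid
  fx_el_z <- res$valence
  iz_of <- rep(seq_len(grid$nz), grid$nr)
  bath <- which(abs(grid$z_center[iz_of]) > 1.6)  # outside the membrane
  vols <- nplemc:::.cell_volumes(grid)[bath]
  qb <- vapply(seq_len(dim(res$fieldset$block_conc)[3]), function(b) {
    cb <- res$fieldset$block_conc[, bath, b]
    sum((fx_el_z %*% cb) * vols) * molar_to_density()
  }, 0)
  se <- sd(qb) / sqrt(length(qb))
  # net bath charge in e, compared with the total ion content
  n_tot <- sum(res$fieldset$conc[, bath] %*% vols) * molar_to_density()
  expect_lt(abs(mean(qb)), 3 * se + 0.02 * n_tot)
})
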