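# Deterministic transport building blocks: flux evaluation, the continuity
# solve, and boundary-condition handling.

uniform_tube <- function(R = 1, L = 4, nz = 8, nr = 3) {
  # a cylinder whose membrane spans (almost) the whole cell: a uniform tube
  sys <- pore_system(R + 1, L / 2,
                     membrane = c(-L / 2 + 1e-9, L / 2 - 1e-9),
                     wall_profile = R)
  list(system = sys, grid = build_subvolume_grid(sys, nz, nr))
}

test_that("zero potential gradient gives zero flux and zero current", {
  tb <- uniform_tube()
  ncell <- tb$grid$nz * tb$grid$nr
  conc <- matrix(0.7, 1, ncell)
  mu <- matrix(1.3, 1, ncell)
  D <- matrix(1.5, 1, ncell)
  fl <- np_flux(conc, mu, D, tb$grid)
  expect_true(all(abs(unlist(fl$flows)) < 1e-14))
  expect_equal(total_current(fl, valence = 1)$total, 0)
})

test_that("uniform tube with a linear potential drop gives the closed-form flux", {
  R <- 1; L <- 4
  tb <- uniform_tube(R, L, nz = 8, nr = 3)
  grid <- tb$grid
  ncell <- grid$nz * grid$nr
  c0 <- 0.5; D0 <- 2.0; dmu_total <- 0.8
  conc <- matrix(c0, 1, ncell)
  D <- matrix(D0, 1, ncell)
  iz_of <- rep(seq_len(grid$nz), grid$nr)
  mu_z <- dmu_total * (grid$z_center - grid$z_center[1]) /
    (grid$z_center[grid$nz] - grid$z_center[1])
  mu <- matrix(mu_z[iz_of], 1, ncell)
  fl <- np_flux(conc, mu, D, grid)
  # j = -D c (dmu/dz), per unit area, in particles/nm^2/ns
  grad <- dmu_total / (grid$z_center[grid$nz] - grid$z_center[1])
  j_expect <- -D0 * c0 * molar_to_density() * grad
  ax <- fl$flux_density[[1]][seq_len(fl$network$n_axial)]
  expect_equal(max(abs(ax - j_expect)), 0, tolerance = 1e-12)
  # I = z e j A exactly
  cur <- total_current(fl, valence = 1, z = 0)
  expect_equal(cur$total, 1 * nplemc:::.e_pA_ns * j_expect * pi * R^2,
               tolerance = 1e-9)
  # divergence vanishes for the linear profile away from the bath slabs
  # (the boundary slabs exchange particles with the baths by construction)
  iz_all <- rep(seq_len(grid$nz), grid$nr)
  interior <- iz_all != 1 & iz_all != grid$nz
  expect_lt(max(abs(fl$divergence[1, interior])), 1e-12)
})

test_that("flux divergence matches the brute-force stencil oracle", {
  sys <- pore_system(2, 3, membrane = c(-1, 1), wall_profile = 0.9)
  grid <- build_subvolume_grid(sys, 6, 4)
  ncell <- grid$nz * grid$nr
  set.seed(42)
  conc <- matrix(runif(ncell, 0.1, 2), 1, ncell)
  mu <- matrix(rnorm(ncell, 0, 0.5), 1, ncell)
  D <- matrix(runif(ncell, 0.5, 2), 1, ncell)
  fl <- np_flux(conc, mu, D, grid)
  div_oracle <- oracle_divergence(grid, conc[1, ], D[1, ], mu[1, ])
  expect_equal(as.vector(fl$divergence), div_oracle, tolerance = 1e-9)
})

test_that("the continuity solve matches a dense direct solve", {
  sys <- pore_system(2, 3, membrane = c(-1, 1), wall_profile = 0.9)
  grid <- build_subvolume_grid(sys, 5, 3)
  ncell <- grid$nz * grid$nr
  set.seed(17)
  conc <- matrix(runif(ncell, 0.05, 3), 1, ncell)
  D <- matrix(runif(ncell, 0.2, 2), 1, ncell)
  bmu <- matrix(c(0.9, -0.4), 1, 2)
  mu <- solve_mu_given_c(conc, D, grid, bmu)
  mu_oracle <- oracle_dense_mu_solve(grid, conc[1, ], D[1, ], 0.9, -0.4)
  expect_equal(as.vector(mu[1, ]), mu_oracle, tolerance = 1e-10)
  # the solved field is divergence-free in the interior
  fl <- np_flux(conc, mu, D, grid)
  iz_of <- rep(seq_len(grid$nz), grid$nr)
  interior <- iz_of != 1 & iz_of != grid$nz
  scale <- max(abs(unlist(fl$flows)))
  expect_lt(max(abs(fl$divergence[1, interior])), 1e-10 * scale)
})

test_that("solve limits: uniform coefficients give a linear profile,
           equal boundaries a constant", {
  tb <- uniform_tube(nz = 7, nr = 1)
  grid <- tb$grid
  ncell <- grid$nz
  conc <- matrix(1, 1, ncell)
  D <- matrix(1, 1, ncell)
  mu <- solve_mu_given_c(conc, D, grid, matrix(c(1, 0), 1, 2))
  # 1D Laplace: linear in the cell-center coordinate
  expect_equal(as.vector(mu[1, ]),
               1 - (grid$z_center - grid$z_center[1]) /
                 (grid$z_center[ncell] - grid$z_center[1]),
               tolerance = 1e-10)
  mu2 <- solve_mu_given_c(conc, D, grid, matrix(c(0.3, 0.3), 1, 2))
  expect_equal(as.vector(mu2[1, ]), rep(0.3, ncell), tolerance = 1e-12)
  expect_equal(max(abs(unlist(np_flux(conc, mu2, D, grid)$flows))), 0,
               tolerance = 1e-14)
})

test_that("boundary potentials carry the bath values plus the voltage split", {
  el <- model_salt(2, 1, 0.1)
  tab <- calibrate_chemical_potentials(el, interactions = "none")
  U <- 150
  bmu <- boundary_potentials(tab, tab, el$valence, U)
  vt <- thermal_voltage_mV()
  expect_equal(bmu[, "left"] - bmu[, "right"],
               el$valence * U / vt, ignore_attr = TRUE)
  expect_equal(unname((bmu[, "left"] + bmu[, "right"]) / 2),
               tab$mu_total)
  # and the solved field honors them exactly at the boundary cells
  tb <- uniform_tube(nz = 6, nr = 2)
  ncell <- tb$grid$nz * tb$grid$nr
  conc <- matrix(0.4, 2, ncell)
  D <- matrix(1, 2, ncell)
  mu <- solve_mu_given_c(conc, D, tb$grid, bmu)
  iz_of <- rep(seq_len(tb$grid$nz), tb$grid$nr)
  for (s in 1:2) {
    expect_true(all(mu[s, iz_of == 1] == bmu[s, "left"]))
    expect_true(all(mu[s, iz_of == tb$grid$nz] == bmu[s, "right"]))
  }
})

test_that("diffusion profile switches between bulk and pore values", {
  fx <- make_fixture("tiny-00", seed = 1)
  D <- diffusion_profile(fx$electrolyte, fx$grid, fx$system)
  expect_true(all(D > 0))
  iz_of <- rep(seq_len(fx$grid$nz), fx$grid$nr)
  pore_cells <- fx$grid$in_pore[iz_of]
  d_bulk <- fx$electrolyte$species[[1]]$d_bulk * 1e9
  d_pore <- fx$electrolyte$species[[1]]$d_pore * 1e9
  expect_true(all(D[1, pore_cells] == d_pore))
  expect_true(all(D[1, !pore_cells] == d_bulk))
})
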