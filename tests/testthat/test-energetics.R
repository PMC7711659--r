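sp_na <- lookup_ion("Na+")
sp_cl <- lookup_ion("Cl-")
sp_tab <- list("Na+" = sp_na, "Cl-" = sp_cl)

test_that("pair energy implements the hard-sphere plus Coulomb form", {
  lB <- bjerrum_length(78.45, 298.15)
  # frozen value computed from CODATA constants
  expect_equal(lB, 0.71441, tolerance = 1e-4)
  # overlap: infinite-energy sentinel
  contact <- sp_na$radius + sp_cl$radius
  expect_identical(pair_energy(sp_na, sp_cl, contact * 0.999), Inf)
  # two +1 ions at r = lB interact with exactly 1 kT
  expect_equal(pair_energy(sp_na, sp_na, lB), 1, tolerance = 1e-12)
  # 1/r scaling and symmetry
  for (r in c(0.5, 0.9, 2.7)) {
    expect_equal(pair_energy(sp_na, sp_cl, 2 * r),
                 pair_energy(sp_na, sp_cl, r) / 2)
    expect_equal(pair_energy(sp_na, sp_cl, r), pair_energy(sp_cl, sp_na, r))
  }
})

test_that("external energy enforces walls and sums fixed charges", {
  lB <- bjerrum_length(78.45, 298.15)
  sys <- pore_system(3, 4, membrane = c(-1, 1), wall_profile = 1,
                     fixed_charges = data.frame(x = 0, y = 0, z = 3.5,
                                                q = -1))
  # +1 ion at distance lB from a -1 e fixed charge: exactly -1 kT
  expect_equal(external_energy(sp_na, c(0, 0, 3.5 - lB), sys), -1,
               tolerance = 1e-9)
  # ion center closer to the pore wall than its radius: sentinel
  expect_identical(
    external_energy(sp_na, c(1 - 0.5 * sp_na$radius, 0, 0), sys), Inf)
  # membrane face exclusion just outside the slab
  expect_identical(
    external_energy(sp_cl, c(2, 0, 1 + 0.5 * sp_cl$radius), sys), Inf)
  # no fixed charges, open bath: zero
  sys0 <- pore_system(3, 4)
  expect_equal(external_energy(sp_na, c(1, 0, 2), sys0), 0)
})

test_that("incremental move energies match full recomputation", {
  sys <- pore_system(2.5, 3,
                     fixed_charges = data.frame(x = c(0, 1), y = c(0, -1),
                                                z = c(-2, 2),
                                                q = c(-1, 0.5)))
  cfg <- random_config(sys, sp_tab, 10, seed = 31)
  u0 <- total_energy(cfg, sys, sp_tab)
  expect_equal(u0, oracle_config_energy(cfg, sys, sp_tab))
  set.seed(32)
  for (k in 1:12) {
    type <- sample(c("insert", "delete", "displace"), 1)
    move <- switch(type,
      insert = list(type = "insert",
                    species = sample(names(sp_tab), 1),
                    position = c(runif(1, -1, 1), runif(1, -1, 1),
                                 runif(1, -2, 2))),
      delete = list(type = "delete", index = sample(nrow(cfg), 1)),
      displace = list(type = "displace", index = sample(nrow(cfg), 1),
                      position = c(runif(1, -1, 1), runif(1, -1, 1),
                                   runif(1, -2, 2))))
    dU <- delta_energy(cfg, move, sys, sp_tab)
    cfg2 <- switch(move$type,
      insert = rbind(cfg, data.frame(species = move$species,
                                     x = move$position[1],
                                     y = move$position[2],
                                     z = move$position[3])),
      delete = cfg[-move$index, ],
      displace = {
        tmp <- cfg
        tmp$x[move$index] <- move$position[1]
        tmp$y[move$index] <- move$position[2]
        tmp$z[move$index] <- move$position[3]
        tmp
      })
    u1 <- total_energy(cfg2, sys, sp_tab)
    if (is.finite(dU)) {
      expect_equal(dU, u1 - u0, tolerance = 1e-9)
    } else {
      expect_identical(u1, Inf)
    }
  }
  # insertion far from all charges in a huge open box changes nothing
  sys_big <- pore_system(50, 50)
  empty <- data.frame(species = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0))
  expect_equal(delta_energy(empty,
                            list(type = "insert", species = "Na+",
                                 position = c(0, 0, 0)),
                            sys_big, sp_tab), 0)
  # displacement into overlap gives the sentinel
  two <- data.frame(species = c("Na+", "Na+"), x = c(0, 1), y = 0, z = 0)
  expect_identical(
    delta_energy(two, list(type = "displace", index = 2,
                           position = c(0.05, 0, 0)), sys_big, sp_tab),
    Inf)
})

test_that("configuration energy is invariant under rotation about the pore axis", {
  sys <- pore_system(2.5, 3, membrane = c(-1, 1), wall_profile = 1)
  # ring charge placed on the wall keeps rotational symmetry of walls only;
  # use an axis-centered fixed charge so the external field is symmetric
  sys$fixed_charges <- data.frame(x = 0, y = 0, z = 2.5, q = -2)
  cfg <- random_config(sys, sp_tab, 8, seed = 77)
  u0 <- total_energy(cfg, sys, sp_tab)
  for (ang in c(0.3, 1.2, pi)) {
    rot <- cfg
    rot$x <- cos(ang) * cfg$x - sin(ang) * cfg$y
    rot$y <- sin(ang) * cfg$x + cos(ang) * cfg$y
    expect_equal(total_energy(rot, sys, sp_tab), u0, tolerance = 1e-9)
  }
})

test_that("the engine's energy kernel agrees with the R-level sums", {
  pat <- charge_pattern(-0.4835, 0.4835, 0.4835, pore_radius = 1,
                        pore_length = 2, grid_dz = 0.4)
  sys <- build_region_charge_pore(pat, cell_radius = 2.5,
                                  cell_half_length = 2.5)
  el <- electrolyte(list(sp_na, sp_cl), c("Na+" = 1, "Cl-" = 1))
  grid <- build_subvolume_grid(sys, 4, 2)
  cfg <- random_config(sys, sp_tab, 12, seed = 55)
  u_r <- total_energy(cfg, sys, sp_tab)
  u_cpp <- nplemc:::lemc_config_energy(
    nplemc:::.engine_geom(sys), nplemc:::.engine_species(el),
    nplemc:::.engine_fixed(sys), nplemc:::.engine_grid(grid),
    as.matrix(cfg[, c("x", "y", "z")]),
    match(cfg$species, el$names) - 1L, 0L)
  expect_equal(u_cpp, u_r, tolerance = 1e-9)
  # and the wall test agrees pointwise with the R implementation
  set.seed(9)
  pts <- cbind(runif(500, -2.5, 2.5), runif(500, -2.5, 2.5),
               runif(500, -2.5, 2.5))
  acc_cpp <- nplemc:::lemc_accessible(nplemc:::.engine_geom(sys),
                                      sp_cl$radius, pts)
  acc_r <- is_accessible(sys, sp_cl$radius, pts[, 1], pts[, 2], pts[, 3])
  expect_identical(acc_cpp, acc_r)
})
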