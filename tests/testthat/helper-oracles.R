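# Independent oracles and shared fixtures for the test suite.  Oracles are
# deliberately written as plain, slow R (double loops, dense matrices,
# brute-force sampling) so they share no code path with the implementation
# they check.

# ---- energy oracle: O(N^2) double loop over explicit pairs --------------

oracle_config_energy <- function(config, system, species_table,
                                 dielectric = 78.45, temperature = 298.15) {
  n <- nrow(config)
  lB <- bjerrum_length(dielectric, temperature)
  u <- 0
  for (i in seq_len(n)) {
    sp <- species_table[[config$species[i]]]
    if (!is_accessible(system, sp$radius, config$x[i], config$y[i],
                       config$z[i])) {
      return(Inf)
    }
    fc <- system$fixed_charges
    if (!is.null(fc)) {
      for (k in seq_len(nrow(fc))) {
        d <- sqrt((fc$x[k] - config$x[i])^2 + (fc$y[k] - config$y[i])^2 +
                    (fc$z[k] - config$z[i])^2)
        u <- u + sp$valence * fc$q[k] * lB / d
      }
    }
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        spj <- species_table[[config$species[j]]]
        d <- sqrt((config$x[i] - config$x[j])^2 +
                    (config$y[i] - config$y[j])^2 +
                    (config$z[i] - config$z[j])^2)
        if (d < sp$radius + spj$radius) return(Inf)
        u <- u + sp$valence * spj$valence * lB / d
      }
    }
  }
  u
}

# random non-overlapping configuration inside a system
random_config <- function(system, species_table, n, seed) {
  set.seed(seed)
  rows <- list()
  names_sp <- names(species_table)
  while (length(rows) < n) {
    nm <- sample(names_sp, 1)
    sp <- species_table[[nm]]
    x <- runif(1, -system$cell_radius, system$cell_radius)
    y <- runif(1, -system$cell_radius, system$cell_radius)
    z <- runif(1, -system$cell_half_length, system$cell_half_length)
    if (!is_accessible(system, sp$radius, x, y, z)) next
    ok <- TRUE
    for (r in rows) {
      d <- sqrt((r$x - x)^2 + (r$y - y)^2 + (r$z - z)^2)
      if (d < sp$radius + species_table[[r$species]]$radius) ok <- FALSE
    }
    if (ok) rows[[length(rows) + 1]] <- list(species = nm, x = x, y = y,
                                             z = z)
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# ---- grand-canonical oracle by truncated direct summation ---------------

# <N> of hard spheres in a cylindrical cell: Q_N estimated by brute-force
# uniform sampling of N-point configurations in the geometric cell, with
# wall accessibility and pairwise overlap checked explicitly.
oracle_hs_mean_n <- function(system, radius, activity, n_max = 8,
                             samples = 2e5, seed = 1) {
  set.seed(seed)
  R <- system$cell_radius
  L <- system$cell_half_length
  qn <- numeric(n_max + 1)
  qn[1] <- 1
  qn_se <- numeric(n_max + 1)
  for (N in seq_len(n_max)) {
    r <- sqrt(matrix(runif(samples * N, 0, R^2), samples, N))
    phi <- matrix(runif(samples * N, 0, 2 * pi), samples, N)
    x <- r * cos(phi); y <- r * sin(phi)
    z <- matrix(runif(samples * N, -L, L), samples, N)
    ok <- rep(TRUE, samples)
    for (i in seq_len(N)) {
      ok <- ok & is_accessible(system, radius, x[, i], y[, i], z[, i])
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          d2 <- (x[, i] - x[, j])^2 + (y[, i] - y[, j])^2 +
            (z[, i] - z[, j])^2
          ok <- ok & d2 >= (2 * radius)^2
        }
      }
    }
    p <- mean(ok)
    qn[N + 1] <- p
    qn_se[N + 1] <- sqrt(p * (1 - p) / samples)
  }
  wts <- activity^(0:n_max) * qn / factorial(0:n_max)
  mean_n <- sum((0:n_max) * wts) / sum(wts)
  # crude first-order error propagation from the Q_N estimates
  d_mean <- vapply(seq_len(n_max), function(N) {
    w <- activity^N / factorial(N)
    (N * w * sum(wts) - w * sum((0:n_max) * wts)) / sum(wts)^2
  }, 0)
  list(mean_n = mean_n,
       se = sqrt(sum((d_mean * qn_se[-1])^2)),
       qn = qn)
}

# ---- dense Nernst-Planck oracles ----------------------------------------

# face conductances recomputed with explicit loops; returns a dense matrix
# L with L[a, b] = g(a, b) for neighbors, plus the face list
oracle_face_conductances <- function(grid, conc, D, floor = 1e-8) {
  nz <- grid$nz; nr <- grid$nr
  ncell <- nz * nr
  idx <- function(iz, ir) (ir - 1) * nz + iz
  G <- matrix(0, ncell, ncell)
  ann <- matrix(0, nz, nr)
  for (iz in seq_len(nz)) {
    for (ir in seq_len(nr)) {
      ann[iz, ir] <- pi * (grid$r_edges2[iz, ir + 1] -
                             grid$r_edges2[iz, ir])
    }
  }
  dz <- diff(grid$z_edges)
  cfun <- function(a, b) max((conc[a] + conc[b]) / 2, floor) *
    molar_to_density()
  dfun <- function(a, b) (D[a] + D[b]) / 2
  for (iz in seq_len(nz - 1)) {
    for (ir in seq_len(nr)) {
      a <- idx(iz, ir); b <- idx(iz + 1, ir)
      area <- min(ann[iz, ir], ann[iz + 1, ir])
      dist <- grid$z_center[iz + 1] - grid$z_center[iz]
      G[a, b] <- G[b, a] <- dfun(a, b) * cfun(a, b) * area / dist
    }
  }
  for (iz in seq_len(nz)) {
    for (ir in seq_len(nr - 1)) {
      a <- idx(iz, ir); b <- idx(iz, ir + 1)
      area <- 2 * pi * sqrt(grid$r_edges2[iz, ir + 1]) * dz[iz]
      dist <- grid$r_center[iz, ir + 1] - grid$r_center[iz, ir]
      G[a, b] <- G[b, a] <- dfun(a, b) * cfun(a, b) * area / dist
    }
  }
  G
}

# dense direct solve of the continuity equation for one species
oracle_dense_mu_solve <- function(grid, conc, D, mu_left, mu_right,
                                  floor = 1e-8) {
  nz <- grid$nz; nr <- grid$nr
  ncell <- nz * nr
  G <- oracle_face_conductances(grid, conc, D, floor)
  iz_of <- rep(seq_len(nz), nr)
  mu <- numeric(ncell)
  mu[iz_of == 1] <- mu_left
  mu[iz_of == nz] <- mu_right
  interior <- which(iz_of != 1 & iz_of != nz)
  A <- matrix(0, length(interior), length(interior))
  b <- numeric(length(interior))
  for (ii in seq_along(interior)) {
    a <- interior[ii]
    nbrs <- which(G[a, ] > 0)
    A[ii, ii] <- sum(G[a, nbrs])
    for (nb in nbrs) {
      jj <- match(nb, interior)
      if (!is.na(jj)) A[ii, jj] <- A[ii, jj] - G[a, nb] else
        b[ii] <- b[ii] + G[a, nb] * mu[nb]
    }
  }
  mu[interior] <- solve(A, b)
  mu
}

# net outflow per cell computed independently from a mu field
oracle_divergence <- function(grid, conc, D, mu, floor = 1e-8) {
  G <- oracle_face_conductances(grid, conc, D, floor)
  ncell <- grid$nz * grid$nr
  div <- numeric(ncell)
  for (a in seq_len(ncell)) {
    for (b in seq_len(ncell)) {
      if (G[a, b] > 0) div[a] <- div[a] + G[a, b] * (mu[a] - mu[b])
    }
  }
  div
}

# ---- shared heavy computations (cached across test files) ---------------

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# calibration table for the 1 M NaCl nanopore electrolyte shared by all
# tiny-* nanopore fixtures
nacl_mu_table <- function() {
  cached("nacl_mu", {
    fx <- make_fixture("tiny-00", seed = 1)
    do.call(calibrate_chemical_potentials,
            c(list(fx$electrolyte), fx$calibration))
  })
}

# calibration table for the 0.1 M 3:1 localized-charge electrolyte
localized_mu_table <- function() {
  cached("loc_mu", {
    fx <- make_fixture("tiny-localized", seed = 1)
    do.call(calibrate_chemical_potentials,
            c(list(fx$electrolyte), fx$calibration))
  })
}

# equilibrium run of the neutral symmetric pore (profiles, zero currents)
eq00_result <- function() {
  cached("eq00", {
    fx <- make_fixture("tiny-00", seed = 1, voltage_mV = 0)
    run_fixture(fx, mu_table = nacl_mu_table())
  })
}

# small-voltage run of the neutral pore (slope conductance, conservation)
g00_result <- function() {
  cached("g00", {
    fx <- make_fixture("tiny-00", seed = 1, voltage_mV = 20)
    run_fixture(fx, mu_table = nacl_mu_table())
  })
}
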