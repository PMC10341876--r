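test_that("temperature schedules are geometric with exact endpoints", {
  ts <- temperature_schedule(300, 575, 16)
  expect_length(ts, 16)
  expect_equal(ts[1], 300)
  expect_equal(ts[16], 575)
  expect_equal(ts, 300 * (575 / 300)^((0:15) / 15), tolerance = 1e-12)
  ratios <- ts[-1] / ts[-16]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(temperature_schedule(300, 575, 2), c(300, 575))
  expect_equal(temperature_schedule(1, 4, 3), c(1, 2, 4), tolerance = 1e-12)
  expect_error(temperature_schedule(300, 575, 1), "at least 2")
  expect_error(temperature_schedule(-1, 4, 3), "T_min")
  expect_error(temperature_schedule(5, 4, 3), "T_min")
})

test_that("minima pool stays sorted, deduplicated and capped", {
  set.seed(31)
  pool <- minima_pool(capacity = 5, dim = 3L)
  base <- rnorm(9)
  for (k in 1:50) {
    e <- sample(c(1, 2, 3, 4, 5, 6, 7), 1) + runif(1, 0, 1e-8)
    x <- base + e  # distinct structures for distinct energies
    pool <- pool_insert(pool, e, x)
    expect_true(!is.unsorted(pool$energies))
    expect_lte(pool_size(pool), 5)
    if (pool_size(pool) > 1) {
      expect_true(all(diff(pool$energies) > 1e-7))
    }
  }
  # a structural duplicate at the same energy is not inserted twice
  pool2 <- minima_pool(10)
  pool2 <- pool_insert(pool2, 1.0, base)
  pool2 <- pool_insert(pool2, 1.0 + 1e-9, base + 1e-9)
  expect_equal(pool_size(pool2), 1)
  # same energy but genuinely different structure is kept
  pool2 <- pool_insert(pool2, 1.0, rev(base) + 2)
  expect_equal(pool_size(pool2), 2)
})

test_that("basin-hopping is reproducible and an identity run returns its start", {
  pot <- potential_lj(4)
  start <- c(0, 0, 0, 1.1, 0, 0, 0.5, 1, 0, 0.6, 0.4, 0.9)
  cfg <- bh_config(n_steps = 1, temperature = 1, max_step_size = 0,
                   seed = 7, keep_lowest = 10)
  q <- quench(pot, start, cfg$loose_rms_tol)
  res <- basin_hop(pot, q$x, cfg = cfg)
  expect_equal(pool_size(res$pool), 1)
  expect_equal(res$pool$energies[1], q$energy, tolerance = 1e-9)

  cfg2 <- bh_config(n_steps = 200, temperature = 1, max_step_size = 0.3,
                    seed = 42, keep_lowest = 20)
  r1 <- basin_hop(pot, start, cfg = cfg2)
  r2 <- basin_hop(pot, start, cfg = cfg2)
  expect_identical(r1$pool$energies, r2$pool$energies)
  expect_identical(r1$stats, r2$stats)
})

test_that("rigid-body dimer moves preserve internal monomer geometry", {
  set.seed(5)
  n <- 8
  x <- coords_flat(matrix(rnorm(3 * n, sd = 1.5), n, 3))
  monomers <- list(1:4, 5:8)
  sched <- move_schedule(rigid_translation_size = 0.5,
                         rigid_rotation_size = 1.2,
                         radial_expansion_factor = 1.3)
  for (k in 1:10) {
    y <- dimer_move(x, monomers, sched)
    mx <- coords_matrix(x); my <- coords_matrix(y)
    for (idx in monomers) {
      expect_lt(max(abs(dist(mx[idx, ]) - dist(my[idx, ]))), 1e-10)
    }
  }
  # zero-size move leaves the configuration unchanged
  y0 <- dimer_move(x, monomers, sched,
                   rotations = list(c(0, 0, 0), c(0, 0, 0)),
                   translations = list(c(0, 0, 0), c(0, 0, 0)),
                   expansion = 1)
  expect_equal(y0, x, tolerance = 1e-12)
  # monomer index sets must partition the particles
  expect_error(dimer_move(x, list(1:4, 4:8), sched), "disjoint")
  expect_error(dimer_move(x, list(1:3, 5:8), sched), "disjoint")
})

test_that("dimer rotation matches an independent rotation-matrix application", {
  set.seed(6)
  n <- 6
  x <- coords_flat(matrix(rnorm(3 * n), n, 3))
  monomers <- list(1:3, 4:6)
  rot <- c(0, 0, pi)
  y <- dimer_move(x, monomers, move_schedule(),
                  rotations = list(rot, c(0, 0, 0)),
                  translations = list(c(0, 0, 0), c(0, 0, 0)),
                  expansion = 1)
  mx <- coords_matrix(x); my <- coords_matrix(y)
  cm <- colMeans(mx[1:3, ])
  for (i in 1:3) {
    expected <- rodrigues(mx[i, ] - cm, c(0, 0, 1), pi) + cm
    expect_equal(my[i, ], expected, tolerance = 1e-10)
  }
})

test_that("group rotations preserve bonds, respect periodicity, match Rodrigues", {
  set.seed(7)
  n <- 8
  x <- random_chain_config(n)
  m <- coords_matrix(x)
  y <- group_rotation_move(x, n, pivot = 4, angle = 1.3)
  my <- coords_matrix(y)
  bonds0 <- sqrt(rowSums((m[-1, ] - m[-n, ])^2))
  bonds1 <- sqrt(rowSums((my[-1, ] - my[-n, ])^2))
  expect_equal(bonds0, bonds1, tolerance = 1e-10)
  expect_equal(m[1:4, ], my[1:4, ])  # head untouched

  expect_equal(group_rotation_move(x, n, pivot = 4, angle = 0), x)
  expect_equal(group_rotation_move(x, n, pivot = 4, angle = 2 * pi), x,
               tolerance = 1e-9)

  # final bead rotated about the penultimate bond axis vs Rodrigues oracle
  y2 <- group_rotation_move(x, n, pivot = n - 1, angle = pi)
  axis <- m[n - 1, ] - m[n - 2, ]
  expected <- rodrigues(m[n, ] - m[n - 1, ], axis, pi) + m[n - 1, ]
  expect_equal(coords_matrix(y2)[n, ], expected, tolerance = 1e-9)

  expect_error(group_rotation_move(x[1:9], 3), "too short")
})

test_that("replica exchange at equal temperatures always accepts", {
  expect_equal(exchange_acceptance(-5, -3, 2, 2), 1)
  expect_equal(exchange_acceptance(-3, -5, 2, 2), 1)
  # standard Metropolis form otherwise
  expect_equal(exchange_acceptance(-5, -3, 1, 2),
               min(1, exp((1 / 1 - 1 / 2) * (-5 - -3))), tolerance = 1e-12)
})

test_that("BHPT merges replica pools and beats no single replica", {
  pot <- potential_lj(6)
  start <- random_cluster_config(pot, seed = 3)
  base <- bh_config(n_steps = 300, temperature = 1.0, max_step_size = 0.35,
                    seed = 11, keep_lowest = 30)
  pres <- bhpt(pot, start, cfg = bhpt_config(n_replicas = 4, T_min = 0.6,
                                             T_max = 2.0, exchange_interval = 10,
                                             base = base))
  expect_equal(length(pres$temperatures), 4)
  single <- basin_hop(pot, start, cfg = base)
  expect_lte(pres$pool$energies[1], single$pool$energies[1] + 1e-9)
  # deterministic under the same seed
  pres2 <- bhpt(pot, start, cfg = bhpt_config(n_replicas = 4, T_min = 0.6,
                                              T_max = 2.0, exchange_interval = 10,
                                              base = base))
  expect_identical(pres$pool$energies, pres2$pool$energies)
})

test_that("tight convergence refines, is idempotent, and merges duplicates", {
  pot <- potential_lj(7)
  cfg <- bh_config(n_steps = 300, temperature = 1, max_step_size = 0.35,
                   seed = 2, keep_lowest = 15)
  res <- basin_hop(pot, random_cluster_config(pot, seed = 2), cfg = cfg)
  tp <- tight_converge(res$pool, pot, 1e-7)
  for (i in seq_len(pool_size(tp))) {
    g <- pot_eval(pot, tp$coords[[i]])$gradient
    expect_lte(sqrt(mean(g^2)), 1e-7)
  }
  # idempotence: already-tight minima pass through with negligible drift
  tp2 <- tight_converge(tp, pot, 1e-7)
  expect_equal(tp2$energies, tp$energies, tolerance = 1e-10)

  # two perturbed copies of one minimum merge under refinement
  q <- quench(pot, random_cluster_config(pot, seed = 9), 1e-7)
  set.seed(10)
  pa <- q$x + rnorm(length(q$x), sd = 5e-3)
  pb <- q$x + rnorm(length(q$x), sd = 5e-3)
  pool <- minima_pool(10)
  pool <- pool_insert(pool, pot_eval(pot, pa)$energy, pa)
  pool <- pool_insert(pool, pot_eval(pot, pb)$energy, pb)
  expect_equal(pool_size(pool), 2)
  merged <- tight_converge(pool, pot, 1e-7)
  expect_equal(pool_size(merged), 1)
})

test_that("Metropolis sampling over a mirror-symmetric double well is unbiased", {
  # Two equal-energy mirror wells (single mult-2 dihedral term): quenched-state
  # visit frequencies must match the Boltzmann ratio (here 1:1) within 3 SE.
  pot <- potential_bead_chain(4, k_bond = 100, k_angle = 20,
                              dihedral_amp = 0.8, dihedral_mult = 2L,
                              dihedral_phase = 0, eps_nb = 0)
  sel <- site_selection(1, 4, 1:4)
  set.seed(13)
  start <- quench(pot, random_chain_config(4), 1e-6)$x
  cfg <- bh_config(n_steps = 600, temperature = 0.4, max_step_size = 0.45,
                   seed = 77, keep_lowest = 10)
  # track the chain by re-running with the recorded pool + visits via dihedral
  # of the accepted state: reconstruct by instrumented loop
  visits <- c(pos = 0, neg = 0)
  set.seed(cfg$seed)
  q <- quench(pot, start, cfg$loose_rms_tol)
  x <- q$x; E <- q$energy
  for (s in seq_len(cfg$n_steps)) {
    prop <- x + runif(length(x), -cfg$max_step_size, cfg$max_step_size)
    qn <- tryCatch(quench(pot, prop, cfg$loose_rms_tol),
                   error = function(e) NULL)
    if (is.null(qn) || !qn$converged) next
    if (qn$energy <= E || runif(1) < exp(-(qn$energy - E) / cfg$temperature)) {
      x <- qn$x; E <- qn$energy
    }
    d <- tryCatch(dihedral(coords_matrix(x), sel), error = function(e) NA)
    if (!is.na(d)) {
      if (d > 0) visits["pos"] <- visits["pos"] + 1 else
        visits["neg"] <- visits["neg"] + 1
    }
  }
  n <- sum(visits)
  p_hat <- visits["pos"] / n
  se <- sqrt(0.5 * 0.5 / n)  # null: p = 1/2 (equal quenched energies)
  expect_lt(abs(p_hat - 0.5), 3 * se + 0.5 / n)
})
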