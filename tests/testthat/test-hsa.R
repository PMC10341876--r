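make_db <- function(energy, lfp = 0, horder = 1, kappa = 3L) {
  n <- length(energy)
  spdb(data.frame(energy = energy,
                  log_freq_product = rep_len(lfp, n),
                  horder = rep_len(horder, n)), kappa = kappa)
}

test_that("log-weights obey symmetry, degeneracy shifts and the Boltzmann limit", {
  expect_equal(log_weight(1, 2, 1, 3, 0.5), log_weight(1, 2, 1, 3, 0.5))
  # doubling the degeneracy adds exactly ln 2
  expect_equal(log_weight(1, 2, 2, 3, 0.5) - log_weight(1, 2, 1, 3, 0.5),
               log(2), tolerance = 1e-14)
  # kT -> 0: weight ratio of the higher minimum vanishes
  lr <- log_weight(1.5, 0, 1, 3, 1e-3) - log_weight(1.0, 0, 1, 3, 1e-3)
  expect_lt(exp(lr), 1e-100)
  # monotone decreasing in E at fixed kT
  expect_gt(log_weight(1, 0, 1, 3, 0.2), log_weight(1.1, 0, 1, 3, 0.2))
})

test_that("occupation probabilities normalise and match a high-precision oracle", {
  expect_equal(occupation_probabilities(make_db(0.7), 0.3), 1)
  expect_equal(occupation_probabilities(make_db(c(1, 1)), 0.3), c(0.5, 0.5))
  # two-state oracle in exact arithmetic-friendly form
  dE <- 0.4; dL <- 0.6; n2 <- 3
  db <- spdb(data.frame(energy = c(0, dE), log_freq_product = c(0, dL),
                        horder = c(1, n2)), kappa = 5L)
  for (kbt in c(0.02, 0.05, 0.1, 0.2, 0.3, 0.5, 0.8, 1, 2, 5)) {
    r <- n2 * exp(-dE / kbt - dL)          # w2/w1
    expect_equal(occupation_probabilities(db, kbt),
                 c(1 / (1 + r), r / (1 + r)), tolerance = 1e-12)
  }
  expect_error(occupation_probabilities(
    structure(list(minima = data.frame()), class = "elcv_spdb"), 0.1))
})

test_that("occupation derivatives are conservative, signed, and match finite differences", {
  expect_equal(occupation_derivatives(make_db(0.7), 0.3), 0)
  db <- make_db(c(0, 0.4))
  for (kbt in c(0.05, 0.1, 0.3, 1)) {
    d <- occupation_derivatives(db, kbt)
    expect_lt(d[1], 0)   # lower minimum drains
    expect_gt(d[2], 0)   # higher minimum fills
    expect_lt(abs(sum(d)), 1e-12)
  }
  set.seed(41)
  db10 <- random_spdb(10, seed = 41, kappa = 4L)
  for (kbt in c(0.1, 0.35, 1.2)) {
    d <- occupation_derivatives(db10, kbt)
    h <- kbt * 1e-4
    fd <- (occupation_probabilities(db10, kbt + h) -
             occupation_probabilities(db10, kbt - h)) / (2 * h)
    expect_equal(d, fd, tolerance = 1e-6)
    expect_lt(abs(sum(d)), 1e-12)
  }
})

test_that("heat capacity reduces to kappa for degenerate databases", {
  grid <- kbt_grid(0.05, 2, 50)
  c1 <- heat_capacity_curve(make_db(0.3, kappa = 7L), grid)
  expect_equal(c1$cv, rep(7, 50), tolerance = 1e-14)
  c2 <- heat_capacity_curve(make_db(c(0.3, 0.3), kappa = 7L), grid)
  expect_equal(c2$cv, rep(7, 50), tolerance = 1e-14)
})

test_that("two-state curves match the closed form to 1e-10 everywhere", {
  delta <- 0.35
  db <- make_db(c(0, delta), kappa = 6L)
  grid <- kbt_grid(0.01, 2, 400)
  curve <- heat_capacity_curve(db, grid)
  expect_lt(max(abs(curve$cv - 6 - two_state_cv_oracle(delta, grid))), 1e-10)
})

test_that("heat capacity equals beta^2 d2lnZ/dbeta2 on randomized databases", {
  grid <- kbt_grid(0.06, 2, 30)
  for (s in 1:5) {
    db <- random_spdb(30, seed = 100 + s, kappa = 5L)
    curve <- heat_capacity_curve(db, grid)
    oracle <- fd_cv_oracle(db$minima, db$kappa, grid)
    expect_lt(max(abs(curve$cv - oracle) / abs(curve$cv)), 1e-6)
  }
})

test_that("low- and high-temperature limits are correct", {
  db <- spdb(data.frame(energy = c(0, 0.2, 0.5),
                        log_freq_product = c(1, -1, 0.5),
                        horder = c(1, 2, 1)), kappa = 3L)
  p_cold <- occupation_probabilities(db, 1e-3)
  expect_equal(p_cold[1], 1, tolerance = 1e-12)
  p_hot <- occupation_probabilities(db, 1e5)
  w <- db$minima$horder * exp(-db$minima$log_freq_product)
  expect_equal(p_hot, w / sum(w), tolerance = 1e-4)
})

test_that("feature detection applies the threshold and melting rules", {
  # constructed curve: peaks at 0.05 and 0.15 plus a melting peak at 0.8
  grid <- kbt_grid(0.02, 2, 600)
  bump <- function(x, mu, s) exp(-((log(x) - log(mu))^2) / (2 * s^2))
  cv <- 3 + 2 * bump(grid, 0.05, 0.1) + 1.5 * bump(grid, 0.15, 0.1) +
    4 * bump(grid, 0.8, 0.2)
  curve <- structure(list(kbt = grid, cv = cv, mean_energy = cv * 0,
                          kappa = 3L), class = "elcv_thermo_curve")
  feats <- detect_features(curve, feature_config(threshold_low = 0.086,
                                                 exclude_melting = TRUE))
  expect_gte(length(feats), 1)
  expect_equal(feats[[1]]$kbt, 0.15, tolerance = 0.01)
  expect_false(any(vapply(feats, `[[`, numeric(1), "kbt") > 0.5))
  # without the threshold the 0.05 peak is first
  feats_all <- detect_features(curve, feature_config(threshold_low = 1e-6,
                                                     exclude_melting = TRUE))
  expect_equal(feats_all[[1]]$kbt, 0.05, tolerance = 0.01)
  # monotone curve: no peaks
  cv_mono <- seq(1, 5, length.out = 600)
  curve_mono <- structure(list(kbt = grid, cv = cv_mono, mean_energy = cv_mono * 0,
                               kappa = 3L), class = "elcv_thermo_curve")
  feats_mono <- detect_features(curve_mono, feature_config(threshold_low = 1e-6))
  expect_false(any(vapply(feats_mono, `[[`, character(1), "kind") == "peak"))
})

test_that("the two-state peak location matches a dense-scan argmax", {
  delta <- 0.35
  db <- make_db(c(0, delta), kappa = 6L)
  grid <- kbt_grid(0.01, 2, 500)
  curve <- heat_capacity_curve(db, grid)
  feats <- detect_features(curve, feature_config(threshold_low = 1e-6,
                                                 exclude_melting = FALSE))
  expect_length(feats, 1)
  dense <- seq(0.05, 0.5, by = 1e-5)
  argmax <- dense[which.max(two_state_cv_oracle(delta, dense))]
  spacing <- diff(grid)[feats[[1]]$index]
  expect_lt(abs(feats[[1]]$kbt - argmax), spacing)
})

test_that("feature contributions split by sign and cover the requested fraction", {
  delta <- 0.35
  db <- make_db(c(0, delta), kappa = 6L)
  grid <- kbt_grid(0.01, 2, 400)
  curve <- heat_capacity_curve(db, grid)
  f <- detect_features(curve, feature_config(threshold_low = 1e-6,
                                             exclude_melting = FALSE))[[1]]
  f <- feature_contributions(db, f, feature_config())
  expect_equal(f$positive_set$id, 2)   # the higher minimum fills
  expect_equal(f$negative_set$id, 1)
  expect_equal(f$positive_coverage, 1)

  # brute-force prefix check on a larger database
  db20 <- random_spdb(20, seed = 55, kappa = 4L)
  curve20 <- heat_capacity_curve(db20, grid)
  feats <- detect_features(curve20, feature_config(threshold_low = 1e-6,
                                                   exclude_melting = FALSE))
  expect_gte(length(feats), 1)  # this seed's database has an interior peak
  fc <- feature_contributions(db20, feats[[1]], feature_config(coverage = 0.98))
  d <- occupation_derivatives(db20, feats[[1]]$kbt)
  for (sgn in c(1, -1)) {
    ids_all <- which(sign(d) == sgn)
    ord <- ids_all[order(-abs(d[ids_all]), ids_all)]
    tot <- sum(abs(d[ord]))
    cum <- cumsum(abs(d[ord]))
    k_min <- which(cum >= 0.98 * tot)[1]
    got <- if (sgn > 0) fc$positive_set$id else fc$negative_set$id
    expect_equal(got, ord[seq_len(k_min)])
    # minimality: dropping the last member breaks coverage
    if (k_min > 1) expect_lt(cum[k_min - 1], 0.98 * tot)
  }
  # coverage 1 returns every minimum of that sign
  fc1 <- feature_contributions(db20, feats[[1]], feature_config(coverage = 1))
  expect_setequal(fc1$positive_set$id, which(d > 0))
  expect_setequal(fc1$negative_set$id, which(d < 0))
})

test_that("first-feature temperature honours the detection window", {
  # melting-only database: single funnel, its only peak is the melting peak
  set.seed(61)
  res <- generate_funnel_db(funnel_spec(n_funnels = 1, minima_per_funnel = 12,
                                        spread = 0.3, seed = 61))
  grid <- kbt_grid(0.01, 3, 400)
  expect_true(is.na(first_feature_temperature(res$db, grid, feature_config())))

  # designed two-funnel feature inside the window is reported
  res2 <- generate_funnel_db(funnel_spec(target_feature_kbt = 0.12, seed = 8))
  grid2 <- kbt_grid(0.01, 1, 400)
  t1 <- first_feature_temperature(res2$db, grid2,
                                  feature_config(exclude_melting = FALSE))
  expect_equal(t1, 0.12, tolerance = 0.01)
  # a feature above threshold_high is not reported
  res3 <- generate_funnel_db(funnel_spec(target_feature_kbt = 0.35, seed = 9))
  t3 <- first_feature_temperature(res3$db, grid2,
                                  feature_config(exclude_melting = FALSE))
  expect_true(is.na(t3))
})

test_that("raising the two-state gap raises the peak temperature", {
  peaks <- vapply(c(0.2, 0.3, 0.4, 0.5), function(delta) {
    dense <- seq(0.01, 1, by = 1e-4)
    dense[which.max(two_state_cv(delta, dense))]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("temperature grid validation rejects bad input", {
  db <- make_db(c(0, 1))
  expect_error(heat_capacity_curve(db, c(0.2, 0.1)), "increasing")
  expect_error(heat_capacity_curve(db, c(-0.1, 0.2)), "positive")
  expect_error(kbt_grid(0, 1), "kbt_min")
  expect_error(feature_config(threshold_low = 0.4, threshold_high = 0.3))
})
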