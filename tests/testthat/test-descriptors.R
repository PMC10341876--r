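test_that("end-to-end distance handles trivial and constructed cases", {
  sel <- site_selection(1, 6, c(1, 3, 4, 6))
  chain <- cbind(0:5, 0, 0)
  expect_equal(end_to_end(chain, sel), 5)
  coincident <- chain
  coincident[6, ] <- coincident[1, ]
  expect_equal(end_to_end(coincident, sel), 0)
  expect_error(end_to_end(chain, site_selection(1, 99, c(1, 3, 4, 6))),
               "out of range")
})

test_that("dihedrals follow the signed IUPAC convention", {
  sel <- site_selection(1, 4, 1:4)
  # planar cis: 0 degrees
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  expect_equal(dihedral(cis, sel), 0, tolerance = 1e-12)
  # planar trans: 180 degrees (and inside (-180, 180])
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  expect_equal(dihedral(trans, sel), 180, tolerance = 1e-12)
  # right-handed twist is positive; matches an independent formula
  p <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, cos(1), sin(1)))
  got <- dihedral(p, sel)
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  # (n1 x n2) . b2hat = (b2hat x n1) . n2  (scalar triple product, cyclic)
  m1 <- pracma_cross(b2 / sqrt(sum(b2^2)), n1)
  want <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  expect_gt(got, 0)
  expect_equal(got, want, tolerance = 1e-9)
  # collinear degeneracy is an error
  line <- cbind(0:3, 0, 0)
  expect_error(dihedral(line, sel), "collinear|degenerate")
})

test_that("descriptors are rigid-motion invariant; dihedral flips under mirrors", {
  set.seed(71)
  sel <- default_site_selection(12)
  for (k in 1:5) {
    m <- elcv:::conformer_template("helical", 12) + matrix(rnorm(36, sd = 0.1), 12, 3)
    d0 <- end_to_end(m, sel); a0 <- dihedral(m, sel)
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, 3, byrow = TRUE)
    m2 <- sweep(m %*% t(Rz %*% Rx), 2, runif(3, -5, 5), FUN = "+")
    expect_equal(end_to_end(m2, sel), d0, tolerance = 1e-9)
    expect_equal(dihedral(m2, sel), a0, tolerance = 1e-9)
    mirror <- m
    mirror[, 3] <- -mirror[, 3]
    expect_equal(dihedral(mirror, sel), -a0, tolerance = 1e-9)
    expect_equal(end_to_end(mirror, sel), d0, tolerance = 1e-9)
  }
})

test_that("helical template descriptors match their construction parameters", {
  n <- 12
  sel <- default_site_selection(n)
  m <- elcv:::conformer_template("helical", n)
  # construction: radius 1.2, twist 100 deg/site, rise 0.45/site
  step <- 100 * pi / 180; r <- 1.2; rise <- 0.45
  i1 <- sel$end_a - 1; i2 <- sel$end_b - 1
  want <- sqrt((r * cos(i2 * step) - r * cos(i1 * step))^2 +
                 (r * sin(i2 * step) - r * sin(i1 * step))^2 +
                 ((i2 - i1) * rise)^2)
  expect_equal(end_to_end(m, sel), want, tolerance = 1e-12)
  expect_gt(dihedral(m, sel), 0)  # right-handed helix twists positive
})

test_that("correlation data filters by contributors and energy window", {
  set.seed(73)
  n <- 10
  coords <- lapply(1:n, function(i)
    coords_flat(elcv:::conformer_template("extended", 8) +
                  matrix(rnorm(24, sd = 0.05), 8, 3)))
  minima <- data.frame(energy = c(0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4, 4.5),
                       log_freq_product = 0, horder = 1)
  db <- spdb(minima, kappa = 3L, coords = coords)
  feature <- list(kind = "peak", kbt = 0.1,
                  positive_set = data.frame(id = c(3, 5), dpdT = c(1, 2)),
                  negative_set = data.frame(id = 1, dpdT = -3))
  sel <- default_site_selection(8)
  # window 2.6 excludes minimum 5 (rel energy 2.0 <= 2.6 keeps it; use 1.6)
  rec <- correlation_data(db, feature, descriptor_config(energy_window = 1.6),
                          sel)
  expect_equal(rec$id, c(1, 3))
  expect_true(all(rec$contributes))
  # infinite window, unrestricted: every minimum appears
  rec_all <- correlation_data(db, feature,
                              descriptor_config(energy_window = Inf,
                                                restrict_to_contributors = FALSE),
                              sel)
  expect_equal(nrow(rec_all), n)
  expect_equal(sum(rec_all$contributes), 3)
  # empty contribution sets give an empty record set
  empty <- list(kind = "peak", kbt = 0.1,
                positive_set = data.frame(id = integer(0), dpdT = numeric(0)),
                negative_set = data.frame(id = integer(0), dpdT = numeric(0)))
  expect_equal(nrow(correlation_data(db, empty, descriptor_config(), sel)), 0)
  # missing coordinates are reported with the minimum id
  db_nc <- db
  db_nc$coords[[3]] <- NULL
  db_nc$coords <- c(db_nc$coords[1:2], list(NULL), db_nc$coords[3:9])
  expect_error(correlation_data(db_nc, feature, descriptor_config(), sel),
               "minimum 3")
})

test_that("spread statistics quantify pooled family separation", {
  single <- data.frame(end_to_end = 2, dihedral = 30)
  s1 <- spread_statistics(single)
  expect_equal(s1$distance_range, 0)
  expect_equal(s1$dihedral_sd, 0)
  set.seed(74)
  hp <- generate_conformers("hairpin", 100, jitter = 0.08, seed = 1)$truth
  hx <- generate_conformers("helical", 100, jitter = 0.08, seed = 2)$truth
  pooled <- data.frame(end_to_end = c(hp$end_to_end, hx$end_to_end),
                       dihedral = c(hp$dihedral, hx$dihedral))
  sp <- spread_statistics(pooled)
  expect_gt(sp$distance_range,
            max(spread_statistics(hp)$distance_range,
                spread_statistics(hx)$distance_range))
  expect_error(spread_statistics(pooled[0, ]), "no records")
})

test_that("conformation classes follow the distance ordering with half-open bins", {
  b <- c(3, 5, 7, 9)
  expect_equal(as.character(classify_conformation(1, b)), "hairpin")
  expect_equal(as.character(classify_conformation(10, b)), "extended")
  expect_equal(as.character(classify_conformation(5, b)), "question_mark")
  expect_equal(as.character(classify_conformation(c(3.5, 8), b)),
               c("S_shaped", "W_shaped"))
  expect_error(classify_conformation(1, c(3, 2, 7, 9)), "increasing")
})

test_that("interstrand separation orders close and far dimers", {
  close_d <- generate_dimer_configs("extended", "extended", separation = 2,
                                    n_samples = 5, seed = 5)
  far_d <- generate_dimer_configs("extended", "extended", separation = 8,
                                  n_samples = 5, seed = 5)
  expect_gt(mean(far_d$truth$interstrand), mean(close_d$truth$interstrand))
  # geometric lower bound: separation minus both monomer radii
  rad <- function(m) max(sqrt(rowSums(sweep(m, 2, colMeans(m))^2)))
  for (k in 1:5) {
    m <- far_d$frames[[k]]
    r1 <- rad(m[far_d$monomers[[1]], ]); r2 <- rad(m[far_d$monomers[[2]], ])
    expect_gte(far_d$truth$interstrand[k], 8 - r1 - r2 - 1e-9)
  }
})

test_that("feature-vs-propensity reporting mirrors the per-group comparison", {
  tab <- data.frame(label = c("a", "b", "c", "d"),
                    feature_kbt = c(0.1, 0.2, 0.3, 0.4),
                    propensity = c(4, 3, 2, 1))
  res <- feature_vs_propensity(tab)
  expect_equal(res$rank_correlation, -1)
  tab2 <- rbind(tab, data.frame(label = "none", feature_kbt = NA,
                                propensity = 5))
  res2 <- feature_vs_propensity(tab2)
  expect_equal(res2$excluded, "none")
  expect_equal(res2$n_used, 4)
  # three groups, within-group anti-ordering but no global ordering
  tab3 <- data.frame(
    label = paste0("p", 1:6),
    group = rep(c("g1", "g2", "g3"), each = 2),
    amyloid = rep(c(TRUE, FALSE), 3),
    feature_kbt = c(0.10, 0.12, 0.20, 0.22, 0.30, 0.32),
    propensity = c(5, 4, 5, 4, 5, 4))
  res3 <- feature_vs_propensity(tab3)
  expect_true(all(res3$per_group$amyloid_lowest))
  expect_lt(abs(res3$rank_correlation), 0.5)
  expect_error(feature_vs_propensity(tab2[5, ]), "at least 2")
})
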