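#' Synthetic multi-funnel stationary-point databases
#'
#' Generates databases with the statistical structure the heat-capacity
#' analysis assumes: funnels whose bottoms differ in energy and in vibrational
#' entropy (via a log-frequency-product offset), internally connected by low
#' barriers and mutually connected only at or above a high inter-funnel
#' barrier. A two-funnel database with bottom gap delta and entropy ratio g
#' produces a low-temperature configurational heat-capacity peak at
#' kT = delta / x*(g), where x*(g) is the argmax of the two-state closed form;
#' `funnel_spec` can solve this design equation for a requested feature
#' temperature.
#'
#' @param n_funnels number of funnels.
#' @param minima_per_funnel minima count per funnel (recycled).
#' @param bottom_energies funnel bottom energies; ignored when
#'   `target_feature_kbt` is given (two funnels: bottoms 0 and the designed
#'   gap).
#' @param spread intra-funnel energy spread (exponential scale above the
#'   bottom); defaults to 5% of the designed gap, or 0.02.
#' @param lfp_offsets per-funnel log-frequency-product offsets (entropy
#'   control: a lower offset means higher vibrational entropy).
#' @param barrier_height inter-funnel barrier height above the higher of the
#'   two connected funnel bottoms.
#' @param kappa vibrational degrees of freedom recorded in the database.
#' @param lfp_jitter within-funnel jitter of the log frequency product.
#' @param target_feature_kbt optional designed feature temperature (requires
#'   exactly two funnels).
#' @param seed RNG seed.
#' @export
funnel_spec <- function(n_funnels = 2L, minima_per_funnel = 10L,
                        bottom_energies = NULL, spread = NULL,
                        lfp_offsets = 0, barrier_height = 1,
                        kappa = 10L, lfp_jitter = 0.02,
                        target_feature_kbt = NULL, seed = 1L) {
  stopifnot(n_funnels >= 1, all(minima_per_funnel >= 1), barrier_height > 0)
  minima_per_funnel <- rep_len(as.integer(minima_per_funnel), n_funnels)
  lfp_offsets <- rep_len(lfp_offsets, n_funnels)
  delta <- NA_real_
  g <- NA_real_
  if (!is.null(target_feature_kbt)) {
    if (n_funnels != 2L)
      stop("a designed feature temperature needs exactly two funnels",
           call. = FALSE)
    g <- exp(lfp_offsets[1] - lfp_offsets[2])
    xs <- stats::optimize(function(x) two_state_cv(x, 1, g),
                          c(0.05, 60), maximum = TRUE)$maximum
    delta <- xs * target_feature_kbt
    bottom_energies <- c(0, delta)
  }
  if (is.null(bottom_energies))
    bottom_energies <- seq(0, by = 0.3, length.out = n_funnels)
  stopifnot(length(bottom_energies) == n_funnels)
  if (is.null(spread)) spread <- if (is.finite(delta)) 0.05 * delta else 0.02
  structure(list(n_funnels = as.integer(n_funnels),
                 minima_per_funnel = minima_per_funnel,
                 bottom_energies = bottom_energies, spread = spread,
                 lfp_offsets = lfp_offsets, barrier_height = barrier_height,
                 kappa = as.integer(kappa), lfp_jitter = lfp_jitter,
                 target_feature_kbt = target_feature_kbt,
                 designed_delta = delta, designed_g = g,
                 seed = as.integer(seed)),
            class = "elcv_funnel_spec")
}

#' @rdname funnel_spec
#' @param spec an `elcv_funnel_spec`.
#' @return `generate_funnel_db`: list with `db` (an `elcv_spdb`) and
#'   `manifest` (design truth: spec parameters, designed gap and entropy
#'   ratio, designed feature temperature).
#' @export
generate_funnel_db <- function(spec) {
  stopifnot(inherits(spec, "elcv_funnel_spec"))
  set.seed(spec$seed)
  minima <- data.frame(energy = numeric(0), log_freq_product = numeric(0),
                       horder = numeric(0))
  funnel_of <- integer(0)
  bottoms_id <- integer(spec$n_funnels)
  for (f in seq_len(spec$n_funnels)) {
    cnt <- spec$minima_per_funnel[f]
    e <- spec$bottom_energies[f] +
      c(0, if (cnt > 1) stats::rexp(cnt - 1, rate = 1 / spec$spread))
    lfp <- spec$lfp_offsets[f] + stats::rnorm(cnt, sd = spec$lfp_jitter)
    bottoms_id[f] <- nrow(minima) + 1L
    minima <- rbind(minima, data.frame(energy = e, log_freq_product = lfp,
                                       horder = 1))
    funnel_of <- c(funnel_of, rep(f, cnt))
  }
  ts <- data.frame(energy = numeric(0), log_freq_product = numeric(0),
                   horder = numeric(0), min1 = integer(0), min2 = integer(0))
  intra_barrier <- 2 * spec$spread
  ts_lfp <- function(i, j) mean(minima$log_freq_product[c(i, j)]) - 0.5
  for (f in seq_len(spec$n_funnels)) {
    ids <- which(funnel_of == f)
    b <- bottoms_id[f]
    for (i in setdiff(ids, b)) {
      ts <- rbind(ts, data.frame(
        energy = max(minima$energy[i], minima$energy[b]) + intra_barrier,
        log_freq_product = ts_lfp(i, b), horder = 1, min1 = b, min2 = i))
    }
  }
  # Exact-curve calibration: with a designed feature temperature, the
  # two-state closed form fixes the funnel-bottom gap only up to the drawn
  # intra-funnel fine structure, which shifts the peak by a few percent.
  # Solve a 1D root problem for a rigid shift of the second funnel so that
  # the argmax of the exact HSA curve lands on the target.
  calibrated_delta <- spec$designed_delta
  if (!is.null(spec$target_feature_kbt)) {
    target <- spec$target_feature_kbt
    f2 <- which(funnel_of == 2L)
    cv_conf <- function(th, e) {
      lw <- log(minima$horder) - e / th - minima$log_freq_product
      p <- exp(lw - max(lw)); p <- p / sum(p)
      mu <- sum(p * e)
      sum(p * (e - mu)^2) / th^2
    }
    peak_at <- function(shift) {
      e <- minima$energy
      e[f2] <- e[f2] + shift
      stats::optimize(function(th) -cv_conf(th, e),
                      c(0.3 * target, 5 * target), tol = 1e-9)$minimum
    }
    obj <- function(shift) peak_at(shift) - target
    lo <- -0.5 * spec$designed_delta
    hi <- 1.0 * spec$designed_delta
    shift <- tryCatch(stats::uniroot(obj, c(lo, hi), tol = 1e-6)$root,
                      error = function(e) 0)
    minima$energy[f2] <- minima$energy[f2] + shift
    calibrated_delta <- spec$designed_delta + shift
  }
  inter_energies <- numeric(0)
  for (f in seq_len(spec$n_funnels - 1L)) {
    b1 <- bottoms_id[f]; b2 <- bottoms_id[f + 1L]
    e_ts <- max(minima$energy[b1], minima$energy[b2]) + spec$barrier_height
    inter_energies <- c(inter_energies, e_ts)
    ts <- rbind(ts, data.frame(energy = e_ts,
                               log_freq_product = ts_lfp(b1, b2), horder = 1,
                               min1 = b1, min2 = b2))
  }
  if (length(inter_energies) && nrow(ts)) {
    intra_max <- suppressWarnings(
      max(ts$energy[seq_len(nrow(ts) - length(inter_energies))]))
    if (is.finite(intra_max) && min(inter_energies) <= intra_max)
      stop("infeasible barrier constraints: inter-funnel barrier does not ",
           "exceed the intra-funnel transition states", call. = FALSE)
  }
  db <- spdb(minima, if (nrow(ts)) ts else NULL, kappa = spec$kappa,
             metadata = list(title = "synthetic multi-funnel database"))
  manifest <- list(
    n_funnels = spec$n_funnels,
    minima_per_funnel = spec$minima_per_funnel,
    bottom_energies = spec$bottom_energies,
    spread = spec$spread, lfp_offsets = spec$lfp_offsets,
    barrier_height = spec$barrier_height, kappa = spec$kappa,
    lfp_jitter = spec$lfp_jitter, seed = spec$seed,
    designed_delta = calibrated_delta,
    two_state_delta = spec$designed_delta, designed_g = spec$designed_g,
    designed_feature_kbt = spec$target_feature_kbt,
    funnel_of = funnel_of)
  list(db = db, manifest = manifest)
}

## ---- conformer generators ------------------------------------------------

conformer_template <- function(family, n) {
  m <- matrix(0, n, 3)
  if (family == "hairpin") {
    h <- ceiling(n / 2)
    for (i in seq_len(h)) m[i, ] <- c(i - 1, 0, 0)
    for (i in (h + 1):n) m[i, ] <- c(n - i, 1.0, 0)
  } else if (family == "helical") {
    step <- 100 * pi / 180          # right-handed (positive) twist
    r <- 1.2; rise <- 0.45
    for (i in seq_len(n)) {
      th <- (i - 1) * step
      m[i, ] <- c(r * cos(th), r * sin(th), (i - 1) * rise)
    }
  } else if (family == "extended") {
    for (i in seq_len(n)) m[i, ] <- c(i - 1, 0.05 * (-1)^i, 0)
  } else stop("unknown conformer family: ", family, call. = FALSE)
  m
}

#' Conformer family generator
#'
#' Builds 3D toy chains from family templates -- a U-turn hairpin, a helix
#' with positive twist, and a near-straight extended chain -- with Gaussian
#' site jitter, emulating the conformation classes seen in hexapeptide
#' landscapes (listed in order of increasing end-to-end distance).
#'
#' @param family "hairpin", "helical" or "extended".
#' @param n_samples number of conformers.
#' @param chain_length number of sites (>= 6).
#' @param jitter Gaussian site jitter standard deviation.
#' @param seed RNG seed.
#' @return list with `frames` (coordinate matrices), `truth` (data frame with
#'   each sample's exact end-to-end distance and dihedral under the default
#'   site selection), `sel`, and `family`.
#' @export
generate_conformers <- function(family, n_samples, chain_length = 12L,
                                jitter = 0.1, seed = 1L) {
  stopifnot(n_samples >= 1, chain_length >= 6, jitter >= 0)
  set.seed(seed)
  tmpl <- conformer_template(family, chain_length)
  sel <- default_site_selection(chain_length)
  frames <- lapply(seq_len(n_samples), function(k) {
    tmpl + matrix(stats::rnorm(3 * chain_length, sd = jitter), ncol = 3)
  })
  truth <- data.frame(
    sample = seq_len(n_samples),
    end_to_end = vapply(frames, end_to_end, numeric(1), sel = sel),
    dihedral = vapply(frames, dihedral, numeric(1), sel = sel))
  list(frames = frames, truth = truth, sel = sel, family = family)
}

#' Dimer configuration generator
#'
#' Places two jittered monomer chains with their centroids at a given
#' separation and a random relative angle-axis orientation; per-monomer truth
#' descriptors and the interstrand separation are recorded.
#'
#' @param family_a,family_b monomer families.
#' @param separation centroid separation (> 0).
#' @param n_samples number of dimer configurations.
#' @param chain_length sites per monomer.
#' @param jitter Gaussian site jitter.
#' @param seed RNG seed.
#' @return list with `frames`, `monomers` (two index sets), and `truth`.
#' @export
generate_dimer_configs <- function(family_a, family_b, separation,
                                   n_samples = 10L, chain_length = 12L,
                                   jitter = 0.05, seed = 1L) {
  if (!(separation > 0))
    stop("separation must be positive", call. = FALSE)
  set.seed(seed)
  sel <- default_site_selection(chain_length)
  ta <- conformer_template(family_a, chain_length)
  tb <- conformer_template(family_b, chain_length)
  monomers <- list(seq_len(chain_length),
                   chain_length + seq_len(chain_length))
  frames <- list()
  rows <- list()
  for (k in seq_len(n_samples)) {
    a <- ta + matrix(stats::rnorm(3 * chain_length, sd = jitter), ncol = 3)
    b <- tb + matrix(stats::rnorm(3 * chain_length, sd = jitter), ncol = 3)
    a <- sweep(a, 2, colMeans(a))
    b <- sweep(b, 2, colMeans(b))
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ang <- stats::runif(1, 0, pi)
    b <- b %*% t(rotation_matrix_aa(u * ang))
    b <- sweep(b, 2, c(separation, 0, 0), FUN = "+")
    m <- rbind(a, b)
    frames[[k]] <- m
    rows[[k]] <- data.frame(
      sample = k,
      end_to_end_a = end_to_end(a, sel), dihedral_a = dihedral(a, sel),
      end_to_end_b = end_to_end(b, sel), dihedral_b = dihedral(b, sel),
      interstrand = interstrand_separation(m, monomers))
  }
  list(frames = frames, monomers = monomers, truth = do.call(rbind, rows),
       sel = sel)
}
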