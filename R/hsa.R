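#' Harmonic superposition thermodynamics
#'
#' In the classical harmonic superposition approximation (HSA) the total
#' partition function is the sum of the harmonic partition functions of all
#' catalogued local minima,
#' \deqn{Z(\beta) = \sum_a n_a e^{-\beta E_a} (\beta)^{-\kappa} e^{-L_a},}
#' where \eqn{E_a} is the minimum's energy, \eqn{L_a} the sum of the logs of
#' its \eqn{\kappa} positive normal-mode frequencies, and \eqn{n_a} its
#' degeneracy order. All temperatures are expressed as kT in energy units
#' (the same units as the minima energies; kcal/mol for peptide databases).
#' Occupation probabilities, mean energies, and the heat capacity
#' \deqn{C_V/k_B = \kappa + (\langle E^2\rangle - \langle E\rangle^2)/(kT)^2}
#' follow from Boltzmann averages over the minima, evaluated in the log domain
#' for stability.
#'
#' @name hsa
NULL

#' Log statistical weight of one minimum
#'
#' Returns ln w_a = ln n_a - E_a/kT + kappa ln kT - L_a, with additive
#' constants common to all minima omitted. Vectorised over minima.
#'
#' @param energy,log_freq_product,horder the minimum's E_a, L_a and n_a.
#' @param kappa vibrational degrees of freedom.
#' @param kbt temperature as kT in energy units (> 0).
#' @export
log_weight <- function(energy, log_freq_product, horder, kappa, kbt) {
  stopifnot(kbt > 0)
  log(horder) - energy / kbt + kappa * log(kbt) - log_freq_product
}

log_weights_db <- function(db, kbt) {
  log_weight(db$minima$energy, db$minima$log_freq_product, db$minima$horder,
             db$kappa, kbt)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Occupation probabilities of the minima
#'
#' p_a = w_a / sum_b w_b, computed via log-sum-exp; sums to 1 to 1e-12.
#' @param db an `elcv_spdb`.
#' @param kbt temperature (kT, energy units).
#' @return numeric vector of probabilities, one per minimum.
#' @export
occupation_probabilities <- function(db, kbt) {
  if (n_minima(db) < 1) stop("empty database", call. = FALSE)
  lw <- log_weights_db(db, kbt)
  p <- exp(lw - logsumexp(lw))
  p / sum(p)
}

#' Temperature derivatives of the occupation probabilities
#'
#' dp_a/d(kT) = p_a (E_a - <E>) / (kT)^2; the derivatives sum to zero.
#' @inheritParams occupation_probabilities
#' @export
occupation_derivatives <- function(db, kbt) {
  p <- occupation_probabilities(db, kbt)
  E <- db$minima$energy
  p * (E - sum(p * E)) / kbt^2
}

#' Heat-capacity curve under the harmonic superposition approximation
#'
#' @param db an `elcv_spdb`.
#' @param grid strictly increasing vector of kT values (> 0).
#' @return an `elcv_thermo_curve`: list with `kbt`, `cv` (in units of kB,
#'   including the kappa*kB harmonic baseline), `mean_energy`, and `kappa`.
#' @export
heat_capacity_curve <- function(db, grid) {
  if (!is.numeric(grid) || any(grid <= 0) || any(diff(grid) <= 0))
    stop("temperature grid must be positive and strictly increasing",
         call. = FALSE)
  E <- db$minima$energy
  cv <- numeric(length(grid))
  me <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p <- occupation_probabilities(db, grid[i])
    mu <- sum(p * E)
    v <- sum(p * (E - mu)^2)
    me[i] <- mu
    cv[i] <- db$kappa + v / grid[i]^2
  }
  structure(list(kbt = grid, cv = cv, mean_energy = me, kappa = db$kappa),
            class = "elcv_thermo_curve")
}

#' @export
print.elcv_thermo_curve <- function(x, ...) {
  cat(sprintf("<thermo curve: %d kT points in [%.4g, %.4g], kappa = %d, max CV/kB = %.4g>\n",
              length(x$kbt), min(x$kbt), max(x$kbt), x$kappa, max(x$cv)))
  invisible(x)
}

#' @export
as.data.frame.elcv_thermo_curve <- function(x, ...) {
  data.frame(kbt = x$kbt, cv = x$cv, mean_energy = x$mean_energy)
}

#' Two-state configurational heat capacity (closed form)
#'
#' For two minima separated by an energy gap `delta` with a
#' temperature-independent weight ratio g (degeneracy/entropy factor), the
#' configurational part of the heat capacity is
#' \deqn{C_V/k_B - \kappa = (\delta/kT)^2 \, g e^{-\delta/kT} /
#'   (1 + g e^{-\delta/kT})^2.}
#' @param delta energy gap (> 0).
#' @param kbt temperature(s).
#' @param g weight ratio of the upper state relative to the lower
#'   (g = (n_2/n_1) exp(L_1 - L_2)); 1 for equal entropy.
#' @export
two_state_cv <- function(delta, kbt, g = 1) {
  x <- delta / kbt
  w <- g * exp(-x)
  x^2 * w / (1 + w)^2
}

#' Feature-detection configuration
#'
#' Defaults follow the analysis conventions for hexapeptide landscapes: the
#' feature of interest is the first peak or inflection above kT = 0.086
#' (energy units; kcal/mol for the peptide databases), the comparison window
#' for feature temperatures is (0.076, 0.300), contribution sets cover 98% of
#' each sign group, and the melting peak (the highest-kT peak on the grid) is
#' excluded.
#'
#' @param threshold_low lower kT threshold for reported features.
#' @param threshold_high upper kT bound used by
#'   [first_feature_temperature()].
#' @param coverage fraction of each sign group's total |dp/dT| covered by the
#'   reported contribution sets.
#' @param exclude_melting drop the highest-kT peak (the melting peak)?
#' @export
feature_config <- function(threshold_low = 0.086, threshold_high = 0.300,
                           coverage = 0.98, exclude_melting = TRUE) {
  stopifnot(threshold_low > 0, threshold_high > threshold_low,
            coverage > 0, coverage <= 1)
  structure(list(threshold_low = threshold_low, threshold_high = threshold_high,
                 coverage = coverage, exclude_melting = exclude_melting),
            class = "elcv_feature_config")
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] > y[i - 1] & y[i] > y[i + 1]]
}

#' Detect heat-capacity features
#'
#' Peaks are interior local maxima of CV(kT); inflections are interior local
#' maxima of dCV/d(kT) on rising parts of the curve that are not the flank of
#' a detected peak. Every resolved peak owns one rising-flank slope maximum
#' (the nearest one below it), which is suppressed -- an inflection feature
#' is therefore a genuine shoulder, a slope maximum with another slope
#' maximum (or no peak at all) between itself and the next peak. A relative
#' prominence floor of 1e-3 on the slope curve suppresses numerical ripple.
#' Features at or below `cfg$threshold_low` are discarded; with
#' `cfg$exclude_melting` the highest-kT peak is labelled as the melting peak
#' and removed. Remaining features are returned in ascending kT.
#'
#' @param curve an `elcv_thermo_curve` on a reasonably dense grid.
#' @param cfg a `feature_config`.
#' @return list of features, each a list with `kind` ("peak"/"inflection"),
#'   `kbt`, `index` (grid index), and `cv`.
#' @export
detect_features <- function(curve, cfg = feature_config()) {
  kbt <- curve$kbt; cv <- curve$cv
  if (length(kbt) < 3) return(list())
  peak_idx <- local_maxima(cv)
  melting_idx <- integer(0)
  if (cfg$exclude_melting && length(peak_idx)) {
    melting_idx <- peak_idx[which.max(kbt[peak_idx])]
    peak_idx <- setdiff(peak_idx, melting_idx)
  }
  # slope by central differences on the (possibly nonuniform) grid
  slope <- numeric(length(kbt))
  n <- length(kbt)
  slope[1] <- (cv[2] - cv[1]) / (kbt[2] - kbt[1])
  slope[n] <- (cv[n] - cv[n - 1]) / (kbt[n] - kbt[n - 1])
  slope[2:(n - 1)] <- (cv[3:n] - cv[1:(n - 2)]) / (kbt[3:n] - kbt[1:(n - 2)])
  infl_idx <- local_maxima(slope)
  infl_idx <- infl_idx[slope[infl_idx] > 0]   # rising shoulders only
  # prominence floor relative to the slope scale; suppress ripple
  if (length(infl_idx)) {
    prom <- vapply(infl_idx, function(i) {
      left <- slope[max(1, i - 5):i]
      right <- slope[i:min(n, i + 5)]
      slope[i] - max(min(left), min(right))
    }, numeric(1))
    infl_idx <- infl_idx[prom > 1e-3 * max(abs(slope))]
  }
  # every peak owns its rising flank: drop the closest slope maximum below
  # each detected peak (melting included)
  for (p in c(peak_idx, melting_idx)) {
    below <- infl_idx[infl_idx < p]
    if (length(below)) infl_idx <- setdiff(infl_idx, max(below))
  }
  infl_idx <- setdiff(infl_idx, c(peak_idx, melting_idx))
  feats <- c(
    lapply(peak_idx, function(i) list(kind = "peak", kbt = kbt[i],
                                      index = i, cv = cv[i])),
    lapply(infl_idx, function(i) list(kind = "inflection", kbt = kbt[i],
                                      index = i, cv = cv[i])))
  feats <- Filter(function(f) f$kbt > cfg$threshold_low, feats)
  feats[order(vapply(feats, `[[`, numeric(1), "kbt"))]
}

#' Decompose a feature into contributing minima
#'
#' At the feature's temperature, minima are split by the sign of dp_a/d(kT);
#' within each sign group, sorted by |dp_a/dT| descending (ties broken by
#' lower minimum id), the minimal prefix whose summed magnitude reaches
#' `cfg$coverage` of the group total is reported.
#'
#' @param db the `elcv_spdb` behind the curve.
#' @param feature one element of the [detect_features()] result.
#' @param cfg a `feature_config`.
#' @return the feature augmented with `positive_set` and `negative_set`
#'   (data frames with `id`, `dpdT`) and their achieved coverages.
#' @export
feature_contributions <- function(db, feature, cfg = feature_config()) {
  d <- occupation_derivatives(db, feature$kbt)
  pick <- function(ids) {
    mag <- abs(d[ids])
    ord <- ids[order(-mag, ids)]
    total <- sum(mag)
    if (total == 0) {
      return(list(set = data.frame(id = integer(0), dpdT = numeric(0)),
                  coverage = 1))
    }
    cum <- cumsum(abs(d[ord]))
    k <- if (cfg$coverage == 1) length(ord) else
      which(cum >= cfg$coverage * total)[1]
    if (is.na(k)) k <- length(ord)   # summation-order rounding guard
    sel <- ord[seq_len(k)]
    list(set = data.frame(id = sel, dpdT = d[sel]), coverage = cum[k] / total)
  }
  pos <- pick(which(d > 0))
  neg <- pick(which(d < 0))
  feature$positive_set <- pos$set
  feature$negative_set <- neg$set
  feature$positive_coverage <- pos$coverage
  feature$negative_coverage <- neg$coverage
  feature
}

#' Temperature of the first low-temperature feature
#'
#' The kT of the first non-melting feature strictly inside
#' (`threshold_low`, `threshold_high`); `NA` when no such feature exists
#' (e.g. when the only peak is the melting peak).
#'
#' @param db an `elcv_spdb`.
#' @param grid temperature grid.
#' @param cfg a `feature_config`.
#' @export
first_feature_temperature <- function(db, grid, cfg = feature_config()) {
  curve <- heat_capacity_curve(db, grid)
  feats <- detect_features(curve, cfg)
  for (f in feats) {
    if (f$kbt > cfg$threshold_low && f$kbt < cfg$threshold_high) return(f$kbt)
  }
  NA_real_
}

#' Log-spaced temperature grid
#' @param kbt_min,kbt_max grid bounds (> 0).
#' @param n number of points.
#' @export
kbt_grid <- function(kbt_min, kbt_max, n = 400L) {
  stopifnot(kbt_min > 0, kbt_max > kbt_min, n >= 2)
  exp(seq(log(kbt_min), log(kbt_max), length.out = n))
}
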