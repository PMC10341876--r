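# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

## Mueller-Brown stationary points by dense grid scan + Newton refinement.
## Memoised: computed once per test run.
mb_oracle_env <- new.env()

mb_oracle <- function() {
  if (!is.null(mb_oracle_env$inv)) return(mb_oracle_env$inv)
  pot <- potential_mueller_brown()
  newton <- function(x) {
    for (i in 1:100) {
      g <- pot_eval(pot, x)$gradient
      if (!all(is.finite(g)) || !all(is.finite(x))) return(NULL)
      if (sqrt(sum(g^2)) < 1e-12) break
      H <- fd_hessian(pot, x)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      x <- x - step
    }
    x
  }
  acc <- matrix(numeric(0), ncol = 2)
  for (xi in seq(-1.8, 1.2, length.out = 31)) {
    for (yi in seq(-0.5, 2.2, length.out = 28)) {
      x <- newton(c(xi, yi))
      if (is.null(x) || !all(is.finite(x))) next
      if (x[1] < -2 || x[1] > 1.5 || x[2] < -1 || x[2] > 2.5) next
      if (sqrt(sum(pot_eval(pot, x)$gradient^2)) > 1e-8) next
      acc <- rbind(acc, x)
    }
  }
  P <- unique(round(acc, 6))
  rows <- lapply(seq_len(nrow(P)), function(i) {
    x <- newton(P[i, ])
    ev <- eigen(fd_hessian(pot, x), symmetric = TRUE)$values
    data.frame(x = x[1], y = x[2], energy = pot_eval(pot, x)$energy,
               index = sum(ev < 0))
  })
  inv <- do.call(rbind, rows)
  inv <- inv[order(inv$index, inv$energy), ]
  mb_oracle_env$inv <- inv
  inv
}

## Fine-step steepest descent (independent of quench) for connectivity checks:
## displacement capped at `step`, with a small stable rate near stationarity.
sd_oracle <- function(pot, x, step = 2e-3, rate = 2e-4, max_iter = 50000L) {
  for (i in seq_len(max_iter)) {
    g <- pot_eval(pot, x)$gradient
    ng <- sqrt(sum(g^2))
    if (ng < 1e-8) break
    x <- x - g * min(step / ng, rate)
  }
  x
}

## Heat capacity from 5-point central finite differences of lnZ w.r.t. beta.
## Written directly from the database columns, independent of the package's
## moment-based evaluation.
fd_cv_oracle <- function(minima, kappa, kbt) {
  lnZ <- function(b) {
    lw <- log(minima$horder) - b * minima$energy - kappa * log(b) -
      minima$log_freq_product
    m <- max(lw)
    m + log(sum(exp(lw - m)))
  }
  vapply(kbt, function(th) {
    b <- 1 / th
    h <- b * 2e-3
    d2 <- (-lnZ(b + 2 * h) + 16 * lnZ(b + h) - 30 * lnZ(b) +
             16 * lnZ(b - h) - lnZ(b - 2 * h)) / (12 * h^2)
    b^2 * d2
  }, numeric(1))
}

## Two-state configurational heat capacity, evaluated in the log domain
## (x^2 g e^x / (e^x + g)^2, overflow-safe formulation).
two_state_cv_oracle <- function(delta, kbt, g = 1) {
  x <- delta / kbt
  exp(2 * log(x) + log(g) - x - 2 * log1p(g * exp(-x)))
}

## Exhaustive simple-path enumeration for the pair-selection oracle:
## minimum-weight path in a complete graph with given symmetric weights
## (NA = forbidden edge).
brute_min_path <- function(W, source, sink) {
  n <- nrow(W)
  best <- list(cost = Inf, path = NULL)
  visit <- function(path, cost) {
    last <- path[length(path)]
    if (cost >= best$cost) return()
    if (last == sink) {
      best <<- list(cost = cost, path = path)
      return()
    }
    for (nx in setdiff(seq_len(n), path)) {
      w <- W[last, nx]
      if (is.na(w)) next
      visit(c(path, nx), cost + w)
    }
  }
  visit(source, 0)
  best
}

## Random abstract stationary-point database for partition/thermo tests:
## a random spanning tree plus extra edges, TS energies above both endpoints.
random_spdb <- function(n_min, n_extra_ts = n_min, seed = 1,
                        kappa = 3L) {
  set.seed(seed)
  minima <- data.frame(energy = stats::runif(n_min, 0, 2),
                       log_freq_product = stats::rnorm(n_min),
                       horder = sample(1:3, n_min, replace = TRUE))
  # ensure a unique global minimum
  i0 <- which.min(minima$energy)
  minima$energy[i0] <- minima$energy[i0] - 0.01
  edges <- list()
  if (n_min >= 2) {
    perm <- sample(n_min)
    for (k in 2:n_min) {
      edges[[length(edges) + 1L]] <- c(perm[k - 1], perm[k])
    }
    for (k in seq_len(n_extra_ts)) {
      ij <- sample(n_min, 2)
      edges[[length(edges) + 1L]] <- ij
    }
  }
  ts <- NULL
  if (length(edges)) {
    em <- do.call(rbind, edges)
    ts <- data.frame(
      energy = pmax(minima$energy[em[, 1]], minima$energy[em[, 2]]) +
        stats::runif(nrow(em), 0.05, 1.5),
      log_freq_product = stats::rnorm(nrow(em)),
      horder = 1, min1 = em[, 1], min2 = em[, 2])
  }
  spdb(minima, ts, kappa = kappa)
}

## Contact-free random chain configurations (non-adjacent pairs kept apart so
## the finite-difference comparison is not dominated by steep-contact
## truncation error).
random_chain_config <- function(n, min_sep = 1.0) {
  repeat {
    m <- matrix(0, n, 3)
    for (i in 2:n) {
      u <- stats::rnorm(3)
      m[i, ] <- m[i - 1, ] + u / sqrt(sum(u^2))
    }
    d <- as.matrix(stats::dist(m))
    d[abs(row(d) - col(d)) <= 1] <- Inf
    if (min(d) > min_sep) return(coords_flat(m))
  }
}

## Rodrigues rotation, used as the independent oracle for move-set tests.
rodrigues <- function(v, axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
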