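#' Finite-difference Hessian and normal-mode analysis
#'
#' The Hessian is built by central finite differences of the analytic gradient
#' (step 1e-5) and symmetrised; eigenvalues come from the dense symmetric
#' solver. Eigenvalues with |lambda| < `zero_tol` are treated as zero modes
#' (six are expected for 3D clusters and chains: translations plus rotations)
#' and excluded from the log frequency product. In reduced (unit-mass) units
#' the normal-mode frequency of mode i is proportional to sqrt(lambda_i), so
#' the log frequency product is 0.5 * sum(log(lambda_i)) over positive modes,
#' with constants common to all stationary points omitted.
#'
#' @param pot an `elcv_potential`.
#' @param x coordinates of a stationary point.
#' @param step finite-difference step.
#' @export
fd_hessian <- function(pot, x, step = 1e-5) {
  nd <- length(x)
  H <- matrix(0, nd, nd)
  for (i in seq_len(nd)) {
    xp <- x; xp[i] <- x[i] + step
    xm <- x; xm[i] <- x[i] - step
    H[i, ] <- (pot_eval(pot, xp)$gradient - pot_eval(pot, xm)$gradient) /
      (2 * step)
  }
  (H + t(H)) / 2
}

# Orthonormal basis of the rigid-body modes (3 translations + up to 3
# infinitesimal rotations about the centroid) for translation/rotation
# invariant 3D potentials; NULL for external potentials. Away from stationary
# points these modes are not exact Hessian eigenvectors, so they are removed
# by explicit projection rather than an eigenvalue threshold.
rigid_body_modes <- function(pot, x) {
  if (pot$name == "mueller_brown_2d") return(NULL)
  n <- pot$n_particles
  m <- coords_matrix(x, 3L)
  cm <- colMeans(m)
  rel <- sweep(m, 2, cm)
  modes <- list()
  for (k in 1:3) {
    v <- matrix(0, n, 3); v[, k] <- 1
    modes[[length(modes) + 1L]] <- coords_flat(v)
  }
  axes <- diag(3)
  for (k in 1:3) {
    v <- t(apply(rel, 1, function(r) pracma_cross3(axes[k, ], r)))
    modes[[length(modes) + 1L]] <- coords_flat(v)
  }
  U <- do.call(cbind, modes)
  # Gram-Schmidt, dropping degenerate rotations (e.g. linear configurations)
  out <- NULL
  for (j in seq_len(ncol(U))) {
    v <- U[, j]
    if (!is.null(out)) v <- v - out %*% crossprod(out, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) out <- cbind(out, v / nv)
  }
  out
}

pracma_cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Project the rigid-body subspace out of a Hessian, shifting it to a large
# positive eigenvalue so those modes are never selected or counted.
project_hessian <- function(H, U, shift = 1e6) {
  if (is.null(U)) return(list(H = H, n_rigid = 0L, shift = shift))
  P <- diag(nrow(H)) - tcrossprod(U)
  list(H = P %*% H %*% P + shift * tcrossprod(U), n_rigid = ncol(U),
       shift = shift)
}

#' @rdname fd_hessian
#' @param zero_tol residual eigenvalues with |lambda| below this are treated
#'   as zero modes after rigid-body projection.
#' @return `normal_mode_analysis`: list with `eigenvalues` (ascending, rigid
#'   modes removed), `n_negative`, `n_zero`, `log_freq_product` (over
#'   positive modes), and `lowest_mode` (eigenvector of the lowest remaining
#'   eigenvalue).
#' @export
normal_mode_analysis <- function(pot, x, step = 1e-5, zero_tol = 1e-6) {
  H <- fd_hessian(pot, x, step)
  pr <- project_hessian(H, rigid_body_modes(pot, x))
  eg <- eigen(pr$H, symmetric = TRUE)
  lam <- rev(eg$values)            # ascending
  vec <- eg$vectors[, rev(seq_along(eg$values)), drop = FALSE]
  keep <- lam < pr$shift / 2
  lam <- lam[keep]
  vec <- vec[, keep, drop = FALSE]
  zero <- abs(lam) < zero_tol
  neg <- lam < -zero_tol
  pos <- lam > zero_tol
  low_i <- which(!zero)[1]
  list(eigenvalues = lam,
       n_negative = sum(neg),
       n_zero = pr$n_rigid + sum(zero),
       log_freq_product = 0.5 * sum(log(lam[pos])),
       lowest_eigenvalue = lam[low_i],
       lowest_mode = vec[, low_i])
}

## ---- doubly nudged elastic band ------------------------------------------

dneb_tangent <- function(x_prev, x_i, x_next, e_prev, e_i, e_next) {
  tp <- x_next - x_i
  tm <- x_i - x_prev
  if (e_next > e_i && e_i > e_prev) {
    tau <- tp
  } else if (e_next < e_i && e_i < e_prev) {
    tau <- tm
  } else {
    dmax <- max(abs(e_next - e_i), abs(e_prev - e_i))
    dmin <- min(abs(e_next - e_i), abs(e_prev - e_i))
    tau <- if (e_next > e_prev) tp * dmax + tm * dmin else tp * dmin + tm * dmax
  }
  nt <- sqrt(sum(tau^2))
  if (nt < 1e-300) return(tau * 0)
  tau / nt
}

#' Doubly nudged elastic band between two minima
#'
#' Builds a linearly interpolated chain of `n_images` interior images between
#' the two endpoint minima and relaxes it under the doubly nudged force:
#' the perpendicular component of the true gradient, the parallel component
#' of the spring force, plus the portion of the perpendicular spring force
#' orthogonal to the perpendicular true-gradient direction. Returns the
#' interior images that are local maxima of energy along the relaxed band,
#' ordered along the path -- the candidate transition states.
#'
#' @param pot an `elcv_potential`.
#' @param min_a,min_b endpoint minima coordinates.
#' @param n_images number of interior images (>= 3).
#' @param k_spring spring constant.
#' @param max_iter relaxation iteration cap.
#' @param f_tol maximum force component below which the band is converged.
#' @return list with `candidates` (list of coordinate vectors),
#'   `band` (matrix of all images incl. endpoints), `energies`, `converged`.
#' @export
dneb <- function(pot, min_a, min_b, n_images = 11L, k_spring = 1,
                 max_iter = 1000L, f_tol = 1e-3) {
  stopifnot(n_images >= 3)
  nd <- length(min_a)
  if (sqrt(sum((min_a - min_b)^2)) < 1e-8) {
    return(list(candidates = list(), band = rbind(min_a, min_b),
                energies = c(pot_eval(pot, min_a)$energy,
                             pot_eval(pot, min_b)$energy),
                converged = TRUE))
  }
  nim <- n_images + 2L
  band <- matrix(0, nim, nd)
  for (i in seq_len(nim)) {
    f <- (i - 1) / (nim - 1)
    band[i, ] <- (1 - f) * min_a + f * min_b
  }
  band_force <- function(band) {
    ev <- lapply(seq_len(nim), function(i) pot_eval(pot, band[i, ]))
    E <- vapply(ev, `[[`, numeric(1), "energy")
    Fmat <- matrix(0, nim, nd)
    for (i in 2:(nim - 1)) {
      g <- ev[[i]]$gradient
      tau <- dneb_tangent(band[i - 1, ], band[i, ], band[i + 1, ],
                          E[i - 1], E[i], E[i + 1])
      g_perp <- g - sum(g * tau) * tau
      f_true <- -g_perp
      dp <- band[i + 1, ] - band[i, ]
      dm <- band[i, ] - band[i - 1, ]
      f_spring_par <- k_spring * (sqrt(sum(dp^2)) - sqrt(sum(dm^2))) * tau
      g_spring <- k_spring * (dp - dm)
      f_spring_perp <- g_spring - sum(g_spring * tau) * tau
      ng <- sqrt(sum(g_perp^2))
      if (ng > 1e-12) {
        u <- g_perp / ng
        f_dneb <- f_spring_perp - sum(f_spring_perp * u) * u
      } else f_dneb <- f_spring_perp
      Fmat[i, ] <- f_true + f_spring_par + f_dneb
    }
    list(F = Fmat, E = E)
  }
  # FIRE relaxation of the band (interior images only move)
  v <- matrix(0, nim, nd)
  dt <- 5e-3; dt_max <- 5e-2; a_start <- 0.1; a <- a_start; n_up <- 0L
  converged <- FALSE
  bf <- band_force(band)
  for (iter in seq_len(max_iter)) {
    fmax <- max(abs(bf$F))
    if (fmax < f_tol) { converged <- TRUE; break }
    P <- sum(bf$F * v)
    if (P > 0) {
      n_up <- n_up + 1L
      vn <- sqrt(sum(v^2)); fn <- sqrt(sum(bf$F^2))
      v <- (1 - a) * v + a * vn * bf$F / max(fn, 1e-300)
      if (n_up > 5L) { dt <- min(dt * 1.1, dt_max); a <- a * 0.99 }
    } else {
      v[] <- 0; dt <- dt * 0.5; a <- a_start; n_up <- 0L
    }
    v <- v + dt * bf$F
    step <- dt * v
    lim <- 0.1
    nrm <- sqrt(rowSums(step^2))
    scale <- ifelse(nrm > lim, lim / nrm, 1)
    band <- band + step * scale
    bf <- band_force(band)
  }
  ev <- lapply(seq_len(nim), function(i) pot_eval(pot, band[i, ]))
  E <- vapply(ev, `[[`, numeric(1), "energy")
  cand_idx <- (2:(nim - 1))[E[2:(nim - 1)] > E[1:(nim - 2)] &
                              E[2:(nim - 1)] > E[3:nim]]
  list(candidates = lapply(cand_idx, function(i) band[i, ]),
       band = band, energies = E, converged = converged)
}

## ---- hybrid eigenvector-following ----------------------------------------

#' Refine a candidate to an index-1 saddle by eigenvector-following
#'
#' Steps uphill along the lowest non-zero Hessian eigenmode while taking
#' Newton steps downhill in the orthogonal complement, with a trust-radius
#' cap, until the RMS gradient drops below `tol`. On convergence the Hessian
#' index is checked: exactly one negative non-zero eigenvalue is required;
#' convergence to a minimum or to a higher-index saddle raises a classed
#' error (`elcv_not_index1_error`).
#'
#' @param pot an `elcv_potential`.
#' @param candidate starting coordinates, assumed near an index-1 saddle.
#' @param tol RMS-gradient convergence criterion.
#' @param max_iter outer iteration cap.
#' @param trust maximum step norm.
#' @return list with `x`, `energy`, `log_freq_product` (positive modes),
#'   `lowest_eigenvalue`, `lowest_mode`, `rms_grad`.
#' @export
hybrid_ef_refine <- function(pot, candidate, tol = 1e-6, max_iter = 200L,
                             trust = 0.2) {
  x <- candidate
  zero_tol <- 1e-6
  v_prev <- NULL
  push_sign <- NULL
  for (iter in seq_len(max_iter)) {
    g <- pot_eval(pot, x)$gradient
    rms <- sqrt(mean(g^2))
    H <- fd_hessian(pot, x)
    pr <- project_hessian(H, rigid_body_modes(pot, x))
    eg <- eigen(pr$H, symmetric = TRUE)
    lam <- rev(eg$values)
    vec <- eg$vectors[, rev(seq_along(eg$values)), drop = FALSE]
    nz <- which(abs(lam) >= zero_tol & lam < pr$shift / 2)
    if (!length(nz)) stop("degenerate Hessian: all modes are zero modes",
                          call. = FALSE)
    low <- nz[1]
    v <- vec[, low]
    if (!is.null(v_prev) && sum(v * v_prev) < 0) v <- -v  # mode continuity
    v_prev <- v
    if (rms <= tol) {
      n_negative <- sum(lam < -zero_tol)
      if (n_negative == 1L) {
        nma <- normal_mode_analysis(pot, x)
        return(list(x = x, energy = pot_eval(pot, x)$energy,
                    log_freq_product = nma$log_freq_product,
                    lowest_eigenvalue = lam[low],
                    lowest_mode = v, rms_grad = rms))
      }
      msg <- if (n_negative == 0L) "converged to a minimum" else
        sprintf("converged to an index-%d saddle", n_negative)
      stop(structure(class = c("elcv_not_index1_error", "error", "condition"),
                     list(message = msg, call = NULL)))
    }
    gv <- sum(g * v)
    dv <- if (lam[low] < 0) {
      gv / abs(lam[low])     # Newton step toward the saddle along the mode
    } else {
      # still in a convex region: keep climbing uphill along the soft mode
      # with a floor on the step so the walk cannot stall at a minimum
      if (is.null(push_sign)) push_sign <- if (gv >= 0) 1 else -1
      push_sign * max(abs(gv) / lam[low], 0.05)
    }
    delta <- dv * v
    for (i in setdiff(nz, low)) {
      gi <- sum(g * vec[, i])
      delta <- delta - gi / abs(lam[i]) * vec[, i]
    }
    nrm <- sqrt(sum(delta^2))
    if (nrm > trust) delta <- delta * (trust / nrm)
    x <- x + delta
  }
  stop("eigenvector-following did not converge within the iteration budget",
       call. = FALSE)
}

#' Descend from a transition state on both sides
#'
#' Starts two minimisations at +/- `displacement` along the transition state's
#' negative-eigenvalue mode and quenches each to a minimum.
#'
#' @param pot an `elcv_potential`.
#' @param ts result of [hybrid_ef_refine()] (needs `x` and `lowest_mode`).
#' @param displacement step along the mode (> 0).
#' @param rms_tol quench tolerance.
#' @param sd_steps,sd_step_size fine steepest-descent steps taken before the
#'   quasi-Newton quench, so each descent stays in the basin its
#'   steepest-descent path enters rather than hopping past an intermediate
#'   minimum.
#' @return list with `min1`, `min2` (quench results) and `degenerate`
#'   (TRUE when both descents reach the same minimum).
#' @export
descend_both_sides <- function(pot, ts, displacement = 0.01, rms_tol = 1e-6,
                               sd_steps = 200L, sd_step_size = 0.01) {
  if (!(displacement > 0))
    stop("displacement must be positive to break symmetry", call. = FALSE)
  v <- ts$lowest_mode
  sd_descent <- function(x) {
    for (i in seq_len(sd_steps)) {
      g <- pot_eval(pot, x)$gradient
      ng <- sqrt(sum(g^2))
      if (ng < rms_tol) break
      x <- x - g * (min(sd_step_size, ng) / ng)
    }
    x
  }
  q1 <- quench(pot, sd_descent(ts$x + displacement * v), rms_tol)
  q2 <- quench(pot, sd_descent(ts$x - displacement * v), rms_tol)
  if (!q1$converged || !q2$converged)
    stop("descent from the transition state failed to converge", call. = FALSE)
  degen <- abs(q1$energy - q2$energy) < 1e-6 &&
    aligned_rmsd(q1$x, q2$x, pot$dim) < 1e-3
  list(min1 = q1, min2 = q2, degenerate = degen)
}

## ---- pair selection and database growth ----------------------------------

# Hand-rolled union-find; also used by the superbasin analysis.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(as.integer(edges[k, 1])); b <- find(as.integer(edges[k, 2]))
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  # deterministic labels: smallest member id of each component
  as.integer(stats::ave(seq_len(n), roots, FUN = min))
}

#' Select the next pair of minima to attempt to connect
#'
#' Builds a complete graph over the minima in which pairs already connected by
#' a transition state have weight 0 and unconnected pairs a weight increasing
#' with structural distance (best-aligned RMSD squared); pairs recorded as
#' failed in `attempt_history` are removed. The minimum-weight path between
#' `source_id` and `sink_id` is found with Dijkstra's algorithm and the first
#' unconnected pair along it is returned.
#'
#' @param db an `elcv_spdb` with coordinates.
#' @param source_id,sink_id endpoint minimum ids.
#' @param attempt_history data frame with columns `min1`, `min2`, `status`
#'   ("failed" rows are excluded from the graph); may be NULL.
#' @param dim spatial dimensionality for the alignment.
#' @return list with `status` ("connected", "pair", or "exhausted") and,
#'   for "pair", the ids `pair = c(i, j)`.
#' @export
select_next_pair <- function(db, source_id, sink_id, attempt_history = NULL,
                             dim = 3L) {
  n <- n_minima(db)
  stopifnot(source_id >= 1, source_id <= n, sink_id >= 1, sink_id <= n)
  if (is.null(db$coords)) stop("database carries no coordinates", call. = FALSE)
  conn <- matrix(FALSE, n, n)
  if (nrow(db$ts)) {
    for (k in seq_len(nrow(db$ts))) {
      conn[db$ts$min1[k], db$ts$min2[k]] <- TRUE
      conn[db$ts$min2[k], db$ts$min1[k]] <- TRUE
    }
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- if (conn[i, j]) 0 else
        aligned_rmsd(db$coords[[i]], db$coords[[j]], dim)^2
      W[i, j] <- w; W[j, i] <- w
    }
  }
  if (!is.null(attempt_history) && nrow(attempt_history)) {
    failed <- attempt_history[attempt_history$status == "failed", , drop = FALSE]
    for (k in seq_len(nrow(failed))) {
      i <- failed$min1[k]; j <- failed$min2[k]
      if (!conn[i, j]) { W[i, j] <- NA; W[j, i] <- NA }
    }
  }
  # explicit edge list (an adjacency matrix would drop the 0-weight edges of
  # already-connected pairs); failed pairs are simply absent
  pairs <- which(upper.tri(W) & !is.na(W), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs)) {
    g <- igraph::add_edges(g, t(pairs))
    igraph::E(g)$weight <- W[pairs]
  }
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = source_id, to = sink_id, weights = igraph::E(g)$weight,
    output = "vpath"))
  path <- as.integer(sp$vpath[[1]])
  if (length(path) < 2) {
    if (source_id == sink_id) return(list(status = "connected"))
    return(list(status = "exhausted"))
  }
  for (k in seq_len(length(path) - 1)) {
    i <- path[k]; j <- path[k + 1]
    if (!conn[i, j]) return(list(status = "pair", pair = c(i, j)))
  }
  list(status = "connected")
}

match_or_add_minimum <- function(minima, coords, q, pot, e_tol = 1e-6,
                                 rmsd_tol = 1e-3) {
  for (i in seq_along(coords)) {
    if (abs(minima$energy[i] - q$energy) < e_tol &&
        aligned_rmsd(coords[[i]], q$x, pot$dim) < rmsd_tol) {
      return(list(id = i, minima = minima, coords = coords))
    }
  }
  nma <- normal_mode_analysis(pot, q$x)
  minima <- rbind(minima, data.frame(energy = q$energy,
                                     log_freq_product = nma$log_freq_product,
                                     horder = 1))
  coords[[length(coords) + 1L]] <- q$x
  list(id = nrow(minima), minima = minima, coords = coords)
}

#' Grow a connected stationary-point database
#'
#' Iterates pair selection (Dijkstra shortest-gap), doubly nudged elastic band
#' seeding, hybrid eigenvector-following refinement, and two-sided descent
#' until the two endpoint minima are connected or the attempt budget is
#' exhausted. Individual attempt failures are recorded and the loop continues.
#'
#' @param pot an `elcv_potential`.
#' @param initial list of >= 2 starting minima coordinate vectors (they are
#'   tightly quenched on entry).
#' @param budget maximum number of connection attempts.
#' @param n_images,k_spring DNEB parameters.
#' @param rms_tol convergence criterion for minima and transition states.
#' @return an `elcv_spdb` with coordinates for minima and transition states.
#' @export
grow_database <- function(pot, initial, budget = 20L, n_images = 11L,
                          k_spring = 1, rms_tol = 1e-6) {
  stopifnot(length(initial) >= 2)
  minima <- data.frame(energy = numeric(0), log_freq_product = numeric(0),
                       horder = numeric(0))
  coords <- list()
  for (x0 in initial) {
    q <- quench(pot, x0, rms_tol)
    if (!q$converged) stop("initial minimum failed to quench", call. = FALSE)
    res <- match_or_add_minimum(minima, coords, q, pot)
    minima <- res$minima; coords <- res$coords
  }
  ts <- data.frame(energy = numeric(0), log_freq_product = numeric(0),
                   horder = numeric(0), min1 = integer(0), min2 = integer(0))
  ts_coords <- list()
  history <- data.frame(min1 = integer(0), min2 = integer(0),
                        status = character(0))
  add_ts <- function(ref, i1, i2) {
    dup <- which(abs(ts$energy - ref$energy) < 1e-6 &
                   ((ts$min1 == i1 & ts$min2 == i2) |
                      (ts$min1 == i2 & ts$min2 == i1)))
    if (length(dup)) return(FALSE)
    ts <<- rbind(ts, data.frame(energy = ref$energy,
                                log_freq_product = ref$log_freq_product,
                                horder = 1, min1 = i1, min2 = i2))
    ts_coords[[length(ts_coords) + 1L]] <<- ref$x
    TRUE
  }
  db_now <- function() spdb(minima, if (nrow(ts)) ts else NULL,
                            kappa = kappa_of(pot), coords = coords,
                            ts_coords = if (length(ts_coords)) ts_coords)
  for (attempt in seq_len(budget)) {
    sel <- select_next_pair(db_now(), 1L, 2L, history, dim = pot$dim)
    if (sel$status != "pair") break
    i <- sel$pair[1]; j <- sel$pair[2]
    nb <- dneb(pot, coords[[i]], coords[[j]], n_images = n_images,
               k_spring = k_spring)
    added <- FALSE
    for (cand in nb$candidates) {
      ref <- tryCatch(hybrid_ef_refine(pot, cand, tol = rms_tol),
                      error = function(e) NULL)
      if (is.null(ref)) {
        # candidate relaxed into a basin instead: keep the intermediate
        # minimum, it refines later pair selections
        q <- tryCatch(quench(pot, cand, rms_tol), error = function(e) NULL)
        if (!is.null(q) && q$converged) {
          r <- match_or_add_minimum(minima, coords, q, pot)
          minima <- r$minima; coords <- r$coords
        }
        next
      }
      dsc <- tryCatch(descend_both_sides(pot, ref, rms_tol = rms_tol),
                      error = function(e) NULL)
      if (is.null(dsc)) next
      r1 <- match_or_add_minimum(minima, coords, dsc$min1, pot)
      minima <- r1$minima; coords <- r1$coords
      r2 <- match_or_add_minimum(minima, coords, dsc$min2, pot)
      minima <- r2$minima; coords <- r2$coords
      if (add_ts(ref, r1$id, r2$id)) added <- TRUE
    }
    history <- rbind(history,
                     data.frame(min1 = i, min2 = j,
                                status = if (added) "connected" else "failed"))
  }
  db_now()
}

#' Connected components of a database's connectivity graph
#'
#' Union-find over the transition-state edges; labels are the smallest member
#' id of each component.
#' @param db an `elcv_spdb`.
#' @export
db_components <- function(db) {
  edges <- if (nrow(db$ts)) cbind(db$ts$min1, db$ts$min2) else
    matrix(integer(0), ncol = 2)
  uf_components(n_minima(db), edges)
}
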