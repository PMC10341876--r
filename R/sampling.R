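#' Basin-hopping configuration objects
#'
#' `bh_config` collects the knobs of a single basin-hopping run: step count,
#' Metropolis temperature (in energy units, interpreted as kT), maximum
#' Cartesian step, seed, the size of the lowest-energy pool kept, and the
#' loose/tight RMS-gradient tolerances. Production-scale landscape exploration
#' of peptide dimers uses 6e5-8e5 basin-hopping steps accumulated over several
#' runs; desk-scale runs here default to far fewer.
#'
#' `move_schedule` describes the move mix: a rigid-body dimer move is performed
#' after every `cartesian_per_rigid` Cartesian moves (default 111), group
#' rotations are attempted with probability `group_rotation_probability` on
#' chain systems, and the rigid-body move is parameterised by a radial
#' expansion factor about the overall centroid, an angle-axis rotation
#' magnitude, and a translation size.
#'
#' @param n_steps number of basin-hopping steps (>= 1).
#' @param temperature Metropolis temperature on quenched energies (> 0).
#' @param max_step_size maximum per-coordinate Cartesian displacement (>= 0).
#' @param seed integer RNG seed; the run is fully reproducible from it.
#' @param keep_lowest capacity of the lowest-energy pool (default 1000).
#' @param loose_rms_tol RMS-gradient tolerance for in-run quenches.
#' @param tight_rms_tol tolerance for the final tight refinement (default 1e-7).
#' @export
bh_config <- function(n_steps, temperature, max_step_size = 0.4, seed = 1L,
                      keep_lowest = 1000L, loose_rms_tol = 1e-4,
                      tight_rms_tol = 1e-7) {
  stopifnot(n_steps >= 1, temperature > 0, max_step_size >= 0,
            keep_lowest >= 1, tight_rms_tol < loose_rms_tol)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 max_step_size = max_step_size, seed = as.integer(seed),
                 keep_lowest = as.integer(keep_lowest),
                 loose_rms_tol = loose_rms_tol, tight_rms_tol = tight_rms_tol),
            class = "elcv_bh_config")
}

#' @rdname bh_config
#' @param cartesian_per_rigid Cartesian moves between rigid-body dimer moves.
#' @param rigid_translation_size,rigid_rotation_size,radial_expansion_factor
#'   rigid-body move parameters.
#' @param group_rotation_probability probability of a group-rotation move.
#' @export
move_schedule <- function(cartesian_per_rigid = 111L,
                          rigid_translation_size = 0.3,
                          rigid_rotation_size = 0.5,
                          radial_expansion_factor = 1.05,
                          group_rotation_probability = 0) {
  stopifnot(cartesian_per_rigid >= 1, rigid_translation_size > 0,
            rigid_rotation_size > 0, radial_expansion_factor > 0,
            group_rotation_probability >= 0, group_rotation_probability <= 1)
  structure(list(cartesian_per_rigid = as.integer(cartesian_per_rigid),
                 rigid_translation_size = rigid_translation_size,
                 rigid_rotation_size = rigid_rotation_size,
                 radial_expansion_factor = radial_expansion_factor,
                 group_rotation_probability = group_rotation_probability),
            class = "elcv_move_schedule")
}

#' @rdname bh_config
#' @param n_replicas number of replicas (>= 2; default 16).
#' @param T_min,T_max temperature range; replicas are geometrically
#'   (exponentially) distributed between them (defaults 300 and 575).
#' @param exchange_interval basin-hopping steps between replica-exchange
#'   attempts.
#' @param base a `bh_config` giving per-replica step counts and tolerances.
#' @export
bhpt_config <- function(n_replicas = 16L, T_min = 300, T_max = 575,
                        exchange_interval = 10L, base) {
  stopifnot(n_replicas >= 2, T_min > 0, T_max > T_min, exchange_interval >= 1,
            inherits(base, "elcv_bh_config"))
  structure(list(n_replicas = as.integer(n_replicas), T_min = T_min,
                 T_max = T_max, exchange_interval = as.integer(exchange_interval),
                 base = base),
            class = "elcv_bhpt_config")
}

#' Exponentially distributed temperature schedule
#'
#' Geometric progression from `T_min` to `T_max`: consecutive temperatures
#' have a constant ratio, i.e. T_i = T_min * (T_max/T_min)^(i/(n-1)).
#' @param T_min,T_max positive temperature bounds, T_min < T_max.
#' @param n number of temperatures (>= 2).
#' @export
temperature_schedule <- function(T_min, T_max, n) {
  if (!(n >= 2)) stop("need at least 2 temperatures", call. = FALSE)
  if (!(T_min > 0 && T_max > T_min))
    stop("require 0 < T_min < T_max", call. = FALSE)
  T_min * (T_max / T_min)^((seq_len(n) - 1) / (n - 1))
}

## ---- minima pool ---------------------------------------------------------

#' Lowest-energy minima pool
#'
#' An ordered, deduplicated container of (energy, configuration) pairs with a
#' capacity: insertion keeps the list sorted ascending by energy, drops
#' near-duplicates (energy within `e_tol` and best-aligned RMSD within
#' `rmsd_tol`), and trims to the `keep_lowest` capacity.
#'
#' @param capacity maximum number of entries kept.
#' @param dim spatial dimensionality of the stored configurations.
#' @param e_tol,rmsd_tol deduplication tolerances.
#' @export
minima_pool <- function(capacity, dim = 3L, e_tol = 1e-6, rmsd_tol = 1e-3) {
  stopifnot(capacity >= 1)
  structure(list(energies = numeric(0), coords = list(),
                 capacity = as.integer(capacity), dim = as.integer(dim),
                 e_tol = e_tol, rmsd_tol = rmsd_tol),
            class = "elcv_minima_pool")
}

#' @rdname minima_pool
#' @param pool a minima pool.
#' @param energy,x the quenched energy and configuration to insert.
#' @export
pool_insert <- function(pool, energy, x) {
  near <- which(abs(pool$energies - energy) < pool$e_tol)
  for (i in near) {
    if (aligned_rmsd(pool$coords[[i]], x, pool$dim) < pool$rmsd_tol) {
      return(pool)  # duplicate
    }
  }
  pos <- findInterval(energy, pool$energies) + 1L
  pool$energies <- append(pool$energies, energy, after = pos - 1L)
  pool$coords <- append(pool$coords, list(x), after = pos - 1L)
  if (length(pool$energies) > pool$capacity) {
    keep <- seq_len(pool$capacity)
    pool$energies <- pool$energies[keep]
    pool$coords <- pool$coords[keep]
  }
  pool
}

#' @rdname minima_pool
#' @export
pool_size <- function(pool) length(pool$energies)

#' @export
print.elcv_minima_pool <- function(x, ...) {
  cat(sprintf("<minima pool: %d/%d entries%s>\n", pool_size(x), x$capacity,
              if (pool_size(x)) sprintf(", lowest %.6f", x$energies[1]) else ""))
  invisible(x)
}

pool_merge <- function(a, b) {
  for (i in seq_along(b$energies)) a <- pool_insert(a, b$energies[i], b$coords[[i]])
  a
}

## ---- moves ---------------------------------------------------------------

rotation_matrix_aa <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-300) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rigid-body dimer move
#'
#' Moves each of two rigid monomers as a unit: the monomer centroids are
#' expanded radially away from the overall centroid by `radial_expansion_factor`,
#' each monomer is rotated about its own centroid by an angle-axis vector, and
#' translated. Internal monomer geometry is preserved exactly. Random draws use
#' the current RNG state; explicit `rotations`/`translations`/`expansion` make
#' the move deterministic for testing.
#'
#' @param x flat 3D coordinates.
#' @param monomers list of two disjoint particle index vectors covering all
#'   particles.
#' @param schedule a `move_schedule`.
#' @param rotations optional list of two angle-axis vectors.
#' @param translations optional list of two translation vectors.
#' @param expansion optional radial expansion factor override.
#' @export
dimer_move <- function(x, monomers, schedule = move_schedule(),
                       rotations = NULL, translations = NULL,
                       expansion = NULL) {
  n <- length(x) / 3
  idx_all <- sort(c(monomers[[1]], monomers[[2]]))
  if (length(monomers) != 2 || anyDuplicated(c(monomers[[1]], monomers[[2]])) ||
      !identical(idx_all, seq_len(n)))
    stop("monomer index sets must be disjoint and cover all particles",
         call. = FALSE)
  m <- coords_matrix(x, 3L)
  centre <- colMeans(m)
  fac <- if (is.null(expansion)) schedule$radial_expansion_factor else expansion
  for (k in 1:2) {
    idx <- monomers[[k]]
    sub <- m[idx, , drop = FALSE]
    cm <- colMeans(sub)
    new_cm <- centre + fac * (cm - centre)
    rot <- if (is.null(rotations)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      u * stats::runif(1, 0, schedule$rigid_rotation_size)
    } else rotations[[k]]
    tr <- if (is.null(translations)) {
      stats::runif(3, -1, 1) * schedule$rigid_translation_size
    } else translations[[k]]
    R <- rotation_matrix_aa(rot)
    sub <- sweep(sub, 2, cm)
    sub <- sub %*% t(R)
    sub <- sweep(sub, 2, new_cm + tr, FUN = "+")
    m[idx, ] <- sub
  }
  coords_flat(m)
}

#' Group-rotation move for chain systems
#'
#' Rotates a contiguous tail segment (beads `pivot+1` to the end) about the
#' axis of the bond preceding the pivot bead, by Rodrigues rotation. Bond
#' lengths within the segment are preserved exactly.
#'
#' @param x flat 3D chain coordinates.
#' @param n_beads number of beads (>= 4).
#' @param pivot pivot bead index in `2:(n_beads-1)`; drawn at random if NULL.
#' @param angle rotation angle in radians; drawn uniform in (-pi, pi] if NULL.
#' @export
group_rotation_move <- function(x, n_beads, pivot = NULL, angle = NULL) {
  if (n_beads < 4) stop("chain too short for a group rotation", call. = FALSE)
  if (is.null(pivot)) pivot <- sample(2:(n_beads - 1), 1)
  if (pivot < 2 || pivot > n_beads - 1)
    stop("pivot must be an interior bead", call. = FALSE)
  if (is.null(angle)) angle <- stats::runif(1, -pi, pi)
  m <- coords_matrix(x, 3L)
  axis <- m[pivot, ] - m[pivot - 1, ]
  la <- sqrt(sum(axis^2))
  if (la < 1e-12) stop("degenerate bond axis", call. = FALSE)
  R <- rotation_matrix_aa(axis / la * angle)
  tail_idx <- (pivot + 1):n_beads
  sub <- sweep(m[tail_idx, , drop = FALSE], 2, m[pivot, ])
  m[tail_idx, ] <- sweep(sub %*% t(R), 2, m[pivot, ], FUN = "+")
  coords_flat(m)
}

#' Replica-exchange acceptance probability on quenched energies
#'
#' Standard Metropolis criterion for swapping configurations between two
#' temperatures: min(1, exp((1/T1 - 1/T2) (E1 - E2))).
#' @param E1,E2 quenched energies of the two replicas.
#' @param T1,T2 their temperatures.
#' @export
exchange_acceptance <- function(E1, E2, T1, T2) {
  min(1, exp((1 / T1 - 1 / T2) * (E1 - E2)))
}

## ---- basin-hopping -------------------------------------------------------

propose_move <- function(pot, x, moveset, cfg, step_index, monomers, chain) {
  if (!is.null(monomers) && step_index %% moveset$cartesian_per_rigid == 0L) {
    return(dimer_move(x, monomers, moveset))
  }
  if (chain && moveset$group_rotation_probability > 0 &&
      stats::runif(1) < moveset$group_rotation_probability) {
    return(group_rotation_move(x, pot$n_particles))
  }
  x + stats::runif(length(x), -cfg$max_step_size, cfg$max_step_size)
}

#' Basin-hopping global optimisation
#'
#' Proposes a move, quenches to the nearest local minimum at the loose
#' tolerance, and accepts or rejects on quenched energies with a Metropolis
#' rule at `cfg$temperature`. Every successfully quenched minimum is offered to
#' the lowest-energy pool. Fully reproducible from `cfg$seed`.
#'
#' @param pot an `elcv_potential`.
#' @param start starting configuration.
#' @param moveset a `move_schedule`.
#' @param cfg a `bh_config`.
#' @param monomers optional list of two particle index sets; when given,
#'   rigid-body dimer moves are interleaved every
#'   `moveset$cartesian_per_rigid` steps.
#' @param progress_every log a summary to stderr every this many steps
#'   (0 disables).
#' @return list with `pool` (a `minima_pool`) and `stats` (acceptance counts).
#' @export
basin_hop <- function(pot, start, moveset = move_schedule(), cfg,
                      monomers = NULL, progress_every = 0L) {
  stopifnot(inherits(cfg, "elcv_bh_config"))
  set.seed(cfg$seed)
  chain <- pot$name == "bead_chain"
  q <- quench(pot, start, cfg$loose_rms_tol)
  if (!q$converged) stop("starting configuration failed to quench", call. = FALSE)
  x <- q$x; E <- q$energy
  pool <- minima_pool(cfg$keep_lowest, dim = pot$dim)
  pool <- pool_insert(pool, E, x)
  n_acc <- 0L; n_fail <- 0L
  for (s in seq_len(cfg$n_steps)) {
    prop <- propose_move(pot, x, moveset, cfg, s, monomers, chain)
    qn <- tryCatch(quench(pot, prop, cfg$loose_rms_tol),
                   error = function(e) NULL)
    if (is.null(qn) || !qn$converged) { n_fail <- n_fail + 1L; next }
    pool <- pool_insert(pool, qn$energy, qn$x)
    if (qn$energy <= E ||
        stats::runif(1) < exp(-(qn$energy - E) / cfg$temperature)) {
      x <- qn$x; E <- qn$energy; n_acc <- n_acc + 1L
    }
    if (progress_every > 0L && s %% progress_every == 0L) {
      message(sprintf(
        "[basin_hop] step %d/%d: current E %.6f, lowest %.6f, acc %.2f",
        s, cfg$n_steps, E, pool$energies[1], n_acc / s))
    }
  }
  list(pool = pool,
       stats = list(n_steps = cfg$n_steps, n_accepted = n_acc,
                    n_quench_failures = n_fail,
                    acceptance_rate = n_acc / cfg$n_steps))
}

#' Basin-hopping parallel tempering
#'
#' Runs `n_replicas` basin-hopping chains at temperatures exponentially
#' distributed between `T_min` and `T_max`, with Metropolis replica-exchange
#' swaps of adjacent temperature pairs every `exchange_interval` steps.
#' Replicas execute sequentially; the merged, deduplicated pool is returned.
#'
#' @param pot an `elcv_potential`.
#' @param starts a single configuration shared by all replicas, or a list of
#'   one start per replica.
#' @param moveset a `move_schedule`.
#' @param cfg a `bhpt_config`.
#' @param monomers as in [basin_hop()].
#' @return list with `pool`, `temperatures`, and `stats` (per-replica
#'   acceptance and swap counts).
#' @export
bhpt <- function(pot, starts, moveset = move_schedule(), cfg, monomers = NULL) {
  stopifnot(inherits(cfg, "elcv_bhpt_config"))
  base <- cfg$base
  temps <- temperature_schedule(cfg$T_min, cfg$T_max, cfg$n_replicas)
  if (!is.list(starts)) starts <- rep(list(starts), cfg$n_replicas)
  stopifnot(length(starts) == cfg$n_replicas)
  set.seed(base$seed)
  chain <- pot$name == "bead_chain"
  xs <- vector("list", cfg$n_replicas)
  Es <- numeric(cfg$n_replicas)
  for (i in seq_len(cfg$n_replicas)) {
    q <- quench(pot, starts[[i]], base$loose_rms_tol)
    xs[[i]] <- q$x; Es[i] <- q$energy
  }
  pool <- minima_pool(base$keep_lowest, dim = pot$dim)
  for (i in seq_len(cfg$n_replicas)) pool <- pool_insert(pool, Es[i], xs[[i]])
  n_acc <- integer(cfg$n_replicas)
  n_swap_acc <- 0L; n_swap_try <- 0L
  n_rounds <- ceiling(base$n_steps / cfg$exchange_interval)
  step_count <- integer(cfg$n_replicas)
  for (round in seq_len(n_rounds)) {
    for (i in seq_len(cfg$n_replicas)) {
      for (k in seq_len(min(cfg$exchange_interval,
                            base$n_steps - step_count[i]))) {
        step_count[i] <- step_count[i] + 1L
        prop <- propose_move(pot, xs[[i]], moveset, base, step_count[i],
                             monomers, chain)
        qn <- tryCatch(quench(pot, prop, base$loose_rms_tol),
                       error = function(e) NULL)
        if (is.null(qn) || !qn$converged) next
        pool <- pool_insert(pool, qn$energy, qn$x)
        if (qn$energy <= Es[i] ||
            stats::runif(1) < exp(-(qn$energy - Es[i]) / temps[i])) {
          xs[[i]] <- qn$x; Es[i] <- qn$energy; n_acc[i] <- n_acc[i] + 1L
        }
      }
    }
    for (i in seq_len(cfg$n_replicas - 1L)) {
      n_swap_try <- n_swap_try + 1L
      if (stats::runif(1) < exchange_acceptance(Es[i], Es[i + 1], temps[i],
                                                temps[i + 1])) {
        tmp <- xs[[i]]; xs[[i]] <- xs[[i + 1]]; xs[[i + 1]] <- tmp
        tmpE <- Es[i]; Es[i] <- Es[i + 1]; Es[i + 1] <- tmpE
        n_swap_acc <- n_swap_acc + 1L
      }
    }
  }
  list(pool = pool, temperatures = temps,
       stats = list(n_accepted = n_acc, n_swaps_attempted = n_swap_try,
                    n_swaps_accepted = n_swap_acc))
}

#' Tight refinement of a minima pool
#'
#' Re-minimises every pool entry to the tight RMS-gradient criterion
#' (default 1e-7) and re-deduplicates; entries that merge under refinement
#' collapse to one, and entries that fail to converge within the iteration
#' budget are dropped with a warning.
#'
#' @param pool a `minima_pool` of loosely converged minima.
#' @param pot the potential they belong to.
#' @param tol tight RMS-gradient tolerance.
#' @export
tight_converge <- function(pool, pot, tol = 1e-7) {
  out <- minima_pool(pool$capacity, dim = pool$dim,
                     e_tol = pool$e_tol, rmsd_tol = pool$rmsd_tol)
  dropped <- 0L
  for (i in seq_along(pool$energies)) {
    q <- tryCatch(quench(pot, pool$coords[[i]], tol), error = function(e) NULL)
    if (is.null(q) || !q$converged) { dropped <- dropped + 1L; next }
    out <- pool_insert(out, q$energy, q$x)
  }
  if (dropped > 0L)
    warning(sprintf("%d pool entr%s failed tight convergence and were dropped",
                    dropped, if (dropped == 1) "y" else "ies"), call. = FALSE)
  out
}
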