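#' @useDynLib elcv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Toy potentials
#'
#' Differentiable test potentials used to exercise the sampling and
#' transition-state machinery at desk scale: the two-dimensional Mueller-Brown
#' surface, Lennard-Jones atomic clusters in reduced units
#' (\eqn{\epsilon = \sigma = 1}), and a coarse-grained bead-chain peptide model
#' (harmonic bonds, cosine-series backbone dihedrals, Lennard-Jones attraction
#' between beads at least three bonds apart). All energies and lengths are in
#' reduced units.
#'
#' The bead-chain defaults place dihedral minima both near the trans (extended)
#' and gauche (compact) regions, and the nonbonded attraction stabilises
#' compact conformations, so the chain has at least two distinct backbone
#' basins -- an analogue, at toy scale, of the hairpin-versus-helix competition
#' seen in hexapeptide landscapes.
#'
#' @param n_particles number of atoms in the cluster (>= 2).
#' @param n_beads number of beads in the chain (>= 4, so a dihedral exists).
#' @param k_bond harmonic bond stiffness.
#' @param r0 equilibrium bond length.
#' @param dihedral_amp,dihedral_mult,dihedral_phase cosine-series dihedral
#'   parameters: each term contributes
#'   \eqn{A_m (1 + \cos(m\phi - \gamma_m))}.
#' @param k_angle,theta0 bond-angle stiffness and equilibrium angle (degrees)
#'   of the harmonic-cosine angle term \eqn{k_a (\cos\theta - \cos\theta_0)^2/2},
#'   which keeps bends away from collinearity where the torsion is undefined.
#' @param eps_nb,sigma_nb nonbonded Lennard-Jones well depth and size.
#' @param nb_min_sep minimum bond separation for the nonbonded term
#'   (default 3).
#' @return an object of class `elcv_potential`.
#' @examples
#' pot <- potential_lj(7)
#' x <- random_cluster_config(pot, seed = 1)
#' pot_eval(pot, x)$energy
#' @name toy_potentials
NULL

new_potential <- function(name, n_particles, dim, params) {
  stopifnot(is.character(name), n_particles >= 1, dim %in% c(2L, 3L))
  structure(list(name = name, n_particles = as.integer(n_particles),
                 dim = as.integer(dim), params = params),
            class = c(paste0("elcv_", name), "elcv_potential"))
}

#' @rdname toy_potentials
#' @export
potential_mueller_brown <- function() {
  params <- list(
    A = c(-200, -100, -170, 15),
    a = c(-1, -1, -6.5, 0.7),
    b = c(0, 0, 11, 0.6),
    cc = c(-10, -10, -6.5, 0.7),
    x0 = c(1, 0, -0.5, -1),
    y0 = c(0, 0.5, 1.5, 1))
  new_potential("mueller_brown_2d", 1L, 2L, params)
}

#' @rdname toy_potentials
#' @export
potential_lj <- function(n_particles) {
  if (n_particles < 2) stop("LJ cluster needs at least 2 particles", call. = FALSE)
  new_potential("lj_cluster", n_particles, 3L, list(eps = 1, sigma = 1))
}

#' @rdname toy_potentials
#' @export
potential_bead_chain <- function(n_beads,
                                 k_bond = 100, r0 = 1,
                                 k_angle = 20, theta0 = 109.5,
                                 dihedral_amp = c(0.2, 0.4),
                                 dihedral_mult = c(1L, 3L),
                                 dihedral_phase = c(0, 0),
                                 eps_nb = 0.4, sigma_nb = 1,
                                 nb_min_sep = 3L) {
  if (n_beads < 4) stop("bead chain needs at least 4 beads", call. = FALSE)
  stopifnot(all(is.finite(c(k_bond, r0, k_angle, theta0, dihedral_amp,
                            dihedral_phase, eps_nb, sigma_nb))),
            length(dihedral_amp) == length(dihedral_mult),
            length(dihedral_amp) == length(dihedral_phase))
  new_potential("bead_chain", n_beads, 3L,
                list(k_bond = k_bond, r0 = r0,
                     k_angle = k_angle, cos0 = cos(theta0 * pi / 180),
                     dihedral_amp = dihedral_amp,
                     dihedral_mult = as.integer(dihedral_mult),
                     dihedral_phase = dihedral_phase,
                     eps_nb = eps_nb, sigma_nb = sigma_nb,
                     nb_min_sep = as.integer(nb_min_sep)))
}

#' @export
print.elcv_potential <- function(x, ...) {
  cat(sprintf("<elcv potential '%s': %d particle(s), %dD, %d dof>\n",
              x$name, x$n_particles, x$dim, n_dof(x)))
  invisible(x)
}

#' Number of coordinates of a potential's configuration vector
#' @param pot an `elcv_potential`.
#' @export
n_dof <- function(pot) pot$n_particles * pot$dim

#' Vibrational degrees of freedom (zero modes removed)
#'
#' For 3D many-particle systems the six rigid-body modes (three translations,
#' three rotations) are removed; the Mueller-Brown surface is an external 2D
#' potential with no zero modes.
#' @param pot an `elcv_potential`.
#' @export
kappa_of <- function(pot) {
  if (pot$name == "mueller_brown_2d") return(2L)
  as.integer(3L * pot$n_particles - 6L)
}

check_config <- function(pot, x) {
  if (!is.numeric(x) || length(x) != n_dof(pot))
    stop(sprintf("configuration has length %d, expected %d for '%s'",
                 length(x), n_dof(pot), pot$name), call. = FALSE)
  if (!all(is.finite(x)))
    stop("configuration contains non-finite coordinates", call. = FALSE)
  invisible(TRUE)
}

coincident_error <- function(rmin) {
  stop(structure(class = c("elcv_coincident_error", "error", "condition"),
                 list(message = sprintf(
                   "coincident particles (min pair distance %.3g < 1e-6): energy undefined",
                   rmin), call = NULL)))
}

#' Evaluate a toy potential
#'
#' @param pot an `elcv_potential`.
#' @param x flat numeric coordinate vector (length `n_dof(pot)`).
#' @return list with `energy` (scalar) and `gradient` (same length as `x`).
#' @export
pot_eval <- function(pot, x) {
  check_config(pot, x)
  res <- switch(pot$name,
    mueller_brown_2d = mb_eval(pot$params, x),
    lj_cluster = lj_energy_gradient_cpp(x, pot$n_particles),
    bead_chain = bead_chain_energy_gradient_cpp(x, pot$n_particles,
                                                pot$params),
    stop("unknown potential ", pot$name, call. = FALSE))
  if (!is.null(res$min_dist) && res$min_dist < 1e-6) coincident_error(res$min_dist)
  list(energy = res$energy, gradient = as.numeric(res$gradient))
}

mb_eval <- function(p, x) {
  dx <- x[1] - p$x0
  dy <- x[2] - p$y0
  ex <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$cc * dy^2)
  e <- sum(ex)
  gx <- sum(ex * (2 * p$a * dx + p$b * dy))
  gy <- sum(ex * (p$b * dx + 2 * p$cc * dy))
  list(energy = e, gradient = c(gx, gy), min_dist = Inf)
}

#' Central finite-difference gradient
#'
#' Verification oracle for the analytic gradients: perturbs one coordinate at
#' a time by `step` in both directions.
#' @inheritParams pot_eval
#' @param step finite-difference step (> 0).
#' @export
numerical_gradient <- function(pot, x, step = 1e-5) {
  stopifnot(step > 0)
  check_config(pot, x)
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + step
    xm <- x; xm[i] <- x[i] - step
    (pot_eval(pot, xp)$energy - pot_eval(pot, xm)$energy) / (2 * step)
  }, numeric(1))
}

#' Convenient starting configurations
#'
#' `straight_chain_config` lays beads along the x axis at the equilibrium bond
#' length; `random_cluster_config` draws particles uniformly in a cube scaled
#' to roughly unit density.
#' @param pot an `elcv_potential`.
#' @param seed integer seed for the random cluster draw.
#' @param jitter small Gaussian jitter added to the straight chain so that
#'   minimisation can break collinearity (dihedrals are undefined on a line).
#' @export
straight_chain_config <- function(pot, jitter = 0.01, seed = NULL) {
  stopifnot(pot$name == "bead_chain")
  if (!is.null(seed)) set.seed(seed)
  n <- pot$n_particles
  x <- matrix(0, nrow = n, ncol = 3)
  x[, 1] <- (seq_len(n) - 1) * pot$params$r0
  x <- x + matrix(stats::rnorm(3 * n, sd = jitter), ncol = 3)
  as.numeric(t(x))
}

#' @rdname straight_chain_config
#' @export
random_cluster_config <- function(pot, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- max(1, pot$n_particles^(1 / 3)) * 1.2
  # redraw near-overlapping configurations: they are unphysical starts and
  # the steep core makes their quenches ill-conditioned
  for (try in 1:100) {
    x <- stats::runif(n_dof(pot), min = -L, max = L)
    if (min(stats::dist(coords_matrix(x, pot$dim))) > 0.5) return(x)
  }
  x
}

#' Reshape a flat coordinate vector to a particles-by-dim matrix
#' @param x flat coordinate vector.
#' @param dim 2 or 3.
#' @export
coords_matrix <- function(x, dim = 3L) matrix(x, ncol = dim, byrow = TRUE)

#' @rdname coords_matrix
#' @param m particles-by-dim coordinate matrix.
#' @export
coords_flat <- function(m) as.numeric(t(m))
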