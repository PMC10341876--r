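# Local minimisation: limited-memory quasi-Newton descent to an RMS-gradient
# criterion, the convergence style used throughout the stationary-point
# machinery. L-BFGS-B supplies the quasi-Newton steps; convergence is declared
# on sqrt(mean(g^2)) <= rms_tol, with restarts because the line search can
# stop on the function-value criterion first.

#' Quench a configuration to the nearest local minimum
#'
#' @param pot an `elcv_potential`.
#' @param x starting coordinates.
#' @param rms_tol RMS-gradient convergence criterion (loose default 1e-4;
#'   tight refinement uses 1e-7).
#' @param max_iter iteration cap across restarts.
#' @return list with `x`, `energy`, `rms_grad`, `converged`, `n_restarts`.
#' @export
quench <- function(pot, x, rms_tol = 1e-4, max_iter = 10000L) {
  check_config(pot, x)
  if (pot$name %in% c("lj_cluster", "bead_chain")) {
    res <- lbfgs_quench_cpp(x, if (pot$name == "lj_cluster") 1L else 2L,
                            pot$n_particles, pot$params, rms_tol,
                            as.integer(max_iter))
    res$n_restarts <- 0L
    return(res)
  }
  nd <- length(x)
  fn <- function(z) {
    e <- tryCatch(pot_eval(pot, z)$energy, elcv_coincident_error = function(e) Inf)
    if (!is.finite(e)) 1e10 else e
  }
  gr <- function(z) {
    g <- tryCatch(pot_eval(pot, z)$gradient,
                  elcv_coincident_error = function(e) NULL)
    if (is.null(g) || !all(is.finite(g))) rep(0, nd) else g
  }
  cur <- x
  restarts <- 0L
  budget <- max_iter
  repeat {
    res <- tryCatch(
      stats::optim(cur, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = min(budget, 2000L),
                                  factr = 10, pgtol = rms_tol / 10)),
      error = function(e) NULL)
    if (!is.null(res)) cur <- res$par
    g <- gr(cur)
    rms <- sqrt(mean(g^2))
    if (is.finite(rms) && rms <= rms_tol) {
      return(list(x = cur, energy = fn(cur), rms_grad = rms,
                  converged = TRUE, n_restarts = restarts))
    }
    budget <- budget - if (is.null(res)) 100L else 2000L
    restarts <- restarts + 1L
    if (budget <= 0L || restarts > 8L) {
      return(list(x = cur, energy = fn(cur), rms_grad = rms,
                  converged = FALSE, n_restarts = restarts))
    }
  }
}

rms_grad <- function(pot, x) {
  sqrt(mean(pot_eval(pot, x)$gradient^2))
}

# Best-aligned RMSD between two configurations: centring plus optimal proper
# rotation (Kabsch, via the Horn quaternion method in compiled code) for 3D;
# 2D/single-particle cases use plain per-site distance. No permutational
# alignment is attempted.
aligned_rmsd <- function(xa, xb, dim = 3L) {
  if (dim == 2L || length(xa) <= dim) {
    n_at <- length(xa) / dim
    return(sqrt(sum((xa - xb)^2) / n_at))
  }
  kabsch_rmsd_cpp(xa, xb)
}
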