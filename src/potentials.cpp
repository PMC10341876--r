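#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Plain-C++ energy/gradient kernels. Shared by the exported evaluators and by
// the compiled L-BFGS quench so inner loops never cross the R boundary.
// ---------------------------------------------------------------------------

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Lennard-Jones cluster, reduced units (epsilon = sigma = 1).
static double lj_eg(const double *x, int n, double *g, double *rmin_out) {
  double e = 0.0, rmin = HUGE_VAL;
  for (int k = 0; k < 3 * n; ++k) g[k] = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r < rmin) rmin = r;
      if (r < 1e-6) { e = HUGE_VAL; continue; }
      double ir2 = 1.0 / r2;
      double ir6 = ir2 * ir2 * ir2;
      double ir12 = ir6 * ir6;
      e += 4.0 * (ir12 - ir6);
      double fac = 4.0 * (-12.0 * ir12 + 6.0 * ir6) * ir2;
      g[3 * i] += fac * dx;     g[3 * j] -= fac * dx;
      g[3 * i + 1] += fac * dy; g[3 * j + 1] -= fac * dy;
      g[3 * i + 2] += fac * dz; g[3 * j + 2] -= fac * dz;
    }
  }
  if (rmin_out) *rmin_out = rmin;
  return e;
}

struct ChainParams {
  double k_bond, r0, k_angle, cos0, eps_nb, sigma_nb;
  std::vector<double> amp, phase;
  std::vector<int> mult;
  int nb_min_sep;
};

// Bead chain: harmonic bonds + harmonic-cosine angles + cosine-series
// dihedrals + LJ between beads >= nb_min_sep bonds apart. The angle term is
// singularity-free and keeps bends away from collinearity, where the torsion
// gradient diverges.
static double chain_eg(const double *x, int n, const ChainParams &p,
                       double *g, double *rmin_out) {
  double e = 0.0, rmin = HUGE_VAL;
  for (int k = 0; k < 3 * n; ++k) g[k] = 0.0;

  for (int i = 0; i < n - 1; ++i) {
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = x[3 * (i + 1) + k] - x[3 * i + k];
    double r = std::sqrt(dot3(d, d));
    if (r < rmin) rmin = r;
    if (r < 1e-12) { e = HUGE_VAL; continue; }
    double dr = r - p.r0;
    e += 0.5 * p.k_bond * dr * dr;
    double fac = p.k_bond * dr / r;
    for (int k = 0; k < 3; ++k) {
      g[3 * (i + 1) + k] += fac * d[k];
      g[3 * i + k] -= fac * d[k];
    }
  }

  for (int i = 1; i < n - 1; ++i) {
    double u[3], v[3];
    for (int k = 0; k < 3; ++k) {
      u[k] = x[3 * (i - 1) + k] - x[3 * i + k];
      v[k] = x[3 * (i + 1) + k] - x[3 * i + k];
    }
    double lu = std::sqrt(dot3(u, u)), lv = std::sqrt(dot3(v, v));
    if (lu < 1e-12 || lv < 1e-12) { e = HUGE_VAL; continue; }
    double ct = dot3(u, v) / (lu * lv);
    double diff = ct - p.cos0;
    e += 0.5 * p.k_angle * diff * diff;
    double pref = p.k_angle * diff;
    for (int k = 0; k < 3; ++k) {
      double dprev = pref * (v[k] / (lu * lv) - ct * u[k] / (lu * lu));
      double dnext = pref * (u[k] / (lu * lv) - ct * v[k] / (lv * lv));
      g[3 * (i - 1) + k] += dprev;
      g[3 * (i + 1) + k] += dnext;
      g[3 * i + k] -= dprev + dnext;
    }
  }

  for (int i = 0; i + 3 < n; ++i) {
    const double *r1 = &x[3 * i], *r2 = &x[3 * (i + 1)];
    const double *r3 = &x[3 * (i + 2)], *r4 = &x[3 * (i + 3)];
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = r2[k] - r1[k];
      b2[k] = r3[k] - r2[k];
      b3[k] = r4[k] - r3[k];
    }
    double n1[3], n2[3], m1[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double lb2 = std::sqrt(dot3(b2, b2));
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    if (lb2 < 1e-12 || n1sq < 1e-24 || n2sq < 1e-24) { e = HUGE_VAL; continue; }
    cross3(n1, n2, m1);
    double phi = std::atan2(dot3(m1, b2) / lb2, dot3(n1, n2));

    double dEdphi = 0.0;
    for (size_t t = 0; t < p.amp.size(); ++t) {
      e += p.amp[t] * (1.0 + std::cos(p.mult[t] * phi - p.phase[t]));
      dEdphi += -p.amp[t] * p.mult[t] * std::sin(p.mult[t] * phi - p.phase[t]);
    }

    double f1[3], f4[3], f2[3], f3[3];
    double c1 = -lb2 / n1sq, c4 = lb2 / n2sq;
    double pp = dot3(b1, b2) / (lb2 * lb2);
    double qq = dot3(b3, b2) / (lb2 * lb2);
    for (int k = 0; k < 3; ++k) {
      f1[k] = c1 * n1[k];
      f4[k] = c4 * n2[k];
      f2[k] = -(1.0 + pp) * f1[k] + qq * f4[k];
      f3[k] = pp * f1[k] - (1.0 + qq) * f4[k];
    }
    for (int k = 0; k < 3; ++k) {
      g[3 * i + k] += dEdphi * f1[k];
      g[3 * (i + 1) + k] += dEdphi * f2[k];
      g[3 * (i + 2) + k] += dEdphi * f3[k];
      g[3 * (i + 3) + k] += dEdphi * f4[k];
    }
  }

  double s2 = p.sigma_nb * p.sigma_nb;
  for (int i = 0; i < n - p.nb_min_sep; ++i) {
    for (int j = i + p.nb_min_sep; j < n; ++j) {
      double d[3];
      for (int k = 0; k < 3; ++k) d[k] = x[3 * i + k] - x[3 * j + k];
      double r2 = dot3(d, d);
      double r = std::sqrt(r2);
      if (r < rmin) rmin = r;
      if (r < 1e-6) { e = HUGE_VAL; continue; }
      double sr2 = s2 / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      e += 4.0 * p.eps_nb * (sr12 - sr6);
      double fac = 4.0 * p.eps_nb * (-12.0 * sr12 + 6.0 * sr6) / r2;
      for (int k = 0; k < 3; ++k) {
        g[3 * i + k] += fac * d[k];
        g[3 * j + k] -= fac * d[k];
      }
    }
  }

  if (rmin_out) *rmin_out = rmin;
  return e;
}

static ChainParams chain_params_from_list(const List &params) {
  ChainParams p;
  p.k_bond = as<double>(params["k_bond"]);
  p.r0 = as<double>(params["r0"]);
  p.k_angle = as<double>(params["k_angle"]);
  p.cos0 = as<double>(params["cos0"]);
  p.eps_nb = as<double>(params["eps_nb"]);
  p.sigma_nb = as<double>(params["sigma_nb"]);
  p.nb_min_sep = as<int>(params["nb_min_sep"]);
  p.amp = as<std::vector<double> >(params["dihedral_amp"]);
  p.phase = as<std::vector<double> >(params["dihedral_phase"]);
  p.mult = as<std::vector<int> >(params["dihedral_mult"]);
  return p;
}

// [[Rcpp::export]]
List lj_energy_gradient_cpp(NumericVector x, int n) {
  NumericVector g(3 * n);
  double rmin;
  double e = lj_eg(x.begin(), n, g.begin(), &rmin);
  return List::create(_["energy"] = e, _["gradient"] = g, _["min_dist"] = rmin);
}

// [[Rcpp::export]]
List bead_chain_energy_gradient_cpp(NumericVector x, int n, List params) {
  ChainParams p = chain_params_from_list(params);
  NumericVector g(3 * n);
  double rmin;
  double e = chain_eg(x.begin(), n, p, g.begin(), &rmin);
  return List::create(_["energy"] = e, _["gradient"] = g, _["min_dist"] = rmin);
}

// ---------------------------------------------------------------------------
// Compiled L-BFGS quench (two-loop recursion, Armijo backtracking).
// pot_type: 1 = LJ cluster, 2 = bead chain. Convergence on RMS gradient.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List lbfgs_quench_cpp(NumericVector x0, int pot_type, int n_particles,
                      List params, double rms_tol, int max_iter) {
  const int nd = x0.size();
  const int m = 6;
  std::vector<double> x(x0.begin(), x0.end()), g(nd), xnew(nd), gnew(nd);
  std::vector<std::vector<double> > s_hist, y_hist;
  std::vector<double> rho_hist;
  ChainParams cp;
  if (pot_type == 2) cp = chain_params_from_list(params);

  auto eval = [&](const double *xx, double *gg) -> double {
    if (pot_type == 1) return lj_eg(xx, n_particles, gg, nullptr);
    return chain_eg(xx, n_particles, cp, gg, nullptr);
  };

  double e = eval(x.data(), g.data());
  if (!std::isfinite(e)) {
    return List::create(_["x"] = x0, _["energy"] = e, _["rms_grad"] = NA_REAL,
                        _["converged"] = false);
  }
  bool converged = false;
  double rms = 0.0;
  for (int iter = 0; iter < max_iter; ++iter) {
    double g2 = 0.0;
    for (int k = 0; k < nd; ++k) g2 += g[k] * g[k];
    rms = std::sqrt(g2 / nd);
    if (rms <= rms_tol) { converged = true; break; }

    // two-loop recursion
    std::vector<double> q(g);
    int h = (int)s_hist.size();
    std::vector<double> alpha(h);
    for (int i = h - 1; i >= 0; --i) {
      double sq = 0.0;
      for (int k = 0; k < nd; ++k) sq += s_hist[i][k] * q[k];
      alpha[i] = rho_hist[i] * sq;
      for (int k = 0; k < nd; ++k) q[k] -= alpha[i] * y_hist[i][k];
    }
    double gamma = 1.0;
    if (h > 0) {
      double sy = 0.0, yy = 0.0;
      for (int k = 0; k < nd; ++k) {
        sy += s_hist[h - 1][k] * y_hist[h - 1][k];
        yy += y_hist[h - 1][k] * y_hist[h - 1][k];
      }
      if (yy > 0) gamma = sy / yy;
    }
    for (int k = 0; k < nd; ++k) q[k] *= gamma;
    for (int i = 0; i < h; ++i) {
      double yq = 0.0;
      for (int k = 0; k < nd; ++k) yq += y_hist[i][k] * q[k];
      double beta = rho_hist[i] * yq;
      for (int k = 0; k < nd; ++k) q[k] += s_hist[i][k] * (alpha[i] - beta);
    }
    // q is now the descent step direction (for -g); direction d = -q
    double dg = 0.0;
    for (int k = 0; k < nd; ++k) dg += -q[k] * g[k];
    std::vector<double> d(nd);
    if (dg < 0) {
      for (int k = 0; k < nd; ++k) d[k] = -q[k];
    } else {  // not a descent direction: steepest descent reset
      s_hist.clear(); y_hist.clear(); rho_hist.clear();
      double gn = std::sqrt(g2);
      for (int k = 0; k < nd; ++k) d[k] = -g[k] / (gn > 1 ? gn : 1.0);
      dg = 0.0;
      for (int k = 0; k < nd; ++k) dg += d[k] * g[k];
    }
    // cap step norm at 0.5 to avoid wild extrapolation
    double dn2 = 0.0;
    for (int k = 0; k < nd; ++k) dn2 += d[k] * d[k];
    double dn = std::sqrt(dn2);
    if (dn > 0.5) {
      for (int k = 0; k < nd; ++k) d[k] *= 0.5 / dn;
      dg *= 0.5 / dn;
    }
    // Armijo backtracking
    double t = 1.0, enew = 0.0;
    bool ok = false;
    for (int ls = 0; ls < 30; ++ls) {
      for (int k = 0; k < nd; ++k) xnew[k] = x[k] + t * d[k];
      enew = eval(xnew.data(), gnew.data());
      if (std::isfinite(enew) && enew <= e + 1e-4 * t * dg) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) {
      // quasi-Newton direction rejected: retry once along steepest descent
      s_hist.clear(); y_hist.clear(); rho_hist.clear();
      double gn = std::sqrt(g2);
      for (int k = 0; k < nd; ++k) d[k] = -g[k] / (gn > 1 ? gn : 1.0);
      dg = 0.0;
      for (int k = 0; k < nd; ++k) dg += d[k] * g[k];
      t = 1.0;
      for (int ls = 0; ls < 40; ++ls) {
        for (int k = 0; k < nd; ++k) xnew[k] = x[k] + t * d[k];
        enew = eval(xnew.data(), gnew.data());
        if (std::isfinite(enew) && enew <= e + 1e-4 * t * dg) { ok = true; break; }
        t *= 0.5;
      }
      if (!ok) break;
    }
    // history update
    std::vector<double> sv(nd), yv(nd);
    double sy = 0.0;
    for (int k = 0; k < nd; ++k) {
      sv[k] = xnew[k] - x[k];
      yv[k] = gnew[k] - g[k];
      sy += sv[k] * yv[k];
    }
    if (sy > 1e-12) {
      s_hist.push_back(sv); y_hist.push_back(yv); rho_hist.push_back(1.0 / sy);
      if ((int)s_hist.size() > m) {
        s_hist.erase(s_hist.begin());
        y_hist.erase(y_hist.begin());
        rho_hist.erase(rho_hist.begin());
      }
    }
    x = xnew; g = gnew; e = enew;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["energy"] = e, _["rms_grad"] = rms,
                      _["converged"] = converged);
}
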