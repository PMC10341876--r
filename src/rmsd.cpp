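#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Largest eigenvalue of a symmetric 4x4 by cyclic Jacobi sweeps.
static double jacobi4_maxeig(double a[4][4]) {
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) off += a[p][q] * a[p][q];
    if (off < 1e-24) break;
    for (int p = 0; p < 3; ++p) {
      for (int q = p + 1; q < 4; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0);
        double s = t * c;
        for (int k = 0; k < 4; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 4; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
      }
    }
  }
  double m = a[0][0];
  for (int k = 1; k < 4; ++k) if (a[k][k] > m) m = a[k][k];
  return m;
}

// Best-aligned (proper-rotation) RMSD of two 3D structures after centring,
// by the Horn quaternion method. Flat coordinate vectors, same length.
// [[Rcpp::export]]
double kabsch_rmsd_cpp(NumericVector xa, NumericVector xb) {
  int n = xa.size() / 3;
  double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      ca[k] += xa[3 * i + k];
      cb[k] += xb[3 * i + k];
    }
  for (int k = 0; k < 3; ++k) { ca[k] /= n; cb[k] /= n; }
  double R[3][3] = {{0}}, ga = 0.0, gb = 0.0;
  for (int i = 0; i < n; ++i) {
    double pa[3], pb[3];
    for (int k = 0; k < 3; ++k) {
      pa[k] = xa[3 * i + k] - ca[k];
      pb[k] = xb[3 * i + k] - cb[k];
      ga += pa[k] * pa[k];
      gb += pb[k] * pb[k];
    }
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) R[r][c] += pa[r] * pb[c];
  }
  double K[4][4];
  K[0][0] = R[0][0] + R[1][1] + R[2][2];
  K[0][1] = R[1][2] - R[2][1];
  K[0][2] = R[2][0] - R[0][2];
  K[0][3] = R[0][1] - R[1][0];
  K[1][1] = R[0][0] - R[1][1] - R[2][2];
  K[1][2] = R[0][1] + R[1][0];
  K[1][3] = R[2][0] + R[0][2];
  K[2][2] = -R[0][0] + R[1][1] - R[2][2];
  K[2][3] = R[1][2] + R[2][1];
  K[3][3] = -R[0][0] - R[1][1] + R[2][2];
  for (int r = 1; r < 4; ++r)
    for (int c = 0; c < r; ++c) K[r][c] = K[c][r];
  double lmax = jacobi4_maxeig(K);
  double msd = (ga + gb - 2.0 * lmax) / n;
  return msd > 0 ? std::sqrt(msd) : 0.0;
}
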