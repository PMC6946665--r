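// Gauss linking number of two closed polylines, via the discrete double sum
// over segment pairs (solid-angle form of the Gauss integral).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Signed solid angle contribution of segment pair, Arai's closed form:
// quadrilateral spherical excess for segments (a1,a2) and (b1,b2).
static double seg_pair_omega(const double* a1, const double* a2,
                             const double* b1, const double* b2) {
  double r[4][3];
  for (int d = 0; d < 3; ++d) {
    r[0][d] = b1[d] - a1[d];
    r[1][d] = b1[d] - a2[d];
    r[2][d] = b2[d] - a2[d];
    r[3][d] = b2[d] - a1[d];
  }
  double n[4][3];
  // n_i = r_i x r_{i+1}
  for (int i = 0; i < 4; ++i) {
    int j = (i + 1) % 4;
    n[i][0] = r[i][1] * r[j][2] - r[i][2] * r[j][1];
    n[i][1] = r[i][2] * r[j][0] - r[i][0] * r[j][2];
    n[i][2] = r[i][0] * r[j][1] - r[i][1] * r[j][0];
  }
  auto norm = [](const double* v) {
    return std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  };
  auto dot = [](const double* u, const double* v) {
    return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  };
  double omega = 0.0;
  for (int i = 0; i < 4; ++i) {
    int j = (i + 1) % 4;
    double den = norm(n[i]) * norm(n[j]);
    if (den < 1e-300) return NA_REAL; // touching geometry
    double c = dot(n[i], n[j]) / den;
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    omega += std::asin(c);
  }
  // sign from orientation
  double da[3] = { a2[0] - a1[0], a2[1] - a1[1], a2[2] - a1[2] };
  double db[3] = { b2[0] - b1[0], b2[1] - b1[1], b2[2] - b1[2] };
  double cx[3] = { da[1] * db[2] - da[2] * db[1],
                   da[2] * db[0] - da[0] * db[2],
                   da[0] * db[1] - da[1] * db[0] };
  double s = cx[0] * r[0][0] + cx[1] * r[0][1] + cx[2] * r[0][2];
  return (s >= 0 ? 1.0 : -1.0) * omega;
}

// [[Rcpp::export(name = ".cpp_linking_sum")]]
double cpp_linking_sum(NumericMatrix ci, NumericMatrix cj) {
  int ni = ci.nrow(), nj = cj.nrow();
  std::vector<double> A(3 * ni), B(3 * nj);
  for (int i = 0; i < ni; ++i)
    for (int d = 0; d < 3; ++d) A[3 * i + d] = ci(i, d);
  for (int j = 0; j < nj; ++j)
    for (int d = 0; d < 3; ++d) B[3 * j + d] = cj(j, d);
  double total = 0.0;
  for (int i = 0; i < ni; ++i) {
    int i2 = (i + 1) % ni;
    for (int j = 0; j < nj; ++j) {
      int j2 = (j + 1) % nj;
      double w = seg_pair_omega(&A[3 * i], &A[3 * i2], &B[3 * j], &B[3 * j2]);
      if (ISNA(w)) return NA_REAL;
      total += w;
    }
  }
  return total / (4.0 * M_PI);
}
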