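// Gauss-Seidel projection kernel for the position-based-dynamics solver.
// Constraints are projected in place, in a fixed documented order
// (stretch -> bend -> collision), `iterations` times. Stiffness values
// arrive already converted to per-iteration form k' = 1 - (1-k)^(1/n_s).
//
// The bend projection uses the canonical PBD dihedral gradient. Positions
// are expressed relative to p1; n1 = normalize(P2 x P3), n2 = normalize
// (P2 x P4), d = n1.n2, and the constraint passed here is
// C = acos(d) - phi_rest with phi_rest the rest angle in THIS convention
// (the R layer converts from its coplanar-zero convention).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// [[Rcpp::export(name = ".pbd_gauss_seidel")]]
NumericMatrix pbd_gauss_seidel(NumericMatrix positions,
                               NumericVector invmass,
                               IntegerMatrix s_idx,     // e x 2, 0-based
                               NumericVector s_rest,
                               NumericVector s_k,       // per-iteration k'
                               IntegerMatrix b_idx,     // d x 4, 0-based
                               NumericVector b_phi,     // rest angle, Muller conv.
                               NumericVector b_k,
                               IntegerVector c_vert,    // 0-based vertex ids
                               NumericMatrix c_point,
                               NumericMatrix c_normal,
                               int iterations) {
  NumericMatrix P = clone(positions);
  const int n = P.nrow();
  const int ns = s_idx.nrow(), nb = b_idx.nrow(), nc = c_vert.size();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = P(i, 0); py[i] = P(i, 1); pz[i] = P(i, 2); }

  for (int it = 0; it < iterations; ++it) {
    // --- stretch constraints ---
    for (int c = 0; c < ns; ++c) {
      const int i = s_idx(c, 0), j = s_idx(c, 1);
      const double wi = invmass[i], wj = invmass[j];
      const double wsum = wi + wj;
      if (wsum <= 0.0) continue;
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len <= 1e-300) continue;  // coincident: direction undefined
      const double corr = s_k[c] * (len - s_rest[c]) / (len * wsum);
      px[i] -= wi * corr * dx; py[i] -= wi * corr * dy; pz[i] -= wi * corr * dz;
      px[j] += wj * corr * dx; py[j] += wj * corr * dy; pz[j] += wj * corr * dz;
      if (!std::isfinite(px[i]) || !std::isfinite(px[j]))
        stop("non-finite position while projecting stretch constraint %d", c + 1);
    }
    // --- bend constraints ---
    for (int c = 0; c < nb; ++c) {
      const int i1 = b_idx(c, 0), i2 = b_idx(c, 1), i3 = b_idx(c, 2),
                i4 = b_idx(c, 3);
      double P2[3] = {px[i2] - px[i1], py[i2] - py[i1], pz[i2] - pz[i1]};
      double P3[3] = {px[i3] - px[i1], py[i3] - py[i1], pz[i3] - pz[i1]};
      double P4[3] = {px[i4] - px[i1], py[i4] - py[i1], pz[i4] - pz[i1]};
      double c23[3], c24[3];
      cross3(P2, P3, c23);
      cross3(P2, P4, c24);
      const double l23 = norm3(c23), l24 = norm3(c24);
      if (l23 < 1e-12 || l24 < 1e-12) continue;  // degenerate triangle
      double n1[3] = {c23[0] / l23, c23[1] / l23, c23[2] / l23};
      double n2[3] = {c24[0] / l24, c24[1] / l24, c24[2] / l24};
      double d = dot3(n1, n2);
      if (d > 1.0) d = 1.0; else if (d < -1.0) d = -1.0;
      const double C = std::acos(d) - b_phi[c];
      if (std::fabs(C) < 1e-14) continue;
      double t1[3], t2[3], q2[3], q3[3], q4[3], q1[3];
      // q3 = (P2 x n2 + (n1 x P2) d) / |P2 x P3|
      cross3(P2, n2, t1); cross3(n1, P2, t2);
      for (int k = 0; k < 3; ++k) q3[k] = (t1[k] + t2[k] * d) / l23;
      // q4 = (P2 x n1 + (n2 x P2) d) / |P2 x P4|
      cross3(P2, n1, t1); cross3(n2, P2, t2);
      for (int k = 0; k < 3; ++k) q4[k] = (t1[k] + t2[k] * d) / l24;
      // q2 = -(P3 x n2 + (n1 x P3) d)/|P2 x P3| - (P4 x n1 + (n2 x P4) d)/|P2 x P4|
      double u1[3], u2[3], u3[3], u4[3];
      cross3(P3, n2, u1); cross3(n1, P3, u2);
      cross3(P4, n1, u3); cross3(n2, P4, u4);
      for (int k = 0; k < 3; ++k)
        q2[k] = -(u1[k] + u2[k] * d) / l23 - (u3[k] + u4[k] * d) / l24;
      for (int k = 0; k < 3; ++k) q1[k] = -q2[k] - q3[k] - q4[k];
      const double w1 = invmass[i1], w2 = invmass[i2], w3 = invmass[i3],
                   w4 = invmass[i4];
      const double denom = w1 * dot3(q1, q1) + w2 * dot3(q2, q2) +
                           w3 * dot3(q3, q3) + w4 * dot3(q4, q4);
      if (denom < 1e-12) continue;  // near-degenerate gradient
      const double s = std::sqrt(std::max(0.0, 1.0 - d * d)) * C / denom * b_k[c];
      px[i1] -= w1 * s * q1[0]; py[i1] -= w1 * s * q1[1]; pz[i1] -= w1 * s * q1[2];
      px[i2] -= w2 * s * q2[0]; py[i2] -= w2 * s * q2[1]; pz[i2] -= w2 * s * q2[2];
      px[i3] -= w3 * s * q3[0]; py[i3] -= w3 * s * q3[1]; pz[i3] -= w3 * s * q3[2];
      px[i4] -= w4 * s * q4[0]; py[i4] -= w4 * s * q4[1]; pz[i4] -= w4 * s * q4[2];
      if (!std::isfinite(px[i1]) || !std::isfinite(px[i2]) ||
          !std::isfinite(px[i3]) || !std::isfinite(px[i4]))
        stop("non-finite position while projecting bend constraint %d", c + 1);
    }
    // --- collision constraints (inequality: keep on positive side) ---
    for (int c = 0; c < nc; ++c) {
      const int v = c_vert[c];
      if (invmass[v] <= 0.0) continue;
      const double dx = px[v] - c_point(c, 0), dy = py[v] - c_point(c, 1),
                   dz = pz[v] - c_point(c, 2);
      const double Cv = dx * c_normal(c, 0) + dy * c_normal(c, 1) +
                        dz * c_normal(c, 2);
      if (Cv < 0.0) {
        px[v] -= Cv * c_normal(c, 0);
        py[v] -= Cv * c_normal(c, 1);
        pz[v] -= Cv * c_normal(c, 2);
      }
    }
  }
  for (int i = 0; i < n; ++i) { P(i, 0) = px[i]; P(i, 1) = py[i]; P(i, 2) = pz[i]; }
  return P;
}
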