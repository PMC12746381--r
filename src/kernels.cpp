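#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact fields of finite straight current segments.
//
// For a segment p1 -> p2 carrying current I, at field point r:
//   B = (mu0 I / 4 pi) * (u x r1) * (s1/R1 - s2/R2) / d^2
//   A = (mu0 I / 4 pi) * u * log((R1 + R2 + L) / (R1 + R2 - L))
// with u the unit tangent, r1 = r - p1, r2 = r - p2, s_i = u . r_i,
// R_i = |r_i|, d the perpendicular distance and L the segment length.
// The symmetric log form for A is numerically stable everywhere off the
// segment; (u x r1) has magnitude d so B is finite off the wire.

static const double MU0_4PI = 1e-7;

// [[Rcpp::export]]
List segment_fields_cpp(NumericMatrix p1, NumericMatrix p2,
                        NumericVector current, IntegerVector loop_id,
                        NumericMatrix pts, bool want_B, bool want_A,
                        double min_dist) {
  const int m = p1.nrow();
  const int n = pts.nrow();
  NumericMatrix B(want_B ? n : 0, 3), A(want_A ? n : 0, 3);

  for (int s = 0; s < m; ++s) {
    const double ax = p1(s, 0), ay = p1(s, 1), az = p1(s, 2);
    const double dx = p2(s, 0) - ax, dy = p2(s, 1) - ay, dz = p2(s, 2) - az;
    const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0) continue;
    const double ux = dx / L, uy = dy / L, uz = dz / L;
    const double k = MU0_4PI * current[s];
    for (int i = 0; i < n; ++i) {
      const double r1x = pts(i, 0) - ax, r1y = pts(i, 1) - ay,
                   r1z = pts(i, 2) - az;
      const double R1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      const double s1 = ux * r1x + uy * r1y + uz * r1z;
      const double s2 = s1 - L;
      const double R2 = std::sqrt(R1 * R1 - 2.0 * s1 * L + L * L);
      // distance from point to the segment (not the infinite line)
      const double t = std::max(0.0, std::min(L, s1));
      const double qx = r1x - t * ux, qy = r1y - t * uy, qz = r1z - t * uz;
      const double dseg = std::sqrt(qx * qx + qy * qy + qz * qz);
      if (dseg < min_dist)
        stop("field point within %f m of wire segment (loop %d)", min_dist,
             loop_id[s]);
      if (want_B) {
        const double cx = uy * r1z - uz * r1y;
        const double cy = uz * r1x - ux * r1z;
        const double cz = ux * r1y - uy * r1x;
        const double d2 = cx * cx + cy * cy + cz * cz;  // = dline^2
        if (d2 > 0) {
          const double f = k * (s1 / R1 - s2 / R2) / d2;
          B(i, 0) += f * cx;
          B(i, 1) += f * cy;
          B(i, 2) += f * cz;
        }
      }
      if (want_A) {
        const double g = k * std::log((R1 + R2 + L) / (R1 + R2 - L));
        A(i, 0) += g * ux;
        A(i, 1) += g * uy;
        A(i, 2) += g * uz;
      }
    }
  }
  List out = List::create();
  if (want_B) out["B"] = B;
  if (want_A) out["A"] = A;
  return out;
}

// 6-connected component labeling of a logical 3-D mask (column-major dims).
// Returns an integer array: 0 outside the mask, 1..k component labels.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int comp = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++comp;
    queue.clear();
    queue.push_back(seed);
    lab[seed] = comp;
    while (!queue.empty()) {
      const R_xlen_t v = queue.back();
      queue.pop_back();
      const int ix = v % nx, iy = (v / nx) % ny, iz = v / ((R_xlen_t)nx * ny);
      const int dxs[6] = {-1, 1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, -1, 1, 0, 0};
      const int dzs[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        const int jx = ix + dxs[q], jy = iy + dys[q], jz = iz + dzs[q];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        const R_xlen_t w = jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
        if (mask[w] && !lab[w]) {
          lab[w] = comp;
          queue.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
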