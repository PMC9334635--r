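#include <Rcpp.h>
using namespace Rcpp;

// Bilinear interpolation on a cell-centered grid; queries clamped to the
// grid so near-boundary evaluations remain defined.
static inline double interp2(const NumericMatrix &V, double ox, double oy,
                             double h, double x, double y) {
  int nx = V.nrow(), ny = V.ncol();
  double u = (x - ox) / h, v = (y - oy) / h;
  if (u < 0) u = 0; if (u > nx - 1) u = nx - 1;
  if (v < 0) v = 0; if (v > ny - 1) v = ny - 1;
  int i0 = (int)std::floor(u); if (i0 > nx - 2) i0 = nx - 2;
  int j0 = (int)std::floor(v); if (j0 > ny - 2) j0 = ny - 2;
  double fu = u - i0, fv = v - j0;
  return (1 - fu) * (1 - fv) * V(i0, j0) + fu * (1 - fv) * V(i0 + 1, j0) +
         (1 - fu) * fv * V(i0, j0 + 1) + fu * fv * V(i0 + 1, j0 + 1);
}

// central difference of the bilinear interpolant, half-spacing stencil
static inline void grad2(const NumericMatrix &V, double ox, double oy,
                         double h, double x, double y, double &gx,
                         double &gy) {
  double d = 0.5 * h;
  gx = (interp2(V, ox, oy, h, x + d, y) - interp2(V, ox, oy, h, x - d, y)) /
       (2 * d);
  gy = (interp2(V, ox, oy, h, x, y + d) - interp2(V, ox, oy, h, x, y - d)) /
       (2 * d);
}

static inline bool inside(double x, double y, double A, double B) {
  double u = x / A, v = y / B;
  return u * u + v * v <= 1.0;
}

// Overdamped Euler-Maruyama walk on a free-energy landscape F (kBT).
// Steps leaving the ellipse are rejected and their noise redrawn
// (rejection-reflection); after max_tries the particle stays put.
// [[Rcpp::export]]
NumericMatrix cpp_bd_sim(NumericMatrix F, double ox, double oy, double h,
                         double A, double B, double x0, double y0,
                         double D, double dt, int n_steps,
                         int max_tries = 50) {
  NumericMatrix out(n_steps + 1, 2);
  double x = x0, y = y0;
  double amp = std::sqrt(2.0 * D * dt);
  out(0, 0) = x; out(0, 1) = y;
  for (int s = 1; s <= n_steps; ++s) {
    double gx, gy;
    grad2(F, ox, oy, h, x, y, gx, gy);
    double dx_drift = -D * gx * dt, dy_drift = -D * gy * dt;
    double xn = x, yn = y;
    for (int t = 0; t < max_tries; ++t) {
      double cx = x + dx_drift + amp * R::norm_rand();
      double cy = y + dy_drift + amp * R::norm_rand();
      if (inside(cx, cy, A, B)) { xn = cx; yn = cy; break; }
    }
    x = xn; y = yn;
    out(s, 0) = x; out(s, 1) = y;
  }
  return out;
}

// Two coupled overdamped particles: each feels the gridded wall potential
// W (kBT) plus a Gaussian-core mutual repulsion
// U_pair = strength * exp(-|r1-r2|^2 / (2 range^2)).
// Integrated at step dt, recorded every n_sub steps; returns
// (n_frames+1) x 4 matrix of (x1, y1, x2, y2).
// [[Rcpp::export]]
NumericMatrix cpp_two_blob_sim(NumericMatrix W, double ox, double oy,
                               double h, double A, double B,
                               double x1, double y1, double x2, double y2,
                               double pair_strength, double pair_range,
                               double D, double dt, int n_frames, int n_sub,
                               int max_tries = 50) {
  NumericMatrix out(n_frames + 1, 4);
  double amp = std::sqrt(2.0 * D * dt);
  double s2 = pair_range * pair_range;
  out(0, 0) = x1; out(0, 1) = y1; out(0, 2) = x2; out(0, 3) = y2;
  for (int f = 1; f <= n_frames; ++f) {
    for (int s = 0; s < n_sub; ++s) {
      double gx1, gy1, gx2, gy2;
      grad2(W, ox, oy, h, x1, y1, gx1, gy1);
      grad2(W, ox, oy, h, x2, y2, gx2, gy2);
      double rx = x1 - x2, ry = y1 - y2;
      double fpair = pair_strength * std::exp(-(rx * rx + ry * ry) / (2 * s2)) / s2;
      // force on particle 1 is +fpair * (rx, ry); on particle 2 the opposite
      double d1x = -D * (gx1 - fpair * rx) * dt;
      double d1y = -D * (gy1 - fpair * ry) * dt;
      double d2x = -D * (gx2 + fpair * rx) * dt;
      double d2y = -D * (gy2 + fpair * ry) * dt;
      double nx1 = x1, ny1 = y1;
      for (int t = 0; t < max_tries; ++t) {
        double cx = x1 + d1x + amp * R::norm_rand();
        double cy = y1 + d1y + amp * R::norm_rand();
        if (inside(cx, cy, A, B)) { nx1 = cx; ny1 = cy; break; }
      }
      double nx2 = x2, ny2 = y2;
      for (int t = 0; t < max_tries; ++t) {
        double cx = x2 + d2x + amp * R::norm_rand();
        double cy = y2 + d2y + amp * R::norm_rand();
        if (inside(cx, cy, A, B)) { nx2 = cx; ny2 = cy; break; }
      }
      x1 = nx1; y1 = ny1; x2 = nx2; y2 = ny2;
    }
    out(f, 0) = x1; out(f, 1) = y1; out(f, 2) = x2; out(f, 3) = y2;
  }
  return out;
}
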