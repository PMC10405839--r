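#include <Rcpp.h>
using namespace Rcpp;

// Grid convention (shared by all compiled kernels): a field is a ny x nx
// matrix; pixel (i, j) (0-based) has its center at x = x0 + j*ps,
// y = y0 + i*ps, with x0/y0/ps in mm.  Positions are mm, speeds m/s,
// slowness s/m, times s; mm -> m conversion is the 1e-3 factor.

static inline double bilin(const NumericMatrix &F, double x, double y,
                           double x0, double y0, double ps) {
  const double u = (x - x0) / ps, v = (y - y0) / ps;
  const int j0 = (int)std::floor(u), i0 = (int)std::floor(v);
  if (j0 < 0 || i0 < 0 || j0 + 1 >= F.ncol() || i0 + 1 >= F.nrow())
    return 0.0; // outside the grid the perturbation field is zero
  const double fu = u - j0, fv = v - i0;
  return F(i0, j0) * (1 - fu) * (1 - fv) + F(i0, j0 + 1) * fu * (1 - fv) +
         F(i0 + 1, j0) * (1 - fu) * fv + F(i0 + 1, j0 + 1) * fu * fv;
}

// Midpoint-rule line integral of a bilinearly interpolated field along the
// segment (x1,y1)-(x2,y2).  Returns field_units * mm.
double seg_integral(const NumericMatrix &F, double x0, double y0, double ps,
                    double x1, double y1, double x2, double y2,
                    double step_mm) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0) return 0.0;
  const int n = std::max(1, (int)std::ceil(L / step_mm));
  const double ds = L / n;
  double acc = 0.0;
  for (int k = 0; k < n; ++k) {
    const double t = (k + 0.5) / n;
    acc += bilin(F, x1 + t * dx, y1 + t * dy, x0, y0, ps);
  }
  return acc * ds;
}

// [[Rcpp::export(name = ".cpp_line_integral")]]
double cpp_line_integral(NumericMatrix F, double x0, double y0, double ps,
                         double x1, double y1, double x2, double y2,
                         double step_mm) {
  return seg_integral(F, x0, y0, ps, x1, y1, x2, y2, step_mm);
}

// Straight-ray travel-time perturbations for emitter/receiver index pairs:
// 1e-3 * integral of the slowness perturbation (s/m) along each chord.
// [[Rcpp::export(name = ".cpp_pairs_dtof")]]
NumericVector cpp_pairs_dtof(NumericMatrix pert, double x0, double y0,
                             double ps, NumericMatrix elem_pos,
                             IntegerMatrix pairs, double step_mm) {
  const int m = pairs.nrow();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    const int a = pairs(q, 0), b = pairs(q, 1);
    out[q] = 1e-3 * seg_integral(pert, x0, y0, ps, elem_pos(a, 0),
                                 elem_pos(a, 1), elem_pos(b, 0),
                                 elem_pos(b, 1), step_mm);
  }
  return out;
}

// Sparse straight-ray path matrix in triplet form.  Row q corresponds to
// pair q; column is the 0-based column-major pixel index; the weight is the
// bilinearly distributed path length in meters, so that
// L %*% slowness_perturbation gives delta-TOF in seconds.
// [[Rcpp::export(name = ".cpp_path_matrix")]]
List cpp_path_matrix(int ny, int nx, double x0, double y0, double ps,
                     NumericMatrix elem_pos, IntegerMatrix pairs,
                     double step_mm) {
  std::vector<int> ri, ci;
  std::vector<double> w;
  const int m = pairs.nrow();
  ri.reserve(m * 64); ci.reserve(m * 64); w.reserve(m * 64);
  for (int q = 0; q < m; ++q) {
    const int a = pairs(q, 0), b = pairs(q, 1);
    const double x1 = elem_pos(a, 0), y1 = elem_pos(a, 1);
    const double dx = elem_pos(b, 0) - x1, dy = elem_pos(b, 1) - y1;
    const double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0) continue;
    const int n = std::max(1, (int)std::ceil(L / step_mm));
    const double ds = L / n;
    for (int k = 0; k < n; ++k) {
      const double t = (k + 0.5) / n;
      const double u = (x1 + t * dx - x0) / ps, v = (y1 + t * dy - y0) / ps;
      const int j0 = (int)std::floor(u), i0 = (int)std::floor(v);
      if (j0 < 0 || i0 < 0 || j0 + 1 >= nx || i0 + 1 >= ny) continue;
      const double fu = u - j0, fv = v - i0, wq = ds * 1e-3;
      const double ww[4] = {(1 - fu) * (1 - fv), fu * (1 - fv),
                            (1 - fu) * fv, fu * fv};
      const int jj[4] = {j0, j0 + 1, j0, j0 + 1};
      const int ii[4] = {i0, i0, i0 + 1, i0 + 1};
      for (int c = 0; c < 4; ++c) {
        if (ww[c] <= 0) continue;
        ri.push_back(q);
        ci.push_back(jj[c] * ny + ii[c]);
        w.push_back(wq * ww[c]);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["w"] = wrap(w));
}

// Length (mm) of the in-mask portion of a segment, sampled at step_mm with
// nearest-neighbour mask lookup.
// [[Rcpp::export(name = ".cpp_inmask_length")]]
double cpp_inmask_length(NumericMatrix mask, double x0, double y0, double ps,
                         double x1, double y1, double x2, double y2,
                         double step_mm) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0) return 0.0;
  const int n = std::max(1, (int)std::ceil(L / step_mm));
  const double ds = L / n;
  double acc = 0.0;
  for (int k = 0; k < n; ++k) {
    const double t = (k + 0.5) / n;
    const int j = (int)std::lround((x1 + t * dx - x0) / ps);
    const int i = (int)std::lround((y1 + t * dy - y0) / ps);
    if (i >= 0 && j >= 0 && i < mask.nrow() && j < mask.ncol() &&
        mask(i, j) > 0.5)
      acc += ds;
  }
  return acc;
}
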