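#include <Rcpp.h>
using namespace Rcpp;

// Forward circular-mean projection of an initial pressure map p0 onto the
// ring array: each pixel deposits its (area-weighted, 1/r spread) value into
// the time bin of its distance to the element, split linearly between the
// two neighbouring samples.  Sample k (0-based) is at time t0 + k/fs.
// [[Rcpp::export(name = ".cpp_msot_project")]]
NumericMatrix cpp_msot_project(NumericMatrix p0, double x0, double y0,
                               double ps, NumericMatrix elem_pos,
                               double c_mps, double fs, double t0,
                               int n_samples) {
  const int ny = p0.nrow(), nx = p0.ncol(), ne = elem_pos.nrow();
  NumericMatrix out(ne, n_samples);
  // gather non-zero pixels once
  std::vector<double> px, py, pv;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      if (p0(i, j) != 0) {
        px.push_back(x0 + j * ps);
        py.push_back(y0 + i * ps);
        pv.push_back(p0(i, j) * ps * ps);
      }
  const int np = (int)pv.size();
  for (int e = 0; e < ne; ++e) {
    const double ex = elem_pos(e, 0), ey = elem_pos(e, 1);
    for (int q = 0; q < np; ++q) {
      const double dx = px[q] - ex, dy = py[q] - ey;
      const double d = std::sqrt(dx * dx + dy * dy);
      const double t = d * 1e-3 / c_mps;
      const double s = (t - t0) * fs;
      const int k = (int)std::floor(s);
      if (k < 0 || k + 1 >= n_samples) continue;
      const double f = s - k;
      const double w = pv[q] / std::max(d, ps);
      out(e, k) += w * (1 - f);
      out(e, k + 1) += w * f;
    }
  }
  return out;
}

// Forward projection using an explicit per-pixel/element delay table (the
// same two-medium table the back-projector uses), with 1/r spreading from
// the geometric distance.
// [[Rcpp::export(name = ".cpp_msot_project_delays")]]
NumericMatrix cpp_msot_project_delays(NumericMatrix p0, double x0, double y0,
                                      double ps, NumericMatrix elem_pos,
                                      NumericMatrix delays, double fs,
                                      double t0, int n_samples) {
  const int ny = p0.nrow(), nx = p0.ncol(), ne = elem_pos.nrow();
  NumericMatrix out(ne, n_samples);
  for (int e = 0; e < ne; ++e) {
    const double ex = elem_pos(e, 0), ey = elem_pos(e, 1);
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        const double v = p0(i, j);
        if (v == 0) continue;
        const double dx = x0 + j * ps - ex, dy = y0 + i * ps - ey;
        const double d = std::sqrt(dx * dx + dy * dy);
        const double s = (delays(j * ny + i, e) - t0) * fs;
        const int k = (int)std::floor(s);
        if (k < 0 || k + 1 >= n_samples) continue;
        const double f = s - k;
        const double w = v * ps * ps / std::max(d, ps);
        out(e, k) += w * (1 - f);
        out(e, k + 1) += w * f;
      }
  }
  return out;
}

// Two-medium straight-segment delay table: time from every pixel to every
// element through water (speed c_w) outside the body mask and tissue speed
// c_t inside.  Pixels are in column-major order.
// [[Rcpp::export(name = ".cpp_delay_table")]]
NumericMatrix cpp_delay_table(int ny, int nx, double x0, double y0, double ps,
                              NumericMatrix elem_pos, NumericMatrix body_mask,
                              double c_w, double c_t, double step_mm) {
  const int ne = elem_pos.nrow(), np = ny * nx;
  NumericMatrix out(np, ne);
  for (int e = 0; e < ne; ++e) {
    const double ex = elem_pos(e, 0), ey = elem_pos(e, 1);
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        const double xpix = x0 + j * ps, ypix = y0 + i * ps;
        const double dx = ex - xpix, dy = ey - ypix;
        const double d = std::sqrt(dx * dx + dy * dy);
        double lt = 0.0;
        if (d > 0) {
          const int n = std::max(1, (int)std::ceil(d / step_mm));
          const double ds = d / n;
          for (int k = 0; k < n; ++k) {
            const double t = (k + 0.5) / n;
            const int jj = (int)std::lround((xpix + t * dx - x0) / ps);
            const int ii = (int)std::lround((ypix + t * dy - y0) / ps);
            if (ii >= 0 && jj >= 0 && ii < ny && jj < nx &&
                body_mask(ii, jj) > 0.5)
              lt += ds;
          }
        }
        out(j * ny + i, e) = ((d - lt) * 1e-3) / c_w + (lt * 1e-3) / c_t;
      }
    }
  }
  return out;
}

// Back-projection of a (filtered) sinogram given a per-pixel delay table:
// sum over elements of the trace linearly interpolated at the pixel delay.
// [[Rcpp::export(name = ".cpp_backproject")]]
NumericVector cpp_backproject(NumericMatrix b, NumericMatrix delays,
                              double fs, double t0) {
  const int ne = b.nrow(), ns = b.ncol(), np = delays.nrow();
  NumericVector out(np);
  for (int e = 0; e < ne; ++e) {
    for (int p = 0; p < np; ++p) {
      const double s = (delays(p, e) - t0) * fs;
      const int k = (int)std::floor(s);
      if (k < 0 || k + 1 >= ns) continue;
      const double f = s - k;
      out[p] += b(e, k) * (1 - f) + b(e, k + 1) * f;
    }
  }
  return out;
}
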