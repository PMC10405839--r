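#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase band-limited wavelet (must match the acquisition pulse)
static inline double pulse_v(double u, double fc, double sigma) {
  return std::cos(2.0 * M_PI * fc * u) *
         std::exp(-u * u / (2.0 * sigma * sigma));
}
static inline double pulse_d(double u, double fc, double sigma) {
  const double e = std::exp(-u * u / (2.0 * sigma * sigma));
  return e * (-2.0 * M_PI * fc * std::sin(2.0 * M_PI * fc * u) -
              (u / (sigma * sigma)) * std::cos(2.0 * M_PI * fc * u));
}

// ---------------------------------------------------------------------------
// Matching-pursuit first-arrival picking.
//
// Each measured trace is decomposed as a sum of scaled, time-shifted copies
// of the band-limited reference pulse by iterative cross-correlation peak
// extraction with parabolic sub-sample refinement.  The pick is the minimum
// retained shift: robust to overlapping later arrivals, unlike a plain
// threshold/peak picker.
// [[Rcpp::export(name = ".cpp_tof_pick")]]
List cpp_tof_pick(NumericMatrix meas, NumericVector ref_tof, double fs,
                  double t0, double fc, double sigma, double win_half_s,
                  int max_comp, double resid_frac, double amp_frac) {
  const int m = meas.nrow(), ns = meas.ncol();
  const int half = (int)std::ceil(4.5 * sigma * fs);
  std::vector<double> tmpl(2 * half + 1);
  double e_tmpl = 0.0;
  for (int k = -half; k <= half; ++k) {
    tmpl[k + half] = pulse_v(k / fs, fc, sigma);
    e_tmpl += tmpl[k + half] * tmpl[k + half];
  }
  NumericVector tof(m);
  LogicalVector valid(m);
  IntegerVector ncomp(m);
  for (int q = 0; q < m; ++q) {
    const int c0 = std::max(half, (int)std::floor((ref_tof[q] - win_half_s -
                                                   t0) * fs));
    const int c1 = std::min(ns - 1 - half,
                            (int)std::ceil((ref_tof[q] + win_half_s - t0) *
                                           fs));
    if (c1 <= c0) { valid[q] = false; tof[q] = NA_REAL; continue; }
    const int lo = c0 - half, hi = c1 + half;
    std::vector<double> r(hi - lo + 1);
    double energy0 = 0.0;
    for (int k = lo; k <= hi; ++k) {
      r[k - lo] = meas(q, k);
      energy0 += r[k - lo] * r[k - lo];
    }
    if (energy0 <= 0) { valid[q] = false; tof[q] = NA_REAL; continue; }
    double best_tau = NA_REAL, a1 = 0.0;
    int found = 0;
    for (int comp = 0; comp < max_comp; ++comp) {
      // correlation of residual with template, centre at sample c
      int cbest = -1;
      double cmax = 0.0;
      std::vector<double> corr(c1 - c0 + 1);
      for (int c = c0; c <= c1; ++c) {
        double acc = 0.0;
        for (int k = -half; k <= half; ++k)
          acc += r[c + k - lo] * tmpl[k + half];
        corr[c - c0] = acc;
        if (std::fabs(acc) > std::fabs(cmax)) { cmax = acc; cbest = c; }
      }
      if (cbest < 0 || cmax == 0.0) break;
      double delta = 0.0;
      if (cbest > c0 && cbest < c1) {
        const double ym = corr[cbest - c0 - 1], yc = corr[cbest - c0],
                     yp = corr[cbest - c0 + 1];
        const double den = ym - 2 * yc + yp;
        if (den != 0.0) delta = 0.5 * (ym - yp) / den;
        if (delta > 0.5) delta = 0.5;
        if (delta < -0.5) delta = -0.5;
      }
      const double tau = t0 + (cbest + delta) / fs;
      const double amp = cmax / e_tmpl;
      if (comp == 0) a1 = std::fabs(amp);
      if (std::fabs(amp) < amp_frac * a1) break;
      // retain and subtract
      if (found == 0 || tau < best_tau) best_tau = tau;
      ++found;
      for (int k = lo; k <= hi; ++k)
        r[k - lo] -= amp * pulse_v(t0 + k / fs - tau, fc, sigma);
      double energy = 0.0;
      for (size_t k = 0; k < r.size(); ++k) energy += r[k] * r[k];
      if (energy < resid_frac * energy0) break;
    }
    ncomp[q] = found;
    if (found > 0) { tof[q] = best_tau; valid[q] = true; }
    else { tof[q] = NA_REAL; valid[q] = false; }
  }
  return List::create(_["tof"] = tof, _["valid"] = valid,
                      _["n_components"] = ncomp);
}

// ---------------------------------------------------------------------------
// Fan-path travel-time helper shared by the waveform forward model and the
// FWI gradient.  Path p for a pair runs emitter -> control point -> receiver
// where the control point is the chord midpoint offset laterally by
// offsets[p] mm (offset 0 = straight ray).  The path delay is the reference
// (water) TOF plus the line integral of the slowness perturbation.

struct PathAccum {
  double tau;
};

static double path_dtof(const NumericMatrix &pert, double x0, double y0,
                        double ps, double ax, double ay, double bx,
                        double by, double off, double step_mm) {
  const double mx = 0.5 * (ax + bx), my = 0.5 * (ay + by);
  double nxv = -(by - ay), nyv = bx - ax;
  const double nn = std::sqrt(nxv * nxv + nyv * nyv);
  double acc = 0.0;
  const int ny_ = pert.nrow(), nx_ = pert.ncol();
  auto seg = [&](double x1, double y1, double x2, double y2) {
    const double dx = x2 - x1, dy = y2 - y1;
    const double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0) return;
    const int n = std::max(1, (int)std::ceil(L / step_mm));
    const double ds = L / n;
    for (int k = 0; k < n; ++k) {
      const double t = (k + 0.5) / n;
      const double u = (x1 + t * dx - x0) / ps, v = (y1 + t * dy - y0) / ps;
      const int j0 = (int)std::floor(u), i0 = (int)std::floor(v);
      if (j0 < 0 || i0 < 0 || j0 + 1 >= nx_ || i0 + 1 >= ny_) continue;
      const double fu = u - j0, fv = v - i0;
      acc += ds * (pert(i0, j0) * (1 - fu) * (1 - fv) +
                   pert(i0, j0 + 1) * fu * (1 - fv) +
                   pert(i0 + 1, j0) * (1 - fu) * fv +
                   pert(i0 + 1, j0 + 1) * fu * fv);
    }
  };
  if (off == 0.0 || nn == 0.0) {
    seg(ax, ay, bx, by);
  } else {
    const double cx = mx + off * nxv / nn, cy = my + off * nyv / nn;
    seg(ax, ay, cx, cy);
    seg(cx, cy, bx, by);
  }
  return acc * 1e-3;
}

static void path_grad(NumericMatrix &grad, const NumericMatrix &support,
                      double x0, double y0, double ps, double ax, double ay,
                      double bx, double by, double off, double step_mm,
                      double g) {
  double nxv = -(by - ay), nyv = bx - ax;
  const double nn = std::sqrt(nxv * nxv + nyv * nyv);
  const double mx = 0.5 * (ax + bx), my = 0.5 * (ay + by);
  const int ny_ = grad.nrow(), nx_ = grad.ncol();
  auto seg = [&](double x1, double y1, double x2, double y2) {
    const double dx = x2 - x1, dy = y2 - y1;
    const double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0) return;
    const int n = std::max(1, (int)std::ceil(L / step_mm));
    const double ds = L / n;
    for (int k = 0; k < n; ++k) {
      const double t = (k + 0.5) / n;
      const double u = (x1 + t * dx - x0) / ps, v = (y1 + t * dy - y0) / ps;
      const int j0 = (int)std::floor(u), i0 = (int)std::floor(v);
      if (j0 < 0 || i0 < 0 || j0 + 1 >= nx_ || i0 + 1 >= ny_) continue;
      const double fu = u - j0, fv = v - i0;
      const double w = g * ds * 1e-3;
      if (support(i0, j0) > 0.5) grad(i0, j0) += w * (1 - fu) * (1 - fv);
      if (support(i0, j0 + 1) > 0.5) grad(i0, j0 + 1) += w * fu * (1 - fv);
      if (support(i0 + 1, j0) > 0.5) grad(i0 + 1, j0) += w * (1 - fu) * fv;
      if (support(i0 + 1, j0 + 1) > 0.5)
        grad(i0 + 1, j0 + 1) += w * fu * fv;
    }
  };
  if (off == 0.0 || nn == 0.0) {
    seg(ax, ay, bx, by);
  } else {
    const double cx = mx + off * nxv / nn, cy = my + off * nyv / nn;
    seg(ax, ay, cx, cy);
    seg(cx, cy, bx, by);
  }
}

// Waveform-inversion objective and gradient.  slowness is the full s/m grid;
// the loss is the mean over pairs of the mean squared sample error between
// the fan-path estimate  amp/P * sum_p w(t - tau_p)  and the measured
// window.  The gradient is exact for the bilinear path parameterization and
// analytic pulse, distributed only to pixels where `support` is 1.
// [[Rcpp::export(name = ".cpp_fwi_loss_grad")]]
List cpp_fwi_loss_grad(NumericMatrix slowness, double x0, double y0,
                       double ps, NumericMatrix elem_pos, IntegerMatrix pairs,
                       NumericVector ref_tof, NumericVector amp,
                       NumericMatrix meas_win, IntegerVector win_start,
                       double fs, double t0, double fc, double sigma,
                       double water_slowness, NumericVector offsets,
                       NumericMatrix support, double step_mm,
                       bool want_grad) {
  const int m = pairs.nrow(), W = meas_win.ncol();
  const int P = offsets.size();
  const int ny_ = slowness.nrow(), nx_ = slowness.ncol();
  NumericMatrix pert(ny_, nx_);
  for (int j = 0; j < nx_; ++j)
    for (int i = 0; i < ny_; ++i)
      pert(i, j) = slowness(i, j) - water_slowness;
  NumericMatrix grad(ny_, nx_);
  double loss = 0.0;
  std::vector<double> tau(P), est(W), resid(W);
  for (int q = 0; q < m; ++q) {
    const int a = pairs(q, 0), b = pairs(q, 1);
    const double ax = elem_pos(a, 0), ay = elem_pos(a, 1);
    const double bx = elem_pos(b, 0), by = elem_pos(b, 1);
    for (int p = 0; p < P; ++p)
      tau[p] = ref_tof[q] + path_dtof(pert, x0, y0, ps, ax, ay, bx, by,
                                      offsets[p], step_mm);
    const double sc = amp[q] / P;
    double ql = 0.0;
    for (int k = 0; k < W; ++k) {
      const double t = t0 + (win_start[q] + k) / fs;
      double e = 0.0;
      for (int p = 0; p < P; ++p) e += pulse_v(t - tau[p], fc, sigma);
      est[k] = sc * e;
      resid[k] = est[k] - meas_win(q, k);
      ql += resid[k] * resid[k];
    }
    loss += ql / W;
    if (want_grad) {
      for (int p = 0; p < P; ++p) {
        double g = 0.0;
        for (int k = 0; k < W; ++k) {
          const double t = t0 + (win_start[q] + k) / fs;
          g += resid[k] * (-sc * pulse_d(t - tau[p], fc, sigma));
        }
        g *= 2.0 / (W * (double)m);
        if (g != 0.0)
          path_grad(grad, support, x0, y0, ps, ax, ay, bx, by, offsets[p],
                    step_mm, g);
      }
    }
  }
  loss /= m;
  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// Full-record fan-path waveform prediction for a set of pairs (used by the
// forward model on its own, outside the inversion loop).
// [[Rcpp::export(name = ".cpp_forward_waveforms")]]
NumericMatrix cpp_forward_waveforms(NumericMatrix slowness, double x0,
                                    double y0, double ps,
                                    NumericMatrix elem_pos,
                                    IntegerMatrix pairs, NumericVector ref_tof,
                                    NumericVector amp, int n_samples,
                                    double fs, double t0, double fc,
                                    double sigma, double water_slowness,
                                    NumericVector offsets, double step_mm) {
  const int m = pairs.nrow(), P = offsets.size();
  const int ny_ = slowness.nrow(), nx_ = slowness.ncol();
  NumericMatrix pert(ny_, nx_);
  for (int j = 0; j < nx_; ++j)
    for (int i = 0; i < ny_; ++i)
      pert(i, j) = slowness(i, j) - water_slowness;
  NumericMatrix out(m, n_samples);
  for (int q = 0; q < m; ++q) {
    const int a = pairs(q, 0), b = pairs(q, 1);
    for (int p = 0; p < P; ++p) {
      const double tau = ref_tof[q] +
        path_dtof(pert, x0, y0, ps, elem_pos(a, 0), elem_pos(a, 1),
                  elem_pos(b, 0), elem_pos(b, 1), offsets[p], step_mm);
      const double half = 4.5 * sigma;
      int k0 = (int)std::ceil((tau - half - t0) * fs);
      int k1 = (int)std::floor((tau + half - t0) * fs);
      if (k0 < 0) k0 = 0;
      if (k1 > n_samples - 1) k1 = n_samples - 1;
      for (int k = k0; k <= k1; ++k)
        out(q, k) += (amp[q] / P) * pulse_v(t0 + k / fs - tau, fc, sigma);
    }
  }
  return out;
}
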