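#include <Rcpp.h>
using namespace Rcpp;

double seg_integral(const NumericMatrix &F, double x0, double y0, double ps,
                    double x1, double y1, double x2, double y2,
                    double step_mm);

// Band-limited transmit pulse: zero-phase (cosine) carrier at fc under a
// Gaussian envelope of width sigma (s), so the wavelet maximum marks the
// arrival time and delay-and-sum samples the peak at exact focus.
static inline double pulse_val(double u, double fc, double sigma) {
  return std::cos(2.0 * M_PI * fc * u) *
         std::exp(-u * u / (2.0 * sigma * sigma));
}

// [[Rcpp::export(name = ".cpp_pulse")]]
NumericVector cpp_pulse(NumericVector u, double fc, double sigma) {
  NumericVector out(u.size());
  for (R_xlen_t k = 0; k < u.size(); ++k)
    out[k] = pulse_val(u[k], fc, sigma);
  return out;
}

static inline void add_pulse(double *trace, int ns, double fs, double t0,
                             double tof, double amp, double fc,
                             double sigma) {
  const double half = 4.5 * sigma;
  int k0 = (int)std::ceil((tof - half - t0) * fs);
  int k1 = (int)std::floor((tof + half - t0) * fs);
  if (k0 < 0) k0 = 0;
  if (k1 > ns - 1) k1 = ns - 1;
  for (int k = k0; k <= k1; ++k) {
    const double t = t0 + k / fs;
    trace[k] += amp * pulse_val(t - tof, fc, sigma);
  }
}

// Synthetic transmit aperture acquisition on a ring: per transmission the
// direct (through-transmission) wave travels the straight chord with the
// travel time given by the slowness line integral and 1/sqrt(path) spread;
// each point scatterer returns a pulse delayed by the two-leg straight-ray
// travel time, scaled by reflectivity and two-leg geometric spreading.
// Returns an (ntx * nrx * n_samples) array (dims set on the R side).
// [[Rcpp::export(name = ".cpp_sta_simulate")]]
NumericVector cpp_sta_simulate(NumericMatrix sos_map, double x0, double y0,
                               double ps, NumericMatrix elem_pos,
                               IntegerVector tx_idx, IntegerVector rx_idx,
                               NumericMatrix scat_pos, NumericVector scat_refl,
                               double c_w, double fs, double t0,
                               int n_samples, double fc, double sigma,
                               double step_mm, bool with_transmission,
                               int ap_half) {
  const int ntx = tx_idx.size(), nrx = rx_idx.size();
  const int ny = sos_map.nrow(), nx = sos_map.ncol();
  const int nscat = scat_pos.nrow();
  // slowness perturbation relative to water
  NumericMatrix pert(ny, nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      pert(i, j) = 1.0 / sos_map(i, j) - 1.0 / c_w;

  NumericVector out((R_xlen_t)ntx * nrx * n_samples);
  double *po = REAL(out);

  // scatterer <-> element one-way times/distances for all elements used
  const int ne = elem_pos.nrow();
  std::vector<char> used(ne, 0);
  for (int a = 0; a < ntx; ++a) used[tx_idx[a]] = 1;
  for (int a = 0; a < nrx; ++a) used[rx_idx[a]] = 1;
  std::vector<double> stof((size_t)nscat * ne), sdist((size_t)nscat * ne);
  for (int e = 0; e < ne; ++e) {
    if (!used[e]) continue;
    for (int q = 0; q < nscat; ++q) {
      const double dx = scat_pos(q, 0) - elem_pos(e, 0);
      const double dy = scat_pos(q, 1) - elem_pos(e, 1);
      const double d = std::sqrt(dx * dx + dy * dy);
      const double dt = 1e-3 * seg_integral(pert, x0, y0, ps, elem_pos(e, 0),
                                            elem_pos(e, 1), scat_pos(q, 0),
                                            scat_pos(q, 1), step_mm);
      sdist[(size_t)q * ne + e] = d;
      stof[(size_t)q * ne + e] = d * 1e-3 / c_w + dt;
    }
  }

  for (int a = 0; a < ntx; ++a) {
    const int te = tx_idx[a];
    for (int b = 0; b < nrx; ++b) {
      const int re = rx_idx[b];
      // optional receive-aperture restriction: record only elements within
      // ap_half ring positions of the transmitter (ap_half <= 0: all)
      if (ap_half > 0) {
        int dd = std::abs(re - te);
        dd = std::min(dd, ne - dd);
        if (dd > ap_half) continue;
      }
      // column-major layout [tx, rx, sample]; build the trace in a
      // contiguous buffer, then scatter into the output array
      const R_xlen_t base = (R_xlen_t)a + (R_xlen_t)ntx * b;
      std::vector<double> tmp(n_samples, 0.0);
      if (with_transmission && re != te) {
        const double dx = elem_pos(re, 0) - elem_pos(te, 0);
        const double dy = elem_pos(re, 1) - elem_pos(te, 1);
        const double d = std::sqrt(dx * dx + dy * dy);
        const double dt = 1e-3 * seg_integral(pert, x0, y0, ps,
                                              elem_pos(te, 0), elem_pos(te, 1),
                                              elem_pos(re, 0), elem_pos(re, 1),
                                              step_mm);
        add_pulse(tmp.data(), n_samples, fs, t0, d * 1e-3 / c_w + dt,
                  1.0 / std::sqrt(std::max(d, 1.0)), fc, sigma);
      }
      for (int q = 0; q < nscat; ++q) {
        const double d1 = sdist[(size_t)q * ne + te];
        const double d2 = sdist[(size_t)q * ne + re];
        const double tof = stof[(size_t)q * ne + te] +
                           stof[(size_t)q * ne + re];
        const double amp = scat_refl[q] /
                           std::sqrt(std::max(d1 * d2, 1.0));
        add_pulse(tmp.data(), n_samples, fs, t0, tof, amp, fc, sigma);
      }
      for (int k = 0; k < n_samples; ++k)
        po[base + (R_xlen_t)ntx * nrx * k] = tmp[k];
    }
  }
  return out;
}

// Delay-and-sum image for one transmission event over a contiguous receive
// aperture, with Hann receive apodization; accumulates into `img`
// (column-major pixel vector).
static void das_accumulate(const double *data, R_xlen_t ntx, R_xlen_t nrx,
                           int ns, int a /*tx slot*/, int te,
                           const IntegerVector &rx_slots,
                           const NumericVector &apod,
                           const NumericMatrix &elem_pos, int ny, int nx,
                           double x0, double y0, double ps, double sos,
                           double fs, double t0, double *img) {
  const double txx = elem_pos(te, 0), txy = elem_pos(te, 1);
  const int nap = rx_slots.size();
  std::vector<double> dtx((size_t)ny * nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      const double dx = x0 + j * ps - txx, dy = y0 + i * ps - txy;
      dtx[(size_t)j * ny + i] = std::sqrt(dx * dx + dy * dy);
    }
  for (int r = 0; r < nap; ++r) {
    const int slot = rx_slots[r]; // 0-based slot on the rx axis = element id
    const double rxx = elem_pos(slot, 0), rxy = elem_pos(slot, 1);
    const double w = apod[r];
    const double *trace0 = data + (R_xlen_t)a + (R_xlen_t)ntx * slot;
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        const size_t p = (size_t)j * ny + i;
        const double dx = x0 + j * ps - rxx, dy = y0 + i * ps - rxy;
        const double drx = std::sqrt(dx * dx + dy * dy);
        const double s = ((dtx[p] + drx) * 1e-3 / sos - t0) * fs;
        const int k = (int)std::floor(s);
        if (k < 0 || k + 1 >= ns) continue;
        const double f = s - k;
        const double v0 = trace0[(R_xlen_t)ntx * nrx * k];
        const double v1 = trace0[(R_xlen_t)ntx * nrx * (k + 1)];
        img[p] += w * (v0 * (1 - f) + v1 * f);
      }
  }
}

// Single-view DAS.  `data` is the [tx, rx, sample] block; `tx_slot` selects
// the transmission (0-based index on the tx axis); `tx_elem` is its element
// id; `rx_slots` the receive element ids (rx axis must cover all elements).
// [[Rcpp::export(name = ".cpp_das_single")]]
NumericVector cpp_das_single(NumericVector data, IntegerVector dims,
                             NumericMatrix elem_pos, int tx_slot, int tx_elem,
                             IntegerVector rx_slots, NumericVector apod,
                             int ny, int nx, double x0, double y0, double ps,
                             double sos, double fs, double t0) {
  NumericVector img((R_xlen_t)ny * nx);
  das_accumulate(REAL(data), dims[0], dims[1], dims[2], tx_slot, tx_elem,
                 rx_slots, apod, elem_pos, ny, nx, x0, y0, ps, sos, fs, t0,
                 REAL(img));
  return img;
}

// Compound DAS over a list of transmissions (sum of single-view images).
// [[Rcpp::export(name = ".cpp_das_compound")]]
NumericVector cpp_das_compound(NumericVector data, IntegerVector dims,
                               NumericMatrix elem_pos, IntegerVector tx_elems,
                               List rx_slots_list, NumericVector apod,
                               int ny, int nx, double x0, double y0,
                               double ps, double sos, double fs, double t0) {
  NumericVector img((R_xlen_t)ny * nx);
  for (int a = 0; a < tx_elems.size(); ++a) {
    IntegerVector rx_slots = rx_slots_list[a];
    das_accumulate(REAL(data), dims[0], dims[1], dims[2], a, tx_elems[a],
                   rx_slots, apod, elem_pos, ny, nx, x0, y0, ps, sos, fs, t0,
                   REAL(img));
    Rcpp::checkUserInterrupt();
  }
  return img;
}
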