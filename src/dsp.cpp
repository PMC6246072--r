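// Core DSP: 4th-order complex gammatone cascade and framed interaural
// statistics. The complex one-pole cascade gives, per band, an analytic-like
// band signal whose real part is the band-filtered waveform and whose
// envelope/phase support efficient interaural cross-correlation.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::complex<double> cplx;

// Filter one channel through a 4th-order complex one-pole cascade.
// lambda = exp(-2*pi*bw/fs + i*2*pi*fc/fs); gain normalised so that the
// real-part magnitude response at fc equals 1.
static void gammatone_band(const double* x, R_xlen_t n, double fs, double fc,
                           double bw, std::vector<cplx>& out) {
  const double twopi = 2.0 * M_PI;
  cplx lambda = std::exp(cplx(-twopi * bw / fs, twopi * fc / fs));
  cplx ejw = std::exp(cplx(0.0, -twopi * fc / fs));
  cplx h1 = 1.0 / (1.0 - lambda * ejw);
  cplx h = h1 * h1; h = h * h;           // (1/(1-lambda e^-jw))^4 at fc
  double norm = 2.0 / std::abs(h);
  out.resize(n);
  cplx z1(0, 0), z2(0, 0), z3(0, 0), z4(0, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    z1 = x[i] + lambda * z1;
    z2 = z1 + lambda * z2;
    z3 = z2 + lambda * z3;
    z4 = z3 + lambda * z4;
    out[i] = norm * z4;
  }
}

// [[Rcpp::export(name = ".gammatone_bands_cpp")]]
NumericMatrix gammatone_bands_cpp(NumericVector x, double fs,
                                  NumericVector fc, NumericVector bw) {
  R_xlen_t n = x.size();
  int nb = fc.size();
  NumericMatrix res(n, nb);
  std::vector<cplx> band;
  for (int b = 0; b < nb; ++b) {
    gammatone_band(REAL(x), n, fs, fc[b], bw[b], band);
    double* col = &res(0, b);
    for (R_xlen_t i = 0; i < n; ++i) col[i] = band[i].real();
  }
  return res;
}

// [[Rcpp::export(name = ".gammatone_bands_complex_cpp")]]
ComplexMatrix gammatone_bands_complex_cpp(NumericVector x, double fs,
                                          NumericVector fc, NumericVector bw) {
  R_xlen_t n = x.size();
  int nb = fc.size();
  ComplexMatrix res(n, nb);
  std::vector<cplx> band;
  for (int b = 0; b < nb; ++b) {
    gammatone_band(REAL(x), n, fs, fc[b], bw[b], band);
    for (R_xlen_t i = 0; i < n; ++i) {
      res(i, b).r = band[i].real();
      res(i, b).i = band[i].imag();
    }
  }
  return res;
}

// Framed interaural statistics per gammatone band.
//   power   : mean squared Hann-tapered real band signal, window-normalised
//   phase   : argument of the windowed interaural cross-power at lag 0
//   coherence: max over lags (+-lag_max, step lag_step samples) of the
//              magnitude of the normalised complex cross-correlation
//              (analytic-envelope reading of the interaural cross-correlation
//              maximum); ties resolved towards smaller |lag|
// Frames where both ears have zero power get NA phase/coherence.
// [[Rcpp::export(name = ".frame_stats_cpp")]]
List frame_stats_cpp(NumericVector left, NumericVector right, double fs,
                     NumericVector fc, NumericVector bw,
                     int frame_len, int hop, NumericVector window,
                     int lag_max, int lag_step) {
  R_xlen_t n = left.size();
  if (right.size() != n) stop("left/right length mismatch");
  if (window.size() != frame_len) stop("window length must equal frame_len");
  if (n < frame_len) stop("signal shorter than one frame");
  int nb = fc.size();
  int nt = (int)((n - frame_len) / hop) + 1;

  double wss = 0.0;                       // sum of squared window
  for (int i = 0; i < frame_len; ++i) wss += window[i] * window[i];

  // lag order: 0, -s, +s, -2s, +2s ... so strict > keeps the smaller |lag|
  std::vector<int> lags;
  lags.push_back(0);
  for (int l = lag_step; l <= lag_max; l += lag_step) {
    lags.push_back(-l);
    lags.push_back(l);
  }

  NumericMatrix power_l(nb, nt), power_r(nb, nt), phase(nb, nt), coh(nb, nt);
  std::vector<cplx> cl, cr;

  for (int b = 0; b < nb; ++b) {
    gammatone_band(REAL(left), n, fs, fc[b], bw[b], cl);
    gammatone_band(REAL(right), n, fs, fc[b], bw[b], cr);
    for (int t = 0; t < nt; ++t) {
      R_xlen_t s = (R_xlen_t)t * hop;
      double pl = 0.0, pr = 0.0, pcl = 0.0, pcr = 0.0;
      cplx x0(0, 0);
      for (int i = 0; i < frame_len; ++i) {
        double w = window[i];
        cplx a = cl[s + i], c = cr[s + i];
        double ra = w * a.real(), rc = w * c.real();
        pl += ra * ra;
        pr += rc * rc;
        pcl += w * w * std::norm(a);
        pcr += w * w * std::norm(c);
        x0 += (w * a) * std::conj(w * c);
      }
      power_l(b, t) = pl / wss;
      power_r(b, t) = pr / wss;
      if (pl == 0.0 && pr == 0.0) {
        phase(b, t) = NA_REAL;
        coh(b, t) = NA_REAL;
        continue;
      }
      phase(b, t) = std::arg(x0);
      double denom = std::sqrt(pcl * pcr);
      if (denom == 0.0) { coh(b, t) = NA_REAL; continue; }
      double best = -1.0;
      for (size_t k = 0; k < lags.size(); ++k) {
        int lag = lags[k];
        cplx xc(0, 0);
        if (lag == 0) {
          xc = x0;
        } else {
          for (int i = 0; i < frame_len; ++i) {
            R_xlen_t j = s + i - lag;    // right index shifted by lag
            if (j < 0 || j >= n) continue;
            xc += (window[i] * cl[s + i]) * std::conj(window[i] * cr[j]);
          }
        }
        double v = std::abs(xc) / denom;
        if (v > best) best = v;
      }
      coh(b, t) = best > 1.0 ? 1.0 : (best < 0.0 ? 0.0 : best);
    }
  }
  return List::create(_["power_l"] = power_l, _["power_r"] = power_r,
                      _["phase"] = phase, _["coherence"] = coh,
                      _["n_frames"] = nt);
}
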