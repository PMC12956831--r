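// Compiled kernels for the two hot paths: synthetic epoch synthesis and
// multi-band analytic (zero-phase filter + Hilbert) per-epoch summaries.
// All randomness comes from R's RNG so results are reproducible under
// set.seed() on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// within-cycle phase warp (waveform skew): cycle fraction u -> phase psi
static inline double warpPhase(double u, double a) {
  if (a == 0.0) return 2.0 * M_PI * u;
  double ua = (1.0 + a) / 2.0;
  if (u < ua) return M_PI * u / ua;
  return M_PI + M_PI * (u - ua) / (1.0 - ua);
}

// inverse warp: burst preferred phase psi -> cycle fraction u
static inline double unwarpPhase(double psi, double a) {
  psi -= 2.0 * M_PI * std::floor(psi / (2.0 * M_PI));
  if (a == 0.0) return psi / (2.0 * M_PI);
  double ua = (1.0 + a) / 2.0;
  if (psi < M_PI) return ua * psi / M_PI;
  return ua + (1.0 - ua) * (psi - M_PI) / M_PI;
}

// Epoch synthesis under the theta-gamma sequence-coding model; one column
// per epoch. Parameters arrive as a flat named list (see SignalParams).
// [[Rcpp::export]]
arma::mat cppBuildEpochs(List prm, IntegerVector nItems, NumericVector times,
                         double modOnset) {
  const double fs = as<double>(prm["sampleRate"]);
  const double f = as<double>(prm["thetaFreq"]);
  const double base = as<double>(prm["thetaAmpBase"]);
  const double slope = as<double>(prm["thetaAmpSlope"]);
  const double fHigh = as<double>(prm["thetaHighFreq"]);
  const double baseH = as<double>(prm["thetaHighAmpBase"]);
  const double slopeH = as<double>(prm["thetaHighAmpSlope"]);
  const NumericVector gammaFreqs = prm["gammaFreqs"];   // slow, fast
  const NumericVector gammaAmp = prm["gammaAmp"];
  const double burstWidthCycles = as<double>(prm["burstWidthCycles"]);
  const double itemSpacing = as<double>(prm["itemPhaseSpacing"]);
  const double kappa0 = as<double>(prm["couplingBaseKappa"]);
  const double dispSlope = as<double>(prm["dispersionSlope"]);
  const double chi = as<double>(prm["noiseExponent"]);
  const double noiseScale = as<double>(prm["noiseScale"]);
  const double asym = as<double>(prm["asymmetry"]);
  const double evokedAmp = as<double>(prm["evokedAmp"]);
  const double evokedLatency = as<double>(prm["evokedLatency"]);
  const double evokedWidth = as<double>(prm["evokedWidth"]);

  const int n = times.size();
  const int m = nItems.size();
  const double t0 = times[0], t1 = times[n - 1];
  arma::mat x(n, m, arma::fill::zeros);

  NumericVector phi0 = runif(m, 0.0, 2.0 * M_PI);

  // theta carrier (possibly skewed), amplitude grows with sequence load;
  // the sinusoidal case uses an incremental phase rotation (no per-sample
  // trig), the skewed case evaluates the warp per sample
  for (int e = 0; e < m; ++e) {
    double ampFull = base + slope * nItems[e];
    if (asym == 0.0) {
      std::complex<double> rot = std::polar(1.0, 2.0 * M_PI * f * times[0] +
                                            phi0[e]);
      const std::complex<double> step = std::polar(1.0, 2.0 * M_PI * f / fs);
      for (int i = 0; i < n; ++i) {
        double amp = (std::isfinite(modOnset) && times[i] < modOnset) ? base
                                                                      : ampFull;
        x(i, e) = -amp * rot.real();
        rot *= step;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double cyc = f * times[i] + phi0[e] / (2.0 * M_PI);
        double u = cyc - std::floor(cyc);
        double amp = (std::isfinite(modOnset) && times[i] < modOnset) ? base
                                                                      : ampFull;
        x(i, e) = -amp * std::cos(warpPhase(u, asym));
      }
    }
  }

  // high-theta carrier (no bursts attached), sinusoidal
  if (baseH > 0) {
    NumericVector phiH = runif(m, 0.0, 2.0 * M_PI);
    for (int e = 0; e < m; ++e) {
      double ampFull = baseH + slopeH * nItems[e];
      std::complex<double> rot = std::polar(1.0, 2.0 * M_PI * fHigh * times[0] +
                                            phiH[e]);
      const std::complex<double> step = std::polar(1.0, 2.0 * M_PI * fHigh / fs);
      for (int i = 0; i < n; ++i) {
        double amp = (std::isfinite(modOnset) && times[i] < modOnset) ? baseH
                                                                      : ampFull;
        x(i, e) -= amp * rot.real();
        rot *= step;
      }
    }
  }

  // gamma bursts: per theta cycle, nItems bursts at jittered preferred
  // phases, each a Gaussian-windowed piece of the band's carrier
  double tbMin = std::isfinite(modOnset) ? std::max(t0, modOnset) : t0;
  for (int b = 0; b < 2; ++b) {
    double gAmp = gammaAmp[b];
    if (gAmp <= 0) continue;
    double fg = gammaFreqs[b];
    double sigB = burstWidthCycles / (6.0 * fg);
    int halfSupp = std::max(1, (int)std::ceil(3.0 * sigB * fs));
    NumericVector gam0 = runif(m, 0.0, 2.0 * M_PI);
    for (int e = 0; e < m; ++e) {
      int nv = nItems[e];
      if (nv < 1) continue;
      double delta = std::min(itemSpacing, 2.0 * M_PI / nv);
      double sigma = 1.0 / std::sqrt(std::max(kappa0 - dispSlope * nv, 0.25));
      int kmin = (int)std::floor(f * tbMin) - 1;
      int kmax = (int)std::ceil(f * t1) + 1;
      for (int k = kmin; k <= kmax; ++k) {
        for (int j = 1; j <= nv; ++j) {
          double pref = M_PI + (j - (nv + 1) / 2.0) * delta;
          double psi = pref + R::rnorm(0.0, sigma);
          double u = unwarpPhase(psi, asym);
          double tb = (k + u - phi0[e] / (2.0 * M_PI)) / f;
          if (tb < tbMin || tb > t1) continue;
          int c = (int)std::lround((tb - t0) * fs);
          for (int s = -halfSupp; s <= halfSupp; ++s) {
            int idx = c + s;
            if (idx < 0 || idx >= n) continue;
            double dt = s / fs;
            x(idx, e) += gAmp * std::exp(-dt * dt / (2.0 * sigB * sigB)) *
              std::cos(2.0 * M_PI * fg * times[idx] + gam0[e]);
          }
        }
      }
    }
  }

  // 1/f^chi background: sample the white complex spectrum directly, shape
  // by f^(-chi/2), inverse transform; Re and Im are independent epochs
  if (noiseScale > 0) {
    if (chi == 0.0) {
      for (int e = 0; e < m; ++e) {
        NumericVector w = rnorm(n, 0.0, noiseScale);
        for (int i = 0; i < n; ++i) x(i, e) += w[i];
      }
    } else {
      int m2 = (m + 1) / 2;
      arma::vec H(n);
      H[0] = 0.0;
      for (int k = 1; k < n; ++k) {
        double fk = std::min(k, n - k) * fs / n;
        H[k] = std::pow(fk, -chi / 2.0);
      }
      H *= n / std::sqrt(arma::accu(arma::square(H)));
      arma::cx_mat W(n, m2);
      for (int c = 0; c < m2; ++c) {
        NumericVector re = rnorm(n), im = rnorm(n);
        for (int i = 0; i < n; ++i)
          W(i, c) = std::complex<double>(re[i], im[i]) * H[i];
      }
      arma::cx_mat Z = arma::ifft(W);
      for (int e = 0; e < m; ++e) {
        int c = e % m2;
        bool useRe = e < m2;
        for (int i = 0; i < n; ++i)
          x(i, e) += noiseScale * (useRe ? Z(i, c).real() : Z(i, c).imag());
      }
    }
  }

  // phase-locked evoked transient, identical in every epoch
  if (evokedAmp > 0) {
    double sigE = evokedWidth / 6.0;
    for (int i = 0; i < n; ++i) {
      double dt = times[i] - evokedLatency;
      double v = evokedAmp * std::exp(-dt * dt / (2.0 * sigE * sigE)) *
        std::cos(2.0 * M_PI * f * dt);
      if (v != 0.0) for (int e = 0; e < m; ++e) x(i, e) += v;
    }
  }
  return x;
}

// Multi-band analytic summaries for one participant's epoch matrix: for
// every band, per-epoch raw band power over the window (own filter mask);
// for amplitude bands, additionally the amplitude-weighted mean vector
// length against the phase band and the power covariates evaluated on the
// phase band's (widest) mask. One shared forward FFT.
// taps: list of FIR coefficient vectors; phaseBand: 1-based index (its
// mask indexes the PAC window); winIdx: 1-based window sample indices.
// [[Rcpp::export]]
List cppBandOutcomes(const arma::mat& x, List taps, int phaseBand,
                     IntegerVector winIdx, bool normalize, int nfft) {
  const int n = x.n_rows, m = x.n_cols, B = taps.size();
  arma::cx_mat X = arma::fft(arma::join_cols(
    x, arma::mat(nfft - n, m, arma::fill::zeros)));

  // Hilbert one-sided weights
  arma::vec u(nfft, arma::fill::zeros);
  int half = nfft / 2;
  u[0] = 1.0;
  if (nfft % 2 == 0) {
    for (int k = 1; k < half; ++k) u[k] = 2.0;
    u[half] = 1.0;
  } else {
    for (int k = 1; k <= half; ++k) u[k] = 2.0;
  }

  // per-band analytic signals, kept only where needed
  std::vector<arma::uvec> ownIdx(B);
  std::vector<int> halfLen(B);
  arma::cx_mat zPhase;          // phase band restricted to its window
  arma::uvec phaseIdx;
  List powerOwn(B), mvl(B), powerPhaseIdx(B);

  // precompute band masks and window indices
  for (int b = 0; b < B; ++b) {
    NumericVector tp = taps[b];
    halfLen[b] = (int)std::ceil(tp.size() / 2.0);
    std::vector<arma::uword> idx;
    for (int q = 0; q < winIdx.size(); ++q) {
      int i0 = winIdx[q] - 1;                      // 0-based
      if (i0 >= halfLen[b] && i0 < n - halfLen[b]) idx.push_back(i0);
    }
    ownIdx[b] = arma::uvec(idx);
  }
  phaseIdx = (phaseBand >= 1) ? ownIdx[phaseBand - 1] : arma::uvec();

  for (int b = 0; b < B; ++b) {
    NumericVector tp = taps[b];
    arma::vec tv(tp.begin(), tp.size());
    arma::cx_vec Hc = arma::fft(arma::join_cols(
      tv, arma::vec(nfft - tv.n_elem, arma::fill::zeros)));
    arma::vec G = arma::square(arma::abs(Hc)) % u;
    arma::cx_mat z = arma::ifft(arma::cx_mat(X.each_col() %
      arma::conv_to<arma::cx_vec>::from(G)));
    z = z.head_rows(n);

    arma::mat amp2own = arma::square(arma::abs(z.rows(ownIdx[b])));
    powerOwn[b] = wrap(arma::conv_to<arma::rowvec>::from(
      arma::mean(amp2own, 0) / 2.0));

    if (phaseBand >= 1 && b == phaseBand - 1) {
      zPhase = z.rows(phaseIdx);
      arma::mat a2 = arma::square(arma::abs(zPhase));
      powerPhaseIdx[b] = wrap(arma::conv_to<arma::rowvec>::from(
        arma::mean(a2, 0) / 2.0));
      mvl[b] = R_NilValue;
    } else if (phaseBand >= 1) {
      arma::mat am = arma::abs(z.rows(phaseIdx));
      arma::mat a2 = arma::square(am);
      powerPhaseIdx[b] = wrap(arma::conv_to<arma::rowvec>::from(
        arma::mean(a2, 0) / 2.0));
      // unit phasors of the phase band
      arma::cx_mat ph = zPhase / arma::conv_to<arma::cx_mat>::from(
        arma::abs(zPhase));
      arma::cx_rowvec num = arma::sum(arma::cx_mat(ph %
        arma::conv_to<arma::cx_mat>::from(am)), 0);
      arma::rowvec den = normalize ? arma::rowvec(arma::sum(am, 0))
        : arma::rowvec(m, arma::fill::value((double)am.n_rows));
      mvl[b] = wrap(arma::conv_to<arma::rowvec>::from(arma::abs(num) / den));
    } else {
      powerPhaseIdx[b] = R_NilValue;
      mvl[b] = R_NilValue;
    }
  }
  return List::create(_["power"] = powerOwn, _["mvl"] = mvl,
                      _["power_phase_idx"] = powerPhaseIdx,
                      _["n_phase_samples"] = (int)phaseIdx.n_elem);
}
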