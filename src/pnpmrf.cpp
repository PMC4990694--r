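// Core numerical kernels: batched EPG fingerprint simulation and the exact
// non-uniform DFT used for radial k-space encoding. The NDFT exploits the
// uniform sample spacing along each spoke: the complex exponential along a
// spoke is a geometric progression per pixel, so only two sin/cos evaluations
// per (pixel, spoke) pair are needed instead of one per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const std::complex<double> I_UNIT(0.0, 1.0);

// Batched extended-phase-graph simulation.
//
// States per entry: F+_k, F-_k (= conj F+ at -k), Z_k for orders 0..k_max.
// Per excitation: RF mixing, echo read-out at TE (F+_0 scaled by transverse
// decay over TE, demodulated by the schedule RF phase), full-TR relaxation,
// one gradient-spoiler shift, then an optional post-TR recovery delay with
// its own spoiler shift (inter-segment delay).
//
// flip, phase: L x n (per excitation, per entry), radians
// demod:       L, schedule RF phase removed from the recorded signal
// t1, t2, m0:  n tissue vectors (ms, ms, a.u.)
// te:          echo time (ms); tr: L per-excitation repetition intervals (ms)
// extra_delay: L post-TR recovery delays (ms, 0 for most excitations)
// k_max:       highest retained dephasing order
// [[Rcpp::export]]
Rcpp::List cpp_epg_fingerprints(const arma::mat& flip, const arma::mat& phase,
                                const arma::vec& demod,
                                const arma::vec& t1, const arma::vec& t2,
                                const arma::vec& m0,
                                double te, const arma::vec& tr,
                                const arma::vec& extra_delay, int k_max) {
  const unsigned int L = flip.n_rows, n = flip.n_cols;
  cx_mat signal(L, n, fill::zeros);
  bool truncated = false;
  const double trunc_tol = 1e-14;

  cx_vec dem(L);
  for (unsigned int j = 0; j < L; ++j) dem(j) = std::exp(-I_UNIT * demod(j));

  for (unsigned int col = 0; col < n; ++col) {
    const double T1 = t1(col), T2 = t2(col), M0 = m0(col);
    std::vector<std::complex<double>> Fp(k_max + 1, 0.0), Fm(k_max + 1, 0.0),
        Z(k_max + 1, 0.0);
    Z[0] = M0;
    int kact = 0;  // highest potentially populated order
    const double e2te = std::exp(-te / T2);

    auto relax = [&](double dt) {
      const double e1 = std::exp(-dt / T1), e2 = std::exp(-dt / T2);
      for (int k = 0; k <= kact; ++k) {
        Fp[k] *= e2;
        Fm[k] *= e2;
        Z[k] *= e1;
      }
      Z[0] += (1.0 - e1) * M0;
    };
    auto shift = [&]() {
      if (kact == k_max &&
          (std::abs(Fp[k_max]) > trunc_tol || std::abs(Z[k_max]) > trunc_tol))
        truncated = true;
      const int ktop = std::min(kact + 1, k_max);
      for (int k = ktop; k >= 1; --k) Fp[k] = Fp[k - 1];
      Fp[0] = std::conj(Fm[1]);
      for (int k = 0; k < ktop; ++k) Fm[k] = Fm[k + 1];
      Fm[ktop] = 0.0;
      kact = ktop;
    };

    for (unsigned int j = 0; j < L; ++j) {
      const double a = flip(j, col), p = phase(j, col);
      const double ca = std::cos(a), sa = std::sin(a);
      const double c2 = 0.5 * (1.0 + ca), s2 = 0.5 * (1.0 - ca);
      const std::complex<double> eip = std::exp(I_UNIT * p), ei2p = eip * eip;
      const std::complex<double> t12 = ei2p * s2, t13 = -I_UNIT * eip * sa;
      const std::complex<double> t21 = std::conj(ei2p) * s2,
                                 t23 = I_UNIT * std::conj(eip) * sa;
      const std::complex<double> t31 = -0.5 * I_UNIT * std::conj(eip) * sa,
                                 t32 = 0.5 * I_UNIT * eip * sa;
      for (int k = 0; k <= kact; ++k) {
        const std::complex<double> fp = Fp[k], fm = Fm[k], z = Z[k];
        Fp[k] = c2 * fp + t12 * fm + t13 * z;
        Fm[k] = t21 * fp + c2 * fm + t23 * z;
        Z[k] = t31 * fp + t32 * fm + ca * z;
      }
      signal(j, col) = Fp[0] * e2te * dem(j);
      relax(tr(j));
      shift();
      if (extra_delay(j) > 0.0) {
        relax(extra_delay(j));
        shift();
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("signal") = signal,
                            Rcpp::Named("truncated") = truncated);
}

// Exact non-uniform DFT of a Cartesian image at radial spoke samples.
// Sample s on spoke q sits at radius r0 + s*dr (cycles/FOV) along direction
// (cos_t[q], sin_t[q]); pixel (i, j) has coordinates ((i - M/2)/M, (j - M/2)/M)
// in FOV units. Returns nsamp x nspokes.
// [[Rcpp::export]]
arma::cx_mat cpp_ndft_forward(const arma::cx_mat& img, const arma::vec& cos_t,
                              const arma::vec& sin_t, double r0, double dr,
                              int nsamp) {
  const int M = img.n_rows, nq = cos_t.n_elem;
  cx_mat out(nsamp, nq, fill::zeros);
  const double twopi = 2.0 * M_PI;
  std::vector<double> xc(M);
  for (int i = 0; i < M; ++i) xc[i] = (i - M / 2) / static_cast<double>(M);

  // manual re/im arithmetic: the checked std::complex multiply (__muldc3)
  // dominates run time otherwise
  std::vector<double> ar(nsamp), ai(nsamp);
  for (int q = 0; q < nq; ++q) {
    const double c = cos_t(q), s = sin_t(q);
    std::fill(ar.begin(), ar.end(), 0.0);
    std::fill(ai.begin(), ai.end(), 0.0);
    for (int j = 0; j < M; ++j) {
      const double ys = xc[j] * s;
      const std::complex<double>* ic = img.colptr(j);
      for (int i = 0; i < M; ++i) {
        const double vr = ic[i].real(), vi = ic[i].imag();
        if (vr == 0.0 && vi == 0.0) continue;
        const double u = xc[i] * c + ys;
        double pr = std::cos(twopi * r0 * u), pi_ = -std::sin(twopi * r0 * u);
        const double sr = std::cos(twopi * dr * u),
                     si = -std::sin(twopi * dr * u);
        for (int k = 0; k < nsamp; ++k) {
          ar[k] += vr * pr - vi * pi_;
          ai[k] += vr * pi_ + vi * pr;
          const double t = pr * sr - pi_ * si;
          pi_ = pr * si + pi_ * sr;
          pr = t;
        }
      }
    }
    std::complex<double>* acc = out.colptr(q);
    for (int k = 0; k < nsamp; ++k) acc[k] = std::complex<double>(ar[k], ai[k]);
  }
  return out;
}

// Adjoint of cpp_ndft_forward with per-sample weights (density compensation
// and/or apodization, radius-dependent so shared across spokes).
// data: nsamp x nspokes. Returns M x M image.
// [[Rcpp::export]]
arma::cx_mat cpp_ndft_adjoint(const arma::cx_mat& data, const arma::vec& cos_t,
                              const arma::vec& sin_t, const arma::vec& wts,
                              double r0, double dr, int M) {
  const int nsamp = data.n_rows, nq = data.n_cols;
  cx_mat img(M, M, fill::zeros);
  const double twopi = 2.0 * M_PI;
  std::vector<double> xc(M);
  for (int i = 0; i < M; ++i) xc[i] = (i - M / 2) / static_cast<double>(M);
  std::vector<double> wr(nsamp), wi(nsamp);

  for (int q = 0; q < nq; ++q) {
    const double c = cos_t(q), s = sin_t(q);
    bool any = false;
    for (int k = 0; k < nsamp; ++k) {
      wr[k] = wts(k) * data(k, q).real();
      wi[k] = wts(k) * data(k, q).imag();
      if (wr[k] != 0.0 || wi[k] != 0.0) any = true;
    }
    if (!any) continue;
    for (int j = 0; j < M; ++j) {
      const double ys = xc[j] * s;
      std::complex<double>* ic = img.colptr(j);
      for (int i = 0; i < M; ++i) {
        const double u = xc[i] * c + ys;
        double pr = std::cos(twopi * r0 * u), pi_ = std::sin(twopi * r0 * u);
        const double sr = std::cos(twopi * dr * u),
                     si = std::sin(twopi * dr * u);
        double accr = 0.0, acci = 0.0;
        for (int k = 0; k < nsamp; ++k) {
          accr += wr[k] * pr - wi[k] * pi_;
          acci += wr[k] * pi_ + wi[k] * pr;
          const double t = pr * sr - pi_ * si;
          pi_ = pr * si + pi_ * sr;
          pr = t;
        }
        ic[i] += std::complex<double>(accr, acci);
      }
    }
  }
  return img;
}
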