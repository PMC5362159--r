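#include <Rcpp.h>
using namespace Rcpp;

// log(p) and log(1-p) for p = plogis(z), overflow-safe in both tails.
static inline void logit_logprobs(double z, double &lp, double &l1mp) {
  if (z >= 0) {
    const double e = std::exp(-z);
    const double l = std::log1p(e);
    lp = -l;
    l1mp = -z - l;
  } else {
    const double e = std::exp(z);
    const double l = std::log1p(e);
    lp = z - l;
    l1mp = -l;
  }
}

// Bootstrap particle filter for the methylation SSMs, fully in compiled
// code: RSR resampling, (mixture) random-walk transition and the
// random-weight binomial observation with logit-normal replicate effects.
// Uses R's RNG so seeded streams behave exactly as in the R filter.
// lchoose_c holds the precomputed log-binomial coefficients (T x K).
// Returns the log-likelihood estimate and the per-step log mean weights.
// [[Rcpp::export(name = ".meth_pf_cpp")]]
List meth_pf_cpp(IntegerMatrix y, IntegerMatrix n, NumericMatrix lchoose_c,
                 IntegerVector gaps, double sigma1_sq, double sigma2_sq,
                 bool mixture, double beta_sq, int P) {
  const int T = y.nrow(), K = y.ncol();
  std::vector<double> x(P), xnew(P), logw(P), w(P);
  std::vector<int> counts(P);
  NumericVector per_step(T, NA_REAL);
  const double beta_sd = std::sqrt(beta_sq);
  double ll = 0.0;
  bool degenerate = false;

  for (int t = 0; t < T; ++t) {
    if (t == 0) {
      for (int p = 0; p < P; ++p) x[p] = norm_rand();
    } else {
      // normalise previous weights and resample (RSR, one uniform per step)
      double mx = R_NegInf;
      for (int p = 0; p < P; ++p) if (logw[p] > mx) mx = logw[p];
      double s = 0.0;
      for (int p = 0; p < P; ++p) { w[p] = std::exp(logw[p] - mx); s += w[p]; }
      double u = unif_rand() / P;
      long total = 0;
      for (int p = 0; p < P; ++p) {
        const double wp = w[p] / s;
        long r = (long)std::floor((wp - u) * P) + 1;
        if (r < 0) r = 0;
        counts[p] = (int)r;
        u += (double)r / P - wp;
        total += r;
      }
      if (total != P) {
        int imax = 0;
        for (int p = 1; p < P; ++p) if (w[p] > w[imax]) imax = p;
        counts[imax] += (int)(P - total);
      }
      // expand counts into the resampled set and propagate
      const double sd1 = std::sqrt(sigma1_sq * gaps[t]);
      const double sd2 = mixture ? std::sqrt(sigma2_sq * gaps[t]) : sd1;
      int q = 0;
      for (int p = 0; p < P; ++p)
        for (int c = 0; c < counts[p]; ++c) xnew[q++] = x[p];
      for (int p = 0; p < P; ++p) {
        const double sd = (mixture && unif_rand() >= 0.5) ? sd2 : sd1;
        x[p] = xnew[p] + sd * norm_rand();
      }
    }

    // random-weight observation: fresh logit-normal effect per particle
    // and replicate, then the binomial log-pmf
    for (int p = 0; p < P; ++p) logw[p] = 0.0;
    for (int k = 0; k < K; ++k) {
      const int yk = y(t, k), nk = n(t, k);
      const double ck = lchoose_c(t, k);
      for (int p = 0; p < P; ++p) {
        const double z = x[p] + beta_sd * norm_rand();
        double lp, l1mp;
        logit_logprobs(z, lp, l1mp);
        logw[p] += ck + yk * lp + (nk - yk) * l1mp;
      }
    }

    double mx = R_NegInf;
    for (int p = 0; p < P; ++p) if (logw[p] > mx) mx = logw[p];
    if (!R_finite(mx)) { degenerate = true; break; }
    double s = 0.0;
    for (int p = 0; p < P; ++p) s += std::exp(logw[p] - mx);
    per_step[t] = mx + std::log(s / P);
    ll += per_step[t];
  }

  return List::create(_["log_likelihood"] = degenerate ? R_NegInf : ll,
                      _["per_step_log_means"] = per_step,
                      _["degenerate"] = degenerate);
}
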