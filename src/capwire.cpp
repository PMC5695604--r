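// Integer likelihood searches for continuous-occasion abundance models
// (even-capture ECM and two-innate-rates TIRM).
//
// TIRM likelihood, marginal over the unobserved classification:
//   L(N, n_b, alpha) = N!/(N-n)! * R^{-s} *
//       sum_j C(N-n, n_b-j)/C(N, n_b) * E_j(alpha^{c_1},...,alpha^{c_n})
// where E_j is the elementary symmetric polynomial over the observed
// counts' rate weights (the sum over which j observed individuals are
// high-rate), R = n_a + alpha*n_b, n_a = N - n_b.  At alpha = 1 the
// Vandermonde identity collapses the sum to 1 and the ECM likelihood
// N!/(N-n)! * N^{-s} is recovered exactly, so ECM is a true submodel.
// The rate ratio alpha is profiled on a log grid and refined locally.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// logL(N) = lgamma(N+1) - lgamma(N-n+1) - s*log(N), N = n..max_pop
// [[Rcpp::export]]
NumericVector ecm_profile_cpp(int n, double s, int max_pop) {
  NumericVector out(max_pop - n + 1);
  for (int N = n; N <= max_pop; ++N)
    out[N - n] = std::lgamma(N + 1.0) - std::lgamma(N - n + 1.0) -
      s * std::log((double)N);
  return out;
}

namespace {

struct TirmWork {
  std::vector<double> counts;   // observed counts
  double s;
  int n, max_pop;
  std::vector<double> lgam;     // lgam[i] = lgamma(i+1)
  std::vector<double> lE;       // log E_j for current alpha
  double cur_alpha = -1.0;

  TirmWork(NumericVector cnt, int mp) {
    n = cnt.size();
    max_pop = mp;
    s = 0.0;
    counts.resize(n);
    for (int i = 0; i < n; ++i) { counts[i] = cnt[i]; s += cnt[i]; }
    lgam.resize(max_pop + 2);
    for (int i = 0; i <= max_pop + 1; ++i) lgam[i] = std::lgamma(i + 1.0);
    lE.resize(n + 1);
  }

  double lchoose_(int a, int b) const {
    if (b < 0 || b > a) return R_NegInf;
    return lgam[a] - lgam[b] - lgam[a - b];
  }

  // log elementary symmetric polynomials of alpha^{c_i}
  void set_alpha(double alpha) {
    if (alpha == cur_alpha) return;
    cur_alpha = alpha;
    std::fill(lE.begin(), lE.end(), R_NegInf);
    lE[0] = 0.0;
    double la = std::log(alpha);
    for (int i = 0; i < n; ++i) {
      double lx = counts[i] * la;
      for (int j = std::min(i + 1, n); j >= 1; --j) {
        double a = lE[j], b = lx + lE[j - 1];
        double m = std::max(a, b);
        lE[j] = (m == R_NegInf) ? R_NegInf :
          m + std::log(std::exp(a - m) + std::exp(b - m));
      }
    }
  }

  double loglik(int N, int nb, double alpha) {
    if (N < n || nb < 0 || nb > N) return R_NegInf;
    set_alpha(alpha);
    int na = N - nb;
    double R = (double)na + (double)nb * alpha;
    int jlo = std::max(0, n - na), jhi = std::min(nb, n);
    if (jlo > jhi) return R_NegInf;
    double mx = R_NegInf;
    std::vector<double> terms(jhi - jlo + 1);
    for (int j = jlo; j <= jhi; ++j) {
      double t = lchoose_(N - n, nb - j) - lchoose_(N, nb) + lE[j];
      terms[j - jlo] = t;
      if (t > mx) mx = t;
    }
    if (mx == R_NegInf) return R_NegInf;
    double sum = 0.0;
    for (double t : terms) sum += std::exp(t - mx);
    return lgam[N] - lgam[N - n] + mx + std::log(sum) - s * std::log(R);
  }
};

} // namespace

// [[Rcpp::export]]
List tirm_search_cpp(NumericVector counts, int max_pop,
                     NumericVector alpha_grid) {
  TirmWork w(counts, max_pop);
  int n = w.n;

  double best = R_NegInf, balpha = 1.0;
  int bN = n, bnb = 0;
  auto consider = [&](int N, int nb, double alpha) {
    double ll = w.loglik(N, nb, alpha);
    if (ll > best) { best = ll; bN = N; bnb = nb; balpha = alpha; }
  };

  // ECM submodel (nb = 0, alpha = 1)
  for (int N = n; N <= max_pop; ++N) {
    double ll = w.lgam[N] - w.lgam[N - n] - w.s * std::log((double)N);
    if (ll > best) { best = ll; bN = N; bnb = 0; balpha = 1.0; }
  }

  int Nstep = std::max(1, (max_pop - n) / 40);
  // coarse pass over the alpha grid
  for (int ai = 0; ai < alpha_grid.size(); ++ai) {
    double alpha = alpha_grid[ai];
    for (int N = n; N <= max_pop; N += Nstep) {
      int nbstep = std::max(1, N / 25);
      for (int nb = 1; nb <= N - 1; nb += nbstep)
        consider(N, nb, alpha);
    }
  }

  // refine alpha around the best grid point, with local (N, nb) search
  for (int round = 0; round < 2; ++round) {
    double la = std::log(balpha <= 1.0 ? 1.02 : balpha);
    double span = (round == 0) ? 0.5 : 0.15;  // log-scale half-width
    int Nw = (round == 0) ? 2 * Nstep : 8;
    int nbw = (round == 0) ? std::max(4, bN / 12) : 6;
    int bN0 = bN, bnb0 = bnb;
    for (int k = -3; k <= 3; ++k) {
      double alpha = std::exp(la + span * k / 3.0);
      if (alpha < 1.0) alpha = 1.0;
      for (int N = std::max(n, bN0 - Nw); N <= std::min(max_pop, bN0 + Nw);
           ++N)
        for (int nb = std::max(0, bnb0 - nbw);
             nb <= std::min(N - 1, bnb0 + nbw); ++nb)
          consider(N, nb, alpha);
    }
  }

  return List::create(_["logL"] = best, _["N"] = bN, _["n_b"] = bnb,
                      _["alpha"] = balpha);
}
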