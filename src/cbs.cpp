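#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation scan: over all arcs (i, j] of x (0 <= i < j
// <= n, arc != whole), the two-sided t-like statistic
//   T(i,j) = |mean_in - mean_out| / sqrt(sigma2 * (1/k + 1/(n-k)))
// with sigma2 the overall (population) variance of x, held fixed so the
// statistic is permutation-comparable. Leftmost maximizer wins ties.
static double scan_max(const std::vector<double>& S, int n, double sigma2,
                       int* bi, int* bj) {
  double best = -1.0;
  const double tot = S[n];
  for (int i = 0; i < n; ++i) {
    const double Si = S[i];
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i;
      if (k == n) continue;
      const double in = (S[j] - Si) / k;
      const double out = (tot - (S[j] - Si)) / (n - k);
      const double t = std::fabs(in - out) /
        std::sqrt(sigma2 * (1.0 / k + 1.0 / (n - k)));
      if (t > best) { best = t; if (bi) *bi = i; if (bj) *bj = j; }
    }
  }
  return best;
}

static void prefix(const std::vector<double>& x, std::vector<double>& S) {
  S[0] = 0.0;
  for (size_t i = 0; i < x.size(); ++i) S[i + 1] = S[i] + x[i];
}

// [[Rcpp::export(name = ".cbsScan")]]
List cbsScan(NumericVector x) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end()), S(n + 1);
  prefix(v, S);
  double mu = S[n] / n, ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (v[i] - mu) * (v[i] - mu);
  const double sigma2 = ss / n;
  if (n < 2 || sigma2 <= 0.0)
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n);
  int bi = 0, bj = n;
  double best = scan_max(S, n, sigma2, &bi, &bj);
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Permutation test with early stopping: shuffles x (R RNG, so results are
// reproducible under set.seed), recomputes the max scan statistic, and
// stops as soon as the exceedance count reaches ceil(alpha * nperm) --
// at that point p >= alpha is certain and the split will be rejected.
// [[Rcpp::export(name = ".cbsSplitTest")]]
List cbsSplitTest(NumericVector x, int nperm, double alpha) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end()), S(n + 1);
  prefix(v, S);
  double mu = S[n] / n, ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (v[i] - mu) * (v[i] - mu);
  const double sigma2 = ss / n;
  if (n < 2 || sigma2 <= 0.0)
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n,
                        _["p"] = 1.0);
  int bi = 0, bj = n;
  const double obs = scan_max(S, n, sigma2, &bi, &bj);
  const int stopCount = (int)std::ceil(alpha * nperm);
  int exceed = 0, used = 0;
  std::vector<double> w(v);
  for (int b = 0; b < nperm; ++b) {
    for (int k = n - 1; k > 0; --k) {  // Fisher-Yates via R RNG
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(w[k], w[idx]);
    }
    prefix(w, S);
    if (scan_max(S, n, sigma2, nullptr, nullptr) >= obs) ++exceed;
    ++used;
    if (exceed >= stopCount) break;
  }
  const double p = (double)exceed / (double)used;
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj, _["p"] = p);
}
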