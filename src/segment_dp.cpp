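#include <Rcpp.h>
using namespace Rcpp;

// Maximum-a-posteriori segmentation of a Poisson count sequence into
// constant-rate blocks.  Emission model per block: Poisson with rate drawn
// from a conjugate Gamma(alpha, beta) prior, integrated out, giving the
// negative-binomial marginal likelihood
//   lml(S, L) = alpha*log(beta) - lgamma(alpha)
//             + lgamma(alpha + S) - (alpha + S) * log(beta + L)
// (the partition-independent term -sum lgamma(y_i + 1) is dropped).
// Block prior: each bin terminates its block with probability p, i.e. a
// geometric prior on block lengths, contributing
//   (L - 1) * log(1 - p) + log(p)
// per block.  The dynamic program maximizes the summed block scores; the
// lookback is capped at max_block bins for speed (blocks longer than the
// cap are represented as runs of equal-rate segments only if the cap binds,
// so the cap defaults to a value far above typical enriched-domain sizes).
//
// [[Rcpp::export]]
List segment_dp_cpp(IntegerVector counts, double alpha, double beta,
                    double p, int max_block) {
  int n = counts.size();
  if (n == 0) stop("empty track");
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + counts[i];
  const double lp = std::log(p), l1p = std::log1p(-p);
  const double lconst = alpha * std::log(beta) - ::Rf_lgammafn(alpha);
  std::vector<double> best(n + 1, R_NegInf);
  std::vector<int> back(n + 1, 0);
  best[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    int i0 = std::max(0, j - max_block);
    for (int i = i0; i < j; ++i) {
      double S = cs[j] - cs[i];
      double L = j - i;
      double sc = best[i] + lconst + ::Rf_lgammafn(alpha + S) -
                  (alpha + S) * std::log(beta + L) + (L - 1.0) * l1p + lp;
      if (sc > best[j]) {
        best[j] = sc;
        back[j] = i;
      }
    }
  }
  std::vector<int> bounds;
  int j = n;
  while (j > 0) {
    bounds.push_back(j);
    j = back[j];
  }
  std::reverse(bounds.begin(), bounds.end());
  int k = bounds.size();
  IntegerVector start(k), end(k);
  NumericVector rate(k);
  int prev = 0;
  for (int b = 0; b < k; ++b) {
    start[b] = prev;            // 0-based bin index, half-open
    end[b] = bounds[b];
    double S = cs[end[b]] - cs[prev];
    rate[b] = (alpha + S) / (beta + (end[b] - prev));  // posterior mean rate
    prev = bounds[b];
  }
  return List::create(_["start_bin"] = start, _["end_bin"] = end,
                      _["post_mean_rate"] = rate,
                      _["log_posterior"] = best[n]);
}
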