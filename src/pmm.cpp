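#include <Rcpp.h>
using namespace Rcpp;

//' Nearest-predicted-mean donor draw (predictive mean matching kernel)
//'
//' For each missing-row prediction, finds the k observed rows with nearest
//' predicted means (two-pointer scan around the insertion point in the
//' sorted predictions) and returns the observed value of one of them,
//' selected by the supplied uniform draw.
//'
//' @param hs sorted observed predictions
//' @param ys observed values, in the same order as \code{hs}
//' @param hmis predictions for the missing rows
//' @param k donor-pool size
//' @param u uniform(0,1) draws, one per missing row
//' @keywords internal
// [[Rcpp::export]]
NumericVector pmm_match(NumericVector hs, NumericVector ys,
                        NumericVector hmis, int k, NumericVector u) {
  int n = hs.size(), m = hmis.size();
  NumericVector out(m);
  int kk = std::min(k, n);
  for (int i = 0; i < m; ++i) {
    double h = hmis[i];
    int right = std::lower_bound(hs.begin(), hs.end(), h) - hs.begin();
    int left = right - 1;
    std::vector<int> pool;
    pool.reserve(kk);
    for (int t = 0; t < kk; ++t) {
      if (left >= 0 && (right >= n || h - hs[left] <= hs[right] - h))
        pool.push_back(left--);
      else
        pool.push_back(right++);
    }
    int pick = (int)(u[i] * kk);
    if (pick >= kk) pick = kk - 1;
    out[i] = ys[pool[pick]];
  }
  return out;
}
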