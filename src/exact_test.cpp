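#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Markov-chain estimate of the exact conditional probability (margins
// fixed) that a contingency table is no more probable than the observed
// one -- the chain of Raymond & Rousset (1995): repeatedly pick two rows
// and two columns and propose a +/-1 "checkerboard" switch, accepted by
// the Metropolis rule under the multivariate hypergeometric measure.
// Ties (equal probability) count as extreme.

// [[Rcpp::export]]
List cpp_mc_exact(IntegerMatrix tab, int dememorize, int batches,
                  int iter_per_batch) {
  int R = tab.nrow(), C = tab.ncol();
  if (R < 2 || C < 2)
    return List::create(_["p"] = 1.0, _["se"] = 0.0);
  std::vector<int> x(tab.begin(), tab.end());  // column-major
  auto cell = [&](int r, int c) -> int& { return x[c * R + r]; };

  double logp = 0.0;
  for (size_t i = 0; i < x.size(); ++i) logp -= R::lgammafn(x[i] + 1.0);
  const double logp_obs = logp, tie_eps = 1e-9;

  auto step = [&]() {
    int r1 = (int)(R::unif_rand() * R), r2 = (int)(R::unif_rand() * (R - 1));
    if (r2 >= r1) ++r2;
    int c1 = (int)(R::unif_rand() * C), c2 = (int)(R::unif_rand() * (C - 1));
    if (c2 >= c1) ++c2;
    // delta = +1 : x[r1,c1]++, x[r2,c2]++, x[r1,c2]--, x[r2,c1]--
    int delta = (R::unif_rand() < 0.5) ? 1 : -1;
    int a = cell(r1, c1), b = cell(r2, c2), u = cell(r1, c2), v = cell(r2, c1);
    double ratio;
    if (delta == 1) {
      if (u == 0 || v == 0) return;
      ratio = (double)u * v / ((double)(a + 1) * (b + 1));
    } else {
      if (a == 0 || b == 0) return;
      ratio = (double)a * b / ((double)(u + 1) * (v + 1));
    }
    if (ratio >= 1.0 || R::unif_rand() < ratio) {
      cell(r1, c1) += delta; cell(r2, c2) += delta;
      cell(r1, c2) -= delta; cell(r2, c1) -= delta;
      logp += std::log(ratio);
    }
  };

  for (int i = 0; i < dememorize; ++i) step();
  std::vector<double> pb(batches, 0.0);
  for (int b = 0; b < batches; ++b) {
    int hit = 0;
    for (int i = 0; i < iter_per_batch; ++i) {
      step();
      if (logp <= logp_obs + tie_eps) ++hit;
    }
    pb[b] = (double)hit / iter_per_batch;
  }
  double p = 0.0;
  for (int b = 0; b < batches; ++b) p += pb[b];
  p /= batches;
  double v = 0.0;
  for (int b = 0; b < batches; ++b) v += (pb[b] - p) * (pb[b] - p);
  double se = batches > 1 ? std::sqrt(v / (batches - 1) / batches) : NA_REAL;
  return List::create(_["p"] = p, _["se"] = se);
}
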