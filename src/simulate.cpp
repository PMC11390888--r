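#include <Rcpp.h>
using namespace Rcpp;

// LNBRC network simulation: synchronous per 1 ms bin, strictly causal.
// drive: cells x T stimulus drive; fb: cells x Lf feedback kernels;
// coupling pairs (src -> dst) with kernels ckern (pairs x Lc).
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_lnbrc(NumericMatrix drive, NumericVector bias,
                                 NumericMatrix fb, IntegerVector src,
                                 IntegerVector dst, NumericMatrix ckern) {
  const int n = drive.nrow(), T = drive.ncol();
  const int Lf = fb.ncol();
  const int npair = src.size();
  const int Lc = npair > 0 ? ckern.ncol() : 0;
  IntegerMatrix spikes(n, T);
  // acc[i][t]: recurrent (feedback + coupling) drive accumulated from past spikes
  std::vector<double> acc((size_t)n * T, 0.0);
  // index coupling pairs by source cell
  std::vector<std::vector<int>> by_src(n);
  for (int p = 0; p < npair; ++p) by_src[src[p]].push_back(p);

  RNGScope scope;
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      double g = drive(i, t) + bias[i] + acc[(size_t)i * T + t];
      double pr = 1.0 / (1.0 + std::exp(-g));
      if (unif_rand() < pr) {
        spikes(i, t) = 1;
        const int lmaxf = std::min(Lf, T - 1 - t);
        for (int l = 0; l < lmaxf; ++l)
          acc[(size_t)i * T + t + 1 + l] += fb(i, l);
        for (int p : by_src[i]) {
          const int d = dst[p];
          const int lmaxc = std::min(Lc, T - 1 - t);
          for (int l = 0; l < lmaxc; ++l)
            acc[(size_t)d * T + t + 1 + l] += ckern(p, l);
        }
      }
    }
  }
  return spikes;
}
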