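#include <Rcpp.h>
using namespace Rcpp;

// Row-recursive score accumulation:
//   S[n,t] = A[n,t] + max_{j in 1..k} [(1-omega) * S[n-1,t-j] + omega * lp[j]]
// Each row depends only on the previous row, so cells within a row are
// independent (the parallelizable contract); this kernel just evaluates them
// in column order. Ties break toward the smallest lag; 1-based backpointers.
// [[Rcpp::export(name = ".accumulate_cpp")]]
List accumulate_cpp(NumericMatrix A, NumericVector lp, double omega,
                    Nullable<NumericVector> init_log_prior) {
  const int N = A.nrow(), T = A.ncol(), k = lp.size();
  NumericMatrix S(N, T);
  IntegerMatrix bp(N, T);
  std::fill(bp.begin(), bp.end(), NA_INTEGER);

  if (init_log_prior.isNotNull()) {
    NumericVector init(init_log_prior);
    for (int t = 0; t < T; ++t) S(0, t) = A(0, t) + init[t];
  } else {
    for (int t = 0; t < T; ++t) S(0, t) = A(0, t);
  }

  const double w = 1.0 - omega;
  for (int n = 1; n < N; ++n) {
    for (int t = 0; t < T; ++t) {
      double best = R_NegInf;
      int arg = NA_INTEGER;
      const int jmax = std::min(k, t);
      for (int j = 1; j <= jmax; ++j) {
        if (lp[j - 1] == R_NegInf) continue;  // structurally infeasible lag
        const double sp = S(n - 1, t - j);
        if (sp == R_NegInf) continue;
        const double cand = w * sp + omega * lp[j - 1];
        if (cand > best) {
          best = cand;
          arg = t - j + 1;  // 1-based column index
        }
      }
      S(n, t) = A(n, t) + best;
      bp(n, t) = arg;
    }
  }
  return List::create(_["S"] = S, _["bp"] = bp);
}
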