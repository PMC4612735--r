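#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Depth-first enumeration of smoothness-feasible cut-level vectors with
// branch-and-bound pruning. Rays are assigned in natural order; already
// assigned adjacent rays narrow the candidate window to
// [max(idx[a] - dr), min(idx[a] + dr)]. The lower bound adds the
// unconstrained per-ray minima of the remaining rays. Pruning with ">="
// keeps the first (lexicographically smallest) optimum found.
struct BfState {
  const NumericMatrix &cost;
  const std::vector<std::vector<int> > &earlier;
  int R, J, dr;
  std::vector<double> suffix_min;
  std::vector<int> idx, best_idx;
  double best_cost;

  BfState(const NumericMatrix &c,
          const std::vector<std::vector<int> > &e, int dr_)
      : cost(c), earlier(e), R(c.nrow()), J(c.ncol()), dr(dr_),
        suffix_min(R + 1, 0.0), idx(R, 0), best_idx(R, 0),
        best_cost(std::numeric_limits<double>::infinity()) {
    for (int r = R - 1; r >= 0; --r) {
      double m = cost(r, 0);
      for (int j = 1; j < J; ++j) m = std::min(m, cost(r, j));
      suffix_min[r] = suffix_min[r + 1] + m;
    }
  }

  void search(int r, double acc) {
    if (acc + suffix_min[r] >= best_cost) return;
    if (r == R) {
      best_cost = acc;
      best_idx = idx;
      return;
    }
    int lo = 0, hi = J - 1;
    for (size_t a = 0; a < earlier[r].size(); ++a) {
      int ja = idx[earlier[r][a]];
      if (ja - dr > lo) lo = ja - dr;
      if (ja + dr < hi) hi = ja + dr;
    }
    for (int j = lo; j <= hi; ++j) {
      idx[r] = j;
      search(r + 1, acc + cost(r, j));
    }
  }
};

// [[Rcpp::export]]
List bf_cut_cpp(NumericMatrix cost, IntegerMatrix adjacency, int delta_r) {
  int R = cost.nrow();
  std::vector<std::vector<int> > earlier(R);
  for (int e = 0; e < adjacency.nrow(); ++e) {
    int a = adjacency(e, 0) - 1, b = adjacency(e, 1) - 1;
    if (a > b) std::swap(a, b);
    earlier[b].push_back(a);  // constrain the later ray by the earlier one
  }
  BfState st(cost, earlier, delta_r);
  st.search(0, 0.0);
  if (!R_finite(st.best_cost))
    stop("brute-force oracle found no feasible cut vector");
  IntegerVector out(R);
  for (int r = 0; r < R; ++r) out[r] = st.best_idx[r] + 1;  // 1-based
  return List::create(_["cut_index"] = out,
                      _["total_cost"] = st.best_cost);
}
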