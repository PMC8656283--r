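#include <Rcpp.h>
using namespace Rcpp;

// Weighted sampling without replacement (successive sampling / PPSWOR,
// the scheme of R's sample(prob=) without replacement) over a Fenwick tree,
// returning for each iteration the arithmetic mean of the scores of the k
// sampled items. Used as the resampling core of the functional-mutation-
// bias null distribution; draws come from R's RNG so results are
// reproducible under set.seed().

static inline int fenwick_find(const std::vector<double>& tree, int n,
                               double u) {
  // smallest index i (1-based) with prefix-sum(i) > u
  int pos = 0;
  int log2n = 1;
  while ((1 << log2n) <= n) ++log2n;
  for (int pw = (1 << log2n); pw > 0; pw >>= 1) {
    int next = pos + pw;
    if (next <= n && tree[next] <= u) {
      u -= tree[next];
      pos = next;
    }
  }
  return pos + 1;  // 1-based
}

static inline void fenwick_add(std::vector<double>& tree, int n, int i,
                               double delta) {
  for (; i <= n; i += i & (-i)) tree[i] += delta;
}

// [[Rcpp::export]]
NumericVector ppswor_null_means(NumericVector weights, NumericVector scores,
                                int k, int n_iter) {
  int n = weights.size();
  if (scores.size() != n) stop("weights/scores length mismatch");
  int n_pos = 0;
  for (int i = 0; i < n; ++i) {
    if (weights[i] < 0) stop("negative weight");
    if (weights[i] > 0) ++n_pos;
  }
  if (k < 1 || k > n_pos)
    stop("cannot sample %d items from %d with positive weight", k, n_pos);

  std::vector<double> base(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) {
    base[i] += weights[i - 1];
    int j = i + (i & (-i));
    if (j <= n) base[j] += base[i];
  }
  double total0 = 0.0;
  for (int i = 0; i < n; ++i) total0 += weights[i];

  std::vector<double> tree(base);
  std::vector<int> taken(k);
  NumericVector out(n_iter);
  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    double total = total0;
    double acc = 0.0;
    for (int d = 0; d < k; ++d) {
      double u = unif_rand() * total;
      int i = fenwick_find(tree, n, u);
      if (i > n) i = n;  // guard against roundoff at the right edge
      taken[d] = i;
      acc += scores[i - 1];
      fenwick_add(tree, n, i, -weights[i - 1]);
      total -= weights[i - 1];
    }
    out[it] = acc / k;
    for (int d = 0; d < k; ++d)  // restore removed weights
      fenwick_add(tree, n, taken[d], weights[taken[d] - 1]);
  }
  return out;
}
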