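// Felsenstein pruning over codon states, vectorized across site patterns.
// Tips enter as integer state indices (0 = unknown: gap or ambiguous codon,
// contributing an all-ones partial vector). Per-node rescaling guards
// against underflow; the accumulated log-scalers are added back at the root.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// edge: nedge x 2 (parent, child), 1-based node ids, postorder (children
// before parents). P: ns x ns x nedge transition matrices aligned to edge
// rows. tipstates: ntip x npat, 1-based state index, 0 = unknown.
// Returns per-pattern log-likelihood summed over root states weighted by pi.
// [[Rcpp::export]]
arma::vec prune_loglik(const arma::imat& edge,
                       const arma::cube& P,
                       const arma::imat& tipstates,
                       const arma::vec& pi,
                       const int nnode_total) {
  const int ns = pi.n_elem;
  const int npat = tipstates.n_cols;
  const int ntip = tipstates.n_rows;
  const int nedge = edge.n_rows;

  std::vector<mat> partial(nnode_total + 1);
  std::vector<bool> init(nnode_total + 1, false);
  rowvec logscale(npat, fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0);
    const int ch  = edge(e, 1);
    mat contrib(ns, npat);
    if (ch <= ntip) {
      const mat& Pe = P.slice(e);
      for (int s = 0; s < npat; ++s) {
        const int st = tipstates(ch - 1, s);
        if (st > 0) contrib.col(s) = Pe.col(st - 1);
        else contrib.col(s).ones();
      }
    } else {
      mat& part = partial[ch];
      // rescale the completed child partial before propagating
      rowvec m = max(part, 0);
      m.transform([](double v) { return v > 0.0 ? v : 1.0; });
      part.each_row() /= m;
      logscale += log(m);
      contrib = P.slice(e) * part;
    }
    if (!init[par]) {
      partial[par] = contrib;
      init[par] = true;
    } else {
      partial[par] %= contrib;
    }
  }

  const int root = edge(nedge - 1, 0);
  vec out(npat);
  const mat& rp = partial[root];
  for (int s = 0; s < npat; ++s) {
    double L = dot(pi, rp.col(s));
    out(s) = (L > 0.0 ? std::log(L) : -1e308) + logscale(s);
  }
  return out;
}
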