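#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over a discrete rate mixture.
//
// Node ids are 1-based; tips are 1..ntip and the root is ntip+1. The edge
// matrix may be in any order; a postorder traversal is computed internally.
// The transition matrix for an edge of length t at mixture rate r is
//   P = U diag(exp(lambda * t * r)) Uinv
// with (U, lambda, Uinv) the eigendecomposition of the scaled rate matrix
// (real for reversible models via symmetrization, done on the R side). A
// mixture rate of exactly 0 (invariant-sites class) yields P = I.
//
// Returns the per-pattern log-likelihood, the rate categories combined
// with `log_weights` by log-sum-exp. Per-node rescaling keeps partials in
// range on large trees.
// [[Rcpp::export]]
NumericVector pruning_loglik_cpp(IntegerMatrix edge,
                                 NumericVector elen,
                                 int ntip,
                                 int nnode_total,
                                 int root,
                                 NumericVector tip_partials, // s x npat x ntip
                                 NumericMatrix U,
                                 NumericMatrix Uinv,
                                 NumericVector lambda,
                                 NumericVector root_freq,
                                 NumericVector rates,
                                 NumericVector log_weights) {
  const int s = U.nrow();
  const int nedge = edge.nrow();
  const int ncat = rates.size();
  IntegerVector tpdim = tip_partials.attr("dim");
  const int npat = tpdim[1];

  // child edge lists, then iterative postorder over edges
  std::vector<int> head(nnode_total + 1, -1), nxt(nedge, -1);
  for (int e = nedge - 1; e >= 0; --e) {
    int pa = edge(e, 0);
    nxt[e] = head[pa];
    head[pa] = e;
  }
  std::vector<int> po; po.reserve(nedge);
  std::vector<int> stack_node, stack_edge;
  // DFS emitting edges in postorder
  {
    std::vector<int> estack;
    std::vector<int> state;
    // iterative: push root's edges
    std::vector<std::pair<int, bool> > st; // (edge, expanded?)
    for (int e = head[root]; e != -1; e = nxt[e]) st.push_back(std::make_pair(e, false));
    // reverse for stable order
    std::reverse(st.begin(), st.end());
    while (!st.empty()) {
      std::pair<int, bool> top = st.back(); st.pop_back();
      int e = top.first;
      if (top.second) { po.push_back(e); continue; }
      st.push_back(std::make_pair(e, true));
      int ch = edge(e, 1);
      if (ch > ntip) {
        std::vector<int> kids;
        for (int k = head[ch]; k != -1; k = nxt[k]) kids.push_back(k);
        for (std::vector<int>::reverse_iterator it = kids.rbegin(); it != kids.rend(); ++it)
          st.push_back(std::make_pair(*it, false));
      }
    }
  }

  NumericMatrix catll(npat, ncat);
  std::vector<double> part((size_t)nnode_total * npat * s);
  std::vector<double> scale((size_t)nnode_total * npat);
  std::vector<int> seen(nnode_total);
  std::vector<double> P(s * s), expl(s), tmp(s);

  for (int c = 0; c < ncat; ++c) {
    const double rate = rates[c];
    std::fill(seen.begin(), seen.end(), 0);

    for (size_t ei = 0; ei < po.size(); ++ei) {
      const int e = po[ei];
      const int ch = edge(e, 1) - 1, pa = edge(e, 0) - 1;
      const double t = elen[e] * rate;

      if (rate == 0.0) {
        for (int i = 0; i < s; ++i)
          for (int j = 0; j < s; ++j) P[i * s + j] = (i == j) ? 1.0 : 0.0;
      } else {
        for (int k = 0; k < s; ++k) expl[k] = std::exp(lambda[k] * t);
        for (int i = 0; i < s; ++i)
          for (int j = 0; j < s; ++j) {
            double acc = 0.0;
            for (int k = 0; k < s; ++k) acc += U(i, k) * expl[k] * Uinv(k, j);
            P[i * s + j] = acc > 0.0 ? acc : 0.0; // clip tiny negatives
          }
      }

      if (!seen[pa]) {
        for (int p = 0; p < npat; ++p) {
          scale[(size_t)pa * npat + p] = 0.0;
          for (int i = 0; i < s; ++i) part[((size_t)pa * npat + p) * s + i] = 1.0;
        }
        seen[pa] = 1;
      }

      for (int p = 0; p < npat; ++p) {
        const double *cp;
        double chscale = 0.0;
        if (ch < ntip) {
          cp = &tip_partials[((size_t)ch * npat + p) * s];
        } else {
          cp = &part[((size_t)ch * npat + p) * s];
          chscale = scale[(size_t)ch * npat + p];
        }
        for (int i = 0; i < s; ++i) {
          double acc = 0.0;
          for (int j = 0; j < s; ++j) acc += P[i * s + j] * cp[j];
          tmp[i] = acc;
        }
        double *pp = &part[((size_t)pa * npat + p) * s];
        double mx = 0.0;
        for (int i = 0; i < s; ++i) {
          pp[i] *= tmp[i];
          if (pp[i] > mx) mx = pp[i];
        }
        scale[(size_t)pa * npat + p] += chscale;
        if (mx > 0.0 && (mx < 1e-200 || mx > 1e200)) {
          for (int i = 0; i < s; ++i) pp[i] /= mx;
          scale[(size_t)pa * npat + p] += std::log(mx);
        }
      }
    }

    const int r0 = root - 1;
    for (int p = 0; p < npat; ++p) {
      double acc = 0.0;
      const double *rp = &part[((size_t)r0 * npat + p) * s];
      for (int i = 0; i < s; ++i) acc += root_freq[i] * rp[i];
      catll(p, c) = (acc > 0.0) ? std::log(acc) + scale[(size_t)r0 * npat + p]
                                : R_NegInf;
    }
  }

  // combine categories: log sum_c exp(catll + log w_c)
  NumericVector out(npat);
  for (int p = 0; p < npat; ++p) {
    double mx = R_NegInf;
    for (int c = 0; c < ncat; ++c) {
      double v = catll(p, c) + log_weights[c];
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx)) { out[p] = R_NegInf; continue; }
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(catll(p, c) + log_weights[c] - mx);
    out[p] = mx + std::log(acc);
  }
  return out;
}
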