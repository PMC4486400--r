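// Exhaustive canonical-labelling oracle for small graphs: minimizes the
// tuple (invariant pairs in color order, connection-table code, optional
// hydrogen list) over all n! atom numberings and reports the automorphism
// orbits of the minimizers. Used by the test suite as an independent
// reference for the refinement-based search.

#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>

using namespace Rcpp;

static std::vector<int> candidate_tuple(const std::vector<int>& perm,
                                        const std::vector<std::vector<int>>& adj,
                                        const IntegerVector& elemrank,
                                        const IntegerVector& deg,
                                        const IntegerVector& hcounts,
                                        bool use_h) {
  int n = (int)perm.size();
  std::vector<int> out;
  out.reserve(n * 4);
  // perm[c] = atom holding color c+1
  std::vector<int> color(n);
  for (int c = 0; c < n; ++c) color[perm[c]] = c + 1;
  for (int c = 0; c < n; ++c) {
    out.push_back(elemrank[perm[c]]);
    out.push_back(deg[perm[c]]);
  }
  for (int c = 0; c < n; ++c) {
    out.push_back(c + 1);
    std::vector<int> nb;
    for (int w : adj[perm[c]])
      if (color[w] < c + 1) nb.push_back(color[w]);
    std::sort(nb.begin(), nb.end());
    for (int v : nb) out.push_back(v);
  }
  if (use_h)
    for (int c = 0; c < n; ++c) out.push_back(hcounts[perm[c]]);
  return out;
}

// [[Rcpp::export]]
List brute_canonical(IntegerMatrix adjm, IntegerVector elemrank,
                     IntegerVector hcounts, bool use_h) {
  int n = adjm.nrow();
  std::vector<std::vector<int>> adj(n);
  IntegerVector deg(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j)
      if (adjm(i, j)) adj[i].push_back(j);
    deg[i] = (int)adj[i].size();
  }
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  std::vector<int> best;
  std::vector<std::vector<int>> minimizers;
  do {
    std::vector<int> tup =
      candidate_tuple(perm, adj, elemrank, deg, hcounts, use_h);
    if (best.empty() || tup < best) {
      best = tup;
      minimizers.clear();
      minimizers.push_back(perm);
    } else if (tup == best) {
      minimizers.push_back(perm);
    }
  } while (std::next_permutation(perm.begin(), perm.end()));

  // orbits: union atoms holding the same color across minimizers
  std::vector<int> par(n);
  for (int i = 0; i < n; ++i) par[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (par[x] != x) x = par[x] = par[par[x]];
    return x;
  };
  const std::vector<int>& ref = minimizers[0];
  for (const auto& p : minimizers)
    for (int c = 0; c < n; ++c) {
      int a = find(ref[c]), b2 = find(p[c]);
      if (a != b2) par[std::max(a, b2)] = std::min(a, b2);
    }
  // class label = smallest color in the orbit under the reference
  std::vector<int> refcolor(n);
  for (int c = 0; c < n; ++c) refcolor[ref[c]] = c + 1;
  IntegerVector cls(n);
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    int mn = refcolor[i];
    for (int j = 0; j < n; ++j)
      if (find(j) == r && refcolor[j] < mn) mn = refcolor[j];
    cls[i] = mn;
  }

  // extract the code part: skip the 2n invariant entries
  int nb = 0;
  for (int i = 0; i < n; ++i) nb += (int)adj[i].size();
  nb /= 2;
  IntegerVector code(n + nb);
  for (int k = 0; k < n + nb; ++k) code[k] = best[2 * n + k];
  IntegerVector nu(n);
  for (int c = 0; c < n; ++c) nu[ref[c]] = c + 1;
  return List::create(_["code"] = code, _["orbits"] = cls,
                      _["numbering"] = nu,
                      _["n_minimizers"] = (int)minimizers.size());
}
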