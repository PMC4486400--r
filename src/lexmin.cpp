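// Exact lexicographic-minimum connection-table-code search.
//
// Atoms are assigned canonical colors 1..n in order, restricted to the
// block structure of the initial invariant coloring (atoms of a smaller
// initial color always receive smaller canonical numbers). The flattened
// connection-table code (segment per color: color value, then ascending
// smaller-colored neighbors) is built incrementally; branches whose
// partial code exceeds the best known code are pruned.
//
// Structural twins (atoms with identical neighborhoods, possibly
// mutually bonded) generate isomorphic subtrees: only one twin per
// identical partial segment is descended, and the set of minimizing
// numberings is closed afterwards under twin transpositions, so the
// result still contains every numbering attaining the minimal code.

#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

struct SearchState {
  int n;
  std::vector<std::vector<int>> adj;
  std::vector<int> block;      // initial color per atom
  std::vector<int> pos_block;  // required block value at each position
  std::vector<int> twin;       // twin class per atom
  std::vector<int> color;      // assigned color per atom (0 = none)
  std::vector<int> cur;        // partial flattened code
  std::vector<int> best;
  std::vector<std::vector<int>> minimizers;
  long long nodes = 0;
  long long max_nodes;
  size_t max_minimizers;
};

// compare cur (partial) against best over cur's length:
// -1 smaller, 0 tied prefix, +1 larger
int cmp_partial(const SearchState& st) {
  size_t m = st.cur.size();
  for (size_t i = 0; i < m; ++i) {
    if (st.cur[i] < st.best[i]) return -1;
    if (st.cur[i] > st.best[i]) return 1;
  }
  return 0;
}

void dfs(SearchState& st, int pos) {
  if (++st.nodes > st.max_nodes)
    stop("canonicalization search budget exceeded");
  if (pos > st.n) {
    if (st.best.empty()) {
      st.best = st.cur;
      st.minimizers.push_back(st.color);
      return;
    }
    int c = cmp_partial(st);
    if (c < 0) {
      st.best = st.cur;
      st.minimizers.clear();
      st.minimizers.push_back(st.color);
    } else if (c == 0) {
      if (st.minimizers.size() < st.max_minimizers)
        st.minimizers.push_back(st.color);
      else
        stop("too many equivalent canonical numberings");
    }
    return;
  }
  int want = st.pos_block[pos - 1];
  std::vector<std::pair<std::vector<int>, int>> cands;
  for (int a = 0; a < st.n; ++a) {
    if (st.color[a] != 0 || st.block[a] != want) continue;
    std::vector<int> seg;
    seg.push_back(pos);
    std::vector<int> nb;
    for (int w : st.adj[a])
      if (st.color[w] != 0) nb.push_back(st.color[w]);
    std::sort(nb.begin(), nb.end());
    seg.insert(seg.end(), nb.begin(), nb.end());
    cands.emplace_back(std::move(seg), a);
  }
  std::sort(cands.begin(), cands.end());
  std::set<std::pair<std::vector<int>, int>> seen;  // (segment, twin class)
  for (auto& cd : cands) {
    if (!seen.insert({cd.first, st.twin[cd.second]}).second)
      continue;  // isomorphic to an already-descended twin branch
    size_t before = st.cur.size();
    st.cur.insert(st.cur.end(), cd.first.begin(), cd.first.end());
    bool prune = false;
    if (!st.best.empty()) {
      if (st.cur.size() > st.best.size()) prune = true;
      else if (cmp_partial(st) > 0) prune = true;
    }
    if (!prune) {
      st.color[cd.second] = pos;
      dfs(st, pos + 1);
      st.color[cd.second] = 0;
    }
    st.cur.resize(before);
  }
}

}  // namespace

// [[Rcpp::export]]
List lexmin_code_search(IntegerMatrix adjm, IntegerVector init_colors,
                        double max_nodes = 2e7,
                        int max_minimizers = 20000) {
  SearchState st;
  st.n = adjm.nrow();
  st.max_nodes = (long long)max_nodes;
  st.max_minimizers = (size_t)max_minimizers;
  st.adj.resize(st.n);
  for (int i = 0; i < st.n; ++i)
    for (int j = 0; j < st.n; ++j)
      if (adjm(i, j)) st.adj[i].push_back(j);
  st.block.assign(init_colors.begin(), init_colors.end());
  st.pos_block = st.block;
  std::sort(st.pos_block.begin(), st.pos_block.end());
  st.color.assign(st.n, 0);
  if (st.n == 0)
    return List::create(_["code"] = IntegerVector(0),
                        _["numberings"] = IntegerMatrix(0, 0));

  // twin pairs: same block and identical neighborhoods apart from a
  // possible mutual bond; each such transposition is an automorphism
  std::vector<std::pair<int, int>> twin_pairs;
  {
    for (int u = 0; u < st.n; ++u)
      for (int v = u + 1; v < st.n; ++v) {
        if (st.block[u] != st.block[v]) continue;
        std::vector<int> nu, nv;
        for (int w : st.adj[u]) if (w != v) nu.push_back(w);
        for (int w : st.adj[v]) if (w != u) nv.push_back(w);
        if (nu == nv) twin_pairs.emplace_back(u, v);
      }
    // twin classes = connected components of the twin relation
    std::vector<int> par(st.n);
    for (int i = 0; i < st.n; ++i) par[i] = i;
    std::vector<int>* parp = &par;
    auto find = [parp](int x) {
      while ((*parp)[x] != x) x = (*parp)[x] = (*parp)[(*parp)[x]];
      return x;
    };
    for (auto& pr : twin_pairs) {
      int a = find(pr.first), b = find(pr.second);
      if (a != b) par[std::max(a, b)] = std::min(a, b);
    }
    st.twin.resize(st.n);
    for (int i = 0; i < st.n; ++i) st.twin[i] = find(i);
  }

  dfs(st, 1);

  // close the minimizer set under twin transpositions
  {
    std::set<std::vector<int>> pool(st.minimizers.begin(),
                                    st.minimizers.end());
    std::vector<std::vector<int>> queue(st.minimizers.begin(),
                                        st.minimizers.end());
    while (!queue.empty()) {
      std::vector<int> nu = queue.back();
      queue.pop_back();
      for (auto& pr : twin_pairs) {
        std::vector<int> sw = nu;
        std::swap(sw[pr.first], sw[pr.second]);
        if (pool.insert(sw).second) {
          if (pool.size() > st.max_minimizers)
            stop("too many equivalent canonical numberings");
          queue.push_back(sw);
        }
      }
    }
    st.minimizers.assign(pool.begin(), pool.end());
  }

  IntegerVector code(st.best.size());
  std::copy(st.best.begin(), st.best.end(), code.begin());
  IntegerMatrix nus(st.n, (int)st.minimizers.size());
  for (size_t k = 0; k < st.minimizers.size(); ++k)
    for (int i = 0; i < st.n; ++i)
      nus(i, (int)k) = st.minimizers[k][i];
  return List::create(_["code"] = code, _["numberings"] = nus);
}
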