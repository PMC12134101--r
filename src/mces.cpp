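// Exact maximum-common-edge-subgraph search by branch and bound.
//
// Vertices of the smaller graph are mapped injectively (or skipped) onto
// the larger graph; a common edge requires matching element labels on
// both endpoints and an identical bond order. Three devices keep the
// exact search tractable on ~30-atom lipid backbones:
//   * connectivity-guided vertex order (rare elements and high degree
//     first),
//   * candidate ordering by Morgan-refined neighbourhood labels, so a
//     near-isomorphism is walked on the first descent,
//   * a per-edge-type capacity bound: the future gain can never exceed,
//     type by type (element pair + bond order), the smaller of the
//     remaining graph-1 edges and the unconsumed graph-2 edges.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Searcher {
  int n1 = 0, n2 = 0;
  std::vector<int> elem1, elem2;
  std::vector<std::vector<int>> adj1, adj2;
  std::vector<int> order;          // g1 vertices in branching order
  std::vector<int> morgan1, morgan2;
  int n_types = 0;
  std::vector<int> rem1;   // [type] g1 edges still matchable (dynamic)
  std::vector<int> avail2; // [type] unconsumed g2 edges (dynamic)
  std::vector<int> pos;    // g1 vertex -> branching position
  std::vector<std::vector<int>> fut_type; // [pos][type] static future edges
  std::vector<std::vector<int>> cands;
  std::vector<int> map1;
  std::vector<char> used2;
  std::vector<char> skipped;
  int best = 0;
  long long nodes = 0;
  bool trace = false;

  int bound_extra(int k) const {
    int b = 0;
    const std::vector<int>& f = fut_type[k];
    for (int t = 0; t < n_types; ++t)
      b += std::min(f[t], std::min(rem1[t], avail2[t]));
    return b;
  }

  int gain_of(int v, int u, int k, std::vector<int>* types = nullptr) const {
    int g = 0;
    for (int kk = 0; kk < k; ++kk) {
      int p = order[kk];
      int m = map1[p];
      if (m < 0) continue;
      int b = adj1[v][p];
      if (b > 0 && adj2[u][m] == b) {
        ++g;
        if (types) types->push_back(edge_type(elem1[v], elem1[p], b));
      }
    }
    return g;
  }

  std::map<long, int> type_codes;
  int edge_type_mut(int ea, int eb, int o) {
    if (ea > eb) std::swap(ea, eb);
    long key = (long(ea) << 20) | (long(eb) << 8) | o;
    auto it = type_codes.find(key);
    if (it != type_codes.end()) return it->second;
    int code = n_types++;
    type_codes[key] = code;
    return code;
  }
  int edge_type(int ea, int eb, int o) const {
    if (ea > eb) std::swap(ea, eb);
    long key = (long(ea) << 20) | (long(eb) << 8) | o;
    auto it = type_codes.find(key);
    return it == type_codes.end() ? -1 : it->second;
  }

  // every edge of v to an already-placed, non-skipped neighbour leaves
  // the matchable pool when v is placed (it is either matched now or
  // dead); edges to unplaced neighbours of a skipped v die as well
  void pool_remove_placed(int v, int k, std::vector<int>& removed) {
    for (int p = 0; p < n1; ++p) {
      int b = adj1[v][p];
      if (b > 0 && pos[p] < k && !skipped[p]) {
        int t = edge_type(elem1[v], elem1[p], b);
        --rem1[t];
        removed.push_back(t);
      }
    }
  }
  void pool_remove_future(int v, int k, std::vector<int>& removed) {
    for (int p = 0; p < n1; ++p) {
      int b = adj1[v][p];
      if (b > 0 && pos[p] > k) {
        int t = edge_type(elem1[v], elem1[p], b);
        --rem1[t];
        removed.push_back(t);
      }
    }
  }

  void rec(int k, int current) {
    if (trace && ++nodes % 20000000LL == 0)
      Rprintf("nodes %lld best %d depth %d\n", nodes, best, k);
    if (current + bound_extra(k) <= best) return;
    if (k == n1) {
      best = current;
      if (trace) Rprintf("new best %d at %lld nodes\n", best, nodes);
      return;
    }
    int v = order[k];
    // candidates sorted by (immediate gain, Morgan label match) descending
    std::vector<std::pair<long, int>> scored;
    scored.reserve(cands[v].size());
    for (int u : cands[v]) {
      if (used2[u]) continue;
      long s = long(gain_of(v, u, k)) * 4 +
               (morgan1[v] == morgan2[u] ? 1 : 0);
      scored.emplace_back(-s, u);
    }
    std::stable_sort(scored.begin(), scored.end());
    std::vector<int> types, removed;
    for (auto& su : scored) {
      int u = su.second;
      types.clear();
      removed.clear();
      int g = gain_of(v, u, k, &types);
      map1[v] = u;
      used2[u] = 1;
      for (int t : types) --avail2[t];
      pool_remove_placed(v, k, removed);
      rec(k + 1, current + g);
      for (int t : removed) ++rem1[t];
      for (int t : types) ++avail2[t];
      map1[v] = -1;
      used2[u] = 0;
    }
    // leave v unmapped: its edges to placed and future vertices all die
    removed.clear();
    skipped[v] = 1;
    pool_remove_placed(v, k, removed);
    pool_remove_future(v, k, removed);
    rec(k + 1, current);
    for (int t : removed) ++rem1[t];
    skipped[v] = 0;
  }
};

// three rounds of Morgan-style neighbourhood refinement shared across
// both graphs so labels are comparable
static std::vector<int> morgan_labels(
    const std::vector<int>& elem, const std::vector<std::vector<int>>& adj,
    std::map<std::vector<long>, int>& dict, std::vector<int> labels) {
  int n = elem.size();
  for (int round = 0; round < 3; ++round) {
    std::vector<int> next(n);
    for (int v = 0; v < n; ++v) {
      std::vector<long> sig;
      sig.push_back(labels[v]);
      std::vector<long> nb;
      for (int u = 0; u < n; ++u)
        if (adj[v][u] > 0) nb.push_back(long(labels[u]) * 8 + adj[v][u]);
      std::sort(nb.begin(), nb.end());
      sig.insert(sig.end(), nb.begin(), nb.end());
      auto it = dict.find(sig);
      if (it == dict.end()) {
        int code = dict.size();
        dict[sig] = code;
        next[v] = code;
      } else {
        next[v] = it->second;
      }
    }
    labels = next;
  }
  return labels;
}

} // namespace

// min_size: prime the incumbent so only common subgraphs strictly larger
// than min_size - 1 are sought ("myopic" thresholding); pass 0 for a
// fully exact search.
// [[Rcpp::export]]
int mces_size_cpp(IntegerVector elem1, IntegerMatrix edges1,
                  IntegerVector elem2, IntegerMatrix edges2,
                  int min_size = 0, bool trace = false) {
  Searcher s;
  s.trace = trace;
  s.n1 = elem1.size();
  s.n2 = elem2.size();
  s.elem1.assign(elem1.begin(), elem1.end());
  s.elem2.assign(elem2.begin(), elem2.end());
  s.adj1.assign(s.n1, std::vector<int>(s.n1, 0));
  s.adj2.assign(s.n2, std::vector<int>(s.n2, 0));
  for (int r = 0; r < edges1.nrow(); ++r) {
    int i = edges1(r, 0) - 1, j = edges1(r, 1) - 1, o = edges1(r, 2);
    s.adj1[i][j] = o;
    s.adj1[j][i] = o;
  }
  for (int r = 0; r < edges2.nrow(); ++r) {
    int i = edges2(r, 0) - 1, j = edges2(r, 1) - 1, o = edges2(r, 2);
    s.adj2[i][j] = o;
    s.adj2[j][i] = o;
  }

  // edge types over both graphs; graph-2 availability per type
  for (int r = 0; r < edges1.nrow(); ++r)
    s.edge_type_mut(s.elem1[edges1(r, 0) - 1], s.elem1[edges1(r, 1) - 1],
                    edges1(r, 2));
  for (int r = 0; r < edges2.nrow(); ++r)
    s.edge_type_mut(s.elem2[edges2(r, 0) - 1], s.elem2[edges2(r, 1) - 1],
                    edges2(r, 2));
  s.avail2.assign(s.n_types, 0);
  for (int r = 0; r < edges2.nrow(); ++r)
    ++s.avail2[s.edge_type(s.elem2[edges2(r, 0) - 1],
                           s.elem2[edges2(r, 1) - 1], edges2(r, 2))];

  // Morgan labels (shared dictionary so labels are comparable)
  std::map<std::vector<long>, int> dict;
  {
    std::map<long, int> elem_code;
    std::vector<int> init1(s.n1), init2(s.n2);
    for (int v = 0; v < s.n1; ++v) {
      if (!elem_code.count(s.elem1[v])) {
        int c = elem_code.size();
        elem_code[s.elem1[v]] = c;
      }
      init1[v] = elem_code[s.elem1[v]];
    }
    for (int v = 0; v < s.n2; ++v) {
      if (!elem_code.count(s.elem2[v])) {
        int c = elem_code.size();
        elem_code[s.elem2[v]] = c;
      }
      init2[v] = elem_code[s.elem2[v]];
    }
    s.morgan1 = morgan_labels(s.elem1, s.adj1, dict, init1);
    s.morgan2 = morgan_labels(s.elem2, s.adj2, dict, init2);
  }

  // branching order: rare elements and high degree first, then maximal
  // connectivity to the placed prefix
  std::vector<int> deg1(s.n1, 0);
  for (int i = 0; i < s.n1; ++i)
    for (int j = 0; j < s.n1; ++j)
      if (s.adj1[i][j] > 0) ++deg1[i];
  std::map<int, int> elem_count;
  for (int e : s.elem1) ++elem_count[e];

  std::vector<char> placed(s.n1, 0);
  for (int k = 0; k < s.n1; ++k) {
    int pick = -1;
    long best_score = -1000000000L;
    for (int v = 0; v < s.n1; ++v) {
      if (placed[v]) continue;
      long conn = 0;
      for (int p = 0; p < s.n1; ++p)
        if (placed[p] && s.adj1[v][p] > 0) ++conn;
      long score = conn * 100000L - elem_count[s.elem1[v]] * 100L + deg1[v];
      if (score > best_score) {
        best_score = score;
        pick = v;
      }
    }
    placed[pick] = 1;
    s.order.push_back(pick);
  }

  // dynamic pool of matchable g1 edges per type, plus the static
  // per-position future-edge table
  s.pos.assign(s.n1, 0);
  for (int k = 0; k < s.n1; ++k) s.pos[s.order[k]] = k;
  s.rem1.assign(s.n_types, 0);
  s.fut_type.assign(s.n1 + 1, std::vector<int>(s.n_types, 0));
  for (int r = 0; r < edges1.nrow(); ++r) {
    int a = edges1(r, 0) - 1, b = edges1(r, 1) - 1;
    int t = s.edge_type(s.elem1[a], s.elem1[b], edges1(r, 2));
    ++s.rem1[t];
    int last = std::max(s.pos[a], s.pos[b]);
    for (int k = 0; k <= last; ++k) ++s.fut_type[k][t];
  }
  s.skipped.assign(s.n1, 0);

  s.cands.assign(s.n1, {});
  for (int v = 0; v < s.n1; ++v)
    for (int u = 0; u < s.n2; ++u)
      if (s.elem1[v] == s.elem2[u]) s.cands[v].push_back(u);

  s.map1.assign(s.n1, -1);
  s.used2.assign(s.n2, 0);
  s.best = std::max(-1, min_size - 1);
  s.rec(0, 0);
  return s.best;
}
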