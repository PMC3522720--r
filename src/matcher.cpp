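// Backtracking subgraph-monomorphism matcher for node-labeled graphs.
//
// Pattern edges must map to host edges under an injective, label-preserving
// node mapping; the host may have extra edges among the mapped nodes
// (monomorphism, not induced-subgraph semantics).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Prob {
  int np, nh;
  std::vector<int> plab, hlab;
  std::vector<std::vector<int>> padj, hadj;
  std::vector<std::vector<char>> hadjm;
  std::vector<int> order;      // pattern visit order (connected expansion)
  std::vector<int> parent;     // an already-placed neighbour, -1 for roots
};

static bool extend(Prob &P, std::vector<int> &map, std::vector<char> &used,
                   size_t depth, std::vector<std::vector<int>> *all,
                   int cap) {
  if (depth == P.order.size()) {
    if (all) {
      all->push_back(map);
      return (int)all->size() >= cap;   // true stops the search
    }
    return true;
  }
  int u = P.order[depth];
  std::vector<int> cand;
  if (P.parent[depth] >= 0) {
    int pm = map[P.parent[depth]];
    cand = P.hadj[pm];
  } else {
    cand.resize(P.nh);
    for (int i = 0; i < P.nh; ++i) cand[i] = i;
  }
  for (int v : cand) {
    if (used[v] || P.hlab[v] != P.plab[u]) continue;
    bool ok = true;
    for (int w : P.padj[u]) {
      int mw = map[w];
      if (mw >= 0 && !P.hadjm[v][mw]) { ok = false; break; }
    }
    if (!ok) continue;
    map[u] = v; used[v] = 1;
    if (extend(P, map, used, depth + 1, all, cap)) {
      if (!all) return true;
      map[u] = -1; used[v] = 0;
      return true;
    }
    map[u] = -1; used[v] = 0;
  }
  return false;
}

static Prob buildProb(IntegerVector plab, IntegerMatrix pedge,
                      IntegerVector hlab, IntegerMatrix hedge) {
  Prob P;
  P.np = plab.size(); P.nh = hlab.size();
  P.plab.assign(plab.begin(), plab.end());
  P.hlab.assign(hlab.begin(), hlab.end());
  P.padj.assign(P.np, {});
  P.hadj.assign(P.nh, {});
  P.hadjm.assign(P.nh, std::vector<char>(P.nh, 0));
  for (int e = 0; e < pedge.nrow(); ++e) {
    int a = pedge(e, 0) - 1, b = pedge(e, 1) - 1;
    P.padj[a].push_back(b); P.padj[b].push_back(a);
  }
  for (int e = 0; e < hedge.nrow(); ++e) {
    int a = hedge(e, 0) - 1, b = hedge(e, 1) - 1;
    P.hadj[a].push_back(b); P.hadj[b].push_back(a);
    P.hadjm[a][b] = P.hadjm[b][a] = 1;
  }
  // visit order: BFS from node 0 over components (most pattern graphs are
  // connected; roots get full candidate scans)
  std::vector<char> seen(P.np, 0);
  for (int s = 0; s < P.np; ++s) {
    if (seen[s]) continue;
    std::vector<int> q{s};
    seen[s] = 1;
    P.order.push_back(s); P.parent.push_back(-1);
    for (size_t qi = 0; qi < q.size(); ++qi) {
      int u = q[qi];
      for (int w : P.padj[u]) {
        if (seen[w]) continue;
        seen[w] = 1;
        P.order.push_back(w); P.parent.push_back(u);
        q.push_back(w);
      }
    }
    // parent entries hold pattern node ids (index into the mapping array)
  }
  return P;
}

// [[Rcpp::export(name = ".match_exists_cpp")]]
bool match_exists_cpp(IntegerVector plab, IntegerMatrix pedge,
                      IntegerVector hlab, IntegerMatrix hedge) {
  if (plab.size() > hlab.size()) return false;
  Prob P = buildProb(plab, pedge, hlab, hedge);
  std::vector<int> map(P.np, -1);
  std::vector<char> used(P.nh, 0);
  return extend(P, map, used, 0, nullptr, 0);
}

// [[Rcpp::export(name = ".match_all_cpp")]]
IntegerMatrix match_all_cpp(IntegerVector plab, IntegerMatrix pedge,
                            IntegerVector hlab, IntegerMatrix hedge,
                            int cap = 5000) {
  if (plab.size() > hlab.size()) return IntegerMatrix(0, plab.size());
  Prob P = buildProb(plab, pedge, hlab, hedge);
  std::vector<int> map(P.np, -1);
  std::vector<char> used(P.nh, 0);
  std::vector<std::vector<int>> all;
  extend(P, map, used, 0, &all, cap);
  IntegerMatrix out(all.size(), P.np);
  for (size_t r = 0; r < all.size(); ++r) {
    // map is indexed by pattern node id directly
    for (int u = 0; u < P.np; ++u) out(r, u) = all[r][u] + 1;
  }
  return out;
}
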