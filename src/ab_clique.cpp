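#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Bounded, pivotless Bron-Kerbosch over a two-typed, divided network.
//
// Vertices are 0-based here; each vertex belongs to one organism (org[v]),
// each organism is positive or negative (org_pos). A vertex set S has type
// counts c(S, p) / c(S, n): the number of positive / negative organisms
// contributing at least one vertex to S. The search emits exactly the
// maximal cliques with c(S, p) >= alpha and c(S, n) <= beta.
//
// mode 0: output test only.
// mode 1: additionally prune a branch when c(CLIQUE + current, n) > beta
//         (type counts are monotone under superset, so no qualifying
//         maximal clique lives in that subtree).
// mode 2: additionally prune when c(NEWCLIQUE u NEWCAND, p) < alpha (that
//         quantity upper-bounds c(M, p) for every clique M of the subtree).
//
// Pruned candidates still migrate CAND -> NOT so the NOT-empty maximality
// certificate at the leaves stays valid. Candidate order is ascending
// vertex id (callers pass vertices in lexicographic (organism, cog) order),
// which makes the enumeration order deterministic.

namespace {

struct Search {
  int n;
  int n_org;
  std::vector<uint8_t> adj;       // n x n dense adjacency
  std::vector<int> org;           // organism index per vertex
  std::vector<uint8_t> org_pos;   // is organism positive
  int alpha, beta, mode;
  std::vector<int> clique_org_cnt; // vertices of CLIQUE per organism
  int pos_in_clique, neg_in_clique;
  std::vector<int> stamp;          // scratch for union type counts
  int stamp_id;
  long long nodes;
  std::vector<int> clique;
  std::vector<std::vector<int> > cliques;

  bool connected(int a, int b) const { return adj[(size_t)a * n + b] != 0; }

  // c(CLIQUE + {v}, n)
  int neg_count_with(int v) const {
    int o = org[v];
    if (clique_org_cnt[o] == 0 && !org_pos[o]) return neg_in_clique + 1;
    return neg_in_clique;
  }

  // c(CLIQUE u {v} u CAND, p) where clique counts are current
  int pos_count_union(int v, const std::vector<int>& cand) {
    ++stamp_id;
    int cnt = pos_in_clique;
    int o = org[v];
    if (clique_org_cnt[o] == 0 && org_pos[o]) {
      stamp[o] = stamp_id;
      ++cnt;
    }
    for (size_t i = 0; i < cand.size(); ++i) {
      int u = cand[i];
      int ou = org[u];
      if (clique_org_cnt[ou] == 0 && org_pos[ou] && stamp[ou] != stamp_id) {
        stamp[ou] = stamp_id;
        ++cnt;
      }
    }
    return cnt;
  }

  void push_vertex(int v) {
    int o = org[v];
    if (clique_org_cnt[o]++ == 0) {
      if (org_pos[o]) ++pos_in_clique; else ++neg_in_clique;
    }
    clique.push_back(v);
  }

  void pop_vertex() {
    int v = clique.back();
    clique.pop_back();
    int o = org[v];
    if (--clique_org_cnt[o] == 0) {
      if (org_pos[o]) --pos_in_clique; else --neg_in_clique;
    }
  }

  // Bron-Kerbosch maximality cut: once a NOT vertex is adjacent to every
  // remaining candidate, no extension of CLIQUE by CAND vertices can be
  // maximal (that NOT vertex would always extend it further).
  bool dominated(const std::vector<int>& cand,
                 const std::vector<int>& notl) const {
    for (size_t i = 0; i < notl.size(); ++i) {
      bool all = true;
      for (size_t j = 0; j < cand.size(); ++j)
        if (!connected(notl[i], cand[j])) { all = false; break; }
      if (all) return true;
    }
    return false;
  }

  void recurse(std::vector<int>& cand, std::vector<int>& notl) {
    ++nodes;
    if (cand.empty()) {
      if (notl.empty() && pos_in_clique >= alpha && neg_in_clique <= beta)
        cliques.push_back(clique);
      return;
    }
    // iterate over a snapshot; cand/notl mutate as candidates are consumed
    std::vector<int> order(cand);
    for (size_t i = 0; i < order.size(); ++i) {
      // the cut depends only on (CAND, NOT), which evolve identically in
      // all three bound modes, so mode comparisons stay valid
      if (dominated(cand, notl)) return;
      int current = order[i];
      bool expand = true;
      if (mode >= 1 && neg_count_with(current) > beta) expand = false;
      if (expand) {
        std::vector<int> newcand, newnot;
        newcand.reserve(cand.size());
        for (size_t j = 0; j < cand.size(); ++j)
          if (cand[j] != current && connected(cand[j], current))
            newcand.push_back(cand[j]);
        for (size_t j = 0; j < notl.size(); ++j)
          if (connected(notl[j], current)) newnot.push_back(notl[j]);
        if (mode == 2 && pos_count_union(current, newcand) < alpha) {
          // alpha bound: subtree cannot reach alpha positive organisms
        } else {
          push_vertex(current);
          recurse(newcand, newnot);
          pop_vertex();
        }
      }
      // CAND -> NOT regardless of pruning (maximality bookkeeping)
      for (size_t j = 0; j < cand.size(); ++j)
        if (cand[j] == current) { cand.erase(cand.begin() + j); break; }
      notl.push_back(current);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List enumerate_ab_cpp(List adj_list, IntegerVector org, LogicalVector org_pos,
                      int alpha, int beta, int mode) {
  Search s;
  s.n = adj_list.size();
  s.n_org = org_pos.size();
  s.alpha = alpha;
  s.beta = beta;
  s.mode = mode;
  s.adj.assign((size_t)s.n * s.n, 0);
  for (int v = 0; v < s.n; ++v) {
    IntegerVector nb = adj_list[v];
    for (int j = 0; j < nb.size(); ++j) {
      int u = nb[j] - 1;
      s.adj[(size_t)v * s.n + u] = 1;
    }
  }
  s.org.resize(s.n);
  for (int v = 0; v < s.n; ++v) s.org[v] = org[v] - 1;
  s.org_pos.resize(s.n_org);
  for (int o = 0; o < s.n_org; ++o) s.org_pos[o] = org_pos[o] ? 1 : 0;
  s.clique_org_cnt.assign(s.n_org, 0);
  s.pos_in_clique = s.neg_in_clique = 0;
  s.stamp.assign(s.n_org, 0);
  s.stamp_id = 0;
  s.nodes = 0;

  std::vector<int> cand(s.n), notl;
  for (int v = 0; v < s.n; ++v) cand[v] = v;
  s.recurse(cand, notl);

  List cl(s.cliques.size());
  for (size_t i = 0; i < s.cliques.size(); ++i) {
    IntegerVector iv(s.cliques[i].size());
    for (size_t j = 0; j < s.cliques[i].size(); ++j) iv[j] = s.cliques[i][j] + 1;
    cl[i] = iv;
  }
  return List::create(_["cliques"] = cl,
                      _["nodes"] = (double)s.nodes);
}
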