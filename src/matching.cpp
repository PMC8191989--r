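// PEC graph matching core: deterministic extension ("closure") of a partial
// matching between two properly edge-colored directed graphs, and the three
// algorithms built on it (isomorphism, subgraph isomorphism, all maximal
// connected common subgraphs with constraint-replay backtracking).
//
// Graphs arrive as (n, edge matrix) with 0-based node ids and integer label
// ids shared between the two graphs (the R side maps label strings to ids in
// lexicographic order, which fixes every tie-break deterministically).
// The PEC property (at most one outgoing edge per node per label) is assumed;
// it is validated on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <map>
#include <queue>
#include <set>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

struct PGraph {
  int n;
  std::vector<std::vector<std::pair<int, int>>> adj;  // per node: sorted (label, target)
  std::map<int, std::vector<std::pair<int, int>>> by_label;
};

static PGraph make_pgraph(int n, const IntegerMatrix& edges) {
  PGraph g;
  g.n = n;
  g.adj.assign(n, {});
  for (int r = 0; r < edges.nrow(); ++r) {
    int u = edges(r, 0), v = edges(r, 1), l = edges(r, 2);
    g.adj[u].push_back({l, v});
    g.by_label[l].push_back({u, v});
  }
  for (auto& a : g.adj) std::sort(a.begin(), a.end());
  return g;
}

enum Mode { ISO, SUB, MCS };

struct Closure {
  bool failed = false;
  std::vector<int> gmap, hinv;
  std::vector<std::pair<int, int>> pairs;          // matched pairs in match order
  std::vector<long long> blockers;                 // distinct blocking pairs, encoded g*nH+h
  std::vector<std::pair<int, int>> discrepancies;  // conflicting (g', h') in encounter order
};

// Breadth-first closure of a seed matching. For each matched (g, h) and each
// label carried by both, the PEC leaves a single candidate pair (g', h'):
// it is adopted unless one endpoint is already spoken for (a conflict, whose
// blocking pair seeds the backtracking in MCS mode) or the pair is forbidden
// by the branch's constraint list.
static Closure run_closure(const PGraph& G, const PGraph& H,
                           const std::vector<std::pair<int, int>>& seed,
                           const std::unordered_set<long long>& forbidden,
                           Mode mode, const std::vector<char>* blockedH = nullptr) {
  Closure c;
  c.gmap.assign(G.n, -1);
  c.hinv.assign(H.n, -1);
  std::queue<int> q;
  for (const auto& p : seed) {
    int g = p.first, h = p.second;
    if (blockedH && (*blockedH)[h]) { c.failed = true; return c; }
    if (c.gmap[g] == h) continue;
    if (c.gmap[g] != -1 || c.hinv[h] != -1) { c.failed = true; return c; }
    c.gmap[g] = h;
    c.hinv[h] = g;
    c.pairs.push_back({g, h});
    q.push(g);
  }
  std::unordered_set<long long> blockset;
  while (!q.empty()) {
    int g = q.front(); q.pop();
    int h = c.gmap[g];
    const auto& ag = G.adj[g];
    const auto& ah = H.adj[h];
    size_t i = 0, j = 0;
    while (i < ag.size() || j < ah.size()) {
      if (j >= ah.size() || (i < ag.size() && ag[i].first < ah[j].first)) {
        // label present at g only: an unmatched G edge
        if (mode != MCS) { c.failed = true; return c; }
        ++i;
      } else if (i >= ag.size() || ah[j].first < ag[i].first) {
        // label present at h only: fatal for isomorphism, harmless otherwise
        if (mode == ISO) { c.failed = true; return c; }
        ++j;
      } else {
        int gp = ag[i].second, hp = ah[j].second;
        ++i; ++j;
        if (c.gmap[gp] == hp) continue;  // edge already inside the matching
        if (c.gmap[gp] != -1) {
          if (mode != MCS) { c.failed = true; return c; }
          long long code = (long long)gp * H.n + c.gmap[gp];
          if (blockset.insert(code).second) c.blockers.push_back(code);
          c.discrepancies.push_back({gp, hp});
          continue;
        }
        if (c.hinv[hp] != -1) {
          if (mode != MCS) { c.failed = true; return c; }
          long long code = (long long)c.hinv[hp] * H.n + hp;
          if (blockset.insert(code).second) c.blockers.push_back(code);
          c.discrepancies.push_back({gp, hp});
          continue;
        }
        if (blockedH && (*blockedH)[hp]) {
          if (mode != MCS) { c.failed = true; return c; }
          continue;
        }
        long long code = (long long)gp * H.n + hp;
        if (forbidden.count(code)) {
          if (mode != MCS) { c.failed = true; return c; }
          continue;  // this branch was instructed not to add (g', h')
        }
        c.gmap[gp] = hp;
        c.hinv[hp] = gp;
        c.pairs.push_back({gp, hp});
        q.push(gp);
      }
    }
  }
  return c;
}

// true iff no single compatible pair (both endpoints free) can extend the matching
static bool is_maximal(const PGraph& G, const PGraph& H, const Closure& c) {
  for (const auto& p : c.pairs) {
    const auto& ag = G.adj[p.first];
    const auto& ah = H.adj[p.second];
    size_t i = 0, j = 0;
    while (i < ag.size() && j < ah.size()) {
      if (ag[i].first < ah[j].first) ++i;
      else if (ah[j].first < ag[i].first) ++j;
      else {
        int gp = ag[i].second, hp = ah[j].second;
        ++i; ++j;
        if (c.gmap[gp] == -1 && c.hinv[hp] == -1) return false;
      }
    }
  }
  return true;
}

static IntegerMatrix pairs_to_matrix(const std::vector<std::pair<int, int>>& pairs) {
  IntegerMatrix m(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    m(k, 0) = pairs[k].first;
    m(k, 1) = pairs[k].second;
  }
  return m;
}

// Single extension run, exposed for the user-facing extend() wrapper and for
// the determinism property tests. mode: 0 = strict iso, 1 = strict subgraph,
// 2 = permissive (discrepancy-logging).
// [[Rcpp::export]]
List cpp_extend(int nG, IntegerMatrix eG, int nH, IntegerMatrix eH,
                IntegerMatrix seed, IntegerMatrix forbidden, int mode) {
  PGraph G = make_pgraph(nG, eG), H = make_pgraph(nH, eH);
  std::vector<std::pair<int, int>> sv;
  for (int r = 0; r < seed.nrow(); ++r) sv.push_back({seed(r, 0), seed(r, 1)});
  std::unordered_set<long long> fset;
  for (int r = 0; r < forbidden.nrow(); ++r)
    fset.insert((long long)forbidden(r, 0) * nH + forbidden(r, 1));
  Closure c = run_closure(G, H, sv, fset, (Mode)mode);
  return List::create(
      _["failed"] = c.failed,
      _["pairs"] = pairs_to_matrix(c.pairs),
      _["discrepancies"] = pairs_to_matrix(c.discrepancies),
      _["maximal"] = c.failed ? false : is_maximal(G, H, c));
}

// seed color: argmin over shared labels of |E_G,c| x |E_H,c|; ties go to the
// smallest label id (lexicographic label order on the R side)
static int pick_color(const PGraph& G, const PGraph& H) {
  int best = -1;
  long long best_prod = -1;
  for (const auto& kv : G.by_label) {
    auto it = H.by_label.find(kv.first);
    if (it == H.by_label.end()) continue;
    long long prod = (long long)kv.second.size() * it->second.size();
    if (best == -1 || prod < best_prod) { best = kv.first; best_prod = prod; }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_pick_seed_color(int nG, IntegerMatrix eG, int nH, IntegerMatrix eH) {
  PGraph G = make_pgraph(nG, eG), H = make_pgraph(nH, eH);
  return pick_color(G, H);
}

// Isomorphism between two connected graphs with at least one edge each.
// Returns the mapping (nG x 2) or a 0-row matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_iso_connected(int nG, IntegerMatrix eG, int nH, IntegerMatrix eH) {
  IntegerMatrix none(0, 2);
  if (nG != nH || eG.nrow() != eH.nrow()) return none;
  PGraph G = make_pgraph(nG, eG), H = make_pgraph(nH, eH);
  for (const auto& kv : G.by_label) {
    auto it = H.by_label.find(kv.first);
    if (it == H.by_label.end() || it->second.size() != kv.second.size()) return none;
  }
  int col = pick_color(G, H);
  if (col < 0) return none;
  const auto& egs = G.by_label[col];
  const auto& ehs = H.by_label[col];
  std::unordered_set<long long> fset;
  for (const auto& eg : egs) {
    for (const auto& eh : ehs) {
      std::vector<std::pair<int, int>> seed = {{eg.first, eh.first}, {eg.second, eh.second}};
      Closure c = run_closure(G, H, seed, fset, ISO);
      if (!c.failed && (int)c.pairs.size() == nG) return pairs_to_matrix(c.pairs);
    }
  }
  return none;
}

// All complete injections of a connected pattern G (>= 1 edge) into H,
// avoiding blocked H nodes. Deduplicated; order deterministic.
// [[Rcpp::export]]
List cpp_sub_connected(int nG, IntegerMatrix eG, int nH, IntegerMatrix eH,
                       IntegerVector blockedH, bool first_only) {
  PGraph G = make_pgraph(nG, eG), H = make_pgraph(nH, eH);
  std::vector<char> blocked(nH, 0);
  for (int k = 0; k < blockedH.size(); ++k) blocked[blockedH[k]] = 1;
  List out;
  for (const auto& kv : G.by_label) {
    auto it = H.by_label.find(kv.first);
    if (it == H.by_label.end() || it->second.size() < kv.second.size()) return List();
  }
  int col = pick_color(G, H);
  if (col < 0) return List();
  const auto& egs = G.by_label[col];
  const auto& ehs = H.by_label[col];
  std::unordered_set<long long> fset;
  std::set<std::vector<int>> seen;
  // a fixed pattern edge against every H edge of the seed color: the closure
  // is forced by the PEC, so this enumerates every injection exactly once
  const auto& eg = egs.front();
  for (const auto& eh : ehs) {
    std::vector<std::pair<int, int>> seed = {{eg.first, eh.first}, {eg.second, eh.second}};
    Closure c = run_closure(G, H, seed, fset, SUB, &blocked);
    if (c.failed || (int)c.pairs.size() != nG) continue;
    std::vector<int> img(nG);
    for (int g = 0; g < nG; ++g) img[g] = c.gmap[g];
    if (!seen.insert(img).second) continue;
    out.push_back(pairs_to_matrix(c.pairs));
    if (first_only) return out;
  }
  return out;
}

// All maximal connected common subgraphs (>= 2 matched pairs, >= 1 matched
// edge). Seeds range over every pair of equally-colored edges of every shared
// label; each conflict spawns a replayed branch forbidden to use the blocking
// pair (Fig-5-style exploration tree). Results are deduplicated by pair set
// and audited for maximality.
// [[Rcpp::export]]
List cpp_all_mcs(int nG, IntegerMatrix eG, int nH, IntegerMatrix eH, double cap) {
  PGraph G = make_pgraph(nG, eG), H = make_pgraph(nH, eH);
  std::set<std::vector<long long>> results;
  double branches = 0;
  for (const auto& kv : G.by_label) {
    auto it = H.by_label.find(kv.first);
    if (it == H.by_label.end()) continue;
    for (const auto& eg : kv.second) {
      for (const auto& eh : it->second) {
        std::vector<std::pair<int, int>> seed = {{eg.first, eh.first}, {eg.second, eh.second}};
        long long seed0 = (long long)eg.first * H.n + eh.first;
        long long seed1 = (long long)eg.second * H.n + eh.second;
        // Disjoint backtracking over the conflicts of each exploration: the
        // i-th new branch is instructed not to add the i-th blocking pair
        // while keeping the earlier ones committed, so the alternatives
        // partition the search space and no branch is explored twice.
        struct Branch {
          std::vector<long long> forb;
          std::set<long long> committed;
        };
        std::deque<Branch> todo;
        todo.push_back({{}, {}});
        while (!todo.empty()) {
          Branch br = todo.front();
          todo.pop_front();
          if (++branches > cap)
            stop("branch cap exceeded in all_maximal_common_subgraphs");
          std::unordered_set<long long> fset(br.forb.begin(), br.forb.end());
          Closure c = run_closure(G, H, seed, fset, MCS);
          if (c.failed) continue;
          std::set<long long> commit = br.committed;
          for (long long b : c.blockers) {
            if (b == seed0 || b == seed1) continue;  // never unseat the seed
            if (commit.count(b)) continue;           // committed in this subtree
            Branch child;
            child.forb = br.forb;
            child.forb.push_back(b);
            child.committed = commit;
            todo.push_back(child);
            commit.insert(b);
          }
          if (c.pairs.size() >= 2 && is_maximal(G, H, c)) {
            std::vector<long long> key;
            key.reserve(c.pairs.size());
            for (const auto& p : c.pairs) key.push_back((long long)p.first * H.n + p.second);
            std::sort(key.begin(), key.end());
            results.insert(key);
          }
        }
      }
    }
  }
  List out(results.size());
  int k = 0;
  for (const auto& key : results) {
    IntegerMatrix m(key.size(), 2);
    for (size_t r = 0; r < key.size(); ++r) {
      m(r, 0) = (int)(key[r] / H.n);
      m(r, 1) = (int)(key[r] % H.n);
    }
    out[k++] = m;
  }
  return out;
}
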