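#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Trees are encoded as 1-based parent vectors: par[i] is the parent of node
// i+1, 0 for the stored root (the child of the implicit degree-one root, which
// is never materialised; the root edge always contributes 0 to the DC sum).
// leaf[i] is the taxon id (1..m) for leaves, 0 for internal nodes.

static std::vector<int> node_depths(const IntegerVector& par) {
  int nn = par.size();
  std::vector<int> dep(nn, -1);
  std::vector<int> path;
  for (int i = 0; i < nn; ++i) {
    if (dep[i] >= 0) continue;
    path.clear();
    int v = i;
    while (v != -1 && dep[v] < 0) { path.push_back(v); v = par[v] - 1; }
    int base = (v == -1) ? -1 : dep[v];
    for (int k = (int)path.size() - 1; k >= 0; --k) dep[path[k]] = ++base;
  }
  return dep;
}

static inline int lca2(int a, int b, const IntegerVector& par,
                       const std::vector<int>& dep) {
  while (a != b) {
    if (dep[a] > dep[b]) a = par[a] - 1;
    else if (dep[b] > dep[a]) b = par[b] - 1;
    else { a = par[a] - 1; b = par[b] - 1; }
  }
  return a;
}

struct GeneTree {
  IntegerVector par;
  IntegerVector leaf;
  std::vector<int> order;  // node ids, deepest first
};

static GeneTree prep_gene(IntegerVector par, IntegerVector leaf) {
  GeneTree g;
  g.par = par;
  g.leaf = leaf;
  std::vector<int> dep = node_depths(par);
  int nn = par.size();
  g.order.resize(nn);
  for (int i = 0; i < nn; ++i) g.order[i] = i;
  std::sort(g.order.begin(), g.order.end(),
            [&dep](int a, int b) { return dep[a] > dep[b]; });
  return g;
}

// Deep coalescence cost of one gene tree against a species tree given the
// species tree's depths and taxon->node index.  Bottom-up pass: each node's
// LCA image is merged into its parent's.
static long dc_one(const GeneTree& g, const IntegerVector& spar,
                   const std::vector<int>& sdep,
                   const std::vector<int>& s_of_tax) {
  int nn = g.par.size();
  std::vector<int> M(nn, -1);
  for (int k = 0; k < nn; ++k) {
    int u = g.order[k];
    if (g.leaf[u] > 0) M[u] = s_of_tax[g.leaf[u]];
    int p = g.par[u] - 1;
    if (p >= 0) M[p] = (M[p] < 0) ? M[u] : lca2(M[p], M[u], spar, sdep);
  }
  long cost = 0;
  for (int u = 0; u < nn; ++u) {
    int p = g.par[u] - 1;
    if (p >= 0) cost += sdep[M[u]] - sdep[M[p]];
  }
  return cost;
}

static std::vector<int> taxon_index(const IntegerVector& sleaf) {
  int m = 0;
  for (int i = 0; i < sleaf.size(); ++i) if (sleaf[i] > m) m = sleaf[i];
  std::vector<int> s_of_tax(m + 1, -1);
  for (int i = 0; i < sleaf.size(); ++i)
    if (sleaf[i] > 0) s_of_tax[sleaf[i]] = i;
  return s_of_tax;
}

// [[Rcpp::export]]
int cpp_dc_raw(IntegerVector tpar, IntegerVector tleaf,
               IntegerVector spar, IntegerVector sleaf) {
  GeneTree g = prep_gene(tpar, tleaf);
  std::vector<int> sdep = node_depths(spar);
  std::vector<int> s_of_tax = taxon_index(sleaf);
  return (int)dc_one(g, spar, sdep, s_of_tax);
}

// Per-gene-tree raw costs of a profile against one species tree.
// [[Rcpp::export]]
IntegerVector cpp_profile_costs(List gpar, List gleaf,
                                IntegerVector spar, IntegerVector sleaf) {
  int n = gpar.size();
  std::vector<int> sdep = node_depths(spar);
  std::vector<int> s_of_tax = taxon_index(sleaf);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    GeneTree g = prep_gene(gpar[i], gleaf[i]);
    out[i] = (int)dc_one(g, spar, sdep, s_of_tax);
  }
  return out;
}

// Aggregate raw cost of a profile against each candidate row of `cand`, a
// matrix of parent vectors over 2m-1 nodes where nodes 1..m are the leaves
// labelled by taxa 1..m and nodes m+1..2m-1 are internal.
// [[Rcpp::export]]
NumericVector cpp_score_candidates(IntegerMatrix cand, int m,
                                   List gpar, List gleaf) {
  int n = gpar.size(), ncand = cand.nrow(), nn = cand.ncol();
  std::vector<GeneTree> genes(n);
  for (int i = 0; i < n; ++i) genes[i] = prep_gene(gpar[i], gleaf[i]);
  std::vector<int> s_of_tax(m + 1);
  for (int t = 1; t <= m; ++t) s_of_tax[t] = t - 1;
  NumericVector out(ncand);
  IntegerVector spar(nn);
  for (int c = 0; c < ncand; ++c) {
    for (int j = 0; j < nn; ++j) spar[j] = cand(c, j);
    std::vector<int> sdep = node_depths(spar);
    long tot = 0;
    for (int i = 0; i < n; ++i) tot += dc_one(genes[i], spar, sdep, s_of_tax);
    out[c] = (double)tot;
  }
  return out;
}

// All rooted SPR moves on species tree S and the aggregate raw cost of each
// resulting tree against the gene-tree profile.  A move prunes the subtree at
// node u (u != root), suppresses u's old parent p (reusing it as the new
// attachment node), and regrafts on the edge above node w, including the
// implicit root edge (w = root after detaching).  Excluded w: nodes inside
// the pruned subtree, p itself, and u's former sibling (recreates S).
// Returns parallel vectors (u, w, score), 1-based node ids.
// [[Rcpp::export]]
List cpp_spr_scores(IntegerVector spar0, IntegerVector sleaf,
                    List gpar, List gleaf) {
  int nn = spar0.size(), n = gpar.size();
  std::vector<GeneTree> genes(n);
  for (int i = 0; i < n; ++i) genes[i] = prep_gene(gpar[i], gleaf[i]);
  std::vector<int> s_of_tax = taxon_index(sleaf);

  std::vector<int> us, ws;
  std::vector<double> scores;
  std::vector<char> insub(nn);
  IntegerVector det(nn), par2(nn);

  for (int u = 0; u < nn; ++u) {
    int p = spar0[u] - 1;
    if (p < 0) continue;  // cannot prune at the root
    // sibling of u under p (binary tree: exactly one)
    int sib = -1;
    for (int x = 0; x < nn; ++x)
      if (x != u && spar0[x] - 1 == p) { sib = x; break; }
    // membership of the pruned subtree
    for (int x = 0; x < nn; ++x) {
      int v = x;
      char in = 0;
      while (v != -1) { if (v == u) { in = 1; break; } v = spar0[v] - 1; }
      insub[x] = in;
    }
    // detach: sib takes p's place
    for (int x = 0; x < nn; ++x) det[x] = spar0[x];
    det[sib] = spar0[p];  // may become 0 (new root) if p was root
    for (int w = 0; w < nn; ++w) {
      if (insub[w] || w == p || w == sib) continue;
      for (int x = 0; x < nn; ++x) par2[x] = det[x];
      par2[p] = det[w];
      par2[w] = p + 1;
      par2[u] = p + 1;
      std::vector<int> sdep = node_depths(par2);
      long tot = 0;
      for (int i = 0; i < n; ++i)
        tot += dc_one(genes[i], par2, sdep, s_of_tax);
      us.push_back(u + 1);
      ws.push_back(w + 1);
      scores.push_back((double)tot);
    }
  }
  return List::create(_["u"] = wrap(us), _["w"] = wrap(ws),
                      _["score"] = wrap(scores));
}
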