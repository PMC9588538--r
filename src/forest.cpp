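// Sum-of-trees machinery: binary regression trees with grow/prune/change
// Metropolis-Hastings structural moves under the branching prior
// p(split at depth d) = base * (1 + d)^-power, conjugate normal leaf draws,
// and cached fitted sums for Bayesian backfitting.
//
// All randomness comes from R's RNG (unif_rand / norm_rand), so draws are
// reproducible under set.seed() from R.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int var;     // split variable, -1 if terminal
  double cut;  // x[var] <= cut routes left
  int left, right;
  int parent;
  int depth;
  double mu;   // terminal value
  bool alive;
};

struct Tree {
  std::vector<Node> nodes;  // node 0 is the root; pruned slots recycled
  std::vector<int> freelist;
  std::vector<double> fit;  // per-observation contribution g_h(x_i)

  bool is_leaf(int id) const { return nodes[id].var < 0; }
};

struct Forest {
  int n, p, H;
  std::vector<double> X;  // column-major n x p training design
  double base, power;
  double p_grow, p_prune, p_change;
  std::vector<Tree> trees;
  std::vector<double> total;  // cached sum of tree fits
  // move bookkeeping (since construction)
  long prop_grow, acc_grow, prop_prune, acc_prune, prop_change, acc_change;
  // scratch buffers reused across tree updates (flat CSR obs lists)
  std::vector<int> leaf_of, obs_start, obs_idx, node_cnt;
  std::vector<double> node_sum, uniq_buf;

  double x(int i, int j) const { return X[(size_t)j * n + i]; }
};

inline double psplit(const Forest& F, int depth) {
  return F.base * std::pow(1.0 + depth, -F.power);
}

// log marginal likelihood of a node's residuals, dropping terms that cancel
// in structure-move ratios (they depend only on the pooled observations)
inline double log_ml(double nn, double sr, double s2, double sig2) {
  return 0.5 * std::log(sig2 / (sig2 + nn * s2)) +
         s2 * sr * sr / (2.0 * sig2 * (sig2 + nn * s2));
}

void collect_leaves(const Tree& T, int id, std::vector<int>& out) {
  if (T.nodes[id].var < 0) {
    out.push_back(id);
  } else {
    collect_leaves(T, T.nodes[id].left, out);
    collect_leaves(T, T.nodes[id].right, out);
  }
}

// internal nodes whose both children are terminal
void collect_singly_internal(const Tree& T, int id, std::vector<int>& out) {
  if (T.nodes[id].var < 0) return;
  const Node& nd = T.nodes[id];
  if (T.is_leaf(nd.left) && T.is_leaf(nd.right)) {
    out.push_back(id);
  } else {
    collect_singly_internal(T, nd.left, out);
    collect_singly_internal(T, nd.right, out);
  }
}

int route(const Forest& F, const Tree& T, int i) {
  int id = 0;
  while (T.nodes[id].var >= 0) {
    id = (F.x(i, T.nodes[id].var) <= T.nodes[id].cut) ? T.nodes[id].left
                                                      : T.nodes[id].right;
  }
  return id;
}

// flat CSR observation lists per node id, rebuilt from routing
void assign_obs(Forest& F, const Tree& T) {
  size_t m = T.nodes.size();
  F.leaf_of.resize(F.n);
  F.node_cnt.assign(m, 0);
  for (int i = 0; i < F.n; ++i) {
    int id = route(F, T, i);
    F.leaf_of[i] = id;
    F.node_cnt[id]++;
  }
  F.obs_start.assign(m + 1, 0);
  for (size_t t = 0; t < m; ++t)
    F.obs_start[t + 1] = F.obs_start[t] + F.node_cnt[t];
  std::vector<int> pos(F.obs_start.begin(), F.obs_start.end() - 1);
  F.obs_idx.resize(F.n);
  for (int i = 0; i < F.n; ++i) F.obs_idx[pos[F.leaf_of[i]]++] = i;
}

// does some variable take >= 2 distinct values among node id's obs?
bool growable(const Forest& F, int id) {
  int s = F.obs_start[id], e = F.obs_start[id + 1];
  if (e - s < 2) return false;
  for (int j = 0; j < F.p; ++j) {
    double v0 = F.x(F.obs_idx[s], j);
    for (int t = s + 1; t < e; ++t)
      if (F.x(F.obs_idx[t], j) != v0) return true;
  }
  return false;
}

std::vector<int> vars_with_spread(const Forest& F, int id) {
  std::vector<int> out;
  int s = F.obs_start[id], e = F.obs_start[id + 1];
  for (int j = 0; j < F.p; ++j) {
    double v0 = F.x(F.obs_idx[s], j);
    for (int t = s + 1; t < e; ++t)
      if (F.x(F.obs_idx[t], j) != v0) {
        out.push_back(j);
        break;
      }
  }
  return out;
}

// sorted unique values of variable j among node id's obs (into F.uniq_buf)
void unique_vals(Forest& F, int id, int j) {
  int s = F.obs_start[id], e = F.obs_start[id + 1];
  F.uniq_buf.clear();
  for (int t = s; t < e; ++t) F.uniq_buf.push_back(F.x(F.obs_idx[t], j));
  std::sort(F.uniq_buf.begin(), F.uniq_buf.end());
  F.uniq_buf.erase(std::unique(F.uniq_buf.begin(), F.uniq_buf.end()),
                   F.uniq_buf.end());
}

inline int ipick(int m) {  // uniform on 0..m-1
  int k = (int)std::floor(unif_rand() * m);
  if (k >= m) k = m - 1;
  return k;
}

int new_node(Tree& T) {
  if (!T.freelist.empty()) {
    int id = T.freelist.back();
    T.freelist.pop_back();
    return id;
  }
  T.nodes.push_back(Node());
  return (int)T.nodes.size() - 1;
}

void node_stats(const Forest& F, int id, const std::vector<double>& r,
                double& nn, double& sr) {
  int s = F.obs_start[id], e = F.obs_start[id + 1];
  nn = (double)(e - s);
  sr = 0.0;
  for (int t = s; t < e; ++t) sr += r[F.obs_idx[t]];
}

// One structural MH move + conjugate leaf redraw for tree h given partial
// residuals r, residual variance sig2 and leaf prior variance s2.
void update_tree(Forest& F, int h, const std::vector<double>& r, double sig2,
                 double s2) {
  Tree& T = F.trees[h];
  assign_obs(F, T);

  std::vector<int> leaves;
  collect_leaves(T, 0, leaves);
  std::vector<int> single;
  collect_singly_internal(T, 0, single);

  double u_move = unif_rand();
  bool structure_changed = false;

  if (u_move < F.p_grow) {
    // ---- GROW ----
    F.prop_grow++;
    std::vector<int> grow_ok;
    for (size_t t = 0; t < leaves.size(); ++t)
      if (growable(F, leaves[t])) grow_ok.push_back(leaves[t]);
    if (!grow_ok.empty()) {
      int b = (int)grow_ok.size();
      int L = grow_ok[ipick(b)];
      std::vector<int> vok = vars_with_spread(F, L);
      int var = vok[ipick((int)vok.size())];
      unique_vals(F, L, var);
      const std::vector<double>& uq = F.uniq_buf;
      double cut = uq[ipick((int)uq.size())];
      if (cut < uq.back()) {  // otherwise right child empty: auto-reject
        double nP, srP, nL = 0.0, srL = 0.0;
        node_stats(F, L, r, nP, srP);
        for (int t = F.obs_start[L]; t < F.obs_start[L + 1]; ++t) {
          int i = F.obs_idx[t];
          if (F.x(i, var) <= cut) {
            nL += 1.0;
            srL += r[i];
          }
        }
        double nR = nP - nL, srR = srP - srL;
        int d = T.nodes[L].depth;
        int par = T.nodes[L].parent;
        bool par_single =
            par >= 0 && T.is_leaf(T.nodes[par].left) &&
            T.is_leaf(T.nodes[par].right);
        int w2star = (int)single.size() + 1 - (par_single ? 1 : 0);
        double psd = psplit(F, d), psd1 = psplit(F, d + 1);
        double lacc = std::log(F.p_prune / F.p_grow) + std::log((double)b) -
                      std::log((double)w2star) + std::log(psd) +
                      2.0 * std::log1p(-psd1) - std::log1p(-psd) +
                      log_ml(nL, srL, s2, sig2) + log_ml(nR, srR, s2, sig2) -
                      log_ml(nP, srP, s2, sig2);
        if (std::log(unif_rand()) < lacc) {
          int cl = new_node(T);
          int cr = new_node(T);
          Node& nl = T.nodes[cl];
          Node& nr = T.nodes[cr];
          nl.var = nr.var = -1;
          nl.left = nl.right = nr.left = nr.right = -1;
          nl.parent = nr.parent = L;
          nl.depth = nr.depth = d + 1;
          nl.mu = nr.mu = 0.0;
          nl.alive = nr.alive = true;
          T.nodes[L].var = var;
          T.nodes[L].cut = cut;
          T.nodes[L].left = cl;
          T.nodes[L].right = cr;
          F.acc_grow++;
          structure_changed = true;
        }
      }
    }
  } else if (u_move < F.p_grow + F.p_prune) {
    // ---- PRUNE ----
    F.prop_prune++;
    if (!single.empty()) {
      int w2 = (int)single.size();
      int nd = single[ipick(w2)];
      int cl = T.nodes[nd].left, cr = T.nodes[nd].right;
      // growable leaves of the pruned tree: all current growable leaves
      // except the two children, plus the collapsed node (always growable:
      // its split variable still spreads over its unchanged observations)
      int bstar = 1;
      for (size_t t = 0; t < leaves.size(); ++t) {
        int lf = leaves[t];
        if (lf != cl && lf != cr && growable(F, lf)) bstar++;
      }
      double nL, srL, nR, srR;
      node_stats(F, cl, r, nL, srL);
      node_stats(F, cr, r, nR, srR);
      double nP = nL + nR, srP = srL + srR;
      int d = T.nodes[nd].depth;
      double psd = psplit(F, d), psd1 = psplit(F, d + 1);
      double lacc = std::log(F.p_grow / F.p_prune) + std::log((double)w2) -
                    std::log((double)bstar) -
                    (std::log(psd) + 2.0 * std::log1p(-psd1) -
                     std::log1p(-psd)) -
                    (log_ml(nL, srL, s2, sig2) + log_ml(nR, srR, s2, sig2) -
                     log_ml(nP, srP, s2, sig2));
      if (std::log(unif_rand()) < lacc) {
        T.nodes[cl].alive = false;
        T.nodes[cr].alive = false;
        T.freelist.push_back(cl);
        T.freelist.push_back(cr);
        T.nodes[nd].var = -1;
        T.nodes[nd].left = T.nodes[nd].right = -1;
        F.acc_prune++;
        structure_changed = true;
      }
    }
  } else {
    // ---- CHANGE (rule of a node with two terminal children) ----
    F.prop_change++;
    if (!single.empty()) {
      int nd = single[ipick((int)single.size())];
      int cl = T.nodes[nd].left, cr = T.nodes[nd].right;
      std::vector<int> O;
      O.reserve(F.node_cnt[cl] + F.node_cnt[cr]);
      for (int t = F.obs_start[cl]; t < F.obs_start[cl + 1]; ++t)
        O.push_back(F.obs_idx[t]);
      for (int t = F.obs_start[cr]; t < F.obs_start[cr + 1]; ++t)
        O.push_back(F.obs_idx[t]);
      std::vector<int> vok;
      for (int j = 0; j < F.p; ++j) {
        double v0 = F.x(O[0], j);
        for (size_t t = 1; t < O.size(); ++t)
          if (F.x(O[t], j) != v0) {
            vok.push_back(j);
            break;
          }
      }
      int var = vok[ipick((int)vok.size())];
      F.uniq_buf.clear();
      for (size_t t = 0; t < O.size(); ++t)
        F.uniq_buf.push_back(F.x(O[t], var));
      std::sort(F.uniq_buf.begin(), F.uniq_buf.end());
      F.uniq_buf.erase(std::unique(F.uniq_buf.begin(), F.uniq_buf.end()),
                       F.uniq_buf.end());
      const std::vector<double>& uq = F.uniq_buf;
      double cut = uq[ipick((int)uq.size())];
      if (cut < uq.back()) {
        double nLo, srLo, nRo, srRo;
        node_stats(F, cl, r, nLo, srLo);
        node_stats(F, cr, r, nRo, srRo);
        double nP = nLo + nRo, srP = srLo + srRo;
        double nLn = 0.0, srLn = 0.0;
        for (size_t t = 0; t < O.size(); ++t)
          if (F.x(O[t], var) <= cut) {
            nLn += 1.0;
            srLn += r[O[t]];
          }
        double nRn = nP - nLn, srRn = srP - srLn;
        double lacc = log_ml(nLn, srLn, s2, sig2) +
                      log_ml(nRn, srRn, s2, sig2) -
                      log_ml(nLo, srLo, s2, sig2) -
                      log_ml(nRo, srRo, s2, sig2);
        if (std::log(unif_rand()) < lacc) {
          T.nodes[nd].var = var;
          T.nodes[nd].cut = cut;
          F.acc_change++;
          structure_changed = true;
        }
      }
    }
  }

  // conjugate leaf redraw
  if (structure_changed) assign_obs(F, T);
  leaves.clear();
  collect_leaves(T, 0, leaves);
  size_t m = T.nodes.size();
  F.node_sum.assign(m, 0.0);
  for (int i = 0; i < F.n; ++i) F.node_sum[F.leaf_of[i]] += r[i];
  std::vector<double> mu(m, 0.0);
  for (size_t t = 0; t < leaves.size(); ++t) {
    int lf = leaves[t];
    double nn = (double)F.node_cnt[lf], sr = F.node_sum[lf];
    double pv = sig2 * s2 / (sig2 + nn * s2);
    double pm = s2 * sr / (sig2 + nn * s2);
    double draw = pm + std::sqrt(pv) * norm_rand();
    T.nodes[lf].mu = draw;
    mu[lf] = draw;
  }
  // refresh cached fit for this tree and the forest total
  if ((int)T.fit.size() != F.n) T.fit.assign(F.n, 0.0);
  for (int i = 0; i < F.n; ++i) {
    double g = mu[F.leaf_of[i]];
    F.total[i] += g - T.fit[i];
    T.fit[i] = g;
  }
}

Forest* get(SEXP ptr) {
  Rcpp::XPtr<Forest> xp(ptr);
  return xp.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP forest_create_cpp(NumericMatrix X, int H, double base, double power,
                       double p_grow, double p_prune) {
  Forest* F = new Forest();
  F->n = X.nrow();
  F->p = X.ncol();
  F->H = H;
  F->X.assign(X.begin(), X.end());
  F->base = base;
  F->power = power;
  F->p_grow = p_grow;
  F->p_prune = p_prune;
  F->p_change = 1.0 - p_grow - p_prune;
  F->trees.resize(H);
  for (int h = 0; h < H; ++h) {
    Tree& T = F->trees[h];
    Node root;
    root.var = -1;
    root.left = root.right = -1;
    root.parent = -1;
    root.depth = 0;
    root.mu = 0.0;
    root.alive = true;
    T.nodes.push_back(root);
    T.fit.assign(F->n, 0.0);
  }
  F->total.assign(F->n, 0.0);
  F->prop_grow = F->acc_grow = F->prop_prune = F->acc_prune = 0;
  F->prop_change = F->acc_change = 0;
  Rcpp::XPtr<Forest> xp(F, true);
  return xp;
}

// [[Rcpp::export]]
NumericVector forest_update_cpp(SEXP ptr, NumericVector resp, double sigma2,
                                double leaf_sd) {
  Forest* F = get(ptr);
  if ((int)resp.size() != F->n) stop("response length does not match");
  if (!(sigma2 > 0)) stop("sigma2 must be positive");
  double s2 = leaf_sd * leaf_sd;
  std::vector<double> r(F->n);
  for (int h = 0; h < F->H; ++h) {
    Tree& T = F->trees[h];
    for (int i = 0; i < F->n; ++i) r[i] = resp[i] - F->total[i] + T.fit[i];
    update_tree(*F, h, r, sigma2, s2);
  }
  return NumericVector(F->total.begin(), F->total.end());
}

// [[Rcpp::export]]
NumericVector forest_fits_cpp(SEXP ptr) {
  Forest* F = get(ptr);
  return NumericVector(F->total.begin(), F->total.end());
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(SEXP ptr, NumericMatrix Xnew) {
  Forest* F = get(ptr);
  if (Xnew.ncol() != F->p) stop("newdata has wrong number of columns");
  int m = Xnew.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int h = 0; h < F->H; ++h) {
      const Tree& T = F->trees[h];
      int id = 0;
      while (T.nodes[id].var >= 0)
        id = (Xnew(i, T.nodes[id].var) <= T.nodes[id].cut) ? T.nodes[id].left
                                                           : T.nodes[id].right;
      s += T.nodes[id].mu;
    }
    out[i] = s;
  }
  return out;
}

// Compact representation: one matrix per tree with columns
// (var, cut, left, right, mu, depth); var/left/right are 1-based, 0 = leaf.
// [[Rcpp::export]]
List forest_trees_cpp(SEXP ptr) {
  Forest* F = get(ptr);
  List out(F->H);
  for (int h = 0; h < F->H; ++h) {
    const Tree& T = F->trees[h];
    // remap live node ids to consecutive 1-based indices (preorder)
    std::vector<int> order;
    std::vector<int> stack(1, 0);
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      order.push_back(id);
      if (T.nodes[id].var >= 0) {
        stack.push_back(T.nodes[id].right);
        stack.push_back(T.nodes[id].left);
      }
    }
    std::vector<int> remap(T.nodes.size(), 0);
    for (size_t t = 0; t < order.size(); ++t) remap[order[t]] = (int)t + 1;
    NumericMatrix M((int)order.size(), 6);
    for (size_t t = 0; t < order.size(); ++t) {
      const Node& nd = T.nodes[order[t]];
      bool leaf = nd.var < 0;
      M(t, 0) = leaf ? 0 : nd.var + 1;
      M(t, 1) = leaf ? NA_REAL : nd.cut;
      M(t, 2) = leaf ? 0 : remap[nd.left];
      M(t, 3) = leaf ? 0 : remap[nd.right];
      M(t, 4) = nd.mu;
      M(t, 5) = nd.depth;
    }
    colnames(M) = CharacterVector::create("var", "cut", "left", "right", "mu",
                                          "depth");
    out[h] = M;
  }
  return out;
}

// Predict from the compact list representation (posterior snapshots).
// [[Rcpp::export]]
NumericVector predict_trees_cpp(List trees, NumericMatrix Xnew) {
  int m = Xnew.nrow();
  NumericVector out(m);
  for (int h = 0; h < trees.size(); ++h) {
    NumericMatrix M = trees[h];
    for (int i = 0; i < m; ++i) {
      int id = 0;  // 0-based row of M
      while (M(id, 0) > 0) {
        int var = (int)M(id, 0) - 1;
        id = (Xnew(i, var) <= M(id, 1)) ? (int)M(id, 2) - 1 : (int)M(id, 3) - 1;
      }
      out[i] += M(id, 4);
    }
  }
  return out;
}

// Rebuild a live forest from the compact representation.
// [[Rcpp::export]]
SEXP forest_restore_cpp(NumericMatrix X, List trees, double base, double power,
                        double p_grow, double p_prune) {
  SEXP ptr = forest_create_cpp(X, (int)trees.size(), base, power, p_grow,
                               p_prune);
  Forest* F = get(ptr);
  for (int h = 0; h < F->H; ++h) {
    NumericMatrix M = trees[h];
    Tree& T = F->trees[h];
    T.nodes.clear();
    T.freelist.clear();
    for (int t = 0; t < M.nrow(); ++t) {
      Node nd;
      bool leaf = M(t, 0) == 0;
      nd.var = leaf ? -1 : (int)M(t, 0) - 1;
      nd.cut = leaf ? 0.0 : M(t, 1);
      nd.left = leaf ? -1 : (int)M(t, 2) - 1;
      nd.right = leaf ? -1 : (int)M(t, 3) - 1;
      nd.parent = -1;
      nd.depth = (int)M(t, 5);
      nd.mu = M(t, 4);
      nd.alive = true;
      T.nodes.push_back(nd);
    }
    for (size_t t = 0; t < T.nodes.size(); ++t) {
      if (T.nodes[t].var >= 0) {
        T.nodes[T.nodes[t].left].parent = (int)t;
        T.nodes[T.nodes[t].right].parent = (int)t;
      }
    }
    for (int i = 0; i < F->n; ++i) {
      double g = T.nodes[route(*F, T, i)].mu;
      F->total[i] += g - T.fit[i];
      T.fit[i] = g;
    }
  }
  return ptr;
}

// [[Rcpp::export]]
List forest_stats_cpp(SEXP ptr) {
  Forest* F = get(ptr);
  NumericVector leaves(F->H), depth(F->H);
  for (int h = 0; h < F->H; ++h) {
    std::vector<int> lv;
    collect_leaves(F->trees[h], 0, lv);
    leaves[h] = (double)lv.size();
    double dmax = 0;
    for (size_t t = 0; t < lv.size(); ++t)
      dmax = std::max(dmax, (double)F->trees[h].nodes[lv[t]].depth);
    depth[h] = dmax;
  }
  return List::create(
      _["leaves"] = leaves, _["depth"] = depth,
      _["prop"] = NumericVector::create((double)F->prop_grow,
                                        (double)F->prop_prune,
                                        (double)F->prop_change),
      _["acc"] = NumericVector::create((double)F->acc_grow,
                                       (double)F->acc_prune,
                                       (double)F->acc_change));
}
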