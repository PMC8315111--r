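// Sum-of-trees MCMC core.
//
// The sampler is a Metropolis-within-Gibbs backfitter: each tree in turn is
// updated against the partial residuals of the other trees with a
// GROW/PRUNE/CHANGE Metropolis-Hastings move whose acceptance ratio uses the
// leaf-marginalized likelihood, then leaf values, the residual variance, the
// leaf variance, and (optionally) the Dirichlet split probabilities are drawn
// from their conjugate full conditionals.  All randomness comes from a private
// 64-bit generator seeded from R so that runs are reproducible independently
// of the R session RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {
    // 53-bit uniform in (0, 1)
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  // Marsaglia-Tsang, unit scale
  double gamma(double shape) {
    if (shape < 1.0) {
      return gamma(shape + 1.0) * std::pow(unif(), 1.0 / shape);
    }
    const double d = shape - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = normal();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (std::log(u) < 0.5 * x * x + d - d * v + d * std::log(v)) return d * v;
    }
  }
  // inverse-gamma with shape a, scale b
  double inv_gamma(double a, double b) { return b / gamma(a); }
  int sample_int(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  int sample_weighted(const std::vector<double>& w) {
    double u = unif();
    double acc = 0.0;
    for (size_t j = 0; j < w.size(); ++j) {
      acc += w[j];
      if (u <= acc) return (int)j;
    }
    return (int)w.size() - 1;
  }
};

struct Node {
  int var;       // -1 for leaf
  double split;
  double leaf;
  int left, right, parent;
  int depth;
  bool active;
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> freelist;
  Tree() { nodes.push_back(Node{-1, 0.0, 0.0, -1, -1, -1, 0, true}); }
  int alloc() {
    if (!freelist.empty()) {
      int id = freelist.back();
      freelist.pop_back();
      nodes[id].active = true;
      return id;
    }
    nodes.push_back(Node{-1, 0.0, 0.0, -1, -1, -1, 0, true});
    return (int)nodes.size() - 1;
  }
  void release(int id) {
    nodes[id].active = false;
    freelist.push_back(id);
  }
  bool is_stump() const { return nodes[0].var < 0; }
};

inline double psplit(int depth, double alpha, double beta) {
  return alpha * std::pow(1.0 + depth, -beta);
}

// marginal log-likelihood contribution of one leaf (terms that do not cancel
// between trees over the same row set), leaf prior N(m0, sigma_mu2), noise
// N(0, sigma2):
//   0.5 log(sigma2 / (sigma2 + n sigma_mu2))
//   + sigma_mu2 (s - n m0)^2 / (2 sigma2 (sigma2 + n sigma_mu2))
inline double leaf_marg(double n, double s, double sigma2, double sigma_mu2,
                        double m0) {
  double denom = sigma2 + n * sigma_mu2;
  double d = s - n * m0;
  return 0.5 * std::log(sigma2 / denom) +
         sigma_mu2 * d * d / (2.0 * sigma2 * denom);
}

class Sampler {
 public:
  const NumericMatrix& X;
  const double* Xp;
  int n, P, K;
  std::vector<double> y;            // standardized response
  double alpha, beta, m0;
  double s2_shape, s2_scale, smu_shape, smu_scale;
  bool sparsity;
  double dirichlet_conc;
  Rng rng;

  std::vector<std::vector<double>> cuts;  // unique sorted values per predictor
  std::vector<Tree> forest;
  std::vector<std::vector<int>> leaf_of;  // per tree, node id per row
  std::vector<double> resid;              // y - sum_k fit_k
  double sigma2, sigma_mu2;
  std::vector<double> split_probs;

  const double PG = 0.28, PP = 0.28, PC = 0.44;

  Sampler(const NumericMatrix& X_, const std::vector<double>& y_, int K_,
          double alpha_, double beta_, double m0_, double s2sh, double s2sc,
          double smush, double smusc, bool sparse_, double conc_, uint64_t seed)
      : X(X_), Xp(&X_[0]), n(X_.nrow()), P(X_.ncol()), K(K_), y(y_), alpha(alpha_),
        beta(beta_), m0(m0_), s2_shape(s2sh), s2_scale(s2sc), smu_shape(smush),
        smu_scale(smusc), sparsity(sparse_), dirichlet_conc(conc_), rng(seed) {
    cuts.resize(P);
    for (int j = 0; j < P; ++j) {
      std::vector<double> v(n);
      for (int i = 0; i < n; ++i) v[i] = X(i, j);
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
      cuts[j] = v;
    }
    double ybar = 0.0, yvar = 0.0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    for (int i = 0; i < n; ++i) yvar += (y[i] - ybar) * (y[i] - ybar);
    yvar = n > 1 ? yvar / (n - 1) : 1.0;
    sigma2 = yvar > 0 ? yvar : 1.0;
    sigma_mu2 = 0.25 / (4.0 * K);  // (0.5 / (2 sqrt(K)))^2, adapted by Gibbs
    split_probs.assign(P, 1.0 / P);
    forest.assign(K, Tree());
    leaf_of.assign(K, std::vector<int>(n, 0));
    for (int k = 0; k < K; ++k) forest[k].nodes[0].leaf = ybar / K;
    resid.assign(n, 0.0);
    for (int i = 0; i < n; ++i) resid[i] = y[i] - ybar;
  }

  // move probability at a given state under the resample-invalid-moves rule
  double move_prob(bool stump, int which) const {  // 0 grow, 1 prune, 2 change
    if (stump) return which == 0 ? 1.0 : 0.0;
    return which == 0 ? PG : (which == 1 ? PP : PC);
  }

  int count_prunable(const Tree& t) const {
    int w = 0;
    for (const Node& nd : t.nodes)
      if (nd.active && nd.var >= 0 && t.nodes[nd.left].var < 0 &&
          t.nodes[nd.right].var < 0)
        ++w;
    return w;
  }
  int count_leaves(const Tree& t) const {
    int b = 0;
    for (const Node& nd : t.nodes)
      if (nd.active && nd.var < 0) ++b;
    return b;
  }
  int count_internal(const Tree& t) const {
    int m = 0;
    for (const Node& nd : t.nodes)
      if (nd.active && nd.var >= 0) ++m;
    return m;
  }

  void draw_rule(int& var, double& cut) {
    var = rng.sample_weighted(split_probs);
    const std::vector<double>& cv = cuts[var];
    cut = cv[rng.sample_int((int)cv.size())];
  }

  void update_tree(int k, std::vector<double>& r) {
    Tree& t = forest[k];
    std::vector<int>& lo = leaf_of[k];

    bool stump = t.is_stump();
    int move;
    {
      double u = rng.unif();
      if (stump) {
        move = 0;
      } else {
        move = (u < PG) ? 0 : (u < PG + PP ? 1 : 2);
      }
    }

    if (move == 0) {  // GROW
      std::vector<int> leaves;
      for (int id = 0; id < (int)t.nodes.size(); ++id)
        if (t.nodes[id].active && t.nodes[id].var < 0) leaves.push_back(id);
      int b = (int)leaves.size();
      int L = leaves[rng.sample_int(b)];
      int var;
      double cut;
      draw_rule(var, cut);
      double nl = 0, sl = 0, nL = 0, sL = 0, nR = 0, sR = 0;
      for (int i = 0; i < n; ++i) {
        if (lo[i] != L) continue;
        nl += 1.0;
        sl += r[i];
        if (Xp[(size_t)var * n + i] <= cut) {
          nL += 1.0;
          sL += r[i];
        } else {
          nR += 1.0;
          sR += r[i];
        }
      }
      if (nL == 0 || nR == 0) return;  // empty-leaf proposals rejected
      int d = t.nodes[L].depth;
      double ps_d = psplit(d, alpha, beta);
      double ps_c = psplit(d + 1, alpha, beta);
      // prunable count of the proposal
      int w2 = count_prunable(t) + 1;
      int par = t.nodes[L].parent;
      if (par >= 0) {
        int sib = (t.nodes[par].left == L) ? t.nodes[par].right
                                           : t.nodes[par].left;
        if (t.nodes[sib].var < 0) --w2;  // parent was prunable, no longer
      }
      double log_acc =
          leaf_marg(nL, sL, sigma2, sigma_mu2, m0) +
          leaf_marg(nR, sR, sigma2, sigma_mu2, m0) -
          leaf_marg(nl, sl, sigma2, sigma_mu2, m0) +
          std::log(ps_d) + 2.0 * std::log(1.0 - ps_c) - std::log(1.0 - ps_d) +
          std::log(PP) - std::log(move_prob(stump, 0)) + std::log((double)b) -
          std::log((double)w2);
      if (std::log(rng.unif()) < log_acc) {
        int cl = t.alloc(), cr = t.alloc();
        Node& nl_ = t.nodes[L];
        nl_.var = var;
        nl_.split = cut;
        nl_.left = cl;
        nl_.right = cr;
        t.nodes[cl] = Node{-1, 0.0, 0.0, -1, -1, L, nl_.depth + 1, true};
        t.nodes[cr] = Node{-1, 0.0, 0.0, -1, -1, L, nl_.depth + 1, true};
        for (int i = 0; i < n; ++i)
          if (lo[i] == L) lo[i] = (Xp[(size_t)var * n + i] <= cut) ? cl : cr;
      }
    } else if (move == 1) {  // PRUNE
      std::vector<int> prunable;
      for (int id = 0; id < (int)t.nodes.size(); ++id) {
        const Node& nd = t.nodes[id];
        if (nd.active && nd.var >= 0 && t.nodes[nd.left].var < 0 &&
            t.nodes[nd.right].var < 0)
          prunable.push_back(id);
      }
      int w2 = (int)prunable.size();
      int D = prunable[rng.sample_int(w2)];
      int cl = t.nodes[D].left, cr = t.nodes[D].right;
      double nL = 0, sL = 0, nR = 0, sR = 0;
      for (int i = 0; i < n; ++i) {
        if (lo[i] == cl) {
          nL += 1.0;
          sL += r[i];
        } else if (lo[i] == cr) {
          nR += 1.0;
          sR += r[i];
        }
      }
      int d = t.nodes[D].depth;
      double ps_d = psplit(d, alpha, beta);
      double ps_c = psplit(d + 1, alpha, beta);
      int b_prime = count_leaves(t) - 1;
      bool prime_stump = (count_internal(t) == 1);
      double log_acc =
          leaf_marg(nL + nR, sL + sR, sigma2, sigma_mu2, m0) -
          leaf_marg(nL, sL, sigma2, sigma_mu2, m0) -
          leaf_marg(nR, sR, sigma2, sigma_mu2, m0) -
          (std::log(ps_d) + 2.0 * std::log(1.0 - ps_c) -
           std::log(1.0 - ps_d)) +
          std::log(move_prob(prime_stump, 0)) - std::log(PP) +
          std::log((double)w2) - std::log((double)b_prime);
      if (std::log(rng.unif()) < log_acc) {
        Node& nd = t.nodes[D];
        nd.var = -1;
        t.release(cl);
        t.release(cr);
        nd.left = nd.right = -1;
        for (int i = 0; i < n; ++i)
          if (lo[i] == cl || lo[i] == cr) lo[i] = D;
      }
    } else {  // CHANGE
      std::vector<int> internal;
      for (int id = 0; id < (int)t.nodes.size(); ++id)
        if (t.nodes[id].active && t.nodes[id].var >= 0) internal.push_back(id);
      int C = internal[rng.sample_int((int)internal.size())];
      // descendant leaves and rows of the affected subtree
      std::vector<int> stack{C}, desc_leaves;
      std::vector<char> in_sub(t.nodes.size(), 0);
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        in_sub[id] = 1;
        if (t.nodes[id].var < 0) {
          desc_leaves.push_back(id);
        } else {
          stack.push_back(t.nodes[id].left);
          stack.push_back(t.nodes[id].right);
        }
      }
      std::vector<int> rows;
      rows.reserve(64);
      for (int i = 0; i < n; ++i)
        if (in_sub[lo[i]]) rows.push_back(i);
      // old per-leaf stats
      double lm_old = 0.0;
      {
        std::vector<double> cnt(t.nodes.size(), 0.0), sum(t.nodes.size(), 0.0);
        for (int i : rows) {
          cnt[lo[i]] += 1.0;
          sum[lo[i]] += r[i];
        }
        for (int id : desc_leaves)
          lm_old += leaf_marg(cnt[id], sum[id], sigma2, sigma_mu2, m0);
      }
      int old_var = t.nodes[C].var;
      double old_split = t.nodes[C].split;
      int var;
      double cut;
      draw_rule(var, cut);
      t.nodes[C].var = var;
      t.nodes[C].split = cut;
      // reroute
      std::vector<int> new_lo(rows.size());
      std::vector<double> cnt(t.nodes.size(), 0.0), sum(t.nodes.size(), 0.0);
      for (size_t ii = 0; ii < rows.size(); ++ii) {
        int i = rows[ii];
        int id = C;
        while (t.nodes[id].var >= 0)
          id = (Xp[(size_t)t.nodes[id].var * n + i] <= t.nodes[id].split)
                   ? t.nodes[id].left
                   : t.nodes[id].right;
        new_lo[ii] = id;
        cnt[id] += 1.0;
        sum[id] += r[i];
      }
      bool empty = false;
      double lm_new = 0.0;
      for (int id : desc_leaves) {
        if (cnt[id] == 0.0) {
          empty = true;
          break;
        }
        lm_new += leaf_marg(cnt[id], sum[id], sigma2, sigma_mu2, m0);
      }
      if (!empty && std::log(rng.unif()) < lm_new - lm_old) {
        for (size_t ii = 0; ii < rows.size(); ++ii) lo[rows[ii]] = new_lo[ii];
      } else {
        t.nodes[C].var = old_var;
        t.nodes[C].split = old_split;
      }
    }

    // conjugate leaf draws for all leaves of tree k
    std::vector<double> cnt(t.nodes.size(), 0.0), sum(t.nodes.size(), 0.0);
    for (int i = 0; i < n; ++i) {
      cnt[lo[i]] += 1.0;
      sum[lo[i]] += r[i];
    }
    for (int id = 0; id < (int)t.nodes.size(); ++id) {
      Node& nd = t.nodes[id];
      if (!nd.active || nd.var >= 0) continue;
      if (cnt[id] == 0.0) {
        nd.leaf = m0 + std::sqrt(sigma_mu2) * rng.normal();
      } else {
        double prec = cnt[id] / sigma2 + 1.0 / sigma_mu2;
        double mean = (sum[id] / sigma2 + m0 / sigma_mu2) / prec;
        nd.leaf = mean + rng.normal() / std::sqrt(prec);
      }
    }
  }

  void iteration() {
    for (int k = 0; k < K; ++k) {
      Tree& t = forest[k];
      std::vector<int>& lo = leaf_of[k];
      // partial residuals: add this tree's current fit back in
      std::vector<double> r(n);
      for (int i = 0; i < n; ++i) r[i] = resid[i] + t.nodes[lo[i]].leaf;
      update_tree(k, r);
      for (int i = 0; i < n; ++i) resid[i] = r[i] - t.nodes[lo[i]].leaf;
    }
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += resid[i] * resid[i];
    sigma2 = rng.inv_gamma(s2_shape + 0.5 * n, s2_scale + 0.5 * ss);
    double ssmu = 0.0;
    int L = 0;
    for (int k = 0; k < K; ++k)
      for (const Node& nd : forest[k].nodes)
        if (nd.active && nd.var < 0) {
          ssmu += (nd.leaf - m0) * (nd.leaf - m0);
          ++L;
        }
    sigma_mu2 = rng.inv_gamma(smu_shape + 0.5 * L, smu_scale + 0.5 * ssmu);
    if (sparsity) {
      std::vector<double> counts(P, 0.0);
      for (int k = 0; k < K; ++k)
        for (const Node& nd : forest[k].nodes)
          if (nd.active && nd.var >= 0) counts[nd.var] += 1.0;
      double tot = 0.0;
      for (int j = 0; j < P; ++j) {
        split_probs[j] = rng.gamma(dirichlet_conc / P + counts[j]);
        tot += split_probs[j];
      }
      for (int j = 0; j < P; ++j) split_probs[j] /= tot;
    }
  }

  void split_counts(std::vector<int>& out) const {
    out.assign(P, 0);
    for (int k = 0; k < K; ++k)
      for (const Node& nd : forest[k].nodes)
        if (nd.active && nd.var >= 0) ++out[nd.var];
  }

  double predict_row(const NumericMatrix& Xs, int i) const {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      const Tree& t = forest[k];
      int id = 0;
      while (t.nodes[id].var >= 0)
        id = (Xs(i, t.nodes[id].var) <= t.nodes[id].split) ? t.nodes[id].left
                                                           : t.nodes[id].right;
      s += t.nodes[id].leaf;
    }
    return s;
  }

  // preorder serialization: rows of (var + 1, value); var 0 encodes a leaf
  void serialize_tree(const Tree& t, int id, std::vector<double>& var_col,
                      std::vector<double>& val_col) const {
    const Node& nd = t.nodes[id];
    if (nd.var < 0) {
      var_col.push_back(0.0);
      val_col.push_back(nd.leaf);
    } else {
      var_col.push_back(nd.var + 1.0);
      val_col.push_back(nd.split);
      serialize_tree(t, nd.left, var_col, val_col);
      serialize_tree(t, nd.right, var_col, val_col);
    }
  }
};

// decode a (var, value) preorder stream starting at pos; returns value for row
double route_preorder(const std::vector<double>& var_col,
                      const std::vector<double>& val_col, size_t& pos,
                      const NumericMatrix& X, int i, bool take) {
  int var = (int)var_col[pos];
  double val = val_col[pos];
  ++pos;
  if (var == 0) return take ? val : 0.0;
  bool go_left = X(i, var - 1) <= val;
  double out = 0.0;
  double l = route_preorder(var_col, val_col, pos, X, i, take && go_left);
  double r = route_preorder(var_col, val_col, pos, X, i, take && !go_left);
  out = go_left ? l : r;
  return take ? out : 0.0;
}

}  // namespace

// [[Rcpp::export]]
List bart_mcmc_cpp(NumericMatrix X, NumericVector y, NumericMatrix X_test,
                   int K, double alpha, double beta, double m0,
                   double sigma2_shape, double sigma2_scale,
                   double sigmamu2_shape, double sigmamu2_scale, bool sparsity,
                   double dirichlet_conc, int burn_in, int n_post, int thin,
                   double seed, bool keep_forests, bool track_train) {
  int n = X.nrow(), P = X.ncol(), n_test = X_test.nrow();
  std::vector<double> yv(y.begin(), y.end());
  Sampler smp(X, yv, K, alpha, beta, m0, sigma2_shape, sigma2_scale,
              sigmamu2_shape, sigmamu2_scale, sparsity, dirichlet_conc,
              (uint64_t)seed);

  int S = n_post;
  NumericVector sigma2_d(S), sigma_mu2_d(S);
  IntegerMatrix split_d(S, P);
  NumericMatrix test_pred(S, n_test);
  NumericMatrix train_pred(track_train ? S : 0, track_train ? n : 0);
  std::vector<double> f_draw, f_tree, f_var, f_val;

  int total = burn_in + n_post * thin;
  int s = 0;
  for (int it = 0; it < total; ++it) {
    smp.iteration();
    if (it >= burn_in && ((it - burn_in) % thin) == (thin - 1)) {
      if (s >= S) break;
      sigma2_d[s] = smp.sigma2;
      sigma_mu2_d[s] = smp.sigma_mu2;
      std::vector<int> cnts;
      smp.split_counts(cnts);
      for (int j = 0; j < P; ++j) split_d(s, j) = cnts[j];
      for (int i = 0; i < n_test; ++i) test_pred(s, i) = smp.predict_row(X_test, i);
      if (track_train)
        for (int i = 0; i < n; ++i) train_pred(s, i) = yv[i] - smp.resid[i];
      if (keep_forests) {
        for (int k = 0; k < K; ++k) {
          std::vector<double> vc, lc;
          smp.serialize_tree(smp.forest[k], 0, vc, lc);
          for (size_t q = 0; q < vc.size(); ++q) {
            f_draw.push_back(s + 1.0);
            f_tree.push_back(k + 1.0);
            f_var.push_back(vc[q]);
            f_val.push_back(lc[q]);
          }
        }
      }
      ++s;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix forests(keep_forests ? (int)f_draw.size() : 0, 4);
  if (keep_forests) {
    for (int q = 0; q < (int)f_draw.size(); ++q) {
      forests(q, 0) = f_draw[q];
      forests(q, 1) = f_tree[q];
      forests(q, 2) = f_var[q];
      forests(q, 3) = f_val[q];
    }
    colnames(forests) = CharacterVector::create("draw", "tree", "var", "value");
  }
  return List::create(
      _["sigma2"] = sigma2_d, _["sigma_mu2"] = sigma_mu2_d,
      _["split_counts"] = split_d, _["test_pred"] = test_pred,
      _["train_pred"] = train_pred, _["forests"] = forests);
}

// Predict forest sums for each draw in a serialized forest matrix.
// forest columns: draw (1-based), tree, var (0 = leaf else 1-based), value.
// [[Rcpp::export]]
NumericMatrix bart_predict_cpp(NumericMatrix forest, int n_draws,
                               NumericMatrix X) {
  int n = X.nrow();
  int m = forest.nrow();
  std::vector<double> var_col(m), val_col(m);
  std::vector<double> draw_col(m);
  for (int q = 0; q < m; ++q) {
    draw_col[q] = forest(q, 0);
    var_col[q] = forest(q, 2);
    val_col[q] = forest(q, 3);
  }
  // start offset of each draw
  std::vector<size_t> start(n_draws + 1, (size_t)m);
  for (int q = m - 1; q >= 0; --q) start[(int)draw_col[q] - 1] = (size_t)q;
  for (int s = n_draws - 1; s >= 0; --s)
    if (start[s] == (size_t)m) start[s] = start[s + 1];

  NumericMatrix out(n_draws, n);
  for (int s = 0; s < n_draws; ++s) {
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      size_t pos = start[s];
      while (pos < start[s + 1]) {
        tot += route_preorder(var_col, val_col, pos, X, i, true);
      }
      out(s, i) = tot;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
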