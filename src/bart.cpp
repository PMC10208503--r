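// Sum-of-trees (BART) backfitting Gibbs sampler.
//
// Response is assumed pre-scaled to [-0.5, 0.5].  Tree structures move by
// Metropolis-Hastings grow/prune/change proposals against the
// alpha*(1+depth)^(-beta) regularization prior; leaf values and the noise
// variance are Gibbs-drawn.  Missing predictor values are routed by a
// per-split direction flag sampled with the split (missingness incorporated
// in attributes).  Split-rule proposals are uniform over variables and over
// a fixed per-variable cutpoint grid, matching the (uniform) split-rule
// prior, so those terms cancel in the acceptance ratio.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Node {
  int var;        // -1 for leaf
  double cut;     // rule: x < cut goes left
  int miss_left;  // 1: missing goes left
  int left, right;
  double mu;
};
typedef std::vector<Node> Tree;

static const double PGROW = 0.28, PPRUNE = 0.28; // change = 0.44

struct Sampler {
  const NumericMatrix& X;
  const std::vector<double>& ys;
  const std::vector<std::vector<double> >& cuts;
  int n, p;
  double sigma2, s2;   // noise variance, leaf prior variance
  double alpha, beta;
  bool use_missing, prior_only;

  Sampler(const NumericMatrix& X_, const std::vector<double>& ys_,
          const std::vector<std::vector<double> >& cuts_,
          double alpha_, double beta_, bool um, bool po)
    : X(X_), ys(ys_), cuts(cuts_), n(X_.nrow()), p(X_.ncol()),
      sigma2(1.0), s2(1.0), alpha(alpha_), beta(beta_),
      use_missing(um), prior_only(po) {}

  int drop_row(const Tree& tr, int i) const {
    int nd = 0;
    while (tr[nd].var >= 0) {
      double x = X(i, tr[nd].var);
      bool left;
      if (NumericVector::is_na(x)) left = tr[nd].miss_left != 0;
      else left = x < tr[nd].cut;
      nd = left ? tr[nd].left : tr[nd].right;
    }
    return nd;
  }

  void assign(const Tree& tr, std::vector<int>& leaf_of) const {
    leaf_of.resize(n);
    for (int i = 0; i < n; ++i) leaf_of[i] = drop_row(tr, i);
  }

  // Integrated (leaf-marginalized) log-likelihood, dropping terms that are
  // identical for trees sharing the same rows/residuals.
  double loglik(const Tree& tr, const std::vector<int>& leaf_of,
                const std::vector<double>& resid) const {
    if (prior_only) return 0.0;
    std::vector<double> S(tr.size(), 0.0);
    std::vector<int> cnt(tr.size(), 0);
    for (int i = 0; i < n; ++i) { S[leaf_of[i]] += resid[i]; cnt[leaf_of[i]]++; }
    double ll = 0.0;
    for (size_t nd = 0; nd < tr.size(); ++nd) {
      if (tr[nd].var >= 0 || cnt[nd] == 0) continue;
      double denom = sigma2 + cnt[nd] * s2;
      ll += 0.5 * std::log(sigma2 / denom) +
            s2 * S[nd] * S[nd] / (2.0 * sigma2 * denom);
    }
    return ll;
  }

  void depths(const Tree& tr, std::vector<int>& d) const {
    d.assign(tr.size(), 0);
    std::vector<int> stack; stack.push_back(0);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      if (tr[nd].var >= 0) {
        d[tr[nd].left] = d[nd] + 1; d[tr[nd].right] = d[nd] + 1;
        stack.push_back(tr[nd].left); stack.push_back(tr[nd].right);
      }
    }
  }

  double log_psplit(int d) const {
    return std::log(alpha) - beta * std::log1p((double)d);
  }
  double log_pnosplit(int d) const {
    return std::log(1.0 - alpha * std::pow(1.0 + d, -beta));
  }

  void leaf_counts(const Tree& tr, const std::vector<int>& leaf_of,
                   std::vector<int>& cnt) const {
    cnt.assign(tr.size(), 0);
    for (int i = 0; i < n; ++i) cnt[leaf_of[i]]++;
  }

  void splittable_leaves(const Tree& tr, const std::vector<int>& cnt,
                         std::vector<int>& out) const {
    out.clear();
    for (size_t nd = 0; nd < tr.size(); ++nd) {
      if (tr[nd].var < 0 && (prior_only || cnt[nd] >= 2)) out.push_back(nd);
    }
  }

  void prunable_nodes(const Tree& tr, std::vector<int>& out) const {
    out.clear();
    for (size_t nd = 0; nd < tr.size(); ++nd) {
      if (tr[nd].var >= 0 &&
          tr[tr[nd].left].var < 0 && tr[tr[nd].right].var < 0)
        out.push_back(nd);
    }
  }

  bool draw_rule(int& var, double& cut, int& mleft) {
    var = (int)std::floor(unif_rand() * p);
    if (var >= p) var = p - 1;
    const std::vector<double>& cv = cuts[var];
    if (cv.empty()) return false;
    int ci = (int)std::floor(unif_rand() * cv.size());
    if (ci >= (int)cv.size()) ci = cv.size() - 1;
    cut = cv[ci];
    mleft = use_missing ? (unif_rand() < 0.5 ? 1 : 0) : 0;
    return true;
  }

  bool children_nonempty(const Tree& tr, int node,
                         const std::vector<int>& leaf_of_old, int old_node,
                         std::vector<int>& leaf_of_new) const {
    // recompute assignment for rows previously reaching old_node
    leaf_of_new = leaf_of_old;
    int nl = 0, nr = 0;
    for (int i = 0; i < n; ++i) {
      if (leaf_of_old[i] != old_node) continue;
      int nd = drop_subtree(tr, node, i);
      leaf_of_new[i] = nd;
    }
    for (int i = 0; i < n; ++i) {
      if (leaf_of_new[i] == tr[node].left) nl++;
      else if (leaf_of_new[i] == tr[node].right) nr++;
    }
    return nl >= 1 && nr >= 1;
  }

  int drop_subtree(const Tree& tr, int start, int i) const {
    int nd = start;
    while (tr[nd].var >= 0) {
      double x = X(i, tr[nd].var);
      bool left;
      if (NumericVector::is_na(x)) left = tr[nd].miss_left != 0;
      else left = x < tr[nd].cut;
      nd = left ? tr[nd].left : tr[nd].right;
    }
    return nd;
  }

  // One MH structure move on `tr` (in place), given residuals.
  void mh_move(Tree& tr, std::vector<int>& leaf_of,
               const std::vector<double>& resid) {
    std::vector<int> cnt;
    leaf_counts(tr, leaf_of, cnt);
    bool stump = tr.size() == 1;
    double u = unif_rand();
    double pg = stump ? 1.0 : PGROW;
    int move; // 0 grow, 1 prune, 2 change
    if (u < pg) move = 0;
    else if (u < pg + PPRUNE) move = 1;
    else move = 2;
    if (stump && move != 0) return;

    std::vector<int> dth;
    depths(tr, dth);
    double ll_old = loglik(tr, leaf_of, resid);

    if (move == 0) { // grow
      std::vector<int> sl;
      splittable_leaves(tr, cnt, sl);
      if (sl.empty()) return;
      int pick = sl[(int)std::floor(unif_rand() * sl.size()) % sl.size()];
      int var, mleft; double cut;
      if (!draw_rule(var, cut, mleft)) return;
      Tree prop = tr;
      int li = prop.size(), ri = prop.size() + 1;
      Node leaf; leaf.var = -1; leaf.cut = 0; leaf.miss_left = 0;
      leaf.left = leaf.right = -1; leaf.mu = 0;
      prop.push_back(leaf); prop.push_back(leaf);
      prop[pick].var = var; prop[pick].cut = cut; prop[pick].miss_left = mleft;
      prop[pick].left = li; prop[pick].right = ri;
      std::vector<int> leaf_new;
      if (!prior_only &&
          !children_nonempty(prop, pick, leaf_of, pick, leaf_new)) return;
      if (prior_only) { leaf_new = leaf_of; assign(prop, leaf_new); }
      double ll_new = loglik(prop, leaf_new, resid);
      int d = dth[pick];
      double lprior = log_psplit(d) + 2.0 * log_pnosplit(d + 1) -
                      log_pnosplit(d);
      std::vector<int> pr_new;
      prunable_nodes(prop, pr_new);
      double pg_prop = PPRUNE; // prune prob in proposed (never stump)
      double lq = std::log(pg_prop) - std::log((double)pr_new.size()) -
                  (std::log(pg) - std::log((double)sl.size()));
      if (std::log(unif_rand()) < ll_new - ll_old + lprior + lq) {
        tr.swap(prop); leaf_of.swap(leaf_new);
      }
    } else if (move == 1) { // prune
      std::vector<int> pr;
      prunable_nodes(tr, pr);
      if (pr.empty()) return;
      int pick = pr[(int)std::floor(unif_rand() * pr.size()) % pr.size()];
      Tree prop = tr;
      prop[pick].var = -1; prop[pick].left = prop[pick].right = -1;
      std::vector<int> leaf_new(leaf_of);
      for (int i = 0; i < n; ++i) {
        if (leaf_new[i] == tr[pick].left || leaf_new[i] == tr[pick].right)
          leaf_new[i] = pick;
      }
      double ll_new = loglik(prop, leaf_new, resid);
      int d = dth[pick];
      double lprior = -(log_psplit(d) + 2.0 * log_pnosplit(d + 1) -
                        log_pnosplit(d));
      std::vector<int> cnt_new, sl_new;
      leaf_counts(prop, leaf_new, cnt_new);
      splittable_leaves(prop, cnt_new, sl_new);
      bool to_stump = true;
      for (size_t nd2 = 0; nd2 < prop.size(); ++nd2)
        if (prop[nd2].var >= 0) { to_stump = false; break; }
      double pg_new = to_stump ? 1.0 : PGROW;
      double lq = std::log(pg_new) - std::log((double)sl_new.size()) -
                  (std::log(PPRUNE) - std::log((double)pr.size()));
      if (std::log(unif_rand()) < ll_new - ll_old + lprior + lq) {
        tr.swap(prop); leaf_of.swap(leaf_new);
      }
    } else { // change
      std::vector<int> pr;
      prunable_nodes(tr, pr);
      if (pr.empty()) return;
      int pick = pr[(int)std::floor(unif_rand() * pr.size()) % pr.size()];
      int var, mleft; double cut;
      if (!draw_rule(var, cut, mleft)) return;
      Tree prop = tr;
      prop[pick].var = var; prop[pick].cut = cut; prop[pick].miss_left = mleft;
      std::vector<int> leaf_new(leaf_of);
      int nl = 0, nr = 0;
      for (int i = 0; i < n; ++i) {
        if (leaf_of[i] != tr[pick].left && leaf_of[i] != tr[pick].right)
          continue;
        int nd = drop_subtree(prop, pick, i);
        leaf_new[i] = nd;
        if (nd == prop[pick].left) nl++; else nr++;
      }
      if (!prior_only && (nl < 1 || nr < 1)) return;
      double ll_new = loglik(prop, leaf_new, resid);
      // same singly-internal count, uniform rules: symmetric proposal
      if (std::log(unif_rand()) < ll_new - ll_old) {
        tr.swap(prop); leaf_of.swap(leaf_new);
      }
    }
  }

  // Gibbs draw of leaf values given residuals; fills fit vector.
  void draw_leaves(Tree& tr, const std::vector<int>& leaf_of,
                   const std::vector<double>& resid,
                   std::vector<double>& fit) {
    std::vector<double> S(tr.size(), 0.0);
    std::vector<int> cnt(tr.size(), 0);
    for (int i = 0; i < n; ++i) { S[leaf_of[i]] += resid[i]; cnt[leaf_of[i]]++; }
    for (size_t nd = 0; nd < tr.size(); ++nd) {
      if (tr[nd].var >= 0) continue;
      if (prior_only) { tr[nd].mu = norm_rand() * std::sqrt(s2); continue; }
      double denom = sigma2 + cnt[nd] * s2;
      double mean = s2 * S[nd] / denom;
      double sd = std::sqrt(sigma2 * s2 / denom);
      tr[nd].mu = mean + sd * norm_rand();
    }
    fit.resize(n);
    for (int i = 0; i < n; ++i) fit[i] = tr[leaf_of[i]].mu;
  }
};

// Rebuild a tree with only reachable nodes, preorder.
static void compact_rec(const Tree& tr, int nd, Tree& out) {
  int me = out.size();
  out.push_back(tr[nd]);
  if (tr[nd].var >= 0) {
    out[me].left = out.size();
    compact_rec(tr, tr[nd].left, out);
    out[me].right = out.size();
    compact_rec(tr, tr[nd].right, out);
  }
}
static Tree compact(const Tree& tr) {
  Tree out; out.reserve(tr.size());
  compact_rec(tr, 0, out);
  return out;
}

// [[Rcpp::export]]
List fit_bart_cpp(NumericMatrix X, NumericVector ys, List cutpoints,
                  int m, double sigma_mu, double nu, double lambda,
                  double alpha, double beta, int n_burn, int n_draw,
                  bool use_missing, bool prior_only, double sigma_init) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<double> > cuts(p);
  for (int j = 0; j < p; ++j) {
    NumericVector cv = cutpoints[j];
    cuts[j] = std::vector<double>(cv.begin(), cv.end());
  }
  std::vector<double> y(ys.begin(), ys.end());
  Sampler smp(X, y, cuts, alpha, beta, use_missing, prior_only);
  smp.s2 = sigma_mu * sigma_mu;
  smp.sigma2 = sigma_init * sigma_init;

  std::vector<Tree> forest(m);
  std::vector<std::vector<int> > leaf_of(m);
  std::vector<std::vector<double> > fits(m, std::vector<double>(n, 0.0));
  Node stump; stump.var = -1; stump.cut = 0; stump.miss_left = 0;
  stump.left = stump.right = -1; stump.mu = 0.0;
  for (int j = 0; j < m; ++j) {
    forest[j] = Tree(1, stump);
    smp.assign(forest[j], leaf_of[j]);
  }
  std::vector<double> total(n, 0.0), resid(n);

  int total_iter = n_burn + n_draw;
  List draws(n_draw);
  NumericVector sig_out(n_draw);

  for (int it = 0; it < total_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i) resid[i] = y[i] - (total[i] - fits[j][i]);
      smp.mh_move(forest[j], leaf_of[j], resid);
      forest[j] = compact(forest[j]);
      smp.assign(forest[j], leaf_of[j]);
      std::vector<double> newfit;
      smp.draw_leaves(forest[j], leaf_of[j], resid, newfit);
      for (int i = 0; i < n; ++i) total[i] += newfit[i] - fits[j][i];
      fits[j].swap(newfit);
    }
    if (!prior_only) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = y[i] - total[i]; ss += r * r;
      }
      double chi = R::rchisq(nu + n);
      smp.sigma2 = (nu * lambda + ss) / chi;
      if (smp.sigma2 < 1e-18) smp.sigma2 = 1e-18;
    }
    if (it >= n_burn) {
      int nodes_total = 0;
      for (int j = 0; j < m; ++j) nodes_total += forest[j].size();
      NumericMatrix snap(nodes_total, 7);
      int r = 0;
      for (int j = 0; j < m; ++j) {
        for (size_t nd = 0; nd < forest[j].size(); ++nd) {
          const Node& q = forest[j][nd];
          snap(r, 0) = j; snap(r, 1) = q.var; snap(r, 2) = q.cut;
          snap(r, 3) = q.miss_left; snap(r, 4) = q.left; snap(r, 5) = q.right;
          snap(r, 6) = q.mu;
          ++r;
        }
      }
      draws[it - n_burn] = snap;
      sig_out[it - n_burn] = std::sqrt(smp.sigma2);
    }
  }
  return List::create(_["draws"] = draws, _["sigma"] = sig_out);
}

// Predict from a stored forest snapshot for one draw.
static void predict_snap(const NumericMatrix& snap, const NumericMatrix& X,
                         std::vector<double>& out) {
  int n = X.nrow();
  std::fill(out.begin(), out.end(), 0.0);
  int nr = snap.nrow();
  int start = 0;
  while (start < nr) {
    int tree_id = (int)snap(start, 0);
    int end = start;
    while (end < nr && (int)snap(end, 0) == tree_id) ++end;
    for (int i = 0; i < n; ++i) {
      int nd = 0; // root is first row of the tree block
      for (;;) {
        int row = start + nd;
        int var = (int)snap(row, 1);
        if (var < 0) { out[i] += snap(row, 6); break; }
        double x = X(i, var);
        bool left;
        if (NumericVector::is_na(x)) left = snap(row, 3) != 0;
        else left = x < snap(row, 2);
        nd = left ? (int)snap(row, 4) : (int)snap(row, 5);
      }
    }
    start = end;
  }
}

// [[Rcpp::export]]
NumericMatrix predict_bart_cpp(List draws, NumericMatrix X, bool per_draw) {
  int nd = draws.size(), n = X.nrow();
  std::vector<double> buf(n);
  if (per_draw) {
    NumericMatrix out(nd, n);
    for (int d = 0; d < nd; ++d) {
      NumericMatrix snap = draws[d];
      predict_snap(snap, X, buf);
      for (int i = 0; i < n; ++i) out(d, i) = buf[i];
    }
    return out;
  }
  NumericMatrix out(1, n);
  std::vector<double> acc(n, 0.0);
  for (int d = 0; d < nd; ++d) {
    NumericMatrix snap = draws[d];
    predict_snap(snap, X, buf);
    for (int i = 0; i < n; ++i) acc[i] += buf[i];
  }
  for (int i = 0; i < n; ++i) out(0, i) = acc[i] / nd;
  return out;
}

// Number of leaves per tree per draw (diagnostics; also used to check the
// tree prior in prior-only runs).
// [[Rcpp::export]]
IntegerMatrix forest_leaf_counts_cpp(List draws) {
  int nd = draws.size();
  if (nd == 0) return IntegerMatrix(0, 0);
  NumericMatrix first = draws[0];
  int m = (int)first(first.nrow() - 1, 0) + 1;
  IntegerMatrix out(nd, m);
  for (int d = 0; d < nd; ++d) {
    NumericMatrix snap = draws[d];
    for (int r = 0; r < snap.nrow(); ++r) {
      if ((int)snap(r, 1) < 0) out(d, (int)snap(r, 0))++;
    }
  }
  return out;
}
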