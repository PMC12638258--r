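// Histogram-based gradient-boosted decision trees for binary outcomes
// (logistic loss), with per-feature total-gain importance and exact
// path (Saabas) attribution. Deterministic: no internal randomness.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct TreeNode {
  int feature;    // -1 for leaf
  int split_bin;  // go left if bin <= split_bin
  int left, right;
  double value;   // node output (shrunk); internal nodes carry it for attribution
};

struct BuildCtx {
  const IntegerMatrix &Xb;
  const std::vector<double> &g, &h;
  int n_bins, max_depth, min_leaf;
  double lambda, lr, min_gain;
  std::vector<TreeNode> nodes;
  std::vector<double> importance;  // per-feature gain
};

static double leaf_value(double G, double H, double lambda, double lr) {
  return -lr * G / (H + lambda);
}

static int build_node(BuildCtx &ctx, std::vector<int> &idx, int depth) {
  const int p = ctx.Xb.ncol();
  double G = 0.0, H = 0.0;
  for (int i : idx) { G += ctx.g[i]; H += ctx.h[i]; }
  TreeNode node;
  node.feature = -1; node.split_bin = -1; node.left = node.right = -1;
  node.value = leaf_value(G, H, ctx.lambda, ctx.lr);
  int me = (int)ctx.nodes.size();
  ctx.nodes.push_back(node);
  if (depth >= ctx.max_depth || (int)idx.size() < 2 * ctx.min_leaf) return me;

  double parent_score = G * G / (H + ctx.lambda);
  double best_gain = ctx.min_gain;
  int best_f = -1, best_b = -1;
  std::vector<double> hg(ctx.n_bins), hh(ctx.n_bins);
  std::vector<int> hc(ctx.n_bins);
  for (int f = 0; f < p; ++f) {
    std::fill(hg.begin(), hg.end(), 0.0);
    std::fill(hh.begin(), hh.end(), 0.0);
    std::fill(hc.begin(), hc.end(), 0);
    for (int i : idx) {
      int b = ctx.Xb(i, f);
      if (b < 0) b = 0; else if (b >= ctx.n_bins) b = ctx.n_bins - 1;
      hg[b] += ctx.g[i]; hh[b] += ctx.h[i]; hc[b] += 1;
    }
    double GL = 0.0, HL = 0.0; int CL = 0;
    for (int b = 0; b < ctx.n_bins - 1; ++b) {
      GL += hg[b]; HL += hh[b]; CL += hc[b];
      if (CL < ctx.min_leaf) continue;
      int CR = (int)idx.size() - CL;
      if (CR < ctx.min_leaf) break;
      double GR = G - GL, HR = H - HL;
      double gain = GL * GL / (HL + ctx.lambda) + GR * GR / (HR + ctx.lambda)
                    - parent_score;
      if (gain > best_gain) { best_gain = gain; best_f = f; best_b = b; }
    }
  }
  if (best_f < 0) return me;

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(idx.size()); right_idx.reserve(idx.size());
  for (int i : idx)
    (ctx.Xb(i, best_f) <= best_b ? left_idx : right_idx).push_back(i);
  ctx.importance[best_f] += best_gain;
  ctx.nodes[me].feature = best_f;
  ctx.nodes[me].split_bin = best_b;
  int l = build_node(ctx, left_idx, depth + 1);
  int r = build_node(ctx, right_idx, depth + 1);
  ctx.nodes[me].left = l;
  ctx.nodes[me].right = r;
  return me;
}

// [[Rcpp::export]]
List gbt_fit_cpp(IntegerMatrix Xb, NumericVector y, int n_bins, int n_trees,
                 double learning_rate, int max_depth, int min_leaf,
                 double lambda, double min_gain) {
  const int n = Xb.nrow(), p = Xb.ncol();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-12), 1.0 - 1e-12);
  double init = std::log(ybar / (1.0 - ybar));

  std::vector<double> margin(n, init), g(n), h(n);
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-12);
    }
    BuildCtx ctx{Xb, g, h, n_bins, max_depth, min_leaf, lambda,
                 learning_rate, min_gain, {}, importance};
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    build_node(ctx, all, 0);
    importance = ctx.importance;
    int m = (int)ctx.nodes.size();
    IntegerVector feat(m), sb(m), le(m), ri(m);
    NumericVector val(m);
    for (int k = 0; k < m; ++k) {
      feat[k] = ctx.nodes[k].feature; sb[k] = ctx.nodes[k].split_bin;
      le[k] = ctx.nodes[k].left; ri[k] = ctx.nodes[k].right;
      val[k] = ctx.nodes[k].value;
    }
    trees[t] = List::create(_["feature"] = feat, _["split_bin"] = sb,
                            _["left"] = le, _["right"] = ri, _["value"] = val);
    // update margins
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (Xb(i, feat[node]) <= sb[node]) ? le[node] : ri[node];
      margin[i] += val[node];
    }
  }
  return List::create(_["trees"] = trees, _["init"] = init,
                      _["importance"] = NumericVector(importance.begin(), importance.end()));
}

// [[Rcpp::export]]
NumericVector gbt_margin_cpp(List model, IntegerMatrix Xb) {
  const int n = Xb.nrow();
  double init = as<double>(model["init"]);
  List trees = model["trees"];
  NumericVector out(n, init);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], sb = tr["split_bin"],
                  le = tr["left"], ri = tr["right"];
    NumericVector val = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (Xb(i, feat[node]) <= sb[node]) ? le[node] : ri[node];
      out[i] += val[node];
    }
  }
  return out;
}

// Per-prediction additive path attribution: along each decision path the
// change in node value attributes to the split feature; contributions
// plus the bias column sum exactly to the raw margin.
// [[Rcpp::export]]
NumericMatrix gbt_contrib_cpp(List model, IntegerMatrix Xb) {
  const int n = Xb.nrow(), p = Xb.ncol();
  double init = as<double>(model["init"]);
  List trees = model["trees"];
  NumericMatrix out(n, p + 1);  // last column = bias
  for (int i = 0; i < n; ++i) out(i, p) = init;
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], sb = tr["split_bin"],
                  le = tr["left"], ri = tr["right"];
    NumericVector val = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      out(i, p) += val[0];
      while (feat[node] >= 0) {
        int child = (Xb(i, feat[node]) <= sb[node]) ? le[node] : ri[node];
        out(i, feat[node]) += val[child] - val[node];
        node = child;
      }
    }
  }
  return out;
}

// Greedy 1-nearest-neighbour matching without replacement on a sorted
// pool of propensity scores, via a doubly linked availability list.
// case_scores come pre-ordered (randomized order is the caller's job);
// pool_scores must be ascending. Returns ratio rows per case of 1-based
// pool indices (0 => unfilled slot).
// [[Rcpp::export]]
IntegerMatrix nn_match_cpp(NumericVector case_scores, NumericVector pool_scores,
                           int ratio) {
  const int nc = case_scores.size(), np = pool_scores.size();
  std::vector<int> nxt(np + 2), prv(np + 2);
  // sentinel 0 = head, np+1 = tail; nodes 1..np
  for (int i = 0; i <= np + 1; ++i) { nxt[i] = i + 1; prv[i] = i - 1; }
  nxt[np + 1] = -1;
  IntegerMatrix out(nc, ratio);
  for (int c = 0; c < nc; ++c) {
    double sc = case_scores[c];
    // binary search for insertion point over original indices
    int lo = 1, hi = np;
    int pos = np + 1;  // first index with score >= sc
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (pool_scores[mid - 1] >= sc) { pos = mid; hi = mid - 1; }
      else lo = mid + 1;
    }
    for (int r = 0; r < ratio; ++r) {
      // nearest available node on each side of the insertion point:
      // a node i is still linked iff nxt[prv[i]] == i
      int ra = pos;
      while (ra <= np && nxt[prv[ra]] != ra) ++ra;  // ra available iff linked
      int la = pos - 1;
      while (la >= 1 && nxt[prv[la]] != la) --la;
      int pick = -1;
      if (ra > np && la < 1) break;          // pool exhausted
      else if (ra > np) pick = la;
      else if (la < 1) pick = ra;
      else pick = (sc - pool_scores[la - 1] <= pool_scores[ra - 1] - sc) ? la : ra;
      out(c, r) = pick;
      // unlink
      nxt[prv[pick]] = nxt[pick];
      prv[nxt[pick]] = prv[pick];
    }
  }
  return out;
}
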