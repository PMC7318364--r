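// Gradient boosted regression trees with surrogate-split handling of
// missing covariate values, used as the nonparametric propensity score
// estimator.  Trees are least-squares CART grown breadth-first to a fixed
// interaction depth; terminal values are mean residuals.  Missingness on a
// primary split variable is routed by the best surviving surrogate split,
// else by the majority direction.  The boosting loop tracks the average
// absolute standardized mean difference (AASM) per iteration and snapshots
// the fitted probabilities at the running minimizer.
//
// The builder is level-wise: split search, surrogate search and routing
// each make one pass over the presorted per-variable row order per depth
// level, dispatching rows to their current leaf, so a tree costs
// O(p * n * depth) regardless of the number of nodes.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double EPS_TIE = 1e-12;  // value-gap tolerance for candidate splits
static const double EPS_GAIN = 1e-12; // strict improvement margin on SSE gain

struct Surrogate {
  int var;
  double split;  // x < split goes left under normal orientation
  bool reversed; // true: x < split goes right
  double agree;  // fraction agreement with the primary partition
};

struct Node {
  int var = -1; // -1 = terminal
  double split = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
  bool maj_left = true;
  std::vector<Surrogate> surr;
};

static bool value_gap(double prev, double x) {
  return x - prev > EPS_TIE * (1.0 + std::fabs(prev));
}

struct TreeBuilder {
  int n, p;
  std::vector<const double*> Xcol;
  const std::vector<std::vector<int>>& order; // per-var observed rows, ascending x
  const double* r;
  int max_splits, min_node, max_surrogates;

  std::vector<Node> nodes;
  std::vector<int> leaf;    // row -> current node id
  std::vector<int> slot_of; // node id -> active slot, -1 if inactive

  // per-slot scratch for the scanning passes
  std::vector<int> cnt, nL, nLp, nRp, cnt2, leftP, agree_run;
  std::vector<double> sum, SL, prev_x, prev2;
  std::vector<char> has_prev, has_prev2, need_surr;
  std::vector<int> best_var;
  std::vector<double> best_gain, best_split;
  std::vector<std::vector<Surrogate>> cand;

  // per-node candidate split (filled by evaluate, consumed best-first)
  std::vector<int> cand_var, node_n;
  std::vector<double> cand_gain, cand_split;

  TreeBuilder(const NumericMatrix& X,
              const std::vector<std::vector<int>>& order_,
              const double* r_, int max_splits_, int min_node_,
              int max_surrogates_)
    : n(X.nrow()), p(X.ncol()), Xcol(p), order(order_), r(r_),
      max_splits(max_splits_), min_node(min_node_),
      max_surrogates(max_surrogates_), leaf(n, 0) {
    for (int j = 0; j < p; ++j) Xcol[j] = &X(0, j);
  }

  void resize_slots(int k) {
    cnt.resize(k); nL.resize(k); nLp.resize(k);
    nRp.resize(k); cnt2.resize(k); leftP.resize(k); agree_run.resize(k);
    sum.resize(k); SL.resize(k); prev_x.resize(k); prev2.resize(k);
    has_prev.resize(k); has_prev2.resize(k); need_surr.resize(k);
    best_var.resize(k); best_gain.resize(k); best_split.resize(k);
    cand.resize(k);
  }

  // exhaustive best split per node in `ids`: one counting and one scanning
  // pass per variable over the presorted row order
  void evaluate(const std::vector<int>& ids) {
    int k = (int)ids.size();
    if (k == 0) return;
    resize_slots(k);
    slot_of.assign(nodes.size(), -1);
    for (int s = 0; s < k; ++s) slot_of[ids[s]] = s;
    for (int s = 0; s < k; ++s) { best_var[s] = -1; best_gain[s] = 0.0; }
    for (int j = 0; j < p; ++j) {
      const double* xj = Xcol[j];
      std::fill(cnt.begin(), cnt.end(), 0);
      std::fill(sum.begin(), sum.end(), 0.0);
      for (int row : order[j]) {
        int s = slot_of[leaf[row]];
        if (s >= 0) { ++cnt[s]; sum[s] += r[row]; }
      }
      std::fill(nL.begin(), nL.end(), 0);
      std::fill(SL.begin(), SL.end(), 0.0);
      std::fill(has_prev.begin(), has_prev.end(), 0);
      for (int row : order[j]) {
        int s = slot_of[leaf[row]];
        if (s < 0) continue;
        double x = xj[row];
        if (has_prev[s] && value_gap(prev_x[s], x)) {
          int nLs = nL[s], nRs = cnt[s] - nLs;
          if (nLs >= min_node && nRs >= min_node) {
            double SLs = SL[s], SRs = sum[s] - SLs;
            double gain = SLs * SLs / nLs + SRs * SRs / nRs
                          - sum[s] * sum[s] / cnt[s];
            if (gain > best_gain[s] + EPS_GAIN) {
              best_gain[s] = gain;
              best_var[s] = j;
              best_split[s] = 0.5 * (prev_x[s] + x);
            }
          }
        }
        ++nL[s]; SL[s] += r[row]; prev_x[s] = x; has_prev[s] = 1;
      }
    }
    for (int s = 0; s < k; ++s) {
      cand_var[ids[s]] = best_var[s];
      cand_gain[ids[s]] = best_gain[s];
      cand_split[ids[s]] = best_split[s];
    }
  }

  // apply the stored candidate split of node `id`: surrogate search over
  // the other variables, child creation, and routing of the node's rows
  void apply_split(int id) {
    resize_slots(1);
    slot_of.assign(nodes.size(), -1);
    slot_of[id] = 0;
    best_var[0] = cand_var[id];
    best_split[0] = cand_split[id];

    // primary side counts and missing-row detection
    nLp[0] = nRp[0] = 0;
    need_surr[0] = 0;
    cand[0].clear();
    for (int i = 0; i < n; ++i) {
      if (leaf[i] != id) continue;
      double x = Xcol[best_var[0]][i];
      if (ISNAN(x)) need_surr[0] = 1;
      else if (x < best_split[0]) ++nLp[0];
      else ++nRp[0];
    }

    // surrogate search: for every other variable, the split (either
    // orientation) maximizing agreement with the primary partition over
    // rows observed on both; keep those beating the majority rule
    if (need_surr[0]) {
      for (int j = 0; j < p; ++j) {
        if (j == best_var[0]) continue;
        const double* xj = Xcol[j];
        cnt2[0] = leftP[0] = 0;
        for (int row : order[j]) {
          if (slot_of[leaf[row]] < 0) continue;
          double xp = Xcol[best_var[0]][row];
          if (ISNAN(xp)) continue;
          ++cnt2[0];
          if (xp < best_split[0]) ++leftP[0];
        }
        if (cnt2[0] == 0) continue;
        int b_agree = -1;
        double b_split = 0.0;
        bool b_rev = false;
        agree_run[0] = cnt2[0] - leftP[0];
        has_prev2[0] = 0;
        for (int row : order[j]) {
          if (slot_of[leaf[row]] < 0) continue;
          double xp = Xcol[best_var[0]][row];
          if (ISNAN(xp)) continue;
          double x = xj[row];
          if (has_prev2[0] && value_gap(prev2[0], x)) {
            int a_norm = agree_run[0], a_rev = cnt2[0] - a_norm;
            if (a_norm > b_agree) {
              b_agree = a_norm; b_split = 0.5 * (prev2[0] + x); b_rev = false;
            }
            if (a_rev > b_agree) {
              b_agree = a_rev; b_split = 0.5 * (prev2[0] + x); b_rev = true;
            }
          }
          agree_run[0] += (xp < best_split[0]) ? 1 : -1;
          prev2[0] = x; has_prev2[0] = 1;
        }
        if (b_agree < 0) continue;
        double maj = (double)std::max(nLp[0], nRp[0]) / (nLp[0] + nRp[0]);
        double frac = (double)b_agree / cnt2[0];
        if (frac > maj) {
          Surrogate su; su.var = j; su.split = b_split;
          su.reversed = b_rev; su.agree = frac;
          cand[0].push_back(su);
        }
      }
      std::stable_sort(cand[0].begin(), cand[0].end(),
                       [](const Surrogate& a, const Surrogate& b) {
                         return a.agree > b.agree;
                       });
      if ((int)cand[0].size() > max_surrogates) cand[0].resize(max_surrogates);
    }

    int l = (int)nodes.size();
    nodes.push_back(Node());
    nodes.push_back(Node());
    nodes[id].var = best_var[0];
    nodes[id].split = best_split[0];
    nodes[id].maj_left = nLp[0] >= nRp[0];
    nodes[id].surr = cand[0];
    nodes[id].left = l;
    nodes[id].right = l + 1;
    cand_var.resize(nodes.size(), -1);
    cand_gain.resize(nodes.size(), 0.0);
    cand_split.resize(nodes.size(), 0.0);
    node_n.resize(nodes.size(), 0);

    double SLc = 0.0, SRc = 0.0;
    int nLc = 0, nRc = 0;
    const Node& nd = nodes[id];
    for (int i = 0; i < n; ++i) {
      if (leaf[i] != id) continue;
      double x = Xcol[nd.var][i];
      bool go_left;
      if (!ISNAN(x)) {
        go_left = x < nd.split;
      } else {
        go_left = nd.maj_left;
        for (const Surrogate& su : nd.surr) {
          double xv = Xcol[su.var][i];
          if (ISNAN(xv)) continue;
          go_left = (xv < su.split) != su.reversed;
          break;
        }
      }
      if (go_left) { leaf[i] = nd.left; SLc += r[i]; ++nLc; }
      else { leaf[i] = nd.right; SRc += r[i]; ++nRc; }
    }
    nodes[nd.left].value = nLc > 0 ? SLc / nLc : nodes[id].value;
    nodes[nd.right].value = nRc > 0 ? SRc / nRc : nodes[id].value;
    node_n[nd.left] = nLc;
    node_n[nd.right] = nRc;
  }

  // best-first growth: repeatedly split the terminal node whose best
  // split yields the largest SSE reduction, up to `max_splits` splits
  // (the interaction depth)
  void build() {
    nodes.clear();
    nodes.push_back(Node());
    std::fill(leaf.begin(), leaf.end(), 0);
    double S = 0.0;
    for (int i = 0; i < n; ++i) S += r[i];
    nodes[0].value = n > 0 ? S / n : 0.0;
    cand_var.assign(1, -1);
    cand_gain.assign(1, 0.0);
    cand_split.assign(1, 0.0);
    node_n.assign(1, n);
    if (n >= 2 * min_node) evaluate({0});

    for (int done = 0; done < max_splits; ++done) {
      int best_id = -1;
      double bg = 0.0;
      for (int id = 0; id < (int)nodes.size(); ++id) {
        if (nodes[id].var >= 0 || cand_var[id] < 0) continue;
        if (cand_gain[id] > bg + EPS_GAIN) { bg = cand_gain[id]; best_id = id; }
      }
      if (best_id < 0) break;
      apply_split(best_id);
      std::vector<int> kids;
      for (int c : {nodes[best_id].left, nodes[best_id].right})
        if (node_n[c] >= 2 * min_node) kids.push_back(c);
      evaluate(kids);
    }
  }
};

static List serialize_tree(const std::vector<Node>& nodes) {
  int m = (int)nodes.size();
  IntegerVector var(m), left(m), right(m);
  NumericVector split(m), value(m);
  LogicalVector maj_left(m);
  List surr(m);
  for (int i = 0; i < m; ++i) {
    const Node& nd = nodes[i];
    var[i] = nd.var < 0 ? NA_INTEGER : nd.var + 1; // 1-based for R
    split[i] = nd.split;
    left[i] = nd.left + 1;   // 0 = none
    right[i] = nd.right + 1;
    value[i] = nd.value;
    maj_left[i] = nd.maj_left;
    int ns = (int)nd.surr.size();
    NumericMatrix sm(ns, 4);
    for (int kk = 0; kk < ns; ++kk) {
      sm(kk, 0) = nd.surr[kk].var + 1;
      sm(kk, 1) = nd.surr[kk].split;
      sm(kk, 2) = nd.surr[kk].reversed ? 1.0 : 0.0;
      sm(kk, 3) = nd.surr[kk].agree;
    }
    surr[i] = sm;
  }
  return List::create(_["var"] = var, _["split"] = split, _["left"] = left,
                      _["right"] = right, _["value"] = value,
                      _["maj_left"] = maj_left, _["surrogates"] = surr);
}

static std::vector<std::vector<int>> presort(const NumericMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int>> order(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) if (!ISNAN(xj[i])) idx.push_back(i);
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return xj[a] < xj[b]; });
    order[j] = idx;
  }
  return order;
}

static double predict_row(const std::vector<Node>& nodes,
                          const NumericMatrix& X, int i) {
  int cur = 0;
  while (nodes[cur].var >= 0) {
    const Node& nd = nodes[cur];
    double x = X(i, nd.var);
    bool go_left;
    if (!ISNAN(x)) {
      go_left = x < nd.split;
    } else {
      go_left = nd.maj_left;
      for (const Surrogate& s : nd.surr) {
        double xv = X(i, s.var);
        if (ISNAN(xv)) continue;
        go_left = (xv < s.split) != s.reversed;
        break;
      }
    }
    cur = go_left ? nd.left : nd.right;
  }
  return nodes[cur].value;
}

static std::vector<Node> unserialize_tree(const List& tr) {
  IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
  NumericVector split = tr["split"], value = tr["value"];
  LogicalVector maj_left = tr["maj_left"];
  List surr = tr["surrogates"];
  int m = var.size();
  std::vector<Node> nodes(m);
  for (int i = 0; i < m; ++i) {
    nodes[i].var = var[i] == NA_INTEGER ? -1 : var[i] - 1;
    nodes[i].split = split[i];
    nodes[i].left = left[i] - 1;
    nodes[i].right = right[i] - 1;
    nodes[i].value = value[i];
    nodes[i].maj_left = maj_left[i];
    NumericMatrix sm = surr[i];
    for (int kk = 0; kk < sm.nrow(); ++kk) {
      Surrogate s;
      s.var = (int)sm(kk, 0) - 1;
      s.split = sm(kk, 1);
      s.reversed = sm(kk, 2) != 0.0;
      s.agree = sm(kk, 3);
      nodes[i].surr.push_back(s);
    }
  }
  return nodes;
}

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector r, int n_splits,
                  int min_node, int max_surrogates) {
  auto order = presort(X);
  TreeBuilder tb(X, order, r.begin(), n_splits, min_node, max_surrogates);
  tb.build();
  List tree = serialize_tree(tb.nodes);
  NumericVector fitted(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) fitted[i] = tb.nodes[tb.leaf[i]].value;
  tree.attr("fitted") = fitted;
  return tree;
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  std::vector<Node> nodes = unserialize_tree(tree);
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = predict_row(nodes, X, i);
  return out;
}

// AASM given fitted exposure probabilities: exposed-group means/SDs and
// odds-weighted unexposed means over pairwise-complete cells; columns with
// zero exposed SD are skipped.
struct AasmState {
  std::vector<std::vector<int>> unexp; // per column, unexposed observed rows
  std::vector<double> m1, s1;
  int p = 0, n_usable = 0;
};

static AasmState aasm_prepare(const NumericMatrix& X, const IntegerVector& T) {
  AasmState st;
  int n = X.nrow();
  st.p = X.ncol();
  st.unexp.resize(st.p);
  st.m1.assign(st.p, 0.0);
  st.s1.assign(st.p, 0.0);
  for (int j = 0; j < st.p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (ISNAN(xj[i])) continue;
      if (T[i] == 1) { s += xj[i]; ++cnt; }
      else st.unexp[j].push_back(i);
    }
    if (cnt == 0) continue;
    st.m1[j] = s / cnt;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      if (T[i] == 1 && !ISNAN(xj[i])) {
        double d = xj[i] - st.m1[j];
        ss += d * d;
      }
    }
    st.s1[j] = cnt > 1 ? std::sqrt(ss / (cnt - 1)) : 0.0;
    if (st.s1[j] > 0.0) ++st.n_usable;
  }
  return st;
}

static double aasm_eval(const AasmState& st, const NumericMatrix& X,
                        const std::vector<double>& ps) {
  double tot = 0.0;
  int used = 0;
  for (int j = 0; j < st.p; ++j) {
    if (st.s1[j] <= 0.0) continue;
    const double* xj = &X(0, j);
    double wsum = 0.0, wx = 0.0;
    for (int i : st.unexp[j]) {
      double w = ps[i] / (1.0 - ps[i]);
      wsum += w;
      wx += w * xj[i];
    }
    if (wsum <= 0.0) continue;
    tot += std::fabs(st.m1[j] - wx / wsum) / st.s1[j];
    ++used;
  }
  return used > 0 ? tot / used : NA_REAL;
}

// Replace each tree's node values by the one-step Newton estimate for the
// Bernoulli likelihood, sum(r) / sum(p (1 - p)) over the node's rows.
static void newton_terminals(TreeBuilder& tb, const std::vector<double>& ps,
                             const double* r) {
  int n = tb.n;
  std::vector<double> num(tb.nodes.size(), 0.0), den(tb.nodes.size(), 0.0);
  for (int i = 0; i < n; ++i) {
    int id = tb.leaf[i];
    num[id] += r[i];
    den[id] += ps[i] * (1.0 - ps[i]);
  }
  for (size_t id = 0; id < tb.nodes.size(); ++id) {
    if (tb.nodes[id].var >= 0) continue;
    tb.nodes[id].value = den[id] > 1e-12 ? num[id] / den[id] : 0.0;
  }
}

// [[Rcpp::export(name = ".boost_cpp")]]
List boost_cpp(NumericMatrix X, IntegerVector T, double shrinkage,
               int n_splits, int n_trees, int min_node, int max_surrogates,
               bool keep_trees, bool newton) {
  int n = X.nrow();
  double p0 = 0.0;
  for (int i = 0; i < n; ++i) p0 += T[i];
  p0 /= n;
  double g0 = std::log(p0 / (1.0 - p0));

  AasmState st = aasm_prepare(X, T);
  auto order = presort(X);
  std::vector<double> g(n, g0), ps(n, p0), best_ps(n, p0), r(n);
  NumericVector aasm(n_trees + 1);
  aasm[0] = aasm_eval(st, X, ps);
  double best = aasm[0];
  int best_iter = 0;

  TreeBuilder tb(X, order, r.data(), n_splits, min_node, max_surrogates);
  List trees(keep_trees ? n_trees : 0);
  for (int m = 1; m <= n_trees; ++m) {
    for (int i = 0; i < n; ++i) r[i] = T[i] - ps[i];
    tb.build();
    if (newton) newton_terminals(tb, ps, r.data());
    for (int i = 0; i < n; ++i) {
      g[i] += shrinkage * tb.nodes[tb.leaf[i]].value;
      ps[i] = 1.0 / (1.0 + std::exp(-g[i]));
    }
    aasm[m] = aasm_eval(st, X, ps);
    if (aasm[m] < best) {
      best = aasm[m];
      best_iter = m;
      best_ps = ps;
    }
    if (keep_trees) trees[m - 1] = serialize_tree(tb.nodes);
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["g0"] = g0, _["shrinkage"] = shrinkage,
                      _["aasm"] = aasm, _["best_iter"] = best_iter,
                      _["ps_best"] = NumericVector(best_ps.begin(), best_ps.end()),
                      _["trees"] = trees);
}

// [[Rcpp::export(name = ".predict_boost_cpp")]]
NumericVector predict_boost_cpp(List trees, double g0, double shrinkage,
                                int n_iter, NumericMatrix X) {
  int n = X.nrow();
  std::vector<double> g(n, g0);
  for (int m = 0; m < n_iter; ++m) {
    std::vector<Node> nodes = unserialize_tree(trees[m]);
    for (int i = 0; i < n; ++i) g[i] += shrinkage * predict_row(nodes, X, i);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-g[i]));
  return out;
}
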