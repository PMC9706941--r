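// Random survival forest: bootstrap-grown binary trees with log-rank
// split selection and Nelson-Aalen cumulative-hazard estimates in the
// terminal nodes.  Uses R's RNG so forests are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct TreeBuild {
  std::vector<int> split_var;             // 0-based covariate; -1 terminal
  std::vector<double> split_val;          // go left if x <= val
  std::vector<int> left_child, right_child;
  std::vector<int> leaf_id;               // -1 internal
  std::vector< std::vector<double> > leaf_times;
  std::vector< std::vector<double> > leaf_chf;
};

// Log-rank statistic for the split {x <= v} vs {x > v} within a node whose
// member indices are sorted by time ascending.  Returns -1 if the variance
// vanishes or a child would hold fewer than min_ev events.
double split_logrank(const std::vector<int> &mem,
                     const NumericVector &time, const IntegerVector &status,
                     const NumericMatrix &X, int var, double v, int min_ev) {
  const int m = (int)mem.size();
  int n1 = 0, ev1 = 0, ev_tot = 0;
  for (int i = 0; i < m; ++i) {
    bool g1 = X(mem[i], var) <= v;
    if (g1) ++n1;
    if (status[mem[i]] == 1) { ++ev_tot; if (g1) ++ev1; }
  }
  if (ev1 < min_ev || (ev_tot - ev1) < min_ev) return -1.0;
  if (n1 == 0 || n1 == m) return -1.0;

  double OE = 0.0, V = 0.0;
  int i = 0, risk1 = n1;
  while (i < m) {
    int j = i;
    int d = 0, d1 = 0;
    double t = time[mem[i]];
    while (j < m && time[mem[j]] == t) {
      bool g1 = X(mem[j], var) <= v;
      if (status[mem[j]] == 1) { ++d; if (g1) ++d1; }
      ++j;
    }
    int nrisk = m - i;
    if (d > 0) {
      double p1 = (double)risk1 / nrisk;
      OE += d1 - d * p1;
      if (nrisk > 1)
        V += (double)d * (nrisk - d) / (nrisk - 1) * p1 * (1.0 - p1);
    }
    for (int k = i; k < j; ++k)
      if (X(mem[k], var) <= v) --risk1;
    i = j;
  }
  if (V <= 0.0) return -1.0;
  return OE * OE / V;
}

// Nelson-Aalen estimate from the node members (sorted by time ascending).
void leaf_nelson_aalen(const std::vector<int> &mem,
                       const NumericVector &time, const IntegerVector &status,
                       std::vector<double> &out_t, std::vector<double> &out_h) {
  const int m = (int)mem.size();
  double H = 0.0;
  int i = 0;
  while (i < m) {
    int j = i, d = 0;
    double t = time[mem[i]];
    while (j < m && time[mem[j]] == t) {
      if (status[mem[j]] == 1) ++d;
      ++j;
    }
    if (d > 0) {
      H += (double)d / (m - i);
      out_t.push_back(t);
      out_h.push_back(H);
    }
    i = j;
  }
}

void grow_node(TreeBuild &tree, std::vector<int> mem,
               const NumericVector &time, const IntegerVector &status,
               const NumericMatrix &X, int mtry, int min_ev, int node) {
  const int p = X.ncol();
  int ev_tot = 0;
  for (size_t i = 0; i < mem.size(); ++i)
    if (status[mem[i]] == 1) ++ev_tot;

  int best_var = -1;
  double best_val = 0.0, best_stat = 0.0;

  if (ev_tot >= 2 * min_ev && mem.size() >= 2) {
    // draw mtry covariates without replacement (seeded order -> the
    // first-encountered best split is the deterministic tie-break)
    std::vector<int> vars(p);
    for (int v = 0; v < p; ++v) vars[v] = v;
    for (int v = 0; v < p - 1; ++v) {
      int w = v + (int)(unif_rand() * (p - v));
      if (w >= p) w = p - 1;
      std::swap(vars[v], vars[w]);
    }
    std::vector<double> vals;
    for (int vi = 0; vi < mtry && vi < p; ++vi) {
      int var = vars[vi];
      vals.clear();
      for (size_t i = 0; i < mem.size(); ++i) vals.push_back(X(mem[i], var));
      std::sort(vals.begin(), vals.end());
      vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
      // candidate thresholds at observed values (all but the maximum)
      for (size_t ci = 0; ci + 1 < vals.size(); ++ci) {
        double stat = split_logrank(mem, time, status, X, var, vals[ci], min_ev);
        if (stat > best_stat) {
          best_stat = stat;
          best_var = var;
          best_val = vals[ci];
        }
      }
    }
  }

  if (best_var < 0) {
    tree.split_var[node] = -1;
    tree.leaf_id[node] = (int)tree.leaf_times.size();
    std::vector<double> lt, lh;
    leaf_nelson_aalen(mem, time, status, lt, lh);
    tree.leaf_times.push_back(lt);
    tree.leaf_chf.push_back(lh);
    return;
  }

  std::vector<int> lmem, rmem;  // stable partition keeps time order
  for (size_t i = 0; i < mem.size(); ++i) {
    if (X(mem[i], best_var) <= best_val) lmem.push_back(mem[i]);
    else rmem.push_back(mem[i]);
  }
  mem.clear();

  tree.split_var[node] = best_var;
  tree.split_val[node] = best_val;
  int lnode = (int)tree.split_var.size();
  tree.split_var.push_back(-1); tree.split_val.push_back(0.0);
  tree.left_child.push_back(-1); tree.right_child.push_back(-1);
  tree.leaf_id.push_back(-1);
  int rnode = (int)tree.split_var.size();
  tree.split_var.push_back(-1); tree.split_val.push_back(0.0);
  tree.left_child.push_back(-1); tree.right_child.push_back(-1);
  tree.leaf_id.push_back(-1);
  tree.left_child[node] = lnode;
  tree.right_child[node] = rnode;

  grow_node(tree, lmem, time, status, X, mtry, min_ev, lnode);
  grow_node(tree, rmem, time, status, X, mtry, min_ev, rnode);
}

}  // namespace

// [[Rcpp::export(name = ".rsf_grow")]]
List rsf_grow(NumericVector time, IntegerVector status, NumericMatrix X,
              int n_trees, int mtry, int min_terminal_events, bool bootstrap) {
  const int n = time.size();
  List forest(n_trees);

  // training-order sort indices, ties broken by original index
  std::vector<int> base_ord(n);
  for (int i = 0; i < n; ++i) base_ord[i] = i;
  std::stable_sort(base_ord.begin(), base_ord.end(),
                   [&](int a, int b) { return time[a] < time[b]; });

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> mem;
    IntegerVector inbag(n);
    if (bootstrap) {
      std::vector<int> counts(n, 0);
      for (int i = 0; i < n; ++i) {
        int pick = (int)(unif_rand() * n);
        if (pick >= n) pick = n - 1;
        ++counts[pick];
        inbag[i] = pick + 1;
      }
      for (int i = 0; i < n; ++i) {
        int idx = base_ord[i];
        for (int c = 0; c < counts[idx]; ++c) mem.push_back(idx);
      }
    } else {
      mem = base_ord;
      for (int i = 0; i < n; ++i) inbag[i] = i + 1;
    }

    TreeBuild tree;
    tree.split_var.push_back(-1); tree.split_val.push_back(0.0);
    tree.left_child.push_back(-1); tree.right_child.push_back(-1);
    tree.leaf_id.push_back(-1);
    grow_node(tree, mem, time, status, X, mtry, min_terminal_events, 0);

    List leaves_t(tree.leaf_times.size()), leaves_h(tree.leaf_chf.size());
    for (size_t l = 0; l < tree.leaf_times.size(); ++l) {
      leaves_t[l] = wrap(tree.leaf_times[l]);
      leaves_h[l] = wrap(tree.leaf_chf[l]);
    }
    forest[t] = List::create(
      _["split_var"] = wrap(tree.split_var),
      _["split_val"] = wrap(tree.split_val),
      _["left"] = wrap(tree.left_child),
      _["right"] = wrap(tree.right_child),
      _["leaf_id"] = wrap(tree.leaf_id),
      _["leaf_times"] = leaves_t,
      _["leaf_chf"] = leaves_h,
      _["inbag"] = inbag);
  }
  return forest;
}

// [[Rcpp::export(name = ".rsf_predict")]]
NumericMatrix rsf_predict(List forest, NumericMatrix X, NumericVector grid) {
  const int n = X.nrow(), G = grid.size(), T = forest.size();
  NumericMatrix out(n, G);

  for (int t = 0; t < T; ++t) {
    List tree = forest[t];
    IntegerVector split_var = tree["split_var"];
    NumericVector split_val = tree["split_val"];
    IntegerVector left = tree["left"], right = tree["right"];
    IntegerVector leaf_id = tree["leaf_id"];
    List leaf_times = tree["leaf_times"], leaf_chf = tree["leaf_chf"];
    const int L = leaf_times.size();

    // each leaf's cumulative hazard evaluated on the grid
    NumericMatrix leafH(L, G);
    for (int l = 0; l < L; ++l) {
      NumericVector lt = leaf_times[l], lh = leaf_chf[l];
      int j = 0;
      double H = 0.0;
      for (int g = 0; g < G; ++g) {
        while (j < lt.size() && lt[j] <= grid[g]) H = lh[j++];
        leafH(l, g) = H;
      }
    }

    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (split_var[node] >= 0)
        node = (X(i, split_var[node]) <= split_val[node]) ? left[node] : right[node];
      int l = leaf_id[node];
      for (int g = 0; g < G; ++g) out(i, g) += leafH(l, g);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < G; ++g) out(i, g) /= T;
  return out;
}
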