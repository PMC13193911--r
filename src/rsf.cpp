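// Random survival forest core: bootstrap trees with two-group log-rank
// splitting and Nelson-Aalen leaf cumulative hazards on a shared event-time
// grid. Randomness comes from R's RNG so set.seed() controls fits exactly.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Squared standardized two-group log-rank statistic (O-E)^2 / V over the
// event times of the pooled sample. Degenerate tables (no events, empty
// side, zero hypergeometric variance) return 0.
static double logrank_stat_core(const std::vector<double>& time,
                                const std::vector<int>& event,
                                const std::vector<int>& in_left) {
  const int n = (int)time.size();
  // distinct event times
  std::vector<double> et;
  for (int i = 0; i < n; ++i) if (event[i] == 1) et.push_back(time[i]);
  if (et.empty()) return 0.0;
  std::sort(et.begin(), et.end());
  et.erase(std::unique(et.begin(), et.end()), et.end());
  const int B = (int)et.size();
  std::vector<double> d(B, 0), dl(B, 0), Y(B, 0), Yl(B, 0);
  for (int i = 0; i < n; ++i) {
    // at risk at t_b iff time >= t_b; contribute to all bins with t_b <= time
    int pos = (int)(std::upper_bound(et.begin(), et.end(), time[i]) - et.begin());
    for (int b = 0; b < pos; ++b) { Y[b] += 1; if (in_left[i]) Yl[b] += 1; }
    if (event[i] == 1) {
      int b = (int)(std::lower_bound(et.begin(), et.end(), time[i]) - et.begin());
      d[b] += 1; if (in_left[i]) dl[b] += 1;
    }
  }
  double OE = 0.0, V = 0.0;
  for (int b = 0; b < B; ++b) {
    if (Y[b] < 1) continue;
    OE += dl[b] - d[b] * Yl[b] / Y[b];
    if (Y[b] > 1)
      V += d[b] * (Yl[b] / Y[b]) * (1.0 - Yl[b] / Y[b]) * (Y[b] - d[b]) / (Y[b] - 1.0);
  }
  if (V <= 0) return 0.0;
  return OE * OE / V;
}

// [[Rcpp::export(name = ".rsf_logrank_stat")]]
double rsf_logrank_stat(NumericVector time, IntegerVector event,
                        LogicalVector left) {
  const int n = time.size();
  std::vector<double> t(n);
  std::vector<int> e(n), l(n);
  for (int i = 0; i < n; ++i) { t[i] = time[i]; e[i] = event[i]; l[i] = left[i] ? 1 : 0; }
  return logrank_stat_core(t, e, l);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& time;
  const IntegerVector& event;
  const NumericVector& grid;
  int mtry, max_depth, min_split, min_leaf, p;

  std::vector<int> feature, left_child, right_child, leaf_id;
  std::vector<double> threshold;
  std::vector< std::vector<double> > leaf_chf;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& time_,
              const IntegerVector& event_, const NumericVector& grid_,
              int mtry_, int max_depth_, int min_split_, int min_leaf_)
    : X(X_), time(time_), event(event_), grid(grid_), mtry(mtry_),
      max_depth(max_depth_), min_split(min_split_), min_leaf(min_leaf_),
      p(X_.ncol()) {}

  int make_leaf(const std::vector<int>& rows) {
    // Nelson-Aalen cumulative hazard of the node sample on the shared grid.
    const int m = (int)rows.size(), G = grid.size();
    std::vector<std::pair<double,int> > te(m);
    for (int i = 0; i < m; ++i) te[i] = std::make_pair(time[rows[i]], event[rows[i]]);
    std::sort(te.begin(), te.end());
    std::vector<double> chf(G, 0.0);
    double h = 0.0;
    int i = 0, g = 0;
    while (i < m) {
      double t = te[i].first;
      int dcount = 0, tiecount = 0;
      int at_risk = m - i;
      while (i < m && te[i].first == t) { dcount += te[i].second; ++tiecount; ++i; }
      if (dcount > 0) {
        while (g < G && grid[g] < t) { chf[g] = h; ++g; }
        h += (double)dcount / (double)at_risk;
      }
    }
    while (g < G) { chf[g] = h; ++g; }
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left_child.push_back(-1); right_child.push_back(-1);
    leaf_id.push_back((int)leaf_chf.size());
    leaf_chf.push_back(chf);
    return (int)feature.size() - 1;
  }

  // Sample k distinct feature indices with R's RNG, returned sorted so that
  // ties in the split statistic resolve to the lowest feature index.
  std::vector<int> sample_features() {
    std::vector<int> idx(p);
    for (int j = 0; j < p; ++j) idx[j] = j;
    int k = std::min(mtry, p);
    for (int j = 0; j < k; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(idx[j], idx[r]);
    }
    idx.resize(k);
    std::sort(idx.begin(), idx.end());
    return idx;
  }

  bool find_split(const std::vector<int>& rows, int& best_f, double& best_thr) {
    const int m = (int)rows.size();
    // node-local distinct event times
    std::vector<double> et;
    for (int i = 0; i < m; ++i) if (event[rows[i]] == 1) et.push_back(time[rows[i]]);
    if (et.empty()) return false;
    std::sort(et.begin(), et.end());
    et.erase(std::unique(et.begin(), et.end()), et.end());
    const int B = (int)et.size();

    std::vector<double> d(B, 0), Y(B, 0);
    std::vector<int> bin_of(m, -1), pos_of(m, 0);
    for (int i = 0; i < m; ++i) {
      double ti = time[rows[i]];
      int pos = (int)(std::upper_bound(et.begin(), et.end(), ti) - et.begin());
      pos_of[i] = pos;
      for (int b = 0; b < pos; ++b) Y[b] += 1;
      if (event[rows[i]] == 1) {
        int b = (int)(std::lower_bound(et.begin(), et.end(), ti) - et.begin());
        bin_of[i] = b; d[b] += 1;
      }
    }

    double best_stat = 0.0;
    best_f = -1; best_thr = NA_REAL;
    std::vector<int> feats = sample_features();
    std::vector<int> ord(m);
    std::vector<double> dl(B), Ylv(B);

    for (size_t fi = 0; fi < feats.size(); ++fi) {
      int f = feats[fi];
      for (int i = 0; i < m; ++i) ord[i] = i;
      const int col_f = f;
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(rows[a], col_f) < X(rows[b], col_f);
      });
      std::fill(dl.begin(), dl.end(), 0.0);
      std::fill(Ylv.begin(), Ylv.end(), 0.0);
      for (int i = 0; i < m - 1; ++i) {
        int r = ord[i];
        for (int b = 0; b < pos_of[r]; ++b) Ylv[b] += 1;
        if (bin_of[r] >= 0) dl[bin_of[r]] += 1;
        double v1 = X(rows[ord[i]], f), v2 = X(rows[ord[i + 1]], f);
        if (v1 == v2) continue;                 // not a boundary
        int nleft = i + 1, nright = m - nleft;
        if (nleft < min_leaf || nright < min_leaf) continue;
        double OE = 0.0, V = 0.0;
        for (int b = 0; b < B; ++b) {
          if (Y[b] < 1) continue;
          OE += dl[b] - d[b] * Ylv[b] / Y[b];
          if (Y[b] > 1)
            V += d[b] * (Ylv[b] / Y[b]) * (1.0 - Ylv[b] / Y[b]) * (Y[b] - d[b]) / (Y[b] - 1.0);
        }
        if (V <= 0) continue;
        double stat = OE * OE / V;
        if (stat > best_stat) {                 // strict: lowest f, lowest thr win ties
          best_stat = stat; best_f = f; best_thr = 0.5 * (v1 + v2);
        }
      }
    }
    return best_f >= 0 && best_stat > 0.0;
  }

  int build(const std::vector<int>& rows, int depth) {
    const int m = (int)rows.size();
    bool any_event = false;
    for (int i = 0; i < m; ++i) if (event[rows[i]] == 1) { any_event = true; break; }
    if (depth >= max_depth || m < min_split || !any_event)
      return make_leaf(rows);

    int f; double thr;
    if (!find_split(rows, f, thr)) return make_leaf(rows);

    std::vector<int> lrows, rrows;
    for (int i = 0; i < m; ++i) {
      if (X(rows[i], f) <= thr) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    int id = (int)feature.size();
    feature.push_back(f); threshold.push_back(thr);
    left_child.push_back(-2); right_child.push_back(-2);
    leaf_id.push_back(-1);
    int lid = build(lrows, depth + 1);
    int rid = build(rrows, depth + 1);
    left_child[id] = lid; right_child[id] = rid;
    return id;
  }
};

// [[Rcpp::export(name = ".rsf_grow")]]
List rsf_grow(NumericMatrix X, NumericVector time, IntegerVector event,
              NumericVector grid, int n_trees, int mtry, int max_depth,
              int min_split, int min_leaf) {
  const int n = X.nrow(), G = grid.size();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    // bootstrap sample, n draws with replacement
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      boot[i] = r;
    }
    TreeBuilder tb(X, time, event, grid, mtry, max_depth, min_split, min_leaf);
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = boot[i];
    tb.build(rows, 0);

    int nn = (int)tb.feature.size(), nl = (int)tb.leaf_chf.size();
    IntegerVector fv(nn), lc(nn), rc(nn), lid(nn), inbag(n);
    NumericVector thr(nn);
    for (int i = 0; i < nn; ++i) {
      fv[i] = tb.feature[i]; lc[i] = tb.left_child[i]; rc[i] = tb.right_child[i];
      lid[i] = tb.leaf_id[i]; thr[i] = tb.threshold[i];
    }
    NumericMatrix chf(nl, G);
    for (int l = 0; l < nl; ++l)
      for (int g = 0; g < G; ++g) chf(l, g) = tb.leaf_chf[l][g];
    for (int i = 0; i < n; ++i) inbag[i] = boot[i] + 1;
    trees[t] = List::create(_["feature"] = fv, _["threshold"] = thr,
                            _["left"] = lc, _["right"] = rc,
                            _["leaf_id"] = lid, _["leaf_chf"] = chf,
                            _["inbag"] = inbag);
  }
  return trees;
}

// [[Rcpp::export(name = ".rsf_predict_chf")]]
NumericMatrix rsf_predict_chf(List trees, NumericMatrix X, int n_grid) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, n_grid);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector fv = tr["feature"], lc = tr["left"], rc = tr["right"],
      lid = tr["leaf_id"];
    NumericVector thr = tr["threshold"];
    NumericMatrix chf = tr["leaf_chf"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (fv[node] >= 0)
        node = (X(i, fv[node]) <= thr[node]) ? lc[node] : rc[node];
      int l = lid[node];
      for (int g = 0; g < n_grid; ++g) out(i, g) += chf(l, g);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < n_grid; ++g) out(i, g) /= T;
  return out;
}
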