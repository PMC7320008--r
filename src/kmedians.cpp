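#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Internal storage is transposed (d x n / d x k) so one point's features are
// contiguous in memory; the inner distance loops then stream linearly.

static double l1_dist(const std::vector<double>& Xt, int row,
                      const std::vector<double>& Ct, int c, int d,
                      double cutoff) {
  const double* x = &Xt[(size_t)row * d];
  const double* cc = &Ct[(size_t)c * d];
  double s = 0.0;
  for (int j = 0; j < d; ++j) {
    s += std::fabs(x[j] - cc[j]);
    if (s >= cutoff) return s; // early abandon: cannot beat current best
  }
  return s;
}

static void update_centroid(const std::vector<double>& Xt,
                            const std::vector<int>& members,
                            std::vector<double>& Ct, int c, int d) {
  const int m = members.size();
  std::vector<double> buf(m);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < m; ++i) buf[i] = Xt[(size_t)members[i] * d + j];
    const int mid = m / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (m % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      med = 0.5 * (med + lo);
    }
    Ct[(size_t)c * d + j] = med;
  }
}

// Lloyd iterations under the cityblock (L1) distance with component-wise
// median centroid updates. `inits` holds 0-based row indices of the initial
// centroids, one replicate per row; the minimum-objective replicate wins.
// [[Rcpp::export(name = ".kmedians_fit")]]
List kmedians_fit(NumericMatrix X, IntegerMatrix inits, int max_iter) {
  const int n = X.nrow(), d = X.ncol(), k = inits.ncol();
  const int n_rep = inits.nrow();

  std::vector<double> Xt((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) Xt[(size_t)i * d + j] = X(i, j);

  IntegerVector best_labels(n);
  NumericMatrix best_centroids(k, d);
  double best_obj = R_PosInf;
  int best_rep = -1, best_iters = 0;
  NumericVector objectives(n_rep);

  std::vector<int> labels(n), prev(n);
  std::vector<double> Ct((size_t)k * d);
  std::vector<double> dist_to_own(n);

  for (int rep = 0; rep < n_rep; ++rep) {
    for (int c = 0; c < k; ++c) {
      const int r0 = inits(rep, c);
      for (int j = 0; j < d; ++j)
        Ct[(size_t)c * d + j] = Xt[(size_t)r0 * d + j];
    }
    std::fill(prev.begin(), prev.end(), -1);
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      // assignment
      for (int i = 0; i < n; ++i) {
        double bd = l1_dist(Xt, i, Ct, 0, d, R_PosInf);
        int bc = 0;
        for (int c = 1; c < k; ++c) {
          double dd = l1_dist(Xt, i, Ct, c, d, bd);
          if (dd < bd) { bd = dd; bc = c; }
        }
        labels[i] = bc;
        dist_to_own[i] = bd;
      }
      // empty-cluster repair: farthest point becomes a singleton
      std::vector<int> counts(k, 0);
      for (int i = 0; i < n; ++i) counts[labels[i]]++;
      for (int c = 0; c < k; ++c) {
        if (counts[c] == 0) {
          int far = 0;
          double fd = -1.0;
          for (int i = 0; i < n; ++i)
            if (counts[labels[i]] > 1 && dist_to_own[i] > fd) {
              fd = dist_to_own[i];
              far = i;
            }
          counts[labels[far]]--;
          labels[far] = c;
          counts[c] = 1;
          dist_to_own[far] = 0.0;
        }
      }
      if (labels == prev) break;
      prev = labels;
      // update
      std::vector<std::vector<int> > members(k);
      for (int i = 0; i < n; ++i) members[labels[i]].push_back(i);
      for (int c = 0; c < k; ++c)
        if (!members[c].empty()) update_centroid(Xt, members[c], Ct, c, d);
    }
    // final objective under final centroids
    double obj = 0.0;
    for (int i = 0; i < n; ++i)
      obj += l1_dist(Xt, i, Ct, labels[i], d, R_PosInf);
    objectives[rep] = obj;
    if (obj < best_obj) {
      best_obj = obj;
      best_rep = rep;
      best_iters = it;
      for (int i = 0; i < n; ++i) best_labels[i] = labels[i] + 1; // 1-based
      for (int c = 0; c < k; ++c)
        for (int j = 0; j < d; ++j) best_centroids(c, j) = Ct[(size_t)c * d + j];
    }
  }

  return List::create(
    _["labels"] = best_labels,
    _["centroids"] = best_centroids,
    _["objective"] = best_obj,
    _["best_replicate"] = best_rep + 1,
    _["iterations"] = best_iters,
    _["replicate_objectives"] = objectives);
}
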