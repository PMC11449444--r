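#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Squared Euclidean distance between row i of X and center row c of C.
static inline double row_sqdist(const NumericMatrix &X, int i,
                                const NumericMatrix &C, int c) {
  double s = 0.0;
  for (int j = 0; j < X.ncol(); ++j) {
    double d = X(i, j) - C(c, j);
    s += d * d;
  }
  return s;
}

// k-means++ seeding using R's RNG (unif_rand), so set.seed() on the R side
// makes the whole run reproducible.
static void kmeanspp_init(const NumericMatrix &X, NumericMatrix &C) {
  int n = X.nrow(), p = X.ncol(), k = C.nrow();
  std::vector<double> d2(n, std::numeric_limits<double>::infinity());

  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  for (int j = 0; j < p; ++j) C(0, j) = X(first, j);

  for (int c = 1; c < k; ++c) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = row_sqdist(X, i, C, c - 1);
      if (d < d2[i]) d2[i] = d;
      total += d2[i];
    }
    int pick;
    if (total <= 0.0) {
      pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * total, cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (u <= cum) { pick = i; break; }
      }
    }
    for (int j = 0; j < p; ++j) C(c, j) = X(pick, j);
  }
}

// One Lloyd run from a k-means++ start. Empty clusters are re-seeded at the
// point farthest from its current center (documented contract, not an error).
static double lloyd_run(const NumericMatrix &X, int k, int max_iter,
                        IntegerVector &assign_out, NumericMatrix &C) {
  int n = X.nrow(), p = X.ncol();
  kmeanspp_init(X, C);
  std::vector<int> assign(n, -1);
  std::vector<int> sizes(k, 0);

  for (int iter = 0; iter < max_iter; ++iter) {
    bool changed = false;
    // assignment step (repeat within the iteration if a reseed occurs)
    for (;;) {
      std::fill(sizes.begin(), sizes.end(), 0);
      for (int i = 0; i < n; ++i) {
        int best = 0;
        double bestd = row_sqdist(X, i, C, 0);
        for (int c = 1; c < k; ++c) {
          double d = row_sqdist(X, i, C, c);
          if (d < bestd) { bestd = d; best = c; }
        }
        if (assign[i] != best) { assign[i] = best; changed = true; }
        sizes[best]++;
      }
      int empty = -1;
      for (int c = 0; c < k; ++c) if (sizes[c] == 0) { empty = c; break; }
      if (empty < 0) break;
      // farthest point from its own center becomes the new center
      int far_i = 0; double far_d = -1.0;
      for (int i = 0; i < n; ++i) {
        double d = row_sqdist(X, i, C, assign[i]);
        if (d > far_d) { far_d = d; far_i = i; }
      }
      for (int j = 0; j < p; ++j) C(empty, j) = X(far_i, j);
      changed = true;
    }
    // update step
    NumericMatrix newC(k, p);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < p; ++j) newC(assign[i], j) += X(i, j);
    for (int c = 0; c < k; ++c)
      for (int j = 0; j < p; ++j) C(c, j) = newC(c, j) / sizes[c];
    if (!changed) break;
  }

  double inertia = 0.0;
  for (int i = 0; i < n; ++i) {
    inertia += row_sqdist(X, i, C, assign[i]);
    assign_out[i] = assign[i] + 1; // 1-based cluster ids
  }
  return inertia;
}

//' @useDynLib regenphase, .registration = TRUE
// [[Rcpp::export]]
List kmeans_lloyd_cpp(NumericMatrix X, int k, int n_init, int max_iter) {
  int n = X.nrow(), p = X.ncol();
  if (k < 1 || k > n) stop("k must be between 1 and the number of rows");
  IntegerVector best_assign(n), assign(n);
  NumericMatrix best_C(k, p), C(k, p);
  double best_inertia = std::numeric_limits<double>::infinity();
  for (int r = 0; r < n_init; ++r) {
    double inertia = lloyd_run(X, k, max_iter, assign, C);
    if (inertia < best_inertia) {
      best_inertia = inertia;
      best_assign = clone(assign);
      best_C = clone(C);
    }
  }
  return List::create(_["cluster"] = best_assign,
                      _["centers"] = best_C,
                      _["inertia"] = best_inertia);
}
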