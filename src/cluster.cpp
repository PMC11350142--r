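// Month-clustering kernels: restarted Lloyd k-means on the 12 monthly
// feature vectors, exhaustive enumeration of circularly contiguous k-arc
// partitions, and projection of arbitrary labelings onto the nearest
// contiguous partition. n is always 12 and k is 2 or 4, so exhaustive
// enumeration (C(12,2)=66, C(12,4)=495 cut-sets) is cheap; these routines
// are compiled because the parameter search evaluates them ~10^5 times.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static double sq(double x) { return x * x; }

// within-cluster sum of squares for a labeling (labels 1..k)
static double labels_sse(const NumericMatrix &X, const IntegerVector &lab, int k) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> cen(k * d, 0.0);
  std::vector<int> cnt(k, 0);
  for (int i = 0; i < n; i++) {
    int g = lab[i] - 1;
    cnt[g]++;
    for (int j = 0; j < d; j++) cen[g * d + j] += X(i, j);
  }
  for (int g = 0; g < k; g++)
    if (cnt[g] > 0)
      for (int j = 0; j < d; j++) cen[g * d + j] /= cnt[g];
  double sse = 0.0;
  for (int i = 0; i < n; i++) {
    int g = lab[i] - 1;
    for (int j = 0; j < d; j++) sse += sq(X(i, j) - cen[g * d + j]);
  }
  return sse;
}

// [[Rcpp::export(name = ".labels_sse_cpp")]]
double labels_sse_cpp(NumericMatrix X, IntegerVector labels) {
  int k = 0;
  for (int i = 0; i < labels.size(); i++) k = std::max(k, labels[i]);
  return labels_sse(X, labels, k);
}

// Lloyd iterations from given initial center indices; returns SSE, fills lab
static double lloyd(const NumericMatrix &X, int k, const std::vector<int> &init,
                    std::vector<int> &lab) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> cen(k * d);
  for (int g = 0; g < k; g++)
    for (int j = 0; j < d; j++) cen[g * d + j] = X(init[g], j);
  lab.assign(n, 0);
  for (int iter = 0; iter < 100; iter++) {
    bool changed = false;
    for (int i = 0; i < n; i++) {
      int best = 0; double bd = R_PosInf;
      for (int g = 0; g < k; g++) {
        double dd = 0.0;
        for (int j = 0; j < d; j++) dd += sq(X(i, j) - cen[g * d + j]);
        if (dd < bd) { bd = dd; best = g; }
      }
      if (lab[i] != best) { lab[i] = best; changed = true; }
    }
    std::vector<double> nc(k * d, 0.0);
    std::vector<int> cnt(k, 0);
    for (int i = 0; i < n; i++) {
      cnt[lab[i]]++;
      for (int j = 0; j < d; j++) nc[lab[i] * d + j] += X(i, j);
    }
    for (int g = 0; g < k; g++) {
      if (cnt[g] > 0)
        for (int j = 0; j < d; j++) cen[g * d + j] = nc[g * d + j] / cnt[g];
      // empty cluster: reseed on the point farthest from its center
      else {
        int far = 0; double fd = -1.0;
        for (int i = 0; i < n; i++) {
          double dd = 0.0;
          for (int j = 0; j < d; j++) dd += sq(X(i, j) - cen[lab[i] * d + j]);
          if (dd > fd) { fd = dd; far = i; }
        }
        for (int j = 0; j < d; j++) cen[g * d + j] = X(far, j);
      }
    }
    if (!changed && iter > 0) break;
  }
  std::vector<int> l1(n);
  for (int i = 0; i < n; i++) l1[i] = lab[i] + 1;
  IntegerVector lv(l1.begin(), l1.end());
  return labels_sse(X, lv, k);
}

// farthest-point completion of a center set starting from `first`
static std::vector<int> farthest_init(const NumericMatrix &X, int k, int first) {
  int n = X.nrow(), d = X.ncol();
  std::vector<int> init;
  init.push_back(first);
  while ((int)init.size() < k) {
    int best = -1; double bd = -1.0;
    for (int i = 0; i < n; i++) {
      double mind = R_PosInf;
      for (size_t c = 0; c < init.size(); c++) {
        double dd = 0.0;
        for (int j = 0; j < d; j++) dd += sq(X(i, j) - X(init[c], j));
        mind = std::min(mind, dd);
      }
      if (mind > bd + 1e-15) { bd = mind; best = i; }
    }
    init.push_back(best);
  }
  return init;
}

// Best-of-restarts k-means. Restarts alternate between farthest-point
// initialization (first center cycling over the data points) and random
// distinct subsets; deterministic for a given seed via a private mt19937.
// [[Rcpp::export(name = ".kmeans_restarts_cpp")]]
List kmeans_restarts_cpp(NumericMatrix X, int k, int restarts, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  std::vector<int> best_lab(n, 0);
  double best_sse = R_PosInf;
  for (int r = 0; r < restarts; r++) {
    std::vector<int> init;
    if (r % 2 == 0) {
      init = farthest_init(X, k, (r / 2) % n);
    } else {
      std::vector<int> seen;
      while ((int)seen.size() < k) {
        int c = pick(rng);
        if (std::find(seen.begin(), seen.end(), c) == seen.end())
          seen.push_back(c);
      }
      init = seen;
    }
    std::vector<int> lab;
    double sse = lloyd(X, k, init, lab);
    if (sse < best_sse - 1e-12) { best_sse = sse; best_lab = lab; }
  }
  // canonical labels: clusters numbered by first month of occurrence
  std::vector<int> remap(k, 0);
  int nxt = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    if (remap[best_lab[i]] == 0) remap[best_lab[i]] = ++nxt;
    out[i] = remap[best_lab[i]];
  }
  return List::create(_["labels"] = out, _["sse"] = best_sse,
                      _["k_found"] = nxt);
}

// iterate cut-set combinations c[0]<...<c[k-1] over 1..n in lexicographic
// order; returns false when exhausted
static bool next_comb(std::vector<int> &c, int n, int k) {
  int i = k - 1;
  while (i >= 0 && c[i] == n - k + i + 1) i--;
  if (i < 0) return false;
  c[i]++;
  for (int j = i + 1; j < k; j++) c[j] = c[j - 1] + 1;
  return true;
}

// arc id (0..k-1) of each month for cut positions (cut before month c)
static void arcs_of_cuts(const std::vector<int> &cuts, int n, int k,
                         std::vector<int> &arc) {
  arc.assign(n, k - 1); // months before the first cut belong to the last arc
  for (int a = 0; a < k; a++) {
    int from = cuts[a] - 1;
    int to = (a + 1 < k ? cuts[a + 1] - 1 : n) ;
    for (int m = from; m < to; m++) arc[m] = a;
  }
  // wrap: months [0, cuts[0]-1) stay with arc k-1 (set by default above)
}

// SSE of a contiguous partition using prefix sums
static double arcs_sse(const NumericMatrix &X, const std::vector<int> &arc, int k) {
  int n = X.nrow();
  IntegerVector lv(n);
  for (int i = 0; i < n; i++) lv[i] = arc[i] + 1;
  return labels_sse(X, lv, k);
}

// Exhaustive best circularly contiguous k-arc partition; ties (within 1e-9
// relative) resolved by the lexicographically smallest cut-set. Arc labels
// are 1..k in cut order.
// [[Rcpp::export(name = ".contiguous_best_cpp")]]
List contiguous_best_cpp(NumericMatrix X, int k) {
  int n = X.nrow();
  std::vector<int> cuts(k);
  for (int i = 0; i < k; i++) cuts[i] = i + 1;
  std::vector<int> arc, best_arc;
  double best = R_PosInf;
  do {
    arcs_of_cuts(cuts, n, k, arc);
    double s = arcs_sse(X, arc, k);
    if (best_arc.empty() || s < best - 1e-9 * (1.0 + best)) {
      best = s; best_arc = arc;
    }
  } while (next_comb(cuts, n, k));
  IntegerVector out(n);
  for (int i = 0; i < n; i++) out[i] = best_arc[i] + 1;
  return List::create(_["labels"] = out, _["sse"] = best);
}

// Project a labeling onto the contiguous k-arc partition minimizing Hamming
// disagreement (over all arc->label bijections); ties by lower SSE on X,
// then by lexicographically smallest cut-set. Input labels must be 1..k.
// [[Rcpp::export(name = ".project_contiguous_cpp")]]
List project_contiguous_cpp(IntegerVector labels, NumericMatrix X, int k) {
  int n = labels.size();
  std::vector<int> cuts(k);
  for (int i = 0; i < k; i++) cuts[i] = i + 1;
  std::vector<int> arc;
  std::vector<int> best_assign(k);
  std::vector<int> best_arc;
  int best_ham = n + 1;
  double best_sse = R_PosInf;
  std::vector<int> perm(k);
  do {
    arcs_of_cuts(cuts, n, k, arc);
    // per-arc label match counts
    std::vector<int> cnt(k * k, 0); // cnt[a*k + (lab-1)]
    for (int m = 0; m < n; m++) cnt[arc[m] * k + (labels[m] - 1)]++;
    for (int i = 0; i < k; i++) perm[i] = i;
    int arc_best_ham = n + 1;
    std::vector<int> arc_best_assign(k);
    do {
      int match = 0;
      for (int a = 0; a < k; a++) match += cnt[a * k + perm[a]];
      int ham = n - match;
      if (ham < arc_best_ham) { arc_best_ham = ham; arc_best_assign = perm; }
    } while (std::next_permutation(perm.begin(), perm.end()));
    if (arc_best_ham <= best_ham) {
      double s = arcs_sse(X, arc, k);
      bool better = arc_best_ham < best_ham ||
                    (arc_best_ham == best_ham && s < best_sse - 1e-9 * (1.0 + best_sse));
      if (better) {
        best_ham = arc_best_ham;
        best_sse = s;
        best_arc = arc;
        best_assign = arc_best_assign;
      }
    }
  } while (next_comb(cuts, n, k));
  IntegerVector out(n);
  for (int m = 0; m < n; m++) out[m] = best_assign[best_arc[m]] + 1;
  return List::create(_["labels"] = out, _["hamming"] = best_ham,
                      _["sse"] = best_sse);
}
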