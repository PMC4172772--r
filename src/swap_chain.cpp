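#include <Rcpp.h>
using namespace Rcpp;

// Mean checkerboard units (C-score) over all unordered species pairs.
// CU(i,j) = (r_i - S)(r_j - S) with S the number of sites shared by i and j.
static double cscore_of(const IntegerMatrix& m) {
  const int R = m.nrow(), C = m.ncol();
  std::vector<int> rt(R, 0);
  for (int i = 0; i < R; ++i)
    for (int k = 0; k < C; ++k) rt[i] += m(i, k);
  double total = 0.0;
  for (int i = 0; i < R - 1; ++i) {
    for (int j = i + 1; j < R; ++j) {
      int s = 0;
      for (int k = 0; k < C; ++k) s += m(i, k) & m(j, k);
      total += static_cast<double>(rt[i] - s) * static_cast<double>(rt[j] - s);
    }
  }
  return total / (0.5 * R * (R - 1));
}

static inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// One attempted sequential swap: pick two distinct rows and two distinct
// columns uniformly; flip the 2x2 submatrix iff it is a checkerboard.
// Margins are conserved whether or not the flip happens.
static inline bool attempt_swap(IntegerMatrix& m, int R, int C) {
  int r1 = runif_int(R);
  int r2 = runif_int(R - 1);
  if (r2 >= r1) ++r2;
  int c1 = runif_int(C);
  int c2 = runif_int(C - 1);
  if (c2 >= c1) ++c2;
  const int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
  if (a == d && b == c && a != b) {
    m(r1, c1) = b; m(r1, c2) = a;
    m(r2, c1) = d; m(r2, c2) = c;
    return true;
  }
  return false;
}

// Apply n_success successful swaps (up to max_attempts attempts in total).
// [[Rcpp::export]]
List cpp_swap_chain(IntegerMatrix m, int n_success, double max_attempts) {
  IntegerMatrix out = clone(m);
  const int R = out.nrow(), C = out.ncol();
  double attempts = 0;
  int successes = 0;
  while (successes < n_success && attempts < max_attempts) {
    attempts += 1;
    if (attempt_swap(out, R, C)) ++successes;
  }
  return List::create(_["matrix"] = out,
                      _["successes"] = successes,
                      _["attempts"] = attempts);
}

// Sequential-swap null distribution of the C-score: after `burn_in`
// attempted swaps, advance `thin` successful swaps between each of
// `iterations` recorded C-scores. Margins are re-derived and checked at
// every recorded state; `margin_violations` must come back 0.
// [[Rcpp::export]]
List cpp_null_cscore(IntegerMatrix m, double burn_in, int iterations,
                     int thin, double max_attempts_per_swap) {
  IntegerMatrix cur = clone(m);
  const int R = cur.nrow(), C = cur.ncol();
  std::vector<int> rt0(R, 0), ct0(C, 0);
  for (int i = 0; i < R; ++i)
    for (int k = 0; k < C; ++k) {
      rt0[i] += cur(i, k);
      ct0[k] += cur(i, k);
    }
  for (double a = 0; a < burn_in; a += 1) attempt_swap(cur, R, C);

  NumericVector null_values(iterations);
  int margin_violations = 0;
  bool exhausted = false;
  for (int it = 0; it < iterations; ++it) {
    for (int t = 0; t < thin; ++t) {
      double a = 0;
      while (!attempt_swap(cur, R, C)) {
        if (++a >= max_attempts_per_swap) { exhausted = true; break; }
      }
      if (exhausted) break;
    }
    null_values[it] = cscore_of(cur);
    std::vector<int> rt(R, 0), ct(C, 0);
    for (int i = 0; i < R; ++i)
      for (int k = 0; k < C; ++k) {
        rt[i] += cur(i, k);
        ct[k] += cur(i, k);
      }
    if (rt != rt0 || ct != ct0) ++margin_violations;
  }
  return List::create(_["null_values"] = null_values,
                      _["final_matrix"] = cur,
                      _["margin_violations"] = margin_violations,
                      _["exhausted"] = exhausted);
}

// [[Rcpp::export]]
double cpp_cscore(IntegerMatrix m) {
  return cscore_of(m);
}
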