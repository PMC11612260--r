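#include <Rcpp.h>
using namespace Rcpp;

// Core Monte Carlo engine for fixed-fixed null models of binary
// presence-absence matrices. All randomness comes from R's RNG stream
// (unif_rand), so set.seed() in R fully determines the chain.

static inline int rand_index(int n) {
  // uniform draw from 0..n-1; guard against the (theoretical) unif_rand()==1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? (n - 1) : k;
}

static double cscore_of(const IntegerMatrix& m) {
  const int M = m.nrow(), N = m.ncol();
  std::vector<int> r(M, 0);
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < N; ++k) r[i] += m(i, k);
  double total = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      int S = 0;
      for (int k = 0; k < N; ++k) S += m(i, k) & m(j, k);
      total += (double)(r[i] - S) * (double)(r[j] - S);
    }
  }
  double pairs = (double)M * (M - 1) / 2.0;
  return total / pairs;
}

// one sequential-swap attempt; returns true when a checkerboard 2x2
// submatrix was drawn and flipped (row and column totals are conserved)
static inline bool swap_attempt(IntegerMatrix& m, int M, int N) {
  int i = rand_index(M);
  int j = rand_index(M - 1);
  if (j >= i) ++j;
  int a = rand_index(N);
  int b = rand_index(N - 1);
  if (b >= a) ++b;
  const int ia = m(i, a), ib = m(i, b), ja = m(j, a), jb = m(j, b);
  if (ia == jb && ib == ja && ia != ib) {
    m(i, a) = ib; m(i, b) = ia;
    m(j, a) = jb; m(j, b) = ja;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
double cpp_cscore(const IntegerMatrix& m) {
  if (m.nrow() < 2) stop("C-score requires at least 2 taxa (rows)");
  return cscore_of(m);
}

// does any swappable (checkerboard) 2x2 submatrix exist?
// [[Rcpp::export]]
bool cpp_has_swap(const IntegerMatrix& m) {
  const int M = m.nrow(), N = m.ncol();
  if (M < 2 || N < 2) return false;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      bool io = false, jo = false; // column with i-only, column with j-only
      for (int k = 0; k < N; ++k) {
        if (m(i, k) == 1 && m(j, k) == 0) io = true;
        else if (m(i, k) == 0 && m(j, k) == 1) jo = true;
        if (io && jo) return true;
      }
    }
  }
  return false;
}

// Run the sequential-swap chain from `m0`: burn in for `burn_in`
// *successful* swaps, then record the C-score every `thin` *attempted*
// swaps, `n_iter` times. Caller must ensure a swap exists (cpp_has_swap).
// [[Rcpp::export]]
List cpp_null_cscores(const IntegerMatrix& m0, int n_iter, int burn_in,
                      int thin) {
  IntegerMatrix m = clone(m0);
  const int M = m.nrow(), N = m.ncol();
  double attempts = 0, accepts = 0;
  long done = 0;
  while (done < burn_in) {
    attempts += 1;
    if (swap_attempt(m, M, N)) { accepts += 1; ++done; }
  }
  NumericVector sims(n_iter);
  for (int s = 0; s < n_iter; ++s) {
    for (int t = 0; t < thin; ++t) {
      attempts += 1;
      if (swap_attempt(m, M, N)) accepts += 1;
    }
    sims[s] = cscore_of(m);
  }
  return List::create(_["sims"] = sims,
                      _["attempts"] = attempts,
                      _["accepts"] = accepts);
}

// Shuffle a matrix by `n_success` successful swaps (used to sample a
// random member of the fixed-marginal class). Returns the new matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_swap_shuffle(const IntegerMatrix& m0, int n_success) {
  IntegerMatrix m = clone(m0);
  const int M = m.nrow(), N = m.ncol();
  long done = 0;
  while (done < n_success) {
    if (swap_attempt(m, M, N)) ++done;
  }
  return m;
}

// Run `n_attempts` attempted swaps and return the resulting matrix
// (used by simulate() and by marginal-conservation checks).
// [[Rcpp::export]]
IntegerMatrix cpp_swap_attempts(const IntegerMatrix& m0, int n_attempts) {
  IntegerMatrix m = clone(m0);
  const int M = m.nrow(), N = m.ncol();
  for (int t = 0; t < n_attempts; ++t) swap_attempt(m, M, N);
  return m;
}
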