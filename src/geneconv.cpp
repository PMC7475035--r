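#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <random>
#include <vector>
using namespace Rcpp;

// splitmix64 scramble: decorrelates sequential user seeds before they
// reach the Mersenne Twister, whose seed initialization diffuses poorly
static inline uint64_t scramble_seed(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Null distribution for zero-mismatch fragment scores: the order of the
// polymorphic columns is permuted (destroying runs while preserving each
// pair's agreement fraction) and, per permutation, the maximal agreement
// run is recorded for every sequence pair.

static void pair_max_runs(const LogicalMatrix& agree,
                          const std::vector<int>& ord,
                          IntegerMatrix& out, int row) {
  const int n_pairs = agree.nrow();
  const int L = agree.ncol();
  for (int p = 0; p < n_pairs; ++p) {
    int run = 0, mx = 0;
    for (int j = 0; j < L; ++j) {
      if (agree(p, ord[j])) { if (++run > mx) mx = run; }
      else run = 0;
    }
    out(row, p) = mx;
  }
}

// agree: n_pairs x n_columns matrix of pairwise agreement at polymorphic
// columns, in original column order.
// [[Rcpp::export(name = ".cpp_perm_max_runs")]]
IntegerMatrix cpp_perm_max_runs(LogicalMatrix agree, int n_perm,
                                double seed) {
  const int L = agree.ncol();
  std::mt19937_64 rng(scramble_seed(static_cast<uint64_t>(seed)));
  std::vector<int> ord(L);
  std::iota(ord.begin(), ord.end(), 0);
  IntegerMatrix out(n_perm, agree.nrow());
  for (int i = 0; i < n_perm; ++i) {
    for (int j = L - 1; j > 0; --j) {
      std::uniform_int_distribution<int> d(0, j);
      std::swap(ord[j], ord[d(rng)]);
    }
    pair_max_runs(agree, ord, out, i);
  }
  return out;
}

// Exhaustive enumeration of all column-order permutations (tiny inputs).
// [[Rcpp::export(name = ".cpp_exhaustive_max_runs")]]
IntegerMatrix cpp_exhaustive_max_runs(LogicalMatrix agree) {
  const int L = agree.ncol();
  if (L > 8) stop("exhaustive enumeration limited to <= 8 columns");
  long total = 1;
  for (int i = 2; i <= L; ++i) total *= i;
  std::vector<int> ord(L);
  std::iota(ord.begin(), ord.end(), 0);
  IntegerMatrix out((int) total, agree.nrow());
  int row = 0;
  do {
    pair_max_runs(agree, ord, out, row++);
  } while (std::next_permutation(ord.begin(), ord.end()));
  return out;
}
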