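#include <Rcpp.h>
#include <random>
#include <string>
using namespace Rcpp;

// splitmix64 scramble: decorrelates sequential user seeds before they
// reach the Mersenne Twister, whose seed initialization diffuses poorly
static inline uint64_t scramble_seed(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Random nucleotide sequence with a given GC content. Used for flanks,
// intergenic filler and the packaged neutral repeat template.
// [[Rcpp::export(name = ".cpp_random_seq")]]
std::string cpp_random_seq(int len, double gc, double seed) {
  std::mt19937_64 rng(scramble_seed(static_cast<uint64_t>(seed)));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::string out(len, 'A');
  for (int i = 0; i < len; ++i) {
    double u = unif(rng);
    if (u < gc) out[i] = (unif(rng) < 0.5) ? 'G' : 'C';
    else        out[i] = (unif(rng) < 0.5) ? 'A' : 'T';
  }
  return out;
}

static inline char rc_base(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = rc_base(out[i]);
  return out;
}

// Uniformly positioned single-end reads with per-base substitution errors.
// Returns sequences plus the truth (start, strand) for pileup oracles.
// [[Rcpp::export(name = ".cpp_simulate_reads")]]
List cpp_simulate_reads(std::string genome, int read_length, int n_reads,
                        double error_rate, double seed, bool both_strands) {
  std::mt19937_64 rng(scramble_seed(static_cast<uint64_t>(seed)));
  int glen = (int) genome.size();
  std::uniform_int_distribution<int> pos_d(0, glen - read_length);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> base_d(0, 3);
  const char bases[4] = {'A', 'C', 'G', 'T'};

  CharacterVector seqs(n_reads);
  IntegerVector starts(n_reads);
  LogicalVector minus(n_reads);
  std::string buf;
  for (int i = 0; i < n_reads; ++i) {
    int p = pos_d(rng);
    buf.assign(genome, p, read_length);
    bool rev = both_strands && unif(rng) < 0.5;
    if (rev) buf = cpp_revcomp(buf);
    if (error_rate > 0) {
      // geometric skips between error sites instead of per-base draws
      double log1mp = std::log(1.0 - error_rate);
      int j = (int) std::floor(std::log(1.0 - unif(rng)) / log1mp);
      while (j < read_length) {
        char nb = bases[base_d(rng)];
        while (nb == buf[j]) nb = bases[base_d(rng)];
        buf[j] = nb;
        j += 1 + (int) std::floor(std::log(1.0 - unif(rng)) / log1mp);
      }
    }
    seqs[i] = buf;
    starts[i] = p + 1;  // 1-based
    minus[i] = rev;
  }
  return List::create(_["seq"] = seqs, _["start"] = starts,
                      _["minus"] = minus);
}

// 31-bit scrambled seed for R's set.seed: applies the same splitmix64
// decorrelation to R-side streams as the compiled generators use
// [[Rcpp::export(name = ".cpp_scramble_int")]]
int cpp_scramble_int(double seed) {
  uint64_t h = scramble_seed(static_cast<uint64_t>(seed));
  return (int) (h % 2147483646ULL) + 1;
}
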