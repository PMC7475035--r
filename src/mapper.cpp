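#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <string>
#include <unordered_map>
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

// Exact-k-mer-seeded, mismatch-tolerant read placement onto a single
// reference contig. Reads whose best placement is tied across several
// positions are assigned uniformly at random among the ties (seeded), so
// that reads originating from collapsed tandem copies pile up correctly on
// a single-repeat reference.
//
// The index is an open-addressing hash table from 2-bit-encoded k-mers to
// reference positions; k-mers occurring more than once overflow into a
// side map so all candidate positions are recovered.

struct KmerIndex {
  int k;
  std::string ref;
  uint64_t mask;               // capacity - 1 (power of two)
  std::vector<uint64_t> keys;  // EMPTY sentinel = ~0ULL
  std::vector<int32_t> vals;   // first position; -2 = has overflow
  std::unordered_map<uint64_t, std::vector<int32_t> > overflow;
};

static const uint64_t EMPTY_KEY = ~0ULL;

static inline int code(char b) {
  switch (b) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char rc_base(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string cpp_revcomp_local(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = rc_base(out[i]);
  return out;
}

static bool hash_at(const std::string& s, int pos, int k, uint64_t* out) {
  uint64_t h = 0;
  for (int i = 0; i < k; ++i) {
    int c = code(s[pos + i]);
    if (c < 0) return false;
    h = (h << 2) | (uint64_t) c;
  }
  *out = h;
  return true;
}

static inline uint64_t mix(uint64_t h) {
  h ^= h >> 33; h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33; h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(std::string reference, int k) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->ref = reference;
  long n = (long) reference.size() - k + 1;
  if (n < 1) n = 0;
  uint64_t cap = 64;
  while (cap < (uint64_t) (n * 2)) cap <<= 1;
  idx->mask = cap - 1;
  idx->keys.assign(cap, EMPTY_KEY);
  idx->vals.assign(cap, 0);
  uint64_t h;
  for (long i = 0; i < n; ++i) {
    if (!hash_at(idx->ref, (int) i, k, &h)) continue;
    uint64_t slot = mix(h) & idx->mask;
    for (;;) {
      if (idx->keys[slot] == EMPTY_KEY) {
        idx->keys[slot] = h;
        idx->vals[slot] = (int32_t) i;
        break;
      }
      if (idx->keys[slot] == h) {  // duplicate k-mer -> overflow list
        if (idx->vals[slot] != -2) {
          idx->overflow[h].push_back(idx->vals[slot]);
          idx->vals[slot] = -2;
        }
        idx->overflow[h].push_back((int32_t) i);
        break;
      }
      slot = (slot + 1) & idx->mask;
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_length")]]
int cpp_index_length(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return (int) idx->ref.size();
}

static void lookup(const KmerIndex* idx, uint64_t h,
                   std::vector<int32_t>& out) {
  uint64_t slot = mix(h) & idx->mask;
  for (;;) {
    if (idx->keys[slot] == EMPTY_KEY) return;
    if (idx->keys[slot] == h) {
      if (idx->vals[slot] == -2) {
        std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator
            it = idx->overflow.find(h);
        out.insert(out.end(), it->second.begin(), it->second.end());
      } else {
        out.push_back(idx->vals[slot]);
      }
      return;
    }
    slot = (slot + 1) & idx->mask;
  }
}

static int mismatches(const std::string& ref, int pos, const std::string& read,
                      int max_mm) {
  int mm = 0, L = (int) read.size();
  for (int i = 0; i < L; ++i) {
    if (ref[pos + i] != read[i]) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

struct MapScratch {
  std::vector<int32_t> hits;
  std::vector<std::pair<int, bool> > seen;
  std::vector<std::pair<int, bool> > best;
  std::string rev;
};

// place one read; returns true if placed (coverage recorded in cov)
static bool map_read(const KmerIndex* idx, const std::string& fwd,
                     int max_mismatch, std::mt19937_64& rng,
                     std::vector<int32_t>& cov, MapScratch& sc) {
  const int k = idx->k;
  const std::string& ref = idx->ref;
  const int rlen = (int) ref.size();
  int L = (int) fwd.size();
  if (L < k || L > rlen) return false;
  sc.rev.assign(fwd.rbegin(), fwd.rend());
  for (int i = 0; i < L; ++i) sc.rev[i] = rc_base(sc.rev[i]);

  sc.seen.clear(); sc.best.clear();
  int best_mm = max_mismatch + 1;
  int offs[3] = {0, (L - k) / 2, L - k};
  // seed order interleaves strands so a perfect placement on either
  // strand is found before the early exit below
  for (int o = 0; o < 3 && best_mm > 0; ++o) {
    if (o > 0 && offs[o] == offs[o - 1]) continue;
    for (int s = 0; s < 2 && best_mm > 0; ++s) {
      const std::string& rd = s == 0 ? fwd : sc.rev;
      uint64_t h;
      if (!hash_at(rd, offs[o], k, &h)) continue;
      sc.hits.clear();
      lookup(idx, h, sc.hits);
      for (size_t c = 0; c < sc.hits.size(); ++c) {
        int pos = (int) sc.hits[c] - offs[o];
        if (pos < 0 || pos + L > rlen) continue;
        std::pair<int, bool> key(pos, s == 1);
        bool dup = false;
        for (size_t q = 0; q < sc.seen.size(); ++q)
          if (sc.seen[q] == key) { dup = true; break; }
        if (dup) continue;
        sc.seen.push_back(key);
        int mm = mismatches(ref, pos, rd, best_mm);
        if (mm < best_mm) { best_mm = mm; sc.best.clear(); }
        if (mm == best_mm && mm <= max_mismatch) sc.best.push_back(key);
      }
      // a zero-mismatch placement cannot be beaten, and all its ties
      // share every k-mer of the read, so they are already collected
    }
  }
  if (sc.best.empty()) return false;
  int pick = 0;
  if (sc.best.size() > 1) {
    std::uniform_int_distribution<int> d(0, (int) sc.best.size() - 1);
    pick = d(rng);
  }
  cov[sc.best[pick].first] += 1;
  cov[sc.best[pick].first + L] -= 1;
  return true;
}

static List depth_from_cov(std::vector<int32_t>& cov, int rlen,
                           int mapped, int unplaced) {
  IntegerVector depth(rlen);
  int32_t run = 0;
  for (int i = 0; i < rlen; ++i) { run += cov[i]; depth[i] = run; }
  return List::create(_["depth"] = depth, _["mapped"] = mapped,
                      _["unplaced"] = unplaced);
}

// Per-base depth of best placements; ties broken uniformly at random.
// [[Rcpp::export(name = ".cpp_map_reads")]]
List cpp_map_reads(SEXP xp, CharacterVector reads, int max_mismatch,
                   double seed) {
  XPtr<KmerIndex> idx(xp);
  const int rlen = (int) idx->ref.size();
  std::mt19937_64 rng(scramble_seed(static_cast<uint64_t>(seed)));
  std::vector<int32_t> cov(rlen + 1, 0);  // difference array
  int mapped = 0, unplaced = 0;
  MapScratch sc;
  std::string fwd;
  for (int r = 0; r < reads.size(); ++r) {
    fwd = as<std::string>(reads[r]);
    if (map_read(idx.get(), fwd, max_mismatch, rng, cov, sc)) ++mapped;
    else ++unplaced;
  }
  return depth_from_cov(cov, rlen, mapped, unplaced);
}

// Fused read simulation + mapping against several references at once:
// avoids materializing millions of reads as R strings. Read generation
// replicates .cpp_simulate_reads draw-for-draw, so for equal seeds the
// depth vectors equal the two-step path's.
// [[Rcpp::export(name = ".cpp_sim_and_map")]]
List cpp_sim_and_map(List idx_ptrs, std::string genome, int read_length,
                     int n_reads, double error_rate, double sim_seed,
                     int max_mismatch, NumericVector tie_seeds) {
  const int n_ref = idx_ptrs.size();
  if (tie_seeds.size() != n_ref) stop("one tie seed per reference");
  std::vector<KmerIndex*> refs(n_ref);
  std::vector<std::vector<int32_t> > cov(n_ref);
  std::vector<std::mt19937_64> tie_rng;
  for (int i = 0; i < n_ref; ++i) {
    XPtr<KmerIndex> p(as<SEXP>(idx_ptrs[i]));
    refs[i] = p.get();
    cov[i].assign(refs[i]->ref.size() + 1, 0);
    tie_rng.push_back(std::mt19937_64(
        scramble_seed(static_cast<uint64_t>(tie_seeds[i]))));
  }
  std::vector<int> mapped(n_ref, 0), unplaced(n_ref, 0);

  std::mt19937_64 rng(scramble_seed(static_cast<uint64_t>(sim_seed)));
  int glen = (int) genome.size();
  std::uniform_int_distribution<int> pos_d(0, glen - read_length);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> base_d(0, 3);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string buf;
  std::vector<MapScratch> sc(n_ref);

  for (int r = 0; r < n_reads; ++r) {
    int p = pos_d(rng);
    buf.assign(genome, p, read_length);
    bool rev = unif(rng) < 0.5;
    if (rev) buf = cpp_revcomp_local(buf);
    if (error_rate > 0) {
      double log1mp = std::log(1.0 - error_rate);
      int j = (int) std::floor(std::log(1.0 - unif(rng)) / log1mp);
      while (j < read_length) {
        char nb = bases[base_d(rng)];
        while (nb == buf[j]) nb = bases[base_d(rng)];
        buf[j] = nb;
        j += 1 + (int) std::floor(std::log(1.0 - unif(rng)) / log1mp);
      }
    }
    for (int i = 0; i < n_ref; ++i) {
      if (map_read(refs[i], buf, max_mismatch, tie_rng[i], cov[i], sc[i]))
        ++mapped[i];
      else
        ++unplaced[i];
    }
  }
  List out(n_ref);
  for (int i = 0; i < n_ref; ++i)
    out[i] = depth_from_cov(cov[i], (int) refs[i]->ref.size(), mapped[i],
                            unplaced[i]);
  return out;
}
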