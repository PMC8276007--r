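// MinHash bottom-sketches over canonical k-mers, and a scanner for
// CRISPR-like arrays (exact tandem repeat copies separated by spacers).

#include <Rcpp.h>
#include <vector>
#include <set>
#include <string>
#include <cstdint>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

static inline int nt2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// splitmix64 finalizer
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D9ECA9AAC582D3ULL;
  return x ^ (x >> 31);
}

// Bottom `size` distinct hash minima over canonical k-mers (lexicographic
// min of k-mer and reverse complement via 2-bit codes).  Hashes truncated
// to 53 bits so they remain exact in doubles.  size <= 0 keeps everything
// (the exact hashed k-mer set).
// [[Rcpp::export(name = ".minhash_sketch_cpp")]]
NumericVector minhash_sketch_cpp(std::string seq, int k, int size,
                                 double hash_seed) {
  if (k < 1 || k > 26) stop("k must be in 1..26");
  int n = seq.size();
  uint64_t fwd = 0, rev = 0;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int shift = 2 * (k - 1);
  int run = 0;
  uint64_t seed = (uint64_t)hash_seed;
  std::set<uint64_t> keep; // sorted, bounded
  size_t cap = size <= 0 ? SIZE_MAX : (size_t)size;
  for (int i = 0; i < n; ++i) {
    int c = nt2(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - c)) << shift);
    if (++run < k) continue;
    uint64_t canon = fwd < rev ? fwd : rev;
    uint64_t h = mix64(canon ^ mix64(seed)) >> 11; // 53 bits
    if (keep.size() < cap) keep.insert(h);
    else if (h < *keep.rbegin()) {
      keep.insert(h);
      if (keep.size() > cap) keep.erase(std::prev(keep.end()));
    }
  }
  NumericVector out(keep.size());
  int i = 0;
  for (uint64_t h : keep) out[i++] = (double)h;
  return out;
}

// Scan for arrays of >= min_repeats exact copies of a repeat word
// (repeat_min..repeat_max bp) separated by spacers of spacer_min..spacer_max
// bp.  Longer repeat words are preferred; an accepted array is consumed
// before scanning continues.  Spacers within an array must be distinct.
// [[Rcpp::export(name = ".detect_crispr_cpp")]]
List detect_crispr_cpp(std::string seq, int repeat_min, int repeat_max,
                       int spacer_min, int spacer_max, int min_repeats) {
  int n = seq.size();
  List arrays;
  const char* s = seq.c_str();
  int i = 0;
  while (i < n) {
    bool found = false;
    for (int L = repeat_max; L >= repeat_min && !found; --L) {
      if (i + L + spacer_min + L > n) continue;
      std::vector<int> starts;
      starts.push_back(i);
      int p = i;
      while (true) {
        int next = -1;
        for (int sp = spacer_min; sp <= spacer_max; ++sp) {
          int q = p + L + sp;
          if (q + L > n) break;
          if (std::memcmp(s + q, s + i, L) == 0) { next = q; break; }
        }
        if (next < 0) break;
        starts.push_back(next);
        p = next;
      }
      if ((int)starts.size() >= min_repeats) {
        // collect spacers, require mutual distinctness
        std::vector<std::string> spacers;
        bool ok = true;
        for (size_t r = 0; r + 1 < starts.size(); ++r) {
          std::string sp = seq.substr(starts[r] + L,
                                      starts[r + 1] - (starts[r] + L));
          for (const std::string& prev : spacers)
            if (prev == sp) { ok = false; break; }
          if (!ok) break;
          spacers.push_back(sp);
        }
        if (ok) {
          int begin = starts.front() + 1;            // 1-based
          int end = starts.back() + L;               // inclusive
          arrays.push_back(List::create(
            _["begin"] = begin, _["end"] = end,
            _["repeat"] = seq.substr(i, L),
            _["spacers"] = wrap(spacers)));
          i = end; // consume; continue after the array
          found = true;
        }
      }
    }
    if (!found) ++i;
  }
  return arrays;
}
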