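// Alignment kernels: ends-free protein alignment with affine gaps,
// local protein-vs-PSSM alignment, and banded local nucleotide alignment.
// Residues arrive as integer codes (proteins: 0..19 standard order, 20 = X;
// nucleotides: raw char strings, non-ACGT treated as never-matching).

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <cstring>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const double NEG_INF = -1e30;

struct PairAln {
  double score;
  int matches, columns;
  int a_begin, a_end, b_begin, b_end; // 1-based, 0 if nothing aligned
  int i_start, j_start;               // residues consumed before path start
  int i_stop, j_stop;                 // last residues consumed by the path
  std::vector<unsigned char> steps;   // forward order: 1 diag, 2 up(a), 3 left(b)
};

// Global (Needleman-Wunsch) alignment of coded sequences a, b under a
// substitution matrix, affine gap cost open + ext * len, terminal gaps
// penalized.  Identity is counted over path columns between the first and
// last aligned residue pair (terminal gap runs are excluded).
static PairAln aa_overlap_align(const int* a, int m, const int* b, int n,
                                const NumericMatrix& sub,
                                double gap_open, double gap_ext) {
  // state matrices, (m+1) x (n+1)
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF); // gap in b (consume a)
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF); // gap in a (consume b)
  std::vector<unsigned char> tb((m + 1) * (n + 1), 0);   // traceback for M: 1 from M,2 from Ix,3 from Iy, 4 border
  std::vector<unsigned char> tx((m + 1) * (n + 1), 0);   // Ix: 1 open (from M), 2 extend
  std::vector<unsigned char> ty((m + 1) * (n + 1), 0);
  const int W = n + 1;
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= n; ++j) Iy[at(0, j)] = -(gap_open + gap_ext * j);
  for (int i = 1; i <= m; ++i) Ix[at(i, 0)] = -(gap_open + gap_ext * i);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // Ix: consume a_i against gap
      double open = M[at(i - 1, j)] - (gap_open + gap_ext);
      double ext  = Ix[at(i - 1, j)] - gap_ext;
      if (open >= ext) { Ix[at(i, j)] = open; tx[at(i, j)] = 1; }
      else             { Ix[at(i, j)] = ext;  tx[at(i, j)] = 2; }
      // Iy: consume b_j against gap
      open = M[at(i, j - 1)] - (gap_open + gap_ext);
      ext  = Iy[at(i, j - 1)] - gap_ext;
      if (open >= ext) { Iy[at(i, j)] = open; ty[at(i, j)] = 1; }
      else             { Iy[at(i, j)] = ext;  ty[at(i, j)] = 2; }
      // M: align a_i with b_j
      double best = M[at(i - 1, j - 1)]; unsigned char src = 1;
      if (Ix[at(i - 1, j - 1)] > best) { best = Ix[at(i - 1, j - 1)]; src = 2; }
      if (Iy[at(i - 1, j - 1)] > best) { best = Iy[at(i - 1, j - 1)]; src = 3; }
      M[at(i, j)] = best + sub(a[i - 1], b[j - 1]);
      tb[at(i, j)] = src;
    }
  }

  // global: best state at (m, n); terminal gap chains are walked down to
  // the last aligned-pair cell before the core traceback starts
  double best = M[at(m, n)]; int bstate = 1;
  if (Ix[at(m, n)] > best) { best = Ix[at(m, n)]; bstate = 2; }
  if (Iy[at(m, n)] > best) { best = Iy[at(m, n)]; bstate = 3; }

  PairAln res; res.score = best;
  res.matches = 0; res.columns = 0;
  res.a_begin = res.a_end = res.b_begin = res.b_end = 0;

  // traceback
  int i = m, j = n, state = bstate;
  std::vector<unsigned char> steps; // 1 diag, 2 up, 3 left (reverse order)
  std::vector<int> diag_i, diag_j;
  while (i > 0 && j > 0) {
    if (state == 1) {
      unsigned char src = tb[at(i, j)];
      steps.push_back(1); diag_i.push_back(i); diag_j.push_back(j);
      i--; j--; state = src;
      if (i == 0 || j == 0) break;
    } else if (state == 2) {
      unsigned char src = tx[at(i, j)];
      steps.push_back(2);
      i--; state = (src == 1) ? 1 : 2;
    } else {
      unsigned char src = ty[at(i, j)];
      steps.push_back(3);
      j--; state = (src == 1) ? 1 : 3;
    }
  }
  if (!diag_i.empty()) {
    res.a_begin = diag_i.back(); res.a_end = diag_i.front();
    res.b_begin = diag_j.back(); res.b_end = diag_j.front();
    // steps is reversed; trim leading/trailing gap steps outside the core
    int first = -1, last = -1;
    for (int s = 0; s < (int)steps.size(); ++s) {
      if (steps[s] == 1) { if (last < 0) last = s; first = s; }
    }
    for (int s = first; s >= last; --s) {
      res.columns++;
    }
    // count matches over diagonal steps
    for (size_t s = 0; s < diag_i.size(); ++s) {
      int ai = diag_i[s], bj2 = diag_j[s];
      if (a[ai - 1] == b[bj2 - 1] && a[ai - 1] != 20) res.matches++;
    }
  }
  res.i_start = i; res.j_start = j;
  res.i_stop = m; res.j_stop = n;
  res.steps.assign(steps.rbegin(), steps.rend());
  return res;
}

// [[Rcpp::export(name = ".aa_align_pair_cpp")]]
List aa_align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                       double gap_open, double gap_ext) {
  PairAln r = aa_overlap_align(INTEGER(a), a.size(), INTEGER(b), b.size(),
                               sub, gap_open, gap_ext);
  return List::create(_["score"] = r.score, _["matches"] = r.matches,
                      _["columns"] = r.columns,
                      _["a_begin"] = r.a_begin, _["a_end"] = r.a_end,
                      _["b_begin"] = r.b_begin, _["b_end"] = r.b_end,
                      _["a_start"] = r.i_start, _["b_start"] = r.j_start,
                      _["a_stop"] = r.i_stop, _["b_stop"] = r.j_stop,
                      _["steps"] = IntegerVector(r.steps.begin(), r.steps.end()));
}

// Align one query against many references; optional shared word prefilter
// (w > 0): references sharing no exact length-w residue word with the query
// are skipped (row of NA).  Rows: score, identity, cov_q, cov_r.
// [[Rcpp::export(name = ".aa_align_many_cpp")]]
NumericMatrix aa_align_many_cpp(IntegerVector q, List refs, NumericMatrix sub,
                                double gap_open, double gap_ext, int w) {
  int nref = refs.size();
  NumericMatrix out(nref, 4);
  colnames(out) = CharacterVector::create("score", "identity", "cov_q", "cov_r");
  std::unordered_set<uint64_t> words;
  int m = q.size();
  if (w > 0 && m >= w) {
    for (int i = 0; i + w <= m; ++i) {
      uint64_t h = 0;
      for (int s = 0; s < w; ++s) h = h * 21u + (uint64_t)q[i + s];
      words.insert(h);
    }
  }
  for (int r = 0; r < nref; ++r) {
    IntegerVector ref = refs[r];
    int n = ref.size();
    if (w > 0 && m >= w && n >= w) {
      bool hit = false;
      for (int i = 0; i + w <= n && !hit; ++i) {
        uint64_t h = 0;
        for (int s = 0; s < w; ++s) h = h * 21u + (uint64_t)ref[i + s];
        if (words.count(h)) hit = true;
      }
      if (!hit) {
        out(r, 0) = NA_REAL; out(r, 1) = NA_REAL;
        out(r, 2) = NA_REAL; out(r, 3) = NA_REAL;
        continue;
      }
    }
    PairAln a = aa_overlap_align(INTEGER(q), m, INTEGER(ref), n, sub,
                                 gap_open, gap_ext);
    out(r, 0) = a.score;
    out(r, 1) = a.columns > 0 ? (double)a.matches / a.columns : 0.0;
    out(r, 2) = a.a_end > 0 ? (double)(a.a_end - a.a_begin + 1) / m : 0.0;
    out(r, 3) = a.b_end > 0 ? (double)(a.b_end - a.b_begin + 1) / n : 0.0;
  }
  return out;
}

// Local (Smith-Waterman) alignment of a coded protein against a PSSM
// (L columns x 21 residue codes), affine gaps, scores in the PSSM's units.
// [[Rcpp::export(name = ".pssm_local_cpp")]]
List pssm_local_cpp(IntegerVector prot, NumericMatrix pssm,
                    double gap_open, double gap_ext) {
  int m = prot.size();
  int n = pssm.nrow();
  std::vector<double> M((m + 1) * (n + 1), 0.0);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF);
  std::vector<unsigned char> tb((m + 1) * (n + 1), 0); // 0 stop, 1 M, 2 Ix, 3 Iy
  std::vector<unsigned char> tx((m + 1) * (n + 1), 0);
  std::vector<unsigned char> ty((m + 1) * (n + 1), 0);
  const int W = n + 1;
  auto at = [W](int i, int j) { return i * W + j; };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double open = M[at(i - 1, j)] - (gap_open + gap_ext);
      double ext  = Ix[at(i - 1, j)] - gap_ext;
      if (open >= ext) { Ix[at(i, j)] = open; tx[at(i, j)] = 1; }
      else             { Ix[at(i, j)] = ext;  tx[at(i, j)] = 2; }
      open = M[at(i, j - 1)] - (gap_open + gap_ext);
      ext  = Iy[at(i, j - 1)] - gap_ext;
      if (open >= ext) { Iy[at(i, j)] = open; ty[at(i, j)] = 1; }
      else             { Iy[at(i, j)] = ext;  ty[at(i, j)] = 2; }
      double prev = M[at(i - 1, j - 1)]; unsigned char src = 1;
      if (Ix[at(i - 1, j - 1)] > prev) { prev = Ix[at(i - 1, j - 1)]; src = 2; }
      if (Iy[at(i - 1, j - 1)] > prev) { prev = Iy[at(i - 1, j - 1)]; src = 3; }
      double val = prev + pssm(j - 1, prot[i - 1]);
      if (val < 0) { val = pssm(j - 1, prot[i - 1]); src = 0; }
      if (val < 0) { M[at(i, j)] = 0; tb[at(i, j)] = 0; }
      else { M[at(i, j)] = val; tb[at(i, j)] = src == 0 ? 4 : src; } // 4 = fresh start
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  int qb = 0, qe = 0, tb1 = 0, te = 0;
  if (best > 0) {
    qe = bi; te = bj;
    int i = bi, j = bj, state = 1;
    while (i > 0 && j > 0) {
      if (state == 1) {
        unsigned char src = tb[at(i, j)];
        qb = i; tb1 = j;
        i--; j--;
        if (src == 4 || src == 0) break;
        state = src;
      } else if (state == 2) {
        unsigned char src = tx[at(i, j)];
        i--; state = (src == 1) ? 1 : 2;
      } else {
        unsigned char src = ty[at(i, j)];
        j--; state = (src == 1) ? 1 : 3;
      }
    }
  }
  return List::create(_["score"] = best, _["q_begin"] = qb, _["q_end"] = qe,
                      _["t_begin"] = tb1, _["t_end"] = te);
}

// ---------- nucleotide helpers ----------

static inline int nt_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return 4;
  }
}

// Exact shared w-mer positions between a and b (1-based start positions).
// w <= 31. k-mers containing non-ACGT are skipped. Output capped.
// [[Rcpp::export(name = ".shared_kmers_cpp")]]
IntegerMatrix shared_kmers_cpp(std::string a, std::string b, int w,
                               int max_hits = 200000) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  int na = a.size(), nb = b.size();
  uint64_t key = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;
  for (int i = 0; i < na; ++i) {
    int c = nt_code(a[i]);
    if (c == 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= w) idx[key].push_back(i - w + 2); // 1-based start
  }
  std::vector<int> pa, pb;
  key = 0; run = 0;
  for (int j = 0; j < nb; ++j) {
    int c = nt_code(b[j]);
    if (c == 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= w) {
      auto it = idx.find(key);
      if (it != idx.end()) {
        for (int p : it->second) {
          pa.push_back(p); pb.push_back(j - w + 2);
          if ((int)pa.size() >= max_hits) goto done;
        }
      }
    }
  }
done:
  IntegerMatrix out(pa.size(), 2);
  for (size_t i = 0; i < pa.size(); ++i) { out(i, 0) = pa[i]; out(i, 1) = pb[i]; }
  colnames(out) = CharacterVector::create("pos_a", "pos_b");
  return out;
}

// Banded local (Smith-Waterman) nucleotide alignment restricted to
// diagonals d = j - i in [diag_lo, diag_hi].  Linear match/mismatch
// scoring, affine gaps.  Returns the best local alignment's statistics.
// [[Rcpp::export(name = ".banded_local_nt_cpp")]]
List banded_local_nt_cpp(std::string a, std::string b,
                         int diag_lo, int diag_hi,
                         double match, double mismatch,
                         double gap_open, double gap_ext) {
  int m = a.size(), n = b.size();
  int W = diag_hi - diag_lo + 1;
  if (W < 1) stop("empty band");
  if ((double)(m + 1) * W > 6e7) stop("band too large");
  std::vector<double> M((m + 1) * W, 0.0);
  std::vector<double> Ix((m + 1) * W, NEG_INF);
  std::vector<double> Iy((m + 1) * W, NEG_INF);
  std::vector<unsigned char> tb((m + 1) * W, 0);
  std::vector<unsigned char> tx((m + 1) * W, 0);
  std::vector<unsigned char> ty((m + 1) * W, 0);
  auto at = [W, diag_lo](int i, int d) { return i * W + (d - diag_lo); };
  double best = 0.0; int bi = 0, bd = 0;
  for (int i = 1; i <= m; ++i) {
    for (int d = diag_lo; d <= diag_hi; ++d) {
      int j = i + d;
      if (j < 1 || j > n) continue;
      // Ix: consume a_i (predecessor row i-1, diagonal d+1)
      double vx = NEG_INF; unsigned char sx = 0;
      if (d + 1 <= diag_hi && (i - 1) + (d + 1) >= 0 && (i - 1) + (d + 1) <= n) {
        double open = M[at(i - 1, d + 1)] - (gap_open + gap_ext);
        double ext  = Ix[at(i - 1, d + 1)] - gap_ext;
        if (open >= ext) { vx = open; sx = 1; } else { vx = ext; sx = 2; }
      }
      Ix[at(i, d)] = vx; tx[at(i, d)] = sx;
      // Iy: consume b_j (same row, diagonal d-1)
      double vy = NEG_INF; unsigned char sy = 0;
      if (d - 1 >= diag_lo && i + (d - 1) >= 0 && i + (d - 1) <= n) {
        double open = M[at(i, d - 1)] - (gap_open + gap_ext);
        double ext  = Iy[at(i, d - 1)] - gap_ext;
        if (open >= ext) { vy = open; sy = 1; } else { vy = ext; sy = 2; }
      }
      Iy[at(i, d)] = vy; ty[at(i, d)] = sy;
      // M: diagonal predecessor (i-1, same d)
      double prev = 0.0; unsigned char src = 4; // fresh start
      if ((i - 1) + d >= 0 && (i - 1) + d <= n) {
        if (M[at(i - 1, d)] > prev) { prev = M[at(i - 1, d)]; src = 1; }
        if (Ix[at(i - 1, d)] > prev) { prev = Ix[at(i - 1, d)]; src = 2; }
        if (Iy[at(i - 1, d)] > prev) { prev = Iy[at(i - 1, d)]; src = 3; }
      }
      int ca = nt_code(a[i - 1]), cb = nt_code(b[j - 1]);
      double s = (ca != 4 && ca == cb) ? match : mismatch;
      double val = prev + s;
      if (val < 0) { M[at(i, d)] = 0.0; tb[at(i, d)] = 0; }
      else { M[at(i, d)] = val; tb[at(i, d)] = src; }
      if (M[at(i, d)] > best) { best = M[at(i, d)]; bi = i; bd = d; }
    }
  }
  int matches = 0, mismatches = 0, gapcols = 0, columns = 0;
  int a_begin = 0, a_end = 0, b_begin = 0, b_end = 0;
  if (best > 0) {
    int i = bi, d = bd, state = 1;
    a_end = bi; b_end = bi + bd;
    while (i > 0) {
      int j = i + d;
      if (j <= 0) break;
      if (state == 1) {
        unsigned char src = tb[at(i, d)];
        int ca = nt_code(a[i - 1]), cb = nt_code(b[j - 1]);
        if (ca != 4 && ca == cb) matches++; else mismatches++;
        columns++;
        a_begin = i; b_begin = j;
        i--; // same d
        if (src == 4 || src == 0) break;
        state = src;
      } else if (state == 2) {
        unsigned char src = tx[at(i, d)];
        gapcols++; columns++;
        i--; d = d + 1;
        state = (src == 1) ? 1 : 2;
      } else {
        unsigned char src = ty[at(i, d)];
        gapcols++; columns++;
        d = d - 1;
        state = (src == 1) ? 1 : 3;
      }
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["mismatches"] = mismatches, _["gap_columns"] = gapcols,
                      _["columns"] = columns,
                      _["a_begin"] = a_begin, _["a_end"] = a_end,
                      _["b_begin"] = b_begin, _["b_end"] = b_end);
}
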