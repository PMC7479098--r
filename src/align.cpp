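#include <Rcpp.h>
#include <climits>
#include <cstring>
using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch) alignment.
// Scoring: match +1, mismatch -1; a gap of length k costs gap_open + k*gap_ext.
// Three-state DP (M = aligned pair, X = gap in b i.e. consume a, Y = gap in a).
// Tie-breaks are fixed: at every choice the preference order is M > X > Y, so the
// traceback (and hence the identity value) is deterministic and reproducible by an
// independent implementation of the same recurrence.
//
// Storage is band-compressed: row i holds columns j in [i-w, i+w] at offset
// j-i+w, so the diagonal/up/left predecessors sit at constant offsets (0,+1,-1)
// in the previous/current row. With w >= max(n,m) this is the full DP.

static const int NEG = INT_MIN / 4;

struct Aln {
  int score;
  int matches;
  int columns; // alignment columns with terminal-gap runs excluded
  std::string a, b;
};

static inline int max3(int m, int x, int y, int &which) {
  // preference M > X > Y on ties
  int best = m; which = 0;
  if (x > best) { best = x; which = 1; }
  if (y > best) { best = y; which = 2; }
  return best;
}

static Aln nw_affine(const std::string &a, const std::string &b,
                     int band, int match, int mismatch,
                     int gap_open, int gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  int w = (band <= 0) ? std::max(n, m) : band;
  w = std::max(w, std::abs(n - m) + 1);
  w = std::min(w, std::max(n, m));
  const int W = 2 * w + 1;

  std::vector<int> M((size_t)(n + 1) * W, NEG), X(M), Y(M);
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 0), tX(tM), tY(tM);
  auto off = [w](int i, int j) { return j - i + w; };

  M[off(0, 0)] = 0;
  for (int i = 1; i <= n && i <= w; ++i) {
    X[(size_t)i * W + off(i, 0)] = -(gap_open + i * gap_ext);
    tX[(size_t)i * W + off(i, 0)] = 1;
  }
  for (int j = 1; j <= m && j <= w; ++j) {
    Y[(size_t)0 * W + off(0, j)] = -(gap_open + j * gap_ext);
    tY[(size_t)0 * W + off(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, prev = (size_t)(i - 1) * W;
    int jlo = std::max(1, i - w), jhi = std::min(m, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      const int c = off(i, j);        // this row
      const int cd = c;               // (i-1, j-1): same offset, prev row
      const int cu = c + 1;           // (i-1, j): offset+1, prev row
      const int cl = c - 1;           // (i, j-1): offset-1, this row
      int which;
      // M: diagonal
      if (cd >= 0 && cd < W) {
        int best = max3(M[prev + cd], X[prev + cd], Y[prev + cd], which);
        if (best > NEG / 2) {
          M[row + c] = best + ((a[i - 1] == b[j - 1]) ? match : mismatch);
          tM[row + c] = (unsigned char)which;
        }
      }
      // X: consume a[i-1] (gap in b)
      if (cu < W) {
        int fm = (M[prev + cu] > NEG / 2) ? M[prev + cu] - (gap_open + gap_ext) : NEG;
        int fx = (X[prev + cu] > NEG / 2) ? X[prev + cu] - gap_ext : NEG;
        int fy = (Y[prev + cu] > NEG / 2) ? Y[prev + cu] - (gap_open + gap_ext) : NEG;
        int best = max3(fm, fx, fy, which);
        if (best > NEG / 2) { X[row + c] = best; tX[row + c] = (unsigned char)which; }
      }
      // Y: consume b[j-1] (gap in a)
      if (cl >= 0) {
        int fm = (M[row + cl] > NEG / 2) ? M[row + cl] - (gap_open + gap_ext) : NEG;
        int fx = (X[row + cl] > NEG / 2) ? X[row + cl] - (gap_open + gap_ext) : NEG;
        int fy = (Y[row + cl] > NEG / 2) ? Y[row + cl] - gap_ext : NEG;
        int best = max3(fm, fx, fy, which);
        if (best > NEG / 2) { Y[row + c] = best; tY[row + c] = (unsigned char)which; }
      }
    }
  }

  const size_t end = (size_t)n * W + off(n, m);
  int state;
  int score = max3(M[end], X[end], Y[end], state);

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + off(i, j);
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = tX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = tY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // identity: matches / columns, terminal gap columns excluded
  int L = (int)ra.size();
  int first = 0, last = L - 1;
  while (first < L && (ra[first] == '-' || rb[first] == '-')) ++first;
  while (last >= 0 && (ra[last] == '-' || rb[last] == '-')) --last;
  int matches = 0, columns = 0;
  for (int k = first; k <= last; ++k) {
    ++columns;
    if (ra[k] == rb[k]) ++matches;
  }
  Aln out;
  out.score = score; out.matches = matches; out.columns = columns;
  out.a = ra; out.b = rb;
  return out;
}

// [[Rcpp::export(name = ".cpp_nw_align")]]
List cpp_nw_align(std::string a, std::string b, int band = -1,
                  int match = 1, int mismatch = -1,
                  int gap_open = 2, int gap_ext = 1) {
  Aln r = nw_affine(a, b, band, match, mismatch, gap_open, gap_ext);
  double id = (r.columns > 0) ? (double)r.matches / (double)r.columns : NA_REAL;
  return List::create(_["score"] = r.score, _["matches"] = r.matches,
                      _["columns"] = r.columns, _["identity"] = id,
                      _["aligned_a"] = r.a, _["aligned_b"] = r.b);
}

// [[Rcpp::export(name = ".cpp_hamming")]]
IntegerVector cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming distance requires equal lengths");
  int d = 0;
  for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++d;
  return IntegerVector::create(d, (int)a.size());
}

// Pairwise identity matrix for equal-length ungapped sequences (1 - hamming/L).
// [[Rcpp::export(name = ".cpp_hamming_identity_matrix")]]
NumericMatrix cpp_hamming_identity_matrix(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      if (s[i].size() != s[j].size()) stop("sequences must have equal length");
      int d = 0; const char *p = s[i].data(), *q = s[j].data();
      for (size_t k = 0; k < s[i].size(); ++k) if (p[k] != q[k]) ++d;
      double id = 1.0 - (double)d / (double)s[i].size();
      out(i, j) = id; out(j, i) = id;
    }
  }
  return out;
}

// Greedy centroid clustering over sequences already sorted by decreasing
// multiplicity (ties broken upstream). A sequence joins the FIRST centroid, in
// founding order, with identity >= threshold; otherwise it founds a new centroid.
// Equal-length pairs use the gapless (hamming) identity, with a DP confirmation
// when the gapless value falls within `slack` below the threshold; unequal-length
// pairs always use the banded DP.
// [[Rcpp::export(name = ".cpp_greedy_cluster")]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 double slack = 0.02, int band = 32) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<int> centroids; centroids.reserve(256);
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    int hit = -1;
    for (size_t ci = 0; ci < centroids.size(); ++ci) {
      const std::string &c = s[centroids[ci]];
      double id;
      if (c.size() == s[i].size()) {
        int d = 0; const char *p = c.data(), *q = s[i].data();
        for (size_t k = 0; k < c.size(); ++k) if (p[k] != q[k]) ++d;
        id = 1.0 - (double)d / (double)c.size();
        if (id < threshold && id >= threshold - slack) {
          Aln r = nw_affine(c, s[i], band, 1, -1, 2, 1);
          id = (r.columns > 0) ? (double)r.matches / (double)r.columns : 0.0;
        }
      } else {
        Aln r = nw_affine(c, s[i], band, 1, -1, 2, 1);
        id = (r.columns > 0) ? (double)r.matches / (double)r.columns : 0.0;
      }
      if (id >= threshold) { hit = (int)ci; break; }
    }
    if (hit < 0) {
      centroids.push_back(i);
      hit = (int)centroids.size() - 1;
    }
    assign[i] = hit + 1; // 1-based centroid index in founding order
  }
  return assign;
}

// Reference-based bimera scan. All reads and references must share one length L.
// For each read: best_single = max over references of gapless identity;
// best_two = max over breakpoints on a `grid`-nt grid and reference pairs (A,B) of
// (prefix matches to A + suffix matches to B)/L.
// [[Rcpp::export(name = ".cpp_chimera_scan")]]
NumericMatrix cpp_chimera_scan(CharacterVector reads, CharacterVector refs,
                               int grid = 50) {
  int nr = reads.size(), nf = refs.size();
  if (nf < 1) stop("references must be non-empty");
  std::vector<std::string> R(nf);
  for (int i = 0; i < nf; ++i) R[i] = as<std::string>(refs[i]);
  size_t L = R[0].size();
  for (int i = 1; i < nf; ++i)
    if (R[i].size() != L) stop("references must have equal length");

  std::vector<int> cuts;
  for (int b = grid; b < (int)L; b += grid) cuts.push_back(b);
  int nc = (int)cuts.size();

  NumericMatrix out(nr, 2);
  std::vector<int> cum((size_t)nf * (nc + 1));
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    if (rd.size() != L) stop("read length differs from reference length");
    for (int f = 0; f < nf; ++f) {
      const char *p = R[f].data(), *q = rd.data();
      int mcount = 0, ci = 0;
      for (size_t k = 0; k < L; ++k) {
        if (p[k] == q[k]) ++mcount;
        if (ci < nc && (int)(k + 1) == cuts[ci]) {
          cum[(size_t)f * (nc + 1) + ci] = mcount;
          ++ci;
        }
      }
      cum[(size_t)f * (nc + 1) + nc] = mcount;
    }
    int best_single = 0;
    for (int f = 0; f < nf; ++f)
      best_single = std::max(best_single, cum[(size_t)f * (nc + 1) + nc]);
    int best_two = 0;
    for (int b = 0; b < nc; ++b) {
      int bestA = 0, bestB = 0;
      for (int f = 0; f < nf; ++f) {
        int pre = cum[(size_t)f * (nc + 1) + b];
        int suf = cum[(size_t)f * (nc + 1) + nc] - pre;
        bestA = std::max(bestA, pre);
        bestB = std::max(bestB, suf);
      }
      best_two = std::max(best_two, bestA + bestB);
    }
    out(r, 0) = (double)best_single / (double)L;
    out(r, 1) = (nc > 0) ? (double)best_two / (double)L : (double)best_single / (double)L;
  }
  return out;
}

// Per-base substitution errors at `rate`, using R's RNG (seed-deterministic).
// [[Rcpp::export(name = ".cpp_mutate_seqs")]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t k = 0; k < s.size(); ++k) {
      if (unif_rand() < rate) {
        char cur = s[k];
        char nb = cur;
        while (nb == cur) nb = bases[(int)(unif_rand() * 4) & 3];
        s[k] = nb;
      }
    }
    out[i] = s;
  }
  return out;
}

// Mismatch fractions over masked columns of an equal-length (aligned) set.
// Positions count when the mask is TRUE and both residues are in {A,C,G,T}.
// [[Rcpp::export(name = ".cpp_masked_mismatch")]]
List cpp_masked_mismatch(CharacterVector seqs, LogicalVector mask) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  size_t L = s.empty() ? 0 : s[0].size();
  if ((size_t)mask.size() != L) stop("mask length must equal alignment width");
  for (int i = 1; i < n; ++i)
    if (s[i].size() != L) stop("aligned rows must have equal length");
  std::vector<int> keep;
  for (size_t k = 0; k < L; ++k) if (mask[k]) keep.push_back((int)k);
  NumericMatrix p(n, n);
  IntegerMatrix shared(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      int mm = 0, valid = 0;
      const char *a = s[i].data(), *b = s[j].data();
      for (size_t t = 0; t < keep.size(); ++t) {
        char x = a[keep[t]], y = b[keep[t]];
        bool vx = (x == 'A' || x == 'C' || x == 'G' || x == 'T');
        bool vy = (y == 'A' || y == 'C' || y == 'G' || y == 'T');
        if (vx && vy) { ++valid; if (x != y) ++mm; }
      }
      double frac = (valid > 0) ? (double)mm / (double)valid : NA_REAL;
      p(i, j) = frac; p(j, i) = frac;
      shared(i, j) = valid; shared(j, i) = valid;
    }
  }
  return List::create(_["p"] = p, _["shared"] = shared);
}
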