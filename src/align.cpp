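#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap pairwise aligners over A-Z alphabets. The substitution matrix is
// a 26x26 integer lookup indexed by (letter - 'A'); callers are responsible
// for folding non-standard residues into it. Gap convention: a gap of length
// L costs gap_open + L * gap_ext (first gapped position pays open + ext).

static const int NEG = INT_MIN / 4;

static inline int subscore(const IntegerMatrix &sub, char a, char b) {
  return sub(a - 'A', b - 'A');
}

// Smith-Waterman local alignment score with optional traceback for the
// aligned spans. Returns 1-based inclusive spans; zeros when the best score
// is 0 (no positive-scoring cell).
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  int best = 0, bi = 0, bj = 0;
  const int W = m + 1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      int e = std::max(H[idx - 1] - (gap_open + gap_ext), E[idx - 1] - gap_ext);
      int f = std::max(H[idx - W] - (gap_open + gap_ext), F[idx - W] - gap_ext);
      int d = H[idx - W - 1] + subscore(sub, a[i - 1], b[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[idx] = e;
      F[idx] = f;
      H[idx] = h;
      if (h > best) {
        best = h;
        bi = i;
        bj = j;
      }
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  // traceback from the best cell until H hits 0
  int i = bi, j = bj;
  char state = 'H';
  int a_end = bi, b_end = bj, a_start = bi, b_start = bj;
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 'H') {
      if (H[idx] == 0) break;
      int d = H[idx - W - 1] + subscore(sub, a[i - 1], b[j - 1]);
      if (H[idx] == d) {
        a_start = i;
        b_start = j;
        --i;
        --j;
      } else if (H[idx] == E[idx]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      const int idx2 = i * W + j;
      if (E[idx2] == H[idx2 - 1] - (gap_open + gap_ext)) {
        state = 'H';
        b_start = j; // column consumed from b
        --j;
      } else {
        --j;
      }
    } else { // F
      const int idx2 = i * W + j;
      if (F[idx2] == H[idx2 - W] - (gap_open + gap_ext)) {
        state = 'H';
        a_start = i;
        --i;
      } else {
        --i;
      }
    }
  }
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end);
}

static int sw_score_only(const std::string &a, const std::string &b,
                         const IntegerMatrix &sub, int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Eprev(m + 1, NEG),
      Fprev(m + 1, NEG), Ecur(m + 1, NEG), Fcur(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0;
    Ecur[0] = NEG;
    Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int e = std::max(Hcur[j - 1] - (gap_open + gap_ext), Ecur[j - 1] - gap_ext);
      int f = std::max(Hprev[j] - (gap_open + gap_ext), Fprev[j] - gap_ext);
      int d = Hprev[j - 1] + subscore(sub, a[i - 1], b[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      Ecur[j] = e;
      Fcur[j] = f;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

// Vectorized Smith-Waterman scores for paired sequence vectors.
// [[Rcpp::export]]
IntegerVector sw_scores_cpp(CharacterVector a, CharacterVector b,
                            IntegerMatrix sub, int gap_open, int gap_ext) {
  const int n = a.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    out[k] = sw_score_only(as<std::string>(a[k]), as<std::string>(b[k]), sub,
                           gap_open, gap_ext);
  }
  return out;
}

// Needleman-Wunsch global alignment; returns percent-identity components
// (matches / alignment columns) under the same scoring scheme.
// [[Rcpp::export]]
List nw_identity_cpp(std::string a, std::string b, IntegerMatrix sub,
                     int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 && m == 0)
    return List::create(_["identity"] = 1.0, _["matches"] = 0,
                        _["columns"] = 0, _["score"] = 0);
  const int W = m + 1;
  std::vector<int> H((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  H[0] = 0;
  for (int j = 1; j <= m; ++j) {
    E[j] = -(gap_open + j * gap_ext);
    H[j] = E[j];
  }
  for (int i = 1; i <= n; ++i) {
    F[i * W] = -(gap_open + i * gap_ext);
    H[i * W] = F[i * W];
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      int e = std::max(H[idx - 1] - (gap_open + gap_ext), E[idx - 1] - gap_ext);
      int f = std::max(H[idx - W] - (gap_open + gap_ext), F[idx - W] - gap_ext);
      int d = H[idx - W - 1] + subscore(sub, a[i - 1], b[j - 1]);
      E[idx] = e;
      F[idx] = f;
      H[idx] = std::max(d, std::max(e, f));
    }
  }
  // traceback counting columns and identical pairs
  int i = n, j = m, matches = 0, columns = 0;
  char state = 'H';
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (state == 'H') {
      if (i > 0 && j > 0 &&
          H[idx] == H[idx - W - 1] + subscore(sub, a[i - 1], b[j - 1])) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++columns;
        --i;
        --j;
      } else if (j > 0 && H[idx] == E[idx]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      ++columns;
      if (E[idx] == H[idx - 1] - (gap_open + gap_ext)) state = 'H';
      --j;
    } else {
      ++columns;
      if (F[idx] == H[idx - W] - (gap_open + gap_ext)) state = 'H';
      --i;
    }
  }
  double ident = columns > 0 ? (double)matches / (double)columns : 1.0;
  return List::create(_["identity"] = ident, _["matches"] = matches,
                      _["columns"] = columns, _["score"] = H[n * W + m]);
}

// Greedy incremental deduplication in the caller-supplied order: each
// sequence joins the first earlier representative whose global-alignment
// identity reaches the threshold, else opens a new representative. Returns
// the 1-based representative index for every sequence. The min/max length
// ratio bound is exact (matches <= min length, columns >= max length), so
// skipping those pairs cannot change the result.
// [[Rcpp::export]]
IntegerVector dedup_assign_cpp(CharacterVector seqs, double threshold,
                               IntegerMatrix sub, int gap_open, int gap_ext) {
  const int n = seqs.size();
  IntegerVector assign(n);
  std::vector<int> reps;
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    int found = -1;
    for (size_t r = 0; r < reps.size(); ++r) {
      const std::string &sr = s[reps[r]];
      double lmin = std::min(sr.size(), s[i].size());
      double lmax = std::max(sr.size(), s[i].size());
      if (lmax == 0) { found = reps[r]; break; }
      if (lmin / lmax < threshold) continue;
      List res = nw_identity_cpp(s[i], sr, sub, gap_open, gap_ext);
      if (as<double>(res["identity"]) >= threshold) {
        found = reps[r];
        break;
      }
    }
    if (found < 0) {
      reps.push_back(i);
      assign[i] = i + 1;
    } else {
      assign[i] = found + 1;
    }
  }
  return assign;
}

// Longest stop-free run (in codons) for the two shifted forward frames and
// the three reverse-strand frames of a coding sequence; used by the
// synthetic generator's shadow-ORF sanitizer as a cheap objective.
// [[Rcpp::export]]
IntegerVector frame_maxes_cpp(std::string nt) {
  auto is_stop = [](char a, char b, char c) {
    return (a == 'T' && b == 'A' && (c == 'A' || c == 'G')) ||
           (a == 'T' && b == 'G' && c == 'A');
  };
  const int L = nt.size();
  std::string rc(L, 'N');
  for (int i = 0; i < L; ++i) {
    char ch = nt[L - 1 - i];
    rc[i] = ch == 'A' ? 'T' : ch == 'T' ? 'A' : ch == 'C' ? 'G'
            : ch == 'G' ? 'C' : 'N';
  }
  IntegerVector out(5);
  CharacterVector nm = CharacterVector::create("fwd1", "fwd2", "rev0",
                                               "rev1", "rev2");
  int oi = 0;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string &s = strand == 0 ? nt : rc;
    for (int f = 0; f < 3; ++f) {
      if (strand == 0 && f == 0) continue; // coding frame itself
      int run = 0, best = 0;
      for (int p = f; p + 2 < L; p += 3) {
        if (is_stop(s[p], s[p + 1], s[p + 2])) {
          run = 0;
        } else {
          ++run;
          if (run > best) best = run;
        }
      }
      out[oi] = best;
      ++oi;
    }
  }
  out.attr("names") = nm;
  return out;
}
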