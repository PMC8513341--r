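#include <Rcpp.h>
#include <string>
#include <vector>
#include <array>
using namespace Rcpp;

// Plant-style miRNA:target complementarity penalty. The miRNA (5'->3') is
// aligned antiparallel against the transcript site; penalties are 1 per
// mismatch, 0.5 per G:U wobble, 1 per gap, all doubled when the miRNA
// position lies in 2..13 from the miRNA 5' end. At most one gap is allowed,
// so a site of the miRNA's length is scored ungapped and sites one base
// shorter/longer are scored with exactly one gap at the best position.

enum PairKind { MATCH = 0, WOBBLE = 1, MISMATCH = 2 };

static inline int pair_kind(char m, char t) {
  if ((m == 'A' && t == 'U') || (m == 'U' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G'))
    return MATCH;
  if ((m == 'G' && t == 'U') || (m == 'U' && t == 'G')) return WOBBLE;
  return MISMATCH;
}

static inline double wmul(int pos1, int seed_lo, int seed_hi, double mult) {
  return (pos1 >= seed_lo && pos1 <= seed_hi) ? mult : 1.0;
}

// Score one miRNA against one site. `site` is the transcript subsequence
// 5'->3'; internally it is reversed so position i of the miRNA faces
// position i of the reversed site (antiparallel duplex).
// [[Rcpp::export(name = ".score_site")]]
List score_site(std::string mirna, std::string site, double mismatch_w = 1.0,
                double wobble_w = 0.5, double gap_w = 1.0, int seed_lo = 2,
                int seed_hi = 13, double seed_mult = 2.0) {
  const int L = mirna.size();
  std::string rs(site.rbegin(), site.rend());
  const int S = rs.size();
  const double INF = 1e9;

  auto pen = [&](int kind) {
    return kind == MATCH ? 0.0 : (kind == WOBBLE ? wobble_w : mismatch_w);
  };

  double best = INF;
  int best_mm = 0, best_wob = 0, best_gaps = 0;

  if (S == L) { // ungapped
    double sc = 0;
    int mm = 0, wob = 0;
    for (int i = 0; i < L; ++i) {
      int k = pair_kind(mirna[i], rs[i]);
      sc += pen(k) * wmul(i + 1, seed_lo, seed_hi, seed_mult);
      if (k == MISMATCH) ++mm;
      if (k == WOBBLE) ++wob;
    }
    best = sc;
    best_mm = mm;
    best_wob = wob;
    best_gaps = 0;
  } else if (S == L - 1 || S == L + 1) {
    // exactly one gap: in the site (S == L-1, a miRNA base bulges out) or in
    // the miRNA (S == L+1, a site base bulges out). Try every gap placement.
    bool gap_in_site = (S == L - 1);
    int K = gap_in_site ? L : L + 1; // gap positions (1-based miRNA coords)
    for (int g = 1; g <= K; ++g) {
      double sc = 0;
      int mm = 0, wob = 0;
      bool ok = true;
      int mi = 0, si = 0;
      for (int pos = 1; pos <= (gap_in_site ? L : L + 1) && ok; ++pos) {
        if (pos == g) {
          int wpos = std::min(pos, L);
          sc += gap_w * wmul(wpos, seed_lo, seed_hi, seed_mult);
          if (gap_in_site) ++mi; else ++si;
        } else {
          if (mi >= L || si >= S) { ok = false; break; }
          int k = pair_kind(mirna[mi], rs[si]);
          sc += pen(k) * wmul(mi + 1, seed_lo, seed_hi, seed_mult);
          if (k == MISMATCH) ++mm;
          if (k == WOBBLE) ++wob;
          ++mi; ++si;
        }
      }
      if (ok && sc < best) {
        best = sc;
        best_mm = mm;
        best_wob = wob;
        best_gaps = 1;
      }
    }
  } else {
    return List::create(_["score"] = NA_REAL, _["mismatches"] = NA_INTEGER,
                        _["wobbles"] = NA_INTEGER, _["gaps"] = NA_INTEGER);
  }

  return List::create(_["score"] = best, _["mismatches"] = best_mm,
                      _["wobbles"] = best_wob, _["gaps"] = best_gaps);
}

// Slide one miRNA across one transcript, scoring windows of length L-1, L,
// L+1; returns rows (start, end, score, mismatches, wobbles, gaps) for
// windows with score <= cutoff. Coordinates are 1-based inclusive.
// [[Rcpp::export(name = ".scan_one")]]
NumericMatrix scan_one(std::string mirna, std::string tx, double cutoff,
                       double mismatch_w, double wobble_w, double gap_w,
                       int seed_lo, int seed_hi, double seed_mult) {
  const int L = mirna.size();
  const int T = tx.size();
  std::vector<std::array<double, 6>> hits;
  for (int wl = L - 1; wl <= L + 1; ++wl) {
    if (wl < 1) continue;
    for (int s = 0; s + wl <= T; ++s) {
      std::string site = tx.substr(s, wl);
      List r = score_site(mirna, site, mismatch_w, wobble_w, gap_w, seed_lo,
                          seed_hi, seed_mult);
      double sc = as<double>(r["score"]);
      if (sc <= cutoff) {
        hits.push_back({(double)(s + 1), (double)(s + wl), sc,
                        (double)as<int>(r["mismatches"]),
                        (double)as<int>(r["wobbles"]),
                        (double)as<int>(r["gaps"])});
      }
    }
  }
  NumericMatrix out(hits.size(), 6);
  for (size_t i = 0; i < hits.size(); ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = hits[i][j];
  colnames(out) = CharacterVector::create("start", "end", "score",
                                          "mismatches", "wobbles", "gaps");
  return out;
}
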