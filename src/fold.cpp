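#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
#include <array>
#include <cmath>
using namespace Rcpp;

// Secondary-structure prediction by energy-minimizing dynamic programming over
// non-crossing pairings (Nussinov recursion with per-pair energies and a
// stacking bonus). Not a full nearest-neighbour thermodynamic model: loop
// entropies are ignored, which is adequate for screening stem-loops where the
// decision hinges on stem extent and composition.

static inline double pair_energy(char a, char b, double e_gc, double e_au,
                                 double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return 1.0; // sentinel: not pairable (positive, never chosen)
}

static inline bool pairable(char a, char b, double e_gc, double e_au,
                            double e_gu) {
  return pair_energy(a, b, e_gc, e_au, e_gu) < 0.0;
}

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, double e_gc = -3.0, double e_au = -2.0,
             double e_gu = -1.0, double stack_bonus = -1.0, int min_loop = 3) {
  const int n = seq.size();
  const double INF = 1e9;
  // non-ACGU symbols are forced unpaired (pair_energy returns +1 for them)
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c == 'T') seq[i] = 'U';
  }
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);

  std::vector<double> W(n * n, 0.0), P(n * n, INF);
  // Wb[i*n+j]: 1 if P[i][j] used stacked inner pair, for traceback
  std::vector<signed char> Pst(n * n, 0);

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // P[i][j]: energy of i..j given (i,j) paired
      if (pairable(seq[i], seq[j], e_gc, e_au, e_gu) && j - i - 1 >= min_loop) {
        double e = pair_energy(seq[i], seq[j], e_gc, e_au, e_gu);
        double inner_w = W[(i + 1) * n + (j - 1)];
        double inner_p = P[(i + 1) * n + (j - 1)];
        double cand_w = e + inner_w;
        double cand_p = (inner_p < INF / 2) ? e + inner_p + stack_bonus : INF;
        if (cand_p < cand_w) {
          P[i * n + j] = cand_p;
          Pst[i * n + j] = 1;
        } else {
          P[i * n + j] = cand_w;
        }
      }
      // W[i][j]
      double best = W[i * n + (j - 1)]; // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double pkj = P[k * n + j];
        if (pkj >= INF / 2) continue;
        double left = (k > i) ? W[i * n + (k - 1)] : 0.0;
        double cand = left + pkj;
        if (cand < best) best = cand;
      }
      W[i * n + j] = best;
    }
  }

  // traceback
  std::string db(n, '.');
  std::stack<std::array<int, 3>> st; // {i, j, state}: 0 = W, 1 = P
  st.push({0, n - 1, 0});
  const double EPS = 1e-9;
  while (!st.empty()) {
    auto t = st.top();
    st.pop();
    int i = t[0], j = t[1], state = t[2];
    if (i > j) continue;
    if (state == 1) {
      db[i] = '(';
      db[j] = ')';
      if (j - i - 1 < min_loop) continue;
      if (Pst[i * n + j]) {
        st.push({i + 1, j - 1, 1});
      } else {
        st.push({i + 1, j - 1, 0});
      }
      continue;
    }
    if (j - i + 1 < min_loop + 2) continue;
    double w = W[i * n + j];
    if (w >= -EPS) continue; // no pairs
    if (std::abs(w - W[i * n + (j - 1)]) < EPS) {
      st.push({i, j - 1, 0});
      continue;
    }
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      double pkj = P[k * n + j];
      if (pkj >= INF / 2) continue;
      double left = (k > i) ? W[i * n + (k - 1)] : 0.0;
      if (std::abs(w - (left + pkj)) < EPS) {
        if (k > i) st.push({i, k - 1, 0});
        st.push({k, j, 1});
        done = true;
      }
    }
    if (!done) continue; // numerically unreachable; leave unpaired
  }

  double mfe = W[0 * n + (n - 1)];
  if (mfe > 0) mfe = 0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
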