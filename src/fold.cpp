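#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum free energy folding under a simplified nearest-neighbor model.
// Pairs: Watson-Crick + G:U wobble. Energy terms: stacking of adjacent
// pairs, hairpin/bulge/internal loop initiation (tabulated + log
// extrapolation, precomputed in R and passed in), affine multiloop
// (close + per-branch + per-unpaired). No dangles, no terminal-AU terms.
// Internal/bulge loops are capped at max_loop total unpaired bases.

static const double INF = 1e9;

// bases: A=0, C=1, G=2, U=3; pair codes 1..6: CG GC GU UG AU UA
static inline int pair_code(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

struct Params {
  std::vector<double> stack;   // 6x6 row-major: stack[(p-1)*6 + (q-1)]
  std::vector<double> hairpin; // hairpin[l-1] for loop size l >= 1
  std::vector<double> bulge;
  std::vector<double> internal;
  double asym_coef, asym_max;
  double ml_close, ml_branch, ml_unpaired;
  int min_hairpin, max_loop;
};

static Params read_params(List par) {
  Params P;
  NumericMatrix st = par["stack"];
  P.stack.assign(36, 0.0);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) P.stack[i * 6 + j] = st(i, j);
  P.hairpin = as<std::vector<double> >(par["hairpin"]);
  P.bulge = as<std::vector<double> >(par["bulge"]);
  P.internal = as<std::vector<double> >(par["internal"]);
  P.asym_coef = as<double>(par["asym_coef"]);
  P.asym_max = as<double>(par["asym_max"]);
  P.ml_close = as<double>(par["ml_close"]);
  P.ml_branch = as<double>(par["ml_branch"]);
  P.ml_unpaired = as<double>(par["ml_unpaired"]);
  P.min_hairpin = as<int>(par["min_hairpin"]);
  P.max_loop = as<int>(par["max_loop"]);
  return P;
}

static inline double loop_energy(const Params& P, int n1, int n2) {
  int sz = n1 + n2;
  if (n1 == 0 || n2 == 0) {
    if (sz < 1 || sz > (int)P.bulge.size()) return INF;
    return P.bulge[sz - 1];
  }
  if (sz < 2 || sz > (int)P.internal.size()) return INF;
  double asym = P.asym_coef * std::abs(n1 - n2);
  if (asym > P.asym_max) asym = P.asym_max;
  return P.internal[sz - 1] + asym;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, List par) {
  Params P = read_params(par);
  int n = seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = seq[i];

  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF);
  std::vector<double> W(n + 1, 0.0);
#define IX(i, j) ((size_t)(i) * n + (j))

  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int p = pair_code(s[i], s[j]);
      double v = INF;
      if (p && d - 1 >= P.min_hairpin) {
        int hp = d - 1;
        if (hp <= (int)P.hairpin.size()) v = P.hairpin[hp - 1];
        // stack / bulge / internal
        int kmax = std::min(i + P.max_loop + 1, j - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          int n1 = k - i - 1;
          int lmin = k + P.min_hairpin + 1;
          for (int l = j - 1; l >= lmin; --l) {
            int n2 = j - l - 1;
            if (n1 + n2 > P.max_loop) break;
            if (V[IX(k, l)] >= INF) continue;
            double e;
            if (n1 == 0 && n2 == 0) {
              int q = pair_code(s[k], s[l]);
              e = P.stack[(p - 1) * 6 + (q - 1)];
            } else {
              e = loop_energy(P, n1, n2);
            }
            double cand = e + V[IX(k, l)];
            if (cand < v) v = cand;
          }
        }
        // multiloop closed by (i,j): >= 2 interior branches
        for (int u = i + 1; u < j - 1; ++u) {
          double a = WM[IX(i + 1, u)], b = WM[IX(u + 1, j - 1)];
          if (a >= INF || b >= INF) continue;
          double cand = P.ml_close + P.ml_branch + a + b;
          if (cand < v) v = cand;
        }
      }
      V[IX(i, j)] = v;

      double w = INF;
      if (v < INF) w = v + P.ml_branch;
      if (d >= 1) {
        double a = WM[IX(i + 1, j)];
        if (a < INF && a + P.ml_unpaired < w) w = a + P.ml_unpaired;
        a = WM[IX(i, j - 1)];
        if (a < INF && a + P.ml_unpaired < w) w = a + P.ml_unpaired;
        for (int u = i; u < j; ++u) {
          double x = WM[IX(i, u)], y = WM[IX(u + 1, j)];
          if (x < INF && y < INF && x + y < w) w = x + y;
        }
      }
      WM[IX(i, j)] = w;
    }
  }

  // external loop: unpaired bases free
  for (int j = 0; j < n; ++j) {
    double best = (j > 0) ? W[j] : 0.0;  // W[j] holds prefix [0..j-1]
    for (int i = 0; i <= j; ++i) {
      double v = V[IX(i, j)];
      if (v >= INF) continue;
      double cand = (i > 0 ? W[i] : 0.0) + v;
      if (cand < best) best = cand;
    }
    W[j + 1] = best;
  }
  double mfe = (n > 0) ? W[n] : 0.0;

  // traceback
  std::vector<int> pt(n, 0);  // 1-based partner, 0 = unpaired
  const double EPS = 1e-7;
  struct Frame { int i, j, m; };  // m: 0=V, 1=WM
  std::vector<Frame> stk;
  {
    int j = n - 1;
    while (j >= 0) {
      if (std::abs(W[j + 1] - W[j]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j && !found; ++i) {
        double v = V[IX(i, j)];
        if (v >= INF) continue;
        if (std::abs((i > 0 ? W[i] : 0.0) + v - W[j + 1]) < EPS) {
          stk.push_back({i, j, 0});
          j = i - 1;
          found = true;
        }
      }
      if (!found) --j;  // numerical safety
    }
  }
  while (!stk.empty()) {
    Frame f = stk.back();
    stk.pop_back();
    int i = f.i, j = f.j;
    if (f.m == 0) {
      pt[i] = j + 1;
      pt[j] = i + 1;
      int p = pair_code(s[i], s[j]);
      double v = V[IX(i, j)];
      int hp = j - i - 1;
      if (hp >= P.min_hairpin && hp <= (int)P.hairpin.size() &&
          std::abs(v - P.hairpin[hp - 1]) < EPS)
        continue;
      bool found = false;
      int kmax = std::min(i + P.max_loop + 1, j - 2);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int n1 = k - i - 1;
        int lmin = k + P.min_hairpin + 1;
        for (int l = j - 1; l >= lmin; --l) {
          int n2 = j - l - 1;
          if (n1 + n2 > P.max_loop) break;
          if (V[IX(k, l)] >= INF) continue;
          double e;
          if (n1 == 0 && n2 == 0) {
            int q = pair_code(s[k], s[l]);
            e = P.stack[(p - 1) * 6 + (q - 1)];
          } else {
            e = loop_energy(P, n1, n2);
          }
          if (std::abs(e + V[IX(k, l)] - v) < EPS) {
            stk.push_back({k, l, 0});
            found = true;
            break;
          }
        }
      }
      if (found) continue;
      for (int u = i + 1; u < j - 1; ++u) {
        double a = WM[IX(i + 1, u)], b = WM[IX(u + 1, j - 1)];
        if (a >= INF || b >= INF) continue;
        if (std::abs(P.ml_close + P.ml_branch + a + b - v) < EPS) {
          stk.push_back({i + 1, u, 1});
          stk.push_back({u + 1, j - 1, 1});
          break;
        }
      }
    } else {  // WM
      double w = WM[IX(i, j)];
      if (V[IX(i, j)] < INF && std::abs(V[IX(i, j)] + P.ml_branch - w) < EPS) {
        stk.push_back({i, j, 0});
        continue;
      }
      if (i < j && WM[IX(i + 1, j)] < INF &&
          std::abs(WM[IX(i + 1, j)] + P.ml_unpaired - w) < EPS) {
        stk.push_back({i + 1, j, 1});
        continue;
      }
      if (i < j && WM[IX(i, j - 1)] < INF &&
          std::abs(WM[IX(i, j - 1)] + P.ml_unpaired - w) < EPS) {
        stk.push_back({i, j - 1, 1});
        continue;
      }
      for (int u = i; u < j; ++u) {
        double x = WM[IX(i, u)], y = WM[IX(u + 1, j)];
        if (x < INF && y < INF && std::abs(x + y - w) < EPS) {
          stk.push_back({i, u, 1});
          stk.push_back({u + 1, j, 1});
          break;
        }
      }
    }
  }
#undef IX
  return List::create(_["energy"] = (mfe < INF / 2 ? mfe : 0.0),
                      _["pt"] = IntegerVector(pt.begin(), pt.end()));
}
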