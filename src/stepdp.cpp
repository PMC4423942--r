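#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

// log(exp(a) + exp(b)) without underflow
static inline double lse(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double hi = a > b ? a : b;
  double lo = a > b ? b : a;
  return hi + log1p(std::exp(lo - hi));
}

// Grid-discretized step-function dynamic program for the lower tail of the
// permutational null of the log-rank statistic.
//
// The at-risk process is scanned left to right over the n ordered events.
// State (t, r): r group-1 members among the first t events.  The lower-tail
// joint probability P(t, r, v) = Pr(V_t <= v, r ones in first t) is a step
// function of v; it is represented by breakpoints v_i (ascending) and integer
// grid levels k_i (strictly decreasing), the represented probability at v
// being exp(k * L) for the smallest level k whose breakpoint is <= v, where
// L = log(1 - eps1) < 0.  Each step mixes the two parent functions (next
// event in group 0 / group 1) with hypergeometric-process weights, shifts
// their arguments by the per-step statistic increments when the event is
// uncensored, snaps the resulting probabilities UP to the grid, and keeps the
// smallest breakpoint per level so the function stays an over-estimate.
//
// sign = +1 runs the process for the statistic V; sign = -1 runs the mirrored
// process for -V, whose lower tail evaluated at -v is the upper tail of V.
//
// Returns list(v = breakpoints, k = levels) of the final (t = n, r = n1)
// function.  lmax caps the level index (probabilities below the grid floor
// are raised to it, which preserves the over-estimate).
// [[Rcpp::export]]
List stepdp_grid_cpp(IntegerVector cens, int n1, double L, int lmax, int sign) {
  const int n = cens.size();
  const double tol = 1e-12;
  if (n1 < 0 || n1 > n) stop("invalid n1");
  if (L >= 0) stop("grid step L must be negative");

  std::vector< std::vector<double> > curV(n1 + 1), nxtV(n1 + 1);
  std::vector< std::vector<int> > curK(n1 + 1), nxtK(n1 + 1);
  std::vector<char> curHas(n1 + 1, 0), nxtHas(n1 + 1, 0);
  curV[0].push_back(0.0);
  curK[0].push_back(0);
  curHas[0] = 1;

  std::vector<double> mv, ml;  // merged breakpoints / log-values, reused

  for (int t = 0; t < n; ++t) {
    const double atRisk = (double)(n - t);
    const int rmax = std::min(t + 1, n1);
    for (int r = 0; r <= n1; ++r) { nxtHas[r] = 0; nxtV[r].clear(); nxtK[r].clear(); }

    for (int r = 0; r <= rmax; ++r) {
      // branch A: event t+1 in group 0, parent (t, r)
      bool useA = (r <= std::min(t, n1)) && curHas[r] && ((double)(n - t - (n1 - r)) > 0.5);
      // branch B: event t+1 in group 1, parent (t, r-1)
      bool useB = (r >= 1) && curHas[r - 1];
      if (!useA && !useB) continue;

      const double wA = 1.0 - (double)(n1 - r) / atRisk;
      const double wB = (double)(n1 - r + 1) / atRisk;
      const double cv = (double)cens[t];
      const double sA = -sign * cv * (double)(n1 - r) / atRisk;
      const double sB = sign * cv * (1.0 - (double)(n1 - r + 1) / atRisk);
      const double lwA = (useA && wA > 0.0) ? std::log(wA) : R_NegInf;
      const double lwB = useB ? std::log(wB) : R_NegInf;
      if (lwA == R_NegInf) useA = false;
      if (!useA && !useB) continue;

      const std::vector<double> *aV = useA ? &curV[r] : 0;
      const std::vector<int> *aK = useA ? &curK[r] : 0;
      const std::vector<double> *bV = useB ? &curV[r - 1] : 0;
      const std::vector<int> *bK = useB ? &curK[r - 1] : 0;
      const size_t na = useA ? aV->size() : 0, nb = useB ? bV->size() : 0;

      mv.clear(); ml.clear();
      mv.reserve(na + nb); ml.reserve(na + nb);
      size_t i = 0, j = 0;
      double la = R_NegInf, lb = R_NegInf;  // running contributions
      while (i < na || j < nb) {
        const double va = (i < na) ? (*aV)[i] + sA : R_PosInf;
        const double vb = (j < nb) ? (*bV)[j] + sB : R_PosInf;
        double v;
        if (va < vb - tol) {
          v = va; la = lwA + (*aK)[i] * L; ++i;
        } else if (vb < va - tol) {
          v = vb; lb = lwB + (*bK)[j] * L; ++j;
        } else {  // coincide within tolerance: advance both
          v = va < vb ? va : vb;
          la = lwA + (*aK)[i] * L; ++i;
          lb = lwB + (*bK)[j] * L; ++j;
        }
        mv.push_back(v);
        ml.push_back(lse(la, lb));
      }

      // snap UP to the grid and keep the smallest breakpoint per level
      std::vector<double> &oV = nxtV[r];
      std::vector<int> &oK = nxtK[r];
      int lastK = INT_MAX;
      for (size_t q = 0; q < mv.size(); ++q) {
        const double lv = ml[q];
        if (lv == R_NegInf) continue;
        int k = (int)std::floor(lv / L);
        if ((double)k * L < lv) k -= 1;  // guard: grid value must be >= lv
        if (k < 0) k = 0;
        if (k > lmax) k = lmax;
        if (k < lastK) {
          if (!oV.empty() && mv[q] - oV.back() <= tol) {
            oK.back() = k;  // merge: larger probability at the earlier point
          } else {
            oV.push_back(mv[q]);
            oK.push_back(k);
          }
          lastK = k;
        }
      }
      nxtHas[r] = oV.empty() ? 0 : 1;
    }
    curV.swap(nxtV); curK.swap(nxtK); curHas.swap(nxtHas);
  }

  if (!curHas[n1]) stop("internal error: empty final state");
  return List::create(_["v"] = wrap(curV[n1]), _["k"] = wrap(curK[n1]));
}

// Draw `reps` uniformly random labelings with n1 ones and return the linear
// rank form of the log-rank statistic, V = sum of the scores at the labeled
// positions, for each draw.  Uses R's RNG (caller seeds it).
// [[Rcpp::export]]
NumericVector mc_null_stats_cpp(NumericVector scores, int n1, int reps) {
  const int n = scores.size();
  if (n1 < 0 || n1 > n) stop("invalid n1");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    double s = 0.0;
    for (int i = 0; i < n1; ++i) {  // partial Fisher-Yates
      int j = i + (int)(unif_rand() * (double)(n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
      s += scores[idx[i]];
    }
    out[rep] = s;
  }
  return out;
}
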