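#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic dynamic program over an M-line x N-graduation radial lattice.
//
// Stage cost E_i(v_i, v_{i+1}) = -g(i, v_i) when the Euclidean distance
// between consecutive picks is <= delta, else a finite "infinity" sentinel.
// The wrap pair (v_M, v_1) carries the same constraint. Distances between
// graduations on adjacent (uniformly spaced) lines depend only on the two
// radii, so feasibility is a single N x N relation shared by all pairs.
//
// closure = 0 (exact): repeat the open-chain DP once per candidate first
// point and take the best cycle — globally optimal.
// closure = 1 (two-pass): solve the chain with a free first point, fix the
// first point at its optimum, re-solve that single cycle.
//
// Tie-breaks are deterministic: smallest first point, then smallest
// predecessor index at every stage.

struct DpResult {
  std::vector<int> sel;
  double energy;
};

// One pass of the cyclic DP with v_1 fixed at f (0-based), or free if f < 0.
// g: M x N; lo/hi: per-destination contiguous feasible predecessor range
// (inclusive, 0-based; lo > hi means no feasible predecessor).
static DpResult dp_pass(const NumericMatrix &g, const std::vector<int> &lo,
                        const std::vector<int> &hi, double sentinel, int f,
                        bool wrap_constrained) {
  const int M = g.nrow(), N = g.ncol();
  std::vector<double> prev(N), cur(N);
  std::vector<int> parent((size_t)(M - 1) * N);
  const double BIG = sentinel * (M + 2.0);

  for (int j = 0; j < N; ++j) prev[j] = (f < 0 || j == f) ? 0.0 : BIG;

  for (int i = 1; i < M; ++i) {
    // transition line (i-1) -> i, stage cost uses g(i-1, j)
    double best_all = BIG; int best_all_j = 0;
    for (int j = 0; j < N; ++j)
      if (prev[j] < best_all) { best_all = prev[j]; best_all_j = j; }
    for (int k = 0; k < N; ++k) {
      double best = best_all + sentinel; // infeasible fallback
      int bj = best_all_j;
      for (int j = lo[k]; j <= hi[k]; ++j) {
        const double v = prev[j] - g(i - 1, j);
        if (v < best) { best = v; bj = j; }
      }
      cur[k] = best;
      parent[(size_t)(i - 1) * N + k] = bj;
    }
    std::swap(prev, cur);
  }

  // close the cycle: stage M cost g(M-1, v_M), distance to v_1
  double best_total = BIG * 2; int best_k = 0;
  for (int k = 0; k < N; ++k) {
    double close;
    if (!wrap_constrained) {
      close = -g(M - 1, k);
    } else {
      // wrap feasibility: v_1 = f must lie within [lo[f], hi[f]] viewed from k;
      // the relation is symmetric, so test k against the range of f.
      const bool ok = (k >= lo[f] && k <= hi[f]);
      close = ok ? -g(M - 1, k) : sentinel;
    }
    const double tot = prev[k] + close;
    if (tot < best_total) { best_total = tot; best_k = k; }
  }

  DpResult res;
  res.energy = best_total;
  res.sel.assign(M, 0);
  int k = best_k;
  for (int i = M - 1; i >= 1; --i) {
    res.sel[i] = k;
    k = parent[(size_t)(i - 1) * N + k];
  }
  res.sel[0] = k;
  return res;
}

// [[Rcpp::export(name = ".cpp_dp_contour")]]
List cpp_dp_contour(NumericMatrix g, NumericVector radii, double dtheta,
                    double delta, int closure) {
  const int M = g.nrow(), N = g.ncol();
  const double cosd = std::cos(dtheta);

  // contiguous feasible predecessor range per destination graduation
  std::vector<int> lo(N, N), hi(N, -1);
  for (int k = 0; k < N; ++k) {
    for (int j = 0; j < N; ++j) {
      const double d2 = radii[j] * radii[j] + radii[k] * radii[k] -
                        2.0 * radii[j] * radii[k] * cosd;
      if (d2 <= delta * delta + 1e-9) {
        if (j < lo[k]) lo[k] = j;
        if (j > hi[k]) hi[k] = j;
      }
    }
  }

  double maxg = 0.0;
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) maxg = std::max(maxg, std::fabs(g(i, j)));
  const double sentinel = 2.0 * (M + 1.0) * (maxg + 1.0);

  DpResult best;
  if (closure == 0) {
    best.energy = R_PosInf;
    for (int f = 0; f < N; ++f) {
      DpResult r = dp_pass(g, lo, hi, sentinel, f, true);
      if (r.energy < best.energy) best = r;
    }
  } else {
    DpResult open = dp_pass(g, lo, hi, sentinel, -1, false);
    best = dp_pass(g, lo, hi, sentinel, open.sel[0], true);
  }

  // a cycle that used any sentinel edge exceeds M * maxg; feasible ones cannot
  const bool feasible = best.energy <= M * maxg + 1e-9;
  IntegerVector sel(M);
  for (int i = 0; i < M; ++i) sel[i] = best.sel[i] + 1; // 1-based
  return List::create(_["selection"] = sel, _["energy"] = best.energy,
                      _["feasible"] = feasible, _["sentinel"] = sentinel);
}
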