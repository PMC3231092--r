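#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Dual dynamic programming over a cost grid.
//
// States are row pairs (y1, y2), 1 <= y1 <= y2 <= M, constrained to
// dmin <= y2 - y1 <= dmax.  The predecessor of (x, y1, y2) is
// (x - 1, y1 + j1, y2 + j2) with |j1|, |j2| <= k, and the transition
// penalty is alpha * |j2 - j1| + beta * (|j1| + |j2|).  Infeasible states
// carry +Inf, so the separation constraint also binds the predecessor.
//
// Tie-breaking (deterministic): among equal-cost predecessor offsets,
// (0,0) first, then smallest |j1|+|j2|, then lexicographic (j1, j2);
// among equal-cost terminal states, smallest (y1, y2) lexicographically.
//
// Returns 1-based row traces obtained by exact backtracking through the
// predecessor tables C1/C2, the optimal total cost, and (optionally) the
// full J/C1/C2 tables as M x M x N arrays indexed [y1, y2, x].

struct Offset { int j1, j2; double pen; };

// [[Rcpp::export]]
List ddp_core(NumericMatrix cost, int k, int dmin, int dmax,
              double alpha, double beta, bool want_tables) {
  const int M = cost.nrow(), N = cost.ncol();
  if (N < 2) stop("cost map must have at least 2 columns");
  if (k < 1) stop("k must be >= 1");
  if (dmin < 0 || dmax < dmin) stop("require 0 <= d_min <= d_max");
  if (dmin > M - 1) stop("no feasible state: d_min = %d exceeds M - 1 = %d", dmin, M - 1);
  for (int i = 0; i < M * N; ++i)
    if (!std::isfinite(cost[i])) stop("cost map contains non-finite values");

  // offsets in tie-break preference order
  std::vector<Offset> offs;
  for (int j1 = -k; j1 <= k; ++j1)
    for (int j2 = -k; j2 <= k; ++j2)
      offs.push_back({j1, j2, alpha * std::abs(j2 - j1) +
                              beta * (std::abs(j1) + std::abs(j2))});
  std::sort(offs.begin(), offs.end(), [](const Offset &a, const Offset &b) {
    int sa = std::abs(a.j1) + std::abs(a.j2), sb = std::abs(b.j1) + std::abs(b.j2);
    if (sa != sb) return sa < sb;
    if (a.j1 != b.j1) return a.j1 < b.j1;
    return a.j2 < b.j2;
  });

  const double INF = R_PosInf;
  const size_t S = (size_t)M * M;          // state slab per column (y1 fast)
  auto sidx = [M](int y1, int y2) { return (size_t)(y2 - 1) * M + (y1 - 1); }; // 1-based in
  auto feasible = [&](int y1, int y2) {
    return y1 >= 1 && y2 <= M && y1 <= y2 && (y2 - y1) >= dmin && (y2 - y1) <= dmax;
  };

  std::vector<double> Jprev(S, INF), Jcur(S, INF);
  // predecessor tables for all columns (needed for backtracking)
  std::vector<int> C1((size_t)N * S, NA_INTEGER), C2((size_t)N * S, NA_INTEGER);
  std::vector<double> Jfull;
  if (want_tables) Jfull.assign((size_t)N * S, INF);

  for (int y2 = 1; y2 <= M; ++y2)
    for (int y1 = 1; y1 <= y2; ++y1)
      if (feasible(y1, y2))
        Jprev[sidx(y1, y2)] = cost(y1 - 1, 0) + cost(y2 - 1, 0);
  if (want_tables) std::copy(Jprev.begin(), Jprev.end(), Jfull.begin());

  for (int x = 2; x <= N; ++x) {
    std::fill(Jcur.begin(), Jcur.end(), INF);
    size_t base = (size_t)(x - 1) * S;
    for (int y2 = 1; y2 <= M; ++y2) {
      for (int y1 = 1; y1 <= y2; ++y1) {
        if (!feasible(y1, y2)) continue;
        double best = INF;
        int b1 = NA_INTEGER, b2 = NA_INTEGER;
        for (const Offset &o : offs) {
          int a = y1 + o.j1, b = y2 + o.j2;
          if (!feasible(a, b)) continue;
          double jp = Jprev[sidx(a, b)];
          if (!std::isfinite(jp)) continue;
          double cand = jp + o.pen;
          if (cand < best) { best = cand; b1 = a; b2 = b; }
        }
        if (std::isfinite(best)) {
          size_t s = sidx(y1, y2);
          Jcur[s] = best + cost(y1 - 1, x - 1) + cost(y2 - 1, x - 1);
          C1[base + s] = b1;
          C2[base + s] = b2;
        }
      }
    }
    std::swap(Jprev, Jcur);
    if (want_tables) std::copy(Jprev.begin(), Jprev.end(), Jfull.begin() + base);
  }

  // terminal search: smallest (y1, y2) lexicographically among minima
  double best = INF;
  int t1 = -1, t2 = -1;
  for (int y1 = 1; y1 <= M; ++y1)
    for (int y2 = y1; y2 <= M; ++y2) {
      if (!feasible(y1, y2)) continue;
      double v = Jprev[sidx(y1, y2)];
      if (std::isfinite(v) && v < best) { best = v; t1 = y1; t2 = y2; }
    }
  if (t1 < 0) stop("no feasible dual path through the cost map");

  IntegerVector y1(N), y2(N);
  y1[N - 1] = t1; y2[N - 1] = t2;
  for (int x = N; x >= 2; --x) {
    size_t base = (size_t)(x - 1) * S;
    size_t s = sidx(y1[x - 1], y2[x - 1]);
    y1[x - 2] = C1[base + s];
    y2[x - 2] = C2[base + s];
  }

  List out = List::create(_["y1"] = y1, _["y2"] = y2, _["total_cost"] = best);
  if (want_tables) {
    NumericVector J(Jfull.begin(), Jfull.end());
    IntegerVector C1v(C1.begin(), C1.end()), C2v(C2.begin(), C2.end());
    IntegerVector dim = IntegerVector::create(M, M, N);
    J.attr("dim") = dim; C1v.attr("dim") = dim; C2v.attr("dim") = dim;
    out["J"] = J; out["C1"] = C1v; out["C2"] = C2v;
  }
  return out;
}
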