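// Branch-and-bound solver for small 0/1 integer programs.
//
// Minimises c'z over binary z subject to row constraints
//   rlb[r] <= sum_j A[r,j] z_j <= rub[r]
// with sparse rows. Costs must be non-negative (the dominating-set
// models only ever minimise a sum of indicator variables).
//
// The solver keeps, for every row, the lowest and highest value the
// row can still attain given the current partial assignment, prunes
// when a row becomes unsatisfiable, and fixes variables whose value
// is forced (constraint propagation). Depth-first search branches in
// a caller-supplied static order, value 1 first, and prunes on the
// incumbent objective. Completing the search proves optimality.

#include <Rcpp.h>
#include <chrono>
#include <vector>

using namespace Rcpp;

namespace {

struct Problem {
  int n;                      // number of variables
  std::vector<double> cost;   // objective coefficients, >= 0
  // sparse rows
  std::vector<int> rptr;      // length nrow+1
  std::vector<int> rcol;
  std::vector<double> rcoef;
  std::vector<double> rlb, rub;
  // per-variable occurrence lists: (row, coef)
  std::vector<std::vector<std::pair<int, double> > > occ;
  std::vector<int> order;     // branch order (variable indices)
};

struct State {
  std::vector<signed char> val;  // -1 unfixed, 0, 1
  std::vector<double> lo, hi;    // attainable range per row
  double cost_now;
};

class Solver {
public:
  Problem p;
  double best_obj;
  std::vector<signed char> best_sol;
  bool complete;                // search ran to completion
  long long nodes, node_limit;
  double time_limit;            // seconds, <= 0 means none
  std::chrono::steady_clock::time_point t0;
  bool stopped;

  bool out_of_budget() {
    if (node_limit > 0 && nodes > node_limit) return true;
    if (time_limit > 0 && (nodes & 1023) == 0) {
      double el = std::chrono::duration<double>(
                      std::chrono::steady_clock::now() - t0)
                      .count();
      if (el > time_limit) return true;
    }
    return false;
  }

  // Fix variable j to v, updating row ranges. Returns false on a
  // direct row violation.
  bool fix(State &s, int j, int v) {
    s.val[j] = (signed char)v;
    if (v == 1) s.cost_now += p.cost[j];
    for (size_t t = 0; t < p.occ[j].size(); ++t) {
      int r = p.occ[j][t].first;
      double a = p.occ[j][t].second;
      // unfixed contribution was [min(a,0), max(a,0)]; now a*v
      double add = a * v;
      s.lo[r] += add - std::min(a, 0.0);
      s.hi[r] += add - std::max(a, 0.0);
      if (s.lo[r] > p.rub[r] + 1e-9 || s.hi[r] < p.rlb[r] - 1e-9)
        return false;
    }
    return true;
  }

  // Constraint propagation to fixpoint. Returns false on conflict.
  bool propagate(State &s) {
    bool changed = true;
    while (changed) {
      changed = false;
      int nrow = (int)p.rlb.size();
      for (int r = 0; r < nrow; ++r) {
        if (s.lo[r] > p.rub[r] + 1e-9 || s.hi[r] < p.rlb[r] - 1e-9)
          return false;
        for (int t = p.rptr[r]; t < p.rptr[r + 1]; ++t) {
          int j = p.rcol[t];
          if (s.val[j] != -1) continue;
          double a = p.rcoef[t];
          int force = -1;
          if (a > 0) {
            if (s.lo[r] + a > p.rub[r] + 1e-9) force = 0;
            else if (s.hi[r] - a < p.rlb[r] - 1e-9) force = 1;
          } else {
            if (s.lo[r] - a > p.rub[r] + 1e-9) force = 1;
            else if (s.hi[r] + a < p.rlb[r] - 1e-9) force = 0;
          }
          if (force >= 0) {
            if (force == 1 && s.cost_now + p.cost[j] >= best_obj - 1e-9)
              return false;
            if (!fix(s, j, force)) return false;
            changed = true;
          }
        }
      }
    }
    return true;
  }

  void dfs(State s) {
    if (stopped) return;
    ++nodes;
    if (out_of_budget()) { stopped = true; return; }
    if (s.cost_now >= best_obj - 1e-9) return;
    if (!propagate(s)) return;
    if (s.cost_now >= best_obj - 1e-9) return;
    int j = -1;
    for (size_t t = 0; t < p.order.size(); ++t)
      if (s.val[p.order[t]] == -1) { j = p.order[t]; break; }
    if (j == -1) {  // all fixed and feasible
      best_obj = s.cost_now;
      best_sol.assign(s.val.begin(), s.val.end());
      return;
    }
    {  // try 1 first: finds a covering incumbent quickly
      State s1 = s;
      if (s1.cost_now + p.cost[j] < best_obj - 1e-9 && fix(s1, j, 1))
        dfs(s1);
    }
    if (stopped) return;
    {
      State s0 = s;
      if (fix(s0, j, 0)) dfs(s0);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".bip_solve_cpp")]]
List bip_solve_cpp(int n, NumericVector obj, IntegerVector rptr,
                   IntegerVector rcol, NumericVector rcoef,
                   NumericVector rlb, NumericVector rub,
                   IntegerVector order, double time_limit,
                   double node_limit) {
  Solver sv;
  sv.p.n = n;
  sv.p.cost.assign(obj.begin(), obj.end());
  for (int j = 0; j < n; ++j)
    if (sv.p.cost[j] < 0) stop("objective coefficients must be >= 0");
  sv.p.rptr.assign(rptr.begin(), rptr.end());
  sv.p.rcol.assign(rcol.begin(), rcol.end());
  sv.p.rcoef.assign(rcoef.begin(), rcoef.end());
  sv.p.rlb.assign(rlb.begin(), rlb.end());
  sv.p.rub.assign(rub.begin(), rub.end());
  sv.p.occ.assign(n, std::vector<std::pair<int, double> >());
  int nrow = (int)sv.p.rlb.size();
  for (int r = 0; r < nrow; ++r)
    for (int t = sv.p.rptr[r]; t < sv.p.rptr[r + 1]; ++t)
      sv.p.occ[sv.p.rcol[t]].push_back(std::make_pair(r, sv.p.rcoef[t]));
  sv.p.order.assign(order.begin(), order.end());

  sv.best_obj = R_PosInf;
  sv.nodes = 0;
  sv.node_limit = (long long)node_limit;
  sv.time_limit = time_limit;
  sv.t0 = std::chrono::steady_clock::now();
  sv.stopped = false;

  State s0;
  s0.val.assign(n, -1);
  s0.cost_now = 0.0;
  s0.lo.assign(nrow, 0.0);
  s0.hi.assign(nrow, 0.0);
  for (int r = 0; r < nrow; ++r)
    for (int t = sv.p.rptr[r]; t < sv.p.rptr[r + 1]; ++t) {
      double a = sv.p.rcoef[t];
      s0.lo[r] += std::min(a, 0.0);
      s0.hi[r] += std::max(a, 0.0);
    }
  sv.dfs(s0);

  std::string status;
  bool have = R_finite(sv.best_obj) != 0;
  if (!sv.stopped) status = have ? "optimal" : "infeasible";
  else status = have ? "feasible" : "nosolution";

  IntegerVector sol(n, NA_INTEGER);
  if (have)
    for (int j = 0; j < n; ++j) sol[j] = (int)sv.best_sol[j];
  return List::create(_["status"] = status,
                      _["objective"] = have ? sv.best_obj : NA_REAL,
                      _["solution"] = sol,
                      _["nodes"] = (double)sv.nodes);
}
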