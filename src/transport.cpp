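#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
#include <cmath>
#include <queue>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Uncapacitated min-cost transportation by successive shortest paths with
// node potentials (Dijkstra on the bipartite residual graph). Exact for any
// nonnegative cost matrix; each augmentation exhausts a source, a sink, or a
// residual arc, so termination is finite. Sizes here are the truncated
// diffusion supports (<= a few hundred points), where dense Dijkstra wins.
//
// a: source masses over rows src; b: sink masses over cols snk (sum a == sum b)
// C: full ground-cost matrix indexed by src/snk
// plan_out: if non-null, filled with the m x n flow matrix (row-major)
static double transport_ssp(const std::vector<double>& a,
                            const std::vector<double>& b,
                            const std::vector<int>& src,
                            const std::vector<int>& snk,
                            const NumericMatrix& C,
                            std::vector<double>* plan_out) {
  const int m = (int)a.size(), n = (int)b.size();
  if (plan_out) plan_out->assign((size_t)std::max(m, 0) * std::max(n, 0), 0.0);
  if (m == 0 || n == 0) return 0.0;

  std::vector<double> ex(a), de(b);
  std::vector<double> F((size_t)m * n, 0.0);
  std::vector<double> phi(m + n, 0.0), dist(m + n);
  std::vector<int> par(m + n);
  std::vector<char> done(m + n);

  double total = 0.0;
  for (double v : ex) total += v;
  const double tol = 1e-14 * std::max(1.0, total);
  double remaining = total;
  long guard = 0, guard_max = 200L * (m + n) + 10000L;

  while (remaining > 1e-12 * std::max(1.0, total)) {
    if (++guard > guard_max)
      stop("transport solver failed to converge (degenerate problem?)");
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    std::fill(par.begin(), par.end(), -1);
    for (int i = 0; i < m; ++i)
      if (ex[i] > tol) dist[i] = 0.0;

    int tsink = -1;
    for (;;) {
      int u = -1;
      double du = INF;
      for (int v = 0; v < m + n; ++v)
        if (!done[v] && dist[v] < du) { du = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u >= m && de[u - m] > tol) { tsink = u; break; }
      // reduced costs are clamped at 0: they are nonnegative in exact
      // arithmetic, and tiny negative rounding residues would otherwise let
      // Dijkstra re-relax finalized nodes and corrupt the parent tree
      if (u < m) {
        for (int j = 0; j < n; ++j) {
          if (done[m + j]) continue;
          double rc = C(src[u], snk[j]) + phi[u] - phi[m + j];
          double nd = du + std::max(rc, 0.0);
          if (nd < dist[m + j]) { dist[m + j] = nd; par[m + j] = u; }
        }
      } else {
        int j = u - m;
        for (int i = 0; i < m; ++i) {
          if (done[i]) continue;
          if (F[(size_t)i * n + j] > tol) {
            double rc = -C(src[i], snk[j]) + phi[u] - phi[i];
            double nd = du + std::max(rc, 0.0);
            if (nd < dist[i]) { dist[i] = nd; par[i] = u; }
          }
        }
      }
    }
    if (tsink < 0) break; // only numerical dust left unroutable

    double dT = dist[tsink];
    for (int v = 0; v < m + n; ++v)
      phi[v] += std::min(dist[v], dT);

    // bottleneck along the augmenting path
    double amt = de[tsink - m];
    int v0 = tsink;
    for (int v = tsink; par[v] >= 0; v = par[v]) {
      int u = par[v];
      if (v < m) // backward arc sink(u) -> source(v), capacity = flow
        amt = std::min(amt, F[(size_t)v * n + (u - m)]);
      v0 = u;
    }
    amt = std::min(amt, ex[v0]);
    for (int v = tsink; par[v] >= 0; v = par[v]) {
      int u = par[v];
      if (v >= m) F[(size_t)u * n + (v - m)] += amt;
      else        F[(size_t)v * n + (u - m)] -= amt;
    }
    ex[v0] -= amt;
    de[tsink - m] -= amt;
    remaining -= amt;
  }

  double obj = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      obj += F[(size_t)i * n + j] * C(src[i], snk[j]);
  if (plan_out) *plan_out = F;
  return obj;
}

// Drop the smallest-mass entries whose cumulative mass stays below delta,
// then renormalize to unit mass. Operates in place on a full-length vector.
static void truncate_support(std::vector<double>& p, double delta) {
  if (delta <= 0) return;
  const int n = (int)p.size();
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i)
    if (p[i] > 0) idx.push_back(i);
  std::sort(idx.begin(), idx.end(),
            [&](int i, int j) { return p[i] < p[j]; });
  double cum = 0.0;
  for (int k = 0; k < (int)idx.size(); ++k) {
    if (cum + p[idx[k]] >= delta) break;
    cum += p[idx[k]];
    p[idx[k]] = 0.0;
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += p[i];
  if (s > 0)
    for (int i = 0; i < n; ++i) p[i] /= s;
}

// Net-mass reduction: shared mass between p and q transports for free under
// a metric ground cost (zero diagonal + triangle inequality), so only the
// signed difference r = p - q needs routing.
static double w1_net(const std::vector<double>& p, const std::vector<double>& q,
                     const NumericMatrix& C) {
  const int n = (int)p.size();
  std::vector<double> a, b;
  std::vector<int> src, snk;
  for (int i = 0; i < n; ++i) {
    double r = p[i] - q[i];
    if (r > 1e-15) { a.push_back(r); src.push_back(i); }
    else if (r < -1e-15) { b.push_back(-r); snk.push_back(i); }
  }
  double sa = 0, sb = 0;
  for (double v : a) sa += v;
  for (double v : b) sb += v;
  if (sa <= 0 || sb <= 0) return 0.0;
  double f = sa / sb; // absorb rounding so marginals balance exactly
  for (double& v : b) v *= f;
  return transport_ssp(a, b, src, snk, C, nullptr);
}

// [[Rcpp::export]]
List w1_exact_cpp(NumericVector p, NumericVector q, NumericMatrix cost,
                  bool reduce, bool want_plan) {
  const int n = p.size();
  std::vector<double> pv(p.begin(), p.end()), qv(q.begin(), q.end());
  double w;
  NumericMatrix plan;
  if (reduce && !want_plan) {
    w = w1_net(pv, qv, cost);
  } else {
    std::vector<double> a, b;
    std::vector<int> src, snk;
    if (reduce) {
      for (int i = 0; i < n; ++i) {
        double r = pv[i] - qv[i];
        if (r > 1e-15) { a.push_back(r); src.push_back(i); }
        else if (r < -1e-15) { b.push_back(-r); snk.push_back(i); }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        if (pv[i] > 0) { a.push_back(pv[i]); src.push_back(i); }
        if (qv[i] > 0) { b.push_back(qv[i]); snk.push_back(i); }
      }
    }
    double sa = 0, sb = 0;
    for (double v : a) sa += v;
    for (double v : b) sb += v;
    if (sa <= 0 || sb <= 0) {
      w = 0.0;
    } else {
      double f = sa / sb;
      for (double& v : b) v *= f;
      std::vector<double> flows;
      w = transport_ssp(a, b, src, snk, cost, want_plan ? &flows : nullptr);
      if (want_plan) {
        plan = NumericMatrix(n, n);
        if (reduce) // shared mass stays in place
          for (int i = 0; i < n; ++i) plan(i, i) = std::min(pv[i], qv[i]);
        for (int i = 0; i < (int)src.size(); ++i)
          for (int j = 0; j < (int)snk.size(); ++j)
            plan(src[i], snk[j]) += flows[(size_t)i * snk.size() + j];
      }
    }
    if (want_plan && plan.nrow() == 0) {
      plan = NumericMatrix(n, n);
      if (reduce)
        for (int i = 0; i < n; ++i) plan(i, i) = std::min(pv[i], qv[i]);
    }
  }
  if (want_plan) return List::create(_["cost"] = w, _["plan"] = plan);
  return List::create(_["cost"] = w);
}

// Per-edge Ollivier-Ricci curvature at a single diffusion scale:
// kappa_e = 1 - W1(D[i,], D[j,]) / direct_cost[e], ground cost = dist.
// [[Rcpp::export]]
NumericVector edge_kappa_cpp(NumericMatrix D, NumericMatrix dist,
                             IntegerVector ei, IntegerVector ej,
                             NumericVector direct_cost, double trunc_delta) {
  const int ne = ei.size(), n = D.ncol();
  NumericVector kappa(ne);
  std::vector<std::vector<double>> rows(D.nrow(), std::vector<double>(n));
  std::vector<char> prepped(D.nrow(), 0);
  for (int e = 0; e < ne; ++e) {
    int i = ei[e], j = ej[e];
    for (int v : {i, j}) {
      if (!prepped[v]) {
        for (int k = 0; k < n; ++k) rows[v][k] = D(v, k);
        truncate_support(rows[v], trunc_delta);
        prepped[v] = 1;
      }
    }
    double w = w1_net(rows[i], rows[j], dist);
    kappa[e] = 1.0 - w / direct_cost[e];
  }
  return kappa;
}

// ---------------------------------------------------------------------------
// Sparse-graph solver used by the curvature sweep.
//
// When the ground metric is the shortest-path metric of the network itself,
// W1(p, q) equals the optimal value of the uncapacitated min-cost flow that
// routes the signed difference r = p - q through the graph's own edges
// (Beckmann formulation). Successive shortest paths with potentials again,
// but Dijkstra now runs on the sparse adjacency with a binary heap and stops
// at the first settled deficit node, so each solve only explores the ball
// between the two diffusion supports.

struct SparseFlowSolver {
  int n;
  std::vector<int> head, nbr, twin;    // CSR adjacency over directed arcs
  std::vector<double> w;               // arc costs (symmetric)
  std::vector<double> f;               // per-directed-arc flow
  std::vector<double> phi, dist, excess;
  std::vector<int> par_arc, touched, settled_list, used_arcs;
  std::vector<int> path_arcs;
  std::vector<char> path_cancel;
  std::vector<char> on_path;
  std::vector<char> settled, mode_cancel;
  std::vector<std::pair<double, int>> heap; // min-heap with lazy deletion

  SparseFlowSolver(int n_, const std::vector<int>& eu,
                   const std::vector<int>& ev, const std::vector<double>& ew)
      : n(n_) {
    int m = (int)eu.size();
    std::vector<int> deg(n, 0);
    for (int e = 0; e < m; ++e) { deg[eu[e]]++; deg[ev[e]]++; }
    head.assign(n + 1, 0);
    for (int v = 0; v < n; ++v) head[v + 1] = head[v] + deg[v];
    nbr.assign(2 * m, 0);
    twin.assign(2 * m, 0);
    w.assign(2 * m, 0);
    std::vector<int> pos(head.begin(), head.end() - 1);
    for (int e = 0; e < m; ++e) {
      int a = pos[eu[e]]++, b = pos[ev[e]]++;
      nbr[a] = ev[e]; nbr[b] = eu[e];
      twin[a] = b; twin[b] = a;
      w[a] = ew[e]; w[b] = ew[e];
    }
    f.assign(2 * m, 0.0);
    phi.assign(n, 0.0);
    dist.assign(n, INF);
    excess.assign(n, 0.0);
    par_arc.assign(n, -1);
    settled.assign(n, 0);
    mode_cancel.assign(n, 0);
    on_path.assign(n, 0);
    touched.reserve(n);
    settled_list.reserve(n);
    used_arcs.reserve(4 * m);
    heap.reserve(4 * n);
  }

  inline void heap_push(double d, int v) {
    heap.emplace_back(d, v);
    std::push_heap(heap.begin(), heap.end(),
                   std::greater<std::pair<double, int>>());
  }

  // route r = p - q over the graph's arcs; returns the transport cost.
  // Primal-dual min-cost flow: each phase runs one Dijkstra over residual
  // reduced costs from every remaining source, then a blocking flow over
  // the zero-reduced-cost admissible arcs, so the many small sources of a
  // diffusion difference are all routed per phase instead of one per
  // Dijkstra as in plain successive shortest paths.
  double solve(const std::vector<double>& p, const std::vector<double>& q,
               double* phi_warm = nullptr) {
    double total = 0.0;
    for (int v = 0; v < n; ++v) {
      excess[v] = p[v] - q[v];
      dist[v] = INF;
      settled[v] = 0;
      on_path[v] = 0;
      if (excess[v] > 1e-15) total += excess[v];
      // any potential vector this solver ever produces is 1-Lipschitz over
      // the arcs, hence valid for the zero-flow start of a new instance;
      // tau-adjacent instances have nearly identical duals, so warm starts
      // make the Dijkstras shallow
      phi[v] = phi_warm ? phi_warm[v] : 0.0;
    }
    if (total <= 1e-13) return 0.0;
    const double tol = 1e-14 * std::max(1.0, total);
    const double stop_tol = 1e-12 * std::max(1.0, total);
    const double adm_tol = 1e-11; // admissible-arc slack against fp residue
    double remaining = total, obj = 0.0;
    long guard = 0, guard_max = 20L * n + 2000L;
    used_arcs.clear();

    while (remaining > stop_tol) {
      if (++guard > guard_max)
        stop("graph transport solver failed to converge");

      // ---- Dijkstra phase over residual arcs with reduced costs ----
      // (full reset: the blocking flow marks dead nodes beyond the
      // previous phase's touched set)
      for (int v = 0; v < n; ++v) { dist[v] = INF; settled[v] = 0; }
      touched.clear();
      heap.clear();
      for (int s = 0; s < n; ++s)
        if (excess[s] > tol) {
          dist[s] = 0.0;
          touched.push_back(s);
          heap_push(0.0, s);
        }
      double dmax = 0.0;
      bool deficit_reached = false;
      while (!heap.empty()) {
        std::pop_heap(heap.begin(), heap.end(),
                      std::greater<std::pair<double, int>>());
        std::pair<double, int> top = heap.back();
        heap.pop_back();
        int u = top.second;
        if (settled[u] || top.first > dist[u]) continue;
        settled[u] = 1;
        if (dist[u] > dmax) dmax = dist[u];
        // stop at the first deficit: with warm potentials it pops almost
        // immediately, and the blocking flow below still drains every
        // admissible source-sink pair inside the settled region
        if (excess[u] < -tol) { deficit_reached = true; break; }
        double du = dist[u];
        for (int a = head[u]; a < head[u + 1]; ++a) {
          int v = nbr[a];
          if (settled[v]) continue;
          double rc; // reduced cost clamped at 0 against fp residue
          if (f[twin[a]] > tol) rc = -w[a] + phi[u] - phi[v];
          else rc = w[a] + phi[u] - phi[v];
          if (rc < 0) rc = 0;
          double nd = du + rc;
          if (nd < dist[v]) {
            if (dist[v] == INF) touched.push_back(v);
            dist[v] = nd;
            heap_push(nd, v);
          }
        }
      }
      if (!deficit_reached) break; // numerical dust unroutable
      for (int v = 0; v < n; ++v)
        phi[v] += std::min(dist[v], dmax);

      // ---- blocking flow over admissible (zero reduced cost) arcs ----
      // iterative DFS with current-arc pointers; dead nodes are marked so
      // each arc is inspected O(1) times per phase
      for (int v : touched) settled[v] = 0; // reuse as dead marker
      std::vector<int>& cur = par_arc;      // reuse as current-arc pointer
      for (int v = 0; v < n; ++v) cur[v] = head[v];
      double routed = 0.0;
      for (int s = 0; s < n && remaining - routed > stop_tol; ++s) {
        while (excess[s] > tol) {
          // DFS from s to any deficit node along admissible arcs
          path_arcs.clear();
          path_cancel.clear();
          int u = s;
          on_path[s] = 1;
          int t = -1;
          while (t < 0) {
            if (excess[u] < -tol && u != s) { t = u; break; }
            bool advanced = false;
            for (int& a = cur[u]; a < head[u + 1]; ++a) {
              int v = nbr[a];
              if (settled[v] || on_path[v]) continue; // dead or would cycle
              char cancel;
              double rc;
              if (f[twin[a]] > tol) { rc = -w[a] + phi[u] - phi[v]; cancel = 1; }
              else { rc = w[a] + phi[u] - phi[v]; cancel = 0; }
              if (rc > adm_tol || rc < -adm_tol) continue;
              path_arcs.push_back(a);
              path_cancel.push_back(cancel);
              on_path[v] = 1;
              u = v;
              advanced = true;
              break;
            }
            if (!advanced) {
              settled[u] = 1; // dead end for this phase
              on_path[u] = 0;
              if (u == s) break;
              int a = path_arcs.back();
              path_arcs.pop_back();
              path_cancel.pop_back();
              u = nbr[twin[a]];
            }
          }
          if (t < 0) { on_path[s] = 0; break; } // no deficit reachable
          double amt = std::min(excess[s], -excess[t]);
          for (size_t k = 0; k < path_arcs.size(); ++k)
            if (path_cancel[k]) amt = std::min(amt, f[twin[path_arcs[k]]]);
          for (size_t k = 0; k < path_arcs.size(); ++k) {
            int a = path_arcs[k];
            if (path_cancel[k]) { f[twin[a]] -= amt; obj -= amt * w[a]; }
            else { f[a] += amt; obj += amt * w[a]; used_arcs.push_back(a); }
          }
          excess[s] -= amt;
          excess[t] += amt;
          routed += amt;
          on_path[s] = 0;
          for (size_t k = 0; k < path_arcs.size(); ++k)
            on_path[nbr[path_arcs[k]]] = 0;
          // restart DFS from s; current-arc pointers re-check admissibility
          // and capacity, so saturated arcs are skipped naturally
        }
      }
      remaining -= routed;
      if (routed <= stop_tol && remaining > stop_tol) break; // dust
    }
    for (int a : used_arcs) f[a] = 0.0; // reset for the next call
    used_arcs.clear();
    touched.clear();
    if (phi_warm)
      for (int v = 0; v < n; ++v) phi_warm[v] = phi[v];
    return obj;
  }
};

// [[Rcpp::export]]
NumericVector edge_kappa_graph_cpp(NumericMatrix D, IntegerVector gu,
                                   IntegerVector gv, NumericVector gw,
                                   IntegerVector ei, IntegerVector ej,
                                   NumericVector direct_cost,
                                   double trunc_delta) {
  const int n = D.ncol(), ne = ei.size();
  SparseFlowSolver solver(
      n, std::vector<int>(gu.begin(), gu.end()),
      std::vector<int>(gv.begin(), gv.end()),
      std::vector<double>(gw.begin(), gw.end()));
  std::vector<std::vector<double>> rows(D.nrow(), std::vector<double>(n));
  std::vector<char> prepped(D.nrow(), 0);
  NumericVector kappa(ne);
  for (int e = 0; e < ne; ++e) {
    int i = ei[e], j = ej[e];
    for (int v : {i, j}) {
      if (!prepped[v]) {
        for (int k = 0; k < n; ++k) rows[v][k] = D(v, k);
        truncate_support(rows[v], trunc_delta);
        prepped[v] = 1;
      }
    }
    double w1 = solver.solve(rows[i], rows[j]);
    kappa[e] = 1.0 - w1 / direct_cost[e];
  }
  return kappa;
}

// Persistent solver handle for the full curvature sweep: keeps one
// potential bank per network edge so consecutive scales warm-start.
class SweepSolver {
public:
  SweepSolver(int n_, const std::vector<int>& eu, const std::vector<int>& ev,
              const std::vector<double>& ew, int n_query_edges)
      : solver(n_, eu, ev, ew), n(n_),
        phi_bank((size_t)n_query_edges * n_, 0.0) {}
  SparseFlowSolver solver;
  int n;
  std::vector<double> phi_bank;
};

// [[Rcpp::export]]
SEXP sweep_solver_new(int n, IntegerVector gu, IntegerVector gv,
                      NumericVector gw, int n_query_edges) {
  Rcpp::XPtr<SweepSolver> ptr(new SweepSolver(
      n, std::vector<int>(gu.begin(), gu.end()),
      std::vector<int>(gv.begin(), gv.end()),
      std::vector<double>(gw.begin(), gw.end()), n_query_edges));
  return ptr;
}

// [[Rcpp::export]]
NumericVector edge_kappa_warm_cpp(SEXP solver_ptr, NumericMatrix D,
                                  IntegerVector ei, IntegerVector ej,
                                  NumericVector direct_cost,
                                  double trunc_delta) {
  Rcpp::XPtr<SweepSolver> sp(solver_ptr);
  const int n = D.ncol(), ne = ei.size();
  std::vector<std::vector<double>> rows(D.nrow(), std::vector<double>(n));
  std::vector<char> prepped(D.nrow(), 0);
  NumericVector kappa(ne);
  for (int e = 0; e < ne; ++e) {
    int i = ei[e], j = ej[e];
    for (int v : {i, j}) {
      if (!prepped[v]) {
        for (int k = 0; k < n; ++k) rows[v][k] = D(v, k);
        truncate_support(rows[v], trunc_delta);
        prepped[v] = 1;
      }
    }
    double w1 = sp->solver.solve(rows[i], rows[j],
                                 &sp->phi_bank[(size_t)e * sp->n]);
    kappa[e] = 1.0 - w1 / direct_cost[e];
  }
  return kappa;
}
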