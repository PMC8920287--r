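#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact W1 on an undirected graph with nonnegative edge lengths, phrased as
// an uncapacitated minimum-cost flow: supplies b = rho0 - rho1 at the nodes,
// every edge usable in both directions at its length per unit mass.
//
// Solved by the primal-dual (successive shortest path) method: one Dijkstra
// with Johnson potentials per phase, then a Dinic-style blocking flow on the
// admissible (zero reduced cost) subgraph, so one phase routes every
// augmenting path of the current shortest length at once.  All arc costs are
// nonnegative, so plain Dijkstra bootstraps the potentials.

struct Arc {
  int to;
  double cap;
  double cost;
};

static const double EPS = 1e-13;
static const double RC_TOL = 1e-11;  // admissibility tolerance on reduced cost

struct Solver {
  int N;
  std::vector<Arc> arcs;
  std::vector<std::vector<int> > adj;
  std::vector<double> pot, dist;
  std::vector<int> level, ptr;

  explicit Solver(int n) : N(n), adj(n), pot(n, 0.0), dist(n),
                           level(n), ptr(n) {}

  void add_arc(int u, int v, double cap, double c) {
    adj[u].push_back((int)arcs.size());
    arcs.push_back(Arc{v, cap, c});
    adj[v].push_back((int)arcs.size());
    arcs.push_back(Arc{u, 0.0, -c});
  }

  bool dijkstra(int S) {
    const double INF = std::numeric_limits<double>::infinity();
    std::fill(dist.begin(), dist.end(), INF);
    dist[S] = 0.0;
    typedef std::pair<double, int> QI;
    std::priority_queue<QI, std::vector<QI>, std::greater<QI> > pq;
    pq.push(QI(0.0, S));
    while (!pq.empty()) {
      QI top = pq.top();
      pq.pop();
      int u = top.second;
      if (top.first > dist[u] + 1e-15) continue;
      const std::vector<int> &au = adj[u];
      for (size_t k = 0; k < au.size(); ++k) {
        const Arc &a = arcs[au[k]];
        if (a.cap <= EPS) continue;
        double nd = top.first + a.cost + pot[u] - pot[a.to];
        if (nd < dist[a.to] - 1e-15) {
          dist[a.to] = nd;
          pq.push(QI(nd, a.to));
        }
      }
    }
    return true;
  }

  bool admissible(int u, const Arc &a) const {
    if (a.cap <= EPS) return false;
    double rc = a.cost + pot[u] - pot[a.to];
    return std::fabs(rc) <= RC_TOL;
  }

  bool bfs_levels(int S, int T) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    q.push(S);
    level[S] = 0;
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      const std::vector<int> &au = adj[u];
      for (size_t k = 0; k < au.size(); ++k) {
        const Arc &a = arcs[au[k]];
        if (level[a.to] < 0 && admissible(u, a)) {
          level[a.to] = level[u] + 1;
          q.push(a.to);
        }
      }
    }
    return level[T] >= 0;
  }

  double dfs_push(int u, int T, double lim) {
    if (u == T || lim <= EPS) return (u == T) ? lim : 0.0;
    for (int &k = ptr[u]; k < (int)adj[u].size(); ++k) {
      int id = adj[u][k];
      const Arc &a = arcs[id];
      if (level[a.to] != level[u] + 1 || !admissible(u, a)) continue;
      double pushed = dfs_push(a.to, T, std::min(lim, a.cap));
      if (pushed > EPS) {
        arcs[id].cap -= pushed;
        arcs[id ^ 1].cap += pushed;
        return pushed;
      }
    }
    return 0.0;
  }

  // returns unrouted excess
  double run(int S, int T, double excess) {
    double remaining = excess;
    const int max_phase = 10 * N + 100;
    for (int phase = 0; phase < max_phase && remaining > 1e-11; ++phase) {
      dijkstra(S);
      if (!std::isfinite(dist[T])) break;
      for (int v = 0; v < N; ++v)
        if (std::isfinite(dist[v])) pot[v] += dist[v];
      while (remaining > 1e-11 && bfs_levels(S, T)) {
        std::fill(ptr.begin(), ptr.end(), 0);
        for (;;) {
          double pushed = dfs_push(S, T, remaining);
          if (pushed <= EPS) break;
          remaining -= pushed;
          if (remaining <= 1e-11) break;
        }
        break;  // one blocking flow per Dijkstra phase
      }
    }
    return remaining;
  }
};

// [[Rcpp::export(name = ".mcf_solve")]]
List mcf_solve(int n_nodes, IntegerVector tail, IntegerVector head,
               NumericVector cost, NumericVector supply) {
  const double INF = std::numeric_limits<double>::infinity();
  const int n_edges = tail.size();
  const int S = n_nodes, T = n_nodes + 1;
  Solver sv(n_nodes + 2);
  sv.arcs.reserve(4 * (size_t)n_edges + 4 * (size_t)n_nodes);

  // arcs 4e (tail->head) and 4e+2 (head->tail); odd indices are residuals
  for (int e = 0; e < n_edges; ++e) {
    sv.add_arc(tail[e], head[e], INF, cost[e]);
    sv.add_arc(head[e], tail[e], INF, cost[e]);
  }
  double excess = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    if (supply[i] > EPS) {
      sv.add_arc(S, i, supply[i], 0.0);
      excess += supply[i];
    } else if (supply[i] < -EPS) {
      sv.add_arc(i, T, -supply[i], 0.0);
    }
  }

  double remaining = sv.run(S, T, excess);

  // Net flux per undirected edge, signed relative to the stored (tail, head)
  // orientation.  The residual capacity of arc 4e+1 equals the mass pushed
  // tail->head.  The net flux is feasible, and a feasible flow can cost no
  // less than the optimum the augmentations achieved, so it is optimal too.
  NumericVector flux(n_edges);
  double objective = 0.0;
  for (int e = 0; e < n_edges; ++e) {
    double f = sv.arcs[4 * e + 1].cap - sv.arcs[4 * e + 3].cap;
    flux[e] = f;
    objective += cost[e] * std::fabs(f);
  }

  return List::create(_["objective"] = objective,
                      _["flux"] = flux,
                      _["unmet"] = remaining);
}
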