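#include <Rcpp.h>
#include <vector>
#include <limits>
#include <numeric>
#include <algorithm>
using namespace Rcpp;

// Exact dense transportation problem: minimise sum_ij flow[i][j] * cost[i][j]
// subject to row sums = supply, column sums = demand, flow >= 0.
// Solved by successive shortest paths with node potentials (min-cost flow on
// the complete bipartite network; supplies/demands are integer-valued doubles
// so flows stay exact). Costs must be nonnegative.
//
// Returns the optimal objective and one optimal flow matrix (the optimal plan
// need not be unique; only the objective is contractual).
// [[Rcpp::export(name = ".transport_ssp")]]
List transport_ssp(NumericMatrix cost, NumericVector supply, NumericVector demand) {
  const int m = supply.size();
  const int n = demand.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions do not match supply/demand lengths");

  double stot = std::accumulate(supply.begin(), supply.end(), 0.0);
  double dtot = std::accumulate(demand.begin(), demand.end(), 0.0);
  if (std::abs(stot - dtot) > 1e-6 * std::max(1.0, stot))
    stop("total supply and total demand differ");
  for (int i = 0; i < m; ++i) if (supply[i] < 0) stop("negative supply");
  for (int j = 0; j < n; ++j) if (demand[j] < 0) stop("negative demand");

  std::vector<double> rs(supply.begin(), supply.end());
  std::vector<double> rd(demand.begin(), demand.end());
  NumericMatrix flow(m, n);
  std::fill(flow.begin(), flow.end(), 0.0);

  const int V = m + n;
  std::vector<double> pot(V, 0.0);
  std::vector<double> dist(V);
  std::vector<int> par(V);
  std::vector<char> done(V);
  const double INF = std::numeric_limits<double>::infinity();

  double pushed = 0.0;
  while (pushed < dtot - 1e-9) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(par.begin(), par.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    for (int i = 0; i < m; ++i) if (rs[i] > 0) dist[i] = 0.0;

    // dense Dijkstra over reduced costs
    for (int it = 0; it < V; ++it) {
      int u = -1; double best = INF;
      for (int v = 0; v < V; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u < m) {
        for (int j = 0; j < n; ++j) {
          double rc = cost(u, j) + pot[u] - pot[m + j];
          if (rc < 0) rc = 0;  // guard against floating-point drift
          if (dist[u] + rc < dist[m + j]) { dist[m + j] = dist[u] + rc; par[m + j] = u; }
        }
      } else {
        int j = u - m;
        for (int i = 0; i < m; ++i) if (flow(i, j) > 0) {
          double rc = -cost(i, j) + pot[u] - pot[i];
          if (rc < 0) rc = 0;
          if (dist[u] + rc < dist[i]) { dist[i] = dist[u] + rc; par[i] = u; }
        }
      }
    }

    int tgt = -1; double bd = INF;
    for (int j = 0; j < n; ++j)
      if (rd[j] > 0 && dist[m + j] < bd) { bd = dist[m + j]; tgt = m + j; }
    if (tgt < 0) stop("transportation problem infeasible");

    for (int v = 0; v < V; ++v)
      if (dist[v] < INF) pot[v] += std::min(dist[v], bd);

    // bottleneck along the augmenting path
    double bn = rd[tgt - m];
    int s = tgt;
    for (int v = tgt; ; v = par[v]) {
      if (par[v] < 0) { s = v; break; }
      int u = par[v];
      if (u >= m && v < m) bn = std::min(bn, flow(v, u - m));  // residual arc
    }
    bn = std::min(bn, rs[s]);
    if (!(bn > 0)) stop("degenerate augmentation; inconsistent marginals");

    for (int v = tgt; par[v] >= 0; v = par[v]) {
      int u = par[v];
      if (u < m) flow(u, v - m) += bn; else flow(v, u - m) -= bn;
    }
    rs[s] -= bn;
    rd[tgt - m] -= bn;
    pushed += bn;
  }

  double obj = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) obj += flow(i, j) * cost(i, j);

  return List::create(_["objective"] = obj, _["flow"] = flow);
}
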