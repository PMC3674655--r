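#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Graph is CSR over 0-based node ids: ptr has length n+1; the neighbours of u
// are nbr[ptr[u] .. ptr[u+1]-1] with edge weights wt[...]. Neighbour lists are
// sorted ascending by id, which is what makes the greedy reconstruction below
// return the lexicographically smallest optimal path.

static void dijkstra_from(int n, const int* ptr, const int* nbr, const double* wt,
                          int src, std::vector<double>& dist) {
  dist.assign(n, R_PosInf);
  typedef std::pair<double, int> QItem;
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  dist[src] = 0.0;
  pq.push(QItem(0.0, src));
  while (!pq.empty()) {
    QItem top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u]) continue;
    for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
      int v = nbr[k];
      double nd = d + wt[k];
      if (nd < dist[v]) { dist[v] = nd; pq.push(QItem(nd, v)); }
    }
  }
}

// Walk from s towards t following edges that lie on some minimum-cost path
// (w(u,v) + dist_t(v) == dist_t(u)); taking the smallest feasible neighbour at
// every step yields the lexicographically smallest optimal node sequence.
// Edge costs are strictly positive, so dist_t strictly decreases and the walk
// cannot revisit a node.
static bool reconstruct_path(const int* ptr, const int* nbr, const double* wt,
                             int s, int t, const std::vector<double>& dist_t,
                             std::vector<int>& path) {
  path.clear();
  if (!std::isfinite(dist_t[s])) return false;
  int cur = s;
  double rem = dist_t[s];
  path.push_back(cur);
  while (cur != t) {
    int nxt = -1;
    double nxt_rem = 0.0;
    double tol = 1e-9 * std::max(1.0, rem);
    for (int k = ptr[cur]; k < ptr[cur + 1]; ++k) {
      int v = nbr[k];
      double r = dist_t[v];
      if (!std::isfinite(r)) continue;
      if (std::fabs(wt[k] + r - rem) <= tol) { nxt = v; nxt_rem = r; break; }
    }
    if (nxt < 0) stop("internal error: shortest-path reconstruction failed");
    cur = nxt;
    rem = nxt_rem;
    path.push_back(cur);
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_dijkstra_dist(IntegerVector ptr, IntegerVector nbr,
                                NumericVector wt, int src) {
  int n = ptr.size() - 1;
  std::vector<double> dist;
  dijkstra_from(n, ptr.begin(), nbr.begin(), wt.begin(), src, dist);
  return NumericVector(dist.begin(), dist.end());
}

// [[Rcpp::export]]
IntegerVector cpp_reconstruct(IntegerVector ptr, IntegerVector nbr, NumericVector wt,
                              int s, int t, NumericVector dist_t) {
  std::vector<double> dt(dist_t.begin(), dist_t.end());
  std::vector<int> path;
  if (!reconstruct_path(ptr.begin(), nbr.begin(), wt.begin(), s, t, dt, path))
    return IntegerVector(0);
  return IntegerVector(path.begin(), path.end());
}

// All unordered pairs among `seeds` (0-based ids, sorted ascending). Returns
// parallel vectors: pair endpoints, total cost (NA when unreachable) and the
// node sequence of each reachable pair.
// [[Rcpp::export]]
List cpp_all_pairs_paths(IntegerVector ptr, IntegerVector nbr, NumericVector wt,
                         IntegerVector seeds) {
  int n = ptr.size() - 1;
  int m = seeds.size();
  std::vector< std::vector<double> > dist(m);
  for (int i = 0; i < m; ++i)
    dijkstra_from(n, ptr.begin(), nbr.begin(), wt.begin(), seeds[i], dist[i]);

  int npair = m * (m - 1) / 2;
  IntegerVector src(npair), tgt(npair);
  NumericVector cost(npair);
  List paths(npair);
  std::vector<int> path;
  int idx = 0;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      int s = seeds[i], t = seeds[j];
      src[idx] = s; tgt[idx] = t;
      // dist[j] holds distances from t; the graph is undirected.
      if (reconstruct_path(ptr.begin(), nbr.begin(), wt.begin(), s, t, dist[j], path)) {
        cost[idx] = dist[j][s];
        paths[idx] = IntegerVector(path.begin(), path.end());
      } else {
        cost[idx] = NA_REAL;
        paths[idx] = IntegerVector(0);
      }
      ++idx;
    }
  }
  return List::create(_["source"] = src, _["target"] = tgt,
                      _["cost"] = cost, _["paths"] = paths);
}

// Permutation engine: n_perm replicates, each drawing seed_size nodes without
// replacement from `universe` (R's RNG, so set.seed() governs), mining all
// seed-pair shortest paths and tallying interior occurrences. A candidate that
// is itself drawn as a replicate seed scores 0 in that replicate (seed nodes
// are excluded from the tally, mirroring the observed run). Returns, per
// candidate, the number of replicates with count strictly greater than
// `observed`.
// [[Rcpp::export]]
IntegerVector cpp_permutation_exceed(IntegerVector ptr, IntegerVector nbr,
                                     NumericVector wt, IntegerVector universe,
                                     int seed_size, int n_perm,
                                     IntegerVector cand, IntegerVector observed) {
  int n = ptr.size() - 1;
  int nc = cand.size();
  IntegerVector exceed(nc);
  std::vector<int> cnt(n, 0), touched;
  std::vector<char> is_seed(n, 0);
  std::vector< std::vector<double> > dist(seed_size);
  std::vector<int> path;

  for (int rep = 0; rep < n_perm; ++rep) {
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
    IntegerVector smp = sample(universe, seed_size, false);
    std::vector<int> seeds(smp.begin(), smp.end());
    std::sort(seeds.begin(), seeds.end());
    for (int i = 0; i < seed_size; ++i) {
      is_seed[seeds[i]] = 1;
      dijkstra_from(n, ptr.begin(), nbr.begin(), wt.begin(), seeds[i], dist[i]);
    }
    for (int i = 0; i < seed_size; ++i) {
      for (int j = i + 1; j < seed_size; ++j) {
        if (!reconstruct_path(ptr.begin(), nbr.begin(), wt.begin(),
                              seeds[i], seeds[j], dist[j], path))
          continue;  // unreachable pair: skipped, as in the observed run
        for (size_t q = 1; q + 1 < path.size(); ++q) {
          int v = path[q];
          if (cnt[v] == 0) touched.push_back(v);
          ++cnt[v];
        }
      }
    }
    for (int c = 0; c < nc; ++c) {
      int v = cand[c];
      int b = is_seed[v] ? 0 : cnt[v];
      if (b > observed[c]) ++exceed[c];
    }
    for (size_t q = 0; q < touched.size(); ++q) cnt[touched[q]] = 0;
    touched.clear();
    for (int i = 0; i < seed_size; ++i) is_seed[seeds[i]] = 0;
  }
  return exceed;
}

// Interior-occurrence tally over a list of integer node sequences.
// [[Rcpp::export]]
IntegerVector cpp_interior_counts(List paths, int n) {
  IntegerVector cnt(n);
  for (int i = 0; i < paths.size(); ++i) {
    IntegerVector p = paths[i];
    for (int q = 1; q + 1 < p.size(); ++q) ++cnt[p[q]];
  }
  return cnt;
}

// Interior-occurrence counts for one seed set, without materialising paths.
// [[Rcpp::export]]
IntegerVector cpp_seed_counts(IntegerVector ptr, IntegerVector nbr,
                              NumericVector wt, IntegerVector seeds) {
  int n = ptr.size() - 1;
  int m = seeds.size();
  std::vector<int> sd(seeds.begin(), seeds.end());
  std::sort(sd.begin(), sd.end());
  std::vector< std::vector<double> > dist(m);
  for (int i = 0; i < m; ++i)
    dijkstra_from(n, ptr.begin(), nbr.begin(), wt.begin(), sd[i], dist[i]);
  IntegerVector cnt(n);
  std::vector<int> path;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      if (reconstruct_path(ptr.begin(), nbr.begin(), wt.begin(),
                           sd[i], sd[j], dist[j], path))
        for (size_t q = 1; q + 1 < path.size(); ++q) ++cnt[path[q]];
  return cnt;
}
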