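#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Multi-source Dijkstra on a lat/lon raster with 8-connectivity.
// Land cells are impassable; edge weights are great-circle centre-to-centre
// distances, precomputed per latitude row in R and passed in:
//   w_ew[i]   east-west pitch in row i            (length n_lat)
//   w_ns[i]   north-south pitch between rows i,i+1 (length n_lat - 1)
//   w_dg[i]   diagonal pitch between rows i,i+1    (length n_lat - 1)
// Matrices are n_lat x n_lon, row index = latitude (south -> north).
// lon_wrap joins column 0 and column n_lon - 1 (global grids).

// [[Rcpp::export(name = ".wdt_dijkstra")]]
NumericMatrix wdt_dijkstra(LogicalMatrix land, LogicalMatrix source,
                           NumericVector w_ew, NumericVector w_ns,
                           NumericVector w_dg, bool lon_wrap) {
  const int nr = land.nrow(), nc = land.ncol();
  const double inf = std::numeric_limits<double>::infinity();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), inf);

  typedef std::pair<double, int> Node; // (distance, flat index col*nr + row)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (source(i, j) && !land(i, j)) {
        dist(i, j) = 0.0;
        pq.push(Node(0.0, j * nr + i));
      }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    double d = top.first;
    int idx = top.second;
    int i = idx % nr, j = idx / nr;
    if (d > dist(i, j)) continue; // stale entry
    for (int k = 0; k < 8; ++k) {
      int ni = i + di[k];
      if (ni < 0 || ni >= nr) continue;
      int nj = j + dj[k];
      if (nj < 0 || nj >= nc) {
        if (!lon_wrap) continue;
        nj = (nj + nc) % nc;
      }
      if (land(ni, nj)) continue;
      double w;
      if (di[k] == 0) w = w_ew[i];
      else if (dj[k] == 0) w = w_ns[std::min(i, ni)];
      else w = w_dg[std::min(i, ni)];
      double nd = d + w;
      if (nd < dist(ni, nj)) {
        dist(ni, nj) = nd;
        pq.push(Node(nd, nj * nr + ni));
      }
    }
  }

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (land(i, j)) dist(i, j) = NA_REAL;
  return dist;
}
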