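#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// DBSCAN in (pos1, pos2) space under the Chebyshev (box) metric, using an
// eps-sized grid hash. A point is core when it has >= minPts neighbours
// (itself included) within Chebyshev distance eps. Clusters are connected
// components of core points; border points join the cluster of the first
// core neighbour found. Returns 1-based cluster labels, 0 for noise.

static inline int64_t cellKey(int cx, int cy) {
  return (static_cast<int64_t>(cx) << 32) ^ (static_cast<uint32_t>(cy));
}

// [[Rcpp::export(name = ".dbscanChebyshev")]]
IntegerVector dbscanChebyshev(NumericVector x, NumericVector y,
                              double eps, int minPts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  std::vector<int> cx(n), cy(n);
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(x[i] / eps);
    cy[i] = (int)std::floor(y[i] / eps);
    grid[cellKey(cx[i], cy[i])].push_back(i);
  }

  // neighbour enumeration helper over the 3x3 cell block
  auto forNeighbours = [&](int i, bool countOnly, std::vector<int> *out) -> int {
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cellKey(cx[i] + dx, cy[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (std::abs(x[j] - x[i]) <= eps && std::abs(y[j] - y[i]) <= eps) {
            ++cnt;
            if (!countOnly) out->push_back(j);
          }
        }
      }
    return cnt;
  };

  std::vector<char> core(n, 0);
  for (int i = 0; i < n; ++i) {
    // same-cell points are always within eps: cheap lower bound
    int same = (int)grid[cellKey(cx[i], cy[i])].size();
    if (same >= minPts) { core[i] = 1; continue; }
    int upper = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cellKey(cx[i] + dx, cy[i] + dy));
        if (it != grid.end()) upper += (int)it->second.size();
      }
    if (upper < minPts) continue;
    if (forNeighbours(i, true, nullptr) >= minPts) core[i] = 1;
  }

  // expand clusters from core points (classic BFS)
  int cluster = 0;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] != 0) continue;
    ++cluster;
    std::queue<int> q;
    labels[i] = cluster;
    q.push(i);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      if (!core[p]) continue;
      nb.clear();
      forNeighbours(p, false, &nb);
      for (int j : nb) {
        if (labels[j] == 0) {
          labels[j] = cluster;
          if (core[j]) q.push(j);
        }
      }
    }
  }
  return labels;
}
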