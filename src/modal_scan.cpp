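#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Modal clustering scan over the 257x257 density grid.
//
// Points at or above `threshold` are processed in descending density order
// (ties by row-major index). A point with no cluster-labelled 4-neighbour
// founds a new cluster (it is a local maximum); a point whose labelled
// 4-neighbours span two or more clusters becomes a boundary point; otherwise
// it joins its neighbour's cluster. As each point is classified, seven of
// its eight surrounding points are marked contiguous with the classified
// set; the omitted diagonal rotates on a counter modulo 4 to keep the
// marking radially symmetric. Below-threshold points are then absorbed
// iteratively: contiguous-marked points with a classified 4-neighbour are
// classified by the same rule (points seeing only boundary neighbours
// extend the boundary; no new clusters are founded below threshold).
//
// labels: 0 = boundary point, k >= 1 = cluster k. Returns too_many = true
// as soon as more than max_clusters clusters are founded (the caller widens
// the kernel and restarts).

static const int N = 257;

static inline int row_major(int idx) {
  // idx is the R column-major linear index: idx = ix + N*iy
  int ix = idx % N, iy = idx / N;
  return ix * N + iy;
}

// [[Rcpp::export]]
List epp_cluster_scan(NumericMatrix density, double threshold,
                      int max_clusters) {
  const int total = N * N;
  const double *d = REAL(density);

  std::vector<int> order(total);
  for (int i = 0; i < total; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (d[a] != d[b]) return d[a] > d[b];
    return row_major(a) < row_major(b);
  });

  // state: -9 unprocessed, -1 boundary, >=1 cluster id
  std::vector<int> lab(total, -9);
  std::vector<char> contig(total, 0);
  std::vector<int> mode_idx;
  std::vector<double> mode_den;
  int n_clusters = 0;
  bool too_many = false;
  int counter = 0;

  const int dx4[4] = {1, -1, 0, 0};
  const int dy4[4] = {0, 0, 1, -1};
  // diagonals in the skip cycle: NE, SE, SW, NW
  const int ddx[4] = {1, 1, -1, -1};
  const int ddy[4] = {1, -1, -1, 1};

  auto mark_contiguous = [&](int idx) {
    int ix = idx % N, iy = idx / N;
    int skip = counter % 4;
    ++counter;
    for (int k = 0; k < 4; ++k) {
      int x = ix + dx4[k], y = iy + dy4[k];
      if (x >= 0 && x < N && y >= 0 && y < N) contig[x + N * y] = 1;
    }
    for (int k = 0; k < 4; ++k) {
      if (k == skip) continue;
      int x = ix + ddx[k], y = iy + ddy[k];
      if (x >= 0 && x < N && y >= 0 && y < N) contig[x + N * y] = 1;
    }
  };

  // classify by the 4-neighbour rule; allow_found enables founding clusters
  // (above-threshold phase only). Returns false if nothing classifiable.
  auto classify = [&](int idx, bool allow_found) -> bool {
    int ix = idx % N, iy = idx / N;
    int l1 = 0, l2 = 0;  // up to two distinct cluster labels seen
    bool any_boundary = false, any_classified = false;
    for (int k = 0; k < 4; ++k) {
      int x = ix + dx4[k], y = iy + dy4[k];
      if (x < 0 || x >= N || y < 0 || y >= N) continue;
      int l = lab[x + N * y];
      if (l == -9) continue;
      any_classified = true;
      if (l == -1) { any_boundary = true; continue; }
      if (l1 == 0) l1 = l;
      else if (l != l1 && l2 == 0) l2 = l;
    }
    if (l1 == 0) {           // no cluster-labelled neighbour
      if (allow_found) {
        lab[idx] = ++n_clusters;
        mode_idx.push_back(idx);
        mode_den.push_back(d[idx]);
        if (n_clusters > max_clusters) too_many = true;
      } else if (any_boundary) {
        lab[idx] = -1;       // extend the boundary below threshold
      } else {
        return false;        // defer: no classified 4-neighbour yet
      }
    } else if (l2 != 0) {
      lab[idx] = -1;         // meeting point of two clusters
    } else {
      lab[idx] = l1;
    }
    mark_contiguous(idx);
    return true;
  };

  // phase 1: points at or above the noise floor
  for (int oi = 0; oi < total && !too_many; ++oi) {
    int idx = order[oi];
    if (d[idx] < threshold) continue;
    classify(idx, true);
  }

  if (!too_many) {
    // phase 2: absorb the below-threshold points
    bool progress = true;
    while (progress) {
      progress = false;
      for (int oi = 0; oi < total; ++oi) {
        int idx = order[oi];
        if (lab[idx] != -9 || !contig[idx]) continue;
        if (classify(idx, false)) progress = true;
      }
    }
    // isolated leftovers (e.g. an all-zero density): nothing was ever
    // classified, or unreachable diagonal chains; absorb by 8-neighbour
    // minimum cluster label, else mark boundary.
    for (int oi = 0; oi < total; ++oi) {
      int idx = order[oi];
      if (lab[idx] != -9) continue;
      int ix = idx % N, iy = idx / N, best = 0;
      for (int ax = -1; ax <= 1; ++ax)
        for (int ay = -1; ay <= 1; ++ay) {
          int x = ix + ax, y = iy + ay;
          if (x < 0 || x >= N || y < 0 || y >= N) continue;
          int l = lab[x + N * y];
          if (l >= 1 && (best == 0 || l < best)) best = l;
        }
      lab[idx] = best >= 1 ? best : -1;
    }
  }

  IntegerMatrix labels(N, N);
  if (!too_many) {
    for (int i = 0; i < total; ++i) labels[i] = (lab[i] == -1) ? 0 : lab[i];
  }
  return List::create(
      _["labels"] = labels, _["n_clusters"] = n_clusters,
      _["too_many"] = too_many,
      _["mode_idx"] = IntegerVector(mode_idx.begin(), mode_idx.end()),
      _["mode_density"] = NumericVector(mode_den.begin(), mode_den.end()));
}

// Resolve boundary points (label 0) to the lowest-numbered 4-adjacent
// cluster, sweeping until none remain; used for the constant-time event
// lookup table and for child-region masks.
// [[Rcpp::export]]
IntegerMatrix epp_resolve_labels(IntegerMatrix labels) {
  IntegerMatrix out = clone(labels);
  const int dx4[4] = {1, -1, 0, 0};
  const int dy4[4] = {0, 0, 1, -1};
  bool progress = true;
  while (progress) {
    progress = false;
    std::vector<std::pair<int, int>> updates;
    for (int iy = 0; iy < N; ++iy)
      for (int ix = 0; ix < N; ++ix) {
        int idx = ix + N * iy;
        if (out[idx] != 0) continue;
        int best = 0;
        for (int k = 0; k < 4; ++k) {
          int x = ix + dx4[k], y = iy + dy4[k];
          if (x < 0 || x >= N || y < 0 || y >= N) continue;
          int l = out[x + N * y];
          if (l >= 1 && (best == 0 || l < best)) best = l;
        }
        if (best >= 1) updates.push_back({idx, best});
      }
    for (auto &u : updates) { out[u.first] = u.second; progress = true; }
  }
  return out;
}
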