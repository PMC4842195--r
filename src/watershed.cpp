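#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

static void conn_offsets2(int conn,
                          std::vector<int>& di, std::vector<int>& dj) {
  di.clear(); dj.clear();
  const int d4i[] = {-1, 1, 0, 0};
  const int d4j[] = { 0, 0,-1, 1};
  const int d8i[] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int d8j[] = {-1, 0, 1,-1, 1,-1, 0, 1};
  if (conn == 4) {
    di.assign(d4i, d4i + 4); dj.assign(d4j, d4j + 4);
  } else {
    di.assign(d8i, d8i + 8); dj.assign(d8j, d8j + 8);
  }
}

// merge two drainage labels: -2 = none yet; 0 = divide (multiple minima)
static inline int merge_lab(int a, int b) {
  if (a == -2) return b;
  if (a == b) return a;
  return 0;
}

// Watershed transform by immersion: pixels are processed in increasing
// surface order; each pixel drains along its minimum-valued lower
// neighbor(s) (FIFO geodesic first-arrival inside plateaus). Pixels whose
// water reaches two or more distinct catchment basins — tied steepest
// routes or equidistant plateau conflicts — become watershed-line pixels
// (label 0). Regional-minimum plateaus seed basins numbered 1..K in
// raster order of each minimum's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& surface, int conn) {
  int h = surface.nrow(), w = surface.ncol(), n = h * w;
  if (n == 0) stop("empty surface");
  std::vector<int> di, dj;
  conn_offsets2(conn, di, dj);
  int nk = (int) di.size();

  // stable sort of pixel indices by surface value (column-major index ties)
  std::vector<int> ord(n);
  for (int p = 0; p < n; ++p) ord[p] = p;
  const double* v = surface.begin();
  std::stable_sort(ord.begin(), ord.end(),
                   [v](int a, int b) { return v[a] < v[b]; });

  std::vector<int> lab(n, -1);   // -1 unassigned; 0 divide; >=1 basin
  std::vector<int> dist(n, -1);  // BFS distance within the current level
  int K = 0;
  std::vector<int> seed;         // first pixel of each basin's minimum
  std::queue<int> fifo;

  int s = 0;
  while (s < n) {
    int e = s;
    double level = v[ord[s]];
    while (e < n && v[ord[e]] == level) ++e;

    // phase A: level pixels with lower neighbors drain along the steepest
    for (int t = s; t < e; ++t) {
      int p = ord[t];
      int i = p % h, j = p / h;
      double mlv = R_PosInf;
      for (int q = 0; q < nk; ++q) {
        int ni = i + di[q], nj = j + dj[q];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        double nv = surface(ni, nj);
        if (nv < level && nv < mlv) mlv = nv;
      }
      if (!R_finite(mlv)) continue; // no lower neighbor
      int m = -2;
      for (int q = 0; q < nk; ++q) {
        int ni = i + di[q], nj = j + dj[q];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        if (surface(ni, nj) == mlv) m = merge_lab(m, lab[ni + nj * h]);
      }
      lab[p] = m;
      dist[p] = 0;
      fifo.push(p);
    }

    // phase B: geodesic FIFO propagation across the level plateau; a pixel
    // reached at its minimal distance from exits of different basins is a
    // divide
    while (!fifo.empty()) {
      int p = fifo.front(); fifo.pop();
      int i = p % h, j = p / h;
      int d = dist[p];
      for (int q = 0; q < nk; ++q) {
        int ni = i + di[q], nj = j + dj[q];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        if (surface(ni, nj) != level) continue;
        int np = ni + nj * h;
        if (lab[np] == -1) {
          lab[np] = lab[p];
          dist[np] = d + 1;
          fifo.push(np);
        } else if (dist[np] == d + 1 && lab[np] != lab[p]) {
          lab[np] = 0;
        }
      }
    }

    // phase C: untouched level pixels form regional-minimum plateaus
    for (int t = s; t < e; ++t) {
      int p0 = ord[t];
      if (lab[p0] != -1) continue;
      ++K;
      seed.push_back(p0);
      lab[p0] = K;
      fifo.push(p0);
      while (!fifo.empty()) {
        int p = fifo.front(); fifo.pop();
        int i = p % h, j = p / h;
        for (int q = 0; q < nk; ++q) {
          int ni = i + di[q], nj = j + dj[q];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          int np = ni + nj * h;
          if (surface(ni, nj) == level && lab[np] == -1) {
            lab[np] = K;
            fifo.push(np);
          }
        }
      }
    }
    s = e;
  }

  // renumber basins by raster order of each seeding minimum's first pixel
  std::vector<int> rank_of(K + 1, 0);
  std::vector<int> order_k(K);
  for (int k = 0; k < K; ++k) order_k[k] = k;
  std::sort(order_k.begin(), order_k.end(),
            [&seed](int a, int b) { return seed[a] < seed[b]; });
  for (int r = 0; r < K; ++r) rank_of[order_k[r] + 1] = r + 1;
  IntegerMatrix out(h, w);
  for (int p = 0; p < n; ++p) out[p] = lab[p] > 0 ? rank_of[lab[p]] : 0;
  return out;
}
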