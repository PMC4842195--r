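#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighborhood offsets for 4- or 8-connectivity, (di, dj) pairs.
static void conn_offsets(int conn,
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

// Min (erosion) or max (dilation) filter over an arbitrary flat footprint.
// The footprint is applied as given; reflection for dilation happens in R.
// Out-of-bounds neighbors are ignored (footprint restricted to the domain).
// [[Rcpp::export]]
NumericMatrix cpp_minmax_filter(const NumericMatrix& img,
                                const LogicalMatrix& fp,
                                int oi, int oj, bool take_max) {
  int h = img.nrow(), w = img.ncol();
  int fh = fp.nrow(), fw = fp.ncol();
  std::vector<int> di, dj;
  for (int fj = 0; fj < fw; ++fj)
    for (int fi = 0; fi < fh; ++fi)
      if (fp(fi, fj)) { di.push_back(fi - oi); dj.push_back(fj - oj); }
  if (di.empty()) stop("structuring element footprint is empty");
  NumericMatrix out(h, w);
  int k = (int) di.size();
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = take_max ? R_NegInf : R_PosInf;
      for (int m = 0; m < k; ++m) {
        int ni = i + di[m], nj = j + dj[m];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        double v = img(ni, nj);
        if (take_max) { if (v > acc) acc = v; }
        else          { if (v < acc) acc = v; }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Grayscale reconstruction by dilation: hybrid raster-sweep + FIFO queue
// (Vincent-style). Semantically the limit of iterated unit geodesic
// dilations of `marker` under `mask`.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(const NumericMatrix& marker,
                                       const NumericMatrix& mask,
                                       int conn) {
  int h = marker.nrow(), w = marker.ncol();
  NumericMatrix J = clone(marker);
  std::vector<int> di, dj;
  conn_offsets(conn, di, dj);
  int k = (int) di.size();

  // forward sweep (column-major raster order): neighbors already visited
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double m = J(i, j);
      for (int q = 0; q < k; ++q) {
        if (dj[q] > 0 || (dj[q] == 0 && di[q] >= 0)) continue; // not prior
        int ni = i + di[q], nj = j + dj[q];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        if (J(ni, nj) > m) m = J(ni, nj);
      }
      J(i, j) = std::min(m, mask(i, j));
    }
  }
  // backward sweep + queue initialization
  std::queue<int> fifo;
  for (int j = w - 1; j >= 0; --j) {
    for (int i = h - 1; i >= 0; --i) {
      double m = J(i, j);
      for (int q = 0; q < k; ++q) {
        if (dj[q] < 0 || (dj[q] == 0 && di[q] <= 0)) continue; // not later
        int ni = i + di[q], nj = j + dj[q];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        if (J(ni, nj) > m) m = J(ni, nj);
      }
      J(i, j) = std::min(m, mask(i, j));
      for (int q = 0; q < k; ++q) {
        if (dj[q] < 0 || (dj[q] == 0 && di[q] <= 0)) continue;
        int ni = i + di[q], nj = j + dj[q];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        if (J(ni, nj) < J(i, j) && J(ni, nj) < mask(ni, nj)) {
          fifo.push(i + j * h);
          break;
        }
      }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % h, j = p / h;
    double jp = J(i, j);
    for (int q = 0; q < k; ++q) {
      int ni = i + di[q], nj = j + dj[q];
      if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
      if (J(ni, nj) < jp && J(ni, nj) < mask(ni, nj)) {
        J(ni, nj) = std::min(jp, mask(ni, nj));
        fifo.push(ni + nj * h);
      }
    }
  }
  return J;
}

// Regional maxima: connected equal-value plateaus all of whose external
// neighbors are strictly lower. A constant image is entirely a maximum
// (the condition is vacuous). Minima are obtained in R by negating.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(const NumericMatrix& img, int conn) {
  int h = img.nrow(), w = img.ncol(), n = h * w;
  std::vector<int> di, dj;
  conn_offsets(conn, di, dj);
  int k = (int) di.size();
  LogicalMatrix out(h, w);
  std::vector<char> visited(n, 0);
  std::vector<int> comp; comp.reserve(n);
  std::queue<int> fifo;
  for (int j0 = 0; j0 < w; ++j0) {
    for (int i0 = 0; i0 < h; ++i0) {
      int p0 = i0 + j0 * h;
      if (visited[p0]) continue;
      double v = img(i0, j0);
      bool is_max = true;
      comp.clear();
      visited[p0] = 1; fifo.push(p0);
      while (!fifo.empty()) {
        int p = fifo.front(); fifo.pop();
        comp.push_back(p);
        int i = p % h, j = p / h;
        for (int q = 0; q < k; ++q) {
          int ni = i + di[q], nj = j + dj[q];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          double nv = img(ni, nj);
          if (nv == v) {
            int np = ni + nj * h;
            if (!visited[np]) { visited[np] = 1; fifo.push(np); }
          } else if (nv > v) {
            is_max = false;
          }
        }
      }
      if (is_max)
        for (size_t m = 0; m < comp.size(); ++m)
          out[comp[m]] = true;
    }
  }
  return out;
}

// Connected components of a binary mask, labeled 1..K in raster order of
// each component's first pixel (column-major). Background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int conn) {
  int h = mask.nrow(), w = mask.ncol();
  std::vector<int> di, dj;
  conn_offsets(conn, di, dj);
  int k = (int) di.size();
  IntegerMatrix lab(h, w);
  int K = 0;
  std::queue<int> fifo;
  for (int j0 = 0; j0 < w; ++j0) {
    for (int i0 = 0; i0 < h; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++K;
      lab(i0, j0) = K;
      fifo.push(i0 + j0 * h);
      while (!fifo.empty()) {
        int p = fifo.front(); fifo.pop();
        int i = p % h, j = p / h;
        for (int q = 0; q < k; ++q) {
          int ni = i + di[q], nj = j + dj[q];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = K;
            fifo.push(ni + nj * h);
          }
        }
      }
    }
  }
  return lab;
}
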