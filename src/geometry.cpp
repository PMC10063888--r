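#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Raster conventions: an image is an integer matrix indexed [x, y]
// (first dimension along the horizontal image axis), pixel centers at
// integer coordinates, 1-based as in R.

// Stamp a sequence of filled disks along a polyline, producing a band of
// constant (or per-point) width.  `radii` is the stamp radius per sample
// point; a pixel is set when its center lies within the radius.  Writes the
// label `code` in place.
// [[Rcpp::export]]
void cpp_stamp_band(IntegerMatrix labels, NumericVector xs, NumericVector ys,
                    NumericVector radii, int code) {
  const int W = labels.nrow(), H = labels.ncol();
  const int n = xs.size();
  for (int k = 0; k < n; ++k) {
    const double x = xs[k], y = ys[k], r = radii[k];
    if (r < 0) continue;
    const int x0 = std::max(1, (int)std::ceil(x - r));
    const int x1 = std::min(W, (int)std::floor(x + r));
    const int y0 = std::max(1, (int)std::ceil(y - r));
    const int y1 = std::min(H, (int)std::floor(y + r));
    const double r2 = r * r;
    for (int j = y0; j <= y1; ++j) {
      const double dy = j - y, dy2 = dy * dy;
      for (int i = x0; i <= x1; ++i) {
        const double dx = i - x;
        if (dx * dx + dy2 <= r2) labels(i - 1, j - 1) = code;
      }
    }
  }
}

// Fill an axis-aligned ellipse (the optic disc) with label `code`.
// [[Rcpp::export]]
void cpp_fill_ellipse(IntegerMatrix labels, double cx, double cy,
                      double rx, double ry, int code) {
  const int W = labels.nrow(), H = labels.ncol();
  const int x0 = std::max(1, (int)std::ceil(cx - rx));
  const int x1 = std::min(W, (int)std::floor(cx + rx));
  const int y0 = std::max(1, (int)std::ceil(cy - ry));
  const int y1 = std::min(H, (int)std::floor(cy + ry));
  if (rx <= 0 || ry <= 0) return;
  for (int j = y0; j <= y1; ++j) {
    const double v = (j - cy) / ry, v2 = v * v;
    for (int i = x0; i <= x1; ++i) {
      const double u = (i - cx) / rx;
      if (u * u + v2 <= 1.0) labels(i - 1, j - 1) = code;
    }
  }
}

static inline int nb_offsets(const int W, int idx, int* nb) {
  // 8-neighborhood linear offsets for column-major [x, y] storage,
  // clockwise from north (y - 1): P2..P9 of the Zhang-Suen ordering.
  nb[0] = idx - W;       // N
  nb[1] = idx - W + 1;   // NE
  nb[2] = idx + 1;       // E
  nb[3] = idx + W + 1;   // SE
  nb[4] = idx + W;       // S
  nb[5] = idx + W - 1;   // SW
  nb[6] = idx - 1;       // W
  nb[7] = idx - W - 1;   // NW
  return 8;
}

// Zhang-Suen morphological thinning of a binary mask to a 1-px skeleton.
// Pixels outside the image are treated as background.  Works on an active
// pixel list so cost is proportional to the foreground, not the frame.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int W = mask.nrow(), H = mask.ncol();
  std::vector<char> img((size_t)(W + 2) * (H + 2), 0);
  // pad by one background pixel on every side
  const int Wp = W + 2;
  std::vector<int> active;
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < W; ++i)
      if (mask(i, j)) {
        int idx = (j + 1) * Wp + (i + 1);
        img[idx] = 1;
        active.push_back(idx);
      }
  int nb[8];
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (size_t k = 0; k < active.size(); ++k) {
        const int idx = active[k];
        if (!img[idx]) continue;
        nb_offsets(Wp, idx, nb);
        int B = 0, A = 0;
        char p[8];
        for (int t = 0; t < 8; ++t) { p[t] = img[nb[t]]; B += p[t]; }
        if (B < 2 || B > 6) continue;
        for (int t = 0; t < 8; ++t)
          if (!p[t] && p[(t + 1) % 8]) ++A;
        if (A != 1) continue;
        // p[0]=N, p[2]=E, p[4]=S, p[6]=W
        if (sub == 0) {
          if (p[0] && p[2] && p[4]) continue;
          if (p[2] && p[4] && p[6]) continue;
        } else {
          if (p[0] && p[2] && p[6]) continue;
          if (p[0] && p[4] && p[6]) continue;
        }
        kill.push_back(idx);
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
      }
    }
    // compact the active list
    size_t keep = 0;
    for (size_t k = 0; k < active.size(); ++k)
      if (img[active[k]]) active[keep++] = active[k];
    active.resize(keep);
  }
  LogicalMatrix out(W, H);
  for (size_t k = 0; k < active.size(); ++k) {
    const int idx = active[k];
    out((idx % Wp) - 1, (idx / Wp) - 1) = true;
  }
  return out;
}

// Shortest 8-connected path between two pixels of a skeleton point set,
// by Dijkstra with unit/diagonal step costs.  `coords` is an n x 2 matrix
// of (x, y); start/end are 1-based row indices into it.  Returns the
// ordered (x, y) path, or a 0-row matrix when disconnected.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_path(IntegerMatrix coords, int start, int end) {
  const int n = coords.nrow();
  std::unordered_map<long long, int> pos;
  pos.reserve(n * 2);
  for (int k = 0; k < n; ++k)
    pos[(long long)coords(k, 0) * 100000000LL + coords(k, 1)] = k;
  std::vector<double> dist(n, -1.0);
  std::vector<int> prev(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  const int s = start - 1, e = end - 1;
  dist[s] = 0.0;
  q.push(QE(0.0, s));
  const double SQ2 = std::sqrt(2.0);
  while (!q.empty()) {
    QE top = q.top(); q.pop();
    const int u = top.second;
    if (top.first > dist[u] + 1e-12) continue;
    if (u == e) break;
    const int x = coords(u, 0), y = coords(u, 1);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (!dx && !dy) continue;
        std::unordered_map<long long, int>::iterator it =
          pos.find((long long)(x + dx) * 100000000LL + (y + dy));
        if (it == pos.end()) continue;
        const int v = it->second;
        const double w = (dx && dy) ? SQ2 : 1.0;
        if (dist[v] < 0 || dist[u] + w < dist[v] - 1e-12) {
          dist[v] = dist[u] + w;
          prev[v] = u;
          q.push(QE(dist[v], v));
        }
      }
  }
  if (dist[e] < 0) return IntegerMatrix(0, 2);
  std::vector<int> path;
  for (int u = e; u != -1; u = prev[u]) path.push_back(u);
  IntegerMatrix out(path.size(), 2);
  for (size_t k = 0; k < path.size(); ++k) {
    const int u = path[path.size() - 1 - k];
    out(k, 0) = coords(u, 0);
    out(k, 1) = coords(u, 1);
  }
  return out;
}

// Exact Euclidean distance from given foreground pixels to the nearest
// background pixel, searched over offsets sorted by radius with early
// termination.  Pixels outside the image are not background (matching
// the usual distance-transform convention for clipped structures).
// `px`, `py` are 1-based coordinates; `maxR` caps the search.
// [[Rcpp::export]]
NumericVector cpp_nearest_bg(LogicalMatrix mask, IntegerVector px,
                             IntegerVector py, double maxR) {
  const int W = mask.nrow(), H = mask.ncol();
  const int R = (int)std::ceil(maxR);
  // offsets sorted by distance
  std::vector<int> ox, oy;
  std::vector<double> od;
  ox.reserve((2 * R + 1) * (2 * R + 1));
  for (int dx = -R; dx <= R; ++dx)
    for (int dy = -R; dy <= R; ++dy) {
      const double d = std::sqrt((double)dx * dx + (double)dy * dy);
      if (d <= maxR && (dx || dy)) {
        ox.push_back(dx); oy.push_back(dy); od.push_back(d);
      }
    }
  std::vector<size_t> ord(ox.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(),
            [&od](size_t a, size_t b) { return od[a] < od[b]; });
  const int n = px.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    const int x = px[k], y = py[k];
    double best = R_PosInf;
    for (size_t t = 0; t < ord.size(); ++t) {
      const size_t o = ord[t];
      if (od[o] >= best) break;
      const int xx = x + ox[o], yy = y + oy[o];
      if (xx < 1 || xx > W || yy < 1 || yy > H) continue;
      if (!mask(xx - 1, yy - 1)) { best = od[o]; break; }
    }
    out[k] = best;
  }
  return out;
}

// Ridge-corrected half-width at skeleton points: the maximum
// nearest-background distance over the 3x3 neighborhood (restricted to
// the mask), compensating the off-ridge jitter of thinned skeletons.
// [[Rcpp::export]]
NumericVector cpp_ridge_halfwidth(LogicalMatrix mask, IntegerVector px,
                                  IntegerVector py, double maxR) {
  const int W = mask.nrow(), H = mask.ncol();
  const int n = px.size();
  std::vector<int> qx, qy;
  std::vector<int> owner;
  qx.reserve(9 * n); qy.reserve(9 * n); owner.reserve(9 * n);
  for (int k = 0; k < n; ++k)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        const int xx = px[k] + dx, yy = py[k] + dy;
        if (xx < 1 || xx > W || yy < 1 || yy > H) continue;
        if (!mask(xx - 1, yy - 1)) continue;
        qx.push_back(xx); qy.push_back(yy); owner.push_back(k);
      }
  IntegerVector qxv(qx.begin(), qx.end()), qyv(qy.begin(), qy.end());
  NumericVector d = cpp_nearest_bg(mask, qxv, qyv, maxR);
  NumericVector out(n, R_NegInf);
  for (size_t t = 0; t < qx.size(); ++t)
    if (d[t] > out[owner[t]]) out[owner[t]] = d[t];
  return out;
}
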