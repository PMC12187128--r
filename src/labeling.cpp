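// 3D labelling primitives: 26-connected components, exact Euclidean
// distance transform, seeded watershed / masked Voronoi flooding,
// regional maxima with plateau handling, separable filtering, and
// border-pair statistics for label merging.
//
// Volumes are (Z, Y, X) column-major: index(z,y,x) = z + Z*(y + Y*x).

#include <Rcpp.h>
#include <queue>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Nbh26 {
  int dz[26], dy[26], dx[26];
  double step[26];
  Nbh26() {
    int n = 0;
    for (int x = -1; x <= 1; ++x)
      for (int y = -1; y <= 1; ++y)
        for (int z = -1; z <= 1; ++z) {
          if (x == 0 && y == 0 && z == 0) continue;
          dz[n] = z; dy[n] = y; dx[n] = x;
          step[n] = std::sqrt((double)(x * x + y * y + z * z));
          ++n;
        }
  }
};
static const Nbh26 NB;

static inline R_xlen_t vidx(int z, int y, int x, int Z, int Y) {
  return z + (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
}

// 26-connected components of a logical mask, labelled 1..n in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % Z), y = (int)((cur / Z) % Y), x = (int)(cur / ((R_xlen_t)Z * Y));
      for (int k = 0; k < 26; ++k) {
        int zz = z + NB.dz[k], yy = y + NB.dy[k], xx = x + NB.dx[k];
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
        R_xlen_t j = vidx(zz, yy, xx, Z, Y);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// One pass of Felzenszwalb & Huttenlocher's 1D squared distance transform.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n) {
  int k = 0;
  v[0] = 0; zb[0] = R_NegInf; zb[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from every voxel to the nearest
// FALSE voxel of `fg` (0 on the background itself).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  NumericVector out(n);
  const double BIG = 1e20;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? BIG : 0.0;
  int m = std::max(Z, std::max(Y, X));
  std::vector<double> f(m), d(m), zb(m + 1);
  std::vector<int> v(m);
  // along z
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y) {
      for (int z = 0; z < Z; ++z) f[z] = out[vidx(z, y, x, Z, Y)];
      dt1d(f, d, v, zb, Z);
      for (int z = 0; z < Z; ++z) out[vidx(z, y, x, Z, Y)] = d[z];
    }
  // along y
  for (int x = 0; x < X; ++x)
    for (int z = 0; z < Z; ++z) {
      for (int y = 0; y < Y; ++y) f[y] = out[vidx(z, y, x, Z, Y)];
      dt1d(f, d, v, zb, Y);
      for (int y = 0; y < Y; ++y) out[vidx(z, y, x, Z, Y)] = d[y];
    }
  // along x
  for (int y = 0; y < Y; ++y)
    for (int z = 0; z < Z; ++z) {
      for (int x = 0; x < X; ++x) f[x] = out[vidx(z, y, x, Z, Y)];
      dt1d(f, d, v, zb, X);
      for (int x = 0; x < X; ++x) out[vidx(z, y, x, Z, Y)] = d[x];
    }
  return out;
}

// Regional maxima under 26-connectivity; each connected equal-value
// plateau with no strictly greater neighbour becomes one seed label.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector vol, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector lab(n);
  std::vector<char> visited(n, 0);
  std::vector<R_xlen_t> stack, plateau;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (visited[i]) continue;
    double val = vol[i];
    bool is_max = true;
    plateau.clear();
    stack.push_back(i);
    visited[i] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      plateau.push_back(cur);
      int z = (int)(cur % Z), y = (int)((cur / Z) % Y), x = (int)(cur / ((R_xlen_t)Z * Y));
      for (int k = 0; k < 26; ++k) {
        int zz = z + NB.dz[k], yy = y + NB.dy[k], xx = x + NB.dx[k];
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
        R_xlen_t j = vidx(zz, yy, xx, Z, Y);
        if (vol[j] > val) is_max = false;
        else if (vol[j] == val && !visited[j]) { visited[j] = 1; stack.push_back(j); }
      }
    }
    if (is_max) {
      ++next;
      for (R_xlen_t p : plateau) lab[p] = next;
    }
  }
  return lab;
}

struct QItem {
  double key; R_xlen_t order; R_xlen_t idx; int label;
  bool operator>(const QItem &o) const {
    if (key != o.key) return key > o.key;
    return order > o.order;  // FIFO tie-break for determinism
  }
};

// Masked Voronoi partition: every masked voxel is assigned the label of
// the seed reachable with the smallest 26-neighbour geodesic distance.
// [[Rcpp::export]]
IntegerVector cpp_voronoi_flood(IntegerVector seeds, LogicalVector mask,
                                IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector lab(n);
  std::vector<double> dist(n, R_PosInf);
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  R_xlen_t ord = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      dist[i] = 0.0;
      pq.push(QItem{0.0, ord++, i, seeds[i]});
    }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    if (lab[it.idx]) continue;
    lab[it.idx] = it.label;
    int z = (int)(it.idx % Z), y = (int)((it.idx / Z) % Y),
        x = (int)(it.idx / ((R_xlen_t)Z * Y));
    for (int k = 0; k < 26; ++k) {
      int zz = z + NB.dz[k], yy = y + NB.dy[k], xx = x + NB.dx[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      R_xlen_t j = vidx(zz, yy, xx, Z, Y);
      if (!mask[j] || lab[j]) continue;
      double nd = it.key + NB.step[k];
      if (nd < dist[j]) {
        dist[j] = nd;
        pq.push(QItem{nd, ord++, j, it.label});
      }
    }
  }
  return lab;
}

// Meyer-style seeded watershed: masked voxels are flooded from the seeds
// in order of increasing elevation.
// [[Rcpp::export]]
IntegerVector cpp_watershed_flood(NumericVector elev, IntegerVector seeds,
                                  LogicalVector mask, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector lab(n);
  std::vector<char> queued(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  R_xlen_t ord = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      queued[i] = 1;
      pq.push(QItem{elev[i], ord++, i, seeds[i]});
    }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    if (lab[it.idx]) continue;
    lab[it.idx] = it.label;
    int z = (int)(it.idx % Z), y = (int)((it.idx / Z) % Y),
        x = (int)(it.idx / ((R_xlen_t)Z * Y));
    for (int k = 0; k < 26; ++k) {
      int zz = z + NB.dz[k], yy = y + NB.dy[k], xx = x + NB.dx[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      R_xlen_t j = vidx(zz, yy, xx, Z, Y);
      if (!mask[j] || lab[j] || queued[j]) continue;
      queued[j] = 1;
      pq.push(QItem{elev[j], ord++, j, it.label});
    }
  }
  return lab;
}

// 1D correlation along one axis (0=z, 1=y, 2=x) with mirror ("reflect")
// boundary; kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_sepconv(NumericVector vol, IntegerVector dims,
                          NumericVector kernel, int axis) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int kl = kernel.size(), kh = kl / 2;
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  NumericVector out(n);
  int len = axis == 0 ? Z : (axis == 1 ? Y : X);
  for (R_xlen_t i = 0; i < n; ++i) {
    int z = (int)(i % Z), y = (int)((i / Z) % Y), x = (int)(i / ((R_xlen_t)Z * Y));
    int pos = axis == 0 ? z : (axis == 1 ? y : x);
    double acc = 0.0;
    for (int k = -kh; k <= kh; ++k) {
      int p = pos + k;
      if (p < 0) p = -p - 1;          // reflect about the edge
      if (p >= len) p = 2 * len - p - 1;
      R_xlen_t j;
      if (axis == 0) j = vidx(p, y, x, Z, Y);
      else if (axis == 1) j = vidx(z, p, x, Z, Y);
      else j = vidx(z, y, p, Z, Y);
      acc += vol[j] * kernel[k + kh];
    }
    out[i] = acc;
  }
  return out;
}

// For every 26-adjacent pair of distinct positive labels, the mean
// intensity over the (unique) voxels making up the shared border.
// [[Rcpp::export]]
List cpp_border_pairs(IntegerVector labels, NumericVector vol,
                      IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  std::map<std::pair<int, int>, std::vector<R_xlen_t> > border;
  for (R_xlen_t i = 0; i < n; ++i) {
    int a = labels[i];
    if (a <= 0) continue;
    int z = (int)(i % Z), y = (int)((i / Z) % Y), x = (int)(i / ((R_xlen_t)Z * Y));
    for (int k = 0; k < 26; ++k) {
      int zz = z + NB.dz[k], yy = y + NB.dy[k], xx = x + NB.dx[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      R_xlen_t j = vidx(zz, yy, xx, Z, Y);
      int b = labels[j];
      if (b <= 0 || b == a) continue;
      std::pair<int, int> key(std::min(a, b), std::max(a, b));
      border[key].push_back(i);
      border[key].push_back(j);
    }
  }
  const int np = (int)border.size();
  IntegerVector la(np), lb(np);
  NumericVector mean_int(np);
  int r = 0;
  for (auto &kv : border) {
    std::vector<R_xlen_t> &v = kv.second;
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    double s = 0.0;
    for (R_xlen_t j : v) s += vol[j];
    la[r] = kv.first.first;
    lb[r] = kv.first.second;
    mean_int[r] = s / v.size();
    ++r;
  }
  return List::create(_["a"] = la, _["b"] = lb, _["border_mean"] = mean_int);
}
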