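#include <Rcpp.h>
#include <queue>
#include <functional>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Image geometry primitives shared by segmentation and simulation.
// All matrices are row x col; labels use 0 = background.

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Felzenszwalb & Huttenlocher 1D squared-distance transform of a sampled
// function f; result in d. v/z are scratch of size n and n+1.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    if (f[v[k]] == INF) { d[q] = INF; continue; }
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest pixel of
// the zero set (pixels where `zero` != 0).
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericMatrix cpp_edt_sq(IntegerMatrix zero) {
  int nr = zero.nrow(), nc = zero.ncol();
  NumericMatrix d(nr, nc);
  for (int i = 0; i < nr * nc; i++) d[i] = zero[i] != 0 ? 0.0 : INF;

  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // transform columns
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = d(i, j);
    dt1d(f, dd, v, z, nr);
    for (int i = 0; i < nr; i++) d(i, j) = dd[i];
  }
  // transform rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = d(i, j);
    dt1d(f, dd, v, z, nc);
    for (int j = 0; j < nc; j++) d(i, j) = dd[j];
  }
  return d;
}

// ---------------------------------------------------------------------------
// Two-pass 4/8-connected component labelling; components renumbered 1..K in
// raster order of first occurrence.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(IntegerMatrix fg, int connectivity) {
  int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 1;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!fg(i, j)) continue;
      int up = (i > 0) ? lab(i - 1, j) : 0;
      int left = (j > 0) ? lab(i, j - 1) : 0;
      int ul = (connectivity == 8 && i > 0 && j > 0) ? lab(i - 1, j - 1) : 0;
      int dl = (connectivity == 8 && i < nr - 1 && j > 0) ? lab(i + 1, j - 1) : 0;
      int neigh[4] = {up, left, ul, dl};
      int cur = 0;
      for (int t = 0; t < 4; t++)
        if (neigh[t] > 0) cur = cur == 0 ? neigh[t] : std::min(cur, neigh[t]);
      if (cur == 0) {
        parent.push_back(next);
        cur = next++;
      } else {
        for (int t = 0; t < 4; t++) if (neigh[t] > 0) unite(cur, neigh[t]);
      }
      lab(i, j) = cur;
    }
  }
  // flatten and renumber in raster order (column-major raster is fine: it is
  // deterministic and consistent between runs)
  std::vector<int> newid(next, 0);
  int k = 0;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (lab(i, j)) {
        int r = find(lab(i, j));
        if (!newid[r]) newid[r] = ++k;
      }
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (lab(i, j)) lab(i, j) = newid[find(lab(i, j))];
  return lab;
}

// ---------------------------------------------------------------------------
// Nearest-label Voronoi expansion: every background pixel within Euclidean
// distance <= radius of some label gets the label of the nearest labelled
// pixel; ties go to the lower label id. Exact (per-label windowed EDT with
// strict improvement in ascending label order).
// [[Rcpp::export(name = ".cpp_expand_labels")]]
IntegerMatrix cpp_expand_labels(IntegerMatrix labels, double radius) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out(nr, nc);
  NumericMatrix best(nr, nc);
  int maxlab = 0;
  for (int i = 0; i < nr * nc; i++) {
    best[i] = labels[i] > 0 ? 0.0 : INF;
    out[i] = labels[i];
    if (labels[i] > maxlab) maxlab = labels[i];
  }
  if (maxlab == 0 || radius <= 0) return out;
  double r2 = radius * radius;
  int R = (int)std::ceil(radius);

  // bounding boxes per label
  std::vector<int> rmin(maxlab + 1, nr), rmax(maxlab + 1, -1),
                   cmin(maxlab + 1, nc), cmax(maxlab + 1, -1);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      int L = labels(i, j);
      if (L > 0) {
        rmin[L] = std::min(rmin[L], i); rmax[L] = std::max(rmax[L], i);
        cmin[L] = std::min(cmin[L], j); cmax[L] = std::max(cmax[L], j);
      }
    }

  int wmax = std::max(nr, nc);
  std::vector<double> f(wmax), dd(wmax), z(wmax + 1);
  std::vector<int> v(wmax);

  for (int L = 1; L <= maxlab; L++) {
    if (rmax[L] < 0) continue;
    int r0 = std::max(0, rmin[L] - R), r1 = std::min(nr - 1, rmax[L] + R);
    int c0 = std::max(0, cmin[L] - R), c1 = std::min(nc - 1, cmax[L] + R);
    int h = r1 - r0 + 1, w = c1 - c0 + 1;
    NumericMatrix d(h, w);
    for (int j = 0; j < w; j++)
      for (int i = 0; i < h; i++)
        d(i, j) = labels(r0 + i, c0 + j) == L ? 0.0 : INF;
    for (int j = 0; j < w; j++) {
      for (int i = 0; i < h; i++) f[i] = d(i, j);
      dt1d(f, dd, v, z, h);
      for (int i = 0; i < h; i++) d(i, j) = dd[i];
    }
    for (int i = 0; i < h; i++) {
      for (int j = 0; j < w; j++) f[j] = d(i, j);
      dt1d(f, dd, v, z, w);
      for (int j = 0; j < w; j++) d(i, j) = dd[j];
    }
    for (int i = 0; i < h; i++)
      for (int j = 0; j < w; j++) {
        double dv = d(i, j);
        // squared distances between integer grid points are exact in doubles,
        // so strict < keeps the lower (earlier) label on ties
        if (dv <= r2 && dv < best(r0 + i, c0 + j)) {
          best(r0 + i, c0 + j) = dv;
          out(r0 + i, c0 + j) = L;
        }
      }
  }
  return out;
}

// Brute-force O(N*M) oracle for the same assignment; used only by tests.
// [[Rcpp::export(name = ".cpp_expand_labels_brute")]]
IntegerMatrix cpp_expand_labels_brute(IntegerMatrix labels, double radius) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> li, lj, ll;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (labels(i, j) > 0) { li.push_back(i); lj.push_back(j); ll.push_back(labels(i, j)); }
  // sort source pixels by label id so strict < keeps the lowest label on ties
  std::vector<size_t> ord(li.size());
  for (size_t t = 0; t < ord.size(); t++) ord[t] = t;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return ll[a] < ll[b]; });
  double r2 = radius * radius;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      if (labels(i, j) > 0) { out(i, j) = labels(i, j); continue; }
      double bd = INF; int bl = 0;
      for (size_t t = 0; t < ord.size(); t++) {
        size_t s = ord[t];
        double di = i - (double)li[s], dj = j - (double)lj[s];
        double d2 = di * di + dj * dj;
        if (d2 < bd) { bd = d2; bl = ll[s]; }
      }
      out(i, j) = (bd <= r2) ? bl : 0;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Add isotropic Gaussians (peak amp[i], sd sigma[i], 0-based centers y/x) to
// an image, each truncated to a +/- 4 sigma window. Used by the simulator.
// [[Rcpp::export(name = ".cpp_render_spots")]]
NumericMatrix cpp_render_spots(NumericMatrix img, NumericVector y,
                               NumericVector x, NumericVector amp,
                               NumericVector sigma) {
  NumericMatrix out = clone(img);
  int nr = out.nrow(), nc = out.ncol();
  for (int s = 0; s < y.size(); s++) {
    double sg = sigma[s];
    int h = (int)std::ceil(4.0 * sg);
    int r0 = std::max(0, (int)std::floor(y[s] - h));
    int r1 = std::min(nr - 1, (int)std::ceil(y[s] + h));
    int c0 = std::max(0, (int)std::floor(x[s] - h));
    int c1 = std::min(nc - 1, (int)std::ceil(x[s] + h));
    double inv = 1.0 / (2.0 * sg * sg);
    for (int j = c0; j <= c1; j++) {
      double dx = j - x[s];
      for (int i = r0; i <= r1; i++) {
        double dy = i - y[s];
        out(i, j) += amp[s] * std::exp(-(dx * dx + dy * dy) * inv);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marker-based watershed by priority flood: regions grow from markers in
// increasing elevation order, restricted to mask pixels. 8-connected,
// deterministic (FIFO tie-break by insertion order).
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(NumericMatrix elev, IntegerMatrix markers,
                            IntegerMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  struct QE { double pri; long long ord; int i, j; };
  struct Cmp {
    bool operator()(const QE& a, const QE& b) const {
      if (a.pri != b.pri) return a.pri > b.pri;
      return a.ord > b.ord;
    }
  };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  long long ord = 0;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push({elev(i, j), ord++, i, j});
      }
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    int L = lab(e.i, e.j);
    for (int t = 0; t < 8; t++) {
      int ni = e.i + di[t], nj = e.j + dj[t];
      if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = L;
      pq.push({elev(ni, nj), ord++, ni, nj});
    }
  }
  return lab;
}
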