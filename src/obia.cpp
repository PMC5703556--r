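// Low-level raster engines: multiresolution region merging, 4-connected
// component labelling, windowed local maxima and seeded region growing.
// All matrices are column-major (R layout); pixel index i = r + c*nr.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Region {
  bool active = false;
  double n = 0.0;
  double perim = 0.0;                 // boundary edge count (incl. image edge / nodata)
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  uint32_t version = 0;
  std::vector<double> sum, sumsq, sd; // per layer
  // neighbour region id -> shared border length (pixel edges)
  std::vector<std::pair<int, int> > nb;
};

inline double popSd(double n, double s, double q) {
  double v = q / n - (s / n) * (s / n);
  return v > 0.0 ? std::sqrt(v) : 0.0;
}

// Baatz-Schaepe-style heterogeneity increase of merging a and b.
double mergeCost(const Region& a, const Region& b, int shared,
                 const std::vector<double>& w, double shapeW, double compactW) {
  const size_t L = w.size();
  double nm = a.n + b.n;
  double colour = 0.0;
  for (size_t l = 0; l < L; ++l) {
    if (w[l] == 0.0) continue;
    double s = a.sum[l] + b.sum[l], q = a.sumsq[l] + b.sumsq[l];
    double sdm = popSd(nm, s, q);
    colour += w[l] * (nm * sdm - a.n * a.sd[l] - b.n * b.sd[l]);
  }
  double pm = a.perim + b.perim - 2.0 * shared;
  int rmin = std::min(a.rmin, b.rmin), rmax = std::max(a.rmax, b.rmax);
  int cmin = std::min(a.cmin, b.cmin), cmax = std::max(a.cmax, b.cmax);
  double bm = 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
  double ba = 2.0 * ((a.rmax - a.rmin + 1) + (a.cmax - a.cmin + 1));
  double bb = 2.0 * ((b.rmax - b.rmin + 1) + (b.cmax - b.cmin + 1));
  double cmp = std::sqrt(nm) * pm - std::sqrt(a.n) * a.perim - std::sqrt(b.n) * b.perim;
  double smo = nm * pm / bm - a.n * a.perim / ba - b.n * b.perim / bb;
  double shape = compactW * cmp + (1.0 - compactW) * smo;
  return (1.0 - shapeW) * colour + shapeW * shape;
}

inline int nbFind(const std::vector<std::pair<int, int> >& v, int id) {
  for (size_t i = 0; i < v.size(); ++i) if (v[i].first == id) return (int)i;
  return -1;
}

} // namespace

// [[Rcpp::export(name = ".cpp_segment")]]
IntegerMatrix cpp_segment(List layers, NumericVector weights, double scale,
                          double shapeW, double compactW, LogicalMatrix valid) {
  const int nr = valid.nrow(), nc = valid.ncol();
  const size_t L = (size_t)layers.size();
  if ((size_t)weights.size() != L) stop("one weight per layer required");
  std::vector<const double*> lay(L);
  for (size_t l = 0; l < L; ++l) {
    NumericMatrix m = layers[l];
    if (m.nrow() != nr || m.ncol() != nc) stop("layer shape mismatch");
    lay[l] = REAL(m);
  }
  std::vector<double> w(weights.begin(), weights.end());
  const double scale2 = scale * scale;
  const int npix = nr * nc;

  std::vector<Region> reg((size_t)npix);
  std::vector<int> parent((size_t)npix);
  for (int i = 0; i < npix; ++i) parent[i] = i;

  // initialise single-pixel regions
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (!valid(r, c)) continue;
      Region& g = reg[(size_t)i];
      g.active = true;
      g.n = 1.0;
      g.rmin = g.rmax = r;
      g.cmin = g.cmax = c;
      g.sum.resize(L); g.sumsq.resize(L); g.sd.assign(L, 0.0);
      for (size_t l = 0; l < L; ++l) {
        double v = lay[l][i];
        g.sum[l] = v; g.sumsq[l] = v * v;
      }
      double p = 4.0;
      int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && valid(r2, c2)) {
          p -= 1.0;
          g.nb.push_back(std::make_pair(r2 + c2 * nr, 1));
          p += 1.0; // shared edge still counts towards region perimeter
        }
      }
      g.perim = 4.0;
    }
  }

  // local mutual best fitting: sweep the regions in ascending label order;
  // a region merges with its cheapest neighbour when the choice is mutual
  // and admissible (cost < scale^2); repeat until a sweep changes nothing.
  // The fixed scan order and the (cost, smaller-label) tie-break make the
  // result deterministic.
  auto bestNeighbour = [&](int i, double& bestCost) -> int {
    Region& R = reg[(size_t)i];
    int best = -1;
    bestCost = R_PosInf;
    for (size_t t = 0; t < R.nb.size(); ++t) {
      int x = R.nb[t].first;
      double c = mergeCost(R, reg[(size_t)x], R.nb[t].second,
                           w, shapeW, compactW);
      if (c < bestCost || (c == bestCost && x < best)) {
        bestCost = c;
        best = x;
      }
    }
    return best;
  };
  std::vector<int> act;
  act.reserve((size_t)npix);
  for (int i = 0; i < npix; ++i)
    if (reg[(size_t)i].active) act.push_back(i);
  bool changed = true;
  while (changed) {
    changed = false;
    size_t keep = 0;
    for (size_t ii = 0; ii < act.size(); ++ii) {
      int i = act[ii];
      if (!reg[(size_t)i].active) continue;
      act[keep++] = i;
      double ci, cj;
      int s = bestNeighbour(i, ci);
      if (s < 0 || ci >= scale2) continue;
      if (bestNeighbour(s, cj) != i) continue;        // not mutual
      int ia = std::min(i, s), ib = std::max(i, s);   // smaller label survives
      Region& A = reg[(size_t)ia];
      Region& B = reg[(size_t)ib];
      int k = nbFind(A.nb, ib);
      int shared = A.nb[(size_t)k].second;
      double nm = A.n + B.n;
      for (size_t l = 0; l < L; ++l) {
        A.sum[l] += B.sum[l];
        A.sumsq[l] += B.sumsq[l];
        A.sd[l] = popSd(nm, A.sum[l], A.sumsq[l]);
      }
      A.n = nm;
      A.perim = A.perim + B.perim - 2.0 * shared;
      A.rmin = std::min(A.rmin, B.rmin); A.rmax = std::max(A.rmax, B.rmax);
      A.cmin = std::min(A.cmin, B.cmin); A.cmax = std::max(A.cmax, B.cmax);
      A.nb.erase(A.nb.begin() + k);
      for (size_t t = 0; t < B.nb.size(); ++t) {
        int x = B.nb[t].first, sh = B.nb[t].second;
        if (x == ia) continue;
        Region& X = reg[(size_t)x];
        int kb = nbFind(X.nb, ib);
        if (kb >= 0) X.nb.erase(X.nb.begin() + kb);
        int ka = nbFind(X.nb, ia);
        if (ka >= 0) X.nb[(size_t)ka].second += sh;
        else X.nb.push_back(std::make_pair(ia, sh));
        int kk = nbFind(A.nb, x);
        if (kk >= 0) A.nb[(size_t)kk].second += sh;
        else A.nb.push_back(std::make_pair(x, sh));
      }
      B.active = false;
      std::vector<double>().swap(B.sum);
      std::vector<double>().swap(B.sumsq);
      std::vector<double>().swap(B.sd);
      std::vector<std::pair<int, int> >().swap(B.nb);
      parent[(size_t)ib] = ia;
      changed = true;
    }
    act.resize(keep);
  }

  // resolve roots and relabel in scan order (column-major, as stored)
  std::vector<int> lab((size_t)npix, 0);
  int next = 0;
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (!valid(r, c)) { out(r, c) = 0; continue; }
      int root = i;
      while (parent[(size_t)root] != root) root = parent[(size_t)root];
      int j = i;                      // path compression
      while (parent[(size_t)j] != root) { int p = parent[(size_t)j]; parent[(size_t)j] = root; j = p; }
      if (lab[(size_t)root] == 0) lab[(size_t)root] = ++next;
      out(r, c) = lab[(size_t)root];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_cc_label")]]
IntegerMatrix cpp_cc_label(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> stack;
  int next = 0;
  int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || out(r, c) != 0) continue;
      ++next;
      out(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        int rr = i % nr, cc = i / nr;
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && out(r2, c2) == 0) {
            out(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return out;
}

// A pixel is a seed iff no pixel of the window (Chebyshev half-width `range`)
// intersected with the mask beats it: higher value, or equal value with a
// lexicographically smaller (row, col).
// [[Rcpp::export(name = ".cpp_local_maxima")]]
IntegerMatrix cpp_local_maxima(NumericMatrix values, LogicalMatrix mask, int range) {
  const int nr = values.nrow(), nc = values.ncol();
  std::vector<int> rows, cols;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double v = values(r, c);
      if (!R_finite(v)) continue;
      bool seed = true;
      for (int c2 = std::max(0, c - range); seed && c2 <= std::min(nc - 1, c + range); ++c2) {
        for (int r2 = std::max(0, r - range); r2 <= std::min(nr - 1, r + range); ++r2) {
          if (r2 == r && c2 == c) continue;
          if (!mask(r2, c2)) continue;
          double u = values(r2, c2);
          if (!R_finite(u)) continue;
          if (u > v || (u == v && (r2 < r || (r2 == r && c2 < c)))) {
            seed = false; break;
          }
        }
      }
      if (seed) { rows.push_back(r + 1); cols.push_back(c + 1); }
    }
  }
  IntegerMatrix out((int)rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out((int)i, 0) = rows[i];
    out((int)i, 1) = cols[i];
  }
  return out;
}

// Best-first seeded growing: repeatedly assign the unassigned mask pixel
// 4-adjacent to a region whose guiding value differs least from that region's
// seed value. Ties broken on (difference, row, col, region).
// [[Rcpp::export(name = ".cpp_grow")]]
IntegerMatrix cpp_grow(NumericMatrix values, LogicalMatrix mask,
                       IntegerMatrix seeds, NumericVector seedVals) {
  const int nr = values.nrow(), nc = values.ncol();
  const int k = seeds.nrow();
  if (seedVals.size() != k) stop("one guiding value per seed required");
  IntegerMatrix out(nr, nc);
  struct Ent { double d; int r, c, g; };
  struct EntCmp {
    bool operator()(const Ent& x, const Ent& y) const {
      if (x.d != y.d) return x.d > y.d;
      if (x.r != y.r) return x.r > y.r;
      if (x.c != y.c) return x.c > y.c;
      return x.g > y.g;
    }
  };
  std::priority_queue<Ent, std::vector<Ent>, EntCmp> pq;
  int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  auto push = [&](int r, int c, int g) {
    double v = values(r, c);
    double d = R_finite(v) ? std::abs(v - seedVals[g - 1]) : 1e300;
    Ent e; e.d = d; e.r = r; e.c = c; e.g = g;
    pq.push(e);
  };
  for (int s = 0; s < k; ++s) {
    int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc || !mask(r, c))
      stop("seed outside the cluster mask");
    out(r, c) = s + 1;
  }
  for (int s = 0; s < k; ++s) {
    int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    for (int t = 0; t < 4; ++t) {
      int r2 = r + dr[t], c2 = c + dc[t];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && out(r2, c2) == 0) push(r2, c2, s + 1);
    }
  }
  while (!pq.empty()) {
    Ent e = pq.top(); pq.pop();
    if (out(e.r, e.c) != 0) continue;
    out(e.r, e.c) = e.g;
    for (int t = 0; t < 4; ++t) {
      int r2 = e.r + dr[t], c2 = e.c + dc[t];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && out(r2, c2) == 0) push(r2, c2, e.g);
    }
  }
  return out;
}
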