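#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 2D median filter with edge replication; win must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int win) {
  int H = img.nrow(), W = img.ncol(), h = win / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)win * win);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      buf.clear();
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc)
          buf.push_back(img(clampi(r + dr, 0, H - 1), clampi(c + dc, 0, W - 1)));
      size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Per-pixel gradient against the 8 neighbours (edge replication):
// max absolute difference, or the mean of the 8 absolute differences.
// [[Rcpp::export]]
NumericMatrix cpp_gradient8(NumericMatrix img, bool mean_of_8) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double v = img(r, c), acc = 0.0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          double d = std::fabs(img(clampi(r + dr, 0, H - 1),
                                   clampi(c + dc, 0, W - 1)) - v);
          if (mean_of_8) acc += d; else acc = std::max(acc, d);
        }
      out(r, c) = mean_of_8 ? acc / 8.0 : acc;
    }
  }
  return out;
}

// SLIC iterations on a grayscale image. centers: K x 3 (l, row, col),
// 0-based continuous coordinates. Assignment searches only the 2S x 2S
// window of each center; orphans attach to the spatially nearest center.
// Returns 1-based labels plus the final centers and iteration count.
// [[Rcpp::export]]
List cpp_slic(NumericMatrix img, NumericMatrix centers0, double m, double S,
              int max_iter, double tol) {
  int H = img.nrow(), W = img.ncol(), K = centers0.nrow();
  NumericMatrix cen = clone(centers0);
  IntegerMatrix labels(H, W);
  NumericMatrix dist(H, W);
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    std::fill(labels.begin(), labels.end(), 0);
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      double cl = cen(k, 0), cr = cen(k, 1), cc = cen(k, 2);
      int r0 = clampi((int)std::ceil(cr - S), 0, H - 1);
      int r1 = clampi((int)std::floor(cr + S), 0, H - 1);
      int c0 = clampi((int)std::ceil(cc - S), 0, W - 1);
      int c1 = clampi((int)std::floor(cc + S), 0, W - 1);
      for (int r = r0; r <= r1; ++r) {
        for (int c = c0; c <= c1; ++c) {
          double dc_ = std::fabs(img(r, c) - cl);
          double dr_ = r - cr, dcc = c - cc;
          double ds_ = std::sqrt(dr_ * dr_ + dcc * dcc);
          double D = std::sqrt((dc_ / m) * (dc_ / m) + (ds_ / S) * (ds_ / S));
          // ties go to the later center: on a constant image the labeling is
          // then the spatial Voronoi of the grid with half-open cells, e.g.
          // exact 4x4 blocks for k=4 on 8x8 rather than lopsided cells
          if (D <= dist(r, c)) { dist(r, c) = D; labels(r, c) = k + 1; }
        }
      }
    }
    // orphans: nearest center by spatial distance
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        if (labels(r, c) == 0) {
          double best = R_PosInf; int bk = 0;
          for (int k = 0; k < K; ++k) {
            double dr_ = r - cen(k, 1), dcc = c - cen(k, 2);
            double d2 = dr_ * dr_ + dcc * dcc;
            if (d2 < best) { best = d2; bk = k; }
          }
          labels(r, c) = bk + 1;
        }
    // update centers
    NumericVector sl(K), sr(K), sc(K); IntegerVector cnt(K);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        int k = labels(r, c) - 1;
        sl[k] += img(r, c); sr[k] += r; sc[k] += c; cnt[k] += 1;
      }
    double maxdisp = 0.0;
    for (int k = 0; k < K; ++k) {
      if (cnt[k] == 0) continue; // empty cluster keeps its center
      double nl = sl[k] / cnt[k], nr = sr[k] / cnt[k], nc = sc[k] / cnt[k];
      double dr_ = nr - cen(k, 1), dcc = nc - cen(k, 2);
      maxdisp = std::max(maxdisp, std::sqrt(dr_ * dr_ + dcc * dcc));
      cen(k, 0) = nl; cen(k, 1) = nr; cen(k, 2) = nc;
    }
    if (maxdisp < tol) break;
  }
  return List::create(_["labels"] = labels, _["centers"] = cen,
                      _["iterations"] = iters);
}

// 4-connected components of equal-label regions. Returns 1-based comp ids.
static IntegerMatrix comp4(const IntegerMatrix& labels, int& ncomp,
                           std::vector<int>& sizes) {
  int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix comp(H, W);
  std::fill(comp.begin(), comp.end(), 0);
  sizes.clear();
  ncomp = 0;
  const int DR[4] = {-1, 1, 0, 0}, DC[4] = {0, 0, -1, 1};
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      if (comp(r, c) != 0) continue;
      ++ncomp;
      int sz = 0, lab = labels(r, c);
      comp(r, c) = ncomp;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        ++sz;
        for (int d = 0; d < 4; ++d) {
          int rr = p.first + DR[d], cc = p.second + DC[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (comp(rr, cc) == 0 && labels(rr, cc) == lab) {
            comp(rr, cc) = ncomp;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
      sizes.push_back(sz);
    }
  return comp;
}

// Enforce 4-connectivity of a superpixel labeling: split disconnected labels,
// absorb components smaller than min_size into their largest 4-adjacent
// component, relabel densely from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_enforce_connectivity(IntegerMatrix labels0, int min_size) {
  int H = labels0.nrow(), W = labels0.ncol();
  IntegerMatrix cur = clone(labels0);
  const int DR[4] = {-1, 1, 0, 0}, DC[4] = {0, 0, -1, 1};
  for (int pass = 0; pass < 64; ++pass) {
    int ncomp; std::vector<int> sizes;
    IntegerMatrix comp = comp4(cur, ncomp, sizes);
    // largest adjacent component for each undersized component
    std::vector<int> best_nb(ncomp + 1, 0), best_sz(ncomp + 1, -1);
    bool any_small = false;
    for (int k = 1; k <= ncomp; ++k)
      if (sizes[k - 1] < min_size) any_small = true;
    if (!any_small) { // components become the labels
      for (int i = 0; i < H * W; ++i) cur[i] = comp[i];
      return cur;
    }
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        int k = comp(r, c);
        if (sizes[k - 1] >= min_size) continue;
        for (int d = 0; d < 4; ++d) {
          int rr = r + DR[d], cc = c + DC[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          int j = comp(rr, cc);
          if (j != k && sizes[j - 1] > best_sz[k]) {
            best_sz[k] = sizes[j - 1]; best_nb[k] = j;
          }
        }
      }
    bool changed = false;
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        int k = comp(r, c);
        if (sizes[k - 1] < min_size && best_nb[k] > 0) {
          // adopt the label currently carried by the absorbing component
          cur(r, c) = -best_nb[k]; // mark; resolve below
          changed = true;
        } else {
          cur(r, c) = comp(r, c);
        }
      }
    // resolve marks: absorbed pixels take their absorber's component id
    for (int i = 0; i < H * W; ++i)
      if (cur[i] < 0) cur[i] = -cur[i];
    if (!changed) break; // isolated small image (single comp) — nothing to do
  }
  // final dense relabel
  int ncomp; std::vector<int> sizes;
  IntegerMatrix comp = comp4(cur, ncomp, sizes);
  return comp;
}

// Seeded region growing: BFS over pixels with lo <= v <= hi from seeds whose
// own intensity is in range. seeds: n x 2 matrix of 0-based (row, col).
// [[Rcpp::export]]
IntegerMatrix cpp_grow(NumericMatrix img, IntegerMatrix seeds, double lo,
                       double hi, int connectivity) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix mask(H, W);
  std::fill(mask.begin(), mask.end(), 0);
  int nd = (connectivity == 8) ? 8 : 4;
  const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < seeds.nrow(); ++i) {
    int r = seeds(i, 0), c = seeds(i, 1);
    if (r < 0 || r >= H || c < 0 || c >= W)
      stop("seed out of bounds");
    double v = img(r, c);
    if (v >= lo && v <= hi && !mask(r, c)) {
      mask(r, c) = 1;
      q.push(std::make_pair(r, c));
    }
  }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int d = 0; d < nd; ++d) {
      int rr = p.first + DR[d], cc = p.second + DC[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W || mask(rr, cc)) continue;
      double v = img(rr, cc);
      if (v >= lo && v <= hi) {
        mask(rr, cc) = 1;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  return mask;
}

// Binary dilation/erosion with a disk structuring element.
// Outside the image counts as background for dilation and as foreground for
// erosion, so closing (dilate then erode) is extensive at borders.
// [[Rcpp::export]]
IntegerMatrix cpp_morph2d(IntegerMatrix mask, int radius, bool dilate) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<std::pair<int, int> > se;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius)
        se.push_back(std::make_pair(dr, dc));
  IntegerMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      bool hit = dilate ? false : true;
      for (size_t i = 0; i < se.size(); ++i) {
        int rr = r + se[i].first, cc = c + se[i].second;
        bool inside = (rr >= 0 && rr < H && cc >= 0 && cc < W);
        int v = inside ? mask(rr, cc) : (dilate ? 0 : 1);
        if (dilate) { if (v) { hit = true; break; } }
        else        { if (!v) { hit = false; break; } }
      }
      out(r, c) = hit ? 1 : 0;
    }
  return out;
}

// Binary dilation/erosion of a 3D mask (dims d1 x d2 x d3, column-major) with
// a ball structuring element; same border convention as cpp_morph2d.
// [[Rcpp::export]]
IntegerVector cpp_morph3d(IntegerVector mask, IntegerVector dims, int radius,
                          bool dilate) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<int> off1, off2, off3;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      for (int c = -radius; c <= radius; ++c)
        if (a * a + b * b + c * c <= radius * radius) {
          off1.push_back(a); off2.push_back(b); off3.push_back(c);
        }
  IntegerVector out(mask.size());
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        bool hit = dilate ? false : true;
        for (size_t t = 0; t < off1.size(); ++t) {
          int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
          bool inside = (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 &&
                         kk >= 0 && kk < d3);
          int v = inside ? mask[ii + (size_t)d1 * (jj + (size_t)d2 * kk)]
                         : (dilate ? 0 : 1);
          if (dilate) { if (v) { hit = true; break; } }
          else        { if (!v) { hit = false; break; } }
        }
        out[i + (size_t)d1 * (j + (size_t)d2 * k)] = hit ? 1 : 0;
      }
  out.attr("dim") = dims;
  return out;
}

// Boundary voxels of a 3D mask: set voxels with at least one off-mask
// face-neighbour (out-of-bounds counts as off-mask). Returns n x 3 matrix of
// 0-based (i, j, k).
// [[Rcpp::export]]
IntegerMatrix cpp_boundary3d(IntegerVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<int> bi, bj, bk;
  const int O1[6] = {-1, 1, 0, 0, 0, 0};
  const int O2[6] = {0, 0, -1, 1, 0, 0};
  const int O3[6] = {0, 0, 0, 0, -1, 1};
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        if (!mask[i + (size_t)d1 * (j + (size_t)d2 * k)]) continue;
        bool bd = false;
        for (int t = 0; t < 6 && !bd; ++t) {
          int ii = i + O1[t], jj = j + O2[t], kk = k + O3[t];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
            bd = true;
          else if (!mask[ii + (size_t)d1 * (jj + (size_t)d2 * kk)])
            bd = true;
        }
        if (bd) { bi.push_back(i); bj.push_back(j); bk.push_back(k); }
      }
  IntegerMatrix out(bi.size(), 3);
  for (size_t t = 0; t < bi.size(); ++t) {
    out(t, 0) = bi[t]; out(t, 1) = bj[t]; out(t, 2) = bk[t];
  }
  return out;
}

// For each row of X (n x d, physical coordinates), the Euclidean distance to
// the nearest row of Y.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix X, NumericMatrix Y) {
  int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double df = X(i, c) - Y(j, c);
        s += df * df;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
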