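#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Variable-window local-maximum seed detection.
// Window diameter (m) at height h: scale * (c * h^d + floor_m).
// A pixel is a seed iff no pixel in its circular window is taller, and no
// equal-height pixel precedes it in column-major scan order (first-of-tie
// wins; ties are flagged).
// [[Rcpp::export]]
DataFrame cpp_detect_seeds(NumericMatrix chm, double min_height,
                           double win_c, double win_d, double win_floor,
                           double scale, double res) {
  int nr = chm.nrow(), nc = chm.ncol();
  std::vector<int> rows, cols;
  std::vector<double> hs;
  std::vector<int> tie;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double h = chm(r, c);
      if (NumericMatrix::is_na(h) || h < min_height) continue;
      double diam = scale * (win_c * std::pow(h, win_d) + win_floor);
      double rad_px = 0.5 * diam / res;
      if (rad_px < 1.0) rad_px = 1.0;  // window never smaller than immediate neighbours
      int R = (int)std::floor(rad_px);
      double rad2 = rad_px * rad_px;
      bool seed = true, tied = false;
      long pidx = (long)r + (long)c * nr;
      for (int dc = -R; dc <= R && seed; ++dc) {
        int cc = c + dc;
        if (cc < 0 || cc >= nc) continue;
        for (int dr = -R; dr <= R; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= nr) continue;
          if ((double)dr * dr + (double)dc * dc > rad2) continue;
          if (dr == 0 && dc == 0) continue;
          double q = chm(rr, cc);
          if (NumericMatrix::is_na(q)) continue;
          if (q > h) { seed = false; break; }
          if (q == h) {
            tied = true;
            long qidx = (long)rr + (long)cc * nr;
            if (qidx < pidx) { seed = false; break; }
          }
        }
      }
      if (seed) {
        rows.push_back(r + 1); cols.push_back(c + 1);
        hs.push_back(h); tie.push_back(tied ? 1 : 0);
      }
    }
  }
  return DataFrame::create(_["row"] = rows, _["col"] = cols,
                           _["height"] = hs, _["tie"] = tie);
}

struct Cand { double h; long pix; int region; };
struct CandCmp {
  // priority: height descending, then pixel index ascending, then region
  // id ascending (std::priority_queue pops the "largest" element)
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.h != b.h) return a.h < b.h;
    if (a.pix != b.pix) return a.pix > b.pix;
    return a.region > b.region;
  }
};

// Seeded region growing, height-descending queue. A candidate pixel joins
// region k iff (1) unclaimed, (2) height > th_seed * seed height of k,
// (3) height > th_cr * current mean height of k, (4) centre-to-centre
// distance to k's seed <= max_radius_m[k]. Claimed pixels push their
// 4-neighbours as new candidates for the same region.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_regions(NumericMatrix chm,
                               IntegerVector seed_row, IntegerVector seed_col,
                               NumericVector max_radius_m,
                               double th_seed, double th_cr, double res) {
  int nr = chm.nrow(), nc = chm.ncol();
  int ns = seed_row.size();
  IntegerMatrix labels(nr, nc);
  std::vector<double> sum(ns + 1, 0.0), seed_h(ns + 1, 0.0);
  std::vector<double> max_rad(ns + 1, 0.0);
  std::vector<int> cnt(ns + 1, 0), s_r(ns + 1), s_c(ns + 1);
  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;

  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};

  for (int k = 1; k <= ns; ++k) {
    int r = seed_row[k - 1] - 1, c = seed_col[k - 1] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed outside raster");
    double h = chm(r, c);
    if (NumericMatrix::is_na(h)) stop("seed on nodata pixel");
    labels(r, c) = k;
    seed_h[k] = h; sum[k] = h; cnt[k] = 1;
    s_r[k] = r; s_c[k] = c;
    max_rad[k] = max_radius_m[k - 1];
    for (int i = 0; i < 4; ++i) {
      int rr = r + dr4[i], cc = c + dc4[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      double q = chm(rr, cc);
      if (NumericMatrix::is_na(q) || labels(rr, cc)) continue;
      pq.push({q, (long)rr + (long)cc * nr, k});
    }
  }

  while (!pq.empty()) {
    Cand cand = pq.top(); pq.pop();
    int r = (int)(cand.pix % nr), c = (int)(cand.pix / nr);
    if (labels(r, c)) continue;
    int k = cand.region;
    double h = cand.h;
    if (h <= th_seed * seed_h[k]) continue;
    if (h <= th_cr * (sum[k] / cnt[k])) continue;
    double dr = (double)(r - s_r[k]), dc = (double)(c - s_c[k]);
    if (std::sqrt(dr * dr + dc * dc) * res > max_rad[k]) continue;
    labels(r, c) = k;
    sum[k] += h; cnt[k] += 1;
    for (int i = 0; i < 4; ++i) {
      int rr = r + dr4[i], cc = c + dc4[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      double q = chm(rr, cc);
      if (NumericMatrix::is_na(q) || labels(rr, cc)) continue;
      pq.push({q, (long)rr + (long)cc * nr, k});
    }
  }
  return labels;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher)
static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (pixel units) to the nearest TRUE cell.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix g(nr, nc);
  const double INF = 1e18;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {          // columns first
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : INF;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {          // then rows
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) g(r, c) = d[c];
  }
  return g;
}

struct FloodCell { double z; long order; int r, c; };
struct FloodCmp {
  bool operator()(const FloodCell &a, const FloodCell &b) const {
    if (a.z != b.z) return a.z > b.z;   // min-heap on elevation
    return a.order > b.order;           // FIFO among equals
  }
};

// Priority-flood depression filling (8-connected). With eps > 0, filled
// flats are given a minimal monotone gradient towards their outlet so flow
// routing never stalls.
// [[Rcpp::export]]
NumericMatrix cpp_priority_flood(NumericMatrix dtm, double eps) {
  int nr = dtm.nrow(), nc = dtm.ncol();
  NumericMatrix out(nr, nc);
  LogicalMatrix seen(nr, nc);
  std::priority_queue<FloodCell, std::vector<FloodCell>, FloodCmp> pq;
  long order = 0;
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    out(r, c) = dtm(r, c);
    if (NumericMatrix::is_na(dtm(r, c)))
      stop("DTM contains nodata cells; fill or crop before sink filling");
    if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) {
      seen(r, c) = true;
      pq.push({dtm(r, c), order++, r, c});
    }
  }
  while (!pq.empty()) {
    FloodCell cur = pq.top(); pq.pop();
    for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int rr = cur.r + dr, cc = cur.c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (seen(rr, cc)) continue;
      seen(rr, cc) = true;
      double zfill = cur.z + eps;
      if (out(rr, cc) < zfill) out(rr, cc) = zfill;
      pq.push({out(rr, cc), order++, rr, cc});
    }
  }
  return out;
}
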