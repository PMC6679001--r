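#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur, reflecting boundary. Kernel radius ceil(3*sigma),
// truncated and renormalised (same convention documented in ?gaussian_blur).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    ksum += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= ksum;
  int H = img.nrow(), W = img.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int o = -r; o <= r; ++o) {
        int ii = i + o;
        if (ii < 0) ii = -ii - 1;
        else if (ii >= H) ii = 2 * H - ii - 1;
        acc += k[o + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      for (int o = -r; o <= r; ++o) {
        int jj = j + o;
        if (jj < 0) jj = -jj - 1;
        else if (jj >= W) jj = 2 * W - jj - 1;
        acc += k[o + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Rolling-ball background: grayscale opening with a spherical structuring
// element of the given pixel radius; `aspect` converts ball height (px) into
// intensity units (aspect -> 0 gives a flat disc). Returns img - background,
// clamped at zero.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball(const NumericMatrix& img, double radius,
                               double aspect) {
  int H = img.nrow(), W = img.ncol();
  int r = (int)std::floor(radius);
  std::vector<int> du, dv;
  std::vector<double> hgt;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b) {
      double d2 = (double)(a * a + b * b);
      if (d2 <= radius * radius) {
        du.push_back(a);
        dv.push_back(b);
        hgt.push_back(aspect * std::sqrt(radius * radius - d2));
      }
    }
  int m = (int)du.size();
  NumericMatrix ero(H, W), bg(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double mn = R_PosInf;
      for (int q = 0; q < m; ++q) {
        int ii = i + du[q], jj = j + dv[q];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double v = img(ii, jj) - hgt[q];
        if (v < mn) mn = v;
      }
      ero(i, j) = mn;
    }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double mx = R_NegInf;
      for (int q = 0; q < m; ++q) {
        int ii = i + du[q], jj = j + dv[q];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double v = ero(ii, jj) + hgt[q];
        if (v > mx) mx = v;
      }
      // opening can only undershoot the image; clamp for border safety
      bg(i, j) = std::min(mx, img(i, j));
    }
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double v = img(i, j) - bg(i, j);
      out(i, j) = v > 0 ? v : 0.0;
    }
  return out;
}

// 8-connected component labelling; returns integer labels (0 = background).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& bin) {
  int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (bin(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b) {
            int ii = p.first + a, jj = p.second + b;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (bin(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

static inline int nb(const IntegerMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) != 0 ? 1 : 0;
}

// Zhang-Suen thinning of a binary image to a 1-px skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& bin) {
  IntegerMatrix img = clone(bin);
  int H = img.nrow(), W = img.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int i = 0; i < H; ++i)
        for (int j = 0; j < W; ++j) {
          if (img(i, j) == 0) continue;
          int p2 = nb(img, i - 1, j), p3 = nb(img, i - 1, j + 1),
              p4 = nb(img, i, j + 1), p5 = nb(img, i + 1, j + 1),
              p6 = nb(img, i + 1, j), p7 = nb(img, i + 1, j - 1),
              p8 = nb(img, i, j - 1), p9 = nb(img, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      for (size_t q = 0; q < kill.size(); ++q)
        img(kill[q].first, kill[q].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}

static int degree8(const IntegerMatrix& m, int i, int j) {
  int d = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b) {
      if (a == 0 && b == 0) continue;
      d += nb(m, i + a, j + b);
    }
  return d;
}

// Remove skeleton side branches shorter than min_len: walk from every
// endpoint towards the first junction (degree >= 3); if the walk is shorter
// than min_len the spur is deleted. Repeated until stable.
// [[Rcpp::export]]
IntegerMatrix cpp_prune_spurs(const IntegerMatrix& skel, int min_len) {
  IntegerMatrix img = clone(skel);
  int H = img.nrow(), W = img.ncol();
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        if (img(i, j) == 0 || degree8(img, i, j) != 1) continue;
        std::vector<std::pair<int, int> > chain;
        int ci = i, cj = j, pi = -9, pj = -9;
        bool at_junction = false;
        while ((int)chain.size() < min_len) {
          chain.push_back(std::make_pair(ci, cj));
          int ni = -1, njj = -1, found = 0;
          for (int a = -1; a <= 1; ++a)
            for (int b = -1; b <= 1; ++b) {
              if (a == 0 && b == 0) continue;
              int ii = ci + a, jj = cj + b;
              if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
              if (img(ii, jj) == 0 || (ii == pi && jj == pj)) continue;
              ++found;
              ni = ii;
              njj = jj;
            }
          if (found == 0) break;  // isolated chain: whole component
          if (degree8(img, ni, njj) >= 3) { at_junction = true; break; }
          pi = ci; pj = cj; ci = ni; cj = njj;
        }
        if (at_junction && (int)chain.size() < min_len) {
          for (size_t q = 0; q < chain.size(); ++q)
            img(chain[q].first, chain[q].second) = 0;
          changed = true;
        }
      }
  }
  return img;
}

// Number of skeleton endpoints (pixels with exactly one 8-neighbour).
// [[Rcpp::export]]
int cpp_count_endpoints(const IntegerMatrix& skel) {
  int H = skel.nrow(), W = skel.ncol(), n = 0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (skel(i, j) == 0) continue;
      int d = 0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b) {
          if (a == 0 && b == 0) continue;
          d += nb(skel, i + a, j + b);
        }
      if (d == 1) ++n;
    }
  return n;
}

static std::vector<int> bfs_far(const IntegerMatrix& skel, int start,
                                std::vector<int>& parent) {
  int H = skel.nrow(), W = skel.ncol(), N = H * W;
  std::vector<int> dist(N, -1);
  parent.assign(N, -1);
  std::queue<int> q;
  dist[start] = 0;
  q.push(start);
  while (!q.empty()) {
    int v = q.front();
    q.pop();
    int i = v % H, j = v / H;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        if (a == 0 && b == 0) continue;
        int ii = i + a, jj = j + b;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (skel(ii, jj) == 0) continue;
        int w = jj * H + ii;
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          parent[w] = v;
          q.push(w);
        }
      }
  }
  return dist;
}

// Longest geodesic path through a skeleton (double BFS; exact on trees).
// Returns an ordered n x 2 matrix of (row, col), 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_longest_path(const IntegerMatrix& skel) {
  int H = skel.nrow(), W = skel.ncol();
  int start = -1;
  for (int j = 0; j < W && start < 0; ++j)
    for (int i = 0; i < H; ++i)
      if (skel(i, j) != 0) { start = j * H + i; break; }
  if (start < 0) return IntegerMatrix(0, 2);
  std::vector<int> parent;
  std::vector<int> d1 = bfs_far(skel, start, parent);
  int a = start;
  for (size_t v = 0; v < d1.size(); ++v)
    if (d1[v] > d1[a]) a = (int)v;
  std::vector<int> d2 = bfs_far(skel, a, parent);
  int b = a;
  for (size_t v = 0; v < d2.size(); ++v)
    if (d2[v] > d2[b]) b = (int)v;
  std::vector<int> path;
  for (int v = b; v >= 0; v = parent[v]) {
    path.push_back(v);
    if (v == a) break;
  }
  IntegerMatrix out((int)path.size(), 2);
  for (size_t q = 0; q < path.size(); ++q) {
    int v = path[path.size() - 1 - q];
    out((int)q, 0) = v % H + 1;
    out((int)q, 1) = v / H + 1;
  }
  return out;
}

// Render a polyline as a bright ridge with Gaussian cross-section:
// intensity(px) = amp * exp(-d^2 / (2 sigma^2)), d = distance to polyline.
// Coordinates are 1-based pixel centres (x = column, y = row).
// [[Rcpp::export]]
NumericMatrix cpp_render_ridge(const NumericVector& x, const NumericVector& y,
                               int H, int W, double sigma, double amp) {
  NumericMatrix out(H, W);
  int n = x.size();
  double reach = 4.0 * sigma;
  if (n == 0) return out;
  int nseg = (n == 1) ? 1 : (n - 1);
  for (int s = 0; s < nseg; ++s) {
    double x1 = x[s], y1 = y[s];
    double x2 = (n == 1) ? x1 : x[s + 1], y2 = (n == 1) ? y1 : y[s + 1];
    int jlo = std::max(0, (int)std::floor(std::min(x1, x2) - reach) - 1);
    int jhi = std::min(W - 1, (int)std::ceil(std::max(x1, x2) + reach) - 1);
    int ilo = std::max(0, (int)std::floor(std::min(y1, y2) - reach) - 1);
    int ihi = std::min(H - 1, (int)std::ceil(std::max(y1, y2) + reach) - 1);
    double ex = x2 - x1, ey = y2 - y1;
    double el2 = ex * ex + ey * ey;
    for (int i = ilo; i <= ihi; ++i)
      for (int j = jlo; j <= jhi; ++j) {
        double px = j + 1.0, py = i + 1.0;
        double t = 0.0;
        if (el2 > 0) {
          t = ((px - x1) * ex + (py - y1) * ey) / el2;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
        }
        double dx = px - (x1 + t * ex), dy = py - (y1 + t * ey);
        double d2 = dx * dx + dy * dy;
        double v = amp * std::exp(-0.5 * d2 / (sigma * sigma));
        if (v > out(i, j)) out(i, j) = v;
      }
  }
  return out;
}

// Bilinear interpolation at (x = column, y = row), 1-based; clamped at borders.
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& img, const NumericVector& x,
                           const NumericVector& y) {
  int H = img.nrow(), W = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double xx = x[q], yy = y[q];
    if (xx < 1) xx = 1;
    if (xx > W) xx = W;
    if (yy < 1) yy = 1;
    if (yy > H) yy = H;
    int j0 = (int)std::floor(xx) - 1, i0 = (int)std::floor(yy) - 1;
    if (j0 > W - 2) j0 = W - 2;
    if (i0 > H - 2) i0 = H - 2;
    if (j0 < 0) j0 = 0;
    if (i0 < 0) i0 = 0;
    double fx = xx - 1 - j0, fy = yy - 1 - i0;
    out[q] = img(i0, j0) * (1 - fx) * (1 - fy) +
             img(i0, j0 + 1) * fx * (1 - fy) +
             img(i0 + 1, j0) * (1 - fx) * fy +
             img(i0 + 1, j0 + 1) * fx * fy;
  }
  return out;
}

// Minimum distance from each point to a polyline (vertices vx, vy).
// [[Rcpp::export]]
NumericVector cpp_dist_to_polyline(const NumericVector& px,
                                   const NumericVector& py,
                                   const NumericVector& vx,
                                   const NumericVector& vy) {
  int n = px.size(), m = vx.size();
  NumericVector out(n, R_PosInf);
  for (int s = 0; s + 1 < m; ++s) {
    double x1 = vx[s], y1 = vy[s], ex = vx[s + 1] - x1, ey = vy[s + 1] - y1;
    double el2 = ex * ex + ey * ey;
    for (int q = 0; q < n; ++q) {
      double t = 0.0;
      if (el2 > 0) {
        t = ((px[q] - x1) * ex + (py[q] - y1) * ey) / el2;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
      }
      double dx = px[q] - (x1 + t * ex), dy = py[q] - (y1 + t * ey);
      double d2 = dx * dx + dy * dy;
      if (d2 < out[q]) out[q] = d2;
    }
  }
  if (m == 1)
    for (int q = 0; q < n; ++q) {
      double dx = px[q] - vx[0], dy = py[q] - vy[0];
      out[q] = dx * dx + dy * dy;
    }
  return sqrt(out);
}
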