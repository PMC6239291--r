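#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Level {
  int w = 0, h = 0;
  std::vector<float> px;
  float at(int x, int y) const { return px[(size_t)y * w + x]; }
};

typedef std::vector<Level> Pyramid;

// 5-tap binomial smoothing followed by decimation by 2 (replicated borders)
Level downsample(const Level &src) {
  static const float k[5] = {1.f / 16, 4.f / 16, 6.f / 16, 4.f / 16, 1.f / 16};
  const int w = src.w, h = src.h;
  std::vector<float> tmp((size_t)w * h), sm((size_t)w * h);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      float s = 0.f;
      for (int i = -2; i <= 2; ++i) {
        int xx = std::min(std::max(x + i, 0), w - 1);
        s += k[i + 2] * src.at(xx, y);
      }
      tmp[(size_t)y * w + x] = s;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      float s = 0.f;
      for (int i = -2; i <= 2; ++i) {
        int yy = std::min(std::max(y + i, 0), h - 1);
        s += k[i + 2] * tmp[(size_t)yy * w + x];
      }
      sm[(size_t)y * w + x] = s;
    }
  Level out;
  out.w = (w + 1) / 2;
  out.h = (h + 1) / 2;
  out.px.resize((size_t)out.w * out.h);
  for (int y = 0; y < out.h; ++y)
    for (int x = 0; x < out.w; ++x)
      out.px[(size_t)y * out.w + x] = sm[(size_t)(2 * y) * w + (2 * x)];
  return out;
}

// frame is an R column-major matrix: element (row r, col c) at r + c*h
template <typename T>
Pyramid build_pyramid(const T *frame, int h, int w, int levels) {
  Pyramid pyr;
  Level l0;
  l0.w = w;
  l0.h = h;
  l0.px.resize((size_t)w * h);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      l0.px[(size_t)y * w + x] = (float)frame[y + (size_t)x * h];
  pyr.push_back(std::move(l0));
  for (int L = 1; L < levels; ++L) pyr.push_back(downsample(pyr[L - 1]));
  return pyr;
}

inline bool interp(const Level &im, double x, double y, double &out) {
  if (x < 0.0 || y < 0.0 || x > im.w - 2.0 || y > im.h - 2.0) return false;
  int x0 = (int)x, y0 = (int)y;
  double ax = x - x0, ay = y - y0;
  out = (1 - ax) * (1 - ay) * im.at(x0, y0) + ax * (1 - ay) * im.at(x0 + 1, y0) +
        (1 - ax) * ay * im.at(x0, y0 + 1) + ax * ay * im.at(x0 + 1, y0 + 1);
  return true;
}

// One Lucas-Kanade refinement at a single pyramid level. (px,py) is the point
// in this level's coordinates; (gx,gy) holds the displacement guess and is
// updated in place. Returns false when the window leaves the image or the
// structure tensor is singular.
bool lk_level(const Level &A, const Level &B, double px, double py, double &gx,
              double &gy, int r, int maxit, double eps) {
  const int n = 2 * r + 1;
  std::vector<double> T((size_t)n * n), Tx((size_t)n * n), Ty((size_t)n * n);
  double gxx = 0, gxy = 0, gyy = 0;
  size_t idx = 0;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx, ++idx) {
      double sx = px + dx, sy = py + dy;
      double v, vxp, vxm, vyp, vym;
      if (!interp(A, sx, sy, v) || !interp(A, sx + 1, sy, vxp) ||
          !interp(A, sx - 1, sy, vxm) || !interp(A, sx, sy + 1, vyp) ||
          !interp(A, sx, sy - 1, vym))
        return false;
      T[idx] = v;
      Tx[idx] = 0.5 * (vxp - vxm);
      Ty[idx] = 0.5 * (vyp - vym);
      gxx += Tx[idx] * Tx[idx];
      gxy += Tx[idx] * Ty[idx];
      gyy += Ty[idx] * Ty[idx];
    }
  double det = gxx * gyy - gxy * gxy;
  if (det < 1e-9) return false;
  for (int it = 0; it < maxit; ++it) {
    double bx = 0, by = 0;
    idx = 0;
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx, ++idx) {
        double jv;
        if (!interp(B, px + gx + dx, py + gy + dy, jv)) return false;
        double d = T[idx] - jv;
        bx += d * Tx[idx];
        by += d * Ty[idx];
      }
    double nx = (gyy * bx - gxy * by) / det;
    double ny = (gxx * by - gxy * bx) / det;
    gx += nx;
    gy += ny;
    if (nx * nx + ny * ny < eps * eps) break;
  }
  return true;
}

// Coarse-to-fine track of one point from pyramid PA to PB.
// A failure at a coarse level keeps the current guess; a failure at the
// finest level invalidates the point.
bool lk_pyramidal(const Pyramid &PA, const Pyramid &PB, double x, double y,
                  double &ox, double &oy, int r, int maxit, double eps) {
  const int levels = (int)PA.size();
  double gx = 0, gy = 0;
  for (int L = levels - 1; L >= 0; --L) {
    double s = 1.0 / (double)(1 << L);
    bool ok = lk_level(PA[L], PB[L], x * s, y * s, gx, gy, r, maxit, eps);
    if (!ok && L == 0) return false;
    if (L > 0) {
      gx *= 2;
      gy *= 2;
    }
  }
  ox = x + gx;
  oy = y + gy;
  return true;
}

Pyramid pyramid_of_frame(SEXP frames, int h, int w, int t, int levels) {
  size_t off = (size_t)t * h * w;
  if (TYPEOF(frames) == INTSXP)
    return build_pyramid(INTEGER(frames) + off, h, w, levels);
  return build_pyramid(REAL(frames) + off, h, w, levels);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_track_lk")]]
List cpp_track_lk(SEXP frames, NumericMatrix pts, int win, int levels,
                  int max_iter, double eps, double fb_thresh) {
  IntegerVector dm = Rf_getAttrib(frames, R_DimSymbol);
  if (dm.size() != 3) stop("frames must be a 3-D array");
  const int h = dm[0], w = dm[1], nf = dm[2];
  const int k = pts.nrow();
  const int r = win / 2;

  NumericVector pos(Dimension(k, 2, nf), NA_REAL);
  LogicalMatrix valid(k, nf);
  std::vector<double> xs(k), ys(k);
  std::vector<bool> alive(k, true);
  for (int i = 0; i < k; ++i) {
    ys[i] = pts(i, 0);  // row
    xs[i] = pts(i, 1);  // col
    pos[i] = ys[i];
    pos[i + (size_t)k] = xs[i];
    valid(i, 0) = true;
  }

  Pyramid PA = pyramid_of_frame(frames, h, w, 0, levels);
  for (int t = 1; t < nf; ++t) {
    Pyramid PB = pyramid_of_frame(frames, h, w, t, levels);
    for (int i = 0; i < k; ++i) {
      if (!alive[i]) continue;
      double nx, ny, bx, by;
      bool ok = lk_pyramidal(PA, PB, xs[i], ys[i], nx, ny, r, max_iter, eps);
      if (ok) {
        ok = lk_pyramidal(PB, PA, nx, ny, bx, by, r, max_iter, eps);
        if (ok) {
          double ex = bx - xs[i], ey = by - ys[i];
          ok = (ex * ex + ey * ey) <= fb_thresh * fb_thresh;
        }
      }
      if (!ok) {
        alive[i] = false;
        continue;
      }
      xs[i] = nx;
      ys[i] = ny;
      valid(i, t) = true;
      pos[i + (size_t)t * 2 * k] = ny;
      pos[i + (size_t)k + (size_t)t * 2 * k] = nx;
    }
    PA = std::move(PB);
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["positions"] = pos, _["valid"] = valid);
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("dims must have length 2 or 3");
  const int d1 = dims[0], d2 = dims[1], d3 = (nd == 3) ? dims[2] : 1;
  const size_t n = (size_t)d1 * d2 * d3;
  if ((size_t)mask.size() != n) stop("mask length does not match dims");

  // neighbour offsets
  std::vector<std::array<int, 3>> nb;
  bool full = (nd == 2) ? (connectivity == 8) : (connectivity == 26);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (nd == 2 && dz != 0) continue;
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (!full && nn != 1) continue;
        nb.push_back({dx, dy, dz});
      }

  IntegerVector labels(n, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    labels[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / ((size_t)d1 * d2));
      size_t rem = v % ((size_t)d1 * d2);
      int y = (int)(rem / d1);
      int x = (int)(rem % d1);
      for (const auto &o : nb) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3)
          continue;
        size_t u = (size_t)zz * d1 * d2 + (size_t)yy * d1 + xx;
        if (mask[u] && labels[u] == 0) {
          labels[u] = cur;
          stack.push_back(u);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
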