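#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Binary masks are stored as integer matrices indexed [px, py] with pixel
// centres at integer coordinates 1..nx, 1..ny.

// [[Rcpp::export]]
IntegerMatrix raster_triangles_cpp(NumericMatrix P, IntegerMatrix F,
                                   int nx, int ny) {
  IntegerMatrix mask(nx, ny);
  const int m = F.nrow();
  for (int k = 0; k < m; ++k) {
    const int i0 = F(k, 0) - 1, i1 = F(k, 1) - 1, i2 = F(k, 2) - 1;
    const double x0 = P(i0, 0), y0 = P(i0, 1);
    const double x1 = P(i1, 0), y1 = P(i1, 1);
    const double x2 = P(i2, 0), y2 = P(i2, 1);
    if (!R_finite(x0) || !R_finite(x1) || !R_finite(x2) ||
        !R_finite(y0) || !R_finite(y1) || !R_finite(y2)) continue;
    int xlo = (int)std::ceil(std::min(x0, std::min(x1, x2)) - 1e-9);
    int xhi = (int)std::floor(std::max(x0, std::max(x1, x2)) + 1e-9);
    int ylo = (int)std::ceil(std::min(y0, std::min(y1, y2)) - 1e-9);
    int yhi = (int)std::floor(std::max(y0, std::max(y1, y2)) + 1e-9);
    if (xlo < 1) xlo = 1;
    if (ylo < 1) ylo = 1;
    if (xhi > nx) xhi = nx;
    if (yhi > ny) yhi = ny;
    if (xlo > xhi || ylo > yhi) continue;
    const double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (area == 0.0) continue;
    const double tol = 1e-9 * std::fabs(area);
    for (int py = ylo; py <= yhi; ++py) {
      for (int px = xlo; px <= xhi; ++px) {
        const double w0 = (x1 - px) * (y2 - py) - (x2 - px) * (y1 - py);
        const double w1 = (x2 - px) * (y0 - py) - (x0 - px) * (y2 - py);
        const double w2 = (x0 - px) * (y1 - py) - (x1 - px) * (y0 - py);
        if (area > 0) {
          if (w0 >= -tol && w1 >= -tol && w2 >= -tol) mask(px - 1, py - 1) = 1;
        } else {
          if (w0 <= tol && w1 <= tol && w2 <= tol) mask(px - 1, py - 1) = 1;
        }
      }
    }
  }
  return mask;
}

// --- exact 1D squared-distance transform (Felzenszwalb & Huttenlocher) ---
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// exact squared EDT of a point set given as a binary grid (1 = site)
static void edt2d(std::vector<double>& g, int w, int h) {
  const double INF = 1e20;
  std::vector<double> f(std::max(w, h)), d(std::max(w, h));
  std::vector<int> v(std::max(w, h));
  std::vector<double> z(std::max(w, h) + 1);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) f[y] = g[x + y * (size_t)w];
    dt1d(f, d, h, v, z);
    for (int y = 0; y < h; ++y) g[x + y * (size_t)w] = d[y];
  }
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) f[x] = g[x + y * (size_t)w];
    dt1d(f, d, w, v, z);
    for (int x = 0; x < w; ++x) g[x + y * (size_t)w] = d[x];
  }
  (void)INF;
}

struct Bounds { int xlo, xhi, ylo, yhi; bool any; };

// boundary pixel = foreground with a 4-neighbour background (image border
// counts as background); scan limited to the ROI
static void boundary_grid(const int* pa, int nx, int ny, int xlo, int ylo,
                          int w, int h, std::vector<double>& g,
                          std::vector<int>& bx, std::vector<int>& by) {
  const double INF = 1e20;
  std::fill(g.begin(), g.end(), INF);
  for (int j = ylo; j < ylo + h; ++j) {
    const int* col = pa + (size_t)j * nx;
    for (int i = xlo; i < xlo + w; ++i) {
      if (!col[i]) continue;
      bool bd = (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
                 !col[i - 1] || !col[i + 1] || !pa[i + (size_t)(j - 1) * nx] ||
                 !pa[i + (size_t)(j + 1) * nx]);
      if (bd) {
        g[(i - xlo) + (size_t)(j - ylo) * w] = 0.0;
        bx.push_back(i);
        by.push_back(j);
      }
    }
  }
}

// Intersection-over-union plus mean symmetric contour distance of two
// equal-size binary masks.
// [[Rcpp::export]]
List mask_overlap_cpp(IntegerMatrix A, IntegerMatrix B) {
  if (A.nrow() != B.nrow() || A.ncol() != B.ncol())
    stop("mask size mismatch");
  const int nx = A.nrow(), ny = A.ncol();
  long inter = 0, uni = 0;
  const int* pa = INTEGER(A);
  const int* pb = INTEGER(B);
  Bounds ba, bb;
  ba.any = bb.any = false;
  ba.xlo = bb.xlo = nx; ba.xhi = bb.xhi = -1;
  ba.ylo = bb.ylo = ny; ba.yhi = bb.yhi = -1;
  for (int j = 0; j < ny; ++j) {
    const int* ca = pa + (size_t)j * nx;
    const int* cb = pb + (size_t)j * nx;
    for (int i = 0; i < nx; ++i) {
      const bool a = ca[i] != 0, b = cb[i] != 0;
      if (!a && !b) continue;
      if (a && b) ++inter;
      ++uni;
      if (a) {
        ba.any = true;
        if (i < ba.xlo) ba.xlo = i;
        if (i > ba.xhi) ba.xhi = i;
        if (j < ba.ylo) ba.ylo = j;
        if (j > ba.yhi) ba.yhi = j;
      }
      if (b) {
        bb.any = true;
        if (i < bb.xlo) bb.xlo = i;
        if (i > bb.xhi) bb.xhi = i;
        if (j < bb.ylo) bb.ylo = j;
        if (j > bb.yhi) bb.yhi = j;
      }
    }
  }
  double iou = (uni == 0) ? 1.0 : (double)inter / (double)uni;
  double mcd;
  const double far_d = std::sqrt((double)A.nrow() * A.nrow() +
                                 (double)A.ncol() * A.ncol());
  if (!ba.any && !bb.any) {
    mcd = 0.0;
  } else if (!ba.any || !bb.any) {
    mcd = far_d;
  } else {
    const int margin = 1;
    int xlo = std::max(0, std::min(ba.xlo, bb.xlo) - margin);
    int xhi = std::min(nx - 1, std::max(ba.xhi, bb.xhi) + margin);
    int ylo = std::max(0, std::min(ba.ylo, bb.ylo) - margin);
    int yhi = std::min(ny - 1, std::max(ba.yhi, bb.yhi) + margin);
    int w = xhi - xlo + 1, h = yhi - ylo + 1;
    std::vector<double> ga((size_t)w * h), gb((size_t)w * h);
    std::vector<int> ax, ay, bx, by;
    boundary_grid(pa, nx, ny, xlo, ylo, w, h, ga, ax, ay);
    boundary_grid(pb, nx, ny, xlo, ylo, w, h, gb, bx, by);
    edt2d(ga, w, h);
    edt2d(gb, w, h);
    double sab = 0.0, sba = 0.0;
    for (size_t k = 0; k < ax.size(); ++k)
      sab += std::sqrt(gb[(ax[k] - xlo) + (size_t)(ay[k] - ylo) * w]);
    for (size_t k = 0; k < bx.size(); ++k)
      sba += std::sqrt(ga[(bx[k] - xlo) + (size_t)(by[k] - ylo) * w]);
    mcd = 0.5 * (sab / ax.size() + sba / bx.size());
  }
  return List::create(_["iou"] = iou, _["contour_dist"] = mcd,
                      _["intersection"] = (double)inter,
                      _["union_"] = (double)uni);
}

// --- fused render + cost for the registration inner loop ---------------
// Rasterizes projected triangles into a persistent stamp buffer (no
// clearing between calls) and evaluates the silhouette cost against the
// observation over the union region of interest only. Exactly equivalent
// to raster_triangles_cpp + mask_overlap_cpp, just faster.

static std::vector<int> g_stamp;
static int g_cur = 0;

// [[Rcpp::export]]
double render_cost_cpp(NumericMatrix P, IntegerMatrix F, IntegerMatrix obs,
                       int oxlo, int oxhi, int oylo, int oyhi,
                       double w_iou, double w_contour) {
  const int nx = obs.nrow(), ny = obs.ncol();
  const int* po = INTEGER(obs);
  if ((int)g_stamp.size() != nx * ny) {
    g_stamp.assign((size_t)nx * ny, 0);
    g_cur = 0;
  }
  if (g_cur == INT_MAX) {
    std::fill(g_stamp.begin(), g_stamp.end(), 0);
    g_cur = 0;
  }
  const int cur = ++g_cur;
  int rxlo = nx, rxhi = -1, rylo = ny, ryhi = -1;
  const int m = F.nrow();
  bool painted = false;
  for (int k = 0; k < m; ++k) {
    const int i0 = F(k, 0) - 1, i1 = F(k, 1) - 1, i2 = F(k, 2) - 1;
    const double x0 = P(i0, 0), y0 = P(i0, 1);
    const double x1 = P(i1, 0), y1 = P(i1, 1);
    const double x2 = P(i2, 0), y2 = P(i2, 1);
    if (!R_finite(x0) || !R_finite(x1) || !R_finite(x2) ||
        !R_finite(y0) || !R_finite(y1) || !R_finite(y2)) continue;
    int xlo = (int)std::ceil(std::min(x0, std::min(x1, x2)) - 1e-9);
    int xhi = (int)std::floor(std::max(x0, std::max(x1, x2)) + 1e-9);
    int ylo = (int)std::ceil(std::min(y0, std::min(y1, y2)) - 1e-9);
    int yhi = (int)std::floor(std::max(y0, std::max(y1, y2)) + 1e-9);
    if (xlo < 1) xlo = 1;
    if (ylo < 1) ylo = 1;
    if (xhi > nx) xhi = nx;
    if (yhi > ny) yhi = ny;
    if (xlo > xhi || ylo > yhi) continue;
    double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (area == 0.0) continue;
    double sgn = 1.0;
    if (area < 0) { sgn = -1.0; area = -area; }
    const double tol = 1e-9 * area;
    const double dw0 = sgn * (y1 - y2);
    const double dw1 = sgn * (y2 - y0);
    const double dw2 = sgn * (y0 - y1);
    for (int py = ylo; py <= yhi; ++py) {
      double w0 = sgn * ((x1 - xlo) * (y2 - py) - (x2 - xlo) * (y1 - py));
      double w1 = sgn * ((x2 - xlo) * (y0 - py) - (x0 - xlo) * (y2 - py));
      double w2 = sgn * ((x0 - xlo) * (y1 - py) - (x1 - xlo) * (y0 - py));
      int* row = g_stamp.data() + (size_t)(py - 1) * nx - 1;
      for (int px = xlo; px <= xhi; ++px) {
        if (w0 >= -tol && w1 >= -tol && w2 >= -tol) row[px] = cur;
        w0 += dw0;
        w1 += dw1;
        w2 += dw2;
      }
    }
    painted = true;
    if (xlo - 1 < rxlo) rxlo = xlo - 1;
    if (xhi - 1 > rxhi) rxhi = xhi - 1;
    if (ylo - 1 < rylo) rylo = ylo - 1;
    if (yhi - 1 > ryhi) ryhi = yhi - 1;
  }
  const double far_d = std::sqrt((double)nx * nx + (double)ny * ny);
  if (!painted) return w_iou * 1.0 + w_contour * far_d;
  const int margin = 1;
  int xlo = std::max(0, std::min(rxlo, oxlo - 1) - margin);
  int xhi = std::min(nx - 1, std::max(rxhi, oxhi - 1) + margin);
  int ylo = std::max(0, std::min(rylo, oylo - 1) - margin);
  int yhi = std::min(ny - 1, std::max(ryhi, oyhi - 1) + margin);
  const int w = xhi - xlo + 1, h = yhi - ylo + 1;
  const double INF = 1e20;
  std::vector<double> go((size_t)w * h, INF), gr((size_t)w * h, INF);
  std::vector<int> obx, oby, rbx, rby;
  long inter = 0, uni = 0;
  const int* st = g_stamp.data();
  for (int j = ylo; j <= yhi; ++j) {
    for (int i = xlo; i <= xhi; ++i) {
      const size_t id = (size_t)j * nx + i;
      const bool a = po[id] != 0;
      const bool b = st[id] == cur;
      if (a || b) {
        if (a && b) ++inter;
        ++uni;
      }
      if (a) {
        bool bd = (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
                   !po[id - 1] || !po[id + 1] || !po[id - nx] || !po[id + nx]);
        if (bd) {
          go[(i - xlo) + (size_t)(j - ylo) * w] = 0.0;
          obx.push_back(i);
          oby.push_back(j);
        }
      }
      if (b) {
        bool bd = (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
                   st[id - 1] != cur || st[id + 1] != cur ||
                   st[id - nx] != cur || st[id + nx] != cur);
        if (bd) {
          gr[(i - xlo) + (size_t)(j - ylo) * w] = 0.0;
          rbx.push_back(i);
          rby.push_back(j);
        }
      }
    }
  }
  const double iou = (uni == 0) ? 1.0 : (double)inter / (double)uni;
  double mcd;
  if (obx.empty() && rbx.empty()) {
    mcd = 0.0;
  } else if (obx.empty() || rbx.empty()) {
    mcd = far_d;
  } else {
    edt2d(go, w, h);
    edt2d(gr, w, h);
    double sor = 0.0, sro = 0.0;
    for (size_t k = 0; k < obx.size(); ++k)
      sor += std::sqrt(gr[(obx[k] - xlo) + (size_t)(oby[k] - ylo) * w]);
    for (size_t k = 0; k < rbx.size(); ++k)
      sro += std::sqrt(go[(rbx[k] - xlo) + (size_t)(rby[k] - ylo) * w]);
    mcd = 0.5 * (sor / obx.size() + sro / rbx.size());
  }
  return w_iou * (1.0 - iou) + w_contour * mcd;
}

// closest-point distance from point p to triangle (a,b,c), Ericson 5.1.5
static double pt_tri_dist2(const double* p, const double* a, const double* b,
                           const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) {
      bp[i] = p[i] - b[i];
      cp[i] = p[i] - c[i];
    }
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else if (d6 >= 0.0 && d5 <= d6) {
      q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
    } else {
      const double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        const double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
      } else {
        const double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          const double w = d2 / (d2 - d6);
          for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
        } else {
          const double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
          } else {
            const double denom = 1.0 / (va + vb + vc);
            const double v = vb * denom, w = vc * denom;
            for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w;
          }
        }
      }
    }
  }
  const double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// Unsigned nearest distance from each query point to a triangle mesh
// surface; brute force over triangles with a centroid-radius prune.
// [[Rcpp::export]]
NumericVector point_mesh_dist_cpp(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  const int np = P.nrow(), m = F.nrow();
  if (m == 0 || V.nrow() == 0) stop("empty mesh");
  std::vector<double> cx(m), cy(m), cz(m), cr(m);
  std::vector<double> tri((size_t)m * 9);
  for (int k = 0; k < m; ++k) {
    const int ia = F(k, 0) - 1, ib = F(k, 1) - 1, ic = F(k, 2) - 1;
    double* t = &tri[(size_t)k * 9];
    t[0] = V(ia, 0); t[1] = V(ia, 1); t[2] = V(ia, 2);
    t[3] = V(ib, 0); t[4] = V(ib, 1); t[5] = V(ib, 2);
    t[6] = V(ic, 0); t[7] = V(ic, 1); t[8] = V(ic, 2);
    cx[k] = (t[0] + t[3] + t[6]) / 3.0;
    cy[k] = (t[1] + t[4] + t[7]) / 3.0;
    cz[k] = (t[2] + t[5] + t[8]) / 3.0;
    double r2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      const double dx = t[3 * j] - cx[k], dy = t[3 * j + 1] - cy[k],
                   dz = t[3 * j + 2] - cz[k];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    cr[k] = std::sqrt(r2);
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    for (int k = 0; k < m; ++k) {
      const double dx = p[0] - cx[k], dy = p[1] - cy[k], dz = p[2] - cz[k];
      const double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - cr[k];
      if (dc * dc >= best && dc > 0) continue;
      const double d2 = pt_tri_dist2(p, &tri[(size_t)k * 9],
                                     &tri[(size_t)k * 9 + 3],
                                     &tri[(size_t)k * 9 + 6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
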