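#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx); linear index (0-based):
// idx = z + nz * (y + ny * x).

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

struct Offset {
  int dz, dy, dx;
  double norm2;
};

// Search offsets ordered by (|o|, z, y, x) so that scanning with a strict
// "greater than" update implements the documented tie-break rule.
static std::vector<Offset> ordered_offsets(int radius) {
  std::vector<Offset> off;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx) {
        Offset o;
        o.dz = dz; o.dy = dy; o.dx = dx;
        o.norm2 = (double)(dz * dz + dy * dy + dx * dx);
        off.push_back(o);
      }
  std::sort(off.begin(), off.end(), [](const Offset &a, const Offset &b) {
    if (a.norm2 != b.norm2) return a.norm2 < b.norm2;
    if (a.dz != b.dz) return a.dz < b.dz;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dx < b.dx;
  });
  return off;
}

// Zero-normalised cross-correlation between the subset of `ref` centred at
// (cz,cy,cx) and the subset of `def` centred at the offset position.  Voxels
// must be finite in BOTH windows to enter the sums.  Returns NA_REAL when
// the valid fraction is below min_frac or either window has zero variance.
static double zncc_at(const double *ref, const double *def,
                      int nz, int ny, int /*nx*/,
                      int cz, int cy, int cx,
                      int oz, int oy, int ox,
                      int half, double min_frac) {
  double sa = 0.0, sb = 0.0, saa = 0.0, sbb = 0.0, sab = 0.0;
  int n = 0;
  for (int dx = -half; dx <= half; ++dx)
    for (int dy = -half; dy <= half; ++dy) {
      const double *pr = ref + vidx(cz - half, cy + dy, cx + dx, nz, ny);
      const double *pd = def + vidx(cz - half + oz, cy + dy + oy, cx + dx + ox, nz, ny);
      for (int dz = 0; dz <= 2 * half; ++dz) {
        double a = pr[dz], b = pd[dz];
        if (std::isfinite(a) && std::isfinite(b)) {
          sa += a; sb += b;
          saa += a * a; sbb += b * b; sab += a * b;
          ++n;
        }
      }
    }
  int side = 2 * half + 1;
  double nvox = (double)side * side * side;
  if ((double)n < min_frac * nvox || n < 2) return NA_REAL;
  double va = saa - sa * sa / n;
  double vb = sbb - sb * sb / n;
  if (va <= 0.0 || vb <= 0.0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// [[Rcpp::export(name = ".cpp_zncc")]]
double cpp_zncc(NumericVector ref, NumericVector def, IntegerVector dims,
                IntegerVector center, IntegerVector offset, int half,
                double min_frac) {
  return zncc_at(REAL(ref), REAL(def), dims[0], dims[1], dims[2],
                 center[0], center[1], center[2],
                 offset[0], offset[1], offset[2], half, min_frac);
}

// Exhaustive integer search + score neighbourhood for every node.
// nodes: n x 3 matrix of 0-based (z, y, x) subset centres, all guaranteed by
// the caller to keep subset + search inside the volume.
// Returns list(offset = n x 3, cc = n, status = n, neigh = n x 27).
// status: 0 ok, 2 insufficient_valid (all offsets invalid / undefined).
// neigh holds scores at offsets best + (dz,dy,dx), dz,dy,dx in {-1,0,1},
// column index (dz+1) + 3*(dy+1) + 9*(dx+1); NA where outside the window.
// [[Rcpp::export(name = ".cpp_dvc_search")]]
List cpp_dvc_search(NumericVector ref, NumericVector def, IntegerVector dims,
                    IntegerMatrix nodes, int half, int radius,
                    double min_frac) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  const double *pr = REAL(ref), *pd = REAL(def);
  int nn = nodes.nrow();
  std::vector<Offset> off = ordered_offsets(radius);
  int side = 2 * radius + 1;
  int nsc = side * side * side;

  IntegerMatrix best(nn, 3);
  NumericVector cc(nn);
  IntegerVector status(nn);
  NumericMatrix neigh(nn, 27);
  std::vector<double> scores(nsc);

  int side_s = 2 * half + 1;
  double nvox = (double)side_s * side_s * side_s;

  for (int i = 0; i < nn; ++i) {
    int cz = nodes(i, 0), cy = nodes(i, 1), cx = nodes(i, 2);
    // the pairwise-valid count can never exceed the reference-window
    // finite count, so a mostly-masked node skips the whole search
    int nref = 0;
    for (int dx = -half; dx <= half; ++dx)
      for (int dy = -half; dy <= half; ++dy) {
        const double *prw = pr + vidx(cz - half, cy + dy, cx + dx, nz, ny);
        for (int dz = 0; dz <= 2 * half; ++dz)
          if (std::isfinite(prw[dz])) ++nref;
      }
    if ((double)nref < min_frac * nvox) {
      status[i] = 2;
      cc[i] = NA_REAL;
      best(i, 0) = best(i, 1) = best(i, 2) = NA_INTEGER;
      for (int c = 0; c < 27; ++c) neigh(i, c) = NA_REAL;
      continue;
    }
    double bestsc = NA_REAL;
    int bz = 0, by = 0, bx = 0;
    bool any = false;
    for (size_t k = 0; k < off.size(); ++k) {
      double s = zncc_at(pr, pd, nz, ny, nx, cz, cy, cx,
                         off[k].dz, off[k].dy, off[k].dx, half, min_frac);
      int lin = (off[k].dz + radius) +
                side * ((off[k].dy + radius) + side * (off[k].dx + radius));
      scores[lin] = s;
      if (ISNAN(s)) continue;
      if (!any || s > bestsc) {
        any = true;
        bestsc = s;
        bz = off[k].dz; by = off[k].dy; bx = off[k].dx;
      }
    }
    if (!any) {
      status[i] = 2;
      cc[i] = NA_REAL;
      best(i, 0) = best(i, 1) = best(i, 2) = NA_INTEGER;
      for (int c = 0; c < 27; ++c) neigh(i, c) = NA_REAL;
      continue;
    }
    status[i] = 0;
    cc[i] = bestsc;
    best(i, 0) = bz; best(i, 1) = by; best(i, 2) = bx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int oz = bz + dz, oy = by + dy, ox = bx + dx;
          int col = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
          if (std::abs(oz) > radius || std::abs(oy) > radius ||
              std::abs(ox) > radius) {
            neigh(i, col) = NA_REAL;
          } else {
            int lin = (oz + radius) + side * ((oy + radius) + side * (ox + radius));
            neigh(i, col) = scores[lin];
          }
        }
  }
  return List::create(_["offset"] = best, _["cc"] = cc,
                      _["status"] = status, _["neigh"] = neigh);
}

// 3D median filter.  radius in voxels; cubic = false gives the spherical
// (Euclidean) neighbourhood, cubic = true the (2r+1)^3 cube.  NaN voxels
// stay NaN (masking survives filtering); NaN neighbours are excluded from
// the sample.  Neighbourhoods are truncated at the volume boundary.
// [[Rcpp::export(name = ".cpp_median3d")]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dims, int radius,
                           bool cubic) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  const double *p = REAL(vol);
  NumericVector out(vol.size());
  double *q = REAL(out);
  if (radius == 0) {
    std::copy(p, p + vol.size(), q);
    return out;
  }
  std::vector<int> oz, oy, ox;
  double r2 = (double)radius * radius;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx) {
        if (!cubic && (double)(dz * dz + dy * dy + dx * dx) > r2) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
      }
  size_t m = oz.size();
  std::vector<double> buf(m);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double v = p[vidx(z, y, x, nz, ny)];
        R_xlen_t at = vidx(z, y, x, nz, ny);
        if (ISNAN(v)) { q[at] = v; continue; }
        size_t n = 0;
        for (size_t k = 0; k < m; ++k) {
          int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          double w = p[vidx(zz, yy, xx, nz, ny)];
          if (!ISNAN(w)) buf[n++] = w;
        }
        if (n == 0) { q[at] = R_NaN; continue; }
        size_t h = n / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
        double med = buf[h];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + h);
          med = 0.5 * (med + lo);
        }
        q[at] = med;
      }
  return out;
}

// Trilinear sampling of a volume at fractional (z, y, x) positions
// (0-based).  Outside the grid, or when any of the 8 corners is NaN, the
// sample is NaN.  Points landing exactly on integer coordinates read the
// voxel directly (no interpolation error).
// [[Rcpp::export(name = ".cpp_trilinear")]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  const double *p = REAL(vol);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double z = pts(i, 0), y = pts(i, 1), x = pts(i, 2);
    if (!std::isfinite(z) || !std::isfinite(y) || !std::isfinite(x)) {
      out[i] = R_NaN; continue;
    }
    int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
    double fz = z - z0, fy = y - y0, fx = x - x0;
    int z1 = (fz == 0.0) ? z0 : z0 + 1;
    int y1 = (fy == 0.0) ? y0 : y0 + 1;
    int x1 = (fx == 0.0) ? x0 : x0 + 1;
    if (z0 < 0 || z1 >= nz || y0 < 0 || y1 >= ny || x0 < 0 || x1 >= nx) {
      out[i] = R_NaN; continue;
    }
    double acc = 0.0;
    bool bad = false;
    for (int a = 0; a <= 1 && !bad; ++a)
      for (int b = 0; b <= 1 && !bad; ++b)
        for (int c = 0; c <= 1 && !bad; ++c) {
          double w = (a ? fz : 1.0 - fz) * (b ? fy : 1.0 - fy) * (c ? fx : 1.0 - fx);
          if (w == 0.0) continue;
          double v = p[vidx(a ? z1 : z0, b ? y1 : y0, c ? x1 : x0, nz, ny)];
          if (ISNAN(v)) { bad = true; break; }
          acc += w * v;
        }
    out[i] = bad ? R_NaN : acc;
  }
  return out;
}
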