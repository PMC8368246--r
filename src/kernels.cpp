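// Compute kernels for the 3D dense V-Net and for volumetric resampling.
// Arrays follow R's column-major layout: feature maps are (X, Y, Z, C),
// convolution weights are (k, k, k, Cin, Cout) with k in {1, 3}.
// Convolutions are "same" with zero padding of dilation * (k - 1) / 2.

#include <Rcpp.h>
using namespace Rcpp;

static inline int widx(int i, int j, int l, int ci, int co, int k, int cin) {
  return i + k * (j + k * (l + k * (ci + cin * co)));
}

// [[Rcpp::export(name = ".conv3dForward")]]
NumericVector conv3dForward(NumericVector x, IntegerVector dims,
                            NumericVector w, NumericVector b,
                            int k, int cin, int cout, int dilation) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int nvox = X * Y * Z;
  NumericVector out(nvox * cout);
  const int half = (k - 1) / 2;
  // initialise with bias
  for (int co = 0; co < cout; ++co) {
    double bv = b[co];
    double* o = REAL(out) + (R_xlen_t)co * nvox;
    for (int v = 0; v < nvox; ++v) o[v] = bv;
  }
  const double* xp = REAL(x);
  for (int co = 0; co < cout; ++co) {
    double* o = REAL(out) + (R_xlen_t)co * nvox;
    for (int ci = 0; ci < cin; ++ci) {
      const double* in = xp + (R_xlen_t)ci * nvox;
      for (int l = 0; l < k; ++l) {
        int oz = (l - half) * dilation;
        for (int j = 0; j < k; ++j) {
          int oy = (j - half) * dilation;
          for (int i = 0; i < k; ++i) {
            int ox = (i - half) * dilation;
            double wv = w[widx(i, j, l, ci, co, k, cin)];
            if (wv == 0.0) continue;
            int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
            int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
            int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
            for (int z = z0; z < z1; ++z) {
              for (int y = y0; y < y1; ++y) {
                double* orow = o + (R_xlen_t)(z * Y + y) * X;
                const double* irow =
                    in + (R_xlen_t)((z + oz) * Y + (y + oy)) * X + ox;
                for (int xx = x0; xx < x1; ++xx)
                  orow[xx] += wv * irow[xx];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Backward pass: returns gradients w.r.t. input, weights and bias.
// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3dBackward(NumericVector x, IntegerVector dims, NumericVector w,
                    NumericVector gy, int k, int cin, int cout,
                    int dilation) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int nvox = X * Y * Z;
  NumericVector gx(nvox * cin);
  NumericVector gw(w.size());
  NumericVector gb(cout);
  const int half = (k - 1) / 2;
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  for (int co = 0; co < cout; ++co) {
    const double* g = gp + (R_xlen_t)co * nvox;
    double acc = 0.0;
    for (int v = 0; v < nvox; ++v) acc += g[v];
    gb[co] = acc;
    for (int ci = 0; ci < cin; ++ci) {
      const double* in = xp + (R_xlen_t)ci * nvox;
      double* gi = REAL(gx) + (R_xlen_t)ci * nvox;
      for (int l = 0; l < k; ++l) {
        int oz = (l - half) * dilation;
        for (int j = 0; j < k; ++j) {
          int oy = (j - half) * dilation;
          for (int i = 0; i < k; ++i) {
            int ox = (i - half) * dilation;
            double wv = w[widx(i, j, l, ci, co, k, cin)];
            double gwacc = 0.0;
            int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
            int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
            int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
            for (int z = z0; z < z1; ++z) {
              for (int y = y0; y < y1; ++y) {
                const double* grow = g + (R_xlen_t)(z * Y + y) * X;
                const R_xlen_t ioff =
                    (R_xlen_t)((z + oz) * Y + (y + oy)) * X + ox;
                const double* irow = in + ioff;
                double* girow = gi + ioff;
                for (int xx = x0; xx < x1; ++xx) {
                  gwacc += grow[xx] * irow[xx];
                  girow[xx] += wv * grow[xx];
                }
              }
            }
            gw[widx(i, j, l, ci, co, k, cin)] += gwacc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".avgPoolForward")]]
NumericVector avgPoolForward(NumericVector x, IntegerVector dims,
                             IntegerVector f) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int OX = X / fx, OY = Y / fy, OZ = Z / fz;
  NumericVector out((R_xlen_t)OX * OY * OZ * C);
  const double inv = 1.0 / (fx * fy * fz);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int xx = 0; xx < OX; ++xx) {
          double acc = 0.0;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx)
                acc += xp[(R_xlen_t)(xx * fx + dx) +
                          (R_xlen_t)X * ((y * fy + dy) +
                          (R_xlen_t)Y * ((z * fz + dz) + (R_xlen_t)Z * c))];
          op[(R_xlen_t)xx + (R_xlen_t)OX * (y + (R_xlen_t)OY *
             (z + (R_xlen_t)OZ * c))] = acc * inv;
        }
  return out;
}

// [[Rcpp::export(name = ".avgPoolBackward")]]
NumericVector avgPoolBackward(NumericVector gy, IntegerVector dims,
                              IntegerVector f) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int OX = X / fx, OY = Y / fy, OZ = Z / fz;
  NumericVector gx((R_xlen_t)X * Y * Z * C);
  const double inv = 1.0 / (fx * fy * fz);
  const double* gp = REAL(gy);
  double* op = REAL(gx);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int xx = 0; xx < OX; ++xx) {
          double g = gp[(R_xlen_t)xx + (R_xlen_t)OX *
                        (y + (R_xlen_t)OY * (z + (R_xlen_t)OZ * c))] * inv;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx)
                op[(R_xlen_t)(xx * fx + dx) + (R_xlen_t)X *
                   ((y * fy + dy) + (R_xlen_t)Y *
                    ((z * fz + dz) + (R_xlen_t)Z * c))] = g;
        }
  return gx;
}

// [[Rcpp::export(name = ".upsampleForward")]]
NumericVector upsampleForward(NumericVector x, IntegerVector dims,
                              IntegerVector f) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int OX = X * fx, OY = Y * fy, OZ = Z * fz;
  NumericVector out((R_xlen_t)OX * OY * OZ * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y) {
        const double* irow = xp + (R_xlen_t)X *
            ((y / fy) + (R_xlen_t)Y * ((z / fz) + (R_xlen_t)Z * c));
        double* orow = op + (R_xlen_t)OX *
            (y + (R_xlen_t)OY * (z + (R_xlen_t)OZ * c));
        for (int xx = 0; xx < OX; ++xx) orow[xx] = irow[xx / fx];
      }
  return out;
}

// [[Rcpp::export(name = ".upsampleBackward")]]
NumericVector upsampleBackward(NumericVector gy, IntegerVector dims,
                               IntegerVector f) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int OX = X * fx, OY = Y * fy, OZ = Z * fz;
  NumericVector gx((R_xlen_t)X * Y * Z * C);
  const double* gp = REAL(gy);
  double* op = REAL(gx);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y) {
        const double* grow = gp + (R_xlen_t)OX *
            (y + (R_xlen_t)OY * (z + (R_xlen_t)OZ * c));
        double* orow = op + (R_xlen_t)X *
            ((y / fy) + (R_xlen_t)Y * ((z / fz) + (R_xlen_t)Z * c));
        for (int xx = 0; xx < OX; ++xx) orow[xx / fx] += grow[xx];
      }
  return gx;
}

// Trilinear interpolation of a 3D grid at arbitrary (1-based) voxel
// coordinates; out-of-field samples take `fill`.
// [[Rcpp::export(name = ".sampleTrilinear")]]
NumericVector sampleTrilinear(NumericVector src, IntegerVector dims,
                              NumericVector cx, NumericVector cy,
                              NumericVector cz, double fill) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = cx.size();
  NumericVector out(n);
  const double* s = REAL(src);
  for (R_xlen_t v = 0; v < n; ++v) {
    double px = cx[v] - 1.0, py = cy[v] - 1.0, pz = cz[v] - 1.0;
    if (px < 0 || py < 0 || pz < 0 || px > X - 1 || py > Y - 1 ||
        pz > Z - 1) {
      out[v] = fill;
      continue;
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
        z0 = (int)std::floor(pz);
    int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
        z1 = std::min(z0 + 1, Z - 1);
    double tx = px - x0, ty = py - y0, tz = pz - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      int zz = dz ? z1 : z0;
      double wz = dz ? tz : 1 - tz;
      if (wz == 0) continue;
      for (int dy = 0; dy < 2; ++dy) {
        int yy = dy ? y1 : y0;
        double wy = dy ? ty : 1 - ty;
        if (wy == 0) continue;
        for (int dx = 0; dx < 2; ++dx) {
          int xx = dx ? x1 : x0;
          double wx = dx ? tx : 1 - tx;
          if (wx == 0) continue;
          acc += wz * wy * wx *
                 s[(R_xlen_t)xx + (R_xlen_t)X * (yy + (R_xlen_t)Y * zz)];
        }
      }
    }
    out[v] = acc;
  }
  return out;
}

// Nearest-neighbour sampling (used for label maps).
// [[Rcpp::export(name = ".sampleNearest")]]
NumericVector sampleNearest(NumericVector src, IntegerVector dims,
                            NumericVector cx, NumericVector cy,
                            NumericVector cz, double fill) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = cx.size();
  NumericVector out(n);
  const double* s = REAL(src);
  for (R_xlen_t v = 0; v < n; ++v) {
    long xx = std::lround(cx[v]) - 1, yy = std::lround(cy[v]) - 1,
         zz = std::lround(cz[v]) - 1;
    out[v] = (xx < 0 || yy < 0 || zz < 0 || xx >= X || yy >= Y || zz >= Z)
                 ? fill
                 : s[(R_xlen_t)xx + (R_xlen_t)X * (yy + (R_xlen_t)Y * zz)];
  }
  return out;
}
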