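#include <Rcpp.h>
using namespace Rcpp;

// Separable 1D convolution along one axis of a 3D array (column-major,
// dims = c(nx, ny, nz)), zero boundary. w is the full kernel (odd length).
// [[Rcpp::export]]
NumericVector conv_axis3d(NumericVector a, IntegerVector dims,
                          NumericVector w, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n3 = (R_xlen_t)nx * ny * nz;
  NumericVector out(n3);
  const int ntap = w.size();
  const int r = (ntap - 1) / 2;

  R_xlen_t stride;
  int len, no1, no2;
  R_xlen_t so1, so2;
  if (axis == 1) {
    stride = 1; len = nx;
    no1 = ny; so1 = nx;
    no2 = nz; so2 = (R_xlen_t)nx * ny;
  } else if (axis == 2) {
    stride = nx; len = ny;
    no1 = nx; so1 = 1;
    no2 = nz; so2 = (R_xlen_t)nx * ny;
  } else {
    stride = (R_xlen_t)nx * ny; len = nz;
    no1 = nx; so1 = 1;
    no2 = ny; so2 = nx;
  }

  const double *pa = a.begin();
  double *po = out.begin();
  const double *pw = w.begin();

  for (int i2 = 0; i2 < no2; ++i2) {
    for (int i1 = 0; i1 < no1; ++i1) {
      const R_xlen_t base = i1 * so1 + i2 * so2;
      for (int j = 0; j < len; ++j) {
        double acc = 0.0;
        const int klo = std::max(0, r - j);
        const int khi = std::min(ntap - 1, len - 1 - j + r);
        for (int k = klo; k <= khi; ++k)
          acc += pw[k] * pa[base + (R_xlen_t)(j + k - r) * stride];
        po[base + (R_xlen_t)j * stride] = acc;
      }
    }
  }
  return out;
}

// Rasterize tube segments (rows: x0,y0,z0,x1,y1,z1,r in µm) into a logical
// voxel grid; a voxel is inside when its center is within r of the segment.
// Voxel centers sit at (i - 0.5) * spacing.
// [[Rcpp::export]]
LogicalVector raster_tubes(IntegerVector dims, NumericVector spacing,
                           NumericMatrix segs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n3 = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n3);
  int *po = out.begin();

  for (int s = 0; s < segs.nrow(); ++s) {
    const double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    const double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    const double r = segs(s, 6);
    if (ISNAN(ax) || ISNAN(az) || ISNAN(bz)) continue;
    const double r2 = r * r;
    const double ux = bx - ax, uy = by - ay, uz = bz - az;
    const double len2 = ux * ux + uy * uy + uz * uz;

    int lo[3], hi[3];
    const double pmin[3] = {std::min(ax, bx) - r, std::min(ay, by) - r,
                            std::min(az, bz) - r};
    const double pmax[3] = {std::max(ax, bx) + r, std::max(ay, by) + r,
                            std::max(az, bz) + r};
    const int nn[3] = {nx, ny, nz};
    bool empty = false;
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::max(0, (int)std::floor(pmin[d] / spacing[d] - 0.5));
      hi[d] = std::min(nn[d] - 1, (int)std::ceil(pmax[d] / spacing[d] - 0.5));
      if (lo[d] > hi[d]) empty = true;
    }
    if (empty) continue;

    for (int k = lo[2]; k <= hi[2]; ++k) {
      const double pz = (k + 0.5) * spacing[2];
      for (int j = lo[1]; j <= hi[1]; ++j) {
        const double py = (j + 0.5) * spacing[1];
        for (int i = lo[0]; i <= hi[0]; ++i) {
          const double px = (i + 0.5) * spacing[0];
          double t = 0.0;
          if (len2 > 0.0) {
            t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / len2;
            if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
          }
          const double dx = px - (ax + t * ux);
          const double dy = py - (ay + t * uy);
          const double dz = pz - (az + t * uz);
          if (dx * dx + dy * dy + dz * dz <= r2)
            po[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
        }
      }
    }
  }
  return out;
}

// Causal AR(1) pass along rows of a matrix: y[0] = x[0];
// y[i] = x[i] + z * y[i-1].
// [[Rcpp::export]]
NumericMatrix ar1_forward(NumericMatrix x, double z) {
  NumericMatrix y = clone(x);
  const int n = y.nrow(), m = y.ncol();
  for (int j = 0; j < m; ++j) {
    double acc = y(0, j);
    for (int i = 1; i < n; ++i) {
      acc = y(i, j) + z * acc;
      y(i, j) = acc;
    }
  }
  return y;
}

// Anticausal pass along rows: y[n-1] = x[n-1];
// y[i] = z * (y[i+1] - x[i]) for i = n-2 .. 0.
// [[Rcpp::export]]
NumericMatrix ar1_backward(NumericMatrix x, double z) {
  NumericMatrix y = clone(x);
  const int n = y.nrow(), m = y.ncol();
  for (int j = 0; j < m; ++j) {
    double acc = y(n - 1, j);
    for (int i = n - 2; i >= 0; --i) {
      acc = z * (acc - y(i, j));
      y(i, j) = acc;
    }
  }
  return y;
}

// Sample prefiltered quintic B-spline coefficients of a 3D array at
// per-frame (Y, Z) translations. c3: prefiltered volume (dims nx, ny, nz);
// off: matrix nx x 2 of (dy, dz) voxel offsets; wtab: 6-tap weight table
// is computed here from the quintic kernel.
static inline double beta5(double x) {
  double a = std::fabs(x);
  if (a < 1.0)
    return (66.0 - 60.0 * a * a + 30.0 * a * a * a * a -
            10.0 * a * a * a * a * a) / 120.0;
  if (a < 2.0)
    return (51.0 + 75.0 * a - 210.0 * a * a + 150.0 * a * a * a -
            45.0 * a * a * a * a + 5.0 * a * a * a * a * a) / 120.0;
  if (a < 3.0) {
    double b = 3.0 - a;
    return b * b * b * b * b / 120.0;
  }
  return 0.0;
}

// [[Rcpp::export]]
NumericVector spline_shift_frames(NumericVector c3, IntegerVector dims,
                                  NumericMatrix off) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *pc = c3.begin();
  double *po = out.begin();

  for (int x = 0; x < nx; ++x) {
    const double dy = off(x, 0), dz = off(x, 1);
    const int niy = (int)std::floor(dy);
    const int niz = (int)std::floor(dz);
    const double fy = dy - niy, fz = dz - niz;
    double wy[6], wz[6];
    int sy[6], sz[6];
    for (int t = 0; t < 6; ++t) {
      wy[t] = beta5(fy + (t - 3));
      wz[t] = beta5(fz + (t - 3));
      sy[t] = niy - (t - 3);   // shift amount: out[i] = in[i - s]
      sz[t] = niz - (t - 3);
    }
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        double acc = 0.0;
        for (int tz = 0; tz < 6; ++tz) {
          if (wz[tz] <= 0.0) continue;
          const int ksrc = k - sz[tz];
          if (ksrc < 0 || ksrc >= nz) continue;
          double accy = 0.0;
          for (int ty = 0; ty < 6; ++ty) {
            if (wy[ty] <= 0.0) continue;
            const int jsrc = j - sy[ty];
            if (jsrc < 0 || jsrc >= ny) continue;
            accy += wy[ty] *
              pc[x + (R_xlen_t)nx * (jsrc + (R_xlen_t)ny * ksrc)];
          }
          acc += wz[tz] * accy;
        }
        po[x + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = acc;
      }
    }
  }
  return out;
}

// Overlap-normalized cross-correlation search over integer (dy, dz) shifts
// of B against A (zeros excluded from the overlap). Returns (dy, dz, corr).
// [[Rcpp::export]]
NumericVector ncc_search(NumericMatrix A, NumericMatrix B, int m) {
  const int ny = A.nrow(), nz = A.ncol();
  double best = -2.0;
  int bdy = 0, bdz = 0;
  for (int dy = -m; dy <= m; ++dy) {
    for (int dz = -m; dz <= m; ++dz) {
      double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      R_xlen_t n = 0;
      const int jlo = std::max(0, dy), jhi = std::min(ny, ny + dy);
      const int klo = std::max(0, dz), khi = std::min(nz, nz + dz);
      for (int k = klo; k < khi; ++k) {
        for (int j = jlo; j < jhi; ++j) {
          const double a = A(j, k);
          const double b = B(j - dy, k - dz);
          if (a == 0.0 || b == 0.0) continue;
          sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
          ++n;
        }
      }
      if (n < 100) continue;
      const double va = saa - sa * sa / n;
      const double vb = sbb - sb * sb / n;
      if (va <= 0.0 || vb <= 0.0) continue;
      const double cc = (sab - sa * sb / n) / std::sqrt(va * vb);
      if (cc > best) { best = cc; bdy = dy; bdz = dz; }
    }
  }
  return NumericVector::create(bdy, bdz, best);
}
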