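#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample a 3D volume (column-major, dims dx,dy,dz) at continuous 0-based
// voxel coordinates. coords is n x 3. Outside the lattice -> `fill`.
// nearest = true gives nearest-neighbour lookup (used for label maps).
// [[Rcpp::export(name = ".interp3_cpp")]]
NumericVector interp3_cpp(NumericVector vol, IntegerVector dims,
                          NumericMatrix coords, bool nearest, double fill) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const int n = coords.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int i = 0; i < n; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (nearest) {
      int ix = (int)std::lround(x), iy = (int)std::lround(y),
          iz = (int)std::lround(z);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= dx || iy >= dy || iz >= dz) {
        out[i] = fill;
      } else {
        out[i] = v[ix + dx * (iy + (R_xlen_t)dy * iz)];
      }
    } else {
      if (x < 0 || y < 0 || z < 0 || x > dx - 1 || y > dy - 1 || z > dz - 1) {
        out[i] = fill;
        continue;
      }
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
          z0 = (int)std::floor(z);
      if (x0 == dx - 1) --x0;
      if (y0 == dy - 1) --y0;
      if (z0 == dz - 1) --z0;
      double fx = x - x0, fy = y - y0, fz = z - z0;
      double acc = 0.0;
      for (int c = 0; c < 8; ++c) {
        int ox = c & 1, oy = (c >> 1) & 1, oz = (c >> 2) & 1;
        double w = (ox ? fx : 1 - fx) * (oy ? fy : 1 - fy) *
                   (oz ? fz : 1 - fz);
        acc += w * v[(x0 + ox) + dx * ((y0 + oy) + (R_xlen_t)dy * (z0 + oz))];
      }
      out[i] = acc;
    }
  }
  return out;
}

// Adaptive appearance-conditioned shape prior. For each voxel p of the
// co-aligned test volume, scan the search cube C_p (half-width hw) in every
// selected atlas image i, collect atlas voxels rho with
// |g_i(rho) - g_t(p)| <= tau, and return
//   P(KT) = (# collected voxels labelled KT) / (# collected).
// If nothing matches at hw0 the cube grows by 1 until hwMax; an empty match
// set even at hwMax falls back to 0.5.
// [[Rcpp::export(name = ".shape_prior_cpp")]]
NumericVector shape_prior_cpp(NumericVector test, IntegerVector dims,
                              List atlasG, List atlasM, double tau,
                              int hw0, int hwMax) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const int nAtlas = atlasG.size();
  std::vector<const double *> G(nAtlas);
  std::vector<const int *> M(nAtlas);
  for (int a = 0; a < nAtlas; ++a) {
    G[a] = NumericVector(atlasG[a]).begin();
    M[a] = IntegerVector(atlasM[a]).begin();
  }
  NumericVector out((R_xlen_t)dx * dy * dz);
  const double *t = test.begin();
  R_xlen_t p = 0;
  for (int z = 0; z < dz; ++z) {
    for (int y = 0; y < dy; ++y) {
      for (int x = 0; x < dx; ++x, ++p) {
        const double gt = t[p];
        long total = 0, kt = 0;
        for (int hw = hw0; hw <= hwMax; ++hw) {
          total = 0; kt = 0;
          const int xl = std::max(0, x - hw), xu = std::min(dx - 1, x + hw);
          const int yl = std::max(0, y - hw), yu = std::min(dy - 1, y + hw);
          const int zl = std::max(0, z - hw), zu = std::min(dz - 1, z + hw);
          for (int a = 0; a < nAtlas; ++a) {
            const double *g = G[a];
            const int *m = M[a];
            for (int zz = zl; zz <= zu; ++zz) {
              for (int yy = yl; yy <= yu; ++yy) {
                R_xlen_t base = dx * (yy + (R_xlen_t)dy * zz);
                for (int xx = xl; xx <= xu; ++xx) {
                  if (std::fabs(g[base + xx] - gt) <= tau) {
                    ++total;
                    kt += m[base + xx];
                  }
                }
              }
            }
          }
          if (total > 0) break;
        }
        out[p] = (total > 0) ? (double)kt / (double)total : 0.5;
      }
    }
  }
  return out;
}

// For every row of `from` (physical mm coordinates), the Euclidean distance
// to the nearest row of `to`. Brute-force scan; surface sets at desk scale
// stay small enough for this to be exact and fast.
// [[Rcpp::export(name = ".min_dists_cpp")]]
NumericVector min_dists_cpp(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  NumericVector out(n);
  std::vector<double> tx(m), ty(m), tz(m);
  for (int j = 0; j < m; ++j) {
    tx[j] = to(j, 0); ty[j] = to(j, 1); tz[j] = to(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    const double fx = from(i, 0), fy = from(i, 1), fz = from(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double ddx = fx - tx[j], ddy = fy - ty[j], ddz = fz - tz[j];
      const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Shift a 3D array by integer offset d: out[p] = a[p + d]; vacated sites
// take `fill`. Core primitive of the neighborhood engine and the MGRF
// clique sums.
// [[Rcpp::export(name = ".shift3_cpp")]]
NumericVector shift3_cpp(NumericVector a, IntegerVector dims,
                         IntegerVector d, double fill) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const int sx = d[0], sy = d[1], sz = d[2];
  NumericVector out((R_xlen_t)dx * dy * dz, fill);
  const double *src = a.begin();
  double *dst = out.begin();
  const int x0 = std::max(0, -sx), x1 = std::min(dx, dx - sx);
  const int y0 = std::max(0, -sy), y1 = std::min(dy, dy - sy);
  const int z0 = std::max(0, -sz), z1 = std::min(dz, dz - sz);
  for (int z = z0; z < z1; ++z) {
    for (int y = y0; y < y1; ++y) {
      const R_xlen_t dstBase = dx * (y + (R_xlen_t)dy * z);
      const R_xlen_t srcBase = dx * ((y + sy) + (R_xlen_t)dy * (z + sz)) + sx;
      for (int x = x0; x < x1; ++x) dst[dstBase + x] = src[srcBase + x];
    }
  }
  return out;
}
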