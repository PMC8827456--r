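#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Chamfer (quasi-Euclidean) distance transform over the fluid voxel graph.
// Seeds are fluid voxels adjacent to a reactive face, initialized at h/2
// (voxel center to wall face). 26-neighbour weights h, h*sqrt2, h*sqrt3;
// distances propagate through fluid voxels only, so the film cannot jump
// through walls. A few forward/backward raster sweeps reach convergence on
// these convex-ish domains.

// [[Rcpp::export]]
NumericVector chamfer_dist_cpp(IntegerVector seed, IntegerVector fluid,
                               int nx, int ny, int nz, double h) {
  const int n = nx*ny*nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n, INF);
  for (int i = 0; i < n; ++i) if (fluid[i] && seed[i]) d[i] = 0.5*h;

  const double w1 = h, w2 = h*std::sqrt(2.0), w3 = h*std::sqrt(3.0);
  bool changed = true;
  int sweep = 0;
  while (changed && sweep < 12) {
    changed = false; ++sweep;
    bool fwd = (sweep % 2 == 1);
    for (int zi = 0; zi < nz; ++zi) {
      int z = fwd ? zi : nz-1-zi;
      for (int yi = 0; yi < ny; ++yi) {
        int y = fwd ? yi : ny-1-yi;
        for (int xi = 0; xi < nx; ++xi) {
          int x = fwd ? xi : nx-1-xi;
          int i = x + nx*(y + (size_t)ny*z);
          if (!fluid[i]) continue;
          double best = d[i];
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int X = x+dx, Y = y+dy, Z = z+dz;
                if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
                int j = X + nx*(Y + (size_t)ny*Z);
                if (!fluid[j] || d[j] == INF) continue;
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                double w = (m == 1) ? w1 : (m == 2 ? w2 : w3);
                if (d[j] + w < best) best = d[j] + w;
              }
          if (best < d[i]) { d[i] = best; changed = true; }
        }
      }
    }
  }
  return NumericVector(d.begin(), d.end());
}
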