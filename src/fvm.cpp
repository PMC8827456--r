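#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit finite-volume update for one transported species on the voxel
// lattice: first-order upwind convection + central diffusion.
// cellkind: 0 = fluid, 1 = solid wall (zero-flux), 2 = platelet-occupied
// (diffusion-only exchange: convection suppressed through its faces).
// Boundary conditions: inflow C = 0 at x = 0 (advective inflow carries zero
// concentration), zero-gradient advective outflow at x = nx-1, zero-flux on
// every other domain boundary. Internally sub-steps to satisfy the explicit
// stability bound. C in nM, velocities in um/s, h in um, src in nM/s.

// [[Rcpp::export]]
List fvm_advance_cpp(NumericVector C, IntegerVector cellkind,
                     NumericVector ux, NumericVector uy, NumericVector uz,
                     NumericVector src,
                     int nx, int ny, int nz,
                     double D, double h, double dt_total,
                     double cfl_safety, int max_substeps) {
  const int n = nx*ny*nz;
  std::vector<double> c(C.begin(), C.end()), cn(n);

  // stability bound
  double umax = 0;
  for (int i = 0; i < n; ++i) {
    if (cellkind[i] == 1) continue;
    double s = std::fabs(ux[i]) + std::fabs(uy[i]) + std::fabs(uz[i]);
    if (s > umax) umax = s;
  }
  double dt_diff = h*h/(6.0*D);
  double dt_conv = (umax > 0) ? h/umax : R_PosInf;
  double dt_sub = cfl_safety * std::min(dt_diff, dt_conv);
  int nsub = (int)std::ceil(dt_total/dt_sub);
  if (nsub < 1) nsub = 1;
  if (nsub > max_substeps)
    stop("transport stability requires %d sub-steps (> limit %d); reduce dt or refine setup",
         nsub, max_substeps);
  double dt = dt_total/nsub;

  const int strideY = nx, strideZ = nx*ny;
  double mass_out = 0;
  double idx2 = D/(h*h), idx1 = 1.0/h;

  for (int step = 0; step < nsub; ++step) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = x + nx*(y + (size_t)ny*z);
          int ki = cellkind[i];
          if (ki == 1) { cn[i] = 0; continue; }
          double acc = 0;
          // the 6 faces
          const int offs[6] = { +1, -1, +strideY, -strideY, +strideZ, -strideZ };
          const int dim[6] = {0,0,1,1,2,2};
          const int dir[6] = {+1,-1,+1,-1,+1,-1};
          for (int fidx = 0; fidx < 6; ++fidx) {
            int xn = x, yn = y, zn = z;
            if (dim[fidx]==0) xn += dir[fidx];
            else if (dim[fidx]==1) yn += dir[fidx];
            else zn += dir[fidx];
            bool outside = (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz);
            if (outside) {
              // x=0 inflow face: advective influx of C=0 and advective efflux
              // of c_i if local u points out; x=nx-1: zero-gradient outflow
              if (dim[fidx]==0 && xn < 0) {
                double uf = ux[i];
                if (uf < 0) { acc += idx1 * uf * c[i]; mass_out += -uf*c[i]*h*h*dt; }
                // inflow carries C = 0: no contribution
              } else if (dim[fidx]==0 && xn >= nx) {
                double uf = ux[i];
                if (uf > 0) { acc -= idx1 * uf * c[i]; mass_out += uf*c[i]*h*h*dt; }
              }
              continue; // transverse boundaries: zero flux
            }
            int j = i + offs[fidx];
            int kj = cellkind[j];
            if (kj == 1) continue; // wall: zero flux
            // diffusive exchange always (fluid or platelet voxel)
            acc += idx2 * (c[j] - c[i]);
            // convective flux only across fluid-fluid faces
            if (ki == 0 && kj == 0) {
              double uf;
              if (dim[fidx]==0) uf = 0.5*(ux[i]+ux[j]);
              else if (dim[fidx]==1) uf = 0.5*(uy[i]+uy[j]);
              else uf = 0.5*(uz[i]+uz[j]);
              double flux = dir[fidx] * uf; // outward-normal velocity
              // upwind: outgoing flux carries c_i, incoming carries c_j
              if (flux > 0) acc -= idx1 * flux * c[i];
              else acc -= idx1 * flux * c[j];
            }
          }
          double v = c[i] + dt*(acc + src[i]);
          cn[i] = (v > 0) ? v : 0;
        }
    std::swap(c, cn);
  }

  NumericVector out(c.begin(), c.end());
  return List::create(_["C"] = out, _["mass_out"] = mass_out,
                      _["n_substeps"] = nsub, _["dt_sub"] = dt);
}
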