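#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rejection-free (direct) kinetic Monte Carlo engine over the platelet
// population. Events per platelet:
//   mobile : 6 lattice moves (upwind convective projection + diffusive rate)
//            and one attachment event (to collagen face and/or every
//            face-adjacent bound platelet, rates summed; executing it binds
//            to all available partners at once);
//   bound  : one detachment event releasing all bonds. The multi-bond
//            detachment rate is the series (harmonic) combination of the
//            per-bond closed-form rates, so a single bond reduces exactly
//            to the closed-form law.
// Bonds are implicit in adjacency: a bound platelet is bonded to the
// collagen face under it (if any) and to every face-adjacent bound platelet.
// After a detachment, bound neighbours left without any bond are released
// (local cascade). Platelets crossing the outlet face are removed.
// Uses R's RNG so set.seed() controls the stream.

struct KParams {
  double k_att_col, k_att_plt, k_det_col, k_det_plt;
  double gamma_c, gamma_c_p;
  bool vwf_on, g_cont;
  double D, h;
};

static inline double Efun(double g, const KParams& p) {
  if (!p.vwf_on) return 1.0;
  if (g <= 3000.0) return 1.0;
  if (g <= 8000.0) return 1.0 + 19.0*(g - 3000.0)/5000.0;
  return 20.0;
}
static inline double Gfun(double g, const KParams& p) {
  if (g <= 1000.0) return std::exp(g/p.gamma_c);
  double tail = p.g_cont ? std::exp((g - 1000.0)/p.gamma_c_p)
                         : std::exp(g/p.gamma_c_p);
  return std::exp(1000.0/p.gamma_c) * tail;
}

class Engine {
public:
  int nx, ny, nz, n;
  std::vector<int> occ;           // -1 empty fluid, -2 solid, >=0 platelet row
  const int* coll;                // per-voxel: adjacent reactive face?
  const double *ux, *uy, *uz, *gam;
  KParams p;
  std::vector<int> pos;
  std::vector<int> mobile;        // 1 mobile, 0 bound
  std::vector<int> removed;
  std::vector<double> Fxi, Fxidt;
  std::vector<double> rate;       // per-platelet total rate
  double lambda;
  long n_moves = 0, n_attach = 0, n_detach = 0, n_removed = 0, n_cascade = 0;

  int X(int i) const { return i % nx; }
  int Y(int i) const { return (i / nx) % ny; }
  int Z(int i) const { return i / (nx*ny); }

  bool neighbor(int v, int d, int& t) const {
    // d: 0 +x, 1 -x, 2 +y, 3 -y, 4 +z, 5 -z ; returns false if outside
    int x = X(v), y = Y(v), z = Z(v);
    switch (d) {
      case 0: if (++x >= nx) return false; break;
      case 1: if (--x < 0) return false; break;
      case 2: if (++y >= ny) return false; break;
      case 3: if (--y < 0) return false; break;
      case 4: if (++z >= nz) return false; break;
      case 5: if (--z < 0) return false; break;
    }
    t = x + nx*(y + (size_t)ny*z);
    return true;
  }

  double vproj(int v, int d) const {
    switch (d) {
      case 0: return ux[v]; case 1: return -ux[v];
      case 2: return uy[v]; case 3: return -uy[v];
      case 4: return uz[v]; case 5: return -uz[v];
    }
    return 0;
  }

  // motion rate of mobile platelet at voxel v in direction d
  double motion_rate(int v, int d) const {
    int t;
    double conv = std::max(vproj(v, d), 0.0)/p.h;
    double diff = p.D/(p.h*p.h);
    if (!neighbor(v, d, t)) {
      // outside the lattice: allowed only across the outlet (+x) face
      if (d == 0 && X(v) == nx-1) return conv + diff;
      return 0.0;
    }
    if (occ[t] != -1) return 0.0;  // solid or occupied
    return conv + diff;
  }

  double attach_rate_total(int i) const {
    int v = pos[i];
    double r = 0, gi = gam[v];
    if (coll[v])
      r += p.k_att_col * Fxi[i]*Fxidt[i]*Efun(gi, p);
    for (int d = 0; d < 6; ++d) {
      int t;
      if (!neighbor(v, d, t)) continue;
      int j = occ[t];
      if (j >= 0 && !mobile[j]) {
        double gj = gam[pos[j]];
        r += p.k_att_plt * std::sqrt(Fxi[i]*Fxi[j]*Fxidt[i]*Fxidt[j]*
                                     Efun(gi, p)*Efun(gj, p));
      }
    }
    return r;
  }

  // per-bond detach rates; returns number of bonds, fills harmonic sum
  int detach_bonds(int i, double& inv_sum) const {
    int v = pos[i], nb = 0;
    double gi = gam[v];
    inv_sum = 0;
    if (coll[v]) {
      double r = p.k_det_col * Gfun(gi, p) /
                 (Fxi[i]*Fxidt[i]*Efun(gi, p));
      inv_sum += 1.0/r; ++nb;
    }
    for (int d = 0; d < 6; ++d) {
      int t;
      if (!neighbor(v, d, t)) continue;
      int j = occ[t];
      if (j >= 0 && !mobile[j]) {
        double gj = gam[pos[j]];
        double r = p.k_det_plt *
          std::sqrt(Gfun(gi, p)*Gfun(gj, p)) /
          std::sqrt(Fxi[i]*Fxi[j]*Fxidt[i]*Fxidt[j]*Efun(gi, p)*Efun(gj, p));
        inv_sum += 1.0/r; ++nb;
      }
    }
    return nb;
  }

  double total_rate(int i) const {
    if (removed[i]) return 0;
    if (mobile[i]) {
      double r = 0;
      for (int d = 0; d < 6; ++d) r += motion_rate(pos[i], d);
      r += attach_rate_total(i);
      return r;
    }
    double inv;
    int nb = detach_bonds(i, inv);
    return nb > 0 ? 1.0/inv : 0.0;
  }

  void refresh(int i) {
    double nr = total_rate(i);
    lambda += nr - rate[i];
    rate[i] = nr;
  }

  void refresh_around(int v) {
    for (int d = 0; d < 6; ++d) {
      int t;
      if (neighbor(v, d, t) && occ[t] >= 0) refresh(occ[t]);
    }
  }

  void rebuild_lambda() {
    lambda = 0;
    for (size_t i = 0; i < rate.size(); ++i) {
      rate[i] = total_rate((int)i);
      lambda += rate[i];
    }
  }

  void release_cascade(int i) {
    // platelet i just detached (now mobile); free bound neighbours that
    // lost their last bond
    std::vector<int> queue; queue.push_back(i);
    while (!queue.empty()) {
      int k = queue.back(); queue.pop_back();
      int v = pos[k];
      for (int d = 0; d < 6; ++d) {
        int t;
        if (!neighbor(v, d, t)) continue;
        int j = occ[t];
        if (j >= 0 && !mobile[j]) {
          double inv;
          if (detach_bonds(j, inv) == 0) {
            mobile[j] = 1;
            ++n_cascade;
            queue.push_back(j);
          }
        }
      }
    }
  }

  void execute(int i, double u2) {
    if (mobile[i]) {
      // split the platelet's total rate into 6 moves + attach
      double mr[6], cum = 0;
      for (int d = 0; d < 6; ++d) { mr[d] = motion_rate(pos[i], d); cum += mr[d]; }
      double att = attach_rate_total(i);
      double pick = u2 * (cum + att);
      int v = pos[i];
      if (pick < cum) {
        int d = 0; double acc = mr[0];
        while (pick >= acc && d < 5) { acc += mr[++d]; }
        if (mr[d] <= 0) return;  // FP tie on a zero-rate slot: no-op
        int t;
        if (!neighbor(v, d, t)) {
          // outlet crossing: remove
          removed[i] = 1; occ[v] = -1; ++n_removed;
          refresh(i); refresh_around(v);
          return;
        }
        if (occ[t] != -1) stop("KMC event table inconsistency: move into occupied voxel");
        occ[v] = -1; occ[t] = i; pos[i] = t; ++n_moves;
        refresh(i); refresh_around(v); refresh_around(t);
      } else {
        mobile[i] = 0; ++n_attach;
        refresh(i); refresh_around(v);
      }
    } else {
      int v = pos[i];
      mobile[i] = 1; ++n_detach;
      release_cascade(i);
      // cascade may have freed platelets anywhere adjacent; refresh i,
      // neighbours, and all platelets turned mobile (their rates changed)
      rebuild_lambda();
      (void)v;
    }
  }
};

// [[Rcpp::export]]
List kmc_advance_cpp(IntegerVector pos, IntegerVector mobile,
                     NumericVector Fxi, NumericVector Fxidt,
                     IntegerVector occ, IntegerVector collagen_adj,
                     NumericVector ux, NumericVector uy, NumericVector uz,
                     NumericVector gamma_around,
                     int nx, int ny, int nz, double h, double D_platelet,
                     List adh, double t_target, double max_events,
                     bool audit) {
  Engine e;
  e.nx = nx; e.ny = ny; e.nz = nz; e.n = nx*ny*nz;
  e.occ.assign(occ.begin(), occ.end());
  e.coll = INTEGER(collagen_adj);
  e.ux = REAL(ux); e.uy = REAL(uy); e.uz = REAL(uz); e.gam = REAL(gamma_around);
  e.p.k_att_col = adh["k_att_collagen"]; e.p.k_att_plt = adh["k_att_platelet"];
  e.p.k_det_col = adh["k_det_collagen"]; e.p.k_det_plt = adh["k_det_platelet"];
  e.p.gamma_c = adh["gamma_c"]; e.p.gamma_c_p = adh["gamma_c_prime"];
  e.p.vwf_on = adh["vwf_enhancement_on"]; e.p.g_cont = adh["G_continuous_variant"];
  e.p.D = D_platelet; e.p.h = h;
  int np = pos.size();
  e.pos.assign(pos.begin(), pos.end());
  e.mobile.assign(mobile.begin(), mobile.end());
  e.removed.assign(np, 0);
  e.Fxi.assign(Fxi.begin(), Fxi.end());
  e.Fxidt.assign(Fxidt.begin(), Fxidt.end());
  e.rate.assign(np, 0.0);
  e.rebuild_lambda();

  GetRNGstate();
  double t = 0;
  long nev = 0;
  while (t < t_target && nev < (long)max_events) {
    if (e.lambda <= 1e-300) { t = t_target; break; }  // quiescent
    double u1 = unif_rand();
    double dt = -std::log(u1)/e.lambda;
    if (t + dt > t_target) { t = t_target; break; }
    t += dt;
    // pick platelet proportional to rate
    double r = unif_rand()*e.lambda, acc = 0;
    int i = -1;
    for (int k = 0; k < np; ++k) {
      acc += e.rate[k];
      if (r < acc) { i = k; break; }
    }
    if (i < 0) { // FP drift: rebuild and retry
      e.rebuild_lambda();
      continue;
    }
    e.execute(i, unif_rand());
    ++nev;
    if (nev % 20000 == 0) e.rebuild_lambda();
  }
  PutRNGstate();

  double lambda_incr = e.lambda, audit_diff = NA_REAL;
  if (audit) {
    double li = e.lambda;
    e.rebuild_lambda();
    audit_diff = std::fabs(li - e.lambda);
  }

  return List::create(
    _["pos"] = IntegerVector(e.pos.begin(), e.pos.end()),
    _["mobile"] = IntegerVector(e.mobile.begin(), e.mobile.end()),
    _["removed"] = IntegerVector(e.removed.begin(), e.removed.end()),
    _["occ"] = IntegerVector(e.occ.begin(), e.occ.end()),
    _["t_advanced"] = t,
    _["n_events"] = (double)nev,
    _["n_moves"] = (double)e.n_moves, _["n_attach"] = (double)e.n_attach,
    _["n_detach"] = (double)e.n_detach, _["n_removed"] = (double)e.n_removed,
    _["n_cascade"] = (double)e.n_cascade,
    _["lambda"] = lambda_incr, _["audit_diff"] = audit_diff,
    _["rates"] = NumericVector(e.rate.begin(), e.rate.end()));
}
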