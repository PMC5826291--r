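// Coarse-grained Langevin dynamics core: Ashbaugh-Hatch hydrophobic pairs,
// Debye-screened Coulomb with a distance-dependent dielectric, harmonic
// bonds and tethers, fixed wall beads, membrane half-spaces, an optional
// rigid cargo sphere with surface binding spots, BAOAB integration and
// steepest-descent minimization. Units: nm, ps, kJ/mol, Da, e.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KE_COUL = 138.935458; // kJ mol^-1 nm e^-2
static const double KB = 0.00831446262;   // kJ mol^-1 K^-1

struct Dielectric {
  double eps_bulk, A, k, l;
  inline double eval(double r, double &deriv) const {
    double B = eps_bulk - A;
    double ex = k * std::exp(-l * B * (r * 10.0));
    double denom = 1.0 + ex;
    double eps = A + B / denom;
    deriv = B * ex * (l * B * 10.0) / (denom * denom);
    return eps;
  }
};

// C2 quintic switch: 1 below r_on, 0 above r_off
static inline double switch_fn(double r, double r_on, double r_off, double &deriv) {
  if (r <= r_on) { deriv = 0.0; return 1.0; }
  if (r >= r_off) { deriv = 0.0; return 0.0; }
  double x = (r - r_on) / (r_off - r_on);
  double s = 1.0 - (10.0 * x * x * x - 15.0 * x * x * x * x + 6.0 * x * x * x * x * x);
  deriv = -(30.0 * x * x - 60.0 * x * x * x + 30.0 * x * x * x * x) / (r_off - r_on);
  return s;
}

class CGSystem {
public:
  int n_total, n_mobile;
  std::vector<double> x, y, z;        // n_total
  std::vector<double> mass, charge, lambda, diam;
  std::vector<int> bond_a, bond_b;    // 0-based
  double bond_r0, bond_k;
  std::vector<int> teth_bead;         // 0-based
  std::vector<double> teth_x, teth_y, teth_z;
  double teth_k;
  // bond-angle triplets (Kratky-Porod bending)
  std::vector<int> ang_a, ang_b, ang_c;
  double bend_k;
  // exclusion list: up to 2 bonded partners per bead
  std::vector<int> excl1, excl2;
  // geometry
  double pore_radius, half_height, wall_k;
  double box_x, box_y, box_z, box_k;
  bool has_membrane;
  // force field
  double eps0, kappa, lj_factor, coul_cutoff, switch_frac, min_sep;
  Dielectric diel;
  // cargo
  bool has_cargo;
  double cx, cy, cz, cvx, cvy, cvz;
  double cargo_radius, cargo_charge, cargo_mass;
  double site_eps, site_lambda_thr, site_sigma;
  std::vector<double> site_ux, site_uy, site_uz; // unit offsets
  bool restraint_on;
  double restr_z0, restr_k, restr_k_lat;
  // forces
  std::vector<double> fx, fy, fz;
  double cfx, cfy, cfz;
  double potential;
  // cell list
  double cell_size;
  int ncx, ncy, ncz;
  std::vector<int> head, next_in_cell;
  double ox, oy, oz;
  // Verlet pair list with skin, rebuilt on a displacement criterion
  double skin = 0.3;
  std::vector<int> pair_i, pair_j;
  std::vector<double> ref_x, ref_y, ref_z;
  bool list_valid = false;

  void init_from_list(const List &st) {
    NumericMatrix coords = st["coords"];
    n_total = coords.nrow();
    n_mobile = as<int>(st["n_mobile"]);
    x.resize(n_total); y.resize(n_total); z.resize(n_total);
    for (int i = 0; i < n_total; ++i) {
      x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    }
    mass = as<std::vector<double>>(st["mass"]);
    charge = as<std::vector<double>>(st["charge"]);
    lambda = as<std::vector<double>>(st["lambda"]);
    diam = as<std::vector<double>>(st["diameter"]);
    IntegerMatrix bonds = st["bonds"];
    int m = bonds.nrow();
    bond_a.resize(m); bond_b.resize(m);
    excl1.assign(n_total, -1); excl2.assign(n_total, -1);
    for (int i = 0; i < m; ++i) {
      bond_a[i] = bonds(i, 0) - 1; bond_b[i] = bonds(i, 1) - 1;
      int a = bond_a[i], b = bond_b[i];
      if (excl1[a] < 0) excl1[a] = b; else excl2[a] = b;
      if (excl1[b] < 0) excl1[b] = a; else excl2[b] = a;
    }
    bond_r0 = as<double>(st["bond_r0"]);
    bond_k = as<double>(st["bond_k"]);
    bend_k = as<double>(st["bend_k"]);
    // consecutive-bond triplets: beads with two bonded partners
    for (int b = 0; b < n_total; ++b) {
      if (excl1[b] >= 0 && excl2[b] >= 0) {
        ang_a.push_back(excl1[b]); ang_b.push_back(b); ang_c.push_back(excl2[b]);
      }
    }
    IntegerVector tb = st["tether_bead"];
    NumericMatrix ts = st["tether_site"];
    teth_bead.resize(tb.size());
    teth_x.resize(tb.size()); teth_y.resize(tb.size()); teth_z.resize(tb.size());
    for (int i = 0; i < tb.size(); ++i) {
      teth_bead[i] = tb[i] - 1;
      teth_x[i] = ts(i, 0); teth_y[i] = ts(i, 1); teth_z[i] = ts(i, 2);
    }
    teth_k = as<double>(st["tether_k"]);
    List geom = st["geom"];
    pore_radius = as<double>(geom["pore_radius"]);
    half_height = as<double>(geom["half_height"]);
    has_membrane = as<bool>(geom["has_membrane"]);
    wall_k = as<double>(geom["wall_k"]);
    NumericVector box = geom["box"];
    box_x = box[0] / 2.0; box_y = box[1] / 2.0; box_z = box[2] / 2.0;
    box_k = as<double>(geom["box_k"]);
    List ff = st["ff"];
    eps0 = as<double>(ff["epsilon0"]);
    kappa = as<double>(ff["kappa"]);
    lj_factor = as<double>(ff["lj_cutoff_factor"]);
    coul_cutoff = as<double>(ff["coulomb_cutoff"]);
    switch_frac = as<double>(ff["switch_fraction"]);
    min_sep = as<double>(ff["min_separation"]);
    List dl = ff["dielectric"];
    diel.eps_bulk = as<double>(dl["eps_bulk"]);
    diel.A = as<double>(dl["A"]);
    diel.k = as<double>(dl["k"]);
    diel.l = as<double>(dl["l"]);
    List cg = st["cargo"];
    has_cargo = as<bool>(cg["present"]);
    if (has_cargo) {
      NumericVector cc = cg["center"];
      cx = cc[0]; cy = cc[1]; cz = cc[2];
      cargo_radius = as<double>(cg["radius"]);
      cargo_charge = as<double>(cg["charge"]);
      cargo_mass = as<double>(cg["mass"]);
      site_eps = as<double>(cg["site_strength"]);
      site_lambda_thr = as<double>(cg["site_lambda_threshold"]);
      site_sigma = as<double>(cg["site_sigma"]);
      NumericMatrix su = cg["sites"];
      for (int i = 0; i < su.nrow(); ++i) {
        site_ux.push_back(su(i, 0));
        site_uy.push_back(su(i, 1));
        site_uz.push_back(su(i, 2));
      }
      restraint_on = as<bool>(cg["restraint_on"]);
      restr_z0 = as<double>(cg["restraint_z0"]);
      restr_k = as<double>(cg["restraint_k"]);
      restr_k_lat = as<double>(cg["restraint_k_lat"]);
    } else {
      cx = cy = cz = 0.0; cargo_radius = 0.0; cargo_charge = 0.0;
      cargo_mass = 1.0; site_eps = 0.0; site_lambda_thr = 1.0;
      site_sigma = 0.8; restraint_on = false; restr_z0 = 0.0;
      restr_k = 0.0; restr_k_lat = 0.0;
    }
    cvx = cvy = cvz = 0.0;
    fx.assign(n_total, 0.0); fy.assign(n_total, 0.0); fz.assign(n_total, 0.0);
    // fixed-fixed pairs are skipped; lambda = 0 pairs (wall beads) stop at
    // the WCA minimum, attractive pairs at the switched LJ cutoff
    double dmax = 0.0, dmax_mobile = 0.0, dmax_attr = 0.0;
    for (int i = 0; i < n_total; ++i) dmax = std::max(dmax, diam[i]);
    for (int i = 0; i < n_mobile; ++i) {
      dmax_mobile = std::max(dmax_mobile, diam[i]);
      if (lambda[i] > 0.0) dmax_attr = std::max(dmax_attr, diam[i]);
    }
    double rc_wca = 1.122462048309373 * 0.5 * (dmax + dmax_mobile);
    double rc_attr = lj_factor * dmax_attr;
    cell_size = std::max(std::max(rc_wca, rc_attr), coul_cutoff);
  }

  // pair interaction (chain/wall beads); returns energy, accumulates forces
  inline double pair_interaction(int i, int j, double scale_attr, double scale_q) {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    double sigma = 0.5 * (diam[i] + diam[j]);
    bool attractive = lambda[i] * lambda[j] > 0.0;
    // purely repulsive pairs stop at the WCA minimum (potential is exactly
    // zero beyond it), attractive pairs at the switched LJ cutoff
    double rc_lj = attractive ? lj_factor * sigma : 1.122462048309373 * sigma;
    double qq0 = charge[i] * charge[j];
    double rc = (qq0 != 0.0) ? std::max(rc_lj, coul_cutoff) : rc_lj;
    if (r2 >= rc * rc) return 0.0;
    double r = std::sqrt(r2);
    if (r < min_sep) r = min_sep; // clamp: minimization handles overlaps
    double e = 0.0, dudr = 0.0;
    if (r < rc_lj) {
      double lam = attractive ? std::sqrt(lambda[i] * lambda[j]) * scale_attr : 0.0;
      double s2 = sigma * sigma / (r * r);
      double sr6 = s2 * s2 * s2;
      double ulj = 4.0 * eps0 * (sr6 * sr6 - sr6);
      double dulj = 4.0 * eps0 * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
      double rmin = 1.122462048309373 * sigma;
      double u_core, du_core;
      if (r <= rmin) { u_core = ulj + (1.0 - lam) * eps0; du_core = dulj; }
      else { u_core = lam * ulj; du_core = lam * dulj; }
      if (attractive) {
        double dsw;
        double sw = switch_fn(r, switch_frac * lj_factor * sigma,
                              lj_factor * sigma, dsw);
        e += u_core * sw;
        dudr += du_core * sw + u_core * dsw;
      } else {
        e += u_core;
        dudr += du_core;
      }
    }
    double qq = qq0;
    if (qq != 0.0 && r < coul_cutoff) {
      qq *= scale_q;
      double deps;
      double eps_r = diel.eval(r, deps);
      double base = KE_COUL * qq * std::exp(-kappa * r) / (eps_r * r);
      double dbase = base * (-kappa - 1.0 / r - deps / eps_r);
      double dsw;
      double sw = switch_fn(r, switch_frac * coul_cutoff, coul_cutoff, dsw);
      e += base * sw;
      dudr += dbase * sw + base * dsw;
    }
    // cap pathological forces from residual overlaps (normal interaction
    // forces are orders of magnitude below this)
    if (dudr > 1e4) dudr = 1e4; else if (dudr < -1e4) dudr = -1e4;
    double fmag = -dudr / r;
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    return e;
  }

  void build_cells() {
    double xmin = 1e30, ymin = 1e30, zmin = 1e30;
    double xmax = -1e30, ymax = -1e30, zmax = -1e30;
    for (int i = 0; i < n_total; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    if (xmax - xmin > 1e4 || ymax - ymin > 1e4 || zmax - zmin > 1e4)
      stop("coordinates exploded beyond 10 um: timestep instability (minimize the system and/or reduce the timestep)");
    ox = xmin - 1e-6; oy = ymin - 1e-6; oz = zmin - 1e-6;
    ncx = std::max(1, (int)((xmax - ox) / cell_size) + 1);
    ncy = std::max(1, (int)((ymax - oy) / cell_size) + 1);
    ncz = std::max(1, (int)((zmax - oz) / cell_size) + 1);
    head.assign((size_t)ncx * ncy * ncz, -1);
    next_in_cell.assign(n_total, -1);
    for (int i = 0; i < n_total; ++i) {
      int cxi = (int)((x[i] - ox) / cell_size);
      int cyi = (int)((y[i] - oy) / cell_size);
      int czi = (int)((z[i] - oz) / cell_size);
      cxi = std::min(std::max(cxi, 0), ncx - 1);
      cyi = std::min(std::max(cyi, 0), ncy - 1);
      czi = std::min(std::max(czi, 0), ncz - 1);
      int cell = (czi * ncy + cyi) * ncx + cxi;
      next_in_cell[i] = head[cell];
      head[cell] = i;
    }
  }

  void build_pair_list() {
    build_cells();
    pair_i.clear(); pair_j.clear();
    double rl = cell_size + skin;
    double rl2 = rl * rl;
    static const int offs[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int czi = 0; czi < ncz; ++czi)
      for (int cyi = 0; cyi < ncy; ++cyi)
        for (int cxi = 0; cxi < ncx; ++cxi) {
          int cell = (czi * ncy + cyi) * ncx + cxi;
          for (int i = head[cell]; i >= 0; i = next_in_cell[i]) {
            for (int j = next_in_cell[i]; j >= 0; j = next_in_cell[j]) {
              if (i >= n_mobile && j >= n_mobile) continue;
              if (excl1[i] == j || excl2[i] == j) continue;
              double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
              if (dx * dx + dy * dy + dz * dz < rl2) {
                pair_i.push_back(i); pair_j.push_back(j);
              }
            }
            for (int n = 0; n < 13; ++n) {
              int nx = cxi + offs[n][0], ny = cyi + offs[n][1], nz = czi + offs[n][2];
              if (nx < 0 || nx >= ncx || ny < 0 || ny >= ncy || nz < 0 || nz >= ncz)
                continue;
              int ncell = (nz * ncy + ny) * ncx + nx;
              for (int j = head[ncell]; j >= 0; j = next_in_cell[j]) {
                if (i >= n_mobile && j >= n_mobile) continue;
                if (excl1[i] == j || excl2[i] == j) continue;
                double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
                if (dx * dx + dy * dy + dz * dz < rl2) {
                  pair_i.push_back(i); pair_j.push_back(j);
                }
              }
            }
          }
        }
    ref_x = x; ref_y = y; ref_z = z;
    list_valid = true;
  }

  bool list_stale() {
    if (!list_valid) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n_mobile; ++i) {
      double dx = x[i] - ref_x[i], dy = y[i] - ref_y[i], dz = z[i] - ref_z[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  double compute_forces(double scale_attr, double scale_q) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    cfx = cfy = cfz = 0.0;
    double e = 0.0;
    if (list_stale()) build_pair_list();
    for (size_t p = 0; p < pair_i.size(); ++p) {
      e += pair_interaction(pair_i[p], pair_j[p], scale_attr, scale_q);
    }
    // bonds
    for (size_t b = 0; b < bond_a.size(); ++b) {
      int i = bond_a[b], j = bond_b[b];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) stop("coincident bonded neighbours during force evaluation");
      double dr = r - bond_r0;
      e += 0.5 * bond_k * dr * dr;
      double fmag = -bond_k * dr / r;
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
    // Kratky-Porod bending: U = k_bend (1 + cos theta), zero for straight
    if (bend_k > 0.0) {
      for (size_t t = 0; t < ang_a.size(); ++t) {
        int ia = ang_a[t], ib = ang_b[t], ic = ang_c[t];
        double ux = x[ia] - x[ib], uy = y[ia] - y[ib], uz = z[ia] - z[ib];
        double vx2 = x[ic] - x[ib], vy2 = y[ic] - y[ib], vz2 = z[ic] - z[ib];
        double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
        double nv = std::sqrt(vx2 * vx2 + vy2 * vy2 + vz2 * vz2);
        if (nu < 1e-9 || nv < 1e-9) continue;
        double ct = (ux * vx2 + uy * vy2 + uz * vz2) / (nu * nv);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
        e += bend_k * (1.0 + ct);
        // F = -k * d(cos theta)/dr
        double fa_x = -bend_k * (vx2 / (nu * nv) - ct * ux / (nu * nu));
        double fa_y = -bend_k * (vy2 / (nu * nv) - ct * uy / (nu * nu));
        double fa_z = -bend_k * (vz2 / (nu * nv) - ct * uz / (nu * nu));
        double fc_x = -bend_k * (ux / (nu * nv) - ct * vx2 / (nv * nv));
        double fc_y = -bend_k * (uy / (nu * nv) - ct * vy2 / (nv * nv));
        double fc_z = -bend_k * (uz / (nu * nv) - ct * vz2 / (nv * nv));
        fx[ia] += fa_x; fy[ia] += fa_y; fz[ia] += fa_z;
        fx[ic] += fc_x; fy[ic] += fc_y; fz[ic] += fc_z;
        fx[ib] -= fa_x + fc_x; fy[ib] -= fa_y + fc_y; fz[ib] -= fa_z + fc_z;
      }
    }
    // tethers
    for (size_t t = 0; t < teth_bead.size(); ++t) {
      int i = teth_bead[t];
      double dx = x[i] - teth_x[t], dy = y[i] - teth_y[t], dz = z[i] - teth_z[t];
      e += 0.5 * teth_k * (dx * dx + dy * dy + dz * dz);
      fx[i] -= teth_k * dx; fy[i] -= teth_k * dy; fz[i] -= teth_k * dz;
    }
    // membrane half-spaces and box confinement (mobile beads only)
    for (int i = 0; i < n_mobile; ++i) {
      if (has_membrane) {
        double rxy = std::sqrt(x[i] * x[i] + y[i] * y[i]);
        if (rxy > pore_radius + 0.5 && std::fabs(z[i]) < half_height) {
          double pen = half_height - std::fabs(z[i]);
          e += 0.5 * wall_k * pen * pen;
          double sgn = z[i] >= 0 ? 1.0 : -1.0;
          fz[i] += sgn * wall_k * pen;
        }
      }
      double exx = std::fabs(x[i]) - (box_x - 1.0);
      if (exx > 0) { e += 0.5 * box_k * exx * exx; fx[i] -= box_k * exx * (x[i] > 0 ? 1 : -1); }
      double eyy = std::fabs(y[i]) - (box_y - 1.0);
      if (eyy > 0) { e += 0.5 * box_k * eyy * eyy; fy[i] -= box_k * eyy * (y[i] > 0 ? 1 : -1); }
      double ezz = std::fabs(z[i]) - (box_z - 1.0);
      if (ezz > 0) { e += 0.5 * box_k * ezz * ezz; fz[i] -= box_k * ezz * (z[i] > 0 ? 1 : -1); }
    }
    // cargo
    if (has_cargo) {
      for (int i = 0; i < n_total; ++i) {
        double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        double h = d - cargo_radius;
        double sig = 0.5 * (diam[i] + 0.6);
        double hmin = 1.122462048309373 * sig;
        if (h < hmin) {
          double hh = std::max(h, 0.05);
          double sr6 = std::pow(sig / hh, 6);
          e += 4.0 * eps0 * (sr6 * sr6 - sr6) + eps0;
          double du = 4.0 * eps0 * (-12.0 * sr6 * sr6 + 6.0 * sr6) / hh;
          if (du < -1e4) du = -1e4;
          double fmag = -du / std::max(d, 1e-9);
          if (i < n_mobile) {
            fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
          }
          cfx -= fmag * dx; cfy -= fmag * dy; cfz -= fmag * dz;
        }
        if (i < n_mobile && cargo_charge != 0.0 && charge[i] != 0.0) {
          double rc_c = cargo_radius + coul_cutoff;
          if (d < rc_c && d > 1e-6) {
            double qq = scale_q_saved * cargo_charge * charge[i];
            double deps;
            double eps_r = diel.eval(d, deps);
            double base = KE_COUL * qq * std::exp(-kappa * d) / (eps_r * d);
            double dbase = base * (-kappa - 1.0 / d - deps / eps_r);
            double dsw;
            double sw = switch_fn(d, switch_frac * rc_c, rc_c, dsw);
            e += base * sw;
            double du = dbase * sw + base * dsw;
            double fmag = -du / d;
            fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
            cfx -= fmag * dx; cfy -= fmag * dy; cfz -= fmag * dz;
          }
        }
      }
      // binding spots
      if (site_eps > 0.0) {
        for (size_t s = 0; s < site_ux.size(); ++s) {
          double sx = cx + cargo_radius * site_ux[s];
          double sy = cy + cargo_radius * site_uy[s];
          double sz = cz + cargo_radius * site_uz[s];
          double rc_s = 2.5 * site_sigma;
          for (int i = 0; i < n_mobile; ++i) {
            if (lambda[i] <= site_lambda_thr) continue;
            double dx = x[i] - sx, dy = y[i] - sy, dz = z[i] - sz;
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= rc_s * rc_s) continue;
            double r = std::sqrt(std::max(r2, 1e-6));
            double lam = lambda[i] * scale_attr_saved;
            double sr6 = std::pow(site_sigma / r, 6);
            double ulj = 4.0 * site_eps * (sr6 * sr6 - sr6);
            double dulj = 4.0 * site_eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
            double rmin = 1.122462048309373 * site_sigma;
            double u_core, du_core;
            if (r <= rmin) { u_core = ulj + (1.0 - lam) * site_eps; du_core = dulj; }
            else { u_core = lam * ulj; du_core = lam * dulj; }
            double dsw;
            double sw = switch_fn(r, switch_frac * rc_s, rc_s, dsw);
            e += u_core * sw;
            double du = du_core * sw + u_core * dsw;
            double fmag = -du / r;
            fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
            cfx -= fmag * dx; cfy -= fmag * dy; cfz -= fmag * dz;
          }
        }
      }
      // cargo confinement + restraint
      if (restraint_on) {
        double dz0 = cz - restr_z0;
        e += 0.5 * restr_k * dz0 * dz0;
        cfz -= restr_k * dz0;
        e += 0.5 * restr_k_lat * (cx * cx + cy * cy);
        cfx -= restr_k_lat * cx;
        cfy -= restr_k_lat * cy;
      }
      double ezz = std::fabs(cz) - (box_z - 1.0 - cargo_radius);
      if (ezz > 0) { e += 0.5 * box_k * ezz * ezz; cfz -= box_k * ezz * (cz > 0 ? 1 : -1); }
    }
    potential = e;
    return e;
  }

  double scale_attr_saved = 1.0, scale_q_saved = 1.0;
  double forces(double scale_attr, double scale_q) {
    scale_attr_saved = scale_attr;
    scale_q_saved = scale_q;
    return compute_forces(scale_attr, scale_q);
  }
};

// [[Rcpp::export]]
List cg_energy_forces(List state, double scale_attr = 1.0, double scale_q = 1.0) {
  CGSystem sys;
  sys.init_from_list(state);
  double e = sys.forces(scale_attr, scale_q);
  int n = sys.n_total;
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = sys.fx[i]; F(i, 1) = sys.fy[i]; F(i, 2) = sys.fz[i];
  }
  return List::create(_["energy"] = e, _["forces"] = F,
                      _["cargo_force"] = NumericVector::create(sys.cfx, sys.cfy, sys.cfz));
}

// [[Rcpp::export]]
List cg_minimize(List state, int max_iter = 500, double force_tol = 10.0,
                 double step0 = 1e-4, double max_disp = 0.05) {
  CGSystem sys;
  sys.init_from_list(state);
  double alpha = step0;
  double e = sys.forces(1.0, 1.0);
  std::vector<double> x0, y0, z0;
  double c0x = 0, c0y = 0, c0z = 0;
  int it = 0;
  double fmax = 0.0;
  for (it = 0; it < max_iter; ++it) {
    fmax = 0.0;
    for (int i = 0; i < sys.n_mobile; ++i) {
      fmax = std::max(fmax, std::fabs(sys.fx[i]));
      fmax = std::max(fmax, std::fabs(sys.fy[i]));
      fmax = std::max(fmax, std::fabs(sys.fz[i]));
    }
    if (sys.has_cargo) {
      fmax = std::max(fmax, std::max(std::fabs(sys.cfx),
             std::max(std::fabs(sys.cfy), std::fabs(sys.cfz))));
    }
    if (fmax < force_tol) break;
    x0 = sys.x; y0 = sys.y; z0 = sys.z;
    c0x = sys.cx; c0y = sys.cy; c0z = sys.cz;
    double scale = alpha;
    if (fmax * alpha > max_disp) scale = max_disp / fmax;
    for (int i = 0; i < sys.n_mobile; ++i) {
      sys.x[i] += scale * sys.fx[i];
      sys.y[i] += scale * sys.fy[i];
      sys.z[i] += scale * sys.fz[i];
    }
    if (sys.has_cargo) {
      sys.cx += scale * sys.cfx; sys.cy += scale * sys.cfy; sys.cz += scale * sys.cfz;
    }
    double e_new = sys.forces(1.0, 1.0);
    if (!std::isfinite(e_new)) stop("diverging energy during minimization");
    if (e_new <= e) {
      e = e_new;
      alpha *= 1.2;
    } else {
      sys.x = x0; sys.y = y0; sys.z = z0;
      sys.cx = c0x; sys.cy = c0y; sys.cz = c0z;
      alpha *= 0.5;
      if (alpha < 1e-12) break;
      sys.forces(1.0, 1.0);
    }
  }
  NumericMatrix out(sys.n_total, 3);
  for (int i = 0; i < sys.n_total; ++i) {
    out(i, 0) = sys.x[i]; out(i, 1) = sys.y[i]; out(i, 2) = sys.z[i];
  }
  return List::create(
    _["coords"] = out, _["energy"] = e, _["iterations"] = it,
    _["max_force"] = fmax, _["converged"] = fmax < force_tol,
    _["cargo_center"] = NumericVector::create(sys.cx, sys.cy, sys.cz));
}

// [[Rcpp::export]]
List cg_run(List state, double dt, double gamma, double temperature,
            int n_steps, int equil_steps, int stride, int ramp_steps,
            bool noise = true) {
  CGSystem sys;
  sys.init_from_list(state);
  int nm = sys.n_mobile;
  std::vector<double> vx(nm, 0.0), vy(nm, 0.0), vz(nm, 0.0);
  double kT = KB * temperature;
  RNGScope scope;
  // Maxwell-Boltzmann start
  if (noise) {
    for (int i = 0; i < nm; ++i) {
      double s = std::sqrt(kT / sys.mass[i]);
      vx[i] = s * norm_rand(); vy[i] = s * norm_rand(); vz[i] = s * norm_rand();
    }
    if (sys.has_cargo) {
      double s = std::sqrt(kT / sys.cargo_mass);
      sys.cvx = s * norm_rand(); sys.cvy = s * norm_rand(); sys.cvz = s * norm_rand();
    }
  }
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(1.0 - c1 * c1);
  if (!noise) { c1 = 1.0; c2 = 0.0; }
  int n_frames = 0;
  for (int s = equil_steps + 1; s <= n_steps; ++s) if (s % stride == 0) ++n_frames;
  NumericVector frames((R_xlen_t)n_frames * nm * 3);
  NumericMatrix cargo_frames(n_frames, 3);
  NumericVector frame_time(n_frames), frame_temp(n_frames), frame_pot(n_frames);
  int n_csamp = sys.has_cargo ? (n_steps - equil_steps) : 0;
  NumericVector cargo_z_samples(std::max(n_csamp, 0));
  int fidx = 0, csidx = 0;
  double ramp = (ramp_steps > 0) ? 0.0 : 1.0;
  sys.forces(ramp, ramp);
  for (int step = 1; step <= n_steps; ++step) {
    if (ramp_steps > 0) ramp = std::min(1.0, (double)step / ramp_steps);
    // B: half kick
    for (int i = 0; i < nm; ++i) {
      double invm = dt / (2.0 * sys.mass[i]);
      vx[i] += invm * sys.fx[i]; vy[i] += invm * sys.fy[i]; vz[i] += invm * sys.fz[i];
    }
    if (sys.has_cargo) {
      double invm = dt / (2.0 * sys.cargo_mass);
      sys.cvx += invm * sys.cfx; sys.cvy += invm * sys.cfy; sys.cvz += invm * sys.cfz;
    }
    // A: half drift
    for (int i = 0; i < nm; ++i) {
      sys.x[i] += 0.5 * dt * vx[i]; sys.y[i] += 0.5 * dt * vy[i]; sys.z[i] += 0.5 * dt * vz[i];
    }
    if (sys.has_cargo) {
      sys.cx += 0.5 * dt * sys.cvx; sys.cy += 0.5 * dt * sys.cvy; sys.cz += 0.5 * dt * sys.cvz;
    }
    // O: Ornstein-Uhlenbeck
    if (noise) {
      for (int i = 0; i < nm; ++i) {
        double s2 = c2 * std::sqrt(kT / sys.mass[i]);
        vx[i] = c1 * vx[i] + s2 * norm_rand();
        vy[i] = c1 * vy[i] + s2 * norm_rand();
        vz[i] = c1 * vz[i] + s2 * norm_rand();
      }
      if (sys.has_cargo) {
        double s2 = c2 * std::sqrt(kT / sys.cargo_mass);
        sys.cvx = c1 * sys.cvx + s2 * norm_rand();
        sys.cvy = c1 * sys.cvy + s2 * norm_rand();
        sys.cvz = c1 * sys.cvz + s2 * norm_rand();
      }
    }
    // A: half drift
    for (int i = 0; i < nm; ++i) {
      sys.x[i] += 0.5 * dt * vx[i]; sys.y[i] += 0.5 * dt * vy[i]; sys.z[i] += 0.5 * dt * vz[i];
    }
    if (sys.has_cargo) {
      sys.cx += 0.5 * dt * sys.cvx; sys.cy += 0.5 * dt * sys.cvy; sys.cz += 0.5 * dt * sys.cvz;
    }
    // force refresh
    sys.forces(ramp, ramp);
    // B: half kick
    for (int i = 0; i < nm; ++i) {
      double invm = dt / (2.0 * sys.mass[i]);
      vx[i] += invm * sys.fx[i]; vy[i] += invm * sys.fy[i]; vz[i] += invm * sys.fz[i];
    }
    if (sys.has_cargo) {
      double invm = dt / (2.0 * sys.cargo_mass);
      sys.cvx += invm * sys.cfx; sys.cvy += invm * sys.cfy; sys.cvz += invm * sys.cfz;
    }
    if (step % 200 == 0) {
      for (int i = 0; i < nm; ++i) {
        if (!std::isfinite(sys.x[i]) || !std::isfinite(sys.y[i]) || !std::isfinite(sys.z[i]))
          stop("NaN coordinates at step %d (timestep instability)", step);
      }
    }
    if (step > equil_steps) {
      if (sys.has_cargo && csidx < n_csamp) cargo_z_samples[csidx++] = sys.cz;
      if (step % stride == 0) {
        for (int i = 0; i < nm; ++i) {
          frames[(R_xlen_t)fidx * nm * 3 + i] = sys.x[i];
          frames[(R_xlen_t)fidx * nm * 3 + nm + i] = sys.y[i];
          frames[(R_xlen_t)fidx * nm * 3 + 2 * nm + i] = sys.z[i];
        }
        cargo_frames(fidx, 0) = sys.cx;
        cargo_frames(fidx, 1) = sys.cy;
        cargo_frames(fidx, 2) = sys.cz;
        frame_time[fidx] = step * dt;
        double ke = 0.0;
        for (int i = 0; i < nm; ++i)
          ke += 0.5 * sys.mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        frame_temp[fidx] = 2.0 * ke / (3.0 * nm * KB);
        frame_pot[fidx] = sys.potential;
        ++fidx;
      }
    }
  }
  NumericMatrix final_coords(sys.n_total, 3);
  for (int i = 0; i < sys.n_total; ++i) {
    final_coords(i, 0) = sys.x[i];
    final_coords(i, 1) = sys.y[i];
    final_coords(i, 2) = sys.z[i];
  }
  return List::create(
    _["frames"] = frames, _["n_frames"] = n_frames, _["n_mobile"] = nm,
    _["cargo_frames"] = cargo_frames, _["cargo_z_samples"] = cargo_z_samples,
    _["time"] = frame_time, _["temperature"] = frame_temp,
    _["potential"] = frame_pot, _["final_coords"] = final_coords,
    _["final_cargo"] = NumericVector::create(sys.cx, sys.cy, sys.cz));
}
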