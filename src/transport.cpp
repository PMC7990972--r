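// Compiled core of the cellular microdosimetry simulator:
//  - nested-sphere geometry queries (region classification, ray-sphere
//    boundary distances) with a uniform-grid acceleration structure for the
//    many small nanoparticle spheres,
//  - rejection placement of nanoparticles (cytosol-random and
//    surface-attached) with analytical overlap checks,
//  - allowed-shape beta spectrum sampling,
//  - condensed-step electron transport (CSDA energy loss on tabulated range
//    tables, Highland multiple scattering) and single-interaction photon
//    attenuation,
//  - the per-decay simulation loop.
// All randomness comes from R's RNG (unif_rand/norm_rand) so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// region codes (keep in sync with R side)
static const int REG_OUTSIDE = 0;
static const int REG_MEMBRANE = 1;
static const int REG_CYTOSOL = 2;
static const int REG_NUCLEUS = 3;
static const int REG_MITO = 4;
static const int REG_NP = 5;
static const int N_REG = 6;

static const double T_EPS = 1e-9;     // nm, boundary tolerance for ray roots

// ---------------------------------------------------------------------------
// material tables: log-log stopping power and linear-in-logE CSDA range
// ---------------------------------------------------------------------------
struct MatTab {
  std::vector<double> logE;  // log(keV), increasing
  std::vector<double> logS;  // log(eV/nm)
  std::vector<double> R;     // CSDA range from table floor, nm, increasing
  double X0;                 // radiation length, nm
};

static double lin_interp(const std::vector<double>& x,
                         const std::vector<double>& y, double xv) {
  const int n = (int)x.size();
  if (xv <= x[0]) return y[0];
  if (xv >= x[n - 1]) return y[n - 1];
  int lo = (int)(std::lower_bound(x.begin(), x.end(), xv) - x.begin()) - 1;
  double w = (xv - x[lo]) / (x[lo + 1] - x[lo]);
  return y[lo] + w * (y[lo + 1] - y[lo]);
}

static double range_of_E(const MatTab& m, double E_keV) {
  return lin_interp(m.logE, m.R, std::log(E_keV));
}

static double E_of_range(const MatTab& m, double R_nm) {
  const int n = (int)m.R.size();
  if (R_nm <= m.R[0]) return std::exp(m.logE[0]);
  if (R_nm >= m.R[n - 1]) return std::exp(m.logE[n - 1]);
  int lo = (int)(std::lower_bound(m.R.begin(), m.R.end(), R_nm) - m.R.begin()) - 1;
  double w = (R_nm - m.R[lo]) / (m.R[lo + 1] - m.R[lo]);
  return std::exp(m.logE[lo] + w * (m.logE[lo + 1] - m.logE[lo]));
}

// ---------------------------------------------------------------------------
// geometry
// ---------------------------------------------------------------------------
struct Grid {
  double orig, h;
  int n;                                // n^3 voxels
  std::vector<std::vector<int> > cells; // NP ids per voxel
  bool empty;

  int idx(int ix, int iy, int iz) const { return (iz * n + iy) * n + ix; }
  int coord(double v) const {
    int i = (int)std::floor((v - orig) / h);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
};

struct Geom {
  double Rc, Ri;          // outer cell radius, inner membrane radius (nm)
  bool has_nuc;
  double nc[3], nr;       // nucleus
  std::vector<double> mx, my, mz, mr;  // mitochondria
  std::vector<double> px, py, pz, pr;  // nanoparticles
  int mat_role[N_REG];    // material index per region role
  Grid grid;

  void build_grid() {
    const int nnp = (int)px.size();
    grid.empty = (nnp == 0);
    if (grid.empty) return;
    double span = Rc + 100.0;
    grid.n = 64;
    grid.orig = -span;
    grid.h = 2.0 * span / grid.n;
    grid.cells.assign((size_t)grid.n * grid.n * grid.n, std::vector<int>());
    for (int i = 0; i < nnp; ++i) {
      int x0 = grid.coord(px[i] - pr[i]), x1 = grid.coord(px[i] + pr[i]);
      int y0 = grid.coord(py[i] - pr[i]), y1 = grid.coord(py[i] + pr[i]);
      int z0 = grid.coord(pz[i] - pr[i]), z1 = grid.coord(pz[i] + pr[i]);
      for (int iz = z0; iz <= z1; ++iz)
        for (int iy = y0; iy <= y1; ++iy)
          for (int ix = x0; ix <= x1; ++ix)
            grid.cells[grid.idx(ix, iy, iz)].push_back(i);
    }
  }
};

static Geom parse_geom(const List& g) {
  Geom G;
  G.Rc = as<double>(g["cell_radius"]);
  G.Ri = as<double>(g["inner_radius"]);
  G.has_nuc = false;
  if (g.containsElementNamed("nucleus") && !Rf_isNull(g["nucleus"])) {
    NumericVector nuc = g["nucleus"];
    if (nuc.size() == 4) {
      G.has_nuc = true;
      G.nc[0] = nuc[0]; G.nc[1] = nuc[1]; G.nc[2] = nuc[2]; G.nr = nuc[3];
    }
  }
  if (g.containsElementNamed("mito") && !Rf_isNull(g["mito"])) {
    NumericMatrix m = g["mito"];
    for (int i = 0; i < m.nrow(); ++i) {
      G.mx.push_back(m(i, 0)); G.my.push_back(m(i, 1));
      G.mz.push_back(m(i, 2)); G.mr.push_back(m(i, 3));
    }
  }
  if (g.containsElementNamed("np") && !Rf_isNull(g["np"])) {
    NumericMatrix m = g["np"];
    for (int i = 0; i < m.nrow(); ++i) {
      G.px.push_back(m(i, 0)); G.py.push_back(m(i, 1));
      G.pz.push_back(m(i, 2)); G.pr.push_back(m(i, 3));
    }
  }
  for (int i = 0; i < N_REG; ++i) G.mat_role[i] = 0;
  if (g.containsElementNamed("mat_role")) {
    IntegerVector mr = g["mat_role"];
    for (int i = 0; i < N_REG && i < mr.size(); ++i) G.mat_role[i] = mr[i];
  }
  G.build_grid();
  return G;
}

static std::vector<MatTab> parse_mats(const List& g) {
  std::vector<MatTab> out;
  List ml = g["materials"];
  for (int i = 0; i < ml.size(); ++i) {
    List m = ml[i];
    MatTab t;
    t.logE = as<std::vector<double> >(m["logE"]);
    t.logS = as<std::vector<double> >(m["logS"]);
    t.R = as<std::vector<double> >(m["range_nm"]);
    t.X0 = as<double>(m["x0_nm"]);
    out.push_back(t);
  }
  return out;
}

static inline double norm2(double x, double y, double z) {
  return x * x + y * y + z * z;
}

static bool in_np(const Geom& G, const double p[3]) {
  if (G.grid.empty) return false;
  const Grid& gr = G.grid;
  const std::vector<int>& ids =
      gr.cells[gr.idx(gr.coord(p[0]), gr.coord(p[1]), gr.coord(p[2]))];
  for (size_t k = 0; k < ids.size(); ++k) {
    int i = ids[k];
    if (norm2(p[0] - G.px[i], p[1] - G.py[i], p[2] - G.pz[i]) <=
        G.pr[i] * G.pr[i] * (1.0 + 1e-12) + 1e-18)
      return true;
  }
  return false;
}

static int region_of(const Geom& G, const double p[3]) {
  double r2 = norm2(p[0], p[1], p[2]);
  // boundary tolerance: points within 1e-9 nm of a surface belong inside
  if (r2 > (G.Rc + T_EPS) * (G.Rc + T_EPS)) return REG_OUTSIDE;
  if (in_np(G, p)) return REG_NP;
  for (size_t i = 0; i < G.mx.size(); ++i) {
    double rr = G.mr[i] + T_EPS;
    if (norm2(p[0] - G.mx[i], p[1] - G.my[i], p[2] - G.mz[i]) <= rr * rr)
      return REG_MITO;
  }
  if (G.has_nuc) {
    double rr = G.nr + T_EPS;
    if (norm2(p[0] - G.nc[0], p[1] - G.nc[1], p[2] - G.nc[2]) <= rr * rr)
      return REG_NUCLEUS;
  }
  if (r2 > (G.Ri + T_EPS) * (G.Ri + T_EPS)) return REG_MEMBRANE;
  return REG_CYTOSOL;
}

// smallest root t in (T_EPS, tmax] of |p + t d - c| = r; +Inf if none
static double ray_sphere(const double p[3], const double d[3],
                         const double c[3], double r, double tmax) {
  double ox = p[0] - c[0], oy = p[1] - c[1], oz = p[2] - c[2];
  double b = d[0] * ox + d[1] * oy + d[2] * oz;
  double cc = ox * ox + oy * oy + oz * oz - r * r;
  double disc = b * b - cc;
  if (disc <= 0.0) return R_PosInf;
  double sq = std::sqrt(disc);
  double t1 = -b - sq, t2 = -b + sq;
  if (t1 > T_EPS && t1 <= tmax) return t1;
  if (t2 > T_EPS && t2 <= tmax) return t2;
  return R_PosInf;
}

// first NP surface crossing along the ray within (0, tmax], via grid walk
static double np_first_hit(const Geom& G, const double p[3], const double d[3],
                           double tmax) {
  if (G.grid.empty) return R_PosInf;
  const Grid& gr = G.grid;
  double best = R_PosInf;
  int ix = gr.coord(p[0]), iy = gr.coord(p[1]), iz = gr.coord(p[2]);
  int sx = d[0] > 0 ? 1 : -1, sy = d[1] > 0 ? 1 : -1, sz = d[2] > 0 ? 1 : -1;
  double tx = d[0] != 0.0
      ? ((gr.orig + (ix + (sx > 0 ? 1 : 0)) * gr.h) - p[0]) / d[0] : R_PosInf;
  double ty = d[1] != 0.0
      ? ((gr.orig + (iy + (sy > 0 ? 1 : 0)) * gr.h) - p[1]) / d[1] : R_PosInf;
  double tz = d[2] != 0.0
      ? ((gr.orig + (iz + (sz > 0 ? 1 : 0)) * gr.h) - p[2]) / d[2] : R_PosInf;
  double dtx = d[0] != 0.0 ? gr.h / std::fabs(d[0]) : R_PosInf;
  double dty = d[1] != 0.0 ? gr.h / std::fabs(d[1]) : R_PosInf;
  double dtz = d[2] != 0.0 ? gr.h / std::fabs(d[2]) : R_PosInf;
  double tcur = 0.0;
  for (int guard = 0; guard < 4 * gr.n; ++guard) {
    const std::vector<int>& ids = gr.cells[gr.idx(ix, iy, iz)];
    for (size_t k = 0; k < ids.size(); ++k) {
      int i = ids[k];
      double c[3] = {G.px[i], G.py[i], G.pz[i]};
      double t = ray_sphere(p, d, c, G.pr[i], tmax);
      if (t < best) best = t;
    }
    double tnext = std::min(tx, std::min(ty, tz));
    if (tnext > std::min(tmax, best)) break;
    if (tx <= ty && tx <= tz) { ix += sx; tx += dtx; }
    else if (ty <= tz)        { iy += sy; ty += dty; }
    else                      { iz += sz; tz += dtz; }
    if (ix < 0 || ix >= gr.n || iy < 0 || iy >= gr.n || iz < 0 || iz >= gr.n)
      break;
    tcur = tnext;
    (void)tcur;
  }
  return best;
}

// distance along the ray to the next region boundary (any sphere surface),
// capped at tmax
static double dist_to_boundary(const Geom& G, const double p[3],
                               const double d[3], double tmax) {
  static const double O[3] = {0.0, 0.0, 0.0};
  double t = ray_sphere(p, d, O, G.Rc, tmax);
  t = std::min(t, ray_sphere(p, d, O, G.Ri, tmax));
  if (G.has_nuc) t = std::min(t, ray_sphere(p, d, G.nc, G.nr, tmax));
  for (size_t i = 0; i < G.mx.size(); ++i) {
    double c[3] = {G.mx[i], G.my[i], G.mz[i]};
    t = std::min(t, ray_sphere(p, d, c, G.mr[i], tmax));
  }
  t = std::min(t, np_first_hit(G, p, d, std::min(t, tmax)));
  return t;
}

// ---------------------------------------------------------------------------
// transport configuration
// ---------------------------------------------------------------------------
struct Cfg {
  double step_fraction, cutoff_keV, max_step, eps_push;
  bool ms;
  int photon_mode;  // 0 escape, 1 single interaction
  std::vector<double> ph_logE, ph_logmu, ph_muen_frac;  // water attenuation
  bool mono_beta;
};

static Cfg parse_cfg(const List& c) {
  Cfg f;
  f.step_fraction = as<double>(c["step_fraction"]);
  f.cutoff_keV = as<double>(c["energy_cutoff"]);
  f.max_step = as<double>(c["max_step"]);
  f.ms = as<bool>(c["multiple_scattering"]);
  f.photon_mode = as<int>(c["photon_mode_int"]);
  f.eps_push = 1e-3;  // nm
  f.ph_logE = as<std::vector<double> >(c["photon_log_e"]);
  f.ph_logmu = as<std::vector<double> >(c["photon_log_mu"]);
  f.ph_muen_frac = as<std::vector<double> >(c["photon_muen_frac"]);
  f.mono_beta = c.containsElementNamed("monoenergetic_beta")
      ? as<bool>(c["monoenergetic_beta"]) : false;
  return f;
}

static void deflect(double d[3], double theta, double phi) {
  // rotate d by polar angle theta about itself with azimuth phi
  double ax = d[0], ay = d[1], az = d[2];
  double ux, uy, uz;
  if (std::fabs(az) < 0.9) { ux = -ay; uy = ax; uz = 0.0; }  // a x (0,0,1)
  else { ux = 0.0; uy = az; uz = -ay; }                      // a x (1,0,0)
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= un; uy /= un; uz /= un;
  double vx = ay * uz - az * uy, vy = az * ux - ax * uz, vz = ax * uy - ay * ux;
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  d[0] = ct * ax + st * (cp * ux + sp * vx);
  d[1] = ct * ay + st * (cp * uy + sp * vy);
  d[2] = ct * az + st * (cp * uz + sp * vz);
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

static const double MC2 = 511.0;  // keV

static double highland_theta0(double E_keV, double x_nm, double X0_nm) {
  double W = E_keV + MC2;
  double p = std::sqrt(W * W - MC2 * MC2);  // keV/c
  double beta = p / W;
  double xr = x_nm / X0_nm;
  if (xr <= 0.0) return 0.0;
  double corr = 1.0 + 0.038 * std::log(xr);
  if (corr < 0.0) corr = 0.0;  // extremely short steps: no deflection
  return 13.6e3 / (beta * p) * std::sqrt(xr) * corr;  // 13.6 MeV -> keV
}

// electron condensed-step loop; deposits in keV accumulated into dep[]
static void run_electron(const Geom& G, const std::vector<MatTab>& mats,
                         double pos[3], double dir[3], double E,
                         const Cfg& cfg, double dep[N_REG], double& escaped) {
  for (long guard = 0; guard < 2000000L; ++guard) {
    int reg = region_of(G, pos);
    if (reg == REG_OUTSIDE) { escaped += E; return; }
    if (E <= cfg.cutoff_keV) { dep[reg] += E; return; }
    const MatTab& mt = mats[G.mat_role[reg]];
    double Rrem = range_of_E(mt, E);
    double tb = dist_to_boundary(G, pos, dir, R_PosInf);
    double s = std::min(cfg.step_fraction * Rrem, cfg.max_step);
    if (s >= tb) s = tb + cfg.eps_push;
    double Rnew = Rrem - s;
    double Enew = (Rnew <= 0.0) ? 0.0 : E_of_range(mt, Rnew);
    if (Enew >= E) Enew = 0.0;  // below table floor
    dep[reg] += (E - Enew);
    pos[0] += dir[0] * s; pos[1] += dir[1] * s; pos[2] += dir[2] * s;
    if (Enew <= cfg.cutoff_keV) {
      int r2 = region_of(G, pos);
      if (r2 == REG_OUTSIDE) escaped += Enew; else dep[r2] += Enew;
      return;
    }
    if (cfg.ms) {
      double th0 = highland_theta0(E, s, mt.X0);
      double th = std::fabs(norm_rand()) * th0;
      deflect(dir, th, 2.0 * M_PI * unif_rand());
    }
    E = Enew;
  }
  // pathological loop: dump residual locally
  int reg = region_of(G, pos);
  if (reg == REG_OUTSIDE) escaped += E; else dep[reg] += E;
}

static void run_photon(const Geom& G, double pos[3], const double dir[3],
                       double E, const Cfg& cfg, double dep[N_REG],
                       double& escaped) {
  if (cfg.photon_mode == 0) { escaped += E; return; }
  if (E < 100.0 || E > 2000.0)
    stop("photon energy outside supported range [100, 2000] keV");
  double logE = std::log(E);
  double mu = std::exp(lin_interp(cfg.ph_logE, cfg.ph_logmu, logE));  // 1/nm
  double frac = lin_interp(cfg.ph_logE, cfg.ph_muen_frac, logE);
  double s = -std::log(unif_rand()) / mu;
  static const double O[3] = {0.0, 0.0, 0.0};
  double texit = ray_sphere(pos, dir, O, G.Rc, R_PosInf);
  if (R_FINITE(texit) && s < texit) {
    double q[3] = {pos[0] + s * dir[0], pos[1] + s * dir[1],
                   pos[2] + s * dir[2]};
    int reg = region_of(G, q);
    if (reg == REG_OUTSIDE) { escaped += E; return; }
    dep[reg] += E * frac;
    escaped += E * (1.0 - frac);
  } else {
    escaped += E;
  }
}

// ---------------------------------------------------------------------------
// beta spectrum: allowed shape N(E) ~ p * W * (Q - E)^2 (no Coulomb term)
// ---------------------------------------------------------------------------
static double beta_shape(double E, double Q) {
  double W = E + MC2;
  double p = std::sqrt(W * W - MC2 * MC2);
  double d = Q - E;
  return p * W * d * d;
}

static double beta_fmax(double Q) {
  double m = 0.0;
  for (int i = 1; i < 512; ++i) {
    double f = beta_shape(Q * i / 512.0, Q);
    if (f > m) m = f;
  }
  return m * 1.02;
}

static double sample_beta_one(double Q, double fmax) {
  for (int i = 0; i < 100000; ++i) {
    double E = Q * unif_rand();
    if (E <= 0.0) continue;
    if (fmax * unif_rand() < beta_shape(E, Q)) return E;
  }
  return Q * 0.5;  // unreachable in practice
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_sample_beta(int n, double Q) {
  if (Q <= 0.0) stop("beta endpoint must be positive");
  double fmax = beta_fmax(Q);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_beta_one(Q, fmax);
  return out;
}

static void iso_dir(double d[3]) {
  double z = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  d[0] = s * std::cos(phi); d[1] = s * std::sin(phi); d[2] = z;
}

// ---------------------------------------------------------------------------
// exported geometry services
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_region_at(List geom, NumericMatrix pts) {
  Geom G = parse_geom(geom);
  IntegerVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    out[i] = region_of(G, p);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_trace_path(List geom, NumericVector origin,
                             NumericVector direction, double max_length) {
  Geom G = parse_geom(geom);
  double p[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {direction[0], direction[1], direction[2]};
  double dn = std::sqrt(norm2(d[0], d[1], d[2]));
  if (std::fabs(dn - 1.0) > 1e-9) stop("direction must be a unit vector");
  std::vector<double> rows;  // region, entry xyz, length
  double remaining = max_length;
  if (region_of(G, p) == REG_OUTSIDE) {
    double out[5] = {REG_OUTSIDE, p[0], p[1], p[2], 0.0};
    NumericMatrix m(1, 5);
    for (int j = 0; j < 5; ++j) m(0, j) = out[j];
    return m;
  }
  for (int guard = 0; guard < 1000000; ++guard) {
    if (remaining <= 0.0) break;
    double tb = dist_to_boundary(G, p, d, R_PosInf);
    double len = std::min(tb, remaining);
    if (!R_FINITE(len)) break;
    double mid[3] = {p[0] + 0.5 * len * d[0], p[1] + 0.5 * len * d[1],
                     p[2] + 0.5 * len * d[2]};
    int reg = region_of(G, mid);
    rows.push_back((double)reg);
    rows.push_back(p[0]); rows.push_back(p[1]); rows.push_back(p[2]);
    rows.push_back(len);
    p[0] += len * d[0]; p[1] += len * d[1]; p[2] += len * d[2];
    remaining -= len;
    if (reg == REG_OUTSIDE) break;
    // nudge across the boundary and stop once outside the cell
    double q[3] = {p[0] + T_EPS * 10 * d[0], p[1] + T_EPS * 10 * d[1],
                   p[2] + T_EPS * 10 * d[2]};
    if (region_of(G, q) == REG_OUTSIDE) break;
  }
  int nr = (int)rows.size() / 5;
  NumericMatrix m(nr, 5);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 5; ++j) m(i, j) = rows[5 * i + j];
  return m;
}

// ---------------------------------------------------------------------------
// nanoparticle placement
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_place_nanoparticles(List geom, int n_free, int n_targeted,
                                      double r_np, int target_role,
                                      int max_attempts) {
  Geom G = parse_geom(geom);
  const int n_total = n_free + n_targeted;
  std::vector<double> cx, cy, cz;
  cx.reserve(n_total); cy.reserve(n_total); cz.reserve(n_total);

  // local grid over new + pre-existing NPs for NP-NP overlap checks
  double span = G.Rc + 100.0;
  Grid gr; gr.n = 64; gr.orig = -span; gr.h = 2.0 * span / gr.n;
  gr.cells.assign((size_t)gr.n * gr.n * gr.n, std::vector<int>());
  gr.empty = false;
  std::vector<double> ex = G.px, ey = G.py, ez = G.pz, er = G.pr;
  for (size_t i = 0; i < ex.size(); ++i)
    gr.cells[gr.idx(gr.coord(ex[i]), gr.coord(ey[i]), gr.coord(ez[i]))]
        .push_back((int)i);

  const double Ri = G.Ri;
  int placed = 0;
  for (int k = 0; k < n_total; ++k) {
    bool targeted = (k < n_targeted);
    bool ok = false;
    double c[3];
    for (int att = 0; att < max_attempts; ++att) {
      if (targeted) {
        double tc[3]; double tr;
        if (target_role == REG_NUCLEUS) {
          if (!G.has_nuc) stop("geometry has no nucleus to target");
          tc[0] = G.nc[0]; tc[1] = G.nc[1]; tc[2] = G.nc[2]; tr = G.nr;
        } else {
          if (G.mx.empty()) stop("geometry has no mitochondria to target");
          int h = (int)std::floor(unif_rand() * G.mx.size());
          if (h >= (int)G.mx.size()) h = (int)G.mx.size() - 1;
          tc[0] = G.mx[h]; tc[1] = G.my[h]; tc[2] = G.mz[h]; tr = G.mr[h];
        }
        double u[3]; iso_dir(u);
        double dist = tr + r_np;  // tangent to the target surface
        c[0] = tc[0] + dist * u[0];
        c[1] = tc[1] + dist * u[1];
        c[2] = tc[2] + dist * u[2];
      } else {
        // uniform in the ball that keeps the NP inside the inner membrane
        double u[3]; iso_dir(u);
        double rad = (Ri - r_np) * std::cbrt(unif_rand());
        c[0] = rad * u[0]; c[1] = rad * u[1]; c[2] = rad * u[2];
      }
      // containment inside inner membrane surface
      double rc = std::sqrt(norm2(c[0], c[1], c[2]));
      if (rc + r_np > Ri + 1e-9) continue;
      // overlap with nucleus (tangency allowed)
      if (G.has_nuc) {
        double d2 = norm2(c[0] - G.nc[0], c[1] - G.nc[1], c[2] - G.nc[2]);
        double lim = G.nr + r_np;
        if (d2 < lim * lim * (1.0 - 1e-12) - 1e-12) continue;
      }
      // overlap with mitochondria
      bool bad = false;
      for (size_t i = 0; i < G.mx.size(); ++i) {
        double d2 = norm2(c[0] - G.mx[i], c[1] - G.my[i], c[2] - G.mz[i]);
        double lim = G.mr[i] + r_np;
        if (d2 < lim * lim * (1.0 - 1e-12) - 1e-12) { bad = true; break; }
      }
      if (bad) continue;
      // overlap with already-placed NPs (grid neighbourhood)
      int ix = gr.coord(c[0]), iy = gr.coord(c[1]), iz = gr.coord(c[2]);
      for (int dz = -1; dz <= 1 && !bad; ++dz)
        for (int dy = -1; dy <= 1 && !bad; ++dy)
          for (int dx = -1; dx <= 1 && !bad; ++dx) {
            int jx = ix + dx, jy = iy + dy, jz = iz + dz;
            if (jx < 0 || jx >= gr.n || jy < 0 || jy >= gr.n ||
                jz < 0 || jz >= gr.n) continue;
            const std::vector<int>& ids = gr.cells[gr.idx(jx, jy, jz)];
            for (size_t q = 0; q < ids.size(); ++q) {
              int i = ids[q];
              double d2 = norm2(c[0] - ex[i], c[1] - ey[i], c[2] - ez[i]);
              double lim = er[i] + r_np;
              if (d2 < lim * lim * (1.0 - 1e-12) - 1e-12) { bad = true; break; }
            }
          }
      if (bad) continue;
      ok = true;
      break;
    }
    if (!ok)
      stop("nanoparticle placement failed after %d attempts (%d of %d placed); "
           "the %s region is too crowded",
           max_attempts, placed, n_total,
           targeted ? "target surface" : "cytosol");
    cx.push_back(c[0]); cy.push_back(c[1]); cz.push_back(c[2]);
    int id = (int)ex.size();
    ex.push_back(c[0]); ey.push_back(c[1]); ez.push_back(c[2]);
    er.push_back(r_np);
    gr.cells[gr.idx(gr.coord(c[0]), gr.coord(c[1]), gr.coord(c[2]))]
        .push_back(id);
    ++placed;
  }
  NumericMatrix out((int)cx.size(), 3);
  for (int i = 0; i < (int)cx.size(); ++i) {
    out(i, 0) = cx[i]; out(i, 1) = cy[i]; out(i, 2) = cz[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_cytosol(List geom, int n, int max_attempts) {
  Geom G = parse_geom(geom);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    bool ok = false;
    for (int att = 0; att < max_attempts; ++att) {
      double u[3]; iso_dir(u);
      double rad = G.Ri * std::cbrt(unif_rand());
      double p[3] = {rad * u[0], rad * u[1], rad * u[2]};
      if (region_of(G, p) == REG_CYTOSOL) {
        out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
        ok = true;
        break;
      }
    }
    if (!ok)
      stop("cytosol rejection sampling failed after %d attempts", max_attempts);
  }
  return out;
}

// pairwise strict-overlap detection among n spheres (tangency allowed within
// tol). Large spheres are checked brute-force against everything; small
// spheres against each other through a uniform grid. Returns 0-based index
// pairs (i < j).
// [[Rcpp::export]]
IntegerMatrix cpp_overlap_pairs(NumericMatrix centers, NumericVector radii,
                                double tol) {
  const int n = centers.nrow();
  std::vector<std::pair<int, int> > hits;
  double maxc = 1.0;
  for (int i = 0; i < n; ++i)
    maxc = std::max(maxc, std::fabs(centers(i, 0)) + radii[i]);
  Grid gr; gr.n = 64; gr.orig = -(maxc + 1.0);
  gr.h = 2.0 * (maxc + 1.0) / gr.n;
  gr.cells.assign((size_t)gr.n * gr.n * gr.n, std::vector<int>());
  std::vector<int> big, small;
  for (int i = 0; i < n; ++i) {
    if (radii[i] > 0.5 * gr.h) big.push_back(i);
    else {
      small.push_back(i);
      gr.cells[gr.idx(gr.coord(centers(i, 0)), gr.coord(centers(i, 1)),
                      gr.coord(centers(i, 2)))].push_back(i);
    }
  }
  for (size_t a = 0; a < big.size(); ++a) {
    int i = big[a];
    for (int j = 0; j < n; ++j) {
      if (j <= i && radii[j] > 0.5 * gr.h) continue;  // big-big once
      if (j == i) continue;
      if (radii[j] <= 0.5 * gr.h && j < i) { /* still check, dedupe below */ }
      double d2 = norm2(centers(i, 0) - centers(j, 0),
                        centers(i, 1) - centers(j, 1),
                        centers(i, 2) - centers(j, 2));
      double lim = radii[i] + radii[j] - tol;
      if (lim > 0 && d2 < lim * lim) {
        hits.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
      }
    }
  }
  for (size_t a = 0; a < small.size(); ++a) {
    int i = small[a];
    int ix = gr.coord(centers(i, 0)), iy = gr.coord(centers(i, 1)),
        iz = gr.coord(centers(i, 2));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jx >= gr.n || jy < 0 || jy >= gr.n ||
              jz < 0 || jz >= gr.n) continue;
          const std::vector<int>& ids = gr.cells[gr.idx(jx, jy, jz)];
          for (size_t q = 0; q < ids.size(); ++q) {
            int j = ids[q];
            if (j <= i) continue;
            double d2 = norm2(centers(i, 0) - centers(j, 0),
                              centers(i, 1) - centers(j, 1),
                              centers(i, 2) - centers(j, 2));
            double lim = radii[i] + radii[j] - tol;
            if (lim > 0 && d2 < lim * lim) {
              hits.push_back(std::make_pair(i, j));
            }
          }
        }
  }
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t k = 0; k < hits.size(); ++k) {
    out((int)k, 0) = hits[k].first;
    out((int)k, 1) = hits[k].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// exported transport
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_transport_electron(List geom, NumericVector pos, NumericVector dir,
                            double E_keV, List cfg) {
  if (E_keV <= 0.0) stop("electron energy must be positive");
  double dn = std::sqrt(norm2(dir[0], dir[1], dir[2]));
  if (std::fabs(dn - 1.0) > 1e-9) stop("direction must be a unit vector");
  Geom G = parse_geom(geom);
  std::vector<MatTab> mats = parse_mats(geom);
  Cfg C = parse_cfg(cfg);
  double p[3] = {pos[0], pos[1], pos[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double dep[N_REG] = {0, 0, 0, 0, 0, 0};
  double escaped = 0.0;
  run_electron(G, mats, p, d, E_keV, C, dep, escaped);
  NumericVector dv(N_REG);
  for (int i = 0; i < N_REG; ++i) dv[i] = dep[i] * 1000.0;  // keV -> eV
  return List::create(_["deposit_ev"] = dv, _["escaped_ev"] = escaped * 1000.0);
}

// [[Rcpp::export]]
List cpp_transport_photon(List geom, NumericVector pos, NumericVector dir,
                          double E_keV, List cfg) {
  if (E_keV <= 0.0) stop("photon energy must be positive");
  Geom G = parse_geom(geom);
  Cfg C = parse_cfg(cfg);
  double p[3] = {pos[0], pos[1], pos[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double dep[N_REG] = {0, 0, 0, 0, 0, 0};
  double escaped = 0.0;
  run_photon(G, p, d, E_keV, C, dep, escaped);
  NumericVector dv(N_REG);
  for (int i = 0; i < N_REG; ++i) dv[i] = dep[i] * 1000.0;  // keV -> eV
  return List::create(_["deposit_ev"] = dv, _["escaped_ev"] = escaped * 1000.0);
}

// [[Rcpp::export]]
List cpp_simulate_decays(List geom, List nuclide, List cfg, int n_decays,
                         int mode) {
  // mode: 0 = discrete (decays inside nanoparticles), 1 = continuous (cytosol)
  Geom G = parse_geom(geom);
  std::vector<MatTab> mats = parse_mats(geom);
  Cfg C = parse_cfg(cfg);
  NumericVector betaE = nuclide["beta_energies"];
  NumericVector betaP = nuclide["beta_intensities"];
  NumericVector gamE = nuclide["gamma_energies"];
  NumericVector gamP = nuclide["gamma_intensities"];
  const int nnp = (int)G.px.size();
  if (mode == 0 && nnp == 0)
    stop("discrete source mode requires at least one nanoparticle");
  std::vector<double> fmax(betaE.size());
  for (int i = 0; i < betaE.size(); ++i) fmax[i] = beta_fmax(betaE[i]);
  // volume-weighted NP choice (uniform when all radii equal)
  std::vector<double> cumv(nnp);
  double vtot = 0.0;
  for (int i = 0; i < nnp; ++i) {
    vtot += G.pr[i] * G.pr[i] * G.pr[i];
    cumv[i] = vtot;
  }
  double dep[N_REG] = {0, 0, 0, 0, 0, 0};
  double escaped = 0.0, emitted = 0.0;

  for (int k = 0; k < n_decays; ++k) {
    double p0[3];
    if (mode == 0) {
      double u = unif_rand() * vtot;
      int i = (int)(std::lower_bound(cumv.begin(), cumv.end(), u) -
                    cumv.begin());
      if (i >= nnp) i = nnp - 1;
      double v[3]; iso_dir(v);
      double rad = G.pr[i] * std::cbrt(unif_rand());
      p0[0] = G.px[i] + rad * v[0];
      p0[1] = G.py[i] + rad * v[1];
      p0[2] = G.pz[i] + rad * v[2];
    } else {
      bool ok = false;
      for (int att = 0; att < 1000000; ++att) {
        double v[3]; iso_dir(v);
        double rad = G.Ri * std::cbrt(unif_rand());
        p0[0] = rad * v[0]; p0[1] = rad * v[1]; p0[2] = rad * v[2];
        if (region_of(G, p0) == REG_CYTOSOL) { ok = true; break; }
      }
      if (!ok) stop("cytosol decay-position sampling failed");
    }
    // exactly one beta per decay
    double u = unif_rand(), acc = 0.0;
    int br = 0;
    for (int i = 0; i < betaP.size(); ++i) {
      acc += betaP[i];
      if (u <= acc) { br = i; break; }
      br = i;
    }
    double Eb = C.mono_beta ? (double)betaE[br]
                            : sample_beta_one(betaE[br], fmax[br]);
    emitted += Eb;
    double d[3]; iso_dir(d);
    double pos[3] = {p0[0], p0[1], p0[2]};
    run_electron(G, mats, pos, d, Eb, C, dep, escaped);
    // gamma lines, each included independently with its intensity
    for (int i = 0; i < gamE.size(); ++i) {
      if (unif_rand() < gamP[i]) {
        emitted += gamE[i];
        double dg[3]; iso_dir(dg);
        double pg[3] = {p0[0], p0[1], p0[2]};
        run_photon(G, pg, dg, gamE[i], C, dep, escaped);
      }
    }
  }
  NumericVector dv(N_REG);
  for (int i = 0; i < N_REG; ++i) dv[i] = dep[i] * 1000.0;
  return List::create(_["deposit_ev"] = dv,
                      _["escaped_ev"] = escaped * 1000.0,
                      _["emitted_ev"] = emitted * 1000.0,
                      _["n_decays"] = n_decays);
}
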