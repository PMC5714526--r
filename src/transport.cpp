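// Photon transport kernel: analogue transport of primary and scattered
// photons from an encapsulated cylindrical seed through a spherical phantom,
// with collision-kerma scoring on a spherical-shell x polar-cone grid, an
// optional cylindrical (R,Z) scoring mesh, and a track-length air-kerma
// estimator for the vacuum/air-ring geometry.
//
// Uses R's RNG (single-threaded) so runs are bit-reproducible under
// set.seed(). Energies in keV, lengths in cm.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double MEC2 = 510.99895;
static const double INF = std::numeric_limits<double>::infinity();
static const double EPS_STEP = 1e-6;

// ---- tabulated material -------------------------------------------------

struct MatTab {
  std::vector<double> logE, logmu;     // linear attenuation, log-log
  std::vector<double> fpe, fpic;       // cumulative type fractions at nodes
  std::vector<double> ftr;             // expected transfer fraction mu_en/mu
  std::vector<double> ray_x, ray_cdf;  // coherent angular sampling table
  double fluor_p, fluor_E, fluor_edge; // K-fluorescence (optional)

  double mu(double E) const { return std::exp(interp(logmu, std::log(E))); }
  double interp(const std::vector<double>& y, double lE) const {
    size_t n = logE.size();
    if (lE <= logE[0]) return y[0];
    if (lE >= logE[n - 1]) return y[n - 1];
    size_t hi = std::upper_bound(logE.begin(), logE.end(), lE) - logE.begin();
    double w = (lE - logE[hi - 1]) / (logE[hi] - logE[hi - 1]);
    return y[hi - 1] * (1 - w) + y[hi] * w;
  }
  double lin(const std::vector<double>& y, double E) const {
    return interp(y, std::log(E));
  }
};

static MatTab make_mat(List m) {
  MatTab t;
  t.logE = as<std::vector<double>>(m["logE"]);
  t.logmu = as<std::vector<double>>(m["log_mu"]);
  t.fpe = as<std::vector<double>>(m["fpe"]);
  t.fpic = as<std::vector<double>>(m["fpic"]);
  t.ftr = as<std::vector<double>>(m["ftr"]);
  t.ray_x = as<std::vector<double>>(m["ray_x"]);
  t.ray_cdf = as<std::vector<double>>(m["ray_cdf"]);
  t.fluor_p = as<double>(m["fluor_p"]);
  t.fluor_E = as<double>(m["fluor_E"]);
  t.fluor_edge = as<double>(m["fluor_edge"]);
  return t;
}

// ---- samplers -----------------------------------------------------------

// Kahn's composition-rejection sampling of the Klein-Nishina distribution.
// Returns x = E/E'; *trials accumulates rejection-loop iterations.
static double kahn_compton(double alpha, long* trials) {
  double x;
  for (;;) {
    if (trials) ++(*trials);
    double r1 = unif_rand(), r2 = unif_rand(), r3 = unif_rand();
    if (r1 <= (1.0 + 2.0 * alpha) / (9.0 + 2.0 * alpha)) {
      x = 1.0 + 2.0 * alpha * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) break;
    } else {
      x = (1.0 + 2.0 * alpha) / (1.0 + 2.0 * alpha * r2);
      double mu = 1.0 - (x - 1.0) / alpha;
      if (r3 <= 0.5 * (mu * mu + 1.0 / x)) break;
    }
  }
  return x;
}

// sample cos(theta) for coherent scattering from the tabulated cumulative
// integral of the squared molecular form factor over x = s^2
static double sample_rayleigh_mu(const MatTab& t, double E) {
  double lam = 12.39841984 / E;           // Angstrom
  double xkin = 1.0 / (lam * lam);        // s^2 at backscatter
  size_t n = t.ray_x.size();
  double cmax;
  if (xkin >= t.ray_x[n - 1]) {
    cmax = t.ray_cdf[n - 1];
  } else {
    size_t hi = std::upper_bound(t.ray_x.begin(), t.ray_x.end(), xkin) -
                t.ray_x.begin();
    double w = (xkin - t.ray_x[hi - 1]) / (t.ray_x[hi] - t.ray_x[hi - 1]);
    cmax = t.ray_cdf[hi - 1] * (1 - w) + t.ray_cdf[hi] * w;
  }
  for (int it = 0; it < 10000; ++it) {
    double u = unif_rand() * cmax;
    size_t hi = std::upper_bound(t.ray_cdf.begin(), t.ray_cdf.end(), u) -
                t.ray_cdf.begin();
    double x;
    if (hi == 0) {
      x = t.ray_x[0];
    } else if (hi >= n) {
      x = t.ray_x[n - 1];
    } else {
      double w = (u - t.ray_cdf[hi - 1]) / (t.ray_cdf[hi] - t.ray_cdf[hi - 1]);
      x = t.ray_x[hi - 1] * (1 - w) + t.ray_x[hi] * w;
    }
    double mu = 1.0 - 2.0 * x / xkin;
    if (mu < -1.0) continue;
    if (unif_rand() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
  return 1.0;  // forward fallback (never reached in practice)
}

static void rotate_direction(double* d, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  double norm = std::sqrt(ux * ux + uy * uy);
  double nx, ny, nz;
  if (norm > 1e-12) {
    nx = ux * ct + st * (ux * uz * cp - uy * sp) / norm;
    ny = uy * ct + st * (uy * uz * cp + ux * sp) / norm;
    nz = uz * ct - st * norm * cp;
  } else {
    nx = st * cp;
    ny = st * sp;
    nz = (uz > 0 ? ct : -ct);
  }
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  d[0] = nx / nn; d[1] = ny / nn; d[2] = nz / nn;
}

// ---- geometry -----------------------------------------------------------

struct Cyl { double r, zmin, zmax; int mat; };

struct Geom {
  std::vector<Cyl> regions;            // priority order
  double br, bzmin, bzmax;             // seed bounding cylinder
  double world_R;
  int phantom_mat;                     // -1 = vacuum
};

static int locate(const Geom& g, const double* p) {
  double rho2 = p[0] * p[0] + p[1] * p[1];
  for (size_t i = 0; i < g.regions.size(); ++i) {
    const Cyl& c = g.regions[i];
    if (rho2 <= c.r * c.r && p[2] >= c.zmin && p[2] <= c.zmax) return (int)i;
  }
  return -1;  // phantom medium
}

static bool in_bound_cyl(const Geom& g, const double* p) {
  return p[0] * p[0] + p[1] * p[1] <= g.br * g.br && p[2] >= g.bzmin &&
         p[2] <= g.bzmax;
}

// positive roots of the lateral surface of an infinite cylinder of radius R
static void cyl_lateral_roots(const double* p, const double* d, double R,
                              double* t1, double* t2) {
  *t1 = *t2 = INF;
  double a = d[0] * d[0] + d[1] * d[1];
  if (a < 1e-16) return;
  double b = p[0] * d[0] + p[1] * d[1];
  double c = p[0] * p[0] + p[1] * p[1] - R * R;
  double disc = b * b - a * c;
  if (disc < 0) return;
  double sq = std::sqrt(disc);
  double r1 = (-b - sq) / a, r2 = (-b + sq) / a;
  if (r1 > EPS_STEP) *t1 = r1;
  if (r2 > EPS_STEP) *t2 = r2;
}

// distance to nearest surface of any seed region or the bounding cylinder
static double dist_to_seed_surface(const Geom& g, const double* p,
                                   const double* d) {
  double tmin = INF, t1, t2;
  for (size_t i = 0; i < g.regions.size(); ++i) {
    const Cyl& c = g.regions[i];
    cyl_lateral_roots(p, d, c.r, &t1, &t2);
    tmin = std::min(tmin, std::min(t1, t2));
    if (std::fabs(d[2]) > 1e-16) {
      double ta = (c.zmin - p[2]) / d[2];
      double tb = (c.zmax - p[2]) / d[2];
      if (ta > EPS_STEP) tmin = std::min(tmin, ta);
      if (tb > EPS_STEP) tmin = std::min(tmin, tb);
    }
  }
  cyl_lateral_roots(p, d, g.br, &t1, &t2);
  tmin = std::min(tmin, std::min(t1, t2));
  if (std::fabs(d[2]) > 1e-16) {
    double ta = (g.bzmin - p[2]) / d[2];
    double tb = (g.bzmax - p[2]) / d[2];
    if (ta > EPS_STEP) tmin = std::min(tmin, ta);
    if (tb > EPS_STEP) tmin = std::min(tmin, tb);
  }
  return tmin;
}

// entry distance into the (finite) seed bounding cylinder from outside
static double dist_to_bound_entry(const Geom& g, const double* p,
                                  const double* d) {
  double tmin = INF, t1, t2;
  cyl_lateral_roots(p, d, g.br, &t1, &t2);
  for (double t : {t1, t2}) {
    if (t < INF) {
      double z = p[2] + t * d[2];
      if (z >= g.bzmin && z <= g.bzmax) tmin = std::min(tmin, t);
    }
  }
  if (std::fabs(d[2]) > 1e-16) {
    for (double zp : {g.bzmin, g.bzmax}) {
      double t = (zp - p[2]) / d[2];
      if (t > EPS_STEP) {
        double x = p[0] + t * d[0], y = p[1] + t * d[1];
        if (x * x + y * y <= g.br * g.br) tmin = std::min(tmin, t);
      }
    }
  }
  return tmin;
}

// exit distance from inside a sphere of radius R centred at origin
static double dist_to_sphere_exit(const double* p, const double* d,
                                  double R) {
  double b = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
  double c = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] - R * R;
  double disc = b * b - c;
  if (disc < 0) return INF;
  return -b + std::sqrt(disc);
}

// ---- scoring grids ------------------------------------------------------

struct PolarGrid {
  std::vector<double> rlo, rhi, tlo, thi;  // theta in degrees
  int nbin() const { return (int)(rlo.size() * tlo.size()); }
  int index(const double* p) const {
    double r = std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
    if (r <= 0) return -1;
    size_t ri = std::upper_bound(rlo.begin(), rlo.end(), r) - rlo.begin();
    if (ri == 0 || r > rhi[ri - 1]) return -1;
    double th = std::acos(std::min(1.0, std::max(-1.0, p[2] / r))) *
                180.0 / M_PI;
    size_t ti = std::upper_bound(tlo.begin(), tlo.end(), th) - tlo.begin();
    if (ti == 0 || th > thi[ti - 1]) return -1;
    return (int)((ri - 1) * tlo.size() + (ti - 1));
  }
};

struct CylGrid {
  std::vector<double> redges, zedges;
  bool active = false;
  int nbin() const {
    return active ? (int)((redges.size() - 1) * (zedges.size() - 1)) : 0;
  }
  int index(const double* p) const {
    double rho = std::sqrt(p[0] * p[0] + p[1] * p[1]);
    size_t ri = std::upper_bound(redges.begin(), redges.end(), rho) -
                redges.begin();
    if (ri == 0 || ri >= redges.size()) return -1;
    size_t zi = std::upper_bound(zedges.begin(), zedges.end(), p[2]) -
                zedges.begin();
    if (zi == 0 || zi >= zedges.size()) return -1;
    return (int)((ri - 1) * (zedges.size() - 1) + (zi - 1));
  }
};

// ---- main kernel --------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_transport(List src, List mats_in, List geom_in, List grid_in,
                       List cfg) {
  RNGScope rng;

  // source
  double core_r = as<double>(src["core_r"]);
  double core_zmin = as<double>(src["core_zmin"]);
  double core_zmax = as<double>(src["core_zmax"]);
  std::vector<double> evec = as<std::vector<double>>(src["energies"]);
  std::vector<double> ecdf = as<std::vector<double>>(src["cdf"]);

  // materials
  std::vector<MatTab> mats;
  for (int i = 0; i < mats_in.size(); ++i) mats.push_back(make_mat(mats_in[i]));

  // geometry
  Geom g;
  {
    NumericVector cr = geom_in["cyl_r"], czmin = geom_in["cyl_zmin"],
                  czmax = geom_in["cyl_zmax"];
    IntegerVector cmat = geom_in["cyl_mat"];
    for (int i = 0; i < cr.size(); ++i) {
      g.regions.push_back({cr[i], czmin[i], czmax[i], cmat[i]});
    }
    g.br = as<double>(geom_in["bound_r"]);
    g.bzmin = as<double>(geom_in["bound_zmin"]);
    g.bzmax = as<double>(geom_in["bound_zmax"]);
    g.world_R = as<double>(geom_in["world_R"]);
    g.phantom_mat = as<int>(geom_in["phantom_mat"]);
  }

  // polar scoring grid
  PolarGrid pg;
  pg.rlo = as<std::vector<double>>(grid_in["r_lo"]);
  pg.rhi = as<std::vector<double>>(grid_in["r_hi"]);
  pg.tlo = as<std::vector<double>>(grid_in["theta_lo"]);
  pg.thi = as<std::vector<double>>(grid_in["theta_hi"]);

  CylGrid cg;
  if (grid_in.containsElementNamed("cyl_redges") &&
      !Rf_isNull(grid_in["cyl_redges"])) {
    cg.redges = as<std::vector<double>>(grid_in["cyl_redges"]);
    cg.zedges = as<std::vector<double>>(grid_in["cyl_zedges"]);
    cg.active = true;
  }

  // air-kerma ring
  int mode = as<int>(cfg["mode"]);  // 0 water, 1 airkerma
  double ring_rin = 0, ring_rout = 0, ring_ct_lo = 0, ring_ct_hi = 0,
         d_ref = 100, delta_cut = 0;
  std::vector<double> air_logE, air_logmuen;
  if (mode == 1) {
    ring_rin = as<double>(geom_in["ring_rin"]);
    ring_rout = as<double>(geom_in["ring_rout"]);
    double c1 = as<double>(geom_in["cone_lo_deg"]) * M_PI / 180.0;
    double c2 = as<double>(geom_in["cone_hi_deg"]) * M_PI / 180.0;
    ring_ct_lo = std::cos(c2);  // smaller cosine
    ring_ct_hi = std::cos(c1);
    d_ref = as<double>(geom_in["d_ref"]);
    delta_cut = as<double>(geom_in["delta_keV"]);
    air_logE = as<std::vector<double>>(geom_in["air_logE"]);
    air_logmuen = as<std::vector<double>>(geom_in["air_log_muen_rho"]);
  }
  // mass energy-absorption of the scoring medium for track-length scoring
  std::vector<double> sc_logE, sc_logmuen;
  if (cfg.containsElementNamed("score_logE") &&
      !Rf_isNull(cfg["score_logE"])) {
    sc_logE = as<std::vector<double>>(cfg["score_logE"]);
    sc_logmuen = as<std::vector<double>>(cfg["score_log_muen_rho"]);
  }
  auto tab1d = [](const std::vector<double>& lx, const std::vector<double>& ly,
                  double E) {
    double lE = std::log(E);
    size_t n = lx.size();
    if (lE <= lx[0]) return std::exp(ly[0]);
    if (lE >= lx[n - 1]) return std::exp(ly[n - 1]);
    size_t hi = std::upper_bound(lx.begin(), lx.end(), lE) - lx.begin();
    double w = (lE - lx[hi - 1]) / (lx[hi] - lx[hi - 1]);
    return std::exp(ly[hi - 1] * (1 - w) + ly[hi] * w);
  };

  long n_hist = as<double>(cfg["n_histories"]);
  int n_batch = as<int>(cfg["n_batch"]);
  double cutoff = as<double>(cfg["cutoff_keV"]);
  int interactions = as<int>(cfg["interactions"]);  // 0 full, 1 primary, 2 none
  int estimator = as<int>(cfg["estimator"]);        // 0 collision, 1 tracklen
  double substep = as<double>(cfg["substep"]);
  bool fluor = as<bool>(cfg["fluorescence"]);

  NumericMatrix tally(pg.nbin(), n_batch);
  NumericMatrix cyl_tally(std::max(cg.nbin(), 1), n_batch);
  NumericVector air_tally(n_batch);
  double emitted = 0, deposited = 0;
  long lost = 0, compton_trials = 0, compton_samples = 0;

  // track-length tally along a flight segment (both ring and polar modes)
  auto segment_score = [&](const double* p0, const double* dir, double tlen,
                           double E, int batch) {
    if (mode == 1) {
      if (E < delta_cut) return;
      // clip segment to radial interval [ring_rin, ring_rout]
      double b = p0[0] * dir[0] + p0[1] * dir[1] + p0[2] * dir[2];
      double r02 = p0[0] * p0[0] + p0[1] * p0[1] + p0[2] * p0[2];
      double t_in = 0, t_out = tlen;
      double disc_out = b * b - (r02 - ring_rout * ring_rout);
      if (disc_out < 0) return;
      double sq = std::sqrt(disc_out);
      t_out = std::min(t_out, -b + sq);
      t_in = std::max(t_in, -b - sq);
      double disc_in = b * b - (r02 - ring_rin * ring_rin);
      if (disc_in >= 0) {
        // segments start near the seed (vacuum elsewhere): the in-shell part
        // begins where the ray exits the inner sphere
        t_in = std::max(t_in, -b + std::sqrt(disc_in));
      }
      if (t_out <= t_in) return;
      int nsub = std::max(1, (int)std::ceil((t_out - t_in) / substep));
      double dt = (t_out - t_in) / nsub;
      double muen = tab1d(air_logE, air_logmuen, E);
      for (int i = 0; i < nsub; ++i) {
        double t = t_in + (i + 0.5) * dt;
        double q[3] = {p0[0] + t * dir[0], p0[1] + t * dir[1],
                       p0[2] + t * dir[2]};
        double r = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2]);
        if (r < ring_rin || r > ring_rout) continue;
        double ct = q[2] / r;
        if (ct < ring_ct_lo || ct > ring_ct_hi) continue;
        air_tally[batch] += dt * E * muen * (r * r) / (d_ref * d_ref);
      }
    } else if (estimator == 1 && !sc_logE.empty()) {
      double muen = tab1d(sc_logE, sc_logmuen, E);
      int nsub = std::max(1, (int)std::ceil(tlen / substep));
      double dt = tlen / nsub;
      for (int i = 0; i < nsub; ++i) {
        double t = (i + 0.5) * dt;
        double q[3] = {p0[0] + t * dir[0], p0[1] + t * dir[1],
                       p0[2] + t * dir[2]};
        int b = pg.index(q);
        if (b >= 0) tally(b, batch) += dt * E * muen;
      }
    }
  };

  for (long h = 0; h < n_hist; ++h) {
    int batch = (int)((h * (long)n_batch) / n_hist);
    // source sampling: uniform in core, isotropic, line spectrum
    double rho = core_r * std::sqrt(unif_rand());
    double phi = 2.0 * M_PI * unif_rand();
    double p[3] = {rho * std::cos(phi), rho * std::sin(phi),
                   core_zmin + (core_zmax - core_zmin) * unif_rand()};
    double muz = 2.0 * unif_rand() - 1.0;
    double psi = 2.0 * M_PI * unif_rand();
    double st = std::sqrt(std::max(0.0, 1.0 - muz * muz));
    double d[3] = {st * std::cos(psi), st * std::sin(psi), muz};
    double u = unif_rand();
    size_t li = std::lower_bound(ecdf.begin(), ecdf.end(), u) - ecdf.begin();
    if (li >= evec.size()) li = evec.size() - 1;
    double E = evec[li];
    emitted += E;
    bool scattered = false;

    long steps = 0;
    bool alive = true;
    while (alive) {
      if (++steps > 1000000L) { ++lost; break; }
      bool inzone = in_bound_cyl(g, p);
      int mat;
      double t_srf;
      if (inzone) {
        mat = locate(g, p);
        if (mat >= 0) mat = g.regions[mat].mat;
        else mat = g.phantom_mat;
        t_srf = dist_to_seed_surface(g, p, d);
      } else {
        mat = g.phantom_mat;
        double t_entry = dist_to_bound_entry(g, p, d);
        double t_world = dist_to_sphere_exit(p, d, g.world_R);
        t_srf = std::min(t_entry, t_world);
        if (t_srf == INF) t_srf = t_world;  // safety
      }
      double mu = 0;
      if (mat >= 0 && interactions != 2) mu = mats[mat].mu(E);
      double t_col = (mu > 0) ? -std::log(unif_rand()) / mu : INF;
      double t_move = std::min(t_col, t_srf);
      bool collide = t_col < t_srf;
      if (!inzone) {
        double t_world = dist_to_sphere_exit(p, d, g.world_R);
        if (t_move >= t_world) { t_move = t_world; collide = false; }
        // track-length scoring along the in-phantom flight
        segment_score(p, d, t_move, E, batch);
        if (t_move >= t_world) {
          alive = false;  // escapes the world
          break;
        }
      } else if (estimator == 1 && mode == 0 && mat == g.phantom_mat) {
        segment_score(p, d, t_move, E, batch);
      }
      p[0] += (t_move + (collide ? 0 : EPS_STEP)) * d[0];
      p[1] += (t_move + (collide ? 0 : EPS_STEP)) * d[1];
      p[2] += (t_move + (collide ? 0 : EPS_STEP)) * d[2];
      if (!collide) continue;

      // ---- real collision in material `mat` ----
      const MatTab& mt = mats[mat];
      double ftr = mt.lin(mt.ftr, E);
      // detector bins score kerma-to-water: only collisions in the phantom
      // medium contribute (seed-region collisions are not water kerma)
      bool in_phantom_medium = (mat == g.phantom_mat);
      if (estimator == 0 && mode == 0 && in_phantom_medium) {
        int b = pg.index(p);
        if (b >= 0) tally(b, batch) += E * ftr;
      }
      if (cg.active && in_phantom_medium) {
        int b = cg.index(p);
        if (b >= 0) cyl_tally(b, batch) += E * ftr;
      }
      deposited += E * ftr;

      if (interactions == 1) {
        // primary-only mode: the history ends at its first real collision
        alive = false; break;
      }

      double utype = unif_rand();
      double ppe = mt.lin(mt.fpe, E), pic = mt.lin(mt.fpic, E);
      if (utype < ppe) {
        // photoelectric
        if (fluor && mt.fluor_p > 0 && E > mt.fluor_edge &&
            unif_rand() < mt.fluor_p) {
          E = mt.fluor_E;
          double m2 = 2.0 * unif_rand() - 1.0;
          double ps = 2.0 * M_PI * unif_rand();
          double s2 = std::sqrt(std::max(0.0, 1.0 - m2 * m2));
          d[0] = s2 * std::cos(ps); d[1] = s2 * std::sin(ps); d[2] = m2;
          scattered = true;
          continue;
        }
        alive = false;
      } else if (utype < pic) {
        // Compton
        double alpha = E / MEC2;
        compton_samples++;
        double x = kahn_compton(alpha, &compton_trials);
        double Enew = E / x;
        double ct = 1.0 - (x - 1.0) / alpha;
        rotate_direction(d, ct, 2.0 * M_PI * unif_rand());
        scattered = true;
        if (Enew < cutoff) {
          // local absorption of the sub-cutoff photon
          if (estimator == 0 && mode == 0 && in_phantom_medium) {
            int b = pg.index(p);
            if (b >= 0) tally(b, batch) += Enew;
          }
          if (cg.active && in_phantom_medium) {
            int b = cg.index(p);
            if (b >= 0) cyl_tally(b, batch) += Enew;
          }
          deposited += Enew;
          alive = false;
        } else {
          E = Enew;
        }
      } else {
        // Rayleigh: elastic redirection
        double ct = sample_rayleigh_mu(mt, E);
        rotate_direction(d, ct, 2.0 * M_PI * unif_rand());
        scattered = true;
      }
    }
  }

  return List::create(
      _["tally"] = tally, _["cyl_tally"] = cg.active ? cyl_tally : NumericMatrix(0, 0),
      _["air_tally"] = air_tally, _["emitted_keV"] = emitted,
      _["deposited_keV"] = deposited, _["lost"] = (double)lost,
      _["compton_efficiency"] =
          compton_samples > 0 ? (double)compton_samples / (double)compton_trials
                              : NA_REAL,
      _["n_histories"] = (double)n_hist);
}

// ---- standalone samplers for validation ---------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy_keV, int n) {
  RNGScope rng;
  NumericMatrix out(n, 2);
  double alpha = energy_keV / MEC2;
  long trials = 0;
  for (int i = 0; i < n; ++i) {
    double x = kahn_compton(alpha, &trials);
    out(i, 0) = energy_keV / x;
    out(i, 1) = 1.0 - (x - 1.0) / alpha;
  }
  out.attr("efficiency") = (double)n / (double)trials;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_rayleigh(double energy_keV, int n, List mat) {
  RNGScope rng;
  MatTab t = make_mat(mat);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_rayleigh_mu(t, energy_keV);
  return out;
}
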