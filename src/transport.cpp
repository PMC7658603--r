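// Weighted Monte Carlo random-walk transport of optical photon packets
// through a layered slab stack with an optional embedded sphere.
// Implicit capture + Russian roulette; Henyey-Greenstein scattering;
// unpolarized Fresnel reflection/refraction at refractive-index mismatches;
// pathlength fluence estimator on a z-voxel grid; luminescence conversion
// of absorption deposits inside the sphere (single generation).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

namespace {

struct Packet {
  double x, y, z, ux, uy, uz, wl, w;
  int prov;              // 0 = excitation (Cherenkov / external), 1 = luminescence
  bool in_sphere;
  bool entered_tallied;  // first-entry spectral tally done (prov 0)
  bool exit_tallied;     // first-exit tally done
};

struct Model {
  std::vector<double> zb;        // layer boundaries, length L+1
  int L;
  double hx, hy, zmax;
  bool has_sphere;
  double cx, cy, cz, r, r2;
  int sphere_med;                // column index of sphere medium, -1 if none
  std::vector<double> wl_grid;   // shared property wavelength grid
  std::vector<double> mua, mus, gg, nn; // nw x M column-major
  int nw, M;
  double n_ambient;
  bool fluor_on;
  std::vector<double> exc_prob;  // on wl_grid: f(lambda) * QY
  std::vector<double> em_wl, em_cdf;
};

inline double runif01() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

inline double interp(const std::vector<double>& xg, const double* y,
                     int n, double x) {
  if (x <= xg[0]) return y[0];
  if (x >= xg[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; (xg[mid] <= x ? lo : hi) = mid; }
  double t = (x - xg[lo]) / (xg[lo + 1] - xg[lo]);
  return y[lo] + t * (y[lo + 1] - y[lo]);
}

inline int layer_of(const Model& m, double z) {
  int k = 0;
  while (k < m.L - 1 && z >= m.zb[k + 1]) ++k;
  return k;
}

inline bool inside_sphere(const Model& m, double x, double y, double z) {
  if (!m.has_sphere) return false;
  double dx = x - m.cx, dy = y - m.cy, dz = z - m.cz;
  return dx * dx + dy * dy + dz * dz < m.r2;
}

inline void isotropic_dir(double& ux, double& uy, double& uz) {
  double cost = 2.0 * unif_rand() - 1.0;
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * unif_rand();
  ux = sint * std::cos(phi); uy = sint * std::sin(phi); uz = cost;
}

// HG deflection applied to current direction (standard MCML rotation)
inline void hg_deflect(double g, double& ux, double& uy, double& uz) {
  double cost;
  if (std::fabs(g) < 1e-6) {
    cost = 2.0 * unif_rand() - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
    cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (cost < -1.0) cost = -1.0; else if (cost > 1.0) cost = 1.0;
  }
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * unif_rand();
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp; uy = sint * sinp; uz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    double nuz = -sint * cosp * den + uz * cost;
    double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
    ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
  }
}

inline double fresnel_R(double n1, double n2, double cosi) {
  if (std::fabs(n1 - n2) < 1e-12) return 0.0;
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - cosi * cosi);
  if (s2 >= 1.0) return 1.0; // total internal reflection
  double cost = std::sqrt(1.0 - s2);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

inline double sample_em_wl(const Model& m) {
  double u = unif_rand();
  const std::vector<double>& c = m.em_cdf;
  int n = (int)c.size();
  int lo = 0, hi = n - 1;
  if (u <= c[0]) return m.em_wl[0];
  while (hi - lo > 1) { int mid = (lo + hi) / 2; (c[mid] <= u ? lo : hi) = mid; }
  double dc = c[hi] - c[lo];
  double t = dc > 0 ? (u - c[lo]) / dc : 0.0;
  return m.em_wl[lo] + t * (m.em_wl[hi] - m.em_wl[lo]);
}

struct Tally {
  double launched[2] = {0, 0}, absorbed[2] = {0, 0}, top[2] = {0, 0},
         side_bottom[2] = {0, 0}, roulette_net[2] = {0, 0};
  std::vector<double> fluence;          // nz x 2
  int nz = 0; double dzv = 0;
  int nb; double b0, bw;                // spectral bins
  std::vector<double> spec_in_tumor, spec_exit_tumor, spec_surface0,
      spec_surface1, exc_hist, gen_hist;
  double gen_w = 0, exited_w = 0; long gen_n = 0;
  std::vector<double> surf;             // x,y,wl,w,prov rows
  bool record_surface;
  long n_aborted = 0;
  int bin(double wl) const {
    int b = (int)std::floor((wl - b0) / bw);
    if (b < 0) b = 0;
    if (b >= nb) b = nb - 1;
    return b;
  }
};

inline void score_fluence(Tally& t, double z0, double z1, double w,
                          double len, int prov) {
  if (t.nz <= 0 || len <= 0) return;
  double* f = t.fluence.data() + (size_t)prov * t.nz;
  double dz = z1 - z0;
  if (std::fabs(dz) < 1e-12) {
    int b = (int)(z0 / t.dzv);
    if (b >= 0 && b < t.nz) f[b] += w * len;
    return;
  }
  double zlo = std::min(z0, z1), zhi = std::max(z0, z1);
  int b0i = std::max(0, (int)(zlo / t.dzv));
  int b1i = std::min(t.nz - 1, (int)(zhi / t.dzv));
  double scale = len / std::fabs(dz);
  for (int b = b0i; b <= b1i; ++b) {
    double lo = std::max(zlo, b * t.dzv), hi = std::min(zhi, (b + 1) * t.dzv);
    if (hi > lo) f[b] += w * (hi - lo) * scale;
  }
}

// Trace one packet to termination; spawned luminescence packets are pushed
// onto `sec`. Returns nothing; all scoring goes into `t`.
void trace(Packet pk, const Model& m, Tally& t, std::vector<Packet>& sec,
           double w_roulette, double roulette_surv, long max_steps) {
  // per-packet property cache (wavelength is fixed during transport)
  std::vector<double> cmua(m.M), cmus(m.M), cg(m.M), cn(m.M);
  std::vector<char> cached(m.M, 0);
  double exc = -1.0; // lazily computed f(wl)*QY for this packet

  t.launched[pk.prov] += pk.w;
  if (pk.prov == 0 && pk.in_sphere && !pk.entered_tallied) {
    t.spec_in_tumor[t.bin(pk.wl)] += pk.w;
    pk.entered_tallied = true;
  }

  long steps = 0;
  const double EPS = 1e-7;
  while (pk.w > 0) {
    if (++steps > max_steps) { t.n_aborted++; t.absorbed[pk.prov] += pk.w; return; }
    int layer = layer_of(m, pk.z);
    int med = pk.in_sphere ? m.sphere_med : layer;
    if (!cached[med]) {
      const double* base = m.mua.data() + (size_t)med * m.nw;
      cmua[med] = interp(m.wl_grid, base, m.nw, pk.wl);
      cmus[med] = interp(m.wl_grid, m.mus.data() + (size_t)med * m.nw, m.nw, pk.wl);
      cg[med]   = interp(m.wl_grid, m.gg.data() + (size_t)med * m.nw, m.nw, pk.wl);
      cn[med]   = interp(m.wl_grid, m.nn.data() + (size_t)med * m.nw, m.nw, pk.wl);
      cached[med] = 1;
    }
    double mua = cmua[med], mus = cmus[med], g = cg[med], n1 = cn[med];
    double mut = mua + mus;
    double s = (mut > 0) ? -std::log(runif01()) / mut : DBL_MAX;

    // nearest boundary along the flight direction
    double db = DBL_MAX;
    int btype = -1; // 0 plane up, 1 plane down, 2 side, 3 sphere
    if (pk.uz > 1e-12) {
      double zb_next = pk.in_sphere ? m.zmax : m.zb[layer + 1];
      double d = (zb_next - pk.z) / pk.uz;
      if (pk.in_sphere) { /* plane crossings inside sphere are not boundaries */ }
      if (d < db) { db = d; btype = 1; }
    } else if (pk.uz < -1e-12) {
      double zb_prev = pk.in_sphere ? 0.0 : m.zb[layer];
      double d = (zb_prev - pk.z) / pk.uz;
      if (d < db) { db = d; btype = 0; }
    }
    if (pk.ux > 1e-12)      { double d = (m.hx - pk.x) / pk.ux;  if (d < db) { db = d; btype = 2; } }
    else if (pk.ux < -1e-12){ double d = (-m.hx - pk.x) / pk.ux; if (d < db) { db = d; btype = 2; } }
    if (pk.uy > 1e-12)      { double d = (m.hy - pk.y) / pk.uy;  if (d < db) { db = d; btype = 2; } }
    else if (pk.uy < -1e-12){ double d = (-m.hy - pk.y) / pk.uy; if (d < db) { db = d; btype = 2; } }
    if (m.has_sphere) {
      double px = pk.x - m.cx, py = pk.y - m.cy, pz = pk.z - m.cz;
      double b = px * pk.ux + py * pk.uy + pz * pk.uz;
      double c = px * px + py * py + pz * pz - m.r2;
      double disc = b * b - c;
      if (disc > 0) {
        double sq = std::sqrt(disc);
        double t1 = -b - sq, t2 = -b + sq;
        double dsp = DBL_MAX;
        if (pk.in_sphere) dsp = t2; // exit distance
        else if (t1 > EPS) dsp = t1;
        if (dsp > EPS && dsp < db) { db = dsp; btype = 3; }
      }
    }

    if (s < db) {
      // interaction inside the current medium
      double z0 = pk.z;
      pk.x += s * pk.ux; pk.y += s * pk.uy; pk.z += s * pk.uz;
      score_fluence(t, z0, pk.z, pk.w, s, pk.prov);
      if (mut <= 0) { t.absorbed[pk.prov] += pk.w; return; } // cannot happen (s=INF)
      double dw = pk.w * mua / mut;
      t.absorbed[pk.prov] += dw;
      if (m.fluor_on && pk.prov == 0 && pk.in_sphere && dw > 0) {
        if (exc < 0)
          exc = interp(m.wl_grid, m.exc_prob.data(), m.nw, pk.wl);
        double wem = dw * exc;
        if (wem > 0) {
          t.gen_w += wem; t.gen_n++;
          t.exc_hist[t.bin(pk.wl)] += wem;
          Packet em;
          em.x = pk.x; em.y = pk.y; em.z = pk.z;
          isotropic_dir(em.ux, em.uy, em.uz);
          em.wl = sample_em_wl(m);
          em.w = wem; em.prov = 1; em.in_sphere = true;
          em.entered_tallied = true; em.exit_tallied = false;
          t.gen_hist[t.bin(em.wl)] += wem;
          sec.push_back(em);
        }
      }
      pk.w -= dw;
      if (pk.w < w_roulette) {
        if (unif_rand() < roulette_surv) {
          double w_new = pk.w / roulette_surv;
          t.roulette_net[pk.prov] += pk.w - w_new;
          pk.w = w_new;
        } else {
          t.roulette_net[pk.prov] += pk.w;
          return;
        }
      }
      hg_deflect(g, pk.ux, pk.uy, pk.uz);
      continue;
    }

    // move to the boundary
    double z0 = pk.z;
    pk.x += db * pk.ux; pk.y += db * pk.uy; pk.z += db * pk.uz;
    score_fluence(t, z0, pk.z, pk.w, db, pk.prov);

    if (btype == 2) { t.side_bottom[pk.prov] += pk.w; return; }
    if (btype == 1 && !pk.in_sphere && layer == m.L - 1) {
      // bottom of the volume: matched absorbing boundary
      t.side_bottom[pk.prov] += pk.w; return;
    }
    if (btype == 1 && pk.in_sphere) { t.side_bottom[pk.prov] += pk.w; return; }

    if (btype == 3) {
      // sphere surface
      double rx = (pk.x - m.cx) / m.r, ry = (pk.y - m.cy) / m.r,
             rz = (pk.z - m.cz) / m.r;
      double ddotr = pk.ux * rx + pk.uy * ry + pk.uz * rz;
      bool exiting = pk.in_sphere;
      double Nx = exiting ? -rx : rx, Ny = exiting ? -ry : ry,
             Nz = exiting ? -rz : rz;
      double cosi = -(pk.ux * Nx + pk.uy * Ny + pk.uz * Nz);
      if (cosi < 0) cosi = 0; // grazing guard
      int far_layer = layer_of(m, pk.z);
      int far_med = exiting ? far_layer : m.sphere_med;
      if (!cached[far_med]) {
        cmua[far_med] = interp(m.wl_grid, m.mua.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cmus[far_med] = interp(m.wl_grid, m.mus.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cg[far_med]   = interp(m.wl_grid, m.gg.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cn[far_med]   = interp(m.wl_grid, m.nn.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cached[far_med] = 1;
      }
      double n2 = cn[far_med];
      double R = fresnel_R(n1, n2, cosi);
      if (unif_rand() < R) {
        // reflect: d' = d + 2 cosi N
        pk.ux += 2 * cosi * Nx; pk.uy += 2 * cosi * Ny; pk.uz += 2 * cosi * Nz;
        pk.x += pk.ux * EPS; pk.y += pk.uy * EPS; pk.z += pk.uz * EPS;
      } else {
        double eta = n1 / n2;
        double cost = std::sqrt(std::max(0.0, 1.0 - eta * eta * (1.0 - cosi * cosi)));
        pk.ux = eta * pk.ux + (eta * cosi - cost) * Nx;
        pk.uy = eta * pk.uy + (eta * cosi - cost) * Ny;
        pk.uz = eta * pk.uz + (eta * cosi - cost) * Nz;
        double norm = std::sqrt(pk.ux * pk.ux + pk.uy * pk.uy + pk.uz * pk.uz);
        pk.ux /= norm; pk.uy /= norm; pk.uz /= norm;
        pk.x += pk.ux * EPS; pk.y += pk.uy * EPS; pk.z += pk.uz * EPS;
        pk.in_sphere = !exiting ? true : false;
        if (exiting && !pk.exit_tallied) {
          if (pk.prov == 0) t.spec_exit_tumor[t.bin(pk.wl)] += pk.w;
          else t.exited_w += pk.w;
          pk.exit_tallied = true;
        }
        if (!exiting && pk.prov == 0 && !pk.entered_tallied) {
          t.spec_in_tumor[t.bin(pk.wl)] += pk.w;
          pk.entered_tallied = true;
        }
      }
      (void)ddotr;
      continue;
    }

    if (btype == 0) {
      int plane = layer; // upper plane of current layer
      if (plane == 0) {
        // top surface: Fresnel against ambient
        double cosi = -pk.uz; // uz < 0, normal (0,0,1) facing the packet
        double R = fresnel_R(n1, m.n_ambient, cosi);
        if (unif_rand() < R) {
          pk.uz = -pk.uz;
          pk.z = EPS;
          continue;
        }
        t.top[pk.prov] += pk.w;
        if (pk.prov == 0) t.spec_surface0[t.bin(pk.wl)] += pk.w;
        else t.spec_surface1[t.bin(pk.wl)] += pk.w;
        if (t.record_surface) {
          t.surf.push_back(pk.x); t.surf.push_back(pk.y);
          t.surf.push_back(pk.wl); t.surf.push_back(pk.w);
          t.surf.push_back((double)pk.prov);
        }
        return;
      }
      // interior layer plane, moving up
      int far_med = plane - 1;
      if (!cached[far_med]) {
        cmua[far_med] = interp(m.wl_grid, m.mua.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cmus[far_med] = interp(m.wl_grid, m.mus.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cg[far_med]   = interp(m.wl_grid, m.gg.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cn[far_med]   = interp(m.wl_grid, m.nn.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cached[far_med] = 1;
      }
      double n2 = cn[far_med];
      double cosi = -pk.uz;
      double R = fresnel_R(n1, n2, cosi);
      if (unif_rand() < R) { pk.uz = -pk.uz; pk.z += EPS; }
      else {
        double eta = n1 / n2;
        double cost = std::sqrt(std::max(0.0, 1.0 - eta * eta * (1.0 - cosi * cosi)));
        double sxy = (std::fabs(pk.uz) < 1.0) ? std::sqrt(std::max(0.0, 1.0 - pk.uz * pk.uz)) : 0.0;
        // refract: scale transverse by eta, set uz from cost (moving up)
        if (sxy > 1e-12) {
          double scale = eta; // sin(theta_t) = eta sin(theta_i)
          pk.ux *= scale; pk.uy *= scale;
        }
        pk.uz = -cost;
        double norm = std::sqrt(pk.ux * pk.ux + pk.uy * pk.uy + pk.uz * pk.uz);
        pk.ux /= norm; pk.uy /= norm; pk.uz /= norm;
        pk.z -= EPS;
        pk.in_sphere = inside_sphere(m, pk.x, pk.y, pk.z);
      }
      continue;
    }

    if (btype == 1) {
      // interior layer plane, moving down
      int far_med = layer + 1;
      if (!cached[far_med]) {
        cmua[far_med] = interp(m.wl_grid, m.mua.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cmus[far_med] = interp(m.wl_grid, m.mus.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cg[far_med]   = interp(m.wl_grid, m.gg.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cn[far_med]   = interp(m.wl_grid, m.nn.data() + (size_t)far_med * m.nw, m.nw, pk.wl);
        cached[far_med] = 1;
      }
      double n2 = cn[far_med];
      double cosi = pk.uz;
      double R = fresnel_R(n1, n2, cosi);
      if (unif_rand() < R) { pk.uz = -pk.uz; pk.z -= EPS; }
      else {
        double eta = n1 / n2;
        double cost = std::sqrt(std::max(0.0, 1.0 - eta * eta * (1.0 - cosi * cosi)));
        pk.ux *= eta; pk.uy *= eta;
        pk.uz = cost;
        double norm = std::sqrt(pk.ux * pk.ux + pk.uy * pk.uy + pk.uz * pk.uz);
        pk.ux /= norm; pk.uy /= norm; pk.uz /= norm;
        pk.z += EPS;
        pk.in_sphere = inside_sphere(m, pk.x, pk.y, pk.z);
      }
      continue;
    }
  }
  // weight reached exactly zero without termination event (rare)
  t.absorbed[pk.prov] += pk.w;
}

} // namespace

// [[Rcpp::export(name = ".mc_trace_cpp")]]
List mc_trace_cpp(NumericMatrix sources, NumericVector layer_z,
                  NumericVector wl_grid, NumericMatrix mua, NumericMatrix mus,
                  NumericMatrix g, NumericMatrix n,
                  double half_x, double half_y,
                  bool has_sphere, NumericVector sphere, int sphere_med,
                  double n_ambient,
                  bool fluor_on, NumericVector exc_prob,
                  NumericVector em_wl, NumericVector em_cdf,
                  double w_roulette, double roulette_surv,
                  int nz_fluence, NumericVector spec_bins,
                  bool record_surface, double max_steps) {
  Model m;
  m.zb = as<std::vector<double>>(layer_z);
  m.L = (int)m.zb.size() - 1;
  m.zmax = m.zb[m.L];
  m.hx = half_x; m.hy = half_y;
  m.has_sphere = has_sphere;
  if (has_sphere) {
    m.cx = sphere[0]; m.cy = sphere[1]; m.cz = sphere[2];
    m.r = sphere[3]; m.r2 = m.r * m.r;
  } else { m.cx = m.cy = m.cz = 0; m.r = 0; m.r2 = 0; }
  m.sphere_med = sphere_med;
  m.wl_grid = as<std::vector<double>>(wl_grid);
  m.nw = (int)m.wl_grid.size();
  m.M = mua.ncol();
  m.mua.assign(mua.begin(), mua.end());
  m.mus.assign(mus.begin(), mus.end());
  m.gg.assign(g.begin(), g.end());
  m.nn.assign(n.begin(), n.end());
  m.n_ambient = n_ambient;
  m.fluor_on = fluor_on;
  m.exc_prob = as<std::vector<double>>(exc_prob);
  m.em_wl = as<std::vector<double>>(em_wl);
  m.em_cdf = as<std::vector<double>>(em_cdf);

  Tally t;
  t.nz = nz_fluence;
  if (t.nz > 0) { t.dzv = m.zmax / t.nz; t.fluence.assign((size_t)t.nz * 2, 0.0); }
  t.b0 = spec_bins[0];
  t.bw = spec_bins[1];
  t.nb = (int)spec_bins[2];
  t.spec_in_tumor.assign(t.nb, 0.0); t.spec_exit_tumor.assign(t.nb, 0.0);
  t.spec_surface0.assign(t.nb, 0.0); t.spec_surface1.assign(t.nb, 0.0);
  t.exc_hist.assign(t.nb, 0.0); t.gen_hist.assign(t.nb, 0.0);
  t.record_surface = record_surface;

  std::vector<Packet> sec;
  sec.reserve(1024);
  int np = sources.nrow();
  for (int i = 0; i < np; ++i) {
    Packet pk;
    pk.x = sources(i, 0); pk.y = sources(i, 1); pk.z = sources(i, 2);
    pk.ux = sources(i, 3); pk.uy = sources(i, 4); pk.uz = sources(i, 5);
    pk.wl = sources(i, 6); pk.w = sources(i, 7);
    pk.prov = 0;
    pk.in_sphere = inside_sphere(m, pk.x, pk.y, pk.z);
    pk.entered_tallied = false; pk.exit_tallied = false;
    if (pk.z < 0 || pk.z > m.zmax || std::fabs(pk.x) > m.hx ||
        std::fabs(pk.y) > m.hy)
      continue; // born outside: skip (footprint can exceed the volume)
    trace(pk, m, t, sec, w_roulette, roulette_surv, (long)max_steps);
    // transport this primary's luminescence immediately (single generation)
    if (!sec.empty()) {
      std::vector<Packet> none;
      for (size_t k = 0; k < sec.size(); ++k)
        trace(sec[k], m, t, none, w_roulette, roulette_surv, (long)max_steps);
      sec.clear();
    }
    if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix summ(5, 2);
  for (int p = 0; p < 2; ++p) {
    summ(0, p) = t.launched[p]; summ(1, p) = t.absorbed[p];
    summ(2, p) = t.top[p]; summ(3, p) = t.side_bottom[p];
    summ(4, p) = t.roulette_net[p];
  }
  rownames(summ) = CharacterVector::create("launched", "absorbed", "top",
                                           "side_bottom", "roulette_net");
  colnames(summ) = CharacterVector::create("excitation", "luminescence");

  NumericMatrix fl(t.nz > 0 ? t.nz : 0, 2);
  if (t.nz > 0)
    for (int p = 0; p < 2; ++p)
      for (int b = 0; b < t.nz; ++b) fl(b, p) = t.fluence[(size_t)p * t.nz + b];

  int nsurf = (int)(t.surf.size() / 5);
  NumericMatrix surf(nsurf, 5);
  for (int i = 0; i < nsurf; ++i)
    for (int j = 0; j < 5; ++j) surf(i, j) = t.surf[(size_t)i * 5 + j];
  colnames(surf) = CharacterVector::create("x", "y", "wavelength", "weight", "prov");

  return List::create(
    _["summary"] = summ,
    _["fluence"] = fl,
    _["surface_events"] = surf,
    _["spec_in_tumor"] = NumericVector(t.spec_in_tumor.begin(), t.spec_in_tumor.end()),
    _["spec_exit_tumor"] = NumericVector(t.spec_exit_tumor.begin(), t.spec_exit_tumor.end()),
    _["spec_surface_excitation"] = NumericVector(t.spec_surface0.begin(), t.spec_surface0.end()),
    _["spec_surface_luminescence"] = NumericVector(t.spec_surface1.begin(), t.spec_surface1.end()),
    _["lum_generated_weight"] = t.gen_w,
    _["lum_generated_count"] = (double)t.gen_n,
    _["lum_exited_weight"] = t.exited_w,
    _["exc_hist"] = NumericVector(t.exc_hist.begin(), t.exc_hist.end()),
    _["em_hist"] = NumericVector(t.gen_hist.begin(), t.gen_hist.end()),
    _["n_aborted"] = (double)t.n_aborted);
}
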