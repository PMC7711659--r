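// Local Equilibrium Monte Carlo engine for the Primitive Model.
//
// Samples ion configurations from a grand-canonical-like measure in which
// the electrochemical potential mu_{i,alpha} is constant within each
// subvolume alpha but may differ between subvolumes.  Moves: particle
// insertion and deletion (mobile species only) and single-particle
// displacement (all ions, including confined structural ions).  Energies
// are direct pairwise Coulomb sums plus hard-sphere and hard-wall
// constraints in a finite cylindrical cell -- no periodic boundaries, no
// Ewald summation.
//
// Units: lengths nm, energies kT, charges e.  Concentration unit:
// 1 mol/L = conc_unit particles/nm^3.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Geometry {
  double Rcell, Lhalf;
  bool has_membrane;
  double zmL, zmR;
  std::vector<double> wz, wR;  // piecewise linear wall profile

  double wall_radius(double z) const {
    const int n = wz.size();
    if (n == 0) return INF;
    if (z <= wz[0]) return wR[0];
    if (z >= wz[n - 1]) return wR[n - 1];
    for (int i = 1; i < n; ++i) {
      if (z <= wz[i]) {
        double t = (z - wz[i - 1]) / (wz[i] - wz[i - 1]);
        return wR[i - 1] + t * (wR[i] - wR[i - 1]);
      }
    }
    return wR[n - 1];
  }

  // hard-wall check for an ion center (radius a) at (x, y, z);
  // conf: optional confinement box {z1, z2, r1, r2} for structural ions
  bool accessible(double a, double x, double y, double z,
                  const double *conf) const {
    double r2 = x * x + y * y;
    double rmax = Rcell - a;
    if (std::fabs(z) > Lhalf || r2 > rmax * rmax) return false;
    if (has_membrane) {
      if (z >= zmL && z <= zmR) {
        double rw = wall_radius(z) - a;
        if (rw < 0.0 || r2 > rw * rw) return false;
      } else {
        double face = (z < zmL) ? zmL : zmR;
        double dz = std::fabs(z - face);
        if (dz < a) {
          double Rf = wall_radius(face);
          double r = std::sqrt(r2);
          if (r >= Rf) return false;
          double dr = Rf - r;
          if (dr * dr + dz * dz < a * a) return false;
        }
      }
    }
    if (conf) {
      double r = std::sqrt(r2);
      if (z < conf[0] || z > conf[1] || r < conf[2] || r > conf[3])
        return false;
    }
    return true;
  }
};

struct Grid {
  std::vector<double> zedges;       // nz + 1
  int nz, nr;
  std::vector<double> redges2;      // nz * (nr + 1), row-major by slab
  std::vector<double> vol;          // nz * nr, cell index = ir * nz + iz

  // cell index of a point, or -1 if outside the grid
  int locate(double z, double r2) const {
    if (z < zedges[0] || z > zedges[nz]) return -1;
    int lo = 0, hi = nz;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (z >= zedges[mid]) lo = mid; else hi = mid;
    }
    int iz = lo;
    const double *re = &redges2[iz * (nr + 1)];
    if (r2 > re[nr]) return -1;
    int ir = 0;
    while (ir < nr - 1 && r2 > re[ir + 1]) ++ir;
    return ir * nz + iz;
  }
};

struct State {
  // mobile ions
  std::vector<double> x, y, z;
  std::vector<int> sp, cell;
  // structural ions (fixed count)
  std::vector<double> sx, sy, sz;
  std::vector<double> s_rad, s_chg;
  std::vector<double> s_conf;  // 4 per ion
  std::vector<int> counts;     // ns * ncell
};

enum Interactions { FULL = 0, HARD = 1, NONE = 2 };

struct Model {
  Geometry geom;
  Grid grid;
  std::vector<double> sp_rad, sp_val;  // mobile species
  int ns;
  std::vector<double> fx, fy, fz, fq;  // fixed charges
  double lB;
  double conc_unit;
  int mode;  // Interactions

  // interaction energy of a (radius, valence) particle at p with all other
  // ions and fixed charges; skip_m / skip_s exclude one mobile/structural
  // ion (index or -1)
  double particle_energy(const State &st, double rad, double val,
                         double px, double py, double pz,
                         int skip_m, int skip_s) const {
    double u = 0.0;
    const bool coulomb = (mode == FULL);
    const bool cores = (mode != NONE);
    const int nm = st.x.size();
    for (int j = 0; j < nm; ++j) {
      if (j == skip_m) continue;
      double dx = st.x[j] - px, dy = st.y[j] - py, dz = st.z[j] - pz;
      double d2 = dx * dx + dy * dy + dz * dz;
      double contact = rad + sp_rad[st.sp[j]];
      if (cores && d2 < contact * contact) return INF;
      if (coulomb) u += val * sp_val[st.sp[j]] * lB / std::sqrt(d2);
    }
    const int nst = st.sx.size();
    for (int j = 0; j < nst; ++j) {
      if (j == skip_s) continue;
      double dx = st.sx[j] - px, dy = st.sy[j] - py, dz = st.sz[j] - pz;
      double d2 = dx * dx + dy * dy + dz * dz;
      double contact = rad + st.s_rad[j];
      if (cores && d2 < contact * contact) return INF;
      if (coulomb) u += val * st.s_chg[j] * lB / std::sqrt(d2);
    }
    if (coulomb) {
      const int nf = fx.size();
      for (int j = 0; j < nf; ++j) {
        double dx = fx[j] - px, dy = fy[j] - py, dz = fz[j] - pz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        u += val * fq[j] * lB / d;
      }
    }
    return u;
  }
};

Model build_model(List geomL, List speciesL, NumericMatrix fixed,
                  List gridL) {
  Model m;
  m.geom.Rcell = as<double>(geomL["cell_radius"]);
  m.geom.Lhalf = as<double>(geomL["cell_half_length"]);
  m.geom.has_membrane = as<bool>(geomL["has_membrane"]);
  if (m.geom.has_membrane) {
    m.geom.zmL = as<double>(geomL["zm_left"]);
    m.geom.zmR = as<double>(geomL["zm_right"]);
    m.geom.wz = as<std::vector<double> >(geomL["wall_z"]);
    m.geom.wR = as<std::vector<double> >(geomL["wall_R"]);
  } else {
    m.geom.zmL = m.geom.zmR = 0.0;
  }
  m.sp_rad = as<std::vector<double> >(speciesL["radius"]);
  m.sp_val = as<std::vector<double> >(speciesL["valence"]);
  m.ns = m.sp_rad.size();
  m.lB = as<double>(speciesL["lB"]);
  m.conc_unit = as<double>(speciesL["conc_unit"]);
  for (int i = 0; i < fixed.nrow(); ++i) {
    m.fx.push_back(fixed(i, 0));
    m.fy.push_back(fixed(i, 1));
    m.fz.push_back(fixed(i, 2));
    m.fq.push_back(fixed(i, 3));
  }
  m.grid.zedges = as<std::vector<double> >(gridL["z_edges"]);
  m.grid.nz = as<int>(gridL["nz"]);
  m.grid.nr = as<int>(gridL["nr"]);
  NumericMatrix re2 = gridL["r_edges2"];
  m.grid.redges2.resize(m.grid.nz * (m.grid.nr + 1));
  for (int iz = 0; iz < m.grid.nz; ++iz)
    for (int k = 0; k <= m.grid.nr; ++k)
      m.grid.redges2[iz * (m.grid.nr + 1) + k] = re2(iz, k);
  NumericMatrix vol = gridL["volume"];
  m.grid.vol.resize(m.grid.nz * m.grid.nr);
  for (int iz = 0; iz < m.grid.nz; ++iz)
    for (int ir = 0; ir < m.grid.nr; ++ir)
      m.grid.vol[ir * m.grid.nz + iz] = vol(iz, ir);
  return m;
}

} // namespace

// [[Rcpp::export]]
List lemc_engine(List geomL, List speciesL, NumericMatrix fixed,
                 List structuralL, List gridL, NumericMatrix muM,
                 List runL) {
  Model m = build_model(geomL, speciesL, fixed, gridL);
  const int ncell = m.grid.nz * m.grid.nr;
  if (muM.nrow() != m.ns || muM.ncol() != ncell)
    stop("mu matrix must be n_species x n_cells");
  std::vector<double> mu(m.ns * ncell);
  for (int s = 0; s < m.ns; ++s)
    for (int c = 0; c < ncell; ++c)
      mu[s * ncell + c] = muM(s, c);

  State st;
  st.counts.assign(m.ns * ncell, 0);
  NumericMatrix spos = structuralL["positions"];       // k x 3
  NumericVector srad = structuralL["radius"];
  NumericVector schg = structuralL["charge"];
  NumericMatrix sconf = structuralL["confinement"];    // k x 4
  const int nstruct = spos.nrow();
  for (int i = 0; i < nstruct; ++i) {
    st.sx.push_back(spos(i, 0));
    st.sy.push_back(spos(i, 1));
    st.sz.push_back(spos(i, 2));
    st.s_rad.push_back(srad[i]);
    st.s_chg.push_back(schg[i]);
    for (int k = 0; k < 4; ++k) st.s_conf.push_back(sconf(i, k));
  }

  const int sweeps = as<int>(runL["sweeps"]);
  const int equil = as<int>(runL["equilibration"]);
  const double p_ins = as<double>(runL["p_insert"]);
  const double p_del = as<double>(runL["p_delete"]);
  const double dmax = as<double>(runL["max_step"]);
  const int mps = as<int>(runL["moves_per_sweep"]);
  const int nblocks = as<int>(runL["blocks"]);
  const int widom = as<int>(runL["widom_per_sweep"]);
  m.mode = as<int>(runL["interactions"]);
  if (sweeps <= equil) stop("sweeps must exceed equilibration");

  // accumulators
  std::vector<double> block_sum(nblocks * m.ns * ncell, 0.0);
  std::vector<int> block_n(nblocks, 0);
  std::vector<double> widom_sum(m.ns * ncell, 0.0);
  std::vector<double> widom_n(ncell, 0.0);
  const int nsample = sweeps - equil;
  long acc[3] = {0, 0, 0}, att[3] = {0, 0, 0};

  for (int sweep = 0; sweep < sweeps; ++sweep) {
    for (int mv = 0; mv < mps; ++mv) {
      double u = unif_rand();
      if (u < p_ins) {
        // --- insertion ---
        att[0]++;
        int s = (int)(unif_rand() * m.ns); if (s >= m.ns) s = m.ns - 1;
        int c = (int)(unif_rand() * ncell); if (c >= ncell) c = ncell - 1;
        int iz = c % m.grid.nz, ir = c / m.grid.nz;
        const double *re = &m.grid.redges2[iz * (m.grid.nr + 1)];
        double z = m.grid.zedges[iz] +
          unif_rand() * (m.grid.zedges[iz + 1] - m.grid.zedges[iz]);
        double r2 = re[ir] + unif_rand() * (re[ir + 1] - re[ir]);
        double r = std::sqrt(r2), phi = 2.0 * M_PI * unif_rand();
        double px = r * std::cos(phi), py = r * std::sin(phi);
        double dU;
        if (!m.geom.accessible(m.sp_rad[s], px, py, z, 0)) {
          dU = INF;
        } else {
          dU = m.particle_energy(st, m.sp_rad[s], m.sp_val[s], px, py, z,
                                 -1, -1);
        }
        if (std::isfinite(dU)) {
          int N = st.counts[s * ncell + c];
          double lacc = std::log(m.conc_unit * m.grid.vol[c] / (N + 1)) +
            mu[s * ncell + c] - dU;
          if (lacc >= 0.0 || unif_rand() < std::exp(lacc)) {
            st.x.push_back(px); st.y.push_back(py); st.z.push_back(z);
            st.sp.push_back(s); st.cell.push_back(c);
            st.counts[s * ncell + c]++;
            acc[0]++;
          }
        }
      } else if (u < p_ins + p_del) {
        // --- deletion ---
        att[1]++;
        int s = (int)(unif_rand() * m.ns); if (s >= m.ns) s = m.ns - 1;
        int c = (int)(unif_rand() * ncell); if (c >= ncell) c = ncell - 1;
        int N = st.counts[s * ncell + c];
        if (N == 0) continue;
        int pick = (int)(unif_rand() * N); if (pick >= N) pick = N - 1;
        int idx = -1;
        for (int j = 0, seen = 0; j < (int)st.x.size(); ++j) {
          if (st.sp[j] == s && st.cell[j] == c) {
            if (seen == pick) { idx = j; break; }
            ++seen;
          }
        }
        double Uk = m.particle_energy(st, m.sp_rad[s], m.sp_val[s],
                                      st.x[idx], st.y[idx], st.z[idx],
                                      idx, -1);
        double lacc = std::log((double)N / (m.conc_unit * m.grid.vol[c])) -
          mu[s * ncell + c] + Uk;
        if (lacc >= 0.0 || unif_rand() < std::exp(lacc)) {
          st.counts[s * ncell + c]--;
          int last = st.x.size() - 1;
          st.x[idx] = st.x[last]; st.y[idx] = st.y[last];
          st.z[idx] = st.z[last]; st.sp[idx] = st.sp[last];
          st.cell[idx] = st.cell[last];
          st.x.pop_back(); st.y.pop_back(); st.z.pop_back();
          st.sp.pop_back(); st.cell.pop_back();
          acc[1]++;
        }
      } else {
        // --- displacement ---
        int ntot = st.x.size() + nstruct;
        if (ntot == 0) continue;
        att[2]++;
        int i = (int)(unif_rand() * ntot); if (i >= ntot) i = ntot - 1;
        double ddx = (2.0 * unif_rand() - 1.0) * dmax;
        double ddy = (2.0 * unif_rand() - 1.0) * dmax;
        double ddz = (2.0 * unif_rand() - 1.0) * dmax;
        if (i < (int)st.x.size()) {
          // mobile ion: mu terms enter when the move crosses cells
          int s = st.sp[i];
          double nx = st.x[i] + ddx, ny = st.y[i] + ddy, nz2 = st.z[i] + ddz;
          if (!m.geom.accessible(m.sp_rad[s], nx, ny, nz2, 0)) continue;
          int cnew = m.grid.locate(nz2, nx * nx + ny * ny);
          if (cnew < 0) continue;
          double Uold = m.particle_energy(st, m.sp_rad[s], m.sp_val[s],
                                          st.x[i], st.y[i], st.z[i], i, -1);
          double Unew = m.particle_energy(st, m.sp_rad[s], m.sp_val[s],
                                          nx, ny, nz2, i, -1);
          if (!std::isfinite(Unew)) continue;
          double lacc = mu[s * ncell + cnew] - mu[s * ncell + st.cell[i]] -
            (Unew - Uold);
          if (lacc >= 0.0 || unif_rand() < std::exp(lacc)) {
            st.counts[s * ncell + st.cell[i]]--;
            st.counts[s * ncell + cnew]++;
            st.x[i] = nx; st.y[i] = ny; st.z[i] = nz2; st.cell[i] = cnew;
            acc[2]++;
          }
        } else {
          // structural ion: plain Metropolis inside its confinement
          int k = i - st.x.size();
          double nx = st.sx[k] + ddx, ny = st.sy[k] + ddy,
            nz2 = st.sz[k] + ddz;
          const double *conf = &st.s_conf[4 * k];
          if (!m.geom.accessible(st.s_rad[k], nx, ny, nz2, conf)) continue;
          double Uold = m.particle_energy(st, st.s_rad[k], st.s_chg[k],
                                          st.sx[k], st.sy[k], st.sz[k],
                                          -1, k);
          double Unew = m.particle_energy(st, st.s_rad[k], st.s_chg[k],
                                          nx, ny, nz2, -1, k);
          if (!std::isfinite(Unew)) continue;
          double lacc = -(Unew - Uold);
          if (lacc >= 0.0 || unif_rand() < std::exp(lacc)) {
            st.sx[k] = nx; st.sy[k] = ny; st.sz[k] = nz2;
            acc[2]++;
          }
        }
      }
    }
    if (sweep >= equil) {
      int b = (int)(((long)(sweep - equil)) * nblocks / nsample);
      if (b >= nblocks) b = nblocks - 1;
      block_n[b]++;
      double *bs = &block_sum[(size_t)b * m.ns * ncell];
      for (int j = 0; j < (int)st.x.size(); ++j)
        bs[st.sp[j] * ncell + st.cell[j]] += 1.0;
      // Widom test insertions: per-cell <exp(-dU)> estimates of the
      // excess chemical potential (rho(r) = e^mu <exp(-dU)> pointwise)
      for (int w = 0; w < widom; ++w) {
        int c = (int)(unif_rand() * ncell); if (c >= ncell) c = ncell - 1;
        int iz = c % m.grid.nz, ir = c / m.grid.nz;
        const double *re = &m.grid.redges2[iz * (m.grid.nr + 1)];
        double z = m.grid.zedges[iz] +
          unif_rand() * (m.grid.zedges[iz + 1] - m.grid.zedges[iz]);
        double r2 = re[ir] + unif_rand() * (re[ir + 1] - re[ir]);
        double r = std::sqrt(r2), phi = 2.0 * M_PI * unif_rand();
        double px = r * std::cos(phi), py = r * std::sin(phi);
        widom_n[c] += 1.0;
        for (int s = 0; s < m.ns; ++s) {
          if (!m.geom.accessible(m.sp_rad[s], px, py, z, 0)) continue;
          double dU = m.particle_energy(st, m.sp_rad[s], m.sp_val[s],
                                        px, py, z, -1, -1);
          if (std::isfinite(dU))
            widom_sum[s * ncell + c] += std::exp(-dU);
        }
      }
    }
    if ((sweep & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // concentrations in mol/L per cell, plus per-block values
  NumericMatrix conc(m.ns, ncell), conc_se(m.ns, ncell);
  NumericVector blocks_out(nblocks * m.ns * ncell);
  for (int s = 0; s < m.ns; ++s) {
    for (int c = 0; c < ncell; ++c) {
      double vc = m.grid.vol[c] * m.conc_unit;
      double mean = 0.0, sq = 0.0;
      for (int b = 0; b < nblocks; ++b) {
        double cb = block_sum[(size_t)b * m.ns * ncell + s * ncell + c] /
          (block_n[b] * vc);
        blocks_out[(size_t)b * m.ns * ncell + s * ncell + c] = cb;
        mean += cb; sq += cb * cb;
      }
      mean /= nblocks;
      double var = sq / nblocks - mean * mean;
      conc(s, c) = mean;
      conc_se(s, c) = std::sqrt(std::max(0.0, var) / nblocks);
    }
  }
  NumericMatrix widom_mean(m.ns, ncell);
  NumericVector widom_count(ncell);
  for (int c = 0; c < ncell; ++c) {
    widom_count[c] = widom_n[c];
    for (int s = 0; s < m.ns; ++s)
      widom_mean(s, c) = widom_n[c] > 0 ?
        widom_sum[s * ncell + c] / widom_n[c] : NA_REAL;
  }
  NumericMatrix struct_pos(nstruct, 3);
  for (int i = 0; i < nstruct; ++i) {
    struct_pos(i, 0) = st.sx[i];
    struct_pos(i, 1) = st.sy[i];
    struct_pos(i, 2) = st.sz[i];
  }
  return List::create(
    _["conc"] = conc,
    _["conc_se"] = conc_se,
    _["block_conc"] = blocks_out,
    _["n_blocks"] = nblocks,
    _["n_mobile"] = (int)st.x.size(),
    _["n_structural"] = nstruct,
    _["structural_positions"] = struct_pos,
    _["attempts"] = NumericVector::create(att[0], att[1], att[2]),
    _["accepts"] = NumericVector::create(acc[0], acc[1], acc[2]),
    _["widom_mean"] = widom_mean,
    _["widom_n"] = widom_count);
}

// [[Rcpp::export]]
double lemc_config_energy(List geomL, List speciesL, NumericMatrix fixed,
                          List gridL, NumericMatrix positions,
                          IntegerVector species_idx, int interactions) {
  // total energy of an explicit mobile-ion configuration (kT); used to
  // cross-check the engine's energy kernel against the R-level sums
  Model m = build_model(geomL, speciesL, fixed, gridL);
  m.mode = interactions;
  State st;
  const int n = positions.nrow();
  double u = 0.0;
  for (int i = 0; i < n; ++i) {
    int s = species_idx[i];
    double px = positions(i, 0), py = positions(i, 1), pz = positions(i, 2);
    if (!m.geom.accessible(m.sp_rad[s], px, py, pz, 0)) return R_PosInf;
    double du = m.particle_energy(st, m.sp_rad[s], m.sp_val[s], px, py, pz,
                                  -1, -1);
    if (!std::isfinite(du)) return R_PosInf;
    u += du;
    st.x.push_back(px); st.y.push_back(py); st.z.push_back(pz);
    st.sp.push_back(s); st.cell.push_back(0);
  }
  return u;
}

// [[Rcpp::export]]
LogicalVector lemc_accessible(List geomL, double radius, NumericMatrix pos) {
  // expose the hard-wall test of the engine for property tests
  Geometry g;
  g.Rcell = as<double>(geomL["cell_radius"]);
  g.Lhalf = as<double>(geomL["cell_half_length"]);
  g.has_membrane = as<bool>(geomL["has_membrane"]);
  if (g.has_membrane) {
    g.zmL = as<double>(geomL["zm_left"]);
    g.zmR = as<double>(geomL["zm_right"]);
    g.wz = as<std::vector<double> >(geomL["wall_z"]);
    g.wR = as<std::vector<double> >(geomL["wall_R"]);
  }
  LogicalVector out(pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i)
    out[i] = g.accessible(radius, pos(i, 0), pos(i, 1), pos(i, 2), 0);
  return out;
}
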