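// Particle-based stochastic reaction-diffusion engine.
//
// Brownian dynamics of point particles on a periodic square (plane2d) or on
// a sphere with a cytosolic interior (sphere3d), with first-order,
// second-order (reactive-radius) and surface-association reactions executed
// per discrete time step. Update order within a step: (optional pheromone
// emission) -> diffusion with boundary handling -> first-order events ->
// second-order events via neighbor search, with each particle participating
// in at most one reaction per step and bimolecular candidates processed in
// shuffled order.

#include <Rcpp.h>
#include <xoshiro.h>
#include <boost/random/poisson_distribution.hpp>
#include <boost/random/binomial_distribution.hpp>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// xoshiro256+ uniform stream with a Marsaglia-Tsang ziggurat normal
// sampler (128 layers); the per-step cost is dominated by Gaussian draws
// for diffusion, so the fast path matters.
struct Rng {
  dqrng::xoshiro256plus gen;
  uint32_t kn[128];
  double wn[128], fn[128];
  static constexpr double ZR = 3.442619855899;

  explicit Rng(uint64_t seed) : gen(seed) {
    const double m1 = 2147483648.0, vn = 9.91256303526217e-3;
    double dn = ZR, tn = ZR;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  double unif() { return (gen() >> 11) * 0x1.0p-53; }

  double gauss() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)gen();
      int iz = hz & 127;
      if ((uint32_t)std::llabs((long long)hz) < kn[iz]) return hz * wn[iz];
      if (iz == 0) { // tail beyond ZR
        double xx, yy;
        do {
          xx = -std::log(unif()) / ZR;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return (hz > 0) ? ZR + xx : -(ZR + xx);
      }
      double xx = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * xx * xx)) {
        return xx;
      }
    }
  }

  // Fisher-Yates helper
  int below(int n) { return static_cast<int>(unif() * n) % n; }
};

const int COMP_CYTOSOL = 0;
const int COMP_MEMBRANE = 1;
const int COMP_EXTRA = 2;

struct Engine {
  // geometry
  bool plane;
  double L = 0.0;      // plane side
  double R = 0.0;      // cell radius
  double invR = 0.0;
  double R_absorb = 0; // absorbing shell (0 = none)
  bool has_emitter = false;
  double ex = 0, ey = 0, ez = 0, eR = 0; // emitter sphere
  double dt;
  double offset; // dissociation placement distance (rho + 1e-5)

  // species tables
  int nsp;
  std::vector<double> sd_step; // sqrt(2 D dt) per species
  // ultra-slow species (per-step sd < 0.1% of the reactive radius) take
  // one aggregated Gaussian step every `stride` steps with sd scaled by
  // sqrt(stride): marginally identical Brownian increments, fewer draws
  std::vector<int> dstride;
  std::vector<double> sd_stride;
  std::vector<int> comp;
  std::vector<char> fo_any, so_active;

  // first-order channels per species (includes surface association and the
  // frozen-field channel marker)
  std::vector<std::vector<int>> fo_by_sp;
  std::vector<double> fo_prob;
  std::vector<int> fo_p1, fo_p2;
  std::vector<char> fo_field; // frozen-field channel: prob looked up by angle

  // second-order: key matrix nsp*nsp -> encoded (rxn*2 + swapped) + 1, 0 none
  std::vector<int> so_key;
  std::vector<double> so_prob, so_rho2;
  std::vector<int> so_pa, so_pb; // products for role-a / role-b (-1 binding partner dies)
  std::vector<int> so_r1v, so_r2v; // reactant species per role
  std::vector<int> so_anchor;    // binding: which role keeps position (0=a,1=b,-1 n/a)

  // frozen pheromone field: hazard of the field channel as a function of the
  // cosine of the polar angle to the field axis
  bool has_field = false;
  double fx = 0, fy = 0, fz = 1;
  std::vector<double> field_cos, field_prob; // ascending in cos

  // pheromone bookkeeping
  int pher_sp = -1;
  double emit_rate = 0;
  double src_x = 0, src_y = 0, src_z = 0;
  int bath_target = -1; // maintain this many free pheromone (-1 = off)
  bool absorb_on = true; // absorbing vs reflecting outer shell
  bool well_mixed = false;

  // state
  std::vector<double> x, y, z;
  std::vector<int> sp, id;
  std::vector<long long> stamp;
  long long step_no = 0;
  int next_id = 0;
  int n_pher = 0;

  // grid
  double cell = 0.05, inv_cell = 20.0, gx0 = 0, gy0 = 0, gz0 = 0;
  int ncx = 0, ncy = 0, ncz = 0;
  std::vector<int> head, nxt;
  std::vector<int> touched;

  Rng rng;
  explicit Engine(uint64_t seed) : rng(seed) {}

  int n() const { return (int)sp.size(); }

  void wrap(double &v) const {
    // single steps are far smaller than L, so one conditional suffices
    while (v >= L) v -= L;
    while (v < 0) v += L;
  }

  void project_to_sphere(int i) {
    double r2 = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
    if (r2 < 1e-24) {
      double gx = rng.gauss(), gy = rng.gauss(), gz = rng.gauss();
      double f = R / std::sqrt(gx * gx + gy * gy + gz * gz);
      x[i] = gx * f; y[i] = gy * f; z[i] = gz * f;
      return;
    }
    double f = R / std::sqrt(r2);
    x[i] *= f; y[i] *= f; z[i] *= f;
  }

  void add_particle(int s, double px, double py, double pz) {
    sp.push_back(s); x.push_back(px); y.push_back(py); z.push_back(pz);
    id.push_back(next_id++);
    stamp.push_back(step_no); // newborns do not react again this step
    n_by_sp[s]++;
    if (s == pher_sp) n_pher++;
  }

  bool need_compact = false;

  void kill(int i) {
    if (sp[i] == pher_sp) n_pher--;
    n_by_sp[sp[i]]--;
    sp[i] = -1;
    need_compact = true;
  }

  void compact() {
    if (!need_compact) return;
    need_compact = false;
    int m = n();
    for (int i = 0; i < m;) {
      if (sp[i] < 0) {
        --m;
        sp[i] = sp[m]; x[i] = x[m]; y[i] = y[m]; z[i] = z[m];
        id[i] = id[m]; stamp[i] = stamp[m];
      } else {
        ++i;
      }
    }
    sp.resize(m); x.resize(m); y.resize(m); z.resize(m);
    id.resize(m); stamp.resize(m);
  }

  // ---- placement on species change -----------------------------------
  // Keep the particle's angular coordinate; move it radially onto the
  // compartment it now belongs to (sphere mode only).
  void adjust_compartment(int i, int oldc) {
    if (plane) return;
    int newc = comp[sp[i]];
    if (newc == oldc) return;
    if (newc == COMP_MEMBRANE) {
      project_to_sphere(i);
    } else if (newc == COMP_EXTRA) {
      project_to_sphere(i);
      double f = (R + offset) / R;
      x[i] *= f; y[i] *= f; z[i] *= f;
    }
    // membrane -> cytosol: position on the surface is a valid cytosolic
    // position; the particle diffuses inward afterwards.
  }

  void change_species(int i, int s_new) {
    int oldc = comp[sp[i]];
    if (sp[i] == pher_sp) n_pher--;
    if (s_new == pher_sp) n_pher++;
    n_by_sp[sp[i]]--;
    n_by_sp[s_new]++;
    sp[i] = s_new;
    adjust_compartment(i, oldc);
  }

  // Place a dissociation product at `offset` from the parent position.
  void spawn_offspring(int parent, int s_new) {
    double px = x[parent], py = y[parent], pz = z[parent];
    if (plane) {
      double a = 2 * M_PI * rng.unif();
      px += offset * std::cos(a);
      py += offset * std::sin(a);
      wrap(px); wrap(py);
      add_particle(s_new, px, py, 0.0);
      return;
    }
    int c = comp[s_new];
    double r = std::sqrt(px * px + py * py + pz * pz);
    if (r < 1e-12) r = R;
    if (c == COMP_CYTOSOL) {
      double f = std::max(0.0, (r - offset)) / r;
      add_particle(s_new, px * f, py * f, pz * f);
    } else if (c == COMP_EXTRA) {
      double f = (r + offset) / r;
      add_particle(s_new, px * f, py * f, pz * f);
    } else {
      // membrane: random tangent direction, chord step, re-project
      double ux = px / r, uy = py / r, uz = pz / r;
      double gx = rng.gauss(), gy = rng.gauss(), gz = rng.gauss();
      double d = gx * ux + gy * uy + gz * uz;
      gx -= d * ux; gy -= d * uy; gz -= d * uz;
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (gn < 1e-12) { gx = -uy; gy = ux; gz = 0; gn = std::sqrt(gx * gx + gy * gy); }
      double qx = px + offset * gx / gn, qy = py + offset * gy / gn,
             qz = pz + offset * gz / gn;
      double qr = std::sqrt(qx * qx + qy * qy + qz * qz);
      add_particle(s_new, qx / qr * R, qy / qr * R, qz / qr * R);
    }
  }

  // ---- per-step phases ------------------------------------------------

  void emit_phase() {
    if (emit_rate <= 0) return;
    boost::random::poisson_distribution<int> pois(emit_rate * dt);
    int k = pois(rng.gen);
    for (int j = 0; j < k; ++j) add_particle(pher_sp, src_x, src_y, src_z);
  }

  void respawn_bath() {
    // uniform position in the shell R < r < R_absorb, outside the emitter
    for (int tries = 0; tries < 1000; ++tries) {
      double gx = rng.gauss(), gy = rng.gauss(), gz = rng.gauss();
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (gn < 1e-12) continue;
      double u = rng.unif();
      double r3 = R * R * R + u * (R_absorb * R_absorb * R_absorb - R * R * R);
      double r = std::cbrt(r3);
      double px = gx / gn * r, py = gy / gn * r, pz = gz / gn * r;
      if (has_emitter) {
        double dx = px - ex, dy = py - ey, dz = pz - ez;
        if (dx * dx + dy * dy + dz * dz < eR * eR) continue;
      }
      add_particle(pher_sp, px, py, pz);
      return;
    }
  }

  void lose_pheromone(int i) {
    kill(i);
    if (bath_target >= 0 && n_pher < bath_target) respawn_bath();
  }

  void diffuse_phase() {
    int m = n();
    if (plane) {
      for (int i = 0; i < m; ++i) {
        int spi = sp[i];
        if (dstride[spi] > 1 && (step_no % dstride[spi]) != 0) continue;
        double s = sd_stride[spi];
        if (s <= 0) continue;
        x[i] += s * rng.gauss();
        y[i] += s * rng.gauss();
        wrap(x[i]); wrap(y[i]);
      }
      return;
    }
    for (int i = 0; i < m; ++i) {
      int spi = sp[i];
      if (dstride[spi] > 1 && (step_no % dstride[spi]) != 0) continue;
      double s = sd_stride[spi];
      if (s <= 0) continue;
      int c = comp[spi];
      if (c == COMP_MEMBRANE) {
        // tangent-plane Gaussian step, then radial re-projection
        double ux = x[i] * invR, uy = y[i] * invR, uz = z[i] * invR;
        double gx = rng.gauss(), gy = rng.gauss(), gz = rng.gauss();
        double d = gx * ux + gy * uy + gz * uz;
        x[i] += s * (gx - d * ux);
        y[i] += s * (gy - d * uy);
        z[i] += s * (gz - d * uz);
        project_to_sphere(i);
      } else if (c == COMP_CYTOSOL) {
        x[i] += s * rng.gauss();
        y[i] += s * rng.gauss();
        z[i] += s * rng.gauss();
        double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (r > R && r > 1e-12) { // reflect at the membrane
          double f = (2 * R - r) / r;
          if (f < 0) f = 0; // pathological overshoot: clamp to center
          x[i] *= f; y[i] *= f; z[i] *= f;
        }
      } else { // extracellular
        x[i] += s * rng.gauss();
        y[i] += s * rng.gauss();
        z[i] += s * rng.gauss();
        double r2 = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
        double r = std::sqrt(r2);
        if (R_absorb > 0 && r > R_absorb) {
          if (absorb_on) { // absorbed at the outer shell
            lose_pheromone(i);
            continue;
          }
          // uniform-bath protocol: closed domain, shell reflects
          double f = (2 * R_absorb - r) / r;
          x[i] *= f; y[i] *= f; z[i] *= f;
          r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        }
        if (r < R && r > 1e-12) { // reflect off the receiver cell
          double f = (2 * R - r) / r;
          x[i] *= f; y[i] *= f; z[i] *= f;
        }
        if (has_emitter) {
          double dx = x[i] - ex, dy = y[i] - ey, dz = z[i] - ez;
          double dr = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (dr < eR && dr > 1e-12) { // reflect off the emitter cell
            double f = (2 * eR - dr) / dr;
            x[i] = ex + dx * f; y[i] = ey + dy * f; z[i] = ez + dz * f;
          }
        }
      }
    }
  }

  double field_lookup(int i) const {
    // linear interpolation of the field-channel probability in cos(theta)
    double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
    double c = (r < 1e-12) ? 1.0 : (x[i] * fx + y[i] * fy + z[i] * fz) / r;
    size_t m = field_cos.size();
    if (c <= field_cos.front()) return field_prob.front();
    if (c >= field_cos.back()) return field_prob.back();
    size_t lo = 0, hi = m - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (field_cos[mid] <= c) lo = mid; else hi = mid;
    }
    double w = (c - field_cos[lo]) / (field_cos[hi] - field_cos[lo]);
    return field_prob[lo] * (1 - w) + field_prob[hi] * w;
  }

  // Exact thinning: every particle is a first-order candidate with
  // probability P_fo_max (the largest per-species total firing probability),
  // realized as a Binomial count plus a uniform without-replacement pick;
  // candidates then fire their species' channels at the true probabilities.
  double P_fo_max = 0.0;
  std::vector<double> fo_tot; // per-species upper bound on total fo prob
  std::vector<int> picked;

  void first_order_phase() {
    if (P_fo_max <= 0) return;
    int m = n();
    if (m == 0) return;
    boost::random::binomial_distribution<int> binom(m, P_fo_max);
    int k = binom(rng.gen);
    if (k <= 0) return;
    picked.clear();
    for (int e = 0; e < k; ++e) {
      int i;
      bool dup;
      do {
        i = rng.below(m);
        dup = false;
        for (size_t q = 0; q < picked.size(); ++q) {
          if (picked[q] == i) { dup = true; break; }
        }
      } while (dup);
      picked.push_back(i);
      int spi = sp[i];
      if (spi < 0 || !fo_any[spi] || stamp[i] == step_no) continue;
      double u = rng.unif() * P_fo_max;
      double cum = 0.0;
      const std::vector<int> &ch = fo_by_sp[spi];
      for (size_t c = 0; c < ch.size(); ++c) {
        int r = ch[c];
        cum += fo_field[r] ? field_lookup(i) : fo_prob[r];
        if (u < cum) {
          stamp[i] = step_no;
          change_species(i, fo_p1[r]);
          if (fo_p2[r] >= 0) spawn_offspring(i, fo_p2[r]);
          break;
        }
      }
    }
  }

  // ---- neighbor grid --------------------------------------------------

  void setup_grid(double rho_max) {
    if (plane) {
      // cell ~ 2 rho keeps the cell-count array cache-resident for the
      // counting-sort scan
      ncx = std::max(3, (int)std::floor(L / (2 * rho_max)));
      cell = L / ncx; // >= rho_max
      inv_cell = 1.0 / cell;
      ncy = ncx; ncz = 1;
      gx0 = 0; gy0 = 0; gz0 = 0;
    } else {
      double ext = (R_absorb > 0) ? R_absorb : R;
      ext += 4 * offset;
      int maxdim = 128;
      cell = std::max(rho_max, 2 * ext / maxdim);
      ncx = std::max(3, (int)std::ceil(2 * ext / cell));
      inv_cell = 1.0 / cell;
      ncy = ncx; ncz = ncx;
      gx0 = -ext; gy0 = -ext; gz0 = -ext;
      head.assign((size_t)ncx * ncy * ncz, -1);
    }
  }

  inline int cell_of(int i) const {
    if (plane) {
      int cx = (int)((x[i] - gx0) * inv_cell); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
      int cy = (int)((y[i] - gy0) * inv_cell); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
      return cy * ncx + cx;
    }
    int cx = (int)((x[i] - gx0) * inv_cell); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)((y[i] - gy0) * inv_cell); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    int cz = (int)((z[i] - gz0) * inv_cell); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
    return (cz * ncy + cy) * ncx + cx;
  }

  double dist2(int i, int j) const {
    double dx = x[i] - x[j], dy = y[i] - y[j];
    if (plane) {
      // minimum image under periodicity
      if (dx > 0.5 * L) dx -= L; else if (dx < -0.5 * L) dx += L;
      if (dy > 0.5 * L) dy -= L; else if (dy < -0.5 * L) dy += L;
      return dx * dx + dy * dy;
    }
    double dz = z[i] - z[j];
    return dx * dx + dy * dy + dz * dz; // Euclidean chord
  }

  struct Cand { int i, j, rxn; bool swapped; };
  std::vector<Cand> cands;
  std::vector<int> cellidx, active;
  // counting-sort grid buffers (plane)
  std::vector<int> cstart, cfill, sorder, scell, ssp2, kcell;
  std::vector<double> sx, sy;
  // asymmetric scan: per step each reaction designates its currently rarer
  // reactant species as the scanner; only scanner particles probe the grid
  // (full neighborhood), so scan cost tracks the rare species' abundance
  std::vector<int> n_by_sp, scan_key;
  std::vector<char> is_scanner, is_target;

  void assign_scanners() {
    scan_key.assign((size_t)nsp * nsp, 0);
    is_scanner.assign(nsp, 0);
    is_target.assign(nsp, 0);
    for (size_t r = 0; r < so_prob.size(); ++r) {
      int r1 = so_r1v[r], r2 = so_r2v[r];
      if (n_by_sp[r1] == 0 || n_by_sp[r2] == 0) continue; // nothing to pair
      int s = (n_by_sp[r1] <= n_by_sp[r2]) ? r1 : r2;
      int t = (s == r1) ? r2 : r1;
      if (scan_key[s * nsp + t]) std::swap(s, t); // slot taken: other side scans
      if (scan_key[s * nsp + t]) {
        Rcpp::stop("two bimolecular reactions share the same species pair");
      }
      scan_key[s * nsp + t] = (int)r * 2 + (s == so_r2v[r] ? 1 : 0) + 1;
      is_scanner[s] = 1;
      is_target[t] = 1;
    }
  }

  inline void try_pair(int i, int j) {
    if (j == i) return;
    int key = scan_key[sp[i] * nsp + sp[j]];
    if (!key) return;
    int enc = key - 1;
    int rxn = enc >> 1;
    if (dist2(i, j) <= so_rho2[rxn]) {
      cands.push_back({i, j, rxn, (enc & 1) != 0});
    }
  }

  // Counting-sort cell grid over the current target species only; scanner
  // particles (the rarer reactant of each reaction) probe their 3x3
  // neighborhood as three contiguous row ranges. Each reaction is examined
  // from its scanner side exactly once per pair.
  std::vector<int> scanners;

  inline void probe_row(int i, int spi, int row, int cx) {
    // cells (cx-1, cx, cx+1) of `row`, contiguous unless wrapping
    if (cx >= 1 && cx <= ncx - 2) {
      int c0 = row * ncx + cx - 1;
      for (int b = cstart[c0]; b < cstart[c0 + 3]; ++b) try_pair_mixed(i, spi, b);
    } else {
      for (int ox = -1; ox <= 1; ++ox) {
        int nx = (cx + ox + ncx) % ncx;
        int cc = row * ncx + nx;
        for (int b = cstart[cc]; b < cstart[cc + 1]; ++b) try_pair_mixed(i, spi, b);
      }
    }
  }

  inline void try_pair_mixed(int i, int spi, int b) {
    int j = sorder[b];
    if (j == i) return;
    int key = scan_key[spi * nsp + ssp2[b]];
    if (!key) return;
    double dx = x[i] - sx[b], dy = y[i] - sy[b];
    if (dx > 0.5 * L) dx -= L; else if (dx < -0.5 * L) dx += L;
    if (dy > 0.5 * L) dy -= L; else if (dy < -0.5 * L) dy += L;
    int enc = key - 1, rxn = enc >> 1;
    if (dx * dx + dy * dy <= so_rho2[rxn]) {
      cands.push_back({i, j, rxn, (enc & 1) != 0});
    }
  }

  void second_order_plane() {
    int m = n();
    assign_scanners();
    active.clear();
    scanners.clear();
    for (int i = 0; i < m; ++i) {
      int spi = sp[i];
      if (spi < 0) continue;
      if (is_target[spi]) active.push_back(i);
      if (is_scanner[spi]) scanners.push_back(i);
    }
    if (scanners.empty()) return;
    int M = (int)active.size();
    int ncell = ncx * ncy;
    cstart.assign(ncell + 1, 0);
    scell.resize(M);
    for (int a = 0; a < M; ++a) {
      int c = cell_of(active[a]);
      scell[a] = c;
      cstart[c + 1]++;
    }
    for (int c = 0; c < ncell; ++c) cstart[c + 1] += cstart[c];
    cfill.assign(cstart.begin(), cstart.end() - 1);
    sorder.resize(M); sx.resize(M); sy.resize(M); ssp2.resize(M);
    for (int a = 0; a < M; ++a) {
      int i = active[a], c = scell[a];
      int k = cfill[c]++;
      sorder[k] = i; sx[k] = x[i]; sy[k] = y[i]; ssp2[k] = sp[i];
    }
    cands.clear();
    for (size_t s = 0; s < scanners.size(); ++s) {
      int i = scanners[s];
      int spi = sp[i];
      int c = cell_of(i);
      int cx = c % ncx, cy = c / ncx;
      for (int oy = -1; oy <= 1; ++oy) {
        probe_row(i, spi, (cy + oy + ncy) % ncy, cx);
      }
    }
    process_candidates();
  }

  void process_candidates() {
    int nc = (int)cands.size();
    for (int k = nc - 1; k > 0; --k) {
      int j = rng.below(k + 1);
      std::swap(cands[k], cands[j]);
    }
    for (int k = 0; k < nc; ++k) {
      const Cand &cd = cands[k];
      if (stamp[cd.i] == step_no || stamp[cd.j] == step_no) continue;
      if (sp[cd.i] < 0 || sp[cd.j] < 0) continue;
      if (rng.unif() >= so_prob[cd.rxn]) continue;
      int a = cd.swapped ? cd.j : cd.i; // role r1
      int b = cd.swapped ? cd.i : cd.j; // role r2
      apply_second_order(cd.rxn, a, b);
    }
  }

  void second_order_phase() {
    if (well_mixed) { second_order_well_mixed(); return; }
    if (plane) { second_order_plane(); return; }
    int m = n();
    assign_scanners();
    nxt.resize(m);
    touched.clear();
    scanners.clear();
    for (int i = 0; i < m; ++i) {
      int spi = sp[i];
      if (spi < 0) continue;
      if (is_scanner[spi]) scanners.push_back(i);
      if (!is_target[spi]) continue;
      int c = cell_of(i);
      nxt[i] = head[c];
      head[c] = i;
      touched.push_back(c);
    }
    if (scanners.empty() || so_rho2.empty()) {
      for (size_t t = 0; t < touched.size(); ++t) head[touched[t]] = -1;
      return;
    }
    // when every target species is membrane-bound, cytosolic scanners
    // farther than rho from the surface cannot have a partner in range
    bool tgt_membrane = true;
    for (int s = 0; s < nsp; ++s) {
      if (is_target[s] && comp[s] != COMP_MEMBRANE) tgt_membrane = false;
    }
    double rho_m = std::sqrt(
      *std::max_element(so_rho2.begin(), so_rho2.end()));
    double rmin2 = (R - rho_m) * (R - rho_m);
    cands.clear();
    // scanner particles probe their full 3x3x3 neighborhood
    for (size_t a = 0; a < scanners.size(); ++a) {
      int i = scanners[a];
      if (tgt_membrane && comp[sp[i]] != COMP_MEMBRANE) {
        double r2 = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
        if (r2 < rmin2) continue;
      }
      int ci = cell_of(i);
      int cx = ci % ncx, cy = (ci / ncx) % ncy, cz = ci / (ncx * ncy);
      for (int oz = -1; oz <= 1; ++oz) {
        int nz = cz + oz;
        if (nz < 0 || nz >= ncz) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int ny = cy + oy;
          if (ny < 0 || ny >= ncy) continue;
          for (int ox = -1; ox <= 1; ++ox) {
            int nx = cx + ox;
            if (nx < 0 || nx >= ncx) continue;
            int cc = (nz * ncy + ny) * ncx + nx;
            for (int j = head[cc]; j >= 0; j = nxt[j]) try_pair(i, j);
          }
        }
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) head[touched[t]] = -1;
    process_candidates();
  }

  void apply_second_order(int rxn, int a, int b) {
    stamp[a] = step_no;
    stamp[b] = step_no;
    if (so_pb[rxn] >= 0) { // two products: in-place species changes
      if (sp[a] != so_pa[rxn]) change_species(a, so_pa[rxn]);
      if (sp[b] != so_pb[rxn]) change_species(b, so_pb[rxn]);
    } else { // binding: single product at the anchor reactant's position
      int keep = (so_anchor[rxn] == 1) ? b : a;
      int gone = (keep == a) ? b : a;
      change_species(keep, so_pa[rxn]);
      if (sp[gone] == pher_sp) {
        lose_pheromone(gone);
      } else {
        kill(gone);
      }
    }
  }

  // Spatial gate removed: every reactant pair is a candidate with hazard
  // scaled by the ratio of the reaction area to the domain area, so that
  // the well-mixed mass-action flux matches the spatial engine's. Used as
  // an oracle for reaction bookkeeping (plane geometry only).
  void second_order_well_mixed() {
    double A = L * L;
    int nrxn = (int)so_prob.size();
    std::vector<std::vector<int>> by_sp(nsp);
    int m = n();
    for (int i = 0; i < m; ++i) {
      if (sp[i] >= 0 && so_active[sp[i]]) by_sp[sp[i]].push_back(i);
    }
    for (int r = 0; r < nrxn; ++r) {
      if (so_prob[r] <= 0 || so_rho2[r] <= 0) continue;
      int s1 = -1, s2 = -1;
      for (int a = 0; a < nsp && s1 < 0; ++a) {
        for (int bsp = 0; bsp < nsp; ++bsp) {
          int key = so_key[a * nsp + bsp];
          if (key && ((key - 1) >> 1) == r && !((key - 1) & 1)) {
            s1 = a; s2 = bsp;
            break;
          }
        }
      }
      if (s1 < 0) continue;
      double frac = M_PI * so_rho2[r] / A; // P(pair within rho), uniform
      double mean_events = frac * so_prob[r] *
        (double)by_sp[s1].size() * (double)by_sp[s2].size();
      if (mean_events <= 0) continue;
      boost::random::poisson_distribution<int> pois(mean_events);
      int k = pois(rng.gen);
      for (int e = 0; e < k; ++e) {
        if (by_sp[s1].empty() || by_sp[s2].empty()) break;
        int a = by_sp[s1][rng.below((int)by_sp[s1].size())];
        int b = by_sp[s2][rng.below((int)by_sp[s2].size())];
        if (a == b) continue;
        if (stamp[a] == step_no || stamp[b] == step_no) continue;
        if (sp[a] != s1 || sp[b] != s2) continue;
        apply_second_order(r, a, b);
      }
    }
  }

  void step() {
    ++step_no;
    emit_phase();
    if (!well_mixed) diffuse_phase();
    first_order_phase();
    second_order_phase();
    compact();
  }
};

Engine *make_engine(const List &cfg, const List &state, uint64_t seed) {
  Engine *E = new Engine(seed);
  E->plane = as<std::string>(cfg["mode"]) == "plane2d";
  E->dt = as<double>(cfg["dt"]);
  E->offset = as<double>(cfg["offset"]);
  if (E->plane) {
    E->L = as<double>(cfg["L"]);
  } else {
    E->R = as<double>(cfg["R"]);
    E->invR = 1.0 / E->R;
    E->R_absorb = as<double>(cfg["R_absorb"]);
  }
  E->nsp = as<int>(cfg["nsp"]);
  NumericVector D = cfg["D"];
  IntegerVector comp = cfg["comp"];
  for (int s = 0; s < E->nsp; ++s) {
    E->sd_step.push_back(std::sqrt(2.0 * D[s] * E->dt));
    E->comp.push_back(comp[s]);
  }

  IntegerVector fo_sp = cfg["fo_sp"], fo_p1 = cfg["fo_p1"], fo_p2 = cfg["fo_p2"];
  NumericVector fo_prob = cfg["fo_prob"];
  LogicalVector fo_field = cfg["fo_field"];
  E->fo_by_sp.assign(E->nsp, {});
  E->fo_any.assign(E->nsp, 0);
  for (int r = 0; r < fo_sp.size(); ++r) {
    E->fo_prob.push_back(fo_prob[r]);
    E->fo_p1.push_back(fo_p1[r]);
    E->fo_p2.push_back(fo_p2[r]);
    E->fo_field.push_back(fo_field[r] ? 1 : 0);
    E->fo_by_sp[fo_sp[r]].push_back(r);
    E->fo_any[fo_sp[r]] = 1;
  }

  IntegerVector so_r1 = cfg["so_r1"], so_r2 = cfg["so_r2"];
  IntegerVector so_pa = cfg["so_pa"], so_pb = cfg["so_pb"], so_anchor = cfg["so_anchor"];
  NumericVector so_prob = cfg["so_prob"], so_rho = cfg["so_rho"];
  E->so_key.assign((size_t)E->nsp * E->nsp, 0);
  E->so_active.assign(E->nsp, 0);
  double rho_max = 0.0;
  for (int r = 0; r < so_r1.size(); ++r) {
    E->so_r1v.push_back(so_r1[r]);
    E->so_r2v.push_back(so_r2[r]);
    E->so_prob.push_back(so_prob[r]);
    E->so_rho2.push_back(so_rho[r] * so_rho[r]);
    E->so_pa.push_back(so_pa[r]);
    E->so_pb.push_back(so_pb[r]);
    E->so_anchor.push_back(so_anchor[r]);
    E->so_key[so_r1[r] * E->nsp + so_r2[r]] = r * 2 + 0 + 1;
    if (so_r2[r] != so_r1[r]) {
      E->so_key[so_r2[r] * E->nsp + so_r1[r]] = r * 2 + 1 + 1;
    }
    E->so_active[so_r1[r]] = 1;
    E->so_active[so_r2[r]] = 1;
    rho_max = std::max(rho_max, (double)so_rho[r]);
  }

  E->well_mixed = as<bool>(cfg["well_mixed"]);
  E->pher_sp = as<int>(cfg["pher_sp"]);

  if (cfg.containsElementNamed("emitter") && !Rf_isNull(cfg["emitter"])) {
    NumericVector em = cfg["emitter"];
    E->has_emitter = true;
    E->ex = em[0]; E->ey = em[1]; E->ez = em[2]; E->eR = em[3];
  }
  if (cfg.containsElementNamed("emission") && !Rf_isNull(cfg["emission"])) {
    NumericVector es = cfg["emission"];
    E->emit_rate = es[0];
    E->src_x = es[1]; E->src_y = es[2]; E->src_z = es[3];
  }
  E->bath_target = as<int>(cfg["bath_target"]);
  E->absorb_on = as<bool>(cfg["absorb_on"]);

  if (cfg.containsElementNamed("field") && !Rf_isNull(cfg["field"])) {
    List fl = cfg["field"];
    E->has_field = true;
    NumericVector ax = fl["axis"];
    E->fx = ax[0]; E->fy = ax[1]; E->fz = ax[2];
    NumericVector fc = fl["cos"], fp = fl["prob"];
    E->field_cos.assign(fc.begin(), fc.end());
    E->field_prob.assign(fp.begin(), fp.end());
  }

  {
    double rr = (rho_max > 0) ? rho_max : 0.05;
    for (int s = 0; s < E->nsp; ++s) {
      int st = (E->sd_step[s] > 0 && E->sd_step[s] < 1e-3 * rr) ? 20 : 1;
      E->dstride.push_back(st);
      E->sd_stride.push_back(E->sd_step[s] * std::sqrt((double)st));
    }
  }

  // per-species total first-order probability bound (field channels enter
  // with their maximal ring probability) for the thinning sampler
  E->fo_tot.assign(E->nsp, 0.0);
  for (int s = 0; s < E->nsp; ++s) {
    for (size_t c = 0; c < E->fo_by_sp[s].size(); ++c) {
      int r = E->fo_by_sp[s][c];
      double p = E->fo_prob[r];
      if (E->fo_field[r] && !E->field_prob.empty()) {
        p = *std::max_element(E->field_prob.begin(), E->field_prob.end());
      }
      E->fo_tot[s] += p;
    }
  }
  E->P_fo_max = 0.0;
  for (int s = 0; s < E->nsp; ++s) {
    E->P_fo_max = std::max(E->P_fo_max, E->fo_tot[s]);
  }

  if (rho_max <= 0) rho_max = E->offset;
  E->setup_grid(rho_max);

  E->n_by_sp.assign(E->nsp, 0);
  IntegerVector ssp = state["species"];
  NumericMatrix pos = state["pos"];
  for (int i = 0; i < ssp.size(); ++i) {
    E->n_by_sp[ssp[i]]++;
    E->sp.push_back(ssp[i]);
    E->x.push_back(pos(i, 0));
    E->y.push_back(pos(i, 1));
    E->z.push_back(E->plane ? 0.0 : pos(i, 2));
    E->id.push_back(E->next_id++);
    E->stamp.push_back(-1);
    if (ssp[i] == E->pher_sp) E->n_pher++;
  }
  return E;
}

List snapshot(const Engine &E) {
  int m = E.n();
  IntegerVector ssp(m), sid(m);
  NumericMatrix pos(m, E.plane ? 2 : 3);
  for (int i = 0; i < m; ++i) {
    ssp[i] = E.sp[i];
    sid[i] = E.id[i];
    pos(i, 0) = E.x[i];
    pos(i, 1) = E.y[i];
    if (!E.plane) pos(i, 2) = E.z[i];
  }
  return List::create(_["species"] = ssp, _["id"] = sid, _["pos"] = pos);
}

} // namespace

// [[Rcpp::export(name = ".ps_run")]]
List ps_run(List cfg, List state, double t_end, double record_every,
            double seed) {
  Engine *E = make_engine(cfg, state, (uint64_t)seed);
  double dt = E->dt;
  long long nsteps = (long long)std::llround(t_end / dt);
  long long rec = (long long)std::llround(record_every / dt);
  if (rec < 1) rec = 1;
  int nsnap = (int)(nsteps / rec) + 1;
  List snaps(nsnap);
  NumericVector times(nsnap);
  snaps[0] = snapshot(*E);
  times[0] = 0.0;
  int si = 1;
  for (long long s = 1; s <= nsteps; ++s) {
    E->step();
    if (s % rec == 0) {
      snaps[si] = snapshot(*E);
      times[si] = s * dt;
      ++si;
      if (si % 8 == 0) Rcpp::checkUserInterrupt();
    }
  }
  List out = List::create(_["times"] = times, _["snapshots"] = snaps);
  delete E;
  return out;
}

// [[Rcpp::export(name = ".ps_pair_hist_2d")]]
NumericVector ps_pair_hist_2d(NumericMatrix pts, double L, int nbins,
                              double rmax) {
  // ordered-pair counts of minimum-image distances, binned on [0, rmax]
  int n = pts.nrow();
  NumericVector h(nbins);
  double binw = rmax / nbins;
  for (int i = 1; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1);
    for (int j = 0; j < i; ++j) {
      double dx = xi - pts(j, 0), dy = yi - pts(j, 1);
      if (dx > 0.5 * L) dx -= L; else if (dx < -0.5 * L) dx += L;
      if (dy > 0.5 * L) dy -= L; else if (dy < -0.5 * L) dy += L;
      double d = std::sqrt(dx * dx + dy * dy);
      int b = (int)(d / binw);
      if (b >= nbins) b = nbins - 1;
      h[b] += 2.0; // both ordered pairs
    }
  }
  return h;
}

// [[Rcpp::export(name = ".ps_pair_hist_3d")]]
NumericVector ps_pair_hist_3d(NumericMatrix pts, double R, int nbins,
                              double rmax) {
  // ordered-pair counts of geodesic distances on the sphere of radius R
  int n = pts.nrow();
  NumericVector h(nbins);
  double binw = rmax / nbins;
  for (int i = 1; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < i; ++j) {
      double c = (xi * pts(j, 0) + yi * pts(j, 1) + zi * pts(j, 2)) / (R * R);
      if (c > 1) c = 1; else if (c < -1) c = -1;
      double d = R * std::acos(c);
      int b = (int)(d / binw);
      if (b >= nbins) b = nbins - 1;
      h[b] += 2.0;
    }
  }
  return h;
}
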