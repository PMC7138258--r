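// 2-D voxel-grid Monte Carlo photon transport for photoacoustic fluence
// simulation. Each scan slice is an independent (x, z) problem: photons enter
// at the z = 0 surface and are tracked with the classic hop/drop/spin scheme
// on a regular grid (mcxyz-style substeps at voxel boundaries).
//
// Two fluence estimators are scored in a single pass:
//   * track-length:  phi(v) = sum(w * path length in v) / (h^2 * N)
//   * deposition:    phi(v) = sum(w * mu_a/mu_t at collisions in v) / (mu_a * h^2 * N)
// plus an exact energy ledger (launched + roulette_gain =
// deposited + exited + roulette_lost) used by the conservation tests.
//
// All randomness comes from a PCG32 stream seeded from R, so runs are
// bit-for-bit reproducible for a fixed (seed, batch schedule).
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t stream) {
    state = 0u;
    inc = (stream << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform in the open interval (0, 1)
  double runif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

const double W_MIN = 1e-4;      // Russian roulette threshold weight
const double P_SURVIVE = 0.1;   // roulette survival probability

struct Ledger {
  double deposited = 0.0, exited = 0.0, rlost = 0.0, rgain = 0.0;
};

// Per-photon tracer. Scores track length into `track`, collision deposits
// into `dep`. If `stamp`/`visited` are non-null, records each voxel at most
// once per photon (photon id = `pid`).
inline void trace_photon(const double* mu_a, const double* mu_s,
                         int nx, int nz, double h,
                         double x, double z, double ux, double uz,
                         Pcg32& rng, double* track, double* dep, Ledger& led,
                         int* stamp, int* visited, int* n_visited, int pid) {
  double w = 1.0;
  int ix = (int)std::floor(x / h);
  int iz = (int)std::floor(z / h);
  double sleft = -std::log(rng.runif());
  const double INF = std::numeric_limits<double>::infinity();

  for (;;) {
    if (ix < 0 || ix >= nx || iz < 0 || iz >= nz) { led.exited += w; return; }
    int v = ix + nx * iz;
    double ma = mu_a[v], ms = mu_s[v];
    double mt = ma + ms;

    // distance to the next voxel boundary along (ux, uz)
    double dbx = INF, dbz = INF;
    if (ux > 0)      dbx = ((ix + 1) * h - x) / ux;
    else if (ux < 0) dbx = (ix * h - x) / ux;
    if (uz > 0)      dbz = ((iz + 1) * h - z) / uz;
    else if (uz < 0) dbz = (iz * h - z) / uz;
    bool cross_x = dbx < dbz;
    double db = cross_x ? dbx : dbz;
    if (db < 0) db = 0;  // numerical guard

    if (mt * db < sleft) {
      // hop to the boundary
      if (track) track[v] += w * db;
      if (stamp && stamp[v] != pid) { stamp[v] = pid; visited[(*n_visited)++] = v; }
      x += db * ux; z += db * uz;
      sleft -= mt * db;
      if (cross_x) ix += (ux > 0) ? 1 : -1; else iz += (uz > 0) ? 1 : -1;
    } else {
      // collision inside this voxel
      double d = sleft / mt;
      if (track) track[v] += w * d;
      if (stamp && stamp[v] != pid) { stamp[v] = pid; visited[(*n_visited)++] = v; }
      x += d * ux; z += d * uz;
      double dw = w * ma / mt;
      if (dep) dep[v] += dw;
      led.deposited += dw;
      w -= dw;
      if (w <= 0) return;  // pure absorber: photon terminated
      double th = 2.0 * M_PI * rng.runif();
      ux = std::cos(th); uz = std::sin(th);
      sleft = -std::log(rng.runif());
      if (w < W_MIN) {
        if (rng.runif() < P_SURVIVE) {
          led.rgain += w * (1.0 / P_SURVIVE - 1.0);
          w /= P_SURVIVE;
        } else {
          led.rlost += w;
          return;
        }
      }
    }
  }
}

// Source sampling. type: 0 = pencil at x0, 1 = line spanning the full lateral
// width, 2 = slab spanning [x0, x1]. All sources sit on z = 0 and point +z.
inline void sample_source(int type, double x0, double x1, double width,
                          Pcg32& rng, double& x, double& z,
                          double& ux, double& uz) {
  if (type == 0) x = x0;
  else if (type == 1) x = rng.runif() * width;
  else x = x0 + rng.runif() * (x1 - x0);
  z = 0.0;
  ux = 0.0; uz = 1.0;
}

} // namespace

// [[Rcpp::export]]
List mc_fluence_cpp(NumericMatrix mu_a, NumericMatrix mu_s, double spacing,
                    int source_type, double src_x0, double src_x1,
                    double n_photons, int n_batches, int seed) {
  int nx = mu_a.nrow(), nz = mu_a.ncol();
  int nvox = nx * nz;
  double width = nx * spacing;
  long long N = (long long)n_photons;
  if (n_batches < 1) n_batches = 1;

  std::vector<double> track(nvox, 0.0), dep(nvox, 0.0), btrack(nvox, 0.0);
  std::vector<double> m1(nvox, 0.0), m2(nvox, 0.0);  // batch-mean moments
  Ledger led;
  Pcg32 rng((uint64_t)(uint32_t)seed, 0x9e3779b97f4a7c15ULL);

  long long per_batch = N / n_batches;
  double h2 = spacing * spacing;
  for (int b = 0; b < n_batches; ++b) {
    long long nb = per_batch + (b == n_batches - 1 ? N - per_batch * n_batches : 0);
    std::fill(btrack.begin(), btrack.end(), 0.0);
    for (long long i = 0; i < nb; ++i) {
      double x, z, ux, uz;
      sample_source(source_type, src_x0, src_x1, width, rng, x, z, ux, uz);
      trace_photon(&mu_a[0], &mu_s[0], nx, nz, spacing, x, z, ux, uz,
                   rng, btrack.data(), dep.data(), led,
                   nullptr, nullptr, nullptr, 0);
    }
    for (int v = 0; v < nvox; ++v) {
      track[v] += btrack[v];
      double bm = btrack[v] / ((double)nb * h2);  // batch fluence estimate
      m1[v] += bm;
      m2[v] += bm * bm;
    }
  }

  NumericMatrix phi_track(nx, nz), phi_se(nx, nz), dep_out(nx, nz);
  double B = (double)n_batches;
  for (int v = 0; v < nvox; ++v) {
    phi_track[v] = track[v] / ((double)N * h2);
    dep_out[v] = dep[v];
    if (n_batches > 1) {
      double mean = m1[v] / B;
      double var = (m2[v] / B - mean * mean) * B / (B - 1.0);
      phi_se[v] = std::sqrt(std::max(var, 0.0) / B);
    } else phi_se[v] = NA_REAL;
  }
  return List::create(
    _["phi_track"] = phi_track, _["phi_se"] = phi_se, _["deposit"] = dep_out,
    _["ledger"] = NumericVector::create(
      _["launched"] = (double)N, _["deposited"] = led.deposited,
      _["exited"] = led.exited, _["roulette_lost"] = led.rlost,
      _["roulette_gain"] = led.rgain));
}

// Single-target fluence contribution map in homogeneous background tissue.
// Photons are launched in batches until at least `min_hits` distinct photons
// have traversed the target voxel; FCM(v') = P(photon passed v' | passed v),
// each photon counted once per voxel.
// [[Rcpp::export]]
List mc_fcm_cpp(int target, double bg_mu_a, double bg_mu_s,
                int nx, int nz, double spacing,
                int source_type, double src_x0, double src_x1,
                int min_hits, double batch_photons, int max_batches, int seed) {
  int nvox = nx * nz;
  double width = nx * spacing;
  std::vector<double> mu_a(nvox, bg_mu_a), mu_s(nvox, bg_mu_s);
  std::vector<double> num(nvox, 0.0);
  std::vector<int> stamp(nvox, -1), visited(nvox);
  Ledger led;
  Pcg32 rng((uint64_t)(uint32_t)seed, 0xda3e39cb94b95bdbULL);

  long long hits = 0, photons = 0;
  int batches = 0;
  long long nb = (long long)batch_photons;
  int pid = 0;
  while (hits < min_hits && batches < max_batches) {
    for (long long i = 0; i < nb; ++i) {
      ++pid;
      int n_visited = 0;
      double x, z, ux, uz;
      sample_source(source_type, src_x0, src_x1, width, rng, x, z, ux, uz);
      trace_photon(mu_a.data(), mu_s.data(), nx, nz, spacing, x, z, ux, uz,
                   rng, nullptr, nullptr, led,
                   stamp.data(), visited.data(), &n_visited, pid);
      if (stamp[target] == pid) {
        ++hits;
        for (int k = 0; k < n_visited; ++k) num[visited[k]] += 1.0;
      }
    }
    photons += nb;
    ++batches;
  }

  NumericMatrix fcm(nx, nz);
  if (hits > 0)
    for (int v = 0; v < nvox; ++v) fcm[v] = num[v] / (double)hits;
  return List::create(_["fcm"] = fcm, _["hits"] = (double)hits,
                      _["photons"] = (double)photons,
                      _["batches"] = batches);
}

// Whole-bank FCM computation in one shared photon pass: pairwise visit counts
// over all plane voxels accumulate simultaneously, so FCM[v](v') =
// pair(v, v') / denom(v) for every target v at once. Identical estimator to
// mc_fcm_cpp, tractable for nx*nz targets. Stops when the worst-covered voxel
// reaches `min_hits` (or the batch cap).
// [[Rcpp::export]]
List mc_fcm_bank_cpp(double bg_mu_a, double bg_mu_s,
                     int nx, int nz, double spacing,
                     int source_type, double src_x0, double src_x1,
                     int min_hits, double batch_photons, int max_batches,
                     int seed) {
  int n = nx * nz;
  double width = nx * spacing;
  std::vector<double> mu_a(n, bg_mu_a), mu_s(n, bg_mu_s);
  std::vector<int> pair((size_t)n * n, 0);   // upper triangle (a < b) counts
  std::vector<double> denom(n, 0.0);
  std::vector<int> stamp(n, -1), visited(n);
  Ledger led;
  Pcg32 rng((uint64_t)(uint32_t)seed, 0xd1b54a32d192ed03ULL);

  long long photons = 0;
  int batches = 0, pid = 0;
  long long nb = (long long)batch_photons;
  double min_denom = 0.0;
  while (batches < max_batches) {
    for (long long i = 0; i < nb; ++i) {
      ++pid;
      int m = 0;
      double x, z, ux, uz;
      sample_source(source_type, src_x0, src_x1, width, rng, x, z, ux, uz);
      trace_photon(mu_a.data(), mu_s.data(), nx, nz, spacing, x, z, ux, uz,
                   rng, nullptr, nullptr, led,
                   stamp.data(), visited.data(), &m, pid);
      std::sort(visited.begin(), visited.begin() + m);
      for (int j = 0; j < m; ++j) {
        denom[visited[j]] += 1.0;
        size_t base = (size_t)n * visited[j];
        for (int k = 0; k < j; ++k) pair[base + visited[k]]++;
      }
    }
    photons += nb;
    ++batches;
    min_denom = *std::min_element(denom.begin(), denom.end());
    if (min_denom >= min_hits) break;
    Rcpp::checkUserInterrupt();
  }

  // bank: column v holds FCM[v] over the plane
  NumericMatrix bank(n, n);
  for (int vb = 0; vb < n; ++vb) {
    size_t base = (size_t)n * vb;
    double* col = &bank[0] + base;
    for (int va = 0; va < vb; ++va) col[va] = pair[base + va];
    for (int va = vb + 1; va < n; ++va) col[va] = pair[(size_t)n * va + vb];
    col[vb] = denom[vb];
    if (denom[vb] > 0) {
      double inv = 1.0 / denom[vb];
      for (int va = 0; va < n; ++va) col[va] *= inv;
    }
  }
  return List::create(_["bank"] = bank,
                      _["hits"] = NumericVector(denom.begin(), denom.end()),
                      _["min_hits_achieved"] = min_denom,
                      _["photons"] = (double)photons,
                      _["batches"] = batches);
}
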