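// Brownian-dynamics / photophysics simulator for gated STED-FCS.
//
// Physics per excitation pulse for a molecule at min-image radius r from the
// optical axis:
//   excitation probability   p(r)  = p0 * exp(-2 r^2 / w_exc^2)
//   doughnut profile         d(r)  = (2 e r^2 / w_d^2) * exp(-2 r^2 / w_d^2)
//                                    (exact zero on axis, peak 1 at w_d/sqrt2)
//   total decay rate         k_tot = k_fl * (1 + zeta * d(r))
//   microtime ~ Exp(k_tot) (+ optional Gaussian IRF jitter), wrapped into the
//   excitation period; the photon is detected only if the decay was
//   spontaneous (probability k_fl / k_tot) and survives detection_efficiency.
// Triplet crossing blocks excitation for an exponential dark dwell;
// photobleaching silences the molecule, which is re-inserted uniformly at
// random (stationary concentration).  Background photons are Poisson in
// macrotime with uniform microtime.
//
// RNG: xoshiro256++ streams seeded via splitmix64 from the one user seed.
// Every molecule owns separate diffusion / photophysics / bleach
// sub-streams (plus one global background stream), so that raising
// bleach_prob alone perturbs the realization only through the affected
// molecules' lifelines: the first uniform of each molecule's bleach
// stream drives a geometric excitations-to-bleach counter, which is a
// nested coupling (a higher bleach probability bleaches the same
// molecule strictly earlier), while all unbleached molecules reproduce
// the bleach-free trace exactly.  This makes paired comparisons across
// bleach levels nearly noise-free.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  double expo() { return -std::log(1.0 - unif()); }     // mean 1
  double norm() {                                       // polar Box-Muller
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
  // exact Binomial(n, p) by inversion (cost ~ np, fine for np ~ O(1))
  int binom(int n, double p) {
    if (p <= 0.0 || n == 0) return 0;
    if (p >= 1.0) return n;
    double u = unif();
    double pk = std::exp(n * std::log1p(-p));  // P(X = 0)
    double cdf = pk;
    int k = 0;
    const double odds = p / (1.0 - p);
    while (u > cdf && k < n) {
      pk *= odds * (double)(n - k) / (double)(k + 1);
      ++k;
      cdf += pk;
    }
    return k;
  }
  int poisson(double mu) {  // inversion with running product; mu modest
    if (mu <= 0.0) return 0;
    if (mu > 50.0) {        // split to keep the product stable
      int a = poisson(mu / 2.0);
      return a + poisson(mu - mu / 2.0);
    }
    double L = std::exp(-mu), prod = unif();
    int k = 0;
    while (prod > L) { prod *= unif(); ++k; }
    return k;
  }
};

inline double wrap_mod(double x, double L) {
  // x modulo L into [0, L)
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0;  // guard the rounding edge
  return x;
}

inline double wrap_box(double x, double L) {
  // into [-L/2, L/2)
  return wrap_mod(x + L / 2.0, L) - L / 2.0;
}

struct Photon { double tick; double micro; };

} // namespace

// [[Rcpp::export(name = ".simulate_stream_cpp")]]
List simulate_stream_cpp(double D_um2_s, int n_mol, double box_um,
                         double duration_s, double rep_rate_hz,
                         double w_exc_um, double exc_prob_peak,
                         double k_fl_per_ns, double zeta, double w_d_um,
                         double det_eff, double isc_prob, double tau_dark_s,
                         double bleach_prob, double background_rate,
                         double irf_sigma_ns, double timestep_s,
                         double seed) {
  const double period_ns = 1e9 / rep_rate_hz;
  const int pulses_per_step =
      std::max((int64_t)1, (int64_t)std::llround(timestep_s * rep_rate_hz));
  const double dt = pulses_per_step / rep_rate_hz;
  const int64_t n_pulses = (int64_t)std::llround(duration_s * rep_rate_hz);
  const int64_t n_steps = (n_pulses + pulses_per_step - 1) / pulses_per_step;

  uint64_t mix = (uint64_t)seed;
  Xoshiro rng_bg(Xoshiro::splitmix64(mix));
  std::vector<Xoshiro> rng_dyn, rng_phot, rng_bleach;
  rng_dyn.reserve(n_mol); rng_phot.reserve(n_mol); rng_bleach.reserve(n_mol);
  for (int i = 0; i < n_mol; ++i) {
    rng_dyn.emplace_back(Xoshiro::splitmix64(mix));
    rng_phot.emplace_back(Xoshiro::splitmix64(mix));
    rng_bleach.emplace_back(Xoshiro::splitmix64(mix));
  }

  const double w2 = w_exc_um * w_exc_um;
  const double wd2 = w_d_um * w_d_um;
  const double step_sd = std::sqrt(2.0 * D_um2_s * dt);
  // beyond r2_cut the chance of any excitation in a step is < 1e-9
  const double r2_cut =
      0.5 * w2 * std::log(std::max(1.0, exc_prob_peak * pulses_per_step / 1e-9));

  const bool bleach_only = (isc_prob <= 0.0);
  const int64_t kNever = INT64_MAX / 2;

  std::vector<double> x(n_mol), y(n_mol);
  std::vector<int64_t> dark_until(n_mol, -1);  // pulse index; -1 = free
  // excitations remaining until photobleaching, ~ Geometric(bleach_prob)
  std::vector<int64_t> to_bleach(n_mol, kNever);
  auto draw_bleach_counter = [&](Xoshiro &rng) -> int64_t {
    if (bleach_prob <= 0.0) return kNever;
    double u = rng.unif();
    return 1 + (int64_t)std::floor(std::log1p(-u) / std::log1p(-bleach_prob));
  };
  // Far-field stride: a molecule well outside the excitation cutoff takes
  // one Gaussian step of K substeps (exactly equivalent in law), with K
  // capped so a 6-sigma excursion cannot reach the active zone unseen.
  std::vector<int64_t> next_upd(n_mol, 0), last_upd(n_mol, 0);
  const double r_cut = std::sqrt(r2_cut);
  const double sigma1 = std::sqrt(2.0 * D_um2_s * dt);
  const int64_t stride_cap = 256;
  auto safe_stride = [&](double r) -> int64_t {
    if (sigma1 <= 0.0) return stride_cap;
    const double margin = r - r_cut;
    if (margin <= 12.0 * sigma1) return 1;
    const double k = (margin / (6.0 * sigma1)) * (margin / (6.0 * sigma1));
    return std::min(stride_cap, (int64_t)k);
  };

  for (int i = 0; i < n_mol; ++i) {
    x[i] = (rng_dyn[i].unif() - 0.5) * box_um;
    y[i] = (rng_dyn[i].unif() - 0.5) * box_um;
    if (bleach_only) to_bleach[i] = draw_bleach_counter(rng_bleach[i]);
  }

  std::vector<Photon> ph;
  ph.reserve((size_t)std::min(5e7, duration_s * 1e6));
  std::vector<int> slots;
  int64_t n_bleached = 0;

  for (int64_t s = 0; s < n_steps; ++s) {
    const int64_t pulse0 = s * pulses_per_step;
    const int pulses_here =
        (int)std::min((int64_t)pulses_per_step, n_pulses - pulse0);
    for (int i = 0; i < n_mol; ++i) {
      if (next_upd[i] > s) continue;
      const double sd_here = step_sd * std::sqrt((double)(s - last_upd[i] + 1));
      x[i] = wrap_box(x[i] + sd_here * rng_dyn[i].norm(), box_um);
      y[i] = wrap_box(y[i] + sd_here * rng_dyn[i].norm(), box_um);
      last_upd[i] = s + 1;
      const double r2 = x[i] * x[i] + y[i] * y[i];
      if (exc_prob_peak <= 0.0) continue;
      if (r2 > r2_cut) {
        next_upd[i] = s + safe_stride(std::sqrt(r2));
        continue;
      }
      if (dark_until[i] >= pulse0 + pulses_here) continue;
      const double p_exc = exc_prob_peak * std::exp(-2.0 * r2 / w2);
      const double dshape = (2.0 * M_E * r2 / wd2) * std::exp(-2.0 * r2 / wd2);
      const double k_tot = k_fl_per_ns * (1.0 + zeta * dshape);
      if (bleach_only) {
        // no triplet: only the excitation *count* matters for bleaching,
        // so draw it in one binomial and track a geometric countdown
        const double p_em = (k_fl_per_ns / k_tot) * det_eff;
        int ne = rng_phot[i].binom(pulses_here, p_exc);
        while (ne > 0) {
          const bool bleaches = (int64_t)ne >= to_bleach[i];
          const int n_emit = bleaches ? (int)(to_bleach[i] - 1) : ne;
          const int nd = rng_phot[i].binom(n_emit, p_em);
          for (int q = 0; q < nd; ++q) {
            const int j = (int)(rng_phot[i].unif() * pulses_here);
            double m = rng_phot[i].expo() / k_tot;
            if (irf_sigma_ns > 0.0) m += irf_sigma_ns * rng_phot[i].norm();
            m = wrap_mod(m, period_ns);
            ph.push_back({(double)(pulse0 + j), m});
          }
          if (!bleaches) { to_bleach[i] -= ne; break; }
          // bleached: replace with a fresh molecule elsewhere; the
          // remainder of this (<= timestep) position update is skipped
          x[i] = (rng_bleach[i].unif() - 0.5) * box_um;
          y[i] = (rng_bleach[i].unif() - 0.5) * box_um;
          to_bleach[i] = draw_bleach_counter(rng_bleach[i]);
          ++n_bleached;
          break;
        }
      } else {
        int first_avail = 0;
        if (dark_until[i] > pulse0)
          first_avail = (int)(dark_until[i] - pulse0);
        const int n_avail = pulses_here - first_avail;
        if (n_avail <= 0) continue;
        const int ne = rng_phot[i].binom(n_avail, p_exc);
        if (ne == 0) continue;
        slots.clear();
        for (int q = 0; q < ne; ++q)
          slots.push_back(first_avail + (int)(rng_phot[i].unif() * n_avail));
        std::sort(slots.begin(), slots.end());
        for (int q = 0; q < ne; ++q) {
          const int64_t pulse = pulse0 + slots[q];
          if (pulse < dark_until[i]) continue;  // entered triplet mid-step
          if (bleach_prob > 0.0 && rng_bleach[i].unif() < bleach_prob) {
            // photobleached: replace with a fresh molecule elsewhere
            x[i] = (rng_bleach[i].unif() - 0.5) * box_um;
            y[i] = (rng_bleach[i].unif() - 0.5) * box_um;
            dark_until[i] = -1;
            ++n_bleached;
            break;  // remaining drawn excitations no longer apply
          }
          if (isc_prob > 0.0 && rng_phot[i].unif() < isc_prob) {
            const double dwell_s = tau_dark_s * rng_phot[i].expo();
            dark_until[i] =
                pulse + std::max((int64_t)1,
                                 (int64_t)std::llround(dwell_s * rep_rate_hz));
            continue;
          }
          // radiative vs stimulated decay, then detector throughput
          if (rng_phot[i].unif() >= k_fl_per_ns / k_tot) continue;
          if (rng_phot[i].unif() >= det_eff) continue;
          double m = rng_phot[i].expo() / k_tot;
          if (irf_sigma_ns > 0.0) m += irf_sigma_ns * rng_phot[i].norm();
          m = wrap_mod(m, period_ns);
          ph.push_back({(double)pulse, m});
        }
      }
    }
  }

  // uncorrelated background
  const int nbg = rng_bg.poisson(background_rate * duration_s);
  for (int q = 0; q < nbg; ++q) {
    const double tick = std::floor(rng_bg.unif() * (double)n_pulses);
    ph.push_back({tick, rng_bg.unif() * period_ns});
  }

  std::sort(ph.begin(), ph.end(),
            [](const Photon &a, const Photon &b) { return a.tick < b.tick; });
  const size_t N = ph.size();
  NumericVector ticks(N), micro(N);
  for (size_t q = 0; q < N; ++q) { ticks[q] = ph[q].tick; micro[q] = ph[q].micro; }
  return List::create(_["macro_ticks"] = ticks, _["microtimes_ns"] = micro,
                      _["n_bleached"] = (double)n_bleached,
                      _["n_background"] = (double)nbg,
                      _["tick_s"] = 1.0 / rep_rate_hz,
                      _["n_pulses"] = (double)n_pulses);
}
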