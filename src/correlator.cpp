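// Photon-mode autocorrelation on an integer macrotime tick grid.
//
// Estimator convention (shared by the multi-tau path and the brute-force
// oracle, which implement it independently): at coarsening u = 2^level the
// photon times are binned to c = floor(t / u) and the coarse trace length is
// M = ceil(T / u).  For a coarse lag k the symmetric-normalization estimate is
//
//   G(k) = P_k * (M - k) / (N_L(k) * N_R(k)) - 1
//
// with P_k the number of ordered photon pairs at coarse lag exactly k,
// N_L(k) the photons with c < M - k and N_R(k) the photons with c >= k.
// For a homogeneous Poisson stream E[G] ~ 0 at every lag; G is reported in
// the fluctuation convention (G -> 0 for uncorrelated signal).
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct LagSpec {
  int64_t k;        // coarse lag (in units of u)
  int64_t u;        // coarsening factor (ticks per coarse bin)
};

// Multi-tau lag schedule: level 0 covers k = 1..m at u = 1; every further
// level covers k = m/2+1..m at u = 2^level, i.e. m/2 points per octave.
std::vector<LagSpec> lag_schedule(int m, int64_t max_lag_ticks) {
  std::vector<LagSpec> out;
  for (int64_t k = 1; k <= m; ++k)
    if (k <= max_lag_ticks) out.push_back({k, 1});
  int64_t u = 2;
  while (u * (m / 2 + 1) <= max_lag_ticks) {
    for (int64_t k = m / 2 + 1; k <= m; ++k)
      if (k * u <= max_lag_ticks) out.push_back({k, u});
    u *= 2;
  }
  return out;
}

inline int64_t ceil_div(int64_t a, int64_t b) { return (a + b - 1) / b; }

} // namespace

// [[Rcpp::export(name = ".multi_tau_lags")]]
DataFrame multi_tau_lags(int m, double max_lag_ticks) {
  std::vector<LagSpec> sched = lag_schedule(m, (int64_t)max_lag_ticks);
  int n = sched.size();
  NumericVector k(n), u(n);
  for (int i = 0; i < n; ++i) { k[i] = sched[i].k; u[i] = sched[i].u; }
  return DataFrame::create(_["k"] = k, _["u"] = u);
}

// Fast multi-tau pair counting.  times: sorted integer-valued macrotime
// ticks.  Returns per lag: k, u, lag_ticks, pairs, NL, NR, M.
// [[Rcpp::export(name = ".multi_tau_count")]]
DataFrame multi_tau_count(NumericVector times, double T_ticks, int m,
                          double max_lag_ticks) {
  const int64_t T = (int64_t)T_ticks;
  std::vector<LagSpec> sched = lag_schedule(m, (int64_t)max_lag_ticks);
  const int nlag = sched.size();
  NumericVector k_out(nlag), u_out(nlag), lag_out(nlag), pairs(nlag),
      NL(nlag), NR(nlag), M_out(nlag);

  // current coarsened representation: unique times + weights
  std::vector<int64_t> ct;
  std::vector<double> cw;
  ct.reserve(times.size());
  cw.reserve(times.size());
  for (R_xlen_t i = 0; i < times.size(); ++i) {
    int64_t t = (int64_t)times[i];
    if (!ct.empty() && ct.back() == t) cw.back() += 1.0;
    else { ct.push_back(t); cw.push_back(1.0); }
  }
  int64_t cur_u = 1;

  int idx = 0;
  while (idx < nlag) {
    int64_t u = sched[idx].u;
    // coarsen by 2 until at this level's resolution
    while (cur_u < u) {
      size_t w = 0;
      for (size_t i = 0; i < ct.size(); ++i) {
        int64_t c = ct[i] >> 1;
        if (w > 0 && ct[w - 1] == c) cw[w - 1] += cw[i];
        else { ct[w] = c; cw[w] = cw[i]; ++w; }
      }
      ct.resize(w); cw.resize(w);
      cur_u *= 2;
    }
    const int64_t M = ceil_div(T, u);
    // lags of this level, contiguous [lo, hi]
    int lvl_end = idx;
    while (lvl_end < nlag && sched[lvl_end].u == u) ++lvl_end;
    const int64_t lo = sched[idx].k, hi = sched[lvl_end - 1].k;
    std::vector<double> acc(hi - lo + 1, 0.0);
    // two-pointer window pair counting on unique coarse times
    size_t jlo = 0, jhi = 0;
    const size_t nu = ct.size();
    for (size_t i = 0; i < nu; ++i) {
      if (jlo < i + 1) jlo = i;  // lags are >= 1, partner strictly later
      while (jlo < nu && ct[jlo] < ct[i] + lo) ++jlo;
      if (jhi < jlo) jhi = jlo;
      while (jhi < nu && ct[jhi] <= ct[i] + hi) ++jhi;
      for (size_t j = jlo; j < jhi; ++j)
        acc[ct[j] - ct[i] - lo] += cw[i] * cw[j];
    }
    // cumulative weights for NL / NR by binary search on unique times
    std::vector<double> cum(nu + 1, 0.0);
    for (size_t i = 0; i < nu; ++i) cum[i + 1] = cum[i] + cw[i];
    const double Ntot = cum[nu];
    for (int q = idx; q < lvl_end; ++q) {
      int64_t k = sched[q].k;
      // NL = weight with c < M - k
      int64_t lim = M - k;
      size_t p = std::lower_bound(ct.begin(), ct.end(), lim) - ct.begin();
      double nl = cum[p];
      // NR = weight with c >= k
      p = std::lower_bound(ct.begin(), ct.end(), k) - ct.begin();
      double nr = Ntot - cum[p];
      k_out[q] = (double)k; u_out[q] = (double)u;
      lag_out[q] = (double)(k * u);
      pairs[q] = acc[k - lo]; NL[q] = nl; NR[q] = nr; M_out[q] = (double)M;
    }
    idx = lvl_end;
  }
  return DataFrame::create(_["k"] = k_out, _["u"] = u_out,
                           _["lag_ticks"] = lag_out, _["pairs"] = pairs,
                           _["NL"] = NL, _["NR"] = NR, _["M"] = M_out);
}

// Brute-force oracle: identical estimator, computed by a naive O(N^2)
// double loop with linear-scan photon counting.  Independent of the
// multi-tau code above; intended for small streams only.
// [[Rcpp::export(name = ".brute_force_count")]]
DataFrame brute_force_count(NumericVector times, double T_ticks,
                            NumericVector k_in, NumericVector u_in) {
  const int64_t T = (int64_t)T_ticks;
  const R_xlen_t N = times.size();
  const int nlag = k_in.size();
  NumericVector lag_out(nlag), pairs(nlag), NL(nlag), NR(nlag), M_out(nlag);
  for (int q = 0; q < nlag; ++q) {
    const int64_t k = (int64_t)k_in[q], u = (int64_t)u_in[q];
    const int64_t M = ceil_div(T, u);
    double P = 0.0, nl = 0.0, nr = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) {
      const int64_t ci = ((int64_t)times[i]) / u;
      if (ci < M - k) nl += 1.0;
      if (ci >= k) nr += 1.0;
      for (R_xlen_t j = i + 1; j < N; ++j) {
        const int64_t d = ((int64_t)times[j]) / u - ci;
        if (d > k) break;          // times sorted: lags only grow
        if (d == k) P += 1.0;
      }
    }
    lag_out[q] = (double)(k * u); pairs[q] = P;
    NL[q] = nl; NR[q] = nr; M_out[q] = (double)M;
  }
  return DataFrame::create(_["k"] = k_in, _["u"] = u_in,
                           _["lag_ticks"] = lag_out, _["pairs"] = pairs,
                           _["NL"] = NL, _["NR"] = NR, _["M"] = M_out);
}
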