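#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Self-contained, platform-stable RNG for the Brownian-dynamics engine:
// xoshiro256++ seeded through splitmix64, normals by Box-Muller.
// Trajectories are therefore bit-reproducible from a single integer seed,
// independent of R's RNG state.

namespace {

struct Rng {
  uint64_t s[4];
  bool has_spare;
  double spare;
};

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

inline uint64_t next_u64(Rng &r) {
  const uint64_t result = rotl(r.s[0] + r.s[3], 23) + r.s[0];
  const uint64_t t = r.s[1] << 17;
  r.s[2] ^= r.s[0];
  r.s[3] ^= r.s[1];
  r.s[1] ^= r.s[2];
  r.s[0] ^= r.s[3];
  r.s[2] ^= t;
  r.s[3] = rotl(r.s[3], 45);
  return result;
}

inline double unif01(Rng &r) {
  return (next_u64(r) >> 11) * 0x1.0p-53;  // [0, 1)
}

inline double rnorm1(Rng &r) {
  if (r.has_spare) {
    r.has_spare = false;
    return r.spare;
  }
  double u1;
  do { u1 = unif01(r); } while (u1 <= 0.0);
  const double u2 = unif01(r);
  const double m = std::sqrt(-2.0 * std::log(u1));
  r.spare = m * std::sin(2.0 * M_PI * u2);
  r.has_spare = true;
  return m * std::cos(2.0 * M_PI * u2);
}

inline void seed_rng(Rng &r, double seed) {
  uint64_t x = static_cast<uint64_t>(seed);
  for (int i = 0; i < 4; ++i) r.s[i] = splitmix64(x);
  r.has_spare = false;
  r.spare = 0.0;
}

// Uniform-grid linear interpolation of the model tables (w, dw/dz, D, dD/dz).
struct Tables {
  const double *w, *wp, *d, *dp;
  double z_lo, inv_dz;
  int n;
};

struct Eval { double w, wp, d, dp; };

inline void eval_tables(const Tables &tb, double z, Eval &e) {
  double u = (z - tb.z_lo) * tb.inv_dz;
  if (u < 0.0) u = 0.0;
  if (u > tb.n - 1.0) u = tb.n - 1.0;
  int i = static_cast<int>(u);
  if (i >= tb.n - 1) i = tb.n - 2;
  const double f = u - i;
  e.w = tb.w[i] + f * (tb.w[i + 1] - tb.w[i]);
  e.wp = tb.wp[i] + f * (tb.wp[i + 1] - tb.wp[i]);
  e.d = tb.d[i] + f * (tb.d[i + 1] - tb.d[i]);
  e.dp = tb.dp[i] + f * (tb.dp[i + 1] - tb.dp[i]);
}

// One step of overdamped dynamics with position-dependent D. The
// Euler-Maruyama update
//   z' = z + [D(z) F(z)/kBT + D'(z)] dt + sqrt(2 D(z) dt) xi,
// F = -(w'(z) + k (z - c)), with reflecting walls at +/- box_half,
// either taken directly (metropolis = false) or used as the proposal of a
// Metropolis-adjusted (smart Monte Carlo) step, which removes the O(dt)
// bias of the sampled measure: accept z' with probability
//   min(1, pi(z') q(z|z') / (pi(z) q(z'|z))),  pi = exp(-(w+u)/kBT).
// Near the walls w and D are flat (vapor phase), so image terms in q from
// the reflection cancel.
struct StepState {
  double z;
  Eval e;
  long n_prop, n_acc;
};

inline double drift_mean(const Eval &e, double z, double dt, double kBT,
                         double bias_c, double bias_k) {
  const double force = -(e.wp + bias_k * (z - bias_c));
  return z + (e.d * force / kBT + e.dp) * dt;
}

inline void do_step(const Tables &tb, Rng &rng, StepState &st, double dt,
                    double kBT, double bias_c, double bias_k,
                    double box_half, bool metropolis) {
  const double dv = st.e.d > 0.0 ? st.e.d : 0.0;
  if (metropolis && dv <= 0.0) return;  // frozen dynamics
  const double m = drift_mean(st.e, st.z, dt, kBT, bias_c, bias_k);
  double zp = m + std::sqrt(2.0 * dv * dt) * rnorm1(rng);
  while (zp > box_half || zp < -box_half) {
    if (zp > box_half) zp = 2.0 * box_half - zp; else zp = -2.0 * box_half - zp;
  }
  Eval ep;
  eval_tables(tb, zp, ep);
  if (!metropolis) {
    st.z = zp;
    st.e = ep;
    return;
  }
  st.n_prop++;
  const double dvp = ep.d > 0.0 ? ep.d : 0.0;
  const double ub = 0.5 * bias_k * (st.z - bias_c) * (st.z - bias_c);
  const double ubp = 0.5 * bias_k * (zp - bias_c) * (zp - bias_c);
  const double mp = drift_mean(ep, zp, dt, kBT, bias_c, bias_k);
  const double s2 = 2.0 * dv * dt, s2p = 2.0 * dvp * dt;
  double loga = -((ep.w + ubp) - (st.e.w + ub)) / kBT;
  if (dvp <= 0.0) {
    loga = -INFINITY;  // no reverse move: reject
  } else {
    loga += -(st.z - mp) * (st.z - mp) / (2.0 * s2p) - 0.5 * std::log(s2p);
    loga -= -(zp - m) * (zp - m) / (2.0 * s2) - 0.5 * std::log(s2);
  }
  if (loga >= 0.0 || std::log(1.0 - unif01(rng)) < loga) {
    st.z = zp;
    st.e = ep;
    st.n_acc++;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_langevin_path(double z0, double n_steps, double dt,
                       int thin, double kBT, double bias_center,
                       double bias_k, double box_half,
                       double table_zlo, double table_dz,
                       NumericVector wval, NumericVector wprime,
                       NumericVector dcoef, NumericVector dprime,
                       double seed, bool metropolis) {
  const R_xlen_t ns = static_cast<R_xlen_t>(n_steps);
  Tables tb{wval.begin(), wprime.begin(), dcoef.begin(), dprime.begin(),
            table_zlo, 1.0 / table_dz, static_cast<int>(wprime.size())};
  Rng rng;
  seed_rng(rng, seed);
  const R_xlen_t n_out = ns / thin + 1;
  NumericVector out(n_out);
  StepState st{z0, Eval(), 0, 0};
  eval_tables(tb, st.z, st.e);
  out[0] = st.z;
  R_xlen_t j = 1;
  for (R_xlen_t t = 1; t <= ns; ++t) {
    do_step(tb, rng, st, dt, kBT, bias_center, bias_k, box_half, metropolis);
    if (t % thin == 0) out[j++] = st.z;
    if ((t & 0xFFFFF) == 0) {
      if (!std::isfinite(st.z)) stop("non-finite position at step %td", (ptrdiff_t)t);
      Rcpp::checkUserInterrupt();
    }
  }
  if (!std::isfinite(st.z)) stop("non-finite position at end of run");
  return List::create(_["samples"] = out,
                      _["acceptance"] = st.n_prop > 0 ?
                        (double)st.n_acc / (double)st.n_prop : NA_REAL);
}

// Streaming variant: accumulates a histogram of the visited positions
// instead of storing the path (used for long Boltzmann-fidelity runs).
// [[Rcpp::export]]
NumericVector cpp_langevin_hist(double z0, double n_steps, double dt,
                                double kBT, double bias_center, double bias_k,
                                double box_half, double table_zlo,
                                double table_dz, NumericVector wval,
                                NumericVector wprime,
                                NumericVector dcoef, NumericVector dprime,
                                double seed, double hist_lo, double hist_dz,
                                int n_bins, double n_burn, int stride,
                                bool metropolis) {
  const R_xlen_t ns = static_cast<R_xlen_t>(n_steps);
  const R_xlen_t burn = static_cast<R_xlen_t>(n_burn);
  Tables tb{wval.begin(), wprime.begin(), dcoef.begin(), dprime.begin(),
            table_zlo, 1.0 / table_dz, static_cast<int>(wprime.size())};
  Rng rng;
  seed_rng(rng, seed);
  NumericVector counts(n_bins);
  StepState st{z0, Eval(), 0, 0};
  eval_tables(tb, st.z, st.e);
  for (R_xlen_t t = 1; t <= ns; ++t) {
    do_step(tb, rng, st, dt, kBT, bias_center, bias_k, box_half, metropolis);
    if (t > burn && ((t - burn) % stride == 0)) {
      const double u = (st.z - hist_lo) / hist_dz;
      if (u >= 0.0 && u < n_bins) counts[static_cast<int>(u)] += 1.0;
    }
    if ((t & 0xFFFFF) == 0) {
      if (!std::isfinite(st.z)) stop("non-finite position at step %td", (ptrdiff_t)t);
      Rcpp::checkUserInterrupt();
    }
  }
  return counts;
}

// Self-consistent WHAM iteration.
//   p(b)  propto  sum_i n_i(b) / sum_i N_i exp(f_i/kBT) E(b,i)
//   f_i = -kBT log sum_b p(b) E(b,i)
// with E(b,i) the (bin-averaged) bias Boltzmann factor exp(-u_i(b)/kBT).
// [[Rcpp::export]]
List cpp_wham(NumericVector nb, NumericVector Ni, NumericMatrix E,
              double kBT, double tol, int max_iter) {
  const int B = nb.size();
  const int W = Ni.size();
  if (E.nrow() != B || E.ncol() != W)
    stop("bias factor matrix must be n_bins x n_windows");
  std::vector<double> f(W, 0.0), fnew(W), g(W), p(B), denom(B);
  // Bias factors of a stiff window are negligible outside a few window
  // widths; restrict each window to the bin range where E is above a
  // tiny relative threshold (exact for unbiased windows: E = 1).
  std::vector<int> lo(W, 0), hi(W, B - 1);
  for (int i = 0; i < W; ++i) {
    double emax = 0.0;
    for (int b = 0; b < B; ++b) if (E(b, i) > emax) emax = E(b, i);
    const double thr = emax * 1e-14;
    int l = 0, h = B - 1;
    while (l < B && E(l, i) <= thr) ++l;
    while (h >= 0 && E(h, i) <= thr) --h;
    lo[i] = std::min(l, B - 1);
    hi[i] = std::max(h, 0);
  }
  std::vector<double> resid_hist;
  resid_hist.reserve(max_iter > 0 ? std::min(max_iter, 1000000) : 16);
  int iter = 0;
  double resid = R_PosInf;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (int i = 0; i < W; ++i) g[i] = std::exp(f[i] / kBT);
    std::fill(denom.begin(), denom.end(), 0.0);
    for (int i = 0; i < W; ++i) {
      const double c = Ni[i] * g[i];
      const double *Ei = &E(0, i);
      for (int b = lo[i]; b <= hi[i]; ++b) denom[b] += c * Ei[b];
    }
    double psum = 0.0;
    for (int b = 0; b < B; ++b) {
      p[b] = (denom[b] > 0.0 && nb[b] > 0.0) ? nb[b] / denom[b] : 0.0;
      psum += p[b];
    }
    if (psum <= 0.0) stop("WHAM: all bins empty");
    for (int b = 0; b < B; ++b) p[b] /= psum;
    for (int i = 0; i < W; ++i) {
      double s = 0.0;
      const double *Ei = &E(0, i);
      for (int b = lo[i]; b <= hi[i]; ++b) s += p[b] * Ei[b];
      fnew[i] = -kBT * std::log(s);
    }
    const double f0 = fnew[0];
    resid = 0.0;
    for (int i = 0; i < W; ++i) {
      fnew[i] -= f0;  // gauge: f_1 = 0
      const double d = std::fabs(fnew[i] - f[i]);
      if (d > resid) resid = d;
      f[i] = fnew[i];
    }
    resid_hist.push_back(resid);
    if (resid < tol) break;
  }
  const bool converged = resid < tol;
  const int kept = std::min<int>(10, resid_hist.size());
  NumericVector tail(kept);
  for (int i = 0; i < kept; ++i)
    tail[i] = resid_hist[resid_hist.size() - kept + i];
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["p"] = NumericVector(p.begin(), p.end()),
                      _["iterations"] = std::min(iter, max_iter),
                      _["residual"] = resid,
                      _["residual_tail"] = tail,
                      _["converged"] = converged);
}
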