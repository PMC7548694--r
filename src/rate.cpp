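// Fixed-step RK4 integrator for the three-population rate model with
// B-cell-driven synaptic depression (e) and optional P-cell-driven
// facilitation (z) of the A<-P connection.  Noise and stimulus currents are
// held piecewise constant within a step.  Units: s, pA, spikes/s.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double softplus(double x) {
  // numerically stable log(1 + exp(x))
  if (x > 30.0) return x + std::log1p(std::exp(-x));
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct RateSys {
  double W[3][3];   // nonnegative magnitudes, indexed (post, pre)
  double k[3], t[3], tau[3], F;
  double eta_d, tau_d;
  bool e_dynamic;
  bool fac_on;
  double eta_f, tau_f, zmax;

  // state x = (P, B, A, e, z); I = external input per population (pA)
  void rhs(const double* x, const double* I, double* dx) const {
    const double P = x[0], B = x[1], A = x[2], e = x[3], z = x[4];
    const double wap = fac_on ? W[2][0] * (1.0 + z) : W[2][0];
    const double in[3] = {
        W[0][0] * P - W[0][1] * B - W[0][2] * A + I[0],
        W[1][0] * P - W[1][1] * B - W[1][2] * A + I[1],
        wap * P - W[2][1] * B * e - W[2][2] * A + I[2]};
    for (int p = 0; p < 3; ++p)
      dx[p] = (-x[p] + F * softplus(k[p] * (in[p] + t[p]))) / tau[p];
    dx[3] = e_dynamic ? (1.0 - e) / tau_d - eta_d * B * e : 0.0;
    dx[4] = fac_on ? -z / tau_f + eta_f * P * (zmax - z) : 0.0;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_rate_simulate")]]
List cpp_rate_simulate(NumericMatrix W, NumericVector k, NumericVector t_thr,
                       NumericVector tau, double F, double eta_d, double tau_d,
                       bool e_dynamic, double e0, bool fac_on, double eta_f,
                       double tau_f, double zmax, double z0,
                       NumericVector init, double duration, double dt,
                       int record_every, NumericMatrix noise, List stim) {
  RateSys sys;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) sys.W[i][j] = W(i, j);
  for (int i = 0; i < 3; ++i) {
    sys.k[i] = k[i]; sys.t[i] = t_thr[i]; sys.tau[i] = tau[i];
  }
  sys.F = F; sys.eta_d = eta_d; sys.tau_d = tau_d; sys.e_dynamic = e_dynamic;
  sys.fac_on = fac_on; sys.eta_f = eta_f; sys.tau_f = tau_f; sys.zmax = zmax;

  const int n_steps = static_cast<int>(std::llround(duration / dt));
  const bool have_noise = noise.nrow() == 3 && noise.ncol() >= n_steps;
  if (noise.nrow() > 0 && !have_noise)
    stop("noise matrix must be 3 x n_steps");

  // stimulus schedule: per entry (pop, amp, on_s, off_s)
  struct Pulse { int pop; double amp; int on, off; };
  std::vector<Pulse> pulses;
  for (int i = 0; i < stim.size(); ++i) {
    List s = stim[i];
    pulses.push_back({as<int>(s["pop"]), as<double>(s["amp"]),
                      static_cast<int>(std::llround(as<double>(s["on_s"]) / dt)),
                      static_cast<int>(std::llround(as<double>(s["off_s"]) / dt))});
  }

  double x[5] = {init[0], init[1], init[2], e0, z0};
  const int n_samples = n_steps / record_every + 1;
  NumericVector t_out(n_samples);
  NumericMatrix rates(n_samples, 3);
  NumericVector e_out(n_samples), z_out(n_samples);
  auto sample = [&](int kk, int s) {
    t_out[kk] = s * dt;
    for (int p = 0; p < 3; ++p) rates(kk, p) = x[p];
    e_out[kk] = x[3]; z_out[kk] = x[4];
  };
  sample(0, 0);
  int kk = 1;

  double I[3], k1[5], k2[5], k3[5], k4[5], xt[5];
  for (int s = 0; s < n_steps; ++s) {
    for (int p = 0; p < 3; ++p) I[p] = have_noise ? noise(p, s) : 0.0;
    for (const Pulse& pl : pulses)
      if (s >= pl.on && s < pl.off) I[pl.pop] += pl.amp;

    sys.rhs(x, I, k1);
    for (int i = 0; i < 5; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    sys.rhs(xt, I, k2);
    for (int i = 0; i < 5; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    sys.rhs(xt, I, k3);
    for (int i = 0; i < 5; ++i) xt[i] = x[i] + dt * k3[i];
    sys.rhs(xt, I, k4);
    for (int i = 0; i < 5; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    // the continuous-time e/z dynamics cannot leave their intervals; guard the
    // discrete step against overshoot at the boundaries
    if (x[3] < 0.0) x[3] = 0.0; else if (x[3] > 1.0) x[3] = 1.0;
    if (sys.fac_on) { if (x[4] < 0.0) x[4] = 0.0; else if (x[4] > zmax) x[4] = zmax; }

    if (!std::isfinite(x[0]) || !std::isfinite(x[1]) || !std::isfinite(x[2]))
      stop("non-finite rate-model state at t = %f s", s * dt);
    if ((s + 1) % record_every == 0 && kk < n_samples) sample(kk++, s + 1);
  }

  return List::create(_["t"] = t_out, _["rates"] = rates, _["e"] = e_out,
                      _["z"] = z_out);
}
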