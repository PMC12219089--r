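#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear diode characteristic h(x).
static inline double chua_h(double x, double m0, double m1) {
  return m1 * x + 0.5 * (m0 - m1) * (std::fabs(x + 1.0) - std::fabs(x - 1.0));
}

struct ChuaPar { double alpha, beta, m0, m1; };

static inline void deriv(const double s[3], double ds[3], const ChuaPar& p) {
  ds[0] = p.alpha * (s[1] - s[0] - chua_h(s[0], p.m0, p.m1));
  ds[1] = s[0] - s[1] + s[2];
  ds[2] = -p.beta * s[1];
}

// Fixed-step classical RK4 for the Chua oscillator. Takes `skip_steps`
// burn-in steps, then records the state every `keep_every` steps, the
// first record immediately after burn-in, until `n_keep` rows are kept.
// [[Rcpp::export]]
NumericMatrix chua_rk4(NumericVector state0, double alpha, double beta,
                       double m0, double m1, double dt, int skip_steps,
                       int keep_every, int n_keep) {
  ChuaPar par{alpha, beta, m0, m1};
  double s[3] = {state0[0], state0[1], state0[2]};
  NumericMatrix out(n_keep, 3);
  const long total = (long)skip_steps + (long)(n_keep - 1) * keep_every;
  int kept = 0;
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  for (long step = 0; step <= total; ++step) {
    if (step >= skip_steps && (step - skip_steps) % keep_every == 0) {
      out(kept, 0) = s[0];
      out(kept, 1) = s[1];
      out(kept, 2) = s[2];
      if (++kept == n_keep) break;
    }
    deriv(s, k1, par);
    for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2, par);
    for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3, par);
    for (int i = 0; i < 3; ++i) tmp[i] = s[i] + dt * k3[i];
    deriv(tmp, k4, par);
    for (int i = 0; i < 3; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (std::fabs(s[0]) > 1e6 || std::fabs(s[1]) > 1e6 ||
        std::fabs(s[2]) > 1e6)
      stop("Chua integration diverged (|state| > 1e6) at step %ld with dt = %g; "
           "reduce dt or check parameters", step, dt);
  }
  return out;
}
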