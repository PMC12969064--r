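#include <Rcpp.h>
using namespace Rcpp;

// Phase-velocity field of the five-oscillator neurovascular network.
// Oscillator order: 0 Ox, 1 Glu, 2 GOa, 3 GO, 4 MO.
// Coupling order:   0 eps_Glu_GO, 1 eps_MO_GO, 2 eps_Glu_GOa, 3 eps_MO_GOa,
//                   4 eps_GO_MO,  5 eps_GOa_MO, 6 eps_Ox_MO.
// The MO->GO and MO->GOa terms are inhibitory (minus sign); supply
// oscillators (Ox, Glu) have no incoming couplings.
static inline void velocity(const double *phi, double t,
                            const double *omega, const double *A,
                            const double *wmod, const double *eps,
                            const double *forcing, double *out) {
  double w[5];
  for (int i = 0; i < 5; ++i) {
    w[i] = (A[i] == 0.0) ? omega[i]
                         : omega[i] * (1.0 + A[i] * std::sin(wmod[i] * t));
  }
  out[0] = w[0] + forcing[0];
  out[1] = w[1] + forcing[1];
  out[2] = w[2] - eps[3] * std::sin(phi[4] - phi[2])
                + eps[2] * std::sin(phi[1] - phi[2]) + forcing[2];
  out[3] = w[3] - eps[1] * std::sin(phi[4] - phi[3])
                + eps[0] * std::sin(phi[1] - phi[3]) + forcing[3];
  out[4] = w[4] + eps[4] * std::sin(phi[3] - phi[4])
                + eps[5] * std::sin(phi[2] - phi[4])
                + eps[6] * std::sin(phi[0] - phi[4]) + forcing[4];
}

// Classical fixed-step RK4 over n_steps steps. `forcing` holds the
// already-scaled (sigma * eta) additive noise, one row per step, held
// constant across the four stages of that step; pass a 1x5 zero matrix for
// noise-free runs. Returns an (n_steps + 1) x 5 matrix of unwrapped phases.
// [[Rcpp::export]]
NumericMatrix rk4_integrate_cpp(NumericVector phi0, double t0, double dt,
                                int n_steps, NumericVector omega,
                                NumericVector A, NumericVector wmod,
                                NumericVector eps, NumericMatrix forcing) {
  if (phi0.size() != 5 || omega.size() != 5 || A.size() != 5 ||
      wmod.size() != 5 || eps.size() != 7)
    stop("internal: bad parameter array length");
  const bool noisy = forcing.nrow() == n_steps;
  if (!noisy && forcing.nrow() != 1)
    stop("internal: forcing must have n_steps rows or a single zero row");

  NumericMatrix out(n_steps + 1, 5);
  double phi[5], k1[5], k2[5], k3[5], k4[5], tmp[5], f[5];
  for (int i = 0; i < 5; ++i) {
    phi[i] = phi0[i];
    out(0, i) = phi[i];
    f[i] = forcing(0, i);
  }
  const double *om = omega.begin(), *a = A.begin(), *wm = wmod.begin(),
               *ep = eps.begin();
  for (int s = 0; s < n_steps; ++s) {
    const double t = t0 + s * dt;
    if (noisy)
      for (int i = 0; i < 5; ++i) f[i] = forcing(s, i);
    velocity(phi, t, om, a, wm, ep, f, k1);
    for (int i = 0; i < 5; ++i) tmp[i] = phi[i] + 0.5 * dt * k1[i];
    velocity(tmp, t + 0.5 * dt, om, a, wm, ep, f, k2);
    for (int i = 0; i < 5; ++i) tmp[i] = phi[i] + 0.5 * dt * k2[i];
    velocity(tmp, t + 0.5 * dt, om, a, wm, ep, f, k3);
    for (int i = 0; i < 5; ++i) tmp[i] = phi[i] + dt * k3[i];
    velocity(tmp, t + dt, om, a, wm, ep, f, k4);
    for (int i = 0; i < 5; ++i) {
      phi[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(phi[i]))
        stop("non-finite phase for oscillator index %d at step %d", i + 1,
             s + 1);
      out(s + 1, i) = phi[i];
    }
  }
  return out;
}
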