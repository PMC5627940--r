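// Coupled neural-mass network integrator.
//
// Each node is a lumped excitatory/inhibitory population pair. Membrane
// potentials are produced by critically damped second-order synaptic filters
// (kernels A*a*t*exp(-a*t) and B*b*t*exp(-b*t)); pulse densities by logistic
// sigmoids S(V) = q / (1 + exp(r*(Vd - V))). Inter-node coupling is excitatory,
// delayed by a fixed number of steps, and weighted by the (possibly degenerated)
// structural matrix W.
//
// The linear filters are advanced with the exact matrix-exponential one-step
// map for piecewise-constant drive, which is unconditionally stable:
//   y_ss = (A/a) * u
//   [y; z] <- [y_ss; 0] + expm(dt * [[0,1],[-a^2,-2a]]) %*% [y - y_ss; z]
// with expm known in closed form for the critically damped (double pole) case.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoid_rate(double v, double vd, double q, double r) {
  return q / (1.0 + std::exp(r * (vd - v)));
}

// [[Rcpp::export]]
List simulate_network_cpp(const arma::mat& W,
                          double g,
                          int delay_steps,
                          const arma::vec& Vd1,
                          const arma::vec& Vd2,
                          double A, double B, double a, double b,
                          double C1, double C2, double q, double r,
                          const arma::mat& P,      // n_steps x n, noise drive (>= 0)
                          double dt,
                          arma::vec ve, arma::vec ze,
                          arma::vec vi, arma::vec zi,
                          arma::mat E_hist,        // delay_steps x n, oldest row first
                          int record_every) {
  const int n = W.n_rows;
  const int n_steps = P.n_rows;
  if ((int) P.n_cols != n)
    stop("noise matrix has %d columns but the network has %d nodes",
         (int) P.n_cols, n);
  if (delay_steps > 0 && ((int) E_hist.n_rows != delay_steps || (int) E_hist.n_cols != n))
    stop("delay buffer must be %d x %d", delay_steps, n);

  const int n_rec = n_steps / record_every;
  arma::mat sig(n_rec, n), spk(n_rec, n);

  // closed-form one-step propagators for the two critically damped filters
  const double ea = std::exp(-a * dt);
  const double m11e = ea * (1.0 + a * dt), m12e = ea * dt;
  const double m21e = -a * a * dt * ea,   m22e = ea * (1.0 - a * dt);
  const double eb = std::exp(-b * dt);
  const double m11i = eb * (1.0 + b * dt), m12i = eb * dt;
  const double m21i = -b * b * dt * eb,    m22i = eb * (1.0 - b * dt);
  const double dc_e = A / a, dc_i = B / b;

  arma::vec E(n), I(n), drive_e(n), drive_i(n), E_delayed(n);
  arma::vec msd(n, arma::fill::zeros);
  int pos = 0, irec = 0;

  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      E(i) = sigmoid_rate(ve(i), Vd1(i), q, r);
      I(i) = sigmoid_rate(vi(i), Vd2(i), q, r);
    }
    msd += E;

    if (delay_steps > 0) {
      E_delayed = E_hist.row(pos).t();
      E_hist.row(pos) = E.t();
      pos = (pos + 1) % delay_steps;
    } else {
      E_delayed = E;
    }

    drive_e = P.row(t).t() + g * (W * E_delayed) - C2 * I;
    drive_i = C1 * E;

    for (int i = 0; i < n; ++i) {
      double yss = dc_e * drive_e(i);
      double dy = ve(i) - yss, z = ze(i);
      ve(i) = yss + m11e * dy + m12e * z;
      ze(i) = m21e * dy + m22e * z;

      yss = dc_i * drive_i(i);
      dy = vi(i) - yss; z = zi(i);
      vi(i) = yss + m11i * dy + m12i * z;
      zi(i) = m21i * dy + m22i * z;
    }

    if ((t + 1) % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        sig(irec, i) = ve(i);
        spk(irec, i) = sigmoid_rate(ve(i), Vd1(i), q, r);
      }
      ++irec;
    }

    if ((t & 255) == 255 || t == n_steps - 1) {
      if (!ve.is_finite() || !vi.is_finite()) {
        int bad = 0;
        for (int i = 0; i < n; ++i)
          if (!std::isfinite(ve(i)) || !std::isfinite(vi(i))) { bad = i; break; }
        stop("integration diverged at node %d, step %d (dt = %g, a = %g, b = %g)",
             bad + 1, t + 1, dt, a, b);
      }
    }
  }
  msd /= (double) n_steps;

  // return the delay buffer reordered oldest-row-first for the next cycle
  arma::mat hist_out(E_hist.n_rows, E_hist.n_cols);
  if (delay_steps > 0) {
    for (int k = 0; k < delay_steps; ++k)
      hist_out.row(k) = E_hist.row((pos + k) % delay_steps);
  }

  return List::create(
    _["signals"] = sig,
    _["spike_density"] = spk,
    _["mean_spike_density"] = msd,
    _["ve"] = ve, _["ze"] = ze, _["vi"] = vi, _["zi"] = zi,
    _["E_hist"] = hist_out);
}
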