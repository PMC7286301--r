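// Fixed-step integrators for the Jansen-Rit network (Euler-Maruyama for the
// noisy system, RK4 for deterministic runs) and for the reduced phase model.
// Written in C++ because parameter sweeps integrate the 6N-dimensional SDE at
// dt = 1e-4 s for tens of simulated seconds.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct JRPar {
  double A, B, a, b, C1, C2, C3, C4, P, numax, v0, r;
};

inline JRPar unpack(const arma::vec& p) {
  JRPar q;
  q.A = p(0); q.B = p(1); q.a = p(2); q.b = p(3);
  q.C1 = p(4); q.C2 = p(5); q.C3 = p(6); q.C4 = p(7);
  q.P = p(8); q.numax = p(9); q.v0 = p(10); q.r = p(11);
  return q;
}

inline double sigm(double v, const JRPar& p) {
  double z = p.r * (p.v0 - v);
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return p.numax / (1.0 + std::exp(z));
}

// deterministic drift; y is N x 6, dy written in place
inline void drift(const arma::mat& y, const arma::mat& W, double eps,
                  const JRPar& p, arma::mat& dy, arma::vec& fy) {
  const arma::uword n = y.n_rows;
  for (arma::uword i = 0; i < n; ++i)
    fy(i) = sigm(y(i, 1) - y(i, 2), p);
  arma::vec coup = eps * (W * fy);
  for (arma::uword i = 0; i < n; ++i) {
    dy(i, 0) = y(i, 3);
    dy(i, 1) = y(i, 4);
    dy(i, 2) = y(i, 5);
    dy(i, 3) = p.A * p.a * fy(i) - 2.0 * p.a * y(i, 3) - p.a * p.a * y(i, 0);
    dy(i, 4) = p.A * p.a * (p.P + coup(i) + p.C2 * sigm(p.C1 * y(i, 0), p))
               - 2.0 * p.a * y(i, 4) - p.a * p.a * y(i, 1);
    dy(i, 5) = p.B * p.b * p.C4 * sigm(p.C3 * y(i, 0), p)
               - 2.0 * p.b * y(i, 5) - p.b * p.b * y(i, 2);
  }
}

} // namespace

// Integrate the network model. method: 0 = Euler(-Maruyama), 1 = RK4
// (deterministic only). noise_mode: 1 = SDE (increment sd*sqrt(dt)),
// 2 = per-step additive value with sd `noise_sd`. The stochastic forcing
// perturbs the extracortical input P inside the y4 drive, i.e. the state
// increment is A*a*increment. Returns the observable y1 - y2 sampled every
// `keep_every` steps after discarding `n_discard` steps, plus final state.
// [[Rcpp::export]]
List jr_integrate_cpp(arma::mat y0, const arma::mat& W, const arma::vec& par,
                      double eps, double dt, int n_steps, int n_discard,
                      int keep_every, double noise_sd, int noise_mode,
                      int method) {
  const JRPar p = unpack(par);
  const arma::uword n = y0.n_rows;
  arma::mat y = y0;
  arma::mat k1(n, 6), k2(n, 6), k3(n, 6), k4(n, 6), tmp(n, 6);
  arma::vec fy(n);
  const int n_keep = (n_steps - n_discard + keep_every - 1) / keep_every;
  arma::mat out(n, n_keep > 0 ? n_keep : 0);
  int kept = 0;
  const double amp = (noise_mode == 1) ? noise_sd * std::sqrt(dt) : noise_sd;

  for (int s = 0; s < n_steps; ++s) {
    if (method == 0) {
      drift(y, W, eps, p, k1, fy);
      y += dt * k1;
      if (noise_sd > 0.0) {
        for (arma::uword i = 0; i < n; ++i)
          y(i, 4) += p.A * p.a * amp * norm_rand();
      }
    } else {
      drift(y, W, eps, p, k1, fy);
      tmp = y + 0.5 * dt * k1;
      drift(tmp, W, eps, p, k2, fy);
      tmp = y + 0.5 * dt * k2;
      drift(tmp, W, eps, p, k3, fy);
      tmp = y + dt * k3;
      drift(tmp, W, eps, p, k4, fy);
      y += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    if (!y.is_finite())
      stop("non-finite state at step %d: integration diverged", s + 1);
    if (s >= n_discard && ((s - n_discard) % keep_every == 0)) {
      out.col(kept++) = y.col(1) - y.col(2);
    }
  }
  return List::create(_["y"] = out, _["state"] = y);
}

namespace {

// periodic cubic Hermite evaluation of H on a uniform grid over [0, 2pi)
inline double hermite_eval(double x, const arma::vec& hv, const arma::vec& hd,
                           double h) {
  const arma::uword K = hv.n_elem;
  const double twopi = 2.0 * M_PI;
  x -= twopi * std::floor(x / twopi);
  if (x >= twopi) x -= twopi;  // guard against rounding at the boundary
  if (x < 0) x = 0;
  arma::uword j = static_cast<arma::uword>(std::floor(x / h));
  if (j >= K) j = K - 1;
  arma::uword j1 = (j + 1) % K;
  double t = (x - j * h) / h;
  double t2 = t * t, t3 = t2 * t;
  double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t;
  double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  return h00 * hv(j) + h10 * h * hd(j) + h01 * hv(j1) + h11 * h * hd(j1);
}

} // namespace

// RK4 integration of the phase model
//   theta_i' = Omega + eps * sum_j w_ij H(theta_j - theta_i)
// with H given as values + derivatives on a uniform grid over [0, 2pi)
// (periodic cubic Hermite interpolation). Returns trajectories sampled every
// keep_every steps (including the initial state as the first column).
// [[Rcpp::export]]
arma::mat phase_integrate_cpp(arma::vec theta, const arma::mat& W, double eps,
                              double Omega, const arma::vec& hv,
                              const arma::vec& hd, double dt, int n_steps,
                              int keep_every) {
  const arma::uword n = theta.n_elem;
  const arma::uword K = hv.n_elem;
  const double h = 2.0 * M_PI / K;
  arma::mat out(n, n_steps / keep_every + 1);
  arma::vec k1(n), k2(n), k3(n), k4(n), tmp(n);
  int kept = 0;
  out.col(kept++) = theta;

  auto rhs = [&](const arma::vec& th, arma::vec& d) {
    for (arma::uword i = 0; i < n; ++i) {
      double acc = 0.0;
      for (arma::uword j = 0; j < n; ++j) {
        double w = W(i, j);
        if (w != 0.0)
          acc += w * hermite_eval(th(j) - th(i), hv, hd, h);
      }
      d(i) = Omega + eps * acc;
    }
  };

  for (int s = 0; s < n_steps; ++s) {
    rhs(theta, k1);
    tmp = theta + 0.5 * dt * k1; rhs(tmp, k2);
    tmp = theta + 0.5 * dt * k2; rhs(tmp, k3);
    tmp = theta + dt * k3;       rhs(tmp, k4);
    theta += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if ((s + 1) % keep_every == 0)
      out.col(kept++) = theta;
  }
  return out.cols(0, kept - 1);
}

// Deterministic RK4 trajectory of a single uncoupled node, returning the
// full 6-component state every `keep_every` steps after `n_discard` steps.
// Used for limit-cycle extraction and the adjoint construction.
// [[Rcpp::export]]
arma::mat jr_single_states_cpp(arma::vec y0, const arma::vec& par, double dt,
                               int n_steps, int n_discard, int keep_every) {
  const JRPar p = unpack(par);
  arma::mat W(1, 1, arma::fill::zeros);
  arma::mat y = y0.t();
  arma::mat k1(1, 6), k2(1, 6), k3(1, 6), k4(1, 6), tmp(1, 6);
  arma::vec fy(1);
  const int n_keep = (n_steps - n_discard + keep_every - 1) / keep_every;
  arma::mat out(n_keep > 0 ? n_keep : 0, 6);
  int kept = 0;
  for (int s = 0; s < n_steps; ++s) {
    drift(y, W, 0.0, p, k1, fy);
    tmp = y + 0.5 * dt * k1;
    drift(tmp, W, 0.0, p, k2, fy);
    tmp = y + 0.5 * dt * k2;
    drift(tmp, W, 0.0, p, k3, fy);
    tmp = y + dt * k3;
    drift(tmp, W, 0.0, p, k4, fy);
    y += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!y.is_finite())
      stop("non-finite state at step %d: integration diverged", s + 1);
    if (s >= n_discard && ((s - n_discard) % keep_every == 0))
      out.row(kept++) = y;
  }
  return out;
}
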