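#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Hard winner-take-all: one winner per hypercolumn, lowest index wins ties.
static inline void wta(const arma::vec& s, int H, int U,
                       arma::ivec& win, arma::vec& o) {
  o.zeros();
  for (int h = 0; h < H; ++h) {
    int base = h * U;
    int best = 0;
    double bv = s[base];
    for (int u = 1; u < U; ++u) {
      if (s[base + u] > bv) { bv = s[base + u]; best = u; }
    }
    win[h] = best;
    o[base + best] = 1.0;
  }
}

// Euler(-Maruyama) integration of the rate dynamics:
//   tau_s ds_j/dt = beta_j + (1/H) sum_i w_ij o_i - g_a a_j - s_j + I_j
//   tau_a da_j/dt = o_j - a_j
// with per-step noise increment sigma_in * sqrt(dt) on s (sigma_in in current
// units; the caller converts from the user-facing stationary sd sigma_out).
// Units are laid out hypercolumn-major: unit u of hypercolumn h is h*U + u.
// Returns the per-step WTA winners (1-based within each hypercolumn) and,
// optionally, the full s/a trajectories.
// [[Rcpp::export]]
List cpp_run_recall(const arma::mat& w, const arma::vec& beta, int H, int U,
                    double tau_s, double tau_a, const arma::vec& g_a,
                    double sigma_in, double dt, double t_total,
                    const arma::ivec& cue_units, double cue_amp,
                    double cue_duration, bool record_traj) {
  const int N = H * U;
  const int n_steps = (int) std::round(t_total / dt);
  arma::vec s = beta;
  arma::vec a(N, arma::fill::zeros);
  arma::vec o(N), I(N, arma::fill::zeros);
  arma::ivec win(H);
  const bool cueing = cue_units.n_elem > 0 && cue_duration > 0.0;
  // the cue activates its pattern: activation is clamped to the cued pattern
  // while the cue lasts (the cue current raises its support meanwhile), and
  // the WTA competition is free afterwards
  if (cueing) {
    o.zeros();
    for (arma::uword k = 0; k < cue_units.n_elem; ++k) {
      o[cue_units[k]] = 1.0;
      win[cue_units[k] / U] = cue_units[k] % U;
    }
  } else {
    wta(s, H, U, win, o);
  }
  arma::imat winners(n_steps, H);
  arma::mat s_traj, a_traj;
  if (record_traj) {
    s_traj.set_size(n_steps, N);
    a_traj.set_size(n_steps, N);
  }
  const double noise_sd = sigma_in * std::sqrt(dt);
  for (int t = 0; t < n_steps; ++t) {
    const double tm = t * dt;
    I.zeros();
    if (tm < cue_duration) {
      for (arma::uword k = 0; k < cue_units.n_elem; ++k)
        I[cue_units[k]] = cue_amp;
    }
    arma::vec drive = beta + (w.t() * o) / (double) H - g_a % a - s + I;
    s += (dt / tau_s) * drive;
    if (noise_sd > 0.0) {
      NumericVector xi = rnorm(N);
      for (int j = 0; j < N; ++j) s[j] += noise_sd * xi[j];
    }
    a += (dt / tau_a) * (o - a);
    if (!s.is_finite())
      stop("integration diverged to non-finite state at t = %f ms", tm);
    if (!(cueing && tm + dt < cue_duration)) wta(s, H, U, win, o);
    for (int h = 0; h < H; ++h) winners(t, h) = win[h] + 1;
    if (record_traj) {
      s_traj.row(t) = s.t();
      a_traj.row(t) = a.t();
    }
  }
  List out = List::create(_["winners"] = winners,
                          _["s_final"] = s,
                          _["a_final"] = a);
  if (record_traj) {
    out["s"] = s_traj;
    out["a"] = a_traj;
  }
  return out;
}
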