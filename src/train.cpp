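#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Integrates the z- and p-traces over a clamped activation series.
//   tau_z_pre  dz_pre/dt  = o - z_pre        (slow presynaptic filter)
//   tau_z_post dz_post/dt = o - z_post       (fast postsynaptic filter)
//   tau_p dp./dt = z. - p.                   (EWMA probability estimates)
//   tau_p dP_ij/dt = z_pre_i z_post_j - P_ij (joint, pre = row, post = col)
// `active` holds the clamped pattern index per step (0 = silent);
// `pattern_units` is n_patterns x H of global 1-based unit indices.
// z is updated first, then p from the updated z (one consistent Euler order,
// shared with the R-level single-step update).
// [[Rcpp::export]]
List cpp_train_traces(const arma::ivec& active, const arma::imat& pattern_units,
                      int N, double dt, double tau_z_pre, double tau_z_post,
                      double tau_p, int record_every, int avg_steps) {
  const int T = active.n_elem;
  const int H = pattern_units.n_cols;
  arma::vec z_pre(N, arma::fill::zeros), z_post(N, arma::fill::zeros);
  arma::vec p_pre(N, arma::fill::zeros), p_post(N, arma::fill::zeros);
  arma::vec o(N, arma::fill::zeros);
  arma::mat P(N, N, arma::fill::zeros);
  const double kpre = dt / tau_z_pre, kpost = dt / tau_z_post, kp = dt / tau_p;

  const int n_rec = record_every > 0 ? T / record_every : 0;
  arma::mat rec_p_pre, rec_p_post;
  arma::vec rec_t;
  if (n_rec > 0) {
    rec_p_pre.set_size(n_rec, N);
    rec_p_post.set_size(n_rec, N);
    rec_t.set_size(n_rec);
  }
  // optional time-average of the p-traces over the last avg_steps steps
  // (one protocol period): the steady-state EWMA oscillates with the
  // presentation phase, and the period average removes that phase bias
  const bool averaging = avg_steps > 0 && avg_steps <= T;
  arma::vec sum_p_pre, sum_p_post;
  arma::mat sum_P;
  if (averaging) {
    sum_p_pre.zeros(N);
    sum_p_post.zeros(N);
    sum_P.zeros(N, N);
  }
  int ri = 0;
  int prev = -1;
  for (int t = 0; t < T; ++t) {
    const int pid = active[t];
    if (pid != prev) {        // clamp changes only at pulse boundaries
      o.zeros();
      if (pid > 0)
        for (int h = 0; h < H; ++h) o[pattern_units(pid - 1, h) - 1] = 1.0;
      prev = pid;
    }
    z_pre  += kpre  * (o - z_pre);
    z_post += kpost * (o - z_post);
    p_pre  += kp * (z_pre - p_pre);
    p_post += kp * (z_post - p_post);
    // column-major manual loop: P_ij tracks z_pre[i] * z_post[j]
    for (int j = 0; j < N; ++j) {
      const double zj = z_post[j];
      double* col = P.colptr(j);
      for (int i = 0; i < N; ++i)
        col[i] += kp * (z_pre[i] * zj - col[i]);
    }
    if (averaging && t >= T - avg_steps) {
      sum_p_pre += p_pre;
      sum_p_post += p_post;
      sum_P += P;
    }
    if (n_rec > 0 && (t + 1) % record_every == 0 && ri < n_rec) {
      rec_p_pre.row(ri) = p_pre.t();
      rec_p_post.row(ri) = p_post.t();
      rec_t[ri] = (t + 1) * dt;
      ++ri;
    }
  }
  List out = List::create(_["z_pre"] = z_pre, _["z_post"] = z_post,
                          _["p_pre"] = p_pre, _["p_post"] = p_post,
                          _["p_joint"] = P, _["t"] = T * dt);
  if (averaging) {
    out["p_pre_mean"] = sum_p_pre / (double) avg_steps;
    out["p_post_mean"] = sum_p_post / (double) avg_steps;
    out["p_joint_mean"] = sum_P / (double) avg_steps;
  }
  if (n_rec > 0) {
    out["history"] = List::create(_["t"] = rec_t, _["p_pre"] = rec_p_pre,
                                  _["p_post"] = rec_p_post);
  }
  return out;
}
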