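#' BCPNN learning configuration
#'
#' Time constants of the synaptic traces and the probability floor of the
#' log-odds weight computation. The presynaptic z-filter is typically slow
#' (NMDA-like) and the postsynaptic one fast (AMPA-like); their asymmetry is
#' what turns temporal adjacency into asymmetric (sequence-encoding) weights.
#' `tau_z_pre` is validated against the biologically motivated 5-150 ms range
#' and can be taken outside it with a warning.
#'
#' @param tau_z_pre presynaptic z-trace time constant (ms), default 25.
#' @param tau_z_post postsynaptic z-trace time constant (ms), default 5.
#' @param tau_p probability-trace time constant (ms), default 5000.
#' @param epsilon probability floor applied inside the logarithms of the
#'   weight computation, default `1e-7`.
#' @return an object of class `learning_config`.
#' @export
learning_config <- function(tau_z_pre = 25, tau_z_post = 5, tau_p = 5000,
                            epsilon = 1e-7) {
  stopifnot(tau_z_pre > 0, tau_z_post > 0, tau_p > 0,
            epsilon > 0, epsilon < 1)
  if (tau_z_pre < 5 || tau_z_pre > 150)
    warning("tau_z_pre = ", tau_z_pre, " ms is outside the usual 5-150 ms range")
  structure(list(tau_z_pre = tau_z_pre, tau_z_post = tau_z_post,
                 tau_p = tau_p, epsilon = epsilon),
            class = "learning_config")
}

#' @export
print.learning_config <- function(x, ...) {
  cat(sprintf("BCPNN config: tau_z_pre = %g ms, tau_z_post = %g ms, tau_p = %g ms, epsilon = %g\n",
              x$tau_z_pre, x$tau_z_post, x$tau_p, x$epsilon))
  invisible(x)
}

#' Zero-initialised trace state
#'
#' Traces start at exactly zero; the epsilon floor only enters the logarithms
#' at weight computation, never the trace dynamics.
#'
#' @param N number of units.
#' @return an object of class `trace_state` with `z_pre`, `z_post`, `p_pre`,
#'   `p_post` (length-`N` vectors), `p_joint` (`N x N`) and elapsed time `t`.
#' @export
trace_state <- function(N) {
  structure(list(z_pre = numeric(N), z_post = numeric(N),
                 p_pre = numeric(N), p_post = numeric(N),
                 p_joint = matrix(0, N, N), t = 0),
            class = "trace_state")
}

#' @export
print.trace_state <- function(x, ...) {
  cat(sprintf("Trace state (%d units, t = %g ms): p_pre in [%.3g, %.3g]\n",
              length(x$p_pre), x$t, min(x$p_pre), max(x$p_pre)))
  invisible(x)
}

#' One Euler step of the synaptic trace dynamics
#'
#' The z-traces low-pass filter the activation with their respective time
#' constants; the p-traces low-pass filter the z-traces (and, for the joint
#' trace, the outer product presynaptic-z times postsynaptic-z, with the
#' presynaptic unit on rows) with `tau_p`. z is updated first and the p
#' update uses the updated z, matching the compiled batch integration.
#'
#' @param traces a [trace_state()].
#' @param o activation vector (logical or 0/1).
#' @param cfg a [learning_config()].
#' @param dt step (ms); should be at most one fifth of the fastest z time
#'   constant.
#' @return the updated `trace_state`.
#' @export
update_traces <- function(traces, o, cfg, dt) {
  o <- as.numeric(o)
  z_pre <- traces$z_pre + (dt / cfg$tau_z_pre) * (o - traces$z_pre)
  z_post <- traces$z_post + (dt / cfg$tau_z_post) * (o - traces$z_post)
  kp <- dt / cfg$tau_p
  structure(list(
    z_pre = z_pre, z_post = z_post,
    p_pre = traces$p_pre + kp * (z_pre - traces$p_pre),
    p_post = traces$p_post + kp * (z_post - traces$p_post),
    p_joint = traces$p_joint + kp * (outer(z_pre, z_post) - traces$p_joint),
    t = traces$t + dt), class = "trace_state")
}

#' Offline batch training on an input series
#'
#' Integrates the trace dynamics over the whole clamped activation series
#' (starting from zero traces) in compiled code and computes the connectivity
#' once at the end with [weights_from_probabilities()]. Weights stay frozen
#' during recall.
#'
#' @param series an input series from [build_input_series()].
#' @param cfg a [learning_config()].
#' @param record_every optionally record the marginal p-traces every this
#'   many steps (0 = no history), for inspecting the probability evolution.
#' @param average_last_period if `TRUE` (default) the probabilities entering
#'   the weight computation are the time-average of the p-traces over the
#'   final protocol period. At the periodic steady state the EWMA p-traces
#'   oscillate around the activation probabilities with the presentation
#'   phase, so an end-of-series snapshot systematically inflates recently
#'   presented patterns; the period average is phase-free. Set to `FALSE`
#'   for the raw final-instant traces.
#' @return list with elements `connectivity` (a [connectivity()]), `traces`
#'   (the final instantaneous [trace_state()]), `traces_mean` (the
#'   period-averaged traces used for the weights, when averaging) and, if
#'   requested, `history`.
#' @export
train_offline <- function(series, cfg = learning_config(), record_every = 0,
                          average_last_period = TRUE) {
  stopifnot(inherits(series, "input_series"), inherits(cfg, "learning_config"))
  if (series$n_steps == 0) stop("empty input series")
  avg_steps <- if (isTRUE(average_last_period) &&
                   !is.null(series$period_steps))
    min(series$period_steps, series$n_steps) else 0L
  res <- cpp_train_traces(series$active, pattern_unit_matrix(series$patterns),
                          series$patterns$N, series$dt, cfg$tau_z_pre,
                          cfg$tau_z_post, cfg$tau_p,
                          as.integer(record_every), as.integer(avg_steps))
  traces <- structure(list(z_pre = as.numeric(res$z_pre),
                           z_post = as.numeric(res$z_post),
                           p_pre = as.numeric(res$p_pre),
                           p_post = as.numeric(res$p_post),
                           p_joint = res$p_joint, t = res$t),
                      class = "trace_state")
  est <- traces
  out <- list(connectivity = NULL, traces = traces)
  if (avg_steps > 0) {
    est <- structure(list(z_pre = traces$z_pre, z_post = traces$z_post,
                          p_pre = as.numeric(res$p_pre_mean),
                          p_post = as.numeric(res$p_post_mean),
                          p_joint = res$p_joint_mean, t = res$t),
                     class = "trace_state")
    out$traces_mean <- est
  }
  out$connectivity <- weights_from_probabilities(est, cfg)
  if (!is.null(res$history)) out$history <- res$history
  out
}

#' Log-odds weights and biases from probability traces
#'
#' The BCPNN weight is the log-odds ratio of co-activation against
#' independence, `w_ij = log(p_ij / (p_i p_j))`, with the presynaptic
#' marginal for the source and the postsynaptic marginal for the target; the
#' bias is `beta_j = log(p_j)`. Every probability entering a logarithm is
#' floored at `epsilon`, which removes the ill-defined zero-probability case
#' and bounds the weights.
#'
#' @param traces a [trace_state()].
#' @param cfg a [learning_config()] (supplies `epsilon`).
#' @return a [connectivity()].
#' @export
weights_from_probabilities <- function(traces, cfg = learning_config()) {
  eps <- cfg$epsilon
  p_i <- pmax(traces$p_pre, eps)
  p_j <- pmax(traces$p_post, eps)
  w <- log(pmax(traces$p_joint, eps)) - log(outer(p_i, p_j))
  connectivity(w, log(p_j), epsilon = eps)
}

#' Naive Hebbian association weights
#'
#' Baseline rule that weights an association purely by its relative
#' co-occurrence frequency, ignoring the overall activation probabilities of
#' the units involved: `w = counts / sum(counts)`. Two associations observed
#' equally often get equal weight no matter how active their source units
#' were otherwise — the failure mode the probabilistic (log-odds) rule avoids.
#'
#' @param coactivation_counts non-negative matrix of co-occurrence counts
#'   (source on rows).
#' @return weight matrix of the same shape.
#' @export
naive_hebbian_weights <- function(coactivation_counts) {
  m <- as.matrix(coactivation_counts)
  if (any(m < 0)) stop("counts must be non-negative")
  tot <- sum(m)
  if (tot == 0) stop("all-zero counts")
  m / tot
}
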