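#' Fit a sequence-learning attractor network with the BCPNN rule
#'
#' The main entry point: expands patterns, sequences and a timed protocol
#' into a clamped activation series, integrates the synaptic z- and p-traces
#' over it, and computes the log-odds connectivity once at the end (offline
#' batch learning). The returned object carries everything needed to inspect
#' the learned structure ([summary()], [coef()]), predict recall tempo
#' ([predict()]) and run recall episodes ([simulate()]).
#'
#' @param patterns a [pattern_set()].
#' @param sequences a list of [sequence_spec()]s (integer vectors are
#'   coerced); a single vector is treated as one sequence.
#' @param protocol a [training_protocol()].
#' @param config a [learning_config()].
#' @param dt integration step for training (ms); must be at most one fifth of
#'   the fastest z time constant.
#' @param record_every optionally record marginal p-traces every this many
#'   steps.
#' @return an object of class `bcpnn_net` with components `w`, `beta`,
#'   `connectivity`, `traces`, `patterns`, `sequences`, `protocol`, `config`,
#'   `dt` and `call`.
#' @examples
#' ps <- orthogonal_patterns(H = 1, U = 5, n_patterns = 5)
#' fit <- bcpnn(ps, list(1:5), training_protocol(T_p = 100, epochs = 10),
#'              learning_config(tau_z_pre = 50, tau_z_post = 5))
#' summary(fit)
#' @export
bcpnn <- function(patterns, sequences, protocol = training_protocol(),
                  config = learning_config(), dt = NULL, record_every = 0) {
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, function(s)
    if (inherits(s, "sequence_spec")) s else sequence_spec(s))
  if (is.null(dt)) dt <- min(config$tau_z_pre, config$tau_z_post) / 5
  if (dt > min(config$tau_z_pre, config$tau_z_post) / 5)
    stop("dt must be at most one fifth of the fastest z time constant")
  series <- build_input_series(patterns, sequences, protocol, dt = dt)
  trained <- train_offline(series, config, record_every = record_every)
  structure(list(w = trained$connectivity$w, beta = trained$connectivity$beta,
                 connectivity = trained$connectivity, traces = trained$traces,
                 history = trained$history, patterns = patterns,
                 sequences = sequences, protocol = protocol, config = config,
                 dt = dt, call = match.call()),
            class = "bcpnn_net")
}

#' @export
print.bcpnn_net <- function(x, ...) {
  cat("BCPNN sequence network\n")
  cat("  ", length(x$patterns$patterns), " patterns over ", x$patterns$H,
      " hypercolumn(s) x ", x$patterns$U, " units (N = ", x$patterns$N,
      ")\n", sep = "")
  cat("  sequences:", length(x$sequences), "| protocol:",
      sprintf("T_p = %g ms, IPI = %g ms, %d epochs", x$protocol$T_p,
              x$protocol$IPI, x$protocol$epochs), "\n")
  cat(sprintf("  traces: tau_z_pre = %g ms, tau_z_post = %g ms, tau_p = %g ms\n",
              x$config$tau_z_pre, x$config$tau_z_post, x$config$tau_p))
  cat(sprintf("  weights in [%.2f, %.2f], bias in [%.2f, %.2f]\n",
              min(x$w), max(x$w), min(x$beta), max(x$beta)))
  invisible(x)
}

#' @export
coef.bcpnn_net <- function(object, ...) {
  list(w = object$w, beta = object$beta)
}

#' @export
summary.bcpnn_net <- function(object, params = network_params(), ...) {
  trans <- lapply(object$sequences, function(s)
    summarize_transitions(object$connectivity, object$patterns, s, params))
  structure(list(fit = object, transitions = trans, params = params),
            class = "summary.bcpnn_net")
}

#' @export
print.summary.bcpnn_net <- function(x, ...) {
  print(x$fit)
  for (i in seq_along(x$transitions)) {
    cat("\nSequence", i, "transitions:\n")
    print(x$transitions[[i]], digits = 3)
  }
  invisible(x)
}

#' Predicted recall timing for a fitted network
#'
#' Applies the closed-form persistence-time theory to the learned
#' connectivity: per transition of the chosen sequence, the transition
#' parameter `B` and the predicted dwell time under the given adaptation
#' gain (or under gains set for a target dwell time).
#'
#' @param object a fitted `bcpnn_net`.
#' @param sequence index of the trained sequence to predict for.
#' @param g_a adaptation gain (scalar or per-unit); alternatively give
#'   `T_per` to set gains by inversion.
#' @param T_per target dwell time (ms); when supplied, per-pattern gains from
#'   [gains_for_target()] are used.
#' @param params a [network_params()] supplying the time constants.
#' @param ... unused.
#' @return the transition data frame of [summarize_transitions()].
#' @export
predict.bcpnn_net <- function(object, sequence = 1, g_a = NULL, T_per = NULL,
                              params = network_params(), ...) {
  if (!is.null(T_per)) {
    params$g_a <- gains_for_target(object$connectivity, object$patterns,
                                   object$sequences, T_per, params)
  } else if (!is.null(g_a)) {
    params$g_a <- g_a
  }
  summarize_transitions(object$connectivity, object$patterns,
                        object$sequences[[sequence]], params)
}

#' Simulate recall episodes from a fitted network
#'
#' Runs `nsim` independently seeded recall episodes of a trained sequence,
#' cueing its first pattern. The recall tempo is set either directly through
#' `g_a` or through a target dwell time `T_per` (gain inversion).
#'
#' @param object a fitted `bcpnn_net`.
#' @param nsim number of episodes.
#' @param seed integer seed (episode `i` uses a child seed spawned from it).
#' @param sequence index of the trained sequence to recall.
#' @param sigma_out noise level.
#' @param T_per target dwell time (ms), used to set per-pattern gains; or
#' @param g_a explicit adaptation gain.
#' @param total_duration episode length (ms); a default is derived from the
#'   expected dwell times.
#' @param record store full trajectories.
#' @param params a [network_params()].
#' @param ... unused.
#' @return a list of `recall_result`s (length `nsim`), or a single
#'   `recall_result` when `nsim = 1`.
#' @export
simulate.bcpnn_net <- function(object, nsim = 1, seed = 1, sequence = 1,
                               sigma_out = 0, T_per = NULL, g_a = NULL,
                               total_duration = NULL, record = FALSE,
                               params = network_params(), ...) {
  target <- object$sequences[[sequence]]
  params$sigma_out <- sigma_out
  if (!is.null(T_per)) {
    params$g_a <- gains_for_target(object$connectivity, object$patterns,
                                   object$sequences, T_per, params)
  } else if (!is.null(g_a)) {
    params$g_a <- g_a
  }
  if (is.null(total_duration))
    total_duration <- default_recall_duration(object$connectivity, params,
                                              object$patterns, target)
  runs <- lapply(seq_len(nsim), function(i)
    run_recall(object$connectivity, params, object$patterns,
               cue = target[1], total_duration = total_duration,
               target = target, record = record,
               seed = child_seed(seed, i)))
  if (nsim == 1) runs[[1]] else runs
}

#' Plot the learned weight matrix
#'
#' Base-graphics image of the weight matrix (source unit on the vertical
#' axis, matching the usual connectivity-matrix orientation).
#'
#' @param x a fitted `bcpnn_net`.
#' @param ... passed to [graphics::image()].
#' @export
plot.bcpnn_net <- function(x, ...) {
  N <- nrow(x$w)
  graphics::image(seq_len(N), seq_len(N), t(x$w[N:1, , drop = FALSE]),
                  xlab = "target unit j", ylab = "source unit i",
                  main = "BCPNN weight matrix", axes = FALSE, ...)
  graphics::axis(1); graphics::axis(2, at = seq_len(N), labels = rev(seq_len(N)))
  invisible(x)
}

#' Write / read a learned connectivity as plain text
#'
#' Dense weight matrix and bias as CSV plus a JSON metadata sidecar.
#'
#' @param conn a [connectivity()].
#' @param path base path; writes `<path>_w.csv`, `<path>_beta.csv`,
#'   `<path>.json`.
#' @param meta optional metadata list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(conn, path, meta = list()) {
  stopifnot(inherits(conn, "connectivity"))
  utils::write.table(conn$w, paste0(path, "_w.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(beta = conn$beta), paste0(path, "_beta.csv"),
                     sep = ",", row.names = FALSE)
  jsonlite::write_json(c(list(N = conn$N), meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  w <- as.matrix(utils::read.table(paste0(path, "_w.csv"), sep = ","))
  beta <- utils::read.csv(paste0(path, "_beta.csv"))$beta
  dimnames(w) <- NULL
  connectivity(w, beta)
}
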