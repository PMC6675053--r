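#' Network dynamics parameters
#'
#' Constants of the rate dynamics: the synaptic time constant `tau_s`, the
#' adaptation time constant `tau_a`, the adaptation gain `g_a` (scalar or
#' per-unit vector, in units of the weights), the target stationary standard
#' deviation `sigma_out` of the support current under noise, and the Euler
#' integration step `dt`. `tau_s < tau_a` is required (the quasi-static
#' persistence-time theory and the Ornstein-Uhlenbeck noise convention both
#' rest on the separation of time scales).
#'
#' @param tau_s synaptic time constant (ms), default 10.
#' @param tau_a adaptation time constant (ms), default 250.
#' @param g_a adaptation gain (scalar or per-unit vector), default 1.
#' @param sigma_out target stationary sd of `s` under noise, default 0.
#' @param dt integration step (ms), default 0.5; must satisfy
#'   `dt <= tau_s / 5`.
#' @param cue_amplitude additive cue current applied to cue-pattern units.
#' @param cue_duration cue duration (ms).
#' @return an object of class `network_params`.
#' @export
network_params <- function(tau_s = 10, tau_a = 250, g_a = 1, sigma_out = 0,
                           dt = 0.5, cue_amplitude = 1, cue_duration = 50) {
  stopifnot(tau_s > 0, tau_a > 0, sigma_out >= 0, all(g_a >= 0), dt > 0)
  if (tau_s >= tau_a)
    stop("tau_s must be smaller than tau_a (separation of time scales)")
  if (tau_s / tau_a > 0.5)
    warning("tau_s / tau_a > 0.5: the persistence-time theory assumes ",
            "tau_s << tau_a")
  if (dt > tau_s / 5)
    stop("dt must be at most tau_s / 5 for stable integration")
  structure(list(tau_s = tau_s, tau_a = tau_a, g_a = g_a,
                 sigma_out = sigma_out, dt = dt,
                 cue_amplitude = cue_amplitude, cue_duration = cue_duration),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("Network parameters: tau_s = %g ms, tau_a = %g ms, sigma_out = %g, dt = %g ms\n",
              x$tau_s, x$tau_a, x$sigma_out, x$dt))
  cat("  g_a:", if (length(x$g_a) == 1) x$g_a else
    paste0("per-unit vector [", paste(round(range(x$g_a), 3), collapse = ", "), "]"),
    "\n")
  invisible(x)
}

# user-facing sigma_out (stationary sd of s) -> diffusion amplitude of the
# per-step increment sigma_in * sqrt(dt); stationary OU variance
# sigma_in^2 * tau_s / 2 then equals sigma_out^2.
sigma_in_from_out <- function(sigma_out, tau_s) sigma_out * sqrt(2 / tau_s)

#' Learned connectivity
#'
#' The product of training: an `N x N` weight matrix (`w[i, j]` = weight from
#' unit `i` to unit `j`) and a bias vector `beta`. With the probability floor
#' `epsilon` applied inside the logarithms, all weights are bounded in
#' `[2 log(epsilon), -log(epsilon)]` and biases in `[log(epsilon), 0]`.
#'
#' @param w numeric `N x N` matrix.
#' @param beta numeric vector of length `N`.
#' @param epsilon probability floor used for the bound check, default `1e-7`.
#' @return an object of class `connectivity`.
#' @export
connectivity <- function(w, beta, epsilon = 1e-7) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == ncol(w), length(beta) == nrow(w))
  if (!all(is.finite(w)) || !all(is.finite(beta)))
    stop("connectivity must be finite")
  if (any(w < 2 * log(epsilon) - 1e-9) || any(w > -log(epsilon) + 1e-9))
    stop("weights outside the bounds implied by the epsilon floor")
  structure(list(w = w, beta = as.numeric(beta), N = nrow(w)),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("Connectivity: %d x %d weights in [%.2f, %.2f], bias in [%.2f, %.2f]\n",
              x$N, x$N, min(x$w), max(x$w), min(x$beta), max(x$beta)))
  invisible(x)
}

#' Handcrafted sequence-chain connectivity
#'
#' Builds the stereotyped connectivity that supports ordered recall of the
#' chain `1 -> 2 -> ... -> n`: self-excitation `w_self` within a pattern,
#' `w_next` from each pattern to its successor, and uniform `w_rest`
#' (strongest inhibition) everywhere else. Useful for studying the recall
#' dynamics in isolation from learning.
#'
#' @param n_patterns chain length.
#' @param H number of hypercolumns (each with `U = n_patterns` units).
#' @param w_self,w_next,w_rest weight values (`w_self > w_next > w_rest`).
#' @param beta uniform bias value.
#' @return list with a [connectivity()] and the matching
#'   [orthogonal_patterns()] set.
#' @export
chain_connectivity <- function(n_patterns, H = 1, w_self = 1, w_next = -1,
                               w_rest = -3, beta = 0) {
  stopifnot(w_self > w_next, w_next > w_rest)
  ps <- orthogonal_patterns(H = H, U = n_patterns, n_patterns = n_patterns)
  N <- ps$N
  w <- matrix(w_rest, N, N)
  for (k in seq_len(n_patterns)) {
    uk <- pattern_units(ps, k)
    w[uk, uk] <- w_self
    if (k < n_patterns) w[uk, pattern_units(ps, k + 1)] <- w_next
  }
  list(connectivity = connectivity(w, rep(beta, N)), patterns = ps)
}

#' Winner-take-all selection
#'
#' Selects, within each hypercolumn, the unit with the maximal support
#' current; ties are broken deterministically in favour of the lowest unit
#' index. A hypercolumn is never silent.
#'
#' @param s numeric vector of support currents.
#' @param layout either a single hypercolumn size `U` (equal-sized
#'   hypercolumns laid out contiguously) or a list of index vectors
#'   partitioning `seq_along(s)`.
#' @return logical activation vector with exactly one `TRUE` per hypercolumn.
#' @export
wta_select <- function(s, layout) {
  if (is.numeric(layout) && length(layout) == 1) {
    U <- as.integer(layout)
    if (length(s) %% U != 0) stop("length(s) is not a multiple of U")
    layout <- split(seq_along(s), rep(seq_len(length(s) / U), each = U))
  }
  if (any(lengths(layout) == 0)) stop("empty hypercolumn")
  idx <- sort(unname(unlist(layout)))
  if (!identical(as.integer(idx), seq_along(s)))
    stop("layout must partition the units")
  o <- logical(length(s))
  for (block in layout) o[block[which.max(s[block])]] <- TRUE
  o
}

#' One Euler(-Maruyama) step of the rate dynamics
#'
#' Advances the network state by one step `dt`: the support current `s`
#' integrates the bias, the recurrent drive `(1/H) * t(w) %*% o`, the
#' adaptation current `-g_a * a`, leak, external current `I` and (for
#' `sigma_out > 0`) an additive Gaussian increment; the adaptation `a` relaxes
#' toward the activation `o`; finally the winner-take-all map recomputes `o`.
#' This is the reference single-step implementation; [run_recall()] runs the
#' same scheme in compiled code.
#'
#' @param state list with numeric `s`, logical `o`, numeric `a`, time `t`.
#' @param conn a [connectivity()].
#' @param params a [network_params()].
#' @param patterns a [pattern_set()] providing the hypercolumn layout.
#' @param I external current vector (default none).
#' @return the updated state.
#' @export
step_dynamics <- function(state, conn, params, patterns, I = NULL) {
  N <- conn$N
  if (is.null(I)) I <- numeric(N)
  g_a <- rep_len(params$g_a, N)
  drive <- conn$beta + as.numeric(crossprod(conn$w, state$o)) / patterns$H -
    g_a * state$a - state$s + I
  s <- state$s + (params$dt / params$tau_s) * drive
  if (params$sigma_out > 0) {
    s <- s + sigma_in_from_out(params$sigma_out, params$tau_s) *
      sqrt(params$dt) * stats::rnorm(N)
  }
  a <- state$a + (params$dt / params$tau_a) * (state$o - state$a)
  if (!all(is.finite(s))) stop("integration diverged to non-finite state")
  list(s = s, o = wta_select(s, patterns$U), a = a,
       t = state$t + params$dt)
}

#' Initial network state
#'
#' `s` starts at the bias (its noise-free, input-free asymptote), adaptation
#' at zero, and the activation from the first winner-take-all application.
#'
#' @inheritParams step_dynamics
#' @return a state list for [step_dynamics()].
#' @export
initial_state <- function(conn, patterns) {
  list(s = conn$beta, o = wta_select(conn$beta, patterns$U),
       a = numeric(conn$N), t = 0)
}

#' Run a recall episode
#'
#' Cues one pattern with a strong additive current for `cue_duration`, then
#' lets the recurrent dynamics run freely until `total_duration`. Pattern
#' activation events are extracted with [detect_pattern_activations()] and,
#' if a target sequence is supplied, success is judged with
#' [evaluate_success()].
#'
#' @param conn a [connectivity()].
#' @param params a [network_params()]; `sigma_out`, `g_a`, `dt`,
#'   `cue_amplitude` and `cue_duration` are taken from here.
#' @param patterns a [pattern_set()].
#' @param cue pattern id to cue.
#' @param total_duration episode length (ms).
#' @param target optional [sequence_spec()] to judge success against.
#' @param record if `TRUE`, store the full `s`/`a` trajectories.
#' @param seed optional seed for the noise stream.
#' @return an object of class `recall_result`: data frame `events`
#'   (`pattern`, `onset`, `offset`, `duration` in ms), `success` (logical or
#'   `NA`), the per-step `winners` matrix, and optional trajectories.
#' @export
run_recall <- function(conn, params, patterns, cue, total_duration,
                       target = NULL, record = FALSE, seed = NULL) {
  stopifnot(inherits(conn, "connectivity"), inherits(params, "network_params"),
            inherits(patterns, "pattern_set"))
  if (cue < 1 || cue > length(patterns$patterns)) stop("unknown cue pattern")
  if (total_duration < params$cue_duration)
    stop("total_duration must be at least the cue duration")
  if (!is.null(seed)) set.seed(seed)
  g_a <- rep_len(params$g_a, conn$N)
  res <- cpp_run_recall(conn$w, conn$beta, patterns$H, patterns$U,
                        params$tau_s, params$tau_a, g_a,
                        sigma_in_from_out(params$sigma_out, params$tau_s),
                        params$dt, total_duration,
                        pattern_units(patterns, cue) - 1L,
                        params$cue_amplitude, params$cue_duration,
                        isTRUE(record))
  events <- detect_pattern_activations(res$winners, patterns,
                                       dt = params$dt, tau_s = params$tau_s)
  success <- if (is.null(target)) NA else evaluate_success(events, target)
  structure(list(events = events, success = success, winners = res$winners,
                 s = res$s, a = res$a, dt = params$dt,
                 total_duration = total_duration, cue = cue),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("Recall episode (%g ms, cue = pattern %d): %d event(s)\n",
              x$total_duration, x$cue, nrow(x$events)))
  if (nrow(x$events))
    cat("  order:", paste(x$events$pattern, collapse = " -> "), "\n")
  if (!is.na(x$success)) cat("  success:", x$success, "\n")
  invisible(x)
}

#' Extract pattern activation events from an activation time series
#'
#' A pattern is considered active on steps where all of its `H` units are
#' simultaneously the winners of their hypercolumns. Maximal such intervals
#' longer than `tau_s` are kept as events (shorter blips are discarded);
#' events of the same pattern separated by a gap of at most `tau_s` are
#' merged, so that sub-`tau_s` winner-take-all jitter around transitions does
#' not split a dwell.
#'
#' @param o_timeseries either the compact per-step winners matrix (steps x
#'   `H`, within-hypercolumn indices) or a dense logical steps x `N`
#'   activation matrix.
#' @param patterns a [pattern_set()].
#' @param dt step size of the series (ms).
#' @param tau_s the activation threshold duration (ms).
#' @return data frame with columns `pattern`, `onset`, `offset`, `duration`.
#' @export
detect_pattern_activations <- function(o_timeseries, patterns, dt, tau_s = 10) {
  winners <- as_winners(o_timeseries, patterns)
  n <- nrow(winners)
  pid <- integer(n)
  um <- matrix(unlist(patterns$patterns), ncol = patterns$H, byrow = TRUE)
  for (k in seq_len(nrow(um))) {
    hit <- winners[, 1] == um[k, 1]
    h <- 2L
    while (h <= patterns$H && any(hit)) {
      hit <- hit & winners[, h] == um[k, h]
      h <- h + 1L
    }
    pid[hit] <- k
  }
  r <- rle(pid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L & r$lengths * dt > tau_s
  ev <- data.frame(pattern = r$values[keep],
                   onset = (starts[keep] - 1L) * dt,
                   offset = ends[keep] * dt)
  if (nrow(ev) > 1) {
    merged <- ev[1, ]
    for (i in 2:nrow(ev)) {
      last <- nrow(merged)
      if (ev$pattern[i] == merged$pattern[last] &&
          ev$onset[i] - merged$offset[last] <= tau_s) {
        merged$offset[last] <- ev$offset[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  ev$duration <- ev$offset - ev$onset
  rownames(ev) <- NULL
  ev
}

as_winners <- function(x, patterns) {
  if (is.logical(x) || (is.matrix(x) && ncol(x) == patterns$N &&
                        all(x %in% c(0, 1)))) {
    t(apply(x, 1, function(row) {
      w <- integer(patterns$H)
      for (h in seq_len(patterns$H)) {
        block <- row[((h - 1) * patterns$U + 1):(h * patterns$U)]
        w[h] <- which(as.logical(block))[1]
      }
      w
    }))
  } else {
    x
  }
}

#' Judge sequence-recall success
#'
#' Conservative criterion: recall is successful if and only if, starting from
#' the cue, the extracted events reproduce the target pattern order exactly —
#' no skipped patterns and no intruding patterns; events after the last
#' target pattern are ignored. Consecutive repeats of the same pattern are
#' collapsed first: under noise a dwell can be split into two events by a
#' transient partial dropout that the recurrent drive corrects, and such a
#' re-entry is a detection artifact, not an intrusion.
#'
#' @param events event data frame from [detect_pattern_activations()], or an
#'   integer vector of event pattern ids.
#' @param target a [sequence_spec()] (or integer vector).
#' @return logical.
#' @export
evaluate_success <- function(events, target) {
  ids <- if (is.data.frame(events)) events$pattern else as.integer(events)
  ids <- rle(ids)$values
  target <- as.integer(unclass(target))
  length(ids) >= length(target) &&
    all(ids[seq_along(target)] == target)
}
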