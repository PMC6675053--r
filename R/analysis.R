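#' Closed-form persistence time of an attractor transition
#'
#' For orthogonal patterns and a homogeneous protocol the time a pattern
#' stays active before handing over to its successor is
#' `T_per = tau_a * log(1 / (1 - B)) + tau_a * log(1 / (1 - tau_s / tau_a))`
#' with the dimensionless transition parameter
#' `B = (dw + dbeta) / g_a`, where `dw = w_self - w_next` and
#' `dbeta = beta_self - beta_next`. The formula is defined only on
#' `0 < B < 1`: `B <= 0` means the connectivity does not favour a forward
#' transition, `B >= 1` means the adaptation is too weak ever to overcome the
#' self-excitation.
#'
#' @param dw weight difference `w_self - w_next`.
#' @param dbeta bias difference `beta_self - beta_next` (0 for homogeneous
#'   training).
#' @param g_a adaptation gain (> 0).
#' @param tau_s,tau_a synaptic and adaptation time constants (ms),
#'   `tau_s < tau_a`.
#' @return predicted persistence time in ms (vectorised over `dw`, `dbeta`,
#'   `g_a`).
#' @seealso [gain_for_target()] for the exact inversion,
#'   [persistence_time_floor()] for the `B -> 0` lower bound.
#' @export
theoretical_persistence_time <- function(dw, dbeta = 0, g_a, tau_s = 10,
                                         tau_a = 250) {
  stopifnot(all(g_a > 0), tau_s < tau_a)
  B <- (dw + dbeta) / g_a
  bad <- B <= 0 | B >= 1
  if (any(bad)) {
    cond <- structure(
      class = c("bcpnnseq_domain_error", "error", "condition"),
      list(message = paste0("persistence time undefined for B outside (0, 1); got B = ",
                            paste(signif(B[bad], 6), collapse = ", ")),
           call = sys.call(-1), B = B[bad]))
    stop(cond)
  }
  tau_a * log(1 / (1 - B)) + tau_a * log(1 / (1 - tau_s / tau_a))
}

#' Lower bound of the persistence time
#'
#' The `B -> 0+` limit of the closed-form persistence time,
#' `tau_a * log(1 / (1 - tau_s / tau_a))`, which is bounded below by `tau_s`.
#'
#' @inheritParams theoretical_persistence_time
#' @return the limit in ms.
#' @export
persistence_time_floor <- function(tau_s = 10, tau_a = 250) {
  stopifnot(tau_s < tau_a)
  tau_a * log(1 / (1 - tau_s / tau_a))
}

#' Adaptation gain for a target persistence time
#'
#' Exact algebraic inverse of the persistence-time formula: solving for the
#' transition parameter gives
#' `B = 1 - exp(-T_per / tau_a) / (1 - tau_s / tau_a)` and hence
#' `g_a = (dw + dbeta) / B`. Composition with
#' [theoretical_persistence_time()] is the identity to machine precision.
#'
#' @inheritParams theoretical_persistence_time
#' @param target_T_per desired persistence time (ms); must exceed
#'   [persistence_time_floor()].
#' @return adaptation gain (vectorised).
#' @export
gain_for_target <- function(dw, dbeta = 0, target_T_per, tau_s = 10,
                            tau_a = 250) {
  stopifnot(tau_s < tau_a)
  if (any(dw + dbeta <= 0))
    stop("dw + dbeta must be positive (w_self must exceed w_next)")
  floor_ms <- persistence_time_floor(tau_s, tau_a)
  if (any(target_T_per <= floor_ms)) {
    cond <- structure(
      class = c("bcpnnseq_domain_error", "error", "condition"),
      list(message = sprintf(
        "target persistence time must exceed the B -> 0 lower bound (%.4f ms)",
        floor_ms), call = sys.call(-1)))
    stop(cond)
  }
  B <- 1 - exp(-target_T_per / tau_a) / (1 - tau_s / tau_a)
  (dw + dbeta) / B
}

# effective pattern-level drive a -> b: mean over target units of the
# 1/H-normalised summed input they receive when pattern a is fully active
pattern_drive <- function(conn, patterns, a, b) {
  ua <- pattern_units(patterns, a)
  ub <- pattern_units(patterns, b)
  mean(colSums(conn$w[ua, ub, drop = FALSE])) / patterns$H
}

#' Transition summaries of a sequence under a connectivity
#'
#' For each ordered transition `k -> k+1` of the sequence, reads off the
#' pattern-level effective weights (unit weights aggregated consistently with
#' the `1/H` normalisation of the current equation): `w_self`, `w_next`,
#' `w_prev` (back to the predecessor), `w_rest` (largest drive to any other
#' pattern), the biases, the differences `dw_next`, `dbeta_next`, the
#' transition parameter `B` and, where `0 < B < 1`, the predicted persistence
#' time. For overlapping (non-orthogonal) patterns the prediction is
#' approximate.
#'
#' @param conn a [connectivity()].
#' @param patterns a [pattern_set()].
#' @param seq a [sequence_spec()] (or integer vector).
#' @param params a [network_params()] supplying `g_a`, `tau_s`, `tau_a`.
#' @return data frame with one row per transition.
#' @export
summarize_transitions <- function(conn, patterns, seq,
                                  params = network_params()) {
  ids <- as.integer(unclass(seq))
  n_pat <- length(patterns$patterns)
  if (any(ids < 1 | ids > n_pat)) stop("sequence refers to unknown patterns")
  g_a <- rep_len(params$g_a, conn$N)
  out <- vector("list", length(ids) - 1L)
  for (t in seq_len(length(ids) - 1L)) {
    k <- ids[t]; nxt <- ids[t + 1L]
    w_self <- pattern_drive(conn, patterns, k, k)
    w_next <- pattern_drive(conn, patterns, k, nxt)
    w_prev <- if (t > 1) pattern_drive(conn, patterns, k, ids[t - 1L]) else NA_real_
    others <- setdiff(seq_len(n_pat), c(k, nxt, if (t > 1) ids[t - 1L]))
    w_rest <- if (length(others))
      max(vapply(others, function(m) pattern_drive(conn, patterns, k, m),
                 numeric(1)))
    else NA_real_
    beta_self <- mean(conn$beta[pattern_units(patterns, k)])
    beta_next <- mean(conn$beta[pattern_units(patterns, nxt)])
    g_k <- mean(g_a[pattern_units(patterns, k)])
    dw <- w_self - w_next
    db <- beta_self - beta_next
    B <- if (g_k > 0) (dw + db) / g_k else NA_real_
    T_pred <- if (!is.na(B) && B > 0 && B < 1)
      theoretical_persistence_time(dw, db, g_k, params$tau_s, params$tau_a)
    else NA_real_
    out[[t]] <- data.frame(from = k, to = nxt, w_self = w_self,
                           w_next = w_next, w_prev = w_prev, w_rest = w_rest,
                           beta_self = beta_self, beta_next = beta_next,
                           dw_next = dw, dbeta_next = db, g_a = g_k, B = B,
                           T_per_pred = T_pred)
  }
  do.call(rbind, out)
}

#' Per-unit adaptation gains targeting a persistence time
#'
#' Inverts the persistence-time formula per pattern: each pattern's units get
#' the gain that gives the pattern's outgoing transition the target dwell
#' time, using that pattern's own `dw_next + dbeta_next` under the trained
#' connectivity. A pattern appearing in several sequences (or a unit shared
#' by several patterns) gets the mean of the gains implied by each context;
#' terminal patterns inherit their sequence's mean gain.
#'
#' @param conn a [connectivity()].
#' @param patterns a [pattern_set()].
#' @param sequences list of sequences.
#' @param target_T_per desired dwell time (ms).
#' @param params a [network_params()] (time constants).
#' @return numeric vector of length `N`.
#' @export
gains_for_target <- function(conn, patterns, sequences, target_T_per,
                             params = network_params()) {
  if (!is.list(sequences)) sequences <- list(sequences)
  n_pat <- length(patterns$patterns)
  gain_lists <- vector("list", n_pat)
  for (s in sequences) {
    tr <- summarize_transitions(conn, patterns, s, params)
    gains <- gain_for_target(tr$dw_next, tr$dbeta_next, target_T_per,
                             params$tau_s, params$tau_a)
    ids <- as.integer(unclass(s))
    for (t in seq_along(gains))
      gain_lists[[ids[t]]] <- c(gain_lists[[ids[t]]], gains[t])
    last <- ids[length(ids)]
    gain_lists[[last]] <- c(gain_lists[[last]], mean(gains))
  }
  pat_gain <- vapply(gain_lists, function(g)
    if (is.null(g)) NA_real_ else mean(g), numeric(1))
  pat_gain[is.na(pat_gain)] <- mean(pat_gain, na.rm = TRUE)
  unit_gains <- matrix(NA_real_, length(patterns$patterns), patterns$N)
  for (k in seq_len(n_pat)) unit_gains[k, pattern_units(patterns, k)] <- pat_gain[k]
  g <- colMeans(unit_gains, na.rm = TRUE)
  g[is.nan(g)] <- mean(pat_gain)
  g
}

wald_ci <- function(p_hat, n) {
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  c(max(0, p_hat - half), min(1, p_hat + half))
}

# core Monte-Carlo loop over a Bernoulli trial function; trial_fn(i) must use
# the current RNG stream and return a logical
success_rate_core <- function(trial_fn, n_trials, seed) {
  successes <- 0L
  for (i in seq_len(n_trials)) {
    set.seed(child_seed(seed, i))
    if (isTRUE(trial_fn(i))) successes <- successes + 1L
  }
  p_hat <- successes / n_trials
  ci <- wald_ci(p_hat, n_trials)
  structure(list(p_hat = p_hat, n_trials = as.integer(n_trials),
                 ci_low = ci[1], ci_high = ci[2], seed = seed),
            class = "success_rate_estimate")
}

#' @export
print.success_rate_estimate <- function(x, ...) {
  cat(sprintf("Success rate: %.3f (Wald 95%% CI [%.3f, %.3f], n = %d)\n",
              x$p_hat, x$ci_low, x$ci_high, x$n_trials))
  invisible(x)
}

#' Estimate the sequence-recall success rate under noise
#'
#' Runs `n_trials` independently seeded recall episodes at the given noise
#' level and reports the fraction of fully correct recalls with its Wald 95%
#' confidence interval `p +- 1.96 * sqrt(p (1 - p) / n)` (clipped to `[0, 1]`).
#' Trial seeds are spawned from `seed` by a counter scheme, so enlarging
#' `n_trials` does not reshuffle earlier trials.
#'
#' @param conn a [connectivity()].
#' @param params a [network_params()]; its `sigma_out` is overridden by the
#'   `sigma_out` argument if given.
#' @param patterns a [pattern_set()].
#' @param seq target [sequence_spec()]; its first pattern is cued.
#' @param sigma_out noise level (stationary sd of `s`); default taken from
#'   `params`.
#' @param n_trials number of Monte-Carlo trials.
#' @param seed integer seed.
#' @param total_duration episode length (ms); defaults to cue +
#'   `1.5 * length(seq) * mean predicted T_per` (and at least 500 ms more
#'   than the cue).
#' @param trial_fn optional replacement trial generator
#'   `function(i) logical`, used for calibration tests; when supplied the
#'   network arguments are ignored.
#' @return a `success_rate_estimate` with fields `p_hat`, `n_trials`,
#'   `ci_low`, `ci_high`, `seed`.
#' @export
estimate_success_rate <- function(conn = NULL, params = NULL, patterns = NULL,
                                  seq = NULL, sigma_out = NULL,
                                  n_trials = 200, seed = 1,
                                  total_duration = NULL, trial_fn = NULL) {
  stopifnot(n_trials >= 1)
  if (is.null(trial_fn)) {
    stopifnot(inherits(conn, "connectivity"),
              inherits(params, "network_params"))
    if (!is.null(sigma_out)) params$sigma_out <- sigma_out
    target <- sequence_spec(unclass(seq))
    if (is.null(total_duration))
      total_duration <- default_recall_duration(conn, params, patterns, target)
    trial_fn <- function(i) {
      run_recall(conn, params, patterns, cue = target[1],
                 total_duration = total_duration, target = target)$success
    }
  }
  success_rate_core(trial_fn, n_trials, seed)
}

default_recall_duration <- function(conn, params, patterns, target) {
  tr <- summarize_transitions(conn, patterns, target, params)
  tper <- tr$T_per_pred
  est <- if (all(is.na(tper))) 300 else mean(tper, na.rm = TRUE)
  params$cue_duration + max(500, 1.5 * length(target) * est)
}

#' Stochastic bisection for the 50% noise threshold
#'
#' Finds `sigma_50`, the noise level at which the probability of fully
#' correct sequence recall crosses 0.5, by naive bisection on the Monte-Carlo
#' success-rate estimates: the search stops as soon as 0.5 lies inside the
#' Wald confidence interval of the estimate at the current midpoint.
#'
#' @inheritParams estimate_success_rate
#' @param bracket `c(sigma_lo, sigma_hi)` with success above 0.5 at the lower
#'   and below 0.5 at the upper end.
#' @param n_trials trials per bisection step.
#' @param max_iter iteration cap.
#' @param trial_fn optional replacement generator `function(sigma, i)
#'   logical` for calibration tests.
#' @return an object of class `sigma50_result`: `sigma50`, `iterations`,
#'   `final_estimate`, and the bracket/estimate `history` data frame.
#' @export
find_sigma50 <- function(conn = NULL, params = NULL, patterns = NULL,
                         seq = NULL, bracket = c(0, 3), n_trials = 200,
                         seed = 1, max_iter = 25, total_duration = NULL,
                         trial_fn = NULL) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (is.null(trial_fn)) {
    stopifnot(inherits(conn, "connectivity"),
              inherits(params, "network_params"))
    target <- sequence_spec(unclass(seq))
    if (is.null(total_duration))
      total_duration <- default_recall_duration(conn, params, patterns, target)
    trial_fn <- function(sigma, i) {
      p <- params
      p$sigma_out <- sigma
      run_recall(conn, p, patterns, cue = target[1],
                 total_duration = total_duration, target = target)$success
    }
  }
  est_at <- function(sigma, iter) {
    success_rate_core(function(i) trial_fn(sigma, i), n_trials,
                      child_seed(seed, 10000 + iter))
  }
  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- est_at(lo, 0L)
  e_hi <- est_at(hi, 1L)
  if (e_lo$p_hat <= 0.5 || e_hi$p_hat >= 0.5) {
    cond <- structure(
      class = c("bcpnnseq_bracket_error", "error", "condition"),
      list(message = sprintf(
        "invalid bracket: success %.3f at sigma = %g, %.3f at sigma = %g (need > 0.5 > )",
        e_lo$p_hat, lo, e_hi$p_hat, hi), call = sys.call(-1)))
    stop(cond)
  }
  history <- data.frame(iteration = integer(0), sigma = numeric(0),
                        p_hat = numeric(0), ci_low = numeric(0),
                        ci_high = numeric(0))
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    est <- est_at(mid, 1L + iter)
    history <- rbind(history, data.frame(iteration = iter, sigma = mid,
                                         p_hat = est$p_hat,
                                         ci_low = est$ci_low,
                                         ci_high = est$ci_high))
    if (est$ci_low <= 0.5 && est$ci_high >= 0.5) {
      return(structure(list(sigma50 = mid, iterations = iter,
                            final_estimate = est, history = history),
                       class = "sigma50_result"))
    }
    if (est$p_hat > 0.5) lo <- mid else hi <- mid
  }
  cond <- structure(
    class = c("bcpnnseq_convergence_error", "error", "condition"),
    list(message = sprintf("sigma50 bisection did not converge in %d iterations",
                           max_iter),
         call = sys.call(-1),
         partial = list(sigma50 = (lo + hi) / 2, history = history)))
  stop(cond)
}

#' @export
print.sigma50_result <- function(x, ...) {
  cat(sprintf("sigma50 = %.4f after %d bisection step(s); final p_hat = %.3f [%.3f, %.3f]\n",
              x$sigma50, x$iterations, x$final_estimate$p_hat,
              x$final_estimate$ci_low, x$final_estimate$ci_high))
  invisible(x)
}

#' Representational overlap of two patterns
#'
#' Fraction of hypercolumns in which the two patterns activate the same unit.
#'
#' @param p1,p2 patterns as integer vectors of per-hypercolumn unit indices
#'   (equal length).
#' @return fraction in `[0, 1]`.
#' @export
representational_overlap <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("patterns span different numbers of hypercolumns")
  mean(as.integer(p1) == as.integer(p2))
}

#' Sequential overlap of two equal-length sequences
#'
#' Number of positionally aligned pattern pairs with non-zero
#' representational overlap.
#'
#' @param seq_a,seq_b sequences (ids into `patterns`), equal length.
#' @param patterns a [pattern_set()].
#' @return integer count.
#' @export
sequential_overlap <- function(seq_a, seq_b, patterns) {
  a <- as.integer(unclass(seq_a)); b <- as.integer(unclass(seq_b))
  if (length(a) != length(b)) stop("sequences must have equal length")
  sum(vapply(seq_along(a), function(i)
    representational_overlap(patterns$patterns[[a[i]]],
                             patterns$patterns[[b[i]]]) > 0, logical(1)))
}

#' Maximum solvable disambiguation window
#'
#' Trains pairs of sequences whose middle window of `w` patterns is identical
#' (representational overlap 1) for increasing `w`, sets per-pattern
#' adaptation gains for the requested dwell time, cues both sequences, and
#' returns the largest `w` for which both are recalled fully correctly. At
#' `sigma_out > 0` "correct" means an estimated success rate above 0.5 for
#' both cues.
#'
#' @param length sequence length (>= 3).
#' @param H hypercolumns.
#' @param sigma_out noise level (0 for the deterministic regime).
#' @param T_per target dwell time (ms) set through the gain inversion.
#' @param protocol a [training_protocol()] (pulse structure and epochs).
#' @param config a [learning_config()].
#' @param params a [network_params()].
#' @param dt_train integration step for training (ms).
#' @param n_trials trials per cue when `sigma_out > 0`.
#' @param seed seed for noisy trials.
#' @param max_window largest window to try (default `length - 2`, the largest
#'   window excluding the endpoints).
#' @return the largest solvable window size (0 if none), with attribute
#'   `detail` (per-window success of both cues).
#' @export
max_disambiguation_window <- function(length = 10, H = 10, sigma_out = 0,
                                      T_per = 50,
                                      protocol = training_protocol(
                                        T_p = 100, IPI = 0, epochs = 30),
                                      config = learning_config(
                                        tau_z_pre = 25, tau_z_post = 5),
                                      params = network_params(),
                                      dt_train = 1, n_trials = 100, seed = 1,
                                      max_window = length - 2) {
  stopifnot(length >= 3)
  best <- 0L
  detail <- data.frame(window = integer(0), ok_a = logical(0),
                       ok_b = logical(0))
  for (w in seq_len(max_window)) {
    pair <- overlapping_pair(H = H, length = length, sequential_overlap = w,
                             representational_overlap = 1)
    series <- build_input_series(pair$patterns,
                                 list(pair$seq_a, pair$seq_b),
                                 protocol, dt = dt_train)
    trained <- train_offline(series, config)
    p <- params
    p$g_a <- gains_for_target(trained$connectivity, pair$patterns,
                              list(pair$seq_a, pair$seq_b), T_per, params)
    ok <- vapply(list(pair$seq_a, pair$seq_b), function(sq) {
      if (sigma_out <= 0) {
        p$sigma_out <- 0
        dur <- p$cue_duration + 1.5 * length * T_per + 500
        run_recall(trained$connectivity, p, pair$patterns, cue = sq[1],
                   total_duration = dur, target = sq)$success
      } else {
        est <- estimate_success_rate(trained$connectivity, p, pair$patterns,
                                     sq, sigma_out = sigma_out,
                                     n_trials = n_trials, seed = seed)
        est$p_hat > 0.5
      }
    }, logical(1))
    detail <- rbind(detail, data.frame(window = w, ok_a = ok[1], ok_b = ok[2]))
    if (all(ok)) best <- w else break
  }
  structure(best, detail = detail)
}

#' Measured persistence times of a recall episode
#'
#' Convenience extractor: event durations of the interior events of the
#' first pass through the patterns. Events from re-activation cycles (a
#' pattern id appearing a second time) are discarded, as are the first event
#' (shaped by the cue) and the last kept event (possibly truncated).
#'
#' @param result a `recall_result` from [run_recall()].
#' @return numeric vector of durations (ms), possibly empty.
#' @export
measured_persistence_times <- function(result) {
  ev <- result$events
  rep_at <- which(duplicated(ev$pattern))
  if (length(rep_at)) ev <- ev[seq_len(rep_at[1] - 1L), , drop = FALSE]
  if (nrow(ev) <= 2) return(numeric(0))
  ev$duration[2:(nrow(ev) - 1L)]
}
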