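test_that("persistence-time formula is defined exactly on 0 < B < 1", {
  expect_domain_error(theoretical_persistence_time(0, 0, 1))
  expect_domain_error(theoretical_persistence_time(-0.5, 0, 1))
  expect_domain_error(theoretical_persistence_time(1, 0, 1))
  expect_domain_error(theoretical_persistence_time(1.2, 0, 1))
  for (B in seq(0.01, 0.99, by = 0.07))
    expect_true(is.finite(theoretical_persistence_time(B, 0, 1)))
  # the condition carries the offending B
  err <- tryCatch(theoretical_persistence_time(2, 0, 1), condition = identity)
  expect_equal(err$B, 2)
})

test_that("persistence time grows monotonically in B and diverges at 1", {
  B <- seq(0.05, 0.95, by = 0.05)
  tp <- vapply(B, function(b) theoretical_persistence_time(b, 0, 1),
               numeric(1))
  expect_true(all(diff(tp) > 0))
  expect_gt(theoretical_persistence_time(0.999, 0, 1), 1500)
})

test_that("the B -> 0 limit is bounded below by tau_s", {
  floor_ms <- persistence_time_floor(10, 250)
  expect_gte(floor_ms, 10)
  expect_equal(theoretical_persistence_time(1e-12, 0, 1), floor_ms,
               tolerance = 1e-6)
})

test_that("closed form matches an independent ODE-crossing computation", {
  skip_if_not_installed("deSolve")
  # independent oracle: integrate the two-unit current dynamics during a
  # dwell (active unit with growing adaptation vs successor) and find the
  # crossing time s_active(t) = s_next(t)
  tau_s <- 10; tau_a <- 250
  w_self <- 1; w_next <- -1
  crossing_time <- function(g_a) {
    rhs <- function(t, y, parms) {
      a <- 1 - exp(-t / tau_a)
      list(c((w_self - g_a * a - y[1]) / tau_s,
             (w_next - y[2]) / tau_s))
    }
    y0 <- c(w_self, w_next)  # quasi-static currents at dwell onset
    times <- seq(0, 4000, by = 0.01)
    sol <- deSolve::ode(y0, times, rhs, NULL)
    idx <- which(sol[, 2] <= sol[, 3])[1]
    stats::uniroot(function(t) {
      s <- deSolve::ode(y0, c(0, t), rhs, NULL)
      s[2, 2] - s[2, 3]
    }, c(sol[idx - 1, 1], sol[idx, 1]), tol = 1e-8)$root
  }
  dw <- w_self - w_next
  for (B in c(0.2, 0.5, 0.8)) {
    expect_equal(crossing_time(dw / B),
                 theoretical_persistence_time(dw, 0, dw / B),
                 tolerance = 1e-3, info = paste("B =", B))
  }
})

test_that("gain inversion is the exact inverse of the formula", {
  for (target in c(50, 300, 1200)) {
    g <- gain_for_target(1.5, 0.1, target)
    expect_equal(theoretical_persistence_time(1.5, 0.1, g), target,
                 tolerance = 1e-10)
  }
  # long dwell limit: g_a approaches dw + dbeta from above
  expect_equal(gain_for_target(2, 0, 5000), 2, tolerance = 1e-6)
  expect_gt(gain_for_target(2, 0, 5000), 2)
  expect_domain_error(gain_for_target(2, 0, 5))      # below the floor
  expect_error(gain_for_target(-1, 0, 300), "positive")
})

test_that("transition summaries read off handcrafted connectivity", {
  hc <- chain_connectivity(5, w_self = 1, w_next = -1, w_rest = -3)
  tr <- summarize_transitions(hc$connectivity, hc$patterns,
                              sequence_spec(1:5),
                              network_params(g_a = 4))
  expect_equal(tr$w_self, rep(1, 4))
  expect_equal(tr$w_next, rep(-1, 4))
  expect_equal(tr$w_prev[-1], rep(-3, 3))
  expect_equal(tr$w_rest, rep(-3, 4))
  expect_equal(tr$B, rep(0.5, 4))
  expect_equal(tr$T_per_pred,
               rep(theoretical_persistence_time(2, 0, 4), 4))
})

test_that("the realized successor maximises the outgoing drive", {
  fit <- standard_net()
  conn <- fit$connectivity
  ps <- fit$patterns
  for (k in 1:4) {
    drives <- vapply(setdiff(1:5, k), function(m)
      mean(conn$w[pattern_units(ps, k), pattern_units(ps, m)]), numeric(1))
    expect_equal(setdiff(1:5, k)[which.max(drives)], k + 1,
                 info = paste("pattern", k))
  }
})

test_that("Wald interval arithmetic and trivial estimates are exact", {
  est <- estimate_success_rate(trial_fn = function(i) TRUE, n_trials = 50)
  expect_equal(est$p_hat, 1)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
  # half-width at p = 0.5, n = 1000
  est2 <- estimate_success_rate(trial_fn = local({
    k <- 0
    function(i) { k <<- k + 1; k %% 2 == 0 }
  }), n_trials = 1000)
  expect_equal(est2$p_hat, 0.5)
  expect_equal(est2$ci_high - est2$p_hat, 1.96 * sqrt(0.25 / 1000),
               tolerance = 1e-12)
})

test_that("Wald coverage on Bernoulli data matches exact enumeration", {
  # exact coverage of the Wald interval at n = 200, p = 0.8 by enumeration
  n <- 200; p <- 0.8
  k <- 0:n
  half <- 1.96 * sqrt((k / n) * (1 - k / n) / n)
  covers <- abs(k / n - p) <= half
  exact <- sum(stats::dbinom(k[covers], n, p))
  # Monte-Carlo coverage through the estimator machinery
  reps <- 400
  hit <- logical(reps)
  for (r in seq_len(reps)) {
    est <- estimate_success_rate(trial_fn = function(i) stats::runif(1) < p,
                                 n_trials = n, seed = 5000 + r)
    hit[r] <- est$ci_low <= p && p <= est$ci_high
  }
  mc <- mean(hit)
  se <- sqrt(exact * (1 - exact) / reps)
  expect_lt(abs(mc - exact), 4 * se)
  expect_gt(mc, 0.85)  # approximately nominal 95%
})

test_that("stochastic bisection recovers an injected threshold", {
  # success probability 1 - Phi((sigma - 1) / 0.1): true sigma50 = 1
  trial_fn <- function(sigma, i) stats::runif(1) < 1 - stats::pnorm((sigma - 1) / 0.1)
  res <- find_sigma50(bracket = c(0.3, 1.7), n_trials = 400, seed = 2,
                      trial_fn = trial_fn)
  expect_lt(abs(res$sigma50 - 1), 0.1)
  # stopping rule: the final estimate's CI contains one half
  expect_lte(res$final_estimate$ci_low, 0.5)
  expect_gte(res$final_estimate$ci_high, 0.5)
  expect_equal(nrow(res$history), res$iterations)
})

test_that("sigma50 search rejects invalid brackets", {
  expect_error(find_sigma50(bracket = c(0, 1), n_trials = 50, seed = 1,
                            trial_fn = function(sigma, i) TRUE),
               class = "bcpnnseq_bracket_error")
})

test_that("representational overlap counts shared hypercolumns", {
  expect_equal(representational_overlap(c(12, 3, 3), c(3, 3, 3)), 2 / 3)
  expect_equal(representational_overlap(c(1, 2), c(1, 2)), 1)
  expect_equal(representational_overlap(c(1, 2), c(3, 4)), 0)
  expect_error(representational_overlap(c(1, 2), c(1, 2, 3)), "hypercolumns")
})

test_that("sequential overlap counts aligned overlapping positions", {
  pair <- overlapping_pair(H = 3, length = 6, sequential_overlap = 2,
                           representational_overlap = 2 / 3)
  expect_equal(sequential_overlap(pair$seq_a, pair$seq_b, pair$patterns), 2)
  expect_equal(sequential_overlap(sequence_spec(1:4), sequence_spec(1:4),
                                  orthogonal_patterns(2, 4, 4)), 4)
  expect_error(sequential_overlap(sequence_spec(1:3), sequence_spec(1:4),
                                  orthogonal_patterns(2, 4, 4)), "equal")
})

test_that("simulated dwell times track the closed form across B", {
  hc <- chain_connectivity(6)
  dw <- 2; dt <- 0.5
  for (B in c(0.2, 0.5, 0.8)) {
    params <- network_params(g_a = dw / B, dt = dt, cue_duration = 30)
    pred <- theoretical_persistence_time(dw, 0, dw / B)
    rec <- run_recall(hc$connectivity, params, hc$patterns, 1,
                      total_duration = 30 + 6.5 * pred + 300)
    tper <- measured_persistence_times(rec)
    expect_gte(length(tper), 3)
    expect_true(all(abs(tper - pred) <= 2 * dt), info = paste("B =", B))
  }
})

test_that("small disambiguation windows are solved at zero noise", {
  w <- max_disambiguation_window(length = 6, H = 6, sigma_out = 0,
                                 T_per = 50,
                                 protocol = training_protocol(T_p = 100,
                                                              IPI = 0,
                                                              epochs = 20),
                                 max_window = 2, seed = 1)
  expect_gte(as.integer(w), 1)
  detail <- attr(w, "detail")
  expect_true(all(c("ok_a", "ok_b") %in% names(detail)))
})
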