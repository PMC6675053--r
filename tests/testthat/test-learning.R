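test_that("z-traces relax toward the activation with their time constants", {
  cfg <- learning_config(tau_z_pre = 50, tau_z_post = 5)
  tr <- trace_state(2)
  n <- 200; dt <- 1
  for (i in seq_len(n)) tr <- update_traces(tr, c(1, 0), cfg, dt)
  expect_equal(tr$z_pre[1], 1 - (1 - dt / 50)^n, tolerance = 1e-12)
  expect_equal(tr$z_post[1], 1 - (1 - dt / 5)^n, tolerance = 1e-12)
  expect_equal(tr$z_pre[2], 0)
  # decay from 1 after input removal
  for (i in seq_len(100)) tr <- update_traces(tr, c(0, 0), cfg, dt)
  expect_lt(tr$z_pre[1], 0.2)
  expect_gt(tr$p_pre[1], 0)  # p lags z
})

test_that("traces stay in [0, 1] for arbitrary boolean input", {
  cfg <- learning_config(tau_z_pre = 10, tau_z_post = 5, tau_p = 200)
  set.seed(11)
  tr <- trace_state(3)
  for (i in 1:500) {
    tr <- update_traces(tr, stats::runif(3) < 0.3, cfg, dt = 1)
    vals <- c(tr$z_pre, tr$z_post, tr$p_pre, tr$p_post, tr$p_joint)
    expect_true(all(vals >= 0 & vals <= 1 + 1e-12))
  }
})

test_that("stationary p estimates recover the activation duty cycle", {
  # two patterns alternating with T_p = 100, IPI = 100: each unit is active
  # a quarter of the time; closed-form expectation for the period-averaged
  # EWMA of a low-passed periodic pulse train is the duty cycle
  ps <- orthogonal_patterns(H = 1, U = 2, n_patterns = 2)
  series <- build_input_series(ps, list(c(1, 2)),
                               training_protocol(T_p = 100, IPI = 100,
                                                 epochs = 120),
                               dt = 1)
  out <- train_offline(series, learning_config(tau_z_pre = 25,
                                               tau_z_post = 5,
                                               tau_p = 5000))
  expect_equal(out$traces_mean$p_pre, c(0.25, 0.25), tolerance = 0.01)
  expect_equal(out$traces_mean$p_post, c(0.25, 0.25), tolerance = 0.01)
})

test_that("stepwise replay matches the batch trace integration", {
  ps <- orthogonal_patterns(H = 2, U = 3, n_patterns = 3)
  series <- build_input_series(ps, list(1:3),
                               training_protocol(T_p = 30, IPI = 10,
                                                 epochs = 2),
                               dt = 1)
  cfg <- learning_config(tau_z_pre = 20, tau_z_post = 5, tau_p = 300)
  batch <- train_offline(series, cfg, average_last_period = FALSE)
  o_mat <- as.matrix(series)
  tr <- trace_state(ps$N)
  for (i in seq_len(nrow(o_mat))) tr <- update_traces(tr, o_mat[i, ], cfg, 1)
  expect_equal(tr$p_joint, batch$traces$p_joint, tolerance = 1e-12)
  expect_equal(tr$p_pre, batch$traces$p_pre, tolerance = 1e-12)
  expect_equal(tr$z_post, batch$traces$z_post, tolerance = 1e-12)
})

test_that("asymmetric traces learn forward-biased connectivity", {
  fit <- standard_net(tau_z_pre = 50, tau_z_post = 5)
  tr <- summarize_transitions(fit$connectivity, fit$patterns,
                              sequence_spec(1:5))
  mid <- tr[-1, ]  # rows with a defined w_prev
  expect_true(all(mid$w_self > mid$w_next))
  expect_true(all(mid$w_next > mid$w_prev))
  # homogeneous protocol: bias differences vanish
  expect_true(all(abs(tr$dbeta_next) < 0.01))
})

test_that("equal trace time constants give a symmetric weight matrix", {
  ps <- orthogonal_patterns(H = 1, U = 4, n_patterns = 4)
  fit <- bcpnn(ps, list(1:4), training_protocol(T_p = 50, epochs = 30),
               learning_config(tau_z_pre = 15, tau_z_post = 15))
  expect_equal(fit$w, t(fit$w), tolerance = 1e-10)
})

test_that("log-odds weights honour independence and the epsilon floor", {
  cfg <- learning_config()
  mk <- function(p_pre, p_post, p_joint) {
    structure(list(z_pre = p_pre, z_post = p_post, p_pre = p_pre,
                   p_post = p_post, p_joint = p_joint, t = 0),
              class = "trace_state")
  }
  # independence: w = 0
  tr <- mk(c(0.5, 0.4), c(0.5, 0.4), outer(c(0.5, 0.4), c(0.5, 0.4)))
  expect_equal(weights_from_probabilities(tr, cfg)$w,
               matrix(0, 2, 2), tolerance = 1e-12)
  # never co-active: the floor caps the inhibition at log(eps / 0.25)
  tr0 <- mk(c(0.5, 0.5), c(0.5, 0.5), matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(weights_from_probabilities(tr0, cfg)$w[1, 2],
               log(1e-7 / 0.25))
  # perfect co-activation of half-time-active units: w = log 2
  tr2 <- mk(0.5, 0.5, matrix(0.5, 1, 1))
  expect_equal(weights_from_probabilities(tr2, cfg)$w[1, 1], log(2))
})

test_that("trained weights satisfy the floor-implied bounds", {
  fit <- standard_net()
  eps <- fit$config$epsilon
  expect_true(all(fit$w >= 2 * log(eps) & fit$w <= -log(eps)))
  expect_true(all(fit$beta >= log(eps) & fit$beta <= 0))
})

test_that("forward/backward asymmetry follows the trace asymmetry", {
  # w_next > w_prev exactly when tau_z_pre > tau_z_post
  for (tz in c(5, 10, 40, 80)) {
    fit <- standard_net(tau_z_pre = tz, tau_z_post = 20, epochs = 30)
    tr <- summarize_transitions(fit$connectivity, fit$patterns,
                                sequence_spec(1:5))
    mid <- tr[-1, ]
    if (tz > 20) {
      expect_true(all(mid$w_next > mid$w_prev), info = paste("tau_z_pre", tz))
    } else {
      expect_true(all(mid$w_next < mid$w_prev), info = paste("tau_z_pre", tz))
    }
  }
  # at equal time constants the split collapses to residual edge effects,
  # two orders of magnitude below the asymmetric regimes
  fit_eq <- standard_net(tau_z_pre = 20, tau_z_post = 20, epochs = 30)
  tr_eq <- summarize_transitions(fit_eq$connectivity, fit_eq$patterns,
                                 sequence_spec(1:5))
  expect_true(all(abs(tr_eq$w_next[-1] - tr_eq$w_prev[-1]) < 0.01))
})

test_that("naive Hebbian weighting ignores base rates, the log-odds rule does not", {
  counts <- matrix(0, 4, 4)
  counts[1, 2] <- 99; counts[1, 3] <- 1; counts[4, 3] <- 1
  nh <- naive_hebbian_weights(counts)
  expect_equal(nh[1, 3], nh[4, 3])          # equal raw frequency
  expect_equal(nh[1, 2], 99 / 101)
  expect_equal(sum(nh), 1)
  expect_error(naive_hebbian_weights(matrix(0, 2, 2)), "all-zero")
  expect_error(naive_hebbian_weights(matrix(-1, 2, 2)), "non-negative")

  single <- matrix(0, 2, 2); single[1, 2] <- 1
  ns <- naive_hebbian_weights(single)
  expect_equal(ns[1, 2], 1)
  expect_true(all(ns[-3] == 0))

  assoc <- association_fit()
  w <- assoc$trained$connectivity$w
  expect_gt(w[4, 3], w[1, 3])  # H -> G more significant than E -> G
})
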