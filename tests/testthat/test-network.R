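test_that("winner-take-all picks the per-hypercolumn maximum", {
  expect_equal(wta_select(c(0.2, 0.1, 0.3, 0.9), layout = 2),
               c(TRUE, FALSE, FALSE, TRUE))
  # ties break to the lowest unit index
  expect_equal(wta_select(c(0.5, 0.5), layout = 2), c(TRUE, FALSE))
  # a hypercolumn is never silent
  expect_equal(wta_select(-3, layout = 1), TRUE)
  expect_error(wta_select(c(1, 2), layout = list(1:2, integer(0))),
               "empty hypercolumn")
})

test_that("support current decays exponentially without input", {
  ps <- orthogonal_patterns(H = 1, U = 2, n_patterns = 2)
  conn <- connectivity(matrix(0, 2, 2), c(0, 0))
  params <- network_params(g_a = 0, sigma_out = 0, dt = 0.5)
  st <- list(s = c(1, 0.5), o = c(FALSE, TRUE), a = c(0, 0), t = 0)
  for (i in 1:40) st <- step_dynamics(st, conn, params, ps)
  # o contributes nothing (w = 0); discrete-time homogeneous solution
  expect_equal(st$s, c(1, 0.5) * (1 - 0.5 / 10)^40, tolerance = 1e-12)
})

test_that("adaptation relaxes toward the activation with tau_a", {
  ps <- orthogonal_patterns(H = 1, U = 1, n_patterns = 1)
  conn <- connectivity(matrix(5, 1, 1), 0)  # self-excitation keeps o = 1
  params <- network_params(g_a = 0, dt = 0.5)
  st <- initial_state(conn, ps)
  n <- 400
  for (i in seq_len(n)) st <- step_dynamics(st, conn, params, ps)
  expect_equal(st$a, 1 - (1 - 0.5 / 250)^n, tolerance = 1e-12)
  expect_true(all(st$a >= 0 & st$a <= 1))
})

test_that("sigma_out is the stationary standard deviation of s", {
  # with w = 0, beta = 0, g_a = 0 the support current is a pure
  # Ornstein-Uhlenbeck process; its stationary sd must match sigma_out
  ps <- orthogonal_patterns(H = 2, U = 2, n_patterns = 2)
  conn <- connectivity(matrix(0, 4, 4), rep(0, 4))
  params <- network_params(g_a = 0, sigma_out = 0.3, dt = 0.5,
                           cue_amplitude = 0, cue_duration = 0)
  rec <- run_recall(conn, params, ps, cue = 1, total_duration = 60000,
                    record = TRUE, seed = 42)
  s_tail <- rec$s[20000:nrow(rec$s), 2]
  expect_equal(sd(s_tail), 0.3, tolerance = 0.05)
})

test_that("handcrafted chain connectivity recalls the sequence in order", {
  hc <- chain_connectivity(5)
  dw <- 2  # w_self - w_next
  params <- network_params(g_a = dw / 0.5, dt = 0.5)  # B = 0.5
  rec <- run_recall(hc$connectivity, params, hc$patterns, cue = 1,
                    total_duration = 1200, target = sequence_spec(1:5))
  expect_true(rec$success)
  expect_equal(rec$events$pattern[1:5], 1:5)
})

test_that("without adaptation the cued pattern persists indefinitely", {
  hc <- chain_connectivity(5)
  params <- network_params(g_a = 0, dt = 0.5)
  rec <- run_recall(hc$connectivity, params, hc$patterns, cue = 1,
                    total_duration = 2000)
  expect_equal(nrow(rec$events), 1L)
  expect_equal(rec$events$pattern, 1L)
})

test_that("weak adaptation (B >= 1) stalls recall on the cued pattern", {
  hc <- chain_connectivity(5)
  params <- network_params(g_a = 1.8, dt = 0.5)  # B = 2 / 1.8 > 1
  rec <- run_recall(hc$connectivity, params, hc$patterns, cue = 1,
                    total_duration = 3000)
  expect_equal(unique(rec$events$pattern), 1L)
})

test_that("pattern events require all hypercolumns and outlast tau_s", {
  ps <- orthogonal_patterns(H = 2, U = 3, n_patterns = 3)
  # winners matrix: pattern 1 for 100 steps, pattern 2 for 5 steps (blip),
  # then mixed winners (no full pattern)
  winners <- rbind(matrix(1L, 100, 2), matrix(2L, 5, 2),
                   matrix(c(3L, 1L), 60, 2, byrow = TRUE))
  ev <- detect_pattern_activations(winners, ps, dt = 1, tau_s = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pattern, 1L)
  expect_equal(ev$duration, 100)

  # alternating activations both count once long enough
  winners2 <- rbind(matrix(1L, 50, 2), matrix(2L, 50, 2),
                    matrix(1L, 50, 2))
  ev2 <- detect_pattern_activations(winners2, ps, dt = 1, tau_s = 10)
  expect_equal(ev2$pattern, c(1L, 2L, 1L))
  expect_equal(ev2$duration, rep(50, 3))

  # sub-tau_s activity is never an event
  ev3 <- detect_pattern_activations(matrix(1L, 5, 2), ps, dt = 1, tau_s = 10)
  expect_equal(nrow(ev3), 0L)
})

test_that("success criterion is conservative prefix matching", {
  expect_true(evaluate_success(1:5, sequence_spec(1:5)))
  expect_false(evaluate_success(c(1, 2, 4), sequence_spec(1:5)))
  # trailing events after the target are ignored
  expect_true(evaluate_success(c(1, 2, 3, 2), sequence_spec(1:3)))
  expect_false(evaluate_success(c(2, 1, 3), sequence_spec(1:3)))
  # split dwells (consecutive duplicates) are artifacts, not intrusions
  expect_true(evaluate_success(c(1, 1, 2, 2, 3), sequence_spec(1:3)))
  # a genuine revisit of an earlier pattern is an intrusion
  expect_false(evaluate_success(c(1, 2, 1, 3), sequence_spec(1:3)))
})

test_that("zero-noise recall is bitwise reproducible", {
  hc <- chain_connectivity(4)
  params <- network_params(g_a = 4, dt = 0.5)
  r1 <- run_recall(hc$connectivity, params, hc$patterns, 1, 1000)
  r2 <- run_recall(hc$connectivity, params, hc$patterns, 1, 1000)
  expect_identical(r1$winners, r2$winners)
  expect_identical(r1$events, r2$events)
})

test_that("seeded noisy recalls are reproducible and seeds matter", {
  hc <- chain_connectivity(4)
  params <- network_params(g_a = 4, sigma_out = 0.5, dt = 0.5)
  r1 <- run_recall(hc$connectivity, params, hc$patterns, 1, 800, seed = 7)
  r2 <- run_recall(hc$connectivity, params, hc$patterns, 1, 800, seed = 7)
  r3 <- run_recall(hc$connectivity, params, hc$patterns, 1, 800, seed = 8)
  expect_identical(r1$winners, r2$winners)
  expect_false(identical(r1$winners, r3$winners))
})

test_that("middle transitions of a homogeneous chain share one dwell time", {
  hc <- chain_connectivity(6)
  params <- network_params(g_a = 2 / 0.4, dt = 0.5)
  pred <- theoretical_persistence_time(2, 0, 2 / 0.4)
  rec <- run_recall(hc$connectivity, params, hc$patterns, 1,
                    total_duration = 7 * pred)
  tper <- measured_persistence_times(rec)
  expect_gte(length(tper), 3)
  expect_lt(diff(range(tper)), 1e-9)
})
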