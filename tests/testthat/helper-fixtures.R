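# shared fixtures, built once per test run

# standard 5-pattern single-hypercolumn network trained at the reference
# protocol; memoised because several files inspect it
standard_net <- local({
  cache <- new.env(parent = emptyenv())
  function(tau_z_pre = 25, tau_z_post = 5, T_p = 100, IPI = 0, epochs = 50,
           n = 5, H = 1) {
    key <- paste(tau_z_pre, tau_z_post, T_p, IPI, epochs, n, H, sep = "_")
    if (is.null(cache[[key]])) {
      ps <- orthogonal_patterns(H = H, U = n, n_patterns = n)
      cache[[key]] <- bcpnn(ps, list(seq_len(n)),
                            training_protocol(T_p = T_p, IPI = IPI,
                                              epochs = epochs),
                            learning_config(tau_z_pre = tau_z_pre,
                                            tau_z_post = tau_z_post))
    }
    cache[[key]]
  }
})

# association protocol with counts E->F: 99, E->G: 1, H->G: 1 encoded as
# two-pulse presentations; the rare associations are interleaved mid-stream
# and tau_p spans the whole series so the p-traces estimate frequencies
association_fit <- function() {
  ps <- orthogonal_patterns(H = 1, U = 4, n_patterns = 4)  # E, F, G, H
  seqs <- c(rep(list(c(1L, 2L)), 99), list(c(1L, 3L)), list(c(4L, 3L)))
  seqs <- seqs[order(c(seq_len(99), 34.5, 67.5))]
  series <- build_input_series(ps, seqs,
                               training_protocol(T_p = 100, IPI = 0,
                                                 epochs = 1,
                                                 inter_sequence_gap = 500),
                               dt = 1)
  cfg <- learning_config(tau_z_pre = 25, tau_z_post = 5,
                         tau_p = series$duration)
  list(patterns = ps, trained = train_offline(series, cfg), cfg = cfg)
}

expect_domain_error <- function(expr) {
  expect_error(expr, class = "bcpnnseq_domain_error")
}
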