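#' Deterministic child seeds
#'
#' Spawns per-trial seeds from one master seed by a counter scheme, so that
#' increasing the number of trials never reshuffles earlier trials. Values
#' stay below 2^31.
#'
#' @param seed master integer seed.
#' @param i counter (trial index).
#' @return an integer seed.
#' @export
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483629)
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

cfg_require <- function(config, keys) {
  missing <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
  if (length(missing))
    stop("config validation failed; missing keys: ",
         paste(missing, collapse = ", "))
}

cfg_protocol <- function(config) {
  training_protocol(T_p = cfg_get(config, "T_p_ms", 100),
                    IPI = cfg_get(config, "IPI_ms", 0),
                    epochs = cfg_get(config, "epochs", 50),
                    inter_sequence_gap = cfg_get(config, "gap_ms", 1000))
}

cfg_learning <- function(config) {
  learning_config(tau_z_pre = cfg_get(config, "tau_z_pre_ms", 25),
                  tau_z_post = cfg_get(config, "tau_z_post_ms", 5),
                  tau_p = cfg_get(config, "tau_p_ms", 5000),
                  epsilon = cfg_get(config, "epsilon", 1e-7))
}

cfg_params <- function(config) {
  network_params(tau_s = cfg_get(config, "tau_s_ms", 10),
                 tau_a = cfg_get(config, "tau_a_ms", 250),
                 sigma_out = cfg_get(config, "sigma_out", 0),
                 dt = cfg_get(config, "dt_ms", 0.5),
                 cue_amplitude = cfg_get(config, "cue_amplitude", 1),
                 cue_duration = cfg_get(config, "cue_duration_ms", 50))
}

cfg_patterns <- function(config) {
  cfg_require(config, c("H", "n_patterns"))
  H <- config$H
  n <- config$n_patterns
  U <- cfg_get(config, "units_per_hypercolumn", n)
  ps <- orthogonal_patterns(H = H, U = U, n_patterns = n)
  seqs <- cfg_get(config, "sequences", list(seq_len(n)))
  if (!is.list(seqs)) seqs <- list(seqs)
  list(patterns = ps, sequences = lapply(seqs, sequence_spec))
}

cfg_fit <- function(config) {
  spec <- cfg_patterns(config)
  list(spec = spec,
       fit = bcpnn(spec$patterns, spec$sequences, cfg_protocol(config),
                   cfg_learning(config),
                   dt = cfg_get(config, "dt_train_ms", NULL)))
}

#' Run a configured experiment
#'
#' Composes the package's generators, trainer, simulator and analysis tools
#' into the standard experiments, driven by a flat key-value configuration
#' (an R list, or a path to a YAML/JSON file). Results are written into a
#' deterministic directory layout: a config snapshot (`config.json`), result
#' tables (CSV) or objects (JSON), and a `manifest.json` listing the outputs
#' with checksums. All randomness is derived from `seed`, so re-running a
#' config reproduces the outputs bit for bit.
#'
#' Experiment kinds and their main keys (defaults in parentheses follow the
#' standard parameter table):
#' \describe{
#'   \item{`train`}{`H`, `n_patterns`, `sequences`, `T_p_ms` (100), `IPI_ms`
#'     (0), `epochs` (50), `tau_z_pre_ms` (25), `tau_z_post_ms` (5) —
#'     writes the learned connectivity and per-sequence transition tables.}
#'   \item{`recall`}{`train` keys plus `sigma_out` (0), `T_per_ms` (100),
#'     `duration_ms` — writes the recall events and success flag.}
#'   \item{`tper-sweep`}{`B_grid` — predicted vs measured persistence time on
#'     handcrafted chain connectivity.}
#'   \item{`noise-sweep`}{`train` keys plus `sigma_grid`, `n_trials` (200),
#'     `T_per_ms` — tidy success-rate table with Wald CIs.}
#'   \item{`sigma50`}{`train` keys plus `bracket` (0, 3), `n_trials` (200),
#'     `T_per_ms` — stochastic-bisection result.}
#'   \item{`overlap-grid`}{`length`, `H`, `seq_ov_grid`, `rep_ov_grid`,
#'     `T_per_ms` (50) — zero-noise success over the overlap plane.}
#'   \item{`disambiguation`}{`length`, `H`, `T_per_grid`, `sigma_out` (0) —
#'     maximum disambiguation window per dwell time.}
#' }
#' `fast: true` caps trial counts at 50 for quick smoke runs.
#'
#' @param config list or path to a YAML/JSON config file; must contain
#'   `kind`.
#' @param out output directory (created if needed); defaults to
#'   `config$out` or a temporary directory.
#' @param seed master seed; defaults to `config$seed` (1).
#' @return invisibly, the manifest list (kind, seed, output files).
#' @export
run_experiment <- function(config, out = NULL, seed = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg_require(config, "kind")
  kind <- config$kind
  kinds <- c("train", "recall", "tper-sweep", "noise-sweep", "sigma50",
             "overlap-grid", "disambiguation")
  if (!kind %in% kinds)
    stop("config validation failed; unknown kind: ", kind)
  if (is.null(seed)) seed <- cfg_get(config, "seed", 1)
  config$seed <- seed
  if (is.null(out)) out <- cfg_get(config, "out", tempfile("experiment_"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(config$fast))
    config$n_trials <- min(cfg_get(config, "n_trials", 200), 50)
  jsonlite::write_json(config, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message("[bcpnnseq] experiment '", kind, "' (seed ", seed, ") -> ", out)

  files <- switch(kind,
    "train" = exp_train(config, out),
    "recall" = exp_recall(config, out, seed),
    "tper-sweep" = exp_tper_sweep(config, out),
    "noise-sweep" = exp_noise_sweep(config, out, seed),
    "sigma50" = exp_sigma50(config, out, seed),
    "overlap-grid" = exp_overlap_grid(config, out),
    "disambiguation" = exp_disambiguation(config, out, seed))

  files <- c("config.json", files)
  manifest <- list(kind = kind, seed = seed,
                   package_version = as.character(utils::packageVersion("bcpnnseq")),
                   files = as.list(files),
                   md5 = as.list(unname(tools::md5sum(file.path(out, files)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

exp_train <- function(config, out) {
  fitted <- cfg_fit(config)
  write_connectivity(fitted$fit$connectivity, file.path(out, "connectivity"),
                     meta = list(seed = config$seed))
  trans <- do.call(rbind, lapply(seq_along(fitted$spec$sequences), function(i) {
    tr <- summarize_transitions(fitted$fit$connectivity,
                                fitted$spec$patterns,
                                fitted$spec$sequences[[i]], cfg_params(config))
    cbind(sequence = i, tr)
  }))
  utils::write.csv(trans, file.path(out, "transitions.csv"), row.names = FALSE)
  c("connectivity_w.csv", "connectivity_beta.csv", "connectivity.json",
    "transitions.csv")
}

exp_recall <- function(config, out, seed) {
  fitted <- cfg_fit(config)
  res <- simulate(fitted$fit, nsim = 1, seed = seed,
                  sigma_out = cfg_get(config, "sigma_out", 0),
                  T_per = cfg_get(config, "T_per_ms", 100),
                  total_duration = cfg_get(config, "duration_ms", NULL),
                  params = cfg_params(config))
  utils::write.csv(res$events, file.path(out, "events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(success = res$success, cue = res$cue,
                            seed = seed,
                            events = res$events),
                       file.path(out, "recall.json"), auto_unbox = TRUE,
                       digits = NA)
  c("events.csv", "recall.json")
}

exp_tper_sweep <- function(config, out) {
  B_grid <- cfg_get(config, "B_grid", seq(0.1, 0.9, by = 0.1))
  params <- cfg_params(config)
  hc <- chain_connectivity(cfg_get(config, "n_patterns", 5))
  dw <- 2  # w_self - w_next of the handcrafted chain
  rows <- lapply(B_grid, function(B) {
    p <- params
    p$g_a <- dw / B
    pred <- theoretical_persistence_time(dw, 0, p$g_a, p$tau_s, p$tau_a)
    dur <- p$cue_duration + (length(hc$patterns$patterns) + 1) * pred + 500
    rec <- run_recall(hc$connectivity, p, hc$patterns, cue = 1,
                      total_duration = dur)
    data.frame(B = B, predicted = pred,
               measured = mean(measured_persistence_times(rec)))
  })
  utils::write.csv(do.call(rbind, rows), file.path(out, "tper_sweep.csv"),
                   row.names = FALSE)
  "tper_sweep.csv"
}

exp_noise_sweep <- function(config, out, seed) {
  cfg_require(config, "sigma_grid")
  fitted <- cfg_fit(config)
  params <- cfg_params(config)
  params$g_a <- gains_for_target(fitted$fit$connectivity,
                                 fitted$spec$patterns,
                                 fitted$spec$sequences,
                                 cfg_get(config, "T_per_ms", 100), params)
  n_trials <- cfg_get(config, "n_trials", 200)
  rows <- lapply(config$sigma_grid, function(sg) {
    est <- estimate_success_rate(fitted$fit$connectivity, params,
                                 fitted$spec$patterns,
                                 fitted$spec$sequences[[1]], sigma_out = sg,
                                 n_trials = n_trials, seed = seed)
    data.frame(sigma_out = sg, p_hat = est$p_hat, ci_low = est$ci_low,
               ci_high = est$ci_high, n_trials = est$n_trials, seed = seed)
  })
  utils::write.csv(do.call(rbind, rows), file.path(out, "noise_sweep.csv"),
                   row.names = FALSE)
  "noise_sweep.csv"
}

exp_sigma50 <- function(config, out, seed) {
  fitted <- cfg_fit(config)
  params <- cfg_params(config)
  params$g_a <- gains_for_target(fitted$fit$connectivity,
                                 fitted$spec$patterns,
                                 fitted$spec$sequences,
                                 cfg_get(config, "T_per_ms", 100), params)
  res <- find_sigma50(fitted$fit$connectivity, params, fitted$spec$patterns,
                      fitted$spec$sequences[[1]],
                      bracket = cfg_get(config, "bracket", c(0, 3)),
                      n_trials = cfg_get(config, "n_trials", 200),
                      seed = seed)
  jsonlite::write_json(list(sigma50 = res$sigma50,
                            iterations = res$iterations,
                            p_hat = res$final_estimate$p_hat,
                            ci_low = res$final_estimate$ci_low,
                            ci_high = res$final_estimate$ci_high,
                            n_trials = res$final_estimate$n_trials,
                            seed = seed, history = res$history),
                       file.path(out, "sigma50.json"), auto_unbox = TRUE,
                       digits = NA)
  "sigma50.json"
}

exp_overlap_grid <- function(config, out) {
  cfg_require(config, c("length", "H"))
  L <- config$length; H <- config$H
  seq_ov_grid <- cfg_get(config, "seq_ov_grid", seq_len(L - 2))
  rep_ov_grid <- cfg_get(config, "rep_ov_grid", (0:H) / H)
  T_per <- cfg_get(config, "T_per_ms", 50)
  protocol <- cfg_protocol(config)
  lc <- cfg_learning(config)
  params <- cfg_params(config)
  rows <- list()
  for (m in seq_ov_grid) for (rho in rep_ov_grid) {
    if (abs(rho * H - round(rho * H)) > 1e-8) next
    pair <- overlapping_pair(H = H, length = L, sequential_overlap = m,
                             representational_overlap = rho)
    fit <- bcpnn(pair$patterns, list(pair$seq_a, pair$seq_b), protocol, lc)
    p <- params
    p$g_a <- gains_for_target(fit$connectivity, pair$patterns,
                              list(pair$seq_a, pair$seq_b), T_per, params)
    dur <- p$cue_duration + 1.5 * L * T_per + 500
    ok <- vapply(list(pair$seq_a, pair$seq_b), function(sq)
      run_recall(fit$connectivity, p, pair$patterns, cue = sq[1],
                 total_duration = dur, target = sq)$success, logical(1))
    rows[[length(rows) + 1L]] <-
      data.frame(sequential_overlap = m, representational_overlap = rho,
                 success = all(ok))
  }
  utils::write.csv(do.call(rbind, rows), file.path(out, "overlap_grid.csv"),
                   row.names = FALSE)
  "overlap_grid.csv"
}

exp_disambiguation <- function(config, out, seed) {
  cfg_require(config, c("length", "H"))
  T_per_grid <- cfg_get(config, "T_per_grid", 50)
  rows <- lapply(T_per_grid, function(tp) {
    w <- max_disambiguation_window(
      length = config$length, H = config$H,
      sigma_out = cfg_get(config, "sigma_out", 0), T_per = tp,
      protocol = cfg_protocol(config), config = cfg_learning(config),
      params = cfg_params(config),
      n_trials = cfg_get(config, "n_trials", 100), seed = seed)
    data.frame(T_per = tp, max_window = as.integer(w))
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(out, "disambiguation.csv"), row.names = FALSE)
  "disambiguation.csv"
}
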