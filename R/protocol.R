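#' Timed training protocol
#'
#' Describes how sequences are clamped onto the network during training: each
#' pattern is presented for the pulse time `T_p`, presentations within a
#' sequence are separated by the inter-pulse interval `IPI`, the whole set of
#' sequences is repeated for `epochs` epochs, and distinct sequences are
#' separated by `inter_sequence_gap` of silence. All times in milliseconds.
#'
#' @param T_p pulse time (ms), default 100.
#' @param IPI inter-pulse interval (ms), default 0.
#' @param epochs number of training epochs, default 50.
#' @param inter_sequence_gap silence between distinct sequence presentations
#'   (ms), default 1000.
#' @return an object of class `training_protocol`.
#' @export
training_protocol <- function(T_p = 100, IPI = 0, epochs = 50,
                              inter_sequence_gap = 1000) {
  stopifnot(T_p > 0, IPI >= 0, epochs >= 1, inter_sequence_gap >= 0)
  structure(list(T_p = T_p, IPI = IPI, epochs = as.integer(epochs),
                 inter_sequence_gap = inter_sequence_gap),
            class = "training_protocol")
}

#' @export
print.training_protocol <- function(x, ...) {
  cat(sprintf("Training protocol: T_p = %g ms, IPI = %g ms, %d epoch(s), %g ms gap\n",
              x$T_p, x$IPI, x$epochs, x$inter_sequence_gap))
  invisible(x)
}

#' Build the clamped activation series of a training protocol
#'
#' Expands patterns, sequences and a [training_protocol()] into a step-by-step
#' activation series: during a pulse exactly the pattern's units are active,
#' during an IPI or a gap no unit is. The clamp is a pure activation signal
#' driving the learning traces; it does not pass through the network
#' recurrence. The gap is inserted between consecutive sequence presentations
#' when the protocol contains more than one sequence (single-sequence epochs
#' are presented contiguously).
#'
#' The series is stored compactly as the active pattern index per step
#' (0 = silent); use [as.matrix()] for the dense time-by-units boolean form.
#'
#' @param patterns a [pattern_set()].
#' @param sequences a list of [sequence_spec()]s (plain integer vectors are
#'   coerced).
#' @param protocol a [training_protocol()].
#' @param dt integration step (ms); must divide `T_p` and `IPI` to within one
#'   step.
#' @return an object of class `input_series` with fields `active`, `dt`,
#'   `patterns`, `n_steps`, `duration`.
#' @export
build_input_series <- function(patterns, sequences, protocol, dt = 1) {
  stopifnot(inherits(patterns, "pattern_set"),
            inherits(protocol, "training_protocol"), dt > 0)
  if (!is.list(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0) stop("empty sequence list")
  sequences <- lapply(sequences, function(s)
    if (inherits(s, "sequence_spec")) s else sequence_spec(s))
  n_pulse <- as.integer(round(protocol$T_p / dt))
  n_ipi <- as.integer(round(protocol$IPI / dt))
  n_gap <- as.integer(round(protocol$inter_sequence_gap / dt))
  if (abs(n_pulse * dt - protocol$T_p) > dt || n_pulse < 1)
    stop("dt does not divide T_p")
  if (abs(n_ipi * dt - protocol$IPI) > dt)
    stop("dt does not divide IPI")

  one_seq <- function(ids) {
    unlist(lapply(ids, function(k)
      c(rep(as.integer(k), n_pulse), integer(n_ipi))))
  }
  blocks <- rep(lapply(sequences, function(s) one_seq(unclass(s))),
                protocol$epochs)
  use_gap <- length(sequences) > 1 && n_gap > 0
  if (use_gap && length(blocks) > 1) {
    gap <- integer(n_gap)
    out <- vector("list", 2L * length(blocks) - 1L)
    out[seq(1, length(out), by = 2)] <- blocks
    out[seq(2, length(out), by = 2)] <- list(gap)
    active <- unlist(out)
  } else {
    active <- unlist(blocks)
  }
  # one protocol period (one epoch, counting one gap per presentation) --
  # the natural averaging window for steady-state probability estimates
  n_total <- length(active)
  period_steps <- if (use_gap) (n_total + n_gap) %/% protocol$epochs
  else n_total %/% protocol$epochs
  structure(list(active = as.integer(active), dt = dt, patterns = patterns,
                 n_steps = n_total, duration = n_total * dt,
                 epochs = protocol$epochs, period_steps = period_steps),
            class = "input_series")
}

#' @export
print.input_series <- function(x, ...) {
  cat(sprintf("Input series: %d steps of %g ms (%.1f s), %d units\n",
              x$n_steps, x$dt, x$duration / 1000, x$patterns$N))
  invisible(x)
}

#' @rdname build_input_series
#' @param x an `input_series`.
#' @param ... unused.
#' @export
as.matrix.input_series <- function(x, ...) {
  o <- matrix(FALSE, x$n_steps, x$patterns$N)
  um <- pattern_unit_matrix(x$patterns)
  for (k in seq_len(nrow(um))) {
    rows <- which(x$active == k)
    if (length(rows)) o[rows, um[k, ]] <- TRUE
  }
  o
}

#' Write / read an input series as plain text
#'
#' The activation series is written as a one-column CSV of active pattern
#' indices plus a JSON sidecar holding `dt`, the pattern layout and the
#' duration.
#'
#' @param series an `input_series`.
#' @param path base path; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_input_series <- function(series, path) {
  stopifnot(inherits(series, "input_series"))
  utils::write.csv(data.frame(active = series$active),
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- list(dt = series$dt, n_steps = series$n_steps,
               duration = series$duration, H = series$patterns$H,
               U = series$patterns$U,
               patterns = series$patterns$patterns)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_input_series
#' @export
read_input_series <- function(path) {
  active <- utils::read.csv(paste0(path, ".csv"))$active
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pats <- if (is.matrix(meta$patterns)) {
    lapply(seq_len(nrow(meta$patterns)), function(i) meta$patterns[i, ])
  } else {
    as.list(meta$patterns)
  }
  ps <- pattern_set(pats, H = meta$H, U = meta$U)
  structure(list(active = as.integer(active), dt = meta$dt, patterns = ps,
                 n_steps = length(active), duration = length(active) * meta$dt),
            class = "input_series")
}
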