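#' Pattern sets over hypercolumns
#'
#' A pattern set holds the stored cell assemblies of a modular attractor
#' network: `H` hypercolumns, each with `U` mutually exclusive units, and a
#' list of patterns where each pattern activates exactly one unit per
#' hypercolumn (a minicolumn code). The global index of unit `u` of
#' hypercolumn `h` is `(h - 1) * U + u`.
#'
#' @param patterns list of integer vectors, one per pattern; element `h` is
#'   the active unit (in `1:U`) of hypercolumn `h`.
#' @param H number of hypercolumns.
#' @param U number of units per hypercolumn (uniform across hypercolumns).
#' @return an object of class `pattern_set` with fields `H`, `U`, `patterns`
#'   and total unit count `N = H * U`.
#' @seealso [orthogonal_patterns()], [overlapping_pair()]
#' @export
pattern_set <- function(patterns, H, U) {
  stopifnot(is.list(patterns), length(patterns) >= 1,
            H >= 1, U >= 1)
  for (k in seq_along(patterns)) {
    p <- as.integer(patterns[[k]])
    if (length(p) != H)
      stop("pattern ", k, " has length ", length(p), ", expected H = ", H)
    if (any(p < 1L) || any(p > U))
      stop("pattern ", k, " has unit indices outside 1..U")
    patterns[[k]] <- p
  }
  structure(list(H = as.integer(H), U = as.integer(U),
                 N = as.integer(H * U), patterns = patterns),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("Pattern set:", length(x$patterns), "patterns over", x$H,
      "hypercolumn(s) x", x$U, "units (N =", x$N, "units)\n")
  invisible(x)
}

#' @export
length.pattern_set <- function(x) length(x$patterns)

#' Global unit indices of one pattern
#'
#' @param ps a [pattern_set()].
#' @param k pattern index.
#' @return integer vector of length `H` with global unit indices.
#' @export
pattern_units <- function(ps, k) {
  stopifnot(inherits(ps, "pattern_set"), k >= 1, k <= length(ps$patterns))
  (seq_len(ps$H) - 1L) * ps$U + ps$patterns[[k]]
}

# n_patterns x H matrix of global unit indices (C++ interface)
pattern_unit_matrix <- function(ps) {
  n <- length(ps$patterns)
  m <- matrix(0L, n, ps$H)
  for (k in seq_len(n)) m[k, ] <- pattern_units(ps, k)
  m
}

#' Canonical orthogonal pattern layout
#'
#' Pattern `k` activates unit `k` in every hypercolumn, so all pairs of
#' patterns have representational overlap 0.
#'
#' @param H number of hypercolumns.
#' @param U units per hypercolumn.
#' @param n_patterns number of patterns; must not exceed `U`.
#' @return a [pattern_set()].
#' @export
orthogonal_patterns <- function(H, U, n_patterns) {
  if (n_patterns > U)
    stop("capacity error: cannot place ", n_patterns,
         " pairwise disjoint patterns with U = ", U, " units per hypercolumn")
  pattern_set(lapply(seq_len(n_patterns), function(k) rep(k, H)), H = H, U = U)
}

#' Sequence specification
#'
#' An ordered list of pattern indices of length at least 2 with no immediate
#' repetition (the network recalls non-repeating patterns).
#'
#' @param pattern_ids integer vector of indices into a pattern set.
#' @return integer vector of class `sequence_spec`.
#' @export
sequence_spec <- function(pattern_ids) {
  ids <- as.integer(pattern_ids)
  if (length(ids) < 2) stop("a sequence needs at least 2 patterns")
  if (any(diff(ids) == 0L))
    stop("immediate repetition of a pattern id is not allowed")
  structure(ids, class = "sequence_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat("Sequence:", paste(unclass(x), collapse = " -> "), "\n")
  invisible(x)
}

#' Generate a pair of sequences with controlled overlap
#'
#' Constructs two equal-length sequences whose aligned patterns overlap in a
#' centered window: `sequential_overlap` consecutive positions (excluding the
#' first and last position of the sequences) where the aligned pattern pair
#' shares the active unit in `representational_overlap * H` hypercolumns. With
#' `representational_overlap = 1` the window patterns are identical (shared
#' pattern ids): the sequence-disambiguation regime. All other pattern pairs
#' across the two sequences are fully disjoint. The shared hypercolumns are
#' the same (leading) set for every overlapped pair.
#'
#' @param H hypercolumns.
#' @param U units per hypercolumn; defaults to the number needed
#'   (`2 * length`).
#' @param length sequence length (>= 3).
#' @param sequential_overlap number of overlapping aligned positions
#'   (0 to `length - 2`).
#' @param representational_overlap fraction of hypercolumns shared by each
#'   overlapped pair; `representational_overlap * H` must be an integer.
#' @param placement `"centered"` (default) or `"random"` placement of the
#'   overlap window among the interior positions.
#' @param seed optional seed used only for `placement = "random"`.
#' @return list with elements `patterns` (a [pattern_set()]), `seq_a` and
#'   `seq_b` (two [sequence_spec()]s).
#' @export
overlapping_pair <- function(H, length, sequential_overlap,
                             representational_overlap, U = 2L * length,
                             placement = c("centered", "random"),
                             seed = NULL) {
  placement <- match.arg(placement)
  L <- as.integer(length)
  m <- as.integer(sequential_overlap)
  if (L < 3) stop("length must be at least 3")
  if (m < 0) stop("sequential_overlap must be non-negative")
  if (m > L - 2L)
    stop("placement error: an overlap window of ", m, " patterns cannot ",
         "avoid the first and last position of length-", L, " sequences")
  k_shared <- representational_overlap * H
  if (abs(k_shared - round(k_shared)) > 1e-8)
    stop("representational_overlap * H must be an integer number of ",
         "hypercolumns")
  k_shared <- as.integer(round(k_shared))
  n_b_own <- if (k_shared == H) L - m else L  # distinct patterns needed for b
  if (L + n_b_own > U)
    stop("capacity error: need ", L + n_b_own,
         " distinct unit indices per hypercolumn but U = ", U)

  if (m > 0) {
    first <- if (placement == "centered") {
      2L + (L - 2L - m) %/% 2L
    } else {
      if (!is.null(seed)) set.seed(seed)
      sample(seq.int(2L, L - m), 1L)
    }
    window <- seq.int(first, first + m - 1L)
  } else {
    window <- integer(0)
  }

  pats <- lapply(seq_len(L), function(i) rep(i, H))      # sequence a
  seq_a <- seq_len(L)
  seq_b <- integer(L)
  next_id <- L
  for (i in seq_len(L)) {
    if (i %in% window && k_shared == H) {
      seq_b[i] <- i                                      # identical pattern
    } else {
      p <- rep(L + i, H)                                 # own disjoint units
      if (i %in% window && k_shared > 0L)
        p[seq_len(k_shared)] <- i                        # share leading HCs
      next_id <- next_id + 1L
      pats[[length(pats) + 1L]] <- p
      seq_b[i] <- length(pats)
    }
  }
  list(patterns = pattern_set(pats, H = H, U = U),
       seq_a = sequence_spec(seq_a),
       seq_b = sequence_spec(seq_b))
}
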