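#' Microstate temporal metrics
#'
#' Per class: coverage (fraction of samples), mean segment duration (ms over
#' maximal runs) and occurrence (segments per second).
#'
#' @param labels a `label_sequence`.
#' @return A data.frame of class `microstate_metrics` with columns `class`,
#'   `coverage`, `mean_duration`, `occurrence`. Classes never observed get
#'   coverage and occurrence 0 and `NA` duration.
#' @export
compute_metrics <- function(labels) {
  stopifnot(inherits(labels, "label_sequence"))
  l <- labels$labels
  fs <- labels$sampling_rate
  K <- labels$n_states
  n <- length(l)
  r <- rle(l)
  cov <- tabulate(l + 1L, nbins = K) / n
  dur <- occ <- numeric(K)
  for (k in seq_len(K)) {
    runs <- r$lengths[r$values == k - 1L]
    dur[k] <- if (length(runs)) mean(runs) * 1000 / fs else NA_real_
    occ[k] <- length(runs) / (n / fs)
  }
  out <- data.frame(class = seq_len(K) - 1L, coverage = cov,
                    mean_duration = dur, occurrence = occ)
  class(out) <- c("microstate_metrics", "data.frame")
  out
}

#' Markov transition matrix of a microstate sequence
#'
#' With `self_allowed = TRUE`, transitions are counted over consecutive
#' sample pairs (time step `1/fs`, i.e. 2 ms at 500 Hz), quantifying
#' microstate stability. With `self_allowed = FALSE`, transitions are
#' counted over consecutive distinct segments (zero diagonal), quantifying
#' the syntax of actual state changes. Rows of classes never observed as a
#' transition origin are `NA` and flagged in `defined`.
#'
#' @param labels a `label_sequence`.
#' @param self_allowed logical.
#' @return A list of class `transition_matrix`: `probs` (K x K,
#'   row-stochastic where defined), `counts`, `self_allowed`, `defined`
#'   (per-row flag), `step_duration` (ms; sample-level chains only),
#'   `n_observations`.
#' @export
transition_matrix <- function(labels, self_allowed = TRUE) {
  stopifnot(inherits(labels, "label_sequence"))
  l <- labels$labels
  K <- labels$n_states
  if (self_allowed) {
    from <- l[-length(l)]; to <- l[-1]
  } else {
    seg <- rle(l)$values
    if (length(seg) < 2) {
      stop("invalid-input: self-excluded chain needs >= 2 segments")
    }
    from <- seg[-length(seg)]; to <- seg[-1]
  }
  counts <- matrix(0, K, K)
  for (i in seq_along(from)) {
    counts[from[i] + 1L, to[i] + 1L] <- counts[from[i] + 1L, to[i] + 1L] + 1
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, NA, rs)
  structure(list(probs = probs, counts = counts,
                 self_allowed = self_allowed, defined = rs > 0,
                 step_duration = if (self_allowed)
                   1000 / labels$sampling_rate else NA_real_,
                 n_observations = length(from)),
            class = "transition_matrix")
}

#' Truncate label sequences to a common length
#'
#' Sequence length biases Lempel-Ziv complexity, so epochs are equalized to
#' the minimum length present before LZC computation.
#'
#' @param sequences a list of `label_sequence` objects.
#' @return The list with every sequence truncated to the minimum length.
#' @export
equalize_lengths <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  n <- min(vapply(sequences, length, integer(1)))
  lapply(sequences, function(s) {
    s$labels <- s$labels[seq_len(n)]
    if (!is.null(s$correlation_trace)) {
      s$correlation_trace <- s$correlation_trace[seq_len(n)]
    }
    if (!is.null(s$corr_matrix)) {
      s$corr_matrix <- s$corr_matrix[, seq_len(n), drop = FALSE]
    }
    s
  })
}

#' Lempel-Ziv (LZ76) complexity of a symbol sequence
#'
#' The number of phrases in the exhaustive production parsing of the
#' sequence (Lempel-Ziv 1976): each phrase is the shortest continuation
#' that does not occur as a substring of the preceding text; a final
#' incomplete phrase counts as one. Returned raw (unnormalized); with
#' `normalized = TRUE` the count is multiplied by
#' `log(n, base = alphabet) / n`.
#'
#' @param symbols integer vector (e.g. microstate labels 0-3) or a
#'   `label_sequence`.
#' @param normalized return the length-normalized value too (default FALSE).
#' @return A list of class `complexity_result`: `lzc` (integer phrase
#'   count), `sequence_length`, `alphabet_size`, and optionally
#'   `lzc_normalized`.
#' @export
lz76_complexity <- function(symbols, normalized = FALSE) {
  if (inherits(symbols, "label_sequence")) symbols <- symbols$labels
  symbols <- as.integer(symbols)
  if (length(symbols) == 0) stop("invalid-input: empty sequence")
  if (anyNA(symbols)) stop("invalid-input: sequence contains NA")
  lzc <- lz76_count_cpp(symbols)
  out <- list(lzc = lzc, sequence_length = length(symbols),
              alphabet_size = length(unique(symbols)))
  if (normalized) {
    a <- max(2L, out$alphabet_size)
    out$lzc_normalized <- lzc * log(length(symbols), base = a) /
      length(symbols)
  }
  structure(out, class = "complexity_result")
}

#' Reference LZ76 parser (naive substring search)
#'
#' A direct-from-definition exhaustive-history parser using naive substring
#' search, independent of the production implementation behind
#' [lz76_complexity()]. Intended for validation.
#'
#' @param symbols integer vector.
#' @return Integer phrase count.
#' @export
lz76_reference <- function(symbols) {
  symbols <- as.integer(symbols)
  if (length(symbols) == 0) stop("invalid-input: empty sequence")
  lz76_brute_cpp(symbols)
}

#' Exhaustive equivalence sweep of the two LZ76 parsers
#'
#' Enumerates every sequence of length 1..`max_len` over an alphabet of
#' `alphabet` symbols and compares [lz76_complexity()]'s parser with the
#' independent [lz76_reference()] parser on each.
#'
#' @param max_len maximum sequence length (e.g. 12).
#' @param alphabet alphabet size (e.g. 4).
#' @return List with `total` sequences checked and `mismatches`.
#' @export
lz76_sweep_check <- function(max_len, alphabet = 4) {
  stopifnot(max_len >= 1, alphabet >= 2)
  lz76_sweep_cpp(as.integer(max_len), as.integer(alphabet))
}
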