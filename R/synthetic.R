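#' Configuration for the synthetic EEG generator
#'
#' Defines the generative model: alpha-band (8-13 Hz) activity whose scalp
#' topography switches among `n_states` planted template maps as a
#' semi-Markov process, an optional additive narrowband SSVEP component at
#' `ssvep_frequency` weighted per channel by `ssvep_channel_gains`, and
#' spatially independent 1/f background noise scaled to the requested
#' signal-to-noise ratio.
#'
#' @param n_channels number of electrodes (default 64, the shipped montage).
#' @param sampling_rate sampling frequency in Hz (default 500).
#' @param duration recording length in seconds (default 30).
#' @param n_states number of planted microstate classes K (default 4).
#' @param mean_segment_duration mean microstate segment duration in ms
#'   (default 60; segment durations are gamma, shape 2).
#' @param transition_matrix K x K successor probabilities with zero diagonal
#'   (self-transitions are expressed through segment durations, not the
#'   chain); default uniform over the other states.
#' @param alpha_band two-vector (low, high) Hz of the carrier band (8, 13).
#' @param ssvep_frequency SSVEP frequency in Hz, or `NULL` for none.
#' @param ssvep_channel_gains non-negative per-channel SSVEP amplitudes (µV);
#'   default all zero.
#' @param noise_exponent spectral slope of the 1/f^a background (default 1).
#' @param snr ratio of microstate-signal RMS to noise RMS, averaged over
#'   channels (default 5); `Inf` disables noise.
#' @param seed integer seed fixing all randomness.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 64, sampling_rate = 500,
                             duration = 30, n_states = 4,
                             mean_segment_duration = 60,
                             transition_matrix = NULL,
                             alpha_band = c(8, 13),
                             ssvep_frequency = NULL,
                             ssvep_channel_gains = NULL,
                             noise_exponent = 1, snr = 5, seed = 1) {
  if (sampling_rate <= 0) stop("invalid-configuration: sampling_rate must be > 0")
  if (duration <= 0) stop("invalid-configuration: duration must be > 0")
  if (n_states < 2) stop("invalid-configuration: n_states must be >= 2")
  if (n_states > n_channels) {
    stop("invalid-configuration: n_states cannot exceed n_channels")
  }
  if (mean_segment_duration <= 0) {
    stop("invalid-configuration: mean_segment_duration must be > 0")
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (n_states - 1), n_states, n_states)
    diag(transition_matrix) <- 0
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == n_states)) {
    stop("invalid-configuration: transition_matrix must be n_states x n_states")
  }
  if (any(diag(transition_matrix) != 0)) {
    stop("invalid-configuration: transition_matrix diagonal must be zero")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8)) {
    stop("invalid-configuration: transition_matrix rows must sum to 1")
  }
  if (length(alpha_band) != 2 || alpha_band[1] <= 0 ||
      alpha_band[1] >= alpha_band[2] || alpha_band[2] >= sampling_rate / 2) {
    stop("invalid-configuration: alpha_band must be 0 < low < high < Nyquist")
  }
  if (!is.null(ssvep_frequency) &&
      (ssvep_frequency <= 0 || ssvep_frequency >= sampling_rate / 2)) {
    stop("invalid-configuration: ssvep_frequency outside (0, Nyquist)")
  }
  if (is.null(ssvep_channel_gains)) ssvep_channel_gains <- rep(0, n_channels)
  if (length(ssvep_channel_gains) != n_channels ||
      any(ssvep_channel_gains < 0)) {
    stop("invalid-configuration: ssvep_channel_gains must be n_channels non-negative weights")
  }
  if (!(snr > 0)) stop("invalid-configuration: snr must be > 0 (may be Inf)")
  structure(
    list(n_channels = n_channels, sampling_rate = sampling_rate,
         duration = duration, n_states = n_states,
         mean_segment_duration = mean_segment_duration,
         transition_matrix = transition_matrix, alpha_band = alpha_band,
         ssvep_frequency = ssvep_frequency,
         ssvep_channel_gains = as.numeric(ssvep_channel_gains),
         noise_exponent = noise_exponent, snr = snr,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' 2-D electrode layout used for template smoothness
#'
#' For 64 channels this is the shipped cap; otherwise a deterministic
#' sunflower arrangement on the unit disk.
#'
#' @param n_channels number of electrodes.
#' @return Matrix with columns x, y.
#' @export
electrode_layout <- function(n_channels) {
  if (n_channels == 64) {
    m <- load_montage()
    return(cbind(x = m$x, y = m$y))
  }
  i <- seq_len(n_channels)
  r <- sqrt((i - 0.5) / n_channels)
  th <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Generate planted microstate template topographies
#'
#' Each template is a spatially smooth dipolar pattern over the 2-D electrode
#' layout: the inner product of the electrode offset from a random centre
#' with a random orientation, tapered by a Gaussian of the distance. Maps are
#' average-referenced (zero mean across channels) and unit-norm. Draws are
#' repeated until all pairwise absolute spatial correlations are below 0.95.
#'
#' @param n_channels number of electrodes.
#' @param n_states number of templates K (must not exceed `n_channels`).
#' @param seed integer seed; output is deterministic given the seed.
#' @return K x n_channels matrix of unit-norm maps.
#' @export
generate_templates <- function(n_channels, n_states, seed = 1) {
  if (n_states > n_channels) {
    stop("invalid-configuration: n_states cannot exceed n_channels")
  }
  xy <- electrode_layout(n_channels)
  set.seed(as.integer(seed))
  for (attempt in seq_len(100)) {
    tpl <- matrix(0, n_states, n_channels)
    for (k in seq_len(n_states)) {
      ctr <- runif(2, -0.6, 0.6)
      ang <- runif(1, 0, 2 * pi)
      u <- c(cos(ang), sin(ang))
      sig <- runif(1, 0.5, 0.9)
      d <- cbind(xy[, 1] - ctr[1], xy[, 2] - ctr[2])
      tpl[k, ] <- (d %*% u) * exp(-rowSums(d^2) / (2 * sig^2))
    }
    tpl <- normalize_maps(tpl)
    cc <- spatial_corr(tpl, tpl)
    if (max(abs(cc[upper.tri(cc)])) < 0.95) return(tpl)
  }
  stop("invalid-configuration: could not draw sufficiently distinct templates")
}

#' Generate a planted semi-Markov microstate label sequence
#'
#' Segment durations are gamma-distributed (shape 2) with the configured
#' mean; successor states are drawn from the configured zero-diagonal
#' transition matrix. The first state is uniform.
#'
#' @param config a [synthetic_config()].
#' @param seed optional seed override (defaults to `config$seed`).
#' @return A `label_sequence` (0-based labels) of length
#'   `duration * sampling_rate`, with the planted segment table in
#'   `attr(, "segments")`.
#' @export
generate_label_sequence <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  P <- config$transition_matrix
  if (any(rowSums(P) == 0)) {
    stop("invalid-configuration: degenerate transition row (all zero)")
  }
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  set.seed(as.integer(seed))
  K <- config$n_states
  mean_samp <- config$mean_segment_duration * fs / 1000
  # draw in blocks until the sequence is long enough
  states <- integer(0); lens <- integer(0)
  cur <- sample.int(K, 1)
  total <- 0L
  while (total < n) {
    len <- max(1L, as.integer(round(rgamma(1, shape = 2, scale = mean_samp / 2))))
    states <- c(states, cur); lens <- c(lens, len)
    total <- total + len
    cur <- sample.int(K, 1, prob = P[cur, ])
  }
  labels <- rep.int(states - 1L, lens)[seq_len(n)]
  out <- new_label_sequence(labels, fs, K)
  attr(out, "segments") <- data.frame(state = states - 1L, length = lens)
  out
}

#' Synthesize a multichannel EEG recording with known ground truth
#'
#' The microstate component is `template[label(t)] * x(t)` where `x(t)` is a
#' band-limited Gaussian carrier in the configured alpha band (unit RMS,
#' scaled to 10 µV RMS). An SSVEP sinusoid at `ssvep_frequency` is added with
#' per-channel amplitudes `ssvep_channel_gains`, plus spatially independent
#' 1/f noise scaled so that RMS(microstate signal)/RMS(noise), averaged over
#' channels, equals `snr`.
#'
#' @param config a [synthetic_config()].
#' @param templates optional K x channels matrix of planted templates (e.g.
#'   shared across simulated subjects); default: drawn from `config$seed`.
#' @return A list with elements `recording` (an [eeg_recording()]) and
#'   `ground_truth` (planted templates, labels, coverages, transition matrix,
#'   SSVEP parameters, seed).
#' @export
synthesize_eeg <- function(config, templates = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  C <- config$n_channels

  if (is.null(templates)) {
    templates <- generate_templates(C, config$n_states, seed = config$seed)
  }
  stopifnot(nrow(templates) == config$n_states, ncol(templates) == C)
  lab_seq <- generate_label_sequence(config, seed = config$seed + 1L)
  labels <- lab_seq$labels

  set.seed(config$seed + 2L)
  x <- bandlimited_noise(n, fs, config$alpha_band[1], config$alpha_band[2])
  x <- 10 * x / rms(x)                       # 10 µV RMS alpha carrier

  sig <- t(templates)[, labels + 1L, drop = FALSE] *
    matrix(x, nrow = C, ncol = n, byrow = TRUE)

  if (!is.null(config$ssvep_frequency)) {
    s <- sin(2 * pi * config$ssvep_frequency * (seq_len(n) - 1) / fs)
    sig <- sig + config$ssvep_channel_gains %o% s
  }

  if (is.finite(config$snr)) {
    sig_rms <- mean(sqrt(rowMeans(
      (t(templates)[, labels + 1L, drop = FALSE] *
         matrix(x, nrow = C, ncol = n, byrow = TRUE))^2)))
    noise <- matrix(0, C, n)
    for (i in seq_len(C)) {
      noise[i, ] <- one_over_f_noise(n, fs, config$noise_exponent)
    }
    noise <- noise * (sig_rms / config$snr) / mean(sqrt(rowMeans(noise^2)))
    sig <- sig + noise
  }

  chn <- if (C == 64) load_montage()$name else sprintf("CH%02d", seq_len(C))
  rec <- eeg_recording(sig, chn, fs, condition = "synthetic",
                       subject_id = "SYN")

  cov <- tabulate(labels + 1L, nbins = config$n_states) / length(labels)
  gt <- structure(
    list(templates = templates, labels = labels, coverages = cov,
         transition_matrix = config$transition_matrix,
         ssvep_frequency = config$ssvep_frequency,
         ssvep_channel_gains = config$ssvep_channel_gains,
         seed = config$seed),
    class = "synthetic_ground_truth"
  )
  list(recording = rec, ground_truth = gt)
}

#' Generate a flicker stimulus train
#'
#' `fixed` mode emits a 50% duty-cycle square train at the given frequency.
#' `random` mode keeps each on-phase at 12.5 ms and draws off-intervals from
#' a uniform distribution on (0.2 ms, 2*mean - 0.2 ms], so the configured
#' mean off-interval is honoured and every off-interval is strictly positive.
#'
#' @param mode `"fixed"` or `"random"`.
#' @param frequency_or_mean_off flicker frequency in Hz (fixed mode) or mean
#'   off-interval in ms (random mode).
#' @param duration train duration in seconds.
#' @param seed integer seed (random mode).
#' @return A list of class `flicker_train` with strictly interleaved
#'   `on_times` and `off_times` (seconds).
#' @export
generate_flicker_stimulus <- function(mode = c("fixed", "random"),
                                      frequency_or_mean_off, duration,
                                      seed = 1) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("invalid-configuration: duration must be > 0")
  if (frequency_or_mean_off <= 0) {
    stop("invalid-configuration: frequency/mean off-interval must be > 0")
  }
  if (mode == "fixed") {
    period <- 1 / frequency_or_mean_off
    on <- seq(0, duration - period / 2, by = period)
    off <- on + period / 2
  } else {
    on_ms <- 12.5
    mean_off <- frequency_or_mean_off
    lo <- min(0.2, mean_off)                 # strictly positive support
    hi <- 2 * mean_off - lo
    set.seed(as.integer(seed))
    n_guess <- ceiling(duration * 1000 / (on_ms + mean_off) * 1.3) + 10
    offs <- runif(n_guess, lo, hi)
    t <- 0; on <- numeric(0); off <- numeric(0); i <- 1
    while (t < duration) {
      on <- c(on, t)
      t <- t + on_ms / 1000
      off <- c(off, t)
      if (i > length(offs)) offs <- c(offs, runif(n_guess, lo, hi))
      t <- t + offs[i] / 1000
      i <- i + 1
    }
  }
  structure(list(on_times = on, off_times = off, mode = mode,
                 frequency_or_mean_off = frequency_or_mean_off),
            class = "flicker_train")
}

#' Write a recording and its ground truth to the text fixture format
#'
#' The recording is a tab-delimited matrix (rows = channels), with a JSON
#' sidecar for metadata; ground truth (if given) is serialized as JSON.
#'
#' @param rec an [eeg_recording()].
#' @param path base path (without extension).
#' @param ground_truth optional `synthetic_ground_truth`.
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(rec, path, ground_truth = NULL) {
  data_path <- paste0(path, ".tsv")
  meta_path <- paste0(path, ".json")
  utils::write.table(rec$data, data_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(channel_names = rec$channel_names,
               sampling_rate = rec$sampling_rate,
               condition = rec$condition, subject_id = rec$subject_id)
  gt_path <- NULL
  if (!is.null(ground_truth)) {
    gt_path <- paste0(path, "_truth.json")
    jsonlite::write_json(unclass(ground_truth), gt_path, digits = NA,
                         auto_unbox = TRUE)
    meta$ground_truth <- basename(gt_path)
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  invisible(c(data_path, meta_path, gt_path))
}

#' Read a recording from the text fixture format
#' @param path base path used in [write_recording()].
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dat <- as.matrix(read.delim(paste0(path, ".tsv"), header = FALSE))
  eeg_recording(dat, meta$channel_names, meta$sampling_rate,
                meta$condition, meta$subject_id)
}

rms <- function(x) sqrt(mean(x^2))

# Gaussian noise strictly band-limited to [low, high] Hz by Fourier masking.
bandlimited_noise <- function(n, fs, low, high) {
  w <- rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  X <- fft(w)
  X[f < low | f > high] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

# 1/f^a noise by spectral shaping of white noise; amplitude floored below
# 0.5 Hz to avoid unbounded drift. Unit-RMS output.
one_over_f_noise <- function(n, fs, exponent = 1) {
  w <- rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  scale <- pmax(f, 0.5)^(-exponent / 2)
  scale[1] <- 0                              # no DC
  x <- Re(fft(fft(w) * scale, inverse = TRUE)) / n
  x / rms(x)
}
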