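#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-half-bandwidth
#' product `nw`, via the classical symmetric-tridiagonal eigenproblem
#' (Sturm-sequence bisection for the eigenvalues, inverse iteration for the
#' eigenvectors). Tapers are unit-energy and ordered by decreasing spectral
#' concentration.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product (default 4).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  stopifnot(n >= 4, nw > 0, k >= 1, k < n)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.fs_env[[key]])) return(.fs_env[[key]])
  W <- nw / n
  i <- seq_len(n)
  d <- ((n - 1 - 2 * (i - 1)) / 2)^2 * cos(2 * pi * W)
  e <- (i * (n - i) / 2)[-n]

  count_below <- function(x) {
    cnt <- 0L; q <- d[1] - x
    if (q < 0) cnt <- 1L
    for (j in 2:n) {
      if (q == 0) q <- .Machine$double.eps * (abs(d[j]) + abs(e[j - 1]))
      q <- (d[j] - x) - e[j - 1]^2 / q
      if (q < 0) cnt <- cnt + 1L
    }
    cnt
  }
  lo0 <- min(d - c(0, abs(e)) - c(abs(e), 0))
  hi0 <- max(d + c(0, abs(e)) + c(abs(e), 0))
  # j-th largest eigenvalue: count_below(x) >= n - j + 1 iff x above it
  eigval <- function(j) {
    lo <- lo0; hi <- hi0
    for (it in 1:120) {
      mid <- (lo + hi) / 2
      if (count_below(mid) >= n - j + 1) hi <- mid else lo <- mid
      if (hi - lo < 1e-10 * max(1, abs(hi))) break
    }
    (lo + hi) / 2
  }

  solve_tridiag <- function(shift, b) {
    # Thomas algorithm for (T - shift I) v = b with partial robustness
    aa <- d - shift
    cc <- e
    v <- b
    for (j in 2:n) {
      if (abs(aa[j - 1]) < 1e-300) aa[j - 1] <- 1e-300
      mju <- cc[j - 1] / aa[j - 1]
      aa[j] <- aa[j] - mju * cc[j - 1]
      v[j] <- v[j] - mju * v[j - 1]
    }
    if (abs(aa[n]) < 1e-300) aa[n] <- 1e-300
    v[n] <- v[n] / aa[n]
    for (j in (n - 1):1) v[j] <- (v[j] - cc[j] * v[j + 1]) / aa[j]
    v
  }

  tapers <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lam <- eigval(j)
    v <- sin(pi * j * i / (n + 1))           # deterministic start
    for (it in 1:4) {
      if (j > 1) {
        prev <- tapers[, seq_len(j - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- solve_tridiag(lam, v)
      v <- v / sqrt(sum(v^2))
    }
    s <- sum(v)
    if (abs(s) > 1e-8) {
      if (s < 0) v <- -v
    } else if (v[which.max(abs(v))[1]] < 0 && v[2] - v[1] < 0) {
      v <- -v
    }
    tapers[, j] <- v
  }
  .fs_env[[key]] <- tapers
  tapers
}

#' Multitaper power spectral density
#'
#' One-sided multitaper PSD (DPSS tapers, eigenvalue-unweighted average)
#' per channel, in µV²/Hz, satisfying Parseval: the PSD integrated over
#' 0..Nyquist approximates the signal variance.
#'
#' @param rec an [eeg_recording()].
#' @param fmin,fmax frequency range to retain (Hz), `fmin < fmax <= Nyquist`.
#' @param nw time-half-bandwidth product (default 4).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return A list of class `spectral_result`: `frequencies` (Hz),
#'   `psd` (channels x frequencies), `method`.
#' @export
compute_psd <- function(rec, fmin = 0, fmax = rec$sampling_rate / 2,
                        nw = 4, k = 2 * nw - 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  nyq <- fs / 2
  if (fmin < 0 || fmin >= fmax || fmax > nyq + 1e-9) {
    stop("invalid-parameter: need 0 <= fmin < fmax <= Nyquist")
  }
  n <- ncol(rec$data)
  tap <- dpss_tapers(n, nw = nw, k = k)
  nf <- n %/% 2 + 1
  acc <- matrix(0, nrow(rec$data), nf)
  xt <- t(rec$data)                          # n x C
  for (j in seq_len(k)) {
    Y <- stats::mvfft(xt * tap[, j])
    acc <- acc + t(Mod(Y[seq_len(nf), , drop = FALSE])^2)
  }
  psd <- acc / (k * fs)
  # one-sided scaling: double interior bins
  inner <- 2:(nf - if (n %% 2 == 0) 1 else 0)
  psd[, inner] <- 2 * psd[, inner]
  freqs <- (seq_len(nf) - 1) * fs / n
  keep <- freqs >= fmin - 1e-12 & freqs <= fmax + 1e-12
  rownames(psd) <- rec$channel_names
  structure(list(frequencies = freqs[keep],
                 psd = psd[, keep, drop = FALSE],
                 method = "multitaper"),
            class = "spectral_result")
}

#' Absolute band power by trapezoidal integration
#'
#' Integrates the PSD over the closed interval `[low, high]` on the
#' frequency grid, per channel.
#'
#' @param spec a `spectral_result`.
#' @param band two-vector (low, high) in Hz.
#' @return Named numeric vector of absolute power (µV²) per channel.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectral_result"), length(band) == 2)
  f <- spec$frequencies
  idx <- which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12)
  if (length(idx) == 0) {
    stop("invalid-parameter: band does not intersect the frequency grid")
  }
  if (length(idx) == 1) {
    return(stats::setNames(rep(0, nrow(spec$psd)), rownames(spec$psd)))
  }
  fi <- f[idx]
  p <- spec$psd[, idx, drop = FALSE]
  w <- diff(fi)
  out <- as.numeric((p[, -1, drop = FALSE] + p[, -length(idx), drop = FALSE]) %*%
                      w) / 2
  stats::setNames(out, rownames(spec$psd))
}

#' Relative band power
#'
#' `r = a / T`, the fraction of total power contained in a band.
#'
#' @param abs_power absolute band power (µV²).
#' @param total_power total-band power (µV²), > 0.
#' @return Fraction in `[0, 1]` (vectorized).
#' @export
relative_power <- function(abs_power, total_power) {
  if (any(total_power <= 0)) stop("undefined-ratio: total power must be > 0")
  if (any(abs_power > total_power * (1 + 1e-6) + 1e-12)) {
    stop("invalid-input: band power exceeds total power")
  }
  pmin(pmax(abs_power / total_power, 0), 1)
}

#' Convert a power ratio to decibels
#'
#' `10 * log10(value)`.
#'
#' @param value positive ratio (vectorized).
#' @return Value in dB.
#' @export
to_decibel <- function(value) {
  if (any(value <= 0)) stop("domain error: decibel of non-positive value")
  10 * log10(value)
}

#' Region-level absolute and relative band power
#'
#' For every scalp region, absolute power is the mean of the member
#' channels' band powers; relative power is computed per channel against
#' that channel's own total-band power and then averaged within the region
#' (`average = "ratios"`, the default), or from region-mean powers
#' (`average = "powers"`).
#'
#' @param spec a `spectral_result` covering all channels.
#' @param montage an `eeg_montage` covering all channels of `spec`.
#' @param band two-vector (low, high) Hz, e.g. `c(39, 41)`.
#' @param total_band total-power band (default 0.1-100 Hz).
#' @param average `"ratios"` or `"powers"` (order of averaging).
#' @return A data.frame of class `band_power_table`: region, band edges,
#'   `abs_power`, `rel_power`, `n_channels`.
#' @export
region_percent_power <- function(spec, montage, band,
                                 total_band = c(0.1, 100),
                                 average = c("ratios", "powers")) {
  average <- match.arg(average)
  channels <- rownames(spec$psd)
  regions <- montage_regions(montage, channels)
  a <- band_power(spec, band)
  tot <- band_power(spec, total_band)
  r <- relative_power(a, tot)
  reg_levels <- unique(montage$region[montage$name %in% channels])
  rows <- lapply(reg_levels, function(rg) {
    mem <- which(regions == rg)
    if (length(mem) == 0) stop("invalid-montage: region without channels: ", rg)
    rel <- if (average == "ratios") mean(r[mem]) else
      mean(a[mem]) / mean(tot[mem])
    data.frame(region = rg, band_low = band[1], band_high = band[2],
               abs_power = mean(a[mem]), rel_power = rel,
               n_channels = length(mem), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("band_power_table", "data.frame")
  out
}
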