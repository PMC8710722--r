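#' Common average reference
#'
#' Re-references every channel to the instantaneous mean over all channels:
#' `out[i, t] = in[i, t] - mean_j in[j, t]`. After CAR the channel mean at
#' every sample is zero.
#'
#' @param rec an [eeg_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) {
    stop("invalid-input: common average reference needs >= 2 channels")
  }
  replace_data(rec, sweep(rec$data, 2, colMeans(rec$data)))
}

# Zero-phase (forward-backward) Butterworth filtering of every channel.
filtfilt_matrix <- function(data, filt) {
  t(apply(data, 1, function(x) signal::filtfilt(filt, x)))
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth filtering applied forward and backward (zero phase).
#' Narrow bands (`high/low <= 5`, e.g. the 8-13 Hz alpha band) use a single
#' band-pass section, which is nearly flat inside the band; wide bands
#' (e.g. 0.1-100 Hz) use a cascade of high-pass and low-pass stages, which
#' stays numerically stable at very low corner frequencies. `low = 0` gives
#' a pure low-pass.
#'
#' @param rec an [eeg_recording()].
#' @param low,high corner frequencies in Hz, `0 <= low < high < Nyquist`.
#' @param order Butterworth order per stage (default 4).
#' @return The filtered recording (same length).
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (low < 0 || low >= high || high >= nyq) {
    stop("invalid-parameter: need 0 <= low < high < Nyquist")
  }
  dat <- rec$data
  if (low > 0 && high / low <= 5) {
    bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
    dat <- filtfilt_matrix(dat, bp)
  } else {
    if (low > 0) {
      if (low >= nyq) stop("invalid-parameter: low corner above Nyquist")
      hp <- signal::butter(order, low / nyq, type = "high")
      dat <- filtfilt_matrix(dat, hp)
    }
    if (high < nyq) {
      lp <- signal::butter(order, high / nyq, type = "low")
      dat <- filtfilt_matrix(dat, lp)
    }
  }
  replace_data(rec, dat)
}

#' Zero-phase notch filter
#'
#' Order-2 Butterworth band-stop (width 3 Hz, centred on `freq`), applied
#' forward-backward. Attenuation at the notch frequency exceeds 20 dB while
#' frequencies 5 Hz or more away are affected by less than 1 dB.
#'
#' @param rec an [eeg_recording()].
#' @param freq notch frequency in Hz (0 < freq < Nyquist), e.g. 50 for mains.
#' @param width stop-band width in Hz (default 3).
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, freq, width = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (freq <= 0 || freq >= nyq) {
    stop("invalid-parameter: notch frequency outside (0, Nyquist)")
  }
  bs <- signal::butter(2, c(freq - width / 2, freq + width / 2) / nyq,
                       type = "stop")
  replace_data(rec, filtfilt_matrix(rec$data, bs))
}

#' Split a recording into consecutive fixed-length epochs
#'
#' Non-overlapping epochs from the start of the recording; a trailing
#' remainder shorter than one epoch is dropped.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_duration epoch length in seconds.
#' @return A list of class `epoch_set`: `epochs` (list of recordings) and
#'   `epoch_duration`.
#' @export
epoch_recording <- function(rec, epoch_duration) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_duration * rec$sampling_rate)
  n <- ncol(rec$data)
  if (len < 1 || n < len) {
    stop("invalid-input: recording shorter than one epoch")
  }
  k <- n %/% len
  epochs <- lapply(seq_len(k), function(i) {
    replace_data(rec, rec$data[, ((i - 1) * len + 1):(i * len), drop = FALSE])
  })
  structure(list(epochs = epochs, epoch_duration = epoch_duration),
            class = "epoch_set")
}

#' Flag outliers by the 1.5 x IQR box-plot rule
#'
#' Quartiles use linear interpolation (R's default type 7). Values below
#' `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR` are flagged. Used for
#' subject-level screening of total broadband power.
#'
#' @param values numeric vector (length >= 4).
#' @return Integer indices of flagged values (possibly empty).
#' @export
iqr_outliers <- function(values) {
  if (length(values) < 4) stop("invalid-input: need at least 4 values")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  which(values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr)
}
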