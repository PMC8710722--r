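#' Construct an EEG recording
#'
#' The basic currency of the pipeline: a channels-by-samples matrix of scalp
#' potentials (microvolts) with channel labels, sampling rate and experiment
#' metadata.
#'
#' @param data numeric matrix, channels in rows, samples in columns (µV).
#' @param channel_names character vector, one unique label per row of `data`.
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param condition experimental condition label, e.g. `"rest"`, `"random"`,
#'   `"flicker40"`.
#' @param subject_id subject label.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names = NULL, sampling_rate,
                          condition = "rest", subject_id = "S1") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names)) {
    channel_names <- rownames(data)
    if (is.null(channel_names)) {
      channel_names <- sprintf("CH%02d", seq_len(nrow(data)))
    }
  }
  if (length(channel_names) != nrow(data)) {
    stop("invalid-input: channel_names length must equal number of data rows")
  }
  if (anyDuplicated(channel_names)) {
    stop("invalid-input: channel names must be unique")
  }
  if (anyNA(data)) stop("invalid-input: recording contains missing values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("invalid-input: sampling_rate must be a positive scalar")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, channel_names = channel_names,
         sampling_rate = as.numeric(sampling_rate),
         condition = condition, subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s / %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              x$sampling_rate, ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Replace the data matrix of a recording, keeping metadata
#' @param rec an `eeg_recording`.
#' @param data replacement channels-by-samples matrix (same channel count).
#' @return A new `eeg_recording`.
#' @keywords internal
replace_data <- function(rec, data) {
  stopifnot(nrow(data) == nrow(rec$data))
  rec$data <- data
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Load an electrode montage
#'
#' Reads a montage table (columns `name`, `x`, `y`, `region`) giving 2-D
#' head-surface coordinates and a scalp-region label for every electrode.
#' The shipped default is a 64-channel 10/20-extension cap whose regions are
#' the seven anterior-posterior areas F, FC, C, CP, P, PO, O plus the mastoid
#' references M.
#'
#' @param path path to a montage CSV; default: the shipped 64-channel cap.
#' @return A data.frame with class `eeg_montage`.
#' @export
load_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage_64ch.csv",
                        package = "flickerstates", mustWork = TRUE)
  }
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "region")
  if (!all(need %in% names(m))) {
    stop("invalid-montage: montage file must have columns name, x, y, region")
  }
  if (anyDuplicated(m$name)) stop("invalid-montage: duplicate channel names")
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' Map channels to scalp regions
#'
#' @param montage an `eeg_montage`.
#' @param channels channel names to map; default all montage channels.
#' @return Named character vector region per channel.
#' @export
montage_regions <- function(montage, channels = montage$name) {
  idx <- match(channels, montage$name)
  if (anyNA(idx)) {
    stop("invalid-montage: channels not in montage: ",
         paste(channels[is.na(idx)], collapse = ", "))
  }
  stats::setNames(montage$region[idx], channels)
}

# Pearson correlation between topographies (spatial correlation).
# `a` may be a matrix with topographies in rows; `b` one topography or matrix.
spatial_corr <- function(a, b) {
  if (is.null(dim(a)) && is.null(dim(b))) return(as.numeric(cor(a, b)))
  a <- if (is.null(dim(a))) matrix(a, nrow = 1) else a
  b <- if (is.null(dim(b))) matrix(b, nrow = 1) else b
  cor(t(a), t(b))
}

# Center (across channels) and scale rows of a topography matrix to unit norm.
# Rows with zero variance become zero rows.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  nrm[nrm == 0] <- 1
  maps / nrm
}
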