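#' Construct a microstate label sequence
#'
#' Per-sample class labels (0-based) at a known sampling rate, optionally
#' carrying the per-sample absolute spatial correlation with the assigned
#' template (`correlation_trace`) and the full class-by-sample absolute
#' correlation matrix used for segment smoothing.
#'
#' @param labels integer vector of labels in `0..n_states-1`.
#' @param sampling_rate Hz.
#' @param n_states number of classes K.
#' @param correlation_trace optional numeric vector, same length as labels.
#' @param corr_matrix optional K x length(labels) matrix of |correlations|.
#' @return An object of class `label_sequence`.
#' @export
new_label_sequence <- function(labels, sampling_rate, n_states,
                               correlation_trace = NULL, corr_matrix = NULL) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stop("invalid-input: empty label sequence")
  if (any(labels < 0) || any(labels >= n_states)) {
    stop("invalid-input: labels outside 0..n_states-1")
  }
  structure(list(labels = labels, sampling_rate = sampling_rate,
                 n_states = as.integer(n_states),
                 correlation_trace = correlation_trace,
                 corr_matrix = corr_matrix),
            class = "label_sequence")
}

#' @export
length.label_sequence <- function(x) length(x$labels)

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, K=%d, %d segments\n",
              length(x$labels), x$sampling_rate, x$n_states,
              length(rle(x$labels)$lengths)))
  invisible(x)
}

#' Global field power
#'
#' The spatial standard deviation of the scalp topography at every sample,
#' with the population (N) denominator. A reference-independent index of
#' instantaneous whole-brain signal strength; its peaks mark moments of
#' high topographic signal-to-noise where microstate maps are sampled.
#'
#' @param rec an [eeg_recording()] (or channels-by-samples matrix), >= 2
#'   channels.
#' @return Numeric vector, one GFP value per sample.
#' @export
global_field_power <- function(rec) {
  dat <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  if (nrow(dat) < 2) stop("invalid-input: GFP needs >= 2 channels")
  mu <- colMeans(dat)
  sqrt(colMeans(dat^2) - mu^2)
}

#' Find GFP peaks
#'
#' Strict local maxima of the GFP series; of any two peaks closer than
#' `min_separation` samples, only the larger is kept.
#'
#' @param gfp numeric GFP series (length >= 3).
#' @param min_separation minimum peak separation in samples (default 1).
#' @return Integer vector of peak indices (possibly empty), increasing.
#' @export
find_gfp_peaks <- function(gfp, min_separation = 1) {
  n <- length(gfp)
  if (n < 3) stop("invalid-input: series too short for peak finding")
  i <- 2:(n - 1)
  pk <- i[gfp[i] > gfp[i - 1] & gfp[i] > gfp[i + 1]]
  if (min_separation > 1 && length(pk) > 1) {
    ord <- pk[order(gfp[pk], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_separation)) {
        kept <- c(kept, p)
      }
    }
    pk <- sort(kept)
  }
  pk
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' Alternates (a) assignment of every map to the template maximizing the
#' squared spatial correlation (so map polarity is ignored) and (b) template
#' update as the dominant eigenvector of the sum of outer products of the
#' assigned maps. Convergence is declared when the improvement in global
#' explained variance (GEV) falls below `tol`; the best of `n_restarts`
#' random initializations (by GEV) is returned.
#'
#' @param maps n_maps x n_channels matrix of topographies (e.g. maps at GFP
#'   peaks); they are average-referenced and unit-normalized internally.
#' @param n_states number of classes K (default 4).
#' @param n_restarts random restarts (default 20).
#' @param max_iter iteration cap per restart (default 500).
#' @param tol GEV convergence tolerance (default 1e-6).
#' @param seed integer seed (initialization), makes the fit deterministic.
#' @param gfp optional per-map weights for GEV (default: the maps' own GFP).
#' @return A list of class `microstate_model`: `templates` (K x channels,
#'   unit norm), `gev`, `n_states`, `polarity_invariant = TRUE`, `fit_meta`.
#' @export
modified_kmeans <- function(maps, n_states = 4, n_restarts = 20,
                            max_iter = 500, tol = 1e-6, seed = 1,
                            gfp = NULL) {
  maps <- as.matrix(maps)
  n_maps <- nrow(maps)
  if (n_maps < n_states) {
    stop("invalid-input: fewer maps than requested states")
  }
  if (is.null(gfp)) gfp <- global_field_power(t(maps))
  X <- normalize_maps(maps)
  w2 <- gfp^2 / sum(gfp^2)                   # GEV weights
  set.seed(as.integer(seed))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    tmpl <- X[sample.int(n_maps, n_states), , drop = FALSE]
    gev_prev <- -Inf; it <- 0; converged <- FALSE
    repeat {
      it <- it + 1
      A <- X %*% t(tmpl)                     # correlations (rows unit, centered)
      assign_k <- max.col(A^2, ties.method = "first")
      for (k in seq_len(n_states)) {
        sel <- assign_k == k
        if (!any(sel)) {                     # empty cluster: reseed
          tmpl[k, ] <- X[sample.int(n_maps, 1), ]
          next
        }
        # GEV-optimal update: dominant eigenvector of the GFP^2-weighted
        # scatter, so the alternation monotonically increases GEV
        S <- crossprod(X[sel, , drop = FALSE] * sqrt(w2[sel]))
        ev <- eigen(S, symmetric = TRUE)
        tmpl[k, ] <- ev$vectors[, 1]
      }
      tmpl <- normalize_maps(tmpl)
      A <- X %*% t(tmpl)
      assign_k <- max.col(A^2, ties.method = "first")
      gev <- sum(w2 * A[cbind(seq_len(n_maps), assign_k)]^2)
      if (gev - gev_prev < tol) { converged <- gev - gev_prev > -tol; break }
      if (it >= max_iter) break
      gev_prev <- gev
    }
    if (is.null(best) || gev > best$gev) {
      best <- list(tmpl = tmpl, gev = gev, iters = it, converged = converged)
    }
  }
  structure(
    list(templates = best$tmpl, gev = best$gev, n_states = n_states,
         polarity_invariant = TRUE,
         fit_meta = list(n_restarts = n_restarts, iterations = best$iters,
                         converged = best$converged, seed = seed, tol = tol)),
    class = "microstate_model"
  )
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K=%d over %d channels, GEV=%.3f\n",
              x$n_states, ncol(x$templates), x$gev))
  invisible(x)
}

#' Back-fit microstate templates to a recording
#'
#' Labels every sample with the template of maximal absolute spatial
#' correlation (polarity-free); ties go to the lowest class index. Samples
#' with zero topographic variance get class 0 and correlation 0.
#'
#' @param model a `microstate_model`.
#' @param rec an [eeg_recording()] with the model's channel count.
#' @return A `label_sequence` carrying `correlation_trace` and the full
#'   `corr_matrix` (K x samples absolute correlations).
#' @export
backfit <- function(model, rec) {
  stopifnot(inherits(model, "microstate_model"),
            inherits(rec, "eeg_recording"))
  if (ncol(model$templates) != nrow(rec$data)) {
    stop("invalid-input: model/recording channel mismatch")
  }
  Xc <- sweep(rec$data, 2, colMeans(rec$data))
  nrm <- sqrt(colSums(Xc^2))
  nrm[nrm == 0] <- Inf
  cors <- abs((model$templates %*% Xc) / rep(nrm, each = model$n_states))
  labels <- max.col(t(cors), ties.method = "first") - 1L
  trace <- cors[cbind(labels + 1L, seq_along(labels))]
  new_label_sequence(labels, rec$sampling_rate, model$n_states,
                     correlation_trace = trace, corr_matrix = cors)
}

#' Reject (reassign) microstate segments shorter than a minimum duration
#'
#' Iteratively, every sample of a segment shorter than `min_duration` is
#' reassigned to the neighbouring segment's class with the higher absolute
#' spatial correlation at that sample, until no short segment remains.
#' Sequence length is preserved. If the whole sequence is one short segment
#' it is returned unchanged with attribute `short_sequence = TRUE`.
#'
#' @param labels a `label_sequence` with a `corr_matrix` (from [backfit()]).
#' @param min_duration minimum segment duration in ms (default 30;
#'   `ceiling(min_duration * fs / 1000)` samples).
#' @return The smoothed `label_sequence`.
#' @export
reject_short_segments <- function(labels, min_duration = 30) {
  stopifnot(inherits(labels, "label_sequence"), min_duration >= 0)
  min_samp <- ceiling(min_duration * labels$sampling_rate / 1000)
  if (min_samp <= 1) return(labels)
  l <- labels$labels
  if (length(l) < min_samp) {
    attr(labels, "short_sequence") <- TRUE
    warning("sequence shorter than the minimum segment duration")
    return(labels)
  }
  cm <- labels$corr_matrix
  if (is.null(cm)) {
    stop("invalid-input: corr_matrix required for segment reassignment")
  }
  for (pass in seq_len(1000)) {
    r <- rle(l)
    if (length(r$lengths) == 1 || all(r$lengths >= min_samp)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    # fix the shortest segment first, then re-derive runs
    s <- which.min(r$lengths + ifelse(r$lengths >= min_samp, Inf, 0))
    left <- if (s > 1) r$values[s - 1] else NA
    right <- if (s < length(r$values)) r$values[s + 1] else NA
    for (t in starts[s]:ends[s]) {
      if (is.na(left)) l[t] <- right
      else if (is.na(right)) l[t] <- left
      else l[t] <- if (cm[left + 1L, t] >= cm[right + 1L, t]) left else right
    }
  }
  labels$labels <- l
  labels$correlation_trace <- cm[cbind(l + 1L, seq_along(l))]
  labels
}

#' Global explained variance of a labeled recording
#'
#' `GEV = sum_t (GFP_t * corr(x_t, template[label_t]))^2 / sum_t GFP_t^2`,
#' the GFP-weighted fraction of topographic variance explained by the
#' assigned templates.
#'
#' @param model a `microstate_model`.
#' @param rec the labeled [eeg_recording()].
#' @param labels the `label_sequence` from [backfit()].
#' @return GEV fraction in `[0, 1]`.
#' @export
compute_gev <- function(model, rec, labels) {
  stopifnot(inherits(model, "microstate_model"),
            inherits(rec, "eeg_recording"),
            inherits(labels, "label_sequence"),
            length(labels) == ncol(rec$data))
  g <- global_field_power(rec)
  if (sum(g^2) == 0) stop("undefined: zero total GFP")
  Xc <- sweep(rec$data, 2, colMeans(rec$data))
  nrm <- sqrt(colSums(Xc^2))
  nrm[nrm == 0] <- Inf
  tmpl <- model$templates[labels$labels + 1L, , drop = FALSE]
  co <- colSums(t(tmpl) * Xc) / nrm
  sum((g * co)^2) / sum(g^2)
}

#' Idealized canonical microstate reference maps (synthetic)
#'
#' Smooth stand-ins for the four canonical resting-state microstate
#' topographies: A (left-posterior to right-frontal diagonal), B
#' (right-posterior to left-frontal diagonal), C (occipital-to-frontal,
#' symmetric), D (fronto-central focal). These are idealized synthetic
#' patterns constructed from the electrode layout, used only to give fitted
#' classes a reproducible A-D ordering; they are not empirical group maps.
#'
#' @param n_channels number of electrodes (default 64, shipped montage).
#' @return 4 x n_channels matrix, rows named A-D, unit norm.
#' @export
canonical_templates <- function(n_channels = 64) {
  xy <- electrode_layout(n_channels)
  x <- xy[, 1]; y <- xy[, 2]
  tpl <- rbind(
    A = -x + y,                              # L-post to R-front gradient
    B = x + y,                               # R-post to L-front gradient
    C = y,                                   # posterior-anterior axis
    D = exp(-((x)^2 + (y - 0.3)^2) / 0.35) - 0.35  # fronto-central focus
  )
  normalize_maps(tpl)
}

#' Relabel model classes by best match to reference maps
#'
#' Greedy matching by absolute spatial correlation between fitted and
#' reference templates, so that class ordering is comparable across runs.
#'
#' @param model a `microstate_model`.
#' @param reference reference templates (default [canonical_templates()]).
#' @return The model with rows of `templates` permuted and named after the
#'   matched reference rows; permutation stored in `fit_meta$relabeling`.
#' @export
relabel_states <- function(model, reference = NULL) {
  if (is.null(reference)) reference <- canonical_templates(ncol(model$templates))
  stopifnot(nrow(reference) == model$n_states)
  cc <- abs(spatial_corr(model$templates, reference))
  perm <- integer(model$n_states)            # perm[ref] = fitted class
  for (i in seq_len(model$n_states)) {
    idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    perm[idx[2]] <- idx[1]
    cc[idx[1], ] <- -1
    cc[, idx[2]] <- -1
  }
  model$templates <- model$templates[perm, , drop = FALSE]
  rn <- rownames(reference)
  rownames(model$templates) <- if (is.null(rn)) {
    LETTERS[seq_len(model$n_states)]
  } else rn
  model$fit_meta$relabeling <- perm
  model
}
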