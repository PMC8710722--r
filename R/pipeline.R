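#' Default pipeline configuration
#'
#' Mirrors the study's printed acquisition and analysis settings: 500 Hz
#' sampling, 0.1-100 Hz band-pass, 50 Hz notch, CAR, alpha band (8-13 Hz)
#' for microstate clustering, K = 4 classes, 30 ms minimum segment
#' duration, 39-41 Hz stimulation band over a 0.1-100 Hz total band,
#' alpha = q = 0.05. The synthetic experiment simulates three conditions
#' (rest, random flicker, 40 Hz flicker) with a 40 Hz SSVEP injected over
#' posterior regions only in the `flicker40` condition.
#'
#' @param seed master seed.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    mode = "synthetic",
    n_subjects = 10,
    conditions = c("rest", "random", "flicker40"),
    synthetic = list(
      n_channels = 64, sampling_rate = 500, duration = 30, n_states = 4,
      mean_segment_duration = 60, alpha_band = c(8, 13),
      noise_exponent = 1, snr = 5,
      ssvep = list(frequency = 40,
                   region_gains = list(O = 1.5, PO = 1.0, P = 0.6, CP = 0.25),
                   subject_sd = 0.2)
    ),
    preprocessing = list(bandpass = c(0.1, 100), notch = 50),
    spectral = list(band = c(39, 41), total_band = c(0.1, 100), nw = 4),
    microstates = list(n_states = 4, n_restarts = 20, tol = 1e-6,
                       min_segment_ms = 30, cluster_band = c(8, 13),
                       lzc_band = c(1, 100)),
    stats = list(alpha = 0.05, q = 0.05),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Parses a YAML file (or takes a list), checks every constraint and
#' returns the validated `run_config`, or raises one error listing all
#' violations found (not just the first).
#'
#' @param config path to a YAML config file, or a config list.
#' @return A `run_config` (invisibly the same list, validated).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("parse error: config file not found: ", config)
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) stop("parse error: ", conditionMessage(e)))
  }
  base <- unclass(default_run_config())
  cfg <- utils::modifyList(base, config, keep.null = TRUE)
  # YAML sequences of mixed int/double arrive as lists; flatten numeric pairs
  as_num <- function(x) if (is.list(x)) as.numeric(unlist(x)) else x
  for (f in c("alpha_band")) cfg$synthetic[[f]] <- as_num(cfg$synthetic[[f]])
  cfg$preprocessing$bandpass <- as_num(cfg$preprocessing$bandpass)
  for (f in c("band", "total_band")) cfg$spectral[[f]] <- as_num(cfg$spectral[[f]])
  for (f in c("cluster_band", "lzc_band")) {
    cfg$microstates[[f]] <- as_num(cfg$microstates[[f]])
  }
  cfg$conditions <- as.character(unlist(cfg$conditions))
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)

  chk(cfg$mode %in% c("synthetic", "files"), "mode: must be 'synthetic' or 'files'")
  chk(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 1, "n_subjects: must be >= 1")
  chk(length(cfg$conditions) >= 2, "conditions: need at least two conditions")
  s <- cfg$synthetic
  chk(s$sampling_rate > 0, "synthetic.sampling_rate: must be > 0")
  chk(s$duration > 0, "synthetic.duration: must be > 0")
  chk(s$n_states >= 2, "synthetic.n_states: must be >= 2")
  chk(s$n_states <= s$n_channels, "synthetic.n_states: must not exceed n_channels")
  chk(s$mean_segment_duration > 0, "synthetic.mean_segment_duration: must be > 0")
  chk(length(s$alpha_band) == 2 && s$alpha_band[1] < s$alpha_band[2],
      "synthetic.alpha_band: need low < high")
  chk(s$snr > 0, "synthetic.snr: must be > 0")
  p <- cfg$preprocessing
  chk(length(p$bandpass) == 2 && p$bandpass[1] < p$bandpass[2],
      "preprocessing.bandpass: need low < high")
  chk(p$bandpass[2] < s$sampling_rate / 2 + 1e-9,
      "preprocessing.bandpass: high edge above Nyquist")
  chk(is.null(p$notch) || (p$notch > 0 && p$notch < s$sampling_rate / 2),
      "preprocessing.notch: outside (0, Nyquist)")
  sp <- cfg$spectral
  chk(length(sp$band) == 2 && sp$band[1] < sp$band[2],
      "spectral.band: need low < high")
  chk(length(sp$total_band) == 2 && sp$total_band[1] < sp$total_band[2],
      "spectral.total_band: need low < high")
  ms <- cfg$microstates
  chk(is.numeric(ms$n_states) && ms$n_states >= 1,
      "microstates.n_states: must be >= 1")
  chk(ms$n_restarts >= 1, "microstates.n_restarts: must be >= 1")
  chk(ms$tol > 0, "microstates.tol: must be > 0")
  chk(ms$min_segment_ms >= 0, "microstates.min_segment_ms: must be >= 0")
  chk(length(ms$cluster_band) == 2 && ms$cluster_band[1] < ms$cluster_band[2],
      "microstates.cluster_band: need low < high")
  chk(length(ms$lzc_band) == 2 && ms$lzc_band[1] < ms$lzc_band[2],
      "microstates.lzc_band: need low < high")
  st <- cfg$stats
  chk(st$alpha > 0 && st$alpha < 1, "stats.alpha: must lie in (0, 1)")
  chk(st$q > 0 && st$q < 1, "stats.q: must lie in (0, 1)")
  if (identical(cfg$mode, "files")) {
    chk(!is.null(cfg$files) && all(file.exists(unlist(cfg$files))),
        "files: all referenced recordings must exist")
  }
  if (length(v)) {
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "))
  }
  class(cfg) <- "run_config"
  cfg
}

# per-subject/condition seed, deterministic and well below 2^31
run_seed <- function(master, subject, cond_idx) {
  (as.integer(master) %% 100000L) * 10000L + subject * 10L + cond_idx
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> spectral -> microstates -> dynamics -> stats.
#' In synthetic mode the run also emits a ground-truth-versus-recovered
#' comparison (template correlations, label agreement, coverage/duration
#' errors, transition-matrix error). Fully reproducible given the master
#' seed; all tables are written as CSV under `output_dir` together with a
#' JSON run report.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [validate_config()]).
#' @param output_dir directory for output tables (created if needed);
#'   `NULL` keeps everything in memory.
#' @param seed optional master-seed override.
#' @return A list of class `run_report`: all result tables, warnings,
#'   stage timings, output paths.
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL,
                         seed = NULL) {
  config <- validate_config(unclass(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (config$mode != "synthetic") {
    stop("stage=input: only synthetic mode is implemented for end-to-end runs")
  }
  t0 <- Sys.time()
  warnings_log <- character(0)
  timing <- list()
  tick <- function(stage, t) {
    timing[[stage]] <<- round(as.numeric(Sys.time()) - as.numeric(t), 2)
  }

  scfg <- config$synthetic
  K <- config$microstates$n_states
  conds <- config$conditions
  montage <- load_montage()
  regions <- montage_regions(montage)

  ## --- simulate + preprocess + per-recording feature extraction -----------
  ts <- Sys.time()
  tpl_planted <- generate_templates(scfg$n_channels, scfg$n_states,
                                    seed = config$seed)
  set.seed(config$seed)
  subj_gain <- exp(rnorm(config$n_subjects, 0, scfg$ssvep$subject_sd))

  gains_base <- rep(0, scfg$n_channels)
  for (rg in names(scfg$ssvep$region_gains)) {
    gains_base[regions == rg] <- scfg$ssvep$region_gains[[rg]]
  }

  power_rows <- list()
  rec_store <- list()   # per recording: alpha rec, lzc rec, ground truth
  peak_maps <- list()
  peak_gfp <- list()
  ri <- 0
  for (s in seq_len(config$n_subjects)) {
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      ri <- ri + 1
      has_ssvep <- identical(cond, "flicker40")
      sc <- synthetic_config(
        n_channels = scfg$n_channels, sampling_rate = scfg$sampling_rate,
        duration = scfg$duration, n_states = scfg$n_states,
        mean_segment_duration = scfg$mean_segment_duration,
        alpha_band = scfg$alpha_band,
        ssvep_frequency = if (has_ssvep) scfg$ssvep$frequency else NULL,
        ssvep_channel_gains = if (has_ssvep) gains_base * subj_gain[s] else NULL,
        noise_exponent = scfg$noise_exponent, snr = scfg$snr,
        seed = run_seed(config$seed, s, ci))
      sim <- synthesize_eeg(sc, templates = tpl_planted)
      rec <- sim$recording
      rec$condition <- cond
      rec$subject_id <- sprintf("S%02d", s)

      rec <- bandpass_filter(rec, config$preprocessing$bandpass[1],
                             config$preprocessing$bandpass[2])
      if (!is.null(config$preprocessing$notch)) {
        rec <- notch_filter(rec, config$preprocessing$notch)
      }
      rec <- common_average_reference(rec)

      spec <- compute_psd(rec, nw = config$spectral$nw)
      bp <- region_percent_power(spec, montage, config$spectral$band,
                                 config$spectral$total_band)
      bp$subject <- rec$subject_id
      bp$condition <- cond
      power_rows[[ri]] <- bp

      alpha_rec <- bandpass_filter(rec, config$microstates$cluster_band[1],
                                   config$microstates$cluster_band[2])
      lzc_rec <- bandpass_filter(rec, config$microstates$lzc_band[1],
                                 min(config$microstates$lzc_band[2],
                                     rec$sampling_rate / 2 * 0.996))
      g <- global_field_power(alpha_rec)
      pk <- find_gfp_peaks(g)
      peak_maps[[ri]] <- t(alpha_rec$data[, pk, drop = FALSE])
      peak_gfp[[ri]] <- g[pk]
      rec_store[[ri]] <- list(subject = rec$subject_id, condition = cond,
                              alpha = alpha_rec, lzc = lzc_rec,
                              truth = sim$ground_truth)
    }
  }
  power_table <- do.call(rbind, power_rows)
  power_table <- power_table[, c("subject", "condition", "region",
                                 "band_low", "band_high", "abs_power",
                                 "rel_power", "n_channels")]
  tick("simulate_preprocess_spectral", ts)

  ## --- group-level microstate model ---------------------------------------
  ts <- Sys.time()
  model <- modified_kmeans(do.call(rbind, peak_maps), n_states = K,
                           n_restarts = config$microstates$n_restarts,
                           tol = config$microstates$tol,
                           seed = config$seed + 7L,
                           gfp = unlist(peak_gfp))
  model <- relabel_states(model)
  if (!model$fit_meta$converged) {
    warnings_log <- c(warnings_log, "microstates: k-means did not converge")
  }
  tick("microstate_clustering", ts)

  ## --- per-recording dynamics ---------------------------------------------
  ts <- Sys.time()
  metric_rows <- list(); trans_rows <- list(); recovery_rows <- list()
  lzc_sequences <- list(); lzc_meta <- list()
  for (ri in seq_along(rec_store)) {
    st <- rec_store[[ri]]
    lab <- reject_short_segments(backfit(model, st$alpha),
                                 config$microstates$min_segment_ms)
    met <- compute_metrics(lab)
    met$subject <- st$subject; met$condition <- st$condition
    met$gev <- compute_gev(model, st$alpha, lab)
    metric_rows[[ri]] <- met

    for (self in c(TRUE, FALSE)) {
      tm <- transition_matrix(lab, self_allowed = self)
      if (!all(tm$defined)) {
        warnings_log <- c(warnings_log, sprintf(
          "dynamics: undefined Markov row(s) in %s/%s (self=%s)",
          st$subject, st$condition, self))
      }
      df <- expand.grid(from = seq_len(K) - 1L, to = seq_len(K) - 1L)
      df$prob <- as.numeric(tm$probs[cbind(df$from + 1L, df$to + 1L)])
      df$self_allowed <- self
      df$subject <- st$subject; df$condition <- st$condition
      trans_rows[[length(trans_rows) + 1L]] <- df
    }

    lab_b <- reject_short_segments(backfit(model, st$lzc),
                                   config$microstates$min_segment_ms)
    lzc_sequences[[ri]] <- lab_b
    lzc_meta[[ri]] <- data.frame(subject = st$subject,
                                 condition = st$condition)

    # ground truth vs recovered
    truth <- st$truth
    cc <- abs(spatial_corr(model$templates, truth$templates))
    match_perm <- integer(K); cc2 <- cc
    for (i in seq_len(K)) {
      idx <- which(cc2 == max(cc2), arr.ind = TRUE)[1, ]
      match_perm[idx[2]] <- idx[1]           # planted k -> fitted class
      cc2[idx[1], ] <- -1; cc2[, idx[2]] <- -1
    }
    mapped <- (match_perm - 1L)[truth$labels + 1L]
    agree <- mean(mapped == lab$labels)
    planted_met <- compute_metrics(new_label_sequence(
      truth$labels, st$alpha$sampling_rate, K))
    fitted_cov <- met$coverage[match_perm]
    fitted_dur <- met$mean_duration[match_perm]
    seg_tm <- transition_matrix(lab, self_allowed = FALSE)
    perm_probs <- seg_tm$probs[match_perm, match_perm]
    recovery_rows[[ri]] <- data.frame(
      subject = st$subject, condition = st$condition,
      min_template_corr = min(cc[cbind(match_perm, seq_len(K))]),
      label_agreement = agree,
      max_coverage_error = max(abs(fitted_cov - planted_met$coverage)),
      max_duration_rel_error = max(abs(fitted_dur - planted_met$mean_duration) /
                                     planted_met$mean_duration),
      max_transition_error = max(abs(perm_probs - truth$transition_matrix),
                                 na.rm = TRUE))
  }
  metrics_table <- do.call(rbind, metric_rows)
  transitions_table <- do.call(rbind, trans_rows)
  recovery_table <- do.call(rbind, recovery_rows)

  lzc_sequences <- equalize_lengths(lzc_sequences)
  lzc_table <- do.call(rbind, lzc_meta)
  lzc_table$lzc <- vapply(lzc_sequences,
                          function(s) lz76_complexity(s)$lzc, 1L)
  lzc_table$sequence_length <- length(lzc_sequences[[1]])
  tick("dynamics", ts)

  ## --- statistics ----------------------------------------------------------
  ts <- Sys.time()
  q <- config$stats$q
  stats_rows <- list()
  add_family <- function(family, values_by_cond) {
    an <- one_way_anova(values_by_cond)
    ph <- pairwise_posthoc(values_by_cond)
    adj <- fdr_bky(ph$p_raw, q)
    rbind(
      data.frame(family = family, contrast = "omnibus",
                 statistic = an$F, df = paste(an$df_between, an$df_within,
                                              sep = ","),
                 p_raw = an$p, p_adjusted = NA_real_, significant = NA),
      data.frame(family = family,
                 contrast = paste(ph$group_a, ph$group_b, sep = " vs "),
                 statistic = ph$t, df = as.character(ph$df),
                 p_raw = ph$p_raw, p_adjusted = adj$p_adjusted,
                 significant = adj$significant))
  }
  for (rg in unique(power_table$region)) {
    sub <- power_table[power_table$region == rg, ]
    grp <- split(sub$rel_power, factor(sub$condition, levels = conds))
    stats_rows[[length(stats_rows) + 1L]] <-
      add_family(paste0("percent_power:", rg), grp)
  }
  for (metric in c("coverage", "mean_duration", "occurrence")) {
    for (k in seq_len(K) - 1L) {
      sub <- metrics_table[metrics_table$class == k, ]
      grp <- split(sub[[metric]], factor(sub$condition, levels = conds))
      if (any(vapply(grp, function(x) any(is.na(x)), TRUE))) next
      stats_rows[[length(stats_rows) + 1L]] <-
        add_family(sprintf("%s:class%d", metric, k), grp)
    }
  }
  stats_rows[[length(stats_rows) + 1L]] <-
    add_family("lzc", split(lzc_table$lzc,
                            factor(lzc_table$condition, levels = conds)))
  # transition probabilities: one-way ANOVA + Tukey HSD per (from, to) cell
  tsub <- transitions_table[!transitions_table$self_allowed &
                              transitions_table$from != transitions_table$to, ]
  for (ft in unique(paste(tsub$from, tsub$to))) {
    sel <- tsub[paste(tsub$from, tsub$to) == ft, ]
    if (any(is.na(sel$prob))) next
    grp <- split(sel$prob, factor(sel$condition, levels = conds))
    an <- one_way_anova(grp)
    tk <- tukey_hsd(grp)
    stats_rows[[length(stats_rows) + 1L]] <- rbind(
      data.frame(family = paste0("transition:", gsub(" ", "->", ft)),
                 contrast = "omnibus", statistic = an$F,
                 df = paste(an$df_between, an$df_within, sep = ","),
                 p_raw = an$p, p_adjusted = NA_real_, significant = NA),
      data.frame(family = paste0("transition:", gsub(" ", "->", ft)),
                 contrast = paste(tk$group_a, tk$group_b, sep = " vs "),
                 statistic = tk$q, df = as.character(tk$df),
                 p_raw = NA_real_, p_adjusted = tk$p_adjusted,
                 significant = tk$p_adjusted < config$stats$alpha))
  }
  stats_table <- do.call(rbind, stats_rows)
  tick("stats", ts)

  ## --- outputs -------------------------------------------------------------
  paths <- list()
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name) {
      p <- file.path(output_dir, paste0(name, ".csv"))
      write.csv(tab, p, row.names = FALSE)
      paths[[name]] <<- p
    }
    wr(power_table, "band_power")
    wr(metrics_table, "microstate_metrics")
    wr(transitions_table, "transition_probabilities")
    wr(lzc_table, "lzc")
    wr(recovery_table, "ground_truth_recovery")
    wr(stats_table, "stats_results")
  }
  report <- structure(list(
    config = unclass(config),
    model = model,
    tables = list(band_power = power_table, metrics = metrics_table,
                  transitions = transitions_table, lzc = lzc_table,
                  recovery = recovery_table, stats = stats_table),
    warnings = warnings_log, timing = timing, paths = paths,
    versions = list(flickerstates = as.character(
      utils::packageVersion("flickerstates")), R = R.version.string),
    wall_time = round(as.numeric(Sys.time()) - as.numeric(t0), 2)),
    class = "run_report")
  if (!is.null(output_dir)) {
    rp <- report; rp$model <- NULL; rp$tables <- NULL
    jsonlite::write_json(rp, file.path(output_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report$paths$run_report <- file.path(output_dir, "run_report.json")
  }
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d subjects x %d conditions, K=%d, GEV=%.3f, %ss\n",
              x$config$n_subjects, length(x$config$conditions),
              x$model$n_states, x$model$gev, x$wall_time))
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}
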