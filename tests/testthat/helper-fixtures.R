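# Shared fixtures and independent oracles for the test suite.

.fixtures <- new.env()

# Greedy bijective matching of fitted to planted templates by |corr|;
# returns perm with perm[planted_k] = fitted class (1-based).
greedy_match <- function(fitted, planted) {
  cc <- abs(cor(t(fitted), t(planted)))
  K <- nrow(cc)
  perm <- integer(K)
  for (i in seq_len(K)) {
    idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    perm[idx[2]] <- idx[1]
    cc[idx[1], ] <- -1
    cc[, idx[2]] <- -1
  }
  perm
}

# The standard synthetic recovery fixture: 64 channels, K = 4, snr = 5,
# 60 s at 500 Hz, fixed seed. The generated carrier is already band-limited
# to the alpha band, so back-fitting runs on the generated band directly.
recovery_fixture <- function() {
  if (!is.null(.fixtures$recovery)) return(.fixtures$recovery)
  cfg <- synthetic_config(duration = 60, snr = 5, seed = 42)
  sim <- synthesize_eeg(cfg)
  rec <- common_average_reference(sim$recording)
  g <- global_field_power(rec)
  pk <- find_gfp_peaks(g)
  model <- modified_kmeans(t(rec$data[, pk, drop = FALSE]), 4,
                           seed = 1, gfp = g[pk])
  labels <- reject_short_segments(backfit(model, rec), 30)
  perm <- greedy_match(model$templates, sim$ground_truth$templates)
  .fixtures$recovery <- list(
    sim = sim, rec = rec, model = model, labels = labels, perm = perm,
    matched_corr = abs(cor(t(model$templates),
                           t(sim$ground_truth$templates)))[cbind(perm, 1:4)],
    planted = new_label_sequence(sim$ground_truth$labels, 500, 4))
  .fixtures$recovery
}

# Pure-R LZ76 oracle: direct definition via string substring search.
# Third, independent route for small sequences.
lz76_r_oracle <- function(s) {
  txt <- paste(s, collapse = ",")
  toks <- strsplit(txt, ",")[[1]]
  n <- length(toks)
  cnt <- 0L; h <- 1L
  while (h <= n) {
    j <- h
    while (j <= n) {
      phrase <- paste(toks[h:j], collapse = ",")
      prefix <- if (j > 1) paste(toks[1:(j - 1)], collapse = ",") else ""
      if (!grepl(phrase, prefix, fixed = TRUE)) break
      j <- j + 1L
    }
    cnt <- cnt + 1L
    if (j > n) break
    h <- j + 1L
  }
  cnt
}

# Independently coded two-stage adaptive step-up reference (explicit
# stage-wise loops, no shared code with fdr_bky).
bky_reference <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  bh_reject <- function(pv, level) {
    o <- order(pv)
    k <- 0L
    for (i in seq_len(m)) if (pv[o][i] <= i / m * level) k <- i
    out <- logical(m)
    if (k > 0) out[o[seq_len(k)]] <- TRUE
    out
  }
  s1 <- bh_reject(p, qp)
  r1 <- sum(s1)
  if (r1 == 0L) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  bh_reject(p, qp * m / (m - r1))
}

# Numerical-integration oracle for the studentized range CDF.
srange_cdf <- function(q, k, df) {
  inner <- function(z, qs) dnorm(z) * (pnorm(z) - pnorm(z - qs))^(k - 1)
  outer_f <- function(s) {
    vapply(s, function(si) {
      k * integrate(inner, -Inf, Inf, qs = q * si, rel.tol = 1e-9)$value *
        2 * df * si * dchisq(df * si^2, df)
    }, 1)
  }
  integrate(outer_f, 0, Inf, rel.tol = 1e-8)$value
}

# RMS helper for filter-response oracles.
rms <- function(x) sqrt(mean(x^2))

# Single-channel sinusoid recording duplicated over a few channels.
tone_recording <- function(freq, fs = 500, dur = 10, n_channels = 2) {
  t <- (0:(round(dur * fs) - 1)) / fs
  eeg_recording(matrix(rep(sin(2 * pi * freq * t), n_channels),
                       n_channels, byrow = TRUE), sampling_rate = fs)
}
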