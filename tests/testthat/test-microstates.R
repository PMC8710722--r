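test_that("global field power is the population spatial standard deviation", {
  r <- eeg_recording(matrix(c(3, -3), 2, 4), sampling_rate = 500)
  expect_equal(global_field_power(r), rep(3, 4))
  r2 <- eeg_recording(matrix(7, 5, 4), sampling_rate = 500)
  expect_equal(global_field_power(r2), rep(0, 4))
  set.seed(1)
  topo <- matrix(rnorm(64 * 10), 64)
  brute <- apply(topo, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(global_field_power(topo), brute, tolerance = 1e-12)
  expect_error(global_field_power(matrix(1, 1, 5)), "invalid-input")
})

test_that("GFP peaks are strict local maxima at the alpha-doubled rate", {
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_length(find_gfp_peaks(1:10), 0)
  # min separation keeps the larger of close peaks
  g <- c(0, 3, 0, 5, 0)
  expect_identical(find_gfp_peaks(g, min_separation = 3), 4L)
  # rectified alpha: two GFP peaks per cycle
  cfg <- synthetic_config(duration = 30, snr = Inf, seed = 2,
                          alpha_band = c(9.5, 10.5))
  rec <- synthesize_eeg(cfg)$recording
  rate <- length(find_gfp_peaks(global_field_power(rec))) / 30
  expect_lt(abs(rate - 20) / 20, 0.1)
})

test_that("modified k-means recovers exact mixtures and ignores polarity", {
  set.seed(3)
  base <- matrix(rnorm(2 * 64), 2)
  base[1, ] <- base[1, ] - mean(base[1, ])
  base[2, ] <- base[2, ] - mean(base[2, ])
  base[2, ] <- base[2, ] - sum(base[1, ] * base[2, ]) /
    sum(base[1, ]^2) * base[1, ]             # orthogonalize
  base <- base / sqrt(rowSums(base^2))
  maps <- base[rep(1:2, each = 50), ] * runif(100, 0.5, 2) *
    sample(c(-1, 1), 100, TRUE)
  fit <- modified_kmeans(maps, 2, seed = 1)
  cc <- abs(cor(t(fit$templates), t(base)))
  expect_equal(sort(apply(cc, 1, max)), c(1, 1), tolerance = 1e-6)
  # appending the sign-flipped copy changes nothing
  fit2 <- modified_kmeans(rbind(maps, -maps), 2, seed = 1)
  expect_equal(fit2$gev, fit$gev, tolerance = 1e-9)
  expect_error(modified_kmeans(maps[1, , drop = FALSE], 2), "invalid-input")
})

test_that("back-fitting matches templates polarity-free with lowest-index ties", {
  fx <- recovery_fixture()
  model <- fx$model
  # recording built from template 2 (0-based) under arbitrary signed scaling
  set.seed(4)
  sc <- runif(50, 0.1, 3) * sample(c(-1, 1), 50, TRUE)
  rec <- eeg_recording(t(model$templates[3, , drop = FALSE][rep(1, 50), ] * sc),
                       sampling_rate = 500)
  lab <- backfit(model, rec)
  expect_true(all(lab$labels == 2L))
  expect_gt(min(lab$correlation_trace), 1 - 1e-9)
  # exact ties (duplicated template) resolve to the lowest class index
  dup <- model
  dup$templates[2, ] <- dup$templates[1, ]
  rec_t <- eeg_recording(t(dup$templates[1, , drop = FALSE][c(1, 1, 1), ]),
                         sampling_rate = 500)
  expect_true(all(backfit(dup, rec_t)$labels == 0L))
  # zero topographic variance: correlation 0, class 0
  rec0 <- eeg_recording(matrix(1, 64, 3), sampling_rate = 500)
  lab0 <- backfit(model, rec0)
  expect_true(all(lab0$labels == 0L))
  expect_true(all(lab0$correlation_trace == 0))
  expect_error(backfit(model, eeg_recording(matrix(1, 3, 3),
                                            sampling_rate = 500)),
               "invalid-input")
})

test_that("short-segment rejection absorbs sub-threshold runs and preserves length", {
  K <- 3
  lab <- rep(c(0L, 1L, 2L), c(100, 5, 100))
  cm <- matrix(0.1, K, 205)
  cm[1, 1:103] <- 0.9                        # left class wins first part
  cm[3, 104:205] <- 0.9
  ls <- new_label_sequence(lab, 500, K, corr_matrix = cm)
  out <- reject_short_segments(ls, 30)       # 15-sample minimum
  r <- rle(out$labels)
  expect_identical(r$values, c(0L, 2L))
  expect_length(out$labels, 205)
  # a sequence with no short segments is a fixed point
  ls2 <- new_label_sequence(rep(c(0L, 1L), c(60, 60)), 500, 2,
                            corr_matrix = matrix(0.5, 2, 120))
  expect_identical(reject_short_segments(ls2, 30)$labels, ls2$labels)
  # property: noisy labels end with all segments >= 30 ms
  fx <- recovery_fixture()
  noisy <- fx$labels
  set.seed(5)
  flip <- sample(length(noisy$labels), 300)
  noisy$labels[flip] <- sample(0:3, 300, TRUE)
  sm <- reject_short_segments(noisy, 30)
  expect_gte(min(rle(sm$labels)$lengths), 15)
  expect_length(sm$labels, length(noisy$labels))
})

test_that("GEV is 1 for exact template sequences and 0 for orthogonal labels", {
  fx <- recovery_fixture()
  model <- fx$model
  lab_idx <- rep(0:3, each = 25)
  set.seed(6)
  amp <- runif(100, 0.5, 2)
  rec <- eeg_recording(t(model$templates[lab_idx + 1, ] * amp),
                       sampling_rate = 500)
  ls <- new_label_sequence(lab_idx, 500, 4)
  expect_equal(compute_gev(model, rec, ls), 1, tolerance = 1e-9)
  # labels pointing at near-orthogonal wrong templates give ~no explanation
  base <- matrix(rnorm(2 * 64), 2)
  base <- base - rowMeans(base)
  base[2, ] <- base[2, ] - sum(base[1, ] * base[2, ]) /
    sum(base[1, ]^2) * base[1, ]
  base <- base / sqrt(rowSums(base^2))
  model2 <- structure(list(templates = base, gev = NA, n_states = 2,
                           polarity_invariant = TRUE, fit_meta = list()),
                      class = "microstate_model")
  rec2 <- eeg_recording(t(base[rep(1, 20), ]), sampling_rate = 500)
  ls2 <- new_label_sequence(rep(1L, 20), 500, 2)  # wrong, orthogonal class
  expect_equal(compute_gev(model2, rec2, ls2), 0, tolerance = 1e-9)
})

test_that("negating the recording changes nothing downstream", {
  cfg <- synthetic_config(duration = 20, snr = 5, seed = 11)
  sim <- synthesize_eeg(cfg)
  rec <- common_average_reference(sim$recording)
  neg <- eeg_recording(-rec$data, rec$channel_names, rec$sampling_rate)
  expect_equal(global_field_power(rec), global_field_power(neg))
  run <- function(r) {
    g <- global_field_power(r)
    pk <- find_gfp_peaks(g)
    model <- modified_kmeans(t(r$data[, pk]), 4, n_restarts = 5, seed = 1,
                             gfp = g[pk])
    lab <- reject_short_segments(backfit(model, r), 30)
    list(model = model, lab = lab, gev = compute_gev(model, r, lab),
         met = compute_metrics(lab), tm = transition_matrix(lab, FALSE),
         lzc = lz76_complexity(lab)$lzc)
  }
  a <- run(rec); b <- run(neg)
  expect_gt(min(abs(diag(cor(t(a$model$templates), t(b$model$templates))))),
            1 - 1e-9)                        # identical up to sign
  expect_identical(a$lab$labels, b$lab$labels)
  expect_equal(a$gev, b$gev, tolerance = 1e-12)
  expect_equal(a$met, b$met)
  expect_equal(a$tm$probs, b$tm$probs)
  expect_identical(a$lzc, b$lzc)
})

test_that("GEV grows with the number of classes on the same data", {
  fx <- recovery_fixture()
  g <- global_field_power(fx$rec)
  pk <- find_gfp_peaks(g)
  maps <- t(fx$rec$data[, pk[seq(1, length(pk), by = 3)]])
  gevs <- vapply(1:5, function(K) {
    modified_kmeans(maps, K, n_restarts = 5, seed = 2)$gev
  }, 1)
  expect_true(all(diff(gevs) > -1e-6))
})

test_that("fitted classes can be relabeled against reference maps", {
  fx <- recovery_fixture()
  ref <- canonical_templates(64)
  rl <- relabel_states(fx$model, ref)
  expect_identical(rownames(rl$templates), c("A", "B", "C", "D"))
  expect_setequal(rl$fit_meta$relabeling, 1:4)
  # model JSON round trip
  p <- file.path(tempdir(), "model.json")
  write_microstate_model(rl, p)
  rt <- read_microstate_model(p)
  expect_equal(rt$templates, rl$templates, tolerance = 1e-12)
  expect_equal(rt$gev, rl$gev, tolerance = 1e-12)
})
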