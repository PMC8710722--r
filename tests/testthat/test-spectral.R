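test_that("multitaper PSD satisfies Parseval and localizes tones", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(2 * 8192), 2), sampling_rate = 500)
  spec <- compute_psd(rec)
  integral <- sum(diff(spec$frequencies) *
                    (spec$psd[1, -1] + spec$psd[1, -ncol(spec$psd)]) / 2)
  expect_lt(abs(integral - var(rec$data[1, ])) / var(rec$data[1, ]), 0.1)

  tone <- tone_recording(40, dur = 10)
  st <- compute_psd(tone)
  expect_lt(abs(st$frequencies[which.max(st$psd[1, ])] - 40),
            500 / 5000 + 1e-9)

  z <- eeg_recording(matrix(0, 2, 1000), sampling_rate = 500)
  expect_true(all(compute_psd(z)$psd == 0))
  expect_error(compute_psd(rec, 10, 400), "invalid-parameter")
})

test_that("band power integrates the grid and is additive over a partition", {
  freqs <- seq(0, 100, by = 0.5)
  flat <- structure(list(frequencies = freqs,
                         psd = matrix(1, 1, length(freqs)),
                         method = "test"), class = "spectral_result")
  expect_equal(unname(band_power(flat, c(39, 41))), 2)
  parts <- rbind(c(0, 30), c(30, 70), c(70, 100))
  s <- sum(apply(parts, 1, function(b) band_power(flat, b)))
  expect_equal(s, unname(band_power(flat, c(0, 100))), tolerance = 1e-9)
  expect_error(band_power(flat, c(150, 160)), "invalid-parameter")

  # a pure tone is captured almost entirely by its 2 Hz band
  st <- compute_psd(tone_recording(40, dur = 10))
  expect_gt(band_power(st, c(39, 41))[1] / band_power(st, c(0, 250))[1], 0.95)

  # enlarging a band never decreases power
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(2 * 5000), 2), sampling_rate = 500)
  sp <- compute_psd(rec)
  expect_gte(band_power(sp, c(5, 50))[1], band_power(sp, c(10, 40))[1])
})

test_that("relative power and decibel conversion obey their identities", {
  expect_equal(relative_power(3, 3), 1)
  expect_equal(relative_power(0, 3), 0)
  expect_error(relative_power(1, 0), "undefined-ratio")
  expect_error(relative_power(2, 1), "invalid-input")
  # flat-spectrum expectation for a 2 Hz band of a 0.1-100 Hz total
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(60000), 2), sampling_rate = 500)
  sp <- compute_psd(rec)
  r <- relative_power(band_power(sp, c(39, 41)), band_power(sp, c(0.1, 100)))
  expect_lt(abs(r[1] - 2 / 99.9) / (2 / 99.9), 0.2)

  expect_identical(to_decibel(1), 0)
  expect_identical(to_decibel(10), 10)
  expect_identical(to_decibel(100), 20)
  x <- c(-3.2, 0, 7.5)
  expect_equal(to_decibel(10^(x / 10)), x, tolerance = 1e-12)
  expect_error(to_decibel(0), "domain")
})

test_that("band power scales quadratically while relative power is scale-free", {
  set.seed(6)
  rec <- eeg_recording(matrix(rnorm(2 * 5000), 2), sampling_rate = 500)
  rec3 <- eeg_recording(3 * rec$data, sampling_rate = 500)
  a1 <- band_power(compute_psd(rec), c(8, 13))
  a3 <- band_power(compute_psd(rec3), c(8, 13))
  expect_equal(unname(a3 / a1), rep(9, 2), tolerance = 1e-9)
  t1 <- band_power(compute_psd(rec), c(0.1, 100))
  t3 <- band_power(compute_psd(rec3), c(0.1, 100))
  expect_equal(relative_power(a1, t1), relative_power(a3, t3),
               tolerance = 1e-9)
})

test_that("region aggregation follows the montage", {
  m <- load_montage()
  set.seed(7)
  dat <- matrix(rnorm(64 * 3000), 64)
  rec <- eeg_recording(dat, m$name, 500)
  sp <- compute_psd(rec)
  tab <- region_percent_power(sp, m, c(39, 41))
  expect_setequal(tab$region, c("F", "FC", "C", "CP", "P", "PO", "O", "M"))
  # region with one channel equals that channel's value: restrict to POZ
  sp1 <- sp
  sp1$psd <- sp1$psd[c("POZ", "FPZ"), , drop = FALSE]
  t1 <- region_percent_power(sp1, m, c(39, 41))
  a <- band_power(sp, c(39, 41))
  expect_equal(t1$abs_power[t1$region == "PO"], unname(a["POZ"]),
               tolerance = 1e-12)
  # identical channels give identical regions
  rec_same <- eeg_recording(matrix(rep(dat[1, ], 64), 64, byrow = TRUE),
                            m$name, 500)
  t2 <- region_percent_power(compute_psd(rec_same), m, c(39, 41))
  expect_lt(diff(range(t2$rel_power)), 1e-12)
  # occipital SSVEP produces the posterior gradient
  gains <- rep(0, 64); gains[m$region == "O"] <- 1
  cfg <- synthetic_config(duration = 10, snr = 5, seed = 8,
                          ssvep_frequency = 40, ssvep_channel_gains = gains)
  r40 <- synthesize_eeg(cfg)$recording
  t3 <- region_percent_power(compute_psd(r40), m, c(39, 41))
  expect_gt(t3$rel_power[t3$region == "O"], t3$rel_power[t3$region == "F"])
})
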