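test_that("coverage, duration and occurrence follow their definitions", {
  # single-class sequence
  ls <- new_label_sequence(rep(1L, 500), 500, 2)
  m <- compute_metrics(ls)
  expect_equal(m$coverage, c(0, 1))
  expect_equal(m$occurrence[2], 1)           # one run in one second
  expect_equal(m$mean_duration[2], 1000)
  # alternating 50-sample runs at 500 Hz
  ls2 <- new_label_sequence(rep(rep(c(0L, 1L), 10), each = 50), 500, 2)
  m2 <- compute_metrics(ls2)
  expect_equal(m2$mean_duration, c(100, 100))
  expect_equal(m2$coverage, c(0.5, 0.5))
  # conservation: sum_k occurrence * duration = 1000 * sum coverage
  fx <- recovery_fixture()
  m3 <- compute_metrics(fx$labels)
  lhs <- sum(m3$occurrence * m3$mean_duration)
  expect_lt(abs(lhs - 1000 * sum(m3$coverage)) / 1000, 0.05)
})

test_that("recovered metrics track the generator ground truth", {
  fx <- recovery_fixture()
  met <- compute_metrics(fx$labels)
  pmet <- compute_metrics(fx$planted)
  expect_lt(max(abs(met$coverage[fx$perm] - pmet$coverage)), 0.05)
  expect_lt(max(abs(met$mean_duration[fx$perm] - pmet$mean_duration) /
                  pmet$mean_duration), 0.2)
})

test_that("transition matrices are row-stochastic with the declared diagonal", {
  # constant sequence, self allowed: identity row
  ls <- new_label_sequence(rep(2L, 100), 500, 3)
  tm <- transition_matrix(ls, self_allowed = TRUE)
  expect_equal(tm$probs[3, 3], 1)
  expect_identical(tm$defined, c(FALSE, FALSE, TRUE))
  expect_equal(tm$step_duration, 2)          # 1/fs at 500 Hz
  # forced cycle gives a permutation matrix
  ls2 <- new_label_sequence(rep(rep(0:2, 20), each = 5), 500, 3)
  tm2 <- transition_matrix(ls2, self_allowed = FALSE)
  expect_equal(tm2$probs, rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  expect_true(all(diag(tm2$probs) == 0))
  # hand-counted oracle on a seeded 30-segment sequence
  set.seed(9)
  segs <- integer(30); segs[1] <- sample(0:2, 1)
  for (i in 2:30) segs[i] <- sample(setdiff(0:2, segs[i - 1]), 1)
  ls3 <- new_label_sequence(rep(segs, each = 10), 500, 3)
  tm3 <- transition_matrix(ls3, self_allowed = FALSE)
  hand <- matrix(0, 3, 3)
  for (i in 2:30) hand[segs[i - 1] + 1, segs[i] + 1] <-
      hand[segs[i - 1] + 1, segs[i] + 1] + 1
  expect_equal(tm3$counts, hand)
  expect_equal(tm3$probs, hand / rowSums(hand))
  expect_error(transition_matrix(new_label_sequence(rep(0L, 10), 500, 2),
                                 self_allowed = FALSE), "invalid-input")
})

test_that("length equalization truncates to the shortest epoch", {
  mk <- function(n) new_label_sequence(rep(0L, n), 500, 2)
  out <- equalize_lengths(list(mk(100), mk(80), mk(90)))
  expect_equal(vapply(out, length, 1L), rep(80L, 3))
  same <- equalize_lengths(list(mk(50), mk(50)))
  expect_equal(vapply(same, length, 1L), rep(50L, 2))
  # outputs are prefixes of inputs
  a <- new_label_sequence(c(0L, 1L, 0L, 1L, 1L), 500, 2)
  tr <- equalize_lengths(list(a, mk(3)))[[1]]
  expect_identical(tr$labels, a$labels[1:3])
})

test_that("LZ76 matches its oracles and satisfies complexity properties", {
  classic <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_identical(lz76_complexity(classic)$lzc, 6L)
  expect_identical(lz76_reference(classic), 6L)
  expect_identical(lz76_r_oracle(classic), 6L)
  expect_identical(lz76_complexity(rep(0L, 4))$lzc, 2L)
  # three-way agreement on random short sequences (pure-R third route)
  set.seed(10)
  for (i in 1:50) {
    s <- sample(0:3, sample(1:20, 1), replace = TRUE)
    expect_identical(lz76_complexity(s)$lzc, lz76_r_oracle(s))
    expect_identical(lz76_reference(s), lz76_r_oracle(s))
  }
  # relabeling invariance
  set.seed(11)
  s <- sample(0:3, 500, TRUE)
  perm <- sample(0:3)
  expect_identical(lz76_complexity(s)$lzc, lz76_complexity(perm[s + 1])$lzc)
  # monotone under concatenation
  x <- sample(0:3, 200, TRUE); y <- sample(0:3, 200, TRUE)
  expect_gte(lz76_complexity(c(x, y))$lzc, lz76_complexity(x)$lzc)
  # random beats constant at fixed length
  rnd <- mean(replicate(20, lz76_complexity(sample(0:3, 300, TRUE))$lzc))
  expect_gt(rnd, lz76_complexity(rep(2L, 300))$lzc)
  expect_error(lz76_complexity(integer(0)), "invalid-input")
  # bounds
  r <- lz76_complexity(s)
  expect_gte(r$lzc, 1L)
  expect_lte(r$lzc, r$sequence_length)
})

test_that("both LZ76 parsers agree exhaustively on short alphabets", {
  sw <- lz76_sweep_check(8, 4)
  expect_equal(sw$mismatches, 0)
  expect_equal(sw$total, sum(4^(1:8)))
  sw2 <- lz76_sweep_check(10, 2)
  expect_equal(sw2$mismatches, 0)
})
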