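# Synthetic activity families with known cue structure.
make_activity <- function(n_trials, n_neurons, cue, signal_idx, gap = 1,
                          noise = 0.1) {
  A <- matrix(rnorm(n_trials * n_neurons, 0.3, noise), n_trials, n_neurons)
  A[, signal_idx] <- A[, signal_idx] + gap * (cue == "up")
  A
}

test_that("cue responsiveness: perfect separation, flat neurons, permutation null", {
  set.seed(1)
  cue <- rep(c("up", "down"), 50)
  A <- make_activity(100, 5, cue, signal_idx = 1, gap = 2, noise = 0.05)
  A[, 2] <- 0.3                      # constant: uninformative
  r2 <- cue_responsiveness(A, cue)
  expect_equal(r2[1], 1)             # separable
  expect_lt(r2[2], 0.05)
  expect_true(all(r2 >= 0 & r2 <= 1))
  # shuffled labels concentrate near zero
  null_r2 <- replicate(30, max(cue_responsiveness(A[, 3:5], sample(cue))))
  expect_lt(stats::quantile(null_r2, 0.9), 0.1)
  # monotone in separation
  gaps <- c(0, 0.1, 0.3, 0.6)
  cue2 <- rep(c("up", "down"), 100)
  r2g <- vapply(gaps, function(g) {
    set.seed(7)
    cue_responsiveness(make_activity(200, 1, cue2, 1, gap = g, noise = 0.2),
                       cue2)
  }, numeric(1))
  expect_true(all(diff(r2g) > 0))
  expect_error(cue_responsiveness(A, rep("up", 100)))
})

test_that("selectivity classification covers the four corners and counts sum", {
  expect_equal(classify_selectivity(0.9, 0.9, 0.5), "both")
  expect_equal(classify_selectivity(0.9, 0.1, 0.5), "match-only")
  expect_equal(classify_selectivity(0.1, 0.9, 0.5), "nonmatch-only")
  expect_equal(classify_selectivity(0.1, 0.1, 0.5), "non-responsive")
  expect_error(classify_selectivity(0.5, 0.5, 0))
  set.seed(2)
  r2m <- runif(100); r2n <- runif(100)
  cats <- classify_selectivity(r2m, r2n)
  expect_equal(length(cats), 100)
  counts <- table(factor(cats, levels = c("non-responsive", "match-only",
                                          "nonmatch-only", "both")))
  expect_equal(sum(counts), 100)
})

test_that("linear decoder recovers separable labels and stays at chance on noise", {
  set.seed(3)
  labels <- rep(c(1, 0), 100)
  A <- make_activity(200, 10, ifelse(labels == 1, "up", "down"),
                     signal_idx = 1:3, gap = 1.5, noise = 0.1)
  expect_equal(decode_variable(A, labels), 1)
  # labels independent of activity: accuracy within the permutation band
  null_acc <- replicate(20, decode_variable(A, sample(labels)))
  expect_lt(mean(null_acc), 0.58)
  expect_gt(mean(null_acc), 0.42)
  expect_error(decode_variable(A, rep(1, 200)))
})

test_that("condition correlation summarizes unit-label agreement", {
  set.seed(4)
  labels <- rep(c(1, -1), 50)
  A <- cbind(labels, rnorm(100))
  expect_equal(condition_correlation(A, labels), 1)
  expect_lt(condition_correlation(A[, 2, drop = FALSE], labels), 0.3)
  per_unit <- condition_correlation(A, labels, summarize = "none")
  expect_equal(per_unit[[1]], 1)
})

test_that("pattern correlation compares condition means", {
  set.seed(5)
  A <- matrix(rnorm(200 * 20, 1), 200, 20)
  half <- rep(c(TRUE, FALSE), 100)
  # same generating pattern: correlation of condition means near the
  # noise-limited value; identical split means correlate exactly at 1
  expect_equal(pattern_correlation(rbind(A, A), c(half, half), c(half, half)), 1)
  # disjoint structured conditions: strong anticorrelation
  B <- A; B[half, 1:10] <- B[half, 1:10] + 3; B[!half, 11:20] <- B[!half, 11:20] + 3
  expect_lt(pattern_correlation(B, half, !half), 0)
})
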