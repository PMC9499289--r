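# Closed-loop driver tests on deliberately small problems.
small_config <- function(...) {
  tc_config(task = list(n_blocks = 2L, trials_per_block = 30L),
            network = reservoir_params(n_neurons = 40L, n_sub = 16L),
            ...)
}

test_that("an experiment produces a coherent trial table", {
  res <- simulate_experiment(small_config(), seed = 1)
  expect_s3_class(res, "tc_experiment")
  tr <- res$trials
  expect_equal(nrow(tr), 60)
  expect_true(all(tr$reward %in% 0:1))
  expect_equal(tr$reward, as.integer(tr$response == tr$target))
  expect_equal(tr$chosen_rule == "match", tr$response == tr$cue)
  # rule consistency references the block's dominant rule
  dom <- ifelse(tr$association_level > 0.5, "match", "non-match")
  expect_equal(tr$rule_consistent, as.integer(tr$chosen_rule == dom))
  # value inputs are probabilities and MD activations a proper mixture
  expect_true(all(tr$q_hat >= 0 & tr$q_hat <= 1))
  expect_true(all(abs(rowSums(tr$md_avg) - 1) < 1e-9))
  expect_equal(dim(res$rates), c(60L, 40L))
  expect_true(all(res$block_summary$accuracy >= 0 &
                  res$block_summary$accuracy <= 1))
})

test_that("identical config and seed reproduce the experiment bit-exactly", {
  a <- simulate_experiment(small_config(), seed = 7)
  b <- simulate_experiment(small_config(), seed = 7)
  expect_identical(a$trials, b$trials)
  expect_identical(a$W_out, b$W_out)
  expect_identical(a$W_ct, b$W_ct)
  c_ <- simulate_experiment(small_config(), seed = 8)
  expect_false(identical(a$trials$response, c_$trials$response))
})

test_that("lesioned and intact runs share the same task realization", {
  a <- simulate_experiment(small_config(), seed = 3)
  b <- simulate_experiment(small_config(md = list(lesion = TRUE)), seed = 3)
  expect_identical(a$trials[, c("cue", "rewarded_rule", "target")],
                   b$trials[, c("cue", "rewarded_rule", "target")])
})

test_that("corticothalamic norm is conserved across every trial", {
  res <- simulate_experiment(small_config(), seed = 2)
  set.seed(3 + 1000003L)
  net0 <- build_network(reservoir_params(n_neurons = 40L, n_sub = 16L))
  expect_equal(sqrt(sum(res$W_ct^2)),
               sqrt(sum(simulate_experiment(small_config(), 2)$W_ct^2)),
               tolerance = 1e-12)
  # the recorded norm equals the initialization target to 1e-9
  set.seed(2 + 1000003L)
  net <- build_network(reservoir_params(n_neurons = 40L, n_sub = 16L))
  expect_equal(sqrt(sum(res$W_ct^2)), net$ct_target_norm, tolerance = 1e-9)
})

test_that("clipping bounds corticothalamic weights throughout", {
  res <- simulate_experiment(small_config(), seed = 5)
  expect_true(all(abs(res$W_ct) <= 0.1 / (1 - 1e-9)))
})

test_that("lesion compensation keeps population activity near intact levels", {
  p <- reservoir_params(n_neurons = 100L, n_sub = 40L)
  a <- simulate_experiment(tc_config(
    task = list(n_blocks = 2L, trials_per_block = 100L), network = p), 5)
  b <- simulate_experiment(tc_config(
    task = list(n_blocks = 2L, trials_per_block = 100L), network = p,
    md = list(lesion = TRUE)), 5)
  expect_lt(abs(mean(b$rates) - mean(a$rates)) / mean(a$rates), 0.2)
})

test_that("the forced-MD minimal model pins MD to the block context", {
  cfg <- small_config(md = list(forced = TRUE, g_add = 0, g_mult = 1),
                      vmpfc = list(enabled = FALSE))
  res <- simulate_experiment(cfg, seed = 4)
  tr <- res$trials
  expect_true(all(tr$md_avg[tr$association_level > 0.5, 1] == 1))
  expect_true(all(tr$md_avg[tr$association_level < 0.5, 2] == 1))
  expect_true(all(is.na(tr$q_hat)))
})

test_that("OFC routing records switch posteriors and context beliefs", {
  cfg <- small_config(ofc = list(route_target = "md"))
  res <- simulate_experiment(cfg, seed = 6)
  tr <- res$trials
  expect_true(all(tr$p_switch >= 0 & tr$p_switch <= 1))
  expect_true(all(tr$ofc_context %in% 1:2))
  # routing weight norms restored after every trial
  expect_equal(sqrt(sum(res$W_route_md^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(res$W_route_pfc^2)), 2, tolerance = 1e-9)
})

test_that("summary and accuracy helpers slice the trial table consistently", {
  res <- simulate_experiment(small_config(), seed = 9)
  s <- summary(res)
  expect_s3_class(s, "summary.tc_experiment")
  acc_all <- experiment_accuracy(res, "accuracy")
  expect_equal(acc_all, mean(res$trials$correct))
  acc_09 <- experiment_accuracy(res, "accuracy", levels = 0.9)
  tr <- res$trials
  expect_equal(acc_09, mean(tr$correct[tr$association_level == 0.9]))
  ps <- experiment_accuracy(res, "accuracy", post_switch_trials = 10)
  expect_equal(ps, mean(tr$correct[tr$block_index == 1][1:10]))
})

test_that("sweeps tabulate one row per cell and seed", {
  cfg <- small_config(md = list(forced = TRUE, g_add = 0, g_mult = 1),
                      vmpfc = list(enabled = FALSE), record_rates = FALSE)
  sw <- run_sweep(cfg, grid = list(g_mult = c(1, 5)), seeds = 1:2)
  expect_s3_class(sw, "tc_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(c("g_mult", "seed", "accuracy", "steady_ratio_correct",
                    "cue_correlation", "rule_correlation") %in% names(sw)))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  expect_error(run_sweep(cfg, grid = list(nonsense = 1:2), seeds = 1))
})
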