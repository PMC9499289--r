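test_that("switch posterior matches brute-force enumeration on all short histories", {
  p <- ofc_params(prior_switch = 1 / 350)
  for (L in 1:6) {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), L))
    for (i in seq_len(nrow(grid))) {
      h <- as.logical(grid[i, ])
      expect_equal(switch_probability(h, p),
                   brute_switch_probability(h, 1 / 350, 0.9),
                   tolerance = 1e-9)
    }
  }
})

test_that("switch posterior behaves sensibly at the extremes", {
  p <- ofc_params(prior_switch = 1 / 350)
  expect_lt(switch_probability(rep(TRUE, 10), p), 0.01)
  # clean mid-horizon switch: high posterior
  expect_gt(switch_probability(c(rep(TRUE, 5), rep(FALSE, 5)), p), 0.9)
  # the likelihood over split points peaks at the true split
  h <- c(rep(TRUE, 5), rep(FALSE, 5))
  cl <- 0.9
  p_c <- ifelse(h, cl, 1 - cl)
  lik <- vapply(1:10, function(i)
    prod(p_c[seq_len(i - 1)]) * prod(1 - p_c[i:10]), numeric(1))
  expect_equal(which.max(lik), 6)  # post-switch trials start right after trial 5
  # degenerate one-trial history is still a probability
  p1 <- switch_probability(FALSE, p)
  expect_gte(p1, 0)
  expect_lte(p1, 1)
})

test_that("context belief flips only strictly above threshold and is an involution", {
  b <- c(TRUE, FALSE)
  expect_false(update_context_belief(c(1, 0), 0.5, 0.5, b)$flipped)
  up <- update_context_belief(c(1, 0), 0.51, 0.5, b)
  expect_true(up$flipped)
  expect_equal(up$c_nodes, c(0, 1))
  expect_length(up$buffer, 0)     # buffer cleared on flip
  up2 <- update_context_belief(up$c_nodes, 0.9, 0.5, up$buffer)
  expect_equal(up2$c_nodes, c(1, 0))
})

test_that("detection latency after a 0.9 -> 0.1 switch stays within the horizon", {
  set.seed(99)
  p <- ofc_params(prior_switch = 1 / 2000)
  lat <- replicate(100, {
    buf <- runif(10) < 0.9          # pre-switch consistent outcomes
    c_nodes <- c(1, 0)
    k <- 0
    repeat {
      k <- k + 1
      o <- runif(1) < 0.9           # post-switch: consistent w.p. 0.1
      buf <- utils::tail(c(buf, !o), p$horizon)
      ps <- switch_probability(buf, p)
      if (ps > p$theta_s || k > 50) break
    }
    k
  })
  expect_lte(median(lat), 10)
})

test_that("routing Hebbian updates keep target norms and build associations", {
  set.seed(8)
  W <- matrix(runif(4, 0, 0.01), 2, 2)
  W <- W / sqrt(sum(W^2))
  # norms restored to 1e-9
  W1 <- routing_hebbian_update(W, c(1, 0), c(0.8, 0.1), 0.001, 1)
  expect_equal(sqrt(sum(W1^2)), 1, tolerance = 1e-9)
  # uniform rates: centered rates vanish, update is pure rescale
  W2 <- routing_hebbian_update(W, c(1, 0), c(0.5, 0.5), 0.001, 1)
  expect_equal(W2, W, tolerance = 1e-12)
  # repeated pairing of context A with MD neuron 1: row A peaks at neuron 1
  # and row B at neuron 2 (the anti-symmetric structure of centered Hebb)
  for (i in 1:500) W <- routing_hebbian_update(W, c(1, 0), c(0.9, 0.05), 0.01, 1)
  expect_equal(which.max(W[1, ]), 1L)
  expect_equal(which.max(W[2, ]), 2L)
})

test_that("routing signal obeys gating, duration, and truncation", {
  W <- rbind(c(0.6, 0.1, -0.3), c(0.2, 0.5, 0.1))
  expect_equal(routing_signal(c(1, 0), W, 0, 10), c(0.6, 0.1, -0.3))
  expect_equal(routing_signal(c(0, 1), W, 0, 10), c(0.2, 0.5, 0.1))
  expect_equal(routing_signal(c(1, 0), W, 10, 10), numeric(3))  # past window
  expect_equal(routing_signal(c(1, 0), W, 0, 10, enabled = FALSE), numeric(3))
  # truncation keeps the largest-magnitude entries
  expect_equal(routing_signal(c(1, 0), W, 0, 10, n_targets = 1),
               c(0.6, 0, 0))
})

test_that("pathway parameter counts match the architectures", {
  expect_identical(count_pathway_parameters(2, 2, 500, "pfc"), 1000L)
  expect_identical(count_pathway_parameters(2, 2, 500, "md"), 4L)
  expect_identical(count_pathway_parameters(1, 1, 1, "md"), 1L)
  expect_error(count_pathway_parameters(2, 2, 500, "cerebellum"))
})
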