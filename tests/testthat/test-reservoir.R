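test_that("network construction follows the wiring plan", {
  set.seed(1)
  p <- reservoir_params()
  net <- build_network(p)
  # zero-centered recurrent rows
  expect_lt(max(abs(rowMeans(net$W_rec))), 1e-12)
  # 200 neurons per cue population, 100 neurons with no feedforward input
  cue_in <- rowSums(net$W_inp[, 1:2] != 0)
  expect_equal(sum(cue_in > 0), 400)
  expect_equal(sum(cue_in == 0), 100)
  # every cued neuron receives exactly one cue and one value input
  expect_true(all(cue_in %in% c(0, 1)))
  val_in <- rowSums(net$W_inp[, 3:4] != 0)
  expect_equal(sum(val_in > 0), 400)
  # each cue-value combination projects to 100 neurons
  for (cue_col in 1:2) for (val_col in 3:4)
    expect_equal(sum(net$W_inp[, cue_col] != 0 & net$W_inp[, val_col] != 0), 100)
  # nonzero input weights lie in [0.2, 0.4]
  nz <- net$W_inp[net$W_inp != 0]
  expect_true(all(nz >= 0.2 & nz <= 0.4))
  # recurrent variance as specified (loose sampling check)
  expect_lt(abs(stats::var(as.vector(net$W_rec)) - 0.75 / sqrt(400)), 0.002)
  # corticothalamic norm recorded
  expect_equal(sqrt(sum(net$W_ct^2)), net$ct_target_norm)
  expect_true(all(net$W_out == 0))
  expect_error(build_network(reservoir_params(n_neurons = 300)))
})

test_that("identical seeds give identical networks", {
  p <- small_params()
  set.seed(5); a <- build_network(p)
  set.seed(5); b <- build_network(p)
  expect_identical(a, b)
})

test_that("zero input with no noise is a fixed point and rates stay in [0, 1)", {
  n <- 10
  I <- numeric(n); r <- numeric(n)
  W <- matrix(0.1, n, n)
  st <- step_dynamics(I, r, numeric(n), numeric(n), numeric(n), W,
                      0.001, 0.02, noise = 0)
  expect_equal(st$I, numeric(n))
  expect_equal(st$r, numeric(n))
  # random excursions stay bounded
  set.seed(2)
  I <- rnorm(n, 0, 3); r <- pmax(tanh(I), 0)
  for (i in 1:50) {
    st <- step_dynamics(I, r, rnorm(n), rnorm(n), rnorm(n, 0, 0.2), W,
                        0.001, 0.02, noise = rnorm(n, 0, 0.03))
    I <- st$I; r <- st$r
    expect_true(all(r >= 0 & r < 1))
  }
})

test_that("constant drive converges geometrically at rate dt/tau", {
  # leaky integrator closed form: I_t = d (1 - (1 - dt/tau)^t)
  d <- 0.7; n_steps <- 120; k <- 0.001 / 0.02
  I <- 0; r <- 0
  W0 <- matrix(0, 1, 1)
  for (t in seq_len(n_steps)) {
    st <- step_dynamics(I, r, d, 0, 0, W0, 0.001, 0.02, noise = 0,
                        activation = "identity")
    I <- st$I; r <- 0  # keep recurrence silent
    expect_equal(I, d * (1 - (1 - k)^t), tolerance = 1e-12)
  }
})

test_that("linear-regime trajectory matches the closed-form solution", {
  # with identity activation and no noise the system is linear:
  # I_{t+1} = A I_t + k b,  A = (1-k) Id + k W,  solved in closed form
  set.seed(9)
  n <- 10; k <- 0.05
  W <- matrix(rnorm(n * n, 0, 0.2), n, n)
  b <- rnorm(n)
  I0 <- rnorm(n)
  A <- (1 - k) * diag(n) + k * W
  # closed form via eigendecomposition: I_t = A^t I0 + (I-A)^{-1}(I - A^t) k b
  eg <- eigen(A)
  Apow <- function(t) Re(eg$vectors %*% diag(eg$values^t) %*% solve(eg$vectors))
  I <- I0; r <- I0
  for (t in 1:40) {
    st <- step_dynamics(I, r, b, numeric(n), numeric(n), W, 0.001, 0.02,
                        noise = 0, activation = "identity")
    I <- st$I; r <- st$r
    At <- Apow(t)
    closed <- as.vector(At %*% I0 +
                          solve(diag(n) - A, (diag(n) - At) %*% (k * b)))
    expect_lt(max(abs(I - closed)) / max(abs(closed)), 1e-6)
  }
})

test_that("non-finite states abort with a diagnostic", {
  expect_error(step_dynamics(Inf, 0, 0, 0, 0, matrix(0, 1, 1), 0.001, 0.02),
               "non-finite")
})
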