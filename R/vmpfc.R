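# vmPFC: maximum-likelihood estimator of the match-strategy expected reward q
# over a sliding horizon of recent trials, with divergence detection and a
# bank of previously encountered values. Emits (q, 1 - q) as the value inputs
# to the reservoir.

#' Likelihood of the match-strategy reward probability
#'
#' Given the outcomes of recent trials, each resolved to "the match strategy
#' would have been rewarded on this trial" (TRUE/FALSE), the likelihood of a
#' candidate value q is the product of Bernoulli terms: q for every
#' match-rewarded trial and (1 - q) otherwise, i.e. `q^k (1-q)^(n-k)`.
#' Returned unnormalized over the grid (the evidence term is constant in q).
#'
#' @param match_rewarded logical vector over the horizon; TRUE where the match
#'   strategy was (or would have been) rewarded.
#' @param grid grid of candidate q values on [0, 1].
#' @export
strategy_likelihood <- function(match_rewarded,
                                grid = seq(0, 1, length.out = 101)) {
  if (length(match_rewarded) == 0) stop("empty history")
  k <- sum(match_rewarded)
  n <- length(match_rewarded)
  grid^k * (1 - grid)^(n - k)
}

#' Maximum-likelihood q over a grid, ties broken toward 0.5
#' @inheritParams strategy_likelihood
#' @export
ml_value_estimate <- function(match_rewarded,
                              grid = seq(0, 1, length.out = 101)) {
  lik <- strategy_likelihood(match_rewarded, grid)
  best <- which(lik >= max(lik) - 1e-15)
  grid[best[which.min(abs(grid[best] - 0.5))]]
}

#' Value-estimator parameters
#'
#' @param horizon number of recent trials kept in the history buffer.
#' @param divergence_threshold divergence between the current estimate and the
#'   recent match-reward average that triggers a possible block change; also
#'   reused as the bank-matching tolerance.
#' @param grid_resolution number of q grid points on [0, 1].
#' @param adapt_rate exponential tracking rate (per trial) by which the held
#'   estimate follows the windowed ML estimate, and by which a freshly created
#'   estimate adapts toward the recent average.
#' @export
value_estimator_params <- function(horizon = 10L, divergence_threshold = 0.15,
                                   grid_resolution = 101L, adapt_rate = 0.2) {
  list(horizon = as.integer(horizon),
       divergence_threshold = divergence_threshold,
       grid = seq(0, 1, length.out = grid_resolution),
       adapt_rate = adapt_rate)
}

#' Create a fresh value-estimator state
#' @param params output of [value_estimator_params()].
#' @export
value_estimator_state <- function(params = value_estimator_params()) {
  list(q_hat = 0.5, history = logical(0), bank = numeric(0),
       adapting = FALSE, n_diverged = 0L, params = params)
}

#' Update the strategy-value estimate with one trial outcome
#'
#' Pushes the trial's match-rewarded indicator into the horizon buffer and
#' moves the held estimate `q_hat` toward the windowed maximum-likelihood
#' value (exponential tracking, so the estimate changes slowly relative to
#' the fast window statistics). Once the buffer is full, if `q_hat` diverges
#' from the recent match-reward average by more than the threshold the
#' estimator considers a possible block change: the current estimate is added
#' to the bank of previously encountered values, the recent average is
#' matched against the bank (within the same tolerance) and a matching stored
#' value is reused; otherwise a new estimate is created at 0.5 and adapts
#' toward the recent average until it is consistent again. A block change is
#' considered only when the estimate *starts and stays* divergent — two
#' consecutive diverged trials — so single-trial excursions of the noisy
#' window average do not reset a well-calibrated estimate.
#'
#' @param state a value-estimator state.
#' @param match_rewarded logical; TRUE if the match strategy was rewarded (or
#'   would have been) on the completed trial.
#' @return updated state; `state$q_hat` is the value input emitted for the
#'   next trial (the value pair sent to the reservoir is `c(q_hat, 1 - q_hat)`).
#' @export
update_value_estimate <- function(state, match_rewarded) {
  p <- state$params
  state$history <- utils::tail(c(state$history, match_rewarded), p$horizon)
  recent <- mean(state$history)
  diverged <- length(state$history) >= p$horizon &&
    abs(state$q_hat - recent) > p$divergence_threshold
  state$n_diverged <- if (diverged) state$n_diverged + 1L else 0L
  if (state$adapting) {
    state$q_hat <- state$q_hat + p$adapt_rate * (recent - state$q_hat)
    if (abs(state$q_hat - recent) <= p$divergence_threshold)
      state$adapting <- FALSE
  } else if (state$n_diverged >= 2L) {
    # block change: bank the outgoing estimate (unless an equivalent value
    # is already stored), then reuse a stored value or create a fresh one
    if (!length(state$bank) ||
        min(abs(state$bank - state$q_hat)) > p$divergence_threshold)
      state$bank <- c(state$bank, state$q_hat)
    hit <- which(abs(state$bank - recent) <= p$divergence_threshold)
    if (length(hit)) {
      state$q_hat <- state$bank[hit[which.min(abs(state$bank[hit] - recent))]]
    } else {
      state$q_hat <- 0.5
      state$adapting <- TRUE
    }
    state$n_diverged <- 0L
  } else {
    q_ml <- ml_value_estimate(state$history, p$grid)
    state$q_hat <- state$q_hat + p$adapt_rate * (q_ml - state$q_hat)
  }
  state
}
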