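# dlPFC reservoir construction: fixed recurrent weights, structured cue/value
# inputs, fixed MD modulation weights, plastic corticothalamic and readout
# weights.

#' Reservoir parameters
#'
#' Defaults follow the reference configuration: a 500-neuron rate reservoir
#' with membrane time constant 20 ms integrated at 1 ms steps; trials are 200
#' steps (200 ms) with cue and value inputs on for the first 100 steps; i.i.d.
#' Gaussian noise of variance 1e-3 enters each neuron's rate-of-change at
#' every step. Each of the two cue input units projects to a population of
#' `n_sub` = 200 neurons; within each cue population the first half also
#' receives the match-value input and the second half the non-match-value
#' input, so each cue-by-strategy combination targets 100 neurons and
#' neurons 401-500 receive no feedforward input at all. Trial-averaged rates
#' are taken over `analysis_window` (steps 51-150); decisions and readout
#' learning use `decision_window` (steps 101-200).
#'
#' @param n_neurons reservoir size.
#' @param tau membrane time constant, seconds.
#' @param dt integration step, seconds.
#' @param n_steps steps per trial.
#' @param input_steps steps during which cue/value inputs are on.
#' @param noise_var variance of the per-step Gaussian noise term.
#' @param n_sub neurons per cue input population.
#' @param md_weight_sd spread (SD) of the fixed MD-to-dlPFC modulation
#'   weights shared by the additive and multiplicative pathways.
#' @param analysis_window,decision_window inclusive step ranges (1-based).
#' @return list of class `tc_params`.
#' @export
reservoir_params <- function(n_neurons = 500L, tau = 0.02, dt = 0.001,
                             n_steps = 200L, input_steps = 100L,
                             noise_var = 1e-3, n_sub = 200L,
                             md_weight_sd = 0.1,
                             analysis_window = c(51L, 150L),
                             decision_window = c(101L, 200L)) {
  stopifnot(tau > dt, dt > 0, input_steps <= n_steps,
            analysis_window[1] >= 1, analysis_window[2] <= n_steps,
            decision_window[1] >= 1, decision_window[2] <= n_steps)
  structure(list(n_neurons = as.integer(n_neurons), tau = tau, dt = dt,
                 n_steps = as.integer(n_steps),
                 input_steps = as.integer(input_steps),
                 noise_var = noise_var, n_sub = as.integer(n_sub),
                 md_weight_sd = md_weight_sd,
                 analysis_window = as.integer(analysis_window),
                 decision_window = as.integer(decision_window)),
            class = "tc_params")
}

#' Build the network weights
#'
#' Draws all synaptic matrices from the current RNG state:
#' \itemize{
#'   \item `W_rec` (n x n, fixed): Gaussian with mean 0 and variance
#'     `0.75/sqrt(2*n_sub)`, each row then shifted to exactly zero mean.
#'   \item `W_inp` (n x 4, fixed): columns cue-up, cue-down, value-match,
#'     value-non-match. Cue-up projects to neurons 1..n_sub, cue-down to
#'     n_sub+1..2*n_sub; within each cue population the first half receives
#'     the match-value input and the second half the non-match-value input.
#'     Nonzero weights are uniform in [0.2, 0.4].
#'   \item `W_md` (n x n_md, fixed): Gaussian mean 0, variance 0.1; shared by
#'     the additive and multiplicative MD-to-dlPFC pathways.
#'   \item `W_ct` (n_md x n, plastic): corticothalamic weights, small
#'     zero-mean uniform values in [-0.01, 0.01] (zero-mean so that neither
#'     MD neuron starts with a systematic input advantage); the Frobenius
#'     norm at initialization is stored as `ct_target_norm` and restored at
#'     every trial end.
#'   \item `W_out` (2 x n, plastic): readout weights, initialized at zero.
#'   \item `W_route_md` (2 x n_md), `W_route_pfc` (2 x n): OFC routing
#'     weights, small random values normalized to Frobenius norms 1 and 2.
#' }
#'
#' @param params a `tc_params` list.
#' @param n_md number of MD neurons (default 2).
#' @return list of class `tc_network`.
#' @export
build_network <- function(params = reservoir_params(), n_md = 2L) {
  n <- params$n_neurons
  n_sub <- params$n_sub
  if (n < 2L * n_sub) stop("n_neurons must be >= 2 * n_sub")
  rec_sd <- sqrt(0.75 / sqrt(2 * n_sub))
  W_rec <- matrix(stats::rnorm(n * n, sd = rec_sd), n, n)
  W_rec <- W_rec - rowMeans(W_rec)

  W_inp <- matrix(0, n, 4)
  half <- n_sub %/% 2L
  up_idx <- seq_len(n_sub)
  down_idx <- n_sub + seq_len(n_sub)
  W_inp[up_idx, 1] <- stats::runif(n_sub, 0.2, 0.4)
  W_inp[down_idx, 2] <- stats::runif(n_sub, 0.2, 0.4)
  match_idx <- c(up_idx[seq_len(half)], down_idx[seq_len(half)])
  nonmatch_idx <- c(up_idx[half + seq_len(n_sub - half)],
                    down_idx[half + seq_len(n_sub - half)])
  W_inp[match_idx, 3] <- stats::runif(length(match_idx), 0.2, 0.4)
  W_inp[nonmatch_idx, 4] <- stats::runif(length(nonmatch_idx), 0.2, 0.4)

  W_md <- matrix(stats::rnorm(n * n_md, sd = params$md_weight_sd), n, n_md)

  W_ct <- matrix(stats::runif(n_md * n, -0.01, 0.01), n_md, n)
  ct_target_norm <- frobenius_norm(W_ct)

  W_out <- matrix(0, 2, n)

  W_route_md <- matrix(stats::runif(2 * n_md, 0, 0.01), 2, n_md)
  W_route_md <- W_route_md / frobenius_norm(W_route_md) * 1
  W_route_pfc <- matrix(stats::runif(2 * n, 0, 0.01), 2, n)
  W_route_pfc <- W_route_pfc / frobenius_norm(W_route_pfc) * 2

  structure(list(W_rec = W_rec, W_inp = W_inp, W_md = W_md, W_ct = W_ct,
                 W_out = W_out, W_route_md = W_route_md,
                 W_route_pfc = W_route_pfc,
                 ct_target_norm = ct_target_norm,
                 n_md = as.integer(n_md), params = params),
            class = "tc_network")
}

frobenius_norm <- function(W) sqrt(sum(W^2))
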