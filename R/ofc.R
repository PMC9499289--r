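# OFC: Bayesian observer over context switches. Two context-belief nodes
# (match-dominant vs non-match-dominant block), a posterior over "a switch
# happened somewhere in the recent horizon", Hebbian routing weights onto MD
# and dlPFC, and a brief trial-onset signal injection used to compare the
# transthalamic (OFC->MD->dlPFC) with the corticocortical (OFC->dlPFC) route.

#' OFC observer parameters
#'
#' @param horizon trials kept in the changepoint buffer.
#' @param theta_s switch threshold on the posterior switch probability; the
#'   belief nodes flip only when the posterior strictly exceeds it.
#' @param prior_switch per-trial prior probability of a switch (the reference
#'   configuration initializes it at 1/T with T the experiment's total trial
#'   count).
#' @param context_likelihood probability that a trial outcome is
#'   rule-consistent under the believed context (mirrors the strongest
#'   contingency, 0.9).
#' @param alpha_route Hebbian learning rate for the routing weights.
#' @param signal_duration_steps steps of routing-signal injection at trial
#'   onset (10 steps = 10 ms at the default dt).
#' @param route_norm_md,route_norm_pfc Frobenius norms the routing weight
#'   matrices are rescaled to after every trial (1 and 2; the dlPFC weights
#'   are shared among many more neurons).
#' @export
ofc_params <- function(horizon = 10L, theta_s = 0.5, prior_switch = 1 / 350,
                       context_likelihood = 0.9, alpha_route = 0.001,
                       signal_duration_steps = 10L,
                       route_norm_md = 1, route_norm_pfc = 2) {
  list(horizon = as.integer(horizon), theta_s = theta_s,
       prior_switch = prior_switch, context_likelihood = context_likelihood,
       alpha_route = alpha_route,
       signal_duration_steps = as.integer(signal_duration_steps),
       route_norm_md = route_norm_md, route_norm_pfc = route_norm_pfc)
}

#' Posterior probability of a context switch within the horizon
#'
#' For each candidate switch point i in the buffer the likelihood is the
#' product of the pre-switch trials' probabilities under the believed context
#' c times the post-switch trials' probabilities under the alternative
#' (per-trial probability `context_likelihood` for a rule-consistent outcome,
#' `1 - context_likelihood` otherwise; the pre-switch range excludes the
#' split point). Switch hypotheses carry prior `prior_switch` each and the
#' no-switch hypothesis the remaining mass; the result is normalized by the
#' total evidence so it is a proper probability in [0, 1].
#'
#' @param consistent logical vector over the buffer: TRUE where the outcome
#'   was rule-consistent with the believed context.
#' @param params output of [ofc_params()].
#' @export
switch_probability <- function(consistent, params = ofc_params()) {
  L <- length(consistent)
  if (L == 0) stop("empty history")
  cl <- params$context_likelihood
  p_c <- ifelse(consistent, cl, 1 - cl)      # under believed context
  p_cbar <- 1 - p_c                          # under the alternative
  lik_noswitch <- prod(p_c)
  lik_switch <- vapply(seq_len(L), function(i) {
    pre <- if (i > 1) prod(p_c[seq_len(i - 1)]) else 1
    pre * prod(p_cbar[i:L])
  }, numeric(1))
  ps <- params$prior_switch
  prior_ns <- max(1 - L * ps, 0)
  ev_switch <- ps * sum(lik_switch)
  ev_switch / (ev_switch + prior_ns * lik_noswitch)
}

#' Flip the context-belief nodes at a detected changepoint
#'
#' If the switch posterior strictly exceeds the threshold the two belief
#' nodes flip (`c' = [1,1] - c`) and the trial buffer is cleared (horizon
#' reset to the current trial); otherwise both are unchanged.
#'
#' @param c_nodes one-hot 2-vector, `c(1, 0)` for the match context.
#' @param p_switch posterior from [switch_probability()].
#' @param theta_s switch threshold.
#' @param buffer the consistency buffer.
#' @return list with `c_nodes`, `buffer`, `flipped`.
#' @export
update_context_belief <- function(c_nodes, p_switch, theta_s, buffer) {
  if (p_switch > theta_s) {
    list(c_nodes = c(1, 1) - c_nodes, buffer = logical(0), flipped = TRUE)
  } else {
    list(c_nodes = c_nodes, buffer = buffer, flipped = FALSE)
  }
}

#' Hebbian update of OFC routing weights
#'
#' `dW = alpha * (c - mean(c)) %o% (rates - mean(rates))` with the context
#' vector and the trial-averaged target rates zero-centered, followed by
#' rescaling of the matrix to its target Frobenius norm.
#'
#' @param W routing weight matrix (2 x n_targets).
#' @param c_nodes one-hot context vector.
#' @param rates trial-averaged rates of the target population.
#' @param alpha learning rate.
#' @param target_norm Frobenius norm restored after the update.
#' @export
routing_hebbian_update <- function(W, c_nodes, rates, alpha, target_norm) {
  dW <- alpha * outer(c_nodes - mean(c_nodes), rates - mean(rates))
  rescale_ct_norm(W + dW, target_norm)
}

#' Routing current injected at trial onset
#'
#' When enabled (the OFC connections are activated only after the first two
#' blocks of an experiment) and within the first `duration` steps of a trial,
#' the current is the row of `W` belonging to the active context node;
#' otherwise a zero vector. `n_targets` truncates the signal to the
#' `n_targets` largest-magnitude entries of that row (used to probe how many
#' target neurons the pathway needs).
#'
#' @param c_nodes one-hot context vector.
#' @param W routing weight matrix (2 x n_targets).
#' @param step_index 0-based step within the trial.
#' @param duration injection duration in steps.
#' @param enabled logical; FALSE before the third block.
#' @param n_targets optional truncation of the signal to this many neurons.
#' @export
routing_signal <- function(c_nodes, W, step_index, duration, enabled = TRUE,
                           n_targets = NULL) {
  if (!enabled || step_index >= duration) return(numeric(ncol(W)))
  cur <- as.vector(crossprod(W, c_nodes))
  if (!is.null(n_targets) && n_targets < length(cur)) {
    keep <- order(abs(cur), decreasing = TRUE)[seq_len(n_targets)]
    masked <- numeric(length(cur))
    masked[keep] <- cur[keep]
    cur <- masked
  }
  cur
}

#' Parameters required by each OFC routing pathway
#'
#' The corticocortical pathway must learn one weight per context node per
#' dlPFC neuron; the transthalamic pathway one per context node per MD neuron.
#'
#' @param n_context_nodes number of OFC context nodes (2).
#' @param n_md number of MD neurons (2).
#' @param n_pfc number of dlPFC neurons (500).
#' @param target `"md"` or `"pfc"`.
#' @return integer parameter count.
#' @export
count_pathway_parameters <- function(n_context_nodes = 2L, n_md = 2L,
                                     n_pfc = 500L, target = c("pfc", "md")) {
  target <- match.arg(target)
  as.integer(n_context_nodes) *
    as.integer(if (target == "md") n_md else n_pfc)
}
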