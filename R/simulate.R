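# Closed-loop experiment driver: task environment -> vmPFC value inputs ->
# reservoir + MD dynamics -> decision -> reward -> node-perturbation readout
# update, Hebbian corticothalamic update with trial-end rescaling, vmPFC and
# OFC state updates, and OFC routing when enabled.

#' Experiment configuration
#'
#' Assembles and validates the configuration consumed by
#' [simulate_experiment()]. Every component's defaults are the reference
#' conditions; presets for the named experiments are provided by
#' [tc_config_human()] and [tc_config_minimal()].
#'
#' @param task schedule settings: `mode`, `n_blocks`, `trials_per_block`,
#'   `levels`, `trial_scale`, `pretrain_blocks`, `quota`.
#' @param network a [reservoir_params()] list.
#' @param n_md number of MD neurons.
#' @param md MD settings: `tau_pre_ms` (eligibility time constant,
#'   milliseconds), `alpha_ct`, `clip_bound`, `rescale` (trial-end norm
#'   restoration), `tau_adapt_ms` (time constant of the winner-take-all
#'   adaptive input baseline and of the Hebbian centering trace; NULL yokes
#'   it to 60 x `tau_pre_ms`), `md_noise_sd` (exploration noise on the
#'   winner-take-all comparison), `wta_hysteresis` (margin a challenger must
#'   exceed to displace the incumbent winner), `lesion`, `lesion_at_block`
#'   (0-based block at which to lesion mid-run, NULL for never),
#'   `lesion_compensation` (recurrent-weight scaling applied with a lesion,
#'   1.3), `forced` (minimal model: one MD neuron artificially activated per
#'   context, corticothalamic learning disabled), `g_add`, `g_mult`
#'   (projection strength factors).
#' @param readout `mu`, `baseline_decay`, `perturb`, `update_mode`
#'   (`"per_step"`: the per-time-step update summed over the trial;
#'   `"trial_mean"`: one update from window-mean perturbation and rates),
#'   `bias_tau_trials` (time constant, in trials, of the slow per-output
#'   activity average subtracted before comparing the two outputs; keeps the
#'   decision referenced to each output's own recent level so that a shared
#'   or constant offset — e.g. after a thalamic state change — cannot pin
#'   the response and silence exploration).
#' @param vmpfc `enabled` plus [value_estimator_params()] fields.
#' @param ofc `route_target` (`"off"`, `"md"`, `"pfc"`), `theta_s`,
#'   `context_likelihood`, `horizon`, `alpha_route`, `signal_duration_steps`,
#'   `n_route_targets` (NULL = all), `enable_after_block` (0-based; routing
#'   currents are injected only from this block on, Hebbian routing learning
#'   runs from the start).
#' @param record_rates keep per-trial trial-averaged reservoir rates (needed
#'   by the post-hoc analyses).
#' @return nested list of class `tc_config`.
#' @export
tc_config <- function(task = list(), network = reservoir_params(), n_md = 2L,
                      md = list(), readout = list(), vmpfc = list(),
                      ofc = list(), record_rates = TRUE) {
  task <- utils::modifyList(list(
    mode = "model_style", n_blocks = 10L, trials_per_block = 500L,
    levels = c(0.9, 0.1), trial_scale = 1L, pretrain_blocks = 0L,
    quota = FALSE), task)
  md <- utils::modifyList(list(
    tau_pre_ms = 2000, alpha_ct = 5e-5, clip_bound = 0.1, rescale = TRUE,
    tau_adapt_ms = NULL, md_noise_sd = 0.05, wta_hysteresis = 0.1,
    lesion = FALSE, lesion_at_block = NULL,
    lesion_compensation = 1.3, forced = FALSE, g_add = 1, g_mult = 1), md)
  # the competition/centering timescale is yoked to the eligibility trace
  # unless set explicitly: deviations are measured at the scale the trace
  # resolves (60x its time constant; 2000 ms -> 600 trials)
  if (is.null(md$tau_adapt_ms)) md$tau_adapt_ms <- 60 * md$tau_pre_ms
  readout <- utils::modifyList(list(
    mu = 5e-5, baseline_decay = 0.1, perturb = TRUE,
    update_mode = "per_step", bias_tau_trials = 50), readout)
  vmpfc <- utils::modifyList(list(
    enabled = TRUE, horizon = 10L, divergence_threshold = 0.15,
    grid_resolution = 101L, adapt_rate = 0.2), vmpfc)
  ofc <- utils::modifyList(list(
    route_target = "off", theta_s = 0.5, context_likelihood = 0.9,
    horizon = 10L, alpha_route = 0.001, signal_duration_steps = 10L,
    n_route_targets = NULL, enable_after_block = 2L), ofc)
  stopifnot(task$mode %in% c("model_style", "human_style"),
            ofc$route_target %in% c("off", "md", "pfc"),
            readout$update_mode %in% c("per_step", "trial_mean"),
            inherits(network, "tc_params"))
  structure(list(task = task, network = network, n_md = as.integer(n_md),
                 md = md, readout = readout, vmpfc = vmpfc, ofc = ofc,
                 record_rates = record_rates),
            class = "tc_config")
}

#' Human-comparison preset
#'
#' The human-style 10-block schedule with every block length multiplied by
#' `trial_scale` (the model needs about 10x as many trials per block as a
#' human to reach the same end-of-block performance) and `pretrain_blocks`
#' pre-training blocks prepended (excluded from performance statistics).
#' @param trial_scale block-length multiplier (default 10).
#' @param pretrain_blocks pre-training blocks (default 2).
#' @param ... passed on to [tc_config()].
#' @export
tc_config_human <- function(trial_scale = 10L, pretrain_blocks = 2L, ...) {
  tc_config(task = list(mode = "human_style", trial_scale = trial_scale,
                        pretrain_blocks = pretrain_blocks), ...)
}

#' Minimal forced-MD preset
#'
#' Isolates the thalamocortical projections: one MD neuron is artificially
#' activated for each context (match-dominant or non-match-dominant block),
#' Hebbian corticothalamic learning is disabled and there are no vmPFC value
#' inputs. Used for the additive/multiplicative gain sweeps, which test the
#' two pathways separated: set the strength factor of the swept pathway and
#' leave the other at 0.
#' @param g_add,g_mult projection strength factors (defaults: additive off,
#'   multiplicative at baseline strength 1).
#' @param n_blocks,trials_per_block alternating 0.9/0.1 schedule size.
#' @param ... passed on to [tc_config()].
#' @export
tc_config_minimal <- function(g_add = 0, g_mult = 1, n_blocks = 4L,
                              trials_per_block = 200L, ...) {
  tc_config(task = list(n_blocks = n_blocks,
                        trials_per_block = trials_per_block),
            md = list(forced = TRUE, g_add = g_add, g_mult = g_mult),
            vmpfc = list(enabled = FALSE), ...)
}

# Dominant rewarded rule of a block ("match" for levels > 0.5, "non-match"
# for levels < 0.5, NA at 0.5 where neither rule dominates).
dominant_rule <- function(level) {
  ifelse(level > 0.5, "match", ifelse(level < 0.5, "non-match", NA_character_))
}

#' Simulate one closed-loop experiment
#'
#' Runs the full model on the configured schedule. Per trial: the vmPFC
#' estimator supplies value inputs (q, 1-q); the reservoir and MD winner-
#' take-all dynamics run for 200 steps with Hebbian corticothalamic learning;
#' the response is read off the output neurons over the decision window and
#' scored against the target; the readout weights take a node-perturbation
#' update against the reward-prediction error; corticothalamic weights are
#' rescaled to their initial norm; vmPFC and OFC states are updated, and OFC
#' routing currents are injected at trial onsets once enabled. Lesion
#' variants zero all MD output to the reservoir and scale the recurrent
#' weights by the compensation factor.
#'
#' The master `seed` spawns separate streams for the task realization, the
#' weight initialization and the dynamics noise, so lesioned and intact runs
#' under the same seed share identical trial sequences.
#'
#' @param config a `tc_config`.
#' @param seed integer master seed.
#' @param resume optional `tc_experiment` from an earlier call: all learned
#'   weights and slow states (plastic matrices, eligibility and running-mean
#'   traces, MD membrane and adaptive baselines, reward and decision
#'   baselines, vmPFC and OFC states) are carried over, so a trained network
#'   can be continued under a different condition (e.g. enabling an OFC
#'   route after pre-training). The resumed run must use the same network
#'   dimensions.
#' @return object of class `tc_experiment`: `trials` (one row per trial),
#'   `rates` (trials x neurons trial-averaged reservoir rates, if recorded),
#'   `schedule`, `block_summary`, final plastic weights, the final slow
#'   `state`, `config`, `seed`.
#' @export
simulate_experiment <- function(config, seed = 1L, resume = NULL) {
  stopifnot(inherits(config, "tc_config"))
  prm <- config$network

  # --- task stream ---------------------------------------------------------
  set.seed(seed)
  sched <- with(config$task, build_schedule(
    mode, n_blocks = n_blocks, trials_per_block = trials_per_block,
    levels = levels, trial_scale = trial_scale,
    pretrain_blocks = pretrain_blocks))
  block_trials <- lapply(seq_len(nrow(sched)), function(b)
    sample_block_trials(sched$association_level[b], sched$n_trials[b],
                        quota = config$task$quota))
  n_total <- sum(sched$n_trials)

  # --- weight stream -------------------------------------------------------
  set.seed(seed + 1000003L)
  net <- build_network(prm, config$n_md)
  lesioned <- isTRUE(config$md$lesion)
  if (lesioned) net$W_rec <- net$W_rec * config$md$lesion_compensation
  if (!is.null(resume)) {
    stopifnot(inherits(resume, "tc_experiment"))
    for (w in c("W_ct", "W_out", "W_route_md", "W_route_pfc"))
      net[[w]] <- resume[[w]]
    net$ct_target_norm <- resume$state$ct_target_norm
  }

  # --- module states -------------------------------------------------------
  vm_cfg <- config$vmpfc
  vm <- if (!is.null(resume) && !is.null(resume$state$vm)) resume$state$vm
        else value_estimator_state(value_estimator_params(
          vm_cfg$horizon, vm_cfg$divergence_threshold, vm_cfg$grid_resolution,
          vm_cfg$adapt_rate))
  ofc_on <- config$ofc$route_target != "off"
  op <- ofc_params(config$ofc$horizon, config$ofc$theta_s,
                   prior_switch = 1 / n_total,
                   context_likelihood = config$ofc$context_likelihood,
                   alpha_route = config$ofc$alpha_route,
                   signal_duration_steps = config$ofc$signal_duration_steps)
  ofc_c <- c(1, 0)
  ofc_buf <- logical(0)
  if (!is.null(resume) && !is.null(resume$state$ofc_c)) {
    ofc_c <- resume$state$ofc_c
    ofc_buf <- resume$state$ofc_buf
  }

  # trials are independent episodes: membrane states (I, I_out) restart from
  # rest at every trial onset; the learning states (eligibility trace rho,
  # MD activation, all plastic weights, reward baseline) persist throughout.
  n <- prm$n_neurons
  I0 <- numeric(n); I_out0 <- numeric(2)
  rho <- numeric(n); rho_bar <- numeric(n)
  md_act <- c(1, rep(0, config$n_md - 1L))
  I_md <- numeric(config$n_md)
  u_bar <- numeric(config$n_md)
  baseline <- 0.5
  out_bar <- numeric(2)
  if (!is.null(resume)) {
    st <- resume$state
    rho <- st$rho; rho_bar <- st$rho_bar; md_act <- st$md_act
    I_md <- st$I_md; u_bar <- st$u_bar
    baseline <- st$baseline; out_bar <- st$out_bar
  }
  tau_pre_steps <- config$md$tau_pre_ms / (prm$dt * 1000)
  tau_adapt_steps <- config$md$tau_adapt_ms / (prm$dt * 1000)
  aw <- prm$analysis_window; dw <- prm$decision_window

  rates <- if (config$record_rates) matrix(NA_real_, n_total, n) else NULL
  md_rates <- matrix(NA_real_, n_total, config$n_md)
  zero_md <- numeric(config$n_md); zero_pfc <- numeric(n)
  col_int <- integer(n_total); col_num <- numeric(n_total)
  col_chr <- character(n_total); col_lgl <- logical(n_total)
  rec <- list(block_index = col_int, association_level = col_num,
              pretrain = col_lgl, cue = col_chr, rewarded_rule = col_chr,
              target = col_chr, response = col_chr, chosen_rule = col_chr,
              reward = col_int, rule_consistent = col_int, q_hat = col_num,
              p_switch = col_num, ofc_context = col_int)
  rec$rule_consistent[] <- NA_integer_; rec$q_hat[] <- NA_real_
  rec$p_switch[] <- NA_real_; rec$ofc_context[] <- NA_integer_

  # --- dynamics stream -----------------------------------------------------
  set.seed(seed + 2000003L)
  row <- 0L
  for (b in seq_len(nrow(sched))) {
    level <- sched$association_level[b]
    bidx <- sched$block_index[b]
    dom <- dominant_rule(level)
    if (!is.null(config$md$lesion_at_block) && !lesioned &&
        bidx >= config$md$lesion_at_block) {
      lesioned <- TRUE
      net$W_rec <- net$W_rec * config$md$lesion_compensation
    }
    forced_idx <- if (isTRUE(config$md$forced)) {
      if (level >= 0.5) 0L else 1L
    } else -1L
    if (forced_idx >= 0) {
      md_act <- numeric(config$n_md)
      md_act[forced_idx + 1L] <- 1
    }
    route_enabled <- ofc_on && bidx >= config$ofc$enable_after_block
    tb <- block_trials[[b]]

    for (k in seq_len(nrow(tb))) {
      row <- row + 1L
      cue <- tb$cue[k]
      q <- if (vm_cfg$enabled) vm$q_hat else NA_real_
      inp4 <- c(as.numeric(cue == "up"), as.numeric(cue == "down"),
                if (vm_cfg$enabled) c(q, 1 - q) else c(0, 0))

      r_md <- zero_md; r_pfc <- zero_pfc; route_steps <- 0L
      if (route_enabled) {
        route_steps <- op$signal_duration_steps
        if (config$ofc$route_target == "md") {
          r_md <- routing_signal(ofc_c, net$W_route_md, 0L, 1L,
                                 n_targets = config$ofc$n_route_targets)
        } else {
          r_pfc <- routing_signal(ofc_c, net$W_route_pfc, 0L, 1L,
                                  n_targets = config$ofc$n_route_targets)
        }
      }

      out <- run_trial_cpp(
        net$W_rec, net$W_inp, net$W_md, net$W_ct, net$W_out,
        I0, I_out0, rho, rho_bar, md_act, I_md, u_bar, inp4, r_md, r_pfc, route_steps,
        prm$n_steps, prm$input_steps, prm$dt / prm$tau,
        sqrt(prm$noise_var), config$md$md_noise_sd,
        config$md$g_add, config$md$g_mult,
        lesioned, forced_idx,
        !isTRUE(config$md$forced), config$md$alpha_ct,
        config$md$clip_bound, tau_pre_steps, tau_adapt_steps,
        config$md$wta_hysteresis,
        isTRUE(config$readout$perturb),
        aw[1], aw[2], dw[1], dw[2], FALSE)
      rho <- out$rho; rho_bar <- out$rho_bar; md_act <- out$md_act
      I_md <- out$I_md; u_bar <- out$u_bar
      net$W_ct <- if (isTRUE(config$md$rescale) && !isTRUE(config$md$forced))
        rescale_ct_norm(out$W_ct, net$ct_target_norm) else out$W_ct

      oc <- out$out_mean - out_bar
      out_bar <- out_bar + (out$out_mean - out_bar) / config$readout$bias_tau_trials
      response <- if (oc[1] >= oc[2]) "up" else "down"
      sc <- score_response(cue, tb$target[k], response)
      reward <- sc$reward

      # readout learning against the reward-prediction error
      bl <- update_reward_baseline(baseline, reward, config$readout$baseline_decay)
      zr <- if (config$readout$update_mode == "per_step") out$zr_acc
            else outer(out$zeta_mean, out$r_dec)
      net$W_out <- node_perturbation_update(net$W_out, zr, bl$delta_e,
                                            config$readout$mu)
      baseline <- bl$baseline

      # observed evidence: would the match strategy have been rewarded?
      mr <- xor(reward == 1, sc$chosen_rule != "match")
      if (vm_cfg$enabled) vm <- update_value_estimate(vm, mr)

      p_switch <- NA_real_
      if (ofc_on) {
        consistent <- mr == (ofc_c[1] == 1)
        ofc_buf <- utils::tail(c(ofc_buf, consistent), op$horizon)
        p_switch <- switch_probability(ofc_buf, op)
        upd <- update_context_belief(ofc_c, p_switch, op$theta_s, ofc_buf)
        ofc_c <- upd$c_nodes; ofc_buf <- upd$buffer
        net$W_route_md <- routing_hebbian_update(
          net$W_route_md, ofc_c, out$md_avg, op$alpha_route, op$route_norm_md)
        net$W_route_pfc <- routing_hebbian_update(
          net$W_route_pfc, ofc_c, out$r_avg, op$alpha_route, op$route_norm_pfc)
      }

      rec$block_index[row] <- bidx; rec$association_level[row] <- level
      rec$pretrain[row] <- sched$pretrain[b]; rec$cue[row] <- cue
      rec$rewarded_rule[row] <- tb$rewarded_rule[k]
      rec$target[row] <- tb$target[k]; rec$response[row] <- response
      rec$chosen_rule[row] <- sc$chosen_rule; rec$reward[row] <- reward
      if (!is.na(dom))
        rec$rule_consistent[row] <- as.integer(sc$chosen_rule == dom)
      rec$q_hat[row] <- q; rec$p_switch[row] <- p_switch
      if (ofc_on) rec$ofc_context[row] <- which.max(ofc_c)
      if (config$record_rates) rates[row, ] <- out$r_avg
      md_rates[row, ] <- out$md_avg
    }
  }

  trials <- data.frame(trial = seq_len(n_total), rec, stringsAsFactors = FALSE)
  trials$correct <- trials$reward
  trials$md_avg <- md_rates  # matrix column: trial-averaged MD activations

  bs <- do.call(rbind, lapply(split(trials, trials$block_index), function(d) {
    data.frame(block_index = d$block_index[1],
               association_level = d$association_level[1],
               pretrain = d$pretrain[1], n_trials = nrow(d),
               accuracy = mean(d$correct),
               ratio_correct = mean(d$rule_consistent))
  }))
  rownames(bs) <- NULL

  structure(list(trials = trials, rates = rates, schedule = sched,
                 block_summary = bs,
                 W_ct = net$W_ct, W_out = net$W_out,
                 W_route_md = net$W_route_md, W_route_pfc = net$W_route_pfc,
                 state = list(rho = rho, rho_bar = rho_bar, md_act = md_act,
                              I_md = I_md, u_bar = u_bar,
                              baseline = baseline, out_bar = out_bar,
                              ct_target_norm = net$ct_target_norm,
                              vm = vm, ofc_c = ofc_c, ofc_buf = ofc_buf),
                 config = config, seed = seed),
            class = "tc_experiment")
}

#' @export
print.tc_experiment <- function(x, ...) {
  tr <- x$trials[!x$trials$pretrain, ]
  cat("<tc_experiment> seed", x$seed, "-", nrow(x$schedule), "blocks,",
      nrow(x$trials), "trials\n")
  cat(sprintf("  accuracy %.3f  ratio correct %.3f (pre-training excluded)\n",
              mean(tr$correct), mean(tr$rule_consistent, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.tc_experiment <- function(object, ...) {
  tr <- object$trials[!object$trials$pretrain, ]
  by_level <- do.call(rbind, lapply(
    split(tr, abs(tr$association_level - 0.5)), function(d) {
      data.frame(levels = paste(sort(unique(d$association_level)),
                                collapse = "/"),
                 n_trials = nrow(d), accuracy = mean(d$correct),
                 ratio_correct = mean(d$rule_consistent, na.rm = TRUE))
    }))
  rownames(by_level) <- NULL
  out <- list(by_level = by_level, block_summary = object$block_summary,
              seed = object$seed)
  class(out) <- "summary.tc_experiment"
  out
}

#' @export
print.summary.tc_experiment <- function(x, ...) {
  cat("Accuracy by association-level pair (pre-training excluded):\n")
  print(x$by_level, digits = 3)
  invisible(x)
}

#' Block-accuracy trace plot
#' @param x a `tc_experiment`.
#' @param metric `"accuracy"` (reward fraction) or `"ratio_correct"`.
#' @param bin trials per bin for the running average.
#' @param ... passed to [plot()].
#' @export
plot.tc_experiment <- function(x, metric = c("accuracy", "ratio_correct"),
                               bin = 25L, ...) {
  metric <- match.arg(metric)
  y <- if (metric == "accuracy") x$trials$correct else x$trials$rule_consistent
  idx <- seq_along(y)
  bins <- split(idx, ceiling(idx / bin))
  by <- vapply(bins, function(i) mean(y[i], na.rm = TRUE), numeric(1))
  bx <- vapply(bins, function(i) mean(i), numeric(1))
  plot(bx, by, type = "l", ylim = c(0, 1), xlab = "trial", ylab = metric, ...)
  edges <- cumsum(x$schedule$n_trials)
  graphics::abline(v = edges[-length(edges)], col = "grey70", lty = 3)
  invisible(x)
}

#' Accuracy of an experiment
#'
#' @param result a `tc_experiment`.
#' @param metric `"accuracy"` (fraction rewarded) or `"ratio_correct"`
#'   (fraction of trials whose chosen rule is the block's dominant rule).
#' @param levels restrict to blocks with these association levels.
#' @param from_block restrict to blocks with `block_index >=` this (0-based).
#' @param post_switch_trials restrict to the first k trials of each
#'   non-initial block.
#' @param include_pretrain include pre-training blocks (default FALSE).
#' @export
experiment_accuracy <- function(result, metric = c("accuracy", "ratio_correct"),
                                levels = NULL, from_block = NULL,
                                post_switch_trials = NULL,
                                include_pretrain = FALSE) {
  metric <- match.arg(metric)
  tr <- result$trials
  if (!include_pretrain) tr <- tr[!tr$pretrain, ]
  if (!is.null(levels)) tr <- tr[tr$association_level %in% levels, ]
  if (!is.null(from_block)) tr <- tr[tr$block_index >= from_block, ]
  if (!is.null(post_switch_trials)) {
    pos <- stats::ave(seq_len(nrow(tr)), tr$block_index, FUN = seq_along)
    first_block <- min(tr$block_index)
    tr <- tr[pos <= post_switch_trials & tr$block_index > first_block, ]
  }
  if (metric == "accuracy") mean(tr$correct)
  else mean(tr$rule_consistent, na.rm = TRUE)
}
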