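# Parameter sweeps over the experiments: additive/multiplicative gain factors
# (minimal forced-MD model), eligibility-trace time constant (full model),
# and OFC routing target x neuron count / signal duration.

# map a sweep key onto its place in the nested config
.sweep_set <- function(config, key, value) {
  switch(key,
    g_add = { config$md$g_add <- value; config },
    g_mult = { config$md$g_mult <- value; config },
    tau_pre_ms = {
      # keep the competition/centering timescale yoked to the trace, as
      # tc_config() does when tau_adapt_ms is not set explicitly
      config$md$tau_adapt_ms <- config$md$tau_adapt_ms /
        config$md$tau_pre_ms * value
      config$md$tau_pre_ms <- value
      config
    },
    route_target = { config$ofc$route_target <- value; config },
    n_route_targets = { config$ofc$n_route_targets <-
                          if (is.na(value)) NULL else value; config },
    signal_duration_steps = { config$ofc$signal_duration_steps <- value; config },
    stop("unknown sweep dimension: ", key))
}

#' Run a parameter sweep
#'
#' For every grid cell and seed, runs [simulate_experiment()] on `config`
#' with the cell's values substituted and aggregates summary measures:
#' overall accuracy and ratio correct, steady-state ratio correct from block
#' 3 onward, post-switch accuracy over the first 30 trials of each block,
#' and the correlations of trial-averaged MD activity with the cue and rule
#' vectors.
#'
#' @param config base `tc_config` (use [tc_config_minimal()] for gain sweeps,
#'   the full model for tau sweeps, and an OFC-enabled config for routing
#'   sweeps).
#' @param grid named list of sweep values; the cross product is run. Keys:
#'   `g_add`, `g_mult`, `tau_pre_ms`, `route_target`, `n_route_targets`,
#'   `signal_duration_steps`.
#' @param seeds integer vector of master seeds.
#' @return data.frame of class `tc_sweep`, one row per grid cell x seed.
#' @export
run_sweep <- function(config, grid, seeds = 1:3) {
  stopifnot(is.list(grid), length(grid) >= 1, !is.null(names(grid)))
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells) * length(seeds))
  i <- 0L
  for (ci in seq_len(nrow(cells))) {
    cfg <- config
    for (key in names(cells)) cfg <- .sweep_set(cfg, key, cells[ci, key])
    for (s in seeds) {
      i <- i + 1L
      res <- simulate_experiment(cfg, s)
      tr <- res$trials[!res$trials$pretrain, ]
      lab_cue <- ifelse(tr$cue == "up", 1, -1)
      lab_rule <- ifelse(tr$rewarded_rule == "match", 1, -1)
      md <- tr$md_avg
      row <- data.frame(
        cells[ci, , drop = FALSE], seed = s,
        accuracy = mean(tr$correct),
        ratio_correct = mean(tr$rule_consistent, na.rm = TRUE),
        steady_ratio_correct = experiment_accuracy(
          res, "ratio_correct", from_block = 2L),
        post_switch_accuracy = experiment_accuracy(
          res, "accuracy", post_switch_trials = 30L),
        cue_correlation = condition_correlation(md, lab_cue),
        rule_correlation = condition_correlation(md, lab_rule),
        row.names = NULL)
      out[[i]] <- row
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("tc_sweep", "data.frame")
  res
}
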