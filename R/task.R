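# Task environment: blocked cue -> rule contingencies with probabilistic reward.

#' Allowed association levels
#'
#' Probability, within a block, that the match rule is the rewarded rule on a
#' trial. Strongly predictive blocks use 0.9 or 0.1, moderately predictive
#' blocks 0.7 or 0.3, and non-predictive blocks 0.5.
#' @export
ASSOCIATION_LEVELS <- c(0.9, 0.7, 0.5, 0.3, 0.1)

# Fixed pseudorandom block order used for the human-style schedule: 10 blocks,
# two per association level, one of the pair 30 trials long and the other 40,
# 350 trials in total. Generated once from a named seed and frozen here so the
# order is identical across runs and machines.
.human_block_order <- data.frame(
  association_level = c(0.5, 0.9, 0.7, 0.1, 0.3, 0.1, 0.9, 0.5, 0.3, 0.7),
  n_trials = c(40L, 30L, 30L, 40L, 40L, 30L, 40L, 30L, 30L, 40L)
)

#' Build a block schedule for the probabilistic inference task
#'
#' A schedule is an ordered set of blocks, each with an association level (the
#' probability that the match rule is rewarded on a trial of that block) and a
#' trial count.
#'
#' Two modes are supported. `"human_style"` reproduces the experiment run with
#' human participants: 10 blocks, two per association level
#' (90/70/50/30/10 percent), one of each pair 30 trials and the other 40,
#' in a fixed pseudorandom order, 350 trials in total. `trial_scale`
#' multiplies every block length (the model needs roughly ten times as many
#' trials per block as a human to reach the same end-of-block performance).
#' `"model_style"` builds `n_blocks` blocks of `trials_per_block` trials with
#' association levels cycled from `levels` (default alternating 0.9/0.1).
#'
#' @param mode `"human_style"` or `"model_style"`.
#' @param n_blocks number of blocks (model_style only).
#' @param trials_per_block trials per block (model_style only; default 500).
#' @param levels association levels cycled over blocks (model_style only).
#' @param trial_scale integer multiplier applied to human-style block lengths.
#' @param pretrain_blocks number of pre-training blocks prepended to a
#'   human-style schedule (alternating 0.9/0.1, 500 trials each, flagged in the
#'   `pretrain` column so they can be excluded from performance statistics).
#' @return A data.frame of class `tc_schedule` with columns `block_index`
#'   (0-based), `association_level`, `n_trials`, `pretrain`.
#' @export
build_schedule <- function(mode = c("model_style", "human_style"),
                           n_blocks = 10L, trials_per_block = 500L,
                           levels = c(0.9, 0.1), trial_scale = 1L,
                           pretrain_blocks = 0L) {
  mode <- match.arg(mode)
  if (mode == "human_style") {
    sched <- .human_block_order
    sched$n_trials <- as.integer(sched$n_trials * trial_scale)
    sched$pretrain <- FALSE
    if (pretrain_blocks > 0) {
      pre <- data.frame(
        association_level = rep(c(0.9, 0.1), length.out = pretrain_blocks),
        n_trials = 500L, pretrain = TRUE)
      sched <- rbind(pre, sched)
    }
  } else {
    if (n_blocks < 1) stop("n_blocks must be >= 1")
    if (trials_per_block < 1) stop("trials_per_block must be >= 1")
    if (!all(levels %in% ASSOCIATION_LEVELS))
      stop("association levels must be in {0.9, 0.7, 0.5, 0.3, 0.1}")
    sched <- data.frame(
      association_level = rep(levels, length.out = n_blocks),
      n_trials = as.integer(trials_per_block),
      pretrain = FALSE)
  }
  sched$block_index <- seq_len(nrow(sched)) - 1L
  sched <- sched[, c("block_index", "association_level", "n_trials", "pretrain")]
  class(sched) <- c("tc_schedule", "data.frame")
  attr(sched, "mode") <- mode
  sched
}

#' Sample the trial stream for one block
#'
#' Cues are exactly balanced within the block (equal numbers of up and down,
#' order shuffled); the rewarded rule is drawn i.i.d. per trial: match with
#' probability `association_level`, non-match otherwise. With
#' `quota = TRUE` the rule outcomes are instead quota-matched exactly
#' (`round(level * n)` match trials, shuffled).
#'
#' The target is the cue transformed by the rewarded rule: identical to the cue
#' under the match rule, the opposite direction under non-match.
#'
#' @param association_level one of 0.9, 0.7, 0.5, 0.3, 0.1.
#' @param n_trials number of trials.
#' @param quota quota-match rule outcomes exactly instead of i.i.d. sampling.
#' @return data.frame with columns `trial_index` (0-based), `cue`,
#'   `rewarded_rule`, `target`.
#' @export
sample_block_trials <- function(association_level, n_trials, quota = FALSE) {
  if (!association_level %in% ASSOCIATION_LEVELS)
    stop("association_level must be one of 0.9, 0.7, 0.5, 0.3, 0.1")
  if (n_trials < 1) stop("n_trials must be >= 1")
  n_up <- n_trials %/% 2L
  cues <- c(rep("up", n_up), rep("down", n_trials - n_up))
  cues <- sample(cues)
  if (quota) {
    n_match <- round(association_level * n_trials)
    rules <- sample(c(rep("match", n_match), rep("non-match", n_trials - n_match)))
  } else {
    rules <- ifelse(stats::runif(n_trials) < association_level, "match", "non-match")
  }
  target <- ifelse(rules == "match", cues, flip_direction(cues))
  data.frame(trial_index = seq_len(n_trials) - 1L,
             cue = cues, rewarded_rule = rules, target = target,
             stringsAsFactors = FALSE)
}

#' @rdname score_response
#' @export
flip_direction <- function(direction) {
  if (!all(direction %in% c("up", "down"))) stop("direction must be 'up' or 'down'")
  ifelse(direction == "up", "down", "up")
}

#' Score a response against a trial's target
#'
#' Reward is 1 iff the response equals the target (the cue transformed by the
#' rewarded rule); the chosen rule is `match` iff the response equals the cue.
#' All arguments are vectorized.
#'
#' @param cue,target trial cue and target, each `"up"` or `"down"`.
#' @param response the model's response, `"up"` or `"down"`.
#' @return data.frame with columns `reward` (0/1 integer) and `chosen_rule`.
#' @export
score_response <- function(cue, target, response) {
  if (!all(response %in% c("up", "down"))) stop("response must be 'up' or 'down'")
  data.frame(reward = as.integer(response == target),
             chosen_rule = ifelse(response == cue, "match", "non-match"),
             stringsAsFactors = FALSE)
}

#' Read/write a schedule as a tab-separated table
#'
#' One row per block: `block_index`, `association_level`, `n_trials`,
#' `pretrain`.
#' @param schedule a `tc_schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  stopifnot(all(c("block_index", "association_level", "n_trials") %in% names(sched)))
  if (is.null(sched$pretrain)) sched$pretrain <- FALSE
  class(sched) <- c("tc_schedule", "data.frame")
  sched
}
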