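# Post-hoc analyses: cue-responsiveness via per-neuron logistic regression,
# selectivity classification, population decoding, condition correlations.

#' Per-neuron cue responsiveness (logistic-regression pseudo R-squared)
#'
#' For each neuron, fits a single-predictor logistic regression of the cue
#' label (1 = up, 0 = down) on the neuron's mean trial activity and returns
#' McFadden's pseudo R-squared, `1 - deviance/null deviance`. If the two cue
#' classes are perfectly linearly separable in that neuron's activity the
#' value is set to exactly 1.
#'
#' @param activity trials x neurons matrix of trial-averaged rates
#'   (steps 50-150 window).
#' @param cue per-trial cue labels, `"up"`/`"down"` (or logical/0-1 for up).
#' @return numeric vector of pseudo R-squared values in [0, 1].
#' @export
cue_responsiveness <- function(activity, cue) {
  y <- if (is.character(cue) || is.factor(cue)) as.integer(cue == "up")
       else as.integer(cue)
  if (length(unique(y)) < 2) stop("need trials of both cues")
  if (sum(y == 1) < 2 || sum(y == 0) < 2) stop("need >= 2 trials per cue")
  apply(activity, 2, function(x) {
    x1 <- x[y == 1]; x0 <- x[y == 0]
    # perfect linear separation (strict, either direction) => R^2 = 1
    if (max(x0) < min(x1) || max(x1) < min(x0)) return(1)
    if (stats::var(x) == 0) return(0)
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
    r2 <- 1 - fit$deviance / fit$null.deviance
    min(max(r2, 0), 1)
  })
}

#' Classify neurons by context-wise cue responsiveness
#'
#' A neuron is counted as cue-responsive in a context if its pseudo
#' R-squared there reaches the cutoff; the four categories are the corners
#' of the (match, non-match) R-squared plane.
#'
#' @param r2_match,r2_nonmatch per-neuron pseudo R-squared within match and
#'   non-match contexts.
#' @param cutoff responsiveness cutoff in (0, 1), default 0.5.
#' @return character vector with levels `"non-responsive"`, `"match-only"`,
#'   `"nonmatch-only"`, `"both"`.
#' @export
classify_selectivity <- function(r2_match, r2_nonmatch, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1, length(r2_match) == length(r2_nonmatch))
  m <- r2_match >= cutoff; nm <- r2_nonmatch >= cutoff
  ifelse(m & nm, "both",
         ifelse(m, "match-only", ifelse(nm, "nonmatch-only", "non-responsive")))
}

#' Context-wise selectivity counts for a simulated experiment
#'
#' Splits non-pretraining trials into match-dominant and non-match-dominant
#' contexts (association level above/below 0.5), computes per-neuron cue
#' responsiveness within each, and tabulates the four selectivity categories.
#'
#' @param result a `tc_experiment` simulated with `record_rates = TRUE`.
#' @param cutoff responsiveness cutoff.
#' @return list with `r2_match`, `r2_nonmatch`, `category`, and `counts`
#'   (named vector over the four categories, summing to n_neurons).
#' @export
experiment_selectivity <- function(result, cutoff = 0.5) {
  if (is.null(result$rates)) stop("experiment was run without record_rates")
  tr <- result$trials
  keep <- !tr$pretrain & tr$association_level != 0.5
  ctx_match <- keep & tr$association_level > 0.5
  ctx_nonmatch <- keep & tr$association_level < 0.5
  r2m <- cue_responsiveness(result$rates[ctx_match, , drop = FALSE],
                            tr$cue[ctx_match])
  r2n <- cue_responsiveness(result$rates[ctx_nonmatch, , drop = FALSE],
                            tr$cue[ctx_nonmatch])
  cat_ <- classify_selectivity(r2m, r2n, cutoff)
  lev <- c("non-responsive", "match-only", "nonmatch-only", "both")
  counts <- vapply(lev, function(l) sum(cat_ == l), numeric(1))
  list(r2_match = r2m, r2_nonmatch = r2n, category = cat_, counts = counts)
}

#' Decode a binary variable from population activity
#'
#' Fits a linear decoder (least squares on a 0/1 target, threshold at 0.5)
#' of the label on trial-averaged population activity and reports held-out
#' accuracy under k-fold cross-validation; chance is 0.5.
#'
#' @param activity trials x units matrix.
#' @param labels per-trial binary labels (two distinct values).
#' @param folds number of cross-validation folds.
#' @return held-out accuracy in [0, 1].
#' @export
decode_variable <- function(activity, labels, folds = 5L) {
  labs <- unique(labels)
  if (length(labs) != 2) stop("labels must take exactly two values")
  y <- as.numeric(labels == labs[1])
  n <- nrow(activity)
  fold <- sample(rep(seq_len(folds), length.out = n))
  X <- cbind(1, activity)
  correct <- logical(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    beta <- stats::lm.fit(X[tr, , drop = FALSE], y[tr])$coefficients
    beta[is.na(beta)] <- 0
    pred <- as.numeric(X[!tr, , drop = FALSE] %*% beta >= 0.5)
    correct[!tr] <- pred == y[!tr]
  }
  mean(correct)
}

#' Correlation of trial-averaged activity with a task variable
#'
#' Correlates each unit's trial-averaged activity with a +/-1 label vector
#' (cues: +1 up, -1 down; rule: +1 match, -1 non-match) and summarizes over
#' units as the maximum absolute Pearson correlation (a single strongly
#' modulated unit is enough to call the population modulated).
#'
#' @param activity trials x units matrix.
#' @param labels per-trial +/-1 vector (or coercible logical).
#' @param summarize `"max_abs"` (default) or `"none"` for per-unit values.
#' @export
condition_correlation <- function(activity, labels,
                                  summarize = c("max_abs", "none")) {
  summarize <- match.arg(summarize)
  labels <- as.numeric(labels)
  cors <- apply(as.matrix(activity), 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, labels)
  })
  if (summarize == "none") cors else max(abs(cors), na.rm = TRUE)
}

#' Correlation between condition-mean population patterns
#'
#' Pearson correlation between the population activity pattern averaged over
#' one set of trials and over another (e.g. match vs non-match context, or
#' up vs down cues), used to quantify how separated the two conditions'
#' representations are.
#'
#' @param activity trials x neurons matrix.
#' @param cond_a,cond_b logical trial selectors.
#' @export
pattern_correlation <- function(activity, cond_a, cond_b) {
  a <- colMeans(activity[cond_a, , drop = FALSE])
  b <- colMeans(activity[cond_b, , drop = FALSE])
  stats::cor(a, b)
}
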