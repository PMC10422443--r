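#' Fall-risk diagnostic evaluation
#'
#' Subjects are labelled fallers either from clinical criteria (Berg Balance
#' Scale below 40, Timed Up and Go above 14 s) or from 3-month fall history,
#' and the sway score is evaluated as a diagnostic marker: ROC curve swept
#' over all observed scores (higher sway predicts faller), trapezoidal AUC
#' (equal to the Mann-Whitney pair-ordering probability, ties counted half),
#' Hanley-McNeil standard error with a normal 95% interval, Youden-index
#' cut-off, and confusion-matrix metrics with qualitative grading.
#'
#' @name diagnostics
NULL

#' Fall-labelling criterion
#'
#' @param mode `"bbs"` (positive iff BBS score below threshold), `"tug"`
#'   (positive iff TUG time above threshold) or `"history"` (positive iff a
#'   fall occurred within the last 3 months).
#' @param bbs_threshold BBS threshold (default 40).
#' @param tug_threshold TUG threshold in seconds (default 14).
#' @param bbs_inclusive If `TRUE`, a BBS score equal to the threshold also
#'   counts positive ("40 or less"); the default is the strict "below 40".
#' @return An object of class `fall_criterion`.
#' @export
fall_criterion <- function(mode = c("bbs", "tug", "history"),
                           bbs_threshold = 40, tug_threshold = 14,
                           bbs_inclusive = FALSE) {
  mode <- match.arg(mode)
  stopifnot(bbs_threshold >= 0, bbs_threshold <= 56, tug_threshold > 0)
  structure(
    list(mode = mode, bbs_threshold = bbs_threshold,
         tug_threshold = tug_threshold, bbs_inclusive = bbs_inclusive),
    class = "fall_criterion"
  )
}

#' Label subjects as fallers under a criterion
#'
#' @param subjects A data frame with, depending on the criterion mode,
#'   columns `bbs_score`, `tug_seconds` or `fell_within_3_months`.
#' @param criterion A [fall_criterion()].
#' @return Logical vector, `TRUE` for fallers.
#' @export
label_faller <- function(subjects, criterion = fall_criterion("bbs")) {
  stopifnot(inherits(criterion, "fall_criterion"))
  field <- switch(criterion$mode,
    bbs = "bbs_score", tug = "tug_seconds", history = "fell_within_3_months")
  if (!field %in% names(subjects) || any(is.na(subjects[[field]]))) {
    stop_swaysense(
      sprintf("criterion mode '%s' needs complete column '%s'", criterion$mode, field),
      "swaysense_data_error"
    )
  }
  switch(criterion$mode,
    bbs = if (criterion$bbs_inclusive) {
      subjects$bbs_score <= criterion$bbs_threshold
    } else {
      subjects$bbs_score < criterion$bbs_threshold
    },
    tug = subjects$tug_seconds > criterion$tug_threshold,
    history = as.logical(subjects$fell_within_3_months)
  )
}

check_cohort <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_swaysense("scores and labels must have equal length",
                   "swaysense_validation_error")
  }
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels))) {
    stop_swaysense("scores and labels must be complete", "swaysense_data_error")
  }
  if (all(labels) || !any(labels)) {
    stop_swaysense("cohort has a single class; ROC undefined",
                   "swaysense_degenerate_cohort")
  }
  labels
}

#' ROC curve of a sway score
#'
#' Sweeps the decision threshold over every unique observed score plus an
#' `Inf` sentinel, with the rule score >= threshold => predicted faller
#' (higher sway means higher risk).
#'
#' @param scores Numeric sway scores.
#' @param labels Logical (or 0/1) faller labels.
#' @return A data frame with columns `threshold`, `sensitivity`, `fpr`
#'   (1 - specificity), monotone in both coordinates.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_cohort(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # last index of each tied block of scores
  idx <- cumsum(rle(s)$lengths)
  data.frame(
    threshold = c(Inf, s[idx]),
    sensitivity = c(0, cumsum(l)[idx] / n_pos),
    fpr = c(0, cumsum(!l)[idx] / n_neg)
  )
}

#' Area under a ROC curve
#'
#' Trapezoidal area over the curve from [roc_curve()]; equals the
#' probability that a random faller outscores a random non-faller, with
#' ties counted one half.
#'
#' @param roc A data frame from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$sensitivity, -1) +
                       utils::tail(roc$sensitivity, -1)) / 2)
}

#' Hanley-McNeil standard error and confidence interval of an AUC
#'
#' Nonparametric standard error with a normal 95% interval clipped to
#' `[0, 1]`.
#'
#' @param auc The AUC estimate.
#' @param n_pos,n_neg Number of positive and negative subjects.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `se` and `ci` (length-2 numeric).
#' @export
auc_se_ci <- function(auc, n_pos, n_neg, conf_level = 0.95) {
  stopifnot(n_pos >= 1, n_neg >= 1, auc >= 0, auc <= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  list(se = se, ci = ci)
}

#' Youden-index optimal cut-off
#'
#' Maximises J = sensitivity + specificity - 1 over the swept thresholds.
#' Ties are broken towards higher sensitivity, then towards the lower
#' threshold.
#'
#' @param roc A data frame from [roc_curve()].
#' @return A list with `cutoff`, `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  j <- roc$sensitivity - roc$fpr
  best <- which(j >= max(j) - 1e-12)
  best <- best[roc$sensitivity[best] >= max(roc$sensitivity[best]) - 1e-12]
  pick <- best[which.min(roc$threshold[best])]
  list(
    cutoff = roc$threshold[pick],
    youden_j = j[pick],
    sensitivity = roc$sensitivity[pick],
    specificity = 1 - roc$fpr[pick]
  )
}

#' Confusion counts at a cut-off
#'
#' @param scores Numeric sway scores.
#' @param labels Logical faller labels.
#' @param cutoff Decision threshold; score >= cutoff predicts faller.
#' @return A list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(scores, labels, cutoff) {
  labels <- check_cohort(scores, labels)
  pred <- scores >= cutoff
  list(
    tp = sum(pred & labels), fp = sum(pred & !labels),
    tn = sum(!pred & !labels), fn = sum(!pred & labels)
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Zero-denominator metrics are returned as `NA` (undefined) rather than
#' raising.
#'
#' @param counts A list with `tp`, `fp`, `tn`, `fn`.
#' @return A list with `sensitivity`, `specificity`, `accuracy` and a
#'   `grades` character vector from [grade()].
#' @export
diagnostic_metrics <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) {
    stop_swaysense("empty cohort", "swaysense_validation_error")
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    accuracy = (counts$tp + counts$tn) / n
  )
  out$grades <- vapply(out[c("sensitivity", "specificity", "accuracy")],
                       function(v) if (is.na(v)) NA_character_ else grade(v),
                       character(1))
  out
}

#' Qualitative grade of a diagnostic proportion
#'
#' Bands: excellent for 0.81 and above, good for 0.61 to below 0.81,
#' moderate for 0.41 to below 0.61, poor below 0.41.
#'
#' @param value Proportion in `[0, 1]`; vectorised.
#' @return Character vector of grades.
#' @export
#' @examples
#' grade(c(0.92, 0.70, 0.55)) # excellent, good, moderate
grade <- function(value) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 1)) {
    stop_swaysense("grade() needs values in [0, 1]", "swaysense_validation_error")
  }
  as.character(cut(value, breaks = c(-Inf, 0.41, 0.61, 0.81, Inf),
                   labels = c("poor", "moderate", "good", "excellent"),
                   right = FALSE))
}

#' Full ROC analysis of a scored cohort
#'
#' Convenience wrapper assembling [roc_curve()], [roc_auc()],
#' [auc_se_ci()], [youden_cutoff()], [confusion()] and
#' [diagnostic_metrics()] into one summary.
#'
#' @inheritParams roc_curve
#' @return An object of class `roc_summary`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- check_cohort(scores, labels)
  roc <- roc_curve(scores, labels)
  auc <- roc_auc(roc)
  band <- auc_se_ci(auc, sum(labels), sum(!labels))
  cut <- youden_cutoff(roc)
  counts <- confusion(scores, labels, cut$cutoff)
  structure(
    c(list(roc = roc, auc = auc, auc_grade = grade(auc),
           se = band$se, ci95 = band$ci,
           n_pos = sum(labels), n_neg = sum(!labels)),
      cut,
      list(counts = counts, metrics = diagnostic_metrics(counts))),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("ROC analysis: %d fallers vs %d non-fallers\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f) [%s]\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$auc_grade))
  cat(sprintf("  Youden cut-off %.3f (J = %.3f)\n", x$cutoff, x$youden_j))
  m <- x$metrics
  cat(sprintf("  sensitivity %.3f [%s], specificity %.3f [%s], accuracy %.3f [%s]\n",
              m$sensitivity, m$grades[["sensitivity"]],
              m$specificity, m$grades[["specificity"]],
              m$accuracy, m$grades[["accuracy"]]))
  invisible(x)
}

#' Welch two-sample comparison from group summaries
#'
#' Independent two-sided t-test from per-group mean, SD and n, with the
#' Welch-Satterthwaite degrees of freedom (no equal-variance pooling).
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return A list with `t`, `df`, `p_value`.
#' @export
#' @examples
#' group_compare(25.20, 3.19, 20, 79.00, 8.25, 20)
group_compare <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2 || sd_a <= 0 || sd_b <= 0) {
    stop_swaysense("each group needs n >= 2 and positive SD",
                   "swaysense_validation_error")
  }
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  t_stat <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t_stat, df = df, p_value = 2 * stats::pt(-abs(t_stat), df))
}
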