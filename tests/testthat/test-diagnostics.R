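test_that("fall labelling follows the clinical thresholds strictly", {
  subj <- data.frame(bbs_score = c(39, 40, 41), tug_seconds = c(14.0, 14.5, 10),
                     fell_within_3_months = c(TRUE, FALSE, FALSE))
  expect_equal(label_faller(subj, fall_criterion("bbs")), c(TRUE, FALSE, FALSE))
  expect_equal(label_faller(subj, fall_criterion("bbs", bbs_inclusive = TRUE)),
               c(TRUE, TRUE, FALSE))
  expect_equal(label_faller(subj, fall_criterion("tug")), c(FALSE, TRUE, FALSE))
  expect_equal(label_faller(subj, fall_criterion("history")),
               c(TRUE, FALSE, FALSE))
  expect_error(label_faller(data.frame(tug_seconds = 10), fall_criterion("bbs")),
               class = "swaysense_data_error")
})

test_that("ROC curve handles perfect, uninformative and tied cohorts", {
  perfect <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(perfect$sensitivity == 1 & perfect$fpr == 0))
  expect_equal(roc_auc(perfect), 1)

  flat <- roc_curve(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(flat$sensitivity, flat$fpr) # the diagonal
  expect_equal(roc_auc(flat), 0.5)

  expect_error(roc_curve(1:4, rep(TRUE, 4)),
               class = "swaysense_degenerate_cohort")
})

test_that("AUC equals Mann-Whitney pair counting on random small cohorts", {
  expect_equal(roc_auc(roc_curve(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))),
               0.75)
  set.seed(31)
  for (n in 4:12) {
    for (rep in 1:20) {
      ch <- random_cohort(n)
      expect_equal(roc_auc(roc_curve(ch$scores, ch$labels)),
                   pair_count_auc(ch$scores, ch$labels),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC is invariant under monotone transforms and complements under label inversion", {
  set.seed(32)
  for (rep in 1:25) {
    ch <- random_cohort(10)
    a <- roc_auc(roc_curve(ch$scores, ch$labels))
    expect_equal(roc_auc(roc_curve(exp(3 * ch$scores), ch$labels)), a)
    expect_equal(roc_auc(roc_curve(ch$scores, !ch$labels)), 1 - a,
                 tolerance = 1e-12)
  }
})

test_that("ROC analysis agrees with the pROC reference on a random cohort", {
  set.seed(33)
  scores <- c(rnorm(15, 0.4, 0.12), rnorm(15, 0.16, 0.2))
  labels <- rep(c(TRUE, FALSE), each = 15)
  ours <- roc_analysis(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(ours$auc, as.numeric(ref$auc), tolerance = 1e-12)
  best <- pROC::coords(ref, "best", best.method = "youden", transpose = FALSE)
  expect_equal(ours$youden_j, best$sensitivity + best$specificity - 1,
               tolerance = 1e-9)
})

test_that("Hanley-McNeil SE and CI behave at the boundaries and match direct arithmetic", {
  degenerate <- auc_se_ci(1.0, 10, 10)
  expect_equal(degenerate$se, 0)
  expect_equal(degenerate$ci, c(1, 1))

  mid <- auc_se_ci(0.5, 500, 500)
  expect_equal(mean(mid$ci), 0.5, tolerance = 1e-9)

  hm <- auc_se_ci(0.92, 20, 20)
  expect_equal(hm$se, 0.0460231423, tolerance = 1e-9)
  expect_true(all(hm$ci >= 0 & hm$ci <= 1))
})

test_that("Youden cut-off maximises J and never loses to an enumerated threshold", {
  flat <- roc_curve(rep(0.3, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(youden_cutoff(flat)$youden_j, 0)

  set.seed(34)
  for (rep in 1:30) {
    ch <- random_cohort(9)
    got <- youden_cutoff(roc_curve(ch$scores, ch$labels))
    expect_equal(got$youden_j, exhaustive_youden(ch$scores, ch$labels),
                 tolerance = 1e-12)
    # the returned cut-off reproduces the reported operating point
    cc <- count_confusion(ch$scores, ch$labels, got$cutoff)
    expect_equal(cc$tp / (cc$tp + cc$fn), got$sensitivity)
    expect_equal(cc$tn / (cc$tn + cc$fp), got$specificity)
  }
})

test_that("confusion counts and metrics follow the standard definitions", {
  scores <- c(0.9, 0.7, 0.3, 0.6, 0.2, 0.8)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cc <- confusion(scores, labels, 0.65)
  expect_equal(cc, count_confusion(scores, labels, 0.65))

  m <- diagnostic_metrics(list(tp = 18, fn = 2, tn = 15, fp = 5))
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$accuracy, 0.825)

  expect_equal(diagnostic_metrics(list(tp = 9, fn = 1, tn = 0, fp = 0))$sensitivity,
               0.9)
  # no negatives at all: specificity undefined, flagged not raised
  expect_true(is.na(diagnostic_metrics(list(tp = 9, fn = 1, tn = 0, fp = 0))$specificity))
  perfect <- diagnostic_metrics(list(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
})

test_that("with equal class sizes accuracy equals the mean of sensitivity and specificity", {
  set.seed(35)
  for (rep in 1:20) {
    scores <- runif(16)
    labels <- rep(c(TRUE, FALSE), 8)
    cutoff <- runif(1)
    m <- diagnostic_metrics(confusion(scores, labels, cutoff))
    expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2)
  }
})

test_that("qualitative grading covers [0,1] with the published bands", {
  expect_equal(grade(c(0.92, 0.70, 0.55, 0.30)),
               c("excellent", "good", "moderate", "poor"))
  # band edges: lower edge inclusive
  expect_equal(grade(c(0.81, 0.809, 0.61, 0.609, 0.41, 0.409, 0, 1)),
               c("excellent", "good", "good", "moderate", "moderate", "poor",
                 "poor", "excellent"))
  expect_error(grade(1.2), class = "swaysense_validation_error")
  expect_error(grade(-0.1), class = "swaysense_validation_error")
})

test_that("Welch comparison from summaries matches t.test on raw data", {
  same <- group_compare(0.4, 0.1, 20, 0.4, 0.1, 20)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # the published age contrast is overwhelmingly significant
  age <- group_compare(25.20, 3.19, 20, 79.00, 8.25, 20)
  expect_lt(age$p_value, 0.001)

  set.seed(36)
  x <- rnorm(18, 1, 1)
  y <- rnorm(25, 1.6, 2)
  ours <- group_compare(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(group_compare(1, 0, 20, 2, 1, 20),
               class = "swaysense_validation_error")
})
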