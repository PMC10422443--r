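#' Cohort pipeline and diagnostic report
#'
#' Ties the stages together: per subject, raw acceleration is reduced to
#' sway scores and attached to the clinical record; per cohort, every
#' anatomical direction (AP, ML, V and their mean) is evaluated as a
#' fall-risk marker under each requested criterion, producing a report with
#' AUC, confidence interval, Youden cut-off, sensitivity, specificity,
#' accuracy and grades per direction-criterion cell.
#'
#' @name pipeline
NULL

REPORT_SCHEMA_VERSION <- "1.0"

#' Run configuration
#'
#' @param map Axis mapping from [axis_map()].
#' @param rate Accelerometer sampling rate (Hz).
#' @param tilt_rate Tilt computation rate (Hz).
#' @param criteria Named list of [fall_criterion()] objects to evaluate.
#' @return A list of class `run_config`.
#' @export
run_config <- function(map = axis_map(), rate = 50, tilt_rate = 25,
                       criteria = list(bbs = fall_criterion("bbs"),
                                       tug = fall_criterion("tug"))) {
  stopifnot(rate > 0, tilt_rate > 0, length(criteria) >= 1)
  if (is.null(names(criteria)) || any(names(criteria) == "")) {
    stop_swaysense("criteria must be a named list", "swaysense_config_error")
  }
  structure(list(map = map, rate = rate, tilt_rate = tilt_rate,
                 criteria = criteria),
            class = "run_config")
}

#' Score one subject's trial and attach it to the clinical record
#'
#' @param accel_csv Path to the subject's accelerometer CSV.
#' @param metadata One-row data frame (or list) with the subject's clinical
#'   record: `subject_id`, `group`, `bbs_score`, `tug_seconds`,
#'   `fell_within_3_months`.
#' @param config A [run_config()].
#' @return The record as a one-row data frame with `score_AP`, `score_ML`,
#'   `score_V`, `score_mean` appended.
#' @export
run_subject <- function(accel_csv, metadata, config = run_config()) {
  metadata <- as.data.frame(metadata)
  needed <- c("subject_id", "group", "bbs_score", "tug_seconds",
              "fell_within_3_months")
  if (nrow(metadata) != 1 || !all(needed %in% names(metadata))) {
    stop_swaysense("metadata must be one row with subject_id, group, bbs_score, tug_seconds, fell_within_3_months",
                   "swaysense_data_error")
  }
  feats <- tryCatch(
    extract_features(read_accel_csv(accel_csv), map = config$map,
                     rate = config$rate, tilt_rate = config$tilt_rate),
    swaysense_error = function(e) {
      stop_swaysense(sprintf("subject %s: %s", metadata$subject_id, conditionMessage(e)),
                     class(e)[1])
    }
  )
  metadata$score_AP <- feats$axis_scores[["AP"]]
  metadata$score_ML <- feats$axis_scores[["ML"]]
  metadata$score_V <- feats$axis_scores[["V"]]
  metadata$score_mean <- feats$mean_score
  metadata
}

#' Evaluate a scored cohort under every direction and criterion
#'
#' @param subjects Data frame of subject records with the four score
#'   columns (`score_AP`, `score_ML`, `score_V`, `score_mean`), e.g. from
#'   [simulate_cohort()] or rows of [run_subject()].
#' @param config A [run_config()]; its `criteria` list selects the fall
#'   labelling modes evaluated.
#' @return An object of class `sway_report`: nested list
#'   `results[[criterion]][[direction]]`, each a [roc_analysis()] summary.
#' @export
run_cohort <- function(subjects, config = run_config()) {
  if (nrow(subjects) < 2) {
    stop_swaysense("cohort needs at least 2 subjects", "swaysense_validation_error")
  }
  directions <- c(AP = "score_AP", ML = "score_ML", V = "score_V",
                  mean = "score_mean")
  missing_cols <- setdiff(directions, names(subjects))
  if (length(missing_cols) > 0) {
    stop_swaysense(paste("missing score columns:", paste(missing_cols, collapse = ", ")),
                   "swaysense_data_error")
  }
  results <- lapply(config$criteria, function(crit) {
    labels <- label_faller(subjects, crit)
    lapply(directions, function(col) roc_analysis(subjects[[col]], labels))
  })
  structure(
    list(schema_version = REPORT_SCHEMA_VERSION,
         n_subjects = nrow(subjects), results = results),
    class = "sway_report"
  )
}

#' @export
print.sway_report <- function(x, ...) {
  cat("Fall-risk diagnostic report (", x$n_subjects, " subjects)\n", sep = "")
  cat(sprintf("%-10s %-5s %6s %13s %7s %6s %6s %6s\n",
              "criterion", "dir", "AUC", "95% CI", "cutoff", "sens", "spec", "acc"))
  for (crit in names(x$results)) {
    for (dir in names(x$results[[crit]])) {
      r <- x$results[[crit]][[dir]]
      cat(sprintf("%-10s %-5s %6.3f [%.3f,%.3f] %7.3f %6.3f %6.3f %6.3f\n",
                  crit, dir, r$auc, r$ci95[1], r$ci95[2], r$cutoff,
                  r$metrics$sensitivity, r$metrics$specificity,
                  r$metrics$accuracy))
    }
  }
  invisible(x)
}

#' Write a diagnostic report as JSON
#'
#' @param report A `sway_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sway_report"))
  out <- list(schema_version = report$schema_version,
              n_subjects = report$n_subjects)
  out$results <- lapply(report$results, function(by_dir) {
    lapply(by_dir, function(r) {
      list(
        auc = r$auc, auc_grade = r$auc_grade, se = r$se,
        ci95 = list(lower = r$ci95[1], upper = r$ci95[2]),
        n_fallers = r$n_pos, n_non_fallers = r$n_neg,
        cutoff = r$cutoff, youden_j = r$youden_j,
        sensitivity = r$metrics$sensitivity,
        specificity = r$metrics$specificity,
        accuracy = r$metrics$accuracy,
        grades = as.list(r$metrics$grades)
      )
    })
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read subject metadata CSV
#'
#' @param path CSV with header
#'   `subject_id,group,bbs_score,tug_seconds,fell_within_3_months`.
#' @return Validated data frame.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) {
    stop_swaysense(sprintf("no such file: %s", path), "swaysense_parse_error")
  }
  df <- utils::read.csv(path)
  needed <- c("subject_id", "group", "bbs_score", "tug_seconds",
              "fell_within_3_months")
  if (!all(needed %in% names(df))) {
    stop_swaysense(paste("metadata needs columns:", paste(needed, collapse = ", ")),
                   "swaysense_parse_error")
  }
  if (any(df$bbs_score < 0 | df$bbs_score > 56, na.rm = TRUE)) {
    stop_swaysense("bbs_score outside [0, 56]", "swaysense_range_error")
  }
  if (any(df$tug_seconds <= 0, na.rm = TRUE)) {
    stop_swaysense("tug_seconds must be positive", "swaysense_range_error")
  }
  df$fell_within_3_months <- as.logical(df$fell_within_3_months)
  df
}
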