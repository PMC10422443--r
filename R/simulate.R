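#' Synthetic cohorts and signals
#'
#' Seeded generators standing in for the clinical study data: score-level
#' cohorts whose mean-direction sway scores follow the published group
#' moments (Gaussian, negatives permitted, since only mean and SD are
#' reported and truncation would bias the moments being matched), and raw
#' 3-axis accelerometer signals — a gravity-oriented baseline plus
#' band-limited random-phase oscillation plus white noise — whose
#' pipeline-derived sway scores are controllable via amplitude calibration.
#'
#' @name synthetic-cohort
NULL

#' Published group parameters
#'
#' Default per-group moments for the two study groups: healthy young adults
#' and older adults with mild cognitive impairment (MCI). The sway-score
#' moments depend on the clinical test during which sway was recorded
#' (`context`): BBS-context healthy 0.16 +/- 0.20 G vs MCI 0.41 +/- 0.12 G;
#' TUG-context healthy 0.36 +/- 0.08 G vs MCI 0.47 +/- 0.12 G. Clinical
#' scores: BBS 54.61 +/- 1.33 vs 39 +/- 5.88; TUG 9.42 +/- 0.25 s vs
#' 14.11 +/- 1.37 s; 20 subjects per group.
#'
#' @param label `"healthy"` or `"mci"`.
#' @param context `"bbs"` or `"tug"`: which trial the sway score comes from.
#' @param n Cohort size.
#' @return A list of class `group_params`.
#' @export
group_params <- function(label = c("healthy", "mci"),
                         context = c("bbs", "tug"), n = 20) {
  label <- match.arg(label)
  context <- match.arg(context)
  stopifnot(n >= 1)
  defaults <- list(
    healthy = list(sway = list(bbs = c(0.16, 0.20), tug = c(0.36, 0.08)),
                   bbs = c(54.61, 1.33), tug = c(9.42, 0.25)),
    mci     = list(sway = list(bbs = c(0.41, 0.12), tug = c(0.47, 0.12)),
                   bbs = c(39, 5.88), tug = c(14.11, 1.37))
  )[[label]]
  structure(
    list(
      label = label, context = context, n = n,
      sway_mean = defaults$sway[[context]][1], sway_sd = defaults$sway[[context]][2],
      bbs_mean = defaults$bbs[1], bbs_sd = defaults$bbs[2],
      tug_mean = defaults$tug[1], tug_sd = defaults$tug[2]
    ),
    class = "group_params"
  )
}

#' Draw sway scores for one group
#'
#' Independent Gaussian draws at the group's sway mean and SD;
#' reproducible under a fixed seed.
#'
#' @param params A [group_params()] object.
#' @param seed Optional integer seed.
#' @param n Number of draws (defaults to `params$n`).
#' @return Numeric vector of sway scores (G).
#' @export
sample_scores <- function(params, seed = NULL, n = params$n) {
  stopifnot(inherits(params, "group_params"))
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, params$sway_mean, params$sway_sd)
}

#' Draw clinical scores for one group
#'
#' Gaussian draws at the group's clinical moments; BBS rounded to integer
#' and clipped to `[0, 56]`, TUG clipped positive.
#'
#' @inheritParams sample_scores
#' @return A data frame with columns `bbs_score` (integer) and
#'   `tug_seconds`.
#' @export
sample_clinical <- function(params, seed = NULL, n = params$n) {
  stopifnot(inherits(params, "group_params"))
  if (!is.null(seed)) set.seed(seed)
  bbs <- pmin(56, pmax(0, round(stats::rnorm(n, params$bbs_mean, params$bbs_sd))))
  tug <- pmax(0.01, stats::rnorm(n, params$tug_mean, params$tug_sd))
  data.frame(bbs_score = as.integer(bbs), tug_seconds = tug)
}

#' Specification of a synthetic accelerometer signal
#'
#' The generated signal is `gravity + sway + noise` per axis: a constant
#' unit-gravity baseline, a sum of `n_components` random-phase sinusoids
#' with frequencies uniform in the sway band (default 0.1-2 Hz, the typical
#' postural-sway bandwidth) scaled to the per-axis amplitude, and white
#' Gaussian noise.
#'
#' @param duration Trial length in seconds (at least 3).
#' @param rate Sampling rate in Hz.
#' @param gravity Baseline orientation as a unit gravity vector (G).
#' @param amplitude Per-axis sway amplitude in G (length 1 or 3, peak of the
#'   oscillatory part).
#' @param band Sway frequency band in Hz.
#' @param noise_sd White-noise SD in G.
#' @param n_components Sinusoids per axis.
#' @param seed Optional integer seed.
#' @return A list of class `signal_spec`.
#' @export
signal_spec <- function(duration = 30, rate = 50, gravity = c(0, 0, 1),
                        amplitude = 0.1, band = c(0.1, 2), noise_sd = 0.005,
                        n_components = 3, seed = NULL) {
  amplitude <- rep_len(amplitude, 3)
  stopifnot(duration >= 3, rate > 0, length(gravity) == 3,
            all(amplitude >= 0), length(band) == 2, band[1] > 0,
            band[1] <= band[2], noise_sd >= 0, n_components >= 1)
  if (abs(sqrt(sum(gravity^2)) - 1) > 1e-6) {
    stop_swaysense("gravity must be a unit vector", "swaysense_config_error")
  }
  peak <- max(abs(gravity)) + max(amplitude) + 6 * noise_sd
  if (peak > ACCEL_FULL_SCALE_G) {
    stop_swaysense("signal specification exceeds the +/-8 G sensor range",
                   "swaysense_range_error")
  }
  structure(
    list(duration = duration, rate = rate, gravity = gravity,
         amplitude = amplitude, band = band, noise_sd = noise_sd,
         n_components = n_components, seed = seed),
    class = "signal_spec"
  )
}

#' Generate a synthetic accelerometer series
#'
#' @param spec A [signal_spec()].
#' @return An acceleration data frame (`t`, `ax`, `ay`, `az`) valid for the
#'   feature pipeline.
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  axes <- lapply(1:3, function(i) {
    sway <- 0
    if (spec$amplitude[i] > 0) {
      freq <- stats::runif(spec$n_components, spec$band[1], spec$band[2])
      phase <- stats::runif(spec$n_components, 0, 2 * pi)
      osc <- rowSums(vapply(seq_len(spec$n_components),
                            function(k) sin(2 * pi * freq[k] * t + phase[k]),
                            numeric(n)))
      sway <- spec$amplitude[i] * osc / spec$n_components
    } else {
      # burn the stream so amplitude zero still consumes this axis's draws
      stats::runif(2 * spec$n_components)
    }
    noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    spec$gravity[i] + sway + noise
  })
  out <- data.frame(t = t, ax = axes[[1]], ay = axes[[2]], az = axes[[3]])
  # clip the rare noise excursion rather than emit out-of-scale samples
  for (col in c("ax", "ay", "az")) {
    out[[col]] <- pmin(ACCEL_FULL_SCALE_G, pmax(-ACCEL_FULL_SCALE_G, out[[col]]))
  }
  out
}

pipeline_mean_score <- function(amplitude, spec) {
  s <- spec
  s$amplitude <- rep_len(amplitude, 3)
  extract_features(generate_signal(s), rate = s$rate)$mean_score
}

#' Calibrate the signal amplitude for a target sway score
#'
#' Monotone one-dimensional search for the per-axis sway amplitude whose
#' pipeline-derived mean sway score matches the target within 2% (relative,
#' with a 1e-4 G absolute floor for near-zero targets). The search holds
#' the spec's seed fixed, so the mapping from amplitude to score is
#' deterministic.
#'
#' @param target Target mean sway score in G (non-negative).
#' @param spec A [signal_spec()] template; its `amplitude` field is ignored.
#' @param tol Relative tolerance on the achieved score.
#' @return The calibrated amplitude in G.
#' @export
calibrate_amplitude <- function(target, spec, tol = 0.02) {
  stopifnot(inherits(spec, "signal_spec"), target >= 0)
  if (target == 0) return(0)
  abs_tol <- max(tol * target, 1e-4)
  score_at <- function(a) pipeline_mean_score(a, spec)
  # expand to bracket the target
  hi <- max(target, 0.01)
  hi_limit <- ACCEL_FULL_SCALE_G - max(abs(spec$gravity)) - 6 * spec$noise_sd
  while (score_at(hi) < target) {
    hi <- hi * 2
    if (hi > hi_limit) {
      stop_swaysense("target score unreachable within the +/-8 G sensor range",
                     "swaysense_range_error")
    }
  }
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    val <- score_at(mid)
    if (abs(val - target) <= abs_tol) return(mid)
    if (val < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a two-group study cohort
#'
#' Draws per-subject sway scores and clinical scores from the published
#' group moments ([group_params()]). At score level the drawn mean-direction
#' score is attached directly (all three axis scores set equal to it, since
#' only mean-direction moments are published). With `signal = TRUE` each
#' subject additionally gets a raw accelerometer trial whose amplitude is
#' calibrated so the pipeline recovers the subject's (non-negative part of
#' the) drawn score, and the attached scores are the ones measured by
#' [extract_features()] on that trial. One global seed fans out to
#' per-subject substreams, so a subject's data do not depend on cohort
#' size ordering.
#'
#' @param n_per_group Subjects per group.
#' @param context `"bbs"` or `"tug"` sway-score context.
#' @param seed Integer seed.
#' @param signal If `TRUE`, generate and score raw signals per subject.
#' @param signal_template A [signal_spec()] used for every subject's trial.
#' @param out_dir Optional directory; when given (with `signal = TRUE`),
#'   per-subject accelerometer CSVs and the metadata CSV are written there.
#' @return A data frame with one row per subject: `subject_id`, `group`,
#'   `bbs_score`, `tug_seconds`, `fell_within_3_months`, `score_AP`,
#'   `score_ML`, `score_V`, `score_mean`.
#' @export
simulate_cohort <- function(n_per_group = 20, context = c("bbs", "tug"),
                            seed = 1, signal = FALSE,
                            signal_template = signal_spec(duration = 12, noise_sd = 0),
                            out_dir = NULL) {
  context <- match.arg(context)
  set.seed(seed)
  groups <- list(
    healthy = group_params("healthy", context, n_per_group),
    mci = group_params("mci", context, n_per_group)
  )
  subject_seeds <- sample.int(.Machine$integer.max - 1, 2 * n_per_group)
  rows <- list()
  idx <- 0
  for (g in names(groups)) {
    p <- groups[[g]]
    clin <- sample_clinical(p, seed = subject_seeds[idx + 1])
    targets <- sample_scores(p, seed = subject_seeds[idx + 2] %% .Machine$integer.max)
    # fall history mirrors the study inclusion criteria: every MCI
    # participant had a fall within 3 months, no healthy participant did
    df <- data.frame(
      subject_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
      group = g,
      bbs_score = clin$bbs_score,
      tug_seconds = clin$tug_seconds,
      fell_within_3_months = g == "mci",
      target_score = targets
    )
    rows[[g]] <- df
    idx <- idx + n_per_group
  }
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL

  if (!signal) {
    subjects$score_AP <- subjects$score_ML <- subjects$score_V <-
      subjects$score_mean <- subjects$target_score
  } else {
    n <- nrow(subjects)
    per_subject_seed <- sample.int(.Machine$integer.max - 1, n)
    scores <- matrix(NA_real_, n, 4,
                     dimnames = list(NULL, c("AP", "ML", "V", "mean")))
    if (!is.null(out_dir) && !dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
    }
    for (i in seq_len(n)) {
      s <- signal_template
      s$seed <- per_subject_seed[i]
      amp <- calibrate_amplitude(max(0, subjects$target_score[i]), s)
      s$amplitude <- rep_len(amp, 3)
      sig <- generate_signal(s)
      feats <- extract_features(sig, rate = s$rate)
      scores[i, ] <- c(feats$axis_scores[c("AP", "ML", "V")], feats$mean_score)
      if (!is.null(out_dir)) {
        write_accel_csv(sig, file.path(out_dir, paste0(subjects$subject_id[i], ".csv")))
      }
    }
    subjects$score_AP <- scores[, "AP"]
    subjects$score_ML <- scores[, "ML"]
    subjects$score_V <- scores[, "V"]
    subjects$score_mean <- scores[, "mean"]
  }
  if (!is.null(out_dir)) {
    utils::write.csv(
      subjects[c("subject_id", "group", "bbs_score", "tug_seconds",
                 "fell_within_3_months")],
      file.path(out_dir, "metadata.csv"), row.names = FALSE, quote = FALSE
    )
  }
  subjects
}

#' Closed-form AUC of two Gaussian score distributions
#'
#' For scores distributed N(mean0, sd0) in negatives and N(mean1, sd1) in
#' positives, the probability a random positive outscores a random negative
#' is `pnorm((mean1 - mean0) / sqrt(sd0^2 + sd1^2))`. Used as the
#' simulation oracle.
#'
#' @param mean0,sd0 Negative-group (healthy) moments.
#' @param mean1,sd1 Positive-group (faller) moments.
#' @return The binormal AUC.
#' @export
binormal_auc <- function(mean0, sd0, mean1, sd1) {
  stats::pnorm((mean1 - mean0) / sqrt(sd0^2 + sd1^2))
}
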