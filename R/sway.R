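#' Windowed sway features
#'
#' Postural sway is summarised per device axis by two windowed series:
#' AMP, the per-second amplitude (max minus min within each complete
#' one-second window — the differencing also removes the constant gravity
#' offset), and RMS, the root mean square of consecutive non-overlapping
#' groups of three AMP values, i.e. one value per 3 s of recording. The
#' scalar sway score of an axis is the mean of its RMS series over the
#' trial, in G, and the mean score averages the three anatomical axes.
#'
#' @name sway-features
NULL

#' Per-second amplitude of a signal
#'
#' Splits a one-axis sample sequence into complete non-overlapping windows of
#' one second (`rate` samples, aligned to the start) and returns max minus
#' min of each; a trailing partial window is dropped.
#'
#' @param x Numeric sample vector for one axis.
#' @param rate Sampling rate in Hz (samples per window).
#' @return Numeric vector of amplitudes, one per complete second.
#' @export
#' @examples
#' amp_per_second(c(0.12, 0.05, 0.31, 0.20), rate = 4) # 0.26
amp_per_second <- function(x, rate) {
  if (length(x) == 0) {
    stop_swaysense("empty input series", "swaysense_empty_series")
  }
  n_win <- length(x) %/% rate
  if (n_win == 0) {
    return(numeric(0))
  }
  m <- matrix(x[seq_len(n_win * rate)], nrow = rate)
  apply(m, 2, max) - apply(m, 2, min)
}

#' RMS over consecutive groups of amplitudes
#'
#' Collapses an AMP sequence into its root mean square over complete
#' non-overlapping groups of `group_size` values (default three, so the
#' output updates every 3 s for per-second input).
#'
#' @param amp Numeric amplitude vector.
#' @param group_size Values per group.
#' @return Numeric vector of RMS values, one per complete group.
#' @export
#' @examples
#' rms_of_groups(c(3, 4, 0)) # sqrt(25/3)
rms_of_groups <- function(amp, group_size = 3) {
  stopifnot(group_size >= 1)
  n_grp <- length(amp) %/% group_size
  if (n_grp == 0) {
    warning("fewer amplitude values than one complete group; empty RMS output")
    return(numeric(0))
  }
  m <- matrix(amp[seq_len(n_grp * group_size)]^2, nrow = group_size)
  sqrt(colMeans(m))
}

#' Device-axis to anatomical-direction mapping
#'
#' For the default chest placement the patch lies flat on the sternum, so the
#' device Z axis points anterior-posteriorly (AP), X medial-laterally (ML)
#' and Y vertically (V). The mapping must be a bijection of X/Y/Z onto
#' AP/ML/V.
#'
#' @param X,Y,Z Anatomical direction carried by each device axis.
#' @return Named character vector mapping device axes to directions.
#' @export
axis_map <- function(X = "ML", Y = "V", Z = "AP") {
  map <- c(X = X, Y = Y, Z = Z)
  if (!setequal(map, c("AP", "ML", "V"))) {
    stop_swaysense("axis map must be a bijection onto AP, ML, V",
                   "swaysense_config_error")
  }
  map
}

#' Extract the windowed sway feature set of one trial
#'
#' Applies [amp_per_second()] and [rms_of_groups()] independently to each
#' device axis, relabels axes anatomically, computes the analogous
#' per-second amplitude of the tilt-angle series (reported, but not scored),
#' and reduces each axis to its scalar sway score (mean of the RMS series,
#' in G). A trial of duration T yields `floor(T)` AMP and `floor(T/3)` RMS
#' values per axis, so at least 3 s of data are required.
#'
#' @param series Acceleration data frame (`t`, `ax`, `ay`, `az`), 50 Hz.
#' @param tilt Optional precomputed [tilt_series()] output; computed from
#'   `series` when `NULL`.
#' @param map Axis mapping from [axis_map()].
#' @param rate Sampling rate in Hz.
#' @param tilt_rate Tilt series rate in Hz.
#' @return An object of class `sway_features`: list with `amp` and `rms`
#'   data frames (columns `window_start`, `AP`, `ML`, `V`), `tilt_amp`
#'   (per-second amplitude of theta/psi/phi), `axis_scores` (named numeric,
#'   G), and `mean_score`.
#' @export
extract_features <- function(series, tilt = NULL, map = axis_map(),
                             rate = 50, tilt_rate = 25) {
  series <- validate_accel_series(series)
  n_sec <- nrow(series) %/% rate
  if (n_sec < 3) {
    stop_swaysense("trial shorter than 3 s: no complete RMS window",
                   "swaysense_insufficient_data")
  }
  if (is.null(tilt)) {
    tilt <- tilt_series(series, tilt_rate = tilt_rate, rate = rate)
  }

  device_cols <- c(X = "ax", Y = "ay", Z = "az")
  amp <- lapply(device_cols, function(col) amp_per_second(series[[col]], rate))
  rms <- lapply(amp, rms_of_groups)
  names(amp) <- names(rms) <- unname(map[names(device_cols)])

  dirs <- c("AP", "ML", "V")
  amp_df <- data.frame(window_start = seq_len(n_sec) - 1)
  rms_df <- data.frame(window_start = 3 * (seq_len(n_sec %/% 3) - 1))
  for (d in dirs) {
    amp_df[[d]] <- amp[[d]]
    rms_df[[d]] <- rms[[d]]
  }

  tilt_amp <- data.frame(window_start = seq_len(nrow(tilt) %/% tilt_rate) - 1)
  for (col in c("theta", "psi", "phi")) {
    tilt_amp[[col]] <- amp_per_second(tilt[[col]], tilt_rate)
  }

  axis_scores <- vapply(rms_df[dirs], mean, numeric(1))
  structure(
    list(
      amp = amp_df, rms = rms_df, tilt_amp = tilt_amp,
      axis_scores = axis_scores, mean_score = mean(axis_scores)
    ),
    class = "sway_features"
  )
}

#' @export
print.sway_features <- function(x, ...) {
  cat("Sway features:", nrow(x$amp), "s of AMP,", nrow(x$rms), "RMS windows\n")
  cat("Axis scores (G):",
      paste(sprintf("%s=%.4f", names(x$axis_scores), x$axis_scores),
            collapse = ", "), "\n")
  cat(sprintf("Mean score (G): %.4f\n", x$mean_score))
  invisible(x)
}

#' Write a sway feature set
#'
#' Writes the windowed series as a long CSV (`window_start,axis,amp,rms`,
#' where `rms` is the value of the 3 s window containing that second, `NA`
#' for trailing seconds without a complete group) and, optionally, the
#' scalar score summary as JSON.
#'
#' @param features A `sway_features` object.
#' @param path Output CSV path.
#' @param summary_path Optional JSON path for the per-subject score summary.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, summary_path = NULL) {
  stopifnot(inherits(features, "sway_features"))
  dirs <- c("AP", "ML", "V")
  n_sec <- nrow(features$amp)
  long <- do.call(rbind, lapply(dirs, function(d) {
    rms_idx <- (features$amp$window_start %/% 3) + 1
    data.frame(
      window_start = features$amp$window_start,
      axis = d,
      amp = features$amp[[d]],
      rms = ifelse(rms_idx <= nrow(features$rms), features$rms[[d]][rms_idx], NA)
    )
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(feature_summary(features), summary_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Scalar score summary of a feature set
#'
#' @param features A `sway_features` object.
#' @return A list with `axis_scores` and `mean_score`.
#' @export
feature_summary <- function(features) {
  stopifnot(inherits(features, "sway_features"))
  list(
    axis_scores = as.list(features$axis_scores),
    mean_score = features$mean_score,
    n_seconds = nrow(features$amp),
    n_rms_windows = nrow(features$rms)
  )
}
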