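#' Acceleration series I/O and validation
#'
#' The raw input is a CSV with header `t,ax,ay,az`: time in seconds
#' (monotone increasing) and accelerations in G, from a sensor configured
#' with a +/-8 G full scale. Values outside that range are rejected.
#'
#' @name accel-io
NULL

ACCEL_FULL_SCALE_G <- 8

validate_accel_series <- function(series) {
  required <- c("t", "ax", "ay", "az")
  if (!is.data.frame(series) || !all(required %in% names(series))) {
    stop_swaysense("acceleration series needs columns t, ax, ay, az",
                   "swaysense_parse_error")
  }
  if (nrow(series) == 0) {
    stop_swaysense("empty acceleration series", "swaysense_empty_series")
  }
  for (col in required) {
    if (!is.numeric(series[[col]]) || any(!is.finite(series[[col]]))) {
      stop_swaysense(sprintf("column '%s' must be finite numeric", col),
                     "swaysense_parse_error")
    }
  }
  if (is.unsorted(series$t, strictly = TRUE)) {
    stop_swaysense("timestamps must be strictly increasing", "swaysense_parse_error")
  }
  a <- c(series$ax, series$ay, series$az)
  if (any(abs(a) > ACCEL_FULL_SCALE_G)) {
    stop_swaysense(
      sprintf("acceleration outside the +/-%d G sensor full scale", ACCEL_FULL_SCALE_G),
      "swaysense_range_error"
    )
  }
  series[required]
}

#' Read an accelerometer CSV
#'
#' @param path Path to a CSV with header `t,ax,ay,az` (seconds, G).
#' @return A validated data frame with columns `t`, `ax`, `ay`, `az`.
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) {
    stop_swaysense(sprintf("no such file: %s", path), "swaysense_parse_error")
  }
  raw <- utils::read.csv(path, colClasses = "numeric")
  validate_accel_series(raw)
}

#' Write an accelerometer CSV
#'
#' @param series A data frame with columns `t`, `ax`, `ay`, `az`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(series, path) {
  series <- validate_accel_series(series)
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
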