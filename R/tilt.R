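#' Tilt estimation from triaxial acceleration
#'
#' A chest-worn accelerometer at rest measures only gravity, so the direction
#' of the measured acceleration vector encodes the inclination of each device
#' axis. These functions convert 3-axis acceleration samples (in G) into
#' inclination angles in degrees: the planar arctangent form, the
#' gravity-vector arccosine form, and the independent per-axis inclination
#' form, plus a quadrant-resolution step that extends the angles to the full
#' 360-degree range using the signs of the acceleration components.
#'
#' All functions are vectorised over samples: `ax`, `ay`, `az` may be numeric
#' vectors of equal length.
#'
#' @name tilt
NULL

RAD2DEG <- 180 / pi

stop_swaysense <- function(msg, class) {
  stop(structure(
    class = c(class, "swaysense_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_sample <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az)) {
    stop_swaysense("ax, ay, az must have equal length", "swaysense_validation_error")
  }
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az))) {
    stop_swaysense("acceleration components must be finite", "swaysense_validation_error")
  }
  if (any(ax == 0 & ay == 0 & az == 0)) {
    stop_swaysense(
      "all-zero acceleration vector: orientation is undefined (free fall)",
      "swaysense_undefined_orientation"
    )
  }
  invisible(NULL)
}

#' Planar tilt angle from the X and Y accelerations
#'
#' Computes `atan(ax / ay)` in degrees. This is the printed planar form of
#' the triple-axis tilt calculation; it is exposed for parity but the main
#' pipeline uses [independent_inclination()], whose denominators include all
#' remaining axes. A zero `ay` is handled as the signed 90-degree limit.
#'
#' @param ax,ay,az Acceleration along the device X, Y and Z axes, in G.
#'   `az` only participates in validation (an all-zero vector is rejected).
#' @return Angle(s) in degrees, in `[-90, 90]`.
#' @export
#' @examples
#' triple_axis_theta(1, 1, 0) # 45
triple_axis_theta <- function(ax, ay, az = 1) {
  check_sample(ax, ay, az)
  out <- atan(ax / ay) * RAD2DEG
  zero <- ay == 0
  out[zero] <- sign(ax[zero]) * 90
  out
}

#' Tilt of the device Z axis from the gravity vector
#'
#' Computes `acos(az / ||a||)` in degrees, the angle between the measured
#' acceleration (assumed pure gravity) and the device Z axis; 0 when the
#' device lies flat with Z up, 180 when inverted.
#'
#' @inheritParams triple_axis_theta
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @export
triple_axis_phi <- function(ax, ay, az) {
  check_sample(ax, ay, az)
  acos(az / sqrt(ax^2 + ay^2 + az^2)) * RAD2DEG
}

#' Independent per-axis inclination angles
#'
#' Computes the inclination of each device axis independently:
#' `theta = atan(ax / sqrt(ay^2 + az^2))`,
#' `psi = atan(ay / sqrt(ax^2 + az^2))`,
#' `phi = atan(sqrt(ax^2 + ay^2) / az)`.
#' Zero denominators are handled as signed 90-degree limits (via the
#' two-argument arctangent, which is exact there). The result carries
#' `quadrant_resolved = FALSE`: theta and psi lie in `[-90, 90]` and phi in
#' `[0, 180]`; use [resolve_quadrant()] for the full range.
#'
#' @inheritParams triple_axis_theta
#' @return A data frame with columns `theta`, `psi`, `phi` (degrees) and
#'   attribute `quadrant_resolved = FALSE`.
#' @export
#' @examples
#' independent_inclination(0, 0, 1) # upright: all zero
independent_inclination <- function(ax, ay, az) {
  check_sample(ax, ay, az)
  out <- data.frame(
    theta = atan2(ax, sqrt(ay^2 + az^2)) * RAD2DEG,
    psi   = atan2(ay, sqrt(ax^2 + az^2)) * RAD2DEG,
    phi   = atan2(sqrt(ax^2 + ay^2), az) * RAD2DEG
  )
  attr(out, "quadrant_resolved") <- FALSE
  out
}

#' Extend inclination angles to the full 360-degree range
#'
#' The independent inclination formulas fold every orientation into the upper
#' hemisphere. This step restores the quadrant from the signs of the
#' acceleration components using two-argument arctangent semantics: the
#' plane-projection denominator of theta and psi carries the sign of `az`, so
#' for `az < 0` the angles are reflected through `+/-(180 - |angle|)`; phi is
#' already full-range via `atan2(sqrt(ax^2 + ay^2), az)`. The operation is
#' idempotent: a resolved input is returned unchanged.
#'
#' @inheritParams triple_axis_theta
#' @param angles Optionally, the output of [independent_inclination()] for
#'   the same samples; if it is already quadrant-resolved it is returned
#'   as is.
#' @return A data frame with columns `theta`, `psi`, `phi` in `(-180, 180]`
#'   degrees and attribute `quadrant_resolved = TRUE`.
#' @export
resolve_quadrant <- function(ax, ay, az, angles = NULL) {
  if (!is.null(angles) && isTRUE(attr(angles, "quadrant_resolved"))) {
    return(angles)
  }
  check_sample(ax, ay, az)
  # sign carried by the denominator; az == 0 stays in the principal range
  dsign <- ifelse(az < 0, -1, 1)
  out <- data.frame(
    theta = atan2(ax, dsign * sqrt(ay^2 + az^2)) * RAD2DEG,
    psi   = atan2(ay, dsign * sqrt(ax^2 + az^2)) * RAD2DEG,
    phi   = atan2(sqrt(ax^2 + ay^2), az) * RAD2DEG
  )
  attr(out, "quadrant_resolved") <- TRUE
  out
}

#' Tilt-angle series from an acceleration series
#'
#' Decimates a regularly sampled acceleration series (nominally 50 Hz) to the
#' tilt computation rate (default 25 Hz, i.e. every second sample, no
#' anti-alias filter) and applies [independent_inclination()] followed by
#' [resolve_quadrant()] to every retained sample.
#'
#' @param series A data frame with columns `t` (seconds, monotone increasing,
#'   regularly spaced), `ax`, `ay`, `az` (G), as returned by
#'   [read_accel_csv()] or [generate_signal()].
#' @param tilt_rate Tilt output rate in Hz; must divide the sampling rate.
#' @param rate Sampling rate in Hz of `series`.
#' @param tol Relative tolerance on sampling-interval regularity.
#' @return A data frame with columns `t`, `theta`, `psi`, `phi` (degrees),
#'   quadrant-resolved.
#' @export
tilt_series <- function(series, tilt_rate = 25, rate = 50, tol = 0.01) {
  series <- validate_accel_series(series)
  dt <- diff(series$t)
  if (length(dt) > 0 && any(abs(dt - 1 / rate) > tol / rate)) {
    stop_swaysense(
      sprintf("timestamps deviate from regular %g Hz sampling beyond tolerance", rate),
      "swaysense_sampling_error"
    )
  }
  step <- rate / tilt_rate
  if (abs(step - round(step)) > 1e-9 || step < 1) {
    stop_swaysense("tilt_rate must divide the sampling rate", "swaysense_config_error")
  }
  keep <- seq(1, nrow(series), by = round(step))
  sub <- series[keep, , drop = FALSE]
  ang <- resolve_quadrant(sub$ax, sub$ay, sub$az)
  cbind(t = sub$t, ang)
}
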