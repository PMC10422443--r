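test_that("per-second amplitude is max minus min over complete windows", {
  expect_equal(amp_per_second(c(0.12, 0.05, 0.31, 0.20), rate = 4), 0.26)
  expect_equal(amp_per_second(rep(0.7, 100), rate = 50), c(0, 0))
  # 2.5 s at 50 Hz: exactly two complete windows, trailing half dropped
  expect_length(amp_per_second(runif(125), rate = 50), 2)
  expect_error(amp_per_second(numeric(0), rate = 50),
               class = "swaysense_empty_series")
})

test_that("RMS of amplitude groups collapses complete groups of three", {
  expect_equal(rms_of_groups(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(rms_of_groups(c(3, 4, 0)), 2.8867513459, tolerance = 1e-9)
  expect_length(rms_of_groups(runif(7)), 2)
  expect_warning(out <- rms_of_groups(c(1, 2)), "fewer")
  expect_length(out, 0)
})

test_that("windowed features are translation-invariant and scale with the dynamic part", {
  set.seed(21)
  x <- runif(200)
  # adding a constant offset (gravity) leaves AMP unchanged
  expect_equal(amp_per_second(x + 0.98, rate = 50), amp_per_second(x, rate = 50))
  # scaling the dynamic part scales AMP, RMS and the score exactly
  base <- x - mean(x)
  for (k in c(1, 2.5, 7)) {
    expect_equal(amp_per_second(k * base, 50), k * amp_per_second(base, 50))
    expect_equal(rms_of_groups(amp_per_second(k * base, 50)),
                 k * rms_of_groups(amp_per_second(base, 50)))
  }
})

test_that("a T-second trial yields floor(T) AMP and floor(T/3) RMS values per axis", {
  set.seed(22)
  for (dur in c(3.0, 4.7, 6.2, 9.96, 13.5)) {
    n <- floor(dur * 50)
    x <- runif(n)
    amp <- amp_per_second(x, 50)
    expect_length(amp, floor(n / 50))
    if (length(amp) >= 3) {
      expect_length(suppressWarnings(rms_of_groups(amp)), floor(length(amp) / 3))
    }
  }
})

test_that("a motionless subject has zero amplitude and zero sway scores", {
  f <- extract_features(static_series(duration = 6))
  expect_true(all(as.matrix(f$amp[c("AP", "ML", "V")]) == 0))
  expect_equal(unname(f$axis_scores), c(0, 0, 0))
  expect_equal(f$mean_score, 0)
})

test_that("feature extraction equals the naive loop reference on random signals", {
  set.seed(23)
  n <- 8 * 50
  series <- data.frame(
    t = (seq_len(n) - 1) / 50,
    ax = 0.02 * rnorm(n), ay = 0.05 * rnorm(n), az = 1 + 0.1 * rnorm(n)
  )
  f <- extract_features(series)
  # default chest mapping: Z -> AP, X -> ML, Y -> V
  expect_equal(f$axis_scores[["AP"]], naive_axis_score(series$az, 50)$score)
  expect_equal(f$axis_scores[["ML"]], naive_axis_score(series$ax, 50)$score)
  expect_equal(f$axis_scores[["V"]], naive_axis_score(series$ay, 50)$score)
  expect_equal(f$rms$AP, naive_axis_score(series$az, 50)$rms)
  expect_equal(f$mean_score, mean(f$axis_scores))
})

test_that("axis mapping must be bijective and relabels scores", {
  expect_error(axis_map(X = "AP", Y = "AP", Z = "V"),
               class = "swaysense_config_error")
  set.seed(24)
  n <- 6 * 50
  series <- data.frame(t = (seq_len(n) - 1) / 50, ax = 0.3 * rnorm(n),
                       ay = 0 * rnorm(n), az = rep(1, n))
  f <- extract_features(series, map = axis_map(X = "AP", Y = "ML", Z = "V"))
  expect_equal(f$axis_scores[["AP"]], naive_axis_score(series$ax, 50)$score)
  expect_equal(f$axis_scores[["V"]], 0)
})

test_that("trials shorter than one RMS window are rejected", {
  expect_error(extract_features(static_series(duration = 2)),
               class = "swaysense_insufficient_data")
})

test_that("accelerometer CSV round-trips and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(25)
  series <- generate_signal(signal_spec(duration = 4, amplitude = 0.2, seed = 3))
  write_accel_csv(series, path)
  back <- read_accel_csv(path)
  expect_equal(back, series, tolerance = 1e-12)

  # two valid rows parse to two samples
  writeLines(c("t,ax,ay,az", "0,0.1,0,1", "0.02,0.1,0,1"), path)
  expect_equal(nrow(read_accel_csv(path)), 2)

  # values outside the sensor full scale are rejected
  writeLines(c("t,ax,ay,az", "0,9.0,0,1", "0.02,0.1,0,1"), path)
  expect_error(read_accel_csv(path), "8 G", class = "swaysense_range_error")

  # non-monotone time
  writeLines(c("t,ax,ay,az", "0.02,0.1,0,1", "0,0.1,0,1"), path)
  expect_error(read_accel_csv(path), class = "swaysense_parse_error")

  # missing column
  writeLines(c("t,ax,ay", "0,0.1,0"), path)
  expect_error(read_accel_csv(path), class = "swaysense_parse_error")
})

test_that("feature CSV output carries the windowed series in long form", {
  path <- withr::local_tempfile(fileext = ".csv")
  f <- extract_features(generate_signal(signal_spec(duration = 7, amplitude = 0.1,
                                                    seed = 5)))
  write_features(f, path)
  long <- read.csv(path)
  expect_equal(nrow(long), 3 * 7) # 3 axes x floor(T) seconds
  expect_setequal(unique(long$axis), c("AP", "ML", "V"))
  # seconds 6 and 7 have no complete 3 s group
  expect_true(all(is.na(long$rms[long$window_start >= 6])))
  expect_false(any(is.na(long$rms[long$window_start < 6])))
})
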