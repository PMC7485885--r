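# helper: minimal all-on-surface recording from x/y (units) and pressure
flat_rec <- function(x, y = 0, pressure = 500, fs = 200, tilt_x = 30,
                     tilt_y = 10) {
  n <- length(x)
  pen_recording(
    tibble::tibble(t = (0:(n - 1)) / fs, x = x, y = rep_len(y, n),
                   pressure = rep_len(pressure, n),
                   tilt_x = rep_len(tilt_x, n), tilt_y = rep_len(tilt_y, n),
                   on_surface = TRUE),
    fs = fs)
}

test_that("speed_series reads the trace in mm/s", {
  # 4 units = 1 mm per 5 ms step -> 200 mm/s
  rec <- flat_rec(seq(0, 396, by = 4))
  expect_equal(speed_series(rec), rep(200, 99), tolerance = 1e-12)

  # stationary pen: zero speed
  rec0 <- flat_rec(rep(5, 50))
  expect_equal(speed_series(rec0), rep(0, 49))

  # circle of radius r traversed at angular rate w: speed ~ r * w
  fs <- 200; n <- 400; r_mm <- 5; w <- 2 * pi    # one turn in 1 s
  t <- (0:(n - 1)) / fs
  rec_c <- flat_rec(r_mm / 0.25 * cos(w * t), r_mm / 0.25 * sin(w * t))
  expect_equal(mean(speed_series(rec_c)), r_mm * w, tolerance = 1e-3)

  # pen-up only: refused
  up <- random_recording(61, n = 80)
  up$on_surface[] <- FALSE
  up$pressure[] <- 0
  expect_error(speed_series(up), class = "handwritr_insufficient_data")
})

test_that("space_between_words averages planted inter-word gaps", {
  prof <- script_profile(word_gap_mean_mm = 5, word_gap_sd_mm = 0,
                         tremor_amp_mm = 0, n_lines = 2, words_per_line = 3)
  rec <- simulate_recording(prof, seed = 5)
  expect_equal(feature_space_between_words(rec), 5, tolerance = 0.35)

  # single word: no gaps -> missing
  one <- simulate_recording(script_profile(n_lines = 1, words_per_line = 1),
                            seed = 6)
  expect_true(is.na(feature_space_between_words(one)))
})

test_that("density SD follows hand-counted grids", {
  cfg <- feature_config(density_cell_units = 10)
  # 10 points in one cell, 30 in another -> sd(c(10, 30))
  x <- c(rep(1, 10), rep(15, 30))
  rec <- flat_rec(x, y = 1)
  expect_equal(feature_density_sd(rec, cfg), sd(c(10, 30)))
  # all in one cell -> 0 by convention
  rec1 <- flat_rec(rep(3, 40), y = 2)
  expect_equal(feature_density_sd(rec1, cfg), 0)
})

test_that("tremor median tracks a planted tremor frequency", {
  prof <- script_profile(tremor_freq_hz = 12, tremor_amp_mm = 0.3,
                         n_lines = 2, words_per_line = 3)
  rec <- simulate_recording(prof, seed = 9)
  expect_equal(feature_tremor_median(rec), 12, tolerance = 1 / 12)

  # straight-line trace: the residual is identically zero -> missing
  straight <- flat_rec(seq(1, 800, by = 2), y = 7)
  expect_true(is.na(feature_tremor_median(straight)))

  # monotone response to planted frequency
  med <- vapply(c(6, 10, 14), function(f) {
    feature_tremor_median(simulate_recording(
      script_profile(tremor_freq_hz = f, tremor_amp_mm = 0.3,
                     n_lines = 1, words_per_line = 3), seed = 13))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("in-air ratio is the off-surface share of task time", {
  rec <- random_recording(71, n = 500)
  dt <- diff(rec$t)
  expect_equal(feature_in_air_ratio(rec),
               sum(dt[!rec$on_surface[-500]]) / sum(dt))
  all_on <- flat_rec(1:50)
  expect_equal(feature_in_air_ratio(all_on), 0)
  up <- random_recording(72, n = 80)
  up$on_surface[] <- FALSE
  up$pressure[] <- 0
  expect_equal(feature_in_air_ratio(up), 1)
})

test_that("pressure features obey closed forms", {
  # constant pressure: change speeds exactly zero
  rec <- flat_rec(1:200, pressure = 640)
  ps <- feature_pressure_stats(rec)
  expect_identical(ps$mean_pressure, 640)
  expect_identical(ps$mean_speed_pressure_change, 0)
  expect_identical(ps$sd_speed_pressure_change, 0)

  # ramp of r units/sample at 200 Hz, buckets of 10 -> 200 r units/s
  r <- 0.8
  ramp <- flat_rec(1:400, pressure = 100 + r * (0:399))
  ps <- feature_pressure_stats(ramp)
  expect_equal(ps$mean_speed_pressure_change, 200 * r, tolerance = 1e-6)
  expect_equal(ps$sd_speed_pressure_change, 0, tolerance = 1e-6)

  # fewer than two complete buckets: missing, not zero
  tiny <- flat_rec(1:15, pressure = 300 + (0:14))
  ps <- feature_pressure_stats(tiny)
  expect_false(is.na(ps$mean_pressure))
  expect_true(is.na(ps$mean_speed_pressure_change))

  # alternating ramps against the loop oracle
  zig <- flat_rec(1:300, pressure = 400 + 50 * abs(sin((0:299) / 7)))
  expect_equal(unclass(feature_pressure_stats(zig))[1:3],
               oracle_pressure(zig, feature_config())[1:3],
               tolerance = 1e-12)
})

test_that("tilt features respond to planted tilt structure", {
  ref <- make_test_reference(500)
  # matched grade-3 child: small tilt-x distance; constant tilt: missing
  rec <- simulate_recording(script_profile(grade = 3, n_lines = 1,
                                           words_per_line = 3), seed = 21)
  tset <- feature_tilt_set(rec, ref, 3)
  expect_gte(tset$dist_mean_tiltx_freq, 0)
  expect_false(is.na(tset$bandwidth_tiltx))
  expect_false(is.na(tset$median_psd_tilty))

  flat <- flat_rec(1:100, tilt_x = 30, tilt_y = 10)
  tflat <- feature_tilt_set(flat, ref, 3)
  expect_true(is.na(tflat$bandwidth_tiltx))
  expect_true(is.na(tflat$median_psd_tilty))

  # tilt-y frequency moves the tilt-y spectral median
  med <- vapply(c(2, 6), function(f) {
    feature_tilt_set(simulate_recording(
      script_profile(tilt_y_freq = f, n_lines = 1, words_per_line = 3),
      seed = 22))$median_psd_tilty
  }, numeric(1))
  expect_lt(med[1], med[2])

  # a tilt-shifted child is farther from the typical spectrum than a
  # matched one
  shifted <- simulate_recording(
    script_profile(grade = 3, tilt_x_freq = 6, tilt_x_amp2 = 3,
                   n_lines = 1, words_per_line = 3), seed = 21)
  expect_gt(feature_tilt_set(shifted, ref, 3)$dist_mean_tiltx_freq,
            tset$dist_mean_tiltx_freq)
})

test_that("extract_features returns one deterministic, NA-honest row", {
  ref <- make_test_reference(600)
  rec <- simulate_recording(script_profile(grade = 2, n_lines = 2,
                                           words_per_line = 3), seed = 31,
                            child_id = "kid_7")
  f1 <- extract_features(rec, ref, 2)
  f2 <- extract_features(rec, ref, 2)
  expect_identical(f1, f2)
  expect_equal(names(f1), c("child_id", feature_names()))
  expect_equal(f1$child_id, "kid_7")
  expect_false(anyNA(f1[feature_names()]))

  # no reference: the two distance features are missing, others intact
  f3 <- extract_features(rec)
  expect_true(is.na(f3$dist_mean_speed_freq))
  expect_true(is.na(f3$dist_mean_tiltx_freq))
  expect_equal(f3$mean_pressure, f1$mean_pressure)

  # a dot recording degrades to mostly-missing without erroring
  dot <- flat_rec(rep(10, 30), pressure = 400)
  fd <- extract_features(dot)
  expect_true(is.na(fd$median_psd_speed))
  expect_true(is.na(fd$median_psd_tremor))
  expect_equal(fd$mean_pressure, 400)
  expect_equal(fd$in_air_time_ratio, 0)
})
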