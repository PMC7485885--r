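test_that("simulate_recording is deterministic and well-formed", {
  prof <- script_profile(n_lines = 2, words_per_line = 3)
  r1 <- simulate_recording(prof, seed = 3)
  r2 <- simulate_recording(prof, seed = 3)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- simulate_recording(prof, seed = 4)
  expect_false(identical(r1$x, r3$x))
  expect_s3_class(validate_recording(r1), "pen_recording")
  # both pen states present; pressure inside the device range
  expect_true(any(r1$on_surface) && any(!r1$on_surface))
  expect_true(all(r1$pressure[r1$on_surface] >= 15 &
                    r1$pressure[r1$on_surface] <= 1023))
  expect_error(simulate_recording(list()),
               class = "handwritr_parameter_error")
})

test_that("the generator honours its closed-loop kinematic targets", {
  # no modulation, no tremor: constant speed at the base rate
  prof <- script_profile(speed_mod_amps = c(0, 0), tremor_amp_mm = 0,
                         base_speed_mm_s = 25, n_lines = 1,
                         words_per_line = 2)
  rec <- simulate_recording(prof, seed = 5)
  v <- speed_series(rec)
  expect_equal(mean(v), 25, tolerance = 0.02)
  expect_lt(sd(v) / mean(v), 0.02)

  # letter geometry: ink height ~ letter_height_mm
  on <- rec$on_surface
  height_mm <- diff(range(rec$y[on])) * 0.25
  expect_equal(height_mm, 5, tolerance = 0.1)

  # planted word gaps are recovered by the gap feature
  prof2 <- script_profile(word_gap_mean_mm = 6, word_gap_sd_mm = 0,
                          tremor_amp_mm = 0, n_lines = 2,
                          words_per_line = 4)
  rec2 <- simulate_recording(prof2, seed = 6)
  expect_equal(feature_space_between_words(rec2), 6, tolerance = 0.05)
})

test_that("generator parameters move their features monotonically", {
  gaps <- seq(3, 10, length.out = 8)
  got <- vapply(seq_along(gaps), function(i) {
    rec <- simulate_recording(
      script_profile(word_gap_mean_mm = gaps[i], word_gap_sd_mm = 0.2,
                     n_lines = 2, words_per_line = 3), seed = 20 + i)
    feature_space_between_words(rec)
  }, numeric(1))
  expect_gt(cor(gaps, got, method = "spearman"), 0.95)

  # longer pen-ups raise the in-air ratio
  air <- vapply(c(0.1, 0.4, 0.8), function(p) {
    feature_in_air_ratio(simulate_recording(
      script_profile(inter_letter_penup_s = p, n_lines = 1,
                     words_per_line = 3), seed = 30))
  }, numeric(1))
  expect_true(all(diff(air) > 0))

  # flatter pressure dynamics lower the pressure-change SD
  sds <- vapply(c(60, 300), function(s) {
    extract_features(simulate_recording(
      script_profile(pressure_slope_sd = s, n_lines = 2,
                     words_per_line = 3),
      seed = 31))$sd_speed_pressure_change
  }, numeric(1))
  expect_lt(sds[1], sds[2])
})

test_that("dysgraphia subtype offsets perturb profiles as documented", {
  subs <- dysgraphia_subtypes()
  expect_setequal(names(subs),
                  c("TD", "mild", "kinematic_pressure", "tilt"))
  base <- script_profile(grade = 3)
  kp <- apply_subtype(base, subs$kinematic_pressure, 2)
  expect_lt(kp$word_gap_mean_mm, base$word_gap_mean_mm)
  expect_lt(kp$pressure_slope_sd, base$pressure_slope_sd)
  expect_gt(kp$speed_mod_shift_hz, base$speed_mod_shift_hz)
  mi <- apply_subtype(base, subs$mild, 2)
  expect_gt(mi$word_gap_mean_mm, base$word_gap_mean_mm)
  expect_gt(mi$inter_letter_penup_s, base$inter_letter_penup_s)
  expect_equal(mi$speed_mod_shift_hz, base$speed_mod_shift_hz)
  ti <- apply_subtype(base, subs$tilt, 2)
  expect_gt(ti$tilt_x_freq, base$tilt_x_freq)
  expect_gt(ti$tilt_x_amp2, 0)
  td <- apply_subtype(base, subs$TD, 2)
  expect_equal(td[names(base)], base[names(base)])
  # clamping keeps extreme severities physical
  extreme <- apply_subtype(base, subs$kinematic_pressure, 50)
  expect_gte(extreme$word_gap_mean_mm, 1)
  expect_gte(extreme$pressure_slope_sd, 15)
})

test_that("simulate_cohort lays out the recruited population and truth", {
  spec <- cohort_spec(n_td_per_grade = c(3, 3, 3, 3, 3),
                      n_d_per_grade = c(0, 2, 2, 2, 2),
                      n_lines = 1, words_per_line = 2)
  sim <- simulate_cohort(spec, seed = 40)
  expect_equal(nrow(sim$cohort), 23)
  expect_equal(sum(sim$cohort$group == "D"), 8)
  expect_equal(as.vector(table(sim$cohort$grade)), c(3L, 5L, 5L, 5L, 5L))
  expect_equal(length(sim$recordings), 23)
  expect_equal(names(sim$recordings), sim$cohort$child_id)
  expect_equal(sim$truth$child_id, sim$cohort$child_id)
  expect_true(all(sim$truth$severity[sim$cohort$group == "D"] >= 1))
  expect_true(all(sim$truth$severity[sim$cohort$group == "TD"] == 0))
  expect_true(all(sim$truth$subtype[sim$cohort$group == "TD"] == "TD"))
  expect_true(all(sim$truth$subtype[sim$cohort$group == "D"] %in%
                    c("mild", "kinematic_pressure", "tilt")))

  # full determinism under the seed
  sim2 <- simulate_cohort(spec, seed = 40)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(as.data.frame(sim$recordings[[5]]),
                   as.data.frame(sim2$recordings[[5]]))

  # recordings can be skipped for score-level studies
  fast <- simulate_cohort(spec, seed = 41, make_recordings = FALSE)
  expect_null(fast$recordings)
  expect_equal(nrow(fast$cohort), 23)
})

test_that("BHK scores follow the cohort generative model", {
  spec <- cohort_spec(n_td_per_grade = rep(200, 5),
                      n_d_per_grade = rep(0, 5))
  sim <- simulate_cohort(spec, seed = 42, make_recordings = FALSE)
  fit <- lm(bhk_quality_raw ~ grade + I(gender == "M"), sim$cohort)
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.15)
  fit2 <- lm(bhk_speed_raw ~ grade, sim$cohort)
  expect_equal(unname(coef(fit2)[2]), 57, tolerance = 0.1)
})

test_that("simulate_feature_cohort plants recoverable effects", {
  cohort <- simulate_feature_cohort(
    n = 5000, quality_effects = c(mean_pressure = 2),
    quality_interactions = c(bandwidth_tiltx = 0.5), seed = 43)
  expect_equal(nrow(cohort), 5000)
  expect_true(all(!cohort$dysgraphia))
  fit <- lm(bhk_quality_raw ~ mean_pressure * grade + bandwidth_tiltx *
              grade + I(gender == "M"), cohort)
  co <- coef(fit)
  expect_equal(unname(co["mean_pressure"]), 2, tolerance = 0.15)
  expect_equal(unname(co["grade:bandwidth_tiltx"]), 0.5, tolerance = 0.15)
  expect_equal(unname(attr(cohort, "quality_effects")["mean_pressure"]), 2)
  expect_equal(unname(attr(cohort,
                           "quality_interactions")["bandwidth_tiltx"]),
               0.5)
})
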