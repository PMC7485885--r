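test_that("normalize_feature z-scores and refuses degenerate input", {
  z <- normalize_feature(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  v <- c(rnorm(20), NA)
  zv <- normalize_feature(v)
  expect_true(is.na(zv[21]))
  expect_equal(mean(zv, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(zv, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(normalize_feature(rep(4, 10)),
               class = "handwritr_degenerate_feature")
  expect_error(normalize_feature(c(1, NA)),
               class = "handwritr_degenerate_feature")
})

test_that("BHK normalization and diagnosis reproduce the raw-scale rule", {
  norms <- norm_table(1:5, quality_mean = c(20, 18, 16, 14, 12),
                      quality_sd = rep(0.5, 5),
                      speed_mean = c(80, 140, 190, 250, 300),
                      speed_sd = rep(40, 5))
  # quality is a degradation score: higher raw = worse = more negative
  expect_equal(normalize_bhk(20, 1, norms, "quality"), 0)
  expect_equal(normalize_bhk(21, 1, norms, "quality"), -2)
  expect_equal(normalize_bhk(19, 1, norms, "quality"), 2)
  # speed: higher raw = faster = more positive
  expect_equal(normalize_bhk(160, 2, norms, "speed"), 0.5)
  expect_error(normalize_bhk(20, 7, norms, "quality"),
               class = "handwritr_norms_error")

  # the cutoff is exactly -2, on quality only
  expect_true(diagnose_dysgraphia(-2))
  expect_false(diagnose_dysgraphia(-1.99))
  expect_true(is.na(diagnose_dysgraphia(NA)))

  # exact boundary equivalence on representable numbers
  expect_true(diagnose_dysgraphia(normalize_bhk(21, 1, norms, "quality")))
  expect_false(diagnose_dysgraphia(normalize_bhk(21 - 2^-3, 1, norms,
                                                 "quality")))

  # randomized-table property: diagnosis <=> raw >= mean + 2 sd
  set.seed(41)
  for (i in 1:20) {
    nt <- norm_table(1:5, quality_mean = runif(5, 10, 30),
                     quality_sd = runif(5, 0.5, 8),
                     speed_mean = runif(5, 50, 300),
                     speed_sd = runif(5, 10, 60))
    g <- sample(1:5, 50, replace = TRUE)
    raw <- runif(50, 0, 60)
    got <- diagnose_dysgraphia(normalize_bhk(raw, g, nt, "quality"))
    idx <- match(g, nt$grade)
    want <- raw >= nt$quality_mean[idx] + 2 * nt$quality_sd[idx]
    expect_equal(got, want)
  }
})

test_that("norm_table_from_cohort recovers per-grade moments", {
  set.seed(42)
  cohort <- tibble::tibble(
    grade = rep(1:5, each = 40),
    bhk_quality_raw = rnorm(200, rep(c(20, 18, 16, 14, 12), each = 40), 3),
    bhk_speed_raw = rnorm(200, rep(c(80, 140, 190, 250, 300), each = 40),
                          30))
  nt <- norm_table_from_cohort(cohort)
  for (g in 1:5) {
    sub <- cohort[cohort$grade == g, ]
    expect_equal(nt$quality_mean[nt$grade == g], mean(sub$bhk_quality_raw))
    expect_equal(nt$speed_sd[nt$grade == g], sd(sub$bhk_speed_raw))
  }
})

test_that("fit_bhk_model matches the normal-equation oracle", {
  for (seed in 1:5) {
    cohort <- simulate_feature_cohort(
      n = 120, quality_effects = c(median_psd_speed = 1.5), seed = seed)
    fit <- fit_bhk_model(cohort, "median_psd_speed",
                         boot_config = bootstrap_config(100, seed))
    z <- normalize_feature(cohort$median_psd_speed)
    X <- cbind(1, z, cohort$grade, as.numeric(cohort$gender == "M"))
    want <- oracle_ols(X, cohort$bhk_quality_raw)
    expect_equal(unname(fit$coefficients$estimate), unname(want),
                 tolerance = 1e-8)
  }
})

test_that("noise-free data gives exact estimates with degenerate intervals", {
  cohort <- tibble::tibble(
    grade = rep(1:5, each = 6), gender = rep(c("F", "M"), 15),
    f = rep(seq(-1, 1, length.out = 10), 3))
  cohort$f <- cohort$f + 0.01 * seq_len(30)     # break collinearity
  z <- normalize_feature(cohort$f)
  cohort$bhk_quality_raw <- 30 + 2 * z - 1.5 * cohort$grade +
    0.5 * (cohort$gender == "M")
  # lm warns about the deliberately perfect fit; that is the point here
  fit <- suppressWarnings(
    fit_bhk_model(cohort, "f", boot_config = bootstrap_config(200, 3)))
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "z"], 2, tolerance = 1e-8)
  expect_equal(co$conf.low[co$term == "z"], co$conf.high[co$term == "z"],
               tolerance = 1e-6)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-10)
})

test_that("bootstrap inference is seeded, reproducible, and tightens with B", {
  cohort <- simulate_feature_cohort(
    n = 60, quality_effects = c(in_air_time_ratio = 2), seed = 8)
  f1 <- fit_bhk_model(cohort, "in_air_time_ratio",
                      boot_config = bootstrap_config(300, 11))
  f2 <- fit_bhk_model(cohort, "in_air_time_ratio",
                      boot_config = bootstrap_config(300, 11))
  expect_identical(tidy(f1), tidy(f2))
  f3 <- fit_bhk_model(cohort, "in_air_time_ratio",
                      boot_config = bootstrap_config(300, 12))
  expect_false(identical(tidy(f1)$conf.low, tidy(f3)$conf.low))

  # CI-endpoint Monte-Carlo spread shrinks roughly like 1/sqrt(B)
  lows <- function(B) {
    vapply(1:12, function(s) {
      fit <- fit_bhk_model(cohort, "in_air_time_ratio",
                           boot_config = bootstrap_config(B, 100 + s))
      fit$coefficients$conf.low[fit$coefficients$term == "z"]
    }, numeric(1))
  }
  expect_lt(sd(lows(3200)) / sd(lows(200)), 0.7)
})

test_that("percentile p values are honest under the null and floored", {
  expect_equal(percentile_p(c(-1, -2, 1, 2)), 1)
  expect_equal(percentile_p(rep(5, 400)), 1 / 400)   # never crosses zero
  set.seed(51)
  cohort <- simulate_feature_cohort(n = 120, seed = 52)  # all effects zero
  ps <- vapply(1:30, function(s) {
    cohort <- simulate_feature_cohort(n = 120, seed = 1000 + s)
    fit <- fit_bhk_model(cohort, "mean_pressure",
                         boot_config = bootstrap_config(400, s))
    fit$coefficients$p.value[fit$coefficients$term == "z"]
  }, numeric(1))
  # null p values are roughly uniform: no pile-up below 0.05
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})

test_that("collinear designs are rejected with the offending term named", {
  cohort <- simulate_feature_cohort(n = 60, seed = 61)
  cohort$grade <- 3                       # constant grade
  expect_error(fit_bhk_model(cohort, "mean_pressure"),
               "grade", class = "handwritr_rank_error")
  small <- simulate_feature_cohort(n = 60, seed = 62)[1:5, ]
  expect_error(fit_bhk_model(small, "mean_pressure"),
               class = "handwritr_data_error")
})

test_that("run_model_battery covers the feature x outcome x form grid", {
  cohort <- simulate_feature_cohort(
    n = 80, quality_effects = c(median_psd_speed = 2), seed = 71)
  bat <- run_model_battery(
    cohort, "td", features = c("median_psd_speed", "mean_pressure"),
    boot_config = bootstrap_config(150, 5))
  expect_equal(nrow(bat), 2 * 2 * 2)
  expect_setequal(unique(bat$term), c("z", "z:grade"))
  expect_true(all(bat$dataset == "TD"))
  expect_true(all(bat$conf.low <= bat$estimate &
                    bat$estimate <= bat$conf.high))

  # scope filter: dysgraphic children are excluded from the TD scope
  cohort2 <- cohort
  cohort2$dysgraphia[1:30] <- TRUE
  bat2 <- run_model_battery(
    cohort2, "td", features = "median_psd_speed",
    outcomes = "bhk_quality_raw", forms = "main",
    boot_config = bootstrap_config(150, 5))
  expect_equal(unique(bat2$n), 50)
  bat3 <- run_model_battery(
    cohort2, "all", features = "median_psd_speed",
    outcomes = "bhk_quality_raw", forms = "main",
    boot_config = bootstrap_config(150, 5))
  expect_equal(unique(bat3$n), 80)
  expect_equal(unique(bat3$dataset), "TD+D")

  # reproducible under the same bootstrap config
  bat4 <- run_model_battery(
    cohort, "td", features = c("median_psd_speed", "mean_pressure"),
    boot_config = bootstrap_config(150, 5))
  expect_identical(bat, bat4)
})
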