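#' Z-score a feature vector
#'
#' Centers and scales by the sample mean and SD of the non-missing values;
#' missing entries stay missing. Each digital feature is normalized this
#' way before entering a regression so estimates are per-SD and comparable
#' across features.
#'
#' @param values Numeric vector.
#' @return Z-scored vector of the same length.
#' @export
normalize_feature <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) {
    abort("need at least 2 non-missing values to normalize",
          class = "handwritr_degenerate_feature")
  }
  s <- sd(values[ok])
  if (s == 0) {
    abort("zero variance: feature cannot be normalized",
          class = "handwritr_degenerate_feature")
  }
  (values - mean(values[ok])) / s
}

#' Per-grade BHK norm table
#'
#' Means and SDs of the raw BHK quality and speed scores in a reference
#' population, per school grade. Used to place a child's raw scores on the
#' age-normalized scale on which the diagnostic cutoff of -2 is defined.
#' `norm_table_from_cohort()` estimates the table from a (typically
#' developing) cohort.
#'
#' @param grade Integer grades covered.
#' @param quality_mean,quality_sd,speed_mean,speed_sd Per-grade raw-score
#'   moments (SDs must be positive).
#' @return Tibble of class `hw_norm_table`.
#' @export
norm_table <- function(grade, quality_mean, quality_sd, speed_mean,
                       speed_sd) {
  stopifnot(all(quality_sd > 0), all(speed_sd > 0))
  tibble::new_tibble(
    tibble::tibble(grade = as.integer(grade), quality_mean = quality_mean,
                   quality_sd = quality_sd, speed_mean = speed_mean,
                   speed_sd = speed_sd),
    class = "hw_norm_table")
}

#' @rdname norm_table
#' @param cohort Cohort tibble with `grade`, `bhk_quality_raw`,
#'   `bhk_speed_raw`.
#' @export
norm_table_from_cohort <- function(cohort) {
  tab <- cohort |>
    dplyr::group_by(.data$grade) |>
    dplyr::summarise(quality_mean = mean(.data$bhk_quality_raw),
                     quality_sd = sd(.data$bhk_quality_raw),
                     speed_mean = mean(.data$bhk_speed_raw),
                     speed_sd = sd(.data$bhk_speed_raw), .groups = "drop")
  norm_table(tab$grade, tab$quality_mean, tab$quality_sd, tab$speed_mean,
             tab$speed_sd)
}

#' Age-normalize a raw BHK score
#'
#' The BHK quality score is a degradation score (higher = worse); its
#' normalized value is `(mean_grade - raw) / sd_grade`, so a raw score two
#' SDs above the grade mean lands at -2, the diagnostic cutoff. Speed
#' counts characters in 5 minutes (higher = faster), normalized as
#' `(raw - mean_grade) / sd_grade`, so slower-than-typical writing is
#' negative.
#'
#' @param raw Raw score(s).
#' @param grade Matching grade(s).
#' @param norms A [norm_table()].
#' @param kind `"quality"` or `"speed"`.
#' @return Normalized score(s).
#' @export
normalize_bhk <- function(raw, grade, norms, kind = c("quality", "speed")) {
  kind <- match.arg(kind)
  idx <- match(grade, norms$grade)
  if (anyNA(idx)) {
    abort(paste0("grade(s) missing from norm table: ",
                 paste(unique(grade[is.na(idx)]), collapse = ", ")),
          class = "handwritr_norms_error")
  }
  if (kind == "quality") {
    (norms$quality_mean[idx] - raw) / norms$quality_sd[idx]
  } else {
    (raw - norms$speed_mean[idx]) / norms$speed_sd[idx]
  }
}

#' Diagnose dysgraphia from the normalized BHK quality score
#'
#' Dysgraphia is diagnosed on handwriting quality only: true iff the
#' age-normalized quality score is at or below -2 (equivalently, the raw
#' degradation score is at least two SDs above the grade mean).
#'
#' @param quality_norm Normalized quality score(s).
#' @return Logical vector; `NA` where the input is missing.
#' @export
diagnose_dysgraphia <- function(quality_norm) {
  quality_norm <= -2
}

#' Bootstrap configuration
#'
#' Case-resampling bootstrap settings for the regression models: BCa 95%
#' confidence intervals and two-sided percentile p values
#' (`2 * min(prop <= 0, prop >= 0)`, floored at `1/replications`).
#'
#' @param replications Bootstrap replications (default 10000).
#' @param seed Integer seed making every fit reproducible.
#' @return List of class `hw_bootstrap_config`.
#' @export
bootstrap_config <- function(replications = 10000, seed = 1L) {
  stopifnot(replications >= 100)
  structure(list(replications = as.integer(replications),
                 ci_method = "bca", p_method = "percentile",
                 seed = as.integer(seed)),
            class = "hw_bootstrap_config")
}

# percentile two-sided p from bootstrap replicates of one coefficient
percentile_p <- function(t) {
  B <- length(t)
  p <- 2 * min(mean(t <= 0), mean(t >= 0))
  min(max(p, 1 / B), 1)
}

#' Developmental linear model for one digital feature
#'
#' Fits `outcome ~ normalized(feature) + grade + gender` by OLS, with
#' `grade` numeric (1-5) and gender coded F = 0, M = 1; with
#' `interaction = TRUE` a `grade x normalized(feature)` term is added, whose
#' coefficient tells how the feature's predictive value changes across the
#' school curriculum. Inference is by case-resampling bootstrap (children
#' resampled with replacement) because BHK residuals need not be normal:
#' per-coefficient BCa 95% intervals and two-sided percentile p values.
#' Rows with a missing feature or outcome are dropped listwise.
#'
#' @param cohort Cohort tibble with `grade`, `gender` ("F"/"M"), the
#'   outcome column and the feature column.
#' @param feature Name of the feature column.
#' @param outcome `"bhk_quality_raw"` or `"bhk_speed_raw"` (any numeric
#'   column works).
#' @param interaction Add the `grade:feature` interaction term?
#' @param boot_config A [bootstrap_config()].
#' @return A `hw_model_fit` with a per-term coefficient table
#'   (`estimate`, `conf.low`, `conf.high`, `p.value`), `n` used, residual
#'   summary and the configuration. [tidy()] returns the coefficient
#'   table, [glance()] the fit summary.
#' @export
fit_bhk_model <- function(cohort, feature, outcome = "bhk_quality_raw",
                          interaction = FALSE,
                          boot_config = bootstrap_config()) {
  stopifnot(feature %in% names(cohort), outcome %in% names(cohort))
  dat <- tibble::tibble(
    y = cohort[[outcome]],
    feat = cohort[[feature]],
    grade = as.numeric(cohort$grade),
    gender = as.numeric(cohort$gender == "M"))
  dat <- dat[complete.cases(dat), ]
  if (nrow(dat) < 10) {
    abort("fewer than 10 complete cases", class = "handwritr_data_error")
  }
  dat$z <- normalize_feature(dat$feat)
  form <- if (interaction) y ~ z + grade + gender + z:grade
          else y ~ z + grade + gender
  X <- model.matrix(form, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("collinear design; offending term(s): ",
                 paste(dropped, collapse = ", ")),
          class = "handwritr_rank_error")
  }
  fit <- lm(form, data = dat)
  est <- coef(fit)
  terms <- names(est)

  stat <- function(d, idx) {
    Xi <- X[idx, , drop = FALSE]
    qr.coef(qr(Xi), d$y[idx])
  }
  set.seed(boot_config$seed)
  bo <- boot::boot(dat, stat, R = boot_config$replications)

  ci <- purrr::map(seq_along(terms), function(j) {
    tj <- bo$t[, j]
    if (!all(is.finite(tj)) || var(tj) < 1e-24) {
      return(c(est[j], est[j]))
    }
    # small B makes boot.ci warn about extreme order statistics; the
    # endpoints are still the documented BCa estimates
    out <- tryCatch(
      suppressWarnings(boot::boot.ci(bo, type = "bca", index = j)$bca[4:5]),
      error = function(e) NULL)
    if (is.null(out)) {
      out <- unname(quantile(tj, c(0.025, 0.975)))
    }
    out
  })
  p <- purrr::map_dbl(seq_along(terms), function(j) {
    tj <- bo$t[, j][is.finite(bo$t[, j])]
    if (length(tj) == 0 || var(tj) < 1e-24) {
      return(if (est[j] == 0) 1 else 1 / max(length(tj), 1))
    }
    percentile_p(tj)
  })

  structure(list(
    outcome = outcome, feature = feature, interaction = interaction,
    n = nrow(dat),
    coefficients = tibble::tibble(
      term = terms, estimate = unname(est),
      conf.low = purrr::map_dbl(ci, 1), conf.high = purrr::map_dbl(ci, 2),
      p.value = p),
    r.squared = summary(fit)$r.squared,
    residual_summary = unname(quantile(fit$residuals,
                                       c(0, 0.25, 0.5, 0.75, 1))),
    boot_config = boot_config),
    class = "hw_model_fit")
}

#' @export
print.hw_model_fit <- function(x, ...) {
  cat(sprintf("<hw_model_fit> %s ~ %s%s (n = %d, B = %d)\n",
              x$outcome, x$feature,
              if (x$interaction) " * grade" else " + grade + gender",
              x$n, x$boot_config$replications))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_bhk_model
#' @param x A `hw_model_fit`.
#' @param ... Unused.
#' @method tidy hw_model_fit
#' @export
tidy.hw_model_fit <- function(x, ...) x$coefficients

#' @rdname fit_bhk_model
#' @method glance hw_model_fit
#' @export
glance.hw_model_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, feature = x$feature,
                 interaction = x$interaction, n = x$n,
                 r.squared = x$r.squared,
                 replications = x$boot_config$replications)
}

#' Run the full developmental model battery
#'
#' Fits, per digital feature and outcome, the main-effects model and (when
#' requested) the interaction model, on the chosen dataset scope: `"td"`
#' restricts to non-dysgraphic children first, `"all"` keeps the mixed
#' TD + D population that resembles school screening. Each row reports the
#' quantity of interest: the normalized-feature estimate for the main
#' model, the `feature x grade` estimate for the interaction model.
#'
#' @param cohort Cohort tibble with `dysgraphia`, `grade`, `gender`, BHK
#'   outcome columns and feature columns.
#' @param scope `"td"` or `"all"`.
#' @param outcomes Outcome columns to model.
#' @param forms Model forms: any of `"main"`, `"interaction"`.
#' @param features Feature columns (default the twelve digital features).
#' @param boot_config A [bootstrap_config()].
#' @return Tibble: `feature`, `outcome`, `form`, `dataset`, `term`,
#'   `estimate`, `conf.low`, `conf.high`, `p.value`, `n`.
#' @export
run_model_battery <- function(cohort, scope = c("td", "all"),
                              outcomes = c("bhk_quality_raw",
                                           "bhk_speed_raw"),
                              forms = c("main", "interaction"),
                              features = feature_names(),
                              boot_config = bootstrap_config()) {
  scope <- match.arg(scope)
  if (scope == "td") {
    cohort <- dplyr::filter(cohort, !.data$dysgraphia)
  }
  if (nrow(cohort) == 0) {
    abort("no children in the requested scope",
          class = "handwritr_scope_error")
  }
  grid <- tidyr::expand_grid(feature = features, outcome = outcomes,
                             form = forms)
  purrr::pmap_dfr(grid, function(feature, outcome, form) {
    fit <- fit_bhk_model(cohort, feature, outcome,
                         interaction = form == "interaction",
                         boot_config = boot_config)
    want <- if (form == "interaction") "z:grade" else "z"
    row <- fit$coefficients[fit$coefficients$term == want, ]
    tibble::tibble(feature = feature, outcome = outcome, form = form,
                   dataset = if (scope == "td") "TD" else "TD+D",
                   term = want, estimate = row$estimate,
                   conf.low = row$conf.low, conf.high = row$conf.high,
                   p.value = row$p.value, n = fit$n)
  })
}
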