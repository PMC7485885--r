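#' Run the full handwriting-analysis pipeline
#'
#' Reproduces the analysis skeleton on a cohort of recordings: (optional)
#' cross-device pressure harmonization, feature extraction, per-grade
#' reference spectra built from the typically developing children,
#' BHK normalization and dysgraphia diagnosis, the developmental model
#' battery (TD and TD+D scopes, quality and speed outcomes, with and
#' without the grade interaction), and K-means subtyping of the dysgraphic
#' subset. All stages are pure functions of the inputs and seeds, recorded
#' in the returned manifest.
#'
#' @param cohort Cohort tibble with `child_id`, `grade`, `gender`,
#'   `handedness`, `bhk_quality_raw`, `bhk_speed_raw` (e.g. from
#'   [simulate_cohort()]).
#' @param recordings Named list of [pen_recording()]s keyed by `child_id`.
#' @param norms A [norm_table()], or `NULL` to estimate one from the
#'   recruited-in-school children (`group == "TD"` when a `group` column
#'   exists, otherwise the whole cohort).
#' @param calibration Optional list `list(source =, target =)` of
#'   [fit_calibration()] curves applied to every recording first.
#' @param config A [feature_config()].
#' @param boot_config A [bootstrap_config()].
#' @param cluster_k Fixed k for the subtyping, or `NULL` for [choose_k()].
#' @param seed Integer seed for the clustering stage.
#' @param out_dir Optional directory; when given, every table is written
#'   as tab-separated text plus a `manifest` file.
#' @return List of class `hw_pipeline_result`: `cohort` (with normalized
#'   scores, diagnosis and features), `reference`, `norms`,
#'   `demographics`, `models` (battery tibble over both scopes),
#'   `clustering` (a [subtype_clustering()] result, or `NULL` with a
#'   notice when no children carry a diagnosis), `manifest`.
#' @export
run_pipeline <- function(cohort, recordings, norms = NULL,
                         calibration = NULL,
                         config = feature_config(),
                         boot_config = bootstrap_config(),
                         cluster_k = NULL, seed = 1L, out_dir = NULL) {
  stopifnot(all(cohort$child_id %in% names(recordings)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "handwritr_pipeline_error")
    })
  }
  recs <- recordings[cohort$child_id]

  if (!is.null(calibration)) {
    recs <- stage("calibration", purrr::map(recs, harmonize_pressure,
                                            source = calibration$source,
                                            target = calibration$target))
  }

  ref_idx <- if ("group" %in% names(cohort)) which(cohort$group == "TD")
             else seq_len(nrow(cohort))
  reference <- stage("reference", build_reference_spectra(
    recs[ref_idx], cohort$grade[ref_idx], config))

  features <- stage("features", purrr::map_dfr(seq_len(nrow(cohort)),
    function(i) extract_features(recs[[i]], reference, cohort$grade[i],
                                 config)))
  cohort <- dplyr::left_join(cohort, features, by = "child_id")

  if (is.null(norms)) {
    norms <- stage("norms", norm_table_from_cohort(cohort[ref_idx, ]))
  }
  cohort$bhk_quality_norm <- stage("normalize", normalize_bhk(
    cohort$bhk_quality_raw, cohort$grade, norms, "quality"))
  cohort$bhk_speed_norm <- normalize_bhk(cohort$bhk_speed_raw,
                                         cohort$grade, norms, "speed")
  cohort$dysgraphia <- diagnose_dysgraphia(cohort$bhk_quality_norm)

  demographics <- cohort |>
    dplyr::group_by(diagnosed = .data$dysgraphia) |>
    dplyr::summarise(n = dplyr::n(),
                     males = sum(.data$gender == "M"),
                     left_handed = sum(.data$handedness == "L"),
                     quality_mean = mean(.data$bhk_quality_raw),
                     quality_sd = sd(.data$bhk_quality_raw),
                     speed_mean = mean(.data$bhk_speed_raw),
                     speed_sd = sd(.data$bhk_speed_raw), .groups = "drop")

  models <- stage("models", dplyr::bind_rows(
    run_model_battery(cohort, "td", boot_config = boot_config),
    run_model_battery(cohort, "all", boot_config = boot_config)))

  d_sub <- dplyr::filter(cohort, .data$dysgraphia)
  clustering <- NULL
  notice <- NULL
  if (nrow(d_sub) >= 10) {
    clustering <- stage("clustering",
                        subtype_clustering(d_sub, k = cluster_k,
                                           seed = seed))
  } else {
    notice <- sprintf(
      "clustering skipped: only %d diagnosed children (need >= 10)",
      nrow(d_sub))
  }

  manifest <- tibble::tibble(
    key = c("n_children", "n_recordings", "bootstrap_B", "bootstrap_seed",
            "cluster_seed", "calibrated", "notice"),
    value = as.character(c(nrow(cohort), length(recs),
                           boot_config$replications, boot_config$seed,
                           seed, !is.null(calibration),
                           notice %||% "")))

  out <- structure(list(cohort = cohort, reference = reference,
                        norms = norms, demographics = demographics,
                        models = models, clustering = clustering,
                        manifest = manifest),
                   class = "hw_pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    readr::write_tsv(demographics, file.path(out_dir, "demographics.tsv"))
    readr::write_tsv(models, file.path(out_dir, "model_battery.tsv"))
    write_reference_spectra(reference,
                            file.path(out_dir, "reference_spectra.tsv"))
    if (!is.null(clustering)) {
      readr::write_tsv(tidy(clustering),
                       file.path(out_dir, "cluster_assignments.tsv"))
      readr::write_tsv(clustering$summary$continuous,
                       file.path(out_dir, "cluster_summary.tsv"))
    }
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }
  out
}

#' @export
print.hw_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<hw_pipeline_result> %d children, %d diagnosed; %d model rows\n",
    nrow(x$cohort), sum(x$cohort$dysgraphia, na.rm = TRUE),
    nrow(x$models)))
  if (!is.null(x$clustering)) {
    cat(sprintf("clustering: k = %d, Hopkins = %.3f\n", x$clustering$k,
                x$clustering$hopkins))
  }
  invisible(x)
}
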