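#' Feature-extraction configuration
#'
#' Tunable parameters for the digital-feature extractors, with the defaults
#' used throughout: 300-device-unit square density cells, pressure buckets
#' of 10 samples, a 10-sample tremor smoothing window, 3 mm word-gap / 8 mm
#' line-break segmentation thresholds, 95% central mass for spectral
#' bandwidth, and a 0.5 Hz grid for reference-spectrum comparison.
#'
#' @param density_cell_units Side of the square density-grid cell, device
#'   units.
#' @param pressure_bucket Samples per pressure bucket.
#' @param tremor_window Samples in the moving-average smooth used for the
#'   tremor residual.
#' @param gap_mm,linebreak_mm Word segmentation thresholds (see
#'   [segment_words()]).
#' @param bandwidth_mass Central spectral mass for [spectral_bandwidth()].
#' @param ref_bin_hz Frequency-bin width of the reference-spectrum grid.
#' @return A list of class `hw_feature_config`.
#' @export
feature_config <- function(density_cell_units = 300, pressure_bucket = 10,
                           tremor_window = 10, gap_mm = 3, linebreak_mm = 8,
                           bandwidth_mass = 0.95, ref_bin_hz = 0.5) {
  stopifnot(density_cell_units > 0, pressure_bucket >= 1, tremor_window >= 2,
            gap_mm > 0, linebreak_mm > 0,
            bandwidth_mass > 0, bandwidth_mass < 1, ref_bin_hz > 0)
  structure(list(density_cell_units = density_cell_units,
                 pressure_bucket = as.integer(pressure_bucket),
                 tremor_window = as.integer(tremor_window),
                 gap_mm = gap_mm, linebreak_mm = linebreak_mm,
                 bandwidth_mass = bandwidth_mass, ref_bin_hz = ref_bin_hz),
            class = "hw_feature_config")
}

#' Tangential speed series of the pen-down trajectory
#'
#' Speed in mm/s between consecutive on-surface samples within a stroke
#' (pen-up gaps never contribute a pair), concatenated across strokes in
#' writing order. This is the two-dimensional handwriting trace read as a
#' time series; its spectrum carries the kinematic features.
#'
#' @param rec A [pen_recording()].
#' @return Numeric vector of speeds (mm/s).
#' @export
speed_series <- function(rec) {
  strokes <- segment_strokes(rec)
  res <- rec_resolution(rec)
  out <- purrr::pmap(strokes, function(stroke, start, end) {
    idx <- start:(end - 1L)
    if (length(idx) < 2) return(numeric(0))
    dx <- diff(rec$x[idx]); dy <- diff(rec$y[idx]); dt <- diff(rec$t[idx])
    sqrt(dx^2 + dy^2) * res / dt
  })
  v <- unlist(out, use.names = FALSE)
  if (length(v) < 1) {
    abort("fewer than 2 on-surface samples in any stroke",
          class = "handwritr_insufficient_data")
  }
  v
}

#' Mean space between words
#'
#' Mean, over within-line consecutive word pairs, of the horizontal white
#' gap between the words' bounding boxes, in mm.
#'
#' @param rec A [pen_recording()].
#' @param config A [feature_config()].
#' @return Gap in mm, or `NA` if no line holds two words.
#' @export
feature_space_between_words <- function(rec, config = feature_config()) {
  words <- tryCatch(segment_words(rec, config$gap_mm, config$linebreak_mm),
                    error = function(e) NULL)
  if (is.null(words)) return(NA_real_)
  boxes <- words |>
    dplyr::group_by(.data$line, .data$word) |>
    dplyr::summarise(xmin = min(.data$xmin), xmax = max(.data$xmax),
                     .groups = "drop") |>
    dplyr::arrange(.data$word)
  gaps <- boxes |>
    dplyr::group_by(.data$line) |>
    dplyr::mutate(gap = .data$xmin - dplyr::lag(.data$xmax)) |>
    dplyr::ungroup()
  g <- gaps$gap[!is.na(gaps$gap)]
  if (length(g) == 0) return(NA_real_)
  mean(g)
}

#' SD of handwriting density
#'
#' Tessellates the trace bounding box with square cells
#' (`density_cell_units` device units a side, anchored at the bounding-box
#' minimum), counts the on-surface samples falling in each occupied cell,
#' and returns the sample SD of those counts. A compact, evenly-paced trace
#' gives uniform counts (low SD); dense letter clusters inflate it. A
#' single occupied cell returns 0 by convention.
#'
#' @inheritParams feature_space_between_words
#' @return SD of per-occupied-cell counts (points/cell); `NA` with no
#'   on-surface samples.
#' @export
feature_density_sd <- function(rec, config = feature_config()) {
  on <- rec$on_surface
  if (!any(on)) return(NA_real_)
  cell <- config$density_cell_units
  x <- rec$x[on]; y <- rec$y[on]
  ix <- floor((x - min(x)) / cell)
  iy <- floor((y - min(y)) / cell)
  counts <- as.numeric(table(paste(ix, iy)))
  if (length(counts) == 1) return(0)
  sd(counts)
}

# perpendicular deviation (mm) of each stroke's trace from its centered
# moving-average smooth; NA-trimmed at the window edges
tremor_residual <- function(rec, window) {
  strokes <- segment_strokes(rec)
  res <- rec_resolution(rec)
  pieces <- purrr::pmap(strokes, function(stroke, start, end) {
    idx <- start:(end - 1L)
    n <- length(idx)
    if (n < window + 2) return(numeric(0))
    x <- rec$x[idx]; y <- rec$y[idx]
    w <- rep(1 / window, window)
    xs <- as.numeric(stats::filter(x, w, sides = 2))
    ys <- as.numeric(stats::filter(y, w, sides = 2))
    keep <- which(!is.na(xs))
    if (length(keep) < 3) return(numeric(0))
    xs <- xs[keep]; ys <- ys[keep]
    xr <- x[keep] - xs; yr <- y[keep] - ys
    # unit tangent of the smooth via central differences
    tx <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[-c(length(xs) - 1, length(xs))]) / 2,
            xs[length(xs)] - xs[length(xs) - 1])
    ty <- c(ys[2] - ys[1], (ys[-(1:2)] - ys[-c(length(ys) - 1, length(ys))]) / 2,
            ys[length(ys)] - ys[length(ys) - 1])
    nt <- sqrt(tx^2 + ty^2)
    perp <- ifelse(nt > 0, (xr * ty - yr * tx) / pmax(nt, .Machine$double.eps),
                   0)
    perp * res
  })
  unlist(pieces, use.names = FALSE)
}

#' Median tremor frequency
#'
#' The tremor series is the perpendicular deviation of the pen-down trace
#' from its centered moving-average smooth, per stroke and concatenated;
#' the feature is the spectral median of that series. Abnormal movements
#' show up as high-frequency residual power, pushing the median up.
#'
#' @inheritParams feature_space_between_words
#' @return Median tremor frequency in Hz; `NA` when fewer than
#'   `2 * tremor_window` on-surface samples remain or the residual is flat.
#' @export
feature_tremor_median <- function(rec, config = feature_config()) {
  if (sum(rec$on_surface) < 2 * config$tremor_window) return(NA_real_)
  r <- tremor_residual(rec, config$tremor_window)
  if (length(r) < 8) return(NA_real_)
  if (sd(r) < 1e-12) return(NA_real_)     # perfectly smooth trace
  ps <- power_spectrum(r, rec_fs(rec))
  if (spectrum_degenerate(ps)) return(NA_real_)
  spectral_median(ps)
}

#' In-air time ratio
#'
#' Fraction of the total task duration during which the pen is off the
#' surface: the sum of inter-sample intervals whose left sample is
#' off-surface, over the total recorded duration.
#'
#' @param rec A [pen_recording()].
#' @return Ratio in \[0, 1\].
#' @export
feature_in_air_ratio <- function(rec) {
  dt <- diff(rec$t)
  total <- sum(dt)
  if (total <= 0) return(NA_real_)
  sum(dt[!rec$on_surface[-nrow(rec)]]) / total
}

#' Pressure features: mean pressure and pressure-change speeds
#'
#' `mean_pressure` is the average on-surface pressure. The pressure-change
#' speed works on consecutive non-overlapping buckets of
#' `pressure_bucket` on-surface samples: for each adjacent bucket pair the
#' speed is the absolute difference of the bucket mean pressures divided by
#' the time between the buckets' centres. The feature pair is the mean and
#' the sample SD of those speeds; a child who modulates pen pressure
#' flexibly (better automation) shows a larger SD.
#'
#' @inheritParams feature_space_between_words
#' @return Named list: `mean_pressure`, `mean_speed_pressure_change`,
#'   `sd_speed_pressure_change` (device units, units/s). The change speeds
#'   are `NA` with fewer than two complete buckets.
#' @export
feature_pressure_stats <- function(rec, config = feature_config()) {
  on <- rec$on_surface
  if (!any(on)) {
    return(list(mean_pressure = NA_real_,
                mean_speed_pressure_change = NA_real_,
                sd_speed_pressure_change = NA_real_))
  }
  p <- rec$pressure[on]
  t <- rec$t[on]
  out <- list(mean_pressure = mean(p),
              mean_speed_pressure_change = NA_real_,
              sd_speed_pressure_change = NA_real_)
  b <- config$pressure_bucket
  n_buckets <- floor(length(p) / b)
  if (n_buckets >= 2) {
    grp <- rep(seq_len(n_buckets), each = b)
    used <- seq_len(n_buckets * b)
    pm <- tapply(p[used], grp, mean)
    tc <- tapply(t[used], grp, mean)
    speeds <- abs(diff(pm)) / diff(tc)
    out$mean_speed_pressure_change <- mean(speeds)
    out$sd_speed_pressure_change <-
      if (length(speeds) > 1) sd(speeds) else 0
  }
  out
}

#' Tilt features
#'
#' Passes the on-surface tilt-x and tilt-y series through the shared
#' spectral machinery: distance of the tilt-x spectrum to the grade
#' reference, central-mass bandwidth of the tilt-x spectrum, and spectral
#' median of the tilt-y series (lower in children with handwriting
#' difficulties).
#'
#' @inheritParams feature_space_between_words
#' @param ref A [build_reference_spectra()] object (or `NULL`: the distance
#'   is returned missing).
#' @param grade School grade of the writer.
#' @return Named list: `dist_mean_tiltx_freq`, `bandwidth_tiltx`,
#'   `median_psd_tilty`. Constant tilt gives degenerate spectra, reported
#'   as `NA`.
#' @export
feature_tilt_set <- function(rec, ref = NULL, grade = NULL,
                             config = feature_config()) {
  on <- rec$on_surface
  out <- list(dist_mean_tiltx_freq = NA_real_, bandwidth_tiltx = NA_real_,
              median_psd_tilty = NA_real_)
  fs <- rec_fs(rec)
  tx <- rec$tilt_x[on]; ty <- rec$tilt_y[on]
  if (length(tx) >= 8) {
    psx <- power_spectrum(tx, fs)
    if (!spectrum_degenerate(psx)) {
      out$bandwidth_tiltx <- spectral_bandwidth(psx, config$bandwidth_mass)
      if (!is.null(ref) && !is.null(grade)) {
        out$dist_mean_tiltx_freq <-
          tryCatch(spectral_distance(psx, ref, grade, "tiltx"),
                   handwritr_reference_error = function(e) NA_real_)
      }
    }
  }
  if (length(ty) >= 8) {
    psy <- power_spectrum(ty, fs)
    if (!spectrum_degenerate(psy)) {
      out$median_psd_tilty <- spectral_median(psy)
    }
  }
  out
}

#' Extract the twelve digital handwriting features
#'
#' Computes the full static / kinematic / pressure / tilt feature vector of
#' one recording. Features whose preconditions fail (too few samples,
#' degenerate spectra, fewer than two words, missing reference grade) are
#' returned as `NA`, never silently zero-filled. The function is a pure
#' function of its inputs: the same recording, reference and configuration
#' always give the identical vector.
#'
#' @param rec A [pen_recording()].
#' @param ref A [build_reference_spectra()] object, or `NULL` (spectral
#'   distances come back missing).
#' @param grade School grade of the writer (for the reference lookup).
#' @param config A [feature_config()].
#' @return One-row tibble: `child_id`, then `space_between_words` (mm),
#'   `sd_handwriting_density` (points/cell), `median_psd_tremor`,
#'   `median_psd_speed` (Hz), `dist_mean_speed_freq`, `in_air_time_ratio`,
#'   `mean_pressure`, `mean_speed_pressure_change`,
#'   `sd_speed_pressure_change`, `dist_mean_tiltx_freq`, `bandwidth_tiltx`
#'   (Hz), `median_psd_tilty` (Hz).
#' @export
extract_features <- function(rec, ref = NULL, grade = NULL,
                             config = feature_config()) {
  validate_recording(rec)
  fs <- rec_fs(rec)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  v <- tryCatch(speed_series(rec), error = function(e) numeric(0))
  median_psd_speed <- NA_real_
  dist_speed <- NA_real_
  if (length(v) >= 8) {
    psv <- power_spectrum(v, fs)
    if (!spectrum_degenerate(psv)) {
      median_psd_speed <- spectral_median(psv)
      if (!is.null(ref) && !is.null(grade)) {
        dist_speed <- safe(spectral_distance(psv, ref, grade, "speed"))
      }
    }
  }
  pstats <- feature_pressure_stats(rec, config)
  tilt <- feature_tilt_set(rec, ref, grade, config)

  tibble::tibble(
    child_id = attr(rec, "child_id"),
    space_between_words = feature_space_between_words(rec, config),
    sd_handwriting_density = feature_density_sd(rec, config),
    median_psd_tremor = feature_tremor_median(rec, config),
    median_psd_speed = median_psd_speed,
    dist_mean_speed_freq = dist_speed,
    in_air_time_ratio = feature_in_air_ratio(rec),
    mean_pressure = pstats$mean_pressure,
    mean_speed_pressure_change = pstats$mean_speed_pressure_change,
    sd_speed_pressure_change = pstats$sd_speed_pressure_change,
    dist_mean_tiltx_freq = tilt$dist_mean_tiltx_freq,
    bandwidth_tiltx = tilt$bandwidth_tiltx,
    median_psd_tilty = tilt$median_psd_tilty)
}

#' Names of the twelve digital features
#'
#' @return Character vector of the feature column names produced by
#'   [extract_features()], in table order.
#' @export
feature_names <- function() {
  c("space_between_words", "sd_handwriting_density", "median_psd_tremor",
    "median_psd_speed", "dist_mean_speed_freq", "in_air_time_ratio",
    "mean_pressure", "mean_speed_pressure_change",
    "sd_speed_pressure_change", "dist_mean_tiltx_freq", "bandwidth_tiltx",
    "median_psd_tilty")
}
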