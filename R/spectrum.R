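#' One-sided periodogram of a real series
#'
#' Mean-removed, unwindowed magnitude-squared DFT on the positive
#' frequencies, DC excluded. This is the shared estimator behind every
#' spectral feature (speed, tremor, tilt): their statistics are taken from
#' the normalized spectral distribution, so the periodogram's scale
#' convention is immaterial.
#'
#' @param series Real-valued, uniformly sampled series (length >= 8).
#' @param fs Sampling rate in Hz.
#' @return A `hw_power_spectrum`: tibble with `freq` (Hz, from fs/n to
#'   Nyquist), `power`, `normalized_power` (sums to 1), plus attributes `fs`
#'   and `total_power`. A constant series yields an all-zero spectrum with
#'   `total_power` 0 (degenerate; downstream statistics return missing).
#' @export
power_spectrum <- function(series, fs) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 8) {
    abort("series too short for a spectrum (need >= 8 samples)",
          class = "handwritr_insufficient_data")
  }
  z <- fft(series - mean(series))
  n_keep <- floor(n / 2)
  power <- (Mod(z)^2 / n)[seq_len(n_keep) + 1L]
  freq <- (seq_len(n_keep)) * fs / n
  total <- sum(power)
  norm <- if (total > 0) power / total else rep(0, n_keep)
  tibble::new_tibble(
    tibble::tibble(freq = freq, power = power, normalized_power = norm),
    class = "hw_power_spectrum", fs = fs, total_power = total)
}

spectrum_degenerate <- function(ps) attr(ps, "total_power") <= 0

#' Median frequency of a power spectrum
#'
#' Smallest frequency at which the cumulative normalized power reaches one
#' half. Jerky, poorly automated handwriting concentrates power at higher
#' frequencies, shifting this median upward for speed and tremor series.
#'
#' @param ps A [power_spectrum()].
#' @return Median frequency in Hz, or an error if the spectrum carries no
#'   power.
#' @export
spectral_median <- function(ps) {
  if (spectrum_degenerate(ps)) {
    abort("zero total power: spectral median undefined",
          class = "handwritr_degenerate_spectrum")
  }
  ps$freq[which(cumsum(ps$normalized_power) >= 0.5)[1]]
}

#' Central-mass bandwidth of a power spectrum
#'
#' Width `f_hi - f_lo` of the central frequency interval containing `mass`
#' of the normalized power, excluding equal tail mass on each side. A
#' single-line spectrum has bandwidth 0; spectrally spread pen behaviour
#' (e.g. erratic tilt) widens it.
#'
#' @param ps A [power_spectrum()].
#' @param mass Central spectral mass, in (0, 1). Default 0.95.
#' @return Bandwidth in Hz.
#' @export
spectral_bandwidth <- function(ps, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  if (spectrum_degenerate(ps)) {
    abort("zero total power: bandwidth undefined",
          class = "handwritr_degenerate_spectrum")
  }
  tail_mass <- (1 - mass) / 2
  cum <- cumsum(ps$normalized_power)
  f_lo <- ps$freq[which(cum > tail_mass)[1]]
  f_hi <- ps$freq[which(cum >= 1 - tail_mass)[1]]
  f_hi - f_lo
}

# aggregate a spectrum's normalized power onto a fixed grid of bins
# ((j-1)h, jh], labelled by the upper edge j*h
rebin_spectrum <- function(ps, bin_hz, n_bins) {
  idx <- pmin(ceiling(ps$freq / bin_hz - 1e-12), n_bins)
  out <- numeric(n_bins)
  agg <- tapply(ps$normalized_power, idx, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Per-grade reference spectra of typical writers
#'
#' Averages the normalized speed- and tilt-x spectra of a reference cohort
#' of typically developing children, per school grade, on a fixed frequency
#' grid. The spectral-distance features compare a child's spectrum with the
#' reference of the typical child of the same grade.
#'
#' @param recordings List of [pen_recording()]s from the reference cohort.
#' @param grades Integer vector (same length) of school grades 1-5.
#' @param config A [feature_config()]; uses `ref_bin_hz` and `tremor_window`.
#' @return A `hw_reference_spectra`: tibble with `grade`, `channel`
#'   ("speed" or "tiltx"), `freq` (bin upper edge, Hz) and `power` (mean
#'   normalized power, renormalized per grade x channel), with an
#'   `n_children` attribute. Children whose series are degenerate in a
#'   channel are dropped from that channel's mean; an empty grade is
#'   omitted with a warning.
#' @export
build_reference_spectra <- function(recordings, grades,
                                    config = feature_config()) {
  stopifnot(length(recordings) == length(grades))
  h <- config$ref_bin_hz
  per_child <- function(rec) {
    fs <- rec_fs(rec)
    n_bins <- ceiling(fs / 2 / h)
    out <- list()
    v <- tryCatch(speed_series(rec), error = function(e) NULL)
    if (!is.null(v) && length(v) >= 8) {
      ps <- power_spectrum(v, fs)
      if (!spectrum_degenerate(ps)) {
        out$speed <- rebin_spectrum(ps, h, n_bins)
      }
    }
    tx <- rec$tilt_x[rec$on_surface]
    if (length(tx) >= 8) {
      ps <- power_spectrum(tx, fs)
      if (!spectrum_degenerate(ps)) {
        out$tiltx <- rebin_spectrum(ps, h, n_bins)
      }
    }
    out
  }
  rows <- list()
  counts <- list()
  for (g in sort(unique(grades))) {
    idx <- which(grades == g)
    specs <- purrr::map(recordings[idx], per_child)
    for (ch in c("speed", "tiltx")) {
      mats <- purrr::compact(purrr::map(specs, ch))
      if (length(mats) == 0) {
        warn(sprintf("grade %s has no usable %s spectra; omitted", g, ch))
        next
      }
      m <- Reduce(`+`, mats) / length(mats)
      m <- m / sum(m)
      rows[[paste(g, ch)]] <- tibble::tibble(
        grade = g, channel = ch,
        freq = seq_along(m) * h, power = m)
      counts[[paste(g, ch)]] <- tibble::tibble(grade = g, channel = ch,
                                               n = length(mats))
    }
  }
  if (length(rows) == 0) {
    abort("no usable reference spectra", class = "handwritr_reference_error")
  }
  tibble::new_tibble(dplyr::bind_rows(rows), class = "hw_reference_spectra",
                     bin_hz = h, n_children = dplyr::bind_rows(counts))
}

ref_lookup <- function(ref, grade, channel) {
  sub <- ref[ref$grade == grade & ref$channel == channel, ]
  if (nrow(sub) == 0) {
    abort(sprintf("reference spectra missing grade %s channel %s",
                  grade, channel),
          class = "handwritr_reference_error")
  }
  sub
}

#' Euclidean distance between a spectrum and a grade reference
#'
#' Re-bins the child's normalized spectrum onto the reference grid and
#' takes the Euclidean distance between the two normalized power vectors.
#' Zero iff the spectra agree on the grid; larger values flag more
#' "eclectic" writers relative to the typical child of the same grade.
#'
#' @param ps A [power_spectrum()].
#' @param ref A [build_reference_spectra()] object.
#' @param grade School grade to compare against.
#' @param channel `"speed"` or `"tiltx"`.
#' @return Non-negative dimensionless distance.
#' @export
spectral_distance <- function(ps, ref, grade, channel = c("speed", "tiltx")) {
  channel <- match.arg(channel)
  if (spectrum_degenerate(ps)) {
    abort("zero total power: spectral distance undefined",
          class = "handwritr_degenerate_spectrum")
  }
  sub <- ref_lookup(ref, grade, channel)
  h <- attr(ref, "bin_hz")
  n_ref <- nrow(sub)
  n_child <- ceiling(max(ps$freq) / h - 1e-12)
  n_bins <- max(n_ref, n_child)
  p <- rebin_spectrum(ps, h, n_bins)
  q <- c(sub$power, rep(0, n_bins - n_ref))
  sqrt(sum((p - q)^2))
}

#' Write / read reference spectra as delimited text
#'
#' @param ref A `hw_reference_spectra`.
#' @param path File path (tab-separated: grade, channel, freq, power).
#' @return `write_reference_spectra()` returns `path` invisibly;
#'   `read_reference_spectra()` the reconstructed object.
#' @export
write_reference_spectra <- function(ref, path) {
  counts <- attr(ref, "n_children")
  header <- c(paste0("#bin_hz: ", format(attr(ref, "bin_hz"), digits = 12)),
              paste0("#n_children: ",
                     paste(sprintf("%s:%s:%d", counts$grade, counts$channel,
                                   counts$n), collapse = " ")))
  writeLines(c(header, "grade\tchannel\tfreq\tpower",
               sprintf("%d\t%s\t%.6f\t%.17g",
                       ref$grade, ref$channel, ref$freq, ref$power)), path)
  invisible(path)
}

#' @rdname write_reference_spectra
#' @export
read_reference_spectra <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bin_hz <- as.numeric(sub("^#bin_hz:\\s*", "",
                           grep("^#bin_hz:", lines, value = TRUE)[1]))
  cnt_raw <- strsplit(sub("^#n_children:\\s*", "",
                          grep("^#n_children:", lines, value = TRUE)[1]),
                      "\\s+")[[1]]
  parts <- strsplit(cnt_raw, ":")
  counts <- tibble::tibble(
    grade = as.numeric(vapply(parts, `[`, "", 1)),
    channel = vapply(parts, `[`, "", 2),
    n = as.integer(vapply(parts, `[`, "", 3)))
  dat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  tibble::new_tibble(tibble::as_tibble(dat), class = "hw_reference_spectra",
                     bin_hz = bin_hz, n_children = counts)
}
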