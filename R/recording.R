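#' Construct a pen-tablet recording
#'
#' A recording is a tibble of timestamped pen samples (class
#' `pen_recording`) with acquisition metadata stored in attributes. One row
#' per sample; the Wacom setup emulated here samples at 200 Hz with a
#' spatial resolution of 0.25 mm per device unit. Samples taken while the
#' pen hovers (pen-up) are retained — they carry the in-air time — but are
#' excluded from trajectory, pressure and tilt features downstream.
#'
#' @param samples Data frame with columns `t` (seconds from recording
#'   start), `x`, `y` (position, device units; y grows downward), `pressure`
#'   (device units, 0 when off-surface), `tilt_x`, `tilt_y` (degrees in
#'   \[-90, 90\]) and `on_surface` (logical contact flag).
#' @param fs Nominal sampling rate in Hz.
#' @param resolution_mm Millimetres per device unit.
#' @param device_id,child_id Labels carried through to outputs.
#'
#' @return A `pen_recording`: a tibble of samples with attributes `fs`,
#'   `resolution_mm`, `device_id`, `child_id`.
#' @export
#' @examples
#' rec <- pen_recording(
#'   data.frame(t = (0:9) / 200, x = 0:9, y = 0, pressure = 500,
#'              tilt_x = 30, tilt_y = 10, on_surface = TRUE))
#' rec
pen_recording <- function(samples, fs = 200, resolution_mm = 0.25,
                          device_id = "tablet", child_id = "unknown") {
  samples <- tibble::as_tibble(samples)
  req <- c("t", "x", "y", "pressure", "tilt_x", "tilt_y", "on_surface")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required sample columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "handwritr_format_error")
  }
  samples <- samples[req]
  samples$on_surface <- as.logical(samples$on_surface)
  rec <- tibble::new_tibble(samples, class = "pen_recording",
                            fs = fs, resolution_mm = resolution_mm,
                            device_id = device_id, child_id = child_id)
  validate_recording(rec)
  rec
}

#' Validate a pen recording against its invariants
#'
#' Checks strictly increasing time, non-negative finite timestamps, a median
#' sampling interval within 50% of the nominal 1/fs, non-negative pressure,
#' and zero pressure whenever the pen is off-surface.
#'
#' @param rec A `pen_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error of class
#'   `handwritr_validation_error` naming the first offending row.
#' @export
validate_recording <- function(rec) {
  if (nrow(rec) < 2) {
    abort("a recording needs at least 2 samples",
          class = "handwritr_validation_error")
  }
  t <- rec$t
  if (any(!is.finite(t)) || any(t < 0)) {
    bad <- which(!is.finite(t) | t < 0)[1]
    abort(paste0("non-finite or negative timestamp at row ", bad),
          class = "handwritr_validation_error")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    abort(paste0("time not strictly increasing at row ", bad),
          class = "handwritr_validation_error")
  }
  fs <- rec_fs(rec)
  if (abs(median(dt) - 1 / fs) / (1 / fs) >= 0.5) {
    abort("median sampling interval inconsistent with nominal fs",
          class = "handwritr_validation_error")
  }
  if (any(rec$pressure < 0, na.rm = TRUE)) {
    bad <- which(rec$pressure < 0)[1]
    abort(paste0("negative pressure at row ", bad),
          class = "handwritr_validation_error")
  }
  off <- !rec$on_surface
  if (any(rec$pressure[off] != 0)) {
    bad <- which(off & rec$pressure != 0)[1]
    abort(paste0("nonzero pressure while off-surface at row ", bad),
          class = "handwritr_validation_error")
  }
  invisible(rec)
}

rec_fs <- function(rec) attr(rec, "fs")
rec_resolution <- function(rec) attr(rec, "resolution_mm")

#' @export
print.pen_recording <- function(x, ...) {
  cat(sprintf(
    "<pen_recording> child %s on %s: %d samples, %.3f s, fs = %g Hz, %.2f mm/unit\n",
    attr(x, "child_id"), attr(x, "device_id"), nrow(x),
    diff(range(x$t)), rec_fs(x), rec_resolution(x)))
  NextMethod()
}

#' Read a pen recording from a delimited log file
#'
#' The log format is plain comma-separated text with a header row naming
#' the columns and `#key: value` comment lines holding the acquisition
#' metadata (`fs`, `resolution_mm`, `device_id`, `child_id`). Column names
#' differing from the canonical `t,x,y,pressure,tilt_x,tilt_y,on_surface`
#' can be mapped through `schema`.
#'
#' @param path Path to the log file.
#' @param schema Optional named character vector mapping canonical names to
#'   the names used in the file, e.g. `c(t = "time", pressure = "p")`.
#' @return A [pen_recording()].
#' @export
read_recording <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "handwritr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(fs = 200, resolution_mm = 0.25,
               device_id = "tablet", child_id = "unknown")
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% c("fs", "resolution_mm")) meta[[key]] <- as.numeric(val)
    else if (key %in% c("device_id", "child_id")) meta[[key]] <- val
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(dat)) {
        abort(paste0("schema column not in file: ", schema[[canon]]),
              class = "handwritr_format_error")
      }
      names(dat)[names(dat) == schema[[canon]]] <- canon
    }
  }
  req <- c("t", "x", "y", "pressure", "tilt_x", "tilt_y", "on_surface")
  missing_cols <- setdiff(req, names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "handwritr_format_error")
  }
  dat$on_surface <- as.logical(dat$on_surface)
  pen_recording(dat, fs = meta$fs, resolution_mm = meta$resolution_mm,
                device_id = meta$device_id, child_id = meta$child_id)
}

#' Write a pen recording to a delimited log file
#'
#' Inverse of [read_recording()]: `#key: value` metadata lines, a header
#' row, then one comma-separated row per sample. Timestamps are written to
#' 1e-6 s, positions, pressure and tilt to 1e-4 of a device unit/degree,
#' which is lossless for integer device units.
#'
#' @param rec A [pen_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open for writing: ", path),
          class = "handwritr_io_error")
  })
  on.exit(close(con))
  writeLines(c(
    paste0("#fs: ", format(rec_fs(rec), digits = 12)),
    paste0("#resolution_mm: ", format(rec_resolution(rec), digits = 12)),
    paste0("#device_id: ", attr(rec, "device_id")),
    paste0("#child_id: ", attr(rec, "child_id")),
    "t,x,y,pressure,tilt_x,tilt_y,on_surface",
    sprintf("%.6f,%.4f,%.4f,%.4f,%.4f,%.4f,%d",
            rec$t, rec$x, rec$y, rec$pressure,
            rec$tilt_x, rec$tilt_y, as.integer(rec$on_surface))
  ), con)
  invisible(path)
}

#' Segment a recording into pen-down strokes
#'
#' A stroke is a maximal contiguous run of on-surface samples. Together the
#' strokes partition the on-surface samples of the recording.
#'
#' @param rec A [pen_recording()].
#' @return Tibble with one row per stroke: `stroke` (index), `start`, `end`
#'   (half-open sample-index range `[start, end)` into the recording).
#' @export
segment_strokes <- function(rec) {
  on <- rec$on_surface
  if (!any(on)) {
    return(tibble::tibble(stroke = integer(), start = integer(),
                          end = integer()))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(stroke = seq_len(sum(keep)),
                 start = starts[keep], end = ends[keep] + 1L)
}

stroke_boxes <- function(rec, strokes) {
  res <- rec_resolution(rec)
  purrr::pmap_dfr(strokes, function(stroke, start, end) {
    idx <- start:(end - 1L)
    tibble::tibble(stroke = stroke,
                   xmin = min(rec$x[idx]) * res, xmax = max(rec$x[idx]) * res,
                   ymin = min(rec$y[idx]) * res, ymax = max(rec$y[idx]) * res,
                   ycen = mean(range(rec$y[idx])) * res)
  })
}

#' Group strokes into words and lines
#'
#' Strokes are scanned in writing order. A downward jump of the stroke's
#' vertical centre of at least `linebreak_mm` opens a new line; within a
#' line, a horizontal white gap of at least `gap_mm` between consecutive
#' strokes' bounding boxes opens a new word. The grouping is invariant under
#' rigid translation of the coordinates. The copying-task layout this
#' assumes is left-to-right lines; the thresholds are configuration, not
#' estimated from the data.
#'
#' @param rec A [pen_recording()].
#' @param gap_mm Minimum horizontal bounding-box gap starting a new word.
#' @param linebreak_mm Minimum downward y jump starting a new line.
#' @return Tibble with one row per stroke: `stroke`, `line`, `word` (word
#'   ids are global, in writing order), plus bounding-box columns in mm.
#' @export
segment_words <- function(rec, gap_mm = 3, linebreak_mm = 8) {
  strokes <- segment_strokes(rec)
  if (nrow(strokes) == 0) {
    abort("no strokes to group into words", class = "handwritr_validation_error")
  }
  boxes <- stroke_boxes(rec, strokes)
  n <- nrow(boxes)
  line <- integer(n); word <- integer(n)
  line[1] <- 1L; word[1] <- 1L
  for (i in seq_len(n)[-1]) {
    if (boxes$ycen[i] - boxes$ycen[i - 1] >= linebreak_mm) {
      line[i] <- line[i - 1] + 1L
      word[i] <- word[i - 1] + 1L        # new line always starts a new word
    } else {
      line[i] <- line[i - 1]
      gap <- boxes$xmin[i] - boxes$xmax[i - 1]
      word[i] <- word[i - 1] + (gap >= gap_mm)
    }
  }
  dplyr::bind_cols(boxes, tibble::tibble(line = line, word = word))
}
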