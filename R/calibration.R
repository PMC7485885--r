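#' Fit a polynomial device pressure-response curve
#'
#' Models the mapping from applied weight on the pen tip (grams) to the
#' pressure value reported by the tablet, by least squares on a polynomial
#' of the given degree. Two tablets of different generations report
#' different raw pressure values for the same physical load; fitting each
#' device's response over the 0–400 g range (up to output saturation) is the
#' first half of cross-device harmonization.
#'
#' @param weights Applied weights in grams.
#' @param outputs Device pressure outputs at those weights.
#' @param degree Polynomial degree (default 4).
#' @param valid_range Weight range over which the curve is trusted.
#' @return A `hw_calibration` object: coefficients (intercept first),
#'   degree, valid range and a residual report (`fitted`, `residuals`,
#'   `rmse`).
#' @export
#' @examples
#' w <- seq(0, 400, length.out = 15)
#' cal <- fit_calibration(w, 2.5 * w, degree = 1)
#' predict(cal, c(100, 200))
fit_calibration <- function(weights, outputs, degree = 4,
                            valid_range = c(0, 400)) {
  stopifnot(length(weights) == length(outputs))
  if (length(unique(weights)) < degree + 1) {
    abort(sprintf("need at least %d distinct weights for degree %d",
                  degree + 1, degree),
          class = "handwritr_rank_error")
  }
  fit <- lm(outputs ~ poly(weights, degree, raw = TRUE))
  coefs <- unname(coef(fit))
  out <- structure(
    list(degree = degree, coefficients = coefs, valid_range = valid_range,
         fitted = unname(fit$fitted.values),
         residuals = unname(fit$residuals),
         rmse = sqrt(mean(fit$residuals^2))),
    class = "hw_calibration")
  out
}

#' @export
print.hw_calibration <- function(x, ...) {
  cat(sprintf("<hw_calibration> degree %d on [%g, %g] g, rmse %.4g\n",
              x$degree, x$valid_range[1], x$valid_range[2], x$rmse))
  cat("coefficients:", format(x$coefficients, digits = 6), "\n")
  invisible(x)
}

#' @export
predict.hw_calibration <- function(object, newdata, ...) {
  g <- as.numeric(newdata)
  vapply(g, function(gi) sum(object$coefficients * gi^(0:object$degree)),
         numeric(1))
}

# monotonicity check on a fine grid over the valid range
calibration_monotone <- function(curve, n_grid = 2048) {
  g <- seq(curve$valid_range[1], curve$valid_range[2], length.out = n_grid)
  y <- predict(curve, g)
  all(diff(y) > 0)
}

# invert a monotone-increasing curve: bisection to `tol` grams, then a few
# Newton steps so the round trip target(source^-1(p)) is exact to ~1e-12
invert_calibration <- function(curve, p, tol = 1e-6) {
  lo <- curve$valid_range[1]; hi <- curve$valid_range[2]
  plo <- predict(curve, lo); phi <- predict(curve, hi)
  dcoef <- curve$coefficients[-1] * seq_len(curve$degree)
  dpred <- function(g) sum(dcoef * g^(seq_len(curve$degree) - 1))
  vapply(p, function(pi) {
    if (pi <= plo) return(lo)
    if (pi >= phi) return(hi)
    g <- uniroot(function(g) predict(curve, g) - pi, lower = lo, upper = hi,
                 tol = tol)$root
    for (i in 1:4) {
      slope <- dpred(g)
      if (slope <= 0) break
      g <- min(max(g - (predict(curve, g) - pi) / slope, lo), hi)
    }
    g
  }, numeric(1))
}

#' Harmonize pressures between two calibrated devices
#'
#' Maps each recorded pressure value p through
#' `target(source^-1(p))`: the source curve is inverted by bisection on the
#' shared valid weight range to recover the applied load, and the target
#' curve predicts what the reference device would have reported for that
#' load. Pressures outside the source's output range on the valid weights
#' are clamped to the range endpoints and counted in a warning.
#'
#' @param rec A [pen_recording()].
#' @param source Calibration curve of the device that made the recording.
#' @param target Calibration curve of the reference device.
#' @return The recording with harmonized on-surface pressures (off-surface
#'   samples keep pressure 0). The number of clamped values is attached as
#'   attribute `n_clamped`.
#' @export
harmonize_pressure <- function(rec, source, target) {
  if (!isTRUE(all.equal(source$valid_range, target$valid_range))) {
    abort("source and target curves must share a valid range",
          class = "handwritr_calibration_error")
  }
  if (!calibration_monotone(source)) {
    abort("source curve is not monotone increasing on its valid range",
          class = "handwritr_calibration_error")
  }
  on <- rec$on_surface
  p <- rec$pressure[on]
  lo <- predict(source, source$valid_range[1])
  hi <- predict(source, source$valid_range[2])
  n_clamped <- sum(p < lo | p > hi)
  if (n_clamped > 0) {
    warn(sprintf("%d pressure value(s) outside the calibrated range; clamped",
                 n_clamped))
  }
  grams <- invert_calibration(source, pmin(pmax(p, lo), hi))
  rec$pressure[on] <- predict(target, grams)
  attr(rec, "n_clamped") <- n_clamped
  rec
}

#' Write / read calibration curves as key-value text
#'
#' @param curve A `hw_calibration`.
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a `hw_calibration`.
#' @export
write_calibration <- function(curve, path) {
  writeLines(c(
    paste0("degree: ", curve$degree),
    paste0("coefficients: ",
           paste(format(curve$coefficients, digits = 17), collapse = " ")),
    paste0("valid_range: ",
           paste(format(curve$valid_range, digits = 17), collapse = " "))
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path, warn = FALSE)
  val <- function(key) trimws(sub("^[^:]*:", "",
                                  grep(paste0("^", key, ":"), lines,
                                       value = TRUE)[1]))
  structure(
    list(degree = as.integer(val("degree")),
         coefficients = as.numeric(strsplit(val("coefficients"), "\\s+")[[1]]),
         valid_range = as.numeric(strsplit(val("valid_range"), "\\s+")[[1]]),
         fitted = NULL, residuals = NULL, rmse = NA_real_),
    class = "hw_calibration")
}
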