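# Literal, loop-based reimplementations of the documented feature
# definitions, independent of the package internals (no fft, no dplyr, no
# rle). Used as brute-force oracles; deliberately slow and simple.

oracle_spectrum <- function(series, fs) {
  n <- length(series)
  x <- series - sum(series) / n
  K <- floor(n / 2)
  j <- 0:(n - 1)
  power <- numeric(K)
  for (k in seq_len(K)) {
    re <- sum(x * cos(2 * pi * k * j / n))
    im <- sum(x * sin(2 * pi * k * j / n))
    power[k] <- (re^2 + im^2) / n
  }
  total <- sum(power)
  list(freq = seq_len(K) * fs / n, power = power,
       norm = if (total > 0) power / total else rep(0, K),
       total = total)
}

oracle_spectral_median <- function(sp) {
  cum <- 0
  for (k in seq_along(sp$norm)) {
    cum <- cum + sp$norm[k]
    if (cum >= 0.5) return(sp$freq[k])
  }
  NA_real_
}

oracle_spectral_bandwidth <- function(sp, mass = 0.95) {
  tail_mass <- (1 - mass) / 2
  cum <- cumsum(sp$norm)
  f_lo <- NA_real_; f_hi <- NA_real_
  for (k in seq_along(cum)) {
    if (cum[k] > tail_mass) { f_lo <- sp$freq[k]; break }
  }
  for (k in seq_along(cum)) {
    if (cum[k] >= 1 - tail_mass) { f_hi <- sp$freq[k]; break }
  }
  f_hi - f_lo
}

# bins ((j-1)h, jh] labelled by the upper edge, overflow into the last bin
oracle_rebin <- function(freq, norm, h, n_bins) {
  out <- numeric(n_bins)
  for (k in seq_along(freq)) {
    b <- ceiling(freq[k] / h - 1e-12)
    if (b > n_bins) b <- n_bins
    out[b] <- out[b] + norm[k]
  }
  out
}

oracle_distance <- function(sp, ref, grade, channel) {
  sub <- ref[ref$grade == grade & ref$channel == channel, ]
  if (nrow(sub) == 0) return(NA_real_)
  h <- attr(ref, "bin_hz")
  n_child <- ceiling(max(sp$freq) / h - 1e-12)
  n_bins <- max(nrow(sub), n_child)
  p <- oracle_rebin(sp$freq, sp$norm, h, n_bins)
  q <- c(sub$power, rep(0, n_bins - nrow(sub)))
  s <- 0
  for (k in seq_len(n_bins)) s <- s + (p[k] - q[k])^2
  sqrt(s)
}

# maximal runs of on-surface samples, as a list of index vectors
oracle_strokes <- function(on) {
  runs <- list(); cur <- integer(0)
  for (i in seq_along(on)) {
    if (on[i]) {
      cur <- c(cur, i)
    } else if (length(cur)) {
      runs[[length(runs) + 1]] <- cur; cur <- integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

oracle_words <- function(rec, gap_mm, linebreak_mm) {
  runs <- oracle_strokes(rec$on_surface)
  if (length(runs) == 0) return(NULL)
  res <- attr(rec, "resolution_mm")
  n <- length(runs)
  xmin <- xmax <- ycen <- numeric(n)
  for (s in seq_len(n)) {
    xs <- rec$x[runs[[s]]]; ys <- rec$y[runs[[s]]]
    xmin[s] <- min(xs) * res; xmax[s] <- max(xs) * res
    ycen[s] <- (min(ys) + max(ys)) / 2 * res
  }
  line <- word <- integer(n); line[1] <- 1L; word[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      if (ycen[i] - ycen[i - 1] >= linebreak_mm) {
        line[i] <- line[i - 1] + 1L
        word[i] <- word[i - 1] + 1L
      } else {
        line[i] <- line[i - 1]
        word[i] <- word[i - 1] + as.integer(xmin[i] - xmax[i - 1] >= gap_mm)
      }
    }
  }
  data.frame(xmin = xmin, xmax = xmax, line = line, word = word)
}

oracle_space_between_words <- function(rec, cfg) {
  w <- oracle_words(rec, cfg$gap_mm, cfg$linebreak_mm)
  if (is.null(w)) return(NA_real_)
  gaps <- c()
  for (ln in unique(w$line)) {
    ws <- sort(unique(w$word[w$line == ln]))
    if (length(ws) < 2) next
    for (j in 2:length(ws)) {
      gaps <- c(gaps,
                min(w$xmin[w$word == ws[j]]) - max(w$xmax[w$word == ws[j - 1]]))
    }
  }
  if (length(gaps) == 0) NA_real_ else mean(gaps)
}

oracle_density_sd <- function(rec, cfg) {
  on <- rec$on_surface
  if (!any(on)) return(NA_real_)
  x <- rec$x[on]; y <- rec$y[on]
  ix <- floor((x - min(x)) / cfg$density_cell_units)
  iy <- floor((y - min(y)) / cfg$density_cell_units)
  key <- paste(ix, iy)
  counts <- c()
  for (k in unique(key)) counts <- c(counts, sum(key == k))
  if (length(counts) == 1) return(0)
  sd(counts)
}

oracle_speed_series <- function(rec) {
  runs <- oracle_strokes(rec$on_surface)
  res <- attr(rec, "resolution_mm")
  v <- c()
  for (idx in runs) {
    if (length(idx) < 2) next
    for (j in 2:length(idx)) {
      a <- idx[j - 1]; b <- idx[j]
      d <- sqrt((rec$x[b] - rec$x[a])^2 + (rec$y[b] - rec$y[a])^2) * res
      v <- c(v, d / (rec$t[b] - rec$t[a]))
    }
  }
  v
}

# perpendicular deviation from the centered moving-average smooth. For an
# even window the centered average extends floor(w/2) samples forward and
# floor((w-1)/2) backward (the convention of a centered two-sided filter).
oracle_tremor_residual <- function(rec, window) {
  runs <- oracle_strokes(rec$on_surface)
  res <- attr(rec, "resolution_mm")
  back <- (window - 1) %/% 2
  fwd <- window %/% 2
  out <- c()
  for (idx in runs) {
    n <- length(idx)
    if (n < window + 2) next
    x <- rec$x[idx]; y <- rec$y[idx]
    lo <- back + 1L; hi <- n - fwd
    K <- hi - lo + 1L
    if (K < 3) next
    xs <- ys <- numeric(K)
    for (k in seq_len(K)) {
      i <- lo + k - 1L
      xs[k] <- sum(x[(i - back):(i + fwd)] / window)
      ys[k] <- sum(y[(i - back):(i + fwd)] / window)
    }
    xr <- x[lo:hi] - xs; yr <- y[lo:hi] - ys
    tx <- ty <- numeric(K)
    for (k in seq_len(K)) {
      if (k == 1) { tx[k] <- xs[2] - xs[1]; ty[k] <- ys[2] - ys[1] }
      else if (k == K) { tx[k] <- xs[K] - xs[K - 1]; ty[k] <- ys[K] - ys[K - 1] }
      else { tx[k] <- (xs[k + 1] - xs[k - 1]) / 2
             ty[k] <- (ys[k + 1] - ys[k - 1]) / 2 }
    }
    perp <- numeric(K)
    for (k in seq_len(K)) {
      nt <- sqrt(tx[k]^2 + ty[k]^2)
      perp[k] <- if (nt > 0) (xr[k] * ty[k] - yr[k] * tx[k]) / nt else 0
    }
    out <- c(out, perp * res)
  }
  out
}

oracle_pressure <- function(rec, cfg) {
  on <- rec$on_surface
  out <- list(mean_pressure = NA_real_,
              mean_speed_pressure_change = NA_real_,
              sd_speed_pressure_change = NA_real_)
  if (!any(on)) return(out)
  p <- rec$pressure[on]; t <- rec$t[on]
  out$mean_pressure <- mean(p)
  b <- cfg$pressure_bucket
  nb <- floor(length(p) / b)
  if (nb >= 2) {
    pm <- tc <- numeric(nb)
    for (k in seq_len(nb)) {
      idx <- ((k - 1) * b + 1):(k * b)
      pm[k] <- mean(p[idx]); tc[k] <- mean(t[idx])
    }
    sp <- numeric(nb - 1)
    for (k in seq_len(nb - 1)) {
      sp[k] <- abs(pm[k + 1] - pm[k]) / (tc[k + 1] - tc[k])
    }
    out$mean_speed_pressure_change <- mean(sp)
    out$sd_speed_pressure_change <- if (length(sp) > 1) sd(sp) else 0
  }
  out
}

# the full twelve-feature vector, brute force
oracle_features <- function(rec, ref = NULL, grade = NULL,
                            cfg = feature_config()) {
  fs <- attr(rec, "fs")
  out <- list()
  out$space_between_words <- oracle_space_between_words(rec, cfg)
  out$sd_handwriting_density <- oracle_density_sd(rec, cfg)

  out$median_psd_tremor <- NA_real_
  if (sum(rec$on_surface) >= 2 * cfg$tremor_window) {
    r <- oracle_tremor_residual(rec, cfg$tremor_window)
    if (length(r) >= 8 && sd(r) >= 1e-12) {
      sp <- oracle_spectrum(r, fs)
      if (sp$total > 0) out$median_psd_tremor <- oracle_spectral_median(sp)
    }
  }

  v <- oracle_speed_series(rec)
  out$median_psd_speed <- NA_real_
  out$dist_mean_speed_freq <- NA_real_
  if (length(v) >= 8) {
    sp <- oracle_spectrum(v, fs)
    if (sp$total > 0) {
      out$median_psd_speed <- oracle_spectral_median(sp)
      if (!is.null(ref) && !is.null(grade)) {
        out$dist_mean_speed_freq <- oracle_distance(sp, ref, grade, "speed")
      }
    }
  }

  dt <- diff(rec$t)
  tot <- sum(dt); air <- 0
  for (i in seq_along(dt)) if (!rec$on_surface[i]) air <- air + dt[i]
  out$in_air_time_ratio <- if (tot > 0) air / tot else NA_real_

  ps <- oracle_pressure(rec, cfg)
  out$mean_pressure <- ps$mean_pressure
  out$mean_speed_pressure_change <- ps$mean_speed_pressure_change
  out$sd_speed_pressure_change <- ps$sd_speed_pressure_change

  out$dist_mean_tiltx_freq <- NA_real_
  out$bandwidth_tiltx <- NA_real_
  out$median_psd_tilty <- NA_real_
  tx <- rec$tilt_x[rec$on_surface]; ty <- rec$tilt_y[rec$on_surface]
  if (length(tx) >= 8) {
    sp <- oracle_spectrum(tx, fs)
    if (sp$total > 0) {
      out$bandwidth_tiltx <- oracle_spectral_bandwidth(sp, cfg$bandwidth_mass)
      if (!is.null(ref) && !is.null(grade)) {
        out$dist_mean_tiltx_freq <- oracle_distance(sp, ref, grade, "tiltx")
      }
    }
  }
  if (length(ty) >= 8) {
    sp <- oracle_spectrum(ty, fs)
    if (sp$total > 0) out$median_psd_tilty <- oracle_spectral_median(sp)
  }
  out
}

# compare extract_features() with the oracle on one recording; returns
# list(na_mismatch = character(), max_rel_err = numeric(1))
oracle_compare <- function(rec, ref = NULL, grade = NULL,
                           cfg = feature_config()) {
  got <- extract_features(rec, ref, grade, cfg)
  want <- oracle_features(rec, ref, grade, cfg)
  na_mismatch <- character(0)
  rel <- 0
  for (nm in names(want)) {
    g <- got[[nm]]; w <- want[[nm]]
    if (is.na(g) != is.na(w)) {
      na_mismatch <- c(na_mismatch, nm)
    } else if (!is.na(w)) {
      rel <- max(rel, abs(g - w) / max(1, abs(w)))
    }
  }
  list(na_mismatch = na_mismatch, max_rel_err = rel)
}

# normal-equation OLS oracle for the regression models
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}
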