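#' Script profile: generative parameters of one writer's pen trajectory
#'
#' Describes the kinematic, pressure and tilt structure of a simulated
#' copying task. Letters are stylized loops (the features under test
#' respond to kinematic and spectral structure, not legibility): each
#' letter is a circular arc of `letter_turns` turns and
#' `letter_height_mm` diameter, traversed at `base_speed_mm_s` modulated by
#' a small set of sinusoidal speed-fluctuation components; perpendicular
#' tremor rides on the trace; pen-up hops separate letters, words and
#' lines; pressure follows a piecewise-linear process whose slope resamples
#' at `pressure_switch_rate` per second; tilt is baseline plus one or two
#' sinusoidal components plus sensor noise.
#'
#' Defaults depend on `grade`: older children write faster with less
#' tremor, mirroring the developmental trends the regression models probe.
#'
#' @param grade School grade (1-5) setting the developmental defaults.
#' @param fs Sampling rate (Hz).
#' @param resolution_mm Millimetres per device unit.
#' @param base_speed_mm_s Mean pen-down speed.
#' @param speed_mod_freqs,speed_mod_amps Speed-fluctuation spectrum:
#'   relative amplitude at each frequency (Hz).
#' @param speed_mod_shift_hz Shift applied to every modulation frequency
#'   (subtype offsets act here to make speed spectra "eclectic").
#' @param tremor_amp_mm,tremor_freq_hz Perpendicular tremor.
#' @param letter_height_mm,letter_turns Loop geometry.
#' @param letters_per_word,words_per_line,n_lines Task layout.
#' @param inter_letter_gap_mm,word_gap_mean_mm,word_gap_sd_mm,line_height_mm
#'   Spatial layout (mm).
#' @param inter_letter_penup_s,inter_word_penup_s,inter_line_penup_s
#'   Pen-up (hover) durations.
#' @param pressure_base,pressure_slope_sd,pressure_switch_rate,p_max
#'   Pressure process (device units; slope SD in units/s; switch rate /s).
#' @param tilt_x_base,tilt_x_amp,tilt_x_freq,tilt_x_amp2,tilt_x_freq2
#'   Tilt-x baseline (deg) and oscillation components (deg, Hz).
#' @param tilt_y_base,tilt_y_amp,tilt_y_freq Tilt-y process.
#' @param tilt_noise_sd Tilt sensor noise (deg).
#' @param duration_cap_s Hard cap on simulated duration.
#' @return List of class `hw_script_profile`.
#' @export
script_profile <- function(grade = 3, fs = 200, resolution_mm = 0.25,
                           base_speed_mm_s = 16 + 3 * grade,
                           speed_mod_freqs = c(1.5, 4),
                           speed_mod_amps = c(0.25, 0.12),
                           speed_mod_shift_hz = 0,
                           tremor_amp_mm = 0.22 - 0.02 * grade,
                           tremor_freq_hz = 9,
                           letter_height_mm = 5, letter_turns = 1.25,
                           letters_per_word = 4, words_per_line = 5,
                           n_lines = 3,
                           inter_letter_gap_mm = 1,
                           word_gap_mean_mm = 5, word_gap_sd_mm = 1,
                           line_height_mm = 10,
                           inter_letter_penup_s = 0.15,
                           inter_word_penup_s = 0.6,
                           inter_line_penup_s = 0.9,
                           pressure_base = 520, pressure_slope_sd = 300,
                           pressure_switch_rate = 1.5, p_max = 1023,
                           tilt_x_base = 30, tilt_x_amp = 8,
                           tilt_x_freq = 2.5 + 0.25 * grade,
                           tilt_x_amp2 = 0, tilt_x_freq2 = 7,
                           tilt_y_base = 10, tilt_y_amp = 6,
                           tilt_y_freq = 4,
                           tilt_noise_sd = 0.25,
                           duration_cap_s = 240) {
  prof <- as.list(environment())
  stopifnot(prof$fs > 0, prof$base_speed_mm_s > 0,
            all(prof$speed_mod_amps >= 0), prof$tremor_amp_mm >= 0,
            all(prof$speed_mod_freqs < fs / 2), prof$tremor_freq_hz < fs / 2,
            prof$duration_cap_s > 0)
  structure(prof, class = "hw_script_profile")
}

# keep an offset-perturbed profile physically sensible
clamp_profile <- function(p) {
  p$base_speed_mm_s <- max(p$base_speed_mm_s, 5)
  p$tremor_amp_mm <- max(p$tremor_amp_mm, 0)
  p$speed_mod_shift_hz <- max(p$speed_mod_shift_hz, 0)
  p$word_gap_mean_mm <- max(p$word_gap_mean_mm, 1)
  p$word_gap_sd_mm <- max(p$word_gap_sd_mm, 0)
  p$pressure_slope_sd <- max(p$pressure_slope_sd, 15)
  p$pressure_base <- min(max(p$pressure_base, 80), p$p_max - 80)
  p$pressure_switch_rate <- max(p$pressure_switch_rate, 0.2)
  p$tilt_x_freq <- max(p$tilt_x_freq, 0.3)
  p$tilt_y_freq <- max(p$tilt_y_freq, 0.3)
  p$tilt_x_amp2 <- max(p$tilt_x_amp2, 0)
  p$inter_letter_penup_s <- max(p$inter_letter_penup_s, 0.02)
  p
}

#' Dysgraphia subtype profiles
#'
#' Named parameter-offset vectors applied to a [script_profile()] per unit
#' of latent severity, planting three recoverable subtypes that perturb
#' largely disjoint feature domains (profiles acting on the same axes at
#' different strengths would merge under clustering by construction):
#' * `mild`: near-typical stroke kinematics, but stretched word spacing,
#'   longer pen lifts and slightly raised tremor — a spatial/hesitation
#'   presentation.
#' * `kinematic_pressure`: tighter word spacing, flattened pressure
#'   dynamics (smaller, rarer slope changes, lower baseline) and a shifted
#'   speed-fluctuation spectrum.
#' * `tilt`: shifted tilt-x frequency plus a second high-frequency tilt-x
#'   component (wider bandwidth, larger distance to the typical spectrum)
#'   and a lowered tilt-y frequency.
#' `TD` is the all-zero offset.
#'
#' @return Named list of named numeric offset vectors.
#' @export
dysgraphia_subtypes <- function() {
  list(
    TD = c(),
    mild = c(word_gap_mean_mm = 1.6, inter_letter_penup_s = 0.14,
             tremor_amp_mm = 0.06),
    kinematic_pressure = c(word_gap_mean_mm = -0.6,
                           speed_mod_shift_hz = 0.9,
                           pressure_slope_sd = -90,
                           pressure_base = -55,
                           tremor_amp_mm = 0.02,
                           inter_letter_penup_s = 0.03),
    tilt = c(tilt_x_freq = 0.8, tilt_x_amp2 = 2.5, tilt_y_freq = -0.8,
             tremor_amp_mm = 0.02, inter_letter_penup_s = 0.03))
}

apply_subtype <- function(profile, offsets, severity) {
  for (nm in names(offsets)) {
    profile[[nm]] <- profile[[nm]] + severity * offsets[[nm]]
  }
  clamp_profile(profile)
}

#' Simulate a pen-tablet recording
#'
#' Draws the trajectory a [script_profile()] describes, sampled at `fs`,
#' and returns it as a [pen_recording()]. Deterministic given the seed.
#'
#' @param profile A [script_profile()].
#' @param seed Integer seed.
#' @param child_id,device_id Labels for the recording.
#' @return A [pen_recording()].
#' @export
#' @examples
#' rec <- simulate_recording(script_profile(n_lines = 1, words_per_line = 2),
#'                           seed = 7)
#' extract_features(rec)
simulate_recording <- function(profile, seed = 1L, child_id = "sim",
                               device_id = "sim-tablet") {
  if (!inherits(profile, "hw_script_profile")) {
    abort("profile must be a script_profile()",
          class = "handwritr_parameter_error")
  }
  p <- profile
  set.seed(seed)
  fs <- p$fs; dt <- 1 / fs
  r <- p$letter_height_mm / 2
  arc_per_letter <- p$letter_turns * 2 * pi * r
  freqs <- p$speed_mod_freqs + p$speed_mod_shift_hz
  phases <- runif(length(freqs), 0, 2 * pi)
  tremor_phase <- runif(1, 0, 2 * pi)
  speed_at <- function(t) {
    mod <- rep(1, length(t))
    for (j in seq_along(freqs)) {
      mod <- mod + p$speed_mod_amps[j] * sin(2 * pi * freqs[j] * t +
                                             phases[j])
    }
    pmax(p$base_speed_mm_s * mod, 0.15 * p$base_speed_mm_s)
  }

  xs <- list(); ys <- list(); ons <- list()
  i <- 0L                      # index of the next sample (time = i * dt)
  right_edge <- 0              # right edge of ink on the current line, mm
  line_y <- 0
  last_pos <- c(0, 0)
  max_samples <- ceiling(p$duration_cap_s * fs)
  done <- FALSE

  add_penup <- function(dur) {
    m <- max(1L, round(dur * fs))
    xs[[length(xs) + 1]] <<- rep(last_pos[1], m)
    ys[[length(ys) + 1]] <<- rep(last_pos[2], m)
    ons[[length(ons) + 1]] <<- rep(FALSE, m)
    i <<- i + m
  }
  add_letter <- function(cx, cy) {
    t0 <- i * dt
    m_guess <- ceiling(arc_per_letter / (0.15 * p$base_speed_mm_s) * fs) + 8L
    tk <- t0 + seq_len(m_guess) * dt
    s <- cumsum(speed_at(tk) * dt)
    m <- which(s >= arc_per_letter)[1]
    if (is.na(m)) m <- m_guess
    tt <- c(t0, tk[seq_len(m)])
    ss <- c(0, s[seq_len(m)])
    phi <- -pi / 2 + ss / r
    rk <- r + p$tremor_amp_mm * sin(2 * pi * p$tremor_freq_hz * tt +
                                    tremor_phase)
    xs[[length(xs) + 1]] <<- cx + rk * cos(phi)
    ys[[length(ys) + 1]] <<- cy + rk * sin(phi)
    ons[[length(ons) + 1]] <<- rep(TRUE, m + 1L)
    i <<- i + m + 1L
    last_pos <<- c(cx + rk[m + 1] * cos(phi[m + 1]),
                   cy + rk[m + 1] * sin(phi[m + 1]))
    right_edge <<- cx + r
  }

  for (line in seq_len(p$n_lines)) {
    if (done) break
    line_y <- (line - 1) * p$line_height_mm
    right_edge <- 0
    for (word in seq_len(p$words_per_line)) {
      if (done) break
      if (word > 1) {
        gap <- max(rnorm(1, p$word_gap_mean_mm, p$word_gap_sd_mm), 0.3)
        right_edge <- right_edge + gap - p$inter_letter_gap_mm
        add_penup(p$inter_word_penup_s)
      }
      for (letter in seq_len(p$letters_per_word)) {
        if (i > max_samples) { done <- TRUE; break }
        if (letter > 1) add_penup(p$inter_letter_penup_s)
        cx <- right_edge + p$inter_letter_gap_mm + r
        if (word == 1 && letter == 1) cx <- right_edge + r
        add_letter(cx, line_y)
      }
    }
    if (line < p$n_lines && !done) add_penup(p$inter_line_penup_s)
  }

  x_mm <- unlist(xs); y_mm <- unlist(ys); on <- unlist(ons)
  n <- length(x_mm)
  t <- (seq_len(n) - 1L) * dt

  # pressure: piecewise-linear slope process, resampled at switch times
  n_seg <- max(1L, stats::rpois(1, p$pressure_switch_rate * n * dt) + 1L)
  switch_t <- sort(runif(n_seg - 1, 0, n * dt))
  slopes <- rnorm(n_seg, 0, p$pressure_slope_sd)
  seg <- findInterval(t, switch_t) + 1L
  pressure <- p$pressure_base + rnorm(1, 0, 25) +
    cumsum(slopes[seg] * dt)
  pressure <- pmin(pmax(pressure, 15), p$p_max)
  pressure[!on] <- 0

  tphx <- runif(2, 0, 2 * pi); tphy <- runif(1, 0, 2 * pi)
  tilt_x <- p$tilt_x_base +
    p$tilt_x_amp * sin(2 * pi * p$tilt_x_freq * t + tphx[1]) +
    p$tilt_x_amp2 * sin(2 * pi * p$tilt_x_freq2 * t + tphx[2]) +
    rnorm(n, 0, p$tilt_noise_sd)
  tilt_y <- p$tilt_y_base +
    p$tilt_y_amp * sin(2 * pi * p$tilt_y_freq * t + tphy) +
    rnorm(n, 0, p$tilt_noise_sd)

  pen_recording(
    tibble::tibble(t = t,
                   x = x_mm / p$resolution_mm, y = y_mm / p$resolution_mm,
                   pressure = pressure,
                   tilt_x = pmin(pmax(tilt_x, -90), 90),
                   tilt_y = pmin(pmax(tilt_y, -90), 90),
                   on_surface = on),
    fs = fs, resolution_mm = p$resolution_mm,
    device_id = device_id, child_id = child_id)
}

#' Cohort specification
#'
#' Sample sizes, gender balance, task layout and the BHK generative model
#' linking latent severity to scores:
#' `quality_raw = a0 + a1 * grade + a2 * severity + gender effect + noise`
#' (floored at 0) and
#' `speed_raw = b0 + b1 * grade + b2 * severity + gender effect + noise`
#' (floored at 5). Typically developing children carry severity 0, so
#' their raw quality score is Gaussian given grade and gender and the -2
#' normalized cutoff corresponds to the upper normal tail; dysgraphic
#' children draw severity from N(`severity_mean`, `severity_sd`) truncated
#' at 1. The default marginals (218 TD, 62 D across grades 1-5, boys
#' over-represented in the D group) follow the shape of the cohort the
#' analysis is designed for.
#'
#' @param n_td_per_grade,n_d_per_grade Children per grade 1-5.
#' @param p_male_td,p_male_d Probability of male gender.
#' @param p_left Probability of left-handedness.
#' @param quality_coefs Named vector `a0`, `a1` (grade), `a2` (severity).
#' @param speed_coefs Named vector `b0`, `b1`, `b2`.
#' @param sigma_quality,sigma_speed Residual SDs.
#' @param gender_quality,gender_speed Additive male effect on each score.
#' @param severity_mean,severity_sd Latent severity in the D group.
#' @param subtype_weights Proportions of the D group in each planted
#'   subtype (`mild`, `kinematic_pressure`, `tilt`).
#' @param n_lines,words_per_line,letters_per_word Task layout used for the
#'   simulated recordings.
#' @return List of class `hw_cohort_spec`.
#' @export
cohort_spec <- function(n_td_per_grade = c(48, 42, 36, 44, 48),
                        n_d_per_grade = c(1, 16, 15, 20, 10),
                        p_male_td = 0.5, p_male_d = 0.71, p_left = 0.12,
                        quality_coefs = c(a0 = 22, a1 = -2, a2 = 5),
                        speed_coefs = c(b0 = 20, b1 = 57, b2 = -30),
                        sigma_quality = 3.5, sigma_speed = 40,
                        gender_quality = 0.6, gender_speed = -8,
                        severity_mean = 2.5, severity_sd = 0.5,
                        subtype_weights = c(mild = 13, kinematic_pressure = 25,
                                            tilt = 24) / 62,
                        n_lines = 3, words_per_line = 5,
                        letters_per_word = 4) {
  stopifnot(sigma_quality > 0, sigma_speed > 0,
            length(n_td_per_grade) == 5, length(n_d_per_grade) == 5,
            abs(sum(subtype_weights) - 1) < 1e-8)
  structure(as.list(environment()), class = "hw_cohort_spec")
}

#' Simulate a cohort of children with recordings and planted truth
#'
#' Samples children per grade and group, assigns dysgraphic children a
#' latent severity and a planted subtype, builds each child's
#' [script_profile()] (grade defaults + severity-scaled subtype offsets +
#' mild per-child parameter jitter), generates BHK scores from the
#' specification's linear model, and (optionally) simulates every
#' recording. Deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param subtypes Named offset list, default [dysgraphia_subtypes()].
#' @param seed Integer seed.
#' @param make_recordings Simulate the pen trajectories? With `FALSE` only
#'   the cohort table and planted truth are returned (enough for studies
#'   of the BHK machinery itself).
#' @return List: `cohort` (tibble: child_id, grade, gender, handedness,
#'   group, bhk_quality_raw, bhk_speed_raw), `recordings` (named list of
#'   [pen_recording()]s, or `NULL`), `truth` (tibble: child_id, subtype,
#'   severity, and the generative coefficients as attributes).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            subtypes = dysgraphia_subtypes(),
                            seed = 1L, make_recordings = TRUE) {
  set.seed(seed)
  rows <- list(); truth <- list()
  subnames <- names(spec$subtype_weights)
  id <- 0L
  plan <- list()
  for (g in 1:5) {
    for (grp in c("TD", "D")) {
      n <- if (grp == "TD") spec$n_td_per_grade[g] else spec$n_d_per_grade[g]
      if (n == 0) next
      for (j in seq_len(n)) {
        id <- id + 1L
        p_male <- if (grp == "TD") spec$p_male_td else spec$p_male_d
        male <- runif(1) < p_male
        left <- runif(1) < spec$p_left
        if (grp == "TD") {
          sev <- 0
          subtype <- "TD"
        } else {
          sev <- max(rnorm(1, spec$severity_mean, spec$severity_sd), 1)
          subtype <- sample(subnames, 1, prob = spec$subtype_weights)
        }
        qc <- spec$quality_coefs; sc <- spec$speed_coefs
        quality <- max(qc["a0"] + qc["a1"] * g + qc["a2"] * sev +
                         (if (male) spec$gender_quality else
                            -spec$gender_quality) +
                         rnorm(1, 0, spec$sigma_quality), 0)
        speed <- max(sc["b0"] + sc["b1"] * g + sc["b2"] * sev +
                       (if (male) spec$gender_speed else -spec$gender_speed) +
                       rnorm(1, 0, spec$sigma_speed), 5)
        cid <- sprintf("child_%03d", id)
        rows[[id]] <- tibble::tibble(
          child_id = cid, grade = g,
          gender = if (male) "M" else "F",
          handedness = if (left) "L" else "R",
          group = grp,
          bhk_quality_raw = unname(quality), bhk_speed_raw = unname(speed))
        truth[[id]] <- tibble::tibble(child_id = cid, subtype = subtype,
                                      severity = sev)
        plan[[id]] <- list(child_id = cid, grade = g, subtype = subtype,
                           severity = sev, rec_seed = sample.int(2^30, 1))
      }
    }
  }
  cohort <- dplyr::bind_rows(rows)
  truth_tb <- dplyr::bind_rows(truth)
  attr(truth_tb, "quality_coefs") <- spec$quality_coefs
  attr(truth_tb, "speed_coefs") <- spec$speed_coefs

  recordings <- NULL
  if (make_recordings) {
    recordings <- purrr::map(plan, function(pl) {
      base <- script_profile(grade = pl$grade, n_lines = spec$n_lines,
                             words_per_line = spec$words_per_line,
                             letters_per_word = spec$letters_per_word)
      prof <- apply_subtype(base, subtypes[[pl$subtype]], pl$severity)
      # mild per-child physiology jitter, seeded through the cohort seed
      set.seed(pl$rec_seed)
      prof$base_speed_mm_s <- prof$base_speed_mm_s * rlnorm(1, 0, 0.06)
      prof$tremor_amp_mm <- prof$tremor_amp_mm * rlnorm(1, 0, 0.15)
      prof$pressure_base <- prof$pressure_base * rlnorm(1, 0, 0.06)
      prof$pressure_slope_sd <- prof$pressure_slope_sd * rlnorm(1, 0, 0.12)
      prof$word_gap_mean_mm <- prof$word_gap_mean_mm * rlnorm(1, 0, 0.08)
      prof$tilt_x_freq <- prof$tilt_x_freq * rlnorm(1, 0, 0.05)
      prof$tilt_y_freq <- prof$tilt_y_freq * rlnorm(1, 0, 0.05)
      prof <- clamp_profile(prof)
      simulate_recording(prof, seed = pl$rec_seed + 1L,
                         child_id = pl$child_id)
    })
    names(recordings) <- cohort$child_id
  }
  list(cohort = cohort, recordings = recordings, truth = truth_tb)
}

#' Simulate a feature-level cohort with planted regression effects
#'
#' Fast companion to [simulate_cohort()] for calibration studies of the
#' regression machinery: the twelve features are drawn directly as
#' independent standard normals and the BHK scores are generated from the
#' stated linear model with planted per-feature coefficients, skipping
#' trajectory synthesis entirely.
#'
#' @param n Children.
#' @param quality_effects Named vector of per-SD feature effects on the raw
#'   quality score (unnamed features get 0).
#' @param speed_effects Same for the speed score.
#' @param quality_interactions Named vector of feature-by-grade interaction
#'   effects on the quality score (the score gains
#'   `gamma * feature * grade` per named feature).
#' @param quality_coefs,speed_coefs,sigma_quality,sigma_speed,gender_quality,gender_speed
#'   As in [cohort_spec()].
#' @param seed Integer seed.
#' @return Cohort tibble (all TD: `dysgraphia = FALSE`) with the feature
#'   columns and both raw BHK scores; the planted effect vectors are
#'   attached as attributes `quality_effects` / `speed_effects`.
#' @export
simulate_feature_cohort <- function(n = 218, quality_effects = c(),
                                    speed_effects = c(),
                                    quality_interactions = c(),
                                    quality_coefs = c(a0 = 22, a1 = -2),
                                    speed_coefs = c(b0 = 20, b1 = 57),
                                    sigma_quality = 3.5, sigma_speed = 40,
                                    gender_quality = 0.6, gender_speed = -8,
                                    seed = 1L) {
  set.seed(seed)
  feats <- feature_names()
  qb <- setNames(rep(0, length(feats)), feats)
  qb[names(quality_effects)] <- quality_effects
  sb <- setNames(rep(0, length(feats)), feats)
  sb[names(speed_effects)] <- speed_effects
  qi <- setNames(rep(0, length(feats)), feats)
  qi[names(quality_interactions)] <- quality_interactions
  grade <- sample(1:5, n, replace = TRUE)
  male <- runif(n) < 0.5
  X <- matrix(rnorm(n * length(feats)), n,
              dimnames = list(NULL, feats))
  quality <- quality_coefs["a0"] + quality_coefs["a1"] * grade +
    ifelse(male, gender_quality, -gender_quality) +
    drop(X %*% qb) + grade * drop(X %*% qi) + rnorm(n, 0, sigma_quality)
  speed <- speed_coefs["b0"] + speed_coefs["b1"] * grade +
    ifelse(male, gender_speed, -gender_speed) +
    drop(X %*% sb) + rnorm(n, 0, sigma_speed)
  out <- tibble::tibble(
    child_id = sprintf("child_%03d", seq_len(n)),
    grade = grade, gender = ifelse(male, "M", "F"),
    handedness = "R", group = "TD", dysgraphia = FALSE,
    bhk_quality_raw = pmax(unname(quality), 0),
    bhk_speed_raw = pmax(unname(speed), 5))
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  attr(out, "quality_effects") <- qb
  attr(out, "speed_effects") <- sb
  attr(out, "quality_interactions") <- qi
  out
}
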