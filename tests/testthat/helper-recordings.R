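# Random raw-stream recordings for oracle and property tests. Deliberately
# messy: jittered timestamps, random pen-up runs, occasional word-like
# jumps and carriage returns, random-walk pressure and tilt.
random_recording <- function(seed, n = NULL,
                             child_id = sprintf("rand_%04d", seed)) {
  set.seed(seed)
  if (is.null(n)) n <- sample(40:2000, 1)
  fs <- 200
  t <- (seq_len(n) - 1) / fs + c(0, runif(n - 1, -4e-4, 4e-4))

  on <- logical(0)
  state <- runif(1) > 0.1
  while (length(on) < n) {
    len <- if (state) 15 + rgeom(1, 1 / 30) else 2 + rgeom(1, 1 / 8)
    on <- c(on, rep(state, len))
    state <- !state
  }
  on <- on[seq_len(n)]
  if (runif(1) < 0.15) on <- rep(TRUE, n)

  x <- cumsum(rnorm(n, 0.6, 1.4))
  y <- cumsum(rnorm(n, 0.05, 0.9))
  starts <- which(on & !c(FALSE, on[-n]))
  for (s in setdiff(starts, 1L)) {
    if (runif(1) < 0.6) {
      if (runif(1) < 0.2) {
        dxj <- runif(1, -250, -120); dyj <- runif(1, 30, 60)
      } else {
        dxj <- runif(1, 2, 60); dyj <- runif(1, -4, 4)
      }
      x[s:n] <- x[s:n] + dxj
      y[s:n] <- y[s:n] + dyj
    }
  }

  pressure <- pmin(pmax(500 + cumsum(rnorm(n, 0, 12)), 0), 1023)
  pressure[!on] <- 0
  tilt_x <- pmin(pmax(30 + cumsum(rnorm(n, 0, 0.6)), -90), 90)
  tilt_y <- pmin(pmax(10 + cumsum(rnorm(n, 0, 0.5)), -90), 90)

  pen_recording(
    tibble::tibble(t = t, x = x, y = y, pressure = pressure,
                   tilt_x = tilt_x, tilt_y = tilt_y, on_surface = on),
    fs = fs, resolution_mm = 0.25, child_id = child_id)
}

# small reference-spectra object built from simulated typical writers
make_test_reference <- function(seed = 42) {
  recs <- lapply(1:5, function(g) {
    simulate_recording(
      script_profile(grade = g, n_lines = 1, words_per_line = 2),
      seed = seed + g)
  })
  build_reference_spectra(recs, 1:5)
}
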