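test_that("Welch estimator concentrates sinusoids and conserves variance", {
  fs <- 256
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sqrt(2) * sin(2 * pi * 10 * t)
  ps <- welch_psd(x, fs = fs, freqs = default_grid())
  expect_equal(ps$freqs[which.max(ps$values)], 10)
  # alpha band dominates every other band for a 10-Hz tone
  bands <- eeg_bands()
  powers <- vapply(bands$name, function(b) band_power(ps, b), numeric(1))
  expect_equal(unname(which.max(powers)), which(bands$name == "alpha"))

  set.seed(5)
  w <- rnorm(300 * fs)
  pw <- welch_psd(w, fs = fs, freqs = NULL)
  # Parseval: integrated density matches the variance
  expect_equal(sum(pw$values) * diff(pw$freqs)[1], var(w), tolerance = 0.05)
  # flat spectrum: small coefficient of variation across the grid
  expect_lt(sd(pw$values) / mean(pw$values), 0.2)
})

test_that("Welch estimator rejects too-short signals and out-of-range grids", {
  expect_error(welch_psd(rnorm(100), fs = 256), "too short")
  expect_error(welch_psd(rnorm(256 * 20), fs = 256, freqs = c(0.01, 10)),
               "native")
})

test_that("band definitions and band powers follow the documented edges", {
  d <- band_definition("delta")
  expect_equal(c(d$lo, d$hi), c(1, 4))
  expect_equal(band_definition("gamma")$hi, 45)
  flat <- spectral_data(seq(1, 45, 0.5), rep(2.5, 89))
  expect_equal(band_power(flat, "delta"), 2.5 * 3)
  expect_equal(band_power(flat, list(lo = 10, hi = 20)), 25)
  expect_error(band_power(flat, list(lo = 0.1, hi = 4)), "outside")
})

test_that("medication epochs follow the pre/post window rules", {
  fs <- 64
  ev <- data.frame(time_s = c(600, 800), label = c("bzp_admin", "se_termination"))
  rec <- recording(rnorm(1300 * fs), fs = fs, events = ev)
  nr <- extract_medication_epochs(recording(rec$signal, fs,
                                            events = ev[1, , drop = FALSE]),
                                  "nonresponder")
  expect_equal(nr$pre$meta$window_s, c(240, 540))
  expect_equal(nr$post$meta$window_s, c(960, 1260))
  expect_equal(length(nr$pre$signal) / fs, 300)
  rr <- extract_medication_epochs(rec, "responder")
  expect_equal(rr$pre$meta$window_s, c(240, 540))
  expect_equal(rr$post$meta$window_s, c(860, 1160))
  # neither window may touch the administration timestamp
  expect_lte(rr$pre$meta$window_s[2], 600 - 60)
  expect_gte(rr$post$meta$window_s[1], 600)
  # intermittent responders anchor on the last seizure offset
  ev2 <- data.frame(time_s = c(600, 700, 750),
                    label = c("bzp_admin", "seizure_offset", "seizure_offset"))
  ri <- extract_medication_epochs(recording(rnorm(1300 * fs), fs, events = ev2),
                                  "responder")
  expect_equal(ri$post$meta$window_s, c(810, 1110))
  # errors name the violated rule
  expect_error(extract_medication_epochs(
    recording(rnorm(1300 * fs), fs), "nonresponder"), "bzp_admin")
  expect_error(extract_medication_epochs(
    recording(rnorm(1300 * fs), fs, events = ev[1, , drop = FALSE]),
    "responder"), "se_termination")
  expect_error(extract_medication_epochs(
    recording(rnorm(400 * fs), fs,
              events = data.frame(time_s = 200, label = "bzp_admin")),
    "nonresponder"), "exceeds")
})

test_that("random-phase surrogates reproduce a prescribed spectrum", {
  g <- predict_spectrum(default_parameters())
  s1 <- spectrum_to_timeseries(g, 30, 256, seed = 4)
  s2 <- spectrum_to_timeseries(g, 30, 256, seed = 4)
  expect_identical(s1$signal, s2$signal)
  z <- spectrum_to_timeseries(spectral_data(g$freqs, rep(0, 89) + 1e-300),
                              10, 256, seed = 1)
  expect_lt(max(abs(z$signal)), 1e-100)
  long <- spectrum_to_timeseries(g, 600, 256, seed = 9)
  ps <- welch_psd(long, freqs = seq(2, 44, 0.5))
  target <- stats::approx(g$freqs, g$values, seq(2, 44, 0.5))$y
  K <- ps$meta$n_segments
  expect_lt(max(abs(log(ps$values / target))), 3 * sqrt(1.06 / K) + 0.05)
})

test_that("recordings and spectra round-trip through CSV and EDF", {
  set.seed(2)
  rec <- recording(rnorm(256 * 5) * 40, fs = 256,
                   events = data.frame(time_s = 2, label = "bzp_admin"),
                   meta = list(channel = "vLFP"))
  csv <- tempfile(fileext = ".csv")
  write_recording_csv(rec, csv)
  r2 <- read_recording_csv(csv)
  expect_equal(r2$fs, 256)
  expect_equal(r2$signal, rec$signal, tolerance = 1e-6)
  expect_equal(r2$events$label, "bzp_admin")

  edf <- tempfile(fileext = ".edf")
  write_edf(rec, edf)
  r3 <- read_edf(edf, "vLFP")
  expect_equal(r3$fs, 256)
  # 16-bit quantization over the signal range
  expect_lt(max(abs(r3$signal - rec$signal)), diff(range(rec$signal)) / 60000)

  g <- predict_spectrum(default_parameters())
  g$meta <- list(patient = "P01", condition = "pre")
  sp <- tempfile(fileext = ".csv")
  write_spectrum_csv(g, sp)
  g2 <- read_spectrum_csv(sp)
  expect_equal(g2$values, g$values)
  expect_equal(g2$meta$patient, "P01")
})
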