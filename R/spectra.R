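# Spectral estimation and medication-epoch handling for EEG recordings.

#' EEG recording container
#'
#' @param signal Numeric vector of sampled amplitudes (microvolts).
#' @param fs Sampling rate in Hz.
#' @param events Optional data frame with columns `time_s` and `label`;
#'   labels include `bzp_admin`, `other_asm_admin`, `se_termination`,
#'   `seizure_offset`. Must be time-ordered and within the recording.
#' @param meta Optional list (patient id, group label, ...).
#' @return An object of class `recording`.
#' @export
recording <- function(signal, fs, events = NULL, meta = list()) {
  signal <- as.numeric(signal)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  dur <- length(signal) / fs
  if (is.null(events))
    events <- data.frame(time_s = numeric(0), label = character(0))
  stopifnot(all(c("time_s", "label") %in% names(events)))
  if (nrow(events)) {
    if (any(events$time_s < 0 | events$time_s > dur))
      stop("event timestamps outside the recording")
    if (is.unsorted(events$time_s)) stop("events must be time-ordered")
  }
  structure(list(signal = signal, fs = fs, events = events, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %.1f s at %g Hz, %d events\n",
              length(x$signal) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}

#' Welch averaged-periodogram power spectral density
#'
#' Splits the signal into Hann-tapered, overlapping segments, averages the
#' one-sided periodograms, and (optionally) interpolates the result onto a
#' requested grid. Units are signal-units squared per Hz, so the integral of
#' the full-band density approximates the signal variance.
#'
#' @param rec A `recording`, or a numeric vector (then `fs` must be given).
#' @param window_s Segment length in seconds (default 4, giving 0.25 Hz
#'   native resolution).
#' @param overlap_frac Fractional overlap between segments (default 0.5).
#' @param freqs Target frequency grid in Hz, linearly interpolated from the
#'   native grid; `NULL` returns the full native grid.
#' @param fs Sampling rate, only used when `rec` is a bare numeric vector.
#' @return A `spectral_data`. The native resolution is `1/window_s` Hz.
#' @export
welch_psd <- function(rec, window_s = 4, overlap_frac = 0.5,
                      freqs = default_grid(), fs = NULL) {
  if (inherits(rec, "recording")) {
    x <- rec$signal; fs <- rec$fs
  } else {
    if (is.null(fs)) stop("`fs` required when `rec` is a numeric vector")
    x <- as.numeric(rec)
  }
  nper <- round(window_s * fs)
  step <- max(1, round(nper * (1 - overlap_frac)))
  if (length(x) < nper + step)
    stop(sprintf("signal too short for Welch estimate: %d samples, need >= %d (2 windows)",
                 length(x), nper + step))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann taper
  wnorm <- sum(w^2)
  nf <- floor(nper / 2)
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    acc <- acc + Mod(X[2:(nf + 1)])^2
  }
  psd <- 2 * acc / (length(starts) * fs * wnorm)
  if (nper %% 2 == 0) psd[nf] <- psd[nf] / 2  # Nyquist bin is not doubled
  fgrid <- (fs / nper) * seq_len(nf)
  out_meta <- list(window_s = window_s, overlap_frac = overlap_frac,
                   n_segments = length(starts))
  if (inherits(rec, "recording")) out_meta <- c(out_meta, rec$meta)
  if (is.null(freqs)) return(spectral_data(fgrid, psd, meta = out_meta))
  if (min(freqs) < fgrid[1] || max(freqs) > fgrid[nf])
    stop("requested grid extends beyond the native Welch grid")
  vals <- stats::approx(fgrid, psd, xout = freqs)$y
  spectral_data(freqs, vals, meta = out_meta)
}

#' Standard EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 14-30, gamma 30-45 Hz; the gamma
#' upper edge is capped at the 45 Hz model fitting limit.
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 14, 30),
             hi = c(4, 8, 13, 30, 45))
}

#' Look up a band definition by name
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return One-row data frame with `name`, `lo`, `hi`.
#' @export
band_definition <- function(name) {
  b <- eeg_bands()
  row <- b[b$name == name, ]
  if (nrow(row) != 1) stop("unknown band: ", name)
  row
}

#' Band power by trapezoidal integration
#'
#' @param spec A `spectral_data`.
#' @param band Either a band name (see [eeg_bands()]) or a list/data frame
#'   with `lo` and `hi` in Hz.
#' @return Integrated power (signal units squared) over `[lo, hi]`.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectral_data"))
  if (is.character(band)) band <- band_definition(band)
  lo <- band$lo; hi <- band$hi
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  f <- spec$freqs
  if (lo < min(f) || hi > max(f))
    stop(sprintf("band [%g, %g] outside spectral grid [%g, %g]",
                 lo, hi, min(f), max(f)))
  # clip to [lo, hi] with interpolated endpoints, then trapezoid rule
  inside <- f > lo & f < hi
  xf <- c(lo, f[inside], hi)
  xv <- c(stats::approx(f, spec$values, lo)$y,
          spec$values[inside],
          stats::approx(f, spec$values, hi)$y)
  sum(diff(xf) * (utils::head(xv, -1) + utils::tail(xv, -1)) / 2)
}

#' Extract pre- and post-medication analysis epochs
#'
#' Selects the two 5-minute windows used for spectral fitting: the
#' premedication epoch ends 1 minute before benzodiazepine administration;
#' the postmedication epoch starts 6 minutes after administration in
#' nonresponders, and 1 minute after electrographic termination (the
#' `se_termination` event, or the last `seizure_offset` for intermittent
#' seizures) in responders.
#'
#' @param rec A `recording` carrying a `bzp_admin` event (and, for
#'   responders, a termination anchor).
#' @param group `"responder"` or `"nonresponder"`.
#' @return List with elements `pre` and `post`, each a 300-s `recording`
#'   whose metadata records the condition and window.
#' @export
extract_medication_epochs <- function(rec, group = c("responder", "nonresponder")) {
  stopifnot(inherits(rec, "recording"))
  group <- match.arg(group)
  ev <- rec$events
  admin <- ev$time_s[ev$label == "bzp_admin"]
  if (length(admin) == 0)
    stop("epoch unavailable: no bzp_admin event in the recording")
  admin <- admin[1]
  pre_win <- c(admin - 360, admin - 60)
  if (group == "nonresponder") {
    post_win <- c(admin + 360, admin + 660)
  } else {
    term <- ev$time_s[ev$label == "se_termination"]
    if (length(term) == 0) {
      offs <- ev$time_s[ev$label == "seizure_offset"]
      if (length(offs) == 0)
        stop("epoch unavailable: responder needs an se_termination or seizure_offset event")
      term <- max(offs)
    } else term <- term[1]
    post_win <- c(term + 60, term + 360)
  }
  dur <- length(rec$signal) / rec$fs
  clip <- function(win, label) {
    if (win[1] < 0 || win[2] > dur)
      stop(sprintf("epoch unavailable: %s window [%g, %g] s exceeds the recording (%g s)",
                   label, win[1], win[2], dur))
    idx <- (floor(win[1] * rec$fs) + 1):(floor(win[1] * rec$fs) + 300 * rec$fs)
    recording(rec$signal[idx], rec$fs,
              meta = c(rec$meta, list(condition = label, window_s = win)))
  }
  list(pre = clip(pre_win, "pre"), post = clip(post_win, "post"))
}

#' Random-phase surrogate signal with a prescribed spectrum
#'
#' Synthesizes a stationary Gaussian-like signal whose expected power
#' spectral density equals `spec` on its grid (zero density outside the
#' grid's support), by inverse-Fourier synthesis with independent uniform
#' phases. Seeded and reproducible.
#'
#' @param spec A `spectral_data` with positive density.
#' @param duration_s Signal length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A `recording`.
#' @export
spectrum_to_timeseries <- function(spec, duration_s, fs, seed = 1) {
  stopifnot(inherits(spec, "spectral_data"))
  n <- round(duration_s * fs)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  psd_fun <- function(f) {
    v <- stats::approx(spec$freqs, spec$values, xout = f,
                       yleft = 0, yright = 0)$y
    v[is.na(v)] <- 0
    v
  }
  x <- .synthesize_noise(psd_fun, n, fs)
  recording(x, fs, meta = list(source = "spectrum_surrogate", seed = seed))
}

#' Write a recording to two-column CSV
#' @param rec A `recording`.
#' @param path CSV path; columns `time_s`, `amplitude_uV`. Events, if any,
#'   are written to `<path>.events.json`.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  t <- (seq_along(rec$signal) - 1) / rec$fs
  utils::write.csv(data.frame(time_s = t, amplitude_uV = rec$signal),
                   path, row.names = FALSE)
  if (nrow(rec$events))
    jsonlite::write_json(rec$events, paste0(path, ".events.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from two-column CSV
#' @param path CSV with columns `time_s`, `amplitude_uV` (events read from
#'   `<path>.events.json` when present).
#' @return A `recording`.
#' @export
read_recording_csv <- function(path) {
  d <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(d$time_s))
  ev <- NULL
  ep <- paste0(path, ".events.json")
  if (file.exists(ep)) ev <- jsonlite::read_json(ep, simplifyVector = TRUE)
  recording(d$amplitude_uV, fs = round(fs, 6), events = ev)
}
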