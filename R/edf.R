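# Minimal European Data Format (EDF) input/output for single- or
# multi-channel continuous recordings: an ASCII header plus 16-bit samples,
# one data record per second. Covers the plain continuous-EDF subset needed
# to exchange surrogate EEG; no annotations channel (events travel in a JSON
# sidecar, see write_recording_csv).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write recordings to an EDF file
#'
#' @param recs A `recording` or list of them (equal length and rate);
#'   channel names from each recording's `meta$channel` (default `chan<k>`).
#' @param path Output file path. The signal is truncated to a whole number
#'   of 1-second data records.
#' @param start POSIXct start time stamped into the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recs, path, start = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  if (inherits(recs, "recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1, all(vapply(recs, inherits, TRUE, "recording")))
  fs <- recs[[1]]$fs
  nsamp <- min(vapply(recs, function(r) length(r$signal), 1L))
  if (any(vapply(recs, function(r) r$fs, 1) != fs))
    stop("all channels must share one sampling rate")
  nrec <- floor(nsamp / fs)
  if (nrec < 1) stop("signal shorter than one 1-s data record")
  ns <- length(recs)
  labels <- vapply(seq_len(ns), function(k) {
    ch <- recs[[k]]$meta$channel
    if (is.null(ch)) sprintf("chan%d", k) else as.character(ch)
  }, "")
  pmin_ <- numeric(ns); pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (k in seq_len(ns)) {
    x <- recs[[k]]$signal[seq_len(nrec * fs)]
    r <- range(x)
    if (diff(r) == 0) r <- r + c(-1, 1)
    pmin_[k] <- r[1]; pmax_[k] <- r[2]
    dig[[k]] <- as.integer(round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad("Startdate X X X X", 80),
    .edf_pad(format(start, "%d.%m.%y"), 8),
    .edf_pad(format(start, "%H.%M.%S"), 8),
    .edf_pad(256 * (1 + ns), 8),
    .edf_pad("", 44),
    .edf_pad(nrec, 8),
    .edf_pad("1", 8),
    .edf_pad(ns, 4),
    paste(vapply(labels, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.8g", pmin_), .edf_pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.8g", pmax_), .edf_pad, "", width = 8), collapse = ""),
    paste(rep(.edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(.edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (k in seq_len(ns)) writeBin(dig[[k]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a channel from an EDF file
#'
#' @param path EDF file (continuous, as written by [write_edf()] or other
#'   plain-EDF writers).
#' @param channel Channel label or 1-based index (default first channel).
#' @return A `recording` with the physical-unit signal.
#' @export
read_edf <- function(path, channel = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nch) trimws(readChar(con, nch, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(k) rd(16), "")
  for (k in seq_len(ns)) rd(80)            # transducer
  for (k in seq_len(ns)) rd(8)             # physical dimension
  pmin_ <- vapply(seq_len(ns), function(k) as.numeric(rd(8)), 1)
  pmax_ <- vapply(seq_len(ns), function(k) as.numeric(rd(8)), 1)
  dmin_ <- vapply(seq_len(ns), function(k) as.numeric(rd(8)), 1)
  dmax_ <- vapply(seq_len(ns), function(k) as.numeric(rd(8)), 1)
  for (k in seq_len(ns)) rd(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(k) as.integer(rd(8)), 1L)
  for (k in seq_len(ns)) rd(32)
  ch <- if (is.character(channel)) match(channel, labels) else as.integer(channel)
  if (is.na(ch) || ch < 1 || ch > ns) stop("channel not found: ", channel)
  out <- numeric(nrec * spr[ch])
  pos <- 1L
  for (r in seq_len(nrec)) {
    for (k in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[k], size = 2, endian = "little")
      if (k == ch) {
        out[pos:(pos + spr[k] - 1)] <- v
        pos <- pos + spr[k]
      }
    }
  }
  scale <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
  phys <- (out - dmin_[ch]) * scale + pmin_[ch]
  recording(phys, fs = spr[ch] / recdur,
            meta = list(channel = labels[ch], file = path))
}
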