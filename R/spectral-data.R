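#' Spectral data container
#'
#' Power spectral densities on an ordered frequency grid, with metadata
#' identifying the patient, recording condition and group.
#'
#' @param freqs Strictly increasing numeric vector of frequencies (Hz).
#' @param values Nonnegative power densities, one per frequency.
#' @param meta Optional list with elements such as `patient`, `condition`
#'   (`"pre"` or `"post"`) and `group` (`"responder"`, `"nonresponder"` or
#'   `"unknown"`).
#' @return An object of class `spectral_data`.
#' @export
spectral_data <- function(freqs, values, meta = list()) {
  freqs <- as.numeric(freqs)
  values <- as.numeric(values)
  if (length(freqs) != length(values))
    stop("`freqs` and `values` must have the same length")
  if (any(diff(freqs) <= 0)) stop("`freqs` must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("power values must be finite and nonnegative")
  structure(list(freqs = freqs, values = values, meta = meta),
            class = "spectral_data")
}

#' Default model frequency grid
#'
#' The broadband fitting grid: 1 to 45 Hz in 0.5 Hz steps (89 points).
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
default_grid <- function() seq(1, 45, by = 0.5)

#' @export
print.spectral_data <- function(x, ...) {
  cat(sprintf("spectral_data: %d frequencies, %.2f-%.2f Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Arithmetic mean of spectra on a common grid
#' @param spectra List of `spectral_data` objects sharing one grid.
#' @return A `spectral_data` with elementwise mean power.
#' @export
mean_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  f <- spectra[[1]]$freqs
  for (s in spectra)
    if (!isTRUE(all.equal(s$freqs, f))) stop("spectra are not on a common grid")
  vals <- rowMeans(vapply(spectra, function(s) s$values,
                          numeric(length(f))))
  spectral_data(f, vals, meta = list(n_averaged = length(spectra)))
}

#' Write a spectrum to CSV with a JSON metadata sidecar
#'
#' The CSV has columns `freq_hz` and `power`; metadata goes to
#' `<path>.meta.json`.
#'
#' @param spec A `spectral_data` object.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectral_data"))
  utils::write.csv(data.frame(freq_hz = spec$freqs, power = spec$values),
                   path, row.names = FALSE)
  if (length(spec$meta))
    jsonlite::write_json(spec$meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum_csv()]
#' @param path CSV file path.
#' @return A `spectral_data` object.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- list()
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  spectral_data(d$freq_hz, d$power, meta = meta)
}
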