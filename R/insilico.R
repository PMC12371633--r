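# Forward simulation over synaptic parameter space: group-mean starting
# points, parameter grids and trajectories, spectral-discontinuity
# (state-transition) detection, comprehensive sensitivity screens, and
# escape-route identification.
#
# A transition between an ictal-like and an interictal-like regime is
# operationalized as a discontinuity in log power at a probe frequency
# along a parameter trajectory: near the stability boundary of the
# linearized circuit the resonant power rises extremely steeply, so a
# per-step log-power jump (default log 2) separates the two sides.
# Parameter points whose linearization is unstable are recorded as gaps and
# treated as lying beyond the transition.

#' Group-mean parameter fit
#'
#' Averages a set of spectra (same grid) and inverts the mean spectrum,
#' returning the posterior mean as a parameter set — the starting point
#' used for in-silico navigation of a patient group.
#'
#' @param spectra List of `spectral_data` on a common grid.
#' @param prior First-level prior (default [default_prior()]).
#' @param config See [inversion_config()].
#' @return A `cmc_parameters` at the posterior mean, with the full
#'   `inversion_result` attached as attribute `"fit"`.
#' @export
fit_group_mean <- function(spectra, prior = default_prior(),
                           config = inversion_config()) {
  ms <- mean_spectrum(spectra)
  fit <- invert_spectrum(ms, prior = prior, config = config)
  out <- set_parameters(default_parameters(), fit$posterior$mean)
  attr(out, "fit") <- fit
  out
}

#' Spectra over a 1- or 2-dimensional parameter grid
#'
#' Evaluates [predict_spectrum()] at every point of a grid of log-scale
#' deviations applied to a base parameterization. Unstable points are
#' flagged, not fatal.
#'
#' @param base A `cmc_parameters` object.
#' @param axes Character vector (length 1 or 2) of variable parameter
#'   names.
#' @param ranges List (or vector for one axis) of `c(lo, hi)` log-unit
#'   deviations relative to `base`.
#' @param steps Grid points per axis (scalar or per-axis; >= 2).
#' @param freqs Frequency grid.
#' @return An object of class `parameter_grid`: `axes`, `values` (list of
#'   axis value vectors), `spectra` (list, row-major over the grid; `NULL`
#'   where unstable), `stable` (logical matrix/vector), `base`.
#' @export
parameter_grid_spectra <- function(base, axes, ranges, steps = 41,
                                   freqs = default_grid()) {
  stopifnot(inherits(base, "cmc_parameters"))
  axes <- as.character(axes)
  if (!all(axes %in% cmc_variable_names()))
    stop("unknown parameter name in axes: ",
         paste(setdiff(axes, cmc_variable_names()), collapse = ", "))
  nd <- length(axes)
  stopifnot(nd %in% c(1L, 2L))
  if (!is.list(ranges)) ranges <- list(ranges)
  stopifnot(length(ranges) == nd)
  steps <- rep(as.integer(steps), length.out = nd)
  stopifnot(all(steps >= 2))
  vals <- lapply(seq_len(nd), function(k)
    seq(ranges[[k]][1], ranges[[k]][2], length.out = steps[k]))
  grid_idx <- if (nd == 1) matrix(seq_len(steps[1]), ncol = 1) else
    as.matrix(expand.grid(seq_len(steps[1]), seq_len(steps[2])))
  spectra <- vector("list", nrow(grid_idx))
  stable <- logical(nrow(grid_idx))
  for (r in seq_len(nrow(grid_idx))) {
    dth <- stats::setNames(vapply(seq_len(nd), function(k)
      vals[[k]][grid_idx[r, k]], numeric(1)), axes)
    p <- perturb_parameters(base, dth)
    sp <- tryCatch(predict_spectrum(p, freqs), error = function(e) NULL)
    spectra[r] <- list(sp)   # keeps NULL entries in place
    stable[r] <- !is.null(sp)
  }
  structure(list(axes = axes, values = vals, spectra = spectra,
                 stable = stable, idx = grid_idx, steps = steps,
                 freqs = freqs, base = base), class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter_grid over %s: %s points (%d unstable)\n",
              paste(x$axes, collapse = " x "),
              paste(x$steps, collapse = " x "), sum(!x$stable)))
  invisible(x)
}

#' Detect a spectral-power discontinuity along a track
#'
#' Returns the index (1-based, the post-jump point) of the first adjacent
#' pair whose absolute log-power difference exceeds the threshold, or `NA`
#' if none does. Raising the threshold can never create a detection.
#'
#' @param power_track Positive power values along a trajectory.
#' @param threshold_logratio Per-step log-ratio threshold (default
#'   `log(2)`).
#' @return Integer index or `NA_integer_`.
#' @export
detect_transition <- function(power_track, threshold_logratio = log(2)) {
  if (length(power_track) < 2) stop("track needs at least 2 points")
  if (any(!is.finite(power_track)) || any(power_track <= 0))
    stop("power track must be positive and finite")
  jumps <- abs(diff(log(power_track)))
  hit <- which(jumps > threshold_logratio)
  if (length(hit) == 0) return(NA_integer_)
  hit[1] + 1L
}

#' Probe-frequency power along the diagonal of a square grid
#'
#' Extracts the main diagonal (bottom-left to top-right) of a square
#' two-dimensional [parameter_grid_spectra()] result, records the power at
#' the probe frequency at each point, and runs [detect_transition()].
#' Unstable diagonal points are kept as gaps; the detection treats the
#' finite values flanking a gap as adjacent, so a trajectory that crosses
#' the stability boundary registers the crossing.
#'
#' @param grid A square 2-D `parameter_grid`.
#' @param probe_freq Probe frequency in Hz (default 25).
#' @param threshold_logratio Transition threshold (default `log(2)`).
#' @return An object of class `transition_report`: `trajectory` (matrix of
#'   the two axis values per point), `power_track` (with `NA` gaps),
#'   `transition_index` (index into the trajectory, `NA` if none),
#'   `probe_freq`.
#' @export
trajectory_power <- function(grid, probe_freq = 25,
                             threshold_logratio = log(2)) {
  stopifnot(inherits(grid, "parameter_grid"))
  if (length(grid$axes) != 2 || grid$steps[1] != grid$steps[2])
    stop("trajectory_power needs a square 2-D grid")
  n <- grid$steps[1]
  diag_rows <- which(grid$idx[, 1] == grid$idx[, 2])
  stopifnot(length(diag_rows) == n)
  fi <- which.min(abs(grid$freqs - probe_freq))
  track <- vapply(diag_rows, function(r) {
    sp <- grid$spectra[[r]]
    if (is.null(sp)) NA_real_ else sp$values[fi]
  }, numeric(1))
  traj <- cbind(grid$values[[1]], grid$values[[2]])
  colnames(traj) <- grid$axes
  fin <- which(is.finite(track))
  trans <- NA_integer_
  if (length(fin) >= 2) {
    sub <- detect_transition(track[fin], threshold_logratio)
    if (!is.na(sub)) trans <- fin[sub]
  }
  if (is.na(trans) && any(!is.finite(track)) && length(fin) >= 1) {
    # crossing into instability is itself a state transition
    gap <- which(!is.finite(track))
    trans <- gap[1]
  }
  structure(list(trajectory = traj, power_track = track,
                 transition_index = trans, probe_freq = grid$freqs[fi],
                 threshold_logratio = threshold_logratio),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("transition_report: %d points at %g Hz; transition %s\n",
              nrow(x$trajectory), x$probe_freq,
              if (is.na(x$transition_index)) "not detected" else
                sprintf("at index %d", x$transition_index)))
  invisible(x)
}

#' Comprehensive single-parameter sensitivity screen
#'
#' Sweeps each of the 14 variable synaptic parameters over a symmetric
#' log-unit range around the base point (others held fixed) and records the
#' full spectrum and the probe-frequency power at every step.
#'
#' @param base A `cmc_parameters` object.
#' @param range_logunits Half-width of each sweep (default 1.5).
#' @param steps Steps per sweep (default 41).
#' @param probe_freq Probe frequency in Hz (default 25).
#' @param freqs Frequency grid.
#' @return A list (class `sensitivity_screen`) with one element per
#'   variable parameter: data frame `curve` (`value`, `power`, `stable`)
#'   and the `parameter_grid`.
#' @export
sensitivity_screen <- function(base, range_logunits = 1.5, steps = 41,
                               probe_freq = 25, freqs = default_grid()) {
  vn <- cmc_variable_names()
  fi <- which.min(abs(freqs - probe_freq))
  out <- lapply(vn, function(j) {
    g <- parameter_grid_spectra(base, j, c(-range_logunits, range_logunits),
                                steps = steps, freqs = freqs)
    power <- vapply(g$spectra, function(sp)
      if (is.null(sp)) NA_real_ else sp$values[fi], numeric(1))
    list(curve = data.frame(value = g$values[[1]], power = power,
                            stable = g$stable),
         grid = g)
  })
  names(out) <- vn
  structure(out, class = "sensitivity_screen",
            probe_freq = freqs[fi])
}

# mean squared log-power distance between two spectra on one grid, after
# removing the mean log-ratio (a free gain): electrode scaling is arbitrary,
# so only spectral shape counts and a global rescaling of either spectrum
# leaves the distance unchanged
.log_spec_distance <- function(a, b) {
  d <- log(a) - log(b)
  mean((d - mean(d))^2)
}

#' Rank single-parameter escape routes toward a target spectrum
#'
#' For each variable synaptic parameter, sweeps the parameter around the
#' base point and finds the value minimizing the gain-adjusted mean squared
#' log-power distance to a target spectrum (the mean log-ratio is removed
#' first, so the metric is scale-free and invariant to a global
#' multiplicative rescaling of either spectrum). Parameters are
#' ranked by achieved distance reduction relative to the base; sweeps whose
#' best point lies across a detected probe-frequency transition are
#' flagged.
#'
#' @param base A `cmc_parameters` (e.g. the nonresponder group mean).
#' @param target A `spectral_data` on the model grid (e.g. the responder
#'   postmedication state).
#' @param range_logunits,steps Sweep geometry (defaults 1.5, 41).
#' @param probe_freq Probe frequency for transition flagging (default 25).
#' @param threshold_logratio Transition threshold (default `log(2)`).
#' @return Data frame (class `escape_ranking`) with one row per parameter:
#'   `parameter`, `best_value`, `distance`, `reduction`,
#'   `crosses_transition`, sorted by decreasing reduction.
#' @export
find_escape_parameters <- function(base, target, range_logunits = 1.5,
                                   steps = 41, probe_freq = 25,
                                   threshold_logratio = log(2)) {
  stopifnot(inherits(target, "spectral_data"))
  vn <- cmc_variable_names()
  freqs <- target$freqs
  base_spec <- predict_spectrum(base, freqs)
  d0 <- .log_spec_distance(base_spec$values, target$values)
  fi <- which.min(abs(freqs - probe_freq))
  rows <- lapply(vn, function(j) {
    g <- parameter_grid_spectra(base, j, c(-range_logunits, range_logunits),
                                steps = steps, freqs = freqs)
    dist <- vapply(g$spectra, function(sp)
      if (is.null(sp)) NA_real_ else .log_spec_distance(sp$values, target$values),
      numeric(1))
    if (all(!is.finite(dist))) return(NULL)
    best <- which.min(dist)
    vals <- g$values[[1]]
    # does the path from 0 to the best value cross a transition?
    zero_i <- which.min(abs(vals))
    lo <- min(zero_i, best); hi <- max(zero_i, best)
    seg <- vapply(g$spectra[lo:hi], function(sp)
      if (is.null(sp)) NA_real_ else sp$values[fi], numeric(1))
    fin <- which(is.finite(seg))
    crosses <- any(!is.finite(seg))
    if (!crosses && length(fin) >= 2)
      crosses <- !is.na(detect_transition(seg[fin], threshold_logratio))
    data.frame(parameter = j, best_value = vals[best], distance = dist[best],
               reduction = d0 - dist[best], crosses_transition = crosses)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$reduction), ]
  rownames(out) <- NULL
  attr(out, "base_distance") <- d0
  class(out) <- c("escape_ranking", "data.frame")
  out
}
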