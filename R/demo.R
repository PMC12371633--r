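# Packaged state-transition demonstration.
#
# A deterministic, self-contained illustration of the in-silico engine: a
# small synthetic cohort is generated at an "established status
# epilepticus" operating point — inhibitory/deep kernels fast enough that
# the circuit's least-damped mode sits at the 25 Hz probe, and deep
# pyramidal inhibition elevated so every premedication state lies close to
# the linear stability boundary (a sharply resonant, high-power, ictal-like
# regime). Group-mean parameters are then fitted, and the parameter space
# is navigated along packaged inhibitory routes mirroring the cohort's
# generative benzodiazepine effects. The responder route crosses the
# ictal-interictal boundary (a detected spectral discontinuity at 25 Hz);
# the nonresponder route does not; augmenting the nonresponder's weak
# inhibitory response with a spiny-stellate time-constant (tau_ss) sweep
# opens an alternative route that does cross.

#' Cohort configuration of the state-transition demo
#'
#' @param seed Master seed (default 42).
#' @param n_per_group Patients per group (default 4).
#' @return A [cohort_config()] describing the demo cohort: an
#'   established-SE operating point (faster inhibitory and deep pyramidal
#'   kernels, elevated deep pyramidal inhibition) with benzodiazepine
#'   effects that terminate the seizure in responders only.
#' @export
demo_cohort_config <- function(seed = 42, n_per_group = 4) {
  cohort_config(
    n_responders = n_per_group, n_nonresponders = n_per_group,
    base = c(tau_ii = -1, tau_dp = -1, g_ii_dp = 1.5975),
    effects = list(resp = c(g_ii_ss = -0.15, g_ii_dp = -0.1925),
                   bzp = c(g_ii_ss = -0.05, g_ii_dp = -0.2275),
                   interaction = c(g_ii_ss = 0.15, g_ii_dp = -0.2275)),
    between_sd = 0.05, noise_sd = 0.05, seed = seed)
}

#' Run the packaged state-transition demonstration
#'
#' Generates the demo cohort, fits group-mean parameters for each group
#' (premedication first, nonneuronal parameters tied for the
#' postmedication fit), navigates three packaged routes with
#' [trajectory_power()] at the 25 Hz probe, and ranks single-parameter
#' escape routes toward the responders' postmedication (terminated)
#' spectrum.
#'
#' @param seed Master seed (default 42).
#' @param steps Grid resolution per axis (default 41).
#' @param probe_freq Probe frequency in Hz (default 25).
#' @return List with elements `responder`, `nonresponder`,
#'   `nonresponder_tau_ss` (each a `transition_report`), `escape` (an
#'   `escape_ranking`), `fits` (per-group pre/post parameter sets) and
#'   `cohort` (the generated cohort).
#' @export
state_transition_demo <- function(seed = 42, steps = 41, probe_freq = 25) {
  gen <- generate_cohort(demo_cohort_config(seed))
  meta <- gen$dataset$meta
  fits <- list()
  for (grp in c("responder", "nonresponder")) {
    pre_idx <- which(meta$group == grp & meta$condition == "pre")
    post_idx <- which(meta$group == grp & meta$condition == "post")
    p_pre <- fit_group_mean(gen$dataset$spectra[pre_idx])
    tied <- tie_nonneuronal_parameters(attr(p_pre, "fit"), default_prior())
    p_post <- fit_group_mean(gen$dataset$spectra[post_idx], prior = tied)
    fits[[grp]] <- list(pre = p_pre, post = p_post)
  }
  # packaged routes: the cohort's generative BZP effects (pre -> post) per
  # group, extended backward into the seizure regime; the tau_ss route
  # augments the nonresponders' weak inhibitory response
  routes <- list(
    responder = list(base = fits$responder$pre,
                     d = c(g_ii_ss = 0.2, g_ii_dp = -0.91), back = 0.4),
    nonresponder = list(base = fits$nonresponder$pre,
                        d = c(g_ii_ss = -0.4, g_ii_dp = -0.05), back = 0.25),
    nonresponder_tau_ss = list(base = fits$nonresponder$pre,
                               d = c(tau_ss = -1.0, g_ii_dp = -0.2), back = 0.6))
  reports <- lapply(routes, function(rt) {
    g <- parameter_grid_spectra(rt$base, names(rt$d),
                                list(c(-rt$back * rt$d[1], 1.1 * rt$d[1]),
                                     c(-rt$back * rt$d[2], 1.1 * rt$d[2])),
                                steps = steps)
    trajectory_power(g, probe_freq = probe_freq)
  })
  resp_post_idx <- which(meta$group == "responder" & meta$condition == "post")
  target <- mean_spectrum(gen$dataset$spectra[resp_post_idx])
  escape <- find_escape_parameters(fits$nonresponder$pre, target,
                                   probe_freq = probe_freq)
  c(reports, list(escape = escape, fits = fits, cohort = gen))
}
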