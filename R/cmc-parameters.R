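# Canonical microcircuit parameterization.
#
# The model describes a single cortical column with four neural masses:
# spiny stellate cells (ss), superficial pyramidal cells (sp), inhibitory
# interneurons (ii) and deep pyramidal cells (dp). Each population responds
# to its net synaptic input through a second-order convolution kernel with
# time constant tau. Populations are coupled by excitatory, inhibitory and
# recurrent self-modulatory gains. All parameters are stored as log-scale
# deviations theta from fixed default means, so the physical value is
# default * exp(theta) and positivity is automatic.

#' Population labels of the canonical microcircuit
#' @return Character vector `c("ss", "sp", "ii", "dp")`.
#' @export
cmc_populations <- function() c("ss", "sp", "ii", "dp")

#' Names of all model parameters
#'
#' The first 14 entries are the variable synaptic parameters (4 kernel time
#' constants, 3 excitatory couplings, 3 inhibitory couplings, 4 recurrent
#' self-modulatory gains). The remaining 5 are nonneuronal scaling
#' parameters: neuronal innovation amplitudes (white and pink), channel-noise
#' amplitudes (white and pink) and the electrode gain.
#'
#' @return Character vector of length 19.
#' @export
cmc_parameter_names <- function() {
  c("tau_ss", "tau_sp", "tau_ii", "tau_dp",
    "g_ss_sp", "g_ss_ii", "g_dp_ii",
    "g_ii_ss", "g_ii_sp", "g_ii_dp",
    "g_self_ss", "g_self_sp", "g_self_ii", "g_self_dp",
    "input_white", "input_pink", "noise_white", "noise_pink", "obs_gain")
}

#' Functional families of the variable synaptic parameters
#'
#' Families follow the usual shorthand: `t` time constants, `e` excitatory
#' coupling, `i` inhibitory coupling, `m` self-modulatory coupling.
#'
#' @return Named list of character vectors partitioning the 14 variable
#'   parameters.
#' @export
cmc_parameter_families <- function() {
  list(
    t = c("tau_ss", "tau_sp", "tau_ii", "tau_dp"),
    e = c("g_ss_sp", "g_ss_ii", "g_dp_ii"),
    i = c("g_ii_ss", "g_ii_sp", "g_ii_dp"),
    m = c("g_self_ss", "g_self_sp", "g_self_ii", "g_self_dp")
  )
}

#' Nonneuronal scaling parameter names
#' @return Character vector of the 5 nonneuronal parameter names.
#' @export
cmc_nonneuronal_names <- function() {
  c("input_white", "input_pink", "noise_white", "noise_pink", "obs_gain")
}

#' Variable synaptic parameter names
#' @return Character vector of the 14 variable parameter names.
#' @export
cmc_variable_names <- function() {
  setdiff(cmc_parameter_names(), cmc_nonneuronal_names())
}

# Default means on the natural scale. Time constants in seconds; coupling
# gains dimensionless rate multipliers; amplitude parameters set the scale of
# innovation and channel-noise spectral densities (power per Hz). These are
# packaged conventions chosen for a stable system with resonances inside the
# 1-45 Hz fitting band, not empirical estimates.
.cmc_default_means <- function() {
  c(tau_ss = 0.006, tau_sp = 0.006, tau_ii = 0.016, tau_dp = 0.028,
    g_ss_sp = 120, g_ss_ii = 120, g_dp_ii = 120,
    g_ii_ss = 120, g_ii_sp = 120, g_ii_dp = 120,
    g_self_ss = 60, g_self_sp = 60, g_self_ii = 60, g_self_dp = 60,
    input_white = 1, input_pink = 2,
    noise_white = 0.002, noise_pink = 0.002,
    obs_gain = 1000)
}

.cmc_default_edges <- function() {
  list(
    # excitatory: source -> target
    excitatory = cbind(source = c("ss", "ss", "dp"),
                       target = c("sp", "ii", "ii")),
    # inhibitory: all projections of the interneuron population
    inhibitory = cbind(source = c("ii", "ii", "ii"),
                       target = c("ss", "sp", "dp"))
  )
}

#' Default canonical-microcircuit parameter set
#'
#' Returns the packaged default parameterization: all log-deviations zero,
#' the standard edge assignment (excitatory ss->sp, ss->ii, dp->ii;
#' inhibitory ii->ss, ii->sp, ii->dp; one self-modulatory gain per
#' population), and all 14 synaptic parameters flagged variable. The default
#' system is linearly stable (all Jacobian eigenvalues have negative real
#' part).
#'
#' @param theta Optional named numeric vector of log-scale deviations to
#'   apply; names must be a subset of [cmc_parameter_names()].
#' @param edges Optional list with elements `excitatory` and `inhibitory`,
#'   each a two-column character matrix (`source`, `target`) naming
#'   population edges, overriding the default layout.
#' @return An object of class `cmc_parameters`.
#' @examples
#' p <- default_parameters()
#' count_free_parameters(p)
#' @export
default_parameters <- function(theta = NULL, edges = NULL) {
  nm <- cmc_parameter_names()
  th <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(theta)) {
    if (is.null(names(theta)) || !all(names(theta) %in% nm))
      stop("unknown parameter name in `theta`: ",
           paste(setdiff(names(theta), nm), collapse = ", "))
    th[names(theta)] <- theta
  }
  if (is.null(edges)) edges <- .cmc_default_edges()
  stopifnot(is.list(edges), all(c("excitatory", "inhibitory") %in% names(edges)))
  for (e in edges[c("excitatory", "inhibitory")]) {
    if (!all(e %in% cmc_populations()))
      stop("edge refers to unknown population")
  }
  variable <- stats::setNames(nm %in% cmc_variable_names(), nm)
  structure(
    list(theta = th, means = .cmc_default_means(), edges = edges,
         variable = variable),
    class = "cmc_parameters")
}

#' Apply log-scale deviations to a parameter set
#'
#' @param params A `cmc_parameters` object.
#' @param theta Named numeric vector of log-deviations, added to the current
#'   deviations.
#' @return Modified `cmc_parameters` object.
#' @export
perturb_parameters <- function(params, theta) {
  stopifnot(inherits(params, "cmc_parameters"))
  if (is.null(names(theta)) || !all(names(theta) %in% names(params$theta)))
    stop("unknown parameter name in `theta`: ",
         paste(setdiff(names(theta), names(params$theta)), collapse = ", "))
  params$theta[names(theta)] <- params$theta[names(theta)] + theta
  params
}

#' Replace the deviation vector of a parameter set
#' @param params A `cmc_parameters` object.
#' @param theta Named numeric vector over all parameters (or a subset).
#' @return Modified `cmc_parameters` object.
#' @export
set_parameters <- function(params, theta) {
  stopifnot(inherits(params, "cmc_parameters"))
  p <- params
  p$theta[] <- 0
  perturb_parameters(p, theta)
}

#' Physical (natural-scale) parameter values
#' @param params A `cmc_parameters` object.
#' @return Named numeric vector `means * exp(theta)`.
#' @export
natural_parameters <- function(params) {
  stopifnot(inherits(params, "cmc_parameters"))
  params$means * exp(params$theta)
}

#' Count the variable parameters of a model
#'
#' Counts entries flagged as variable synaptic parameters; nonneuronal
#' scaling parameters are never counted. The default model exposes 14.
#'
#' @param params A `cmc_parameters` object.
#' @return Integer count.
#' @export
count_free_parameters <- function(params) {
  stopifnot(inherits(params, "cmc_parameters"))
  sum(params$variable)
}

#' Freeze parameters (remove them from the variable set)
#' @param params A `cmc_parameters` object.
#' @param names Character vector of parameter names to freeze.
#' @return Modified `cmc_parameters` object.
#' @export
freeze_parameters <- function(params, names) {
  stopifnot(inherits(params, "cmc_parameters"))
  if (!all(names %in% base::names(params$variable)))
    stop("unknown parameter name")
  params$variable[names] <- FALSE
  params
}

#' @export
print.cmc_parameters <- function(x, ...) {
  cat("Canonical microcircuit parameters (", count_free_parameters(x),
      " variable)\n", sep = "")
  nz <- x$theta[x$theta != 0]
  if (length(nz)) {
    cat("nonzero log-deviations:\n")
    print(round(nz, 4))
  } else cat("all log-deviations zero (defaults)\n")
  invisible(x)
}

#' Serialize a parameter set to JSON
#'
#' Writes a flat name to log-deviation map together with the edge-set
#' declaration, readable by [read_cmc_json()].
#'
#' @param params A `cmc_parameters` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_cmc_json <- function(params, path) {
  stopifnot(inherits(params, "cmc_parameters"))
  obj <- list(
    theta = as.list(params$theta),
    variable = names(params$variable)[params$variable],
    edges = lapply(params$edges, function(e)
      data.frame(source = e[, "source"], target = e[, "target"]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from JSON
#' @param path File written by [write_cmc_json()].
#' @return A `cmc_parameters` object.
#' @export
read_cmc_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- lapply(obj$edges, function(e)
    cbind(source = e$source, target = e$target))
  p <- default_parameters(theta = unlist(obj$theta), edges = edges)
  p$variable[] <- names(p$variable) %in% obj$variable
  p
}
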