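# Synthetic cohort generation with known ground truth.
#
# Each patient receives a random synaptic deviation (between-patient
# heterogeneity) on top of group-structured second-level effects expressed
# on the +/-1 effect-coded design (responsiveness, benzodiazepine
# treatment, and their interaction), mirroring the three constituent
# effects the analysis is built to detect: a group difference during
# established status epilepticus, a shared response to the drug, and a
# selective extra response in responders. Effect magnitudes are packaged
# conventions chosen for comfortable identifiability at 300-s spectra; the
# directions encode lower spiny-stellate inhibition in responders before
# treatment, a shared treatment-driven increase of that inhibition, an
# extra interaction-driven increase, and a slight interaction-driven
# decrease of deep pyramidal inhibition.

#' Synthetic cohort configuration
#'
#' @param n_responders,n_nonresponders Patient counts (defaults 8 and 9,
#'   the shape of a typical single-centre paediatric cohort).
#' @param effects Named list with elements `resp`, `bzp`, `interaction`,
#'   each a named vector of second-level effects in log-units on the +/-1
#'   effect-coded design.
#' @param base Named vector of log-deviations shared by every patient
#'   (shifts the whole cohort's operating point).
#' @param between_sd Between-patient standard deviation of synaptic
#'   log-deviations.
#' @param noise_sd Observation noise: multiplicative log-normal standard
#'   deviation on spectra (spectra mode); channel noise is part of the
#'   generative model in time-series mode.
#' @param mode `"spectra"` (emit model spectra with observation noise) or
#'   `"timeseries"` (emit continuous surrogate EEG with medication events).
#' @param fs,duration_s Sampling rate and epoch duration for time-series
#'   output.
#' @param seed Master seed.
#' @return List of settings (class `cohort_config`).
#' @export
cohort_config <- function(n_responders = 8, n_nonresponders = 9,
                          effects = list(
                            resp = c(g_ii_ss = -0.3),
                            bzp = c(g_ii_ss = 0.2),
                            interaction = c(g_ii_ss = 0.4, g_ii_dp = -0.1)),
                          base = NULL,
                          between_sd = 0.1, noise_sd = 0.1,
                          mode = c("spectra", "timeseries"),
                          fs = 256, duration_s = 300, seed = 1) {
  stopifnot(n_responders >= 1, n_nonresponders >= 1, between_sd >= 0,
            noise_sd >= 0)
  mode <- match.arg(mode)
  vn <- cmc_variable_names()
  for (nmv in names(effects))
    if (!all(names(effects[[nmv]]) %in% vn))
      stop("effect map names unknown parameter: ",
           paste(setdiff(names(effects[[nmv]]), vn), collapse = ", "))
  if (!is.null(base) && !all(names(base) %in% cmc_parameter_names()))
    stop("base names unknown parameter")
  structure(list(n_responders = n_responders,
                 n_nonresponders = n_nonresponders,
                 effects = effects, base = base, between_sd = between_sd,
                 noise_sd = noise_sd, mode = mode, fs = fs,
                 duration_s = duration_s, seed = seed),
            class = "cohort_config")
}

# effect vectors expanded over the 14 variable parameters
.effect_beta <- function(config) {
  vn <- cmc_variable_names()
  beta <- matrix(0, 4, length(vn),
                 dimnames = list(c("intercept", "resp", "bzp", "resp_x_bzp"), vn))
  if (!is.null(config$base)) {
    bs <- config$base[names(config$base) %in% vn]
    beta["intercept", names(bs)] <- bs
  }
  map <- c(resp = "resp", bzp = "bzp", interaction = "resp_x_bzp")
  for (nmv in names(map)) {
    ef <- config$effects[[nmv]]
    if (!is.null(ef)) beta[map[[nmv]], names(ef)] <- ef
  }
  beta
}

#' Generate a synthetic cohort with ground truth
#'
#' For each patient, draws a synaptic deviation vector from
#' `N(0, between_sd^2)`, composes pre- and post-medication parameters from
#' the effect-coded second-level model, and emits either noisy model
#' spectra or continuous surrogate EEG (with `bzp_admin` at 600 s and, for
#' responders, `se_termination` at 800 s). Unstable compositions trigger a
#' bounded redraw of the patient deviation. Fully deterministic given the
#' config.
#'
#' @param config A [cohort_config()].
#' @return List with `dataset` (elements `meta`, a data frame; `spectra` or
#'   `recordings`, lists aligned with `meta` rows; `config`) and
#'   `ground_truth` (per-patient true parameters, the true second-level
#'   `beta`, retry log and seed).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  vn <- cmc_variable_names()
  beta <- .effect_beta(config)
  groups <- c(rep("responder", config$n_responders),
              rep("nonresponder", config$n_nonresponders))
  npat <- length(groups)
  ids <- sprintf("P%02d", seq_len(npat))

  meta <- data.frame(patient = rep(ids, each = 2),
                     group = rep(groups, each = 2),
                     condition = rep(c("pre", "post"), npat),
                     other_asm = FALSE)
  spectra <- vector("list", nrow(meta))
  recordings <- vector("list", nrow(meta))
  truth_theta <- vector("list", nrow(meta))
  retries <- integer(npat)

  for (i in seq_len(npat)) {
    r <- if (groups[i] == "responder") 1 else -1
    for (try_ in 1:20) {
      dev <- stats::rnorm(length(vn), 0, config$between_sd)
      names(dev) <- vn
      ok <- TRUE
      th <- list()
      for (cond in c("pre", "post")) {
        p <- if (cond == "post") 1 else -1
        x <- c(intercept = 1, resp = r, bzp = p, resp_x_bzp = r * p)
        theta <- drop(x %*% beta)
        names(theta) <- vn
        theta <- theta + dev
        pr <- perturb_parameters(default_parameters(), theta)
        if (!is.null(config$base)) {
          nnb <- config$base[names(config$base) %in% cmc_nonneuronal_names()]
          if (length(nnb)) pr <- perturb_parameters(pr, nnb)
        }
        if (stability_margin(pr) >= -0.1) { ok <- FALSE; break }
        th[[cond]] <- pr
      }
      if (ok) break
      retries[i] <- retries[i] + 1L
      if (try_ == 20) stop("could not find a stable deviation for patient ", ids[i])
    }
    for (cond in c("pre", "post")) {
      row <- which(meta$patient == ids[i] & meta$condition == cond)
      truth_theta[[row]] <- th[[cond]]$theta
      if (config$mode == "spectra") {
        g <- predict_spectrum(th[[cond]])
        vals <- g$values * exp(stats::rnorm(length(g$values), 0, config$noise_sd))
        spectra[[row]] <- spectral_data(g$freqs, vals,
                                        meta = list(patient = ids[i],
                                                    condition = cond,
                                                    group = groups[i]))
      }
    }
    if (config$mode == "timeseries") {
      recs <- .compose_patient_recording(th, groups[i], config,
                                         seed = config$seed * 1000L + i)
      for (cond in c("pre", "post")) {
        row <- which(meta$patient == ids[i] & meta$condition == cond)
        recordings[[row]] <- recs
      }
    }
  }
  dataset <- list(meta = meta, config = config)
  if (config$mode == "spectra") dataset$spectra <- spectra
  else dataset$recordings <- recordings[seq(1, nrow(meta), by = 2)]
  ground_truth <- list(theta = truth_theta, meta = meta, beta = beta,
                       retries = retries, seed = config$seed)
  list(dataset = dataset, ground_truth = ground_truth)
}

# One continuous surrogate recording per patient: pre-state dynamics until
# the state switch (drug onset for nonresponders at 600 s; electrographic
# termination for responders at 800 s), post-state dynamics afterwards.
.compose_patient_recording <- function(th, group, config, seed) {
  fs <- config$fs
  switch_s <- if (group == "responder") 800 else 600
  total_s <- 1260
  pre <- simulate_timeseries(th$pre, duration = switch_s, fs = fs, seed = seed)
  post <- simulate_timeseries(th$post, duration = total_s - switch_s, fs = fs,
                              seed = seed + 1L)
  ev <- data.frame(time_s = 600, label = "bzp_admin")
  if (group == "responder")
    ev <- rbind(ev, data.frame(time_s = 800, label = "se_termination"))
  recording(c(pre$signal, post$signal), fs = fs, events = ev,
            meta = list(group = group))
}

#' Manifest table for a generated cohort
#'
#' One row per first-level model (patient x condition), consumable by the
#' batch inversion driver and [build_design_matrix()]. With `dir` given,
#' spectra (CSV) or recordings (EDF plus JSON event sidecars) are written
#' and the `path` column filled in.
#'
#' @param dataset The `dataset` element of [generate_cohort()].
#' @param dir Optional output directory.
#' @return Data frame with columns `patient`, `group`, `condition`,
#'   `other_asm`, `path`.
#' @export
cohort_manifest <- function(dataset, dir = NULL) {
  meta <- dataset$meta
  man <- data.frame(patient = meta$patient, group = meta$group,
                    condition = meta$condition, other_asm = meta$other_asm,
                    path = NA_character_)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(dataset$spectra)) {
      for (i in seq_len(nrow(man))) {
        fn <- file.path(dir, sprintf("%s_%s.csv", man$patient[i], man$condition[i]))
        write_spectrum_csv(dataset$spectra[[i]], fn)
        man$path[i] <- fn
      }
    } else {
      pats <- unique(man$patient)
      for (k in seq_along(pats)) {
        fn <- file.path(dir, sprintf("%s.edf", pats[k]))
        rec <- dataset$recordings[[k]]
        write_edf(rec, fn)
        jsonlite::write_json(rec$events, paste0(fn, ".events.json"),
                             auto_unbox = TRUE, digits = NA)
        man$path[man$patient == pats[k]] <- fn
      }
    }
    utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  man
}

#' Batch first-level inversion of a cohort
#'
#' Runs the per-patient two-pass scheme: the premedication spectrum is
#' inverted first; [tie_nonneuronal_parameters()] then pins the nonneuronal
#' scaling parameters before the postmedication inversion, so pre/post
#' differences load onto synaptic parameters.
#'
#' @param dataset Cohort dataset from [generate_cohort()] (spectra mode),
#'   or a list with `meta` and `spectra` built from files.
#' @param prior First-level prior (default [default_prior()]); may be a
#'   list with one `prior_density` per `meta` row (e.g. empirical priors).
#' @param config See [inversion_config()].
#' @param init Optional list of warm-start mean vectors, one per row.
#' @param progress Print one line per patient.
#' @return List with `posteriors` (list of `posterior_density`, aligned
#'   with `meta` rows), `priors` (the per-row priors actually used, with
#'   the postmedication nonneuronal tying applied), `fits` (data frame of
#'   free energy, fit correlation, iterations) and `meta`.
#' @export
invert_cohort <- function(dataset, prior = default_prior(),
                          config = inversion_config(), init = NULL,
                          progress = FALSE) {
  meta <- dataset$meta
  spectra <- dataset$spectra
  if (is.null(spectra)) stop("dataset has no spectra; run welch_psd on epochs first")
  priors <- if (inherits(prior, "prior_density"))
    rep(list(prior), nrow(meta)) else prior
  stopifnot(length(priors) == nrow(meta))
  posteriors <- vector("list", nrow(meta))
  used_priors <- vector("list", nrow(meta))
  fits <- data.frame(free_energy = numeric(nrow(meta)),
                     fit_correlation = numeric(nrow(meta)),
                     iterations = integer(nrow(meta)))
  for (pat in unique(meta$patient)) {
    ipre <- which(meta$patient == pat & meta$condition == "pre")
    ipost <- which(meta$patient == pat & meta$condition == "post")
    stopifnot(length(ipre) == 1, length(ipost) == 1)
    rpre <- invert_spectrum(spectra[[ipre]], prior = priors[[ipre]],
                            config = config,
                            init = if (is.null(init)) NULL else init[[ipre]])
    tied <- tie_nonneuronal_parameters(rpre, priors[[ipost]])
    rpost <- invert_spectrum(spectra[[ipost]], prior = tied, config = config,
                             init = if (is.null(init)) NULL else init[[ipost]])
    posteriors[[ipre]] <- rpre$posterior
    posteriors[[ipost]] <- rpost$posterior
    used_priors[[ipre]] <- priors[[ipre]]
    used_priors[[ipost]] <- tied
    fits[ipre, ] <- list(rpre$posterior$free_energy, rpre$fit_correlation,
                         rpre$iterations)
    fits[ipost, ] <- list(rpost$posterior$free_energy, rpost$fit_correlation,
                          rpost$iterations)
    if (progress)
      message(sprintf("%s: r_pre %.3f r_post %.3f", pat,
                      rpre$fit_correlation, rpost$fit_correlation))
  }
  list(posteriors = posteriors, priors = used_priors, fits = fits, meta = meta)
}
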