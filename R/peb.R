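# Second-level (parametric empirical Bayes) modelling of first-level
# posteriors, hypothesis comparison and family-wise Bayesian model
# reduction.
#
# The hierarchical model places a linear design over the subject-level
# synaptic parameters,
#   theta_i = t(B) x_i + eps_i,   eps_i ~ N(0, Gamma),
# with a Gaussian prior on the second-level effects B. Each first-level
# inversion is summarized by its Gaussian posterior (restricted to the 14
# variable synaptic parameters) together with the prior it was fitted
# under. The second level replaces that first-level prior with the
# design-predicted density N(t(B) x_i, Gamma) analytically (the Bayesian
# model reduction identity), so the subject-level evidence is re-evaluated
# as a function of B without refitting, uncertainty propagates from the
# first level, and the posterior over B is available in closed form. The
# random-effects covariance Gamma is diagonal (one variance per parameter,
# a common fraction of the first-level prior variances) and its scale is
# optimized by empirical Bayes (marginal-likelihood maximization).

#' Build the second-level design matrix
#'
#' Effect-coded (+1/-1) regressors over first-level models (rows are patient
#' x condition): `intercept`, `resp` (+1 responder), `bzp` (+1
#' postmedication), and their product `resp_x_bzp` (the interaction). When
#' the metadata flags non-benzodiazepine antiseizure medication
#' (`other_asm`), nuisance columns `other_asm` and `other_asm_x_resp` are
#' appended; these never take part in hypothesis reductions.
#'
#' @param cohort_meta Data frame with columns `patient`, `group`
#'   (`responder`/`nonresponder`), `condition` (`pre`/`post`) and optionally
#'   `other_asm` (logical, per patient).
#' @return A numeric matrix with labelled columns and attribute
#'   `hypothesis_columns` (the columns subject to hypothesis tests).
#' @export
build_design_matrix <- function(cohort_meta) {
  m <- cohort_meta
  stopifnot(all(c("patient", "group", "condition") %in% names(m)))
  if (!all(m$group %in% c("responder", "nonresponder")))
    stop("group must be responder or nonresponder")
  if (!all(m$condition %in% c("pre", "post")))
    stop("condition must be pre or post")
  tab <- table(m$patient, m$condition)
  if (any(tab != 1))
    stop("manifest error: each patient needs exactly one pre and one post entry")
  resp <- ifelse(m$group == "responder", 1, -1)
  bzp <- ifelse(m$condition == "post", 1, -1)
  X <- cbind(intercept = rep(1, nrow(m)), resp = resp, bzp = bzp,
             resp_x_bzp = resp * bzp)
  if (!is.null(m$other_asm) && any(m$other_asm)) {
    oth <- ifelse(m$other_asm, 1, 0) * bzp
    X <- cbind(X, other_asm = oth, other_asm_x_resp = oth * resp)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("design error: collinear columns: ",
         paste(colnames(X)[drop], collapse = ", "))
  }
  attr(X, "hypothesis_columns") <- c("resp", "bzp", "resp_x_bzp")
  X
}

#' All nonempty parameter-family masks
#'
#' The 14 variable parameters divide into four functional families: `t`
#' (time constants), `m` (self-modulatory coupling), `e` (excitatory
#' coupling), `i` (inhibitory coupling). Every nonempty subset of families
#' defines one candidate model of where group effects may live, giving 15
#' models.
#'
#' @return Named list of 15 logical vectors over the 14 variable
#'   parameters, in lexicographic order of the family-letter names.
#' @export
enumerate_family_models <- function() {
  fam <- cmc_parameter_families()
  letters_ <- sort(names(fam))         # e, i, m, t
  nm <- cmc_variable_names()
  out <- list()
  for (k in 1:4) {
    for (comb in utils::combn(letters_, k, simplify = FALSE)) {
      mask <- stats::setNames(nm %in% unlist(fam[comb]), nm)
      out[[paste(comb, collapse = "")]] <- mask
    }
  }
  out[order(names(out))]
}

#' Family mask by name
#' @param name String over the alphabet `t`, `m`, `e`, `i` (e.g. `"i"`,
#'   `"ei"`).
#' @return Logical vector over the 14 variable parameters.
#' @export
family_mask <- function(name) {
  fam <- cmc_parameter_families()
  letters_ <- strsplit(name, "")[[1]]
  if (!all(letters_ %in% names(fam))) stop("unknown family letter in ", name)
  nm <- cmc_variable_names()
  stats::setNames(nm %in% unlist(fam[letters_]), nm)
}

#' Second-level PEB configuration
#' @param beta_prior_var Prior variance of non-intercept second-level
#'   effects (log-units squared).
#' @param intercept_prior_var Prior variance of the intercept (group-mean)
#'   effects.
#' @param gamma_frac_range Search interval for the random-effects variance
#'   scale, as a fraction of the first-level prior variances.
#' @return List of settings.
#' @export
peb_config <- function(beta_prior_var = 1 / 4, intercept_prior_var = 1,
                       gamma_frac_range = c(1e-3, 1)) {
  list(beta_prior_var = beta_prior_var,
       intercept_prior_var = intercept_prior_var,
       gamma_frac_range = gamma_frac_range)
}

# Per-subject quadratic summaries of the evidence as a function of the
# second-level prediction nu_i = t(B) x_i:
#   dF_i(nu) = c_i + w_i' nu - 0.5 nu' M_i nu
# obtained by replacing the first-level prior (mu0, P0) with N(nu, Gamma)
# in the subject's Gaussian posterior (mu_i, P_i).
.peb_subject_quads <- function(Ps, mus, P0s, mu0s, Pr) {
  ld <- function(A) determinant(A, logarithm = TRUE)$modulus[1]
  ldPr <- ld(Pr)
  lapply(seq_along(Ps), function(i) {
    Pi <- Ps[[i]]; mui <- mus[[i]]
    P0 <- P0s[[i]]; mu0 <- mu0s[[i]]
    Pp <- Pi + Pr - P0
    Pp <- (Pp + t(Pp)) / 2
    Sp <- solve(Pp)
    a <- Pi %*% mui - P0 %*% mu0
    cc <- 0.5 * (ld(Pi) + ldPr - ld(P0) - ld(Pp)) +
      0.5 * (t(a) %*% Sp %*% a - t(mui) %*% Pi %*% mui + t(mu0) %*% P0 %*% mu0)
    list(c = as.numeric(cc),
         w = as.vector(Pr %*% Sp %*% a),
         M = Pr - Pr %*% Sp %*% Pr)
  })
}

# Prior variance vector over vec(B) (parameter-major blocks of length K).
.peb_b_prior <- function(regs, params, mask, config) {
  K <- length(regs)
  pv <- numeric(K * length(params))
  for (j in seq_along(params)) {
    v <- rep(config$beta_prior_var, K)
    v[regs == "intercept"] <- config$intercept_prior_var
    if (!mask[j]) v[regs != "intercept"] <- 1e-12
    pv[(j - 1) * K + seq_len(K)] <- v
  }
  names(pv) <- as.vector(outer(regs, params, function(r, p) paste(r, p, sep = ":")))
  pv
}

# Assemble the Gaussian posterior over vec(B) and the total free energy for
# a given random-effects precision, from the subject quadratics.
.peb_assemble <- function(quads, X, bpv) {
  K <- ncol(X); p <- length(quads[[1]]$w)
  nb <- K * p
  u <- numeric(nb)
  Q <- matrix(0, nb, nb)
  for (i in seq_along(quads)) {
    xi <- X[i, ]
    xx <- tcrossprod(xi)
    u <- u + as.vector(outer(xi, quads[[i]]$w))        # K x p -> vec
    Q <- Q + kronecker(quads[[i]]$M, xx)
  }
  Pb <- Q + diag(1 / bpv, nb)
  Pb <- (Pb + t(Pb)) / 2
  Sb <- solve(Pb)
  bhat <- Sb %*% u
  Ftot <- sum(vapply(quads, function(q) q$c, numeric(1))) +
    0.5 * sum(u * bhat) - 0.5 * sum(log(bpv)) -
    0.5 * determinant(Pb, logarithm = TRUE)$modulus[1]
  list(F = as.numeric(Ftot), mean = as.vector(bhat), cov = Sb)
}

#' Fit the parametric empirical Bayes model
#'
#' @param first_level List of `posterior_density` objects (one per
#'   first-level model, in the row order of `X`).
#' @param X Design matrix from [build_design_matrix()].
#' @param mask Logical family mask over the 14 variable parameters (default
#'   all `TRUE`); parameters outside the mask receive intercept effects
#'   only.
#' @param config See [peb_config()].
#' @param first_prior The prior the first-level inversions were fitted
#'   under (its synaptic block; default [default_prior()]). May be a list
#'   of `prior_density` objects, one per first-level model, when subjects
#'   were inverted under different (e.g. empirical) priors.
#' @return An object of class `peb_result`: `beta` (regressor x parameter
#'   matrix of posterior means), `beta_cov` (per-parameter K x K posterior
#'   blocks), `b_mean`/`b_cov`/`b_prior_var` (the joint Gaussian over all
#'   effects, used for reductions), `gamma` (random-effects variances),
#'   `gamma_frac` (their empirical-Bayes scale), `free_energy`.
#' @export
fit_peb <- function(first_level, X, mask = NULL, config = peb_config(),
                    first_prior = default_prior()) {
  stopifnot(length(first_level) == nrow(X))
  nm <- cmc_variable_names()
  if (is.null(mask)) mask <- stats::setNames(rep(TRUE, length(nm)), nm)
  stopifnot(length(mask) == length(nm))
  K <- ncol(X)
  mus <- lapply(first_level, function(p) p$mean[nm])
  Ps <- lapply(first_level, function(p) {
    S <- p$cov[nm, nm, drop = FALSE]
    solve((S + t(S)) / 2)
  })
  priors <- if (inherits(first_prior, "prior_density"))
    rep(list(first_prior), length(first_level)) else first_prior
  stopifnot(length(priors) == length(first_level))
  mu0s <- lapply(priors, function(p) p$mean[nm])
  P0s <- lapply(priors, function(p) solve(p$cov[nm, nm, drop = FALSE]))
  v0 <- diag(default_prior()$cov[nm, nm])   # reference scale for Gamma
  bpv <- .peb_b_prior(colnames(X), nm, mask, config)

  fit_at <- function(frac) {
    Pr <- diag(1 / (frac * v0), length(nm))
    quads <- .peb_subject_quads(Ps, mus, P0s, mu0s, Pr)
    .peb_assemble(quads, X, bpv)
  }
  opt <- stats::optimize(function(lf) fit_at(exp(lf))$F,
                         interval = log(config$gamma_frac_range),
                         maximum = TRUE)
  frac <- exp(opt$maximum)
  fit <- fit_at(frac)
  beta <- matrix(fit$mean, K, length(nm),
                 dimnames = list(colnames(X), nm))
  beta_cov <- lapply(seq_along(nm), function(j) {
    S <- fit$cov[(j - 1) * K + seq_len(K), (j - 1) * K + seq_len(K),
                 drop = FALSE]
    dimnames(S) <- list(colnames(X), colnames(X))
    S
  })
  names(beta_cov) <- nm
  structure(list(beta = beta, beta_cov = beta_cov,
                 b_mean = fit$mean, b_cov = fit$cov, b_prior_var = bpv,
                 gamma = stats::setNames(frac * v0, nm), gamma_frac = frac,
                 free_energy = fit$F, X = X, mask = mask, config = config,
                 parameters = nm), class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("peb_result: %d models x %d parameters, F = %.2f nats\n",
              nrow(x$X), length(x$parameters), x$free_energy))
  invisible(x)
}

#' Bayesian model reduction of a Gaussian posterior
#'
#' Computes, without refitting, the change in log evidence and the reduced
#' posterior implied by replacing the prior of a fitted Gaussian model with
#' a nested (variance-shrunk) alternative:
#' `dF = log int q(theta) p_r(theta) / p_0(theta) dtheta`.
#'
#' @param post List or `prior_density` with `mean`, `cov` (full posterior).
#' @param prior Full prior (`mean`, `cov`).
#' @param reduced_prior Reduced prior; must only shrink variances (nested).
#' @return List with `dF` (reduced minus full log evidence), `mean`, `cov`
#'   of the reduced posterior.
#' @export
bayesian_model_reduction <- function(post, prior, reduced_prior) {
  mu <- post$mean; Sg <- as.matrix(post$cov)
  mu0 <- prior$mean; S0 <- as.matrix(prior$cov)
  mur <- reduced_prior$mean; Sr <- as.matrix(reduced_prior$cov)
  if (any(diag(Sr) > diag(S0) + 1e-9))
    stop("nesting error: reduced prior must not widen any variance")
  P <- solve(Sg); P0 <- solve(S0); Pr <- solve(Sr)
  Pp <- P + Pr - P0
  Pp <- (Pp + t(Pp)) / 2
  ev <- eigen(Pp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("nesting error: reduced posterior precision not positive definite")
  Sp <- solve(Pp)
  mup <- Sp %*% (P %*% mu + Pr %*% mur - P0 %*% mu0)
  ld <- function(A) determinant(A, logarithm = TRUE)$modulus[1]
  dF <- 0.5 * (ld(P) + ld(Pr) - ld(P0) - ld(Pp)) +
    0.5 * (t(mup) %*% Pp %*% mup - t(mu) %*% P %*% mu -
             t(mur) %*% Pr %*% mur + t(mu0) %*% P0 %*% mu0)
  list(dF = as.numeric(dF), mean = as.vector(mup), cov = Sp)
}

# Reduce a fitted PEB model by shrinking selected (regressor, parameter)
# effect priors to (near) zero. `keep` is a function(regressor, parameter)
# returning TRUE when the effect stays free. Operates on the joint Gaussian
# over all second-level effects.
.reduce_peb <- function(peb, keep) {
  K <- nrow(peb$beta)
  regs <- rownames(peb$beta)
  pv <- peb$b_prior_var
  pvr <- pv
  idx <- 0L
  for (j in seq_along(peb$parameters)) {
    for (k in seq_len(K)) {
      idx <- idx + 1L
      if (regs[k] != "intercept" && !keep(regs[k], peb$parameters[j]))
        pvr[idx] <- 1e-12
    }
  }
  if (all(pvr == pv))
    return(list(dF = 0, beta = peb$beta))
  nb <- length(pv)
  nmv <- names(pv)
  red <- bayesian_model_reduction(
    list(mean = stats::setNames(peb$b_mean, nmv), cov = peb$b_cov),
    list(mean = stats::setNames(numeric(nb), nmv), cov = diag(pv, nb)),
    list(mean = stats::setNames(numeric(nb), nmv), cov = diag(pvr, nb)))
  beta_r <- matrix(red$mean, K, length(peb$parameters),
                   dimnames = dimnames(peb$beta))
  list(dF = red$dF, beta = beta_r)
}

#' Compare the three group-level hypotheses
#'
#' Fits the full second-level model (intercept, responsiveness main effect,
#' benzodiazepine main effect, interaction; plus any nuisance columns) and
#' scores three nested reductions by free energy: hypothesis 1 keeps the two
#' main effects (groups differ in status epilepticus but respond alike);
#' hypothesis 2 keeps the treatment main effect and the interaction (groups
#' start alike but respond differently); hypothesis 3 keeps the full
#' complement of both main effects and the interaction.
#'
#' @param first_level List of `posterior_density` objects.
#' @param cohort_meta Metadata data frame (see [build_design_matrix()]).
#' @param mask Optional family mask restricting where effects may live.
#' @param config See [peb_config()].
#' @param first_prior Prior(s) of the first-level inversions (see
#'   [fit_peb()]).
#' @return An object of class `hypothesis_comparison`: data frame `table`
#'   (hypothesis, free_energy, rel_F), `winner`, `decisive` (winner leads by
#'   more than 3 nats), and the fitted full `peb`.
#' @export
compare_hypotheses <- function(first_level, cohort_meta, mask = NULL,
                               config = peb_config(),
                               first_prior = default_prior()) {
  X <- build_design_matrix(cohort_meta)
  peb <- fit_peb(first_level, X, mask = mask, config = config,
                 first_prior = first_prior)
  sets <- list(
    H1 = c("resp", "bzp"),
    H2 = c("bzp", "resp_x_bzp"),
    H3 = c("resp", "bzp", "resp_x_bzp"))
  hyp_cols <- attr(X, "hypothesis_columns")
  Fs <- vapply(sets, function(kset) {
    keep <- function(reg, par) !(reg %in% hyp_cols) || reg %in% kset
    peb$free_energy + .reduce_peb(peb, keep)$dF
  }, numeric(1))
  rel <- Fs - max(Fs)
  tab <- data.frame(hypothesis = names(sets), free_energy = Fs,
                    rel_F = rel, row.names = NULL)
  ord <- order(-Fs)
  winner <- names(sets)[ord[1]]
  decisive <- (Fs[ord[1]] - Fs[ord[2]]) > 3
  structure(list(table = tab, winner = winner, decisive = decisive,
                 peb = peb), class = "hypothesis_comparison")
}

#' @export
print.hypothesis_comparison <- function(x, ...) {
  tab <- x$table
  tab$free_energy <- round(tab$free_energy, 2)
  tab$rel_F <- round(tab$rel_F, 2)
  print(tab)
  cat("winner:", x$winner, if (x$decisive) "(decisive, dF > 3 nats)" else
    "(not decisive)", "\n")
  invisible(x)
}

#' Family-wise fixed-effects Bayesian model comparison
#'
#' Under a given design (default the full hypothesis-3 complement), scores
#' all 15 family models — every nonempty subset of the parameter families
#' `t`, `m`, `e`, `i` — by Bayesian model reduction of the full fit:
#' non-intercept effects on parameters outside the family mask are pruned.
#'
#' @param first_level List of `posterior_density` objects.
#' @param cohort_meta Metadata data frame.
#' @param keep_regressors Regressors retained in every candidate (default
#'   the full `resp`, `bzp`, `resp_x_bzp` complement).
#' @param config See [peb_config()].
#' @param first_prior Prior(s) of the first-level inversions (see
#'   [fit_peb()]).
#' @return An object of class `family_comparison`: `table` (15 rows:
#'   family, free_energy, rel_F), `winner`, `decisive`, `peb`.
#' @export
compare_family_models <- function(first_level, cohort_meta,
                                  keep_regressors = c("resp", "bzp", "resp_x_bzp"),
                                  config = peb_config(),
                                  first_prior = default_prior()) {
  X <- build_design_matrix(cohort_meta)
  peb <- fit_peb(first_level, X, mask = NULL, config = config,
                 first_prior = first_prior)
  masks <- enumerate_family_models()
  hyp_cols <- attr(X, "hypothesis_columns")
  Fs <- vapply(names(masks), function(fn) {
    msk <- masks[[fn]]
    keep <- function(reg, par) {
      if (reg %in% hyp_cols && !(reg %in% keep_regressors)) return(FALSE)
      if (!(reg %in% hyp_cols)) return(TRUE)   # nuisance columns stay
      msk[par]
    }
    peb$free_energy + .reduce_peb(peb, keep)$dF
  }, numeric(1))
  rel <- Fs - max(Fs)
  tab <- data.frame(family = names(masks), free_energy = Fs, rel_F = rel,
                    row.names = NULL)
  ord <- order(-Fs)
  structure(list(table = tab, winner = names(masks)[ord[1]],
                 decisive = (Fs[ord[1]] - Fs[ord[2]]) > 3, peb = peb),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  tab <- x$table[order(-x$table$free_energy), ]
  tab$free_energy <- round(tab$free_energy, 2)
  tab$rel_F <- round(tab$rel_F, 2)
  print(tab, row.names = FALSE)
  cat("winner:", x$winner, if (x$decisive) "(decisive)" else "(not decisive)", "\n")
  invisible(x)
}

#' Write a free-energy league table to TSV
#' @param comparison A `hypothesis_comparison` or `family_comparison`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_league_table <- function(comparison, path) {
  utils::write.table(comparison$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
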