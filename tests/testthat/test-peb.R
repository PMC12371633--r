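test_that("the design matrix encodes the factorial structure", {
  meta <- data.frame(
    patient = rep(sprintf("P%02d", 1:17), each = 2),
    group = rep(c(rep("responder", 8), rep("nonresponder", 9)), each = 2),
    condition = rep(c("pre", "post"), 17))
  X <- build_design_matrix(meta)
  expect_equal(nrow(X), 34)
  expect_equal(unname(X[, "intercept"]), rep(1, 34))
  expect_equal(X[, "resp_x_bzp"], X[, "resp"] * X[, "bzp"])
  expect_equal(sum(X[, "bzp"]), 0)
  # balanced cohort: the group column sums to zero under +/-1 coding
  meta_b <- meta[meta$patient %in% sprintf("P%02d", 1:16), ]
  expect_equal(sum(build_design_matrix(meta_b)[, "resp"]), 0)
  # missing condition is a manifest error
  expect_error(build_design_matrix(meta[-1, ]), "manifest")
  # nuisance columns appear when other medication is flagged
  meta$other_asm <- meta$patient %in% c("P01", "P09")
  Xo <- build_design_matrix(meta)
  expect_true(all(c("other_asm", "other_asm_x_resp") %in% colnames(Xo)))
})

test_that("family model space enumerates all 15 combinations", {
  masks <- enumerate_family_models()
  expect_length(masks, 15)
  expect_equal(length(unique(vapply(masks, paste, "", collapse = ""))), 15)
  singles <- masks[c("e", "i", "m", "t")]
  cover <- Reduce(`+`, singles)
  expect_equal(unname(cover), rep(1, 14))   # the families partition
  expect_equal(sum(family_mask("i")), 3)
  expect_equal(sum(family_mask("eimt")), 14)
  expect_error(family_mask("x"), "unknown")
})

test_that("Bayesian model reduction is exact on linear-Gaussian models", {
  toy <- linear_toy()
  post <- list(mean = toy$post_mean, cov = toy$post_cov)
  prior <- list(mean = toy$mu0, cov = toy$S0)
  # identity reduction changes nothing
  r0 <- bayesian_model_reduction(post, prior, prior)
  expect_equal(r0$dF, 0, tolerance = 1e-10)
  expect_equal(r0$mean, toy$post_mean, tolerance = 1e-10)
  # pruning the third coefficient matches the directly computed evidences
  S0r <- toy$S0; S0r[3, 3] <- 1e-12
  rr <- bayesian_model_reduction(post, prior, list(mean = toy$mu0, cov = S0r))
  expect_lt(abs(rr$dF - (toy$evidence(S0r) - toy$evidence(toy$S0))), 1e-6)
  # widening is not a nested reduction
  S0w <- toy$S0; S0w[1, 1] <- 4
  expect_error(bayesian_model_reduction(post, prior,
                                        list(mean = toy$mu0, cov = S0w)),
               "nesting")
})

test_that("PEB recovers injected group effects from well-identified first levels", {
  gen <- generate_cohort(cohort_config(n_responders = 6, n_nonresponders = 6,
                                       seed = 31))
  fl <- idealized_first_level(gen$ground_truth, sd = 0.05, seed = 32)
  X <- build_design_matrix(gen$dataset$meta)
  peb <- fit_peb(fl, X)
  truth <- gen$ground_truth$beta
  for (reg in c("resp", "bzp", "resp_x_bzp")) {
    est <- peb$beta[reg, "g_ii_ss"]
    sd_ <- sqrt(peb$beta_cov[["g_ii_ss"]][reg, reg])
    expect_lt(abs(est - truth[reg, "g_ii_ss"]), 2 * sd_)
  }
  # pruning the parameter that carries the strong effect loses evidence
  keep_none_giiss <- function(reg, par) par != "g_ii_ss"
  red <- sedcm:::.reduce_peb(peb, keep_none_giiss)
  expect_lt(red$dF, 0)
  # hypothesis and family comparison identify the generating structure
  hc <- compare_hypotheses(fl, gen$dataset$meta)
  fc <- compare_family_models(fl, gen$dataset$meta)
  expect_equal(hc$winner, "H3")
  expect_equal(fc$winner, "i")
  expect_equal(nrow(fc$table), 15)
  # effect directions reproduce the injected signs
  expect_lt(peb$beta["resp", "g_ii_ss"], 0)
  expect_gt(peb$beta["bzp", "g_ii_ss"], 0)
  expect_gt(peb$beta["resp_x_bzp", "g_ii_ss"], 0)
  expect_lt(peb$beta["resp_x_bzp", "g_ii_dp"], 0)
})

test_that("degenerate single-subject PEB returns the first-level mean", {
  gen <- generate_cohort(cohort_config(n_responders = 1, n_nonresponders = 1,
                                       seed = 41))
  fl <- idealized_first_level(gen$ground_truth, sd = 0.02, seed = 42)
  X1 <- matrix(1, 1, 1, dimnames = list(NULL, "intercept"))
  p1 <- fit_peb(fl[1], X1)
  expect_lt(max(abs(p1$beta["intercept", ] -
                      fl[[1]]$mean[cmc_variable_names()])), 0.05)
})

test_that("inflating first-level uncertainty widens the effect posteriors", {
  gen <- generate_cohort(cohort_config(n_responders = 4, n_nonresponders = 4,
                                       seed = 51))
  fl <- idealized_first_level(gen$ground_truth, sd = 0.05, seed = 52)
  X <- build_design_matrix(gen$dataset$meta)
  # hold the random-effects scale fixed so the check isolates the
  # precision weighting of the first-level uncertainties
  cfg <- peb_config(gamma_frac_range = c(0.1, 0.100001))
  peb1 <- fit_peb(fl, X, config = cfg)
  fl_wide <- lapply(fl, function(p) {
    p$cov <- p$cov * 4
    p
  })
  peb2 <- fit_peb(fl_wide, X, config = cfg)
  v1 <- vapply(peb1$beta_cov, function(S) S["resp", "resp"], numeric(1))
  v2 <- vapply(peb2$beta_cov, function(S) S["resp", "resp"], numeric(1))
  expect_true(all(v2 >= v1 - 1e-10))
})

test_that("fixed-effects family comparison is order-invariant and self-consistent", {
  gen <- generate_cohort(cohort_config(n_responders = 3, n_nonresponders = 3,
                                       seed = 61))
  fl <- idealized_first_level(gen$ground_truth, sd = 0.05, seed = 62)
  fc <- compare_family_models(fl, gen$dataset$meta)
  # the free-energy table is a pure function of the fit: identical rerun
  fc2 <- compare_family_models(fl, gen$dataset$meta)
  expect_equal(fc$table$free_energy, fc2$table$free_energy)
  # identity reduction: the full family equals the unreduced fit
  expect_equal(fc$table$free_energy[fc$table$family == "eimt"],
               fc$peb$free_energy, tolerance = 1e-8)
})
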