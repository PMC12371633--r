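test_that("parameter grids evaluate and recompute spectra faithfully", {
  base <- default_parameters()
  g <- parameter_grid_spectra(base, c("g_ii_ss", "g_ii_dp"),
                              list(c(-0.3, 0.3), c(-0.3, 0.3)), steps = 4)
  expect_length(g$spectra, 16)
  # each grid spectrum matches an independent direct call
  for (r in c(1, 7, 16)) {
    dth <- stats::setNames(c(g$values[[1]][g$idx[r, 1]],
                             g$values[[2]][g$idx[r, 2]]), g$axes)
    direct <- predict_spectrum(perturb_parameters(base, dth))
    expect_equal(g$spectra[[r]]$values, direct$values)
  }
  # zero-width ranges reproduce the base spectrum everywhere
  g0 <- parameter_grid_spectra(base, "g_ii_ss", c(0, 0), steps = 3)
  b <- predict_spectrum(base)
  for (sp in g0$spectra) expect_equal(sp$values, b$values)
  expect_error(parameter_grid_spectra(base, "nope", c(-1, 1)), "unknown")
})

test_that("transition detection finds jumps and is monotone in the threshold", {
  expect_true(is.na(detect_transition(rep(2, 10))))
  # constructed step: [1,1,1,10,10] jumps onto the fourth point
  expect_equal(detect_transition(c(1, 1, 1, 10, 10), log(3)), 4L)
  expect_error(detect_transition(c(1, -1, 2)), "positive")
  set.seed(8)
  for (i in 1:20) {
    track <- exp(cumsum(rnorm(30, 0, 0.6)))
    th <- sort(runif(2, 0.2, 2))
    lo <- detect_transition(track, th[1])
    hi <- detect_transition(track, th[2])
    # raising the threshold never creates a detection
    if (is.na(lo)) expect_true(is.na(hi))
    if (!is.na(hi) && !is.na(lo)) expect_gte(hi, lo)
  }
})

test_that("trajectory power probes the diagonal at 25 Hz by default", {
  base <- default_parameters()
  g <- parameter_grid_spectra(base, c("g_ii_ss", "g_ii_dp"),
                              list(c(-0.2, 0.2), c(-0.2, 0.2)), steps = 7)
  tr <- trajectory_power(g)
  expect_equal(tr$probe_freq, 25)
  expect_equal(nrow(tr$trajectory), 7)
  expect_length(tr$power_track, 7)
  # constant grid gives a constant track and no transition
  gc <- parameter_grid_spectra(base, c("g_ii_ss", "g_ii_dp"),
                               list(c(0, 0), c(0, 0)), steps = 5)
  trc <- trajectory_power(gc)
  expect_lt(diff(range(trc$power_track)), 1e-12)
  expect_true(is.na(trc$transition_index))
  g1 <- parameter_grid_spectra(base, "g_ii_ss", c(-0.2, 0.2), steps = 5)
  expect_error(trajectory_power(g1), "square")
})

test_that("the sensitivity screen sweeps all 14 parameters", {
  sc <- sensitivity_screen(default_parameters(), range_logunits = 0.4,
                           steps = 5)
  expect_length(sc, 14)
  expect_setequal(names(sc), cmc_variable_names())
  # zero range: every curve constant
  sc0 <- sensitivity_screen(default_parameters(), range_logunits = 0,
                            steps = 3)
  for (cu in sc0) expect_lt(diff(range(cu$curve$power)), 1e-12)
  # small-perturbation slope matches central differences of the forward model
  cu <- sc[["g_ii_dp"]]$curve
  mid <- (length(cu$value) + 1) / 2
  slope <- (cu$power[mid + 1] - cu$power[mid - 1]) /
    (cu$value[mid + 1] - cu$value[mid - 1])
  h <- 1e-4
  fi <- which.min(abs(default_grid() - 25))
  fd <- (predict_spectrum(perturb_parameters(default_parameters(),
                                             c(g_ii_dp = h)))$values[fi] -
           predict_spectrum(perturb_parameters(default_parameters(),
                                               c(g_ii_dp = -h)))$values[fi]) / (2 * h)
  expect_equal(slope, fd, tolerance = 0.05)
})

test_that("escape ranking identifies a planted parameter and is scale-free", {
  base <- default_parameters()
  target <- predict_spectrum(perturb_parameters(base, c(tau_ss = -0.5)))
  esc <- find_escape_parameters(base, target, steps = 21)
  expect_equal(esc$parameter[1], "tau_ss")
  expect_lt(abs(esc$best_value[1] + 0.5), 0.2)
  # identity target: no reductions, no flags
  esc0 <- find_escape_parameters(base, predict_spectrum(base), steps = 21)
  expect_lt(max(abs(esc0$reduction)), 1e-10)
  expect_false(any(esc0$crosses_transition))
  # global rescaling of the target changes nothing
  esc2 <- find_escape_parameters(base,
                                 spectral_data(target$freqs, target$values * 12),
                                 steps = 21)
  expect_equal(esc$parameter, esc2$parameter)
  expect_equal(esc$distance, esc2$distance, tolerance = 1e-10)
})

test_that("group-mean fitting averages then inverts", {
  g <- predict_spectrum(default_parameters())
  lst <- list(g, g, g)
  m <- mean_spectrum(lst)
  expect_equal(m$values, g$values)   # averaging is exact for identical input
  p <- fit_group_mean(lst)
  expect_lt(max(abs(p$theta[cmc_variable_names()])), 0.05)
  expect_gte(attr(p, "fit")$fit_correlation, 0.99)
})
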