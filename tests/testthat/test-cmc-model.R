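test_that("default parameterization exposes 14 variable parameters and is stable", {
  p <- default_parameters()
  expect_equal(count_free_parameters(p), 14)
  fam <- cmc_parameter_families()
  expect_equal(sum(lengths(fam)), 14)
  expect_equal(lengths(fam)[c("t", "e", "i", "m")],
               c(t = 4L, e = 3L, i = 3L, m = 4L))
  # stability via direct eigendecomposition
  ev <- eigen(build_jacobian(p)$A, only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
  # freezing all couplings leaves the four time constants
  pf <- freeze_parameters(p, unlist(fam[c("e", "i", "m")]))
  expect_equal(count_free_parameters(pf), 4)
})

test_that("the Jacobian matches finite differences of the rate equations", {
  p <- perturb_parameters(default_parameters(),
                          c(g_ii_ss = 0.2, tau_dp = -0.1))
  ssm <- build_jacobian(p)
  expect_equal(dim(ssm$A), c(8, 8))
  # independent right-hand side built directly from the kernel equations
  nat <- natural_parameters(p)
  pops <- cmc_populations()
  rhs <- function(x) {
    v <- x[c(1, 3, 5, 7)]; u <- x[c(2, 4, 6, 8)]
    names(v) <- names(u) <- pops
    inp <- c(ss = -nat[["g_ii_ss"]] * v["ii"],
             sp = nat[["g_ss_sp"]] * v["ss"] - nat[["g_ii_sp"]] * v["ii"],
             ii = nat[["g_ss_ii"]] * v["ss"] + nat[["g_dp_ii"]] * v["dp"],
             dp = -nat[["g_ii_dp"]] * v["ii"])
    names(inp) <- pops
    out <- numeric(8)
    for (k in seq_along(pops)) {
      pk <- pops[k]
      kap <- 1 / nat[[paste0("tau_", pk)]]
      s <- inp[[pk]] - nat[[paste0("g_self_", pk)]] * v[[pk]]
      out[2 * k - 1] <- u[[pk]]
      out[2 * k] <- kap * s - 2 * kap * u[[pk]] - kap^2 * v[[pk]]
    }
    out
  }
  h <- 1e-6
  J <- matrix(0, 8, 8)
  for (j in 1:8) {
    e <- numeric(8); e[j] <- h
    J[, j] <- (rhs(e) - rhs(-e)) / (2 * h)
  }
  expect_equal(ssm$A, J, tolerance = 1e-6)
})

test_that("zero couplings decouple the populations", {
  vn <- cmc_variable_names()
  p <- default_parameters()
  # send every coupling (not the self gains) to ~zero on the natural scale
  couplings <- c(cmc_parameter_families()$e, cmc_parameter_families()$i)
  p <- perturb_parameters(p, stats::setNames(rep(-30, length(couplings)),
                                             couplings))
  A <- build_jacobian(p)$A
  off <- A
  for (k in 1:4) off[2 * k - 1:0, 2 * k - 1:0] <- 0
  expect_lt(max(abs(off)), 1e-6)
})

test_that("transfer function rolls off at high frequency", {
  ssm <- build_jacobian(default_parameters())
  f <- c(seq(1, 45, 0.5), 200, 400)
  T <- transfer_function(ssm, f)
  expect_lt(max(Mod(T[f >= 200])), 0.01 * max(Mod(T)))
})

test_that("predicted spectrum has the documented additive and scaling structure", {
  p <- default_parameters()
  g <- predict_spectrum(p)
  expect_true(all(g$values > 0))
  # gain scaling is exact: obs_gain^2 on the neuronal part
  nat <- natural_parameters(p)
  noise <- nat[["noise_white"]] + nat[["noise_pink"]] / g$freqs
  g2 <- predict_spectrum(perturb_parameters(p, c(obs_gain = 0.5 * log(4))))
  expect_equal((g2$values - noise) / (g$values - noise),
               rep(4, length(g$freqs)), tolerance = 1e-10)
  # doubling input_white doubles only the white-driven neuronal part
  g3 <- predict_spectrum(perturb_parameters(p, c(input_white = log(2))))
  extra <- g3$values - g$values
  ssm <- build_jacobian(p)
  TT <- Mod(transfer_function(ssm, g$freqs))^2
  expect_equal(extra, nat[["obs_gain"]]^2 * TT * nat[["input_white"]],
               tolerance = 1e-8)
  # removing gain and innovations leaves channel noise
  g4 <- predict_spectrum(perturb_parameters(p, c(obs_gain = -40)))
  expect_equal(g4$values, noise, tolerance = 1e-8)
})

test_that("unstable parameterizations raise an instability error", {
  p <- perturb_parameters(default_parameters(), c(g_ii_dp = 1.5))
  expect_gt(stability_margin(p), 0)
  expect_error(predict_spectrum(p), class = "sedcm_instability")
  expect_error(simulate_timeseries(p, 10, 256, 1), class = "sedcm_instability")
})

test_that("spectral positivity holds across random stable parameter sets", {
  set.seed(42)
  vn <- cmc_variable_names()
  n_ok <- 0
  for (i in 1:40) {
    th <- stats::setNames(runif(length(vn), -1, 1), vn)
    p <- perturb_parameters(default_parameters(), th)
    if (stability_margin(p) >= 0) next
    g <- predict_spectrum(p)
    expect_true(all(is.finite(g$values)) && all(g$values > 0))
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 5)
})

test_that("simulation is seeded and self-consistent with the analytic spectrum", {
  p <- default_parameters()
  r1 <- simulate_timeseries(p, duration = 10, fs = 256, seed = 7)
  r2 <- simulate_timeseries(p, duration = 10, fs = 256, seed = 7)
  expect_identical(r1$signal, r2$signal)
  r3 <- simulate_timeseries(p, duration = 10, fs = 256, seed = 8)
  expect_false(identical(r1$signal, r3$signal))
  # zero innovations and zero channel noise give the zero signal
  p0 <- perturb_parameters(p, c(input_white = -Inf))
  p0$theta[c("input_white", "input_pink", "noise_white", "noise_pink")] <- -Inf
  r0 <- simulate_timeseries(p0, duration = 5, fs = 256, seed = 1)
  expect_equal(max(abs(r0$signal)), 0)
  # Welch PSD of a long simulation tracks the analytic prediction
  rec <- simulate_timeseries(p, duration = 300, fs = 512, seed = 99)
  ps <- welch_psd(rec, window_s = 8, freqs = default_grid())
  g <- predict_spectrum(p)
  K <- ps$meta$n_segments
  tol <- 3 * sqrt(1.06 / K) + 0.03
  expect_lt(max(abs(log(ps$values / g$values))), tol)
})

test_that("parameter sets serialize to JSON and back", {
  p <- perturb_parameters(default_parameters(), c(tau_ii = 0.3, g_ii_ss = -0.2))
  p <- freeze_parameters(p, "tau_sp")
  path <- tempfile(fileext = ".json")
  write_cmc_json(p, path)
  q <- read_cmc_json(path)
  expect_equal(q$theta, p$theta)
  expect_equal(q$variable, p$variable)
  expect_equal(q$edges$excitatory[, "source"], p$edges$excitatory[, "source"])
})
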