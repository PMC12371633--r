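# Shared fixtures for the test suite. Everything is generated in code.

# noisy observed spectrum from a single-parameter perturbation
perturbed_spectrum <- function(name, delta, noise_sd = 0.1, seed = 1) {
  p <- perturb_parameters(default_parameters(), stats::setNames(delta, name))
  g <- predict_spectrum(p)
  set.seed(seed)
  spectral_data(g$freqs, g$values * exp(rnorm(length(g$values), 0, noise_sd)))
}

# idealized first-level posteriors: truth + N(0, sd), diagonal covariance;
# isolates the second level from first-level identifiability
idealized_first_level <- function(ground_truth, sd = 0.05, seed = 1) {
  set.seed(seed)
  vn <- cmc_variable_names()
  lapply(ground_truth$theta, function(th) {
    m <- stats::setNames(numeric(19), cmc_parameter_names())
    m[vn] <- th[vn] + rnorm(length(vn), 0, sd)
    S <- diag(c(rep(sd^2, length(vn)), rep(1e-6, 5)))
    dimnames(S) <- list(names(m), names(m))
    prior_density(m, S, free_energy = 0)
  })
}

# linear-Gaussian toy model with exact evidence
linear_toy <- function(n = 20, p = 3, sigma = 0.2, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b <- c(0.5, -0.3, 0)[seq_len(p)]
  y <- as.vector(X %*% b + rnorm(n, 0, sigma))
  S0 <- diag(p)
  mu0 <- rep(0, p)
  evidence <- function(S0r) {
    Sy <- diag(sigma^2, n) + X %*% S0r %*% t(X)
    as.numeric(-0.5 * n * log(2 * pi) -
                 0.5 * determinant(Sy, logarithm = TRUE)$modulus[1] -
                 0.5 * t(y) %*% solve(Sy, y))
  }
  Spost <- solve(t(X) %*% X / sigma^2 + solve(S0))
  mpost <- as.vector(Spost %*% (t(X) %*% y / sigma^2))
  list(X = X, y = y, sigma = sigma, S0 = S0, mu0 = mu0,
       evidence = evidence, post_mean = mpost, post_cov = Spost)
}
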