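# Linearized canonical microcircuit: state-space form, transfer function,
# predicted power spectrum, and stochastic surrogate time series.
#
# Each population k obeys a second-order convolution kernel
#   v_k'' = kappa_k * s_k - 2 kappa_k v_k' - kappa_k^2 v_k,   kappa_k = 1/tau_k
# where s_k is the net synaptic input: excitatory couplings enter with
# positive sign, inhibitory and recurrent self-modulatory couplings with
# negative sign. The sigmoid firing nonlinearity is linearized at the
# operating point, its slope absorbed into the coupling gains.

#' Build the linearized state-space model
#'
#' Assembles the 8x8 Jacobian `A` (two states per population, depolarization
#' and its derivative), the input mapping `B` (exogenous/innovation input
#' drives the spiny stellate population through its kernel) and the
#' observation vector `C` (a fixed mixture of population depolarizations
#' dominated by the superficial pyramidal cells).
#'
#' @param params A `cmc_parameters` object.
#' @return An object of class `cmc_ssm` with elements `A`, `B`, `C`.
#' @export
build_jacobian <- function(params) {
  stopifnot(inherits(params, "cmc_parameters"))
  nat <- natural_parameters(params)
  pops <- cmc_populations()
  tau <- nat[paste0("tau_", pops)]
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("invalid parameters: non-positive or non-finite time constant")
  kappa <- stats::setNames(1 / tau, pops)

  iv <- function(p) 2L * match(p, pops) - 1L  # depolarization state
  iu <- function(p) 2L * match(p, pops)       # its derivative

  A <- matrix(0, 8, 8)
  for (p in pops) {
    gs <- nat[[paste0("g_self_", p)]]
    A[iv(p), iu(p)] <- 1
    A[iu(p), iv(p)] <- -kappa[[p]]^2 - kappa[[p]] * gs
    A[iu(p), iu(p)] <- -2 * kappa[[p]]
  }
  add_edges <- function(A, edges, sign, prefix) {
    for (j in seq_len(nrow(edges))) {
      src <- edges[j, "source"]; tgt <- edges[j, "target"]
      g <- nat[[paste0(prefix, src, "_", tgt)]]
      A[iu(tgt), iv(src)] <- A[iu(tgt), iv(src)] + sign * kappa[[tgt]] * g
    }
    A
  }
  A <- add_edges(A, params$edges$excitatory, +1, "g_")
  A <- add_edges(A, params$edges$inhibitory, -1, "g_")

  B <- matrix(0, 8, 1)
  B[iu("ss"), 1] <- kappa[["ss"]]
  # scalp signal: superficial pyramidal dominant, deep pyramidal next,
  # a small stellate contribution; interneurons contribute no net dipole
  C <- matrix(0, 1, 8)
  C[1, iv("sp")] <- 1
  C[1, iv("dp")] <- 0.5
  C[1, iv("ss")] <- 0.2
  if (any(!is.finite(A))) stop("invalid parameters: non-finite Jacobian")
  structure(list(A = A, B = B, C = C), class = "cmc_ssm")
}

#' Largest real part of the Jacobian eigenvalues
#' @param params A `cmc_parameters` object (or a `cmc_ssm`).
#' @return Numeric scalar; negative means linearly stable.
#' @export
stability_margin <- function(params) {
  A <- if (inherits(params, "cmc_ssm")) params$A else build_jacobian(params)$A
  max(Re(eigen(A, only.values = TRUE)$values))
}

#' First-order transfer function of the linearized model
#'
#' Evaluates T(f) = C (2i pi f I - A)^{-1} B on a frequency grid, using an
#' eigendecomposition of `A` so the per-frequency cost is O(n).
#'
#' @param ssm A `cmc_ssm` from [build_jacobian()].
#' @param freqs Frequency grid in Hz.
#' @return Complex vector of responses, one per frequency.
#' @export
transfer_function <- function(ssm, freqs) {
  stopifnot(inherits(ssm, "cmc_ssm"))
  A <- ssm$A
  eg <- eigen(A)
  V <- eg$vectors
  vb <- tryCatch(as.vector(solve(V, ssm$B)), error = function(e) NULL)
  if (!is.null(vb)) {
    cv <- as.vector(ssm$C %*% V)
    out <- vapply(freqs, function(f) {
      d <- 2i * pi * f - eg$values
      if (any(Mod(d) < 1e-12))
        stop(sprintf("singular resolvent at %g Hz", f))
      sum(cv * (vb / d))
    }, complex(1))
    return(out)
  }
  # defective eigenbasis: fall back to direct solves
  vapply(freqs, function(f) {
    M <- diag(2i * pi * f, nrow(A)) - A
    res <- tryCatch(solve(M, ssm$B), error = function(e)
      stop(sprintf("singular resolvent at %g Hz", f)))
    (ssm$C %*% res)[1, 1]
  }, complex(1))
}

# Innovation (neuronal input) spectral density at frequency f.
.innovation_density <- function(nat, f) {
  nat[["input_white"]] + nat[["input_pink"]] / f
}

# Channel (nonneuronal) noise spectral density at frequency f.
.channel_density <- function(nat, f) {
  nat[["noise_white"]] + nat[["noise_pink"]] / f
}

#' Predicted power spectrum of the microcircuit
#'
#' The one-sided power density at frequency f is
#' `obs_gain^2 * |T(f)|^2 * g_u(f) + g_n(f)`, where the innovation density
#' `g_u(f) = input_white + input_pink / f` drives the circuit and the
#' channel-noise density `g_n(f) = noise_white + noise_pink / f` adds at the
#' electrode.
#'
#' @param params A `cmc_parameters` object; must describe a stable system.
#' @param freqs Frequency grid in Hz (default [default_grid()]).
#' @return A `spectral_data` with strictly positive values.
#' @export
predict_spectrum <- function(params, freqs = default_grid()) {
  stopifnot(inherits(params, "cmc_parameters"))
  ssm <- build_jacobian(params)
  margin <- stability_margin(ssm)
  if (!is.finite(margin) || margin >= 0)
    stop(structure(class = c("sedcm_instability", "error", "condition"),
                   list(message = sprintf(
                     "unstable parameterization (max Re eigenvalue = %.3g)",
                     margin), call = sys.call())))
  nat <- natural_parameters(params)
  T <- transfer_function(ssm, freqs)
  g <- nat[["obs_gain"]]^2 * Mod(T)^2 * .innovation_density(nat, freqs) +
    .channel_density(nat, freqs)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("predicted spectrum is not strictly positive and finite")
  spectral_data(freqs, g)
}

# Exact zero-order-hold discretization of (A, B) at sampling step dt,
# via the eigendecomposition: Ad = V exp(D dt) V^-1, Bd = A^-1 (Ad - I) B.
.zoh_discretize <- function(A, B, dt) {
  eg <- eigen(A)
  V <- eg$vectors
  Ad <- Re(V %*% (exp(eg$values * dt) * solve(V)))
  Bd <- solve(A, (Ad - diag(nrow(A))) %*% B)
  list(Ad = Ad, Bd = Bd)
}

# Random-phase harmonic synthesis of a real signal with one-sided PSD
# `psd_fun(f)` (power per Hz) at sampling rate fs, length n. Uses an inverse
# FFT over Fourier frequencies (DC excluded).
.synthesize_noise <- function(psd_fun, n, fs) {
  df <- fs / n
  nf <- floor((n - 1) / 2)            # positive Fourier frequencies
  f <- df * seq_len(nf)
  amp <- sqrt(psd_fun(f) * df)        # sd per complex component pair
  phases <- stats::runif(nf, 0, 2 * pi)
  X <- complex(modulus = amp, argument = phases)
  spect <- complex(real = numeric(n))
  spect[2:(nf + 1)] <- X
  spect[n + 1 - seq_len(nf)] <- Conj(X)
  if (n %% 2 == 0) { # Nyquist bin
    fny <- fs / 2
    spect[n / 2 + 1] <- sqrt(psd_fun(fny) * df) *
      sign(stats::runif(1) - 0.5)
  }
  # each retained component pair contributes variance 2*amp^2; dividing by
  # sqrt(2) makes that psd_fun(f)*df, i.e. the target density
  Re(stats::fft(spect, inverse = TRUE)) / sqrt(2)
}

#' Simulate a surrogate EEG time series from the microcircuit
#'
#' Integrates the linearized system, driven by neuronal innovations with
#' spectral density `g_u`, by exact zero-order-hold discretization at the
#' sampling rate, and adds electrode noise with density `g_n`. Fully seeded
#' and reproducible.
#'
#' @param params A stable `cmc_parameters` object.
#' @param duration Length of the simulation in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for the innovation and noise draws.
#' @return A `recording` object (see [recording()]) with the sampled signal.
#' @export
simulate_timeseries <- function(params, duration = 300, fs = 512, seed = 1) {
  stopifnot(inherits(params, "cmc_parameters"), duration * fs >= 2 * fs)
  ssm <- build_jacobian(params)
  if (stability_margin(ssm) >= 0)
    stop(structure(class = c("sedcm_instability", "error", "condition"),
                   list(message = "unstable parameterization", call = sys.call())))
  nat <- natural_parameters(params)
  n <- round(duration * fs)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- if (nat[["input_white"]] == 0 && nat[["input_pink"]] == 0)
    numeric(n) else .synthesize_noise(function(f) .innovation_density(nat, f), n, fs)
  eta <- if (nat[["noise_white"]] == 0 && nat[["noise_pink"]] == 0)
    numeric(n) else .synthesize_noise(function(f) .channel_density(nat, f), n, fs)
  dd <- .zoh_discretize(ssm$A, ssm$B, 1 / fs)
  y <- ss_filter(dd$Ad, dd$Bd[, 1], ssm$C[1, ], u)
  signal <- nat[["obs_gain"]] * y + eta
  recording(signal = signal, fs = fs,
            meta = list(source = "cmc_simulation", seed = seed))
}
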