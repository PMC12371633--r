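---
title: "Inferring synaptic drivers of benzodiazepine response from EEG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synaptic drivers of benzodiazepine response from EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedcm)
```

## The scientific problem

Benzodiazepines (BZPs) are the first-line treatment for status epilepticus
(SE), yet a substantial fraction of patients do not respond. Because BZPs
are positive allosteric modulators of GABA\(_A\) receptors, the difference
between responders and nonresponders plausibly lives at the level of
synaptic inhibition in cortical microcircuits — a quantity that cannot be
read off an EEG trace directly, but can be *inferred* by fitting a
generative model of cortical population dynamics to the EEG power spectrum.

`sedcm` implements that inferential pipeline end to end:

1. a **canonical microcircuit (CMC) neural mass model** of a single
   cortical column whose linearized transfer function predicts the EEG
   power spectrum on 1–45 Hz;
2. **variational Laplace inversion** of that spectral model, yielding a
   Gaussian posterior over log-scale synaptic parameters and a free-energy
   approximation to log model evidence;
3. a **parametric empirical Bayes (PEB)** second level that tests
   group-structured hypotheses (responder/nonresponder differences, BZP
   effects, their interaction) and, via **Bayesian model reduction (BMR)**,
   compares the 15 models formed by all nonempty combinations of the four
   parameter families;
4. an **in-silico engine** that maps seizure-termination routes in
   synaptic parameter space;
5. a **synthetic-cohort generator** with known ground truth, so every
   stage is exercised by parameter- and model-recovery experiments — the
   patient EEG the real analysis would consume is not publicly available.

## The microcircuit model

Four neural masses represent a cortical column: spiny stellate cells
(`ss`), superficial pyramidal cells (`sp`), inhibitory interneurons (`ii`)
and deep pyramidal cells (`dp`). Each population's mean depolarization
\(v_k\) responds to its net synaptic input \(s_k\) through a second-order
convolution kernel

\[
\ddot v_k = \kappa_k s_k - 2\kappa_k \dot v_k - \kappa_k^2 v_k,
\qquad \kappa_k = 1/\tau_k ,
\]

with excitatory couplings entering \(s_k\) positively, and inhibitory and
recurrent self-modulatory couplings negatively. The firing-rate
nonlinearity is linearized at the operating point and its slope absorbed
into the coupling gains: spectral fitting addresses stationary
fluctuations around a fixed point, for which the linearized system is the
exact generative model of second-order statistics.

The **14 variable synaptic parameters** are the four kernel time constants
(`tau_ss`, `tau_sp`, `tau_ii`, `tau_dp`), three excitatory couplings
(ss→sp, ss→ii, dp→ii), three inhibitory couplings (ii→ss, ii→sp, ii→dp)
and four self-modulatory gains. Five **nonneuronal scaling parameters**
(white/pink innovation amplitudes, white/pink channel-noise amplitudes,
electrode gain) complete the observation model:

\[
g(f) = a^2\,|T(f)|^2 \left(u_w + u_p/f\right) + n_w + n_p/f ,
\]

where \(T(f) = C(2\pi i f I - A)^{-1}B\) is the transfer function of the
8-state Jacobian. All parameters are stored as log-scale deviations
\(\theta\) from packaged default means (value \(= \mathrm{default}\cdot
e^{\theta}\)), which makes positivity automatic and lets a single Gaussian
prior act multiplicatively.

### Choices behind the packaged defaults

* **Time constants 6, 6, 16, 28 ms** (ss, sp, ii, dp) and uniform coupling
  gains 120 (self-gains 60). Two constraints drove this: (i) the default
  system must be stable with margin, including under every single ±0.5
  log-unit perturbation used by the recovery experiments, and (ii) *every*
  one of the 14 parameters must leave a usable signature on 1–45 Hz. With
  the faster 2-ms superficial kernels often quoted for this architecture,
  inhibition onto the spiny stellate population — the very parameter the
  analysis is designed to interrogate — changed the in-band spectrum by
  almost nothing (RMS log-spectral effect ≈ 0.10 per 0.5 log-units) and
  was unrecoverable; at 6 ms its signature more than doubles while the
  resonance structure (≈12 Hz alpha-band peak plus a beta-band shoulder)
  stays physiological.
* **Observation vector** \(C\): fixed mixture \(v_{sp} + 0.5\,v_{dp} +
  0.2\,v_{ss}\). Pyramidal populations dominate the scalp signal;
  including a deep pyramidal contribution measurably reduces the
  collinearity between parameter effects compared to a pure superficial
  readout. Interneurons contribute no net dipole.
* **Input enters through the spiny stellate kernel** (the thalamic
  recipient layer), the standard convention.
* **Noise structure**: innovations and channel noise are each white + pink
  with a fixed \(1/f\) exponent; conduction delays are omitted (a single
  virtual channel makes them unidentifiable).
* **Frequency grid**: 1–45 Hz in 0.5 Hz steps (89 points).

The stochastic simulator integrates the same linear system by exact
zero-order-hold discretization at the sampling rate, driven by
random-phase harmonic innovations with density \(g_u\), plus synthesized
channel noise. Simulation and analytic spectrum are two independent routes
to the same quantity; their agreement (Welch estimate within three
standard errors at every grid point) is part of the acceptance suite.
Sampling at 512 Hz keeps the zero-order-hold attenuation at 45 Hz below
3%. The oracle comparison uses 8-s Welch windows (0.125-Hz resolution)
and excludes draws within 2 units of the stability boundary: sharp
resonances and transfer-function notches narrower than the estimator's
resolution would otherwise bias the Welch estimate, and the comparison is
meant to measure the model, not the estimator.

## Spectral estimation and epoch rules

`welch_psd()` uses 4-s Hann windows with 50% overlap (0.25-Hz native
resolution, linearly interpolated onto the model grid). Premedication
epochs end 1 min before BZP administration; postmedication epochs start
6 min after administration in nonresponders, and 1 min after
electrographic termination (the `se_termination` event, or the last
`seizure_offset` in intermittent seizures) in responders; both epochs are
exactly 300 s. Band edges are delta 1–4, theta 4–8, alpha 8–13, beta
14–30 and gamma 30–45 Hz, the gamma ceiling set by the 45-Hz fit limit.

## Variational Laplace inversion

The observation model treats log-power residuals as independent Gaussians
with precision \(e^{\lambda}\): the log transform stabilizes variance
across the 1–45 Hz range and turns the arbitrary microvolt scaling into a
gain offset. With a Gaussian prior \(N(\mu_0, \Sigma_0)\) over \(\theta\),
the Laplace free energy

\[
F = \underbrace{-\tfrac{e^{\lambda}}{2}\lVert y - h(\theta)\rVert^2
  + \tfrac{n}{2}\lambda - \tfrac{n}{2}\log 2\pi}_{\text{accuracy}}
  \; - \; \underbrace{\tfrac12 (\theta-\mu_0)^\top \Sigma_0^{-1}(\theta-\mu_0)
  + \tfrac12 \log\frac{|\Sigma_0|}{|S|}}_{\text{complexity}}
\]

is maximized by Gauss–Newton steps with Levenberg–Marquardt damping;
only steps that increase \(F\) are accepted, so the accepted-iteration
trajectory is non-decreasing by construction. Gradients use central
finite differences (step \(10^{-3}\) log-units; the forward model costs
well under a millisecond on the 89-point grid). The residual precision is
point-estimated by empirical Bayes (\(e^{\hat\lambda} = n/\lVert e
\rVert^2\), capped at \(10^8\) to keep the noiseless self-consistency
limit finite) and kept only when the update raises \(F\). Convergence is
declared after three consecutive iterations improving \(F\) by less than
0.01 nat, with a 128-iteration cap. On a linear-Gaussian model with fixed
precision this machinery reproduces the closed-form log marginal
likelihood to machine precision — the acceptance suite checks \(10^{-6}\).

Prior variances are 1/8 for coupling gains and 1/16 for time constants
and nonneuronal parameters, with no prior covariance. Proposals that land
in the unstable region simply fail the forward model; the step is
rejected and damping increased.

Each patient is fitted in the two-pass scheme: the premedication spectrum
first under the default prior; then `tie_nonneuronal_parameters()` pins
the five nonneuronal parameters (prior variance \(10^{-6}\), centred on
the first posterior) so that the postmedication fit must explain pre/post
differences with synaptic parameters.

## The second level: PEB and BMR

Each first-level posterior over the 14 synaptic parameters enters a
hierarchical linear model \(\theta_i = B^\top x_i + \varepsilon_i\),
\(\varepsilon_i \sim N(0, \Gamma)\), with effect-coded (±1) regressors:
intercept, responsiveness (`resp`), treatment (`bzp`) and their
interaction, plus optional nuisance columns for other antiseizure
medications (excluded from all hypothesis reductions). Effect coding
makes the intercept the grand mean and the main effects orthogonal in
balanced designs.

Rather than regressing posterior means (which are prior-shrunk and would
attenuate group effects), the implementation re-evaluates each subject's
log evidence as a function of the design prediction by the Gaussian
identity behind Bayesian model reduction: replacing the subject's fitting
prior with \(N(B^\top x_i, \Gamma)\) in its posterior yields a quadratic
in \(B\), so the joint posterior over all second-level effects and the
total free energy are available in closed form. \(\Gamma\) is diagonal —
one variance per parameter, parameterized as a common fraction of the
first-level prior variances — and that single scale is optimized by
marginal likelihood. (With full first-level covariances the evidence does
not factor across parameters, so fourteen independent random-effects
scalars would not be separately identifiable at cohort sizes of interest;
the shared-scale form is the identifiable version of a per-parameter
diagonal \(\Gamma\).) Priors on the effects are \(N(0, 1)\) for intercepts
and \(N(0, 1/4)\) for all other regressors.

Hypothesis comparison scores three nested reductions of the full model by
free energy: **H1** keeps the two main effects, **H2** keeps the
treatment main effect and the interaction, **H3** keeps the full
complement. Family comparison reduces the full fit to each of the 15
masks formed by nonempty subsets of the families `t` (time constants),
`m` (self-modulatory), `e` (excitatory), `i` (inhibitory): non-intercept
effects on parameters outside the mask are pruned. All reductions use the
analytic BMR update — no refitting — and a winner is reported as
"decisive" only beyond 3 nats; ties are reported, never silently broken.
Both comparisons derive from a single full fit, so the fixed-effects
league table is invariant to evaluation order.

## The synthetic cohort

`cohort_config()` defaults encode the structure the analysis is built to
detect, as ±1-coded second-level effects on inhibitory couplings:
baseline `g_ii_ss` −0.3 (responders have weaker GABAergic inhibition of
spiny stellate cells during established SE), shared BZP effect +0.2, and
an interaction of +0.4 on `g_ii_ss` with −0.1 on `g_ii_dp` (responders
gain extra stellate inhibition and lose a little deep pyramidal
inhibition). These magnitudes are packaged conventions chosen for
identifiability at 300-s spectra, not measured values; the directions are
the scientific content. Cohort shape defaults to 8 responders and 9
nonresponders. Patient heterogeneity is Gaussian on all 14 synaptic
log-parameters (sd 0.1); unstable compositions trigger a bounded redraw.
Output is either model spectra with multiplicative log-normal observation
noise (sd 0.1), or continuous 1260-s surrogate EEG with `bzp_admin` at
600 s (and `se_termination` at 800 s for responders), switching from
pre-state to post-state dynamics at the drug onset (nonresponders) or the
termination (responders) so that the extracted epochs are stationary.

What the generator emulates: group-structured shifts of inhibitory
coupling, between-patient variability, pink+white observation noise, the
epoch/event layout of a monitored SE admission. What it does not emulate:
nonstationary seizure evolution, spike-wave morphology, artifacts,
montage and volume-conduction effects, intermittent electrographic
patterns. Recovery results on this cohort therefore demonstrate the
*inferential machinery*, not robustness to real-world EEG pathology.

## In-silico navigation and the state-transition demonstration

`parameter_grid_spectra()` evaluates predicted spectra over 1- or 2-D
grids of log-deviations; `trajectory_power()` tracks power at a probe
frequency (default 25 Hz) along the diagonal of a square grid;
`detect_transition()` flags the first adjacent pair whose absolute
log-power jump exceeds a threshold (default \(\log 2\); raising the
threshold can never create a detection). In the linearized circuit an
ictal-like state is operationalized as the sharply resonant, high-power
regime adjacent to the linear stability boundary; crossing the boundary
along a trajectory is recorded as a gap and counts as the transition.
This is the linear surrogate of a seizure-termination discontinuity: a
nonlinear circuit would express the ictal side as a limit cycle, which
the linearization can represent only as instability.

The packaged demonstration (`state_transition_demo()`) generates a small
demo cohort at an "established SE" operating point — `tau_ii` and
`tau_dp` one log-unit faster so the least-damped mode sits at the 25-Hz
probe, and `g_ii_dp` elevated so every premedication state is
near-boundary — with demo-specific effect magnitudes under which both
groups start equally ictal and only responders terminate (net `g_ii_dp`
drop of 0.9 log-units). Group-mean parameters are fitted (pre first, then
nonneuronal-tied post), and three packaged routes are navigated from the
fitted premedication states, along the demo cohort's generative BZP
directions: the responder route crosses the boundary (transition
detected), the nonresponder route stays on the smooth side (none), and a
`tau_ss`-augmented route for the nonresponder crosses it (transition
detected), mirroring the idea that stellate kernel dynamics offer an
alternative exit from SE. `find_escape_parameters()` ranks
single-parameter sweeps by gain-adjusted mean squared log-spectral
distance to the responders' terminated spectrum; sweeps whose optimum
lies across a detected transition are flagged, and the stellate time
constant is among them. The demo's cohort seed (42), routes and operating
point are packaged constants: the demonstration is a deterministic
figure, not an experiment; routes estimated from the demo cohort's own
PEB effects vary too much across seeds to serve a deterministic
demonstration, so the generative directions are used and documented as
such.

## Problem sizes and numerical conventions

The recovery and model-selection experiments in the test suite and the
acceptance script use: 20 single-parameter fixtures (±0.5 log-units,
noise sd 0.1); 10 structured and 10 null cohorts at the default 8+9
shape with two inversions per patient; forward-model checks on five
random stable parameter sets with 600-s simulations at 512 Hz. A full
first-level inversion takes well under a second; a full cohort replicate
(34 inversions plus both second-level comparisons) runs in under 20 s.
Degenerate inputs are handled explicitly: unstable parameterizations
raise a typed error from `predict_spectrum()`; grids record unstable
points as gaps; `detect_transition()` refuses nonpositive power; the BMR
routine refuses non-nested (variance-widening) reductions.

## Known limitations

* **Marginal identifiability of single parameters is limited.** A single
  89-point spectrum fitted with 19 free parameters is underdetermined;
  parameter effects are strongly collinear (self-gains with their
  population's time constant; the two pyramidal-loop couplings with each
  other). Posterior credible intervals are honest about this — coverage
  in the recovery suite comes with substantial shrinkage of the point
  estimates toward the prior.
* **Between-patient level differences are the weakest link.** Shrinkage
  and collinearity at the first level absorb much of a between-group
  baseline difference in `g_ii_ss`, while within-patient (pre/post)
  contrasts are protected by the nonneuronal tying. In model-selection
  experiments at the default effect sizes the inhibitory family is
  recovered essentially always, and treatment and interaction effects are
  detected, but the responsiveness main effect is often not — the
  hypothesis comparison then prefers H2 over the generating H3. Feeding
  the second level idealized first-level posteriors recovers H3 by tens
  of nats, which localizes the information loss squarely at the
  first-level inversion. An iterated scheme that re-inverts under
  empirical group priors was evaluated and rejected: it amplified
  first-pass biases rather than correcting them.
* **Null cohorts produce a decisive parsimony winner.** The three
  candidate designs all carry effects (there is no intercept-only
  candidate), so on data with no group structure the comparison turns on
  which effects each design prunes. Pruning within-subject effects —
  tightly measured at zero — gains Occam evidence; pruning the
  prior-wide between-subject effects gains almost none. H1 therefore
  tends to win decisively on null cohorts. This is correct Bayesian
  behaviour, but it means a decisive hypothesis winner on its own is not
  evidence of group structure; the effect estimates and their credible
  intervals must be read alongside it.
* The linear surrogate of ictal dynamics (instability = seizure) is a
  modelling convention; it supports the qualitative state-transition
  demonstration but not quantitative statements about seizure dynamics.
* Free energies are Laplace approximations around a local optimum; the
  optimizer's monotone-acceptance rule guarantees ascent, not a global
  optimum.
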