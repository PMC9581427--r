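---
title: "Modelling cued auditory decisions with cueddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cued auditory decisions with cueddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueddm)
```

## The scientific problem

In a two-alternative auditory frequency-discrimination task, a listener
reports whether a faint test tone embedded in noise is "low" or "high"
frequency. Expectations about the upcoming tone can come from two very
different sources: an explicit **rule-based cue** (a visual symbol
announcing 5:1, 1:1 or 1:5 odds of a high tone) or a **stimulus-based
cue** (a short sequence of clearly audible tone bursts preceding the
test tone, which is on average non-predictive but biases perception
through recency and adaptation). `cueddm` provides the machinery to ask,
on joint choice and response-time (RT) data, *how* each cue source
biases the decision process: by shifting where evidence accumulation
starts, by tilting the rate at which it accumulates, or by changing
stimulus sensitivity itself.

## The decision model

The core is a generalized drift-diffusion model (DDM). A decision
variable `x` evolves as

    dx = v dt + sigma dW,        sigma = 1,

between two absorbing bounds at `+/-(B - t_B t)`; the linear collapse
`t_B` captures urgency under the response deadline (2 s, or 3 s for
part of the rule-based cohort). Upper-bound crossings are "high"
choices. The drift on a trial is

    v = v_SNR * SNR + bias_evidence + adapt * |SNR|,

where `SNR` is the signed unit-scaled tone level (positive = high
frequency). The three bias routes are:

* **Evidence-accumulation bias** (`bias_evidence`): for rule cues, a
  per-cue constant (`v_Low`, `v_0`, `v_High`); for stimulus cues,
  `v_0 + v_Bias * pt_Bias`, with `pt_Bias` the recency-weighted tone
  history (each pre-test tone contributes `±exp(-p / tau_Bias)`, where
  position `p = 0` is the tone immediately before the test tone).
* **Starting-point bias**: the start fraction of the bound separation
  is a logistic transform `g(z)` of a logit-scale bias; per-cue
  (`z_Low`, `z_0`, `z_High`) for rule cues and
  `g(z_0 + z_Bias * pt_Bias)` for stimulus cues.
* **SNR-dependent adaptation** (`adapt * |SNR|`): an exponentially
  weighted tone-history sum with separate weights for high and low
  tones (`va_High`, `va_Low`, time constant `tau_va`). Negative weights
  push choices *away* from recently repeated frequencies, which is what
  distinguishes repulsive, adaptation-like effects from ordinary biases
  — biases shrink with |SNR| whereas this term grows with it, producing
  the characteristic crossover from attraction at low SNR to repulsion
  at high SNR.

Non-decision time is `ndt = ndt_0 + ndt_Bias * |pt_Bias|`, and a lapse
mixture of weight `lambda` adds a uniform density over both choices and
the response window. RT is decision time plus `ndt`.

One deliberate convention: the rule-based starting points are
parameterized on the logit scale throughout (fitting included), so that
a reported `z_High = 0.39` means a start fraction `g(0.39) = 0.60`.
This is a monotone reparameterization — it does not change the model
class — and it makes rule- and stimulus-based starting-point parameters
directly comparable.

## Numerics

First-passage densities are computed by a finite-difference solution of
the forward (Fokker–Planck) equation on a fixed spatial grid, with the
collapsing bound realized as a moving absorbing (Dirichlet) boundary;
cells swallowed by the moving bound are credited to that bound, and the
diffusive outflow of each step is split between the two bounds in
proportion to the upwinded boundary fluxes, so total probability is
conserved exactly by construction. Time stepping is a theta scheme:
Crank–Nicolson for fixed-bound problems after a short backward-Euler
(Rannacher) startup that damps the oscillations CN develops on the
point-mass initial condition, and fully backward Euler whenever the
bound collapses (a moving Dirichlet boundary re-excites CN
oscillations at every boundary shift). Defaults are `dt = dx = 0.005`;
at these settings fixed-bound absorption probabilities match the
closed form `(1 - e^{-2 mu z_0}) / (1 - e^{-2 mu a})` to about `3e-5`,
and the collapsing-bound solution agrees with a `1e-4`-step
Euler–Maruyama Monte-Carlo oracle to within Kolmogorov–Smirnov
distance 0.005 on decision-time distributions.

Other numerical choices:

* Likelihood evaluation groups trials with identical (drift, start,
  window) drivers and solves each group once; densities at observed RTs
  are linearly interpolated on the solver's time grid, with a floor of
  `1e-10` per trial against sparse tails.
* If the bound collapses to zero inside the window, all remaining mass
  is absorbed at that moment (positive `x` to the upper bound, negative
  to the lower) and the densities are truncated there.
* Start fractions are clamped to `[0.01, 0.99]`.
* The drift-variability variant integrates the DDM density over a
  uniform `v_SNR` band via 15-point Gauss–Legendre quadrature.
* The lapse density is uniform over both choices and `(0, window]`,
  i.e. `1 / (2 * window)` per choice.

## Fitting and model comparison

Each model variant (a nested lattice from the 6-parameter base model to
the 14-parameter stimulus-based full model) is fit per subject by
maximizing the summed log density of observed (choice, RT) pairs with
differential evolution (rand/1/bin, `F = 0.7`, `CR = 0.9`, seedable)
inside generous search boxes, followed by a box-bounded L-BFGS-B
polish. Two initialization devices make the high-dimensional fits
tractable: `embed_in_variant()` maps a reduced fit into a richer
variant's space so richer fits are warm-started from nested ones
(`fit_variant_ladder()` automates the cascade), which also makes the
nesting inequality (`logL(full) >= logL(reduced)`) hold by
construction rather than by optimizer luck — mirroring how negative
log-likelihood-ratio artifacts are otherwise produced by local minima
near the global solution; and a deterministic multistart grid over the
nonlinear axes (time constants log-spaced across their box, adaptation
weights at negative, zero and positive values) can be handed to the
optimizer as initial population members. The full stimulus-based
likelihood has genuinely competing (tau, adaptation-weight) basins;
at small optimizer budgets the fitted time constants and adaptation
weights can land in a neighboring basin even when the drift and bias
gains are recovered well, so budget matters most for exactly those
parameters.

Cohort-level comparison uses mean AIC/BIC and random-effects Bayesian
model selection on `-AIC/2` evidences: a variational Dirichlet
posterior over model frequencies (prior concentration 1), exceedance
probabilities by `1e5` seeded Dirichlet draws, and protection by the
Bayes omnibus risk, `pep = ep * (1 - bor) + bor / K`. When two variants
genuinely tie, `bor` rises and PEP correctly shrinks toward `1/K` — a
feature to keep in mind when reading PEP tables with closely matched
models.

Per-subject likelihood-ratio tests between the full and the
evidence-only / starting-point-only variants classify subjects by which
bias mechanisms their data demand (`classify_subject()`), with negative
log-likelihood ratios clipped at zero.

## Psychometrics and performance landscapes

The logistic choice models share one lapse parameter per fit,
`P(H) = lambda + (1 - 2 lambda) / (1 + e^{-f})`, with `f` built per
condition (cue-specific intercepts; per-position pre-test tone
contrasts coded ±0.5 with positions indexed from 1 — note the DDM's
history sums index from 0, both conventions deliberately preserved).
Fitting is multi-start L-BFGS-B with `lambda` bounded in `[0, 0.2]`.

`performance_grid()` predicts accuracy over a grid of (starting-point,
evidence) bias pairs in a fixed cue context, weighting trial types by
the context's tone probabilities, and normalizes to proportion of the
grid maximum; `contour_97()` extracts the 97%-of-maximum region and
`proportion_max()` interpolates a subject's fitted biases on the
surface. Conventions chosen where the procedure was open: lapse trials
count 50% correct and window-expiry mass counts as incorrect; the rule
contexts sample the `z` grid as realized start fractions in (0.1, 0.9)
(injected through the logit), while the stimulus contexts sample
`z_Bias` directly on a symmetric grid around zero, since fitted
`z_Bias` values are small and signed; stimulus-context grids hold the
fitted adaptation weights fixed.

## Pupillometry

`clean_trace()` implements the stated cleaning rules: blink and missing
spans expanded by ±100 ms; sample-to-sample velocity above 24 a.u./ms
removed, with runs longer than 16 ms also expanded by ±100 ms; linear
interpolation across all flagged spans (gaze likewise); then a
3rd-order zero-phase Butterworth low-pass at 8 Hz (the filter family
and order are our choice — verified by the testable property that
20 Hz is attenuated by more than 20 dB and 1 Hz by less than 1 dB —
applied with odd-reflection padding so the filter's zero initial
conditions cannot leak transients into the trace). Processing order is
interpolate → filter → z-score (within block) → baseline-correct
(mean over 0–40 ms after tone onset), following the order the rules
are stated in. Exclusions: trial at >50% interpolated samples, session
at >60%, gaze excursions beyond the session's 95% fixation circle
(95th percentile of baseline-centered radial distances) for more than
15 consecutive ms, and subjects below 75 surviving trials.

Group inference is deliberately two-stage rather than per-bin mixed
models: per subject and 20-ms bin an OLS regression of pupil on the
contrast codes plus nuisance covariates (tone identity, |SNR|, baseline
diameter, gaze), then a one-sample t-test across subjects per bin, with
Benjamini–Hochberg correction jointly across bins and contrasts. The
two-stage estimator is consistent for the group-level contrast and its
FDR calibration is itself verified by simulation in the test suite;
what it gives up relative to mixed models is efficiency with very
unbalanced designs, not validity.

## The synthetic cohorts

Because the package must be exercisable end-to-end without any data
deposit, `cohort_spec()` / `generate_behavior()` / `generate_pupil()`
produce complete cohorts with the statistical structure the analyses
assume. The generator's defaults are the study conditions themselves:
576-trial rule sessions in twelve 48-trial constant-cue mini-blocks
with `p_high` ∈ {1/6, 1/2, 5/6}; 480-trial stimulus sessions with 38
no-pre-test trials placed uniformly at random (leaving 442 analyzable);
pre-test lengths 2–14 drawn from a truncated geometric distribution
with stop probability 0.45 (mode 2, mean ≈ 3.2 — the stated
"approximately exponential" shape with most sequences 2–3 tones long),
session-level tone balance enforced to within ±2% by resampling; dB
levels −23…−6 mapped linearly onto ±[0.05, 0.5] (the simplest monotone
map consistent with the published endpoints; only the endpoints are
published, and nearby alternatives are reported to behave equivalently).
Subject parameters are Gaussian draws at the published across-subject
means and SDs, truncated to the search boxes; only the rule-based
(z, v) bias pairs are drawn jointly, with a configurable correlation
(default −0.6) matching the coupled-bias finding — other
between-parameter covariances are unpublished and are left at zero.

Synthetic pupil traces are laid out at 1 kHz per trial: a slow AR(1)
arousal drift, low-amplitude sensor noise (both kept below the
cleaning pipeline's velocity threshold so only injected blinks trigger
interpolation), Poisson blinks recorded as missing spans, gaze jitter,
and a choice-locked gamma-shaped transient (shape 2, scale 300 ms)
whose amplitude is raised by `pupil_effect` on cue-incongruent trials
of rule-type conditions. The generator emulates the *contrast
structure* the pipeline must detect — it is not a biophysical pupil
model, the transient amplitude is only approximately in post-z-scoring
units, and real data's luminance responses, slow session drifts and
artifact taxonomies are richer. Passing tests therefore certify the
pipeline's statistical behavior (calibration, recovery of injected
effects), not the realism of any pupil waveform.

## Problem sizes used in the checks

The test suite and the acceptance script run every stage on sizes
chosen to make the full battery reproducible in minutes on a single
core while keeping each check informative: solver validation against
the closed form on a 3×3–5×5 (drift, bound) grid and against a
`2e5`-path Monte-Carlo oracle; parameter recovery on full single
sessions (442–576 analyzable trials) with a differential-evolution
budget of ~40–100 generations and warm-started nested fits; PEP
calibration over a few hundred simulated cohorts; FDR calibration over
200 null cohorts at the contrast stage. These are the package's chosen
verification scales; the same functions run unchanged at larger
populations, generations and cohort counts.

## Known limitations

* Mixed-effects (Kenward–Roger) RT ANOVAs and three-way interaction
  χ² tests are intentionally out of scope; two-stage per-subject
  statistics stand in for them.
* The solver handles constant within-trial drift with linear collapse;
  state-dependent drift, leak, and across-trial non-decision-time
  variability are not modelled.
* Recovery of the adaptation weights from a single 442-trial session
  is noisy (they trade off against `tau_va` and `v_Bias`); cohort-level
  signs and magnitudes are the reliable quantities at that scale.
* At small optimizer budgets the differential-evolution fits are
  approximate MLEs; the warm-start mechanism guarantees nesting
  inequalities but not global optimality.

## A short end-to-end example

```{r example, eval = FALSE}
set.seed(1)
spec <- cohort_spec("stim", n_subjects = 4)
coh <- generate_behavior(spec)

fit <- fit_subject(dplyr::filter(coh$trials, subject_id == "s01"),
                   variant = "full", condition = "stim",
                   optimizer_config = list(np = 45, maxiter = 100,
                                           solver_dt = 0.02,
                                           solver_dx = 0.02),
                   seed = 1)
tidy(fit)
glance(fit)

grid <- performance_grid(fit$estimates, context = "LL")
autoplot(grid)
proportion_max(grid,
               z = fit$free[["z_Bias"]],
               v = fit$free[["v_Bias"]])
```
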