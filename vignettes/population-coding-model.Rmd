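---
title: "A population-coding model of working memory for orientations and facial expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population-coding model of working memory for orientations and facial expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(popcodewm)
```

## The model

In a continuous-report working-memory task an observer memorizes an array of
items, is cued with one of them after a delay, and adjusts a probe to match
the remembered feature. The quantity of interest is the distribution of the
signed error between response and target, and how it changes with the number
of memorized items (set size, N).

`popcodewm` models this with a neural resource account. The probed feature
value is encoded in the spiking of a population of M tuned neurons
(M = 1000 by default). Neuron i has preferred value c_i and mean count

* circular space (orientation, period 180 deg, angles doubled internally):
  f_i(theta) = (gamma/N) * g_i(theta) / sum_j g_j(theta), with the von
  Mises-shaped kernel g_i(theta) = exp((cos(theta - c_i) - 1) / omega^2);
* bounded space (expression intensity, 0-100%): the same expression with the
  Gaussian kernel g_i(theta) = exp(-(theta - c_i)^2 / (2 omega^2)).

The two free parameters are the **gain constant** gamma — the expected total
spike count of the whole population, held constant across set sizes — and the
**tuning width** omega. Divisive normalization (the division by
sum_j g_j(theta)) enforces the resource limit exactly: for every stimulus
value, including values near a bounded edge where fewer neurons live, the
summed expected count is gamma/N. Increasing memory load therefore thins the
spikes available per item; nothing else in the model depends on N.

Spiking is independent Poisson. Decoding is either

* **maximum likelihood (ML)**: the candidate value on a dense decoding grid
  with the highest Poisson log likelihood (ties go to the lowest grid index,
  so a zero-spike pattern decodes to the first grid point); or
* **posterior sampling**: one draw from the discrete posterior proportional
  to likelihood times prior (uniform by default).

Posterior sampling matters for bounded spaces: a bounded space has no
rotational symmetry, and with any non-flat prior the ML readout piles
responses onto the prior mode, which human data do not show. Sampling also
produces the characteristic *inward bias* at extreme intensities without any
explicit bias term: as variability grows with load, the posterior is
truncated at the response bounds and its samples shift toward mid-range.

### Units and conventions

* Orientation works on the doubled circle: a tuning width omega is in
  doubled-angle radians (concentration kappa = 1/omega^2); errors and
  dispersions are reported in stimulus degrees, wrapped into (-90, 90].
* Intensity tuning widths are in % intensity.
* Decoding grids default to 1 degree (pre-doubling) and 0.5%; both are
  configurable via `decoding_grid()`. Grid-snapping quantizes responses by at
  most half a step, far below one histogram bin.

## Fitting

`predict_distribution()` estimates the response distribution for one
(target, set size) by Monte Carlo: n_sim encode-decode cycles binned into
equal-width response bins (40 for orientation, 20 for intensity; n_sim
defaults 10^4 and 10^5 respectively). Each bin receives one pseudo-count
(add-one smoothing), so no observed response has zero likelihood; the floor
is 1/(n_sim + n_bins).

`grid_search_fit()` maximizes the summed log bin-probability of the observed
trials over the standard log-spaced parameter grids
(`default_grids()`), jointly across all set sizes present — normalization
alone carries the load effect, so no per-set-size parameter exists. Two
evaluation methods are provided. `method = "direct"` recomputes
`trial_log_likelihood()` independently at every grid point: exact but
quadratic in the grid. The default `method = "stratified"` exploits a
structural fact of the normalized model: the total spike count K is
Poisson(gamma/N) *whatever the stimulus*, and conditional on K the spiking
neurons are i.i.d. draws from the normalized tuning kernel — so the decoded
response distribution given K does not depend on the gain at all. Response
histograms are therefore simulated once per (width, target, K) stratum and
assembled into every gain's prediction with Poisson weights. Three numerical
choices deserve note:

* **Spike-count cap.** Strata are simulated up to `k_cap` (default 256);
  Poisson tail mass is lumped into the cap stratum. Beyond the cap the
  decoded distribution has saturated far below one histogram bin for every
  width in the default grids, so the approximation only touches grid corners
  with negligible likelihood.
* **Canonical target with sub-grid jitter (circular only).** By rotational
  symmetry one distribution per (width, K) suffices; trials enter through
  their signed error. Because data targets are continuous while simulated
  responses snap to the decoding grid, the canonical target is jittered over
  8 sub-grid offsets. The zero-spike stratum is the single distribution that
  is *not* shift-equivariant (the ML tie-break pins it to the grid origin);
  its error distribution is set analytically to uniform, which is exact for
  designs with uniformly distributed targets such as the grating experiment.
* **Common random numbers.** The same derived seed (and therefore, by
  construction of the sampler, the same uniform stream) is reused across all
  widths, which removes most simulation noise from comparisons along the
  width axis and keeps the likelihood surface smooth. Seeds derive
  deterministically from the master seed per target stratum, so a fit is
  exactly reproducible.

Simulation precision: the per-stratum count is `min(500, n_sim/10)`; the
stratified estimator's effective sample size per cell is m/sum(w_K^2),
typically 5-25 times m, so this matches or exceeds n_sim direct draws. The
smoothing floor deliberately keeps the nominal n_sim. At small n_sim the
floor itself becomes a model distortion — at n_sim = 2000 it injects ~2%
pseudo-uniform mass, which is comparable to the model's genuine zero-spike
guess rate in realistic parameter regimes and measurably biases fitted gains
upward by a couple of grid steps; fits intended for parameter interpretation
should use n_sim of 10^4 or more, which the stratified evaluator makes cheap
(a full 60 x 60 orientation grid fits 1800 trials in a few seconds).

### The width scale of the ML orientation grid

`default_grids("orientation_ml")` spans 60 log-spaced values of gain and
width in [1, 100]. The width axis of this historical grid is on the
concentration scale, kappa = 1/omega^2; the fitter converts to
omega = kappa^(-1/2), i.e. widths in [0.1, 1] doubled-angle radians. This is
deliberate: the posterior-sampling orientation grid spans exactly [0.1, 1]
in width, and only on a common scale are fitted widths comparable across the
two decoders (the cross-decoder width correlation is a headline check).
`FitResult$best_width` is always a tuning width omega, whatever the grid
scale.

### Model comparison

`compare_decoders()` fits the ML and posterior-sampling variants (each k = 2
parameters) to the same orientation trials and reports
`delta_aic = AIC(ML) - AIC(sampling)`; negative values favor ML. It refuses
bounded-space data, where the ML variant is not a sensible model.

## Descriptive statistics

`summarize_trials()` reports bias (mean signed error) and variability per
group. Circular data use directional statistics on the doubled circle: the
circular mean direction, and Fisher's circular standard deviation
sqrt(-2 ln Rbar) with Rbar the mean resultant length (the alternative
sqrt(2(1 - Rbar)) agrees only for small dispersion and is not used).
Dispersions are reported on the stimulus scale (degrees, after halving);
circular tables also carry the raw doubled-angle value in `sd_doubled_rad`
since either scale may be wanted for axes. Bounded data use the plain mean
and the n-1 sample SD. Rbar below 1e-12 is reported as infinite dispersion
rather than an error.

## The synthetic experiment generator

Three designs mirror the structure of the face/grating experiments:

* `design_exp1a()` — faces only, five 600-trial blocks at set sizes 1-5,
  fully balanced: per block each of 60 identities is probed 10 times, twice
  per emotion (angry, disgusted, fearful, happy, sad), once below and once
  above 50% intensity, targets on 10 levels from 10% to 91%; optionally the
  final 300-trial set-size-1 block (each identity-emotion pair once).
* `design_exp1b()` — gratings only, 600 trials at each of set sizes 1/3/5,
  orientations uniform on the circle.
* `design_exp1c()` — mixed arrays of exactly one face plus one or three
  gratings, the probed item uniform over the array.

`generate_responses()` fills in responses with the model under a
**dual-resource rule**: the expression resource is shared among the faces in
an array (N_expr = number of faces) while the orientation resource is shared
among the gratings *plus* w times the number of faces
(`face_orientation_load`, default w = 1): a face automatically costs
orientation resource because it carries low-level orientation structure, but
a grating carries no face-specific information. This reproduces the observed
asymmetry — an added face inflates grating errors, added gratings leave
expression errors untouched. Faces are decoded by posterior sampling and
gratings by ML (each task's fitted decoder); display durations, retention
intervals and similar procedure details are not modeled (the model has no
time parameter), and block-order/practice effects are not simulated.

Default generating parameters were chosen once, for realism, at interior
points of the fitting grids:

* per-emotion gains happy 24 > disgusted 20 > angry 16 > fearful 13 >
  sad 8 (the empirically recovered precision ordering; factor 3 between the
  extremes) with face tuning width 8% — this puts simulated expression
  recall at roughly 3-5% error SD for one face rising to 10-16% at five,
  the scale seen in human data, and inside the regime where boundary
  truncation produces the inward bias from N >= 2 upward. At N = 1 the
  model instead shows a sub-0.3% bias of the *opposite* sign: exact
  Bayesian decoding under divisive normalization slightly favors the edges
  (the -K log S(theta) likelihood term), an honest small-sample property of
  the model rather than a bug.
* orientation gain 12 and width 0.35 doubled-angle radians (about 3 deg
  circular error SD at N = 1, 15-30 deg at N = 5). Low-to-moderate gains
  are not only realistic but also where the two parameters are jointly
  identifiable: at high gain the likelihood surface has a long flat
  gain-width ridge (only the near-Gaussian error width
  omega/sqrt(gamma/N) is constrained), while the zero- and few-spike
  "guessing" tail that pins down the gain separately is present only when
  gamma/N is small.

A deliberate omission: the small response bias toward the neutral (0%)
expression that human observers show at high load is *not* generated. The
model's bias is symmetric about mid-range, and the original modeling work
found that even non-uniform priors could not reproduce the neutral-ward
component; the generator therefore makes no attempt, and analyses of
synthetic data should expect symmetric inward bias only.

What passing tests on these synthetic data do and do not show: they
demonstrate that the pipeline recovers the structure the generator put in —
load-dependent widening, emotion-specific gains, boundary bias, the mixed
array asymmetry — under the model's own assumptions (independent Poisson
spiking, no swap/misbinding errors, no guessing process beyond zero-spike
trials, no practice effects). They cannot certify the model against real
data; for that the fitting tools must be pointed at observed trial tables
via `read_trials()`.

## Problem sizes used in the checks

The packaged tests exercise the full default grids with Monte-Carlo
sizes chosen for single-CPU runs: orientation fits at n_sim = 10^4 (the
historical default), expression fits at n_sim = 10^3 with k_cap = 64
(intensity decoding has saturated below one 5% bin by ~60 spikes), 20
parameter-recovery replicates, 10 synthetic subjects for the decoder
comparison, and 10^4 simulated trials per cell for the distributional
checks. The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch at comparable sizes.

## Worked example

```{r example, eval = FALSE}
set.seed(7)
trials <- generate_responses(design_exp1a(1))
probes <- trials[trials$probed, ]

# descriptive summary by memory load
summarize_trials(probes, "set_size", bounded_space(0, 100))

# fit the posterior-sampling model to the happy-face trials
happy <- probes[probes$emotion == "happy", ]
fit <- grid_search_fit(happy, "expression_sampling", n_sim = 1000,
                       k_cap = 64, seed = 7)
fit
```

## Known limitations

* Single-item decoding only: the probed item's population is simulated in
  isolation; set size acts purely through gain division. Swap/misbinding
  errors are out of scope.
* The stratified fitter's circular branch assumes uniformly distributed
  targets (true for the packaged designs) for its zero-spike stratum; use
  `method = "direct"` for circular designs with strongly non-uniform
  targets.
* Priors other than uniform are supported in decoding
  (`decode_posterior_sample()`) and prediction, but the packaged fits use
  the uniform prior throughout.
* Monte-Carlo likelihoods make AIC differences between near-equivalent
  models noisy at the level of a few units; differences smaller than that
  should not be interpreted.
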