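---
title: "Methods: the multi-mode drift-diffusion model and inference of decision-commitment times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-mode drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In perceptual decision-making tasks with pulsatile evidence, an animal
listens to two Poisson click trains (combined rate 40 clicks/s, ratio
between sides set per trial from 39:1 down to 26:14, durations 0.2-1.0 s,
both trains opening with a simultaneous "stereoclick") and reports which
side played more clicks. A long-standing account of such decisions is the
bounded drift-diffusion model (DDM): a scalar decision variable z
accumulates the click-by-click evidence until it reaches an absorbing bound
±B, at which point the animal has, covertly, made up its mind.

This package implements the multi-mode DDM (MMDDM): a state-space model in
which simultaneously recorded neurons encode z with one weight while
evidence is being accumulated (w_EA) and with a different weight after the
bound has been reached (w_DC). The switch of encoding weights at bound
crossing is what makes the moment of decision commitment visible in the
population spike trains, and the package's central deliverable is the
neurally-inferred time of commitment (nTc): the first time step at which
the posterior probability that z sits at a single bound -- given clicks,
spikes and the behavioural choice -- exceeds 0.8.

## The generative model

**Latent dynamics.** Time is discretized at dt = 0.01 s. While
-B < z < B,

    z(t+1) = z(t) + u(t) + eta,     eta ~ N(0, dt),

and z freezes at B·sign(z) otherwise (absorbing bounds). The initial state
is z(1) ~ N(mu0, 1). The momentary input u(t) is the sum of per-click
inputs of the right clicks minus the left clicks in that step; each click
contributes its sensory-adaptation magnitude C multiplied by i.i.d. noise
zeta ~ N(1, sigma_s2). The dynamic model therefore has exactly three free
parameters: B, sigma_s2 and mu0. The per-step diffusion variance is fixed
at dt; trial-to-trial variability is carried by the per-click noise.

**Sensory adaptation.** Each click's magnitude is depressed by its
predecessors: a state a starts at 1; a click is delivered with C = a and
then a <- a·phi; between clicks a recovers as da/dt = (1-a)/tau_phi. The
stereoclick pair shares one pre-update state and depresses it once. The
exact adaptation constants live in supplementary material we do not have;
phi = 0.6 and tau_phi = 0.2 s are fixed, configurable stand-ins, and are
not free parameters of the fit.

**Emissions.** Given z, each neuron's spike count in a step is
Poisson(lambda·dt) with lambda = softplus(w·z + b), where w = w_EA at
interior states and w = w_DC at the bounds, and b is a decision-irrelevant
baseline. The behavioural choice is the sign of z at the final step of the
trial window (stimulus onset to the earlier of 1 s or fixation exit). The
bin centred at exactly z = 0 contributes probability 1/2 to either choice;
the source text never defines this tie, and the symmetric split is our
convention.

**Baseline.** b(m, t) has a cross-trial component (a smooth function of
the trial's start time within the session) and within-trial components:
causal kernels aligned to stimulus onset, to a window preceding movement
onset, and to the neuron's own spike history. Each component is a linear
combination of Gaussian radial basis functions; the default counts
(intercept + 4 + 4 + 4 + 4 = 17) together with the two encoding weights
give the 19 parameters per neuron. The exact basis family of the original
work is in unavailable supplementary material; counts and supports are
configurable.

## Inference

The latent is marginalized on a grid: n_interior = 99 uniform bins on
(-B, B) plus two absorbing states pinned at ±B. Gaussian transition mass
is assigned by CDF differences over bin edges; mass beyond ±B accrues to
the bounds, and bound rows are identity. The forward pass (scaled to avoid
underflow) yields the trial log-likelihood; the backward pass yields the
smoothed posterior used for nTc.

Step-1 inputs (the stereoclick and any click in the first 10 ms) are
folded into the initial distribution, N(mu0 + m_1, 1 + v_1), so that no
click is dropped; the simulator mirrors this convention exactly.

All parameters are fitted jointly by maximum a posteriori estimation with
zero-mean Gaussian priors on the unconstrained scale (log B, log sigma_s2,
mu0 at sd 2; weights and baseline coefficients at sd 5); a pure
maximum-likelihood switch exists. Positivity of B and sigma_s2 is enforced
by optimizing their logarithms. Gradients for all per-neuron parameters
are exact, via Fisher's identity (the expected complete-data gradient
under the smoothed posterior); the three latent parameters use central
finite differences (6 extra forward passes), since the grid itself moves
with B. The optimizer is L-BFGS-B with data-driven initialization: per
neuron, spike rates are regressed on the cumulative adapted-evidence path
(a noise-free proxy of z), rescaled by the local slope of the softplus at
the neuron's baseline rate. Restarts jitter around this initialization.

By default the baseline coefficients are initialized by a per-neuron
Poisson GLM with a softplus inverse link and then held fixed during the
joint fit; `refine_baseline = TRUE` includes them in the joint
optimization (the original description fits all 19 per-neuron parameters
simultaneously). Freezing is the default because the joint refinement
requires caching neuron-specific spike-history designs for every trial.

**nTc rule.** Commitment is to a side, so the 0.8 threshold applies to the
larger of the two bound posteriors, not their sum; the source text does
not disambiguate, and the max rule is our choice (results there were
reported to be threshold-insensitive). A trial whose bound posterior never
exceeds the threshold has no detected commitment.

## Numerical choices worth knowing about

- The interior grid centres are forced to exact sign symmetry with the
  middle centre at exactly 0. Naive edge-midpoint arithmetic leaves the
  middle centre at ±1e-17; the choice tie rule keys on z == 0, so that
  rounding flips the centre bin between full and half choice probability
  as B varies, making the log-likelihood non-smooth in B at the 0.02-nat
  scale and breaking quasi-Newton line searches.
- If the hard choice factor would annihilate all posterior mass at the
  final step (possible only through numerical underflow, since interior
  mass always spans both signs), the pre-choice state probabilities are
  floored at 1e-300 and the trial is flagged instead of returning NaN.
- Unconstrained latent parameters are clamped to |log B| <= 20 during
  optimization so line-search overshoots cannot build an infinite grid.
- Doubling n_interior from the default changes full-trial log-likelihoods
  by < 1e-3, so grid error is far below parameter uncertainty; fits in the
  test suite use coarser grids (21-49 interior bins) for speed.

## The synthetic world: what the generator emulates, and what it does not

`simulate_session()` produces the full structure consumed by inference:
Poisson click trains with the task's ratio set, adaptation, Euler-simulated
bounded latents, regime-switching Poisson spikes, choices equal to
sign(z(T)), movement onset drawn uniformly within 0.2 s after stimulus end
and a fixed 5-s inter-trial interval (neither is specified in the source;
both only feed the baseline model's event alignment).

The generator's default parameters are the package's stated world and were
chosen once, on two empirical anchors, before the acceptance statistics
were frozen:

- B = 5.5 so that the nTc detection rate on simulated sessions is ~34%,
  matching the reported detection prevalence (34.6% of trials);
- sigma_s2 = 2 so that simulated psychometric accuracy looks like a rat's
  (~94% on the easiest 39:1 ratio, ~74% on the hardest 26:14) rather than
  near-deterministic. With much smaller per-click noise, choices become
  almost a deterministic function of the stimulus; then (i) w_EA is nearly
  unidentifiable because accumulation ends quickly, and (ii) the lapse
  kernel regression degenerates (huge weights with the rare errors
  absorbed by the lapse floor).
- mu0 = 0 (no side bias); per-neuron baselines log-normal around 8
  spikes/s; encoding weights N(0, 0.8^2) with a configurable fraction of
  accumulation-only and commitment-only neurons.

The simulator does not emulate: session-scale nonstationarities (the
cross-trial baseline drift is fittable but not generated by default),
correlated noise across neurons beyond the shared latent, lapses in the
choice rule (the choice emission is deterministic by model definition),
reaction-time responding, or multi-region structure. A green test
therefore establishes internal consistency of model, inference and
analyses in this world -- it cannot establish that real recordings satisfy
the model's assumptions.

## The nTc-aligned psychophysical kernel

The kernel regresses choice on signed click counts (right minus left) in
0.1-s lag bins relative to each trial's nTc, restricted to trials with the
stimulus playing at least 0.2 s on both sides of nTc, with a symmetric
lapse: P(right) = lapse/2 + (1-lapse)·logistic(·), lapse in [0, 0.5] via a
scaled logit. Two design details matter and are deliberate:

- The default lag range is [-0.6, +0.2] s and all clicks earlier than the
  covered range enter through one catch-all regressor. The per-trial
  generative rates are a confounder: trials committed rightward tend to
  have right-heavy clicks after commitment too, so post-nTc bins acquire
  spurious positive weight unless the full pre-nTc evidence is
  conditioned on.
- The default ridge penalty (0.5 on the weights) blocks the lapse-model
  degeneracy on near-deterministic subsets (detected-commitment trials are
  decided correctly ~94% of the time in the stated world): without it the
  optimizer drives weights to ±10 and books the few errors as lapses.

The shuffle control permutes nTc among detected trials only (clipping a
reassigned time beyond a trial's end to its last step) and shows no
post-alignment drop.

## Design decisions that were genuinely open

- PCA of stacked condition PSTHs subtracts the grand row-mean vector from
  every row (column centring), the standard convention; the source
  wording ("the mean across rows is subtracted") is ambiguous.
- Causal Gaussian smoothing kernels (sd 0.1 s, width 0.3 s for PSTHs; sd
  0.05 s for peri-commitment histograms) are truncated and renormalized to
  unit sum, so constant rates are mapped to themselves.
- Bootstrap CIs default to percentile intervals across trials; the
  psychometric curve uses Clopper-Pearson.
- The session container is JSON rather than HDF5: the deployment
  environment has no R HDF5 binding, the data volumes at package scale are
  small, and the schema (versioned, validated, ragged spike/click arrays
  per trial) is container-agnostic.
- Peri-commitment histograms are produced both as raw rates per
  preferred/null choice and as their difference; the source figures are
  ambiguous about which is shown where.

## Known limitations

- The 19-parameter-per-neuron joint refinement (`refine_baseline = TRUE`)
  caches one design matrix per neuron per trial; memory grows as
  neurons x trials x steps x bases.
- Finite-difference gradients for B make each gradient evaluation cost
  about eight forward passes; sessions of hundreds of neurons and
  thousands of trials will want more compute than the test scale.
- The engagement index is undefined for neurons with both weights zero;
  such neurons are flagged, not silently assigned ±1.
- Model comparison (weight switch vs tied weights) uses out-of-sample
  log-likelihood from trial-level cross-validation; no correction is made
  for the tied model being nested.
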