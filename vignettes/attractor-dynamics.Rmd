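---
title: "Inferring attractor dynamics from calcium fluorescence recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring attractor dynamics from calcium fluorescence recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Populations of neurons that integrate evidence over long timescales — for
example accumulating reward history across the trials of a session — are
naturally described as dynamical systems, `x'(t) = f(x(t), u(t))`: the
population state `x` evolves under intrinsic dynamics `f` perturbed by
external inputs `u`.  Two qualitatively different architectures can store
a slowly varying quantity.  A **line attractor** is a one-dimensional
continuum of fixed points; inputs aligned with its *selection vector*
move the state along the line, where it stays, so position on the line
encodes the running sum of past inputs.  A **point attractor** is an
isolated stable fixed point; perturbations decay back and nothing is
accumulated.

`calfads` fits a sequential variational autoencoder of the LFADS family
to trial-structured calcium-fluorescence population recordings, then
reverse-engineers the fitted dynamics to decide, from data alone, which
attractor architecture the recorded circuit implements, and simulates
the fitted system under novel reward schedules.

## The model

Each trial is a sequence of observation vectors `y_t` (one entry per
neuron, 200 ms bins by default).  The generative model is

* an initial generator state `g_0 ~ N(mu_0, sigma_0^2)`,
* a **generator** GRU `g_t = F(g_{t-1}, u_t)` driven by a low-dimensional
  inferred input `u_t` (dimension 1 by default),
* linear **factors** `f_t = W_f g_t` (8 or 32 dimensions),
* a **Gaussian emission** `y_t ~ N(W_y f_t + b_y, diag(exp(r)))` with a
  learned, time-independent per-neuron log-variance `r`.  The Gaussian
  replaces the Poisson spike-count emission of the original LFADS
  because fluorescence is continuous.

Inference is **strictly causal**: a forward-only encoder GRU consumes
`y_1 ... y_t`; the posterior over `g_0` reads the encoder state at the
*first* bin only, and a controller GRU produces `q(u_t)` from the
encoder state at bin `t` together with the factors at `t - 1`.  Nothing
at bin `t` depends on later observations — the property is enforced
architecturally and verified by perturbation tests.  Causality makes the
inferred inputs interpretable as estimates of upstream drive arriving at
each moment.

Training maximizes the evidence lower bound (reconstruction minus the
two KL terms) with the reparameterization trick, Adam, a linear KL
warm-up, inverted dropout on encoder inputs and generator outputs, an L2
penalty on the recurrent kernels of generator and controller, gradient
clipping, and early stopping on validation ELBO.  Odd-indexed trials
(1-based, session order) train the model; even-indexed trials are the
validation set.  Observations are standardized per neuron before
fitting and de-standardized when the model reports denoised rates.

The gradients of all three recurrences are hand-derived reverse-mode
passes in compiled code; the test suite checks them against central
finite differences at relative error below 1e-5.

## Configuration

Two presets are provided.  The `"full"` preset is the analysis-scale
network: 256 generator units, 32 factors, 1 inferred-input dimension,
256 encoder and 256 controller units, L2 penalty 1e-9, dropout keep
rate 0.98, 200 ms bins.  The `"small"` preset (64/8/1/64/64) is the
study scale used throughout the package's own simulation experiments
and tests; it fits a 30-neuron session in under a minute on one core.

Three `"small"`-preset defaults deserve comment:

* `l2_penalty = 2e-2` (instead of the full-scale 1e-9).  A 64-unit
  generator modelling a 4-dimensional synthetic system has many unused
  state directions.  With a negligible recurrent penalty those
  directions keep whatever time constant their initialization and
  training noise leave behind — often near-marginal — which litters the
  fixed-point analysis with spurious slow modes.  The stronger penalty
  contracts every direction the data do not actively defend, so the
  slow modes that survive are the ones the task requires.  This mirrors
  the role of per-dataset hyperparameter selection in the LFADS
  workflow; the penalty is a property of the fitting recipe, not of the
  data generator.
* `dropout_keep_rate = 0.9` (instead of 0.98).  At study scale the
  heavier dropout on encoder inputs and generator outputs acts together
  with the recurrent penalty: a marginal mode that merely memorizes
  trial noise cannot survive when its output is randomly silenced, so
  the surviving slow modes are the task-required ones.  Both keep rates
  are within the range used for the full-scale analyses.
* `max_epochs = 350` with early stopping on validation ELBO evaluated
  every 10 epochs (patience 15 evaluations); the learning rate (Adam,
  1e-2) decays by 0.997 per epoch.  Pruning of left-over marginal modes
  happens late in training, after reconstruction has converged, so the
  epoch budget is set by the dynamics diagnostics rather than by the
  loss curve.

The GRU keep-gate bias of the generator is initialized at +1, biasing
the network toward slow dynamics at the start of training; this is a
standard device for learning long timescales and is symmetric across
attractor classes.

## The synthetic ground-truth generator

`make_system()` builds a discrete-time linear latent system
`x_{t+1} = A x_t + p_t` (4 latents by default) with a known integration
mode: for a line system, `A` has exactly one eigenvalue equal to 1 whose
eigenvector is the integration mode, all other eigenvalue moduli at most
0.9; for a point system the spectral radius is at most 0.9.  Trial
structure: 8 s trials of 40 bins at 200 ms, cue at bin 6 (1 s pre-cue
period), a cue pulse at bins 6–7 orthogonal to the integration mode, and
an outcome pulse at bins 10–11 (about 1 s after the cue, when reward is
collected).  The rewarded pulse has cosine 0.9 with the integration
mode; the unrewarded pulse is orthogonal to it, so only rewards are
integrated.  The latent state **carries over between trials** (no
reset), which is what lets integrated reward ramp across a session;
a reset option exists but is off by default.

Neural rates are an affine readout of the latent state; loadings on the
integration mode are positive so that integrated reward raises bulk
population activity, as in circuits whose line attractor aligns with the
total-activity direction.  Rates pass through a causal single-exponential
calcium kernel (decay 0.4 s, unit DC gain, initialized at steady state;
indicator rise time is sub-bin at 200 ms and omitted) and i.i.d.
Gaussian noise (sd 0.2 against a baseline offset near 1) gives the
recorded fluorescence.  Default sessions are 120 trials of 30 neurons
with reward probability 0.85.

What this generator does **not** emulate: spiking discreteness and
Poisson-like variability, nonlinear calcium-indicator saturation,
shared (correlated) noise, slow drifts unrelated to the task, and
behavioral covariates.  Passing the recovery tests therefore shows that
the pipeline identifies attractor structure under its own model
assumptions at realistic scale — not that those assumptions hold in any
particular recording.

## Fixed-point analysis

The fitted generator, with its input frozen at the trial-averaged
pre-cue inferred input (close to zero), is treated as the map
`h -> F(h, u*)`.  Fixed and slow points minimize the squared one-step
speed `q(h) = ||F(h, u*) - h||^2` — defined **without** a 1/2 factor, so
retention thresholds such as 3e-4 and 1e-3 apply directly to `q`.

The search runs batched Adam from 512 states subsampled from the
posterior generator trajectories (Gaussian jitter, sd 0.1 of the
per-dimension state sd), followed by a Gauss–Newton polish that solves
`(J - I) step = -(F(h) - h)` through a pseudoinverse discarding singular
values below 0.02.  The cutoff makes the polish collapse candidates
along every genuinely contracting direction while leaving marginal
(attractor-manifold) directions untouched: a point attractor's slow
ellipsoid collapses to the single true fixed point, a line attractor
keeps its extent.  Survivors above the speed threshold are discarded;
the rest are deduplicated at radius 0.01 in normalized state units
(state sd), keeping the lowest-speed representative.

Each retained point is linearized with the analytic GRU Jacobian (finite
differences for user-supplied maps).  Classification is an operational
rule — the underlying biology reports the outcome, not the criterion —
with frozen defaults: **line** iff at least K = 5 points are retained,
PC1 of the point cloud explains at least 90 % of its variance, and the
median count of Jacobian eigenvalues with modulus within 0.05 of 1 is
exactly 1; **point** iff all retained points form a single cluster of
radius at most the merge tolerance with no near-unit eigenvalue;
anything else is **other**.  All retained sub-threshold points enter the
PC1 computation ("relevant" points are not further filtered).  The
line-attractor mode is the unit-norm PC1 of the retained points, signed
to point toward increasing total activity.

## Targeted dimensionality reduction

Three hypothesis-driven directions, in reconstructed per-neuron rate
space: the **total-activity mode** (normalized all-ones vector, a proxy
for bulk photometry), the **condition-independent mode** (mean activity
in a 1 s reward window minus a 1 s pre-cue window), and the
**line-attractor mode** (PC1 of the fixed points mapped to rate space).
They are orthonormalized in that order by classical Gram–Schmidt; modes
2–3 are signed to correlate positively with their raw originals.

Fixed points live in generator space while the all-ones vector only
makes sense over neurons, so all three modes are computed in rate space
and generator states are mapped there through the model's two linear
readouts.  Activity is used as denoised means without additional
normalization — z-scoring per neuron before projection would reweight
neurons and is deliberately not applied.

## In silico titration

The trained generator is rolled forward as a standalone system.  The
input library holds trial-averaged inferred inputs of rewarded and
unrewarded trials over the window 1 s before to 3 s after the cue; a
session draws each trial's type from Bernoulli(p_reward), plays the
4 s input, then 1 s of exactly zero input (inter-trial relaxation), and
stops after the relaxation of the 10th rewarded trial or at a 40-trial
cap (the cap terminates low-probability sessions, whose rewarded-trial
bound alone would not).  The photometry proxy is the rate-space
trajectory projected on the total-activity mode, averaged over the 1 s
reward window of each rewarded trial.  Titration simulates many
sessions per probability with initial conditions sampled uniformly along
the segment of the identified line attractor, averages the proxy by
rewarded-trial index, and summarizes each probability by the
least-squares slope of that curve; the standard error of the slope
across sessions provides the noise floor against which a point-attractor
control's flat slopes are judged.

## Session statistics

* **Wilcoxon signed-rank** (paired, two-sided by default): zero
  differences are dropped; at least 5 nonzero pairs are required.  For
  n <= 25 the exact null distribution of the positive-rank sum is
  computed by dynamic-programming convolution over doubled (tie-averaged)
  ranks, so ties are handled exactly; above that a normal approximation
  with tie and continuity correction is used.
* **Task modulation**: 1 s pre-cue baseline against four sequential 1 s
  post-cue windows, per trial type; Benjamini–Hochberg across all
  neurons x windows; a neuron is modulated if any window survives at
  0.01.
* **Recovery time**: 2 s pre-perturbation baseline against sequential
  0.5 s windows; BH pooled across neurons x windows (matching the
  task-modulation wording); recovery is the earliest window start whose
  three consecutive windows are all non-significant, `NA` if none.
* **Ramping**: OLS of 2 s pre-cue baseline rate on trial index, t-based
  two-sided p for zero slope at 0.05, direction by slope sign; at least
  10 trials required for a meaningful interval.
* **Hierarchical bootstrap**: sessions, then neurons within the drawn
  session, then trials within the drawn neuron, all with replacement and
  each matching the size of the level it was drawn from (the
  "matching the size of the original dataset" reading adopted here;
  a flat-count alternative would break exchangeability across unequal
  sessions).  100 iterations by default; mean and SEM are the mean and
  SD of the resampled statistics.
* **Integration statistic**: per-trial 2 s baseline subtraction, mean
  over the 5–7 s window, hierarchical bootstrap of the mean.  The
  one-sided p is the fraction of resampled means on the opposite side of
  zero from the observed statistic, with exact zeros counted one half
  and add-one smoothing `(k + 1)/(B + 1)` so p is never exactly 0 — two
  small departures from the raw fraction that make the degenerate
  all-zero case report p near 0.5 instead of 0.

## Photometry preprocessing

The 405 nm isosbestic channel is resampled to 60 Hz, low-pass filtered,
resampled back to the native rate (1017 Hz by default), fitted to the
490 nm signal by least squares, and subtracted.  The filter is a
zero-phase second-order Butterworth with 2 Hz cutoff — neither filter
family nor cutoff is standard across rigs, so these are package choices,
frozen in the defaults.  The fit is affine (gain plus offset), which
makes the correction invariant to rescaling of the control channel; a
gain-only fit would not absorb detector offsets.  Resampling is linear
interpolation onto the intermediate grid and back; at a 2 Hz passband
on a 60 Hz grid the interpolation error is negligible relative to the
filter's own attenuation.  ΔF/F divides by session-mean raw
fluorescence minus the rig baseline measured without the animal, in
percent.  Whole-session z-scores use mean and SD from the first trial
start to 10 s after the last trial end, applied to the entire trace.

## Numerical choices and degenerate inputs

Every stochastic step takes an explicit seed, and a pipeline master seed
fans out to per-stage sub-seeds, so any stage can be re-run
independently yet reproducibly.  Posterior log-variances are clamped to
[-16, 10] to keep early training finite.  Non-finite training loss
aborts with the epoch index.  Zero-variance neurons, all-zero Wilcoxon
differences, empty bootstrap nestings, windows that do not fit inside a
trial, and singular Gram–Schmidt inputs all raise immediate errors
naming the offender.  A fixed-point search in which no candidate reaches
the speed threshold returns an empty set with a warning (classification
"other"), not an error.

## Problem sizes

The package's own experiments use 30-neuron, 120-trial sessions, the
small preset, 512 fixed-point initializations, 100–300 titration
sessions per probability, 2000 null neurons for the ramping
calibration and 1000 for the task-modulation calibration.  These sizes
were chosen so the full simulation study runs comfortably on a laptop
core while keeping every statistical check well-powered.

## Known limitations

A structural identifiability caveat deserves its own paragraph.  In the
synthetic sessions the reward pulse arrives at a fixed bin of every
rewarded trial and rewards are frequent (p = 0.85), so cumulative reward
and elapsed time are almost perfectly collinear.  Nothing in the
training objective then distinguishes input-driven integration from an
autonomous slow drift along the line: the fitted generator typically
absorbs part of the session ramp into a sub-threshold flow (per-bin
speeds below the 3e-4 retention threshold, so the slow points are still
retained and correctly classified).  Single-trial reconstruction,
attractor classification and parameter-recovery correlations are
unaffected, and probing the generator at its true fixed points recovers
the correct rewarded-minus-unrewarded increment.  But rolling the
generator across many consecutive trials — as the reward-probability
titration does — accumulates the flow once per trial, so the relative
ordering of accumulation slopes across reward probabilities reflects
the arbitrary sign of that flow rather than reward integration, and is
not reproducible across training seeds under these conditions.  In
recordings where reward timing jitters with behavior the degeneracy is
absent; for the bundled simulator it is a known, documented limit of
the in-silico extrapolation.

* The emission model assumes independent Gaussian noise with a static
  per-neuron variance; strongly saturating indicators or shared noise
  violate it.
* The attractor classification rule is a frozen operationalization;
  systems near the line/point boundary (a very slow point attractor, a
  short line) will land in "other" rather than being forced into a
  class.
* The inferred-input dimensionality is 1 by default; richer input
  structure requires raising it and re-examining identifiability.
* Fixed points are found under a single frozen reference input;
  input-dependent attractor rearrangement is out of scope.
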