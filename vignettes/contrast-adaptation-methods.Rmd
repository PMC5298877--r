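---
title: "Measuring contrast adaptation across behavioral states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contrast adaptation across behavioral states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrace)
```

# The measurement problem

A visual-cortex neuron presented with a sustained high-contrast grating
typically reduces its response over seconds — contrast adaptation. Whether
and how strongly it adapts depends on brain state (anesthesia versus
wakefulness) and on the behavioral relevance of the stimulus. Quantifying
this requires a chain of steps, each with conventions that matter: trace
normalization, tuning classification, responsiveness filtering, slope
estimation in defined windows, behavioral trial splits, and rank-based group
comparisons. `adaptrace` implements that chain and ships a synthetic-data
generator with ground truth so every estimator can be validated end to end.

# Signal model and normalization

Raw fluorescence is modeled (and generated) as

F_i(t) = max(0, B_i + A_i · g_i(θ(t)) · c(t) · (1 + s_i,cond · t_rel)) ⊛ k_τ + drift + noise,

where `B_i` is the baseline, `A_i` the peak response amplitude (negative for
suppressed cells), `g_i` the double-Gaussian tuning gain, `c` the contrast
scale, `s_i,cond` the per-condition adaptation slope in (fraction of
response)/s, `t_rel` the time since stimulus onset, and `k_τ` a causal
exponential indicator kernel with unit DC gain. The clip at zero is the
generator's only nonlinearity. Adaptation is linear in time by default
because the downstream readout is a fitted line; an exponential gain mode
(`adaptation_mode = "exponential"`) exists for robustness checks.

Two ΔF/F variants serve different protocols:

* **Pre-stimulus baseline** (`dff_prestim`): per trial, F0 is the mean
  fluorescence over the 2 s before onset (3 s for contrast tuning) and
  ΔF/F = (F − F0)/F0 across the cut window. Cells with F0 ≤ 0 in a trial are
  excluded and listed in the tensor's `exclusions` attribute.
* **Rolling percentile** (`dff_rolling_percentile`): per frame, the 8th
  percentile of F in a ±15 s window is subtracted and the result divided by
  the median of the cell's full-trace fluorescence. Windows truncate (never
  pad) at the trace edges, and percentiles interpolate between order
  statistics (type 7). The median is computed on the raw trace, not on the
  percentile-subtracted one; this is configurable in principle but raw is
  the default because the subtraction would otherwise make the
  normalization depend on the window parameters. Both variants are exactly
  invariant under multiplicative rescaling of the raw trace.

The **block filter** is a centered moving average (20 samples ≈ 0.26 s at a
77.7 Hz resonant-scanner frame rate); edges use shrunken windows so output
length equals input length. Because the filter smears the last ~0.25 s of a
10 s stimulus, slope windows for filtered 10 s protocols end at 9.75 s
(`edge_trim` of 0.25 s).

# Tuning and responsiveness

Direction tuning is fit as a sum of two Gaussians in wrapped angular
distance, forced to peak 180° apart with a common width σ. The linear
parameters (offset and the two lobe amplitudes) are profiled out exactly at
each (θ_p, σ), so the optimizer works in two dimensions; Nelder-Mead is
restarted from each of the 8 measured directions and the best-RSS fit wins,
with ties broken toward the smaller θ_p. σ is constrained to (2°, 120°) via
a logistic transform. Because the offset-only model is nested in the linear
subproblem, the fitted RSS can never exceed the flat-model RSS. Degenerate
flat curves return zero amplitudes with θ_p flagged `NA`. The fit is
equivariant under rotation of the stimulus labels.

Orientation classes use wrapped distances: iso/cross by whichever of the
adapter orientation and its orthogonal is closer to θ_p mod 180°, with an
exact 45° tie assigned to iso; "horizontal-tuned" means θ_p within ±45° of
horizontal, boundary inclusive.

The responsiveness rules use Z scores whose construction is a design choice
(the thresholds 2.58 and 3.29 are the two-sided standard-normal critical
values for p < 0.01 and p < 0.001):

* **Trial-wise**: Z = (mean response − mean baseline) / SD of the
  baseline-window frames of that trial; responsive iff Z > 2.58 in at least
  50% of trials (inclusive). Trials with zero baseline SD are excluded with
  a warning.
* **Session-wise** (two-sided, so suppressed cells qualify): per session,
  Z = (mean response − mean of per-trial baseline means) / (SD of per-trial
  baseline means / √n_trials); responsive iff |Z| > 3.29 in at least half
  the usable sessions (≥ 3 trials each).

Both constructions are recorded in the returned object for auditability.
A property test calibrates the trial-wise rule on an i.i.d. null with a
single-frame response window, where Z is approximately standard normal.

# Adaptation metrics

The **slope of adaptation** is the OLS slope of the trial-averaged,
baseline-subtracted trace against time in seconds. Windows are
configuration, with defaults per protocol: 1–9.75 s (10 s stimuli analyzed
with the block filter), 1–7 s (7 s stimuli), 1–10 s (behavior-task probes).
The first second is excluded because the indicator-driven rise is not
adaptation. All window selections are frame-exact under the half-open
convention `[left, right)` with trial time 0 at onset. Normalization (for
population overlays) divides by the peak of the trial-averaged trace within
the stimulus window; the slope of a normalized trace is exactly the raw
slope divided by that peak. Note that the indicator kernel attenuates
measured slopes relative to the generative fraction-per-second values (the
residual onset transient adds a small positive component inside the
window); recovery tests therefore compare the estimator against its exact
noise-free expectation rather than against the raw generative number.

Per-trial slopes are averaged within session quarters for trajectories:
each session's trials are split, in presentation order, into four contiguous
near-equal quarters (remainders to the earliest quarters — trial counts per
session vary, so quarters are by order, not clock time). Since OLS is linear
in the data, the quarter mean of per-trial slopes equals the slope of the
quarter-averaged trace. The binned sequence is fit with
`y = a + b·exp(−t/τ)` (t = bin index) by profiling τ over a log-spaced grid
in (0.1, 100) bins with a local refinement; a flat RSS profile flags τ as
unidentifiable while still returning the binned values.

**Matched exclusion** equalizes initial conditions between groups: target
cells are ranked by |session-1 response − reference mean| (the reference
being the grating-irrelevant group's session-1 mean response) and the top
⌈0.1·N⌉ removed. The procedure returns a full ledger and never alters
retained cells' data.

**Iso/cross adaptation** pairs, per cell and test contrast, the mean ΔF/F
over seconds 11–12 of two-epoch trials (10 s adapter at iso or cross
orientation, then a test grating). **Suppressed cells** are those whose
average baseline-subtracted stimulus response is negative; the late-window
(8.75–9.75 s) mean quantifies the depth of suppression.

# Behavior

* **Running**: a trial is "running" iff speed exceeds 1 cm/s (strictly) for
  at least half (inclusive) of the stimulus samples.
* **Saccades**: pupil coordinates are median-filtered (width 5 samples);
  events are frame-to-frame displacements exceeding k·MAD with k = 6,
  merged within a 0.2 s refractory gap. The noise scale is the MAD of the
  *unfiltered* displacements: the median filter leaves occasional isolated
  jumps that make the filtered-displacement MAD an unstable denominator,
  while genuine saccadic steps survive filtering intact. These defaults are
  free choices validated on planted events (20 planted steps recovered
  exactly, localized within one sample); no quantitative threshold exists
  to inherit, so the detector's false-positive behavior is checked
  empirically against its Gaussian tail bound.
* **Navigation performance**: fraction of session samples with
  speed > 1 cm/s and |heading| ≤ 25° (inclusive). The denominator is total
  session time; a running-time denominator is an easy variant but total
  time is the default because it makes sessions of equal length comparable.
* **Licking**: per reward, the baseline-corrected pre-reward frequency is
  the lick rate in [−0.5, 0) s minus the rate in [−15, −13) s, counts over
  duration with no smoothing. An animal "anticipates" iff its last-session
  pre-reward rates exceed the first-session rates by a one-sided rank-sum
  test at α = 0.05 (one-sided because anticipation is directional; this
  also gives the flag a nominal 5% false-positive rate under the null,
  which a Monte-Carlo property test verifies).

# Ephys and the optogenetic probe

Spike rates are binned at 1/3 s in half-open bins from stimulus onset. The
preferred cardinal orientation is the one with the higher mean rate over the
first 3.5 s of grating-only trials; cells failing to spike at least once in
the stimulus window in at least half (inclusive) of those trials are
excluded. "Respond" means ≥ 1 spike within the first 3.5 s — the same window
used for classification — since no other operational definition presents
itself. PV+ classification requires a strictly higher rate with the LED than
without (ties are putative excitatory).

The LED intensity is constant and then drops to 50% and ramps linearly to
zero over the final 0.5 s (a rebound-avoidance property of the stimulus).
The probe bin is the first complete bin whose left edge is at or after
*complete* LED-off, and the same absolute-time bin is used for all three
conditions (adapted / control / LED+adapted). In the generator, adaptation
accumulates only with effective (post-silencing) stimulus-driven activity,
declining linearly to a configurable floor; silencing during the first half
of the stimulus therefore leaves a cell unadapted at LED-off, which is
exactly the contrast the probe bin is designed to expose.

# What the generator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
direction-tuned cells with per-condition linear adaptation, indicator
convolution (single exponential, τ = 0.6 s by default, GCaMP6-like — the
transient it creates is the reason slope windows exclude the first second),
shot noise and slow sinusoidal drift, suppressed cells (negative amplitude
on a positive baseline), PV cells with optogenetic drive, locomotion bouts,
saccadic pupil steps, and reward-locked licking with an optional
anticipatory ramp. Defaults are free parameters, not claims about data:
baseline fluorescence 1 a.u., response amplitudes ~0.4 ± 0.15 ΔF/F, tuning
widths 25–40°, frame noise SD 0.1, state slopes −0.05/s (anesthetized) and
+0.01/s (awake), and a relevance trajectory in which the irrelevant
condition's slope drifts from 0 toward −0.02/s over sessions while the
relevant condition stays near 0 (anticipating animals positive). No
published group statistics constrain these choices.

It does **not** emulate spatial imaging (pixels, ROIs, motion), neuropil
contamination, eye video, biophysical indicator nonlinearity, correlated
population noise, or drifting tuning. Passing tests therefore demonstrate
that the estimators are correct and calibrated for data satisfying the
model's assumptions — not that real recordings satisfy them.

# Numerical choices and problem sizes

Half-open windows `[left, right)` everywhere, with a 1e-9 s tolerance when
placing sample times on binary-fraction grids. Frame 1 starts at time 0.
The rolling percentile runs in C++ with a sorted sliding window. The
multi-start tuning objective is evaluated in C++ with the linear parameters
solved by 3×3 normal equations (tiny ridge for the near-collinear
large-sigma limit); reported coefficients come from the exact R solve at
the optimum. All generator randomness derives from a single integer seed,
and identical configurations produce bit-identical datasets.

Validation studies use populations sized to give informative Monte-Carlo
precision at interactive runtimes: slope recovery on 200 cells × 40 trials
(bias measured against the noise-free twin of the same population, which by
linearity of the pipeline is the estimator's expectation); tuning accuracy
on 200 noisy curves at 10% amplitude noise; state-experiment power over 25
replicate datasets of 150 cells; and null false-positive rate over 200
replicates of 60 cells. The orchestrators themselves run on any size.

# Known limitations

Statistical units follow the protocols (cells for imaging and ephys
comparisons, trials for lick tests, animals for behavior summaries), and
p-values are reported uncorrected per comparison by design. The sum-of-
Gaussians fit assumes a single preferred axis and cannot represent
multi-peaked tuning. Suppressed cells pass only the two-sided session-wise
rule, so trial-wise-filtered analyses are blind to them. The lick
anticipation flag compares only the first and last sessions. The indicator
kernel is a single exponential; real indicators have a finite rise time,
which would slightly increase the onset-transient attenuation discussed
above.
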