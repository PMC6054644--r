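---
title: "Models and detection methods in myostep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and detection methods in myostep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`myostep` analyzes the mechanics of processive cytoskeletal motors at the
single-molecule level: unloaded motility of quantum-dot-labelled motors
imaged by TIRF microscopy, and loaded stepping measured with ultrafast
force-clamp optical tweezers (the three-bead "dumbbell" geometry). This
vignette documents the models the package implements, the parameters that
matter, the design choices that were genuinely open, and what the
simulation-based tests do and do not demonstrate about real data.

## The kinetic model

Within one attachment to the actin filament, the motor is modelled by
three competing memoryless clocks: a forward step (+36 nm, the actin
pseudo-repeat), a backward step (-30 nm), and detachment. Each rate obeys
a Bell-type exponential load dependence,

$$k(F) = k_0 \exp\!\left(\frac{|F|\,d}{k_B T}\right),$$

with separate parameter sets on the assistive (force sign negative) and
resistive (positive) branches; the distance parameter $d$ (nm) measures
the force sensitivity of the underlying transition. Derived observables
follow from the same picture:

* run length $L(F) = L_0^{\pm} e^{-|F| d_L^{\pm} / k_B T}$ (decaying),
* detachment rate $k(F) = 1/\langle\tau\rangle = k_0^{\pm} e^{|F| d_k^{\pm} / k_B T}$
  (growing), with the error bar propagated as
  $\sigma_k = \sigma_\tau \langle\tau\rangle^{-2}$, computed, never fitted,
* forward/backward count ratio $R(F) = R_0 e^{-|F| d / k_B T}$, whose
  unit crossing defines the stall force
  $F^{*} = (k_B T / d) \ln R_0$.

`motor_model()` defaults to the fitted single-myosin-5B parameters at
100 uM ATP. Two caveats are deliberate:

* **The stepping-rate and count-ratio parameter sets are not mutually
  consistent at zero force.** The published forward/backward rate
  intercepts imply more backward than forward steps at $F = 0$, while the
  count-ratio model implies a ~54-fold forward excess. These are
  independent fits to different observables with very different leverage
  (the backward-rate intercept is an extrapolation from scarce low-force
  backward steps, with a correspondingly large uncertainty). The
  simulator treats them as independent defaults and does not attempt to
  reconcile them; validation tests that need realistic plus-end-directed
  motion construct their own moderate parameter sets.
* **Branch switching at exactly zero force** uses the mean of the two
  branch rates. This matters only to the simulator; measured runs always
  carry a force sign.

$k_B T$ defaults to 4.114 pN nm (T = 298 K); the trapping temperature is
not part of the published parameter set, so room temperature is assumed
and the value is configurable everywhere it enters.

The optional "inchworm" short-step mixture (`short_step_prob_scale`)
shortens forward steps to 20 nm under resistive load (backward steps to
15 nm under assistive load) with a logistic probability centred at 1 pN.
It emulates the published observation that the mean forward step shrinks
toward ~20 nm at stall; it is off by default because none of the
recovery experiments depend on it.

## The force-clamp measurement geometry

`simulate_clamp_record()` reproduces the measurement, not just the
kinetics. While unbound, the dumbbell is dragged at constant speed and
the clamped force sign alternates at the edges of a spatial window
$[0, D]$, producing a triangular wave; attachment (an exponential
waiting time at `attach_rate`, a nuisance parameter the experiment does
not constrain, default 1 s^-1) freezes the dumbbell on the stepping
staircase. The signed-force convention follows the field: a force
pushing in the motor's direction of motion is assistive and labelled
negative.

The essential asymmetry of this geometry: an assistive run that carries
the dumbbell to the window edge is interrupted there (the force
reverses), so assistive run lengths are censored by $D$; resistive runs
hold the dumbbell away from the reversal edge and are never censored.
The 200-kHz feedback is emulated as instantaneous clamping — bead-trap
relaxation, drag hydrodynamics and feedback latency are out of scope, so
the record is piecewise ideal (ramps and staircases) plus white Gaussian
position noise of `noise_sigma` per sample. The default 8 nm at 200 kHz
corresponds to sub-nanometre noise after millisecond averaging, the
regime the technique operates in.

## Run-length censoring and its correction

Assuming an exponential true run length (mean $L$) and a uniform
attachment position in the window, the measured run length has survival
$S(x) = e^{-x/L}(1 - x/D)$ on $[0, D]$, density
$p(x) = e^{-x/L}(1/L + 1/D - x/(DL))$, and mean

$$\langle L_m \rangle = \frac{1}{D}\left[L^2\left(e^{-D/L} - 1\right) + L D\right],$$

which increases strictly in $L$ with supremum $D/2$. `correct_run_length()`
inverts this map by root bracketing (tolerance $10^{-3}$ nm); a measured
mean at or above $D/2$ has no finite solution and is reported as an
explicit error, and measurement uncertainty is propagated by the delta
method through the closed-form derivative. `sample_truncated_run_lengths()`
draws from $p(x)$ by rejection from a truncated-exponential envelope
(acceptance probability $1 - x/(D+L)$) and serves as the Monte-Carlo
oracle for the closed form. The uniform-attachment assumption holds in
the simulator in the limit of slow attachment relative to the sweep; the
tests use that regime.

## Detection chains

### Force-clamp records

All detectors act on one statistic: the sliding-window linear-regression
slope of position (`sliding_velocity()`).

* **Event detection** (`detect_events()`): attached intervals are where
  $|v|$ stays below a threshold; unbound sweeps sit near the drag
  velocity. Hysteresis absorbs above-threshold excursions shorter than
  two windows (the transient of a step) and discards candidate events
  shorter than three windows. The default 5-ms window keeps the velocity
  noise of an 8-nm record well below a typical drag velocity.
* **Threshold calibration** (`calibrate_threshold()`): the threshold is
  chosen on simulated motor-free records as the *largest* value whose
  empirical false-event rate stays within the budget (default 1% of
  records), i.e. maximal sensitivity subject to false-positive control.
  The direction in which the calibrated threshold moves with the noise
  level depends on the regime (apex-crossing dips versus noise-dominated
  windows), so only the budget itself, verified on held-out records, is
  treated as the invariant.
* **Step detection** (`detect_steps_in_run()`, 2-ms window by default):
  bidirectional threshold crossings of the velocity inside an attached
  segment; plateau positions are sample means between transitions
  (excluding half a window margin) and step sizes are plateau-mean
  differences, signed toward the plus end. Transitions closer than 3 ms
  merge: two steps inside the time resolution are measured as one,
  which is exactly why run assembly caps step amplitudes at 90 nm
  (2.5 lattice steps) rather than discarding large jumps.
* **Run assembly**: the package exposes the literal grouping rule as
  `assemble_runs()` (a step joins the current run iff the gap is under
  3 ms *and* its amplitude under 90 nm). In the full chain
  (`analyze_record()`), runs are defined by attachment intervals — the
  physically unambiguous boundary — with the 3-ms rule acting as the
  step-merge resolution and the 90-nm rule splitting a run at an
  unphysically large jump. The published description of the rule is a
  single sentence that supports both readings; the chain's reading is
  the one that lets noiseless records reproduce the generating run
  structure event-for-event, which the tests verify for every run whose
  dwells all exceed the detector resolution. Censored assistive runs are
  never discarded: they are flagged and corrected through the truncation
  model above.
* **Per-force statistics** (`bin_statistics()`): default bin width
  0.4 pN over +/-3 pN (the binning itself is not part of the published
  analysis description and is configurable). The forward/backward ratio
  is flagged undefined in bins without backward steps.

### Unloaded motility

* **Localization**: spots are local maxima above a robust threshold
  (median + 5 MAD), refined by least-squares fits of a symmetric 2-D
  Gaussian with constant offset — the circular-PSF description of the
  original analysis; an elliptical fit is deliberately not offered.
  Pixel centers sit at integer 0-based coordinates; 91 nm/pixel by
  default. The published analysis does not state its detection threshold
  or ROI size; both are parameters with the defaults above, and the ROI
  half-width is at least three PSF sigmas.
* **Linking** (`link_trajectories()`): greedy nearest-neighbour within a
  per-frame jump limit, ties broken by fit residual, no gap closing by
  default (sparse fields; one-frame gap closing is available).
  Trajectories under 10 frames are discarded and counted, mirroring the
  standard motility filter.
* **Precision** (`localization_precision()`): pooled per-axis standard
  deviation of an immobile spot over at least 20 frames; a linear trend
  exceeding twice the residual noise over the trajectory marks the spot
  as drifting rather than immobile.
* **Run length** (`compute_run_length()`): raw frame-to-frame arc length
  is inflated by localization noise, so the trajectory is reduced to
  block-mean anchors (base block of 5 frames, grown automatically until
  expected inter-anchor travel dominates anchor noise), anchors whose
  separation is statistically indistinguishable from noise are pooled
  (otherwise flat dwells of a stepping trace would contribute their
  |noise| to the arc length), and the polyline is closed by the raw
  endpoints so no travel is lost at the ends. The published analysis
  says only that trajectories were "interpolated"; this estimator is the
  package's documented substitute, exact on noiseless paths and within
  ~2% on noisy constant-velocity fixtures.
* **Step detection** (`detect_steps_unloaded()`): the published step
  sizes came from visually isolated stepping events; the package
  replaces visual inspection with penalized binary change-point
  segmentation on the principal-axis projection. The acceptance
  threshold for a split is 16 noise variances — just above the simulated
  99th percentile of the maximal spurious RSS gain on pure-noise traces
  of 100–3000 frames, putting false plateau splits below ~1% per trace.
  `summarize_steps()` then averages only well-isolated steps: amplitude
  at most 54 nm (1.5 lattice repeats; larger jumps are unresolved
  multiples) and flanking plateaus of at least 6 frames, the automated
  counterpart of "isolating clean stepping events".
* **Michaelis–Menten fits** (`fit_michaelis_menten()`) serve both the
  velocity–ATP curve of the motility assay and ensemble ATPase curves.
* **Gliding filter** (`filter_gliding_velocities()`): filaments with
  velocity dispersion sd/mean above 0.33 are excluded
  (boundary inclusive), non-positive mean velocities are excluded and
  flagged.

### Step-count ratio fitting

Each detected step is a Bernoulli trial whose odds are the ratio model
$R(F)$, so `fit_step_ratio()` fits the exponential ratio model as a
binomial logistic regression in force — the maximum-likelihood use of
the raw counts, which matters because backward steps are scarce far
below stall. Weighted least squares on per-level ratios is retained as a
cross-check (`method = "ratio_ls"`). Even at the published sample sizes
(~2700 forward, ~700 backward steps), the zero-force ratio intercept is
an extrapolation with a relative uncertainty near 15–20%; recovery
experiments at those counts scatter accordingly, which is a property of
the design, not of the fitting route.

## What the synthetic data do and do not emulate

The generators reproduce: Bell-type force dependence on both branches,
the triangular oscillation and its asymmetric censoring, Gaussian
localization/position noise, Poisson shot noise with integrated-Gaussian
PSFs on a constant background, exponential run lengths (discretized on
the 36-nm lattice), and Michaelis–Menten velocity scatter (lognormal,
15% coefficient of variation, mean-one).

They do not emulate: bead–trap–filament compliance and feedback latency,
correlated (1/f) noise and slow drifts, fluorophore blinking and
photobleaching, filament curvature beyond a straight path, multi-motor
interactions, or any Ca2+/calmodulin dependence. Passing recovery tests
therefore demonstrates that the estimators are calibrated and unbiased
under the stated noise model at the published sample sizes — not that
they are robust to every artifact of real recordings.

Two small, quantified biases are accepted rather than hidden:

* the 10-frame motility filter preferentially removes short runs, so a
  pooled mean run length recovered from a filtered ensemble sits
  slightly above the generating mean; recovery experiments use low ATP
  (0.3–0.5 uM), where frames are short relative to run durations and
  the selection effect stays within a few percent (the published
  assay, which applied the same filter, carries the same effect);
* merged double steps and detector-resolution effects are excluded from
  step-size averages by the isolation rule rather than corrected.

## Problem sizes and determinism

Every stochastic operation takes a `seed` and restores the caller's RNG
state; identical seeds give bit-identical outputs, which the pipeline
(`run_pipeline()`) extends to whole artifact bundles stamped with a
configuration fingerprint. Validation and recovery experiments are sized
to the published designs where those are stated (127 motility runs
across 0.3–1000 uM ATP, ~750 loaded runs across 0.5–3 pN, 2729/689
forward/backward steps, at least 42 unloaded steps) and otherwise to a
few hundred runs or records, with force-clamp records simulated at
20–50 kHz — the detectors are sample-rate agnostic, and these rates
resolve every timescale the detectors use.

## Known limitations

* Event boundaries carry an uncertainty of about half an event window;
  the final dwell before detachment is included in the run duration, and
  whether motion before the first detected step belongs to the run is an
  interpretation choice (it does here, via the attachment interval).
* A run truncated at the window edge ends in a step with no plateau
  after it; its final step is undetectable in principle, so truncation
  flags on detected (as opposed to ground-truth) runs rely on the run
  ending within tolerance of the edge.
* The correction of censored run lengths assumes exponential run lengths
  and uniform attachment; both are assumptions of the published
  correction, inherited knowingly.
* `fit_bell()` weights by reported standard errors; with few force
  levels and noisy level means, amplitude intercepts can be biased by a
  few percent, visible in the recovery experiments and well inside the
  published uncertainties.
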