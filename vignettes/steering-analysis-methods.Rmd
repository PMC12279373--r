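---
title: "Methods: from descending-neuron spikes to steering behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from descending-neuron spikes to steering behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerlab)
```

steerlab implements the analysis chain that links intracellular recordings of
steering descending neurons (DNs) in walking *Drosophila* to the fly's
locomotor output, together with seeded synthetic-data generators that emulate
every input modality. This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish about real recordings.

## Kinematic preprocessing

Spherical-treadmill kinematics arrive as three channels at 100 Hz: rotational
(`v_r`), sideways (`v_s`) and forward (`v_f`) velocity, all in deg/s
(translational channels can be viewed in mm/s through the 3.175 mm ball
radius, but every analysis here stays in deg/s so that filters across
channels share units).

Preprocessing is a three-stage pipeline:

1. **Offset correction** (`correct_offset`). Sensor offsets are estimated as
   the median over "inactive" samples, defined by an instantaneous difference
   below 0.025 deg/s, and subtracted globally. If no sample qualifies the
   trace is returned unchanged with a warning flag.
2. **Light Gaussian smoothing** (`smooth_gaussian`), a 50 ms-sigma kernel
   truncated at ±3.5 sigma and renormalized to unit sum. Edges are
   reflect-padded: the alternatives (zero padding, truncation) visibly droop
   at the trace boundaries, while reflection is unbiased for locally smooth
   signals.
3. **Random-walk MAP smoothing** (`smooth_random_walk_map`). The signal is
   modeled as a local-level Gaussian state-space process: the latent path
   follows a random walk with drift `mu` and innovation variance
   `(1 - alpha) * sigma2`, and observations add noise of variance
   `alpha * sigma2`. `alpha = 0.2` by default, i.e. 20% of signal variance is
   attributed to observation noise. Because the model is linear-Gaussian, the
   MAP path equals the posterior mean and solves a symmetric tridiagonal
   linear system in closed form (Thomas algorithm, O(n)); `sigma2` cancels
   from the solution, so only `alpha` and `mu` matter. A general-purpose
   numerical optimizer applied to the joint log-density is retained in the
   test suite as an oracle and agrees to better than 1e-6 RMS. `mu` is
   estimated as the mean first difference of the whole recording (the
   maximum-likelihood estimate under the model); both parameters can be
   overridden via `random_walk_params()`.

`total_speed()` is the scalar activity index `|v_r| + |v_s| + |v_f|` (deg/s).
`classify_inactivity()` bins each channel with the outlier-robust
Freedman-Diaconis width; a sample is inactive when all three channels sit in
the bin centered on their modal value. The modal value itself is localized on
a grid five times finer than the FD width so that the inactive band is truly
centered on the rest mode; with the coarse grid alone, the rest cluster can
straddle a bin edge and half of genuine rest is lost. This classifier assumes
walking occupies a substantial fraction (roughly the upper quartile) of the
recording, so the FD width reflects the walking range; on a recording that is
almost entirely rest it degenerates and is flagged.

## Spike detection and firing rates

`detect_spikes()` high-pass filters the voltage with a first-order Butterworth
at 100 Hz applied forward-backward (zero phase). The method text this follows
names a "band-pass" with a single 100 Hz corner; we read it as a high-pass
for spike-band emphasis and expose an optional `upper_corner` for the
band-pass reading. The filtered trace is divided by a 500 ms rolling median
absolute deviation times 1.4826 (the inverse 0.75 normal quantile, making the
MAD a consistent Gaussian-sigma estimate; deviations are taken from the
global median). Spikes are peaks whose relative prominence, evaluated within
a 10 s neighborhood, exceeds a per-recording threshold; peaks closer than
1 ms are merged keeping the larger. Prominence must be tuned per experiment
in practice; the packaged default (8 normalized units) is calibrated on the
synthetic session generator at a waveform-to-noise ratio of 8, where it
yields precision and recall above 0.99. Candidate peaks are pre-screened with
an upper bound on windowed prominence derived from block minima, which makes
detection linear-time in practice without changing the result.

Two rate estimators are provided: `rate_fine()` (1.25 ms bins, 2.5 ms-sigma
Gaussian) for filter analyses, and `rate_coarse()` (10 ms bins, causal
exponential moving average with a 30 ms window) for display-grade rates. The
exponential filter's decay is set so the stated window holds `1 - exp(-2)`
(about 86%) of the kernel mass — the underlying toolbox routine is
under-documented, so the kernel is defined explicitly here and only its
statistical properties are asserted. Both estimators conserve spike count
(the integral of rate equals the count up to edge mass).

`subthreshold_voltage()` removes spikes with a 35 ms median filter, smooths
with a 5 ms Gaussian, detrends by the average of piecewise linear fits tiled
over 30 s and over 120 s segments (segments tile rather than overlap), and
adds back the initial offset (median of the first 30 s). Note one
consequence: sustained square steps such as immobility hyperpolarization are
partially absorbed by the segment fits, so ground-truth comparisons are made
on sessions without immobility bouts, and bout hyperpolarization is checked
qualitatively. `qc_recording()` enforces the inclusion rules: at least 15
minutes of recording, and exclusion of extended (>= 1 s) epochs more
depolarized than -33 mV.

`resample_neural_to_kinematics()` moves neural signals onto the kinematics
time base by polyphase rational resampling: upsample by 4, apply a
linear-phase FIR anti-alias filter with the group delay compensated exactly,
downsample. The FIR order and cutoff are exposed (`fir_order`, defaults to 10
taps per output sample at cutoff `1/down`); the method text does not state
them.

## Linear-filter (Wiener) estimation and prediction

`estimate_filter()` implements frequency-domain deconvolution between a
firing-rate input and a kinematic output: cross-spectrum and input power
spectrum are averaged over 4 s windows and the filter is
`F = <input* x output> / <input* x input>`, inverse-FFT'd to a two-sided
time-domain kernel. Numerical choices:

- **Windowing.** Taken literally, "1-sample overlapping 4 s windows" means a
  hop of one sample; the default hop is 25% of the window, and `hop = 1` is
  available. The two agree to well under 1% RMS on matched data — the
  maximally overlapped average carries almost no extra information, at ~100x
  the cost.
- **Per-segment Hann taper and demeaning** (the standard Welch detrend)
  control leakage of the strong low-frequency locomotor power into the quiet
  part of the input spectrum. Windowed spectra shrink the implied kernel at
  lag `l` by the taper autocorrelation `rho(l)`; this known multiplicative
  bias is divided out (floored at 0.05 so the far tail is not amplified into
  noise). For already-centered signals `demean = FALSE` disables the detrend.
- **Ridge.** The denominator carries a ridge of 1e-6 times its peak, so dead
  frequency bands cannot blow up the division; a flag records whether the
  ridge was materially active.
- **Slepian smoothing.** The raw filter is low-pass filtered with a unit-sum
  0th-order discrete prolate spheroidal (Slepian) taper: half-bandwidth 15 Hz
  for neuron-to-behavior filters, 6 Hz for behavior-to-neuron. The taper
  length is `rate / bandwidth` samples, which together with the half-bandwidth
  reading gives a time-bandwidth product of 1. The DPSS sequence is computed
  from the standard symmetric tridiagonal eigenproblem (no installed R
  package provides one).

`predict_behavior()` convolves the rate with the filter truncated to
candidate lengths on a fixed log grid inside 0.1-4 s, scores each by the
R-squared of an OLS regression (with intercept — the source text does not say
whether one was included; we include it) of observed on predicted, and keeps
the best. Filters are estimated on the first 20% of a session and evaluated
on the final 80%. `dual_prediction()` sums the two cells' predictions with
equal weight, optionally masking inactivity.

The sign conventions used throughout: positive `v_r` is leftward
(counterclockwise) rotation, so the left cell carries positive rotational
kernels and the right cell mirrored negative ones; positive filter lag means
behavior follows the neuron.

## Event-triggered analyses

`detect_transitions()` finds movement starts and stops as 75 deg/s crossings
of total speed with 750 ms consistency windows: a start needs >= 90% of the
pre-window at or below half the threshold and >= 90% of the post-window above
threshold (stops mirror this). `align_and_average()` averages event-triggered
snippets within experiment before averaging across experiments, with the
s.e.m. across experiments (flagged undefined for a single experiment).

`binned_behavior_map()` shifts the neural channels forward by 150 ms (exactly
15 samples at 100 Hz; no interpolation), reduces all signals to 50 ms
non-overlapping window means, and bins behavior on the 2D grid of the two
neural means; bins with fewer than 20 windows (threshold unstated in the
source; 20 chosen as a conservative display floor) are masked.
`rl_difference_tuning()` bins the left-minus-right rate difference, reports
mean rotational velocity per bin, and fits the unbinned pairs by OLS. Bin
widths default to 10 spikes/s (unstated in the source, configurable).

## Bump tracking and bump-jump trials

`sector_dff()` computes per-sector dF/F with the baseline F defined as the
time-average of the lower half of that sector's raw values. This baseline is
only meaningful when the bump visits and leaves each sector during the
recording; a bump parked on one sector for most of a session inflates that
sector's baseline and flattens its dF/F, which is why the synthetic tests
move the heading across sectors between trials.

`pva()` is the population vector average over the 8 sector center directions
weighted by dF/F (negative weights clipped to zero and the clipped fraction
reported); position is the resultant angle in sector units (0-7,
counterclockwise viewed from the rear), magnitude the resultant modulus.
Circular means and SDs are computed via the resultant vector.

`classify_trials()` applies the trial-inclusion cascade in order: (1) faded
bump — PVA magnitude below the experiment-wide 7th percentile (evaluated on
raw, unsmoothed magnitude) for more than 1 s within the trial; (2) pre-moving
bump — circular SD over the 1 s pre-puff window above 1.5 sectors; (3)
initial position = circular mean of that window; (4) no jump — post-puff
excursion never reaches 0.5 sectors; (5) no return — the bump never dwells
within 0.5 sectors of the initial position for at least 0.5 s after the
maximum excursion. Survivors get a signed jump size (shortest arc at maximum
excursion), a return direction, and an alignment time at the frame of maximal
return speed within the return period (maximum excursion to re-entry into the
0.5-sector band). Return speed is measured on a 3-frame Gaussian-smoothed
position derivative (the source does not state smoothing; 3 frames at ~12 Hz
suppresses frame-to-frame jitter without moving the peak), and ties take the
earlier frame. `align_trials_by_return()` groups included trials by return
direction, aligns on the alignment time, and averages within fly before
averaging across flies.

## Leg kinematics

`body_velocities()` computes, per frame, forward velocity (centroid velocity
along the head-minus-abdomen axis), sideways speed (unsigned orthogonal
component) and rotational speed (unsigned angular velocity of the axis),
averaged over non-overlapping 500 ms windows; windows with mean forward
velocity below 2 mm/s are discarded. `label_swing_stance()` labels a leg in
stance when its camera-frame speed, averaged over three consecutive frames,
is below 8 mm/s (the camera-frame reading of the threshold; body-frame is the
noted alternative). `detect_rotation_events()` finds moments where rotational
speed exceeds 20 deg/s for at least 0.1 s and extracts 500 ms windows
starting 100 ms before the crossing.

`turn_metrics()` computes the five turning metrics with inner/outer side
assignment from the sign of the window's net body rotation (or given
explicitly). Directions are body-centric — the tarsus position is expressed
relative to the body centroid and axis per frame, and the epoch displacement
direction is measured against straight-backward (stance) or straight-forward
(swing), positive toward the fly's right, so left turns give positive stance
directions and mirror-reflecting the arena negates both direction metrics.
The swing-direction metric is computed on swing epochs; the source text
literally repeats the stance definition for it, which would duplicate metric
one, so we read it as a typo (set `literal_swing = TRUE` for the literal
reading). Ratios: mean swing distance of oF and oM over iM and iB; iB stance
duration over the mean of iF, oF, oM, oB; swing duration is the iM/iB mean.
A window is omitted from a metric (with the missing legs named) when any
involved leg lacks a complete relevant epoch. `window_gait_stats()` reports
step frequency (inverse stride period over complete stance-onset-to-onset
strides of all six legs), step length (net tarsus displacement over those
strides) and forward velocity per 500 ms window.

## Perturbation statistics

`bootstrap_unilateral_null()` builds the null distribution for unilateral
activation: per replicate, control flies (with bilateral expression) are
resampled with replacement and each is assigned a random "right"/"left"
expression label (a flip negates the fly's signed rotational velocity); the
replicate statistic is the mean ipsilateral velocity, and the percentile
interval (2.5/97.5 by default; a basic-bootstrap variant is deliberately not
used, matching the source) is the confidence band. Labels are re-randomized
independently inside each replicate; `fixed_labels = TRUE` gives the
sensitivity variant where one label draw is reused. Coverage is nominal
(~95%) against the label-randomization null itself — the hypothesis the
procedure tests; against fresh-fly null draws the percentile interval shows
the usual small-sample undercoverage (~93% at 17 flies), which is a property
of percentile bootstraps, not of this implementation.

`anova_genotype_light()` is the fixed-effects two-factor ANOVA on windows
(genotype x light with interaction), Holm-corrected across the declared
number of metrics, with a Tukey HSD post hoc comparing light on/off within
genotype only where the corrected interaction is significant; flies
contributing fewer than five windows to a metric are dropped. A mixed model
is deliberately not substituted; instead `fly_id_variance_check()` reports
the fraction of total sum of squares attributable to fly identity (flagged
above 0.2 by default) as the guard against fly-dominated variance.

## Connectome pathways

`group_and_filter()` applies the pathway thresholds in order: unitary
connections under 5 synapses are discarded; survivors are grouped by (pre
type, post type) and summed; groups under the synapse minimum or under the
fraction minimum of either cell type's total are discarded. Type totals are
computed on the unitary-filtered table before group filtering, so the
fraction rule is independent of which groups survive (computing fractions
after group filtering would make the rule order-dependent). "Either" total:
a group is discarded when its share of the presynaptic type's output or of
the postsynaptic type's input falls below the threshold — the stricter of
the two readings of "pre- or postsynaptic total". Weights are reported per
hemisphere (half the group total, sides pooled). Presets: `pfl3` (200
synapses, 1%) and `mbon32` (70 synapses, 0.4%). `two_hop_paths()` enumerates
source-intermediate-target chains over filtered edges and ranks by the
bottleneck (smaller) edge weight.

## The synthetic-data generators

`simulate_steering_session()` draws a session under a `sim_config()`: a
latent steering drive (Ornstein-Uhlenbeck, 0.5 s correlation time) feeds
right/left firing rates (baseline 40 spikes/s, 12 spikes/s excursions) whose
anticorrelation is set by `seesaw_coupling` (default 0.6 — the study reports
see-saw organization but no correlation magnitude, so the coupling is a free
parameter, not a fitted value); spikes are an inhomogeneous Poisson process
(2 ms refractory enforced by thinning); each kinematic axis is a known
kernel convolved with the centered rate plus Gaussian noise (defaults
`v_r`/`v_s`/`v_f` noise 20/8/10 deg/s, giving rotational signal-to-noise
around 8-10); immobility bouts (2 per minute, mean 1.5 s) gate the motor
output multiplicatively and hyperpolarize the cells; voltage is a
spline-interpolated subthreshold potential plus a stereotyped 2 ms biphasic
spike waveform (amplitude 40 mV over 2 mV noise by default — the
amplitude-to-noise ratio is the detection difficulty knob).

The default ground-truth kernels give the two cells the study's qualitative
signatures: a monophasic low-gain kernel (alpha function, 150 ms time
constant) and a biphasic high-gain kernel (fast 80 ms positive lobe, slower
shallow undershoot). The undershoot weight (0.2) keeps the biphasic kernel's
net area positive, so sustained firing still drives net ipsiversive turning,
matching the positive rate-to-rotation tuning the study reports; a
zero-net-area differentiator would null the binned tuning curve.

What the generators emulate: the coupling structure, timescales, spike
statistics, immobility, bump geometry, tripod gait, and synapse-table
schema. What they do not: non-Poisson spiking regularity, history-dependent
gain, behavioral state changes other than immobility, optics-level noise in
imaging, leg-slip and grooming artifacts, and real connectome topology.
Passing the recovery tests therefore establishes the correctness of the
estimators under their stated assumptions, not their performance on real
recordings.

Two calibration notes. Filter-recovery validation runs on sessions with
immobility bouts disabled: the immobility gate is a deliberate nonlinearity,
and the recovery claim concerns the linear regime (the default configuration
keeps bouts on). The Poisson time-rescaling check (rescaled inter-spike
intervals exponential by a KS test) runs with the refractory period disabled,
since at 40 spikes/s a 2 ms refractory removes about 8% of short intervals —
a real deviation from Poisson that the test would correctly detect.

`simulate_bump_movie()` renders a von-Mises-shaped bump (half-width 1.2
sectors) over 8 sectors following `heading / 45 deg`, with scripted jumps,
constant-speed returns after a dwell, and amplitude fades; ground-truth
center, offset and amplitude traces are returned. `simulate_gait()` generates
an alternating-tripod gait (4 Hz stride, 2 mm steps, duty 0.55, 400 Hz
frames) with legs planted in the world during stance, so swing/stance labels
and all five turning metrics have exact scripted ground truth (iB stance
prolongation, inner/outer swing scaling, imposed body rotation).
`simulate_connectivity()` emits cell-type-labeled unitary synapse tables.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen so the full suite completes in a
few minutes: 20 simulated sessions of 600 s at 100 Hz for filter recovery;
500 simulated experiments of 17 flies with 1000 bootstrap replicates for
coverage; 50 scripted bump trials; 1000 null ANOVA tables for the type-I
rate; 100 randomized instances per brute-force oracle comparison. The
study-scale quantities that depend on the deposited recordings (per-fly
R-squared values, return-rate percentages, fly counts) are outside what
synthetic data can reproduce and are not asserted.

## Known limitations

- The closed-form smoother assumes the stated local-level model; signals with
  heavy-tailed noise would need a robust variant.
- Welch-ratio filter estimation is biased toward zero when the input itself
  is a noisy estimate (errors-in-variables); using the latent rate, or long
  recordings with high-SNR rate estimates, avoids this.
- The inactivity classifier needs a bimodal rest/walk histogram; recordings
  that are nearly all rest or all walk degenerate (flagged).
- dF/F baselines require the bump to move; static-bump sessions flatten the
  profile (see above).
- The gait generator scripts kinematics, not dynamics: no inertia, slipping,
  or load redistribution.
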