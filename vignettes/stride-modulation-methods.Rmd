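---
title: "Methods: stride-phase tuning, optogenetic perturbation, and slip detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-phase tuning, optogenetic perturbation, and slip detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridemod)
```

## The scientific problem

Cerebellar Purkinje cells inhibit neurons of the cerebellar nuclei (CbN),
the cerebellum's output. During voluntary locomotion both cell types fire
at high rates (tens to low hundreds of spikes/s) that rise and fall
systematically with the stride cycle (~200-300 ms). Optogenetically
driving Purkinje cells with 1 s light *steps* produces asynchronous extra
inhibition that slows CbN firing, while 1 ms pulse *trains* (50-200 Hz)
produce relatively synchronous inhibition that mostly restructures CbN
spike timing at the millisecond scale. Behaviorally, either stimulus can
evoke gait irregularities ("slips"), and slips track the disruption of
stride-related rate modulation rather than the absolute firing rate.

This package implements the full analysis chain for such experiments:
stride segmentation from a hind-paw position trace, phase-normalized
tuning curves and modulation statistics, peri-stimulus analyses for steps
and trains, automated slip classification with paired step-versus-train
comparisons, tuning-preservation correlations, and LFP spectral analysis —
plus a synthetic-session generator that produces ground-truth-labeled data
with the statistical structure the analysis assumes, so that every stage
can be validated by parameter recovery.

## Stride segmentation and phase normalization

The paw x-position is normalized so 1 AU spans the paw's full
forward-to-backward range; a stride appears as one sawtooth cycle (rising
stance, falling swing). `clean_trace()` removes brief square-pulse
tracking losses (rise and fall within 5 samples, amplitude > 0.5 AU) by
linear interpolation; traces with more than 20% flagged samples are
rejected. `detect_strides()` smooths with a 50 ms sliding average, finds
troughs and peaks with a topographic prominence threshold (0.2 AU) and a
100 ms minimum trough separation, then refines every extremum to the
nearest vertex of the unsmoothed trace within half a smoothing window —
the centered boxcar shifts the vertices of an asymmetric sawtooth by
roughly two samples, and the refinement restores single-sample boundary
accuracy on clean data. Trough-peak-trough triples with plant-to-plant
durations of 100-500 ms become strides; at least 30 are required for
session-level statistics.

Strides are normalized into 10 bins split between stance and swing by the
session's median stance fraction with half-up rounding (70% stance gives
7 + 3; the rounding rule and the clamp to at least one bin per phase are
configurable because real data sit near the 0.65 boundary). `bin_edges()`
divides each phase into equal sub-intervals, so the bins tile the stride
exactly and the stance/swing boundary falls on the lift.

Rest epochs are intervals of at least 0.5 s in which the rolling 200 ms
peak-to-peak amplitude stays below 10% of the median stride amplitude;
rest-rate statistics require more than 2 s of total rest. The 10% figure
is the stated criterion; the window sizes are this package's
operationalization and are configurable.

## Firing-rate statistics

The instantaneous firing rate (IFR) is defined as the reciprocal
interspike interval held over that interval — a step function, undefined
outside the first and last spike. Bin rates are time-weighted integrals of
this step function, not sample averages, so they are exact for any bin
placement. The modulation index is MI = (FRmax − FRmin)/(FRmax + FRmin)
over the 10-bin curve, with stance-only and swing-only variants; it is
invariant to uniform rate scaling and equals the generator's target MI
analytically for the built-in tuning shapes.

Spike-phase uniformity is tested with Kuiper's statistic V = D⁺ + D⁻,
which is origin-invariant on the circle. The p-value uses the standard
asymptotic series with the finite-n correction factor
(√n + 0.155 + 0.24/√n); for corrected statistics below 0.4 the series is
numerically unusable and the p-value is reported as 1. Pulse locking uses
the Rayleigh test with the standard exponential approximation. Both
implementations are checked in the test suite against 10,000-draw
uniform-sampling nulls at n = 10, 50 and 200 rather than trusted at face
value.

### Modulation classes

The study's six classes describe the phase relation between the tuning
curve and paw position: I in phase (peak at the lift), II anti-phase, III
leading and IV lagging by a quarter cycle, V two peaks and VI two troughs
at ±90° from the lift, with VII for unclassifiable cells. The original
assignment was done by eye; `classify_modulation()` is an explicit
quantitative proxy. It computes the first two circular Fourier harmonics
of the mean-subtracted bin curve against stride phase. If the fundamental
carries at least twice the power of the second harmonic, the phase
difference between the rate and paw-position fundamentals assigns classes
I-IV in 90° sectors (±45° around each canonical phase). Otherwise the
bins a quarter stride before and after the lift are compared with the
bins at the lift and plant: higher means two peaks (V), lower two troughs
(VI). Curves with Kuiper p ≥ 0.05 or MI < 0.05 are class VII. The
dominance ratio, sector width, and MI floor are stated defaults, not
fitted quantities; on simulated cells of all six classes at MI 0.4 the
round-trip assignment is essentially always correct, with residual errors
confined to adjacent phase classes.

## Optogenetic responses

Step responses are summarized as 50 ms-bin PSTHs over the 1 s stimulus
with the 1 s pre-stimulus rate as baseline (per trial and pooled — the
reference figure is ambiguous about which baseline is drawn, so both are
emitted). Train responses are folded pulse-wise: each spike is assigned to
the most recent pulse onset and binned at 1 ms across one inter-pulse
interval, giving a spike probability per pulse per bin; the pulse sequence
is split into early/middle/late thirds (1-33, 34-67, 68-100 at 100 Hz,
remainder to the late group otherwise). Count conservation —
sum(probability) × frequency = mean stimulus rate — holds exactly by
construction and is asserted in the tests. Rate effects are measured by
direct counting over 1 s windows (`stim_rate_change()`), the post-step
rebound over 200 ms windows flanking stimulus offset, and firing
regularity as the ISI coefficient of variation using the population
(1/n) standard deviation, under which the reference ISI set
{10, 20, 30} ms gives CV = 0.408.

## Slip detection

Screening replaces the study's manual, blinded pre-screening with two
stated rules: trials are discarded when a rest epoch overlaps the stimulus
window without running resuming before the trial ends, or when the last
pre-stimulus stride deviates more than 50% from the median of the three
preceding strides. The reference (control) stride is the last complete
stride ending by stimulus onset, with a configurable 30 ms grace for
strides protruding slightly into the stimulus.

Every stride overlapping the 1 s stimulus is compared with the reference:
duration ≥ 20% longer (prolonged), ≥ 20% shorter (incomplete), stance or
swing slope ≥ 20% lower (arrested); boundaries are inclusive. Any hit
makes the trial a slip; two or more distinct hits (counting the two slope
criteria separately) mark it altered. Trials with no evaluable stimulus
stride are flagged unresolved rather than auto-counted as slips; the
original analysis counted them, accepting a small error, and a flag
reproduces that choice.

Slip latency is operationalized as template divergence: the reference
sawtooth, anchored at the offending stride's plant, is compared with the
(lightly smoothed) trace; the first excursion exceeding 20% of stride
amplitude sustained for ≥ 25 ms marks the slip, and its onset is found by
extrapolating the rising divergence ramp through its half- and
full-threshold crossings back to zero — exact for piecewise-linear
trajectories, and robust to the threshold-crossing delay that would
otherwise bias latencies upward by tens of ms. Trials whose divergence
never reaches threshold have no unambiguous onset and return NA.

Slip probabilities per condition are exact count ratios with a chi-square
test of independence (and Fisher's exact test for two conditions). The
step-versus-train comparison pairs trials from the same cell whose mean
stimulus rates agree within 10 spikes/s, both at least 10 spikes/s, and
applies McNemar's test to the discordant pairs: continuity-uncorrected
χ² = (b−c)²/(b+c) when b + c ≥ 25, exact two-tailed binomial otherwise
(verified against the binomial for every b + c ≤ 20).

## Tuning preservation under stimulation

For non-slip trials, strides inside stimulus windows are pooled per cell,
binned with the session allocation, and the 10-bin light-on curve is
correlated (Pearson) with the no-light curve; r ≥ 0.4 is the descriptive
criterion for preserved modulation (no significance is attached to
individual r values on 10 points). For slip trials the reference stride
serves as a template: its absolute bin durations are tiled across the
slip epoch and the per-bin rates, averaged over tilings, are correlated
with the template's own rates. The tiling *phase* is anchored at the
template stride's end rather than at stimulus onset — the onset falls at
an arbitrary stride phase, and anchoring there would randomize the
correlation even for perfectly preserved modulation; anchoring at the
template boundary makes a cell that keeps its phase modulation through
regular strides score near 1, which is what the comparison is meant to
measure. A single-tiling option and a slip-onset epoch start are
retained.

Prolonged strides are additionally analyzed on polar coordinates: the
prolonged stride itself is lift-aligned and binned, and the angle between
its peak bin and the control tuning's peak bin is reported in 36°
increments (ties to the lowest bin), with a Rayleigh test across trials
and the fraction within ±90° summarizing phase preservation.

## LFP analysis

Ten sweeps per condition are averaged and band-pass filtered 50 Hz-1 kHz
with a 4th-order Butterworth applied forward-backward (zero phase; family
and order are this package's stated choice). The spectrum is a single
1 s periodogram (1 Hz resolution) scaled so that total pre-blanking power
equals the segment variance; bins within 60 ± 2 Hz are interpolated away
to blank mains noise. Harmonic peaks are the maxima within ±2 Hz of each
multiple of the stimulation frequency, with prominence measured against
the median power in a ±10 Hz surround; a flagged harmonic needs
prominence > 3 and power an order of magnitude above the global median
(the absolute guard stops noise fluctuations in empty bands from being
reported as entrainment). Whether spectra should be computed per sweep or
on the averaged sweep is ambiguous in the source description; the default
is the averaged sweep.

## The synthetic-data generator

`gen_paw_trace()` renders one piecewise-linear sawtooth per stride
(amplitude 1 AU, stance fraction 0.65 by default) with additive Gaussian
position noise (0.01 AU default), optional full-scale 1-3-sample
tracking-loss artifacts (0.1/s), and rest epochs as sub-10% jitter.
Durations are truncated-normal redraws on [140, 419] ms; the parent mean
is solved so the truncated mean equals the configured 222 ms exactly. On
this support a truncated normal cannot simultaneously reach the session
SD of 71 ms (its attainable SD tops out in the mid-60s of ms); the
configured SD is therefore the parent SD and empirical session SDs come
out somewhat smaller, which does not affect any recovery analysis since
those compare against the generated ground truth.

Around each stimulus trial the generator renders a *steady-running
window*: stride durations share a local mean (drawn between 210 and
320 ms) with 2% stride-to-stride jitter. This mirrors the recorded data,
where trials surviving screening show within-trial duration stability of
a few percent even though durations across a session span the full
140-419 ms range, and it is what makes a ±20% slip criterion meaningful:
with independently drawn durations (CV ≈ 0.3) every trial would cross
the slip threshold spontaneously. The bounds keep edited slip strides
inside the detectable 100-500 ms duration window.

Slips edit a single stride: prolonged sets its duration to (1+m) times
its predecessor's, incomplete to (1−m) times, arrested keeps the
predecessor's duration and scales both slopes by (1−m). Magnitudes at or
below 0.2 are rejected (sub-threshold by construction); the default 0.5
is conservative relative to the recorded slips, where prolonged strides
more than doubled in duration and slopes fell by half. Ground-truth slip
latency is set by placing stimulus onset 120 ms before the slip stride's
plant.

Spikes come from an inhomogeneous renewal process realized by time
rescaling: exponential (Poisson) intervals by default, or gamma intervals
with shape k for sub-Poisson regularity (CV ≈ 1/√k), since the CV
analysis only makes sense if the simulator can produce regular firing.
The rate follows the tuning function through ground-truth stride phase
and the rest rate elsewhere. Steps add their rate offset with an onset
transient (amplitude 50% of the plateau, τ = 100 ms — the plateau/decay
shape is parameterized, the exact kinetics being free choices); negative
rates are clipped at zero with a warning. Trains either add a spike per
pulse with probability `lock_prob` in a jittered window at the lock
latency (Purkinje) or delete spikes in that window (CbN); a
deterministic mode yields exactly one spike per pulse for constructed
tests. On slip trials the generator replaces stride-phase modulation with
a flat rate during the stimulus, emulating disrupted modulation; on
non-slip trials the tuning persists under the rate offset.

The LFP generator superimposes a damped-oscillation kernel (300 Hz,
τ = 10 ms by default, i.e. a ~50 ms event) at each pulse time, white
noise, and a 60 Hz contaminant, at 10 kHz.

What the generator does *not* emulate: biomechanics (slips are duration
and slope edits, not limb dynamics), multi-limb coordination, the
light-intensity-to-rate-change dose curve (a configurable parameter, not
a reproduction target), ISI distributions of real cells (unreported in
the source; the renewal shape is a free default), and spike sorting
(inputs are spike times; complex spikes are not separated, consistent
with their sub-2% contribution to totals). Passing the recovery tests
therefore demonstrates correctness of the analysis chain under the stated
statistical structure, not robustness to everything real recordings can
contain.

## Problem sizes and numerical choices

The test suite and acceptance script run sessions of 60-220 strides,
30-50 seeds per recovery property, 10-12 cells per cohort property, and
10,000-draw permutation nulls — sizes chosen so the whole suite completes
in a few minutes while keeping Monte-Carlo error well inside the asserted
tolerances. Degenerate inputs are handled explicitly: fewer than two
spikes give an empty IFR, all-zero rates make the MI undefined, argmax
ties resolve to the lowest bin, b + c = 0 gives McNemar p = 1, and
constant tuning vectors make correlations undefined rather than zero.
All randomness flows from explicit integer seeds; two runs of
`run_pipeline()` with the same seed produce byte-identical outputs.

## Known limitations

The classifier's 90° sectors assume the paw fundamental is a meaningful
phase reference; strongly multi-peaked paw trajectories would need the
equal-bin reanalysis option. The slip-latency rule detects divergence of
the paw trace from a sawtooth template and is blind to slips whose first
expression is in untracked body parts, so, as in the original analysis,
latencies are upper bounds on the true perturbation lag. Small prolonged
slips (magnitude near the 20% criterion) produce divergence excursions
that barely reach the 20% amplitude threshold, and their latency
estimates can jump by one template cycle; latency validation therefore
uses the generator's default magnitude 0.5, in line with the large slips
actually reported.
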