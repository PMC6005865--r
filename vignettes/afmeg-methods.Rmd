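---
title: "Methods: behavioral and neuromagnetic analysis of altered auditory feedback during sequence learning"
author: "afmeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: altered-feedback sequence-learning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmeg)
```

# The experimental model

The package analyses a sensorimotor sequence-learning paradigm: participants
repeatedly play short (4-5 note) piano sequences in blocks of 15 trials of
23 s of continuous playing, paced to 200 beats per minute (nominal
inter-onset interval, IOI, 300 ms).  On all but three perturbation-free
trials per block (trials 1, 6 and 10), the auditory feedback of a keystroke
is occasionally altered (AF): the performer hears a pitch other than the one
played.  Alterations are inserted randomly between every 8th and 10th
produced keystroke and land either on a *boundary* element (Bo: first or
last ordinal position of the sequence) or a *within-sequence* element (In).
The scientific question is whether disrupting boundary encoding costs more,
behaviorally and neurally, than disrupting within-sequence elements.

Because no participant-level data are deposited for this paradigm, the
package ships a first-class synthetic generator whose defaults encode the
paradigm above, with configurable ground truth for every downstream
quantity.  All statistical claims the package's tests make are therefore
claims about *recovery of known ground truth* and *calibration under a known
null*, not about any real dataset.

# Synthetic data generator

`simulationConfig()` collects the study conditions.  Defaults worth noting:

* **Timing noise** (`ioiNoiseSd = 75` ms).  At the 300 ms nominal interval
  this yields a coefficient of variation of IOI (cvIOI) around 0.25, the
  variability regime reported for non-pianists in this paradigm.  Gaussian
  IOI noise is truncated at 50 ms to keep onsets strictly increasing.
* **Post-feedback slowing** (`slowingEffect = c(Bo = 50, In = 0)` ms) is
  added to the IOI of the keystroke immediately following an AF event of
  the given class; this reproduces a boundary-specific slowing of the
  magnitude reported for this paradigm (about 49 ms at +1 after AF on
  boundaries, none within the sequence).
* **Errors.**  Each keystroke errs with `baselineErrorProb = 0.001`; within
  the five keystrokes after an AF event the probability is raised by
  `errorBoost` for the class of that AF event.  The defaults
  (`Bo = 0.0030, In = 0.0023`) put the 5-keystroke windowed error rates in
  the empirically reported range (roughly 0.005 after normal feedback,
  0.019/0.016 after AF at Bo/In).
* **AF placement.**  Gaps between consecutive AF events are drawn from the
  integers 8-10 (optionally weighted via `afSpacingWeights`; the placement
  rule is stated only as a range, so the default is uniform).  The target
  class alternates between Bo and In with a random starting class per
  trial, which balances the conditions; when no keystroke of the desired
  class falls inside the admissible window (possible for 5-note sequences,
  where three consecutive positions can all be within-sequence), the drawn
  position is used and labeled by its actual class.  Spacings never leave
  the configured range.
* **MIDI trigger delay** (`midiTriggerDelay = 22.5` ms) is the midpoint of
  the hardware's stated 20-25 ms range; epoching subtracts it so that t = 0
  is the keystroke.
* **Sensor noise** is AR(1) (`noiseAr = 0.9`) with unit-variance
  innovations.  A two-parameter autoregressive spectrum was chosen over a
  1/f model because both parameters are directly testable (the lag-1
  autocorrelation of generated noise is checked against the configured
  coefficient).
* **Planted evoked effects** (`erfEffect()`) deposit a half-sine template on
  the horizontal channel of every pair in a named sensor group, for every
  keystroke matching a feedback/position filter, at a configurable
  post-keystroke window.  The averaged condition contrast therefore equals
  the template exactly in the noiseless limit, which the tests exploit.

What the generator deliberately does **not** emulate: ocular/cardiac
artifacts, head movement, 1/f and line noise, volume-conduction realism,
learning-curve drifts (unless configured), and any correlation between
behavioral errors and neural templates.  Passing tests show the analysis
chain is correct and calibrated, not that it is robust to artifacts the
generator never produces.

# Behavioral metrics

`computeIOI()` defines IOIs strictly within trials; the first keystroke of a
trial has no IOI.  `computeCvIOI()` is sd/mean of the per-trial IOIs.

The windowed **error rate** (`computeErrorRate()`) scores, for each feedback
event, whether at least one pitch error occurs in the next five keystrokes
of the same trial.  Events followed by another AF event inside the window
are excluded from numerator and denominator, since a later alteration could
itself have induced the error.  Three choices the metric's definition leaves
open are resolved as follows:

* the window is clipped at the trial end (a late event with fewer than five
  following keystrokes stays eligible over the truncated window) rather
  than discarded;
* normal-feedback (NF) events are scored with the *same* AF-proximity
  exclusion, keeping the NF/AF comparison symmetric;
* multiple errors in one window count once ("induced an error", not "number
  of errors").

**Post-feedback slowing** (`computePostFeedbackChange()`) is
IOI(+1) − IOI(event) per event, averaged per subject and condition.  NF
keystrokes at +1 or +2 after an AF event are not scored as NF events; the
generated slowing sits exactly on those keystrokes' intervals, and scoring
them as NF reference events would leak the AF effect into the NF baseline.
Aggregation is per subject first, then across subjects, matching the
across-subject permutation tests.

`detectErrors()` re-derives the error column from the pitch stream alone
assuming substitution errors (the stream stays in phase with the pattern
cycle).  This matches the generator's corruption model exactly; insertion
and omission errors would require sequence alignment and are out of scope.

# Resampling statistics

For paired across-subject comparisons (`pairedPermutationTest()`) the test
statistic is the difference in sample means and the null is built by random
sign flips of the per-subject differences -- the canonical permutation
scheme for paired data, where exchanging a subject's two condition labels
flips the sign of that subject's difference.  p-values are the plain
proportion of rearrangements whose statistic is at least as extreme in
absolute value (so identical inputs give p = 1, and the smallest attainable
p is 1/n with n rearrangements; an optional `addOne` flag applies the
(1+b)/(1+B) correction for reports that must avoid literal zeros).  The
default 5000 rearrangements match the behavioral analysis constants; the
effect size PS\_dep = Pr(X\_B > X\_A) over matched pairs accompanies every
test, with ties counted as 0.5 so that PS\_dep(x, x) = 0.5 and swapping
conditions maps PS\_dep to 1 − PS\_dep.

The **2x2 synchronized-rearrangement factorial**
(`factorialPermutationTest()`) represents each effect by its orthogonal
per-subject contrast (main effects: half-difference of cell means;
interaction: the double difference) and sign-flips each contrast across
subjects, synchronously within subject.  For a balanced within-subject
design every contrast is symmetric about zero under its own null, so the
sign-flip distribution is exact and the three tests are mutually orthogonal.
The literature contains several synchronized-rearrangement constructions
(they differ mainly for unbalanced designs); the orthogonal-contrast scheme
is this package's choice and is validated by null calibration (uniform
p-values, correct type-I rate) rather than by reference to one variant.

**Two-stage adaptive FDR** (`fdrTwoStage()`): stage one runs the linear
step-up procedure at q/(1+q); the rejection count r1 estimates the number of
true nulls as m0 = m − r1; stage two re-runs the step-up at (q/(1+q))·m/m0.
The reported corrected threshold p-value is the largest rejected p-value and
is 0 when nothing is rejected -- the same convention used in the
per-segment source tables, where 0 entries mean "no rejection", not
"threshold at zero".

# Event-related fields

The ERF chain is: band-pass filter, matched-control selection, epoching
(−1 to 1 s around the latency-corrected keystroke), baseline correction
(−200 to −100 ms), condition averaging, planar combination.

* **Filter.**  The 1-100 Hz zero-phase band-pass is realized as a 4th-order
  Butterworth applied forward and backward (`signal::filtfilt`).  A
  linear-phase FIR at these band edges and a 1 kHz rate needs thousands of
  taps; the forward-backward IIR gives zero phase with negligible passband
  ripple at a fraction of the cost, and the tests verify passband gain,
  DC removal and >= 20 dB stopband attenuation directly.
* **Matched controls** (`selectMatchedControls()`).  NF events are selected
  per positional class to match the AF event count, excluding error
  keystrokes and NF keystrokes at +1/+2 after an AF event.  Matching is
  greedy nearest-neighbour without replacement on z-scored (preceding IOI,
  keystroke velocity); a covariate-balance warning fires when a selected
  set drifts more than 0.25 pooled standard deviations from the AF means.
  Greedy matching is not optimal, but on random instances its total
  distance is within a few percent of the optimal assignment (tested), and
  it is deterministic.
* **Planar combination** (`combinePlanar()`).  The two orthogonal gradient
  channels at a position are combined as sqrt(h^2 + v^2) (scheme `"norm"`,
  the standard combined-planar magnitude; `"rms"` divides by sqrt(2)).
  Because the combination is nonlinear, order matters: the pipeline
  averages ERFs per condition first and combines afterwards, matching the
  stated order of the analysis chain it reproduces (ERF estimation, then
  combination).  Combined values are non-negative, but condition
  *contrasts* of combined values are signed, so cluster statistics keep
  both tails.

# Cluster-based permutation statistics

`clusterPermutationTest()` implements the max-cluster-mass permutation test
on the paired t-map over sensor positions x time samples within the
0.15-0.37 s analysis window: suprathreshold points (|t| above the two-tailed
paired-t critical value at alpha = 0.05, df = n−1 -- the conventional
default, stated explicitly here because it is a genuine tuning constant)
are grouped into connected components of the spatial-adjacency x
consecutive-samples graph, separately per sign; the null distribution of
the maximum cluster mass per sign is built from per-subject condition swaps
(sign flips), and each observed cluster is significant when its p-value is
below 0.025 for its tail (two-sided family-wise control at 0.05).  Cluster
*mass* (summed t) rather than cluster size is the cluster statistic, as in
the cited method's default.  The peri-keystroke window (−0.2 to 0.15 s) is
exposed as `sanityWindowTest()`: effects of interest live after 0.15 s, so
this window acts as a negative control.

Windows are half-open, [start, end), throughout the package; this makes the
four 55-ms source segments tile 0.15-0.37 s exactly with no shared samples.

# Minimum-norm source estimation

`buildInverse()` computes the L2 minimum-norm inverse
M = R L' (L R L' + lambda^2 C)^-1 with identity source covariance R (depth
weighting, R = diag(1/||L_g||^2), is available behind `depthWeight =
TRUE`).  The noise covariance C is the sample covariance of the silent
pre-trial intervals with diagonal loading epsilon·trace(C)/n (epsilon =
1e-3).  The default regularization follows the SNR rule lambda^2 =
trace(L L')/(trace(C)·snr^2) with snr = 3, exposed and configurable; the
analysis it reproduces reports insensitivity to the exact value, and the
monotonicity of the solution norm in lambda is a tested invariant.  At
lambda = 0 with a rank-deficient Gram matrix the Moore-Penrose
pseudoinverse is used (and logged), which yields the classical minimum-norm
solution on the row space of the leadfield.

The **toy forward model** (`generateForward()`) places grid points in a slab
under the sensor plane; channel sensitivity falls off as a Gaussian kernel
of distance, and the h/v split follows a smooth orientation field, so
neighbouring grid points have similar columns and no point is invisible.
Leadfield columns are unit-normalized by default (`columnNorm = "unit"`).
This is a deliberate identifiability choice: with raw distance-dependent
column norms, the unweighted minimum-norm estimate systematically
mislocalizes toward well-seen grid points -- the same depth bias that makes
depth weighting standard practice on real leadfields -- and closed-loop
localization tests would measure that bias rather than the inverse's
correctness.  Norm-balancing the toy columns (or equivalently enabling
depth weighting) makes the planted-source peak land in the planted point's
grid neighbourhood in well over 80% of runs at the documented noise level
(5% of the peak sensor signal); the package tests use 25 sensor pairs and
an 80-point grid.

Per-segment condition contrasts (`segmentContrastTest()`) average source
currents over the four 55-ms segments, run the paired sign-flip test at
every grid point (one synchronized flip vector per rearrangement, shared
across grid points), and control the FDR across grid points within each
segment with the two-stage procedure.  `regionReport()` summarizes the
masks over the region partition: the "area of significant activation" is
the percentage of a region's grid points in the mask; regions reach the
report when the area is at least 10% (inclusive -- exactly 10.0% is
reported) in some segment, each qualifying segment is listed with the sign
of the mean difference over its significant points ("S1(+), S3(-)" for
reversing effects), and the activation strength is the mean *signed*
current difference over those points, so negative strengths are possible
and meaningful.  Segment means rather than pointwise samples are tested,
matching the "average source current distribution for each segment"
formulation.  Absolute current units on the toy model are nominal; no
absolute amplitude is an acceptance surface.

# Pipeline and reproducibility

`runAll()` chains simulate, behavior, ERF, cluster and source stages and
returns (optionally writes) the full report: per-subject condition tables,
factorial and pairwise test summaries with PS\_dep, a sensor-space 2x2
factorial with two-stage-FDR corrected thresholds over the analysis
window, cluster tables for the four condition contrasts plus their
peri-keystroke sanity checks, the per-segment corrected-threshold table and
the region reports.  Every source of randomness derives from two integer
seeds (the simulation seed in the config, the analysis seed in the
settings) through fixed per-stage offsets, so any stage can be re-run in
isolation and two identical invocations produce byte-identical artifacts.
Serialization is plain text (TSV/CSV for tables and matrices, JSON for
metadata and results, YAML for configurations) with 17-significant-digit
numerics, so write-read round trips are exact.

## Problem sizes used by the shipped checks

The package's acceptance-style checks run at deliberately reduced,
documented sizes chosen so the full suite completes on a single CPU while
keeping every Monte-Carlo margin comfortable: null calibration uses 1000
simulated datasets of 20 subjects with 500 rearrangements; family-wise
error control uses a 20-position x 50-sample grid, 10 subjects, 200
permutations and 300 null simulations; behavioral effect recovery uses 100
experiments of 20 subjects playing one 15-trial block with the planted
50 ms boundary slowing and +0.015 error boost; evoked-contrast recovery
uses 100 runs of 8 subjects, one 8-trial block at 200 Hz with a planted
frontal 0.15-0.205 s template, skipping the band-pass stage (the planted
template and the AR(1) noise both live inside the passband, and the filter
has its own dedicated tests).  The inverse-solution checks use 25 sensor
pairs and 80 grid points.

# Known limitations

* The generator's error model is substitution-only; `detectErrors()`
  inherits that assumption.
* Combined-planar inputs are non-negative magnitudes; subtle effects that
  only rotate the field orientation without changing magnitude are
  invisible to the combined representation.
* The factorial scheme's exactness argument assumes a balanced
  within-subject design; unbalanced designs are rejected rather than
  approximated.
* The toy forward model supports closed-loop inverse validation, not
  physiological interpretation; region labels are arbitrary partitions of
  the grid.
* Monte-Carlo p-values have resolution 1/n rearrangements; reported zeros
  mean "below resolution", and the corrected-threshold convention reports
  0 both when nothing is rejected and when every rejected p is exactly at
  the resolution floor.

# A minimal worked run

```{r runall, eval = FALSE}
cfg <- simulationConfig(
  nSubjects = 6, sequencePatterns = defaultSequencePatterns()[1:2],
  trialsPerBlock = 8, afFreeTrials = c(1, 5), sfreq = 200,
  erfEffects = defaultErfEffects(), seed = 1
)
settings <- runSettings(nRearrangements = 1000, clusterIterations = 250,
                        band = c(1, 90), nPairs = 16, nGrid = 80, seed = 1)
report <- runAll(cfg, settings, outDir = "afmeg-report")
report$behavior$factorial$dIOI
report$cluster$main[["AF-Bo_vs_NF-Bo"]]$clusters
report$source$pThrTable
```
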