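---
title: "Methods: validating surface-recorded single units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating surface-recorded single units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surfspike)
```

`surfspike` implements the statistical validation of putative single-unit
activity (SUA) recorded from the brain surface with a micro-ECoG grid,
against simultaneous penetrating-probe recordings, under auditory
stimulation. This vignette is the package's account of the models it
uses, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design choices made where the design was
genuinely open. No empirical claim is made here beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The analysis model

### Waveform conventions

Extracellular spikes are biphasic. We follow the convention that the
**peak** is the waveform *minimum* (the initial depolarization) and the
**trough** is the *maximum occurring strictly after* the peak, with ties
broken by the earliest index. From a unit's average waveform we take:
duration = peak-to-trough interval (s); amplitude = overall max − min
(µV); trough/peak = ratio of the two extreme values (negative for
canonical spikes); symmetry = Pearson correlation of the mean-removed
waveform with its time-reversal, which is 1 for an even-symmetric shape
and negative for strongly skewed ones. Waveforms that are monotone (no
interior minimum) have undefined features and raise an error; features
are invariant to voltage offsets and equivariant under positive scaling,
and the tests assert both.

### Burst classification: the void parameter

The log₁₀-ISI density captures spike timing across short (intra-burst)
and long (inter-burst) scales. We histogram log₁₀(ISI) over
[−3.5, 1.5] decades (0.3 ms to ~32 s) at 10 bins/decade, smooth with a
3-point boxcar, and renormalize to sum to 1. Peaks are local maxima with
topographic prominence at least 5% of the maximum density; given the two
most prominent peaks, the void parameter is
`1 − g(min)/sqrt(g(peak1) · g(peak2))`, with `g(min)` the density minimum
strictly between them. A unit is bursting when the void parameter is
defined and ≥ 0.7 — the threshold conventional in the ISI-characterization
literature, exposed as an argument. Units with fewer than 20 ISIs, or a
unimodal density, are non-bursting by convention. All binning and
smoothing parameters are arguments; the defaults above are what the test
suite exercises.

### Pair analysis

Cross-correlograms count spike pairs of a depth unit *x* and surface unit
*y* with `t_y − t_x` falling in half-open 5 ms bins over [−100, 100) ms,
so positive lags mean the surface unit fired after the depth unit. Counts
are raw co-occurrences (not rate-normalized). The peak lag is the centre
of the maximal bin; ties break toward the smallest |lag|, negative before
positive, making the statistic deterministic. Analysis periods
(baseline-only versus baseline + stimulus) are an argument; the default
uses the whole record.

SPIKE-distance is the parameter-free, time-resolved dissimilarity built
from previous/following spike-time differences normalized by the local
mean ISIs, time-averaged over the observation interval, with auxiliary
spikes at the interval edges. Because the dissimilarity profile is linear
between consecutive spike events, the package integrates it *exactly*
segment by segment; the test suite checks this implementation against an
independent dense-grid (0.1 ms, trapezoid) evaluation to 10⁻³. Edge
conventions: a pair of empty trains has distance 0; exactly one empty
train gives 1. These keep the statistic defined and bounded on degenerate
input.

Physical distance is the 3D Euclidean distance between electrode
positions (µm). Depth-site z-coordinates are
`insertion_depth + site_index × site_spacing`; the insertion depth is a
geometry argument with a 600 µm default, consistent with closest
surface–depth SUA pairs being at least 600 µm apart. The surface grid
default is 8 × 4 contacts at 200 µm pitch (the exact grid layout of the
32 contacts is configuration-driven).

`pair_table()` emits one record per (depth SUA, surface SUA) pair and the
Pearson correlation of SPIKE-distance versus physical distance across
pairs — the population-level signature that nearby pairs are more
synchronous. With fewer than 3 pairs or zero variance the correlation is
undefined and flagged rather than fabricated.

### Stimulus-evoked response

Spike counts are taken in 5 ms bins around each stimulus onset (window
−200 ms to +300 ms), averaged across trials, and smoothed with a centred
5-tap moving average whose window shrinks at the edges (constants pass
through unchanged). "5th order moving average" is read as a 5-tap filter;
a different tap count is an argument and shifts results by at most one
bin. The stimulus amplitude envelope is the magnitude of the analytic
signal (frequency-domain Hilbert transform), zero-phase low-pass filtered
and evaluated on the 200 Hz grid shared with the binned counts. The
low-pass cutoff before resampling is not fixed by the protocol; the
default is 50 Hz, below the 100 Hz target Nyquist, and is an argument.

The response lag is the lag of maximal |cross-correlation| between the
smoothed average count and the envelope, searched on the 5 ms grid over
[0, 200) ms with no sub-bin interpolation; the envelope is then shifted
forward by this lag. The onset-window Pearson correlation between the
smoothed average and the shifted envelope is Bonferroni-corrected with
family size = (number of analysed units) × (number of stimuli per run) —
the most conservative reading of per-run testing, and an argument — and
deemed significant when corrected p ≤ 0.01.

**Calibration of the correlation p-value.** The correlated series is
smoothed, so its samples are serially dependent and the textbook t test
on r is anti-conservative by roughly the smoothing bandwidth. The package
therefore computes the p-value with an effective sample size (the
Pyper–Peterman cross-correlation adjustment), estimating the noise
autocorrelation from the residuals after regressing the count series on
the envelope — using residuals prevents a strong genuine response from
inflating its own penalty. The naive test is available via
`autocorr_adjust = FALSE`. The adjustment is approximate: over 200
simulated unmodulated units the flagged fraction stays within binomial
error of the corrected nominal level (the acceptance suite computes
this), but the far tail of the null p-distribution remains slightly
heavy. Exact calibration would require a permutation scheme, which the
protocol this mirrors does not use.

The effect size is `(mu_peak − mu_base)/sigma_base` on 5 ms counts:
`mu_peak` over ±50 ms about the peak response (the centre of the maximal
smoothed-average bin in [onset, onset + 300 ms], earliest on ties),
`mu_base` and `sigma_base` over the 1 s pre-stimulus baseline.
`sigma_base` uses population (n) normalization over the 200 baseline
bins; with n = 200 the distinction from n−1 is negligible but fixing it
makes results bit-reproducible.

### Group statistics

Feature comparisons use the two-sided Wilcoxon rank-sum test: exact
enumeration when the smaller group has ≤ 8 observations and no ties,
otherwise the tie-corrected normal approximation *with* continuity
correction — the corrected approximation agrees with exact enumeration to
about 0.01 at n = m = 8, whereas without the correction the discrepancy
reaches ~0.05. Bursting fractions are compared with the Pearson
chi-square test on the 2 × 2 contingency table *without* Yates
correction: on the printed surface/depth bursting table ([[14, 9],
[34, 12]]) the uncorrected statistic is χ² = 1.232 (df = 1), p ≈ 0.267 →
0.27 at two decimals, matching the reported value, while the corrected
one does not. Summary tables report both means and medians for every
feature, since a single central tendency is not otherwise pinned down,
and format bursting fractions as `"k/n = p%"` with percentages at 0
decimals and p-values at two significant figures.

## The synthetic-session generator

The generator stands in for raw recordings that are not publicly
deposited. It emulates the statistical structure the analysis assumes;
its defaults are the study conditions, not tuning knobs.

**Trial schedule.** 54 stimulus presentations by default, with
inter-stimulus silences drawn Uniform(7, 15) s. (One part of the source
protocol states 7–15 s, another 7–12 s; the generator follows the
Methods-style 7–15 s and both are reachable through `session_config()`.)

**Stimulus envelope.** A song-like motif of raised-cosine-gated
syllables on a 200 Hz grid. When seeded, per-syllable amplitudes vary
(0.6–1) and each syllable/gap duration is jittered by ±40%, making the
motif aperiodic. Aperiodicity matters: a strictly regular syllable/gap
train is anti-correlated with itself at half the syllable period, so the
peak-|cross-correlation| lag estimator would tie between the true lag and
true + half-period. Real song has no such symmetry.

**Firing model.** Non-bursting units are inhomogeneous Poisson with
intensity `baseline_rate · D(t) + stimulus_gain · envelope(t − lag)`,
where D(t) is the shared drive described below (mean 1). Bursting units
emit Poisson burst *onsets* at `burst_rate · D(t) + gain/2 · envelope`
with `1 + Geometric(0.5)` spikes per burst at ~3 ms intra-burst
intervals jittered ±20% — this plants the bimodal log-ISI structure the
void parameter detects. Sampling is exact for the piecewise-constant
intensity: per-bin Poisson counts on the 200 Hz grid with uniform
placement within bins (equivalent in distribution to thinning, and
robust to the heavy-tailed intensities the drive produces). The planted
neural lag defaults to 50 ms; spike trains are strictly increasing and
bit-reproducible: per-unit RNG streams are derived from the session seed
by stable hashing of the unit id, so editing the population does not
perturb other units' spikes.

**Distance-decaying synchrony.** One latent Ornstein–Uhlenbeck modulator
per spatial cluster (one cluster per electrode site), time constant
100 ms — slow, correlated ongoing fluctuations of the kind urethane
anesthesia produces. Each unit mixes the cluster modulators with weights
`exp(−d/300 µm)`, normalized to unit variance, and the mixed modulator
enters as a mean-preserving log-normal factor `exp(σ·m(t) − σ²/2)` on the
*baseline* intensity. Consequently the drive correlation — and the
spike-train synchrony — of a unit pair decays with the physical distance
between their electrodes, while stimulus-evoked responses stay reliable
across trials. The modulation depth σ defaults to 2.5. This value was
calibrated against the generator's own purpose: SPIKE-distance is largely
invariant to shared slow rate modulation (it normalizes by local ISIs),
so at σ ≈ 1 the emergent correlation between SPIKE-distance and electrode
distance across surface–depth pairs is an order of magnitude weaker than
the ~0.3 reported for real surface/depth populations; σ = 2.5 reproduces
an emergent correlation of ~0.3 at the default population size (12
surface × 11 depth ≈ 130 pairs, matching the scale of the real pair
population). A side effect worth knowing: with the drive on, *ongoing*
activity itself is bursty, so classified bursting fractions exceed the
planted per-unit bursting flags; the burst-classification checks
therefore use controlled homogeneous and burst trains.

**Waveforms.** A difference-of-Gaussians template (narrow negative lobe,
broader positive lobe at `duration` separation) whose extrema are matched
to the requested peak/trough amplitudes by a short fixed-point iteration,
rendered at the session sample rate (30 kHz default; 20 kHz supported)
and averaged over 50 noisy snippets (5 µV i.i.d. noise per sample by
default). Group targets for duration, amplitude, trough/peak, rate and
bursting probability are the surface/depth central tendencies of the
characterization table (`group_feature_targets()`); per-unit parameters are
log-normal around them so sample medians converge to the targets, which
the tests verify within 20% at n = 200 per group.

**What the generator does not emulate.** Continuous voltage traces (only
snippet-level waveforms), spike-sorting errors and unit contamination,
cell-type diversity beyond the two statistical groups, non-stationarity
across a session, adaptation or context-dependent auditory responses
beyond the onset, and overlapping-spike artifacts. Passing tests
therefore demonstrate that the *analysis* recovers planted structure
under realistic point-process statistics — not that it would be robust to
sorting artifacts or drifting recordings.

## Signal conditioning

High-pass filtering is zero-phase: a 3rd-order Butterworth (300 Hz
default) applied forward and backward. Edges use odd-reflection padding
with steady-state filter initialization (the padded record is treated as
if it had sat at its first value forever); the pad scales with the
slowest corner frequency (25 cycles), so DC rejection and time-reversal
symmetry hold to numerical precision — both are asserted in tests.
Stimulus onsets are detected from the 1–5 kHz sync tone by band-pass
filtering, rectification, and thresholding at 0.5 × the 95th percentile
of the rectified magnitude (robust to amplitude scaling), one detection
per burst under a 1 s refractory. This threshold presumes tone bursts
occupy a nontrivial fraction of the record, as they do in the recording
protocol; for very sparse bursts (< 5% duty) the percentile falls in
silence and the threshold degenerates. Envelope resampling evaluates the
already zero-phase-band-limited magnitude directly on the 200 Hz grid —
delay-free by construction, which polyphase resampling of this signal is
not.

## Problem sizes in the test and acceptance suites

Simulation-based checks use: planted-lag recovery at 50 trials × 10 seeds
per lag in {0, 25, 50, 100} ms with a 2 Hz baseline and high (40 Hz)
gain; type-I control over one 200-unit unmodulated session at default
trial count; effect-size monotonicity over planted gains {0, 1, 2, 4} ×
baseline with 30-trial sessions, 20 paired seeds; distance–synchrony sign
recovery over 20 default sessions of 12 + 11 units; burst classification
over 40 seeds each of 1000-spike homogeneous and burst trains. These
sizes are the package's choices for a thorough yet quick default run
(the full suite takes about two minutes).

## Known limitations

- The onset-window p-value calibration is approximate in the far tail
  (see above); family-wise control relies on the conservative Bonferroni
  family.
- The void-parameter peak detection is sensitive to its smoothing and
  prominence settings on marginal densities; both are exposed, and the
  defaults are validated only under the test conditions.
- SPIKE-distance on very sparse trains is dominated by the edge-spike
  convention; pairs where one train is empty return exactly 1.
- Session I/O is plain CSV (`write_session()`/`read_session()`); no HDF5
  container is written.
- The rank-sum/chi-square table mirrors a fixed report layout; it is not
  a general-purpose statistics interface.
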