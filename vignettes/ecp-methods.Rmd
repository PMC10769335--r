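---
title: "Models and methods behind ecptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecptools)
```

This vignette is the package's own account of its methods: the artifact
model and removal algorithm, the chemometric model for dopamine estimation,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one reasonable option
existed.

## The problem

Fast-scan cyclic voltammetry (FSCV) applies a triangular voltage sweep
(−0.4 V → 1.3 V → −0.4 V at 400 V/s, i.e., 8.5 ms) to a carbon-fiber
electrode ten times per second, holding −0.4 V in between to accumulate
dopamine at the surface. When electrophysiology (EPhys) electrodes record
nearby, each sweep couples into them as a millivolt-scale transient. After
the 250 Hz high-pass used for spike detection, these transients look enough
like action potentials to contaminate any sorted unit. Because coupling
depends on inter-electrode distance and electrode impedance, the artifact's
shape varies from channel to channel and session to session — which is why
the package removes artifacts by *when* they occur (their periodicity)
rather than by *what* they look like (template subtraction).

## Scan-artifact removal

`detect_scan_artifacts()` → `enforce_periodicity()` →
`interpolate_segments()`, composed by `clean_recording()`:

1. Channels are averaged; artifacts are coherent across electrodes while
   spikes and low-frequency fluctuations average away.
2. The average is band-pass filtered at 10–100 Hz and rectified. The
   detection filter is an order-2 Butterworth applied forward–backward
   (4 poles, zero phase) so that detected peak times carry no group delay;
   the *data* path is never filtered.
3. Peaks are threshold crossings at `threshold_mult = 1.75` × the SD of the
   rectified signal, each refined to the first local maximum that follows.
4. Only peaks periodic at `scan_rate_hz = 10` survive: walking the peak
   list, a peak is retained when its spacing to the previous retained peak
   is within `period_tolerance_ms = 5` of a whole number of periods;
   retained gaps of k periods receive k−1 inserted peaks at the predicted
   times, each refined to the local maximum of the detection signal within
   ± tolerance (the prediction is kept unrefined if the maximum sits on the
   search-window edge). Insertion is what catches artifacts that dipped
   below the detection threshold.
5. Each channel is linearly interpolated across
   [peak − 5 ms, peak + 7 ms]; overlapping windows are merged first, edge
   windows are clamped, and a window that loses one boundary sample to the
   record edge is filled with the surviving boundary's value.

**Why −5..+7 ms.** The window must cover the 8.5 ms scan plus amplifier
recovery and tissue low-pass broadening; the asymmetric 12 ms window does,
and it makes the arithmetic exact: at 10 scans/s, 12 ms per scan is 12% of
the record. (With windows closed on both ends in sample space the measured
fraction is 12.03% — one extra sample per window.)

**The periodicity-evidence guard.** On an artifact-free record the
rectified 10–100 Hz noise still crosses a 1.75 × SD threshold constantly,
and near-10 Hz subsequences of random peaks always exist; naively inserting
into their "gaps" would interpolate 12% of a clean recording. Two checks
prevent that: the retained peaks must amount to at least
`min_evidence_frac = 0.5` of the expected scan count, and a linear fit of
retained peak times against the cumulative period index must leave an RMS
residual below a quarter of the tolerance. Genuine scans are phase-locked
to a (possibly slowly drifting) grid and pass easily; chains assembled from
noise random-walk in phase and fail. Both checks run before any insertion,
and an empty event list means not a single sample is touched.

**The 60 Hz variant** (`remove_line_harmonics()`) replaces the band-pass
with a 300 Hz high-pass — line interference on a shared ground is typically
non-sinusoidal, with harmonics well above 300 Hz — and thresholds at
`threshold_mult_mean = 8` × the rectified signal's mean rather than its SD
(on a high-passed trace the mean of the rectified signal is a more stable
noise-floor estimate than the SD, which the artifact spikes themselves
inflate). Rectification is applied as in the scan variant, treating bipolar
noise symmetrically. Periodicity is enforced at 1/60 s with a 1 ms
tolerance and interpolation spans ±0.5 ms.

## Spike extraction

The data path is a 4-pole Butterworth high-pass at 250 Hz applied causally
(forward only): its group delay is common to all events, so relative spike
timing is preserved, and causality means the output at time *t* depends
only on samples up to *t* (verified by a truncation-equivalence test).
Detection thresholds at −4 × a robust SD (median absolute amplitude /
0.6745, insensitive to the spikes themselves), requires
`min_width_samples = 3` consecutive sub-threshold samples (a 0.1 ms width
criterion that rejects single-sample noise excursions), aligns each event
to the trough within 1 ms after the crossing, and then locks out detection
for `dead_time_ms = 2` — covering the 1.6 ms extraction window and the
causal filter's rebound undershoot, which would otherwise re-trigger on the
same spike. Waveforms are 48 samples with 8 prethreshold samples
(1.6 ms / 0.267 ms at 30 kHz).

Events are invalidated when their energy or nonlinear (Teager) energy
exceeds the median by 5 × IQR — an automated stand-in for the manual
prominence-based rejection of electrostatic and pump glitches, whose exact
manual criteria are not quantifiable — or when they fall within ±1 ms of a
known artifact time. Principal components are recomputed on the surviving
events and k-means clusters them in PC1–PC2, with k ∈ 1..4 chosen by mean
silhouette (k = 1 unless some k ≥ 2 reaches 0.5). Residual artifact events
that escape both rules — e.g., switching-transient remnants just outside
the interpolation window — segregate into their own cluster and betray
themselves by firing at exactly the scan rate with all ISI mass at the scan
period; the README's worked example shows one.

Cell types are assigned heuristically from the qualitative physiology of
the striatum: a unit is a putative TAN (tonically active neuron) if its
mean rate is 2–12 Hz and its trough-to-peak width exceeds 0.4 ms, a
putative MSN (medium spiny neuron) if its rate is below 1 Hz and more than
10% of its ISIs are shorter than 10 ms (sparse but bursty), and `other`
otherwise. These thresholds are heuristics, not fitted values.

## Dopamine chemometrics

Each scan's voltammogram is background-subtracted at a reference scan
(usually an alignment event, giving all trials a common baseline) and
projected onto an orthonormal basis built from standards: the leading
singular direction of each analyte class (dopamine, pH, movement artifact),
orthonormalized in that order, plus pooled components until ≥ 99% of
training variance is captured. ΔDA in nM is the dopamine score times a
calibration slope fitted by least squares through the origin against known
concentrations. Two nulling rules mark scans as missing rather than
reporting a value: residual variance outside the subspace above Q_α (the
95th percentile of training residuals by default — the tolerance itself is
a free parameter in the literature), and Pearson correlation above 0.8 with
the movement template. The movement template stored for screening is the
class's denoised singular direction, not a raw training-row mean, whose own
noise would cap the attainable correlation. Nulled scans propagate as `NA`
through trial averaging: they leave the mean's denominator instead of being
zero-filled.

One bookkeeping subtlety: background subtraction differences two noisy
frames, doubling the noise variance relative to a single frame. Training
standards must therefore carry at least √2 × the stream's per-frame noise
for Q_α to be calibrated correctly; the generator defaults (0.05 nA
standards, 0.02 nA stream frames) respect this.

## The synthetic-data generator

The generator defines the study conditions for every property test and for
the acceptance script; its defaults are fixed choices, not tuning knobs.

**Cells.** MSN: 0.5 Hz baseline, brief high-frequency bursts (30 ms at
200 × baseline, 150 ms after each event — ~100 Hz instantaneous, keeping
the overall rate under 1 Hz while pushing the burst index past 0.1); narrow
biphasic waveform (0.25 ms trough-to-peak). TAN: 5 Hz baseline, cue-locked
pause (200 ms at 2% of baseline) followed by a 2 × rebound; broad waveform
(0.5 ms, twice the MSN width, echoing the longer after-hyperpolarization of
tonically active neurons). Spike trains are inhomogeneous-Poisson by
thinning with 1 ms refractory censoring. Waveform templates are
trough-normalized, 1.6 ms long, and cosine-tapered to zero over their final
0.3 ms — a truncated positive lobe would otherwise ring through the causal
high-pass as a spurious deep trough. The default trough amplitude is
300 µV: the causal 250 Hz high-pass attenuates the broad TAN trough by
roughly half, and 300 µV keeps both cell types in the filtered-band
SNR ≥ 8 regime that a sortable, well-isolated unit presumes.

**Noise.** White (15 µV SD) plus spectrally shaped 1/f (10 µV SD) per
channel, with optional 60 Hz line interference (sine or broadband sawtooth)
at a common phase across channels. These magnitudes are plausible
extracellular background; no published values exist for this preparation.

**Artifacts.** Three morphologies, all anchored at the scan onset and
repeated at the scan rate from `phase_s`:

* **R** (resistive): a symmetric triangular pulse spanning the 8.5 ms scan
  — a scaled copy of the applied ramp.
* **RC**: the same pulse convolved with a normalized exponential
  (`rc_tau = 4` ms, kernel truncated at 4τ, support ≈ 24.5 ms), plus brief
  charge-injection switching transients at the scan boundaries, modeled as
  damped 800 Hz oscillations (τ = 0.8 ms) at 30% of the pulse amplitude.
* **RAIL**: the pulse scaled past the ±1 mV input range and clipped, with
  the same switching transients, followed by an underdamped
  amplifier-recovery segment (−0.6 × clip level, 800 Hz ringing decaying
  with `recovery_tau = 2.5` ms, truncated at 6.5τ; support ≈ 24.8 ms). At
  injection the artifact-plus-signal sum is re-clipped, as a saturating
  amplifier would.

The smooth components alone would make all three kinds equally recoverable:
anything slow is erased by the spike path's 250 Hz high-pass, and the
12 ms interpolation window removes the rest. The reported recovery deficits
for RC and rail artifacts imply structure that is both *fast* (surviving
the high-pass) and *outside* the window — which is exactly what switching
transients and recovery ringing are. Their amplitudes and time constants
were fixed from that reasoning; recovery itself is always computed
end-to-end, never assumed. Within-kind scan-to-scan shape variability and
electrode drift are *not* modeled, nor are spike-train correlations between
units; passing recovery tests on this generator therefore demonstrates the
algorithm's behavior under idealized periodic artifacts, not performance on
every in vivo pathology.

**CV streams.** Each 850-point frame (8.5 ms at an assumed 100 kHz
within-scan digitization) is a smooth non-faradaic background plus scaled
analyte shapes plus current noise. The dopamine shape has its oxidation
peak near +0.6 V on the anodic sweep and reduction trough near −0.2 V on
the cathodic sweep; sensitivity defaults to 0.02 nA peak current per nM.
Dopamine transients step up at onset and decay exponentially; movement
bouts use the movement shape at realistic (large) magnitudes.

**Behavioral trials.** Central cue, peripheral target after a 1.6 s
fixation, reward 4 s after the target; the direction↔reward-size mapping
switches every 20–30 trials (uniform), and target direction is drawn
per trial.

All draws descend from one master seed through a deterministic
Park–Miller-style splitting function (`split_seed()`), so identical seeds
give bit-identical outputs.

## Validation harness

`run_validation()` follows the published design: reference spikes are
sorted from the clean recording (a ground-truth mode exists for synthetic
inputs), artifacts are injected, the record is cleaned and re-sorted, and
recovery is the percentage of reference spikes matched within
`tol_ms = 0.5` (below typical ISIs, above alignment jitter) by greedy
one-to-one nearest matching — chosen over optimal assignment for
transparency, with a brute-force assignment oracle verifying equality on
small instances in the tests. Recovery is monotone non-increasing in window
width, 100% when nothing is injected and detection stays silent, and
deterministic given seeds.

## Numerical conventions and degenerate inputs

Times are seconds from `t0`; sample indices are 1-based in R; interpolation
windows are closed on both ends in sample space. Zero-variance input yields
an empty event list; fewer than two raw peaks skips periodicity enforcement
with a warning; records shorter than three periods are rejected; waveform
windows that would cross a record edge are skipped and logged; conditions
with fewer than two trials are excluded from averages with a warning.
Detection-path filtering is zero-phase, data-path filtering causal, and the
cleaned output is bit-identical to the input outside merged interpolation
windows.

## Problem sizes

The test suite exercises 5–60 s recordings at 30 kHz; the acceptance script
uses a 60 s, 5-channel recording for detection completeness, a 240 s
2-channel recording (~2 400 reference spikes per artifact kind) for
recovery, and 100 seeded runs for cell-type classification. These sizes put
binomial standard errors well below the margins being tested while keeping
a full run in minutes on one core.

## Known limitations

* Artifact removal assumes ≥ 1 coherent channel and strict scan
  periodicity; aperiodic glitches are out of scope (they are exactly what
  the periodicity rule protects against removing).
* Spikes that fall inside an interpolation window are unrecoverable by
  construction; the ~12% budget is the floor on spike loss at 10 Hz scans.
* The cell-type rule is a two-feature heuristic; it will call a
  scan-locked residual cluster "TAN" if one survives sorting — the ISI
  histogram (mass at the scan period) is the intended tiebreaker.
* Q_α and the retained component count depend on the standards provided;
  the chemometric module distinguishes only the analytes it was trained on
  and cannot separate molecules with near-identical voltammograms.
* The generator's artifact amplitudes and fast-component parameters are
  fixed design choices anchored to reported recovery behavior, not
  measurements of any particular rig.
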