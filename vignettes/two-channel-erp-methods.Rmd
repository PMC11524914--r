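---
title: "Methods: two-channel prefrontal ERP analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-channel prefrontal ERP analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erp2ch)
```

## Scope

`erp2ch` analyses event-related potentials (ERPs) recorded from just two
prefrontal electrodes (Fp1, Fp2) during an active auditory oddball task:
256 frequent standard tones and 64 rare target tones (4:1) at a 1000 ms
onset asynchrony, 50 ms tone duration, 250 Hz sampling, a 1 s lead-in —
a 5 min 21 s session.  With two channels, the usual multichannel EEG
machinery (ICA artifact correction, average re-referencing, channel
interpolation, source models) is unavailable; the pipeline therefore
leans on stimulus-locked averaging, variability measures, and the
*inter-channel* relationship between the left and right prefrontal
signals.

The package has two halves that validate each other:

* an **analysis pipeline**: preprocessing, N100/P200/P300 component
  extraction, single-trial P300 variability, behavioral measures,
  phase-locking value (PLV) and magnitude-squared coherence (COH)
  connectivity, ERSP/ITC time-frequency maps with permutation
  significance, time-trial maps, and covariate-adjusted group
  statistics;
* a **synthetic session generator** that produces two-channel oddball
  recordings with known ground truth for every quantity the pipeline
  estimates.

## Preprocessing

The continuous recording is band-passed 0.1–30 Hz with a Hamming-window
linear-phase FIR applied with group-delay compensation (zero net delay).
The default order is `8 * fs` (2001 taps at 250 Hz): long enough that
the 0.1 Hz edge has a feasible transition band, and applied on the
continuous signal *before* epoching so no per-epoch edge artifacts are
introduced.  Epochs span −200..800 ms around each onset (half-open;
sample *k* sits at −200 + 4*k* ms), giving 250 samples: the analysis
range of interest ends at 700 ms and the extra tail gives margin for the
P300 window and time-frequency edges.  Baseline correction subtracts the
−200..0 ms mean per epoch and channel.

Artifact screening is an automated amplitude criterion: any epoch
exceeding ±100 µV on either channel is dropped (an error is raised if
nothing survives — the participant is excluded).  Standard epochs are
then randomly subsampled to 64, the target count, so that
trial-count-sensitive measures (variability statistics, PLV, coherence)
are computed from the same number of epochs in both conditions; the
selection is seeded and order-preserving.

## Components and behavior

Component search windows are 60–200 ms (N100, negative), 180–300 ms
(P200, positive) and 300–600 ms (P300, positive).  A component is the
largest strict local extremum of the appropriate sign inside its window;
peaks below 2 µV in magnitude, or lying on a window boundary, are not
accepted (ties resolve to the earliest latency).  Absence is a value,
not an error: analysis proceeds when the P300 is missing but N100 or
P200 are present, which is the norm for standard epochs.  Detection runs
on the two-channel mean trace (the participant-level value) and on each
channel separately.

Single-trial P300 variability is estimated per epoch from the
two-channel mean trace low-passed at 10 Hz (zero-phase FIR): the maximum
in 300–600 ms gives that trial's latency and amplitude, and sample SDs
(n−1) across trials give `P300_lat_std` / `P300_amp_std`.  The windowed
maximum on a smoothed single trial is the simplest estimator that is
robust at single-trial SNR; its residual noise floor inflates the
measured SD, so the statistic is most meaningful as a *between-group*
contrast, not an absolute jitter estimate.

Behavioral scoring assigns each button press to the stimulus whose
response window (100–1000 ms after onset, half-open) contains it; the
first press claims the trial.  Claimed targets are correct, unclaimed
targets are misses; claimed standards are false alarms.  RT mean/SD use
correct target responses only.  The window start excludes anticipatory
presses and the end is bounded by the onset asynchrony (overlapping
windows raise an error).

## Connectivity

**PLV.**  Both channels of every epoch are band-filtered (theta 4–8,
alpha 8–13, beta 13–30 Hz) and their instantaneous phases extracted with
the Hilbert transform; with θ(t, n) the Fp1−Fp2 phase difference of
epoch n,

PLV(t) = |Σₙ exp(j θ(t, n))| / N ∈ [0, 1].

Implementation: each epoch is mirror-padded by 200 ms, the zero-phase
amplitude response of the band FIR is applied in the frequency domain
(circular convolution on the symmetric extension), the analytic signal
is formed, and the pad discarded.  This choice makes the chain *exact*
for tones that are reflection-symmetric at the epoch ends and
bin-centred on the padded length, which is what the identity tests
exploit (PLV = 1 for copied channels; PLV = 0 for phase offsets at the
fourth roots of unity).  Summary features per band: maximum and its time
(searched over the positive window, earliest tie wins) and mean PLV over
the P200 (180–300 ms), P300 (300–600 ms) and positive (0–700 ms)
windows.  The "positive window" is taken as the 0–700 ms analysis range;
it is configurable.

**Coherence.**  Welch's averaged periodogram with one segment per
epoch: the post-stimulus span of each epoch is Hann-tapered, FFT length
256 (≈0.98 Hz bins), and

C(f) = |Wxy(f)|² / (Wxx(f) · Wyy(f)) ∈ [0, 1],

with the spectral densities averaged over epochs before combining.  No
within-epoch subsegmentation: 250-sample epochs are too short to split
further without destroying frequency resolution.  With N independent
segments the estimator has the well-known positive bias E[C] ≈ 1/N under
independence, which the calibration tests check at N = 64.  Band
features: maximum and its frequency, mean, and SD across bins; SDs are
reported ×100 (a "percentile" scale for a quantity bounded by 1), per
band and across the 4–30 Hz union.  Band-limited coherence is read off
the full spectrum rather than recomputed from band-passed signals —
Eq.-level coherence is already frequency-resolved.

## Time-frequency and time-trial maps

ERSP/ITC use a sliding 64-sample Hann window with a hop of one sample,
frequency bins k·fs/64 ≈ 3.9 Hz, cropped to the 0–30 Hz analysis range.
ERSP is the trial-averaged power in dB relative to the mean baseline
power per frequency, 10·log10(P(f,t)/P̄ᵦ(f)): positive = event-related
synchronization (ERS), negative = desynchronization (ERD).  ITC is the
magnitude of the trial-averaged unit phasor, computed per channel and
averaged.

Pointwise significance against the baseline uses a seeded permutation
scheme: trials are resampled with replacement and, for each resampled
trial, a random baseline frame is drawn; the statistic is recomputed 200
times and each map point compared with the null of its frequency
(two-sided for ERSP, upper-sided for ITC; add-one p-values; α = 0.01).
The trial bootstrap matters: at hop 1 the baseline frames of one trial
overlap almost completely, so resampling frames alone would collapse the
null variance and flag everything.  The mask is pointwise (no
multiple-comparison correction), intended for map display; the
calibration test checks that its false-positive fraction on stationary
noise stays near the nominal 1%.

Time-trial maps show the two-channel mean trace of every epoch in
presentation order, smoothed along the trial axis with a 10-epoch boxcar
(valid convolution, n−9 rows — no edge fabrication).  They expose
habituation: a per-trial decay of the standard P200 shows as a monotone
fading of the 200–300 ms band down the map.

## Group statistics

Two-group comparisons follow a gated scheme: Shapiro-Wilk normality per
group at α = 0.05 — if either group rejects and the data are positive,
both are log-transformed (otherwise the transform is skipped and
flagged); Levene's test (centre = mean) for equal variance — pooled t
when it holds, Welch's t when it rejects.  ANCOVA fits
`value ~ group + age + sex + education` without group×covariate
interactions (a parallel-lines model); the group effect is the type-II
F, and with four subgroups all six pairwise contrasts are reported with
Bonferroni adjustment (`emmeans`).  Calibration tests verify a ~5%
type-I rate for the gated path and uniform null ANCOVA p-values.

Grand-average PLV curves are compared between groups over seven 100 ms
intervals (0–700 ms) and grand-average coherence spectra over seven
ranges partitioning 4–30 Hz (theta 4–8, low alpha 8–10, high alpha
10–13, low beta 13–16, middle beta 16–20, high beta 20–23, very high
beta 23–30); per-sample/per-bin uncorrected masks accompany the
interval and band tests and are exploratory display aids.

## The synthetic generator

Each synthetic channel is built from:

* **1/f background** (spectral shaping of white noise), RMS
  `noise_scale` (default 6 µV), of which a fraction `noise_coupling`
  (default 0.85 of power) is common to both channels — this sets a flat
  broadband coherence ceiling like the strong volume conduction of two
  nearby prefrontal electrodes;
* a **shared beta-band oscillation** (16–30 Hz, RMS `beta_amp` = 4 µV);
* **beta-specific inter-channel decoupling**: within each
  inter-stimulus segment, the beta-band content of channel 2 (background
  beta and oscillation alike) is phase-rotated against channel 1 by a
  von Mises(0, κ) draw, smoothed over 80 ms at segment boundaries.  κ
  (`beta_coupling_kappa`) therefore controls beta PLV and beta coherence
  directly — the mean resultant of von Mises phases is I₁(κ)/I₀(κ) —
  while theta/alpha coupling is identical across groups.  The band is
  confined to 16–30 Hz with a sharp (501-tap) FIR so the decoupling
  cannot leak into the measured alpha band;
* **post-stimulus beta gain** `beta_erd_gain` (a power factor) over
  300–500 ms after every onset: values < 1 produce a beta ERD;
* **evoked components**: Gaussian deflections (SDs 25/35/50 ms for
  N100/P200/P300) at per-trial jittered latencies, identical on both
  channels; the standard-epoch P200 decays by `p200_habituation` per
  trial.  The P300 width and its 430 ms mean latency keep the
  jitter-smeared averaged P300 from bleeding into the P200 window,
  which would otherwise turn the P300-jitter group contrast into a
  spurious P200-amplitude difference;
* **behavior**: per target, with probability 1−miss, a press at onset +
  RT ~ Normal(rt_mean, rt_sd) truncated to (100, soa); false alarms per
  standard with their own probability.

The ongoing activity is passed through the emulated acquisition chain of
the portable device (2nd-order 55–65 Hz band-stop, 1st-order 2.6 Hz
high-pass, 8th-order 43 Hz low-pass Butterworth, applied causally), and
the evoked templates are added afterwards: a first-order 2.6 Hz
high-pass removes most of the energy of a 60 ms-wide P300, so the
profile's component parameters are defined as the morphology *of the
recorded signal* — the quantity the detection stage must recover.  The
±393 µV input range is enforced (clipping is an error), and recordings
can be written to EDF with the device's 16-bit quantisation.

### Default group profiles

The four subgroup profiles (`CN`, `SCD`, `aMCI`, `naMCI`) are synthetic
choices, not estimates from any cohort.  They encode, qualitatively, the
structure the analysis is designed to resolve:

| parameter | CN | SCD | aMCI | naMCI |
|---|---|---|---|---|
| beta coupling κ | 8 | 6 | 2 | 3 |
| beta ERD gain (power) | 0.55 | 0.55 | 1 (absent) | 1 (absent) |
| target P300 latency jitter (ms) | 40 | 43 | 55 | 50 |
| RT mean / SD (ms) | 335/65 | 340/75 | 345/95 | 350/105 |
| miss / false-alarm rate | .015/.002 | .02/.003 | .04/.006 | .05/.008 |
| P200 habituation per trial | 0.9975 | 0.9975 | 0.996 | 0.996 |

N100/P200 parameters are identical everywhere (no sensory-component
group effect); the β coupling ordering is CN > SCD > naMCI > aMCI and
ERD is present only in the healthy subgroups.  Because the MCI beta
coherence drops against an otherwise flat broadband ceiling, the
across-bin coherence SD (`COH_std`) rises in MCI — the direction the
variability analysis expects.  Effect sizes are deliberately strong:
the generator's job is to make the qualitative pattern recoverable at
cohort sizes a test suite can afford, not to mimic population effect
sizes.  Covariates are drawn from plausible elderly-cohort
distributions per subgroup, and age mildly shifts RT and target P300
latency so covariate adjustment has something real to do.

What the generator does **not** emulate: ocular/EMG artifact
morphology (only amplitude outliers), non-stationary drift, electrode
impedance changes, or any biophysical head model.  Passing tests
therefore demonstrate the estimators' correctness and the pipeline's
sensitivity to the modelled structure — not performance on real
recordings.

## Validation sizes and numerical choices

* Estimator calibrations: von Mises κ = 2 PLV at N = 256 epochs × 100
  replicates against the closed form I₁(2)/I₀(2) ≈ 0.698 and a
  brute-force phase-average oracle; coherence bias at N = 64 segments;
  ITC of random phases vs the Rayleigh level (√π/2)·N^(−1/2) ≈ 0.111.
* ERSP: doubling/halving post-stimulus beta power must read
  ±10·log10 2 ≈ ±3.01 dB within 0.4 dB.
* The end-to-end pattern check runs 20 master seeds with 10
  participants per subgroup (20 per main group): each finding —
  significant RT_std, P300_lat_std, COH_std and beta PLV; null
  N100/P200 components; null alpha/theta PLV; HC-only beta ERD — must
  replicate in at least 80% of seeds.  Replication is assessed per
  finding across seeds; at these effect sizes every true effect tests
  at |t| ≳ 4, so the binding constraint is the nominal 5% false-positive
  rate of the null findings, not power.
* Ties in peak and maxima searches resolve to the earliest
  latency/lowest frequency; SDs use the n−1 denominator; all epoch
  windows are half-open `[start, end)`; all randomness flows through
  named integer seeds (no hidden global state).

## Known limitations

* The per-epoch phase-rotation model makes the inter-channel phase
  offset piecewise constant within a segment; real coupling fluctuates
  continuously.
* The automated ±100 µV rejection is a stand-in for visual artifact
  screening and will not catch low-amplitude ocular contamination.
* The permutation mask is pointwise; treat contiguous significant
  regions, not single pixels, as meaningful.
* The single-trial P300 estimator's noise floor biases absolute
  latency-SD values upward; use it comparatively.
* With two channels, connectivity cannot be localised: PLV/COH describe
  the Fp1–Fp2 pair only, and volume conduction contributes to both.
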