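---
title: "Methods: simulating and analyzing the paired-stimulus local–global paradigm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing the paired-stimulus local–global paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lgerp)
```

## The paradigm

`lgerp` implements an auditory oddball design built from stimulus *pairs*.
The first sound of every pair is a 1000-Hz standard tone (S); the second is
either S again (S–S pair), a 1500-Hz frequency deviant (F; S–F pair), or a
spoken-numeral train deviant (T; S–T pair). Acoustic change *within* a pair
(S–F, S–T) is the **local** deviance and drives the mismatch negativity
(MMN) and, for the richer numeral stimuli, the P3a. An S–T pair appearing
after a run of same-type pairs violates the *across-pair* regularity — the
**global** deviance — and, when the listener is actively counting targets,
drives the P3b. Because the P3b requires voluntary attention while the
earlier components do not, contrasting an active (target-counting) session
with a passive (distracted) session carrying the *identical* sound sequence
dissociates voluntary from involuntary attention.

A default session has 1380 pairs: 30 leading S–S pairs establish the
regularity and are excluded, leaving 555 S–S, 540 S–F and 255 S–T analyzed
pairs (S–T = 18.89%). Each S–T pair is labelled by its context — 121 sit
after S–S runs, 134 after S–F runs — and any two S–T pairs are separated by
at least three intervening pairs. Within a pair the onset asynchrony is
350 ms; stimuli last 200 ms; pairs are separated by a 1000–1300 ms jitter in
50-ms steps.

### Generator design

The schedule constraints are enforced *by construction*, not by rejection
sampling: S–T positions are drawn uniformly over all placements satisfying
the separation constraint via the classic gap transform (sample strictly
increasing slack positions, shift each by a multiple of the minimum gap).
The `min_intervening_pairs` pairs before each S–T pair are then forced to
that pair's context type, and the remaining slots are filled by a random
permutation of the leftover S–S/S–F pairs, so composition counts are exact
for every seed and infeasibility is detected arithmetically. We treat the
published percentages as count ratios: the protocol reports exact per-session
counts, and exact counts make every downstream trial-count assertion sharp.

The inter-pair jitter is measured from the *offset* of a pair's second
stimulus to the onset of the next pair. The alternative reading
(onset-to-onset) would give a ~34.5-minute session, incompatible with the
published ~40-minute duration; offset-to-onset gives ~39 minutes. The
active and passive schedules generated from one seed are identical event
lists, as in the published design.

## The synthetic EEG model

`simulate_recording()` writes, at 1000 Hz on a 64-channel 10–20 montage
(including CPz, the online reference, and the mastoids M1/M2):

* **Components** — each is a Gaussian-envelope deflection (signed peak
  amplitude x per-channel topography gain) added at qualifying events, with
  trial-wise latency jitter (default SD 10 ms). Defaults: P1 (+2 µV,
  76 ms), N1 (−4, 124), P2 (+3, 184) on every stimulus; MMN (−3, 148) on
  deviant second stimuli; P3a (+4, 248) on S–T seconds; P3b (+4, 330,
  centroparietal) on S–T seconds in the active condition only. The published
  protocol reports no microvolt effect sizes, so amplitudes are free parameters
  chosen to give realistic single-trial SNR against the default noise and
  near-ceiling individual detection at full trial counts, mirroring the
  published detection table qualitatively. Topographies are synthetic
  two-pole gain maps (frontocentral anchored near FCz, centroparietal
  between CPz and Pz) — the claims being validated are sensor-level, so no
  forward model is used.
* **Background** — spatially correlated 1/f broadband noise (default
  exponent 1, 6 µV per channel, neighbor correlation 0.3 via a shared
  component) plus a posterior-dominant 10-Hz alpha rhythm (3 µV), and
  optional ±150 µV excursions for rejection testing. Pink noise is shaped
  in the frequency domain; because the real and imaginary parts of one
  inverse FFT of a white complex spectrum are independent, two series are
  obtained per transform, and the scale is applied analytically.
* **Referencing** — all channels are expressed against CPz at "recording"
  time; mastoids carry background only. Component and noise streams derive
  independent seeds from the master seed, which makes simulations exactly
  additive across component sets — a property the tests exploit.

Between participants, each component's amplitude is scaled by
N(1, 0.2) and its latency shifted by N(0, 5 ms), drawn once per participant
and shared across that participant's two sessions.

What the generator does *not* emulate: ocular/muscle artifacts (ICA-grade
cleaning is out of scope), non-stationary arousal drift, and any acoustic
structure of the stimuli. Passing pipeline tests on this data therefore
validates the *analysis machinery*, not claims about real recordings.

## Preprocessing

`filter_chain()` applies a 50-Hz notch, 1-Hz high-pass and 30-Hz low-pass —
all linear-phase Hamming-window FIR kernels applied zero-phase, so ERP
latencies are not shifted — then re-references to the M1/M2 mean and
decimates to 250 Hz. Since zero-phase linear filters commute, the three are
applied in a single FFT pass (the product of their real transfer
functions), which is numerically identical to sequential filtering and much
faster; kernel lengths (3301/3301/441 taps) give ~1-Hz transition bands and
>40 dB notch attenuation, asserted in tests.

Epochs are cut on the 4-ms grid: 450-ms epochs (−100..348 ms, 113 samples,
baseline −100..0) for the first-standard and local contrasts; the
resting-state control uses the 450 ms preceding stimulus onset (−448..0,
baseline −450..−350); global contrasts use 900-ms epochs (−100..796)
locked to the pair's second stimulus, comparing the T of each S–T pair with
the second stimulus of the immediately preceding context pair. Trials are
paired by construction, and ±100 µV amplitude rejection is *matched*: a
rejection in either member of a pair drops both, keeping counts equal. The
published procedure states matching for the S/RS contrast; we apply it to
all five contrasts because every contrast is paired, which preserves
balanced classes everywhere.

## Group statistics

`permutation_test()` computes the mass-univariate paired t map, enhances it
with TFCE (E = 0.5, H = 2, the method's canonical exponents; integration
step = map maximum / 50; connectivity = Delaunay-based channel adjacency x
consecutive samples, positive and negative parts enhanced separately), and
builds the null from random sign flips of participant difference waveforms
using the maximum absolute enhanced statistic (two-tailed, observed
labeling included). When `2^n` does not exceed the permutation budget the
null enumerates *all* sign patterns, making p-values exact — with six
participants the smallest attainable two-tailed p is 2/64 ≈ 0.031.
Point-wise significance at the 1−α null quantile is then reduced to
reported clusters by two post-hoc filters, in this order: at least two
mutually adjacent channels significant at a common time point, and at least
20 ms duration. TFCE yields point-wise inference, so the published
two-electrode/20-ms rules are implemented as reporting criteria on the
significant mask.

**Small-cohort caveat.** The t statistic is scale-free: in near-noise-free
synthetic averages a chance across-participant variance collapse at any
no-signal cell produces arbitrarily large t, and sign-flip nulls then
swamp genuine effects. For such regimes `hat` (default 0) adds a fraction
of the map-wide maximum standard error to every denominator — the
variance-regularized ("hat") t. It is applied identically to observed and
permuted maps, so exchangeability is untouched; the smoke-scale recovery
analyses use `hat = 0.05`, while the default remains the plain paired t of
the published pipeline.

## Individual sensitivity

`evaluate_sensitivity()` implements the dual permutation framework: trials
are averaged into 50 temporally contiguous blocks (floor division; remainder
trials dropped from the end; single trials with a warning when fewer trials
than blocks exist), features are the block-averaged channels x time samples
inside the contrast's window (0–300 ms for the first-standard and local
contrasts, 0–400 ms for global), and a linear SVM (e1071/libsvm, default
regularization; linear because features far exceed samples) is scored by
stratified fivefold cross-validation. The true-label distribution re-draws
the fold assignment each of 1000 iterations; the null distribution also
permutes the labels once per iteration. A component counts as detected when
the mean true accuracy exceeds the null's 95th percentile; the empirical
p-value is reported alongside. Standardization is fit on training folds
only. When features outnumber samples the SVM is fit on rows of a Cholesky
factor of the standardized Gram matrix — the linear kernel depends on the
data only through inner products, so the solution is identical (verified
prediction-for-prediction in the tests) at a fraction of the cost.

## Sensor x epoch sweep

`run_sweep()` evaluates active-vs-passive discrimination over nested
8/16/32/64-channel caps crossed with 25/50/75/100% of epochs taken in
temporal order (emulating shorter recordings). Configurations whose epoch
count cannot fill the blocks use raw epochs as samples — at published trial
counts this happens exactly at the 25% fraction. Accuracy per cell is the
mean over repeated cross-validations (500 by default), averaged over
participants; `correlate_performance()` computes Spearman correlations of
the 16 cell means against epoch fraction and sensor count, with 95%
percentile-bootstrap intervals obtained by resampling *participants* (the
quantity correlated is a participant mean, so participants are the
exchangeable unit).

## Problem sizes used for validation

The shipped validation suite runs entirely on synthetic data at desk scale,
chosen so each property is sharply testable: the paradigm checks use the
full default session; cluster calibration uses 200 null cohorts of 8
participants with 200 permutations on 8-channel maps; exhaustive agreement
uses 4 participants (16 sign patterns); component recovery uses the smoke
fixture (6 participants, 300 analyzed pairs, amplitudes at 10x the noise
SD, `hat = 0.05`); decoding calibration uses 100 exchangeable datasets with
50-iteration frameworks; the sweep check uses a 6-participant cohort of
constructed epochs with a broad centroparietal effect over spatially
correlated noise (which is what makes extra sensors redundant and epochs
decisive, the regime the published data exhibit). `make_fixtures()` exposes
the unit/smoke scales programmatically.

## Known limitations

* Synthetic topographies and noise are stand-ins; none of the shipped
  results are claims about real recordings.
* The smoke fixture carries roughly a quarter of a full session's trials,
  so its global contrasts (~27 context trials instead of ~120) are
  genuinely under-powered at default SNR: passive-condition global
  detection rates and the active-vs-passive cluster can sit at or below
  the significance boundary there. This is a property of the reduced
  scale, not of the method; the full default session restores the
  published trial counts.
* The resting-state baseline window (−450..−350 ms) can overlap late
  activity of the preceding pair at short inter-pair intervals; this is
  reproduced as published rather than corrected.
* ICA-based artifact removal, bad-channel interpolation and EDF ingestion
  are documented hook points, not shipped features; real-data use starts
  from an `lg_recording` built by the caller.
* The 121/134 context split is treated as a free configuration parameter;
  the published text does not state how it was chosen.
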