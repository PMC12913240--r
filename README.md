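# lgerp — paired-stimulus local–global auditory ERP pipelines

`lgerp` is an R toolbox for the **paired-stimulus local–global auditory
oddball paradigm**: a single-session EEG design that tracks the whole
auditory processing hierarchy — obligatory sensory registration (P1–N1–P2
complex), automatic deviance detection (mismatch negativity, MMN),
involuntary attention orienting (P3a) and voluntary target evaluation
(P3b) — with individual-level statistical sensitivity. It is written for
cognitive-neurophysiology researchers who want to study, power, or extend
this paradigm without access to recordings: every stage runs end-to-end on
simulated data, and the analysis stages accept real data in the same
containers.

The package covers:

* **Schedule generation** — exact-count sessions of stimulus pairs
  (standard S, frequency deviant F, train deviant T; every pair starts
  with S) with context-labelled global deviants, a minimum-separation
  constraint between S–T pairs, 350-ms within-pair SOA and 1000–1300-ms
  jittered inter-pair intervals; BIDS-style events TSV I/O.
* **EEG simulation** — 64-channel 10–20 recordings at 1000 Hz: Gaussian
  ERP components with configurable amplitude/latency/topography over
  spatially correlated 1/f + alpha background, CPz online reference,
  per-participant amplitude and latency idiosyncrasies.
* **Preprocessing** — zero-phase FIR 50-Hz notch / 1-Hz high-pass /
  30-Hz low-pass chain, mastoid re-referencing, 250-Hz downsampling,
  paired epoch extraction for the five contrasts, matched ±100 µV
  amplitude rejection.
* **Group statistics** — paired-t maps enhanced with threshold-free
  cluster enhancement (TFCE, E = 0.5, H = 2), sign-flip permutation nulls
  (max-|TFCE|, two-tailed, exact enumeration at small n), cluster
  reporting with the ≥2-adjacent-channels and ≥20-ms criteria.
* **Individual sensitivity** — 50-block averaging, linear-SVM fivefold
  cross-validation, dual 1000-iteration permutation framework with a
  95th-percentile detection threshold.
* **Sensor × epoch sweep** — the 4×4 factorial (8/16/32/64 sensors ×
  25–100% epochs) of active-vs-passive discrimination with Spearman
  correlations and participant-level percentile bootstrap.

The five contrasts are `P1N1P2` (first standard vs preceding resting
state), `Local_SF` / `Local_ST` (within-pair deviant vs standard) and
`Global_SS_ST1` / `Global_SF_ST2` (train deviant vs the second stimulus of
the preceding context pair).

## Worked example

Generate one default session and check its composition:

```r
library(lgerp)
sch <- generate_session(paradigm_config(), "active", seed = 1)
firsts <- subset(sch, position == "first" & analyzed)
table(firsts$pair_type)
#>
#>  SF  SS  ST
#> 540 555 255
round(max(sch$onset_ms) / 60000, 1)   # session length, minutes
#> [1] 39.1
```

Simulate a two-session participant, preprocess, and test one contrast:

```r
cfg <- make_fixtures("smoke")          # 6 participants, 300 analyzed pairs
part <- simulate_participant(cfg$paradigm, cfg$noise, participant_id = 1,
                             seed = 1)
rec  <- filter_chain(part$passive)     # notch/HP/LP, M1/M2 reference, 250 Hz
eps  <- extract_epochs(rec, "Local_ST", participant_id = 1)
rej  <- reject_amplitude(eps$A, eps$B) # matched +/-100 uV rejection
sens <- sensitivity_from_epochs(rej$A, rej$B, n_blocks = 25, n_iter = 100,
                                seed = 1)
sens
#> <lg_sensitivity> Local_ST participant 1: accuracy 0.832 +/- 0.033,
#>   null 95th pct 0.641 -> detected (p = 0.009901)
```

The train deviant's MMN–P3a complex separates deviant epochs from their
within-pair standards well above the 95th percentile of the
shuffled-label null, so this synthetic participant counts as *detected* —
the individual-level criterion the paradigm is designed around. A full
cohort (`run_study(cfg)`) additionally returns the group-level TFCE
cluster tables per contrast, a detection-count table across conditions,
and the sensor × epoch sweep; `tidy()`, `glance()` and `autoplot()`
methods turn every result object into tibbles and ggplots.

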