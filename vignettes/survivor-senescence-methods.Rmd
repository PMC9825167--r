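---
title: "Measuring survivor-associated senescence: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring survivor-associated senescence: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telosas)
```

## The phenomenon and the measurements

Telomerase-negative yeast that escape senescence ("survivors") maintain
telomeres by homology-directed repair (HDR). In clonal type II survivor
populations a telomere of defined starting length shortens steadily, the
culture's replicative potential falls as the telomere approaches a critical
length, TERRA rises, and HDR then re-elongates the telomere — after which
the cycle can repeat. `telosas` implements the quantitative procedures this
cyclic phenotype requires, and a simulator that generates every input table
those procedures consume.

The analysis chain is deliberately simple and auditable: each stage is a
small, separately exported function, and the simulator writes its ground
truth next to every synthetic table so recovery can be asserted rather than
assumed.

## Replicative potential and population doublings

Daily serial dilution to a fixed OD600 (default 0.01) defines the protocol.
Population doublings realized in a day are `log2(od_end / od_start)`; the
protocol itself never states a PD formula, and this is the standard
definition consistent with dilution to a fixed OD. Percent replicative
potential divides every later `od_end` by the *single day-0* reading of the
reference clone (the empty-vector transformant) — not by day-matched
controls. A day-matched variant exists behind `day_matched = TRUE` but is
not the default. Series with missing days are rejected rather than
interpolated: the protocol is strictly daily, and imputing a missing day
would silently move minima.

## The SAS-rate statistic

The rate of survivor-associated senescence is the number of PDs from the
start of propagation to the selected minimum of the potential profile.
Four numerical choices matter:

* **Smoothing** is one pass of consecutive-pair averaging (`(v[i] +
  v[i+1])/2`), shortening the series by one. Whether the original
  measurement smoothed once or repeatedly is not documented; we smooth once
  and expose `passes` for the repeated reading.
* **"Neighborhood of four"** is read as four values on *each side* (a
  9-value window): position *i* qualifies iff its full window exists and no
  value in it is strictly smaller. Symmetric windows are the standard
  reading; `k` is a parameter, so the 2-per-side reading is one argument
  away.
* **Ties**: "no other value is inferior" is read as *strictly* less, so
  plateaus still yield minima (otherwise a constant stretch would have
  none); tied candidates within one window, and flat runs, are deduplicated
  to their earliest position. A consequence worth knowing: a long flat
  stretch at the *start* of a profile (a clone far from senescence, measured
  noise-free) itself qualifies as a plateau minimum. In practice OD noise
  breaks such ties; the test suite constructs single-cycle worlds with a
  short lead-in when it needs the selected minimum to be the cycle minimum.
* **Early-day exclusion**: minima on days ≤ 3 are discarded (growth right
  after the solid-to-liquid transfer is erratic); the bound is the
  `exclude_days` argument. The manual cross-condition "profile similarity"
  criterion sometimes used to pick among minima is *not* automated — it is
  available only as an explicit `forced` override.

Group comparisons (`compare_sas()`) are a thin wrapper over the unpaired
two-tailed t-test (Student by default, `welch = TRUE` for the
unequal-variance variant); nothing bespoke.

## Shortening-rate estimators

Two estimators, both in bp/PD with shortening positive:

* `rate_diffquot()` — the mean of consecutive difference quotients. On
  equally spaced PDs it telescopes to `(first − last) / span`.
* `rate_regression()` — unweighted OLS slope of length on PD, sign-flipped.

Both are invariant to adding a constant to all lengths and agree exactly on
noise-free linear series. Rates are only estimated on the *pre-HDR segment*
of a trajectory (`pre_event_segment()`); including a re-elongation event
would turn a shortening rate into an average of two different processes.
Fold changes divide same-method estimates (treatment over control).

Southern-blot-derived lengths are kept *relative*: the migration coordinate
is a monotone proxy for length (largest x = longest telomere, which is the
normalization divisor), and no bp calibration from migration distance is
attempted. Absolute bp rates belong to telomere-PCR-style length tables.

## qPCR and ChIP conventions

TERRA is quantified as percent of the reference transcript,
`100 · E^−(Ct_target − Ct_ref)` with amplification efficiency fixed at
`E = 2` (an `efficiency` argument exists, defaulting to perfect doubling,
because the underlying measurement uses plain ΔCt). Fold changes to a
reference group average *after* the exponential transform, on the percent
scale, matching the "divided by the average among the reference clones"
convention. No-RT controls are validated (flagged within 5 cycles of the RT
sample) but never subtracted.

ChIP enrichment is percent input with a dilution-factor-corrected Input:
`100 · IP / (Input / input_fraction)`; "corrected Input" is interpreted as
this dilution correction, with the fraction configurable (0.05 for the
50-μl-of-1-ml protocol; 1/60 for R-ChIP dot blots). TAP experiments divide
tagged by untagged percent input before the wild-type fold change; the full
chain is invariant to any common calibration factor. Same-day
survivor/wild-type pairing is an explicit `day` column, with the wild-type
locus mean as fallback when a batch lacks its same-day partner.

## The simulator: a stated world

`sim_config()` defaults describe one survivor clone under daily dilution:

| parameter | default | why |
|---|---|---|
| `shorten_rate_mean` | 2.7 bp/PD | typical survivor shortening rate; the R-loop-depleted arm of `run_demo()` multiplies it by 1.6 |
| `shorten_rate_sd` | 0.5 bp | modest per-PD stochasticity |
| `initial_length` | 350 bp | defined starting length of the tracked telomere |
| `critical_length` | 100 bp | HDR trigger; (350 − 100)/2.7 ≈ 93 PD of shortening per cycle, one cycle in ~3 weeks of culture |
| `senesce_length` | 200 bp | growth-penalty onset |
| `hdr_prob_per_pd` | 0.5 | re-elongation observed promptly (within a sampling interval) once critically short |
| `type1_gain` | 150 bp | fixed, Y′-element-like addition |
| `type2_gain_*` | lognormal, median 250 bp | heterogeneous TG-repeat additions; heavy-tailed and positive |
| `terra_fold_short` | 6 | TERRA at critically short vs long telomeres |
| `max/min_doublings_per_day` | 5 / 1.68 | 2^(5−1.68) ≈ 10-fold OD span between healthy and critically short cultures |
| `od_noise_cv`, `ct_noise_sd`, `band_position_noise_sd` | 0.05, 0.15 cycles, 0.005 | multiplicative lognormal OD/ChIP noise, additive Gaussian Ct and band-position noise — matching the measurement physics of each assay |

Update rules and their rationale:

* Per PD the length shrinks by a draw from
  Normal(`shorten_rate_mean`, `shorten_rate_sd`) **truncated at zero by
  clipping** (`max(draw, 0)`), not by rejection resampling: rejection
  shifts the realized mean upward (by 2.8% at rate 1, sd 0.5), which would
  make "the estimator recovers the nominal rate" false by construction;
  clipping keeps the realized mean within 0.4% of nominal over the 1–10
  bp/PD range. A single PD also cannot erode more than half the remaining
  tract. Consequence: at very low rates a zero-shortening PD is possible,
  so "length strictly decreases between non-event records" holds at the
  defaults but not for every conceivable configuration.
* HDR is a hard length threshold with a per-PD firing probability — the
  simplest rule consistent with "re-elongation once critically short".
  Long telomeres never recombine here; whether they occasionally do in
  reality is an open question, modelled as zero.
* **Growth–length coupling**: daily doublings are `max_doublings_per_day`
  at or above `senesce_length`, interpolate linearly down to
  `min_doublings_per_day` at `critical_length`, and *keep falling linearly
  toward zero below the critical length* rather than plateauing. A hard
  lower plateau would make the worst-growth day ambiguous whenever a
  sub-critical dwell spans two days; the strictly monotone map makes growth
  a faithful readout of the shortest telomere everywhere below
  `senesce_length`, which is precisely the assumption (worst growth day =
  shortest-telomere day) the downstream SAS analysis relies on — and
  deepening senescence with deficit is biologically sensible.
* **TERRA–length coupling** is a logistic in length rescaled to hit its
  endpoints exactly: fold 1 at/above `senesce_length`, `terra_fold_short`
  at/below `critical_length`, monotone non-increasing in between
  (`terra_length_scale` sets the steepness). The fold is treated as
  per-telomere signal. A fold `f` maps to a ΔCt shift of `−log2(f)`.

### What the generator does and does not emulate

It emulates: gradual per-PD shortening with abrupt re-elongation, the daily
dilution protocol, potential fluctuations tracking the shortest telomere,
TERRA rising ~6-fold at short telomeres, Gaussian bands on lane profiles,
and ChIP tables with known enrichment ratios. It does **not** emulate:
multiple telomeres per clone (one tracked telomere stands in for the
shortest), population heterogeneity after repeated HDR (real fluctuations
damp late in propagation as subclones with distinct lengths mix),
sequence-level structure, replication-fork or R-loop mechanics, or
competition between type I and type II survivors. A green recovery test
therefore establishes that the estimators are correct *for this generative
structure*, not that the biology has no further complications.

## Reproducibility

Every simulator function takes an explicit integer seed and restores the
RNG state afterwards; identical (config, seed) gives bit-identical outputs.
`run_demo()` derives per-clone, per-arm seeds arithmetically from the master
seed (all below 2^31), writes every table as TSV, and records the config
digest and the MD5 of every output in a JSON manifest written atomically —
reruns with the same seed are file-identical.

## Limitations

* The earliest-admissible-minimum rule inherits the plateau semantics
  discussed above; profiles that are genuinely flat early can select an
  early plateau minimum. This mirrors the underlying measurement's reliance
  on manual curation (`forced`) for ambiguous profiles.
* Band detection assumes reasonably separated Gaussian-like bands; smeared
  type II telomere distributions need the prominence threshold tuned and
  will not resolve overlapping bands.
* `relative_length()` cannot make a tied maximum unique: tied longest bands
  all map to 1, with the first occurrence taken as the reference.
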