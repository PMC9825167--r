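# telosas

Quantitative analysis of **survivor-associated senescence (SAS)** in
telomerase-negative budding yeast.

Type II survivors maintain telomeres by homology-directed repair (HDR)
instead of telomerase. Followed as *clonal* populations, their telomeres are
not static: a telomere shortens steadily (a few bp per population doubling,
PD), the culture gradually loses replicative potential as the telomere
becomes critically short, TERRA (the telomeric lncRNA) accumulates, and an
HDR event then re-elongates the telomere and restores growth — a cyclic,
senescence-like phenotype. `telosas` implements the measurements this
phenomenology calls for, plus a stochastic simulator of the whole process so
every stage can be exercised and tested without wet-lab data.

## What it computes

* **Growth metrics** — population doublings from daily serial-dilution OD600
  readings, `PD = log2(OD_end / OD_start)`, and percent replicative
  potential, `100 · OD_end(day) / OD_end(reference, day 0)`
  (`population_doublings()`, `replicative_potential()`).
* **SAS rate** — the potential profile is smoothed by averaging consecutive
  value pairs; position *i* is a local minimum iff no value in a window of
  *k* = 4 values per side is strictly smaller; minima in the first 3 days are
  excluded; the statistic is the PDs from the start of propagation to the
  earliest remaining minimum (`smooth_pairwise()`, `find_local_minima()`,
  `select_minimum()`, `sas_pd_count()`, wrapper `sas_rate()`, group
  comparison `compare_sas()`).
* **Telomere shortening rates** (bp/PD, shortening positive) — mean of
  consecutive difference quotients `(L[i-1] − L[i]) / (PD[i] − PD[i-1])`
  (`rate_diffquot()`) and the sign-flipped OLS slope of length on PD
  (`rate_regression()`), with treatment/control fold changes
  (`rate_fold_change()`, table wrapper `shortening_rates()`).
* **Densitometry** — band detection on 1-D lane profiles by
  prominence-thresholded peaks (`detect_bands()`), relative telomere length
  with the longest band set to 1 (`relative_length()`), percent-of-first
  normalization (`percent_of_first()`).
* **TERRA RT-qPCR** — `% reference = 100 · 2^−(Ct_target − Ct_reference)`
  (`percent_reference()`, `terra_quant()`), fold change to a reference
  group's per-locus mean (`fold_change_to_group()`), and the cell-cycle
  decline statistic `100 · (earlyS − G2) / earlyS` (`cell_cycle_drop()`).
* **ChIP-qPCR** — percent input `100 · IP / (Input / input_fraction)`
  (`percent_input()`), TAP tagged/untagged background correction
  (`tap_normalize()`), fold change to same-day wild type
  (`fold_change_to_wildtype()`), full chain `chip_fold_change()`.
* **Simulator** — `sim_config()` + `simulate_telomere_trajectory()`,
  `simulate_daily_culture()`, `simulate_terra_cts()`,
  `generate_lane_profile()`, `generate_chip_dataset()`; every generated
  table carries its ground truth for recovery tests. `run_demo()` runs a
  two-arm cohort (EV vs faster-shortening RNH1) end to end and writes all
  tables plus a reproducibility manifest.

All user-facing functions take data frames first and return tibbles; result
objects have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(telosas)
cfg <- sim_config()                       # EV-like survivor clone, 2.7 bp/PD
traj <- simulate_telomere_trajectory(cfg, seed = 7)
growth <- simulate_daily_culture(traj, cfg, seed = 8, condition = "EV")
potential <- replicative_potential(growth)
sas_rate(potential)
#> # A tibble: 1 × 8
#>   clone_id condition n_minima day_min pd_to_min ...
#> 1 clone1   EV               3      22      86.6
```

The clone's replicative potential reaches its selected local minimum on day
22, after 86.6 PDs — the SAS rate for this clone. The shortening rate over
the pre-HDR segment recovers the generative 2.7 bp/PD:

```r
pre <- pre_event_segment(traj)
rate_regression(pre$length_bp, pre$pd)
#> Telomere shortening rate (regression): 2.781 bp/PD (n = 92 points)

percent_reference(c(23, 24, 20.5), 23)    # delta-Ct quantification
#> [1] 100.0000  50.0000 565.6854
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package end to end — a five-clone, two-arm cohort through
simulation, replicative potential, SAS-rate measurement, shortening-rate
estimation with RNH1/EV fold changes, TERRA quantification and ChIP
normalization — prints the cohort summary table, and writes the JSON report
to `--out`.
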