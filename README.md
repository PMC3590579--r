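# meipulse

Multiscale entropy analysis of wrist arterial pulse recordings acquired under
a cuff-occlusion reactive-hyperemia protocol.

Endothelial dysfunction — impaired vasodilatory capacity of the vascular
endothelium — is an early marker of atherosclerosis, and is commonly probed
by occluding the upper arm for a few minutes and measuring the dilatory
response after release. The classical summary, the **dilatation index**

    DI = Amp_RH / Amp_Baseline × 100%,

compares the mean pulse amplitude in a one-minute hyperemic window with a
one-minute baseline window. It captures the *magnitude* of the response but
is insensitive to subtle, early vascular change. This package implements the
complementary **multiscale entropy index**: the full 14 minutes of per-beat
pulse amplitudes `X_1..X_N` (baseline + hyperemia, occlusion removed) are
detrended by empirical mode decomposition and their sample entropy `S_E(τ)`
is computed on coarse-grained copies

    y_j^(τ) = (1/τ) Σ_{i=(j−1)τ+1..jτ} X'_i ,   τ = 1..10,

with `S_E = −ln(A/B)` the Richman–Moorman conditional-probability entropy
(template length m = 2, tolerance r = 0.15 × SD, Chebyshev distance,
self-matches excluded). The small-scale and large-scale indices are the band
sums

    MEI_SS = Σ_{τ=1..5} S_E(τ),   MEI_LS = Σ_{τ=6..10} S_E(τ).

Reduced large-scale complexity (lower `MEI_LS`) accompanies ageing and
diabetes even when DI does not discriminate.

The package is aimed at physiological-signal researchers: it provides the
full pipeline (beat detection → amplitude series → EMD detrending → MSE →
MEI and DI), a seeded synthetic-cohort generator emulating four subject
archetypes (healthy young, healthy middle-aged/elderly, well-controlled and
poorly controlled diabetic) with ground-truth manifests, and cohort-level
comparison/correlation reporting.

## Worked example

```r
library(meipulse)

sim <- simulate_recording(group = 1, seed = 42)  # healthy-young archetype
res <- analyze_recording(sim$recording)
res
#> <mei_analysis>
#>   beats: 355 baseline + 639 hyperemic (split at 356)
#>   DI = 206.90%
#>   MEI_SS = 9.7203, MEI_LS = 8.6977 (r = 0.01732)
```

The 17-minute, 500-Hz recording yielded 994 beats; the amplitude series was
split at beat 356 (first hyperemic beat). The DI of ~207% reflects the
archetype's programmed hyperemic gain of 2.0. The per-scale entropy curve is
available too:

```r
res$mei$curve
#> <mse_curve> m = 2, r = 0.15 x SD, scales 1..10
#>  tau    s_e   n flag
#>    1 2.0890 994   ok
#>    2 1.9646 497   ok
#>    ...
#>   10 1.4564  99   ok
```

A near-flat curve like this (entropy retained at large scales) is the
signature of 1/f-dominated, "complex" fluctuations; white-noise-dominated
fluctuations decline steeply with scale, giving a lower `MEI_LS`. Cohort
level:

```r
coh <- analyze_cohort(group_sizes = c(5, 5, 5, 5), master_seed = 1)
cohort_report(coh[, c("group", "di_percent", "mei_ss", "mei_ls",
                      "age_years", "hba1c_pct")])
#> Group comparison (mean ± SD; * p<0.05, ** p<0.001):
#>    variable         group1        group2        group3        group4 ...
#>  di_percent 191.78 ± 13.28 161.01 ± 4.41 149.56 ± 7.13 129.65 ± 4.89
#>      mei_ls    8.94 ± 0.63   8.06 ± 0.76   7.66 ± 0.53   7.16 ± 0.56
#>  ...
```

Mean `MEI_LS` decreases monotonically across the four archetypes, and DI
falls from ~192% to ~130%, recovering the programmed group structure.

A thin command-line front end is installed with the package
(`exec/mei`): `mei simulate`, `mei analyze`, `mei cohort`, `mei version`.

```sh
Rscript exec/mei simulate --group 1 --n 1 --seed 5 --out sim/
Rscript exec/mei analyze sim/g1_seed5.csv --out result.json
```

## Layout

* `R/` — pipeline implementation (signal model, beat detection, EMD,
  entropy, hemodynamics, simulator, cohort statistics).
* `src/` — compiled sample-entropy pair counting.
* `vignettes/multiscale-entropy-index.Rmd` — methods: model, parameters,
  design decisions, limitations.
* `inst/extdata/reference_group_stats.csv` — published reference group
  summary statistics used to anchor the simulator metadata and the
  consistency checks.
* `tests/testthat/` — unit, property and acceptance tests (the brute-force
  entropy oracle lives in `helper-oracles.R`).
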