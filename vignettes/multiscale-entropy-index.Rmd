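---
title: "Methods: the multiscale entropy index for cuff-occlusion pulse recordings"
author: "meipulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multiscale entropy index for cuff-occlusion pulse recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meipulse)
```

## The measurement and the two indices

A wrist cuff held at a low sensing pressure (40 mmHg) records the arterial
pulse waveform at 500 Hz through a 17-minute protocol: 5 minutes of baseline,
3 minutes of upper-arm occlusion at 200 mmHg, and 9 minutes of reactive
hyperemia after cuff release. Two summaries are computed from the per-beat
pulse amplitudes:

* **Dilatation index (DI)** — the ratio of the mean beat amplitude in a
  representative one-minute hyperemic window to that in a one-minute baseline
  window, in percent:
  $$\mathrm{DI} = \frac{\mathrm{Amp}_{RH}}{\mathrm{Amp}_{Baseline}} \times 100\%.$$
  DI captures the *magnitude* of the endothelium-mediated dilatory response.

* **Multiscale entropy indices (MEI)** — the beat-amplitude sequence
  $X_1,\dots,X_N$ (baseline and hyperemic beats concatenated, occlusion
  excluded; $N \approx 1000$) is detrended to $X'_1,\dots,X'_N$ and its sample
  entropy $S_E(\tau)$ is computed on coarse-grained copies
  $$y^{(\tau)}_j = \frac{1}{\tau}\sum_{i=(j-1)\tau+1}^{j\tau} X'_i,
    \qquad 1 \le j \le \lfloor N/\tau \rfloor,$$
  for scale factors $\tau = 1,\dots,10$. The two indices are the band sums
  $$\mathrm{MEI}_{SS} = \sum_{\tau=1}^{5} S_E(\tau), \qquad
    \mathrm{MEI}_{LS} = \sum_{\tau=6}^{10} S_E(\tau).$$
  MEI captures the *complexity* of the beat-to-beat amplitude fluctuations;
  reduced large-scale complexity accompanies ageing and diabetes and is the
  more sensitive marker.

Sample entropy follows the Richman–Moorman definition: with template length
$m$ and tolerance $r$, $B$ counts template pairs $i < j \le N - m$ whose
$m$-point templates match within Chebyshev distance $r$, $A$ counts the same
pairs whose $(m{+}1)$-point extensions also match, and
$S_E = -\ln(A/B)$. Self-matches are excluded. $B = 0$ leaves $S_E$ undefined
and $A = 0$ makes it infinite; both are *flagged*, propagate to a flagged MEI,
and are never silently replaced by zero.

## Pipeline stages and their tunables

`analyze_recording()` chains the stages; every tunable lives in
`analysis_config()`.

**Beat detection** (`detect_beats`). The recording is band-passed 0.5–10 Hz
with a zero-phase (forward–backward) 2nd-order Butterworth filter; the whole
recording is filtered at once (with reflective padding) so that phase
boundaries carry signal context and filter transients stay at the recording
ends. Candidate peaks are local maxima whose local prominence exceeds 0.3
times a rolling median prominence; peaks closer than the refractory period
$60/\mathrm{max\_hr}$ s (default max 150 bpm) keep only the larger. Accepted
peaks snap to the raw-signal maximum within ±0.1 s, the footpoint is the raw
minimum between consecutive peaks (first beat: preceding 0.5 s), and the
amplitude is peak minus footpoint. A final screen drops beats whose amplitude
falls below 0.3 times the rolling median amplitude, which removes residual
edge artefacts. The detector is deterministic; no published footpoint
algorithm is reproduced here, so it is validated against the bundled
simulator's ground truth (median beat-time error < 10 ms, amplitude recovery
within 2% RMS at 60 dB SNR, degrading gracefully at 20 dB).

**Phase handling**. Beats are assigned to the phase containing their peak.
The occlusion phase is discarded; baseline and hyperemic amplitudes are
concatenated and the phase split index recorded. An optional `n_beats`
truncates to a strict total (dropping beats from the end of each phase
proportionally) for fidelity with the nominal 1000-beat series.

**EMD detrending** (`emd_detrend`). The empirical mode decomposition uses
cubic-spline envelopes through the extrema with mirror extension of two
extrema at each end; a series endpoint lying outside the envelope is treated
as an extremum first, which keeps envelopes tracking drift at the boundaries
(without this, a strong trend leaks into mid-frequency IMFs). Sifting stops
on the Cauchy criterion (relative change between sifts < 0.2, at most 100
sifts); the decomposition stops when the residue has fewer than 4 extrema.
The Cauchy-only stopping is deliberate: forcing the extrema/zero-crossing
balance exactly over-sifts, draining the amplitude modulation that the
multiscale analysis measures, so IMFs satisfy the balance only approximately.
The decomposition is exactly additive (reconstruction to machine precision)
and fully deterministic — no ensemble variant is used.

The *trend* is the residue plus, optionally, slow IMFs. The contract default
of `emd_detrend()` removes the residue only (`trend_imfs = 0`). The analysis
pipeline instead defaults to `trend_imfs = "auto"`: the residue plus every
IMF whose mean oscillation period exceeds 100 beats, an order of magnitude
beyond the largest analysed scale ($\tau = 10$). The occlusion-release step
in the amplitude envelope is not always absorbed by the residue; on simulated
recordings the residue-only trend leaves up to twice the programmed
fluctuation SD in the "detrended" series and distorts the group comparison,
while the period-based trend removes the envelope reliably and leaves
stationary fluctuations essentially untouched. Components slower than 100
beats carry no information any analysed scale can use, so removing them is
conservative.

**Entropy parameters**. The reference description specifies neither $m$ nor
$r$; the package uses the Costa-convention defaults $m = 2$,
$r = 0.15 \times \mathrm{SD}$ of the scale-1 detrended series, held fixed
across scales. All three choices are configurable (`m`, `r_value`, `r_mode`,
`r_fixed_across_scales`). Because $r$ is fixed in absolute units while
coarse-graining shrinks the SD of uncorrelated series, white noise shows the
classic declining $S_E(\tau)$ whereas 1/f-correlated series stay flat — the
mechanism that makes $\mathrm{MEI}_{LS}$ discriminate fluctuation complexity.
Consequently the absolute MEI values depend on $(m, r)$; group *differences*
are the meaningful output, and published group means cannot be pinned to a
unique parameterization.

**DI windows** (`select_windows`). The phase layout makes the published
window placement ambiguous, so the package defines its own policy: the
baseline window is the last 60 s of baseline; the hyperemic window is the
60-s window (10-s steps over the first 180 s of hyperemia) maximizing the
mean amplitude, which captures the early hyperemic peak regardless of the
subject's decay rate. A `fixed` policy and explicit windows are available,
and the windows used are echoed in the result for audit.

## The synthetic cohort

`simulate_cohort()` emulates four subject archetypes — healthy young,
healthy middle-aged/elderly, well-controlled diabetic, poorly controlled
diabetic — so that the entire pipeline can be validated against known ground
truth. Per beat,
$$X_i = \mathrm{env}(t_i)\,(1 + f_i),$$
where the envelope is flat at `base_amp` during baseline and decays as
$1 + (\mathrm{gain}-1)\,e^{-t/\tau_{RH}}$ after release, and the fluctuation
$f_i$ is a mixture of spectrally synthesized 1/f noise and white noise with
variance shares `complexity` and `1 - complexity`, scaled to `fluct_cv`
(default 0.1). Beats are rendered as an asymmetric pulse template (fast rise,
slow decay, dicrotic bump) spanning each RR interval, on a 40-unit DC offset
with a small respiratory wander and sensor noise at `snr_db` (default 40 dB).
Everything is seeded and bit-reproducible.

Parameter choices, made once:

* `hr_bpm = 71`, `hr_cv = 0.05` — gives ≈ 994 beats over the 14 analysed
  minutes, matching the nominal 1000-point series.
* `gain` = 2.0 / 1.65 / 1.6 / 1.33 for groups 1–4 — anchored to the reference
  group DI means (≈ 202%, 165%, 162%, 133%).
* `rh_tau_s = 300` — with the envelope form fixed above, the decay constant
  must keep the one-minute hyperemic window mean close to the peak gain for
  the programmed gain to be recoverable as DI; 300 s is within the
  physiological range of a sustained post-occlusion response observed over a
  9-minute window, and yields a recovered DI within 5% of gain × 100.
* `complexity` = 0.95 / 0.55 / 0.32 / 0.08 — *calibrated* free parameters.
  The mixture-fraction → $\mathrm{MEI}_{LS}$ response flattens near
  complexity 1, and the group gains couple into the entropy through the
  residual envelope variance, so round evenly spaced complexity values do not
  produce evenly separated groups. The calibration swept the mean
  $\mathrm{MEI}_{LS}$ over a complexity grid at each group's gain (20 seeds
  per grid point) and inverted the response surface for uniformly spaced
  group means, mirroring the roughly uniform adjacent-group separation of the
  reference cohort. The archetype ordering is then recovered by the full
  pipeline robustly across master seeds, with adjacent-group effect sizes
  (Cohen's d ≈ 0.7–0.9 at 20 subjects/group) comparable to the reference
  study's marginally significant adjacent comparisons.
* Group sizes default to 30/40/40/30 (the 140-subject reference design);
  subject metadata (age, HbA1c, fasting glucose, HDL) is drawn from the
  published group distributions shipped in
  `inst/extdata/reference_group_stats.csv` and is *labelling only* — it does
  not feed back into the signal model.

What the simulator does **not** emulate: arrhythmia and ectopic beats, motion
artefacts, sensor drift and saturation, respiratory modulation of amplitude
beyond a token wander, any mechanistic hemodynamics, and any true coupling
between metadata and signal complexity. Passing tests therefore demonstrate
that the pipeline recovers what the generative model encodes; they do not
validate the clinical claims on real recordings.

## Numerical choices and degenerate inputs

* Coarse-graining discards remainder samples (`floor(N/tau)` blocks).
* The optimized sample-entropy counter (C++) is verified against an
  independent brute-force template-matching oracle to 10⁻¹² over randomized
  instances.
* A constant series under `fraction_of_sd` tolerance is rejected
  ("degenerate tolerance"); under an absolute tolerance its entropy is
  exactly 0.
* Degenerate scales ($B = 0$ or $A = 0$, plausible at $\tau = 10$ where the
  coarse series has ≈ 100 points) are flagged per scale, propagate to a
  flagged undefined MEI, surface in the CLI exit status, and serialize as
  JSON `null`.
* Recordings within ±1 s of the nominal protocol length are accepted; longer
  ones are truncated, shorter ones are never extrapolated.
* Sample indices are 1-based with closed ranges (native R convention); beat
  indices in prose are the 1-based $X_i$.
* Ties in the hyperemic window search resolve to the earliest window;
  detection ties inside the refractory period resolve to the larger filtered
  peak. All stages are deterministic given the configuration and seed.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen to finish
in minutes while keeping every estimate meaningful: 100 randomized instances
(N ≤ 300) for the entropy-oracle sweep, 100 fixtures for EMD completeness,
50 seeds at N = 1000 for the noise-signature comparison, 20 simulated
subjects per group for the full-pipeline group comparison, and 20 seeds for
DI recovery. The group-ordering check fixes its master seed, as a group
comparison at n = 20 with d ≈ 0.7 adjacent effects is reproducible but not
guaranteed for every random draw.

## Known limitations

* The beat detector is a stated stand-in for the unpublished reference
  algorithm and is validated only against the simulator.
* The EMD is the plain deterministic variant; no EEMD/CEEMDAN, so heavy mode
  mixing in pathological recordings is not addressed.
* Absolute MEI values are parameterization-dependent (see above) and sit on
  a different scale from the published group means, which were obtained with
  unstated $(m, r)$ and detrending choices.
* Several published p-values are not reproducible from the published
  means/SDs/group sizes under any standard two-sample t-test (e.g. the
  group-1-vs-2 small-scale index and DI, and the group-2-vs-3 large-scale
  index), suggesting adjusted or nonparametric testing; the package's
  consistency checks assert only the self-consistent ones
  (`summary_t()` reproduces p ≈ 0.026 and p ≈ 0.023 for the two large-scale
  comparisons printed as 0.025 and 0.024) and this discrepancy is documented
  rather than hidden.
* No multiple-testing correction is applied in the cohort report, matching
  the reference analysis; the report says so explicitly.

## A minimal worked run

```{r example, eval = FALSE}
sim <- simulate_recording(group = 1, seed = 42)
res <- analyze_recording(sim$recording)
res
write_result(res, "subject_g1.json")
```
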