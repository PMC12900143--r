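---
title: "Methods: simulated supply-chain play and EEG band-power analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated supply-chain play and EEG band-power analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroplay)
```

`neuroplay` implements the computational stack of a class of experiments in
which students play a virtual-reality supply-chain role-play game while a
14-channel consumer EEG headset records their brain activity, and two groups
(here labelled *experimental* and *control*) are compared on spectral band
power, band-ratio cognitive-state indices and survey responses. Because raw
recordings from such studies are typically not shareable, the package ships
a seeded synthetic-cohort generator with known ground truth; every analysis
stage is exercised against that ground truth.

## The supply-chain game

The player manages a retailer inside a four-actor chain
(farmer → manufacturer → distributor → retailer) facing a scripted
seven-day customer demand of 5, 8, 12, 8, 8, 5, 3 units and a starting
inventory of 10. The two computer-controlled actors (distributor,
manufacturer) follow a service-level replenishment policy with a 95% target:

* safety stock `SS = z · D̄ · L`,
* reorder point `ROP = SS + D̄ · L`,
* order quantity `EOQ = sqrt(2 · D̄ · K / h)`,

with `z` the service-level factor, `D̄` mean daily demand, `L` the lead time
and `K`, `h` the ordering and holding costs (both 1 by default). The safety
stock rule is implemented exactly in this linearised form. It differs from
the textbook `z · σ_D · √L`: the linear form ignores demand dispersion, so
its buffers are systematically larger whenever `D̄ > σ_D √L / L`. We keep the
linear form because it is the game's stated NPC logic; the classical variant
can be obtained by passing an effective `mean_demand`.

Choices the game's description leaves open, fixed here as package defaults
(all configurable):

* `z = 1.645`, the one-sided 95% standard-normal quantile;
* lead time 1 day on every link;
* order quantities are integers: `ceiling(EOQ)`, and the trigger
  "inventory position ≤ ROP" is inclusive;
* inventory position counts on-hand **plus in-transit** stock, the standard
  (R, Q) reading that prevents double-ordering during the lead time;
* within a day: arrivals → fulfilment → ordering → shipping, so day-1
  demand is servable from starting stock;
* unmet demand is lost, never backordered (the game reports "lost sales");
* the farmer is an infinite source, the customer a pure demand sink;
* unit price and the player's holding rate default to 1, mirroring the
  NPCs' unit costs;
* NPC starting inventories are not part of the scripted scenario and must
  come from the configuration; the default of 20 units roughly covers the
  reorder point plus one order cycle.

A consequence worth stating plainly: with `K = h = 1` and `D̄ = 7`,
`EOQ ≈ 3.74`, so NPC orders only take the values 0 or 4. A 0/4-valued
series can never be more variable than the scripted demand (population
variance 52/7 ≈ 7.43), so under these printed parameters the classical
bullwhip ratio `var(orders)/var(demand)` of an NPC is bounded above by
`4/7.43 ≈ 0.54`. Order *batching* amplifies variability only when the batch
exceeds mean demand; the engine computes and reports the ratio as defined,
and the package does not tune parameters to force amplification.

## Synthetic EEG cohorts

`generate_recording()` builds each channel as a sum over five bands of
band-limited Gaussian noise plus `1/f` background noise plus transient
artifacts. Band-limited noise is white noise passed through an ideal
(brick-wall) FFT band-pass; each event segment is rescaled so its RMS
equals the configured amplitude exactly, which makes the configured
amplitudes recoverable ground truth rather than approximate targets.
Defaults, chosen once as plausible surface-EEG magnitudes:

| parameter | default | meaning |
|---|---|---|
| sampling rate | 128 Hz | common output rate of the 14-channel headset class |
| event durations | 60, 60, 180, 300 s | eyes-open, eyes-closed, lecture, play |
| band RMS (θ, α, βL, βH, γ) | 3, 3, 1.5, 1.2, 0.8 µV | per channel |
| occipital alpha gain | 1.5 | posterior alpha dominance at O1/O2 |
| eyes-closed alpha factor | 2 | alpha release during event 2 |
| group effect | βL/βH × 1.5 at AF4, F4, F8, FC6, events 3–4 | experimental profile |
| noise | 1/f, 2 µV RMS | background |
| artifacts | 2/min, 150 µV, 0.3 s | movement bursts |

The group-effect profile mirrors the qualitative finding such studies
report — elevated right-frontal/prefrontal beta in the experimental group —
but its magnitude is a free generator parameter: it is a truth for the
pipeline to recover, not an empirical claim. Contact quality (CQ) and EEG
quality (EQ) are emulated as 1 Hz percent series near 100, forced low during
injected dropouts; only their relation to the 70% inclusion threshold
matters downstream.

What the generator deliberately does **not** emulate: volume conduction and
inter-channel correlation, non-stationary band power within an event,
eye-blink/EMG spectral signatures, and the vendor's proprietary metric
formulas. Passing tests therefore demonstrate that the pipeline recovers
known spectral structure under realistic noise — not that it reproduces any
particular human dataset.

## Feature extraction

Quality gate: a participant is kept only if, in every analysed event, the
fraction of seconds in which *all* channels have CQ ≥ 70 and EQ ≥ 70 reaches
the coverage level (default 1.0, i.e. consistently good contact; the
threshold is inclusive). Epochs are 2 s, non-overlapping, Hann-windowed —
2 s gives 0.5 Hz resolution, comfortably resolving the 4 Hz-wide theta
band — and an epoch is rejected when any channel's peak-to-peak amplitude
exceeds 100 µV, a standard surface-EEG artifact heuristic.

Band power integrates the one-sided periodogram over half-open ranges
`[low, high)`: θ 4–8, α 8–12, βL 12–16, βH 16–25, γ 25–45 Hz. The α and βL
edges are chosen to tile the gap between the named θ/βH/γ edges exactly;
half-open assignment makes the five bands a partition of 4–45 Hz, so band
powers sum to the total in-range power to machine precision (a tested
invariant). DC is removed per epoch, making band powers invariant to offset
and sign.

### Performance-metric proxies

The vendor's attention/engagement/excitement/stress/relaxation/interest
metrics are closed-form secrets; the package instead defines transparent
band-ratio indices (documented in `?performance_metrics`), standardises each
against the participant's own baseline (events 1–2) and squashes with the
logistic function, so a window identical to the baseline mean scores exactly
0.5 and all values live in [0, 1]. These are declared *replacements*, not
reconstructions.

Metric windows are 10 s (the index is computed from the mean band powers of
the accepted 2 s epochs inside the window; a window with no accepted epoch
is missing). The 10 s cadence is chosen so the pooled per-group counts of
the study-style summary tables come out at participants × windows — 9 × 30 =
270 and 6 × 30 = 180 for a 300 s event, 3 × 18 = 54 for a 180 s one — the
pooling granularity such studies tabulate. Missing windows are counted, and
can be filled by `interpolate_missing()` (linear interior, nearest-value
edges; observed values never altered).

## Topography

Electrode means per group × event × band are normalised to 0–1 within each
panel (`(v − min)/(max − min)`; an all-equal panel maps to 0.5), matching
the per-panel colour scales of published heatmap figures. Interpolation is
inverse-distance weighting with power 2 over a disk of 1.1 × the outermost
electrode radius. IDW was preferred over spline surfaces because it is
exact at electrode sites, bounded by the input range and resolution-stable —
three properties the test suite pins; no second interpolator is offered, to
keep every rendered panel covered by those invariants. 2-D positions come
from an azimuthal projection of the standard 10-20 sphere, symmetrised
across homologous pairs; MNI152 coordinates mix study-reported scalp
locations with mirror-completed and template-projected entries, each flagged
by provenance.

## Statistics

Shapiro–Wilk screens normality (the study context is tie-heavy 7-point
Likert data and skewed metric pools, so non-parametric tests are the
default). The Mann–Whitney U test delegates to `stats::wilcox.test`: exact
enumeration when both samples are tie-free and `n_x · n_y ≤ 64`, otherwise
midranks with tie and continuity corrections; `W` follows the usual R
convention so tabulated values are directly comparable. A completely
degenerate comparison (all pooled values identical) is reported as p = 1.

The permutation test uses the standardised difference of group means,
seeded label shuffles and the add-one estimator
`p = (1 + #{|Z*| ≥ |Z|})/(n_perm + 1)` (default 10,000 permutations;
999–1999 in desk-scale configurations), which keeps p ≥ 1/(n_perm+1) and
makes the test valid at finite replicates. All alternatives are two-sided.
Raw p-values are reported; `adjust_pvalues()` applies Holm (or any
`p.adjust` method) when a family-wise view is wanted.

Likert sentiment maps 1–3 → negative, 4 → neutral, 5–7 → positive and
reports percentages per question and group.

## Pipeline, determinism and problem sizes

`run_pipeline()` archives its full configuration (`config.yaml`, plus a
hash in the run report), logs every exclusion with a reason, and writes all
tables as CSV; a fixed master seed yields byte-identical CSVs across runs
(numeric CSVs are written with round-trip-exact formatting). EDF+ was chosen
as the signal interchange format; quality series ride along as auxiliary
`CQ_`/`EQ_` channels and event markers as annotations, a documented dialect
of the format. Per-event availability (e.g. a smaller control group in one
event than another, as published figure captions sometimes show) is handled
naturally: summaries count whatever participants supply data for the event.

Test problem sizes are deliberately modest and stated here as package
choices: unit tests use 10–20 s events with 2–4 participants; the
study-shaped recovery check uses the full 9 + 6 cohort at default durations;
statistical calibration uses 1000 null replicates of a 199-permutation test;
the demo pipeline uses 3 + 2 participants with 20–60 s events.

## Known limitations

* The generator's independence across channels understates the spatial
  smoothness of real scalp maps; IDW rendering partially reintroduces it.
* The proxy metrics share a baseline-logistic scale with the vendor's 0–1
  outputs but not their formulas; absolute levels are not comparable
  across instruments.
* The game engine is deterministic and single-player; it models the
  decision problem, not the VR experience.
* With the printed cost parameters the NPC policy cannot amplify demand
  variance (see above); bullwhip diagnostics are most informative under
  configurations with `EOQ > D̄`.
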