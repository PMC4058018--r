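---
title: "Counting circulating melanoma cells: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting circulating melanoma cells: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcount)
```

## The measurement model

A cytospin slide carries a known number of cells (by default 50,000) drawn
from a CD45-depleted blood fraction. Three fluorescence channels are
acquired per field of view (FOV) on an 8-bit scale: DAPI (nuclei), red
(CD45, leukocytes) and green (Melan-A or S100B, melanoma marker). The
counting algorithm makes three assumptions worth stating explicitly:

* **Nuclei anchor cells.** Every countable object is a nucleated cell; the
  DAPI channel alone drives segmentation, and red/green intensities are
  read out relative to each nucleus. Fluorescent material without a nucleus
  is debris by definition.
* **Global thresholds per slide.** One red and one green threshold apply to
  the whole slide, chosen from the pooled per-cell intensity
  distributions — mirroring the original operator step of picking
  thresholds off a scatterplot. Thresholds are *not* adapted per FOV.
* **Classes are exclusive and exhaustive.** Every accepted (nucleated,
  non-border) cell lands in exactly one of green (CMC), red (leukocyte),
  yellow (dual) or null; this partition is enforced and tested.

A cell is a CMC iff it is green-positive, red-negative, has a well-defined
nuclear margin, and shows a staining pattern consistent with the marker
(Melan-A: predominantly cytoplasmic, uniform or punctate; S100B: cytoplasmic
and/or nuclear). Dual-positive cells are reported but never counted as CMCs
— their identity is left unresolved on purpose. Cell size is deliberately
not a criterion: cultured melanoma lines are visibly larger than
leukocytes, but patient CMCs often are not, so a size gate would bias
patient counts downward.

## Tunable parameters

All cut-offs live in `count_config()` and are validated on construction:

| parameter | default | units | rationale |
|---|---|---|---|
| `min_area`, `max_area` | 30, 5000 | px² | reject speckle and fused clumps; a 6 px-radius nucleus has area ≈ 113 px² |
| `ar_max` | 2.5 | – | nuclei are near-elliptical; elongated smears are artefacts |
| `circ_min` | 0.6 | – | circularity 4πA/P² (clamped to 1); irregular blobs fail |
| `margin_min` | 0.15 | – | margin score = mean boundary gradient / mean interior intensity; sharp nuclei score ≈ 0.5–0.6, heavily defocused ones < 0.1 |
| `annulus_width` | 4 | px | cytoplasm ring beyond the nucleus where red/green are read |
| `green_cv_cut` | 0.6 | – | per-pixel CV of annulus green; uniform staining ≈ 0.05–0.3, punctate ≈ 0.9–1.1 |
| `stringency` | 1.25 | – | green-threshold bias: ×1.25 for patient slides (against green), ÷1.25 for controls (toward green) |
| `debris_min_area` | 20 | px² | smallest anuclear blob tallied as debris |

The source material states the *direction* of the patient/control
stringency bias but not its magnitude, and the numeric morphology cut-offs
of the original supplementary criteria are not published; the values above
are this package's own defaults, chosen so that the synthetic ground-truth
benchmarks below pass with headroom, and every one is config-exposed.

The enumeration step has two bookkeeping inputs, `cells_per_slide`
(default 50,000) and `blood_volume_ml` (default 10 mL), both per-sample
fields in the manifest rather than constants — whether every sample in the
original cohort used exactly 10 mL is not stated.

## What the synthetic generator emulates — and what it does not

`make_fov()` renders nuclei as filled ellipses whose margins are smoothed
by a Gaussian of σ = 1/`margin_sharpness`, making the well-defined-margin
rule a *controllable* ground-truth property: the margin filter can be
tested in both directions by turning one knob. Green staining comes in
three patterns (uniform annulus; punctate foci in the annulus; uniform plus
nuclear, S100B-like); leukocytes carry red annuli; dual cells both; debris
is a union of small irregular ellipses with no nucleus — the original
material does not quantify debris morphology, so this model is an
assumption of ours, not a reproduction. Objects are placed without overlap
by rejection sampling (≤ 1000 attempts, then an error naming the failing
object): touching-cell resolution is out of scope, matching slides where
cells are mostly non-contiguous. Slide totals are spread over FOVs by
multinomial thinning, so per-FOV counts of a rare class are
Poisson-distributed while slide totals are conserved exactly.

Passing the synthetic benchmarks therefore shows that the *algorithmic*
chain — thresholding, morphology filters, annulus measurement, four-class
rules, extrapolation — is correct and well-calibrated on images whose
statistics it was designed for. It does **not** demonstrate robustness to
real-slide pathologies the generator omits: spectral bleed-through, uneven
illumination, autofluorescence, touching or overlapping cells, focus
gradients, and staining heterogeneity beyond the modelled patterns.

## Numerical choices

* **Isodata threshold.** Iterated from the midpoint of the occupied range;
  foreground is strictly above the threshold. The test suite checks the
  iterate against an exhaustive scan of all 256 candidates for the
  intermeans fixed-point condition on random bimodal histograms. A
  single-level histogram is a hard error — except in `select_thresholds()`,
  where a degenerate per-cell distribution (e.g. an all-negative channel)
  falls back to that single level, so the patient-mode bias still lands
  above every cell.
* **Connectivity and labels.** 8-connected components (4-connected labels
  merged across diagonals by union-find), relabelled in raster order.
* **Perimeter and circularity.** Boundary-pixel perimeter estimator;
  because digital perimeter estimates bias circularity upward for small
  near-circular objects, circularity is clamped at 1. A digital disk of
  radius 20 px scores ≥ 0.9; a large square tends to π/4.
* **Margin score.** Central-difference gradient magnitude averaged over
  8-connected boundary pixels, divided by mean interior intensity —
  scale-invariant, so it does not penalise dim nuclei.
* **Annulus measurement.** Intensities are read over a disc-dilated
  annulus that excludes all nuclear pixels. Whether the original script
  measured whole-cell masks or annuli is unstated; the annulus was chosen
  because it isolates cytoplasmic signal, which the Melan-A pattern rule
  needs anyway. Nuclei whose annulus would leave the image are flagged and
  excluded from tallies, preventing double counting across tiled FOVs.
* **Debris blobs.** Segmented at a robust per-channel background cut
  (median + 5 MAD) rather than the per-cell scatter thresholds, which can
  sit inside background noise on marker-negative slides; blobs touching a
  dilated nuclear mask are attributed to cells, the rest with area ≥
  `debris_min_area` are debris.
* **Empty slides.** With no measurable cells and no explicit thresholds,
  the slide reports all-zero tallies (thresholds pinned at 255); 1–9 cells
  raise an error suggesting explicit thresholds, since an intensity
  distribution that thin cannot support threshold selection.
* **Cox model.** Partial likelihood via `survival::coxph`, Breslow ties by
  default (the common default of the era's statistical packages), Efron by
  flag; Wald intervals exp(β ± 1.96 se). Tests cross-check the single-
  covariate fit against a grid search of the Breslow partial likelihood.
* **Exact Mann–Whitney.** The conditional null distribution of the rank
  sum given observed ties is built by dynamic-programming convolution over
  doubled (hence integer) average ranks, exact up to combined n = 25;
  beyond that a tie-corrected normal approximation is used. Two-sided
  p = 2·min(lower, upper), capped at 1.

## Open design decisions

* **Log base for the Cox covariate.** "Log-transformation of the counts"
  leaves the base open. The natural log is the default (HR per e-fold of
  count) and reproduces the published HR 1.46, CI (0.91–2.36), p = 0.12 on
  the packaged table; `run_cohort()` reports the log10 fit alongside
  (HR 2.40 — the same model, different per-unit scaling).
* **The ≤ 100/mL subgroup split.** On the BRAF-V600E-positive cutaneous
  subset, the log-rank test at the published ≤ 100 CMC/mL dichotomy gives
  p = 0.075 here, close to but not exactly the published p = 0.06. The
  original formulation behind that figure is not specified; we flag the
  discrepancy rather than tune the dichotomy to force agreement.
* **Limit of detection.** The published "limit of sensitivity of detection"
  (10 cells/mL by regression) has no stated operational rule. Ours is
  explicit and different in kind: the smallest spike level whose recovered
  counts exceed the maximum healthy background in ≥ 95% of replicates,
  ties resolved upward, with an `Inf` sentinel when no tested level
  qualifies. We make no claim of reproducing the published number, whose
  underlying raw data are not deposited.
* **Healthy controls.** Only the range (0–3 positives/mL, N = 10) is
  published; the packaged `healthy_controls_synthetic.csv` is a labelled
  synthetic stand-in within that range. The patients-vs-healthy
  Mann–Whitney conclusion rests on complete separation (minimum patient
  value 21/mL), so it is insensitive to the exact stand-in values.
* **Generator defaults.** Depletion efficiency 0.985 (middle of the
  reported 98–99% range), CMC loss 0.02 and spike recovery 0.95
  (spiked cells "fully recovered" within confidence limits), cohort
  median count 287/mL with ln-scale sd 1.8 (range spanning tens to tens of
  thousands), baseline hazard 0.007/month with 36-month censoring. These
  are fixed study conditions, not tuning knobs.

## Problem sizes used in the checks

The packaged benchmarks run at deliberately moderate scale: counting
accuracy on 20 slides spanning 5–500 true CMCs over 400 leukocytes each
(512×512 px FOVs, ~70 objects per FOV); control specificity on ten
5,000-cell marker-negative slides; Cox interval coverage over 200 cohorts
of 150 patients; recovery regression at 1,000 replicates per spike level.
A production slide (300+ FOVs, 50,000 cells) runs the same code path; the
synthetic sizes were chosen to exercise the same densities per FOV.

## Known limitations

* Per-FOV analysis only — no stitched-mosaic segmentation; cells split
  across FOV borders are excluded rather than merged, which slightly
  undercounts at high FOV counts (the generator places no objects across
  borders, so synthetic benchmarks do not probe this).
* No spectral unmixing or illumination correction; inputs are assumed
  flat-fielded 8-bit stacks.
* The four-class rule set is a faithful reconstruction from the published
  fragments of the original criteria; the verbatim supplementary rule list
  is not public, so equivalence cannot be verified rule-by-rule.
* Threshold selection on a slide whose per-cell intensity distribution is
  unimodal (e.g. pure leukocytes) splits the single mode arbitrarily
  between "red" and "null"; CMC counts are unaffected, but red/null
  tallies on such slides should not be over-interpreted.
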