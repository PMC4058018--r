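# cmcount

Enumeration of circulating melanoma cells (CMCs) from multichannel
immunofluorescence images of CD45-depleted blood fractions.

## The problem

Circulating tumour cells are rare — often a handful among millions of
leukocytes — and melanoma cells lack a reliable surface marker for positive
capture. A negative-selection workflow sidesteps this: leukocytes are tagged
with an anti-CD45 antibody and pulled out in a magnetic separator, leaving an
untouched, CMC-enriched fraction (the *Eluate*). Cells are deposited on
cytospin slides (50,000 cells per slide), stained with DAPI (nuclei), an
anti-CD45 counterstain (red) and a melanoma marker — Melan-A or S100B —
(green), and imaged as a grid of several hundred fields of view (FOVs).

`cmcount` implements the semi-automated counting algorithm and the
statistics around it, for researchers analysing such slides or benchmarking
rare-cell counting pipelines:

1. **Segmentation** — each DAPI FOV is thresholded with the isodata
   (intermeans) algorithm, the default automatic threshold in ImageJ:
   iterate *t* ← round((μ₍≤t₎ + μ₍>t₎)/2) to its fixed point on the 0–255
   histogram. Nuclear masks are filtered on area, aspect ratio, circularity
   (4πA/P², clamped to 1) and a margin score (boundary gradient / interior
   intensity) that operationalises the "well-defined nuclear margin" rule.
2. **Measurement** — red/green means over a cytoplasmic annulus around each
   nucleus, nuclear green, and the annulus green CV that separates uniform
   from punctate staining.
3. **Classification** — global red/green thresholds are chosen from the
   per-cell intensity distributions (biased against green for patient
   slides, toward green for healthy controls), and each nucleated cell falls
   into one of four classes: **green** (CMC: green⁺, red⁻, nucleated, with a
   marker-consistent staining pattern), **red** (leukocyte), **yellow**
   (dual-positive, never counted as a CMC) and **null**. Anuclear blobs are
   debris; border-touching cells are excluded. Cell size is *not* a
   criterion.
4. **Enumeration** — a slide tally *n* becomes a concentration via the
   cytospin sampling ratio, `n × (total cells in fraction / cells per slide)
   / blood volume`, with Poisson counting error CV = 100/√n %.
5. **Spike-in analysis** — recovery regression with 95% confidence band and
   an exceedance-over-background limit of detection.
6. **Cohort statistics** — exact Mann–Whitney (ties handled by
   dynamic-programming enumeration), univariate Cox proportional hazards on
   log counts, log-rank, Spearman, and ΔΔCt fold enrichment for miR qPCR.

Because no patient images are publicly deposited, a first-class synthetic
module renders ground-truthed FOVs (nuclei with controllable margin
sharpness, uniform/punctate/nuclear-cytoplasmic green patterns, red
leukocytes, dual-positive cells, anuclear debris) and simulates the magnetic
separation, spike-in series and survival cohorts, so every stage is testable
end to end.

## Worked example

```r
library(cmcount)

# a synthetic Eluate slide: 12 CMCs among 150 leukocytes over 8 FOVs
spec  <- scene_spec(n_cmc = 12, n_leuko = 150, n_dual = 4, n_debris = 10, seed = 42)
slide <- make_slide(spec, n_fov = 8)
counts <- count_slide(slide)
counts
#> <slide_count>
#>   CMC (green):     12  (Poisson CV 29%)
#>   leukocyte (red): 150
#>   dual (yellow):   4
#>   null:            0
#>   debris: 14, border-excluded: 0
#>   thresholds: t_red 70.0, t_green 82.5 (patient)

# 12 CMCs on a 50,000-cell slide from a 2.5e6-cell fraction, 10 mL draw:
per_ml(counts$tally[["n_cmc"]], total_cells_in_fraction = 2.5e6,
       cells_per_slide = 5e4, blood_volume_ml = 10)
#> [1] 60
```

All 12 planted CMCs are recovered; the dual-positive ("yellow") cells are
reported but excluded from the CMC count, and the Poisson CV says a count of
12 carries ~29% sampling error. The per-mL figure scales the slide count by
the fraction of the blood draw actually deposited on the slide.

The published patient table ships with the package:

```r
tab <- melanoma_cohort()
cox_ph_single(tab$survival_months, !tab$alive_at_analysis, log(tab$n_cmc_ml))
#> <cox_fit> HR 1.461, 95% CI (0.907, 2.356), p = 0.119
#>   (beta 0.379, se 0.244; 6 events / 11 subjects, breslow ties)

mann_whitney_exact(tab$n_cmc_ml, healthy_controls()$n_cmc_ml)$p
#> [1] 5.67e-06
```

Each e-fold increase in CMC/mL multiplies the hazard of death by ~1.46
(not significant in 11 patients), and patient counts separate completely
from the healthy-donor background.

A thin CLI wrapper for shell use lives at
`system.file("scripts", "cmcount.R", package = "cmcount")`
(subcommands `simulate`, `count`, `cohort`, `spike`, `demo`).

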