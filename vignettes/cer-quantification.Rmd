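---
title: "Quantifying chromosome association of mitotic reporters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome association of mitotic reporters: methods and design}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay

During metaphase, some regulatory proteins concentrate on the condensed
chromosomes of the metaphase plate. The strength of that association can be
read out from a single wide-field fluorescence image of a live cell
expressing a GFP-tagged construct, as a **chromosome enrichment ratio**:

$$ \mathrm{CER} \;=\; \frac{\bar I_{\mathrm{chrom}} - \bar I_{\mathrm{bg}}}
                          {\bar I_{\mathrm{cell}} - \bar I_{\mathrm{bg}}}, $$

the background-subtracted mean intensity of the metaphase-plate region
divided by the background-subtracted mean intensity of the whole cell. The
plate region is drawn by hand on the transmitted-light (DIC) channel, where
the chromosome mass is visible regardless of where the fluorescence sits;
the whole-cell region is segmented automatically by thresholding the
fluorescence channel at 12 standard deviations above the mean background
signal. A CER of 1 means the plate holds reporter at exactly the whole-cell
average concentration; published cohorts place the boundary between
chromosome-associated and excluded constructs at a CER of about 1.6.

Alongside the ratio, each cell receives a qualitative three-way call —
*positive*, *absent*, or *cannot-call* — where cannot-call covers cells
that are too dim or too bright to score (the quantitative analogue is a
whole-cell mean intensity outside the 50–500 window) or whose metaphase
plate is not well-defined in DIC. Cohorts of at least 8 quantified cells
per construct are compared with exact tests: Wilcoxon rank-sum for CER
distributions, Fisher's exact test for call frequencies, with an
Anderson–Darling screen to justify the nonparametric route.

The package implements this measurement chain end to end, and — because no
public image data exist for assays of this kind at this scale — drives it
with a synthetic metaphase-cell generator whose ground truth is known
analytically, so every stage is testable without a microscope.

## The synthetic cell model

A cell is an ellipse (default semi-axes 36 × 40 px at the scale of a 40X
objective with a 2×2-binned CCD, ≈0.32 µm/px) with a dome-shaped projected
thickness

$$ t(x, y) = \left(1 - r^2\right)^{p}, $$

where $r$ is the normalized elliptical radius and $p$ = 0.5 by default —
the projected thickness of a hemisphere, appropriate for a rounded mitotic
cell. The expected image is

$$ E(x, y) = b + t(x, y)\, m(x, y)\, A , $$

with $b$ the camera offset (20 ADU), $A$ the cell's expression level, and
$m$ a compartment multiplier: `chrom_enrich` on the central plate ellipse
(22 × 7 px), `spindle_enrich` on a pole-to-pole barrel, `centrosome_enrich`
as two Gaussian foci (σ = 3 px) at the spindle poles, 1 elsewhere. Noise is
Poisson shot noise on expected photons (4.6 photons/ADU) plus Gaussian read
noise (0.8 ADU), both optional.

Three consequences of this model carry the scientific content:

* **A uniform fluorophore reads CER > 1.** The plate sits in the thickest
  part of the cell, so even with $m \equiv 1$ the projected plate signal
  exceeds the whole-cell average (≈1.42 under the default geometry, and
  exactly 1.0 when $p = 0$ flattens the cell). This reproduces the
  geometric explanation for free GFP's CER of ~1.37 despite its exclusion
  from chromatin.
* **Ground truth is analytic.** The noise-free CER is a closed-form
  function of the profile and geometry, so `calibrate_profile()` can solve
  the plate multiplier that yields any attainable target CER exactly. The
  shipped catalogue (`inst/extdata/constructs.yaml`) encodes a published
  construct panel through its reported mean CERs (1.87 for the full-length
  fusion, 1.37 for GFP, 2.45/2.34/2.14 for N-terminal fragments, and so
  on); calibration reduces each entry to a plate multiplier between ~1 and
  ~2.2.
* **Per-cell expression is lognormal** (mean 200 ADU, CV 0.9), the
  right-skewed spread characteristic of transient transfection. Together
  with an ill-defined-plate probability of 0.18 this calibrates the
  cannot-call fraction into the reported 20–30% band. Draws are truncated
  at the level where the brightest compartment would hit the 12-bit
  ceiling — far above the 500-ADU overexpression cut, so the truncation
  only prevents the generator from refusing (by design it errors rather
  than silently clipping saturated expectations).

The emulated hand ROI is the truth plate ellipse shrunk by a seeded 0–2 px
erosion. An operator tracing the chromosome mass in DIC errs *inward* —
tracing outward would sweep in cytoplasm whose concentration differs from
the plate's by the full enrichment contrast. The asymmetry matters
quantitatively: at a plate of ~480 px and perimeter ~100 px, a 1-px outward
error contaminates the ROI mean by ~20% of pixels and biases high-CER
measurements down by 0.1–0.3, whereas a 1–2 px inward error changes the ROI
mean only through the mild thickness gradient across the plate (≲1.5%,
verified by the noise-free round-trip tests).

## Choices with a quantitative rationale

**Camera defaults.** The segmentation threshold is
$b + 12\,\sigma_{\mathrm{read}}$, and the QC window admits cells with
whole-cell means down to 50 ADU (signal ≈ 30 ADU over background). If the
threshold sits too close to that dim floor, the thresholded mask of a dim
cell keeps only its bright core, inflating $\bar I_{\mathrm{cell}}$ and
biasing CER low — with 2-ADU read noise the cohort bias reaches ~4% of the
CER, and cells far too dim to measure can even pass QC because the same
inflation lifts their measured mean past 50. The defaults (read noise 0.8
ADU, threshold ≈ 29.6 ADU) keep the threshold well below the dimmest
admissible cell's signal; under them, cohorts of 10 recover calibrated CERs
across 1.0–2.45 to within ±0.05.

**QC endpoints inclusive.** "Between 50 and 500" is read inclusively — the
weaker assumption — and the window is recorded in each measurement.

**Largest connected component.** The 12-SD threshold alone would admit
debris or neighbouring cells; one cell is imaged per measurement, so the
largest component is kept and a second component ≥ 50% of it triggers an
ambiguity warning rather than silent acceptance.

**Population SD for background.** The masked pixels are the entire
population of interest; at ≥ 100 pixels the $n$ vs $n-1$ distinction is
negligible, and the choice is documented rather than consequential.

**Negative ratios are reported.** A chromosome mean below background
yields a negative CER with a warning; clamping would bias cohort means and
break the linearity that the rank-based statistics assume.

**Positivity threshold 1.6, strict.** The published correlate is a band
("above 1.6–1.7"); the lower bound is the default because the published
figures draw their reference line at 1.6, the comparison is strict
(`cer > threshold`), and both are configurable. Classifications with 1.6
vs 1.7 can differ only for cells with CER in (1.6, 1.7].

**Tukey-hinge quartiles, range whiskers.** Matching the published box-plot
legend (box = 2nd and 3rd quartiles, whiskers = range, diamond = mean);
`fivenum()` hinges are used since the original software's quartile
convention is unknown, and the convention is written into the run log.

**Two-sided conventions for exact tests.** Fisher: sum of hypergeometric
probabilities ≤ the observed table's (relative tolerance 1e−12, so exact
rational ties are included symmetrically). Wilcoxon: double the smaller
tail, capped at 1, with mid-ranks for ties and the permutation distribution
computed over the observed tied configuration by a shift-algorithm dynamic
programme on doubled ranks — exact at every sample size, no normal
approximation. Anderson–Darling: case-3 statistic with the
$(1 + 0.75/n + 2.25/n^2)$ adjustment, rejection at 0.752 (α = 0.05), n ≥ 8
required.

**Contamination correction.** The chromosome pellet captures a fraction
$c$ of cytoplasmic protein (≈17%, measured with tubulin). Under the linear
mixing model the observed fraction is $f = T + c(1 - T)$, so the default
correction is its exact inverse, $T = (f - c)/(1 - c)$; the naive
subtraction $f - c$ is reported alongside because published corrected
ranges are compatible with either. With the published inputs (51% observed
cyclin B1, 45% CDK1, $c$ = 17%) the two models bracket the reported
"approximately 30–40%" range: 41.0/34.0% and 33.7/28.0%.

## What the generator does and does not emulate

It emulates: the dome-thickness geometry that inflates uniform-fluorophore
CERs; compartmentalized enrichment with exact ground truth; broad lognormal
expression and the resulting over/under-expression cannot-calls;
ill-defined plates as a Bernoulli truth flag (a human DIC judgment the
pipeline cannot re-derive, so it arrives as metadata); shot and read noise;
conservative hand-ROI error.

It does not emulate: **biological cell-to-cell variability in the
enrichment itself** — all cells of a construct share one true CER, so
per-cell scatter reflects measurement error only (SD ≈ 0.02–0.05) and is
several-fold smaller than real cohorts show. Synthetic Wilcoxon
comparisons are therefore far more powerful at equal $n$ than real ones: a
0.05 CER difference separates synthetic cohorts decisively, where real
cohorts need ~0.3. Passing tests demonstrate the correctness and
calibration of the *measurement and statistical machinery*, not realistic
effect-size inference. Also out of scope: DIC physics (the DIC channel is
represented only by masks and the plate flag), 3-D/confocal rendering,
kinetochore-scale structure, time-lapse kinetics, and gel densitometry
upstream of band integrals.

## Degenerate inputs and numerical edges

The generator refuses saturating expectations (no silent clipping) and
geometries whose plate is not strictly inside the cell or whose background
margin is under 10 px. Quantification errors name their stage: empty
background mask, empty post-threshold mask ("no cell detected"), empty ROI,
whole-cell mean at or below background ("degenerate cell signal"). All
RNG flows from explicit seeds; cohorts draw child seeds from the master
seed, so any cell is reproducible in isolation. Noise-free generation is
bit-deterministic and equals the expected image exactly, which anchors the
1e−9 formula-fidelity bound actually met at ~1e−16.

## Problem sizes

The validation suite and the reproduction script size their simulations
as: cohorts of 10 for recovery of the five calibration CERs
{1.0, 1.37, 1.6, 1.87, 2.45}; 100 runs of five 12-cell cohorts for the
rank-ordering check; 500 null cohort pairs for the Wilcoxon type-I rate
(binomial 99% CI around 0.05); 500 normal and 200 exponential samples for
the Anderson–Darling size/power checks; the exhaustive exact-test sweep
covers every 2×2 table and every untied rank configuration with total ≤ 16,
plus tied configurations against direct enumeration. On one CPU the full
suite runs in about two minutes.
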