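# cerquant

Quantification of mitotic chromosome association for fluorescent reporter
proteins, built around the **chromosome enrichment ratio (CER)**:

```
        mean(chromosome ROI) - mean(background)
CER  =  ---------------------------------------
        mean(whole cell)     - mean(background)
```

The chromosome region is a hand-drawn ROI over the metaphase plate (drawn
on the DIC channel, independent of the fluorescence); the whole-cell region
is segmented by thresholding the fluorescence channel at 12 standard
deviations above mean background and keeping the largest connected
component. A CER of 1 means the plate carries reporter at the whole-cell
average concentration; cohorts separate into chromosome-associated and
excluded constructs around a CER of ~1.6. Each cell also receives a
qualitative call — positive / absent / cannot-call — and cohorts are
compared with exact statistics (Wilcoxon rank-sum on CER distributions,
Fisher's exact test on call frequencies, Anderson–Darling normality
screen). A companion fractionation module converts immunoblot densitometry
of chromosome-enriched vs cytoplasmic fractions into a
contamination-corrected estimate of the chromosome-associated protein
fraction.

The package is aimed at cell biologists quantifying protein localization in
single mitotic cells, and ships a **synthetic metaphase-cell generator**
with analytic ground truth — dome-shaped cell thickness, compartment
enrichment multipliers, lognormal per-cell expression, Poisson + read
camera noise, emulated hand-ROI error — so the entire measurement chain is
validated end to end without any microscope data. Profiles are calibrated
so noise-free synthetic cohorts reproduce published per-construct mean CERs
exactly; the geometry alone explains why a uniformly distributed
fluorophore still reads CER ≈ 1.4 (the plate sits in the thickest part of
the cell).

## Worked example

```r
library(cerquant)

g     <- cell_geometry()                          # 128x128 px, 12-bit
profs <- load_construct_catalogue(geometry = g)   # calibrated construct panel

wt  <- generate_cohort(profs[["WT_1-433"]], 10, g, noise_model(), seed = 1)
ms  <- lapply(wt, quantify_cell)
sm  <- summarize_cohort(ms, sapply(wt, `[[`, "plate_defined"), "WT_1-433")
sm
#> cohort 'WT_1-433': 10 cells (8 positive / 0 absent / 2 cannot-call)
#>   CER (n=8 eligible): mean 1.871, median 1.872, IQR [1.865, 1.881], range [1.843, 1.890]

gfp <- generate_cohort(profs[["GFP"]], 10, g, noise_model(), seed = 2)
gsm <- summarize_cohort(lapply(gfp, quantify_cell),
                        sapply(gfp, `[[`, "plate_defined"), "GFP")
wilcoxon_exact(sm$cer_values, gsm$cer_values)
#> Wilcoxon exact rank-sum test (two-sided)
#>   statistic = 100, p-value = 0.0001554 (exact)

correct_contamination(51, 17)   # observed 51% in CHR, 17% contamination
#> observed 51.0% with 17.0% contamination
#>   corrected: 41.0% (proportional mixing) / 34.0% (subtraction)
```

The wild-type-like cohort recovers its calibrated mean CER of 1.87 within
measurement noise and scores positive; the GFP-like cohort sits at 1.37 —
above 1 purely through cell-thickness geometry — and scores absent. The
exact Wilcoxon p-value compares the two CER distributions over all
rank permutations; the fractionation call converts an observed 51%
chromosome-fraction signal into a corrected 34–41% association estimate
under the two documented contamination models.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/`:

1. `01_simulate_cohorts.R` — simulate annotated cohorts, write multi-page
   TIFFs + JSON truth sidecars + manifest;
2. `02_quantify_cer.R` — re-read the TIFFs, quantify every cell, compare to
   ground truth;
3. `03_score_and_compare.R` — the complete 12-construct experiment in one
   `run_experiment()` call: per-cohort summaries, pairwise exact tests
   against the full-length reference, box-and-whisker figure, seeded run
   log;
4. `04_fractionation.R` — contamination-corrected fractions from published
   band percentages plus synthetic round-trip validation.

Methodological background, parameter rationale and known limitations are in
`vignettes/cer-quantification.Rmd`.

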