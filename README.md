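# ribokinetics

Separating active translational regulation from the kinetic distortion of
ribosome density that accompanies transcriptional change.

## The problem

Ribosome density (RD) — footprint signal divided by mRNA abundance — is the
standard Ribo-Seq proxy for translation efficiency. But newly synthesized
mRNAs take time to become fully loaded with ribosomes. When transcription
rates step up (for example after acute DNA damage activates p53), the
transcript pool of an induced gene is transiently enriched for young,
under-loaded molecules, so its RD drops even though nothing about its
translation changed; repressed genes show the mirror inflation. Measured
far from steady state, this *passive kinetic effect* produces a strong
negative correlation between ΔRD and ΔmRNA across the transcriptome and
will swamp any naive "translation efficiency" analysis.

`ribokinetics` implements the regression-based correction: fit

  Δlog₂RD = a + b·Δlog₂mRNA        (OLS per genotype, on replicate means)

to capture the passive trend, score every gene by its signed orthogonal
(or vertical) distance from the line, and call genes with |distance| > 1
log₂ unit candidates for *active* translational regulation, combined
across two genotypes into a seven-way class (`up_wt_only`, `up_ko_only`,
`up_both`, the three `down` mirrors, `none`).

Around that core the package provides:

* **Footprint counting** — 25–35 nt length retention, ORF assignment via
  the 12 nt (start) / 15 nt (stop) 5′-end offset window, and single-gene
  multi-mapping resolution.
* **Median-of-ratios normalization**, low-count filtering (default:
  genes with a mean below 10 RNA reads in the treated condition of either
  genotype are removed), and per-condition RD computation.
* **Polysome-profile quantification** — UV-trace polysome percentages,
  spike-in normalized RT-qPCR fraction distributions
  (`AF^(−Ct_target) / AF^(−Ct_spike)`), cumulative curves across 13
  fractions, and the area-above-the-cumulative-curve association score.
* **A synthetic-data generator** whose loading-kinetics model (linear
  ramp to full load over an effective fill time, exponential age
  distribution under a step change in synthesis) reproduces the passive
  distortion, with configurable planted active regulation and
  negative-binomial count noise — so every claim the pipeline makes can be
  checked against ground truth.

## Worked example

```r
library(ribokinetics)

res <- run_pipeline(list(simulation = simulation_config(
  n_genes = 2000, n_replicates = 4, nb_dispersion = 0.05,
  planted_frac = 0.05, planted_delta = 2,
  planted_classes = "up_wt_only", seed = 2)))
res$fits$WT
#> Passive trend: delta_RD = 0.0618 -0.3721 * delta_mRNA  (R_P = -0.579, n = 2000)
#>   residual SD: 0.5296 vertical, 0.4963 orthogonal
unlist(res$class_counts)
#> up_wt_only  up_ko_only  up_both  down_wt_only  down_ko_only  down_both  none
#>        102           1        1             2             0          0  1894
```

The negative slope and Pearson correlation are the passive kinetic trend;
the 100 genes carrying a planted +2 log₂ translational offset in the WT
NCS condition are recovered inside the 102 `up_wt_only` calls, while the
passive bulk stays in `none`. On a passive-only cohort (no planting) the
same run leaves ~99.7 % of genes unclassified and fits R_P ≈ −0.79.

The numbered drivers under `analysis/` narrate the full workflow —
`01_simulate_data.R` (study-design cohorts), `02_footprint_counting.R`,
`03_passive_regression.R` (fits, classes, scatter),
`04_polysome_quantification.R` (UV-trace percentage, fraction
distributions and association scores) — writing their tables under
`results/`.

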