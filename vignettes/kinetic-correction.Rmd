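---
title: "Separating active translational regulation from kinetic RD distortion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating active translational regulation from kinetic RD distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribokinetics)
```

## The passive kinetic effect and why a regression is needed

Ribosome density (RD) — normalized footprint counts divided by normalized
mRNA counts — is only a faithful proxy for translation efficiency at
steady state. A transcript must be transcribed, processed, exported and
progressively loaded with ribosomes before it carries its full complement;
while transcription rates are changing, the age composition of each gene's
transcript pool is shifted. Shortly after an induction step the pool is
enriched for young, under-loaded molecules and RD is depressed; after
repression the surviving pool is old and fully loaded, and RD is inflated.
Across a transcriptome measured a few hours into an acute response this
produces a strong negative correlation between Δlog₂RD and Δlog₂mRNA that
has nothing to do with translational control.

The package's core statistic therefore fits the bulk trend by ordinary
least squares on per-genotype replicate means,

$$\Delta \log_2 RD = a + b\,\Delta\log_2 mRNA,$$

and treats the signed distance of each gene from the line as its
regulation score. The distance is **orthogonal** by default (Euclidean
distance to the line, `residual / sqrt(1 + b²)`, positive above it);
vertical residuals are available via `mode = "vertical"`. The analysis
text behind this design says only "distance from the regression line", so
the mode is recorded in every fit and output rather than hidden. Genes
with distance > 1 log₂ unit (strictly; ties excluded) are called
translationally up-regulated, below −1 down-regulated, and the calls from
the two genotypes combine into seven classes. Down-regulation mirrors
up-regulation by symmetry; no separate rule is published for it, which is
why the thresholds are shared. When a gene is classified in one genotype
only (it failed the count filter in the other), the default pipeline drops
it (`drop_single_genotype = TRUE`); keeping it classifies on the available
genotype and flags the provenance.

## The loading-kinetics model in the generator

No closed kinetic model is published for this correction, so the generator
uses the simplest one that produces the documented transient: a transcript
of age $a$ carries ribosome load $\rho \min(a/T, 1)$ with steady density
$\rho$ and *fill time* $T$; transcript ages are distributed as
$n(a,t) \propto k(t-a)e^{-\delta a}$ for first-order decay $\delta$ and a
step in synthesis rate $k$ of fold change $F$ at $t=0$. Both the
population mean RD at sampling time $t$ and the pre-step steady state have
closed forms (`passive_rd_ratio_vec()`); the test suite checks them
against direct numerical integration of the age distribution to 1e-6.
Alternatives (e.g. exponential approach to full load) change only the
curve's shape, which nothing downstream consumes.

Parameter defaults, chosen once for realism:

* `decay_rate`: log-normal across genes, median 0.25 h⁻¹ (half-life
  ≈ 2.8 h, typical for mammalian mRNA), sdlog 0.4;
* `sample_time = 4` h — the acute-treatment duration the design emulates;
* `fill_time = 6` h — an *effective* timescale lumping processing, export
  and progressive ribosome recruitment. A single ribosome transits an ORF
  in minutes, but the RD depression observed hours into real responses
  implies a much slower effective approach to full load; with $T = 6$ h
  the deterministic curve yields a transcriptome-wide correlation of about
  −0.7 at 4 h, the strength seen in practice. This constant is a model
  stand-in, not an estimate of any molecular rate;
* `steady_density`: log-normal, median 5 ribosomes/transcript, sdlog 0.5
  (it cancels from all RD contrasts and only shapes footprint depth);
* fold changes: $\log_2 F \sim N(0, 1.5)$, shared between genotypes so the
  NCS-vs-control contrast is comparable across them;
* counts: negative binomial with shared dispersion 0.05
  (`variance = μ + 0.05 μ²`), the standard bulk model; dispersion 0 gives
  Poisson;
* `library_size = 5e6` usable reads per library, a realistic post-filter
  depth for both assays.

Active regulation is planted as a log₂ offset `delta` multiplying the
footprint expectation in the NCS condition of the affected genotype(s);
classes are planted symmetrically by default so every classifier branch is
exercised. The generator writes the per-gene truth (fold change, decay,
passive ratio, offsets, class) beside the count tables.

What the generator does *not* emulate: gene-length and codon-usage biases,
positional footprint structure, multi-isoform RNA complexity, batch
effects, and any proteome layer. Passing tests therefore demonstrate that
the statistics recover what they are defined to recover under the stated
noise model — not that the biological model of any real dataset is
correct.

## Normalization and filtering choices

Size factors are the median across usable genes (positive in all samples)
of the sample/reference ratio, the reference being the gene's
cross-sample geometric mean. The median over an even number of ratios is
the arithmetic midpoint of the central two — stated because the popular
log-scale implementation averages geometrically and differs in the last
few digits. Footprint and RNA libraries get separate factors, since depth
differs by assay. A consequence worth knowing: median-ratio factors are
invariant to a global rescaling of all libraries, so *normalized* counts
(and raw RD values) scale with overall depth; every quantity the
classifier consumes is a within-assay condition contrast, which is exactly
invariant to any per-library rescaling.

The default count filter removes genes whose mean raw RNA count in the
treated (NCS) condition of either genotype is below 10 — strictly below,
computed on replicate means, consistent with the regression being fitted
on means. The published wording is ambiguous about whether the filter
applies to RNA-Seq only or to the treated condition generally; the
condition set is a plain argument (`conditions =`), and a threshold-5
variant on normalized counts is available by passing the normalized matrix
with `threshold = 5`.

## Polysome quantification choices

Fraction quantities are spike-normalized as
$AF_{target}^{-Ct}/AF_{spike}^{-Ct_{spike}}$. The equation as usually
printed in methods sections carries $AF^{+Ct}$, which taken literally is
the reciprocal of an abundance ratio; the package uses the standard
$AF^{-Ct}$ convention (quantity halves per extra cycle) so that
quantification inverts the generator's forward model exactly.
Amplification factors default to 2.0 unless a measured primer efficiency
is supplied.

The association score is the area above the cumulative distribution,
computed as a right-Riemann sum over unit-spaced fraction indices and
normalized by the number of fractions K, so it lives in [0, (K−1)/K]:
0 when all mRNA sits in fraction 1, 12/13 ≈ 0.923 when all sits in
fraction 13, strictly increasing under any rightward mass shift. The raw
(unnormalized) area is returned alongside; a trapezoidal variant
(linearly interpolated cumulative curve) is available by flag since the
step-vs-interpolated reading is not standardized. UV-trace percentages
integrate baseline-subtracted absorbance trapezoidally over annotated
monosome and polysome regions; the baseline is a supplied constant or the
minimum over a designated inter-peak window.

## Numerical and degenerate-input behaviour

* `passive_rd_ratio` returns exactly 1 at `F = 1`, `fill_time = 0` or
  `sample_time = 0` (the limits are set explicitly, not left to
  cancellation), and rejects non-positive rates.
* `delta_log2` flags zero/negative means as `NA`; flagged genes are
  excluded from fits and distances.
* OLS requires ≥ 3 finite pairs and ≥ 2 distinct abscissae; a degenerate
  x configuration is an error, not a silent NA slope.
* Zero-weight fractions travel as `Ct = Inf` and quantify to exactly 0,
  so single-fraction distributions round-trip bit-exactly.
* Classification uses strict inequalities; a distance of exactly 1 is
  `none`. Opposite up/down calls across genotypes are resolved in favour
  of the up call (both distances stay visible in the output).
* Seeded runs are bit-reproducible: one seed governs each generated table
  and is recorded in the ground truth; `run_pipeline()` re-runs with an
  identical config reproduce identical file hashes.

## Problem sizes

The shipped analyses and checks use 2,000-gene cohorts with 4 replicates
per condition (the emulated design), 20-cohort batches for false-positive
rates, 10,000 synthetic reads for counting equivalence, and 100–1,000
random cases for the algebraic identities — sizes at which every property
under test is already stable.

## Known limitations

* The fill-time constant is an effective, not mechanistic, parameter; do
  not interpret it as a ribosome transit time.
* The regression correction assumes one global passive trend; gene-class
  specific kinetics (e.g. very short-lived transcripts) appear as
  residual structure it cannot separate from active regulation.
* Orthogonal distances mix the units of the two axes; with slopes near
  −0.4 the practical difference from vertical residuals is ~7 %, but the
  threshold of 1 is convention-bound either way.
* The polysome score treats fractions as ordinal with unit spacing;
  sucrose coordinates are not used.
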