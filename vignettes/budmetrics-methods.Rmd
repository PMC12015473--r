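---
title: "Methods: digital bud morphometrics and trait genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital bud morphometrics and trait genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budmetrics)
```

`budmetrics` packages the analysis chain behind scanner-based bud
phenotyping of tea germplasm: image morphometrics, germplasm diversity
statistics, phenotype clustering, trait–expression screening, and
candidate-interval construction from association scans. This vignette
explains the models and the numerical and design choices, and states
exactly what the synthetic-data module does and does not emulate.

## Imaging model

Buds are imaged on a flatbed scanner against black light-absorbing
cloth, so the image model is bright, roughly convex objects on a dark,
lightly noisy background with no perspective distortion. Calibration is
purely resolution-driven: one pixel is $s = 2.54/\mathrm{dpi}$ cm on a
side (0.00423 cm at the usual 600 dpi). No fiducial markers are used.

Segmentation thresholds the brightness channel $V=\max(R,G,B)$ — robust
to the green–brown hue range of tea buds — with Otsu's method by
default and a fixed threshold as fallback for pathological histograms.
Morphological opening (disc radius 2 px) removes speckle, closing
bridges small gaps, holes are filled, and components are labelled with
8-connected foreground / 4-connected background, the standard
complementary pair that keeps hole filling consistent. Components
smaller than 0.02 cm² (far below the ~0.27 cm² minimum of real apical
buds) are discarded, and components touching the image border are
excluded by default since they are likely truncated by the scan window.

The four features per bud are defined as:

* **area** $A$ — foreground pixel count × $s^2$. Because the synthetic
  renderer thresholds 4×-supersampled coverage at 0.5, and a real
  scanner's pixel response behaves similarly, pixel counting is close
  to unbiased.
* **perimeter** $P$ — arc length of the 0.5-level contour of the mask,
  taken after light Gaussian smoothing ($\sigma = 1$ px). Counting
  boundary pixels overestimates oblique edges by up to ~27 %; a
  marching-squares contour of the raw binary mask still carries a few
  percent of staircase bias at unfavourable edge angles. Smoothing
  first lets the interpolated contour track straight edges at sub-pixel
  accuracy. Smoothing also shifts the level set inward by
  $\sigma^2\kappa/2$ at curvature $\kappa$; integrated around a convex
  contour this removes $\pi\sigma^2$ px of length, which is added back
  as a first-order correction. Across stadiums, ellipses and circles at
  600 dpi the residual error is well under 1 %.
* **length and width** $(L, W)$ — the sides of the minimum-area rotated
  bounding rectangle of the contour's convex hull, found by rotating
  calipers over hull edges. This caliper definition is exact for
  straight buds and deterministic; a medial-axis (curved) length is
  deliberately not implemented, since strongly curved buds have no
  closed-form oracle and panels are scanned with buds laid straight.
  Degenerate single-pixel masks return $L = W = s$, $P = 4s$ by
  convention.

These definitions satisfy, and the tests assert, $L \ge W$, the
isoperimetric inequality $P \ge 2\sqrt{\pi A}$, and $A \le L\,W$ for
every emitted row, plus scale equivariance across dpi and ≤ 2 % drift
under rotation at 600 dpi.

Digital-vs-manual validation is modelled as an OLS regression of
estimates on reference values with $R^2$ (squared Pearson correlation)
and RMSE in trait units; on 50 synthetic buds the extracted lengths
achieve $R^2 \ge 0.99$ and RMSE ≤ 0.07 cm, the benchmark reported for
calliper validation of this kind of software.

## What the synthetic scenes emulate — and what they do not

Scenes are built from stadiums (rectangle + semicircular caps),
ellipses and circles because all four features have closed forms: for a
stadium of length $L$ and width $W$ with $a = L - W$,
$A = aW + \pi(W/2)^2$ and $P = 2a + \pi W$; ellipse perimeters use
Ramanujan's second approximation (relative error < 10⁻⁶ at bud aspect
ratios). Shapes are rasterized by 4× supersampling the analytic inside
test and thresholding coverage at 0.5, giving crisp edges within
±0.125 px of the true boundary; the background is near-black with
Gaussian noise, and geometry is independent of the noise seed.

The scenes do **not** emulate bud curvature, trichome fuzz, shadows,
specular highlights, or touching buds. Passing the closed-form suite
therefore demonstrates the correctness of the measurement chain on
well-separated, straight, crisply imaged objects — the intended
operating regime — not robustness to messy acquisitions. Overlapping
buds must be physically separated before scanning.

## Diversity statistics

All per-trait statistics operate on accession means (arithmetic mean of
replicate buds); heritability alone uses the replicate table.

* **CV** = σ/μ × 100 with the sample (n−1) SD throughout.
* **Shannon–Wiener $H'$**: germplasm convention grades a continuous
  trait into 10 classes anchored at the sample moments — class 1 below
  μ−2σ, classes 2–9 in successive 0.5σ bands, class 10 above μ+2σ —
  and computes $H' = -\sum p_i \ln p_i$ over occupied classes. The
  binning makes $H'$ invariant to affine rescaling of the trait. For a
  normally distributed trait the exact band probabilities give
  $H' = 2.0878$; values above 1.9 therefore indicate near-normal,
  well-spread variation, matching the 1.93–1.97 range published for
  bud traits. Note the $\ln 10 \approx 2.303$ ceiling is not attainable
  by real samples: equal occupancy of all 10 classes is inconsistent
  with the classes being anchored at the sample's own mean and SD.
* **Broad-sense heritability**: with clonal replicates within
  accession, a single-environment one-way random-effects decomposition
  gives $\sigma^2_g = (MS_{between} - MS_{within})/n_0$ (truncated at
  0), with $n_0 = (N - \sum n_i^2/N)/(a-1)$ for unbalanced designs, and
  $h^2 = \sigma^2_g/(\sigma^2_g + MS_{within})$, clipped to [0, 1].
  This is the natural estimator when replication is clonal buds in one
  environment; multi-environment decompositions are out of scope. On a
  simulated 280 × 15 panel the estimator recovers a true $h^2 = 0.75$
  within ±0.05.
* **Normality** uses Royston's Shapiro–Wilk as implemented in
  `stats::shapiro.test` (3 ≤ n ≤ 5000).

The phenotype simulator draws
$y_{ijt} = \mu_t + g_{it} + e_{ijt}$, $g \sim N(0, \sigma^2_g)$,
$e \sim N(0, \sigma^2_e)$, with defaults set to the published panel
scale (e.g. bud length 2.65 ± 0.38 cm) and $\sigma_e$ chosen per trait
so the target heritabilities are 0.72/0.90/0.71/0.60; 15 replicates per
accession mirrors the minimum sampling used in such panels. Trait
effects are drawn independently across traits, so the simulator does
not emulate the strong inter-trait correlations of real buds — cluster
structure is instead planted explicitly via group offsets when needed.

## Clustering

Accessions are clustered on Euclidean distances over trait means.
Defaults: z-score standardization per trait (so perimeter, an order of
magnitude larger than width, does not dominate the metric) and Ward
linkage (`ward.D2`, the Euclidean form of Ward's criterion). Ward on a
few-hundred-accession standardized panel produces merge heights in the
10–20 range, consistent with cutting a 280-accession tree into four
groups at height 16; single/complete linkage heights top out far lower
and could not be cut there. Both choices are configurable. Cutting is
by height or by group count; groups are canonically labelled I, II, …
by descending size so "Group I" is always the largest, and summaries
report per-group trait means and a region × group table over the top-N
regions of origin (default 15).

## Expression screening

The extreme-design screen correlates each gene's expression with each
bud trait across 8 samples (4 small-bud, 4 large-bud accessions), with
the t-transform p-value ($t = r\sqrt{(n-2)/(1-r^2)}$, df = n − 2), and
requires $p < 0.01$ *and* $|\log_2 FC| > 1$. Choices worth making
explicit:

* **No multiple-testing correction** — deliberately mirrors the raw
  screen; this is candidate generation, not inference, and is
  documented as such. Null calibration is still tested: on simulated
  null matrices the pre-filter positive rate sits within 3 binomial SEs
  of 1 %.
* **Fold-change orientation** is fixed large-over-small with
  pseudocount ε = 0.1 on group-mean TPM, so unexpressed genes get a
  finite FC without crushing moderate ratios. Reports of the same
  family of genes as both "upregulated in large buds" and "negatively
  correlated with size" appear in this literature because the FC sign
  convention is often left implicit; fixing the orientation removes the
  ambiguity.
* **Correlation scale** defaults to raw TPM (with a `log` switch),
  since the published screen correlates abundance directly.
* n = 8 is small; p-values are exact only under bivariate normality.

The expression simulator plants linked genes as
$\log_2(TPM+1) = b_0 + \beta z(\text{trait}) + N(0, \sigma)$ (slope
±1.5 by default, alternating sign) over a null background of
log-normal baselines. The planted-recovery fixture uses 100 genes with
30 strongly linked (noise SD 0.05): large enough that false positives
are possible in principle, small enough that exact 30/30 recovery with
zero extras is the expected outcome of a correct implementation.

## Association intervals

Per-trait scans (`chrom, pos, p`) are combined; a SNP is a candidate if
significant in ≥ 2 of the four size traits — the multi-trait support
rule that suppresses trait-specific noise. The significance default is
$10^{-6}$: methods texts for this analysis quote $P < 6\times10^{-6}$
while the Manhattan-plot threshold line is drawn at
$-\log_{10}P = 6$; the stricter plotted line is the default and the
threshold is a plain argument. Candidates are flanked by 100 kb each
side (clipped to chromosome ends), and per-chromosome intervals that
overlap *or are book-ended* (next start ≤ current end + 1) are merged —
the behaviour of the standard BED merge tool — with source SNPs and
supporting traits unioned into merged records. Coordinates are 1-based
inclusive internally (GFF/VCF convention); BED export converts to
0-based half-open at the file boundary only. Gene overlap requires ≥ 1
shared bp, and genes are counted once across intervals. The merge is
idempotent and monotone in flank and support threshold, and is tested
against a brute-force per-bp painting oracle.

Lead-SNP stratification groups accessions by unphased genotype class
(0/0, 0/1, 1/1; missing excluded; phasing separators normalized), runs
a one-way ANOVA per trait, Tukey HSD on the studentized range
(Tukey–Kramer for unbalanced classes, via `stats::TukeyHSD`), and a
compact letter display at α = 0.05 built by insert-and-absorb: start
with one letter covering all classes, split any letter containing a
significantly different pair, absorb subset letters.

## Problem sizes and determinism

The test suite and acceptance script run everything at desk scale:
50-bud closed-form batches at 600 dpi, 280 × 15 phenotype panels,
1000-gene null and 100-gene planted expression matrices, and
100-fixture randomized merge checks on 40–60 kb toy chromosomes (small
enough for the per-bp oracle). These sizes give each statistical check
comfortable power while keeping a full run in minutes on one core.
Every stochastic step takes an explicit seed; identical seeds and
configurations produce byte-identical outputs, and pipeline artifacts
carry provenance headers (package version, seed, configuration hash) so
mixed-provenance inputs are detectable downstream.

## Known limitations

* Caliper length under-measures strongly curved buds; no medial-axis
  option.
* Color/texture features, multi-organ classification and
  camera imaging with perspective are out of scope.
* The heritability model is single-environment; genotype × environment
  variance is not separable from genetic variance here.
* The association stage consumes per-SNP p-values; the mixed-model
  association engine itself (kinship, REML) is upstream and out of
  scope, as are LD structure and imputation.
* Published headline counts from real panels (e.g. hundreds of
  intervals spanning ~156 Mb with ~2900 genes) depend on undeposited
  images and genotypes; this package reproduces the *procedures* and
  their printed worked examples, not those dataset-specific counts.
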