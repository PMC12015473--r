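# budmetrics

Digital bud phenotyping and downstream trait genetics for tea
(*Camellia sinensis*) germplasm.

Apical bud size — length, width, perimeter, area — is a harvest-relevant,
highly heritable quantitative trait in tea. `budmetrics` implements the
full analysis chain used to characterize it in large germplasm panels:

1. **Imaging** — buds are scanned on black light-absorbing cloth with a
   flatbed scanner (typically 600 dpi PNG). The brightness channel
   `V = max(R,G,B)` is Otsu-thresholded, cleaned by morphological
   opening/closing and hole filling, and 8-connected components become
   bud masks. Per bud: area `A` = pixel count × s², perimeter `P` =
   sub-pixel 0.5-level contour length × s, and `(L, W)` = sides of the
   minimum-area rotated bounding rectangle (rotating calipers), with
   `s = 2.54/dpi` cm/px.
2. **Diversity statistics** — per trait: max/min/mean/SD, CV = σ/μ×100,
   Shannon–Wiener index `H′ = −Σ pᵢ ln pᵢ` over 10 grading classes
   anchored at μ ± 2σ in 0.5σ steps, broad-sense heritability
   `h² = σ²g/(σ²g + MS_within)` from a one-way random-effects
   decomposition of clonal replicate buds, and a Shapiro–Wilk normality
   test.
3. **Clustering** — Ward hierarchical clustering of accessions on
   z-scored trait means, cut by height or group count, with per-group
   and region-of-origin summaries.
4. **Expression screening** — per-gene Pearson correlation between TPM
   and bud size across a 4-small vs 4-large extreme-accession design
   (`p < 0.01`), a `|log2FC| > 1` filter (large over small, pseudocount
   0.1), per-trait gene sets, their four-way intersection, and a
   row-z-scored matrix for heatmaps.
5. **Association intervals** — SNPs significant (`P < 1e-6` by default)
   in ≥ 2 traits are flanked by 100 kb, overlapping/book-ended windows
   merged, genes overlapped from GFF3, and phenotypes stratified by
   lead-SNP genotype with one-way ANOVA + Tukey HSD compact letters.

A synthetic-data module generates every input the chain consumes —
scanner scenes built from stadium/ellipse shapes with *closed-form*
length/width/perimeter/area ground truth, replicate phenotype tables
with known heritability, TPM matrices with planted trait-linked genes,
and association scans with planted multi-trait peaks — so the whole
pipeline runs and is testable fully offline.

## Worked example

Render a bud-shaped stadium (2.65 × 0.35 cm, the mean bud size of a
diverse tea panel) at 600 dpi, segment it, and measure it:

```r
library(budmetrics)

sp <- shape_spec("stadium", length_cm = 2.65, width_cm = 0.35,
                 center_px = c(350, 350), angle_deg = 25)
sp$perimeter_cm; sp$area_cm2        # closed forms: 5.700 cm, 0.9012 cm^2

sc    <- render_scene(list(sp), dpi = 600, size_px = c(700, 700), seed = 42)
masks <- segment_buds(sc$image)
measure_bud(masks[[1]], px_scale(sc$image))
#>   length_cm width_cm perimeter_cm area_cm2
#> 1    2.6502   0.3521         5.73   0.9024
```

Every measured feature is within a fraction of a percent of its
analytic value. Simulate a 280-accession × 15-replicate panel at the
reference trait scale and summarize it:

```r
ph <- simulate_phenotypes(seed = 1)
stats_table(ph)
#>       trait   max   min  mean     sd cv_pct h_prime    h2 shapiro_p
#> 1      area 1.101 0.260 0.590 0.1368   23.2    2.05 0.578    0.0769
#> 2    length 3.834 1.613 2.652 0.3948   14.9    2.08 0.734    0.6274
#> 3 perimeter 8.094 3.070 5.776 0.8231   14.2    2.09 0.700    0.6091
#> 4     width 0.478 0.203 0.347 0.0512   14.8    2.08 0.904    0.3923
```

CVs land in the published 14–25 % range, diversity indices exceed 1.9,
and the heritabilities recover the panel's 0.60–0.90 targets. The
published 100-kb worked example reproduces exactly:

```r
build_intervals(data.frame(chrom = "Chr10", pos = 14322573,
                           traits = "length,width"),
                c(Chr10 = 2.5e7))
#>   chrom    start      end n_snps  snp_pos       traits
#> 1 Chr10 14222573 14422573      1 14322573 length,width
```

i.e. the 14.22–14.42 Mb candidate window around the lead SNP
Chr10:14322573.

A thin shell front end over the same functions ships at
`system.file("exec", "budmetrics", package = "budmetrics")` with
subcommands `simulate`, `extract`, `stats`, `cluster`, `screen`,
`intervals`, `stratify` and `run`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "budmetrics",
                               load_package = "installed")'
```

The suite checks every stage against independent oracles: closed-form
shape geometry, hand-worked ANOVA tables, exact normal band
probabilities, `cor.test`, brute-force per-bp interval merging, and
planted-truth recovery from the simulators.

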