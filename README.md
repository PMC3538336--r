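# seedscan

Automated seed morphometry from flatbed-scanner images, and preparation of
per-line phenotypes for quantitative genetics.

Seed size is a classic quantitative trait: in populations such as the
Arabidopsis Ler × Cvi recombinant inbred and near-isogenic lines, a large
share of the variance in seed area and axis lengths is genetic, and mapping
that variation requires measuring thousands of individual seeds accurately
and reproducibly. `seedscan` implements the image-analysis half of that
workflow:

1. **Batch thresholding** — an Otsu threshold per image, pooled into one
   batch threshold (the mean of the defined per-image thresholds), so every
   scan in a batch is segmented consistently.
2. **Segmentation** — dark seeds on a light platen: a pixel is foreground
   iff its intensity is strictly below the threshold; foreground is split
   into 8-connected components (C++ flood fill).
3. **Morphometry** — per component: pixel area and the axes of the
   moment-equivalent ellipse (second central moments with a 1/12
   pixel-extent correction; major = 4√λ₁, minor = 4√λ₂), converted to mm
   via the image dpi.
4. **Filtering** — every component is audited through three tests and kept
   in the output with its flags: border contact (clipped shapes), ellipse
   consistency (pixel area within 10% of π·major·minor/4 — rejects touching
   seed pairs and fibrous debris), and aspect ratio (major/minor ≤ 2.5 —
   rejects scratches). Only components passing all three are accepted
   seeds.
5. **Phenotypes** — per-line trait means with unweighted replicate
   averaging, one-way ANOVA variance components
   (V_A = max(0, (MS_M − MS_E)/n₀), unbalanced-design n₀), and broad-sense
   heritability H² = V_A/(V_A + V_E).

A synthetic seed-field generator (`fieldSpec()` / `renderField()`) renders
anti-aliased, noisy scanner-like images with exact per-object ground truth
— single seeds, obliquely touching pairs, scratches, debris — so the whole
pipeline is testable without scanner data. See the methods vignette
(`vignettes/seed-morphometry.Rmd`) for the model, parameter rationale, and
the generator's limits.

## Worked example

Render a small synthetic field, segment it at its Otsu threshold, and
measure it:

```r
library(seedscan)

spec <- fieldSpec(width = 640L, height = 640L, nSingles = 6L, nPairs = 2L,
                  nScratches = 1L, nDebris = 2L, rngSeed = 7L)
f <- renderField(spec)
f$image
#> RasterImage 'synth-7': 640 x 640 px, 3200 dpi, range [24, 255]

t <- otsuThreshold(f$image)
t
#> [1] 141

lab <- labelComponents(binarize(f$image, t))
lab
#> ComponentLabeling 'synth-7': 11 components, 0 touching the border

rec <- filterComponents(measureComponents(lab), dpi = 3200)
table(accepted = rec$accepted)
#> accepted
#> FALSE  TRUE
#>     5     6

head(rec[rec$accepted, c("label", "area_mm2", "major_mm", "minor_mm")], 3)
#>   label area_mm2 major_mm minor_mm
#> 6     6    0.121    0.523    0.296
#> 7     7    0.146    0.602    0.309
#> 8     8    0.140    0.571    0.311
```

All 6 single seeds are accepted; the 2 touching pairs fail the
ellipse-consistency test, the scratch fails the aspect test, and the 2
debris fragments fail the ellipse test — 11 components, 6 accepted, and
every rejected component remains in `rec` with its per-filter flags.

From accepted per-seed records with `line_id` (and optionally
`replicate_id`) columns, phenotypes and heritability follow:

```r
ph  <- lineMeans(records)          # per line x replicate means
fin <- replicateAverage(ph)        # unweighted replicate averaging
exportPhenotypes(fin, "phenotypes.csv")
heritabilityReport(records)        # ANOVA components + H2 per trait
```

With externally known variance components, `heritability()` (or the
command-layer `cmdHerit(va=, ve=)`) gives the ratio directly:

```r
heritability(2.60e-4, 9.78e-5)
#> [1] 0.7266295
cmdHerit(va = 2.60e-4, ve = 9.78e-5)$H2
#> [1] 0.727
```

## Command-line use

`inst/scripts/seedscan` is a thin Rscript wrapper over the exported
`cmd*()` functions:

```sh
seedscan measure   --in scans/ --out run1/ --dpi 3200
seedscan aggregate --records run1/ --sheet lines.csv --out seeds.csv
seedscan herit     --input seeds.csv --out herit.csv
seedscan synth     --spec field.yaml --out synth/ --n-images 5
```

`measure` writes per-image seed-record CSVs, a `thresholds.json` sidecar,
and a `run_summary.json` with stage-wise rejection counts.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "seedscan",
                               load_package = "installed")'
```

The suite checks each stage against independent re-implementations
(brute-force Otsu, label-propagation connected components, hand-worked
ANOVA, analytic digital disks/ellipses) plus property tests — rotation
equivariance, filter monotonicity, generator determinism, RNG-state
restoration, and recovery of simulated heritability.

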