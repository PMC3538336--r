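---
title: "Methods: automated seed morphometry and heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated seed morphometry and heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscan)
```

# Overview

`seedscan` measures seed size and shape from 8-bit grayscale flatbed-scanner
images and turns the per-seed measurements into per-line phenotype values
suitable for quantitative genetics (for example QTL mapping on recombinant
inbred lines). The pipeline is:

1. **Thresholding** — a per-image Otsu threshold, pooled across a scanning
   batch into one batch threshold.
2. **Segmentation** — dark-foreground binarization and 8-connected component
   labeling.
3. **Morphometry** — area and moment-equivalent ellipse axes per component.
4. **Filtering** — reject touching pairs, scratches, debris and
   border-clipped objects; keep an audited record of every component.
5. **Phenotypes** — per-line means, replicate averaging, one-way ANOVA
   variance components, broad-sense heritability.

A synthetic seed-field generator with per-object ground truth makes every
stage testable without scanner hardware.

# Model and assumptions

The imaging model is dark seeds on a light, approximately uniform
background: a grayscale image $I \in \{0,\dots,255\}^{r\times c}$ with known
resolution in dots per inch (dpi). All physical quantities derive from the
pixel pitch $25.4/\mathrm{dpi}$ mm.

## Batch Otsu thresholding

For one image, the Otsu threshold $t^\*$ maximizes the between-class
variance of the split $\{I < t\}$ vs $\{I \ge t\}$ over candidate
thresholds $t = 1,\dots,255$ (256 histogram bins). Ties take the lowest
$t$; an image whose histogram occupies a single bin has no defined
threshold (`NA`). A scanning batch is thresholded at the **mean of the
defined per-image thresholds**, so that one unusually dirty or empty scan
does not get its own idiosyncratic segmentation; `cmdMeasure()` can
optionally fall back to per-image thresholds or a manual threshold.

Binarization is **strictly below**: a pixel is foreground iff
$I_{ij} < t$. The strict inequality matches the class convention of the
threshold search, so the two stages cannot disagree about boundary bins.

## Moment-equivalent ellipse

For a labeled component with pixel centers $(r_k, c_k)$, the second
central moments (population covariance) are corrected for the unit pixel
extent by adding $1/12$ — the variance of a uniform distribution over one
pixel — to each diagonal term:

$$\Sigma = \mathrm{cov}(r, c) + \begin{pmatrix}1/12 & 0\\ 0 & 1/12\end{pmatrix}.$$

With eigenvalues $\lambda_1 \ge \lambda_2$, the ellipse with the same
second moments has axes

$$\text{major} = 4\sqrt{\lambda_1},\qquad \text{minor} = 4\sqrt{\lambda_2}.$$

The $1/12$ term makes the limit cases sane: a single pixel measures
$4/\sqrt{12} \approx 1.155$ px on both axes rather than 0, and a one-pixel-wide
line gets a positive minor axis. Tests verify the estimator against
analytic digital disks and ellipses (within 2–3% at radius 15–30 px) and
exact equivariance under 90° rotation.

## Artifact filters

Each component is audited through three tests; only a component passing
all three is an accepted seed, and rejected components stay in the output
with their per-filter flags:

* **Border**: components touching the image edge are excluded (their shape
  is clipped, so their measurements are biased).
* **Ellipse consistency**: the pixel area must agree with the area of the
  fitted ellipse, $\pi\cdot\text{major}\cdot\text{minor}/4$, within a
  relative tolerance (default `tol = 0.10`). A convex, smooth seed sits
  within ~1% of its moment ellipse; a dumbbell of two touching seeds or a
  cross of fibers deviates far more. The 0.10 default leaves a wide margin
  on both sides for the geometries in question (singles ≲1%, oblique
  touching pairs ≳15%).
* **Aspect ratio**: $\text{major}/\text{minor} \le 2.5$ (inclusive — a ratio
  of exactly 2.5 is kept). Seeds of the species targeted here are roughly
  2:1; scratches and fibers are 10:1 or more.

Loosening either tolerance can only grow the accepted set (a monotonicity
property the tests check directly).

## Phenotypes and heritability

Per-seed mm-scale traits (area, major axis, minor axis) are averaged per
line and replicate; a line's final value is the **unweighted mean of its
replicate means**, so each mother plant counts equally regardless of how
many seeds it shed (a `"pooled"` mode that weights by seed count is
available for comparison).

Variance components come from the one-way random-effects model
$y_{ij} = \mu + g_i + e_{ij}$ fitted by ANOVA moments:
$V_A = \max(0, (MS_M - MS_E)/n_0)$ with
$n_0 = (N - \sum_i n_i^2/N)/(a-1)$ for $a$ lines, and broad-sense
heritability $H^2 = V_A/(V_A+V_E)$.

**Choice of $V_E$.** How the environmental variance should be estimated is
genuinely underdetermined: the published variance-component tables this
package ships (for Ler × Cvi recombinant inbred and near-isogenic line
populations, `inst/extdata/ler_cvi_variance_components.csv`) report a
$V_E$ that is *not* equal to $MS_E$, without a derivation. The package
therefore defaults to the transparent estimator $V_E = MS_E$ and labels it
`V_E_method = "MS_E"`, while accepting a user-supplied $V_E$ (labeled
`"supplied"`) so externally derived components can be used unchanged. When
computing $H^2$ from the shipped table, both components are supplied, so
the ratio reproduces the published values (to within the 3-significant-figure
precision the components are recorded at — one table row rounds to 0.661
while its recorded $H^2$ is 0.662, a one-ulp printing artifact of the
rounded inputs).

# Synthetic field generator

`fieldSpec()` / `renderField()` produce a scanner-like field with exact
per-object ground truth, so segmentation and filtering can be validated
end to end.

## Defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| canvas | 2048 × 2048 px | holds the default object counts at ~14% bounding density |
| dpi | 3200 | typical high-resolution flatbed scan of small seeds |
| seed size | 0.55 × 0.30 mm axes, 5% CV | small-seeded crucifer scale |
| intensities | foreground 60, background 220 | dark seed on light platen |
| noise | i.i.d. Gaussian, sd 8 | scanner sensor noise |
| counts | 50 singles, 10 pairs, 5 scratches, 10 debris | a realistically dirty scan |
| `ellipse tol` / `maxRatio` | 0.10 / 2.5 | see filter section |

Objects are rendered by 4×4 supersampled coverage (per-pixel fractional
coverage mapped linearly between background and foreground intensity,
max-combined across objects), which reproduces the anti-aliased edges of a
real scan rather than hard binary silhouettes. Placement is rejection
sampling on bounding circles with a margin, so distinct objects never
merge; rendering proceeds largest-first (scratches, pairs, singles,
debris) so dense fields still place.

These defaults are the *study conditions*: tests and the acceptance
checks run the generator as configured here, not a tuned variant.

## Artifact geometry — two deliberate choices

* **Touching pairs meet obliquely** (angle between major axes drawn from
  60–90°), not end-to-end. A collinear, end-to-end union of two seed
  ellipses deviates from its own moment ellipse by only ~8–9% — *inside*
  the 0.10 consistency tolerance — so collinear pairs would not be
  reliably rejected by the filter that is supposed to catch them. Oblique
  contact, besides being the common way seeds actually lodge against each
  other, produces an L-shaped union that deviates by ≥15% and is rejected
  decisively.
* **Debris are small fibrous crosses** (two thin bars, 0.10–0.16 mm), not
  round specks. The pipeline has no area gate, so a round speck would pass
  both filters; fibrous fragments are the debris class the filters can and
  should catch.

## What the generator does and does not show

Passing the generator-based tests demonstrates that thresholding,
labeling, measurement and filtering are mutually consistent and accurate
on anti-aliased, noisy, geometrically known objects — e.g. that every
single seed is recovered with <5% area error, every pair fails the
ellipse test, every scratch fails the aspect test, and ≥99% of true
foreground survives batch thresholding. It does **not** demonstrate
robustness to phenomena the model omits: non-uniform illumination,
JPEG-like compression artifacts, translucent or germinating seeds, dust
films that shift the background mode, or seeds differing strongly from
ellipses. Real deployments should spot-check the audit table
(`filterComponents()` output) rather than trust the accepted set blindly.

# Numerical choices

* Otsu: 256 bins, candidates 1–255, lowest-index tie-break, `NA` for
  single-bin histograms; batch mean excludes `NA` images with a warning.
* Labeling: 8-connectivity, first-encounter (row-major) label order,
  iterative stack flood fill in C++ (no recursion, so deep components
  cannot overflow the stack). The test suite checks it against an
  independent minimum-label-propagation implementation on random masks.
* Covariance uses the population ($1/n$) normalization plus the $1/12$
  pixel-extent correction; eigenvalues by the closed 2×2 form.
* $V_A$ is floored at 0; $H^2$ is reported to 3 decimals in report
  tables and the CLI, full precision in the S4 object.
* Seeds for the RNG are kept below $2^{31}$; `renderField()` restores the
  caller's RNG state, so generation does not perturb surrounding code.

# Problem sizes exercised

The test suite runs, among others: 100 random histograms against a
brute-force Otsu oracle; 50 random 200×200 masks against the labeling
oracle; digital disks/ellipses up to radius 30; 640×640 generator fields
across several seeds plus one full 2048×2048 field with the default 75
objects; ANOVA designs up to 161 lines × 2 replicates; and a 160-line
null/positive simulation (20 repetitions) checking that estimated $V_A$
is unbiased within 15% and $H^2$ recovers 0.5 ± 0.05.

# Known limitations

* TIFF output does not carry resolution metadata in this build (the
  underlying writer has no resolution argument); PNG round-trips dpi via
  its pHYs chunk. TIFF *input* resolution tags are honored when present.
* The moment ellipse under-measures axes of very small components
  (< ~8 px across) relative to their continuous ideal; at 3200 dpi seeds
  are ~70×38 px, far from that regime.
* The batch threshold assumes the batch shares illumination and platen
  state; mixing scanners or settings in one batch violates it.
* An empty *noisy* image has no meaningful Otsu threshold of its own (the
  method will split the noise distribution near its mean); such images
  are handled correctly only through the batch mean, which is why empty
  or near-empty scans should never be thresholded in isolation.
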