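---
title: "Methods: lymphocyte STAU2 immunofluorescence screening"
author: "stau2screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lymphocyte STAU2 immunofluorescence screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stau2screen)
```

## The screening problem

Secretory factors released by breast tumours alter protein expression in
circulating white blood cells, so a tumour-induced protein measured in
lymphocytes can serve as a blood-accessible screening marker. The pipeline
implemented here quantifies one such marker, STAU2 (staufen double-stranded
RNA-binding protein 2), by immunofluorescence on fixed white blood cells:
a nuclear stain (blue) locates cells, an anti-CD45 stain (red) identifies
leukocytes, and the anti-STAU2 stain (green) carries the diagnostic signal.
Each blood sample is reduced to two statistics — the average STAU2
fluorescence intensity and the percentage of STAU2-positive cells — and a
two-axis cut-off rule on that plane classifies the sample as screen-positive
or screen-negative.

The package covers the full computational chain: synthetic image and cohort
generation, per-cell signal quantification, cohort-level cut-off evaluation,
Bayesian post-test risk, and the cross-study expression intersection used
to nominate the marker in the first place.

## Per-cell quantification

**Detection.** Each channel is binarized at `detection_threshold`
(default 140 grey units — the lower bound of the capture intensity range;
the acquisition software's own threshold is not published) and
8-connected components are extracted. Each blob is measured by its
centroid, pixel area, mean interior grey value, and perimeter.

**Perimeter estimator.** The perimeter is the polygon length through the
ordered 8-connected outer boundary contour, multiplied by a 0.95 chain-code
correction (digital straight segments overestimate smooth boundaries by
roughly 5%) and scaled by the µm-per-pixel calibration. For digital disks
of radius ≥ 5 px this estimator sits within a few percent of the true
2πr, which the test suite asserts against planted disks.

**Filters.** Two inclusive range filters mirror the screening protocol:

| filter | perimeter (µm) | mean grey |
|---|---|---|
| capture (all channels, at detection) | 25–200 | 140–300 |
| positivity (green signal of a cell) | 25–150 | 150–280 |

All bounds are inclusive; the protocol publishes the ranges without
open/closed notation, and inclusive bounds are the natural reading. The
relation between the two intensity scales is not further specified at the
source, so both are treated as the same grey-value axis.

**Colocalization.** A cell is one red (CD45) signal. Green signals are
assigned to red signals by greedy nearest-centroid matching in (y, x) scan
order, with a maximum centroid distance of 5 µm (the protocol requires
only that positive cells show red and green "in the same position"; 5 µm
is under one cell radius, and the matching is deterministic with ties
broken by scan order). Unmatched green signals are discarded and counted.
A cell is *positive* iff its green signal exists and passes the positivity
ranges.

**Per-sample statistics.** With `n` cells and `k` positive cells pooled
over a well's fields (up to 12 per well):

* `pct_positive = 100·k/n`;
* `avg_intensity` has two modes. The protocol's literal wording — positive
  cell intensity divided by the intensity of positive *and* negative
  cells — yields a dimensionless ratio ≤ 1, which cannot be the grey-value
  scale on which the published group means (e.g. 110.50) live. The default
  mode `mean_of_positives` therefore reports the arithmetic mean green
  intensity over positive cells (scale-compatible with the published
  values); `ratio_as_stated` preserves the literal formula, with cells
  lacking a green signal contributing zero to the denominator.

With zero cells both statistics are flagged undefined rather than raising
an error, so empty wells survive batch processing.

Exposure-time metadata is annotation only; no photometric correction is
applied. Interassay variation is handled as multiplicative per-batch
rescaling against a shared positive-control sample
(`adjust_interassay()`); the original protocol states that cocultured
positive samples were used for this adjustment but not the functional
form, and a ratio adjustment is the simplest form that equalizes the
control across batches.

## The synthetic-data generators

The generators are first-class, tested code: they define the conditions
under which every downstream claim is verified.

**Field images.** Cells are rendered as non-overlapping filled disks of
uniform interior intensity (minimum centre distance = sum of radii), so
the true perimeter (2πr) and the true mean grey value of every planted
blob are analytically known, and each blob corresponds to exactly one
cell. Every cell gets a blue and a red disk; exactly
`round(positive_fraction · n_cells)` cells also get a green disk.
Gaussian background noise is optional; grey values are clipped to the bit
depth. Defaults: 400×400 px fields at 0.65 µm/px (typical 20×
widefield; the calibration is configurable everywhere because the
acquisition calibration is not published), radii 5–10 µm, per-cell
intensities uniform in 180–260 so planted cells sit strictly inside all
filter ranges. What is *not* simulated: optics (point-spread function,
chromatic shift), staining chemistry, plate spatial effects, or touching
cells — so passing tests demonstrate correctness of the measurement
chain, not robustness to segmentation pathology on real images.

One caveat surfaced by testing: "raising the detection threshold never
decreases to fewer detections" holds exactly for uniform-interior blobs,
but on noisy images a higher threshold can split one component into
several; the property is therefore asserted in the noiseless regime.

**Cohorts.** Per group, `(avg_intensity, pct_positive)` pairs are drawn
from a correlated bivariate normal law truncated to intensity ≥ 0 and
percentage in [0, 100]. Defaults are the published group descriptives
(cancer 110.50 ± 23.38 and 61.87 ± 12.44; normal 56.47 ± 32.03 and
33.02 ± 18.10; 358/363 samples) with ρ = 0.95, chosen so the pooled
cohort reproduces the observed linear relation (R² > 0.9) with margin.
Truncation is by resampling, not clipping — clipping would pile mass on
the boundaries. Resampling alone, however, still shifts the realized
moments (the normal group's intensity law has ≈ 4% mass below zero, which
biases its truncated mean upward by ≈ 2 grey units). The generator
therefore *moment-calibrates* the pre-truncation parameters: truncated
means, SDs and correlation are computed by Gauss–Legendre quadrature over
the support rectangle and the generating parameters adjusted by
fixed-point iteration until the truncated law's moments equal the
configured values (tolerance 10⁻⁶, typically < 10 iterations). The
configured numbers are thus the moments of the distribution the samples
actually follow, which is what calibration tests assert at
n = 10,000 per group.

**Expression pairs.** Two studies over a shared universe (default 1,000
genes, 20 samples per group, baseline N(8, 1)): 50 genes shifted
+2 SD in the cases of both studies, 50 per study shifted in that study
only, the rest null. A candidate gene list (default 100 genes, 80% drawn
from the planted shared set) feeds the list-variant intersection. These
sizes give near-complete power per planted gene at α = 0.05, so the
intersection statistic — not per-gene power — is what the tests exercise.

All generators are byte-for-byte deterministic under a fixed seed.

## Cohort evaluation

**Quadrant classifier.** A cut-off point `(X, Y)` on the
(intensity, % positive) plane calls a sample positive iff
`avg_intensity ≥ X` **or** `pct_positive ≥ Y`; only the lower-left
quadrant is negative. Bounds are inclusive on the positive side (the
published figure shades quadrants without stating boundary handling).
The three published cut-offs A (63.50, 40.00), B (90.28, 53.34) and
C (117.20, 63.38) ship as `stau2_cutoffs()`. With `Y = ∞` the rule
degenerates to the single-axis intensity rule and reproduces the
corresponding ROC point exactly, which is tested.

**Metrics.** From the 2×2 table: sensitivity, specificity, PPV, NPV,
accuracy, the sample odds ratio `(tp·tn)/(fp·fn)` with Woolf 95% CI
(`log OR ± 1.96·√(1/tp+1/fp+1/fn+1/tn)`), and a chi-squared p-value
without continuity correction (the original analysis names its software
but not the exact test; the uncorrected chi-squared reproduces the
published figures). Zero cells trigger the Haldane–Anscombe +0.5
correction for the odds ratio, flagged in the output. Published
sensitivity/specificity pairs are converted back to counts by
round-half-up of `rate × group size` (`confusion_from_rates()`); this
reconstruction is the canonical path from printed rates to the worked
examples and recovers the published odds ratio, CI, accuracy and
predictive values to the printed decimals. One published row (NPV at the
%-positive-40.00 ROC point) is not consistent with its own printed rates
and group sizes under any rounding; no reconstruction is forced to match
it.

**ROC.** `score ≥ threshold` ⇒ positive, one point per distinct score,
AUC by trapezoid; equal by construction to the case–control concordance
probability with ties at ½, which the tests verify by brute force and
against an independent implementation.

**Group comparisons** use Welch's t-test by default (pooled-variance
optional); the original states only "independent sample t-tests", and
Welch is the safer default for unequal group variances.

## Post-test risk

`posterior_probability()` updates a prevalence with a screening result
via Bayes' theorem, computed in odds space
(`post-odds = pre-odds × LR`, `LR+ = sens/(1−spec)`,
`LR− = (1−sens)/spec`) to avoid cancellation at prevalences of order
10⁻⁴. Probability-form and odds-form agree to machine precision (tested
on a parameter grid). At the balanced cut-off (sens 82.96%,
spec 83.47%) and a pre-test risk of 1 in 220, a positive screen yields
2.24% — matching the published 2.25% up to the rounding of its printed
inputs; both the printed rates and the exact-count rates (297/358,
303/363) give the same figure to two decimals.

## Cross-study intersection

Per study, each gene gets an equal-variance two-sample t-test (the
classic microarray convention; Welch optional) and a call: `up` if
p < α and the case mean is higher, `down` for the opposite sign, `ns`
otherwise. α defaults to 0.05 per gene with **no** multiple-testing
correction — the intersection statistic downstream is what controls
chance agreement, and corrected calls would change the published-style
gene counts. Over the shared universe the 2×2 of direction-in-A ×
direction-in-B is tested by chi-squared (no continuity correction),
falling back to Fisher's exact test when any expected cell is below 5;
the odds ratio uses Haldane +0.5 on zero cells. The list variant crosses
calls with membership in a fixed candidate list. Fisher p-values equal
exhaustive hypergeometric enumeration on small universes, and under
label permutation the intersection p-value is uniform (Kolmogorov
distance 0.026 < 0.05 over 1,000 permutation replicates at 10,000 genes,
5 samples per group, α = 0.2 for the per-gene calls — α raised there so
all expected 2×2 cells stay ≥ 5 and the discrete p-value distribution is
fine-grained).

Genes absent from one study are dropped from the universe, not imputed.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 10,000 samples per group
for cohort calibration (3-standard-error bands), 12 fields × 25 cells for
well-level ground-truth recovery, 1,000-gene expression pairs for planted
recovery, and 1,000 permutation replicates for null calibration — sizes at
which the stochastic assertions have comfortable margins while a full run
stays under a minute apiece. Degenerate inputs follow one rule
throughout: impossible *configurations* (empty radius ranges, prevalence
at 0 or 1, single-class ROC input, sub-minimal group sizes) raise errors;
degenerate *data* (empty wells, blank channels, zero positive cells)
produce empty or NA-flagged results.

## Limitations

* The image simulator's disks are an idealization; performance on real
  micrographs with touching cells, uneven illumination or autofluorescence
  is out of scope (no watershed splitting, no illumination correction).
* Cohort simulation reproduces first and second moments and the
  intensity/percentage correlation, not higher-order structure (skew,
  batch effects, stage strata beyond labels).
* The published cohort-level p-values and GEO-derived gene counts depend
  on the original patient data and are reproduced in *form* (the same
  statistics computed on synthetic cohorts), not in value.
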