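---
title: "From chromatograms to quality grades: the Q-marker evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chromatograms to quality grades: the Q-marker evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmarkereval)
```

## The problem

Herbal medicinal material such as Gentianae Radix et Rhizoma (*Gentiana
scabra* Bunge., GSB) varies in quality with origin, provenance and
cultivation. Pharmacopoeial control traditionally tracks a single
constituent, but efficacy rests on several co-occurring compounds. The
quality-marker (Q-marker) framework instead asks for a small set of
inherent, quantifiable constituents linked to the material's effect, and
then grades batches by their joint content. This package implements that
workflow end to end for a 44-batch GSB study in which swertiamarin,
gentiopicroside and sweroside are the markers: fingerprinting,
chemometric and binding screens to choose markers, calibration-based
quantification, and a multi-criteria quality ranking.

The packaged data are the published per-batch marker contents (mg/g,
batches S1–S44) plus the published calibration lines; raw chromatograms
and plate readings are not deposited anywhere, so a synthetic generator
with the study's statistical structure stands in for them.

## Fingerprint construction

A chromatogram is a `time_min`/`intensity_mau` table. `detect_peaks()`
takes local maxima above a height and a prominence threshold and
integrates each peak by the trapezoid rule between its flanking minima,
subtracting the valley-to-valley chord as a local baseline. The defaults in
`build_fingerprint()` (2 mAU height and prominence) sit an order of
magnitude above the synthetic detector noise (0.2 mAU); with instrument
data they should be set relative to the observed noise floor.

Retention times drift between runs, mostly as a batch-level stretch, so
`calibrate_rt()` performs the multi-point calibration that fingerprint
software applies before matching: a proportional pre-scaling on the
dominant peak, then a piecewise-linear warp of each batch onto the median
retention times of the anchor clusters (every peak recovered in all
batches). Anchor clusters are formed at three times the matching window
because the pre-scaled residual grows with retention time; with two or
fewer anchors the warp degrades to the identity. After warping,
`match_common_peaks()` clusters the pooled peaks greedily — seeds in
descending area, ties to the smaller retention time, each batch
contributing its nearest peak within the window — and keeps the clusters
with exactly one peak from every batch as the *common peaks*. The window
is interpreted as the maximum |RT − centroid| and defaults to 0.10 min.
Matching is deterministic and idempotent.

The reference fingerprint R is the element-wise median over batches
(`build_reference()`), using the lower median for even counts so the
reference is always an observed value. Similarity is the cosine congruence
of common-peak area vectors (`fingerprint_similarity()`), the convention
of the fingerprint-evaluation software family; it is scale-invariant and
reaches 1 exactly for proportional profiles. A Pearson variant is
available behind `method = "correlation"`. Relative retention times and
areas divide each batch's row by its value at the reference peak S, chosen
automatically as the common peak with the largest median area — in the
real material that is the dominant secoiridoid peak.

## What the synthetic chromatograms emulate — and what they do not

`generate_chromatograms()` draws Gaussian peaks from 25 templates
(5–75 min, one dominant reference peak) with:

* a per-batch linear time stretch with sd equal to `rt_jitter_rsd_pct`
  (default 2%), plus 0.01-min peak-level jitter. The stretch reproduces
  the observed retention-time RSD band (0.635–3.917%) while remaining
  removable by the multi-point calibration — which is exactly why real
  software calibrates before matching at 0.10 min;
* lognormal area variation, with per-peak RSDs spread geometrically (with
  a squared exponent) over the observed 19.439–144.854% band and assigned
  so the largest peaks vary least. That mirrors real material, where only
  trace constituents have extreme relative-area RSDs; it is also what
  keeps batch similarities at the observed ≥ 0.95 level despite >100%
  RSDs on some peaks;
* linear baseline drift and additive Gaussian detector noise.

Not emulated: peak tailing (all peaks are symmetric Gaussians), detector
saturation, co-elution requiring valley-drop splitting, wavelength
dependence, or correlated constituent chemistry beyond the area structure
above. Tests passing on this generator therefore certify the *algorithms*
(detection, calibration, matching, similarity) under realistic noise, not
performance on pathological real chromatography.

## Marker screening

`pca_cor()` is PCA on the correlation matrix — the convention of the
social-science-style statistical packages used in this field, recognizable
because the eigenvalues sum to the number of variables. Loadings are
eigenvectors scaled by √λ; signs are fixed so the largest-magnitude
loading of each component is positive, which yields the conventional
all-positive first component on positively correlated content data.

`opls_da()` fits two-class OPLS-DA by NIPALS: for each orthogonal
component the X-loading part orthogonal to the predictive weights is
removed, then a single predictive PLS1 component is fitted on the deflated
matrix. The class vector is ±1-coded and centered; X is unit-variance
scaled. The fit is deterministic (initialized from the class vector, no
random starts). `vip()` reports the predictive-component VIP,
`√(p·w²)`, whose squared mean is 1 by construction; `select_markers()`
applies the strict `VIP > 1` rule. Q² comes from 7-fold cross-validation
with interleaved sample-order folds — deterministic, at the cost of
ignoring any ordering structure in the input — and
`opls_permutation_q2()` provides the permutation null. One orthogonal
component is the default; the study data never supported more. Which
two-class grouping to use (wild vs cultivated, provinces, PCA clusters) is
a user decision passed as the label vector, not a package default.

## The binding screen

The four-control plate design measures whether a small molecule quenches
liver-protein fluorescence beyond additivity. With group means `F_A`
(lysate), `F_B` (lysate + ligand), `F_C` (protein), `F_D`
(protein + ligand), the activity percentage is

$$AP = \frac{F_B + F_C - F_A - F_D}{F_B + F_C - 2F_A} \times 100.$$

`activity_percentage()` evaluates the statistic; `activity_from_plate()`
computes it on replicate means and also replicate-wise (replicates paired
by index) for a dispersion estimate. A non-positive denominator means the
assay controls are inconsistent and is an error. Negative APs
(enhancement) and APs above 100 (over-quench) are reported unclipped,
because Z-normalization follows and clipping would distort ranks.
`screen_binding()` Z-normalizes across components and ranks descending,
ties broken alphabetically; the top three are the active candidates. The
synthetic plate generator places `F_D` so the noiseless AP equals the
configured quench fraction × 100 exactly, giving the screen a known truth;
condition-selection scans (incubation time, concentration) are not
modelled because the study fixed them by inspection.

## Quantification

`fit_calibration()` is unweighted OLS of area on concentration —
unweighted because no weighting scheme was reported for the published
curves; a heteroscedastic laboratory would want 1/x weighting, which can
be applied by pre-scaling. `concentration_from_area()` inverts the line,
flags extrapolation beyond the fitted range, and maps areas below the
intercept to 0 with a `below_lod` flag rather than returning a negative
concentration, since contents are physical quantities. `content_mg_g()`
applies the extraction scheme (default 0.5 g powder into 20 mL solvent),
and `spike_recovery()` is the standard-addition accuracy statistic. LOD/
LOQ estimation is out of scope.

## Quality evaluation

The decision matrix is batches × marker contents. The stage follows the
canonical entropy-TOPSIS construction, with two points that were genuinely
open and were fixed by reproduction against the published intermediate
tables:

* **Proportions from normalized values.** The proportion matrix is
  computed from the min-max normalized matrix (not the raw contents); the
  published proportion table confirms this (e.g. first-batch swertiamarin
  0.804/21.92 ≈ 0.037). Zero proportions use the `0·ln 0 := 0` convention,
  which actually occurs because min-max creates exact zeros.
* **Where the weights multiply.** Entropy weights applied to the min-max
  normalized matrix (`variant = "normalized"`) reproduce the published
  closeness endpoints exactly (0.953 and 0.043 at 3 decimals); applying
  them to the proportion matrix (`variant = "proportion"`, selectable)
  gives 0.952/0.044. The normalized variant is therefore the default.

Ideal and anti-ideal solutions are per-criterion maxima and minima of the
weighted matrix; distances are Euclidean; closeness is `d⁻/(d⁺+d⁻)`. All
criteria are treated as benefit-type (more content is better). Ranks use
average ties internally and first-occurrence order in reports.

`composite_score()` is the second ranking device: z-score the contents,
take the first correlation-PCA component's scores Y, and weight by its
variance proportion, `F = (λ₁/p)·Y`. The coefficients are always
recomputed from the data's own eigendecomposition. On the packaged table
Y's coefficients are (0.582, 0.602, 0.547) and λ₁/p = 0.846. The published
score table agrees with the recomputation to its printed 2 decimals except
that its own ranks 6/7 are swapped relative to its printed scores (S1 is
printed rank 6 with a lower score than S9 at rank 7); the package reports
the self-consistent ranking.

`hca_grade()` standardizes the three contents plus their total, clusters
with Euclidean distance and average linkage (the between-groups default of
the statistical software family; Ward is selectable and gives the same
partition here), cuts at k = 3, and orders grade labels by mean closeness.
On the packaged table the split is 15/17/12 with the top-ranked batches in
grade 1.

## Numerical conventions

* Sample (n−1) standard deviations throughout (standardization, RSD,
  Z-scores).
* Lower median for even counts in the reference fingerprint.
* Internal computation is never rounded; comparisons against published
  3-decimal tables round only at the comparison.
* Eigenvector signs: largest-magnitude loading positive per component.
* Matching ties: smaller retention time wins; ranking ties: average
  internally, first occurrence in reports.
* Degenerate inputs error early with the offending column named (constant
  columns in standardization and min-max; all-uniform proportion columns;
  zero similarity vectors; non-positive assay denominators).

## Problem sizes and seeds

The synthetic study conditions are 44 batches × 25 template peaks, 3
replicates per plate condition, 5 candidate components with quench
fractions (0.8, 0.7, 0.6, 0.2, 0.1), and a two-fold content shift for the
high-quality group; the default generator seed is 20251106 and every
generator is bit-reproducible given (config, seed). Repeated-screen
frequencies (e.g. how often the binding screen recovers the three strong
binders) use 100 consecutive seeds. These sizes match the study; nothing
in the tests depends on larger simulations.

## Known limitations

* Peak integration has no valley-drop splitting; heavily fused peaks
  merge.
* The congruence similarity is computed on common-peak vectors, not whole
  curves; the exact algorithm of the commercial fingerprint software is
  unpublished, so agreement with it can only be qualitative.
* OPLS-DA supports exactly two classes; multi-class screening requires
  one-vs-rest runs.
* The entropy-TOPSIS reconstruction is validated against the published
  endpoint values and intermediate tables, but the original tool chain is
  not available to compare against cell by cell.
* A grey-relational analysis is mentioned alongside the published ranking
  but never specified; it is not implemented.
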