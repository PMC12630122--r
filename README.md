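# qmarkereval

Chemometrics toolkit for discovering **quality markers (Q-markers)** in
herbal material and for ranking batch quality from their contents, built
around a 44-batch *Gentiana scabra* Bunge. (GSB, Gentianae Radix et
Rhizoma) case study. It is aimed at analysts doing HPLC-fingerprint quality
control of multi-batch medicinal material who need the whole chain — from
chromatograms to a defensible quality grading — as reproducible, tested
code rather than a sequence of point-and-click tools.

## What it computes

**Fingerprinting.** Multi-batch chromatograms are reduced to peak tables
(local-maximum detection, valley-to-valley trapezoid integration),
retention times are calibrated by piecewise-linear warping onto a shared
anchor-peak set, and peaks are matched across batches at a 0.10-min window.
Peaks present in every batch are the *common peaks*; the element-wise
(lower) median over batches gives the reference fingerprint R, and each
batch's similarity to R is the cosine congruence of the common-peak area
vectors. Relative retention times and areas are expressed against the
reference peak S (the largest stable common peak), with RSD
(`sd/mean × 100`) as the validation statistic.

**Marker screening.** Correlation-matrix PCA (eigenvalues λ sum to the
number of variables p; loadings are eigenvectors × √λ) plus two-class
OPLS-DA: orthogonal variation is removed by NIPALS deflation and one
predictive PLS component is fitted, with variable importance
`VIP_j = √(p · w_j²)` on the predictive weights, so mean(VIP²) = 1 and
variables with VIP > 1 are the screening candidates.

**Binding screen.** The fluorescence-quenching activity percentage of the
four-control plate design (A lysate, B lysate + ligand, C protein,
D protein + ligand):

```
AP = (F_B + F_C − F_A − F_D) / (F_B + F_C − 2 F_A) × 100
```

the shortfall of the observed mixture fluorescence below its additive
expectation. APs are Z-normalized across components and the top-k become
the active Q-marker candidates.

**Quantification.** Ordinary least-squares calibration of peak area (mAU)
on concentration (mg/mL), inversion to concentration, content
`c · V · dilution / m` in mg/g under the 0.5 g / 20 mL extraction scheme,
and spike recovery `(measured − original)/added × 100`.

**Quality evaluation.** On the batches × markers content table: min-max
normalization, proportion matrix `p_ij = x_ij / Σ_i x_ij`, entropy weights
`w_j ∝ 1 − e_j` with `e_j = −(1/ln n) Σ p ln p`, TOPSIS closeness
`C_i = d⁻/(d⁺ + d⁻)` to the per-criterion ideal/anti-ideal, a
first-principal-component composite score `F = (λ₁/p) · Y`, and three-grade
hierarchical clustering (Euclidean, average linkage) of the standardized
contents plus total.

The package ships the published 44-batch content table (swertiamarin,
gentiopicroside, sweroside, mg/g) as a checksummed plain-text fixture, and
a seeded synthetic-data generator (Gaussian-peak chromatograms, four-control
plates, grouped content tables) so every stage is testable without
instrument data.

## Worked example

```r
library(qmarkereval)
contents <- as.matrix(gsb_contents()[, 1:3])   # 44 batches, mg/g
ev <- evaluate_quality(contents)

ev$topsis
#> Entropy-weighted TOPSIS (normalized variant), 44 alternatives
#> closeness range: 0.043 (S33) to 0.953 (S10)

round(ev$weights$w, 4)
#>    swertiamarin gentiopicroside       sweroside
#>          0.2393          0.4555          0.3052

head(ev$report$table[order(ev$report$table$closeness_rank), ], 3)
#>     closeness closeness_rank pc_score overall_score score_rank grade
#> S10 0.9534185              1 2.657513      2.248252          1     1
#> S1  0.8701498              2 2.028518      1.716123          7     1
#> S9  0.8617206              3 2.036982      1.723284          6     1
```

Batch S10 is closest to the ideal solution (closeness 0.953) and also tops
the PCA composite score (Y = 2.66, F = 2.25); S33 is the worst on both
(closeness 0.043, rank 44). The entropy weights say gentiopicroside, the
most dispersed content, carries the most evaluative information. The
three-grade clustering splits the batches 15 / 17 / 12 with the top-ranked
batches in grade 1, and the two ranking devices agree with Spearman
ρ = 0.987.

The `analysis/` directory holds the numbered stage drivers
(`01_simulate_fingerprint.R` … `05_evaluate_quality.R`) that run the whole
workflow — synthetic fingerprint, marker screening, binding screen,
quantification, quality evaluation — and write their tables under
`results/`.

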