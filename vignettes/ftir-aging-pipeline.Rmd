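---
title: "Age discrimination in striated muscle from ATR-FTIR spectra: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age discrimination in striated muscle from ATR-FTIR spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirage)
```

## The problem

Attenuated-total-reflectance Fourier-transform infrared (ATR-FTIR)
spectroscopy measures the mid-infrared absorbance (4000–600 cm⁻¹) of a
tissue specimen pressed on a crystal. The spectrum is a superposition of
absorption bands assigned to functional groups — lipid C–H stretches around
3050–2800 cm⁻¹, the protein Amide I/II envelope and the ester carbonyl in
1800–1500 cm⁻¹, and carbohydrate/nucleic-acid bands in the 1200–900 cm⁻¹
fingerprint region. `ftirage` implements a chemometric workflow that asks
whether such spectra carry an *aging fingerprint* in mouse cardiac and
skeletal muscle: can the age group of an animal (6, 12, 17 or 24 months) be
read off its spectrum, and which bands drive the separation?

Because no public spectral cohort exists for this design, the package ships
a synthetic-cohort generator with known, configurable age and tissue
effects. Every downstream stage is validated against that ground truth; the
generator is first-class, tested code, not a fixture.

## The synthetic cohort

`generate_cohort()` emulates the study design: 2 tissues × 4 ages × 10
biological × 3 technical replicates = 240 spectra. Each spectrum is

$$ A(\nu) \;=\; s \left[ \sum_b a_b(t, m)\, g_b \,
   e^{-(\nu - c_b)^2 / 2\sigma_b^2} \;+\; \beta_0 + \beta_1 u + \beta_2 u^2
   \right] + \varepsilon(\nu), $$

with band amplitudes linear in age,
$a_b(t, m) = \text{base}_b + \text{slope}_b(t)\, m + \text{offset}_b \cdot
[t = \text{cardiac}]$, a per-animal lognormal amplitude effect $g_b$ shared
across that animal's technical replicates, a random quadratic baseline per
spectrum ($u$ is the wavenumber scaled to $[-1, 1]$), lognormal
sample-amount scatter $s$ (what area normalization must remove), and iid
Gaussian noise $\varepsilon$. Defaults (all configurable via
`cohort_config()`):

* grid 3998→902 cm⁻¹ at 2 cm⁻¹ — finer than the instrument's stated
  8 cm⁻¹ resolution so that peak windows always contain several points;
* `noise_sd = 0.05` (5 % of the largest band amplitude),
  `scale_jitter_sd = 0.15`, `bio_amplitude_sd = 0.05`,
  `baseline_coeffs_sd = (0.05, 0.05, 0.02)`;
* the band catalogue of `default_band_catalogue()`: 20 Gaussian components
  at the canonical assigned centers. The configured aging directions are
  the qualitative signature the analysis must recover — the intermolecular
  β-sheet band (1628 cm⁻¹) grows with age in cardiac muscle and shrinks in
  skeletal muscle, the antiparallel β-sheet band (1693 cm⁻¹) shrinks in
  both, carbonyl (1741) and glucose (1045) grow, glycogen (1155) and
  phosphate (1081) shrink in skeletal muscle, and the CH₂/CH₃ lipid bands
  move in opposite directions in the two tissues.

Band widths matter more than they look: second-derivative spectroscopy can
only separate sub-bands whose spacing is roughly twice their Gaussian
width. The closest assigned pairs (1693/1682, 1554/1540, 1169/1155) are
11–14 cm⁻¹ apart, so the catalogue gives those components σ ≈ 5 cm⁻¹ —
narrow enough that each pair stays resolvable in the second derivative (the
premise of the peak-intensity analysis), while the raw Amide I envelope
remains a single smooth band dominated by the broad α-helix component
(σ = 14 cm⁻¹).

What the generator does **not** emulate: ATR penetration-depth dispersion,
water-vapor lines, Mie scattering, band-center drift between tissues
(available via `center_jitter_sd`, off by default), and non-linear aging
trajectories. Passing tests therefore show that the *procedure* recovers
known effects of this simplified form, not that real muscle spectra behave
this way.

## Preprocessing

Per spectral region (3050–2800, 1800–1500, 1200–900 cm⁻¹), in order:

1. **Cut** (`cut_region()`): closed-interval subset of the grid.
2. **Baseline** (`baseline_correct()`): default is the rubberband
   correction — subtract the lower convex hull of the trace, the common
   choice for ATR tissue spectra; a linear endpoint chord is available for
   cross-checking.
3. **Area normalization** (`area_normalize()`): divide by the trapezoidal
   integral, so differences in the amount of tissue on the crystal cannot
   masquerade as spectral differences. This makes every downstream
   quantity invariant to positive scaling of the raw spectrum.
4. **Savitzky–Golay second derivative** (`second_derivative_sg()`): local
   quadratic least-squares differentiation, output scaled by 1/step² so it
   estimates the true d²A/dν², with polynomial refits at the edges (no
   length shrinkage).

The SG window is the decisive noise/resolution trade-off. A 3-point window
(the classic central second difference, `sg_params(3)`) amplifies white
noise by a factor ≈ 0.61/step²·step² = 0.61 of the noise SD; a 7-point
quadratic window has gain ≈ 0.055 and a 9-point window ≈ 0.029, while the
windowed-maximum positions of the closest band pair (1693/1682) remain
distinct up to 9 points and merge at 11. The pipeline default is therefore
`sg_params(9)`; both readings of a "three smoothing points" convention
(total window 3, or 3 points per side = window 7) are available as
`sg_params(3)` and `sg_params(7)`, and the window used is always recorded
in the report.

## Chemometrics

**PCA and Q-residual screening.** `pca_fit()` is a mean-centered SVD.
Outlier screening runs per tissue on the raw full-range spectra, before
region cutting: the Q residual (squared prediction error)
$Q_i = \lVert x_i^c - PP^\top x_i^c \rVert^2$ measures how far a sample
sits from the model subspace, and `flag_outliers()` applies a robust MAD
rule ($q > \text{med} + 3.5 \cdot 1.4826 \cdot \text{MAD}$ by default; a
quantile rule is available). With a low-rank clean cohort a single gross
artifact can be *masked* (absorbed into a retained component); the
screening component count is deliberately a parameter.

**Kernel PLS1.** `pls_fit()` regresses age (months) on the
second-derivative spectra with single-response partial least squares,
fitted by the improved kernel algorithm: all factor extraction happens on
the cross-product matrices $X^\top X$ and $X^\top y$ of the centered data,
which is algebraically equivalent to NIPALS for one response (the test
suite holds the two to within 1e-8, and full-rank PLS to ordinary least
squares within 1e-6). Per-factor prediction error comes from seeded random
10-fold cross-validation; `select_n_factors()` picks the smallest factor
count whose CV-RMSE is within 2 % of the curve minimum (a one-sided
parsimony band — the qualitative "maximize explained variance without
overfitting" rule needs *some* quantitative form, and the selected count
plus the whole CV curve are always reported so a manual override,
`pipeline_config(factors = )`, can mirror hand-picked choices).

**Score discrimination.** `score_discrimination()` reads a score plot the
way a spectroscopist does: orient the factor axis so the older group has
the higher mean score, then classify by the sign of the score (threshold
fixed at 0, the score-plot origin; no ROC optimization, which would be
optimistically biased). Sensitivity and specificity are reported in
percent for 6 M vs 24 M. The pipeline evaluates each factor up to the
selected count and reports the best-separating one, mirroring how a
discriminating factor is chosen by eye; note that *training* scores are
optimistically biased (under a pure null this statistic sits well above
the chance value of sens+spec = 100), so the cross-validated predictions
(`y_cv`) are stored alongside and used for null-calibration checks.

## Band-intensity indices

`compute_panel()` evaluates nine biomarker indices per sample. Peak
intensities come from the inverted second derivative (−d²A/dν², which
turns band minima into sharp maxima) except for the Amide I/II peaks,
which are read from the baseline-corrected, area-normalized, non-derived
spectra (Amide I located as the raw maximum in 1700–1600 cm⁻¹, Amide II in
1560–1480 cm⁻¹):

| index | definition | source |
|---|---|---|
| acyl chain length | (I₂₈₅₁+I₂₉₂₂)/(I₂₉₅₉+I₂₈₇₁) | inverted 2nd deriv. |
| lipid unsaturation | I₃₀₁₃/(I₂₈₅₁+I₂₉₂₂) | inverted 2nd deriv. |
| triglycerides | I₁₇₄₁ | inverted 2nd deriv. |
| total protein | I_AmideI + I_AmideII | non-derived |
| antiparallel β fraction | I₁₆₉₃/(I₁₆₉₃+I₁₆₈₂+I₁₆₂₈) | inverted 2nd deriv. |
| intermolecular β fraction | I₁₆₂₈/(I₁₆₉₃+I₁₆₈₂+I₁₆₂₈) | inverted 2nd deriv. |
| fibril formation | I_AmideII/I_AmideI | non-derived |
| cholesterol esters | I₁₁₆₉ | inverted 2nd deriv. |
| glucose | I₁₀₄₅ | inverted 2nd deriv. |

Design notes. The peak search window is ±6 cm⁻¹ by default because real
band centers drift a few cm⁻¹ between tissues; a windowed local maximum
absorbs the drift. "Total protein" is implemented as the Amide I + Amide
II *sum* and "fibril formation" as their *ratio* — the two published
formulations of the total-protein panel collide (the caption text names a
sum but prints the ratio), so the package emits both and documents the
ambiguity instead of resolving it. The two β fractions deliberately do not
add to 1; the remainder is the 1682 cm⁻¹ β-sheet share.

Because the windowed maximum is a nonlinear statistic, its value on a
noisy trace is biased upward by roughly the local noise SD. The pipeline
therefore averages each animal's technical-replicate *spectra* (after
preprocessing, before extraction; `average_tech_spectra()`), which cuts
both the bias and the variance — rather than averaging the extracted
values afterwards (`panel_replicates = "rows"` restores that behaviour).
The animal is the inferential unit either way.

## Inference

`two_way_anova()` fits the ordinary fixed-effects tissue × age ANOVA on
one value per animal. Balanced designs use the classical orthogonal
partition; unbalanced designs (after outlier removal) use Type II sums of
squares via effect-coded model comparisons — no a-priori emphasis on the
interaction, the standard choice for this design. `pairwise_cells()` runs
the comparison family used for the figures — cardiac vs skeletal at each
age, $t = \Delta \bar y / \sqrt{MS_\text{res}(1/n_a + 1/n_b)}$ on the
residual df — and applies the Šidák correction
$p_\text{adj} = 1 - (1-p)^m$ over the family (per index, m = 4). Šidák is
applied to p-values rather than to critical values; at a fixed α the
decision rule is equivalent. Technical replicates are averaged per animal
first, preventing pseudoreplication.

## Numerical choices and degenerate inputs

* Wavenumbers are stored ascending (plots reverse the axis); linear
  interpolation for regridding, with extrapolation refused.
* The rubberband hull is computed by Andrew's monotone chain; contact
  points are exactly zero after subtraction, and rounding dust is clamped
  at zero.
* SG differentiation requires a uniform grid (checked at 1e-6 relative)
  and a window no longer than the trace.
* Area normalization refuses a nonpositive integral; constant responses,
  empty design cells, zero residual df, and single-tissue PCA comparisons
  are all hard errors naming the offending input.
* All randomness (simulation, CV folds) flows from one master seed; rerun
  with the same config and seed and every artifact is identical.

## Validation strategy and problem sizes

The test suite works at three levels: closed-form oracles (SG derivative
of polynomials and Gaussians, Šidák arithmetic, Q residuals of constructed
rows), independent reimplementations (NIPALS PLS, brute-force cell-sum
ANOVA), and end-to-end parameter recovery on the default synthetic cohort
(240 spectra), where the configured aging signature must reappear in the
report: the cardiac intermolecular β fraction rising across 6→24 M, the
skeletal one not rising, amide-region 6 M vs 24 M discrimination at ≥90 %
sensitivity and specificity, and PLS-predicted age correlating with true
age at R ≥ 0.6. Null calibration uses 1000 ANOVA replicates (rejection
rate at α = 0.05 must sit in [0.035, 0.065]) and a no-effect cohort for
PLS (cross-validated sens+spec within 100 ± 30).

## Known limitations

* At the default noise level the β-fraction *group means* move by only a
  few multiples of their standard errors between adjacent ages; strict
  monotonicity across all three age steps is at the edge of what the
  design (10 animals/group) can resolve, and the skeletal antiparallel
  fraction in particular can wiggle at a given seed. The discrimination
  and correlation statistics are far more robust read-outs.
* Tissue offsets on a few bands are small relative to the residual
  variance after second differentiation, so cross-tissue PC1 separation
  on the default cohort is partial — simulate a larger marker band to see
  the textbook 100 % separation (see `compare_tissues_pca()` tests).
* The windowed-maximum intensity is upward-biased on noisy traces; for
  very weak bands (I₁₆₉₃ at old ages) this compresses true declines.
* PLS training-score discrimination is optimistically biased; prefer the
  cross-validated statistics when honesty matters more than comparability
  with score-plot practice.

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
report$panel_summary[, c("tissue", "age_months",
                         "intermolecular_beta_fraction_mean")]
```
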