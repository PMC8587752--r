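# ftirage

Chemometric analysis of ATR-FTIR spectra for aging fingerprints in mouse
striated muscle.

Mid-infrared absorbance spectra of cardiac and skeletal muscle carry
overlapping absorption bands of lipids (3050–2800 cm⁻¹), proteins
(1800–1500 cm⁻¹, the Amide I/II envelope) and carbohydrates/nucleic acids
(1200–900 cm⁻¹, the fingerprint region). `ftirage` asks whether the age
group of an animal (6, 12, 17 or 24 months) can be read off such spectra,
and through which bands. It is written for spectroscopists and
biostatisticians who want the full workflow as tested, scriptable code
rather than point-and-click chemometrics software.

The package implements:

* **Spectral I/O** — long-format CSV (one row per spectral point, with
  tissue/age/replicate metadata), a minimal JCAMP-DX reader, and linear
  regridding onto a common wavenumber axis.
* **A synthetic cohort generator** — Gaussian bands at the canonical
  assigned wavenumbers with per-tissue linear age slopes, per-animal
  amplitude effects, random quadratic baselines, multiplicative
  sample-amount scatter and additive noise; 2 tissues × 4 ages × 10
  biological × 3 technical replicates by default, fully seeded, with a
  `ground_truth()` table for parameter-recovery tests.
* **Preprocessing** — region cutting, rubberband (lower convex hull)
  baseline correction, area normalization
  (∫A dν = 1, so sample amount cancels), and Savitzky–Golay
  second-derivative spectroscopy with true d²A/dν² scaling.
* **Chemometrics** — PCA with Q-residual (squared prediction error)
  outlier screening; kernel-algorithm PLS1 regression of age on
  second-derivative spectra with seeded random 10-fold cross-validation,
  parsimonious factor selection, and score-plot discrimination
  (sensitivity/specificity of 6 M vs 24 M classification by score sign).
* **Nine band-intensity biomarker indices** — acyl chain length
  (I₂₈₅₁₊₂₉₂₂/I₂₉₅₉₊₂₈₇₁), lipid unsaturation (I₃₀₁₃/I₂₈₅₁₊₂₉₂₂),
  triglycerides (I₁₇₄₁), total protein, antiparallel and intermolecular
  β-sheet fractions (I₁₆₉₃ and I₁₆₂₈ over I₁₆₉₃₊₁₆₈₂₊₁₆₂₈), fibril
  formation (I_AmideII/I_AmideI), cholesterol esters (I₁₁₆₉) and glucose
  (I₁₀₄₅), extracted from inverted second-derivative spectra (Amide peaks
  from non-derived spectra).
* **Inference** — ordinary two-way ANOVA (tissue × age; Type II sums of
  squares when unbalanced) and Šidák-adjusted cardiac-vs-skeletal
  contrasts at each age, one observation per animal.

## Worked example

```r
library(ftirage)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
```

```
study_report
  spectra: 240 (removed 0 outliers)
  PLS cardiac.lipid          factors 1 (disc. factor 1), R = 0.550, sens 80.0%, spec 86.7%
  PLS skeletal.lipid         factors 1 (disc. factor 1), R = 0.572, sens 73.3%, spec 70.0%
  PLS cardiac.amide          factors 1 (disc. factor 1), R = 0.763, sens 100.0%, spec 93.3%
  PLS skeletal.amide         factors 3 (disc. factor 1), R = 0.890, sens 90.0%, spec 90.0%
  PLS cardiac.fingerprint    factors 1 (disc. factor 1), R = 0.646, sens 80.0%, spec 90.0%
  PLS skeletal.fingerprint   factors 3 (disc. factor 1), R = 0.871, sens 93.3%, spec 86.7%
  PCA tissue separation lipid        PC1 sens 56.7%, spec 54.2%
  PCA tissue separation amide        PC1 sens 60.8%, spec 61.7%
  PCA tissue separation fingerprint  PC1 sens 58.3%, spec 60.8%
```

Reading this: the pipeline simulated the default 240-spectrum cohort,
found no Q-residual outliers, and fitted one PLS model per tissue per
region. `R` is the Pearson correlation between PLS-predicted and true age
(e.g. 0.89 in the skeletal amide region — a strong aging signal in the
protein bands); `sens`/`spec` score how well the best discriminating
factor separates 6-month from 24-month animals by score sign (100 %/93 %
for cardiac amide). The PCA lines score cardiac-vs-skeletal separation on
PC1 per region; with the default generator the tissue offsets are modest,
so separation is partial. The report also carries the per-sample index
panel (`report$panel`), group means ± SD (`report$panel_summary`) — e.g.
the cardiac intermolecular β-sheet fraction rises from 0.577 (6 M) to
0.679 (24 M) — and the ANOVA/contrast tables (`report$stats`).

A command-line front end is included:

```sh
Rscript inst/cli/ftirage.R simulate --seed 17 --out cohort.csv
Rscript inst/cli/ftirage.R analyze --input cohort.csv --seed 1 --out results/
```

See `vignettes/ftir-aging-pipeline.Rmd` for the model, the preprocessing
and window choices, and known limitations.

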