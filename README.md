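# popfluor

Single-cell bioreporter fluorescence heterogeneity analysis.

## The problem

Whole-cell bioreporters couple a promoter of interest (here the alkane
1-monooxygenase promoter, P*alkB*) to a fluorescent protein, so that each
cell's fluorescence is a proxy for its promoter activity. In bacterial
populations — in liquid culture or on leaf surfaces — expression of such
catabolic genes is often strongly heterogeneous: most cells stay dim while
a minority subpopulation activates the promoter, a pattern consistent with
bet-hedging. Quantifying that heterogeneity from microscopy requires a
chain of steps, each of which `popfluor` implements as tested, reusable
functions:

1. **Segmentation** — bacterial cells appear dark in phase contrast; the
   image is thresholded at `mean − k·sd` (k in 1–4, population SD), the
   mask is refined by watershed splitting, erosion and dilation, and
   connected particles with physical area in 0.25–6.0 µm² are measured
   (area, perimeter, best-fit-ellipse axes and angle, circularity
   `4πA/P²`, Feret calipers, aspect ratio, roundness `4A/(π·major²)`,
   solidity `A/A_hull`), mapped onto the fluorescence channel.
2. **Cell/non-cell classification** — an L1-penalised logistic regression
   (penalty tuned on a log grid from 10⁻⁴ to 10⁻¹) and a 500-tree random
   forest (25 mtry × min-node combinations) are trained on labelled
   particle tables with a stratified 75/25 split and 10-fold
   cross-validation, the better family selected by held-out ROC-AUC.
3. **Background correction** — the percentile auto-threshold masks out
   biomass; 50 random 2×2-px squares in the background give per-square
   mean fluorescence, and each cell's signal is corrected by subtracting
   the per-image median of those means.
4. **Population statistics** — distribution shape is summarised by moment
   skewness `b₁ = m₃/m₂^{3/2}` and raw kurtosis `b₂ = m₄/m₂²` (normal
   reference: 0 and 3); a baseline threshold

   `I = Q75 + 1.5 × IQR`

   is fitted on a control population (no-inducer medium per timepoint, or
   time zero), every value is expressed relative to `I`, and a cell is
   "high-fluorescence" iff its relative value exceeds 1. Per-replicate
   top-quantile (1% or 10%) fold changes are tested against baseline
   (one-sample t) and across timepoints (ANOVA + Tukey HSD, or
   Kruskal-Wallis + Dunn with Holm-Bonferroni, gated by Shapiro-Wilk and
   Levene at α = 0.05). Colony counts normalise to CFU per gram fresh
   weight.

Because the original micrographs are not shipped, the package includes a
**synthetic generator** (`simulate_micrograph()`, `simulate_feature_table()`,
`simulate_cell_population()`) that renders elliptical cells and four kinds
of debris on noisy 8-bit phase/fluorescence channels, with per-cell
fluorescence drawn from a two-component lognormal mixture (fraction
`p_high` of strongly expressing cells). Every downstream stage is tested
against this known ground truth.

## Worked example

```r
library(popfluor)

cfg <- simulation_config(seed = 42)        # 30 cells + 10 debris, p_high = 0.1
res <- simulate_micrograph(cfg)
particles <- detect_particles(res$micrograph)
nrow(particles)
#> [1] 41

train <- simulate_feature_table(cfg, 600)
fit <- train_and_tune(train, classifier_spec("rf", seed = 42))
fit$report
#> <classifier_report rf: cv ROC-AUC 1.000, test ROC-AUC 1.000, accuracy 1.000>
particles <- apply_model(fit$model, particles)
sum(particles$label == "cell")
#> [1] 30

bm  <- background_mask(res$micrograph$phase, dark_foreground = TRUE)
est <- estimate_background(res$micrograph$fluor, bm, seed = 42,
                           image_id = res$micrograph$image_id)
est$median_background
#> [1] 7.75

cells <- particles[particles$label == "cell", ]
cells$timepoint <- 1
pop <- correct_fluorescence(cells, est)

ctrl <- simulate_cell_population(simulation_config(p_high = 0, seed = 7), 2000)
bl <- fit_baseline(ctrl$value, source = "uninduced control")
bl
#> <baseline_model (uninduced control): Q75 = 19.6, IQR = 8.345, I = 32.12>
summarize_population(relative_fluorescence(pop, bl))
#>   condition timepoint n_replicates n_cells median_rel_fluor iqr_rel_fluor
#> 1 synthetic         1            1      30            0.474         0.151
#>   proportion_high max_rel_fluor skewness kurtosis
#> 1            3.33            5.82     5.03     26.9
```

Reading the summary row: the 41 detected particles reduce to the 30 true
cells after classification; after background subtraction (median 7.75 of
the sampled square means) the median cell sits at 0.47× the baseline
threshold `I`, 3.3% of cells exceed baseline (one strongly expressing cell
reaches 5.8×), and the strong right skew (5.0) with heavy tails (kurtosis
26.9 ≫ 3) is the signature of a minority high-expression subpopulation on
a dim majority.

The `analysis/` scripts chain these stages into full study-style runs:

- `01_simulate_data.R` — synthetic micrograph sets with ground truth,
- `02_train_classifiers.R` — model comparison and feature importances,
- `03_invitro_analysis.R` — control-baselined heterogeneity table and
  top-1% subpopulation tests,
- `04_inplanta_analysis.R` — time-zero-baselined table, top-10% tests,
  CFU gFW⁻¹ normalisation.

Tables land in `results/`, bulky run artefacts under `scratch/`.

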