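---
title: "Methods: single-cell bioreporter heterogeneity quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell bioreporter heterogeneity quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfluor)
```

## The measurement model

A bioreporter strain carries a fluorescent protein under the promoter of
interest, so the fluorescence of a single cell measures that cell's
promoter activity. The quantity of scientific interest is not the mean of
the population but its *shape*: a population in which a minority of cells
strongly activates the promoter while the majority stays dim produces a
right-skewed, heavy-tailed fluorescence distribution, and the fraction of
cells above a control-derived baseline estimates the size of the active
subpopulation.

`popfluor` implements the full chain from paired phase-contrast and
fluorescence micrographs to those population statistics. This vignette
records the methodological choices, their defaults, and their limits.

## Segmentation

Cells are dark objects on a bright phase-contrast background. The
threshold is

\[ t = \bar{x} - k\,\sigma(x), \qquad k \in [1, 4], \]

with $\sigma$ the population (1/n) standard deviation — pixel sets are
complete populations, and at image scale the 1/n vs 1/(n−1) difference is
far below quantisation noise. Pixels strictly below $t$ are foreground
candidates. The default is $k = 2$ for clean liquid-culture-style fields;
noisier leaf-wash-style fields warrant larger $k$ (a lower, more
conservative threshold). **The choice of $k$ interacts with object
density**: the image mean and SD are computed over all pixels, so a field
crowded with dark cells inflates $\sigma$ and drags the threshold into the
cell intensity distribution, punching holes into cell masks that the
subsequent erosion amplifies. At the generator's default density (~6% of
pixels are object) $k = 2$ leaves cells intact; above roughly 12% object
coverage $k = 1$ is the appropriate setting.

Mask refinement applies, in configurable order (default: watershed, then
erode, then dilate, both with a one-pixel-radius 3×3 structuring element):

- *watershed*: basins of the distance map split touching convex objects;
  the split removes, from the higher-numbered basin only, pixels
  8-adjacent to another basin, which guarantees a clean separation line
  while eroding only one side by one pixel;
- *erosion/dilation*: a morphological opening that removes speckle noise.

Connected components use 8-connectivity (the standard particle-analysis
convention for small convex objects). Components are filtered to physical
areas between 0.25 and 6.0 µm² — the filter is in µm², so a calibrated
pixel size is mandatory; there is no pixel-unit fallback.

### Shape descriptors

All conventions are fixed once: pixel coordinates are 0-based (row, col)
in exported tables; angles are degrees in [0, 180) from the +x (column)
axis with rows increasing downward; lengths are µm via the pixel size.

- **Perimeter** is the length of the marching-squares boundary polygon
  (level 0.5 on the padded particle mask) after a circular three-point
  moving average of its vertices. The smoothing removes the staircase
  bias of the raw contour; against closed forms the estimator is accurate
  to ~4% for discs, squares and 2:1 ellipses at cell-relevant sizes,
  which motivates the ±5% tolerance used for rasterized shapes in the
  tests (pixelation error is irreducible).
- **Best-fit ellipse** (major, minor, angle) comes from the second-order
  moments of the pixel coordinates with the 1/12 single-pixel variance
  correction; axis lengths are $4\sqrt{\lambda_i}$.
- **Feret calipers** are computed on the convex hull of the pixel corner
  points (the hull of the corners of the centre-hull pixels equals the
  hull of all corners — a Minkowski-sum identity — so the computation
  stays small). Feret is the maximal vertex pair distance; MinFeret the
  minimal edge-supported width; the reported start coordinate is the
  lower-x endpoint.
- **Circularity** $4\pi A/P^2$ and **roundness** $4A/(\pi\,\mathrm{major}^2)$
  are capped at 1; **solidity** is pixel count over hull polygon area and
  cannot exceed 1 by construction.
- A single-pixel particle takes the degenerate values major = minor =
  pixel size, solidity 1.

## Cell/non-cell classification

Detected particles include debris, so a supervised classifier separates
cells from non-cells on the descriptor set (area, perimeter, axes, Feret
widths, aspect ratio, roundness, circularity, solidity; optionally the
growth condition as a categorical predictor). Two families are supported:

- L1-penalised logistic regression, penalty tuned over a log-spaced grid
  from $10^{-4}$ to $10^{-1}$. The grid *range* is fixed; its resolution
  (default 20 points) is configurable. Predictors are standardized inside
  the penalised fit, as L1 penalties are scale-sensitive.
- Random forest with 500 trees, tuned over 25 combinations of predictors
  per split (5 values spanning 1..p) and minimum node size (2, 5, 10, 20,
  40).

Both use a stratified 75/25 train/test split and stratified ten-fold
cross-validation on the training set (stratification is the defensible
default under cell/debris imbalance); the best hyperparameters maximise
mean CV ROC-AUC, and families are compared by held-out ROC-AUC with ties
broken by accuracy and then declared order. Within the penalty grid, ties
on CV ROC-AUC are broken toward the *smaller* penalty: ranking performance
is equal, but weaker shrinkage keeps the predicted probabilities
calibrated around the 0.5 labelling cutoff. Classification applies a 0.5
probability threshold (configurable at application time). ROC-AUC is the
rank-based (Mann-Whitney) statistic with midrank ties; all confusion
metrics (accuracy, precision, recall = sensitivity, F1, Cohen's kappa,
specificity) are computed from the held-out confusion matrix.

The categorical condition predictor is available but off by default: it
is useful for importance inspection, but a condition-aware classifier
cannot transfer to conditions unseen in training.

## Background correction

Biomass is masked by the percentile auto-threshold: the intensity cutoff
at which foreground occupies as nearly as possible the target fraction
(default 50%) of pixels; the background mask is its inversion. The
orientation of "foreground" is explicit: bright-side foreground by
default (biomass bright, as in a fluorescence channel), with a
`dark_foreground` switch that the pipeline enables when masking from the
phase channel, where biomass is dark.

Fifty 2×2-pixel squares are sampled uniformly *without replacement* among
positions lying entirely inside the background mask — partial overlap
with biomass would contaminate the estimate. If fewer than fifty valid
positions exist, all are used and a warning is recorded. Each cell's mean
fluorescence is corrected by subtracting its own image's **median of the
square means**; the pooled pixel median is recorded alongside as a
diagnostic, since a defensible alternative reading of the procedure pools
the square pixels. Negative corrected values are **retained**: clipping
at zero would truncate the left flank of the distribution and bias the
skewness and kurtosis statistics that carry the scientific conclusion.
Correction is a per-image affine shift, so within-image differences
between cells are preserved exactly.

## Population statistics

- Moment skewness $b_1 = m_3/m_2^{3/2}$ and raw kurtosis $b_2 = m_4/m_2^2$
  (1/n central moments; normal reference 0 and 3; $b_2 \ge b_1^2 + 1$ for
  any sample). Both error on zero-variance input.
- The baseline threshold $I = Q_{75} + 1.5 \times \mathrm{IQR}$ is fitted
  on pooled control values. The quantile convention is linear
  interpolation of order statistics (R type 7), declared once and used
  for $Q_{75}$, the IQR and top-quantile selection. On normal null data
  this criterion flags ≈0.35% of independent draws — the classical
  IQR-outlier rate — which the tests verify by Monte Carlo.
- Relative fluorescence divides by $I$; "high-fluorescence" is the strict
  inequality rel > 1, so a cell exactly at baseline is not high. The
  normalisation by $I$ (rather than by the control median) makes
  "exceeds baseline" and "relative value > 1" the same statement; the
  control-median alternative can be obtained by scaling with
  `baseline$threshold_I / median(control)` if needed.
- Summaries are computed on values **pooled across replicates** within
  condition × timepoint (cell counts add up across replicates);
  per-replicate statistics are used only where the error structure is
  per-replicate, i.e. the top-quantile fold-change tests.
- Replicates with fewer than 20 cells are excluded (configurable; the
  threshold must be explicit because it materially changes pooled
  statistics), with warnings logged.
- Top-quantile analysis: per replicate, cells at or above the $1-q$
  quantile of that replicate's relative values; the replicate's fold
  change is their median. $q$ = 0.01 suits dense liquid-culture samples,
  $q$ = 0.10 sparser leaf washes. Replicates with fewer than
  $\lceil 1/q \rceil$ cells are excluded. Per timepoint, a one-sample
  t-test compares replicate fold changes against 1 (reported as NA when
  fewer than two replicates remain or variance vanishes). Across
  timepoints, Shapiro-Wilk (every group) and Levene's test gate at
  α = 0.05 between ANOVA + Tukey HSD and Kruskal-Wallis + Dunn's pairwise
  z-tests (tie-corrected joint ranks) with Holm-Bonferroni adjustment.
  The gate is explicit because the analysis protocol lists both branches
  without a stated rule.
- CFU gFW⁻¹ = colonies × dilution × (wash volume / plated volume) /
  fresh weight, with the wash volume tracked explicitly.

## The synthetic generator

The generator is the package's test bed and stands in for the study's raw
data. It emulates:

- dark elliptical cells (uniform interior intensity plus Gaussian pixel
  noise — the simplest shape consistent with the measured descriptors) on
  a brighter noisy background, 8-bit with clipping at 0 and 255, so that
  strong expressors saturate realistically;
- per-cell fluorescence from a two-component lognormal mixture: a
  low-expression majority (meanlog log 15, sdlog 0.35) and a
  high-expression minority (meanlog log 120, sdlog 0.25) of fraction
  `p_high`. Lognormal components produce the right-skewed, heavy-tailed
  populations the method is designed to summarise with only two
  parameters each;
- four debris archetypes chosen so solidity and aspect ratio are
  genuinely informative: sub-window specks, oversized blobs, concave
  two-lobe fragments, and elongated fibres;
- replicate × condition × timepoint structure via the pipeline design
  table.

Defaults: 512×512 px fields at 0.065 µm/px (a typical 100× oil-objective
calibration — the original acquisition calibration is not known, so pixel
size is a free parameter); 30 cells and 10 debris per field; cell areas
0.5–4.0 µm² (inside the 0.25–6.0 µm² detection window, so simulated cells
are detectable by construction); axis ratios 1.2–3.5; phase background
180 ± 6 with cell contrast 60; fluorescence background 8 ± 3. Objects are
placed by rejection sampling with pixel-level collision tests and a 3-px
margin; an overcrowded configuration fails with an explicit density error
rather than silently overlapping objects.

In feature space, `simulate_feature_table()` draws debris descriptors
pulled away from the cell distributions by `class_separation`: 0 makes the
classes identically distributed (classifier AUC ≈ 0.5 by construction), 1
shifts all debris solidity strictly below all cell solidity (a threshold
on solidity alone separates perfectly). The default 0.8 was chosen as a
moderately separated regime; in practice the joint feature distributions
it produces are still linearly separable, so held-out ROC-AUC sits near 1
— comfortably above the >0.9 contract the classifier stage is held to.

What the generator does **not** emulate: phase-contrast halo optics and
the point-spread function, uneven illumination, focus drift, cell-cell
adhesion and microcolonies, autofluorescent leaf debris with structured
texture, and time-lapse correlation. Passing tests therefore demonstrate
the correctness of the measurement and statistics chain under a faithful
geometric/statistical model, not robustness to every optical artefact of
real micrographs.

## Numerical choices and degenerate inputs

- 8-bit conversion: linear min-max rescale then round half up; a constant
  image maps to zeros.
- Quantiles: R type 7 everywhere.
- Moment statistics and Shapiro-Wilk error on zero variance; summary
  tables report NA shape statistics for zero-variance groups instead of
  failing the whole run.
- The percentile mask of a constant image is all background (no biomass
  evidence).
- Seeds: one global pipeline seed fans out to per-stage, per-image seeds
  through fixed offsets; identical seeds give bit-identical images,
  tables and fitted models (`ranger` is seeded and run single-threaded).

## Problem sizes

The shipped tests run the statistics on 10⁵-draw null samples, mixture
recovery on 5000-cell populations against a 2×10⁵-draw Monte-Carlo
oracle, classifier contracts on a 2000-particle fixture under the full
tuning protocol, and segmentation contracts on three 512×512 fields —
sizes chosen so the whole suite completes in about a minute while keeping
every Monte-Carlo tolerance at 3 standard errors or tighter.

## Known limitations

- The threshold rule is global per image; no illumination-field
  correction is attempted, so strong shading would need preprocessing.
- The classifier is trained on the synthetic feature distribution; for
  real data it should be retrained on manually labelled particles from
  the same imaging setup.
- No mixture-model deconvolution of the fluorescence distribution is
  attempted; the IQR criterion is a robust threshold, not a component
  assignment.
- Kruskal-Wallis omnibus and Dunn post-hoc p-values answer different
  questions and can disagree on borderline data; both are reported
  without reconciliation.
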