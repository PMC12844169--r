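---
title: "QC-driven two-stage drift correction for single-cell ToF-SIMS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC-driven two-stage drift correction for single-cell ToF-SIMS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normsvr)
```

## The problem

Single-cell ToF-SIMS measures, for every cell, a vector of secondary-ion
intensities (peak areas) across hundreds of feature ions. The measurement is
sensitive to where on the silicon wafer a cell sits, to the state of the
primary-ion source, and to anything that changes between acquisition days.
Cells measured at different collection points on one wafer, or in different
batches, therefore separate in principal-component space for reasons that
have nothing to do with biology, and the relative standard deviation (RSD)
of most ions across nominally identical samples is far above what counting
statistics would predict.

The corrective strategy implemented here relies on *cell-scale quality
control*: single cells of similar size, interleaved through the acquisition
sequence at a fixed ratio (one QC after every four cells, and one at each
end of the sequence). Because QC samples share one reference profile, any
variation among them is technical, and a model of that variation can be
transferred to the cell samples measured around them. No internal standard
is required.

## The two-stage model

**Stage 1 — QC Z-score normalization.** For feature ion $j$, let $\mu_j$ and
$\sigma_j$ be the mean and sample standard deviation (denominator $n-1$) of
its intensity over the QC samples. Every intensity is standardized as

$$z_{ij} = \frac{x_{ij} - \mu_j}{\sigma_j}.$$

Using QC statistics — not statistics over the cells — keeps biological
heterogeneity out of the normalization parameters: $z_{ij}$ measures
deviation from the technical reference in units of technical spread, and it
puts ions whose raw intensities span four decades on one scale, so that no
high-intensity ion dominates the downstream regression. Features with
$\sigma_j = 0$ carry no calibratable signal; the default policy drops them
(recorded in the fit), and an `epsilon` policy that floors $\sigma_j$ at a
machine-epsilon scale is available for degenerate but valid inputs such as
noise-free simulations.

**Stage 2 — QC-driven SVR drift correction.** For each retained feature
independently, an $\epsilon$-insensitive support vector regression is
fitted to the *QC samples'* z-scores as a function of acquisition
covariates: scaled acquisition order (position in the batch sequence mapped
to $[0,1]$), collection region (one-hot), and batch (one-hot). The fitted
function $\hat d_j(\cdot)$ is the predicted technical-error surface. It is
evaluated at every sample's covariates — cells and QC alike — and
subtracted:

$$z^{\mathrm{corr}}_{ij} = z_{ij} - \hat d_j(\mathrm{covariates}_i),$$

after which the inverse transform $\hat x_{ij} = z^{\mathrm{corr}}_{ij}
\sigma_j + \mu_j$ returns the table to the raw intensity scale (negative
back-transformed values are clipped at zero and counted; correction can
legitimately push a low signal below $\mu_j - k\sigma_j$).

Two design choices deserve emphasis, because the underlying method
description leaves them open:

* *Covariate-based design matrix.* The drift model regresses on acquisition
  covariates (order, region, batch), not on other features' intensities.
  This is the minimal reading of "drift as a function of influencing
  factors", and it guarantees structurally that cell intensities can never
  leak into the fitted models — permuting the cell rows of the input leaves
  the model set bit-identical, which the test suite asserts. A
  MetNormalizer-style formulation with correlated feature intensities as
  predictors would break that guarantee. `fit_drift_models()` accepts any
  metadata-derived design through the covariate set, which is the hook for
  alternative encodings.
* *Subtractive correction in z-space.* No correction equation is printed in
  the method's source description. Subtraction on the standardized scale is
  the natural composition with Stage 1, reduces to
  $\hat x = x - \sigma_j \hat d_j$ on the raw scale, and makes the
  corrected QC samples standardized residuals of the drift fit.

**Hyperparameters.** Each feature's $(C, \epsilon, \gamma)$ is chosen by
exhaustive grid search with seeded $k$-fold cross-validation ($k = 5$ by
default) over the QC samples of the fitting unit, minimizing mean held-out
squared error. Ties break toward the smallest $C$, then $\epsilon$, then
$\gamma$ — a deterministic preference for the least flexible model. Default
grids are $C \in \{0.1, 1, 10, 100\}$, $\epsilon \in \{0.01, 0.05, 0.1\}$
(z units), $\gamma \in \{\mathrm{scale}, 0.1, 1, 10\}$ with
$\mathrm{scale} = 1/(p\,\mathrm{var}(X))$; the kernel is RBF by default,
with a linear option. The grid itself is not prescribed by the method's
source; these values mirror common QC-based SVR practice and are fully
configurable. Folds are assigned by a seeded shuffle; an
acquisition-order-contiguous ("blocked") assignment is available for a
harder, extrapolation-honest assessment of drift models.

**Fitting scope.** With more than one batch, drift curves are fitted per
batch by default (instrument state differs between batches; the batch
indicator is then redundant within a unit and is dropped). Pooled fitting
can be forced. QC statistics for Stage 1 are pooled across all QC samples
by default — matching the definition of $\mu_j, \sigma_j$ over *all* QC
samples — with a per-batch option. Categorical covariate levels unseen
during fitting are an error at prediction time, never an extrapolation.

**Degenerate fits.** When every training point lies inside the
$\epsilon$-tube, libsvm returns a model with no support vectors, from which
it cannot predict. The SVR solution in that case is a constant; the
implementation substitutes the training mean, which for a flat QC signal is
the correct zero-drift answer.

## Diagnostics

The evaluation module reproduces the standard battery for judging a
correction:

* **RSD distributions** per feature over QC rows and over cell rows
  (sample sd, percent), with histogram, cumulative curve, and
  fraction-below-threshold summaries (strict inequality; zero-mean features
  get infinite RSD and are excluded from denominators).
* **PCA** with mean-centering and, by default, unit-variance scaling —
  without a fixed scaling convention, comparing raw against normalized
  tables is meaningless because their units differ wildly. Component signs
  follow the convention that each component's largest-magnitude loading is
  positive, so scores are reproducible across numerical libraries.
* **Batch-mixing score**: the mean silhouette width of batch (or region)
  labels on the first two PC scores, a scalar for what a reader judges from
  a two-dimensional score plot. High values mean tight label clusters
  (strong batch effect); values near zero or below mean mixing.
* **Correlation report**: the Pearson sample-by-sample matrix of the
  corrected table (block structure exposes residual batch effects);
  per-sample Spearman correlation between each sample's feature vector
  before and after correction (rank preservation — average ranks for ties);
  and a least-squares fit of per-sample log10 mean intensity after vs
  before.
* **LOESS ion trends**: local linear regression (degree 1, tricube weights,
  no robustness iterations, span 0.75 by default) of a single ion over the
  acquisition sequence. The smoother's parameters are stated here because
  the name "LOESS" alone does not pin them down.

## The synthetic-data generator

The real single-cell tables this method was developed on are not publicly
archived, so the package ships a generator that reproduces the two
experimental designs with known ground truth:

$$x_{ij} = p_{ij}\; b_{B(i),j}\; r_{R(i),j}\; \bigl(1 + A\,s_j(t_i)\bigr)\;
\eta_{ij}$$

with $p_{ij}$ the drift-free profile (a fixed reference profile for QC
rows; log-normal cell profiles with biological CV around the same base for
cells), $b$ and $r$ log-normal batch and region offsets, $s_j$ a smooth
drift shape (sinusoidal by default, with per-feature phase and sign;
linear and exponential-decay shapes available) scaled to $[-1, 1]$ over the
batch sequence, $A$ the relative drift amplitude, and $\eta$ log-normal
technical noise. Drift is multiplicative because mass-spectrometric signal
drift acts proportionally on count rates. QC samples are pseudo-cells
sharing one profile — the cell-scale QC principle — never blanks. All five
component matrices are stored, so the observed table can be reconstructed
exactly and counterfactuals (e.g. the drift-free table) are available to
tests. The generator also returns the ground-truth technical surface in
z units, directly comparable to the fitted $\hat d_j$.

Default conditions emulate the three-batch design: 3 batches × 52 cells
with QC interleaved 4:1 (14 QC per batch), 457 features, technical CV 10%,
drift amplitude 0.4 on 80% of features. Offset magnitudes are not stated
quantitatively anywhere in the method's source; they were calibrated once
so the generated data reproduce its qualitative findings: per-feature batch
offsets with log-sd 0.5 and region offsets with log-sd 0.3 make
between-batch (or, in the single-batch three-region design, between-region)
variation dominate the leading principal components of the raw table, give
raw QC RSD medians above 50%, and survive total-area normalization
(per-feature offsets cannot be removed by a row-sum rescale) — while
leaving within-sample intensity ranks recoverable after correction. Base
intensities span four decades (log10 range 1.5–5.5), a realistic spread
for ToF-SIMS peak areas.

What the generator does *not* emulate: detector saturation and dead-time
effects, correlated ion suppression between co-localized species, spatial
pixel structure within a cell, m/z-dependent noise, or contamination events.
Passing the validation suite therefore shows the pipeline recovers known
smooth multiplicative drift and offsets under log-normal noise; it does not
certify performance against failure modes outside that model.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: QC-column
standardization to 1e-10 after Stage 1; linear-kernel SVR against the
ordinary-least-squares line on noiseless linear drift (50 replicates,
$n_{qc} = 20$, within 1% slope error); PCA explained variances against a
brute-force covariance eigendecomposition (20 random matrices up to 10×10,
1e-8); and the full pipeline on the three-batch design above (457 features),
where it checks drift recovery (mean absolute error ≤ 0.5 z units for ≥ 90%
of drifted features), the QC RSD contrast, batch-silhouette collapse after
correction (with total-area normalization retaining batch structure), rank
preservation (median per-sample Spearman ≥ 0.95; exactly preserved ranks in
the feature-homogeneous limit), and byte-level determinism of the demo
pipeline under a fixed seed. The three-batch fit at default grids takes a
few minutes on one CPU; all other checks run in seconds.

## Known limitations

* With ~14 QC points per batch, the per-batch SVR sees few observations;
  the cross-validated grid search guards against overfitting, but sharp
  drift features between QC positions are invisible in principle.
* Correction quality degrades for features whose QC variation is dominated
  by noise rather than systematic drift; the epsilon-tube then correctly
  yields a near-zero correction, but such features retain their noise.
* Batch and region are categorical: the method interpolates along
  acquisition order within known levels, and refuses (by design) to
  extrapolate to unseen batches or regions.
* The Spearman rank-preservation guarantee is exact only under
  feature-homogeneous drift; with heterogeneous drift, rank changes among
  features with nearly equal intensities are expected and quantified by the
  correlation report rather than prevented.
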