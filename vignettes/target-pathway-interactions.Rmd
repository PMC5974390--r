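---
title: "Linking drug targets to pathway activation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking drug targets to pathway activation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large drug screens measure the response (log-IC50) of hundreds of cancer
cell lines to hundreds of compounds.  Treating each drug or each gene in
isolation wastes most of the shared structure in such a panel: drugs
hitting the same protein target behave alike, and cell lines with the same
signaling state respond alike.  `tpinteract` fits one multitask model over
the whole matrix and extracts from it an interpretable object: a
**target x pathway interaction matrix** whose entry (T, P) answers
*"does activation of pathway P make cells more sensitive to drugs that
target protein T?"*

## The factorization model

Let $Y$ be the $n_D \times n_C$ response matrix (drugs x cell lines,
missing entries allowed), $x_i \in \{0,1\}^{F_D}$ drug $i$'s binary target
profile and $z_j \in \mathbb{R}^{F_C}$ cell line $j$'s pathway activity
scores.  The observation model is

$$ y_{ij} \sim \mathcal{N}(m + d_i^\top c_j,\ \alpha^{-1}), $$

with latent vectors of dimension $L$ tied to the side information through
link matrices $\beta_D$ ($F_D \times L$) and $\beta_C$ ($F_C \times L$):

$$ d_i \sim \mathcal{N}(\mu_D + \beta_D^\top x_i,\ \Lambda_D^{-1}), \qquad
   c_j \sim \mathcal{N}(\mu_C + \beta_C^\top z_j,\ \Lambda_C^{-1}). $$

Each axis carries a Normal--Wishart hyperprior on $(\mu, \Lambda)$
($\mu_0 = 0$, $b_0 = 2$, $W_0 = I$, $\nu_0 = L$) and a matrix-normal prior
on its link matrix, $\beta \sim \mathcal{MN}(0, \lambda_\beta^{-1} I_F,
\Lambda^{-1})$ with $\lambda_\beta \sim \mathrm{Gamma}(2, 2)$.  The
observation precision $\alpha$ is sampled under a $\mathrm{Gamma}(2, 2)$
prior by default (`noise_mode = "adaptive"`); a fixed-precision mode
exists for controlled experiments.  All conditionals are conjugate, so the
model is fitted by a plain Gibbs sampler; the link-matrix draw uses an
exact dense Cholesky factorization of its $F \times F$ posterior row
precision, which is the right tool at the feature counts this package
targets (tens to a few thousand features).  The global mean $m$ is the
observed mean of $Y$, removed before sampling and restored at prediction,
so the low-rank term never has to model a constant offset.

Ignoring the mean offsets, substituting the latent means gives the
bilinear form $\hat y_{ij} = x_i^\top \beta_D \beta_C^\top z_j$: every
prediction is a linear combination of target x pathway products.  The
**interaction matrix** reported by `interaction_matrix()` is

$$ I \;=\; -\,\frac{1}{S}\sum_{s=1}^S \beta_D^{(s)} \beta_C^{(s)\top}, $$

averaged over the $S$ collected Gibbs samples and sign-flipped so that a
*positive* entry means *sensitivity* (lower IC50) when the pathway is
active, matching the convention that lower log-IC50 is a stronger
response.  Only the product $\beta_D \beta_C^\top$ is identified (any
invertible transform of the latent space cancels in the product), which
is exactly why the product, not the factors, is the reported object.

```{r example}
library(tpinteract)
sim <- synth_generate(synth_config(seed = 1))
chain <- macau_fit(sim$response, sim$drug_side, sim$cell_side,
                   sampler_config(seed = 2))
res <- interaction_matrix(chain)
cor(as.vector(res$interaction), as.vector(sim$truth$interaction))
```

## Parameters that matter

* `n_latent` (L): latent dimension.  Defaults follow the reference
  analysis: 30 when drug side information is present, 10 when only
  cell-line features are used.  Too small an L overcrowds the latent
  space; the Bayesian averaging makes a generous L cheap in accuracy
  (though quadratic in run time).
* `burn_in` / `n_collect`: 400 discarded then 600 collected samples by
  default.  Every post-burn-in sample is stored; predictions and
  interactions average over all of them.
* `side_scaling`: `"auto"` standardizes real-valued side features
  (pathway scores) per feature and leaves binary target profiles
  untouched, keeping link weights comparable across pathways while the
  target incidence stays interpretable.  The fitted centers and scales
  are stored in the chain and re-applied verbatim to new entities, so
  cold-start predictions can never leak test-set statistics.
  Zero-variance features under standardization are dropped with a
  warning rather than dividing by zero.
* `seed`: all sampling goes through R's RNG; a fixed seed makes chains,
  predictions and output files bit-reproducible.

Cold-start latents use the predictive mean $\mu + \beta^\top x_{new}$
without a residual draw: the mean minimizes expected squared error, and
averaging residual draws over the chain would converge to the same value
anyway.

## Significance by permutation

`permutation_significance()` refits the whole model `n_perm` times with
each cell line's pathway-score vector independently shuffled
(`perm_mode = "within_cell"`).  This destroys any genuine target-pathway
linkage while preserving each cell line's score multiset; drug targets
are never permuted, because losing the information that two drugs share a
target would change the model class, not just the null.  The alternative
reading -- permuting cell-line labels within each pathway column -- is
available as `perm_mode = "across_cells"`.

The default p-value follows the reference definition exactly: for a
positive observed entry, the fraction of null draws at least as large;
for a negative one, the fraction at least as small (`alternative =
"signed"`, plain `count / n_perm`, so p = 0 is attainable; a
`(count+1)/(n_perm+1)` estimator is available via `smoothed = TRUE`).
Be aware that this sign-conditioned estimator is **anti-conservative by
construction**: conditioning the tail direction on the observed sign
compresses p-values toward zero (for a perfectly sign-symmetric null its
distribution is uniform on $[0, 0.5]$).  `alternative = "two_sided"`
($p = \#\{|null| \ge |obs|\}/n_{perm}$) is the calibrated variant: on
screens generated with no target-pathway signal its p-values are uniform
on $[0,1]$, which is what the package's calibration tests assert.  Use
the signed mode to reproduce the reference behaviour, the two-sided mode
when calibrated error control matters.

q-values use the Benjamini--Hochberg--Yekutieli step-up (via
`stats::p.adjust(method = "BY")`), valid under the arbitrary dependence
among interaction entries; the reporting threshold in
`threshold_significant()` defaults to q <= 20%.

Permuted refits default to a reduced budget (burn-in 100, collect 150)
so that hundreds of permutations stay tractable on one CPU; this is a
desk-scale concession relative to the reference analysis' 1000
full-budget permutations, and is configurable via `perm_config`.

## Validation before interpretation

The quality gate mirrors the reference workflow: before reading any
interaction matrix, run the double cold-start cross-validation
(`setting4_double_cv()`, independent folds over drugs and cells, test
blocks of never-seen drugs x never-seen cells) and require a mean
Pearson r of at least 0.3 (`quality_gate()`).  The four settings --
new cell lines, new drugs, imputation, double cold start -- share
deterministic fold construction and pool all observed test entries per
fold when computing r (a per-drug breakdown can be derived from the
returned fold definitions).  Setting 4 supports both the full k x k
block grid and a lighter diagonal pairing of folds.

## Pathway activity from perturbation footprints

The cell-line features are pathway activity scores learned from
perturbation experiments.  For each experiment, gene-wise z-scores
$(\bar{x}_{pert} - \bar{x}_{ctrl}) / sd_{ctrl}$ are regressed, per gene,
on the experiment's pathway design (+1 activated, -1 inhibited, 0
untouched; signed coding lets one coefficient serve both directions):

$$ z_{g} = \beta_0 + \beta_1\,\mathrm{EGFR} + \dots + \beta_{11}\,\mathrm{PI3K} + \varepsilon. $$

Per pathway, the 100 genes with the smallest two-sided coefficient
p-values keep their coefficients as weights; all other genes are zeroed
(ties at the boundary break by ascending gene identifier, so the model
is deterministic).  Scoring new expression data is then a single matrix
multiplication over the shared genes, `progeny_score()`, with no further
normalization -- it is exactly linear in the expression values.  An
optional per-gene centering flag exists for cross-dataset use, off by
default.

## The synthetic-screen generator

`synth_generate()` draws screens from the model's own generative
equations with a planted, known interaction matrix, so that every stage
of the pipeline can be validated against ground truth without any
external download.  The default configuration is the reference condition
used across the test suite: 100 drugs x 300 cell lines, 20 targets with
1-3 targets per drug, 11 pathways, planted rank 5, standard-normal
pathway scores and link weights, observation noise sd 0.5, 30% missing
at random.  `latent_residual_sd` defaults to 0 -- latents are exact
functions of the side information -- which isolates the planted bilinear
structure as the single source of signal; raising it adds entity-level
heterogeneity that side information cannot explain, which is the more
realistic regime for stress-testing cold-start prediction.
`synth_generate_null()` keeps all shapes and marginals but draws the
cell latents independently of the pathway scores, giving the
ground-truth-negative screens used for permutation calibration;
`synth_perturbations()` plants disjoint blocks of informative genes per
pathway for validating the pathway-model fit.

What the generator deliberately does **not** emulate: the empirical
distribution of real IC50 values (truncation at tested concentration
ranges, heavy tails), correlated missingness, batch structure, or
correlated pathway scores within tissues beyond simple additive mean
shifts (`tissue_effect_sd`).  Passing the planted-recovery tests
therefore demonstrates correctness of the machinery, not performance on
real screens.

Two consequences of the default (zero latent residual) regime are worth
knowing.  First, recovery is easy: the reported recovery correlations
(~0.999) reflect a high signal-to-noise reference condition, not typical
real-data performance.  Second, cold-start prediction is *not* harder
than imputation there: with latents fully determined by side
information, predicting a held-out cell line from its pathway scores is
essentially exact, while in-matrix posterior means carry residual
posterior noise, so settings 1 and 3 both saturate near r = 0.999 and
their ordering becomes a statistical tie (setting 1 marginally ahead).
The intuitive difficulty ordering (imputation easiest, double cold start
hardest) re-emerges as soon as `latent_residual_sd > 0`.

## Numerical choices and edge cases

* Precision-matrix draws use Bartlett-decomposition Wisharts; latent
  draws factor the conditional precision by Cholesky.  A non-positive-
  definite matrix anywhere aborts with the iteration index.
* Drugs or cell lines with zero observed entries are rejected by name
  before sampling (their latents would be prior draws and their
  predictions pure noise).
* Reading matrices accepts empty cells, `NA` and `NaN` (case-insensitive)
  as missing; side-information matrices must be complete, and binary
  target matrices strictly 0/1.  Values are written with 17 significant
  digits so write/read round trips are exact.
* Response values are used as given; a natural-log flag exists in
  `read_matrix()` but is off by default, since the appropriate IC50
  transform depends on the upstream export.
* Report selectors compute the top-5% cutoff over all absolute entries of
  the matrix at hand (per tissue for the per-tissue view, over the whole
  tissues x pairs matrix for cross-tissue views); both published readings
  of the cross-tissue "highest interaction" filter (highest mean, lowest
  variance) are implemented as modes.  The antagonistic-pair table
  requires opposite-signed extremes before ranking by the balance
  statistic $||w_{max}| - |w_{min}||$.

## Problem sizes used by the validation suite

The shipped tests fit chains of a few hundred iterations on screens
between 15 x 30 and 100 x 300, run 200-permutation calibrations on a
40 x 100 screen, and cross-validate with k = 4-5 folds; these sizes give
stable statistics in a few minutes on a single CPU and are stated here
as the package's own reference configuration for its checks.

## Known limitations

* Only the product $\beta_D \beta_C^\top$ is identified; individual link
  matrices are reported in the chain for diagnostics but should not be
  interpreted factor by factor.
* The permutation test refits the model under a reduced budget by
  default; extremely small q-values therefore depend on `n_perm` and the
  smoothing choice.
* Interactions are associations in an observational screen; the
  sensitivity/resistance reading is causal only under additional
  assumptions, and tissue-level results should clear the setting-4
  quality gate before interpretation.
* The dense link-matrix sampler scales as $O(F^3)$ per iteration in the
  feature count; side information with more than a few thousand features
  (e.g. genome-wide expression as raw features) is out of this
  implementation's intended range -- reduce it first (that is what the
  pathway scorer is for).
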