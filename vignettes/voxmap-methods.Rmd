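---
title: "Mapping single cells onto spatial voxels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single cells onto spatial voxels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmap)
```

## The problem

Dissociation-based single-cell and single-nucleus RNA-seq measures deep
transcriptomes but destroys spatial context; spatial technologies keep the
tissue intact but measure either few genes (targeted in situ methods, at
single-cell resolution) or shallow mixtures of cells (array-based capture
spots). voxmap aligns the two: it learns, for every dissociated cell, a
probability distribution over the voxels of a spatial dataset. From that
alignment it imputes genome-wide spatial expression, calls cell types in
space, transfers arbitrary per-cell annotations, and deconvolves multi-cell
spots into individually typed cells.

## The model

Let $S \in \mathbb{R}_{\ge 0}^{n_\text{cells} \times n_\text{genes}}$ be the
single-cell expression matrix, $G \in \mathbb{R}_{\ge 0}^{n_\text{voxels}
\times n_\text{genes}}$ the spatial matrix on a shared gene panel, and
$\vec d$ a probability vector of expected cell densities per voxel. We learn
a mapping matrix $M$ with $M_{ij}$ the probability of cell $i$ residing in
voxel $j$, parametrized as a row-wise softmax of unconstrained logits
$\tilde M$ so that rows are simplex vectors by construction. The objective
minimized over $\tilde M$ is

$$
\Phi(\tilde M) \;=\; w_d\,\mathrm{KL}(\vec m \,\|\, \vec d)
\;-\; w_g \sum_k \cos\!\big((M^\top S)_{*,k},\, G_{*,k}\big)
\;-\; w_v \sum_j \cos\!\big((M^\top S)_{j,*},\, G_{j,*}\big),
$$

where $\vec m$ ($m_j = \sum_i M_{ij}/n_\text{cells}$) is the predicted
density, the second term matches each gene's predicted spatial pattern
across voxels, and the third matches each voxel's expression profile across
genes. Cosine similarity is scale invariant, so the two modalities need not
share a unit of measure — only proportionality of expression is assumed.

When the dissociated profiles outnumber the spatial cells, a per-cell filter
$f_i = \sigma(\tilde f_i) \in (0,1)$ is learned jointly. The filtered
objective replaces $S$ by $\mathrm{diag}(f)\,S$ and $\vec m$ by the density
of filter-weighted cells, and adds three terms: an optional entropy
regularizer $-\lambda_{r1}\sum_{ij} M_{ij}\log M_{ij}$ that sharpens each
cell's spatial distribution, a count term
$\lvert\sum_i f_i - n_\text{target\_cells}\rvert$ pinning the number of
retained cells, and a filter regularizer $\sum_i (f_i - f_i^2)$ that pushes
$f$ toward Boolean values.

Use cases map onto two configurations. For targeted in situ data (one cell
per voxel) the density is uniform and, when cells outnumber voxels, the
filtered mode is used with $n_\text{target\_cells} = n_\text{voxels}$,
enforcing a one-to-one correspondence. For capture-spot data the density
comes from segmented nuclear counts under each spot, plain mode for
probabilistic maps and filtered mode with
$n_\text{target\_cells} = \sum_j \text{seg}_j$ for deconvolution.

## Optimization and numerical choices

No automatic-differentiation engine is assumed: the gradients of every term
are derived analytically and chained through the softmax and sigmoid
parametrizations in closed form; the test suite verifies them against
central finite differences of an independently coded loss at $10^{-4}$
relative tolerance (they agree to $\sim 10^{-9}$). Optimization is
full-batch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning rate 0.1,
double precision throughout, initial logits drawn i.i.d. standard normal
from a single seeded generator. A fit is therefore bit-reproducible from its
configuration, and the package restores the caller's RNG state after every
seeded operation.

Numerical conventions, applied consistently in the loss and its gradients:

* every logarithm and cosine denominator is clamped below at
  $\varepsilon = 10^{-8}$;
* a cosine involving an all-zero vector is defined as 0 (a neutral
  contribution — held-out predictions and dropout-affected measurements may
  legitimately be all-zero);
* the count term's subgradient at its kink is taken as 0;
* argmax ties in deterministic calls break to the lowest index.

Term weights default to $w_d = w_g = w_v = 1$ and $\lambda_{r1} = 0$,
reproducing the bare objective; they are exposed in the configuration
because different data regimes may warrant rebalancing, but no result in
this package depends on non-default weights. Epoch defaults are fixed per
use case (1200 targeted, 300 spots, 6000 deconvolution, 150 atlas-grid) with
no early stopping; convergence is reported, not enforced, via the loss trace
and the sharpness statistic (fraction of mapped cells whose top voxel
probability exceeds 0.5).

Matrices are dense in memory: training panels are a few hundred to a
thousand genes, so even $10^5$ cells fit comfortably, and dense BLAS
products dominate the per-epoch cost.

## Marker selection and gene panels

Mapping uses a marker panel rather than the whole transcriptome: non-marker
genes fluctuate around a basal level and contribute no spatial signal, and
excluding them leaves a large held-out test set. Cells are library-size
normalized (default target sum $10^4$), $\log(1+x)$ transformed, and
per-gene standardized; each cell type is then contrasted against all other
cells with a Welch (unequal-variance) t-test, genes ranked by the signed
statistic so upregulated markers lead, ties broken lexicographically. The
training panel is the union of each type's top-$k$ genes (default
$k = 100$) intersected with the spatially measured genes. A gene constant
across all cells gets statistic 0; a gene with zero within-group variance
but distinct group means is a perfect separator and ranks first. The mapper
itself consumes linear-scale (library-normalized, unlogged) values — cosine
similarity makes any global rescaling immaterial, and a configuration flag
allows log-scale input instead.

## Validation by gene holdout

The imputation surface is $M^\top S_\text{full}$ over all genes of the
single-cell data. A held-out gene — excluded from the training panel — is
scored by the Pearson correlation between its imputed and measured per-voxel
patterns ("spatial correlation"; Spearman behind a flag). Drivers cover
leave-one-out over a panel (refit per fold from the same init seed),
a single train/test partition over all shared genes, and a training-fraction
sweep that subsamples the panel and reports mean train score, mean test
score, and test score scaled by the training mean. Score tables carry each
gene's sparsity (fraction of voxels where it is undetected, evaluated on raw
counts), and summaries stratify genes into non-sparse performing,
non-sparse underperforming, and sparse (sparsity $\ge$ 0.5) regions, since
correlation against mostly-zero measurements is dominated by detection
noise rather than pattern disagreement.

## The synthetic ground truth

All tests run against a generator with known truth, built from three parts:
per-type signatures (a shared positive baseline per gene with disjoint
marker blocks elevated `effect`-fold per type), a tissue (layered contiguous
bands of voxels, each dominated by one type at occupancy 0.8, with
Poisson-distributed cell counts per voxel), and a rendering step that sums
the placed cells' profiles into spots (or one voxel per cell at single-cell
resolution) before applying Poisson counting noise, entrywise Bernoulli
dropout, and a unit-scale mismatch. The standard suite is 5 types, 200
genes (20 markers per type, 8-fold effect), 100 voxels, roughly 300 cells,
noiseless unless a dial is turned — small enough that every end-to-end test
refits in seconds on one CPU. Fixtures regenerate bit-identically from
their recorded parameters.

What the generator does *not* emulate: continuous expression gradients and
intermediate cell states, within-type covariance structure, segmentation
errors, spatial autocorrelation beyond banding, platform-specific capture
biases, and genuinely novel cell types present in only one modality.
Passing tests demonstrate the correctness of the optimization and transfer
machinery under the stated noise model, not performance on any particular
real tissue.

Problem sizes in the shipped tests were chosen to keep the whole suite in
the low minutes: exhaustive-search cross-checks run at 3–8 cells/voxels
(where all permutations, and all subset-assignment combinations, can be
enumerated), leave-one-out runs over a 40-gene panel, and monotonicity
properties average 5 generator seeds.

## Design decisions that were genuinely open

* **Direction of the density divergence.** $\mathrm{KL}(\vec m \| \vec d)$,
  predicted relative to prior, matching the argument order of the objective
  as defined above.
* **Which matrix enters the filtered cosine terms.** The filtered objective
  uses $M^\top (\mathrm{diag}(f) S)$: the filter weights cell expression,
  while rows of $M$ keep their own softmax normalization.
* **Scale of the cosine inputs.** Computed on the matrices as provided
  (post library normalization, no log); cosine's scale invariance makes
  per-row normalization immaterial, and log input remains available.
* **Cell-type calling.** Two deterministic rules are provided: the default
  takes, per voxel, the type maximizing the transferred one-hot type mass
  $(M^\top A)_{j,*}$ — well defined for both spot and single-cell
  resolution — while `method = "cell"` takes the label of the single
  highest-probability cell, the natural reading for one-cell voxels. They
  agree on sharply converged single-cell-resolution mappings.
* **Deconvolution assignment.** Filter-retained cells ($f_i > 0.5$) are
  placed at their argmax voxel and matched to that voxel's segmented cells
  uniformly at random under a dedicated seed, independent of the mapping
  seed, so placement and matching randomness are separable. Surplus placed
  cells in an over-full voxel are reported unplaced (keeping the most
  confident), never silently dropped.
* **Quantile estimator** for score summaries: linear interpolation
  (type 7), recorded here because estimators differ across software.

## Known limitations

The objective is nonconvex; the optimizer finds good optima reliably on
well-separated signatures (the exhaustive-search tests confirm global
optimality up to 8 voxels) but offers no guarantee at scale — inspect the
loss trace and sharpness before trusting a mapping. Cells of identical
expression are interchangeable: their probability mass spreads over the
voxels their profile fits, which is correct but makes per-cell (rather than
per-type) placement meaningless for duplicated profiles. Density priors are
taken as given; segmentation quality directly bounds deconvolution quality.
Annotation transfer emits raw $M^\top A$ without re-normalization — whether
transferred quantities (e.g. accessibility scores) should be rescaled is
application dependent and left to the caller.
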