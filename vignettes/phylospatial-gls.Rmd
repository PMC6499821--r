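---
title: "Phylogenetic-spatial GLS for language diversity: model and methods"
author: "lingscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic-spatial GLS for language diversity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Language diversity -- the number of languages whose traditional homeland
range overlaps a cell of an equal-area grid -- is strongly clustered in
space, and neighboring grid cells also tend to contain *related* languages.
Any regression of diversity on ecological covariates (climate, landscape
barriers, biodiversity) that ignores this double non-independence treats
each cell as a fresh observation and wildly overstates its evidence:
smooth predictor fields regressed on smooth response fields produce
spuriously significant associations. `lingscape` implements a generalized
least squares (GLS) framework in which the residual correlation between
cells is modelled explicitly, together with the grid construction,
similarity matrices, hypothesis tests and diagnostics around it, and a
synthetic-data generator that makes the whole pipeline testable without
restricted language atlases.

## The model

For log language diversity $y$ over $n$ grid cells and design matrix $X$
(always containing an intercept and the cell's land coverage),

$$y \sim \mathcal N(X b,\; \sigma^2 C), \qquad
C = (1 - \alpha) I + \alpha\,[\beta P + (1 - \beta) D],$$

where

* $P_{ij}$ is the **PhyloSor** similarity of the language sets of cells
  $i$ and $j$: twice the branch length shared by the two sets' rooted
  spanning subtrees on the global language tree, divided by the sum of
  their total spanning branch lengths. It is 1 for identical language
  sets and 0 for cells sharing no language family.
* $D_{ij} = e^{-(d_{ij}/\gamma)^2}$ is a Gaussian decay of the
  great-circle distance $d_{ij}$ (km) between cell centroids
  (Earth radius 6371 km), with decay scale $\gamma > 0$ in km.
* $\alpha \in [0,1]$ is the share of residual variance that is structured
  (shared between cells) rather than cell-specific, and
  $\beta \in [0,1]$ splits the structured share between phylogenetic and
  spatial similarity.

The diagonal of $C$ is exactly 1 for any admissible parameters, so
$\sigma^2$ is the marginal residual variance of every cell.

### The language tree and its branch lengths

There is no accepted phylogeny of all languages, so the tree is built from
a taxonomy: nodes are classification groups, tips are languages, and the
root joins all families as a star ("unresolved at the base"). Two
conventions are deliberate choices rather than published facts:

* **Depth normalization.** The taxonomy gives no branch lengths. We fix
  every root-to-tip depth at 1 and place an internal node at depth
  $\ell / L$, where $\ell$ is its level along the classification path and
  $L$ the longest chain through it. Consequently the patristic distance
  between languages of different families is exactly 2 -- the matrix
  maximum, the same for every cross-family pair -- and PhyloSor is
  scale-free. A `edge_lengths = "unit"` switch (one unit per taxonomy
  level) is provided for sensitivity analysis; it loses the
  equal-maximum property and is not used by default. Language isolates
  attach directly under the root with length 1 and so count as distinct
  families.
* **Root paths in PhyloSor.** A cell's spanning subtree includes the
  branches from its languages up to the root. This makes the stated
  endpoints exact on the star tree: cells from disjoint families share no
  branches (similarity 0). The alternative crown-subtree convention is
  available via `include_root_path = FALSE` but breaks the
  0-for-disjoint-families endpoint.

### Fitting

For fixed $(\alpha, \beta, \gamma)$ the coefficients and variance have
closed forms, leaving the profiled negative log-likelihood
$\tfrac n2 \log(2\pi\hat\sigma^2) + \tfrac12 \log|C| + \tfrac n2$.
All solves use the Cholesky factor of $C$; no explicit inverse is formed,
and $\log|C|$ comes from the factor. The three correlation parameters are
estimated by derivative-free Nelder--Mead simplex search (the same family
as subplex) on a transformed scale -- logit $\alpha$, logit $\beta$, and a
bounded logit of $\log\gamma$ on $[\log 1\,\mathrm{km},
\log(5\,d_{\max})]$ -- so the optimizer is unconstrained while the
parameters respect their boxes. Because small-$n$ likelihood surfaces are
multimodal with optima frequently at the $\alpha$ boundaries, the search
is multi-start: a coarse screen over
$\alpha \in \{0.05, 0.2, 0.5, 0.8, 0.95\}$,
$\beta \in \{0.05, 0.5, 0.95\}$ and
$\gamma \in \{0.5, 1, 2\} \times$ median inter-cell distance seeds the
best `n_starts` (default 5) simplex runs (with a small seeded jitter that
never touches the user's RNG stream), and the winner is polished by
restarting the simplex until no further gain. Convergence tolerance is
$10^{-8}$ on the objective. If a correlation matrix cannot be factorized a
ridge of $10^{-10}$ is tried once; persistent failure raises an error
recommending heavier grid subsampling, which is the reason subsampling
exists: adjacent cells of a fine grid are nearly identical and make $C$
numerically singular.

Estimation is by ML, not REML, because the likelihood-ratio tests below
compare models with different fixed effects. Standard errors are
$\hat\sigma^2 (X^\top C^{-1} X)^{-1}$ with the ML $\hat\sigma^2$
(divisor $n$), and $t$ statistics use $n - p$ degrees of freedom; the
package applies the same conventions to its OLS fits so that nested
comparisons are coherent.

### Tests, predicted R², residuals

* **Drop-one LR tests.** Each predictor's contribution beyond covariation
  with the others is tested by dropping it and computing
  $LR = 2\Delta\ell$ against $\chi^2_{df}$, $df$ = number of dropped
  columns ($k-1$ for a $k$-level factor such as biome). Both models
  re-estimate $(\alpha,\beta,\gamma)$. A materially negative LR signals
  that one search found a worse local optimum; each model is then
  restarted from the other's optimum, and only a persistent negative LR
  is an error.
* **Predicted R².** Defined through leave-one-out *conditional*
  predictions $\hat y_i = x_i \hat b + C_{i,-i} C_{-i,-i}^{-1}
  (y - X\hat b)_{-i}$, computed for all cells at once from the precision
  matrix. This is the only reading under which the GLS model can
  out-predict OLS -- the conditional term is exactly the information
  carried by correlated residuals -- so the GLS-minus-OLS difference in
  predicted R² quantifies how much apparent explanatory power rides on
  spatial autocorrelation and phylogenetic non-independence. With
  $C = I$ the definition collapses to the classical in-sample $R^2$.
* **Residuals.** Because $C$ has unit diagonal, standardized residuals
  are simply $r_i/\hat\sigma$; cells beyond $\pm 1.96$ are flagged as
  diversity hotspots (or coldspots). Whitened residuals
  $U^{-\top} r / \hat\sigma$ ($U$ the Cholesky factor) are iid standard
  normal under a correct model and feed the Shapiro--Wilk normality
  check. The two scalings answer different questions, so both are
  exposed.

### Positive definiteness

PhyloSor matrices are not guaranteed positive definite, and neither is
the Gaussian kernel of *great-circle* (rather than Euclidean) distances.
Offending matrices are repaired by clamping eigenvalues at $10^{-8}$ and
rescaling the diagonal to 1. The repair warns with the largest entry
perturbation and refuses (errors) if any entry would move by more than
`max_change` (default 0.01) -- a matrix that indefinite indicates an
upstream problem, not a rounding artifact.

## The synthetic-data generator

The generator replaces the licence-restricted global language atlas with
data that have the statistical structure the analysis assumes, with known
truth. Its defaults describe the study conditions; they were chosen once,
on substantive grounds:

* **Grid**: global cylindrical equal-area grid with 1000 km cells (the
  low-resolution design; cell dimensions are adjusted to the nearest
  exact tiling, so all cells are exactly equal-area).
* **Landmask**: 4 continental discs of roughly 3500 km radius; land
  coverage is computed by polygon clipping, with the small-island floor
  of 0.01 for occupied cells.
* **Languages**: 40 families with $1 + \mathrm{Poisson}(4)$ languages
  each (singletons are isolates; larger families may split into two
  subgroups), homelands uniform on land, range discs with log-normal
  radii (median 400 km) scattered 500 km around the homeland. The tight
  scatter is what makes $P$ spatially structured, as in the real world
  where related languages are neighbors. Speaker counts are log-normal
  (median $e^{8.5} \approx 5000$, sd of logs 1.8), matching the
  heavy-tailed size distribution of real speaker populations.
* **Covariates**: Gaussian random fields over cell centroids with
  squared-exponential covariance, range 2500 km -- smooth continental
  gradients, like real climate layers. Biome is a quantile slicing of an
  extra field.
* **Response**: drawn from the GLS model itself at
  $\alpha = 0.6, \beta = 0.5, \gamma = 1500$ km, $\sigma^2 = 0.3$, with
  nonzero effects of temperature seasonality ($-0.4$), precipitation
  ($0.3$) and productivity ($0.2$) plus land coverage ($0.5$). The
  response is generated directly on the log scale because that is the
  scale the model fits; a rounded count column (`diversity_sim`) exists
  for robustness checks but adds unmodelled noise and is not used in
  calibration tests.

Separate seed offsets drive the landmask, languages, covariate fields and
response noise, so replicate experiments can redraw the noise while
holding the landscape fixed (`gen_response` on an existing cell table).

**What the generator does not emulate** -- and therefore what passing
tests do not show about real data: real coastline and climate geometry;
per-country speaker counts; any historical process of language
birth, death, contact or migration (ranges are static discs); dateline
wrap-around of range polygons; and measurement problems such as
under-documentation of languages. Tests on this generator validate the
*statistical machinery*, not substantive conclusions about real
languages.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: a
brute-force edge-membership PhyloSor implementation; closed-form OLS;
exhaustive grid search over the full $(\alpha, \beta, \log\gamma)$ box on
25-cell instances (where likelihood surfaces can be flat, the optimizer
is compared on the *minimal level set* at grid resolution rather than on
raw argmins, and must always attain at least the grid minimum); parameter
recovery at $n = 300$ over 50 replicates; drop-one type-I error over 200
replicates at $n = 200$, where $n = 200$ was chosen because the LR
calibration is asymptotic and smaller grids leave the test visibly
conservative; and a GLS-vs-OLS predicted-R² contrast over 50 replicates
at both strong ($\alpha = 0.8$) and absent ($\alpha = 0$) structure.

## Numerical choices and degenerate inputs

* Children of every tree node are sorted lexicographically, so
  serialization and tip order are reproducible regardless of input row
  order.
* Grid cells use half-open intervals $[x, x + w)$ for row/column
  assignment, while the overlay predicate counts boundary touches as
  presence (the candidate window is padded by one cell so exact-boundary
  polygons are not missed).
* A numerically perfect fit ($\hat\sigma^2 \le 10^{-14}\,
  \mathrm{var}(y)$) reports zero standardized residuals rather than
  0/0.
* Rank-deficient designs, empty occupant sets, latitudes outside
  $[-90, 90]$, non-positive $\gamma$, and constant-latitude gradients
  raise named errors rather than propagating NaNs.

## Limitations

The taxonomy tree is a proxy for relatedness, not a dated phylogeny;
cross-family distances are a convention, not an estimate. The correlation
model is stationary and isotropic (one $\gamma$ for the whole world), and
variance is homoscedastic across cells. Fits scale as $O(n^3)$ per
likelihood evaluation, which in practice caps unsubsampled grids at a few
thousand cells. CAR/SAR spatial-error alternatives and Bayesian fitting
are out of scope.
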