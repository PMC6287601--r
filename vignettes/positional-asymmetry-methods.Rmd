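---
title: "Object symmetry, positional asymmetry, and phylogeny: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object symmetry, positional asymmetry, and phylogeny: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobesym)
```

## The problem

Many unicellular organisms — the desmid *Micrasterias* is the motivating
case — build bilaterally symmetric structures whose paired parts are
distinguishable only by *position*: a lateral lobe splits into a lower and an
upper sublobe, each of which may split again into terminal lobules. Because
there is no left/right identity, classical directional asymmetry between
repeated structures cannot be defined across individuals; but within a
configuration that contains its own symmetry axis, the population-average
shape difference between the paired sides is well defined. We call it
**positional asymmetry**. This package quantifies it, tests it against
individual-level fluctuating asymmetry (FA) and digitization error, ordinates
it across species, and asks whether its evolution tracks phylogeny.

## Object symmetry: the decomposition

A configuration of $k$ landmarks (here $k = 7$ or $15$) carries a
`symmetry_map`: $p$ mirror pairs and $u$ on-axis landmarks, $k = 2p + u$,
with the axis fixed at $x = 0$. The *reflect-and-relabel* operation $T$
negates $x$ and swaps the labels within each pair; it is an orthogonal
involution of shape space. Any convention for the digitized axis orientation
cancels in the superimposition, so the package takes TPS coordinates as-is.

The object-symmetry superimposition (`joint_symmetry_gpa`) runs generalized
Procrustes analysis (GPA) over the doubled sample
$\{x_i\} \cup \{T(x_i)\}$. Configurations are centered, scaled to unit
centroid size, and rotated to the consensus; reflections are never allowed in
the alignment itself, since reflected copies enter as data and an improper
fit would collapse the very decomposition being estimated. The provisional
consensus is symmetrized — replaced by $(m + T(m))/2$ — at every iteration,
so the converged consensus is *exactly* $T$-invariant. That exactness matters:
with a symmetric consensus and uniqueness of the optimal rotation, the
aligned reflected copy equals $T$(aligned original) to machine precision, and
the components

$$ s_i = \tfrac{1}{2}(x_i + T x_i), \qquad a_i = \tfrac{1}{2}(x_i - T x_i) $$

satisfy $s_i + a_i = x_i$ exactly, with $T s_i = s_i$ and $T a_i = -a_i$.
The symmetric and asymmetric subspaces each have shape dimension
$2p + u - 2$, together spanning the full shape space of dimension $2k - 4$.

## Procrustes ANOVA

For $n$ specimens digitized $r$ times each, `symmetry_anova` partitions the
Procrustes sum of squares of the doubled sample (tangent coordinates at the
joint consensus) into:

| effect | SS (doubled layout) | df |
|---|---|---|
| individuals | $2r\sum_i \lVert\bar s_i - \bar s\rVert^2$ | $(n-1)(2p+u-2)$ |
| positional asymmetry | $2nr\,\lVert\bar a\rVert^2$ | $2p+u-2$ |
| fluctuating asymmetry | $2r\sum_i \lVert\bar a_i - \bar a\rVert^2$ | $(n-1)(2p+u-2)$ |
| measurement error | $2\sum_{ij}(\lVert s_{ij}-\bar s_i\rVert^2 + \lVert a_{ij}-\bar a_i\rVert^2)$ | $n(r-1)(2k-4)$ |

These four sums add up to the total exactly in a balanced design, so the
$R^2$ column sums to 1. F ratios follow the mixed-model logic of bilateral
asymmetry analysis: positional asymmetry and individuals are tested against
the FA mean square (an optional switch pools FA with error — the two
denominators are exposed because published tables rarely say which was used,
and with strong effects both give the minimal permutation p), and FA against
the error mean square. With $r = 1$ the error row is dropped and the FA test
is unavailable, and the result is flagged accordingly.

Permutation schemes respect the exchangeable units of each null:

* **positional asymmetry** — each specimen's original/mirror labeling is
  arbitrary under the null of no average asymmetry, so specimen asymmetric
  components receive independent random sign flips (computed in one matrix
  product across all permutations);
* **individuals** — replicate-level symmetric components are shuffled across
  specimens; the asymmetric block, and hence the denominator, keeps its
  observed grouping (shuffling both blocks deflates the FA denominator and
  makes the test grossly conservative);
* **FA** — replicate-level asymmetric components are shuffled across
  specimens, redistributing variation between the FA and error rows.

All p-values use the add-one rule $(c+1)/(n_\mathrm{perm}+1)$, so $p = 0$ is
impossible and the smallest attainable value at 999 permutations is 0.001.
Under the generator's null ($\delta = 0$, $n = 20$, $r = 2$, 199
permutations) the positional test's measured size at $\alpha = 0.05$ is
0.02–0.08 over 200 simulations, and its p-values pass a Kolmogorov–Smirnov
uniformity check; these calibrations are re-run by the acceptance script.

## Species means and morphospaces

`species_asymmetry_means` estimates each species' positional asymmetry
inside that species' *own* symmetric superimposition (replicates averaged
within specimens, then specimens averaged). This pins the rotational gauge at
the species consensus: in a single global superimposition, between-species
symmetric shape differences interact with the rotation freedom and leak into
the asymmetry estimates at second order, a bias that at realistic effect
sizes exceeds the standard error of a 75-specimen mean. The per-species means
(plus their mirror images) are then merged and re-superimposed by
`mirrored_pca`.

Two ordinations reproduce the two standard views:

* **`mirrored_pca`** — PCA of the $2S$ aligned means-plus-mirrors. Because
  the sample is closed under $T$ and the consensus is exactly symmetric, the
  covariance matrix commutes with $T$ and every eigenvector with a
  non-degenerate eigenvalue is either $T$-invariant (a *symmetric* PC) or
  $T$-anti-invariant (an *asymmetric* PC); classification uses a relative
  tolerance of $10^{-6}$, and a `mixed` class exists for degenerate or noisy
  cases. The ideally symmetric shape projects to 0 on every asymmetric PC,
  and each species' original and mirror sit at opposite scores — the plot
  geometry that makes the degree and direction of asymmetry legible.
* **`asymmetric_pca`** — PCA of the $S$ asymmetric-component vectors alone,
  centered at the grand-mean asymmetry. Scores preserve the inter-species
  distances among asymmetry vectors exactly and are the space onto which the
  phylogeny is mapped.

Eigenvector signs are fixed by making each PC's largest-magnitude loading
positive, so score plots are reproducible up to that convention.

## Phylogenetic analyses

**Squared-change parsimony.** Ancestral states minimize
$Q = \sum_\mathrm{branches} \lVert\Delta\rVert^2 / \ell$ (branch lengths
$\ell$; an unweighted variant sets $\ell = 1$). The minimizer solves the
tree's weighted graph Laplacian restricted to internal nodes, which also
yields the tip-side quadratic form $Q = \mathrm{tr}(X^\top M X)$ used to make
the permutation test cheap. With branch-length weighting the states coincide
with maximum-likelihood ancestral states under Brownian motion (cross-checked
against an independent optimizer and against `phytools::fastAnc` in the test
suite). Branch lengths below $10^{-8}$ are clamped with a warning. Weighted
ML branch lengths are the default, with the unweighted variant behind a flag,
because the signal statistic should reflect the time available for change
where branch lengths are meaningful.

**Phylogenetic signal.** The observed $Q$ is compared with $Q$ under random
permutation of species across the tips; small $Q$ means the phylogeny
explains the arrangement, so the test is left-tailed, with ties counted
toward the tail (a tolerance of $10^{-9}$ relative absorbs summation-order
rounding, so permutation-invariant cases — a star tree, constant tip data —
give $p = 1$ exactly). The test runs on the full asymmetry coordinates by
default: $Q$ is invariant to orthogonal rotation of the trait space, so
running it on all PC scores would give the identical statistic.

**Phylogenetic two-block PLS.** Both trait blocks are transformed by
subtracting the generalized-least-squares mean
$a = (1^\top C^{-1} 1)^{-1} 1^\top C^{-1} X$ and premultiplying by
$C^{-1/2}$ (symmetric eigendecomposition square root, eigenvalues floored at
$10^{-12}$ for stability on non-ultrametric trees), where $C$ is the
Brownian-motion phylogenetic covariance (shared root-to-tip path lengths).
The SVD of the transformed cross-block covariance gives the singular warps;
$r_\mathrm{PLS}$ is the absolute correlation of the first pair of scores.
Significance permutes the tip assignment of one block *after* the
transformation: the whitened rows are exchangeable under the Brownian null,
which keeps the test exact. (Permuting raw tip rows and re-whitening each
replicate would make the test sharply anticonservative — the permuted data
are no longer Brownian, and whitening them manufactures covariance — so that
variant is not offered.) On a star tree with equal branch lengths
the whole procedure reduces to ordinary two-block PLS to $10^{-10}$.

The pipeline pre-wires the three comparisons of interest among the
15-landmark sublobe asymmetry block and the two 7-landmark terminal-lobule
blocks (landmarks 1–7 and 9–15 of the 15-landmark scheme), on the tree
pruned to the lobule-bearing species.

## The synthetic-data generator

`simulate_dataset` emulates the sampling design of the motivating study —
19 species, 75 semicells per species, every specimen digitized twice — on a
pure-birth tree rescaled to depth 1. Species symmetric means and asymmetry
vectors $\delta_s$ evolve as independent-coordinate Brownian motion (rates
$\sigma^2_\mathrm{sym}$, $\sigma^2_\mathrm{asym}$, both 0.002 per coordinate
per unit depth); specimens add symmetric individual deviations
($\sigma_\mathrm{ind} = 0.02$) and asymmetric FA deviations
($\sigma_\mathrm{FA} = 0.01$); each digitization replicate adds raw
coordinate noise ($\sigma_\mathrm{ME} = 0.005$). All scales are Procrustes
units of the unit-centroid-size base shape (an idealized symmetric lobe arc
with 7 or 15 landmarks). The defaults were chosen once to produce the
qualitative regime the study reports — positional asymmetry spanning from a
few percent to the dominant share of between-side variation, FA an order of
magnitude above digitization error — and are not tuned per analysis.

Two structural guarantees matter for validation:

* Generated perturbations are projected onto the symmetric or asymmetric
  subspace **and** orthogonal to the similarity directions (translations,
  rotation, scaling) of the base shape. Procrustes alignment removes
  similarity components; had the "true" $\delta_s$ contained them, part of
  the truth would be unrecoverable by construction. Replicate digitization
  noise is deliberately left raw — real digitization error has no reason to
  respect shape space — and the ANOVA sees exactly its shape-space part,
  giving the clean expectation $E[\mathrm{MS}_\mathrm{error}] =
  2\sigma_\mathrm{ME}^2$ in the doubled layout (verified to within 10%).
* Ground truth is recorded twice: the raw Brownian $\delta_s$, and
  `delta_shape`, the asymmetric component of the noise-free species mean
  after its own symmetric superimposition. The latter is the population value
  of the estimator — it differs from the raw vector only by the
  deterministic center/scale/rotation-gauge bookkeeping that superimposition
  applies — and is the reference for recovery checks (each species' estimate
  within 3 standard errors at the design scale).

What the generator does **not** emulate: the digitization-order artifact of
the real protocol (clockwise vs counterclockwise capture) beyond independent
replicate noise; allometry and size variation (all latent shapes are near
unit size); non-Brownian evolution (no Ornstein–Uhlenbeck or early-burst
modes); and correlated landmark noise. Passing tests therefore certify the
estimators and tests under the model's own assumptions, not robustness to
violations of them.

## Numerical choices

* GPA convergence: change in mean squared residual below $10^{-10}$ *and*
  consensus movement below $10^{-8}$, at most 200 iterations;
  non-convergence warns rather than errors.
* The 2D optimal rotation uses the closed form
  $\theta = \mathrm{atan2}(M_{21}-M_{12},\, M_{11}+M_{22})$ of the SVD
  solution with the determinant constrained to $+1$.
* Plain GPA aligns the consensus to its principal axes for reproducible
  orientation; the symmetric superimposition skips this (the symmetry axis
  already fixes the orientation, and axis swapping would break it).
* Degenerate configurations (centroid size 0) are errors; coincident but
  non-degenerate data are left to the user.
* The TPS writer emits 6 decimals; round-trips are exact at that precision.
* Variable-site counting treats gaps (and, by default, ambiguity codes) as
  non-states; flags expose the stricter conventions since published counts
  rarely state theirs.

## Validation scale

The test suite and acceptance script validate at these problem sizes: oracle
equivalence on 50 random landmark pairs (rotation-grid search) and 100 random
trees of up to 8 tips (direct numerical optimization); null calibrations with
200 simulations each (positional test at $n = 20$, $r = 2$, 199 permutations;
signal and PLS tests with 199 permutations); and one full study at the design
scale of 19 species × 75 specimens × 2 replicates with 999-permutation
ANOVAs. These sizes were chosen to give stable Monte-Carlo estimates of the
quantities being checked.

## Limitations

Only 2D configurations and object symmetry are supported — no matching
symmetry between separate structures, no semilandmarks, no 3D. The
between-species integration analyses compare species means; within-species
integration is a different question. The ANOVA requires a balanced design
(equal replicates per specimen) and at least two specimens; unbalanced data
must be balanced or subsampled upstream. Permutation p-values inherit the
granularity of the permutation count.
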