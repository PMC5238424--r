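---
title: "Methods: modularity, integration, rates and evolvability of landmark modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modularity, integration, rates and evolvability of landmark modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modulrate)
```

`modulrate` analyses the evolution of a two-module partition of a 2-D
landmark configuration — prototypically the face and braincase of a skull —
on a time-calibrated phylogeny. This vignette is the package's account of
the models it fits, the numerical choices it makes, and what its synthetic
data can and cannot tell you about real data.

## Geometry: superimposition and tangent space

Raw landmark coordinates confound shape with position, orientation and
scale. `gpa()` performs *partial* generalized Procrustes superimposition:
each configuration is centered, scaled to unit centroid size, and rotated to
the running consensus by the optimal proper rotation (the SVD solution with
a determinant correction, so reflections — anatomically meaningless for
skulls in lateral view — are never introduced). Scale stays fixed at unit
centroid size; there is no cos(ρ) re-scaling. The loop stops when the
consensus root-mean-square displacement falls below `tol = 1e-10` (default
`max_iter = 100`; non-convergence is a warning plus `converged = FALSE`,
never a silent success). The summed squared distance to the consensus is
recorded per sweep (`q_history`) and is non-increasing, which the tests
assert.

Two choices here are genuinely open and are fixed as follows:

* **Species means are taken after alignment.** With several specimens per
  species, averaging raw coordinates would blend orientation differences
  into shape; aligned conspecifics are averaged and the average re-projected
  to unit centroid size.
* **Tangent projection before statistics.** All downstream statistics are
  linear, so shapes are orthogonally projected onto the tangent plane at the
  consensus first. At the shape ranges the generator enforces (below) the
  projection is numerically almost an identity, but fixing it removes an
  ambiguity.

The alignment is defined only up to one joint rotation of everything (the
consensus orientation is seeded from the first specimen). Coordinates from
two runs with permuted inputs therefore agree up to rotation; the package's
invariance tests compare rotation-invariant summaries (pairwise Procrustes
distances, consensus shape distance) rather than raw coordinates.

Flattening is always `(x1, y1, ..., xp, yp)`, so each module occupies a
contiguous column block. A shape PCA (`shape_pca()`) of the tangent
projections has rank at most `2p - 4`: two translations, one rotation and
one scale are gone. PC1/PC2 are used for phylomorphospace plots only; **all
test statistics run on full tangent coordinates**, because truncating to two
components would discard most of the covariance structure the CR, PLS and
rate machinery is about. (By linearity of GLS estimation, ancestral states
computed on scores equal ancestral states computed on shapes and then
projected; a test asserts this equivalence.)

## The phylogenetic backbone

Every comparative statistic shares one mechanism (`bm_structure()`,
`phylo_transform()`): under Brownian motion the tip covariance is the matrix
`C` of shared root-to-tip path lengths; with `T = L^{-1}` from the Cholesky
factorization `C = L L'` and the GLS root estimate `a`, the whitened data
`U = T (Y - 1 a')` have `U'U` equal to the evolutionary
sums-of-squares-and-cross-products — identical to what Felsenstein's
independent contrasts produce, which the tests verify against `ape::pic()`.
Cholesky (not eigendecomposition) is used because it is deterministic, fast
and standard. Polytomies are accepted as-is; pruned supertrees have them.
Two hard errors protect against garbage: zero-length terminal branches
(named in the message) and condition numbers above `1e12`. No silent ridge
regularization is ever applied — a comparative statistic computed from a
regularized `C` is not trustworthy.

Ancestral states (`ancestral_states()`) are the joint ML estimates under BM,
equivalent to branch-length-weighted squared-change parsimony, computed as
one linear solve on the tree's weighted graph Laplacian. This handles
polytomies — including basal ones — without re-rooting tricks. A
consequence: `ape` flags a star phylogeny as "unrooted" because its root is
a polytomy, yet it is a perfectly good rooted tree for these purposes, so
the package treats the edge-matrix origin (`n + 1`) as the root and does not
consult `ape::is.rooted()`.

On a star phylogeny `C` is proportional to the identity and every statistic
in the package reduces to its ordinary non-phylogenetic counterpart — the
end-to-end tests assert this for the transform, the P-matrix, PLS and the
rate estimator.

## Modularity: the covariance ratio

With `S = U'U/(n-1)` partitioned by module, the covariance ratio is the
Frobenius norm of the between-module block over the geometric mean of the
within-module norms. Two exclusions apply to the denominator blocks: the
diagonal (variances are not covariation) and — by default — the covariance
between the x and y coordinate of the *same* landmark, which reflects
digitizing geometry rather than biological covariation. The exclusion is a
documented dialect choice (`exclude_within_landmark = FALSE` turns it off
for sensitivity analysis); the published coefficient for landmark data uses
the same convention.

The permutation null re-assigns **whole landmarks** (x and y move together)
to pseudo-modules of the observed sizes — permuting coordinates
independently would break landmark geometry. Modularity means the observed
partition covaries *less* across blocks than random partitions, so the
p-value is lower-tailed, with the add-one rule so p is never exactly zero.
When `choose(p, k)` does not exceed `n_perm`, all distinct assignments are
enumerated instead and the p-value is exact (the observed assignment is one
of the enumerated ones, so no add-one is needed); the result records
`exact = TRUE`.

## Integration: phylogenetic two-block PLS

The cross-block evolutionary covariance `S12` is decomposed by SVD; `r_PLS`
is the correlation of the first pair of block scores on the transformed
data. The permutation scheme follows the tip-shuffling logic: block 2's
species rows are permuted on the *original* species means and the
phylogenetic transform is re-applied each iteration, so the null preserves
the tree while breaking the block association. The p-value is upper-tailed
with the add-one rule.

One identity worth stating precisely: if block 2 is a scaled rotation
(similarity transform) of block 1, `r_PLS = 1` exactly, and the tests assert
this to `1e-10`. For a *general* invertible linear map the first singular
pair does not produce perfectly correlated scores (numerically r ≈ 0.97 for
random 4×4 maps), so no such claim is made or tested.

A caveat for interpretation: Procrustes superimposition spreads variation
across all landmarks, so even modules simulated with zero between-module
correlation show substantial r_PLS after GPA — that covariance is really
present in shape space. The integration test's permutation null accounts for
the tree but not for this alignment-induced covariation; r_PLS values on
aligned data should be compared between datasets, not read as the generating
correlation. The package's calibration tests therefore check the PLS null
(uniform p under independence) on data that did not pass through GPA, and
check the *rate* machinery both ways.

## Rates: per-module σ² and the equal-rates null

The net rate of a module is `σ² = tr(U'U)/(n k)` — per *landmark* (not per
coordinate) per unit branch-length time, so modules with different landmark
counts are comparable; for 2-D data the face:braincase ratio is invariant to
this convention. Rates scale inversely with the time units of the tree, the
ratio does not; both invariances are tested.

Significance of the observed ratio comes from simulation: `n_sim` (default
999) datasets of multivariate BM on the same tree under a *common*
per-landmark rate (the pooled observed rate) with the **observed
evolutionary correlation structure preserved**, re-scaled to a common
diagonal. Using an identity correlation instead would understate the
sampling variance of the ratio when traits are integrated, making the test
anticonservative. If the correlation matrix has slightly negative
eigenvalues (it is rank-deficient whenever `n - 1 < 2p`, and Procrustes
removes four more dimensions), it is projected to the nearest positive
semidefinite matrix by clipping — with a warning only when the negativity
exceeds numerical noise.

The default statistic is the direction-free `max(ratio, 1/ratio)`: which
module is faster is typically a post-hoc observation, and a two-sided test
is the honest default. `one_sided = TRUE` reproduces the classical rule
(proportion of simulated ratios at least as large as observed) for
comparison with analyses that report it.

`clade_rates()` applies the same machinery within clades (each clade's
induced subtree) and tests each pair of clades per module against a
single-rate null simulated on the pair's combined subtree. Clades with fewer
than three species are excluded with a warning; non-monophyletic clade
assignments warn but run, since paraphyletic "grades" are sometimes
deliberately analysed.

## Evolvability: P-matrices and random skewers

The phylogenetically corrected P-matrix of a module is `P = U'U/(n-1)` on
the module's columns — the contrasts-equivalent evolutionary covariance.
(The alternative reading, the covariance of reconstructed node-to-node
changes, is nearly identical for ultrametric trees and is noted as a
sensitivity option rather than implemented.)

Random skewers probe `P` with unit selection gradients (standard normal
coordinates, normalized — uniform on the sphere; without unit normalization
evolvability and respondability would scale arbitrarily, and "Gaussian" by
itself does not fix a scale). For each skewer: evolvability `e = β'Pβ`,
respondability `r = |Pβ|`, conditional evolvability `c = (β'P⁻β)⁻¹`,
autonomy `a = c/e`, and constraints `|cos(Δz, v₁)|` with `v₁` the leading
eigenvector — the line of least resistance; the absolute value makes the
index direction-free.

**The eigenspace contract.** Procrustes P-matrices are singular, and naive
inversion of a singular P yields meaningless — even negative — conditional
evolvabilities and autonomies. All indices are therefore computed in the
positive eigenspace of `P` (eigenvalues above `1e-10` of the largest): each
skewer is projected into that space and re-normalized to unit length there.
Within this contract the Hansen–Houle relations `c ≤ e ≤ r` (equality
exactly at eigenvectors) and `a ∈ (0, 1]` are guaranteed, and the tests
assert them on random rank-deficient matrices. Published analyses that
report negative conditional evolvability or autonomy are artifacts of
inverting a singular matrix and cannot (and should not) be reproduced under
this contract. Summary tables report mean, min and max per index; maxima are
the headline figures because a module's best-case response to selection is
usually the quantity of interest.

## The synthetic-data generator

`simulation_spec()` + `simulate_study()` generate complete studies: a
pure-birth tree rescaled to unit height, species-mean deviations from a base
configuration (default: `p` points on the unit circle) drawn jointly from
multivariate BM with a block-structured rate matrix, optional replicate
specimens and i.i.d. digitizing noise, and a truth manifest. The rate matrix
gives each coordinate half its landmark's rate (so `sigma_mult()` recovers
the nominal per-landmark value), applies an equicorrelation `within_cor`
inside each module, and a correlation `rho` between *corresponding*
landmarks across modules; positive semidefiniteness is checked before any
simulation.

Deviations are simulated directly in flattened coordinate space, not on the
pre-shape manifold, which is valid only while shapes stay close to the base
form. The generator enforces this: if any deviation exceeds 5% of the base
configuration's centroid size, the whole deviation field is shrunk by a
common factor (preserving ratios and correlations) and the realized,
post-shrink rates are recorded in the manifest. Defaults (40 species, 10
landmarks split 5 + 5, per-landmark rates 2×10⁻³ and 1×10⁻³ per unit
height, `rho = 0`, no noise) describe a modular two-rate world small enough
for an end-to-end run in seconds.

What the generator does *not* emulate: measurement error correlated across
landmarks, allometry (size-correlated shape, deliberately left in real
analyses as the potential line of least resistance and deliberately absent
here), non-Brownian dynamics (no Ornstein–Uhlenbeck attraction, no early
bursts, no selection regimes), fossil sampling, and semilandmarks. Passing
calibration on synthetic data therefore shows the estimators and their nulls
are correct *under the model they assume*, not that the model fits any
particular empirical system.

## Calibration results asserted by the test suite

The acceptance tests run these experiments end to end (sizes chosen to make
Monte-Carlo bands tight enough to be meaningful):

* rate-ratio recovery: 20 replicate studies, 50 species, 5+5 landmarks,
  true ratio 2.0 — median estimate within [1.7, 2.3];
* rate-test size: 200 equal-rate studies, 40 species, 199 null simulations
  each — rejection at α = 0.05 within the binomial band [0.02, 0.09];
* CR power and size: 100-species star phylogenies; within-module
  correlation 0.7 with independent modules is detected in ≥ 90% of 50
  replicates, while one shared covariance regime rejects at ≈ α;
* PLS: exactness under similarity maps (to 1e-10) and approximate
  uniformity of the permutation p under independence;
* skewer identities (P = I, axis-aligned probes, E[e] = tr(P)/d) and the
  Hansen–Houle inequalities on random PSD matrices;
* oracle equivalences: rotation grid search for Procrustes distance,
  numerical optimization for ancestral states, `ape::pic` for evolutionary
  covariances, and an element-wise script for CR.

## Seeds and determinism

Every stochastic function takes a `seed` and restores the caller's RNG
state. The pipeline (`run_full_analysis()`) derives a named substream per
stage from one master seed, so disabling one stage never shifts another
stage's draws; two runs with the same configuration are numerically
identical apart from timestamps.

## Known limitations

* 2-D landmarks only; `LM3=` files are rejected rather than silently
  truncated.
* Exclusively Brownian motion; rate ratios under strongly non-BM dynamics
  will be biased in ways the equal-rates null does not capture.
* Exactly two modules; multi-module partitions (six-module skull schemes)
  are out of scope, as is any pooling logic beyond the user's own map.
* Taxon matching is exact after whitespace/underscore normalization — no
  fuzzy matching, by design; silently mismatched taxa corrupt comparative
  analyses in ways that are very hard to detect downstream.
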