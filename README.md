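# modulrate

Comparative analysis of **morphological modules** from 2-D landmark data and
a time-calibrated phylogeny. The motivating system is the vertebrate skull,
where the **face** and **braincase** are classic candidate modules: do they
covary as one integrated unit, or evolve as semi-independent blocks — and if
the latter, does one module evolve faster or respond more readily to
selection than the other?

`modulrate` takes a TPS landmark file, a Newick/NEXUS tree and a
landmark-to-module map, and answers four questions about a pair of modules:

1. **Modularity** — the covariance ratio on phylogenetically transformed
   shapes,

   CR = ‖S₁₂‖_F / √(‖S₁₁°‖_F · ‖S₂₂°‖_F),

   where S = UᵀU/(n−1) is the evolutionary trait covariance, S₁₂ the
   between-module block, and ° zeroes the diagonal and same-landmark x/y
   covariances of the within-module blocks. Small CR = modular. Significance
   by permuting whole landmarks across modules (exact enumeration when
   feasible).
2. **Integration** — phylogenetic two-block partial least squares: the SVD
   of S₁₂ gives the first pair of covariation axes, and r_PLS is the
   correlation of the paired block scores (0 = modular, 1 = integrated).
   Significance by permuting one block's species across the tips and
   re-applying the phylogenetic transform.
3. **Rates** — per-module multivariate Brownian-motion rates
   σ̂² = tr(UᵀU)/(n·k) (per landmark per unit time), with the face:braincase
   ratio tested against a simulated null of equal rates in both modules that
   preserves the observed between-trait evolutionary correlations.
4. **Evolvability** — random skewers on the phylogenetically corrected
   P-matrix of each module: 1000 unit selection gradients β are pushed
   through the selection-response equation Δz = Pβ, yielding evolvability
   (βᵀPβ), respondability (‖Pβ‖), conditional evolvability ((βᵀP⁻β)⁻¹),
   autonomy (c/e) and constraints (alignment of Δz with P's leading
   eigenvector). All indices are evaluated in P's positive eigenspace, so
   the Hansen–Houle inequalities c ≤ e ≤ r and a ∈ (0, 1] hold even for the
   rank-deficient matrices Procrustes data produce.

Everything upstream is standard geometric morphometrics: generalized
Procrustes superimposition (partial, reflections forbidden), species means
after alignment, orthogonal tangent-space projection, shape PCA and
phylomorphospace projection via Brownian-motion ancestral states.

The phylogenetic backbone throughout is the GLS whitening transform
U = T(Y − 1aᵀ) with TᵀT = C⁻¹ (C the Brownian covariance of the tree, a the
GLS root estimate), so every statistic reduces to its ordinary
non-phylogenetic counterpart on a star phylogeny.

A synthetic-study generator simulates species-mean configurations under
modular multivariate Brownian motion on pure-birth trees — separately
controllable per-module rates, between-module correlation ρ, within-module
correlation, replicate specimens, digitizing noise — so the entire pipeline
is testable without specimen data.

## Worked example

```r
library(modulrate)

spec  <- simulation_spec(n_species = 40, sigma2_face = 2e-3,
                         sigma2_braincase = 1e-3, seed = 42)
study <- simulate_study(spec)          # tree + landmarks + module map + truth
fit   <- gpa(study$landmarks)          # Procrustes superimposition

cr_test(fit, study$tree, study$modules, n_perm = 999, seed = 42)
#> Phylogenetic modularity (covariance ratio)
#>   CR = 1.0646, p = 0.254 (exact enumeration, 252 assignments)

phylo_pls(fit, study$tree, study$modules, n_perm = 999, seed = 42)
#> Phylogenetic two-block PLS
#>   r_PLS = 0.7216, p = 0.001 (999 permutations)
#>   first pair carries 30.3% of squared cross-block covariance

compare_module_rates(fit, study$tree, study$modules, n_sim = 499, seed = 42)
#> Module rate comparison (multivariate BM)
#>   sigma^2[face] = 0.0001461, sigma^2[braincase] = 7.451e-05
#>   ratio = 1.961, p = 0.002 (499 simulated equal-rate datasets, statistic max(ratio, 1/ratio))

P <- evolutionary_pmatrix(fit, study$tree, study$modules, "face")
skewer_indices(P, n_skewers = 1000, seed = 42)
#> Random-skewers indices for module 'face' (1000 skewers, eigenspace rank 10)
#>  stat evolvability respondability conditional_evolvability autonomy constraints
#>  mean    7.467e-05      8.726e-05                3.083e-05   0.3944   0.4377046
#>   min    2.171e-05      3.356e-05                6.164e-06   0.1168   0.0008728
#>   max    1.293e-04      1.350e-04                1.055e-04   0.9234   0.9679592
```

Reading the output against the generator's truth: the study was simulated
with the face evolving twice as fast as the braincase and no between-module
correlation, and the rate test recovers a ratio of 1.96 (p = 0.002), with
rates in Procrustes units per unit tree height. The CR test correctly finds
no modularity signal (the permutation null asks whether the *observed*
partition covaries less than random partitions, and with no within-module
correlation there is nothing to detect). The r_PLS of 0.72 on uncorrelated
modules is expected: superimposition itself induces covariation among
aligned landmarks, which is real covariance in shape space — one reason the
integration and modularity tests answer different questions.

Every result type has `tidy()`, `glance()` and `autoplot()` methods, and
`run_full_analysis(analysis_config(...))` drives all stages from file paths
with one master seed and writes `report.json` plus rate and evolvability
tables.

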