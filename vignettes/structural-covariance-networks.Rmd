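---
title: "Structural covariance network analysis: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis: models, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

A structural covariance network is a group-level graph over atlas regions
(ROIs).  For each group of subjects, the edge weight between two ROIs is the
Pearson correlation of their gray-matter volumes across the subjects of that
group; anatomy that grows and shrinks together across individuals is read as
evidence of connectivity.  The analysis pipeline is:

1. **Association.** Per group, the N×N Pearson correlation matrix of ROI
   volumes (`group_association_matrix()`).  At least 3 subjects per group
   are required; a zero-variance ROI is a hard error rather than a silent
   `r = 0`, because a fake zero would distort the density ranking below.
2. **Binarization across a density sweep.** At connection density *d* the
   target edge count is `round_half_up(d · N(N−1)/2)` and the *m* largest
   strictly positive correlations become edges
   (`threshold_at_density()`, `density_sweep()`).  Defaults sweep
   *d* = 0.10–0.50 in steps of 0.02 (21 graphs).  Because the ranking does
   not depend on *d*, edge sets are nested across the sweep.
3. **Graph metrics.** Mean nodal clustering coefficient *C*, characteristic
   path length *L*, raw betweenness centrality, and normalization against
   20 degree-preserving rewired reference graphs:
   γ = C/C_rand, λ = L/L_rand, σ = γ/λ (`normalized_metrics()`).
4. **Resilience.** The trajectory of the relative size of the largest
   connected component (LCC ÷ N) as nodes are removed one at a time —
   uniformly at random (averaged over 50 orders by default) or in
   decreasing order of intact-network betweenness ("targeted attack").
5. **Inference.** Every curve is summarized by its trapezoidal area under
   the curve (AUC); groups are compared by permutation tests that reassign
   subjects to groups (preserving group sizes) and rebuild everything per
   relabeling; regional (per-ROI) clustering comparisons are corrected by
   Benjamini–Hochberg FDR at q = 0.05.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| density grid | 0.10–0.50 step 0.02 | fraction of possible edges | below ~0.1 graphs shatter; above 0.5 edges are mostly noise correlations |
| random references | 20 | graphs | convention for γ/λ; ensemble error ∝ 1/√20 |
| swap budget | 10·\|E\| | attempted swaps | standard mixing budget for double edge swaps |
| permutations | 1000 | relabelings | p-resolution 1/1001; scaled suites use 100–500 |
| random-failure orders | 50 | sequences | stabilizes the mean trajectory |
| FDR level q | 0.05 | — | regional discovery control |
| path-length policy | connected pairs | — | low-density covariance graphs are routinely disconnected |

## Numerical and policy choices

* **Edge sign.** Negative correlations are never admitted as edges; when
  they cap the achievable density the shortfall is recorded and warned.
* **Rounding and ties.** Target edge counts use round-half-up (platform
  stable); ties at the rank cutoff break by ascending ROI index.  Real
  correlation data has measure-zero ties, but exactly block-structured
  synthetic targets do not — see below.
* **Disconnected graphs.** *L* averages over reachable pairs by default; a
  harmonic-mean (1 / global efficiency) alternative is available and the
  choice is stamped into outputs.
* **Betweenness.** Raw fractional pair counts (unnormalized): only the
  ranking feeds the attack module, and closed forms on stars and paths stay
  exact.
* **Permutation p-values.** The "+1" convention
  p = (#{null ≥ observed} + 1)/(B + 1), never zero.  With equal group
  sizes, relabelings are drawn as antithetic pairs (each sampled partition
  enters with both orientations), which makes the null sample exactly
  sign-symmetric: exchanging the input's group labels flips the observed
  sign and maps a one-tailed p onto its complement within 2/(B+1).
  Empirically this is also slightly better calibrated than independent
  draws; the residual conservatism of the resilience test comes from tie
  mass in the discrete LCC statistic.
* **Degenerate permutations.** A relabeled group with a constant ROI column
  is redrawn (count logged) instead of aborting the run.
* **One-tailed direction.** The default tests "first group (control) above
  second (patient)", the direction in which reduced patient resilience
  manifests; the regional clustering test is typically run with
  `direction = "less"` (patient above control).  Both the tails and the
  direction are recorded in every result.

## The synthetic cohort generator

`generate_cohort()` draws subject × ROI volume tables from a multivariate
normal with per-ROI means (default 2,000–15,000 mm³) and standard
deviations (10% CV), a group-specific target correlation matrix, and
optional linear covariate effects (age ~ Normal(27, 7) years, sex ~
Bernoulli(0.75), mirroring a typical adult epilepsy-imaging cohort of ~33
vs ~35 subjects).  Volumes are plain normal, not lognormal: correlation-based
analysis is location/scale-free, and realistic mean/sd ratios make negative
draws vanishingly rare.  One master seed feeds fixed per-group and
per-covariate offsets, so group 1's draw does not shift when group 2's size
changes.

**Exact block targets are degenerate.**  An exactly equicorrelated or
block-constant target has massive exact ties, so its "noiseless-limit"
thresholded graph is decided by the index tie-break — e.g. a 3-module
0.6/0.2 target is three disconnected cliques below density 0.31.
`reference_correlation_target()` therefore empiricalizes a block-modular
population through one large fixed-seed reference draw (n = 500), giving
every pair a distinct correlation while preserving the modular structure.
All stated test worlds build on such targets.

**Planted effects.**  `plant_group_difference()` implements two phenotypes:

* `hub_weakening(magnitude, targets)` multiplies every correlation incident
  to the target ROIs by (1 − magnitude).  Counter to the intuition that
  "hubs keep networks resilient", weakening *central* hub ROIs makes
  betweenness-targeted attack **less** damaging — centralized networks are
  the vulnerable ones, and removing their hubs from the covariance
  structure removes the attack's best targets.  The phenotype that robustly
  *reduces* resilience is diffuse weakening of ordinary ROIs in a
  homogeneous-covariance base: at fixed density the weakened regions
  detach, the LCC shrinks, and the attack AUC drops at every density.  The
  resilience test world weakens 13 of 40 ROIs at magnitude 0.6 in a
  homogeneous (r = 0.5) base for exactly this reason.
* `module_boost(magnitude, targets)` raises the correlations among target
  ROIs toward the level `within_r + magnitude` (capped at 0.99).  Boosting
  an intact module does nothing (it is already a clique at most densities),
  and boosting cliques into a homogeneous background raises degree as fast
  as triangles, leaving clustering nearly unchanged.  The phenotype that
  produces a clean regional-clustering increase is *segregation*: long-range
  decoupling plus local hyper-coupling.  The regional test world gives both
  groups a decoupled 15-ROI module (hub_weakening 0.5) and boosts it to a
  0.8-level clique in patients only.

**Monotonicity is approximate.**  The noiseless-limit attack AUC as a
function of hub-weakening magnitude is a step function: edge sets change at
discrete rank cutoffs, and the positive-semidefinite repair perturbs all
entries slightly after each modification.  Every weakened target in the
stated ladder lies *below* the unweakened base, but strictly pairwise
monotone decrease does not hold (jitter on the order of 0.005 AUC), and the
tests assert the former, not the latter.

**What a green test does not establish.**  The generator emulates
second-order structure (covariance), planted group contrasts, and linear
confounds.  It does not emulate registration error, smoothing-induced
spatial autocorrelation between neighboring ROIs, non-Gaussian volume
distributions, site or scanner effects, or any voxel-level process.
Passing suites establish that the pipeline recovers planted covariance
phenotypes at realistic sample sizes — not that any particular clinical
finding is correct.

## Regional FDR needs permutation resolution

With m ROIs and B permutations the smallest attainable p-value is
1/(B+1), while the BH step-up threshold for rank k is kq/m.  At m = 30,
q = 0.05, B = 100, a planted set smaller than 6 ROIs can never be flagged
— the floor 1/101 exceeds 0.05·5/30.  The regional recovery experiment
therefore uses B = 500 with a 15-ROI planted module; global and resilience
comparisons keep B = 100 in scaled suites.

## ROI extraction front end

`extract_roi_volumes()` sums modulated gray-matter probability values over
each ROI's voxels and multiplies by the voxel volume — under modulation,
voxel values are volume-preserving, so the sum *is* a volume in mm³.  Maps
must share the atlas grid exactly; the package never resamples (silent
resampling is a classic irreproducibility source).  Because no NIfTI
reader ships with this R stack, a minimal strict NIfTI-1 reader is
included (single-file `.nii`/`.nii.gz`, common datatypes, slope/intercept
scaling, sform affine); its round trip is tested against an independent
writer.

## Known limitations

* Binary graphs only; weighted or signed variants are out of scope.
* The permutation test under strong alternatives absorbs part of the
  effect into its null (relabeled pseudo-groups are mixtures), which
  bounds attainable significance; this is inherent to label permutation,
  not an implementation artifact.
* The resilience statistic is discrete; its permutation test is mildly
  conservative (rejection ≈ 0.03 at nominal 0.05 in the calibration
  world).
* `recomputed` attack ranking is O(N) betweenness computations per curve
  and is meant for sensitivity checks, not permutation loops.
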