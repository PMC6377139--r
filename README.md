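# scnet — structural covariance network analysis of gray-matter volumes

`scnet` is an R package for group-level graph-theoretical analysis of
**structural covariance networks**: brain graphs whose nodes are atlas
regions (ROIs) and whose edges are inter-regional Pearson correlations of
gray-matter volume across the subjects of a group.  It is aimed at
neuroimaging researchers comparing a patient group against controls when
individual-level connectivity (fMRI/DTI) is unavailable — the covariance of
regional anatomy across subjects stands in for connectivity.

## What it computes

For each group with ROI volumes `x_i` over subjects:

* the N×N association matrix `A_ij = cor(x_i, x_j)` (Pearson);
* binary graphs at connection densities `d = 0.10, 0.12, …, 0.50`, keeping
  the `round_half_up(d·N(N−1)/2)` largest positive correlations as edges;
* global metrics per density: clustering coefficient `C`, characteristic
  path length `L`, and their ratios against 20 degree-preserving rewired
  reference graphs, `γ = C/C_rand`, `λ = L/L_rand`, small-worldness
  `σ = γ/λ`;
* nodal metrics: per-ROI clustering and (raw) betweenness centrality;
* resilience: the relative size of the largest connected component as nodes
  are removed — uniformly at random (mean of 50 orders) or by decreasing
  betweenness ("targeted attack");
* inference: every curve is reduced to its trapezoidal AUC and compared
  between groups by a permutation test (default 1,000 group-size-preserving
  relabelings, one-tailed, p = (#{null ≥ obs}+1)/(B+1)); per-ROI clustering
  comparisons are corrected by Benjamini–Hochberg FDR at q = 0.05.

A synthetic cohort generator (multivariate-normal volumes with controllable
correlation structure, planted group effects and linear confounds) makes the
whole pipeline testable without MRI data, and an optional front end extracts
ROI volumes from modulated gray-matter maps plus an integer-labeled
parcellation atlas (minimal built-in NIfTI-1 reader).

## Worked example

```r
library(scnet)

## a realistic homogeneous-covariance population target, and a patient
## variant with 10 of 30 ROIs diffusely weakened (covariance * 0.4)
tgt <- reference_correlation_target(30, 1, 0.5, 0.5)
patient_tgt <- plant_group_difference(tgt, "hub_weakening",
                                      magnitude = 0.6, target_rois = 1:10)

means <- seq(2000, 15000, length.out = 30)   # ROI mean volumes, mm^3
spec <- cohort_spec(n_per_group = c(35, 33),
                    roi_mean_volumes = means, roi_volume_sd = 0.10 * means,
                    correlation_targets = list(tgt, patient_tgt), seed = 1)
cohort <- generate_cohort(spec)
#> <roi_volume_table> 68 subjects (control=35, patient=33), 30 ROIs,
#>                    covariates: age, sex

A <- group_association_matrix(cohort, "control")
net <- threshold_at_density(A, 0.20)
#> <binary_network> 30 nodes, 87 edges, density 0.200 (requested 0.2)

normalized_metrics(net, random_ensemble(net, n_random = 20, seed = 1))
#> <global_metrics> C=0.4480 L=2.0025 C_rand=0.4135 L_rand=1.9670
#>                  gamma=1.083 lambda=1.018 sigma=1.064

compare_resilience(cohort, density_grid(), "targeted_betweenness",
                   perm_config(n_permutations = 1000, seed = 1))
#> <group_comparison_result> resilience_targeted_betweenness:
#>     observed diff = 0.04185, p = 0.0070 (one-tailed, 1000 permutations)
```

Reading the output: the control network at density 0.20 has clustering well
above its rewired references (γ = 1.08) at comparable path length
(λ = 1.02) — mildly small-world (σ = 1.06).  The resilience comparison is
the pipeline's headline: the observed difference 0.042 is the control-minus-
patient gap in targeted-attack AUC (itself integrated over the density
grid); only 6 of 1,000 relabelings produced a gap at least as large, so the
planted reduction of patient resilience is detected at p = 0.007.

Demographic utilities reproduce the usual cohort table statistics from
printed summaries:

```r
t_test_from_summary(26.4, 7.4, 33, 27.2, 6.3, 35)
#> age difference: t = -0.481, p = 0.632
pearson_chi2_2x2(matrix(c(25, 26, 8, 9), 2))$p
#> 0.8886
```

## Pipeline and CLI

A YAML-configured end-to-end run (cohort → association matrices → sweeps →
metric/resilience curves → permutation comparisons → markdown report):

```r
cfg <- run_config(input = spec, out_dir = "run1", seed = 1)
run_pipeline(cfg)
report("run1")
```

or from the shell via the installed wrapper:

```sh
Rscript inst/cli/scnet all --config analysis.yaml --seed 1 --log-level info
```

Subcommands: `simulate`, `extract`, `build`, `metrics`, `resilience`,
`compare`, `report`, `all`; exit codes 0/1/2 (ok / validation / runtime).

## Documentation

The methods vignette
(`vignettes/structural-covariance-networks.Rmd`) documents the model and
its assumptions, every tunable parameter with units and defaults, the
synthetic worlds behind the acceptance experiments (and what a green test
does and does not establish), numerical tie-break and rounding policies,
and known limitations.
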