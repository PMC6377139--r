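# Synthetic cohort generator: correlation targets, PSD repair, planted
# effects, multivariate-normal sampling, confounds, TSV round trip.

test_that("modular_correlation_target builds the stated block structure", {
    # singleton modules with between_r = 0: identity
    t1 <- modular_correlation_target(4, 4, within_r = 0.9, between_r = 0)
    expect_equal(t1$matrix, diag(4))

    # 2 modules of 3 at within 0.5: block-diagonal compound symmetry;
    # eigenvalues of each block are 1 + 2r and 1 - r (twice)
    t2 <- modular_correlation_target(6, 2, within_r = 0.5, between_r = 0)
    expect_equal(t2$matrix[1, 2], 0.5)
    expect_equal(t2$matrix[1, 4], 0)
    ev <- eigen(t2$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(unique(round(ev, 10))), c(0.5, 2))
    expect_equal(min(ev), 0.5, tolerance = 1e-10)

    # negative equicorrelation beyond the PSD boundary triggers repair:
    # 3x3 with r = -0.9 has eigenvalue 1 + 2r = -0.8 < 0
    t3 <- modular_correlation_target(3, 1, within_r = -0.9, between_r = -0.9)
    ev3 <- eigen(t3$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev3), -1e-10)
    expect_equal(diag(t3$matrix), rep(1, 3))
    expect_gt(t3$matrix[1, 2], -0.9)  # repair pulled the off-diagonal up

    expect_error(modular_correlation_target(6, 2, 0.2, 0.5),
                 class = "scnet_validation_error")
    expect_error(modular_correlation_target(6, 2, 1.0, 0.2),
                 class = "scnet_validation_error")
})

test_that("nearest_psd_repair clips, rescales and is a no-op on PSD input", {
    expect_equal(nearest_psd_repair(diag(3))$matrix, diag(3))

    psd <- modular_correlation_target(5, 1, 0.4, 0.4)$matrix
    expect_equal(nearest_psd_repair(psd)$matrix, psd, tolerance = 1e-12)

    bad <- matrix(c(1, 1.2, 1.2, 1), 2)
    rep2 <- nearest_psd_repair(bad)
    expect_lt(rep2$matrix[1, 2], 1.2)
    expect_gte(min(eigen(rep2$matrix, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    expect_equal(diag(rep2$matrix), c(1, 1))

    expect_error(nearest_psd_repair(matrix(c(1, 0.5, 0.2, 1), 2)),
                 class = "scnet_validation_error")
})

test_that("plant_group_difference implements both effect kinds", {
    base <- modular_correlation_target(10, 2, 0.6, 0.2)

    # hub_weakening at magnitude 1 zeroes every incident correlation
    z <- plant_group_difference(base, "hub_weakening", 1, target_rois = 3)
    expect_equal(unname(z$matrix[3, -3]), rep(0, 9))
    expect_equal(unname(z$matrix[-3, 3]), rep(0, 9))
    expect_equal(z$matrix[1, 2], base$matrix[1, 2], tolerance = 1e-6)

    # continuity: magnitude -> 0+ returns the base within repair tolerance
    eps <- plant_group_difference(base, "hub_weakening", 1e-8, target_rois = 1:2)
    expect_equal(eps$matrix, base$matrix, tolerance = 1e-6)
    eps2 <- plant_group_difference(base, "module_boost", 1e-8, target_rois = 1:3)
    expect_equal(eps2$matrix, base$matrix, tolerance = 1e-6)

    # module_boost raises among-target correlations to within_r + magnitude
    b <- plant_group_difference(base, "module_boost", 0.3, target_rois = 1:3)
    expect_equal(b$matrix[1, 2], 0.9, tolerance = 1e-6)
    expect_equal(b$matrix[1, 6], base$matrix[1, 6], tolerance = 1e-6)
    # capped below 1
    b2 <- plant_group_difference(base, "module_boost", 1, target_rois = 1:3)
    expect_lt(max(b2$matrix[1, 2]), 1)

    expect_error(plant_group_difference(base, "hub_weakening", 0, 1),
                 class = "scnet_validation_error")
    expect_error(plant_group_difference(base, "hub_weakening", 0.5, integer()),
                 class = "scnet_validation_error")
    expect_error(plant_group_difference(base, "module_boost", 0.5, 2),
                 class = "scnet_validation_error")
})

test_that("generate_cohort is deterministic and respects group-wise seeds", {
    tgt <- modular_correlation_target(12, 3, 0.6, 0.2)
    spec <- cohort_spec(c(8, 9), roi_means(12), 0.1 * roi_means(12), tgt,
                        seed = 7)
    tab1 <- generate_cohort(spec)
    tab2 <- generate_cohort(spec)
    expect_identical(tab1, tab2)
    expect_equal(nrow(tab1), 17)
    expect_equal(sum(tab1$group == "control"), 8)

    # group 1's draw is invariant to group 2's size (fixed seed offsets)
    spec_b <- cohort_spec(c(8, 30), roi_means(12), 0.1 * roi_means(12), tgt,
                          seed = 7)
    expect_identical(volume_matrix(generate_cohort(spec_b), "control"),
                     volume_matrix(tab1, "control"))

    # generator refuses a non-PSD target
    bad <- correlation_target(matrix(c(1, 1, 1, 1, 1, -1, 1, -1, 1), 3))
    spec_bad <- cohort_spec(c(5, 5), roi_means(3), rep(10, 3), bad, seed = 1)
    expect_error(generate_cohort(spec_bad), class = "scnet_validation_error")
})

test_that("empirical correlations converge to the target (n = 2000)", {
    # identity target: sampling-error bound ~ 3/sqrt(n) for r near 0
    id <- modular_correlation_target(10, 10, 0.9, 0)
    tab <- make_cohort(id, n_per_group = c(2000, 3), seed = 11)
    emp <- cor(volume_matrix(tab, "control"))
    expect_lt(max(abs(emp[upper.tri(emp)])), 0.08)

    # equicorrelated 0.6: Fisher-z standard error keeps pairs within 0.06
    eq <- modular_correlation_target(8, 1, 0.6, 0.6)
    tab2 <- make_cohort(eq, n_per_group = c(2000, 3), seed = 12)
    emp2 <- cor(volume_matrix(tab2, "control"))
    expect_lt(max(abs(emp2[upper.tri(emp2)] - 0.6)), 0.06)
})

test_that("planted confound coefficients are recovered by regression", {
    n_rois <- 6
    beta_age <- seq(5, 30, length.out = n_rois)
    tgt <- modular_correlation_target(n_rois, 1, 0.3, 0.3)
    spec <- cohort_spec(c(500, 3), roi_means(n_rois), 0.05 * roi_means(n_rois),
                        tgt,
                        confound_model = list(age = beta_age),
                        seed = 21)
    tab <- generate_cohort(spec)
    ctl <- tab[tab$group == "control", ]
    for (j in c(1, 4, 6)) {
        fit <- summary(lm(ctl[[attr(tab, "roi_names")[j]]] ~ ctl$age))
        est <- fit$coefficients["ctl$age", ]
        expect_lt(abs(est["Estimate"] - beta_age[j]), 3 * est["Std. Error"])
    }
})

test_that("ROI volume tables round-trip through TSV", {
    tgt <- modular_correlation_target(5, 1, 0.4, 0.4)
    tab <- make_cohort(tgt, n_per_group = c(4, 4), seed = 3)
    path <- tempfile(fileext = ".tsv")
    write_roi_table(tab, path)
    back <- read_roi_table(path)
    expect_equal(attr(back, "roi_names"), attr(tab, "roi_names"))
    expect_equal(attr(back, "covariate_names"), attr(tab, "covariate_names"))
    expect_equal(volume_matrix(back), volume_matrix(tab), tolerance = 1e-12)
})

test_that("cohort_spec_from_yaml builds a spec with a planted effect", {
    yml <- tempfile(fileext = ".yaml")
    writeLines(c(
        "cohort:",
        "  n_per_group: [10, 12]",
        "  n_rois: 12",
        "  seed: 5",
        "  correlation: {n_modules: 2, within_r: 0.6, between_r: 0.2}",
        "  effect: {kind: hub_weakening, magnitude: 0.5, target_rois: [1, 2]}"),
        yml)
    spec <- cohort_spec_from_yaml(yml)
    expect_equal(spec$n_per_group, c(10L, 12L))
    expect_equal(spec$n_rois, 12)
    expect_equal(spec$correlation_targets[[1]]$matrix[1, 2], 0.6)
    expect_equal(spec$correlation_targets[[2]]$matrix[1, 2],
                 0.6 * 0.5, tolerance = 1e-6)
    tab <- generate_cohort(spec)
    expect_equal(nrow(tab), 22)
})
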