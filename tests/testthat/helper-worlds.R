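# Frozen stated worlds shared by unit and acceptance tests.  Built once per
# test session (memoised in the helper environment); the constructions are
# documented in the methods vignette and must not be adjusted to test
# outcomes.

.world_cache <- new.env(parent = emptyenv())

world_memo <- function(key, build) {
    if (is.null(.world_cache[[key]])) .world_cache[[key]] <- build()
    .world_cache[[key]]
}

roi_means <- function(n) seq(2000, 15000, length.out = n)

# homogeneous-covariance base, 30 ROIs: calibration world
world_base30 <- function() world_memo("base30", function()
    reference_correlation_target(30, 1, 0.5, 0.5, n_reference = 500, seed = 42))

# homogeneous-covariance base, 40 ROIs + diffuse hub weakening: resilience
# power world
world_base40 <- function() world_memo("base40", function()
    reference_correlation_target(40, 1, 0.5, 0.5, n_reference = 500, seed = 42))

world_patient40 <- function() world_memo("patient40", function()
    plant_group_difference(world_base40(), "hub_weakening",
                           magnitude = 0.6, target_rois = 1:13))

# 2-module base with a decoupled target module: regional clustering world;
# both groups share the decoupled baseline, patients add the boost
world_regional <- function() world_memo("regional", function() {
    b <- reference_correlation_target(30, 2, 0.5, 0.25, n_reference = 500,
                                      seed = 42)
    ctrl <- plant_group_difference(b, "hub_weakening", 0.5, 1:15)
    pat <- plant_group_difference(ctrl, "module_boost", 0.3, 1:15)
    list(control = ctrl, patient = pat, targets = 1:15)
})

make_cohort <- function(target_control, target_patient = target_control,
                        n_per_group = c(20, 20), seed = 1) {
    n <- target_control$n_rois
    generate_cohort(cohort_spec(n_per_group, roi_means(n), 0.1 * roi_means(n),
                                list(target_control, target_patient),
                                seed = seed))
}
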