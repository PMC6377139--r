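# Association matrices and density thresholding.

make_table <- function(vols, group = rep("control", nrow(vols)),
                       covs = NULL) {
    colnames(vols) <- default_names <- sprintf("ROI%03d", seq_len(ncol(vols)))
    df <- data.frame(subject_id = sprintf("S%02d", seq_len(nrow(vols))),
                     group = group, stringsAsFactors = FALSE)
    cn <- character()
    if (!is.null(covs)) {
        df <- cbind(df, covs)
        cn <- names(covs)
    }
    roi_volume_table(cbind(df, as.data.frame(vols)),
                     roi_names = default_names, covariate_names = cn)
}

test_that("group_association_matrix reproduces hand-computed correlations", {
    vols <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(1, 3, 2, 4))
    tab <- make_table(vols)
    A <- group_association_matrix(tab, "control")
    expect_equal(A$matrix[1, 2], 1)            # exact linearity
    expect_equal(A$matrix[1, 3], 0.8)          # hand-computed Pearson
    expect_equal(A$n_subjects, 4)
    expect_true(is_perm <- isSymmetric(A$matrix))

    tab_neg <- make_table(cbind(c(1, 2, 3), c(3, 2, 1), c(1, 5, 3)))
    expect_equal(group_association_matrix(tab_neg, "control")$matrix[1, 2], -1)

    # constant column is a loud error naming the ROI
    tab_const <- make_table(cbind(c(1, 2, 3, 4), rep(5, 4)))
    expect_error(group_association_matrix(tab_const, "control"),
                 regexp = "ROI002", class = "scnet_constant_column_error")
    # too few subjects
    expect_error(group_association_matrix(make_table(cbind(1:2, 2:1)), "control"),
                 class = "scnet_validation_error")
})

test_that("residualize regresses out covariates and guards the design", {
    set.seed(4)
    age <- rnorm(200, 40, 10)
    vols <- cbind(10 + 0.3 * age + rnorm(200, 0, 0.1),
                  2 * age,
                  rnorm(200, 50, 5))
    tab <- make_table(vols, covs = data.frame(age = age))

    res <- residualize(tab, "age")
    rv <- volume_matrix(res)
    expect_lt(abs(cor(rv[, 1], age)), 0.05)
    expect_lt(max(abs(rv[, 2])), 1e-10)        # exactly 2*age -> zero residuals

    # empty covariate list mean-centers
    cen <- residualize(tab, character())
    expect_equal(colMeans(volume_matrix(cen)), rep(0, 3),
                 tolerance = 1e-10, ignore_attr = TRUE)

    # collinear design errors, naming the culprit
    tab2 <- make_table(vols, covs = data.frame(age = age, age2 = 2 * age))
    expect_error(residualize(tab2, c("age", "age2")), regexp = "age2",
                 class = "scnet_validation_error")
})

test_that("threshold_at_density places round-half-up positive edges", {
    # N = 90, d = 0.10: round_half_up(0.10 * 4005) = 401
    expect_equal(round_half_up(0.10 * 90 * 89 / 2), 401L)
    set.seed(10)
    m <- cor(matrix(rnorm(120 * 90), 120, 90))
    net <- threshold_at_density(association_matrix(m), 0.10)
    expect_equal(nrow(net$edges), 401L)
    expect_equal(net$density_actual, 401 / 4005)

    # maximum correlation wins at m = 1
    m3 <- diag(3)
    m3[1, 2] <- m3[2, 1] <- 0.9
    m3[1, 3] <- m3[3, 1] <- 0.5
    m3[2, 3] <- m3[3, 2] <- -0.2
    net1 <- threshold_at_density(association_matrix(m3), 1 / 3 - 1e-9)
    expect_equal(unname(net1$edges), matrix(c(1L, 2L), 1))

    # negative correlations never admitted: only 2 of 3 requested edges
    expect_warning(net3 <- threshold_at_density(association_matrix(m3), 0.99),
                   regexp = "capped")
    expect_equal(nrow(net3$edges), 2L)
    expect_equal(net3$density_actual, 2 / 3)
})

test_that("ties at the cutoff break by ascending ROI index", {
    m <- diag(4)
    m[1, 2] <- m[2, 1] <- 0.5
    m[3, 4] <- m[4, 3] <- 0.5
    m[1, 3] <- m[3, 1] <- 0.5
    net <- threshold_at_density(association_matrix(m), 1 / 6 + 1e-9)  # m = 1
    expect_equal(unname(net$edges), matrix(c(1L, 2L), 1))
})

test_that("density_sweep yields nested edge sets on the default grid", {
    grid <- density_grid()
    expect_equal(length(grid$values), 21)
    expect_equal(grid$values[1], 0.10)
    expect_equal(grid$values[21], 0.50)

    tab <- make_cohort(world_base30(), n_per_group = c(25, 3), seed = 2)
    A <- group_association_matrix(tab, "control")
    sweep <- density_sweep(A, grid)
    expect_length(sweep, 21)
    for (k in 2:21) {
        prev <- sweep[[k - 1]]$adjacency
        expect_true(all(sweep[[k]]$adjacency[prev == 1] == 1))
    }
    # edge-count exactness at every density
    rk_pos <- sum(A$matrix[upper.tri(A$matrix)] > 0)
    for (k in seq_along(grid$values)) {
        m_t <- round_half_up(grid$values[k] * 30 * 29 / 2)
        expect_equal(nrow(sweep[[k]]$edges), min(m_t, rk_pos))
    }

    # all-positive matrix: achieved densities match requested within 1/45
    mpos <- modular_correlation_target(10, 1, 0.5, 0.5)$matrix
    swp <- density_sweep(association_matrix(mpos), density_grid(0.1, 0.5, 0.1))
    expect_true(all(abs(vapply(swp, `[[`, 0, "density_actual") -
                        seq(0.1, 0.5, 0.1)) <= 1 / 45 + 1e-12))

    expect_error(density_grid(0.1, 1.0, 0.02), class = "scnet_validation_error")
    expect_error(density_grid(0, 0.5, 0.02), class = "scnet_validation_error")
})

test_that("association and adjacency are equivariant to ROI permutation and
           invariant to per-ROI scaling", {
    tab <- make_cohort(world_base30(), n_per_group = c(15, 3), seed = 8)
    vols <- volume_matrix(tab, "control")
    A <- cor(vols)
    perm <- sample(ncol(vols))
    expect_equal(cor(vols[, perm]), A[perm, perm], ignore_attr = TRUE)

    scaled <- sweep(vols, 2, runif(ncol(vols), 0.5, 3), "*")
    expect_equal(cor(scaled), A, tolerance = 1e-12, ignore_attr = TRUE)

    net <- threshold_at_density(association_matrix(A), 0.2)
    netp <- threshold_at_density(association_matrix(A[perm, perm]), 0.2)
    expect_equal(netp$adjacency, net$adjacency[perm, perm])
})
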