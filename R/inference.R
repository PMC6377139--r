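# Permutation inference: group comparison of AUC summaries and regional
# metrics, Benjamini-Hochberg FDR control, and the demographic t / chi-square
# utilities.
#
# Group labels are permuted (preserving group sizes); every permutation
# rebuilds both groups' association matrices, density sweeps and metric or
# resilience curves from scratch.  Observed differences are always
# first group minus second group, where the first group is "control" when
# that label is present (see group_levels()).

#' Permutation test configuration
#'
#' @param n_permutations number of relabelings (default 1000). Values below
#'   100 trigger a warning: reported p-values need a reasonable Monte-Carlo
#'   resolution.
#' @param tails `"one"` (default, directional) or `"two"`.
#' @param direction for one-tailed tests: `"greater"` tests
#'   first group > second group (the default: control above patient, the
#'   direction structural-covariance resilience studies report);
#'   `"less"` tests the opposite.
#' @param seed integer seed for the relabeling stream.
#' @param statistic `"auc_difference"` (default) or
#'   `"per_density_difference"` (adds per-density p-values).
#' @return object of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 1000,
                        tails = c("one", "two"),
                        direction = c("greater", "less"),
                        seed = 1L,
                        statistic = c("auc_difference", "per_density_difference")) {
    tails <- match.arg(tails)
    direction <- match.arg(direction)
    statistic <- match.arg(statistic)
    if (n_permutations < 1)
        abort_scnet("n_permutations must be positive", "scnet_validation_error")
    if (n_permutations < 100)
        warning("fewer than 100 permutations: p-values will be coarse",
                call. = FALSE)
    structure(list(n_permutations = as.integer(n_permutations), tails = tails,
                   direction = direction, seed = as.integer(seed),
                   statistic = statistic),
              class = "perm_config")
}

#' Randomly reassign subjects to groups
#'
#' Uniformly random relabeling preserving both group sizes; subject rows are
#' otherwise untouched.
#'
#' @param table a `roi_volume_table` with two groups.
#' @param seed optional integer seed.
#' @return the table with permuted `group` labels.
#' @export
permute_group_labels <- function(table, seed = NULL) {
    lev <- group_levels(table)
    n1 <- sum(table$group == lev[1])
    n <- nrow(table)
    idx <- with_seed(seed, sample.int(n, n1))
    g <- rep(lev[2], n)
    g[idx] <- lev[1]
    table$group <- g
    table
}

# --- permutation engine ----------------------------------------------------
#
# stat_fun(volsA, volsB) -> numeric vector (length 1 for global statistics,
# one entry per ROI for regional ones).  A permutation whose relabeled group
# contains a constant ROI column signals scnet_constant_column_error and is
# redrawn with a fresh relabeling (count recorded).
#
# When group sizes are equal, relabelings are drawn in antithetic pairs: for
# each sampled partition both assignments (S as first group, S as second
# group) enter the null sample, so exchanging the group labels of the input
# maps a one-tailed p exactly to its complement.
.permutation_null <- function(vols, n1, n2, stat_fun, n_permutations, seed) {
    n <- n1 + n2
    retries <- 0L
    draw <- function() {
        for (attempt in 1:100) {
            idx <- sample.int(n, n1)
            out <- tryCatch(stat_fun(vols[idx, , drop = FALSE],
                                     vols[-idx, , drop = FALSE]),
                            scnet_constant_column_error = function(e) NULL)
            if (!is.null(out)) return(out)
            retries <<- retries + 1L
        }
        abort_scnet("too many degenerate permutations (constant ROI columns)")
    }
    proto <- numeric(length(stat_fun(vols[seq_len(n1), , drop = FALSE],
                                     vols[-seq_len(n1), , drop = FALSE])))
    as_rows <- function(v, k) {
        if (length(proto) == 1L) matrix(v, nrow = k, ncol = 1L) else t(v)
    }
    null <- with_seed(seed, {
        if (n1 == n2) {
            half <- ceiling(n_permutations / 2)
            s <- as_rows(vapply(seq_len(half), function(k) draw(), proto), half)
            rbind(s, -s)[seq_len(n_permutations), , drop = FALSE]
        } else {
            as_rows(vapply(seq_len(n_permutations), function(k) draw(), proto),
                    n_permutations)
        }
    })
    attr(null, "n_retries") <- retries
    null
}

# Monte-Carlo p-values with the +1 convention (never zero).
.perm_pvalue <- function(observed, null, tails, direction) {
    B <- nrow(null)
    p <- vapply(seq_along(observed), function(j) {
        if (tails == "two") {
            (sum(abs(null[, j]) >= abs(observed[j])) + 1) / (B + 1)
        } else if (direction == "greater") {
            (sum(null[, j] >= observed[j]) + 1) / (B + 1)
        } else {
            (sum(null[, j] <= observed[j]) + 1) / (B + 1)
        }
    }, 0)
    p
}

.cor_checked <- function(vols) {
    if (nrow(vols) < 3)
        abort_scnet("need at least 3 subjects per group",
                    "scnet_validation_error")
    mu <- colMeans(vols)
    cvols <- sweep(vols, 2, mu)
    ss <- colSums(cvols^2)
    if (any(ss == 0))
        abort_scnet("constant ROI column in a (re)labeled group",
                    "scnet_constant_column_error")
    m <- crossprod(cvols) / sqrt(outer(ss, ss))
    diag(m) <- 1
    m
}

# fast per-group metric curve values across the density grid, working on the
# positive-edge ranking prefix at each density (edge sets are nested)
.group_metric_values <- function(vols, grid, metric, pol_int) {
    m <- .cor_checked(vols)
    rk <- .edge_ranking(m)
    n <- ncol(vols)
    m_avail <- length(rk$r)
    vapply(grid$values, function(d) {
        mt <- min(.target_edge_count(n, d), m_avail)
        ei <- as.integer(rk$i[seq_len(mt)])
        ej <- as.integer(rk$j[seq_len(mt)])
        switch(metric,
               clustering = mean(cpp_local_clustering(n, ei, ej)),
               path_length = cpp_path_length(n, ei, ej, pol_int),
               degree = 2 * mt / n)
    }, 0)
}

.group_nodal_clustering_auc <- function(vols, grid) {
    m <- .cor_checked(vols)
    rk <- .edge_ranking(m)
    n <- ncol(vols)
    m_avail <- length(rk$r)
    mat <- vapply(grid$values, function(d) {
        mt <- min(.target_edge_count(n, d), m_avail)
        cpp_local_clustering(n, as.integer(rk$i[seq_len(mt)]),
                             as.integer(rk$j[seq_len(mt)]))
    }, numeric(n))
    apply(matrix(mat, nrow = n), 1, function(v) trapezoid_auc(grid$values, v))
}

# per-density attack AUCs for one group
.group_resilience_profile <- function(vols, grid, kind, n_seq = 20) {
    m <- .cor_checked(vols)
    rk <- .edge_ranking(m)
    n <- ncol(vols)
    m_avail <- length(rk$r)
    vapply(grid$values, function(d) {
        mt <- min(.target_edge_count(n, d), m_avail)
        ei <- as.integer(rk$i[seq_len(mt)])
        ej <- as.integer(rk$j[seq_len(mt)])
        frac <- (0:(n - 1)) / n
        if (kind == "targeted_betweenness") {
            btw <- cpp_betweenness(n, ei, ej)
            ord <- order(-btw, seq_len(n))
            trapezoid_auc(frac, cpp_lcc_trajectory(n, ei, ej, as.integer(ord)))
        } else {
            acc <- numeric(n)
            for (s in seq_len(n_seq))
                acc <- acc + cpp_lcc_trajectory(n, ei, ej, sample.int(n))
            trapezoid_auc(frac, acc / n_seq)
        }
    }, 0)
}

.comparison_result <- function(metric_name, observed, null, config,
                               per_density = NULL, extra = list(),
                               n_retries = 0L) {
    p <- .perm_pvalue(observed, null, config$tails, config$direction)
    structure(c(list(metric_name = metric_name,
                     observed = unname(observed),
                     null_sample = unname(null[, 1]),
                     p_value = p[1],
                     n_permutations = config$n_permutations,
                     tails = config$tails,
                     direction = config$direction,
                     seed = config$seed,
                     n_retries = n_retries,
                     per_density_p = per_density),
                extra),
              class = "group_comparison_result")
}

#' @export
print.group_comparison_result <- function(x, ...) {
    cat(sprintf("<group_comparison_result> %s: observed diff = %.5f, p = %.4f (%s-tailed, %d permutations)\n",
                x$metric_name, x$observed, x$p_value, x$tails,
                x$n_permutations))
    invisible(x)
}

#' Permutation comparison of a global metric AUC between groups
#'
#' The observed statistic is the difference (first group minus second) of
#' the metric curve's AUC over the density grid; the null distribution comes
#' from group-size-preserving relabelings, each rebuilding both groups'
#' association matrices, sweeps and curves.
#'
#' @param table a `roi_volume_table` with two groups.
#' @param metric_name `"clustering"`, `"path_length"`, or `"degree"`.
#' @param grid a [density_grid()].
#' @param config a [perm_config()].
#' @param disconnected_policy path-length policy.
#' @return a `group_comparison_result`.
#' @export
compare_global_metric <- function(table, metric_name, grid = density_grid(),
                                  config = perm_config(),
                                  disconnected_policy = "connected_pairs") {
    lev <- group_levels(table)
    pol_int <- if (disconnected_policy == "connected_pairs") 0L else 1L
    v1 <- volume_matrix(table, lev[1])
    v2 <- volume_matrix(table, lev[2])
    per_density <- config$statistic == "per_density_difference"
    stat_fun <- function(a, b) {
        ca <- .group_metric_values(a, grid, metric_name, pol_int)
        cb <- .group_metric_values(b, grid, metric_name, pol_int)
        d <- trapezoid_auc(grid$values, ca) - trapezoid_auc(grid$values, cb)
        if (per_density) c(d, ca - cb) else d
    }
    observed <- stat_fun(v1, v2)
    null <- .permutation_null(rbind(v1, v2), nrow(v1), nrow(v2), stat_fun,
                              config$n_permutations, config$seed)
    pd <- if (per_density)
        .perm_pvalue(observed[-1], null[, -1, drop = FALSE],
                     config$tails, config$direction)
    .comparison_result(metric_name, observed[1], null[, 1, drop = FALSE],
                       config, per_density = pd,
                       extra = list(groups = lev),
                       n_retries = attr(null, "n_retries") %||% 0L)
}

#' Permutation comparison of regional (nodal) clustering
#'
#' Per-ROI observed difference of the nodal-clustering AUC over the density
#' grid, with one shared set of relabelings across ROIs and
#' Benjamini-Hochberg FDR flags at `q`.
#'
#' @param table a `roi_volume_table`.
#' @param grid a [density_grid()].
#' @param config a [perm_config()].
#' @param q FDR level (default 0.05).
#' @return object of class `regional_result`: `roi_names`,
#'   `observed_diffs`, `p_values`, `fdr_significant`.
#' @export
compare_regional_clustering <- function(table, grid = density_grid(),
                                        config = perm_config(), q = 0.05) {
    lev <- group_levels(table)
    v1 <- volume_matrix(table, lev[1])
    v2 <- volume_matrix(table, lev[2])
    if (ncol(v1) < 2)
        abort_scnet("regional clustering needs at least 2 ROIs",
                    "scnet_validation_error")
    stat_fun <- function(a, b)
        .group_nodal_clustering_auc(a, grid) - .group_nodal_clustering_auc(b, grid)
    observed <- stat_fun(v1, v2)
    null <- .permutation_null(rbind(v1, v2), nrow(v1), nrow(v2), stat_fun,
                              config$n_permutations, config$seed)
    p <- .perm_pvalue(observed, null, config$tails, config$direction)
    structure(list(roi_names = attr(table, "roi_names"),
                   observed_diffs = unname(observed),
                   p_values = p,
                   fdr_significant = bh_fdr(p, q),
                   q = q,
                   groups = lev,
                   n_permutations = config$n_permutations,
                   tails = config$tails,
                   direction = config$direction,
                   n_retries = attr(null, "n_retries")),
              class = "regional_result")
}

#' @export
print.regional_result <- function(x, ...) {
    cat(sprintf("<regional_result> %d ROIs, %d FDR-significant at q = %.2f\n",
                length(x$roi_names), sum(x$fdr_significant), x$q))
    invisible(x)
}

#' Permutation comparison of resilience AUC between groups
#'
#' At each density the attack curve's AUC is computed; the per-density AUC
#' values form each group's resilience profile across the density grid, and
#' the observed statistic is the difference (first minus second group) of
#' that profile's AUC.  The permutation null rebuilds everything per
#' relabeling.
#'
#' @param table a `roi_volume_table`.
#' @param grid a [density_grid()].
#' @param attack_kind `"targeted_betweenness"` or `"random"`.
#' @param config a [perm_config()].
#' @param n_random_sequences random-failure removal orders per density
#'   (random kind only; kept moderate because it runs inside every
#'   permutation).
#' @return a `group_comparison_result` with the two per-density profiles
#'   attached (`profile_first`, `profile_second`).
#' @export
compare_resilience <- function(table, grid = density_grid(),
                               attack_kind = c("targeted_betweenness", "random"),
                               config = perm_config(),
                               n_random_sequences = 20) {
    attack_kind <- match.arg(attack_kind)
    lev <- group_levels(table)
    v1 <- volume_matrix(table, lev[1])
    v2 <- volume_matrix(table, lev[2])
    per_density <- config$statistic == "per_density_difference"
    stat_fun <- function(a, b) {
        pa <- .group_resilience_profile(a, grid, attack_kind, n_random_sequences)
        pb <- .group_resilience_profile(b, grid, attack_kind, n_random_sequences)
        d <- trapezoid_auc(grid$values, pa) - trapezoid_auc(grid$values, pb)
        if (per_density) c(d, pa - pb) else d
    }
    obs_profiles <- with_seed(child_seed(config$seed, 1L), {
        list(.group_resilience_profile(v1, grid, attack_kind,
                                       n_random_sequences),
             .group_resilience_profile(v2, grid, attack_kind,
                                       n_random_sequences))
    })
    p1 <- obs_profiles[[1]]
    p2 <- obs_profiles[[2]]
    observed <- c(trapezoid_auc(grid$values, p1) - trapezoid_auc(grid$values, p2),
                  if (per_density) p1 - p2)
    null <- with_seed(config$seed,
        .permutation_null(rbind(v1, v2), nrow(v1), nrow(v2), stat_fun,
                          config$n_permutations, NULL))
    pd <- if (per_density)
        .perm_pvalue(observed[-1], null[, -1, drop = FALSE],
                     config$tails, config$direction)
    .comparison_result(paste0("resilience_", attack_kind), observed[1],
                       null[, 1, drop = FALSE], config, per_density = pd,
                       extra = list(groups = lev, profile_first = p1,
                                    profile_second = p2,
                                    densities = grid$values),
                       n_retries = attr(null, "n_retries") %||% 0L)
}

#' Benjamini-Hochberg step-up FDR flags
#'
#' Flags every hypothesis with rank at most the largest k such that
#' `p_(k) <= k q / m`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q FDR level.
#' @return logical vector of the same length.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
    m <- length(p_values)
    if (m == 0) return(logical(0))
    if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
        abort_scnet("p-values must lie in [0, 1]", "scnet_validation_error")
    ord <- order(p_values)
    below <- which(p_values[ord] <= seq_len(m) * q / m)
    flags <- logical(m)
    if (length(below)) flags[ord[seq_len(max(below))]] <- TRUE
    flags
}

#' Two-sample pooled t-test from summary statistics
#'
#' Pooled-variance unpaired t-test computed from group means, standard
#' deviations and sizes, with a two-sided p-value on `n1 + n2 - 2` degrees
#' of freedom.  Used for demographic comparisons (e.g. age) reported as
#' rounded summaries.
#'
#' @param mean1,sd1,n1 first group's summary.
#' @param mean2,sd2,n2 second group's summary.
#' @return list with `t`, `df`, `p`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2 || n2 < 2)
        abort_scnet("need n >= 2 per group", "scnet_validation_error")
    if (sd1 <= 0 || sd2 <= 0)
        abort_scnet("standard deviations must be positive",
                    "scnet_validation_error")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction; p-value from the chi-square distribution
#' with 1 degree of freedom.  Used for demographic comparisons (e.g. sex
#' counts).
#'
#' @param counts 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return list with `chi2`, `df`, `p`.
#' @export
pearson_chi2_2x2 <- function(counts) {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == c(2, 2)))
        abort_scnet("counts must be a 2x2 table", "scnet_validation_error")
    if (any(counts < 0) || any(counts != round(counts)))
        abort_scnet("counts must be nonnegative integers",
                    "scnet_validation_error")
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
        abort_scnet("all margins must be positive", "scnet_validation_error")
    e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    chi2 <- sum((counts - e)^2 / e)
    list(chi2 = chi2, df = 1, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
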