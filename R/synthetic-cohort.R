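# Synthetic two-group cohort generator.
#
# Structural covariance analysis needs subject x ROI gray-matter volume
# tables.  This module simulates such tables from a multivariate normal model
# with a user-chosen inter-regional correlation structure, optional planted
# group differences (hub weakening, module boosting) and linear confound
# effects, so the whole downstream pipeline is testable without MRI data.

#' Correlation target for cohort simulation
#'
#' A correlation target is the population inter-regional correlation matrix a
#' simulated group is drawn from.  It must be symmetric with unit diagonal and
#' entries in \[-1, 1\]; positive semi-definiteness is required at sampling
#' time (see [nearest_psd_repair()]).
#'
#' @param matrix square numeric matrix.
#' @param module_assignment optional integer vector mapping each ROI to a
#'   module id.
#' @param roi_names optional character vector of ROI labels.
#' @param within_r optional reference within-module correlation level,
#'   carried along so planted effects can express levels relative to it.
#' @return an object of class `correlation_target`.
#' @export
correlation_target <- function(matrix, module_assignment = NULL,
                               roi_names = NULL, within_r = NULL) {
    if (!is_symmetric_matrix(matrix))
        abort_scnet("correlation target must be a symmetric square matrix",
                    "scnet_validation_error")
    n <- nrow(matrix)
    if (any(abs(diag(matrix) - 1) > 1e-8))
        abort_scnet("correlation target must have unit diagonal",
                    "scnet_validation_error")
    if (any(matrix < -1 - 1e-12 | matrix > 1 + 1e-12))
        abort_scnet("correlation entries must lie in [-1, 1]",
                    "scnet_validation_error")
    if (!is.null(module_assignment) && length(module_assignment) != n)
        abort_scnet("module_assignment length must equal n_rois",
                    "scnet_validation_error")
    if (is.null(roi_names)) roi_names <- default_roi_names(n)
    m <- unname((matrix + t(matrix)) / 2)
    diag(m) <- 1
    structure(list(n_rois = n, matrix = m,
                   module_assignment = module_assignment,
                   roi_names = roi_names,
                   within_r = within_r),
              class = "correlation_target")
}

#' @export
print.correlation_target <- function(x, ...) {
    cat(sprintf("<correlation_target> %d ROIs, min eigenvalue %.4g\n",
                x$n_rois, min(eigen(x$matrix, symmetric = TRUE,
                                    only.values = TRUE)$values)))
    invisible(x)
}

#' Block-modular correlation target
#'
#' Builds a block-structured correlation matrix: `within_r` between ROIs in
#' the same module, `between_r` across modules, unit diagonal.  ROIs are
#' assigned to modules in contiguous blocks of as-equal-as-possible size.
#' If the block construction is not positive semi-definite the matrix is
#' repaired with [nearest_psd_repair()].
#'
#' @param n_rois number of regions.
#' @param n_modules number of modules (>= 1).
#' @param within_r correlation inside modules.
#' @param between_r correlation across modules; must satisfy
#'   `-1 < between_r <= within_r < 1`.
#' @return a [correlation_target()].
#' @export
modular_correlation_target <- function(n_rois, n_modules, within_r, between_r) {
    check_scalar_number(within_r, "within_r")
    check_scalar_number(between_r, "between_r")
    if (n_modules < 1) abort_scnet("n_modules must be >= 1",
                                   "scnet_validation_error")
    if (!(between_r > -1 && between_r <= within_r && within_r < 1))
        abort_scnet("require -1 < between_r <= within_r < 1",
                    "scnet_validation_error")
    modules <- sort(rep_len(seq_len(n_modules), n_rois))
    same <- outer(modules, modules, "==")
    m <- ifelse(same, within_r, between_r)
    diag(m) <- 1
    tgt <- correlation_target(m, module_assignment = modules,
                              within_r = within_r)
    ev_min <- min(eigen(tgt$matrix, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 0) tgt <- nearest_psd_repair(tgt)
    tgt$module_assignment <- modules
    tgt$within_r <- within_r
    tgt
}

#' Nearest positive semi-definite repair of a correlation matrix
#'
#' Eigenvalues below `1e-8` are clipped up to `1e-8`, the matrix is
#' reconstructed and rescaled back to unit diagonal.  An input that is already
#' positive semi-definite (all eigenvalues >= 1e-8) is returned unchanged.
#'
#' @param x a symmetric matrix or a [correlation_target()].
#' @return a [correlation_target()] whose matrix is PSD within 1e-10.
#' @export
nearest_psd_repair <- function(x) {
    mod <- NULL
    rn <- NULL
    wr <- NULL
    if (inherits(x, "correlation_target")) {
        mod <- x$module_assignment
        rn <- x$roi_names
        wr <- x$within_r
        x <- x$matrix
    }
    if (!is_symmetric_matrix(x))
        abort_scnet("nearest_psd_repair requires a symmetric matrix",
                    "scnet_validation_error")
    e <- eigen(x, symmetric = TRUE)
    if (min(e$values) >= 1e-8)
        return(correlation_target(x, module_assignment = mod, roi_names = rn,
                                  within_r = wr))
    lam <- pmax(e$values, 1e-8)
    m <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    m <- pmin(pmax(m, -1), 1)
    diag(m) <- 1
    correlation_target((m + t(m)) / 2, module_assignment = mod,
                       roi_names = rn, within_r = wr)
}

#' Plant a group difference into a correlation target
#'
#' Two effect kinds create ground truth for method validation:
#' * `hub_weakening`: every correlation incident to a target ROI is
#'   multiplied by `1 - magnitude`, emulating regions whose covariance with
#'   the rest of the brain is weakened (the patient-group phenotype whose
#'   network consequence is reduced resilience to attack).
#' * `module_boost`: correlations among the target ROIs are raised toward
#'   the level `within_r + magnitude` (capped at 0.99; entries already above
#'   that level are left alone), emulating locally increased covariance and
#'   hence increased regional clustering.  The reference `within_r` is the
#'   one carried by the target; for targets without one (e.g. empirical
#'   matrices) the mean off-diagonal correlation among the target ROIs is
#'   used.
#'
#' The modified matrix is PSD-repaired before return.
#'
#' @param base a [correlation_target()].
#' @param kind `"hub_weakening"` or `"module_boost"`.
#' @param magnitude effect size in (0, 1].
#' @param target_rois integer indices of affected ROIs (non-empty).
#' @return a [correlation_target()].
#' @export
plant_group_difference <- function(base, kind = c("hub_weakening", "module_boost"),
                                   magnitude, target_rois) {
    kind <- match.arg(kind)
    if (!inherits(base, "correlation_target"))
        abort_scnet("base must be a correlation_target", "scnet_validation_error")
    check_scalar_number(magnitude, "magnitude")
    if (magnitude <= 0 || magnitude > 1)
        abort_scnet("magnitude must lie in (0, 1]", "scnet_validation_error")
    if (length(target_rois) == 0)
        abort_scnet("target_rois must be non-empty", "scnet_validation_error")
    target_rois <- as.integer(target_rois)
    if (any(target_rois < 1 | target_rois > base$n_rois))
        abort_scnet("target_rois out of range", "scnet_validation_error")
    m <- base$matrix
    n <- base$n_rois
    if (kind == "hub_weakening") {
        hit <- matrix(FALSE, n, n)
        hit[target_rois, ] <- TRUE
        hit[, target_rois] <- TRUE
        diag(hit) <- FALSE
        m[hit] <- m[hit] * (1 - magnitude)
    } else {
        if (length(target_rois) < 2)
            abort_scnet("module_boost needs at least 2 target ROIs",
                        "scnet_validation_error")
        blk <- m[target_rois, target_rois]
        ref <- base$within_r
        if (is.null(ref)) ref <- mean(blk[upper.tri(blk)])
        level <- min(ref + magnitude, 0.99)
        boosted <- pmax(blk, level)
        diag(boosted) <- 1
        m[target_rois, target_rois] <- boosted
    }
    nearest_psd_repair(correlation_target(m,
                                          module_assignment = base$module_assignment,
                                          roi_names = base$roi_names,
                                          within_r = base$within_r))
}

#' Cohort specification
#'
#' Describes a two-group synthetic cohort: per-group sample sizes, per-ROI
#' mean volumes and standard deviations (mm^3), one correlation target per
#' group, an optional linear confound model, and covariate samplers.
#'
#' @param n_per_group integer vector of length 2 (group sizes, order
#'   control then patient).
#' @param roi_mean_volumes per-ROI mean volumes in mm^3 (positive).
#' @param roi_volume_sd per-ROI standard deviations in mm^3 (strictly
#'   positive); a scalar is recycled.
#' @param correlation_targets list of two [correlation_target()]s (control,
#'   patient); a single target is used for both groups.
#' @param confound_model optional named list mapping a covariate name to a
#'   per-ROI coefficient vector; covariate effects add linearly to volumes.
#' @param covariate_distributions named list of sampler functions
#'   `function(n)`; defaults provide `age ~ Normal(27, 7)` and
#'   `sex ~ Bernoulli(0.75)` (1 = female), mirroring a typical adult
#'   epilepsy-imaging cohort.
#' @param seed master integer seed; every sampling stream derives a child
#'   seed from it by a fixed offset.
#' @param group_labels labels for the two groups.
#' @param roi_names optional ROI labels.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group,
                        roi_mean_volumes,
                        roi_volume_sd,
                        correlation_targets,
                        confound_model = NULL,
                        covariate_distributions = NULL,
                        seed = 1L,
                        group_labels = c("control", "patient"),
                        roi_names = NULL) {
    if (length(n_per_group) != 2 || any(n_per_group < 1))
        abort_scnet("n_per_group must be two positive integers",
                    "scnet_validation_error")
    if (inherits(correlation_targets, "correlation_target"))
        correlation_targets <- list(correlation_targets, correlation_targets)
    if (length(correlation_targets) != 2 ||
        !all(vapply(correlation_targets, inherits, TRUE, "correlation_target")))
        abort_scnet("correlation_targets must be one or two correlation_target objects",
                    "scnet_validation_error")
    n_rois <- correlation_targets[[1]]$n_rois
    if (correlation_targets[[2]]$n_rois != n_rois)
        abort_scnet("both correlation targets must cover the same ROIs",
                    "scnet_validation_error")
    if (length(roi_volume_sd) == 1) roi_volume_sd <- rep(roi_volume_sd, n_rois)
    if (length(roi_mean_volumes) != n_rois || length(roi_volume_sd) != n_rois)
        abort_scnet("per-ROI vectors must have length n_rois",
                    "scnet_validation_error")
    if (any(roi_volume_sd <= 0))
        abort_scnet("roi_volume_sd must be strictly positive",
                    "scnet_validation_error")
    if (any(roi_mean_volumes <= 0))
        abort_scnet("roi_mean_volumes must be positive", "scnet_validation_error")
    if (is.null(covariate_distributions))
        covariate_distributions <- list(
            age = function(n) rnorm(n, mean = 27, sd = 7),
            sex = function(n) rbinom(n, 1, 0.75))
    if (!is.null(confound_model)) {
        bad <- setdiff(names(confound_model), names(covariate_distributions))
        if (length(bad))
            abort_scnet(paste0("confound_model names missing from covariate_distributions: ",
                               paste(bad, collapse = ", ")),
                        "scnet_validation_error")
        if (!all(vapply(confound_model, length, 1L) == n_rois))
            abort_scnet("each confound coefficient vector must have length n_rois",
                        "scnet_validation_error")
    }
    if (is.null(roi_names)) roi_names <- correlation_targets[[1]]$roi_names
    structure(list(n_per_group = as.integer(n_per_group),
                   n_rois = n_rois,
                   roi_mean_volumes = roi_mean_volumes,
                   roi_volume_sd = roi_volume_sd,
                   correlation_targets = correlation_targets,
                   confound_model = confound_model,
                   covariate_distributions = covariate_distributions,
                   seed = as.integer(seed),
                   group_labels = group_labels,
                   roi_names = roi_names),
              class = "cohort_spec")
}

#' Default cohort specification
#'
#' Mirrors the scale of a typical single-center adult structural-covariance
#' study: 35 controls vs 33 patients over 90 atlas ROIs, ages about
#' Normal(27, 7) years, sex about 75% female, ROI mean volumes spread over
#' 2,000-15,000 mm^3 with a 10% coefficient of variation, and a 4-module
#' correlation structure (within-module r = 0.6, between 0.2).
#'
#' @param n_rois number of ROIs (default 90).
#' @param seed master seed.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(n_rois = 90, seed = 1L) {
    means <- seq(2000, 15000, length.out = n_rois)
    tgt <- modular_correlation_target(n_rois, n_modules = 4,
                                      within_r = 0.6, between_r = 0.2)
    cohort_spec(n_per_group = c(35L, 33L),
                roi_mean_volumes = means,
                roi_volume_sd = 0.10 * means,
                correlation_targets = tgt,
                seed = seed)
}

# symmetric matrix square root with tiny-negative clipping; refuses truly
# non-PSD input (callers must run nearest_psd_repair first).
.target_sqrt <- function(target) {
    e <- eigen(target$matrix, symmetric = TRUE)
    if (min(e$values) < -1e-8)
        abort_scnet("correlation target is not positive semi-definite; run nearest_psd_repair() first",
                    "scnet_validation_error")
    lam <- sqrt(pmax(e$values, 0))
    e$vectors %*% (lam * t(e$vectors))
}

#' Generate a synthetic cohort
#'
#' Draws, per group, subject volume vectors from a multivariate normal with
#' the cohort specification's per-ROI means and standard deviations and the group's target
#' correlation, then adds linear confound contributions.  Each group and each
#' covariate uses a child seed derived from the master seed by a fixed
#' offset, so group 1's draw does not change when group 2's size changes.
#'
#' @param spec a [cohort_spec()].
#' @return a `roi_volume_table`: a data.frame with columns `subject_id`,
#'   `group`, one column per covariate, then one column per ROI, carrying
#'   attributes `roi_names` and `covariate_names`.
#' @export
generate_cohort <- function(spec) {
    if (!inherits(spec, "cohort_spec"))
        abort_scnet("spec must be a cohort_spec", "scnet_validation_error")
    cov_names <- names(spec$covariate_distributions)
    groups <- list()
    for (g in 1:2) {
        n_g <- spec$n_per_group[g]
        root <- .target_sqrt(spec$correlation_targets[[g]])
        covars <- matrix(0, n_g, length(cov_names),
                         dimnames = list(NULL, cov_names))
        for (ci in seq_along(cov_names)) {
            covars[, ci] <- with_seed(child_seed(spec$seed, 10000L * g + 100L * ci),
                                      spec$covariate_distributions[[ci]](n_g))
        }
        z <- with_seed(child_seed(spec$seed, 10000L * g),
                       matrix(rnorm(n_g * spec$n_rois), n_g, spec$n_rois))
        vols <- z %*% root
        vols <- sweep(vols, 2, spec$roi_volume_sd, "*")
        vols <- sweep(vols, 2, spec$roi_mean_volumes, "+")
        if (!is.null(spec$confound_model)) {
            for (cn in names(spec$confound_model)) {
                vols <- vols + outer(covars[, cn], spec$confound_model[[cn]])
            }
        }
        colnames(vols) <- spec$roi_names
        df <- data.frame(
            subject_id = sprintf("S%d_%03d", g, seq_len(n_g)),
            group = rep(spec$group_labels[g], n_g),
            stringsAsFactors = FALSE)
        df <- cbind(df, as.data.frame(covars), as.data.frame(vols))
        groups[[g]] <- df
    }
    tab <- rbind(groups[[1]], groups[[2]])
    rownames(tab) <- NULL
    roi_volume_table(tab, roi_names = spec$roi_names,
                     covariate_names = cov_names)
}

#' ROI volume table
#'
#' The pipeline's universal input: one row per subject with a group label,
#' optional covariates and one gray-matter volume column per ROI.
#'
#' @param data a data.frame containing `subject_id`, `group`, the covariate
#'   columns and the ROI columns.
#' @param roi_names which columns hold ROI volumes (ordered).
#' @param covariate_names which columns hold per-subject covariates.
#' @return the data.frame with class `roi_volume_table` and attributes
#'   `roi_names`, `covariate_names`.
#' @export
roi_volume_table <- function(data, roi_names, covariate_names = character()) {
    if (!all(c("subject_id", "group") %in% names(data)))
        abort_scnet("table needs subject_id and group columns",
                    "scnet_validation_error")
    missing_rois <- setdiff(roi_names, names(data))
    if (length(missing_rois))
        abort_scnet(paste0("missing ROI columns: ",
                           paste(head(missing_rois, 5), collapse = ", ")),
                    "scnet_validation_error")
    vols <- as.matrix(data[roi_names])
    if (!all(is.finite(vols)))
        abort_scnet("ROI volumes must be finite with no missing values",
                    "scnet_validation_error")
    structure(data,
              roi_names = roi_names,
              covariate_names = covariate_names,
              class = c("roi_volume_table", "data.frame"))
}

#' @export
print.roi_volume_table <- function(x, ...) {
    cat(sprintf("<roi_volume_table> %d subjects (%s), %d ROIs, covariates: %s\n",
                nrow(x),
                paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                      collapse = ", "),
                length(attr(x, "roi_names")),
                if (length(attr(x, "covariate_names")))
                    paste(attr(x, "covariate_names"), collapse = ", ")
                else "none"))
    invisible(x)
}

#' Extract the subject x ROI volume matrix
#' @param table a `roi_volume_table`.
#' @param group optional group label to subset.
#' @return numeric matrix, subjects in rows, ROIs in columns.
#' @export
volume_matrix <- function(table, group = NULL) {
    if (!is.null(group)) {
        keep <- table$group == group
        if (!any(keep)) abort_scnet(sprintf("no subjects in group '%s'", group),
                                    "scnet_validation_error")
        table <- table[keep, , drop = FALSE]
    }
    as.matrix(table[attr(table, "roi_names")])
}

#' Group labels of a table in analysis order
#'
#' The first label is `"control"` when present, otherwise the
#' alphabetically first label; observed group differences throughout the
#' package are `first - second`.
#' @param table a `roi_volume_table`.
#' @return character vector of length 2.
#' @export
group_levels <- function(table) {
    g <- sort(unique(as.character(table$group)))
    if (length(g) != 2)
        abort_scnet("expected exactly two groups", "scnet_validation_error")
    if ("control" %in% g) g <- c("control", setdiff(g, "control"))
    g
}

#' Write / read an ROI volume table as TSV
#'
#' Plain UTF-8 TSV, '.' decimal separator; columns `subject_id`, `group`,
#' covariates, then one column per ROI.
#'
#' @param table a `roi_volume_table`.
#' @param path file path.
#' @return `write_roi_table` returns `path` invisibly; `read_roi_table`
#'   returns a `roi_volume_table`.
#' @export
write_roi_table <- function(table, path) {
    hdr <- c("#covariates: ", paste(attr(table, "covariate_names"),
                                    collapse = "\t"))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0(hdr, collapse = ""), con)
    write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
    first <- readLines(path, n = 1)
    covs <- character()
    skip <- 0
    if (startsWith(first, "#covariates:")) {
        skip <- 1
        rest <- trimws(sub("^#covariates:", "", first))
        if (nzchar(rest)) covs <- strsplit(rest, "\t")[[1]]
    }
    df <- read.delim(path, skip = skip, stringsAsFactors = FALSE,
                     check.names = FALSE)
    rois <- setdiff(names(df), c("subject_id", "group", covs))
    roi_volume_table(df, roi_names = rois, covariate_names = covs)
}

#' Build a cohort specification from a YAML config
#'
#' Schema (all volumes in mm^3):
#' ```yaml
#' cohort:
#'   n_per_group: [35, 33]
#'   n_rois: 90
#'   seed: 1
#'   mean_volume_range: [2000, 15000]
#'   volume_cv: 0.10
#'   correlation: {n_modules: 4, within_r: 0.6, between_r: 0.2}
#'   effect: {kind: hub_weakening, magnitude: 0.5, target_rois: [1, 2, 3]}
#' ```
#' The planted `effect`, when present, is applied to the patient group's
#' correlation target only.
#'
#' @param config a file path to a YAML document or an already-parsed list.
#' @return a [cohort_spec()].
#' @export
cohort_spec_from_yaml <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cc <- config$cohort %||% config
    n_rois <- cc$n_rois %||% 90
    rng <- cc$mean_volume_range %||% c(2000, 15000)
    means <- seq(rng[1], rng[2], length.out = n_rois)
    cv <- cc$volume_cv %||% 0.10
    corr <- cc$correlation %||% list()
    tgt <- modular_correlation_target(n_rois,
                                      n_modules = corr$n_modules %||% 4,
                                      within_r = corr$within_r %||% 0.6,
                                      between_r = corr$between_r %||% 0.2)
    targets <- list(tgt, tgt)
    if (!is.null(cc$effect)) {
        targets[[2]] <- plant_group_difference(
            tgt, kind = cc$effect$kind,
            magnitude = cc$effect$magnitude,
            target_rois = unlist(cc$effect$target_rois))
    }
    cohort_spec(n_per_group = unlist(cc$n_per_group %||% c(35, 33)),
                roi_mean_volumes = means,
                roi_volume_sd = cv * means,
                correlation_targets = targets,
                seed = cc$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realistic reference correlation target
#'
#' An exactly block-structured correlation matrix is a degenerate stand-in
#' for empirical anatomical covariance: its massive exact ties make
#' density-thresholded graphs depend on arbitrary tie-breaking.  This helper
#' builds a realistic target as the empirical correlation matrix of one
#' large fixed-seed reference cohort drawn from a block-modular population,
#' which preserves the modular structure while giving every ROI pair a
#' distinct, smoothly heterogeneous correlation.
#'
#' @param n_rois number of ROIs.
#' @param n_modules,within_r,between_r block structure of the population the
#'   reference cohort is drawn from (see [modular_correlation_target()]).
#' @param n_reference reference cohort size (default 2000; larger means
#'   closer to the block ideal).
#' @param seed seed of the reference draw.
#' @return a [correlation_target()] with the population `within_r` and
#'   module assignment attached.
#' @export
reference_correlation_target <- function(n_rois, n_modules, within_r,
                                         between_r, n_reference = 2000,
                                         seed = 42L) {
    pop <- modular_correlation_target(n_rois, n_modules, within_r, between_r)
    means <- seq(2000, 15000, length.out = n_rois)
    spec <- cohort_spec(c(n_reference, 3L), means, 0.10 * means, pop,
                        seed = seed)
    ref <- generate_cohort(spec)
    emp <- cor(volume_matrix(ref, "control"))
    out <- nearest_psd_repair(correlation_target(emp, within_r = within_r))
    out$module_assignment <- pop$module_assignment
    out
}
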