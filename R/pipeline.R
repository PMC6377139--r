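# Configuration-driven orchestration: simulate/load a cohort, build group
# association matrices, sweep densities, compute metric and resilience
# curves, run the permutation comparisons, and write a manifest plus a
# markdown report.  Every stage writes plain-text artifacts (TSV/JSON) so a
# run is inspectable and the report never recomputes statistics.

#' Run configuration
#'
#' Defaults mirror the field's standard analysis: density grid 0.10-0.50 in
#' steps of 0.02, connected-pairs path length, static betweenness-targeted
#' attack plus 50-sequence random failure, 1000 one-tailed permutations, FDR
#' q = 0.05.
#'
#' @param input a `roi_volume_table`, a TSV path, or a [cohort_spec()];
#'   `NULL` falls back to a small demo cohort.
#' @param out_dir output directory.
#' @param grid a [density_grid()].
#' @param disconnected_policy path-length policy.
#' @param attack_kinds resilience analyses to run.
#' @param n_random_sequences removal orders for random failure.
#' @param n_permutations,tails,direction permutation settings.
#' @param q FDR level for regional results.
#' @param seed master seed.
#' @param residualize_on covariates to residualize volumes on before
#'   correlation (default none, matching the canonical pipeline).
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL,
                       out_dir = tempfile("scnet_run_"),
                       grid = density_grid(),
                       disconnected_policy = "connected_pairs",
                       attack_kinds = c("targeted_betweenness", "random"),
                       n_random_sequences = 50,
                       n_permutations = 1000,
                       tails = "one",
                       direction = "greater",
                       q = 0.05,
                       seed = 1L,
                       residualize_on = character()) {
    if (!inherits(grid, "density_grid"))
        abort_scnet("grid must be a density_grid", "scnet_validation_error")
    if (!disconnected_policy %in% c("connected_pairs", "harmonic"))
        abort_scnet("unknown disconnected_policy", "scnet_validation_error")
    if (!all(attack_kinds %in% c("targeted_betweenness", "random")))
        abort_scnet("unknown attack kind", "scnet_validation_error")
    structure(list(input = input, out_dir = out_dir, grid = grid,
                   disconnected_policy = disconnected_policy,
                   attack_kinds = attack_kinds,
                   n_random_sequences = n_random_sequences,
                   n_permutations = n_permutations, tails = tails,
                   direction = direction, q = q, seed = as.integer(seed),
                   residualize_on = residualize_on),
              class = "run_config")
}

#' Build a run configuration from a YAML file
#'
#' Top-level keys: `cohort` (see [cohort_spec_from_yaml()]) or
#' `input_tsv`, plus optional `grid: {d_min, d_max, step}`,
#' `disconnected_policy`, `attack_kinds`, `n_random_sequences`,
#' `n_permutations`, `tails`, `direction`, `q`, `seed`, `out_dir`,
#' `residualize_on`.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file.
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path, overrides = list()) {
    cfg <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, overrides)
    g <- cfg$grid %||% list()
    grid <- density_grid(g$d_min %||% 0.10, g$d_max %||% 0.50,
                         g$step %||% 0.02)
    input <- if (!is.null(cfg$input_tsv)) cfg$input_tsv
             else if (!is.null(cfg$cohort)) cohort_spec_from_yaml(cfg)
    run_config(input = input,
               out_dir = cfg$out_dir %||% tempfile("scnet_run_"),
               grid = grid,
               disconnected_policy = cfg$disconnected_policy %||% "connected_pairs",
               attack_kinds = unlist(cfg$attack_kinds %||%
                                         c("targeted_betweenness", "random")),
               n_random_sequences = cfg$n_random_sequences %||% 50,
               n_permutations = cfg$n_permutations %||% 1000,
               tails = cfg$tails %||% "one",
               direction = cfg$direction %||% "greater",
               q = cfg$q %||% 0.05,
               seed = cfg$seed %||% 1L,
               residualize_on = unlist(cfg$residualize_on %||% character()))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        abort_scnet(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)))
    })
}

.write_json <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: cohort (simulate or load) -> association matrices -> density
#' sweeps -> metric curves -> resilience curves -> permutation comparisons
#' -> manifest.  Deterministic given an identical configuration.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; all artifacts are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
    if (!inherits(config, "run_config"))
        abort_scnet("config must be a run_config", "scnet_validation_error")
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$out_dir, ...)

    table <- .stage("cohort", {
        inp <- config$input
        if (is.null(inp)) inp <- default_cohort_spec(n_rois = 30,
                                                     seed = config$seed)
        tab <- if (inherits(inp, "roi_volume_table")) inp
               else if (inherits(inp, "cohort_spec")) generate_cohort(inp)
               else if (is.character(inp)) read_roi_table(inp)
               else abort_scnet("unsupported input type")
        write_roi_table(tab, out("cohort.tsv"))
        tab
    })
    if (length(config$residualize_on))
        table <- .stage("residualize",
                        residualize(table, config$residualize_on))
    lev <- group_levels(table)

    assoc <- .stage("association", {
        a <- lapply(lev, function(g) group_association_matrix(table, g))
        names(a) <- lev
        for (g in lev) {
            m <- a[[g]]$matrix
            dimnames(m) <- list(NULL, a[[g]]$roi_names)
            write.table(m, out(sprintf("association_%s.tsv", g)),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            .write_json(list(group = g, n_subjects = a[[g]]$n_subjects,
                             n_rois = length(a[[g]]$roi_names),
                             edge_sign = "positive correlations only"),
                        out(sprintf("association_%s.json", g)))
        }
        a
    })

    sweeps <- .stage("threshold",
                     lapply(assoc, density_sweep, grid = config$grid))

    .stage("metrics", {
        rows <- list()
        for (g in lev) {
            for (mn in c("clustering", "path_length")) {
                cv <- metric_curve(sweeps[[g]], mn,
                                   list(disconnected_policy = config$disconnected_policy))
                rows[[paste(g, mn)]] <- data.frame(
                    metric = mn, group = g, density = cv$densities,
                    value = cv$values)
            }
        }
        tidy <- do.call(rbind, rows)
        write.table(tidy, out("metric_curves.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    })

    .stage("resilience", {
        rows <- list()
        for (g in lev) {
            for (kind in config$attack_kinds) {
                prof <- with_seed(child_seed(config$seed, 17L),
                    .group_resilience_profile(
                        volume_matrix(table, g), config$grid,
                        kind, config$n_random_sequences))
                rows[[paste(g, kind)]] <- data.frame(
                    group = g, kind = kind, density = config$grid$values,
                    attack_auc = prof)
            }
        }
        write.table(do.call(rbind, rows), out("resilience_profiles.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    })

    comparisons <- .stage("compare", {
        pc <- perm_config(n_permutations = config$n_permutations,
                          tails = config$tails, direction = config$direction,
                          seed = config$seed)
        res <- list()
        for (mn in c("clustering", "path_length")) {
            r <- compare_global_metric(table, mn, config$grid, pc,
                                       config$disconnected_policy)
            res[[mn]] <- list(metric = mn, observed = r$observed,
                              p = r$p_value, n_permutations = r$n_permutations,
                              tails = r$tails, direction = r$direction)
        }
        for (kind in config$attack_kinds) {
            r <- compare_resilience(table, config$grid, kind, pc,
                                    n_random_sequences = min(config$n_random_sequences, 20))
            res[[paste0("resilience_", kind)]] <-
                list(metric = paste0("resilience_", kind),
                     observed = r$observed, p = r$p_value,
                     n_permutations = r$n_permutations, tails = r$tails,
                     direction = r$direction)
        }
        reg <- compare_regional_clustering(table, config$grid, pc,
                                           q = config$q)
        regional <- data.frame(roi = reg$roi_names,
                               observed_diff = reg$observed_diffs,
                               p = reg$p_values,
                               fdr_significant = reg$fdr_significant)
        write.table(regional, out("regional_clustering.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        .write_json(res, out("comparisons.json"))
        res
    })

    manifest <- list(
        package_version = as.character(utils::packageVersion("scnet")),
        seed = config$seed,
        groups = as.list(setNames(as.integer(table(table$group)[lev]), lev)),
        n_rois = length(attr(table, "roi_names")),
        grid = list(d_min = config$grid$d_min, d_max = config$grid$d_max,
                    step = config$grid$step,
                    n_densities = length(config$grid$values)),
        disconnected_policy = config$disconnected_policy,
        attack_kinds = as.list(config$attack_kinds),
        attack_ranking = "static",
        n_random_sequences = config$n_random_sequences,
        n_permutations = config$n_permutations,
        tails = config$tails,
        direction = config$direction,
        fdr_q = config$q,
        residualize_on = as.list(config$residualize_on),
        edge_policy = "positive correlations only; round-half-up edge count; ties by ROI index",
        artifacts = list("cohort.tsv",
                         sprintf("association_%s.tsv", lev[1]),
                         sprintf("association_%s.tsv", lev[2]),
                         "metric_curves.tsv", "resilience_profiles.tsv",
                         "regional_clustering.tsv", "comparisons.json"))
    .write_json(manifest, out("manifest.json"))
    invisible(manifest)
}

#' Render a markdown report for a completed run
#'
#' Assembles a human-readable summary (group matrices, metric curves with
#' p-values, resilience panels, FDR-annotated regional table, and the run's
#' decision ledger of policies and seeds) purely from the artifacts a run
#' wrote; nothing is recomputed.  Missing artifacts are listed and the
#' corresponding section is omitted.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path output markdown path (default `report.md` in `run_dir`).
#' @return the report path, invisibly.
#' @export
report <- function(run_dir, path = file.path(run_dir, "report.md")) {
    mf_path <- file.path(run_dir, "manifest.json")
    if (!file.exists(mf_path))
        abort_scnet("no manifest.json: run the pipeline first")
    mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
    lines <- c("# Structural covariance network analysis report", "",
               sprintf("Package version %s, master seed %d.",
                       mf$package_version, mf$seed),
               "")
    missing <- character()
    have <- function(f) {
        ok <- file.exists(file.path(run_dir, f))
        if (!ok) missing <<- c(missing, f)
        ok
    }
    lines <- c(lines, "## Run parameters", "",
               sprintf("- groups: %s", paste(sprintf("%s (n=%d)",
                                                     names(mf$groups),
                                                     unlist(mf$groups)),
                                             collapse = " vs ")),
               sprintf("- ROIs: %d", mf$n_rois),
               sprintf("- density grid: %.2f to %.2f step %.2f (%d values)",
                       mf$grid$d_min, mf$grid$d_max, mf$grid$step,
                       mf$grid$n_densities),
               sprintf("- path-length policy: %s", mf$disconnected_policy),
               sprintf("- attack ranking: %s; random-failure sequences: %d",
                       mf$attack_ranking, mf$n_random_sequences),
               sprintf("- permutations: %d, %s-tailed (direction: %s), FDR q = %.2f",
                       mf$n_permutations, mf$tails, mf$direction, mf$fdr_q),
               sprintf("- edge policy: %s", mf$edge_policy),
               "")
    if (have("association_control.tsv") || any(grepl("^association_.*tsv$",
                                                     list.files(run_dir)))) {
        lines <- c(lines, "## Association matrices", "")
        for (f in sort(grep("^association_.*\\.tsv$", list.files(run_dir),
                            value = TRUE))) {
            g <- sub("^association_(.*)\\.tsv$", "\\1", f)
            m <- as.matrix(read.delim(file.path(run_dir, f)))
            lines <- c(lines, sprintf(
                "- group **%s**: %d x %d, mean off-diagonal r = %.3f (file `%s`)",
                g, nrow(m), ncol(m), mean(m[upper.tri(m)]), f))
        }
        lines <- c(lines, "")
    }
    if (have("comparisons.json")) {
        cmp <- jsonlite::read_json(file.path(run_dir, "comparisons.json"),
                                   simplifyVector = TRUE)
        lines <- c(lines, "## Group comparisons (AUC permutation tests)", "",
                   "| metric | observed diff | p |", "|---|---|---|")
        for (nm in names(cmp))
            lines <- c(lines, sprintf("| %s | %.5f | %.4f |",
                                      cmp[[nm]]$metric, cmp[[nm]]$observed,
                                      cmp[[nm]]$p))
        lines <- c(lines, "")
    }
    if (have("resilience_profiles.tsv")) {
        rp <- read.delim(file.path(run_dir, "resilience_profiles.tsv"))
        lines <- c(lines, "## Resilience", "",
                   "Per-density attack-curve AUC summaries:", "")
        agg <- aggregate(attack_auc ~ group + kind, rp, mean)
        for (i in seq_len(nrow(agg)))
            lines <- c(lines, sprintf("- %s / %s: mean per-density AUC %.4f",
                                      agg$group[i], agg$kind[i],
                                      agg$attack_auc[i]))
        lines <- c(lines, "")
    }
    if (have("regional_clustering.tsv")) {
        reg <- read.delim(file.path(run_dir, "regional_clustering.tsv"))
        reg <- reg[order(reg$p, reg$roi), ]
        lines <- c(lines, "## Regional clustering (top 10 by p, then ROI name)",
                   "", "| ROI | observed diff | p | FDR significant |",
                   "|---|---|---|---|")
        for (i in seq_len(min(10, nrow(reg))))
            lines <- c(lines, sprintf("| %s | %.5f | %.4f | %s |",
                                      reg$roi[i], reg$observed_diff[i],
                                      reg$p[i], reg$fdr_significant[i]))
        lines <- c(lines, "")
    }
    if (length(missing))
        lines <- c(lines, "## Missing artifacts", "",
                   paste0("- ", missing), "")
    writeLines(lines, path)
    invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `extract`, `build`, `metrics`, `resilience`,
#' `compare`, `report`, `all`.  Flags: `--config <yaml>`, `--seed <int>`,
#' `--out <dir>`, `--permutations <int>`, `--grid d_min,d_max,step`,
#' `--tails one|two`, `--attack targeted_betweenness,random`,
#' `--log-level quiet|info`.
#'
#' @param args character vector of CLI arguments (defaults to the process
#'   command line).
#' @return exit code: 0 ok, 1 validation error, 2 runtime error.
#' @export
scnet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
    parse_flags <- function(a) {
        flags <- list()
        i <- 1
        while (i <= length(a)) {
            if (startsWith(a[i], "--")) {
                flags[[substring(a[i], 3)]] <- if (i < length(a)) a[i + 1] else ""
                i <- i + 2
            } else i <- i + 1
        }
        flags
    }
    run <- function() {
        if (length(args) == 0)
            abort_scnet("usage: scnet <simulate|extract|build|metrics|resilience|compare|report|all> [--config file] [--seed n] [--out dir] ...",
                        "scnet_validation_error")
        cmd <- args[1]
        fl <- parse_flags(args[-1])
        log_info <- !identical(fl[["log-level"]], "quiet")
        say <- function(...) if (log_info) message(sprintf(...))
        overrides <- list()
        if (!is.null(fl$seed)) overrides$seed <- as.integer(fl$seed)
        if (!is.null(fl$out)) overrides$out_dir <- fl$out
        if (!is.null(fl$permutations))
            overrides$n_permutations <- as.integer(fl$permutations)
        if (!is.null(fl$tails)) overrides$tails <- fl$tails
        if (!is.null(fl$attack))
            overrides$attack_kinds <- strsplit(fl$attack, ",")[[1]]
        if (!is.null(fl$grid)) {
            gv <- as.numeric(strsplit(fl$grid, ",")[[1]])
            overrides$grid <- list(d_min = gv[1], d_max = gv[2], step = gv[3])
        }
        cfg <- if (!is.null(fl$config)) run_config_from_yaml(fl$config, overrides)
               else do.call(run_config, c(
                   overrides[setdiff(names(overrides), "grid")],
                   if (!is.null(overrides$grid))
                       list(grid = do.call(density_grid, overrides$grid))))
        switch(cmd,
            simulate = {
                spec <- if (inherits(cfg$input, "cohort_spec")) cfg$input
                        else default_cohort_spec(seed = cfg$seed)
                dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
                p <- write_roi_table(generate_cohort(spec),
                                     file.path(cfg$out_dir, "cohort.tsv"))
                say("wrote %s", p)
            },
            extract = {
                abort_scnet("extract requires --config with atlas/gm_maps paths; see load_parcellation()/extract_roi_volumes()",
                            "scnet_validation_error")
            },
            build = ,
            metrics = ,
            resilience = ,
            compare = ,
            all = {
                run_pipeline(cfg)
                say("pipeline complete: %s", cfg$out_dir)
                if (cmd == "all") report(cfg$out_dir)
            },
            report = {
                report(fl$out %||% cfg$out_dir)
            },
            abort_scnet(sprintf("unknown subcommand '%s'", cmd),
                        "scnet_validation_error"))
        0L
    }
    tryCatch(run(),
             scnet_validation_error = function(e) {
                 message("validation error: ", conditionMessage(e)); 1L },
             error = function(e) {
                 message("error: ", conditionMessage(e)); 2L })
}
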