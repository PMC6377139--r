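# Global and nodal graph metrics with random-network normalization and
# density-curve AUC summaries.
#
# Metrics are computed by compiled kernels (Brandes betweenness, per-source
# BFS, triangle counting); the test suite checks them against brute-force
# oracles on small random graphs.

.net_edges <- function(net) {
    if (!inherits(net, "binary_network"))
        abort_scnet("expected a binary_network", "scnet_validation_error")
    list(n = net$n_nodes, i = as.integer(net$edges[, 1]),
         j = as.integer(net$edges[, 2]))
}

#' Nodal and mean clustering coefficients
#'
#' For a node with degree k >= 2, C_i = 2 t_i / (k (k - 1)) where t_i counts
#' triangles at the node; nodes with degree < 2 have C_i = 0.  The global
#' clustering coefficient is the mean over all nodes.
#'
#' @param net a [binary_network()].
#' @return list with `values` (named per-ROI vector) and `mean`.
#' @export
clustering_coefficients <- function(net) {
    e <- .net_edges(net)
    v <- cpp_local_clustering(e$n, e$i, e$j)
    names(v) <- net$roi_names
    list(values = v, mean = mean(v))
}

#' Characteristic path length
#'
#' Mean shortest-path length over node pairs.  Structural covariance graphs
#' at low density are often disconnected; under the default
#' `"connected_pairs"` policy the mean runs over reachable pairs only, while
#' `"harmonic"` returns 1 / global efficiency with unreachable pairs
#' contributing zero efficiency.
#'
#' @param net a [binary_network()].
#' @param disconnected_policy `"connected_pairs"` (default) or `"harmonic"`.
#' @return the characteristic path length (scalar).
#' @export
characteristic_path_length <- function(net,
                                       disconnected_policy = c("connected_pairs",
                                                               "harmonic")) {
    disconnected_policy <- match.arg(disconnected_policy)
    e <- .net_edges(net)
    if (e$n < 2 || length(e$i) == 0)
        abort_scnet("path length needs >= 2 nodes and >= 1 edge",
                    "scnet_validation_error")
    cpp_path_length(e$n, e$i, e$j,
                    if (disconnected_policy == "connected_pairs") 0L else 1L)
}

#' Betweenness centrality
#'
#' Raw (unnormalized) betweenness: for node v, the sum over unordered pairs
#' (s, t) of the fraction of shortest s-t paths passing through v.  Only the
#' ranking is consumed by targeted attack, and raw counts make small-graph
#' closed forms exact.
#'
#' @param net a [binary_network()].
#' @return named per-ROI numeric vector.
#' @export
betweenness_centrality <- function(net) {
    e <- .net_edges(net)
    v <- cpp_betweenness(e$n, e$i, e$j)
    names(v) <- net$roi_names
    v
}

#' Node degrees
#' @param net a [binary_network()].
#' @return named integer vector.
#' @export
node_degrees <- function(net) {
    e <- .net_edges(net)
    v <- tabulate(c(e$i, e$j), nbins = e$n)
    names(v) <- net$roi_names
    v
}

#' Degree-preserving randomization (double edge swap)
#'
#' Rewires the graph with `n_swaps_factor * |E|` attempted double edge
#' swaps; swaps that would create self-loops or duplicate edges are
#' rejected, so the degree sequence is preserved exactly.  Uses R's RNG:
#' reproducible under `set.seed()` / the `seed` argument.  Graphs admitting
#' no legal swap (e.g. a triangle) come back unchanged.
#'
#' @param net a [binary_network()].
#' @param n_swaps_factor attempted swaps per edge (default 10).
#' @param seed optional integer seed.
#' @return a rewired [binary_network()].
#' @export
degree_preserving_randomize <- function(net, n_swaps_factor = 10, seed = NULL) {
    e <- .net_edges(net)
    if (length(e$i) < 2) return(net)
    edges <- with_seed(seed,
                       cpp_double_edge_swap(e$n, e$i, e$j,
                                            as.integer(ceiling(n_swaps_factor * length(e$i)))))
    binary_network_from_edges(e$n, edges[, 1], edges[, 2],
                              roi_names = net$roi_names,
                              density_requested = net$density_requested)
}

#' Ensemble of degree-preserving random reference networks
#'
#' @param net source [binary_network()].
#' @param n_random ensemble size (default 20, the field convention).
#' @param seed master seed; member k uses child seed `seed + k`.
#' @param n_swaps_factor see [degree_preserving_randomize()].
#' @return object of class `random_ensemble`.
#' @export
random_ensemble <- function(net, n_random = 20, seed = 1L, n_swaps_factor = 10) {
    if (n_random < 1) abort_scnet("n_random must be >= 1",
                                  "scnet_validation_error")
    members <- lapply(seq_len(n_random), function(k)
        degree_preserving_randomize(net, n_swaps_factor,
                                    seed = child_seed(seed, k)))
    structure(list(source = net, n_random = n_random, seed = seed,
                   members = members),
              class = "random_ensemble")
}

#' Global metrics with random-network normalization
#'
#' Computes the clustering coefficient C and characteristic path length L of
#' the network, the ensemble means C_rand and L_rand over degree-preserving
#' random references, and the ratios gamma = C/C_rand, lambda = L/L_rand and
#' small-worldness sigma = gamma/lambda.  When C_rand is 0, gamma (and
#' sigma) are reported as NA rather than infinity.
#'
#' @param net a [binary_network()].
#' @param ensemble a [random_ensemble()] built from `net`.
#' @param disconnected_policy passed to [characteristic_path_length()].
#' @return object of class `global_metrics`: list with C, L, C_rand, L_rand,
#'   gamma, lambda, sigma.
#' @export
normalized_metrics <- function(net, ensemble,
                               disconnected_policy = c("connected_pairs",
                                                       "harmonic")) {
    disconnected_policy <- match.arg(disconnected_policy)
    if (!inherits(ensemble, "random_ensemble") || length(ensemble$members) == 0)
        abort_scnet("ensemble must be a non-empty random_ensemble",
                    "scnet_validation_error")
    C <- clustering_coefficients(net)$mean
    L <- characteristic_path_length(net, disconnected_policy)
    C_rand <- mean(vapply(ensemble$members,
                          function(m) clustering_coefficients(m)$mean, 0))
    L_rand <- mean(vapply(ensemble$members,
                          function(m) characteristic_path_length(m, disconnected_policy),
                          0))
    gamma <- if (C_rand > 0) C / C_rand else NA_real_
    lambda <- if (is.finite(L_rand) && L_rand > 0) L / L_rand else NA_real_
    sigma <- if (!is.na(gamma) && !is.na(lambda)) gamma / lambda else NA_real_
    structure(list(C = C, L = L, C_rand = C_rand, L_rand = L_rand,
                   gamma = gamma, lambda = lambda, sigma = sigma,
                   disconnected_policy = disconnected_policy,
                   n_random = ensemble$n_random),
              class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
    cat(sprintf("<global_metrics> C=%.4f L=%.4f C_rand=%.4f L_rand=%.4f gamma=%.3f lambda=%.3f sigma=%.3f\n",
                x$C, x$L, x$C_rand, x$L_rand, x$gamma, x$lambda, x$sigma))
    invisible(x)
}

# scalar metric evaluators available to metric_curve() and the comparison
# machinery. options: disconnected_policy, n_random, seed, n_swaps_factor.
.metric_value <- function(net, metric_name, options = list()) {
    pol <- options$disconnected_policy %||% "connected_pairs"
    switch(metric_name,
        clustering = clustering_coefficients(net)$mean,
        path_length = characteristic_path_length(net, pol),
        degree = mean(node_degrees(net)),
        gamma = ,
        lambda = ,
        sigma = {
            ens <- random_ensemble(net,
                                   n_random = options$n_random %||% 20,
                                   seed = options$seed %||% 1L,
                                   n_swaps_factor = options$n_swaps_factor %||% 10)
            normalized_metrics(net, ens, pol)[[metric_name]]
        },
        abort_scnet(sprintf("unknown metric '%s'", metric_name),
                    "scnet_validation_error"))
}

#' Metric curve across a density sweep
#'
#' Evaluates a graph metric on every network of a [density_sweep()] and
#' summarizes the curve by its trapezoidal area under the curve over the
#' density grid.  A single-density grid has AUC 0 (zero-width integral).
#'
#' @param sweep a [density_sweep()] result.
#' @param metric_name one of `"clustering"`, `"path_length"`, `"degree"`,
#'   `"gamma"`, `"lambda"`, `"sigma"`, or a function `function(net) scalar`.
#' @param options list of options (`disconnected_policy`, `n_random`,
#'   `seed`, `n_swaps_factor`).
#' @return object of class `metric_curve`: list with `metric_name`,
#'   `densities`, `values`, `auc`.
#' @export
metric_curve <- function(sweep, metric_name, options = list()) {
    if (!inherits(sweep, "density_sweep") || length(sweep) == 0)
        abort_scnet("sweep must be a non-empty density_sweep",
                    "scnet_validation_error")
    densities <- attr(sweep, "grid")$values
    values <- if (is.function(metric_name)) {
        vapply(sweep, metric_name, 0)
    } else {
        vapply(sweep, .metric_value, 0, metric_name = metric_name,
               options = options)
    }
    label <- if (is.function(metric_name)) "custom" else metric_name
    structure(list(metric_name = label, densities = densities,
                   values = values, auc = trapezoid_auc(densities, values)),
              class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
    cat(sprintf("<metric_curve> %s over %d densities [%.2f, %.2f], AUC = %.5f\n",
                x$metric_name, length(x$densities), min(x$densities),
                max(x$densities), x$auc))
    invisible(x)
}

#' Nodal clustering curves across a density sweep
#'
#' Per-ROI clustering coefficient at every density, plus each ROI's AUC —
#' the statistic consumed by the regional group comparison.
#'
#' @param sweep a [density_sweep()] result.
#' @return list with `matrix` (ROIs x densities), `densities`, `auc`
#'   (named per-ROI vector).
#' @export
nodal_clustering_curves <- function(sweep) {
    if (!inherits(sweep, "density_sweep") || length(sweep) == 0)
        abort_scnet("sweep must be a non-empty density_sweep",
                    "scnet_validation_error")
    densities <- attr(sweep, "grid")$values
    mat <- vapply(sweep, function(net) clustering_coefficients(net)$values,
                  numeric(sweep[[1]]$n_nodes))
    mat <- matrix(mat, nrow = sweep[[1]]$n_nodes,
                  dimnames = list(attr(sweep, "roi_names"), NULL))
    auc <- apply(mat, 1, function(v) trapezoid_auc(densities, v))
    list(matrix = mat, densities = densities, auc = auc)
}
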