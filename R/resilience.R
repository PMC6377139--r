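# Network resilience: largest-connected-component trajectories under random
# node failure and betweenness-targeted attack.
#
# The resilience outcome is the relative size of the largest connected
# component (LCC divided by the intact node count) recorded after each node
# removal.  Targeted attack removes nodes in decreasing betweenness of the
# intact network (static ranking; a recomputed mode re-ranks after every
# removal); random failure averages over independent uniformly random
# removal orders.

#' Attack schedule
#'
#' @param kind `"random"` or `"targeted_betweenness"`.
#' @param ranking_mode `"static"` (default: betweenness of the intact
#'   network) or `"recomputed"` (re-ranked after every removal); targeted
#'   attack only.
#' @param n_random_sequences number of random removal orders averaged for
#'   random failure (default 50).
#' @param seed integer seed for random failure.
#' @return object of class `attack_schedule`.
#' @export
attack_schedule <- function(kind = c("targeted_betweenness", "random"),
                            ranking_mode = c("static", "recomputed"),
                            n_random_sequences = 50, seed = 1L) {
    kind <- match.arg(kind)
    ranking_mode <- match.arg(ranking_mode)
    if (n_random_sequences < 1)
        abort_scnet("n_random_sequences must be >= 1", "scnet_validation_error")
    structure(list(kind = kind, ranking_mode = ranking_mode,
                   n_random_sequences = as.integer(n_random_sequences),
                   seed = seed),
              class = "attack_schedule")
}

.resilience_curve <- function(n, relative_lcc, kind) {
    structure(list(fraction_removed = (0:(n - 1)) / n,
                   relative_lcc = relative_lcc,
                   kind = kind,
                   auc = trapezoid_auc((0:(n - 1)) / n, relative_lcc)),
              class = "resilience_curve")
}

#' @export
print.resilience_curve <- function(x, ...) {
    cat(sprintf("<resilience_curve> %s, %d points, AUC = %.4f\n",
                x$kind, length(x$relative_lcc), x$auc))
    invisible(x)
}

# LCC trajectory for one explicit removal order (1-based node indices)
.lcc_trajectory <- function(net, order) {
    e <- .net_edges(net)
    cpp_lcc_trajectory(e$n, e$i, e$j, as.integer(order))
}

#' Targeted-attack resilience curve
#'
#' Nodes are removed one at a time in rank order of decreasing nodal
#' betweenness centrality (ties broken by ROI index).  After each removal
#' the relative LCC is recorded; the curve starts at the intact network.
#'
#' @param net a [binary_network()].
#' @param schedule an [attack_schedule()] with kind `targeted_betweenness`
#'   (default schedule used when omitted).
#' @return object of class `resilience_curve` with `fraction_removed`,
#'   `relative_lcc` and `auc`.
#' @export
targeted_attack_curve <- function(net, schedule = attack_schedule()) {
    if (schedule$kind != "targeted_betweenness")
        abort_scnet("schedule kind must be targeted_betweenness",
                    "scnet_validation_error")
    e <- .net_edges(net)
    n <- e$n
    if (schedule$ranking_mode == "static") {
        btw <- cpp_betweenness(n, e$i, e$j)
        ord <- order(-btw, seq_len(n))
        traj <- cpp_lcc_trajectory(n, e$i, e$j, as.integer(ord))
    } else {
        alive <- rep(TRUE, n)
        traj <- numeric(n)
        adj <- net$adjacency
        for (k in 0:(n - 1)) {
            idx <- which(alive)
            sub <- adj[idx, idx, drop = FALSE]
            ut <- which(upper.tri(sub) & sub == 1, arr.ind = TRUE)
            traj[k + 1] <- max(cpp_lcc_trajectory(length(idx),
                                                  as.integer(ut[, 1]),
                                                  as.integer(ut[, 2]),
                                                  seq_along(idx))[1],
                               1 / length(idx)) * length(idx) / n
            if (k < n - 1) {
                btw <- cpp_betweenness(length(idx), as.integer(ut[, 1]),
                                       as.integer(ut[, 2]))
                drop <- idx[order(-btw, seq_along(idx))[1]]
                alive[drop] <- FALSE
            }
        }
    }
    .resilience_curve(n, traj, "targeted_betweenness")
}

#' Random-failure resilience curve
#'
#' Mean of relative-LCC trajectories over independent uniformly random
#' removal orders.
#'
#' @param net a [binary_network()].
#' @param schedule an [attack_schedule()] with kind `random`.
#' @return object of class `resilience_curve`.
#' @export
random_failure_curve <- function(net, schedule = attack_schedule(kind = "random")) {
    if (schedule$kind != "random")
        abort_scnet("schedule kind must be random", "scnet_validation_error")
    e <- .net_edges(net)
    n <- e$n
    acc <- numeric(n)
    with_seed(schedule$seed, {
        for (s in seq_len(schedule$n_random_sequences)) {
            ord <- sample.int(n)
            acc <- acc + cpp_lcc_trajectory(n, e$i, e$j, as.integer(ord))
        }
    })
    .resilience_curve(n, acc / schedule$n_random_sequences, "random")
}

#' AUC of a resilience curve
#'
#' Trapezoidal integral of the relative LCC over the fraction of removed
#' nodes.  Requires at least two curve points.
#'
#' @param curve a `resilience_curve`.
#' @return scalar AUC.
#' @export
resilience_auc <- function(curve) {
    if (!inherits(curve, "resilience_curve"))
        abort_scnet("expected a resilience_curve", "scnet_validation_error")
    if (length(curve$relative_lcc) < 2)
        abort_scnet("resilience AUC needs at least 2 points",
                    "scnet_validation_error")
    trapezoid_auc(curve$fraction_removed, curve$relative_lcc)
}
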