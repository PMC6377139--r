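# Network construction: group Pearson association matrices and
# density-thresholded binary graphs.
#
# The structural covariance network is a group-level object: edges are
# inter-subject Pearson correlations of regional gray-matter volume, computed
# per group over its subjects, then binarized by keeping the m largest
# positive correlations at each connection density in the sweep.

#' Residualize ROI volumes on covariates
#'
#' Replaces each ROI column by the residuals of an ordinary least-squares fit
#' on an intercept plus the named covariates, computed within the full sample.
#' With an empty covariate list each column is mean-centered
#' (intercept-only regression).  Residualization before correlation is OFF by
#' default in the pipeline; this function is the opt-in pre-step.
#'
#' @param table a `roi_volume_table`.
#' @param covariate_names character vector of covariate column names.
#' @return a `roi_volume_table` with residualized ROI columns.
#' @export
residualize <- function(table, covariate_names = character()) {
    vols <- volume_matrix(table)
    n <- nrow(vols)
    if (length(covariate_names)) {
        missing <- setdiff(covariate_names, names(table))
        if (length(missing))
            abort_scnet(paste0("covariates not in table: ",
                               paste(missing, collapse = ", ")),
                        "scnet_validation_error")
        x <- cbind(`(Intercept)` = 1,
                   as.matrix(as.data.frame(table[covariate_names])))
    } else {
        x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    }
    if (n <= ncol(x))
        abort_scnet("need more subjects than covariates + 1",
                    "scnet_validation_error")
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
        dropped <- colnames(x)[qx$pivot[seq(qx$rank + 1, ncol(x))]]
        abort_scnet(paste0("rank-deficient covariate design; collinear: ",
                           paste(dropped, collapse = ", ")),
                    "scnet_validation_error")
    }
    res <- qr.resid(qx, vols)
    out <- table
    out[attr(table, "roi_names")] <- as.data.frame(res)
    out
}

#' Group association matrix
#'
#' Pairwise Pearson correlation of ROI volumes over the subjects of one
#' group.  A constant ROI column (zero variance) is a hard error naming the
#' ROI: a silent r = 0 would distort the density ranking.
#'
#' @param table a `roi_volume_table`.
#' @param group group label to select.
#' @return an object of class `association_matrix` with fields `matrix`,
#'   `roi_names`, `group`, `n_subjects`.
#' @export
group_association_matrix <- function(table, group) {
    vols <- volume_matrix(table, group = group)
    if (nrow(vols) < 3)
        abort_scnet("need at least 3 subjects per group for correlation",
                    "scnet_validation_error")
    sds <- apply(vols, 2, sd)
    if (any(sds == 0))
        abort_scnet(paste0("constant ROI column(s): ",
                           paste(colnames(vols)[sds == 0], collapse = ", ")),
                    "scnet_constant_column_error")
    m <- cor(vols)
    diag(m) <- 1
    association_matrix(m, roi_names = colnames(vols), group = group,
                       n_subjects = nrow(vols))
}

#' @rdname group_association_matrix
#' @param matrix symmetric correlation matrix with unit diagonal.
#' @param roi_names ordered ROI labels.
#' @param n_subjects number of subjects the matrix was computed from.
#' @export
association_matrix <- function(matrix, roi_names = NULL, group = NA_character_,
                               n_subjects = NA_integer_) {
    if (!is_symmetric_matrix(matrix, tol = 1e-7))
        abort_scnet("association matrix must be symmetric",
                    "scnet_validation_error")
    if (any(abs(diag(matrix) - 1) > 1e-8))
        abort_scnet("association matrix must have unit diagonal",
                    "scnet_validation_error")
    if (is.null(roi_names)) roi_names <- colnames(matrix) %||%
            default_roi_names(nrow(matrix))
    structure(list(matrix = unname(matrix), roi_names = roi_names,
                   group = group, n_subjects = n_subjects),
              class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
    cat(sprintf("<association_matrix> group %s: %d ROIs, %s subjects\n",
                x$group, length(x$roi_names), x$n_subjects))
    invisible(x)
}

#' Connection density grid
#'
#' The default grid follows the field convention for anatomical covariance
#' networks: densities 0.10 to 0.50 in steps of 0.02 (21 values).
#'
#' @param d_min,d_max,step grid parameters with `0 < d_min <= d_max < 1`.
#' @return an object of class `density_grid` with the ordered `values`.
#' @export
density_grid <- function(d_min = 0.10, d_max = 0.50, step = 0.02) {
    check_scalar_number(d_min, "d_min")
    check_scalar_number(d_max, "d_max")
    check_scalar_number(step, "step")
    if (!(d_min > 0 && d_min <= d_max && d_max < 1))
        abort_scnet("require 0 < d_min <= d_max < 1", "scnet_validation_error")
    if (step <= 0) abort_scnet("step must be > 0", "scnet_validation_error")
    k <- floor((d_max - d_min) / step + 1e-9)
    values <- d_min + step * (0:k)
    structure(list(d_min = d_min, d_max = d_max, step = step, values = values),
              class = "density_grid")
}

# ranking of candidate edges: strictly positive upper-triangle correlations,
# ordered by descending r, ties broken by ascending (row, column) index.
# Shared by thresholding and the fast permutation path; the ranking does not
# depend on density, which is what makes sweep edge sets nested.
.edge_ranking <- function(m) {
    n <- nrow(m)
    ut <- which(upper.tri(m), arr.ind = TRUE)  # column-major: ordered by (col, row)
    r <- m[ut]
    pos <- r > 0
    ut <- ut[pos, , drop = FALSE]
    r <- r[pos]
    ord <- order(-r, ut[, 1], ut[, 2])
    list(i = ut[ord, 1], j = ut[ord, 2], r = r[ord], n = n)
}

.target_edge_count <- function(n, d) round_half_up(d * n * (n - 1) / 2)

#' Binarize an association matrix at one connection density
#'
#' The target edge count is `round_half_up(d * N(N-1)/2)`; the m largest
#' strictly positive off-diagonal correlations become edges.  Negative
#' correlations are never admitted: if fewer than m positive correlations
#' exist, all positives become edges, the achieved density is recorded and a
#' warning is raised.  Ties at the cutoff are broken by ascending
#' (row, column) index order.
#'
#' @param A an [association_matrix()] (or plain symmetric matrix).
#' @param d requested connection density in (0, 1).
#' @return an object of class `binary_network`.
#' @export
threshold_at_density <- function(A, d) {
    if (!inherits(A, "association_matrix")) A <- association_matrix(A)
    check_scalar_number(d, "d")
    if (d <= 0 || d >= 1)
        abort_scnet("density must lie in (0, 1)", "scnet_validation_error")
    rk <- .edge_ranking(A$matrix)
    n <- rk$n
    m_target <- .target_edge_count(n, d)
    m_avail <- length(rk$r)
    m_used <- min(m_target, m_avail)
    if (m_avail < m_target)
        warning(sprintf(
            "only %d positive correlations available for %d requested edges; density capped at %.4f",
            m_avail, m_target, m_used / (n * (n - 1) / 2)), call. = FALSE)
    idx <- seq_len(m_used)
    binary_network_from_edges(n, rk$i[idx], rk$j[idx],
                              roi_names = A$roi_names,
                              density_requested = d)
}

#' Construct a binary network
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param roi_names ordered node labels.
#' @param density_requested the density this network was requested at
#'   (NA when built directly).
#' @return an object of class `binary_network` with fields `adjacency`,
#'   `edges` (2-column matrix, i < j), `density_requested`, `density_actual`,
#'   `roi_names`.
#' @export
binary_network <- function(adjacency, roi_names = NULL,
                           density_requested = NA_real_) {
    adjacency <- unname(as.matrix(adjacency))
    if (!is_symmetric_matrix(adjacency, tol = 0))
        abort_scnet("adjacency must be symmetric", "scnet_validation_error")
    if (any(diag(adjacency) != 0))
        abort_scnet("adjacency diagonal must be zero", "scnet_validation_error")
    if (!all(adjacency %in% c(0, 1)))
        abort_scnet("adjacency entries must be 0/1", "scnet_validation_error")
    ut <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
    n <- nrow(adjacency)
    if (is.null(roi_names)) roi_names <- default_roi_names(n)
    structure(list(adjacency = adjacency,
                   edges = unname(ut),
                   n_nodes = n,
                   density_requested = density_requested,
                   density_actual = 2 * nrow(ut) / (n * (n - 1)),
                   roi_names = roi_names),
              class = "binary_network")
}

# internal fast constructor from an edge list (i < j assumed not required)
binary_network_from_edges <- function(n, i, j, roi_names = NULL,
                                      density_requested = NA_real_) {
    ii <- pmin(i, j)
    jj <- pmax(i, j)
    adj <- matrix(0L, n, n)
    adj[cbind(ii, jj)] <- 1L
    adj[cbind(jj, ii)] <- 1L
    if (is.null(roi_names)) roi_names <- default_roi_names(n)
    structure(list(adjacency = adj,
                   edges = cbind(ii, jj, deparse.level = 0),
                   n_nodes = n,
                   density_requested = density_requested,
                   density_actual = 2 * length(ii) / (n * (n - 1)),
                   roi_names = roi_names),
              class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
    cat(sprintf("<binary_network> %d nodes, %d edges, density %.3f (requested %s)\n",
                x$n_nodes, nrow(x$edges), x$density_actual,
                format(x$density_requested)))
    invisible(x)
}

#' Threshold an association matrix across a density grid
#'
#' Because the edge ranking does not depend on density, edge sets are nested:
#' the network at a higher density contains every edge of the networks below
#' it.
#'
#' @param A an [association_matrix()].
#' @param grid a [density_grid()].
#' @return a list of `binary_network`s (class `density_sweep`), one per grid
#'   value, with the grid attached.
#' @export
density_sweep <- function(A, grid = density_grid()) {
    if (!inherits(A, "association_matrix")) A <- association_matrix(A)
    if (!inherits(grid, "density_grid"))
        abort_scnet("grid must be a density_grid", "scnet_validation_error")
    rk <- .edge_ranking(A$matrix)
    n <- rk$n
    m_avail <- length(rk$r)
    capped <- FALSE
    nets <- lapply(grid$values, function(d) {
        m_target <- .target_edge_count(n, d)
        if (m_avail < m_target) capped <<- TRUE
        idx <- seq_len(min(m_target, m_avail))
        binary_network_from_edges(n, rk$i[idx], rk$j[idx],
                                  roi_names = A$roi_names,
                                  density_requested = d)
    })
    if (capped)
        warning("positive-correlation count caps achievable density for part of the sweep",
                call. = FALSE)
    structure(nets, grid = grid, roi_names = A$roi_names, group = A$group,
              class = "density_sweep")
}
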