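# Shared internal helpers: validation, numerics, trapezoid integration.

abort_scnet <- function(msg, class = "scnet_error", call. = FALSE) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = NULL)))
}

#' Round half away from zero
#'
#' Deterministic rounding used for target edge counts: `round_half_up(400.5)`
#' is 401 on every platform, unlike banker's rounding in [base::round()].
#'
#' @param x numeric vector (assumed nonnegative in this package's use).
#' @return integer vector.
#' @export
round_half_up <- function(x) {
    as.integer(floor(x + 0.5))
}

#' Trapezoidal area under a curve
#'
#' @param x ordered abscissae (e.g. connection densities or fractions of
#'   removed nodes).
#' @param y curve values at `x`.
#' @return the trapezoidal integral; 0 for a single point.
#' @export
trapezoid_auc <- function(x, y) {
    if (length(x) != length(y)) abort_scnet("x and y lengths differ")
    if (length(x) < 2) return(0)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

is_symmetric_matrix <- function(m, tol = 1e-8) {
    is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

check_scalar_number <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        abort_scnet(sprintf("%s must be a single finite number", name))
    invisible(x)
}

default_roi_names <- function(n) sprintf("ROI%03d", seq_len(n))

# seed handling: callers pass a master seed; sampling streams derive child
# seeds by fixed offsets so streams stay independent of one another's sizes.
child_seed <- function(seed, offset) {
    (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

with_seed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}
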