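# Brute-force oracles for graph metrics, independent of the compiled
# kernels: triangle enumeration for clustering, per-pair BFS for path
# length, exhaustive shortest-path enumeration for betweenness.

net_from_edges <- function(n, edges) {
    a <- matrix(0, n, n)
    for (e in edges) {
        a[e[1], e[2]] <- 1
        a[e[2], e[1]] <- 1
    }
    binary_network(a)
}

complete_net <- function(n) binary_network(matrix(1, n, n) - diag(n))

random_net <- function(n, p) {
    a <- matrix(0, n, n)
    ut <- which(upper.tri(a))
    a[ut] <- rbinom(length(ut), 1, p)
    a <- a + t(a)
    binary_network(a)
}

oracle_clustering <- function(net) {
    a <- net$adjacency
    n <- nrow(a)
    sapply(seq_len(n), function(u) {
        nb <- which(a[u, ] == 1)
        k <- length(nb)
        if (k < 2) return(0)
        t <- 0
        for (i in seq_len(k - 1))
            for (j in (i + 1):k)
                t <- t + a[nb[i], nb[j]]
        2 * t / (k * (k - 1))
    })
}

oracle_bfs_dist <- function(a, s) {
    n <- nrow(a)
    d <- rep(NA_integer_, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
        nxt <- integer()
        for (u in frontier) {
            for (v in which(a[u, ] == 1)) {
                if (is.na(d[v])) {
                    d[v] <- d[u] + 1
                    nxt <- c(nxt, v)
                }
            }
        }
        frontier <- nxt
    }
    d
}

oracle_path_length <- function(net, policy = "connected_pairs") {
    a <- net$adjacency
    n <- nrow(a)
    ds <- unlist(lapply(seq_len(n), function(s) oracle_bfs_dist(a, s)[-s]))
    if (policy == "connected_pairs") {
        mean(ds[!is.na(ds) & ds > 0])
    } else {
        inv <- ifelse(is.na(ds), 0, 1 / ds)
        1 / mean(inv)
    }
}

# all shortest paths from s to t as lists of node sequences
oracle_all_shortest_paths <- function(a, s, t) {
    d <- oracle_bfs_dist(a, s)
    if (is.na(d[t])) return(list())
    walk <- function(v) {
        if (v == s) return(list(s))
        preds <- which(a[v, ] == 1 & d == d[v] - 1)
        out <- list()
        for (p in preds)
            for (path in walk(p))
                out <- c(out, list(c(path, v)))
        out
    }
    walk(t)
}

components_oracle <- function(net) {
    a <- net$adjacency
    n <- nrow(a)
    comp <- rep(NA_integer_, n)
    cid <- 0
    for (s in seq_len(n)) {
        if (!is.na(comp[s])) next
        cid <- cid + 1
        reach <- which(!is.na(oracle_bfs_dist(a, s)))
        comp[reach] <- cid
    }
    comp
}

oracle_betweenness <- function(net) {
    a <- net$adjacency
    n <- nrow(a)
    bc <- numeric(n)
    for (s in seq_len(n - 1)) {
        for (t in (s + 1):n) {
            paths <- oracle_all_shortest_paths(a, s, t)
            if (!length(paths)) next
            for (p in paths) {
                interior <- setdiff(p, c(s, t))
                bc[interior] <- bc[interior] + 1 / length(paths)
            }
        }
    }
    bc
}
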