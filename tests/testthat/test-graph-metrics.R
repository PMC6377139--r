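# Graph metrics vs closed forms and brute-force oracles; rewiring; AUC.

test_that("closed-form graphs give exact metric values", {
    k4 <- complete_net(4)
    expect_equal(clustering_coefficients(k4)$mean, 1)
    expect_equal(characteristic_path_length(k4), 1)

    p4 <- net_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)))
    expect_equal(characteristic_path_length(p4), 10 / 6)

    star <- net_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
    expect_equal(unname(betweenness_centrality(star)), c(6, 0, 0, 0, 0))
    expect_equal(clustering_coefficients(star)$values,
                 rep(0, 5), ignore_attr = TRUE)

    # K4 minus one edge: degree-3 nodes have C = 2/3, degree-2 nodes C = 1
    km <- net_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
    expect_equal(unname(clustering_coefficients(km)$values),
                 c(2 / 3, 2 / 3, 1, 1))
    expect_equal(clustering_coefficients(km)$mean, 5 / 6)

    # 4-cycle: two shortest paths per diagonal pair, each middle node 1/2
    c4 <- net_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    expect_equal(unname(betweenness_centrality(c4)), rep(0.5, 4))

    # path on 3 nodes: middle 1, ends 0
    p3 <- net_from_edges(3, list(c(1, 2), c(2, 3)))
    expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))

    # two disjoint edges: connected-pairs policy counts reachable pairs only
    d2 <- net_from_edges(4, list(c(1, 2), c(3, 4)))
    expect_equal(characteristic_path_length(d2), 1)
    expect_error(characteristic_path_length(net_from_edges(3, list())),
                 class = "scnet_validation_error")
})

test_that("metrics match brute-force oracles on 200 random graphs (n <= 8)", {
    set.seed(99)
    for (rep in 1:200) {
        n <- sample(3:8, 1)
        net <- random_net(n, runif(1, 0.2, 0.8))
        expect_equal(unname(clustering_coefficients(net)$values),
                     oracle_clustering(net), tolerance = 1e-12)
        expect_equal(unname(betweenness_centrality(net)),
                     oracle_betweenness(net), tolerance = 1e-12)
        if (nrow(net$edges) > 0) {
            expect_equal(characteristic_path_length(net, "connected_pairs"),
                         oracle_path_length(net, "connected_pairs"),
                         tolerance = 1e-12)
            expect_equal(characteristic_path_length(net, "harmonic"),
                         oracle_path_length(net, "harmonic"),
                         tolerance = 1e-12)
        }
    }
})

test_that("double edge swap preserves degrees, is seeded, and fixes K3", {
    # K3 admits no legal swap
    k3 <- complete_net(3)
    expect_equal(degree_preserving_randomize(k3, seed = 1)$adjacency,
                 k3$adjacency)

    set.seed(5)
    net <- random_net(20, 0.3)
    deg <- node_degrees(net)
    for (s in 1:5) {
        rw <- degree_preserving_randomize(net, seed = s)
        expect_equal(node_degrees(rw), deg)
        expect_equal(diag(rw$adjacency), rep(0, 20))
    }
    # different seeds give at least one differing member over an ensemble
    e1 <- random_ensemble(net, n_random = 20, seed = 1)
    e2 <- random_ensemble(net, n_random = 20, seed = 2)
    diffs <- mapply(function(a, b) !identical(a$adjacency, b$adjacency),
                    e1$members, e2$members)
    expect_true(any(diffs))
    # same seed reproduces exactly
    e1b <- random_ensemble(net, n_random = 20, seed = 1)
    expect_identical(lapply(e1$members, `[[`, "adjacency"),
                     lapply(e1b$members, `[[`, "adjacency"))
})

test_that("normalized metrics behave on reference cases", {
    # ensemble of an unswappable graph: gamma = lambda = sigma = 1
    k3 <- complete_net(3)
    gm <- normalized_metrics(k3, random_ensemble(k3, n_random = 5, seed = 1))
    expect_equal(gm$gamma, 1)
    expect_equal(gm$lambda, 1)
    expect_equal(gm$sigma, 1)

    # ring lattice (k = 4) is the classic high-clustering construction:
    # rewired references lose clustering, so gamma > 1
    n <- 20
    edges <- list()
    for (i in 1:n) for (s in 1:2)
        edges <- c(edges, list(c(i, (i + s - 1) %% n + 1)))
    ring <- net_from_edges(n, edges)
    gm2 <- normalized_metrics(ring, random_ensemble(ring, n_random = 20,
                                                    seed = 7))
    expect_gt(gm2$gamma, 1)

    # triangle-free star: C = C_rand = 0 -> gamma missing, not infinite
    star <- net_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
    gm3 <- normalized_metrics(star, random_ensemble(star, n_random = 5,
                                                    seed = 1))
    expect_true(is.na(gm3$gamma))
    expect_true(is.na(gm3$sigma))

    expect_error(normalized_metrics(k3, structure(list(members = list()),
                                                  class = "random_ensemble")),
                 class = "scnet_validation_error")
})

test_that("Erdos-Renyi graphs have gamma and lambda near 1", {
    set.seed(31)
    net <- random_net(100, 0.2)
    gm <- normalized_metrics(net, random_ensemble(net, n_random = 20, seed = 2))
    expect_lt(abs(gm$gamma - 1), 0.15)
    expect_lt(abs(gm$lambda - 1), 0.15)
})

test_that("metric curves integrate by trapezoid and AUC is linear", {
    tab <- make_cohort(world_base30(), n_per_group = c(20, 3), seed = 6)
    A <- group_association_matrix(tab, "control")
    grid <- density_grid()
    sweep <- density_sweep(A, grid)

    # constant curve: AUC = width * value
    cv <- metric_curve(sweep, function(net) 2.5)
    expect_equal(cv$auc, 0.40 * 2.5)

    # degree-sum curve is nondecreasing (nested edge sets)
    dg <- metric_curve(sweep, "degree")
    expect_true(all(diff(dg$values) >= 0))

    # AUC linearity
    c1 <- metric_curve(sweep, "clustering")
    c2 <- metric_curve(sweep, "path_length")
    mixed <- metric_curve(sweep, function(net)
        3 * clustering_coefficients(net)$mean -
            2 * characteristic_path_length(net))
    expect_equal(mixed$auc, 3 * c1$auc - 2 * c2$auc, tolerance = 1e-12)

    # single-density grid: zero-width integral
    s1 <- density_sweep(A, density_grid(0.2, 0.2, 0.02))
    expect_equal(metric_curve(s1, "clustering")$auc, 0)

    # nodal clustering curves agree with the global mean
    nc <- nodal_clustering_curves(sweep)
    expect_equal(colMeans(nc$matrix), c1$values, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(mean(nc$auc)), c1$auc, tolerance = 1e-12)
})
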