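# Resilience curves: targeted attack, random failure, AUC.

test_that("targeted attack on closed-form graphs", {
    # K5 stays connected: curve (5-k)/5 and AUC 0.48 by hand trapezoid
    k5 <- complete_net(5)
    tc <- targeted_attack_curve(k5)
    expect_equal(tc$relative_lcc, c(1, 0.8, 0.6, 0.4, 0.2))
    expect_equal(tc$fraction_removed, (0:4) / 5)
    expect_equal(resilience_auc(tc), 0.48)

    # star: the hub goes first, leaving isolated leaves
    star <- net_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
    ts <- targeted_attack_curve(star)
    expect_equal(ts$relative_lcc[1:2], c(1, 0.2))

    # two triangles joined by a bridge node: the bridge has maximal
    # betweenness, and its removal leaves components of size 3
    tt <- net_from_edges(7, list(c(1, 2), c(1, 3), c(2, 3),
                                 c(1, 4), c(4, 5),
                                 c(5, 6), c(5, 7), c(6, 7)))
    btw <- betweenness_centrality(tt)
    expect_equal(unname(which.max(btw)), 4L)
    ttc <- targeted_attack_curve(tt)
    expect_equal(ttc$relative_lcc[2], 3 / 7)
})

test_that("resilience curves satisfy structural invariants", {
    set.seed(17)
    for (rep in 1:20) {
        net <- random_net(sample(8:25, 1), runif(1, 0.15, 0.5))
        n <- net$n_nodes
        tc <- targeted_attack_curve(net)
        expect_true(all(diff(tc$relative_lcc) <= 1e-12))  # nonincreasing
        expect_equal(tc$relative_lcc[n], 1 / n)           # last survivor
        expect_equal(tc$relative_lcc[1],
                     max(table(components_oracle(net))) / n)
        rc <- random_failure_curve(net, attack_schedule("random",
                                                        n_random_sequences = 5,
                                                        seed = rep))
        expect_true(all(diff(rc$relative_lcc) <= 1e-12))
        expect_equal(rc$relative_lcc[n], 1 / n)
    }
})

test_that("random failure equals targeted attack on symmetric graphs and is
           seeded", {
    k5 <- complete_net(5)
    rc <- random_failure_curve(k5, attack_schedule("random",
                                                   n_random_sequences = 3,
                                                   seed = 1))
    expect_equal(rc$relative_lcc, c(1, 0.8, 0.6, 0.4, 0.2))

    e1 <- net_from_edges(2, list(c(1, 2)))
    r1 <- random_failure_curve(e1, attack_schedule("random",
                                                   n_random_sequences = 4,
                                                   seed = 2))
    expect_equal(r1$relative_lcc, c(1, 0.5))

    set.seed(23)
    net <- random_net(30, 0.3)
    sch <- attack_schedule("random", n_random_sequences = 10, seed = 9)
    expect_identical(random_failure_curve(net, sch),
                     random_failure_curve(net, sch))

    # random failure is on average no more damaging than betweenness-
    # targeted removal on a sparse random graph
    ra <- resilience_auc(random_failure_curve(net,
            attack_schedule("random", n_random_sequences = 50, seed = 4)))
    ta <- resilience_auc(targeted_attack_curve(net))
    expect_gte(ra, ta)
})

test_that("recomputed-ranking mode agrees with static mode on graphs with a
           dominant hub and runs on general graphs", {
    star <- net_from_edges(6, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(1, 6)))
    st <- targeted_attack_curve(star)
    rc <- targeted_attack_curve(star, attack_schedule(ranking_mode = "recomputed"))
    expect_equal(rc$relative_lcc, st$relative_lcc)

    set.seed(3)
    net <- random_net(12, 0.35)
    rc2 <- targeted_attack_curve(net, attack_schedule(ranking_mode = "recomputed"))
    expect_true(all(diff(rc2$relative_lcc) <= 1e-12))
    expect_equal(rc2$relative_lcc[1],
                 targeted_attack_curve(net)$relative_lcc[1])
})

test_that("resilience_auc validates input", {
    expect_error(resilience_auc(structure(list(relative_lcc = 1,
                                               fraction_removed = 0,
                                               kind = "x"),
                                          class = "resilience_curve")),
                 class = "scnet_validation_error")
    # constant curve over [0, 0.9]
    cur <- structure(list(fraction_removed = seq(0, 0.9, 0.1),
                          relative_lcc = rep(1, 10), kind = "x"),
                     class = "resilience_curve")
    expect_equal(resilience_auc(cur), 0.9)
})

test_that("hub weakening lowers noiseless-limit targeted-attack resilience", {
    grid <- density_grid()
    noiseless_profile <- function(tgt) {
        sw <- suppressWarnings(density_sweep(association_matrix(tgt$matrix),
                                             grid))
        trapezoid_auc(grid$values,
                      vapply(sw, function(net)
                          resilience_auc(targeted_attack_curve(net)), 0))
    }
    base_auc <- noiseless_profile(world_base40())
    for (mag in c(0.25, 0.5, 0.75, 1)) {
        weakened <- plant_group_difference(world_base40(), "hub_weakening",
                                           mag, 1:13)
        expect_lte(noiseless_profile(weakened), base_auc)
    }

    # single-density variant: weakening the 3 highest-degree ROIs of a
    # 2-module target does not increase the attack AUC at density 0.2
    b2 <- reference_correlation_target(20, 2, 0.6, 0.3, n_reference = 500,
                                       seed = 42)
    net <- threshold_at_density(association_matrix(b2$matrix), 0.2)
    top3 <- order(-node_degrees(net))[1:3]
    w <- plant_group_difference(b2, "hub_weakening", 0.5, top3)
    wnet <- threshold_at_density(association_matrix(w$matrix), 0.2)
    expect_lte(resilience_auc(targeted_attack_curve(wnet)),
               resilience_auc(targeted_attack_curve(net)))
})
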