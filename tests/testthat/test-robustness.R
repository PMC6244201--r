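test_that("attack orders target the expected nodes first", {
  s5 <- star_net(5)
  ord <- attack_order(s5, "degree")
  expect_identical(ord[1], "n01")   # the hub
  p4 <- path_net(4)
  ordb <- attack_order(p4, "betweenness")
  expect_setequal(ordb[1:2], c("n02", "n03"))  # interior nodes
  # static and recomputed orderings share the first removal
  net <- random_net(12, 0.3, seed = 8)
  expect_identical(attack_order(net, "betweenness")[1],
                   attack_order(net, "betweenness", recompute = TRUE)[1])
  expect_identical(attack_order(net, "degree")[1],
                   attack_order(net, "degree", recompute = TRUE)[1])
  expect_error(attack_order(net, "pagerank"), "arg")
  # random strategy is a seeded permutation of the node set
  r1 <- attack_order(net, "random", seed = 3)
  expect_setequal(r1, net$nodes$id)
  expect_identical(r1, attack_order(net, "random", seed = 3))
})

test_that("connectivity-loss curves match hand-computed efficiencies", {
  # K4: efficiency falls from 6 to 3 after one removal
  k4 <- complete_net(4)
  curve <- attack_curve(k4, attack_order(k4, "degree"))
  expect_identical(curve$connectivity_loss[1], 0)
  expect_equal(curve$connectivity_loss[2], 0.5)
  expect_equal(curve$f_star, 3 / 4)
  # star: removing the hub disconnects everything at once
  s5 <- star_net(5)
  cs <- attack_curve(s5, attack_order(s5, "degree"))
  expect_equal(cs$connectivity_loss[2], 1)
  expect_equal(cs$f_star, 1 / 5)
  # complete graphs stay connected until a single node remains
  for (n in 4:10) {
    kn <- complete_net(n)
    expect_equal(attack_curve(kn, attack_order(kn, "degree"))$f_star,
                 (n - 1) / n)
  }
  # loss always starts at 0 and ends at 1; rate sums to the total loss
  net <- random_net(15, 0.25, seed = 9)
  cv <- attack_curve(net, attack_order(net, "betweenness"))
  expect_identical(cv$connectivity_loss[1], 0)
  expect_equal(cv$connectivity_loss[length(cv$connectivity_loss)], 1)
  expect_equal(sum(cv$loss_rate), 1)
  expect_error(attack_curve(net, rep(net$nodes$id[1], 2)), "duplicated")
  expect_error(attack_curve(net, "no_such_node"), "unknown node")
})

test_that("rewiring nulls are seeded and degenerate correctly", {
  net <- random_net(12, 0.3, seed = 11)
  rn0 <- rewiring_null(net, rewire_fraction = 0, n_rewirings = 5,
                       strategy = "degree", seed = 2)
  expect_true(all(rn0$f_star_samples == rn0$f_star_observed))
  rn1 <- rewiring_null(net, rewire_fraction = 0.1, n_rewirings = 10,
                       strategy = "degree", seed = 2)
  rn2 <- rewiring_null(net, rewire_fraction = 0.1, n_rewirings = 10,
                       strategy = "degree", seed = 2)
  expect_identical(rn1$f_star_samples, rn2$f_star_samples)
  expect_length(rn1$f_star_samples, 10L)
  expect_error(rewiring_null(complete_net(5)), "complete")
})

test_that("rewiring preserves density and thus the typical collapse point", {
  tr <- make_truth(40, "dense_robust", 0.8, seed = 12, block_size = 10)
  g <- igraph::graph_from_data_frame(tr$planted_edges[, 1:2], directed = FALSE)
  net <- net_from_graph(g)
  rn <- rewiring_null(net, rewire_fraction = 0.1, n_rewirings = 30,
                      strategy = "degree", seed = 13)
  expect_lt(abs(mean(rn$f_star_samples) - rn$f_star_observed), 0.1)
})

test_that("robustness t-tests match the closed-form Welch statistic", {
  x <- rnorm(20)
  same <- robustness_test(x, x)
  expect_identical(same$p_value, 1)
  # moments (0.92, 0.02) vs (0.78, 0.02) at n = 500: t = 110.68
  exact_moments <- function(m, s, n, seed) {
    set.seed(seed); z <- rnorm(n); m + s * (z - mean(z)) / sd(z)
  }
  a <- exact_moments(0.92, 0.02, 500, 1)
  b <- exact_moments(0.78, 0.02, 500, 2)
  rt <- robustness_test(a, b)
  t_closed <- (0.92 - 0.78) / sqrt(0.02^2 / 500 + 0.02^2 / 500)
  expect_equal(rt$t_statistic, t_closed, tolerance = 1e-6)
  expect_lt(rt$p_value, 1e-10)
  # symmetry in the argument order
  expect_equal(robustness_test(b, a)$p_value, rt$p_value)
  # zero-variance degenerate cases
  expect_identical(robustness_test(rep(0.5, 4), rep(0.5, 4))$p_value, 1)
})

test_that("degree-targeted attacks beat random attacks on hub graphs", {
  # the classic scale-free fragility property, on planted star forests
  worse <- vapply(1:25, function(s) {
    tr <- make_truth(32, "sparse_fragile", 0.7, seed = s)
    g <- igraph::graph_from_data_frame(tr$planted_edges[, 1:2], directed = FALSE)
    net <- net_from_graph(g)
    targeted <- attack_curve(net, attack_order(net, "degree"))$f_star
    rand <- mean(vapply(1:8, function(r) {
      attack_curve(net, attack_order(net, "random", seed = s * 100 + r))$f_star
    }, numeric(1)))
    targeted <= rand
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("planted dense communities are more attack-robust than fragile ones", {
  dense <- make_truth(40, "dense_robust", 0.8, seed = 3, block_size = 10)
  sparse <- make_truth(40, "sparse_fragile", 0.7, seed = 3)
  nets <- lapply(list(dense, sparse), function(tr) {
    net_from_graph(igraph::graph_from_data_frame(tr$planted_edges[, 1:2],
                                                 directed = FALSE))
  })
  for (strat in c("degree", "betweenness")) {
    fs <- vapply(nets, function(net) {
      attack_curve(net, attack_order(net, strat))$f_star
    }, numeric(1))
    expect_gt(fs[1], fs[2])
  }
})
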