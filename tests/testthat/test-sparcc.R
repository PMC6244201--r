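test_that("variation matrix matches brute-force log-ratio variances", {
  ct <- toy_counts()
  t <- variation_matrix(ct, "add_one")
  # features a and b exactly proportional: their log ratio is constant
  expect_identical(t["a", "b"], 0)
  expect_identical(diag(t), c(a = 0, b = 0, c = 0))
  expect_equal(t["a", "c"], t["b", "c"])
  # independent brute-force computation from the add-one fractions
  frac <- sweep(ct$counts + 1, 2, colSums(ct$counts + 1), "/")
  expect_equal(t["a", "c"], var(log(frac["a", ] / frac["c", ])), tolerance = 1e-12)
  # permuting samples leaves t unchanged
  perm <- count_table(ct$counts[, c(3, 1, 4, 2)])
  expect_equal(variation_matrix(perm, "add_one"), t, tolerance = 1e-12)

  expect_error(variation_matrix(count_table(matrix(1L, 3, 1))), ">= 2 samples")
})

test_that("three-component basis variances follow the closed form", {
  # d = 3 is exactly determined: omega_1^2 = (t_12 + t_13 - t_23) / 2
  for (seed in 1:100) {
    set.seed(seed)
    S <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.1
    v <- diag(S)
    t <- outer(v, v, "+") - 2 * S
    diag(t) <- 0
    dimnames(t) <- list(letters[1:3], letters[1:3])
    got <- basis_correlations(t)$omega2
    want <- c((t[1, 2] + t[1, 3] - t[2, 3]) / 2,
              (t[1, 2] + t[2, 3] - t[1, 3]) / 2,
              (t[1, 3] + t[2, 3] - t[1, 2]) / 2)
    expect_equal(unname(got), pmax(want, 1e-6), tolerance = 1e-10)
  }
  expect_error(basis_correlations(matrix(0, 2, 2)), "underdetermined")
})

test_that("exchangeable variation matrices give equal correlations", {
  t <- matrix(0.8, 6, 6); diag(t) <- 0
  rho <- basis_correlations(t, exclusion_threshold = 1)$rho
  off <- rho[upper.tri(rho)]
  expect_true(all(abs(off - off[1]) < 1e-12))
  expect_identical(unname(diag(rho)), rep(1, 6))
})

test_that("uncorrelated truths estimate near-zero correlations", {
  tr <- make_truth(50, "dense_robust", edge_strength = 0, seed = 5)
  g <- generate_counts(tr, n_samples = 500, depth = 15000, seed = 6)
  est <- estimate_correlations(g$table, n_inner = 5, seed = 7)
  expect_lte(mean(abs(est$rho[upper.tri(est$rho)])), 0.1)
})

test_that("estimate_correlations reduces to one pass under add-one", {
  ct <- count_table(matrix(rpois(40, 30) + 1L, 5, 8))
  est <- estimate_correlations(ct, n_inner = 7, seed = 1,
                               pseudocount_policy = "add_one")
  expect_identical(est$n_inner_draws, 1L)
  direct <- basis_correlations(variation_matrix(ct, "add_one"))
  expect_equal(est$rho, direct$rho, tolerance = 1e-12)
  # determinism under the Dirichlet policy
  e1 <- estimate_correlations(ct, n_inner = 5, seed = 42)
  e2 <- estimate_correlations(ct, n_inner = 5, seed = 42)
  expect_identical(e1$rho, e2$rho)
})

test_that("a strongly correlated planted pair is recovered", {
  tr <- make_truth(20, "dense_robust", edge_strength = 0.8, seed = 10,
                   block_size = 2, n_blocks = 1, neg_fraction = 0)
  expect_identical(nrow(tr$planted_edges), 1L)
  g <- generate_counts(tr, n_samples = 200, depth = 15000, seed = 11)
  est <- estimate_correlations(g$table, n_inner = 10, seed = 12)
  pe <- tr$planted_edges
  expect_gt(est$rho[pe$feature_i, pe$feature_j], 0.5)
})

test_that("correlation estimates are compositionally stable", {
  # multiplying a sample's counts by a constant only perturbs the add-one
  # pseudocount, so estimates move by at most a small numerical margin
  set.seed(13)
  cts <- matrix(rpois(8 * 20, 50) + 5L, 8, 20)
  r1 <- estimate_correlations(cts, pseudocount_policy = "add_one")
  cts2 <- cts; cts2[, 3] <- cts2[, 3] * 5L
  r2 <- estimate_correlations(cts2, pseudocount_policy = "add_one")
  expect_lt(max(abs(r1$rho - r2$rho)), 0.02)
})

test_that("bootstrap p-values form the add-one permutation grid", {
  set.seed(3)
  ct <- count_table(matrix(rpois(4 * 12, 30), 4, 12))
  es <- bootstrap_edge_stats(ct, n_boot = 2, seed = 4, n_inner = 1,
                             pseudocount_policy = "add_one", pool_null = FALSE)
  # per-pair null with K = 2 draws: p in {1/3, 2/3, 1}
  expect_true(all(es$p_value %in% c(1 / 3, 2 / 3, 1)))
  expect_true(all(es$p_value > 0 & es$p_value <= 1))
  expect_true(all(es$q_value > 0 & es$q_value <= 1))
  expect_error(bootstrap_edge_stats(ct, n_boot = 1), "n_boot")
  expect_error(bootstrap_edge_stats(ct, boot_fraction = 0), "boot_fraction")
})

test_that("fully shuffled data do not produce confident edges", {
  set.seed(21)
  cts <- matrix(rpois(12 * 30, 40), 12, 30)
  cts <- t(apply(cts, 1, sample))  # destroy any structure
  es <- bootstrap_edge_stats(count_table(cts), n_boot = 20, n_inner = 5, seed = 22)
  expect_gte(min(es$p_value), 1e-4)
  expect_identical(sum(es$q_value <= 0.01), 0L)
})

test_that("planted-edge recovery power is monotone in sample size", {
  tr <- make_truth(16, "dense_robust", edge_strength = 0.8, seed = 30,
                   block_size = 4, n_blocks = 2, neg_fraction = 0)
  pe <- tr$planted_edges
  recovery <- vapply(c(25, 50, 100, 200), function(n) {
    g <- generate_counts(tr, n_samples = n, depth = 10000, seed = 31)
    est <- estimate_correlations(g$table, n_inner = 5, seed = 32)
    mean(abs(est$rho[cbind(pe$feature_i, pe$feature_j)]) > 0.4)
  }, numeric(1))
  expect_true(all(diff(recovery) >= 0))
  expect_gt(recovery[4], recovery[1] - 1e-9)
})
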