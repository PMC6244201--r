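# shared small classification fixtures
rf_fixture <- function(n = 60, d = 30, n_inf = 3, shift = 2.5, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(d * n), d, n,
              dimnames = list(sprintf("V%03d", 1:d), sprintf("s%03d", 1:n)))
  if (n_inf > 0) X[seq_len(n_inf), y == "B"] <- X[seq_len(n_inf), y == "B"] + shift
  list(X = X, y = y)
}

test_that("forest tuning is deterministic and finds separable data easy", {
  fx <- rf_fixture(n = 40, d = 10, n_inf = 1, shift = 8, seed = 2)
  tuned <- tune_forest(fx$X, fx$y, seed = 3)
  expect_identical(tuned$heldout_error, 0)
  # ties resolve to the earliest grid point
  expect_identical(tuned$mtry, tuned$grid_errors$mtry[
    which.min(tuned$grid_errors$error)])
  tuned2 <- tune_forest(fx$X, fx$y, seed = 3)
  expect_identical(tuned[c("mtry", "ntree", "sampsize_frac", "nodesize")],
                   tuned2[c("mtry", "ntree", "sampsize_frac", "nodesize")])
  expect_error(tune_forest(fx$X, factor(rep("A", 40))), "2 classes")
})

test_that("pure-noise labels keep held-out error high", {
  errs <- vapply(1:5, function(s) {
    fx <- rf_fixture(n = 60, d = 50, n_inf = 0, seed = s + 10)
    small_grid <- data.frame(mtry = 7, ntree = 100, sampsize_frac = 0.8,
                             nodesize = 1)
    tune_forest(fx$X, fx$y, grid = small_grid, seed = s)$heldout_error
  }, numeric(1))
  expect_gte(mean(errs), 0.3)
})

test_that("cross-validated elimination finds a small sufficient variable set", {
  fx <- rf_fixture(n = 60, d = 50, n_inf = 5, shift = 3, seed = 4)
  tuned <- list(mtry = 7, ntree = 150, sampsize_frac = 0.8, nodesize = 1)
  sel <- select_variable_count(fx$X, fx$y, tuned, k_folds = 5, seed = 5)
  expect_lte(sel$n_required_variables, 15)
  expect_identical(sel$cv_error_curve$n_variables[1], 50L)
  # leave-one-out on a small toy still returns a valid curve
  fx2 <- rf_fixture(n = 10, d = 6, n_inf = 1, shift = 6, seed = 6)
  sel2 <- select_variable_count(fx2$X, fx2$y, tuned, k_folds = 10, seed = 7)
  expect_true(all(is.finite(sel2$cv_error_curve$error)))
  expect_gte(sel2$n_required_variables, 1)
})

test_that("jackknife ranking selects a dominant variable and is reproducible", {
  fx <- rf_fixture(n = 50, d = 20, n_inf = 1, shift = 6, seed = 8)
  tuned <- list(mtry = 4, ntree = 100, sampsize_frac = 0.8, nodesize = 1)
  jk <- jackknife_rank(fx$X, fx$y, tuned, n_iter = 60, rank_cutoff = 5, seed = 9)
  expect_true("V001" %in% jk$selected_variables)
  expect_lt(jk$geometric_mean_rank["V001"], 2)
  jk2 <- jackknife_rank(fx$X, fx$y, tuned, n_iter = 60, rank_cutoff = 5, seed = 9)
  expect_identical(jk$selected_variables, jk2$selected_variables)
  expect_identical(jk$geometric_mean_rank, jk2$geometric_mean_rank)
  expect_error(jackknife_rank(fx$X, fx$y, tuned, rank_cutoff = 0), "rank_cutoff")
})

test_that("pure-noise variables are almost never selected", {
  # the full two-stage rule: the one-SE cross-validated variable count
  # (which collapses toward 1 on null data) feeds the jackknife cutoff
  tuned <- list(mtry = 5, ntree = 60, sampsize_frac = 0.8, nodesize = 1)
  n_selected <- vapply(1:20, function(s) {
    fx <- rf_fixture(n = 60, d = 30, n_inf = 0, seed = s + 30)
    cv <- select_variable_count(fx$X, fx$y, tuned, k_folds = 4, seed = s)
    jk <- jackknife_rank(fx$X, fx$y, tuned, n_iter = 100,
                         rank_cutoff = cv$n_required_variables, seed = s)
    length(jk$selected_variables)
  }, integer(1))
  expect_gte(mean(n_selected == 0), 0.95)
})

test_that("stronger planted effects never select fewer true variables", {
  tuned <- list(mtry = 6, ntree = 120, sampsize_frac = 0.8, nodesize = 1)
  hits <- vapply(c(1, 2.5, 5), function(shift) {
    fx <- rf_fixture(n = 60, d = 30, n_inf = 3, shift = shift, seed = 40)
    jk <- jackknife_rank(fx$X, fx$y, tuned, n_iter = 80, rank_cutoff = 8,
                         seed = 41)
    sum(sprintf("V%03d", 1:3) %in% jk$selected_variables)
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("model permutation p-values sit on the add-one grid", {
  fx <- rf_fixture(n = 30, d = 8, n_inf = 1, shift = 6, seed = 12)
  tuned <- list(mtry = 3, ntree = 60, sampsize_frac = 0.8, nodesize = 1)
  pt <- model_permutation_test(fx$X, fx$y, tuned, n_perm = 19, seed = 13)
  expect_true(pt$p_value %in% ((1:20) / 20))
  expect_identical(pt$p_value, 1 / 20)  # separable data beat every permutation
  expect_error(model_permutation_test(fx$X, fx$y, tuned, n_perm = 5), "19")
})

test_that("permutation p-values are roughly uniform under random labels", {
  tuned <- list(mtry = 3, ntree = 40, sampsize_frac = 0.8, nodesize = 1)
  ps <- vapply(1:30, function(s) {
    fx <- rf_fixture(n = 24, d = 6, n_inf = 0, seed = 100 + s)
    model_permutation_test(fx$X, fx$y, tuned, n_perm = 19, seed = s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
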