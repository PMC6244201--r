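#' Two-stage random-forest parameter tuning
#'
#' Stage one of the classifier protocol: a grid search over the number of
#' candidate split variables (`mtry`), tree count, per-tree sample size
#' and terminal-node size, scoring each point by total error on a fixed
#' stratified 70/30 train/test split and returning the minimizer (ties go
#' to the earliest grid point, i.e. the smallest parameter values in grid
#' order).
#'
#' @param norm A `normalized_table` or numeric feature x sample matrix
#'   (predictors are features).
#' @param labels Factor (or coercible) of class labels, one per sample;
#'   >= 2 classes with >= 4 samples each.
#' @param grid data.frame with columns `mtry`, `ntree`, `sampsize_frac`,
#'   `nodesize`; a compact default is supplied.
#' @param seed Integer seed (split and forests are deterministic given it).
#' @return list of class `rf_tuning`: `mtry`, `ntree`, `sampsize_frac`,
#'   `nodesize`, `heldout_error`, `grid_errors`.
#' @export
tune_forest <- function(norm, labels, grid = NULL, seed = 1L) {
  X <- predictor_matrix(norm)
  y <- as.factor(labels)
  if (length(y) != nrow(X)) stop_coab("tune_forest: one label per sample required")
  if (nlevels(droplevels(y)) < 2L || any(table(y) < 4L)) {
    stop_coab("tune_forest: need >= 2 classes with >= 4 samples each")
  }
  d <- ncol(X)
  grid <- grid %||% expand.grid(
    mtry = unique(pmax(1L, round(c(sqrt(d), d / 3)))),
    ntree = c(200L, 500L),
    sampsize_frac = c(0.632, 0.8),
    nodesize = c(1L, 5L))
  with_seed(seed, {
    train <- stratified_split(y, 0.70)
    if (nlevels(droplevels(y[train])) < nlevels(droplevels(y))) {
      train <- stratified_split(y, 0.70)  # one resplit attempt
      if (nlevels(droplevels(y[train])) < nlevels(droplevels(y))) {
        stop_coab("tune_forest: a class is absent from the training split")
      }
    }
    errs <- vapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      fit <- randomForest::randomForest(
        x = X[train, , drop = FALSE], y = y[train],
        mtry = min(g$mtry, d), ntree = g$ntree,
        sampsize = max(2L, floor(g$sampsize_frac * sum(train))),
        nodesize = g$nodesize)
      mean(stats::predict(fit, X[!train, , drop = FALSE]) != y[!train])
    }, numeric(1))
    best <- which.min(errs)  # first minimum = smallest grid point tie-break
    structure(list(mtry = grid$mtry[best], ntree = grid$ntree[best],
                   sampsize_frac = grid$sampsize_frac[best],
                   nodesize = grid$nodesize[best],
                   heldout_error = errs[best],
                   grid_errors = cbind(grid, error = errs)),
              class = "rf_tuning")
  })
}

predictor_matrix <- function(norm) {
  v <- if (inherits(norm, "normalized_table")) norm$values else as.matrix(norm)
  t(v)  # samples x features for the classifier
}

stratified_split <- function(y, frac) {
  train <- logical(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    take <- sample(idx, max(1L, round(frac * length(idx))))
    train[take] <- TRUE
  }
  train
}

rf_fit <- function(X, y, tuned, importance = FALSE) {
  randomForest::randomForest(
    x = X, y = y, mtry = min(tuned$mtry, ncol(X)), ntree = tuned$ntree,
    sampsize = max(2L, floor(tuned$sampsize_frac * nrow(X))),
    nodesize = tuned$nodesize, importance = importance)
}

#' Cross-validated variable-count selection
#'
#' Stage two: recursive variable elimination over a halving schedule. In
#' each of `k_folds` folds a forest is fit on the training portion, its
#' permutation importances rank the variables, and forests restricted to
#' the top-k variables (k halving from all variables down to 1) are scored
#' on the held-out fold. The returned `n_required_variables` is the
#' smallest k whose mean CV error is within one standard error of the
#' minimum (the candidate's own fold-to-fold standard error, the variant
#' that stays stable when the error curve is flat relative to CV noise).
#'
#' @param norm Predictors as in [tune_forest()].
#' @param labels Class labels.
#' @param tuned An `rf_tuning` from [tune_forest()].
#' @param k_folds Number of folds (default 10; `k_folds = n` is
#'   leave-one-out).
#' @param seed Integer seed.
#' @return list: `n_required_variables`, `cv_error_curve` (data.frame
#'   `n_variables`, `error`, `se`).
#' @export
select_variable_count <- function(norm, labels, tuned, k_folds = 10L, seed = 1L) {
  X <- predictor_matrix(norm)
  y <- as.factor(labels)
  n <- nrow(X)
  if (n < k_folds) stop_coab("select_variable_count: n_samples >= k_folds required")
  d <- ncol(X)
  schedule <- d
  while (schedule[length(schedule)] > 1L) {
    schedule <- c(schedule, max(1L, schedule[length(schedule)] %/% 2L))
  }
  with_seed(seed, {
    fold <- sample(rep(seq_len(k_folds), length.out = n))
    err <- matrix(NA_real_, k_folds, length(schedule))
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- rf_fit(X[tr, , drop = FALSE], droplevels(y[tr]), tuned,
                    importance = TRUE)
      imp <- randomForest::importance(fit, type = 1L)[, 1L]
      ord <- order(-imp, names(imp))
      for (s in seq_along(schedule)) {
        keep <- ord[seq_len(schedule[s])]
        sub <- rf_fit(X[tr, keep, drop = FALSE], droplevels(y[tr]), tuned)
        pred <- stats::predict(sub, X[!tr, keep, drop = FALSE])
        err[f, s] <- mean(pred != y[!tr])
      }
    }
    m <- colMeans(err)
    se <- apply(err, 2L, stats::sd) / sqrt(k_folds)
    curve <- data.frame(n_variables = schedule, error = m, se = se)
    ok <- schedule[m <= min(m) + pmax(se, se[which.min(m)])]
    list(n_required_variables = min(ok), cv_error_curve = curve)
  })
}

#' Jackknife geometric-mean-rank variable selection
#'
#' The selection stage: `n_iter` jackknife iterations, each fitting a
#' forest on a random 70% of the variables and 70% of the samples (both
#' without replacement), ranking the included variables by permutation
#' importance (rank 1 = most important). Per variable, the geometric mean
#' of its ranks over the iterations that included it; significance from a
#' one-sided binomial test of the fraction of inclusions ranked worse than
#' `rank_cutoff` against 0.5, Benjamini-Hochberg adjusted across
#' variables. Selected variables satisfy `q <= q_threshold` and
#' `geometric_mean_rank < rank_cutoff`.
#'
#' @param norm Predictors as in [tune_forest()].
#' @param labels Class labels.
#' @param tuned An `rf_tuning`.
#' @param n_iter Jackknife iterations (study-scale default 1000; tests run
#'   it at 100-200).
#' @param var_fraction,sample_fraction Subsampling fractions (default 0.70).
#' @param rank_cutoff Rank threshold, typically the
#'   `n_required_variables` from [select_variable_count()].
#' @param q_threshold FDR cut for selection (default 0.001).
#' @param seed Integer seed.
#' @return list of class `rf_selection`: `geometric_mean_rank` (named),
#'   `n_inclusions`, `p_value`, `q_value`, `selected_variables`,
#'   `never_included`, plus the call parameters.
#' @export
jackknife_rank <- function(norm, labels, tuned, n_iter = 1000L,
                           var_fraction = 0.70, sample_fraction = 0.70,
                           rank_cutoff, q_threshold = 0.001, seed = 1L) {
  if (rank_cutoff < 1) stop_coab("jackknife_rank: rank_cutoff must be >= 1")
  X <- predictor_matrix(norm)
  y <- as.factor(labels)
  d <- ncol(X)
  n <- nrow(X)
  vars <- colnames(X)
  n_var <- max(2L, floor(var_fraction * d))
  log_rank_sum <- stats::setNames(numeric(d), vars)
  incl <- stats::setNames(integer(d), vars)
  worse <- stats::setNames(integer(d), vars)
  seeds <- child_seeds(seed, n_iter)
  for (it in seq_len(n_iter)) {
    rk <- with_seed(seeds[it], {
      v <- sample(vars, n_var)
      s <- sample.int(n, max(4L, floor(sample_fraction * n)))
      ys <- droplevels(y[s])
      if (nlevels(ys) < 2L) NULL else {
        fit <- rf_fit(X[s, v, drop = FALSE], ys, tuned, importance = TRUE)
        imp <- randomForest::importance(fit, type = 1L)[, 1L]
        rank(-imp, ties.method = "average")
      }
    })
    if (is.null(rk)) next
    v <- names(rk)
    log_rank_sum[v] <- log_rank_sum[v] + log(rk)
    incl[v] <- incl[v] + 1L
    worse[v] <- worse[v] + as.integer(rk > rank_cutoff)
  }
  never <- vars[incl == 0L]
  used <- incl > 0L
  gmr <- stats::setNames(rep(NA_real_, d), vars)
  gmr[used] <- exp(log_rank_sum[used] / incl[used])
  # one-sided binomial: informative variables should rarely rank worse
  # than the cutoff, i.e. worse/incl well below 1/2
  p <- stats::setNames(rep(NA_real_, d), vars)
  p[used] <- stats::pbinom(worse[used], incl[used], 0.5)
  q <- stats::setNames(rep(NA_real_, d), vars)
  q[used] <- stats::p.adjust(p[used], method = "BH")
  selected <- vars[used & q <= q_threshold & gmr < rank_cutoff]
  structure(list(geometric_mean_rank = gmr, n_inclusions = incl,
                 p_value = p, q_value = q,
                 selected_variables = selected, never_included = never,
                 rank_cutoff = rank_cutoff, q_threshold = q_threshold,
                 n_iter = n_iter, var_fraction = var_fraction,
                 sample_fraction = sample_fraction),
            class = "rf_selection")
}

#' Permutation test of overall model significance
#'
#' Compares the out-of-bag error of the observed-label forest with the OOB
#' errors of forests fit to `n_perm` label permutations:
#' `p = (1 + #[permuted OOB <= observed OOB]) / (1 + n_perm)`.
#'
#' @param norm Predictors as in [tune_forest()].
#' @param labels Class labels.
#' @param tuned An `rf_tuning`.
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed.
#' @return list: `p_value`, `observed_oob`, `null_oob`.
#' @export
model_permutation_test <- function(norm, labels, tuned, n_perm = 999L, seed = 1L) {
  if (n_perm < 19L) stop_coab("model_permutation_test: n_perm must be >= 19")
  X <- predictor_matrix(norm)
  y <- as.factor(labels)
  oob <- function(fit) fit$err.rate[fit$ntree, "OOB"]
  seeds <- child_seeds(seed, n_perm + 1L)
  observed <- with_seed(seeds[1L], oob(rf_fit(X, y, tuned)))
  null <- vapply(seq_len(n_perm), function(i) {
    with_seed(seeds[i + 1L], {
      oob(rf_fit(X, sample(y), tuned))
    })
  }, numeric(1))
  list(p_value = (1 + sum(null <= observed)) / (1 + n_perm),
       observed_oob = observed, null_oob = null)
}
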