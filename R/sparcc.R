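#' Log-ratio variation matrix of a compositional count table
#'
#' The sufficient statistic of basis-correlation inference:
#' `t[i, j] = Var_s(log(x_i(s) / x_j(s)))` over samples `s`, computed on
#' per-sample fraction estimates. Zeros are handled by the pseudocount
#' policy: `"add_one"` forms fractions from `counts + 1` (deterministic),
#' `"dirichlet_draw"` draws fractions from the per-sample Dirichlet
#' posterior under a uniform prior (one draw; callers average over draws).
#'
#' @param table A [count_table()] (or a bare counts matrix).
#' @param pseudocount_policy `"add_one"` or `"dirichlet_draw"`.
#' @return A symmetric non-negative matrix with zero diagonal, class
#'   `variation_matrix` (a plain matrix with an attribute).
#' @export
variation_matrix <- function(table, pseudocount_policy = c("add_one", "dirichlet_draw")) {
  pseudocount_policy <- match.arg(pseudocount_policy)
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (ncol(counts) < 2L) {
    stop_coab("variation_matrix: need >= 2 samples (variance undefined)")
  }
  if (nrow(counts) < 2L) stop_coab("variation_matrix: need >= 2 features")
  frac <- compositional_fractions(counts, pseudocount_policy)
  t_from_fractions(frac)
}

compositional_fractions <- function(counts, policy) {
  if (policy == "add_one") {
    x <- counts + 1
    sweep(x, 2L, colSums(x), "/")
  } else {
    # one Dirichlet(counts + 1) posterior draw per sample
    g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
                nrow = nrow(counts), dimnames = dimnames(counts))
    sweep(g, 2L, colSums(g), "/")
  }
}

t_from_fractions <- function(frac) {
  L <- log(frac)
  C <- stats::cov(t(L))
  v <- diag(C)
  t <- outer(v, v, "+") - 2 * C
  t[t < 0] <- 0  # numerical guard; exact zeros for proportional features
  diag(t) <- 0
  dimnames(t) <- list(rownames(frac), rownames(frac))
  t
}

#' Solve for basis variances and correlations from a variation matrix
#'
#' Under the sparsity assumption that most basis correlations are near
#' zero, the row sums of the variation matrix satisfy an approximately
#' linear system in the basis variances `omega^2`: the coefficient matrix
#' has `d - 1` on the diagonal and 1 elsewhere. Correlations follow from
#' `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j)`,
#' clipped to `[-1, 1]`. Pairs with the single largest `|rho|` above
#' `exclusion_threshold` are then iteratively removed from the system and
#' the solve repeated (up to `max_exclusions` times), the classical
#' strongly-correlated-pair exclusion. For `d = 3` the system is exact and
#' solved in closed form (`omega_1^2 = (t_12 + t_13 - t_23) / 2`, etc.);
#' `d < 3` is underdetermined and rejected.
#'
#' @param t Variation matrix from [variation_matrix()].
#' @param exclusion_threshold Exclude pairs with `|rho|` above this.
#' @param max_exclusions Maximum number of excluded pairs; default
#'   `floor(d / 2)`.
#' @return A list with `omega2` (named non-negative basis variances; values
#'   that solved negative are clipped to 1e-6 and counted in
#'   `n_clipped`), `rho` (symmetric, unit diagonal, clipped), and
#'   `excluded_pairs` (2-column matrix of feature ids).
#' @export
basis_correlations <- function(t, exclusion_threshold = 0.1,
                               max_exclusions = NULL) {
  t <- as.matrix(t)
  d <- nrow(t)
  if (d < 3L) stop_coab("basis_correlations: underdetermined for d < 3")
  ids <- rownames(t) %||% as.character(seq_len(d))
  max_exclusions <- max_exclusions %||% (d %/% 2L)

  if (d == 3L) {
    omega2 <- c((t[1, 2] + t[1, 3] - t[2, 3]) / 2,
                (t[1, 2] + t[2, 3] - t[1, 3]) / 2,
                (t[1, 3] + t[2, 3] - t[1, 2]) / 2)
    res <- rho_from_omega(t, omega2, ids)
    res$excluded_pairs <- matrix(character(), ncol = 2L)
    return(res)
  }

  excl <- matrix(FALSE, d, d)  # excluded pair indicator
  excluded <- matrix(character(), ncol = 2L)
  for (iter in 0:max_exclusions) {
    inc <- !excl
    diag(inc) <- FALSE
    M <- matrix(1, d, d)
    M[excl] <- 0
    diag(M) <- rowSums(inc)
    tt <- t
    tt[excl] <- 0
    omega2 <- tryCatch(solve(M, rowSums(tt)),
                       error = function(e) rep(mean(diag(t)) + 1, d))
    res <- rho_from_omega(t, omega2, ids)
    if (iter == max_exclusions) break
    rho_off <- abs(res$rho)
    rho_off[!inc] <- 0
    m <- max(rho_off)
    if (m <= exclusion_threshold) break
    ij <- which(rho_off == m, arr.ind = TRUE)[1L, ]
    excl[ij[1L], ij[2L]] <- excl[ij[2L], ij[1L]] <- TRUE
    excluded <- rbind(excluded, sort(ids[ij]))
  }
  res$excluded_pairs <- excluded
  res
}

rho_from_omega <- function(t, omega2, ids) {
  n_clipped <- sum(omega2 <= 0)
  omega2 <- pmax(omega2, 1e-6)
  w <- sqrt(omega2)
  rho <- (outer(omega2, omega2, "+") - t) / (2 * outer(w, w))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(ids, ids)
  names(omega2) <- ids
  list(omega2 = omega2, rho = rho, n_clipped = n_clipped)
}

#' Estimate basis correlations from a count table
#'
#' Averages [basis_correlations()] over `n_inner` Dirichlet posterior
#' draws of the per-sample fractions (the standard way of propagating
#' count uncertainty through the estimator). With
#' `pseudocount_policy = "add_one"` the fractions are deterministic, so
#' every draw is identical and `n_inner = 1` suffices.
#'
#' @param table A [count_table()] or counts matrix.
#' @param n_inner Number of Dirichlet draws to average (default 20).
#' @param seed Integer seed; the estimate is deterministic given it.
#' @param pseudocount_policy See [variation_matrix()].
#' @param exclusion_threshold,max_exclusions Passed to [basis_correlations()].
#' @return A list of class `correlation_estimate`: `rho` (averaged,
#'   clipped, unit diagonal), `n_inner_draws`, `excluded_pairs` (from the
#'   last draw), `n_clipped` (total across draws).
#' @export
estimate_correlations <- function(table, n_inner = 20L, seed = 1L,
                                  pseudocount_policy = c("dirichlet_draw", "add_one"),
                                  exclusion_threshold = 0.1,
                                  max_exclusions = NULL) {
  pseudocount_policy <- match.arg(pseudocount_policy)
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (pseudocount_policy == "add_one") n_inner <- 1L
  with_seed(seed, {
    acc <- NULL
    n_clipped <- 0L
    last <- NULL
    for (k in seq_len(n_inner)) {
      frac <- compositional_fractions(counts, pseudocount_policy)
      t <- t_from_fractions(frac)
      last <- basis_correlations(t, exclusion_threshold, max_exclusions)
      acc <- if (is.null(acc)) last$rho else acc + last$rho
      n_clipped <- n_clipped + last$n_clipped
    }
    rho <- acc / n_inner
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    structure(list(rho = rho, n_inner_draws = n_inner,
                   excluded_pairs = last$excluded_pairs,
                   n_clipped = n_clipped),
              class = "correlation_estimate")
  })
}

#' Bootstrap null-model significance for every feature pair
#'
#' Runs the correlation estimator `n_boot` times on resamples of
#' `ceiling(boot_fraction * n)` samples drawn with replacement, and, for
#' each replicate, on the same resample with every feature's counts
#' independently permuted across samples (the null model). Per pair the
#' observed statistic is the median over bootstrap estimates; the add-one
#' permutation p-value is
#' `p = (1 + #[null |rho| >= observed |rho|]) / (1 + #null draws)`,
#' with the null pool shared across pairs by default (see Details), and
#' q-values are Benjamini-Hochberg over all pairs.
#'
#' @details With 50 replicates a per-pair null cannot produce p below
#' 1/51, so a per-pair pool would make an FDR cut at 0.01 vacuous; the
#' default therefore pools the null `|rho|` values of all pairs within
#' each replicate (`pool_null = TRUE`), under which all pairs' permuted
#' correlations are exchangeable. `pool_null = FALSE` gives the per-pair
#' convention.
#'
#' The default `boot_fraction = 1` is the classical full-size bootstrap.
#' Small subsampling fractions (e.g. 0.30) are supported, but with
#' cohort-sized tables (tens of samples) the permutation null of a
#' handful-of-samples estimate is so wide that no pair can reach a 1%
#' FDR, so full-size resampling is the default.
#'
#' @param table A [count_table()] or counts matrix.
#' @param n_boot Bootstrap replicates (default 50).
#' @param boot_fraction Fraction of samples per replicate (default 1, the
#'   standard bootstrap).
#' @param seed Integer seed.
#' @param n_inner,pseudocount_policy Passed to [estimate_correlations()].
#' @param pool_null Pool null draws across pairs (default `TRUE`).
#' @return A data.frame of class `edge_stats` with one row per unordered
#'   pair: `feature_i`, `feature_j`, `rho_obs` (median signed bootstrap
#'   estimate), `rho_abs` (median absolute estimate, the test statistic),
#'   `p_value`, `q_value`. The pooled null `|rho|` draws are attached as
#'   attribute `"null_abs"` for downstream mode thresholding.
#' @export
bootstrap_edge_stats <- function(table, n_boot = 50L, boot_fraction = 1,
                                 seed = 1L, n_inner = 20L,
                                 pseudocount_policy = "dirichlet_draw",
                                 pool_null = TRUE) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (n_boot < 2L) stop_coab("bootstrap_edge_stats: n_boot must be >= 2")
  if (boot_fraction <= 0 || boot_fraction > 1) {
    stop_coab("bootstrap_edge_stats: boot_fraction must lie in (0, 1]")
  }
  n <- ncol(counts)
  d <- nrow(counts)
  m <- ceiling(boot_fraction * n)
  ids <- rownames(counts)
  ut <- upper.tri(matrix(0, d, d))
  seeds <- child_seeds(seed, 3L * n_boot)

  obs <- matrix(NA_real_, sum(ut), n_boot)
  nul <- matrix(NA_real_, sum(ut), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seeds[b], {
      for (try in 1:10) {
        cand <- sample.int(n, m, replace = TRUE)
        if (length(unique(cand)) >= 3L) break
      }
      if (length(unique(cand)) < 3L) {
        stop_coab("bootstrap_edge_stats: could not draw >= 3 distinct samples")
      }
      cand
    })
    tb <- counts[, idx, drop = FALSE]
    rb <- estimate_correlations(tb, n_inner = n_inner, seed = seeds[n_boot + b],
                                pseudocount_policy = pseudocount_policy)
    # null model: each feature's counts permuted independently across the
    # columns of the same bootstrap matrix
    nb <- with_seed(seeds[2L * n_boot + b], {
      t(apply(tb, 1L, sample))
    })
    rn <- estimate_correlations(nb, n_inner = n_inner, seed = seeds[n_boot + b],
                                pseudocount_policy = pseudocount_policy)
    obs[, b] <- rb$rho[ut]
    nul[, b] <- rn$rho[ut]
  }

  rho_obs <- apply(obs, 1L, stats::median)
  rho_abs <- apply(abs(obs), 1L, stats::median)
  null_abs <- abs(nul)
  if (pool_null) {
    pool <- sort(as.vector(null_abs))
    n_null <- length(pool)
    # count of null values >= each observed statistic via binary search
    ge <- n_null - findInterval(rho_abs - 1e-12, pool)
    p <- (1 + ge) / (1 + n_null)
  } else {
    ge <- rowSums(null_abs >= matrix(rho_abs, nrow(null_abs), n_boot) - 1e-12)
    p <- (1 + ge) / (1 + n_boot)
  }
  q <- stats::p.adjust(p, method = "BH")
  pr <- which(ut, arr.ind = TRUE)
  out <- data.frame(
    feature_i = ids[pr[, "row"]],
    feature_j = ids[pr[, "col"]],
    rho_obs = rho_obs,
    rho_abs = rho_abs,
    p_value = p,
    q_value = q,
    stringsAsFactors = FALSE)
  class(out) <- c("edge_stats", "data.frame")
  attr(out, "null_abs") <- as.vector(null_abs)
  attr(out, "n_boot") <- n_boot
  attr(out, "boot_fraction") <- boot_fraction
  out
}
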