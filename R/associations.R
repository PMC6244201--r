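#' Cumulative-sum-scaling (CSS) normalization
#'
#' Per-sample scaling factor: the sum of that sample's counts that are at
#' or below the chosen quantile of its nonzero count distribution, divided
#' by the median of those sums across samples so the factors are centred
#' at 1. Normalized values are `log2(count / factor + 1)`. The quantile
#' defaults to an adaptive choice: walking up a grid of candidate
#' quantiles, the smallest quantile at which the relative change of the
#' median scaling factor between consecutive candidates exceeds the
#' instability tolerance (high quantiles are dominated by a few very
#' abundant features, which is what CSS truncates away).
#'
#' @param table A [count_table()] or counts matrix.
#' @param quantile Fraction in (0, 1], or `NULL` (default) for the
#'   adaptive rule. `quantile = 1` reduces to total-sum scaling.
#' @param tol Relative-change tolerance of the adaptive rule (default 0.02).
#' @return list of class `normalized_table`: `values` (feature x sample,
#'   log2 scale), `scaling_factors` (named, > 0), `quantile_used`.
#' @export
css_normalize <- function(table, quantile = NULL, tol = 0.02) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  depths <- colSums(counts)
  if (any(depths == 0)) {
    stop_coab("css_normalize: sample(s) with all-zero counts: ",
              paste(colnames(counts)[depths == 0], collapse = ", "))
  }
  raw_factor <- function(q) {
    vapply(seq_len(ncol(counts)), function(j) {
      x <- counts[, j]
      nz <- x[x > 0]
      cut <- stats::quantile(nz, q, names = FALSE, type = 7)
      sum(x[x <= cut])
    }, numeric(1))
  }
  if (is.null(quantile)) {
    grid <- seq(0.05, 1, by = 0.05)
    med <- vapply(grid, function(q) stats::median(raw_factor(q)), numeric(1))
    rel <- abs(diff(med)) / pmax(med[-length(med)], .Machine$double.eps)
    unstable <- which(rel > tol)
    quantile <- if (length(unstable)) grid[unstable[1L]] else 0.5
  }
  stopifnot(quantile > 0, quantile <= 1)
  f <- raw_factor(quantile)
  f <- f / stats::median(f)
  if (any(f <= 0)) {
    stop_coab("css_normalize: non-positive scaling factor for sample(s): ",
              paste(colnames(counts)[f <= 0], collapse = ", "))
  }
  values <- log2(sweep(counts, 2L, f, "/") + 1)
  structure(list(values = values,
                 scaling_factors = stats::setNames(f, colnames(counts)),
                 quantile_used = quantile),
            class = "normalized_table")
}

#' Per-feature linear-model associations with phenotype covariates
#'
#' For each feature, fits an ordinary linear model of its normalized
#' (CSS-log2) abundance on one covariate of interest at a time plus the
#' adjuster terms (the standard "corrected by location, BMI and age"
#' design), and reports the covariate coefficient with its two-sided
#' Wald p-value. q-values are Benjamini-Hochberg within each covariate
#' across features. Features with zero variance get coefficient 0 and
#' p = 1. For a factor covariate the coefficient of its first non-reference
#' level is reported.
#'
#' @param norm A `normalized_table` from [css_normalize()] (or a numeric
#'   feature x sample matrix).
#' @param meta data.frame of per-sample metadata with a `sample_id` column
#'   covering every sample in `norm`.
#' @param formula_covariates Character vector of covariates of interest.
#' @param adjusters Character vector of adjustment terms (default none).
#' @return data.frame of class `feature_association`: `feature_id`,
#'   `covariate`, `coefficient`, `standard_error`, `p_value`, `q_value`.
#' @export
fit_feature_glms <- function(norm, meta, formula_covariates,
                             adjusters = character(0)) {
  values <- if (inherits(norm, "normalized_table")) norm$values else as.matrix(norm)
  if (!"sample_id" %in% names(meta)) {
    stop_coab("fit_feature_glms: meta needs a sample_id column")
  }
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing)) {
    stop_coab("fit_feature_glms: metadata missing for sample(s): ",
              paste(utils::head(missing, 5L), collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  terms_all <- unique(c(formula_covariates, adjusters))
  absent <- setdiff(terms_all, names(meta))
  if (length(absent)) {
    stop_coab("fit_feature_glms: covariate(s) not in metadata: ",
              paste(absent, collapse = ", "))
  }
  n_terms <- length(terms_all)
  if (ncol(values) <= n_terms + 2L) {
    stop_coab("fit_feature_glms: need n_samples > n_terms + 2")
  }
  out <- list()
  for (cv in formula_covariates) {
    rhs <- paste(c(cv, setdiff(adjusters, cv)), collapse = " + ")
    mf <- stats::model.frame(stats::as.formula(paste("~", rhs)), data = meta)
    X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), mf)
    if (qr(X)$rank < ncol(X)) {
      aliased <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
      stop_coab("fit_feature_glms: rank-deficient design; aliased term(s): ",
                paste(aliased, collapse = ", "))
    }
    # name of the coefficient for the covariate of interest
    cn <- colnames(X)
    target <- if (cv %in% cn) cv else grep(paste0("^", cv), cn, value = TRUE)[1L]
    XtXinv <- chol2inv(chol(crossprod(X)))
    res <- t(apply(values, 1L, function(y) {
      if (stats::sd(y) == 0) return(c(0, 0, 1))
      fit <- stats::lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      df <- length(y) - fit$rank
      sigma2 <- rss / df
      se <- sqrt(sigma2 * diag(XtXinv))
      names(se) <- cn
      b <- fit$coefficients[target]
      s <- se[target]
      p <- if (s == 0 || !is.finite(s)) 1 else {
        2 * stats::pt(abs(b / s), df, lower.tail = FALSE)
      }
      c(b, s, p)
    }))
    q <- stats::p.adjust(res[, 3L], method = "BH")
    out[[cv]] <- data.frame(
      feature_id = rownames(values),
      covariate = cv,
      coefficient = res[, 1L],
      standard_error = res[, 2L],
      p_value = res[, 3L],
      q_value = q,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("feature_association", "data.frame")
  res
}

#' Features passed on to network inference
#'
#' The handoff rule: features associated with site and/or BMI class at
#' `q <= q_max` in the association table.
#'
#' @param assoc A `feature_association` from [fit_feature_glms()].
#' @param covariates Covariates whose hits qualify
#'   (default `c("site", "bmi_class")`).
#' @param q_max FDR threshold (default 0.1).
#' @return Character vector of feature ids (union over covariates, input
#'   order preserved).
#' @export
select_network_features <- function(assoc, covariates = c("site", "bmi_class"),
                                    q_max = 0.1) {
  hit <- assoc$covariate %in% covariates & assoc$q_value <= q_max
  unique(assoc$feature_id[hit])
}
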