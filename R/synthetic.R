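#' Plant a ground-truth basis-correlation structure for a synthetic cohort
#'
#' Builds a `synthetic_truth` object holding the latent (basis)
#' log-abundance model from which compositional counts are later drawn.
#' Two archetypes mirror the qualitative contrast between a densely
#' connected, attack-robust community and a hub-dominated fragile one:
#'
#' * `dense_robust` — features are grouped into blocks that each load on a
#'   shared latent factor, giving cliques of strong correlations (positive
#'   and, for features with flipped loadings, negative). Cliques have no
#'   cut vertices among their strong edges.
#' * `sparse_fragile` — a forest of hub-and-spoke systems: each hub
#'   feature drives `leaves_per_hub` leaves (leaf = strength x hub +
#'   noise), so hub-leaf correlations equal `edge_strength` while
#'   leaf-leaf correlations are only `edge_strength^2` — below typical
#'   detection at cohort sample sizes. Every planted edge runs through a
#'   hub (a cut vertex), so the recovered graph fragments and loses all
#'   its edges once the hubs are removed.
#'
#' Both constructions are positive semi-definite by design; a nearest-PSD
#' eigenvalue-clipping projection is nevertheless applied and its maximum
#' effect on any planted correlation recorded (an error is raised if the
#' projection moves any planted |rho| by more than 0.1).
#'
#' @param n_features Number of features (>= 4).
#' @param archetype `"dense_robust"` or `"sparse_fragile"`.
#' @param edge_strength Planted |correlation| on the latent log scale,
#'   in (0, 1); 0 is allowed and yields the identity matrix.
#' @param seed Integer seed; identical seeds give identical truths.
#' @param block_size Features per clique for `dense_robust` (default 25, a
#'   guild-sized block: with a ~50-feature common core this plants a
#'   correlation density around one half, the magnitude reported for real
#'   dense stool communities).
#' @param n_blocks Number of cliques / hubs. Defaults to using all features
#'   for `dense_robust` and `max(2, round(n_features/12))` hubs with 7
#'   leaves each for `sparse_fragile`.
#' @param leaves_per_hub Leaves attached to each hub for `sparse_fragile`.
#' @param neg_fraction Fraction of block members given a flipped (negative)
#'   loading under `dense_robust`, producing inhibitory planted edges.
#' @param log_sd Latent log-abundance standard deviation per feature.
#' @param depth Target sequencing depth (reads/sample) recorded in the truth.
#' @return A `synthetic_truth` list: `basis_correlation`, `log_mean`,
#'   `log_sd`, `planted_edges` (data.frame feature_i, feature_j, rho),
#'   `differential_effects`, `covariate_coefficients`, `depth`,
#'   `archetype`, `seed`, `psd_max_shift`.
#' @export
make_truth <- function(n_features, archetype = c("dense_robust", "sparse_fragile"),
                       edge_strength = 0.8, seed = 1L,
                       block_size = 25L, n_blocks = NULL, leaves_per_hub = 7L,
                       neg_fraction = 0.35, log_sd = 1.0, depth = 15000L) {
  archetype <- match.arg(archetype)
  if (n_features < 4L) stop_coab("make_truth: n_features must be >= 4")
  if (edge_strength < 0 || edge_strength >= 1) {
    stop_coab("make_truth: edge_strength must lie in [0, 1)")
  }
  with_seed(seed, {
    ids <- sprintf("ESV_%03d", seq_len(n_features))
    R <- diag(n_features)
    dimnames(R) <- list(ids, ids)
    planted <- data.frame(feature_i = character(), feature_j = character(),
                          rho = numeric(), stringsAsFactors = FALSE)
    if (edge_strength > 0) {
      if (archetype == "dense_robust") {
        nb <- n_blocks %||% max(1L, n_features %/% block_size)
        members <- seq_len(min(nb * block_size, n_features))
        block <- rep(seq_len(nb), each = block_size)[seq_along(members)]
        # factor loadings: sqrt(strength), a fraction flipped negative
        lo <- sqrt(edge_strength) *
          ifelse(stats::runif(length(members)) < neg_fraction, -1, 1)
        for (b in seq_len(nb)) {
          m <- members[block == b]
          l <- lo[block == b]
          R[m, m] <- tcrossprod(l)
          diag(R)[m] <- 1
          pr <- t(utils::combn(seq_along(m), 2L))
          planted <- rbind(planted, data.frame(
            feature_i = ids[m[pr[, 1L]]], feature_j = ids[m[pr[, 2L]]],
            rho = l[pr[, 1L]] * l[pr[, 2L]], stringsAsFactors = FALSE))
        }
      } else {
        nh <- n_blocks %||% max(1L, n_features %/% (1L + leaves_per_hub))
        if (nh * (1L + leaves_per_hub) > n_features) {
          nh <- max(1L, n_features %/% (1L + leaves_per_hub))
        }
        idx <- 1L
        for (h in seq_len(nh)) {
          hub <- idx
          leaves <- idx + seq_len(leaves_per_hub)
          idx <- idx + 1L + leaves_per_hub
          # single-factor star: PSD by construction for any strength < 1
          R[hub, leaves] <- R[leaves, hub] <- edge_strength
          R[leaves, leaves] <- edge_strength^2
          diag(R)[leaves] <- 1
          planted <- rbind(planted, data.frame(
            feature_i = ids[hub], feature_j = ids[leaves],
            rho = edge_strength, stringsAsFactors = FALSE))
        }
      }
    }
    proj <- nearest_psd(R)
    shift <- 0
    if (nrow(planted)) {
      ii <- match(planted$feature_i, ids)
      jj <- match(planted$feature_j, ids)
      shift <- max(abs(proj[cbind(ii, jj)] - R[cbind(ii, jj)]))
      if (shift > 0.1) {
        stop_coab("make_truth: infeasible edge_strength; PSD projection ",
                  sprintf("moved a planted correlation by %.3f", shift))
      }
      planted$rho <- proj[cbind(ii, jj)]
    }
    # 16S-like rank-abundance: a common core carrying ~97% of reads plus
    # a rare tail, so a 1% mean-abundance filter retains a core of tens
    # of features (as in real cohorts) without starving sample depths
    n_common <- round(0.36 * n_features)
    log_mean <- c(stats::rnorm(n_common, mean = 3, sd = 0.25),
                  stats::rnorm(n_features - n_common, mean = -1, sd = 1))
    names(log_mean) <- ids
    structure(list(
      basis_correlation = proj,
      log_mean = log_mean,
      log_sd = rep(log_sd, n_features),
      planted_edges = planted,
      differential_effects = default_differential_effects(ids),
      covariate_coefficients = default_covariate_coefficients(ids),
      depth = as.integer(depth),
      archetype = archetype,
      seed = as.integer(seed),
      psd_max_shift = shift
    ), class = "synthetic_truth")
  })
}

# Site / BMI-class log-fold-changes: the first features carry cohort
# effects (site stronger than bmi, mirroring the study's stronger
# country-of-origin signal); the rest are null.
default_differential_effects <- function(ids) {
  d <- length(ids)
  n_site <- min(d, max(10L, round(d / 3)))
  n_bmi <- min(d, max(6L, round(d / 5)))
  site <- numeric(d)
  bmi <- numeric(d)
  site[seq_len(n_site)] <- rep(c(1.2, -1.2), length.out = n_site)
  bmi[seq_len(n_bmi)] <- rep(c(0.8, -0.8), length.out = n_bmi)
  data.frame(feature_id = ids, site_lfc = site, bmi_lfc = bmi,
             stringsAsFactors = FALSE)
}

# SCFA-like covariate: linear link on the latent log abundance of a few
# designated features plus Gaussian noise.
default_covariate_coefficients <- function(ids) {
  k <- min(3L, length(ids))
  list(covariate = "scfa_total",
       features = ids[seq_len(k)],
       beta = rep(0.8, k), intercept = 5, noise_sd = 0.5)
}

#' Nearest positive semi-definite projection (eigenvalue clipping)
#'
#' Clips negative eigenvalues to zero and rescales to unit diagonal.
#' @param R Symmetric matrix.
#' @param eps Floor for eigenvalues.
#' @return PSD correlation matrix with unit diagonal.
#' @export
nearest_psd <- function(R, eps = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  S <- e$vectors %*% (vals * t(e$vectors))
  D <- 1 / sqrt(diag(S))
  out <- S * tcrossprod(D)
  dimnames(out) <- dimnames(R)
  (out + t(out)) / 2
}

#' Draw compositional counts for one synthetic cohort
#'
#' Logistic-normal + multinomial generator: per sample, latent log basis
#' abundances are drawn from a multivariate normal whose correlation is the
#' planted `basis_correlation` (scaled by `log_sd`), shifted by the cohort's
#' site/BMI log-fold-changes, exponentiated and normalized to fractions,
#' and counts are drawn as one multinomial of size `depth`. This yields
#' exactly the log-ratio structure the basis-correlation estimator assumes.
#'
#' @param truth A [make_truth()] object.
#' @param n_samples Number of samples (>= 2).
#' @param depth Reads per sample (>= 100); defaults to `truth$depth`.
#' @param seed Integer seed.
#' @param site,bmi_class Cohort labels recorded in the metadata; effects of
#'   size `site_lfc` (for `site = "siteB"`) and `bmi_lfc` (for
#'   `bmi_class = "obese"`) from `truth$differential_effects` are added to
#'   the latent means.
#' @param sample_prefix Prefix for generated sample ids.
#' @return A list with `table` (a [count_table()]), `metadata` (data.frame
#'   with sample_id, site, bmi_class, age and the generated covariate) and
#'   `latent` (the latent log-abundance matrix, features x samples, for
#'   validation of the generator itself).
#' @export
generate_counts <- function(truth, n_samples, depth = truth$depth, seed = 1L,
                            site = "siteA", bmi_class = "lean",
                            sample_prefix = "S") {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_samples < 2L) stop_coab("generate_counts: n_samples must be >= 2")
  if (depth < 100L) stop_coab("generate_counts: depth must be >= 100")
  R <- truth$basis_correlation
  d <- nrow(R)
  Sigma <- R * tcrossprod(truth$log_sd)
  ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop_coab("generate_counts: covariance is not PSD")
  # effects applied symmetrically around the baseline (+lfc/2 in siteB /
  # obese, -lfc/2 in siteA / lean) so the full between-group contrast is
  # the stated log-fold-change while group means straddle the baseline
  mu <- truth$log_mean
  eff <- truth$differential_effects
  mu <- mu + (if (identical(site, "siteB")) 0.5 else -0.5) * eff$site_lfc
  mu <- mu + (if (identical(bmi_class, "obese")) 0.5 else -0.5) * eff$bmi_lfc
  with_seed(seed, {
    Y <- t(MASS::mvrnorm(n_samples, mu = mu, Sigma = Sigma))  # d x n
    frac <- apply(Y, 2L, function(y) {
      p <- exp(y - max(y))
      p / sum(p)
    })
    counts <- apply(frac, 2L, function(p) stats::rmultinom(1L, depth, p))
    sid <- sprintf("%s%03d", sample_prefix, seq_len(n_samples))
    dimnames(counts) <- list(rownames(R), sid)
    dimnames(Y) <- dimnames(counts)
    cc <- truth$covariate_coefficients
    covariate <- cc$intercept +
      as.numeric(crossprod(Y[cc$features, , drop = FALSE], cc$beta)) +
      stats::rnorm(n_samples, sd = cc$noise_sd)
    meta <- data.frame(
      sample_id = sid,
      site = site,
      bmi_class = bmi_class,
      age = round(stats::rnorm(n_samples, 35, 6), 1),
      stringsAsFactors = FALSE)
    meta[[cc$covariate]] <- covariate
    list(table = count_table(counts), metadata = meta, latent = Y)
  })
}

#' Simulate the full 2-site x 2-BMI-class synthetic study
#'
#' Four cohorts in a 2x2 design: the "lean siteA" cohort receives the
#' `dense_robust` planted network and the other three `sparse_fragile`,
#' mirroring a study contrast in which one community is markedly denser and
#' more attack-robust than the rest. Cohort-specific differential effects
#' and covariates come from the shared effect table so that cross-cohort
#' feature associations are estimable.
#'
#' @param n_features Features per cohort table (shared feature set).
#' @param cohort_sizes Named integer vector of samples per cohort; the
#'   default is the balanced 4 x 25 design, and
#'   `preset = "imbalanced"` gives the 29/21/13/37 split.
#' @param depth Reads per sample.
#' @param edge_strength Planted |correlation| for both archetypes.
#' @param seed Master seed.
#' @param preset `"balanced"` or `"imbalanced"`.
#' @return A list with `table` (combined [count_table()]), `metadata`,
#'   `truths` (named list of per-cohort `synthetic_truth`), and `cohorts`
#'   (named list mapping cohort -> sample ids).
#' @export
generate_study <- function(n_features = 150L,
                           cohort_sizes = NULL,
                           depth = 15000L, edge_strength = 0.8, seed = 1L,
                           preset = c("balanced", "imbalanced")) {
  preset <- match.arg(preset)
  design <- data.frame(
    cohort = c("siteA_lean", "siteA_obese", "siteB_lean", "siteB_obese"),
    site = c("siteA", "siteA", "siteB", "siteB"),
    bmi_class = c("lean", "obese", "lean", "obese"),
    stringsAsFactors = FALSE)
  if (is.null(cohort_sizes)) {
    cohort_sizes <- if (preset == "balanced") {
      stats::setNames(rep(25L, 4L), design$cohort)
    } else {
      stats::setNames(c(29L, 21L, 13L, 37L), design$cohort)
    }
  }
  seeds <- child_seeds(seed, 8L)
  truths <- list()
  tabs <- list()
  metas <- list()
  for (k in seq_len(nrow(design))) {
    arch <- if (design$cohort[k] == "siteA_lean") "dense_robust" else "sparse_fragile"
    # hub-and-spoke strength is capped by positive semi-definiteness at
    # 1/sqrt(leaves); with 2 leaves per hub that is ~0.707
    strength <- if (arch == "dense_robust") edge_strength else min(edge_strength, 0.7)
    truths[[design$cohort[k]]] <- make_truth(
      n_features, archetype = arch, edge_strength = strength,
      seed = seeds[k], depth = depth)
    if (k > 1L) {
      # cohorts differ only in their planted correlation structure; the
      # baseline abundances, differential effects and covariate link are
      # shared so cross-cohort feature associations are well defined
      truths[[k]]$log_mean[] <- truths[[1L]]$log_mean
      truths[[k]]$differential_effects <- truths[[1L]]$differential_effects
      truths[[k]]$covariate_coefficients <- truths[[1L]]$covariate_coefficients
    }
    g <- generate_counts(truths[[design$cohort[k]]],
                         n_samples = cohort_sizes[[design$cohort[k]]],
                         depth = depth, seed = seeds[4L + k],
                         site = design$site[k], bmi_class = design$bmi_class[k],
                         sample_prefix = paste0(design$cohort[k], "_"))
    tabs[[k]] <- g$table$counts
    metas[[k]] <- g$metadata
  }
  counts <- do.call(cbind, tabs)
  meta <- do.call(rbind, metas)
  meta$cohort <- rep(design$cohort, vapply(metas, nrow, 1L))
  list(table = count_table(counts), metadata = meta, truths = truths,
       cohorts = split(meta$sample_id, meta$cohort))
}

#' Write a synthetic truth object to JSON
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- unclass(truth)
  out$basis_correlation <- NULL
  out$basis_correlation_values <- as.vector(truth$basis_correlation)
  out$feature_ids <- rownames(truth$basis_correlation)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
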