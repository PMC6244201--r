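#' Resolve a pipeline configuration
#'
#' Fills every stage parameter with its study-mirroring default: 50
#' bootstrap replicates over 30% subsamples, edge FDR 0.01, feature FDR
#' 0.1, 10% edge rewiring with 500 replicates, 1000 jackknife iterations,
#' and a single master seed from which all stage seeds derive. Accepts a
#' YAML file path or a named list; unknown keys are rejected so typos do
#' not silently fall back to defaults.
#'
#' @param config Path to a YAML file, a named list, or `NULL` for pure
#'   defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    counts = NULL,              # path to count TSV, or a count_table
    metadata = NULL,            # path to metadata TSV, or a data.frame
    cohort_columns = c("site", "bmi_class"),
    min_sample_depth = 10100L,
    min_max_count = 10L,
    min_mean_rel_abund = 0.01,
    css_quantile = NULL,
    covariates = c("site", "bmi_class"),
    adjusters = "age",
    q_features = 0.1,
    n_boot = 50L,
    boot_fraction = 1,
    n_inner = 20L,
    q_edges = 0.01,
    rewire_fraction = 0.10,
    n_rewirings = 500L,
    attack_strategies = c("betweenness", "degree"),
    jackknife_n_iter = 1000L,
    min_cohort_samples = 8L,
    run_rf = FALSE,
    seed = 1L)
  user <- if (is.null(config)) list()
  else if (is_string(config)) yaml::read_yaml(config)
  else as.list(config)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_coab("pipeline_config: unknown parameter(s): ",
              paste(unknown, collapse = ", "),
              class = "coabnet_validation_error")
  }
  out <- utils::modifyList(defaults, user)
  structure(out, class = "pipeline_config")
}

#' Run the full per-cohort co-occurrence analysis
#'
#' The composed workflow: filter the count table, CSS-normalize, fit
#' per-feature associations on the full dataset, select the site/BMI
#' associated features, then per cohort infer basis correlations with
#' bootstrap null significance, build the co-occurrence network
#' (FDR + null-mode dual criterion), summarise its topology, and run the
#' targeted-attack robustness analysis with its rewiring null. Finishes
#' with cross-cohort comparison tables (rank-sum tests on node metrics,
#' Welch t-tests on collapse fractions) and a machine-readable manifest.
#'
#' @param config A [pipeline_config()], or anything it accepts.
#' @param out_dir Run directory; one subdirectory per cohort is created.
#' @return Invisibly, a list with `networks`, `summaries`, `robustness`,
#'   `comparisons`, `features_used`, `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("coabnet_run_")) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (is.null(cfg$counts) || is.null(cfg$metadata)) {
    stop_coab("run_pipeline: config must provide counts and metadata",
              class = "coabnet_validation_error")
  }
  table <- if (inherits(cfg$counts, "count_table")) cfg$counts
  else load_count_table(cfg$counts, format = "tsv")
  meta <- if (is.data.frame(cfg$metadata)) cfg$metadata
  else read_sample_metadata(cfg$metadata)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, cohort, expr) {
    tryCatch(expr, error = function(e) {
      stop_coab("pipeline stage '", name, "' failed",
                if (nzchar(cohort)) paste0(" for cohort '", cohort, "'") else "",
                ": ", conditionMessage(e), class = "coabnet_stage_error")
    })
  }
  seeds <- child_seeds(cfg$seed, 64L)

  filtered <- stage("filter", "", filter_features(
    table, cfg$min_sample_depth, cfg$min_max_count, cfg$min_mean_rel_abund))
  meta <- meta[meta$sample_id %in% sample_ids(filtered), , drop = FALSE]
  norm <- stage("normalize", "", css_normalize(filtered, cfg$css_quantile))
  assoc <- stage("associate", "", fit_feature_glms(
    norm, meta, cfg$covariates, cfg$adjusters))
  feats <- select_network_features(assoc, cfg$covariates, cfg$q_features)
  if (length(feats) < 4L) {
    stop_coab("pipeline stage 'feature selection' failed: fewer than 4 ",
              "features pass q <= ", cfg$q_features, class = "coabnet_stage_error")
  }
  utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(feats, file.path(out_dir, "network_features.txt"))

  cohort_of <- interaction(meta[cfg$cohort_columns], drop = TRUE, sep = "_")
  cohorts <- split(meta$sample_id, cohort_of)
  small <- names(cohorts)[vapply(cohorts, length, 1L) < cfg$min_cohort_samples]
  if (length(small)) {
    stop_coab("run_pipeline: cohort(s) below ", cfg$min_cohort_samples,
              " samples: ", paste(small, collapse = ", "),
              class = "coabnet_validation_error")
  }
  networks <- list()
  summaries <- list()
  node_tabs <- list()
  robustness <- list()
  k <- 0L
  for (ch in names(cohorts)) {
    k <- k + 1L
    cdir <- file.path(out_dir, ch)
    dir.create(cdir, showWarnings = FALSE)
    sub <- count_table(filtered$counts[feats, cohorts[[ch]], drop = FALSE])
    rel <- sweep(sub$counts, 2L, colSums(sub$counts), "/")
    abundance <- rowMeans(rel)
    est <- stage("sparcc", ch, estimate_correlations(
      sub, n_inner = cfg$n_inner, seed = seeds[k]))
    stats_ <- stage("bootstrap", ch, bootstrap_edge_stats(
      sub, n_boot = cfg$n_boot, boot_fraction = cfg$boot_fraction,
      n_inner = cfg$n_inner, seed = seeds[8L + k]))
    net <- stage("network", ch, select_edges(
      stats_, est, q_max = cfg$q_edges, abundance = abundance))
    utils::write.table(
      cbind(feature_id = rownames(est$rho), as.data.frame(est$rho)),
      file.path(cdir, "correlations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(stats_), file.path(cdir, "edge_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(net, file.path(cdir, "network.tsv"), "edge-list")
    if (nrow(net$edges) > 0L) {
      write_network(net, file.path(cdir, "network.graphml"), "graphml")
    }
    networks[[ch]] <- net
    if (nrow(net$nodes) == 0L) next
    smry <- stage("topology", ch, network_summary(net))
    summaries[[ch]] <- smry
    node_tabs[[ch]] <- attr(smry, "node_metrics")
    utils::write.table(as.data.frame(smry), file.path(cdir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(node_tabs[[ch]], file.path(cdir, "node_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rb <- list()
    for (strat in cfg$attack_strategies) {
      ord <- attack_order(net, strat)
      curve <- stage("attack", ch, attack_curve(net, ord))
      utils::write.table(
        data.frame(fraction = curve$fractions_removed,
                   loss = curve$connectivity_loss,
                   rate = c(NA, curve$loss_rate)),
        file.path(cdir, paste0("attack_", strat, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      rb[[strat]] <- stage("rewiring", ch, rewiring_null(
        net, rewire_fraction = cfg$rewire_fraction,
        n_rewirings = cfg$n_rewirings, strategy = strat,
        seed = seeds[16L + 2L * k + (strat == "degree")]))
      rb[[strat]]$curve <- curve
    }
    robustness[[ch]] <- rb
  }

  comparisons <- cross_cohort_comparisons(node_tabs, robustness, summaries)
  for (nmcmp in names(comparisons)) {
    utils::write.table(comparisons[[nmcmp]],
                       file.path(out_dir, paste0(nmcmp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("coabnet")),
    parameters = unclass(cfg)[setdiff(names(cfg), c("counts", "metadata"))],
    seed = cfg$seed,
    cohorts = lapply(cohorts, length),
    features_used = length(feats))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(networks = networks, summaries = summaries,
                 robustness = robustness, comparisons = comparisons,
                 features_used = feats, out_dir = out_dir))
}

cross_cohort_comparisons <- function(node_tabs, robustness, summaries) {
  out <- list()
  chs <- names(node_tabs)
  if (length(chs) >= 2L) {
    pairs <- utils::combn(chs, 2L)
    rows <- list()
    for (metric in c("closeness", "degree", "eigenvector", "betweenness")) {
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1L, p]; b <- pairs[2L, p]
        cm <- compare_cohort_metric(node_tabs[[a]][[metric]],
                                    node_tabs[[b]][[metric]],
                                    normalize = metric == "closeness")
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, cohort_a = a, cohort_b = b,
          mean_a = mean(node_tabs[[a]][[metric]]),
          mean_b = mean(node_tabs[[b]][[metric]]),
          statistic = cm$statistic, p_value = cm$p_value, tied = cm$tied,
          stringsAsFactors = FALSE)
      }
    }
    out$topology_comparisons <- do.call(rbind, rows)
    rows <- list()
    strategies <- unique(unlist(lapply(robustness, names)))
    for (strat in strategies) {
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1L, p]; b <- pairs[2L, p]
        if (is.null(robustness[[a]][[strat]]) || is.null(robustness[[b]][[strat]])) next
        rt <- robustness_test(robustness[[a]][[strat]],
                              robustness[[b]][[strat]])
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strat, cohort_a = a, cohort_b = b,
          f_star_a = robustness[[a]][[strat]]$f_star_observed,
          f_star_b = robustness[[b]][[strat]]$f_star_observed,
          t_statistic = rt$t_statistic, p_value = rt$p_value,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) out$robustness_comparisons <- do.call(rbind, rows)
  }
  if (length(summaries)) {
    out$summary_table <- do.call(rbind, lapply(names(summaries), function(ch) {
      cbind(cohort = ch, as.data.frame(summaries[[ch]]))
    }))
  }
  out
}
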