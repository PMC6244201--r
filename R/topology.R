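#' Node-level topology metrics
#'
#' Standard unweighted, undirected definitions on the simple graph:
#' degree; closeness computed within the node's connected component and
#' scaled by the Wasserman-Faust component-coverage factor,
#' `((r - 1) / sum(distances)) * ((r - 1) / (N - 1))` with `r` the number
#' of reachable nodes — on a connected graph this is the usual
#' `(N - 1) / sum(distances)`, and on a fragmented graph it penalizes
#' small components instead of rewarding them; eigenvector centrality
#' scaled so the maximum is 1; raw (unnormalized) betweenness; hub score
#' (which for an undirected graph coincides with eigenvector centrality,
#' kept as its own column to mirror the usual reporting); and the local
#' clustering coefficient.
#'
#' @param net A [cooccurrence_network()] or igraph graph.
#' @return data.frame: `id`, `degree`, `closeness`, `eigenvector`,
#'   `betweenness`, `hub_score`, `transitivity_local`.
#' @export
node_metrics <- function(net) {
  g <- to_graph(net)
  if (igraph::vcount(g) == 0L) stop_coab("node_metrics: empty graph")
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  deg <- igraph::degree(g)
  N <- igraph::vcount(g)
  comp <- igraph::components(g)
  reach <- comp$csize[comp$membership]
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  if (N > 1L) clo <- clo * (reach - 1) / (N - 1)
  clo[deg == 0] <- 0
  eig <- igraph::eigen_centrality(g, weights = NA)$vector
  btw <- igraph::betweenness(g, normalized = FALSE, weights = NA)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  data.frame(id = ids, degree = as.numeric(deg), closeness = as.numeric(clo),
             eigenvector = as.numeric(eig), betweenness = as.numeric(btw),
             hub_score = as.numeric(eig),
             transitivity_local = as.numeric(loc),
             stringsAsFactors = FALSE)
}

# Unweighted view for graph algorithms: all topology and attack metrics
# are defined on the simple graph, so the signed correlation weight must
# not be picked up as an igraph weight attribute.
to_graph <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) as_igraph(net)
  else if (igraph::is_igraph(net)) net
  else stop_coab("expected a cooccurrence_network or igraph graph")
  if ("weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$correlation <- igraph::E(g)$weight
    g <- igraph::delete_edge_attr(g, "weight")
  }
  g
}

#' Whole-network topology summary
#'
#' Every field of the standard interaction-network topology table:
#' counts, percent activation (positive) and inhibitory (negative) edges,
#' edge density `E / (N(N-1)/2)`, global transitivity (3 x triangles /
#' connected triples), diameter and mean shortest path on the largest
#' connected component, degree extremes, Freeman centralization for
#' degree / closeness / eigenvector / betweenness, community count by
#' greedy modularity maximization, and node-table averages.
#'
#' @param net A [cooccurrence_network()] (signed percentages need the
#'   `sign` edge attribute; a bare igraph graph reports them as `NA`).
#' @return A one-row data.frame of class `network_summary`; the node table
#'   is attached as attribute `"node_metrics"`.
#' @export
network_summary <- function(net) {
  g <- to_graph(net)
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N == 0L) stop_coab("network_summary: empty graph")
  nm <- node_metrics(g)
  signs <- if ("sign" %in% igraph::edge_attr_names(g)) igraph::E(g)$sign else NULL
  pct_pos <- if (is.null(signs) || E == 0L) NA_real_ else 100 * mean(signs == "positive")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  comm <- tryCatch(
    length(igraph::cluster_fast_greedy(igraph::simplify(g), weights = NULL)),
    error = function(e) NA_integer_)
  mean_sp <- igraph::mean_distance(giant, directed = FALSE, weights = NA)
  edge_btw <- if (E > 0L) mean(igraph::edge_betweenness(g, weights = NA)) else NA_real_
  out <- data.frame(
    total_nodes = N,
    number_of_edges = E,
    pct_activation_edges = pct_pos,
    pct_inhibitory_edges = if (is.na(pct_pos)) NA_real_ else 100 - pct_pos,
    edge_density = E / (N * (N - 1) / 2),
    transitivity = igraph::transitivity(g, type = "global"),
    diameter = igraph::diameter(giant, directed = FALSE, weights = NA),
    max_node_degree = max(nm$degree),
    min_node_degree = min(nm$degree),
    degree_centralization = igraph::centr_degree(g, loops = FALSE)$centralization,
    closeness_centralization = suppressWarnings(
      igraph::centr_clo(g)$centralization),
    eigen_centralization = igraph::centr_eigen(g)$centralization,
    betweenness_centralization = igraph::centr_betw(g)$centralization,
    n_communities = comm,
    mean_shortest_path = mean_sp,
    average_node_degree = 2 * E / N,
    average_hub_score = mean(nm$hub_score),
    average_closeness = mean(nm$closeness),
    average_eigenvector = mean(nm$eigenvector),
    average_betweenness = mean(nm$betweenness),
    average_edge_betweenness = edge_btw,
    giant_component_fraction = max(comp$csize) / N,
    community_algorithm = "greedy modularity (fast-greedy)",
    stringsAsFactors = FALSE)
  class(out) <- c("network_summary", "data.frame")
  attr(out, "node_metrics") <- nm
  out
}

#' Rank-sum comparison of a node-level metric between two cohorts
#'
#' Two-sided Wilcoxon rank-sum test on per-node metric values from two
#' networks. `normalize = TRUE` divides each cohort's values by its own
#' maximum first (the "normalized" cross-cohort comparison convention);
#' all-tied input returns p = 1 with a tie flag instead of erroring.
#'
#' @param values_a,values_b Numeric vectors (length >= 3 each).
#' @param normalize Divide each vector by its max before testing.
#' @return list: `statistic` (W), `p_value`, `tied` (logical).
#' @export
compare_cohort_metric <- function(values_a, values_b, normalize = FALSE) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop_coab("compare_cohort_metric: each cohort needs >= 3 values")
  }
  if (normalize) {
    if (max(values_a) > 0) values_a <- values_a / max(values_a)
    if (max(values_b) > 0) values_b <- values_b / max(values_b)
  }
  if (length(unique(c(values_a, values_b))) == 1L) {
    return(list(statistic = NA_real_, p_value = 1, tied = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, tied = FALSE)
}

#' Spearman correlation of node abundance against topology metrics
#'
#' For each node metric, Spearman's rho and p-value of normalized node
#' abundance versus the metric. Constant metrics (rho undefined) are
#' reported as `NA`.
#'
#' @param net A [cooccurrence_network()] with node abundances, or an
#'   igraph graph if `abundances` is given.
#' @param abundances Optional named numeric abundance per node id;
#'   defaults to the network's node annotation.
#' @param metrics Which columns of [node_metrics()] to test.
#' @return data.frame: `metric`, `rho_spearman`, `p_value`.
#' @export
abundance_topology_correlation <- function(net, abundances = NULL,
                                           metrics = c("degree", "closeness",
                                                       "eigenvector", "betweenness",
                                                       "transitivity_local")) {
  nm <- node_metrics(net)
  if (is.null(abundances)) {
    if (!inherits(net, "cooccurrence_network")) {
      stop_coab("abundance_topology_correlation: abundances required")
    }
    abundances <- stats::setNames(net$nodes$abundance, net$nodes$id)
  }
  if (any(!nm$id %in% names(abundances)) || anyNA(abundances[nm$id])) {
    stop_coab("abundance_topology_correlation: abundance missing for some node")
  }
  ab <- abundances[nm$id]
  res <- lapply(metrics, function(m) {
    v <- nm[[m]]
    if (length(unique(v)) == 1L) {
      return(data.frame(metric = m, rho_spearman = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(ab, v, method = "spearman"))
    data.frame(metric = m, rho_spearman = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
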