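#' Construct a co-occurrence network object
#'
#' A signed, weighted, simple undirected graph of selected feature pairs.
#' Stored as two data frames rather than a bare igraph object so edge
#' statistics and node abundances survive round trips through text formats;
#' [as_igraph()] converts for graph algorithms.
#'
#' @param edges data.frame with columns `feature_i`, `feature_j`, `weight`
#'   (signed correlation in `[-1, 1]`), `p_value`, `q_value`.
#' @param abundance Optional named numeric: mean relative abundance per
#'   node; missing nodes get `NA`.
#' @param q_max The selection threshold the edges were required to meet
#'   (recorded; validated against the edge q-values when not `NULL`).
#' @return An object of class `cooccurrence_network` with elements
#'   `nodes` (data.frame: `id`, `abundance`) and `edges` (data.frame with
#'   a `sign` column, `"positive"`/`"negative"`, derived from the weight).
#' @export
cooccurrence_network <- function(edges, abundance = NULL, q_max = NULL) {
  required <- c("feature_i", "feature_j", "weight", "p_value", "q_value")
  if (!all(required %in% names(edges))) {
    stop_coab("cooccurrence_network: edges must have columns ",
              paste(required, collapse = ", "),
              class = "coabnet_validation_error")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (any(edges$feature_i == edges$feature_j)) {
      stop_coab("cooccurrence_network: self-loop edge",
                class = "coabnet_validation_error")
    }
    key <- ifelse(edges$feature_i < edges$feature_j,
                  paste(edges$feature_i, edges$feature_j),
                  paste(edges$feature_j, edges$feature_i))
    if (anyDuplicated(key)) {
      stop_coab("cooccurrence_network: duplicate edge",
                class = "coabnet_validation_error")
    }
    if (any(abs(edges$weight) > 1 + 1e-9)) {
      stop_coab("cooccurrence_network: |weight| must be <= 1",
                class = "coabnet_validation_error")
    }
    if (!is.null(q_max) && any(edges$q_value > q_max + 1e-12)) {
      stop_coab("cooccurrence_network: edge q_value above declared q_max",
                class = "coabnet_validation_error")
    }
    edges$sign <- ifelse(edges$weight >= 0, "positive", "negative")
    # canonical order: smaller id first, rows sorted
    flip <- edges$feature_i > edges$feature_j
    tmp <- edges$feature_i[flip]
    edges$feature_i[flip] <- edges$feature_j[flip]
    edges$feature_j[flip] <- tmp
    edges <- edges[order(edges$feature_i, edges$feature_j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges$sign <- character(0)
  }
  node_ids <- sort(unique(c(edges$feature_i, edges$feature_j)))
  ab <- if (is.null(abundance)) rep(NA_real_, length(node_ids)) else {
    unname(abundance[node_ids])
  }
  nodes <- data.frame(id = node_ids, abundance = ab, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, q_max = q_max),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#' @param net A [cooccurrence_network()].
#' @return An undirected igraph graph with edge attributes `weight`
#'   (absolute value is not taken: signed), `sign`, `p`, `q`, and vertex
#'   attribute `abundance`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$feature_i, to = net$edges$feature_j,
                   weight = net$edges$weight, sign = net$edges$sign,
                   p = net$edges$p_value, q = net$edges$q_value,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, abundance = net$nodes$abundance,
                          stringsAsFactors = FALSE))
  g
}

#' Magnitude threshold from the mode of the null |rho| distribution
#'
#' Kernel-density mode of the null-model absolute correlations: edges must
#' exceed, in absolute value, the most probable null magnitude. Gaussian
#' kernel with Silverman's rule-of-thumb bandwidth evaluated on a 512-point
#' grid over `[0, 1]`; a degenerate (all-equal) null returns that value
#' directly.
#'
#' @param null_values Numeric vector of null `|rho|` draws (>= 10 unless
#'   degenerate).
#' @param bandwidth_rule Bandwidth selector passed to [stats::density()]
#'   (default `"nrd0"`, Silverman).
#' @return The mode estimate, a single value in `[0, 1]`.
#' @export
null_mode_threshold <- function(null_values, bandwidth_rule = "nrd0") {
  null_values <- null_values[is.finite(null_values)]
  if (length(unique(null_values)) == 1L) return(null_values[1L])
  if (length(null_values) < 10L) {
    stop_coab("null_mode_threshold: need >= 10 null values")
  }
  dens <- stats::density(null_values, bw = bandwidth_rule, n = 512L,
                         from = 0, to = 1)
  dens$x[which.max(dens$y)]
}

#' Select significant edges into a co-occurrence network
#'
#' The dual criterion: keep pairs with `q_value <= q_max` AND
#' `|rho| > magnitude_threshold`. Nodes are exactly the features incident
#' to at least one kept edge (isolated features are not represented).
#' Edge weights are the signed correlations from `rho` when given,
#' otherwise the signed bootstrap medians in `stats`.
#'
#' @param stats An `edge_stats` data.frame from [bootstrap_edge_stats()].
#' @param rho Optional `correlation_estimate` (full-data estimate) whose
#'   values become the edge weights; must cover the same features.
#' @param q_max FDR threshold (default 0.01).
#' @param magnitude_threshold Minimum `|rho|`, typically from
#'   [null_mode_threshold()] on the pooled null draws; default uses the
#'   attached null pool.
#' @param abundance Optional named mean relative abundances for node
#'   annotation.
#' @return A [cooccurrence_network()].
#' @export
select_edges <- function(stats, rho = NULL, q_max = 0.01,
                         magnitude_threshold = NULL, abundance = NULL) {
  if (is.null(magnitude_threshold)) {
    pool <- attr(stats, "null_abs")
    if (is.null(pool)) {
      stop_coab("select_edges: no magnitude_threshold given and no null ",
                "draws attached to stats")
    }
    magnitude_threshold <- null_mode_threshold(pool)
  }
  keep <- stats$q_value <= q_max & stats$rho_abs > magnitude_threshold
  kept <- stats[keep, , drop = FALSE]
  weight <- kept$rho_obs
  if (!is.null(rho)) {
    R <- if (inherits(rho, "correlation_estimate")) rho$rho else as.matrix(rho)
    missing <- setdiff(unique(c(kept$feature_i, kept$feature_j)), rownames(R))
    if (length(missing)) {
      stop_coab("select_edges: rho does not cover feature(s): ",
                paste(missing, collapse = ", "))
    }
    weight <- R[cbind(kept$feature_i, kept$feature_j)]
  }
  edges <- data.frame(feature_i = kept$feature_i, feature_j = kept$feature_j,
                      weight = weight, p_value = kept$p_value,
                      q_value = kept$q_value, stringsAsFactors = FALSE)
  net <- cooccurrence_network(edges, abundance = abundance, q_max = q_max)
  attr(net, "magnitude_threshold") <- magnitude_threshold
  net
}

#' Write a co-occurrence network to edge-list TSV or GraphML
#'
#' The edge-list TSV has columns `source`, `target`, `weight`, `sign`,
#' `p`, `q` (plus a node table side file is not needed: abundances are
#' stored as extra columns `abundance_source`, `abundance_target`).
#' GraphML goes through igraph for interoperability with Cytoscape-style
#' tools.
#'
#' @param net A [cooccurrence_network()].
#' @param path Output path.
#' @param format `"edge-list"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooccurrence_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  ab <- stats::setNames(net$nodes$abundance, net$nodes$id)
  df <- data.frame(
    source = net$edges$feature_i,
    target = net$edges$feature_j,
    weight = sprintf("%.17g", net$edges$weight),
    sign = net$edges$sign,
    p = sprintf("%.17g", net$edges$p_value),
    q = sprintf("%.17g", net$edges$q_value),
    abundance_source = sprintf("%.17g", ab[net$edges$feature_i]),
    abundance_target = sprintf("%.17g", ab[net$edges$feature_j]),
    stringsAsFactors = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_coab("write_network: cannot open ", path, ": ", conditionMessage(e),
              class = "coabnet_io_error")
  })
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a co-occurrence network written by [write_network()]
#' @param path Input path.
#' @param format `"edge-list"` or `"graphml"`.
#' @return A [cooccurrence_network()].
#' @export
read_network <- function(path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_coab("read_network: file does not exist: ", path,
              class = "coabnet_io_error")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    vd <- igraph::as_data_frame(g, what = "vertices")
    edges <- data.frame(feature_i = ed$from, feature_j = ed$to,
                        weight = ed$weight, p_value = ed$p, q_value = ed$q,
                        stringsAsFactors = FALSE)
    ab <- stats::setNames(vd$abundance, vd$name)
    return(cooccurrence_network(edges, abundance = ab))
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(cooccurrence_network(data.frame(
      feature_i = character(), feature_j = character(), weight = numeric(),
      p_value = numeric(), q_value = numeric(), stringsAsFactors = FALSE)))
  }
  edges <- data.frame(feature_i = df$source, feature_j = df$target,
                      weight = as.numeric(df$weight),
                      p_value = as.numeric(df$p), q_value = as.numeric(df$q),
                      stringsAsFactors = FALSE)
  ab <- stats::setNames(
    as.numeric(c(df$abundance_source, df$abundance_target)),
    c(df$source, df$target))
  ab <- ab[!duplicated(names(ab))]
  cooccurrence_network(edges, abundance = ab)
}
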