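# Shared builders for graph and count fixtures (all generated in code).

# wrap an igraph graph as a cooccurrence_network with constant edge stats
net_from_graph <- function(g, weight = 0.5) {
  stopifnot(!is.null(igraph::V(g)$name))
  el <- igraph::as_edgelist(g)
  cooccurrence_network(data.frame(
    feature_i = as.character(el[, 1]), feature_j = as.character(el[, 2]),
    weight = weight, p_value = 0.001, q_value = 0.001,
    stringsAsFactors = FALSE))
}

named_graph <- function(make, n, ...) {
  g <- make(n, ...)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

complete_net <- function(n) net_from_graph(named_graph(igraph::make_full_graph, n))

star_net <- function(n) {
  net_from_graph(named_graph(igraph::make_star, n, mode = "undirected", center = 1))
}

path_net <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  net_from_graph(g)
}

# small random network with distinct edge attributes, for I/O round-trips
random_net <- function(n_nodes = 10, p = 0.35, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n_nodes, p)
  igraph::V(g)$name <- sprintf("f%02d", seq_len(n_nodes))
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  ab <- stats::setNames(runif(n_nodes), igraph::V(g)$name)
  cooccurrence_network(data.frame(
    feature_i = as.character(el[, 1]), feature_j = as.character(el[, 2]),
    weight = runif(m, -1, 1), p_value = runif(m, 0, 0.01),
    q_value = runif(m, 0, 0.01), stringsAsFactors = FALSE), abundance = ab)
}

# counts with exact proportionality between selected features
toy_counts <- function() {
  cts <- rbind(a = c(10, 20, 40, 80),
               b = c(10, 20, 40, 80),
               c = c(80, 40, 20, 10))
  count_table(cts)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
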