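#' Node removal order for a targeted (or random) attack
#'
#' Descending order of the chosen centrality on the intact graph (static
#' ordering, the classical formulation), or recomputed after every removal
#' with `recompute = TRUE`. Ties break by ascending node id.
#'
#' @param net A [cooccurrence_network()] or igraph graph.
#' @param strategy `"betweenness"`, `"degree"` or `"random"`.
#' @param recompute Re-rank the surviving nodes after each removal.
#' @param seed Seed used only for `strategy = "random"`.
#' @return Character vector of node ids in removal order.
#' @export
attack_order <- function(net, strategy = c("betweenness", "degree", "random"),
                         recompute = FALSE, seed = 1L) {
  strategy <- match.arg(strategy)
  g <- to_graph(net)
  if (igraph::vcount(g) == 0L) stop_coab("attack_order: empty graph")
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (strategy == "random") {
    return(with_seed(seed, sample(igraph::V(g)$name)))
  }
  metric <- function(gr) {
    if (strategy == "degree") igraph::degree(gr)
    else igraph::betweenness(gr, weights = NA)
  }
  if (!recompute) {
    m <- metric(g)
    ids <- igraph::V(g)$name
    return(ids[order(-m, ids)])
  }
  out <- character(0)
  while (igraph::vcount(g) > 0L) {
    m <- metric(g)
    ids <- igraph::V(g)$name
    pick <- ids[order(-m, ids)][1L]
    out <- c(out, pick)
    g <- igraph::delete_vertices(g, pick)
  }
  out
}

#' Connectivity-loss curve under sequential node removal
#'
#' Network efficiency convention: with `E(f)` the sum over unordered pairs
#' of the ORIGINAL node set of `1 / d(u, v)` in the attacked graph (pairs
#' involving removed or mutually unreachable nodes contribute 0),
#' `loss(f) = 1 - E(f) / E(0)`. The removal grid is one node at a time,
#' fractions `k / N`. The collapse fraction `f*` is the smallest fraction
#' at which the loss reaches 1, i.e. no connected pair survives.
#'
#' @param net A [cooccurrence_network()] or igraph graph.
#' @param order Node ids in removal order (a permutation of a prefix of
#'   the node set), e.g. from [attack_order()].
#' @return list of class `attack_curve`: `fractions_removed` (including
#'   0), `connectivity_loss`, `loss_rate` (first difference of the loss
#'   over the grid), `f_star`, `strategy` (attribute of the order if set).
#' @export
attack_curve <- function(net, order) {
  g0 <- to_graph(net)
  if (is.null(igraph::V(g0)$name)) {
    igraph::V(g0)$name <- as.character(seq_len(igraph::vcount(g0)))
  }
  N <- igraph::vcount(g0)
  if (!all(order %in% igraph::V(g0)$name)) {
    stop_coab("attack_curve: order contains unknown node id(s)")
  }
  if (anyDuplicated(order)) stop_coab("attack_curve: duplicated node in order")
  eff <- function(g) {
    if (igraph::vcount(g) < 2L || igraph::ecount(g) == 0L) return(0)
    D <- igraph::distances(g, weights = NA)
    iD <- 1 / D
    iD[!is.finite(iD)] <- 0
    sum(iD[upper.tri(iD)])
  }
  e0 <- eff(g0)
  if (e0 == 0) stop_coab("attack_curve: graph has no connected pair")
  g <- g0
  loss <- numeric(length(order))
  for (k in seq_along(order)) {
    g <- igraph::delete_vertices(g, order[k])
    loss[k] <- 1 - eff(g) / e0
  }
  fractions <- c(0, seq_along(order) / N)
  loss <- c(0, pmin(pmax(loss, 0), 1))
  hit <- which(loss >= 1 - 1e-12)
  f_star <- if (length(hit)) fractions[hit[1L]] else NA_real_
  structure(list(fractions_removed = fractions,
                 connectivity_loss = loss,
                 loss_rate = diff(loss),
                 f_star = f_star),
            class = "attack_curve")
}

#' Collapse fraction f* of a graph under a removal order
#'
#' Fast path used by the rewiring null: the loss reaches 1 exactly when no
#' edge survives, so f* is found by deleting nodes until the edge count
#' hits zero, without computing distance matrices.
#' @param g igraph graph with named vertices.
#' @param order Removal order (all nodes).
#' @return f* as a fraction of the original node count.
#' @export
f_star_only <- function(g, order) {
  N <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) stop_coab("f_star_only: graph has no edges")
  for (k in seq_along(order)) {
    g <- igraph::delete_vertices(g, order[k])
    if (igraph::ecount(g) == 0L) return(k / N)
  }
  1
}

#' Rewiring null ensemble for attack robustness
#'
#' Each replicate moves `ceiling(rewire_fraction * E)` randomly chosen
#' edges to uniformly chosen currently non-adjacent node pairs (degree is
#' not preserved), recomputes the attack order under the given strategy on
#' the rewired graph, and records its collapse fraction f*.
#'
#' @param net A [cooccurrence_network()] or igraph graph.
#' @param rewire_fraction Fraction of edges moved per replicate
#'   (default 0.10).
#' @param n_rewirings Number of replicates (default 500).
#' @param strategy Attack strategy for the f* computation.
#' @param seed Integer seed.
#' @return list of class `rewiring_null`: `f_star_samples` (length
#'   `n_rewirings`), `f_star_observed`, `n_rewirings`, `rewire_fraction`,
#'   `strategy`.
#' @export
rewiring_null <- function(net, rewire_fraction = 0.10, n_rewirings = 500L,
                          strategy = c("betweenness", "degree", "random"),
                          seed = 1L) {
  strategy <- match.arg(strategy)
  g0 <- to_graph(net)
  if (is.null(igraph::V(g0)$name)) {
    igraph::V(g0)$name <- as.character(seq_len(igraph::vcount(g0)))
  }
  N <- igraph::vcount(g0)
  E <- igraph::ecount(g0)
  if (E >= N * (N - 1) / 2) {
    stop_coab("rewiring_null: graph is complete; no non-adjacent pairs")
  }
  n_move <- ceiling(rewire_fraction * E)
  obs <- f_star_only(g0, attack_order(g0, strategy, seed = seed))
  seeds <- child_seeds(seed, n_rewirings)
  samples <- vapply(seq_len(n_rewirings), function(r) {
    g <- with_seed(seeds[r], rewire_edges(g0, n_move))
    ord <- attack_order(g, strategy, seed = seeds[r])
    f_star_only(g, ord)
  }, numeric(1))
  structure(list(f_star_samples = samples, f_star_observed = obs,
                 n_rewirings = n_rewirings, rewire_fraction = rewire_fraction,
                 strategy = strategy),
            class = "rewiring_null")
}

# Move n_move randomly chosen edges to uniformly chosen non-adjacent pairs.
rewire_edges <- function(g, n_move) {
  if (n_move == 0L) return(g)
  E <- igraph::ecount(g)
  move <- sample.int(E, min(n_move, E))
  el <- igraph::as_edgelist(g, names = FALSE)
  N <- igraph::vcount(g)
  adj <- matrix(FALSE, N, N)
  adj[el] <- TRUE
  adj[el[, c(2, 1), drop = FALSE]] <- TRUE
  for (e in move) {
    u <- el[e, 1L]; v <- el[e, 2L]
    adj[u, v] <- adj[v, u] <- FALSE
    # draw a uniformly random non-adjacent unordered pair
    repeat {
      a <- sample.int(N, 1L)
      b <- sample.int(N, 1L)
      if (a != b && !adj[a, b]) break
    }
    el[e, ] <- c(a, b)
    adj[a, b] <- adj[b, a] <- TRUE
  }
  igraph::graph_from_edgelist(el, directed = FALSE) -> g2
  igraph::V(g2)$name <- igraph::V(g)$name[seq_len(igraph::vcount(g2))]
  if (igraph::vcount(g2) < N) {
    g2 <- igraph::add_vertices(g2, N - igraph::vcount(g2),
                               name = igraph::V(g)$name[(igraph::vcount(g2) + 1L):N])
  }
  g2
}

#' Welch t-test between two rewiring-null f* samples
#'
#' Two-sided Welch (unequal-variance) t-test on the collapse-fraction
#' samples of two cohorts' networks. Zero variance in both samples with
#' equal means returns p = 1.
#'
#' @param null_a,null_b [rewiring_null()] objects or bare numeric vectors
#'   of f* samples (length >= 2 each).
#' @return list: `t_statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
robustness_test <- function(null_a, null_b) {
  xa <- if (inherits(null_a, "rewiring_null")) null_a$f_star_samples else null_a
  xb <- if (inherits(null_b, "rewiring_null")) null_b$f_star_samples else null_b
  if (length(xa) < 2L || length(xb) < 2L) {
    stop_coab("robustness_test: both samples need length >= 2")
  }
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    if (mean(xa) == mean(xb)) {
      return(list(t_statistic = 0, p_value = 1, df = NA_real_,
                  mean_a = mean(xa), mean_b = mean(xb)))
    }
    return(list(t_statistic = Inf * sign(mean(xa) - mean(xb)), p_value = 0,
                df = NA_real_, mean_a = mean(xa), mean_b = mean(xb)))
  }
  tt <- stats::t.test(xa, xb, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(xa), mean_b = mean(xb))
}
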