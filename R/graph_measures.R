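#' Node strength
#'
#' \eqn{s_i = \sum_{j \in N(i)} w_{ij}}: the sum of incident edge weights.
#' This is the same quantity that normalizes the neighborhood measure in
#' the curvature computation.
#'
#' @param g a `weighted_graph`.
#' @return a `node_measures` object (measure name `"strength"`).
#' @export
node_strength <- function(g) {
  node_measures(g$node_ids, rowSums(g$weights), "strength")
}

edge_lengths <- function(g, length_mode) {
  ig <- as_igraph(g)
  w <- switch(length_mode,
              hop = NA,
              inverse_weight = 1 / igraph::E(ig)$weight)
  list(graph = ig, weights = w)
}

#' Betweenness centrality
#'
#' \eqn{g_i = \sum_{j \ne i \ne k} \sigma_{jk}(i) / \sigma_{jk}} over
#' unordered pairs, unnormalized, counting all co-optimal shortest paths.
#' By default edge length is the inverse weight \eqn{1/w} (strong
#' connections are short), the standard convention for connectivity
#' matrices; `"hop"` treats every edge as unit length for binarized
#' analyses. Pairs with no connecting path contribute 0.
#'
#' @param g a `weighted_graph`.
#' @param length_mode `"inverse_weight"` (default) or `"hop"`.
#' @return a `node_measures` object (measure name `"betweenness"`).
#' @export
node_betweenness <- function(g, length_mode = c("inverse_weight", "hop")) {
  length_mode <- match.arg(length_mode)
  el <- edge_lengths(g, length_mode)
  b <- igraph::betweenness(el$graph, directed = FALSE, weights = el$weights)
  node_measures(g$node_ids, as.double(b), "betweenness")
}

#' Clustering coefficient
#'
#' The graph is binarized (unit weights) and
#' \eqn{C_i = 2 T_i / (k_i (k_i - 1))}, where \eqn{k_i} is the degree and
#' \eqn{T_i} the number of edges that actually exist among the neighbors of
#' \eqn{i} — the realized fraction of the at most \eqn{k_i(k_i-1)/2}
#' possible neighbor-neighbor edges. Nodes with fewer than two neighbors
#' get 0.
#'
#' @param g a `weighted_graph`.
#' @return a `node_measures` object (measure name `"clustering"`).
#' @export
clustering_coefficient <- function(g) {
  cc <- igraph::transitivity(as_igraph(g), type = "local", isolates = "zero")
  node_measures(g$node_ids, as.double(cc), "clustering")
}

#' Global efficiency
#'
#' \eqn{E = \frac{1}{N(N-1)} \sum_{i \ne j} 1 / \ell_{ij}} with
#' \eqn{\ell_{ij}} the shortest-path length under `length_mode`;
#' disconnected pairs contribute 0. Normalization uses the graph's current
#' node count, so efficiency is comparable along deletion cascades where
#' the network shrinks.
#'
#' @param g a `weighted_graph` with at least 2 nodes.
#' @param length_mode `"hop"` (unit edge lengths; efficiency then lies in
#'   \eqn{[0, 1]}) or `"inverse_weight"`.
#' @return numeric scalar.
#' @export
global_efficiency <- function(g, length_mode = c("hop", "inverse_weight")) {
  length_mode <- match.arg(length_mode)
  n <- n_nodes(g)
  if (n < 2) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  el <- edge_lengths(g, length_mode)
  d <- igraph::distances(el$graph, weights = el$weights)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Entropy rate of the weight-proportional random walk
#'
#' A discrete network entropy: the entropy rate
#' \deqn{S = -\sum_x \pi_x \sum_y p_x(y) \log p_x(y)}
#' of the random walk whose transition measures are the neighborhood
#' measures \eqn{p_x(y) = w_{xy}/d_x}, under its stationary distribution
#' \eqn{\pi_x = d_x / \sum_z d_z}. Isolated nodes carry no stationary mass
#' and are excluded. Natural logarithm (nats).
#'
#' @param g a `weighted_graph` with at least one edge.
#' @return numeric scalar; 0 when every walk step is forced, \eqn{\log(n-1)}
#'   on the complete graph \eqn{K_n}.
#' @export
walk_entropy <- function(g) {
  d <- rowSums(g$weights)
  if (sum(d) == 0) stop("entropy rate needs at least one edge", call. = FALSE)
  pi_x <- d / sum(d)
  h <- vapply(seq_len(n_nodes(g)), function(i) {
    if (d[i] == 0) return(0)
    p <- g$weights[i, ]
    p <- p[p > 0] / d[i]
    -sum(p * log(p))
  }, numeric(1))
  sum(pi_x * h)
}

#' Pearson correlation between two node measures
#'
#' Sample Pearson r across nodes; used to compare curvature with the
#' classical nodal measures. Constant vectors have no defined correlation
#' and raise an error.
#'
#' @param a,b `node_measures` objects (or plain numeric vectors) of equal
#'   length, at least 3 nodes.
#' @return numeric scalar in \eqn{[-1, 1]}.
#' @export
measure_correlation <- function(a, b) {
  va <- if (inherits(a, "node_measures")) a$value else as.double(a)
  vb <- if (inherits(b, "node_measures")) b$value else as.double(b)
  if (length(va) != length(vb)) stop("measures must have equal length")
  if (length(va) < 3) stop("need at least 3 nodes for a correlation")
  if (sd(va) == 0 || sd(vb) == 0)
    stop("correlation undefined: constant measure vector", call. = FALSE)
  cor(va, vb)
}

#' Compute all nodal measures of a graph
#'
#' Convenience wrapper returning strength, betweenness, clustering, and
#' (optionally, since it is the expensive one) scalar and weighted node
#' curvature, aligned to the node order.
#'
#' @param g a `weighted_graph`.
#' @param include_curvature compute the curvature columns (default TRUE).
#' @param length_mode betweenness length mode.
#' @return data.frame, one row per node.
#' @export
all_node_measures <- function(g, include_curvature = TRUE,
                              length_mode = c("inverse_weight", "hop")) {
  length_mode <- match.arg(length_mode)
  out <- data.frame(node_id = g$node_ids,
                    strength = node_strength(g)$value,
                    betweenness = node_betweenness(g, length_mode)$value,
                    clustering = clustering_coefficient(g)$value,
                    stringsAsFactors = FALSE)
  if (include_curvature) {
    ct <- ricci_curvature(g)
    out$curvature <- ct$nodes$kappa_node
    out$weighted_curvature <- ct$nodes$kappa_node_weighted
  }
  out
}
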