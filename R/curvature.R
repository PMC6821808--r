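#' Neighborhood measure of a node
#'
#' The probability measure \eqn{p_x} that the curvature definition attaches
#' to node \eqn{x}: supported exactly on the neighbors of \eqn{x}, with
#' mass proportional to edge weight,
#' \deqn{p_x(y) = w_{xy} / d_x, \qquad d_x = \sum_{y \in N(x)} w_{xy},}
#' where \eqn{d_x} is the node strength. An isolated node has no such
#' measure and raises an error; callers decide the degenerate-node policy.
#'
#' @param g a `weighted_graph`.
#' @param x node id or index.
#' @return a [discrete_measure] on the neighbor ids of `x`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
#' node_distribution(g, 1)
#' @export
node_distribution <- function(g, x) {
  i <- resolve_node(g, x)
  w <- g$weights[i, ]
  nb <- which(w > 0)
  if (length(nb) == 0)
    stop("node '", g$node_ids[i],
         "' is isolated: no neighborhood measure exists", call. = FALSE)
  discrete_measure(g$node_ids[nb], w[nb] / sum(w[nb]))
}

# kappa for one adjacent pair given precomputed hop-distance matrix D
edge_kappa <- function(g, D, i, j) {
  px <- node_distribution(g, i)
  py <- node_distribution(g, j)
  si <- match(px$support, g$node_ids)
  sj <- match(py$support, g$node_ids)
  cost <- D[si, sj, drop = FALSE]
  1 - emd(px, py, cost)$dist / D[i, j]
}

#' Ollivier-Ricci curvature of one edge
#'
#' \deqn{\kappa(x, y) = 1 - W_1(p_x, p_y) / d(x, y)}
#' with \eqn{W_1} the earth mover's distance between the two neighborhood
#' measures under the hop-distance cost of the full graph (transport paths
#' may leave the union of the two neighborhoods), and \eqn{d(x, y)} the hop
#' distance — identically 1 for an adjacent pair. Weights enter only
#' through the measures \eqn{p_x}; the geodesic cost is purely topological.
#'
#' @param g a `weighted_graph`.
#' @param x,y adjacent nodes (ids or indices); nonadjacent pairs error.
#' @return the curvature \eqn{\kappa(x, y)}, a real in \eqn{[-2, 1]}.
#' @examples
#' k3 <- weighted_graph(matrix(1, 3, 3) - diag(3))
#' edge_curvature(k3, 1, 2) # 0.5
#' @export
edge_curvature <- function(g, x, y) {
  i <- resolve_node(g, x)
  j <- resolve_node(g, y)
  if (g$weights[i, j] <= 0)
    stop("nodes '", g$node_ids[i], "' and '", g$node_ids[j],
         "' are not adjacent", call. = FALSE)
  edge_kappa(g, hop_distances(g), i, j)
}

#' Full curvature table of a graph
#'
#' Computes \eqn{\kappa(x, y)} for every edge, the scalar node curvature
#' \eqn{\kappa_x = \sum_{y \in N(x)} \kappa(x, y)}, the weighted node
#' curvature \eqn{\tilde\kappa_x = \sum_y p_x(y) \kappa(x, y)}, and the
#' network averages. Isolated nodes get node curvature 0 by convention (so
#' deletion cascades and group tests stay total); they are flagged in the
#' node table.
#'
#' @param g a `weighted_graph` with at least one node.
#' @return object of class `curvature_table`: list with
#'   \item{edges}{data.frame `x`, `y`, `kappa`, one row per unordered edge}
#'   \item{nodes}{data.frame `node_id`, `kappa_node`, `kappa_node_weighted`,
#'     `isolated`}
#'   \item{network_average}{named vector with `node_mean` (mean of
#'     \eqn{\kappa_x} over non-isolated nodes) and `edge_mean`}
#' @export
ricci_curvature <- function(g) {
  n <- n_nodes(g)
  if (n == 0) stop("empty graph has no curvature", call. = FALSE)
  D <- hop_distances(g)
  ed <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  ed <- ed[order(ed[, 1], ed[, 2]), , drop = FALSE]
  # neighborhood supports and measures, computed once per node
  nbs <- lapply(seq_len(n), function(i) which(g$weights[i, ] > 0))
  pxs <- lapply(seq_len(n), function(i) {
    w <- g$weights[i, nbs[[i]]]
    w / sum(w)
  })
  kap <- vapply(seq_len(nrow(ed)), function(k) {
    i <- ed[k, 1]; j <- ed[k, 2]
    1 - .emd_lp_cpp(pxs[[i]], pxs[[j]],
                    D[nbs[[i]], nbs[[j]], drop = FALSE])$cost / D[i, j]
  }, numeric(1))
  edges <- data.frame(x = g$node_ids[ed[, 1]], y = g$node_ids[ed[, 2]],
                      kappa = kap, stringsAsFactors = FALSE)

  strengths <- rowSums(g$weights)
  knode <- numeric(n)
  kwt <- numeric(n)
  for (k in seq_len(nrow(ed))) {
    i <- ed[k, 1]; j <- ed[k, 2]; w <- g$weights[i, j]
    knode[i] <- knode[i] + kap[k]
    knode[j] <- knode[j] + kap[k]
    kwt[i] <- kwt[i] + w / strengths[i] * kap[k]
    kwt[j] <- kwt[j] + w / strengths[j] * kap[k]
  }
  isolated <- strengths == 0
  nodes <- data.frame(node_id = g$node_ids, kappa_node = knode,
                      kappa_node_weighted = kwt, isolated = isolated,
                      stringsAsFactors = FALSE)
  net <- c(node_mean = if (all(isolated)) NA_real_ else
             mean(knode[!isolated]),
           edge_mean = if (nrow(edges) == 0) NA_real_ else mean(kap))
  structure(list(edges = edges, nodes = nodes, network_average = net),
            class = "curvature_table")
}

#' @export
print.curvature_table <- function(x, ...) {
  cat(sprintf(
    "curvature_table: %d edges, %d nodes; network average %.4f (node), %.4f (edge)\n",
    nrow(x$edges), nrow(x$nodes),
    x$network_average["node_mean"], x$network_average["edge_mean"]))
  invisible(x)
}

#' Scalar node curvature
#'
#' \eqn{\kappa_x = \sum_{y \in N(x)} \kappa(x, y)}: the sum of the
#' curvatures of the edges incident to each node. Isolated nodes get 0.
#'
#' @param g a `weighted_graph`.
#' @param table optional precomputed [ricci_curvature()] result.
#' @return a `node_measures` object (measure name `"curvature"`).
#' @export
node_curvature <- function(g, table = NULL) {
  if (is.null(table)) table <- ricci_curvature(g)
  node_measures(g$node_ids, table$nodes$kappa_node, "curvature")
}

#' Weighted node curvature
#'
#' \eqn{\tilde\kappa_x = \sum_y p_x(y) \kappa(x, y)}: incident edge
#' curvatures averaged under the node's neighborhood measure. The sum runs
#' effectively over the neighbors of \eqn{x}, since \eqn{p_x} vanishes
#' elsewhere. Isolated nodes get 0.
#'
#' @inheritParams node_curvature
#' @return a `node_measures` object (measure name `"weighted_curvature"`).
#' @export
weighted_node_curvature <- function(g, table = NULL) {
  if (is.null(table)) table <- ricci_curvature(g)
  node_measures(g$node_ids, table$nodes$kappa_node_weighted,
                "weighted_curvature")
}

#' Network-average curvature
#'
#' Arithmetic mean of the scalar node curvature over non-isolated nodes
#' (`node_mean`, the default) or of the edge curvature over edges
#' (`edge_mean`).
#'
#' @param g a `weighted_graph` with at least one edge.
#' @param mode `"node_mean"` or `"edge_mean"`.
#' @param table optional precomputed [ricci_curvature()] result.
#' @return numeric scalar.
#' @export
network_average_curvature <- function(g, mode = c("node_mean", "edge_mean"),
                                      table = NULL) {
  mode <- match.arg(mode)
  if (is.null(table)) {
    if (sum(g$weights) == 0)
      stop("graph has no edges; network-average curvature is undefined",
           call. = FALSE)
    table <- ricci_curvature(g)
  }
  unname(table$network_average[mode])
}
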