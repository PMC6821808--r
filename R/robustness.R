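#' Rank-preserving Gaussian transformation of edge weights
#'
#' Streamline counts from tractography are approximately exponentially
#' distributed; for some analyses it is conventional to remap them, without
#' altering the rank ordering of pathways, onto a Gaussian distribution.
#' Each positive weight with (average-tie) rank \eqn{r} among the \eqn{m}
#' positive weights is replaced by
#' \deqn{\mu + \sigma \, \Phi^{-1}\!\left(\frac{r}{m + 1}\right),}
#' zeros stay zero and symmetry is preserved. Note the caveat: the remapped
#' range can differ wildly from the original (e.g. weights in \[1, 1000\]
#' mapped near \[10, 11\]), which changes strengths and any weight-sensitive
#' measure — apply with care.
#'
#' @param g a `weighted_graph` with at least one positive weight.
#' @param target_mean Gaussian mean \eqn{\mu} (default 0.5).
#' @param target_sd Gaussian sd \eqn{\sigma > 0} (default 0.1).
#' @return a `weighted_graph` with transformed weights. Any nonpositive
#'   transformed value (possible for extreme \eqn{\mu, \sigma}) is clipped
#'   to a small positive epsilon with a warning, so adjacency is preserved.
#' @export
gaussian_transform <- function(g, target_mean = 0.5, target_sd = 0.1) {
  stopifnot(target_sd > 0)
  w <- g$weights
  up <- upper.tri(w)
  pos <- which(up & w > 0)
  if (length(pos) == 0)
    stop("graph has no positive weights to transform", call. = FALSE)
  m <- length(pos)
  r <- rank(w[pos], ties.method = "average")
  new_w <- target_mean + target_sd * qnorm(r / (m + 1))
  if (any(new_w <= 0)) {
    eps <- .Machine$double.eps
    warning(sum(new_w <= 0),
            " transformed weight(s) were nonpositive; clipped to epsilon",
            call. = FALSE)
    new_w[new_w <= 0] <- eps
  }
  out <- matrix(0, nrow(w), ncol(w))
  out[pos] <- new_w
  out <- out + t(out)
  weighted_graph(out, node_ids = g$node_ids, labels = g$labels,
                 metadata = g$metadata)
}

delete_node <- function(g, i) {
  keep <- setdiff(seq_len(n_nodes(g)), i)
  weighted_graph(g$weights[keep, keep, drop = FALSE],
                 node_ids = g$node_ids[keep])
}

cascade_score <- function(g, measure, length_mode) {
  switch(measure,
         strength = node_strength(g)$value,
         betweenness = node_betweenness(g, length_mode)$value,
         curvature = node_curvature(g)$value,
         random = runif(n_nodes(g)))
}

#' Targeted node-deletion cascade
#'
#' Repeats until the graph is empty: compute the chosen nodal measure on
#' the current graph, delete the node with the largest value (row and
#' column), and record the global metrics — largest component size, global
#' efficiency, and random-walk entropy rate — on the remaining graph.
#' With `recompute = FALSE` the initial ranking is used throughout
#' (ablation mode). Ties at removal are broken deterministically: isolated
#' nodes go last among ties, then the lowest node index wins.
#'
#' Efficiency is 0 once fewer than 2 nodes remain, and the entropy record
#' is 0 for an edgeless remainder (conventions that keep the trajectory
#' total; the standalone metric functions are stricter).
#'
#' @param g a `weighted_graph`.
#' @param measure `"strength"`, `"betweenness"`, `"curvature"` (scalar node
#'   curvature), or `"random"` (uniform random order, seed-controlled).
#' @param recompute recompute the measure after every removal (default
#'   TRUE, the cascade of interest); FALSE freezes the initial ranking.
#' @param length_mode edge-length convention for betweenness and
#'   efficiency (`"hop"` or `"inverse_weight"`).
#' @param seed optional RNG seed for `measure = "random"`.
#' @return object of class `deletion_trajectory`: a data.frame with columns
#'   `step`, `removed`, `measure_value`, `n_remaining`, `largest_component`,
#'   `efficiency`, `entropy`, plus attributes `measure_name`,
#'   `length_mode`, `recompute`.
#' @export
deletion_cascade <- function(g,
                             measure = c("strength", "betweenness",
                                         "curvature", "random"),
                             recompute = TRUE,
                             length_mode = c("hop", "inverse_weight"),
                             seed = NULL) {
  measure <- match.arg(measure)
  length_mode <- match.arg(length_mode)
  if (!is.null(seed)) set.seed(seed)

  n0 <- n_nodes(g)
  steps <- vector("list", n0)
  frozen <- if (!recompute && n0 > 0)
    setNames(cascade_score(g, measure, length_mode), g$node_ids) else NULL

  cur <- g
  for (s in seq_len(n0)) {
    vals <- if (recompute) cascade_score(cur, measure, length_mode)
            else unname(frozen[cur$node_ids])
    isolated <- rowSums(cur$weights) == 0
    pick <- order(-vals, isolated, seq_along(vals))[1]
    removed_id <- cur$node_ids[pick]
    removed_val <- vals[pick]
    cur <- delete_node(cur, pick)

    n_rem <- n_nodes(cur)
    eff <- if (n_rem >= 2) global_efficiency(cur, length_mode) else 0
    ent <- if (sum(cur$weights) > 0) walk_entropy(cur) else 0
    steps[[s]] <- data.frame(step = s, removed = removed_id,
                             measure_value = removed_val,
                             n_remaining = n_rem,
                             largest_component = largest_component_size(cur),
                             efficiency = eff, entropy = ent,
                             stringsAsFactors = FALSE)
  }
  out <- if (n0 > 0) do.call(rbind, steps) else
    data.frame(step = integer(), removed = character(),
               measure_value = double(), n_remaining = integer(),
               largest_component = integer(), efficiency = double(),
               entropy = double(), stringsAsFactors = FALSE)
  structure(out, measure_name = measure, length_mode = length_mode,
            recompute = recompute,
            class = c("deletion_trajectory", "data.frame"))
}

#' @export
print.deletion_trajectory <- function(x, ...) {
  cat(sprintf("deletion_trajectory: %d steps, measure '%s'%s\n", nrow(x),
              attr(x, "measure_name"),
              if (isTRUE(attr(x, "recompute"))) "" else " (frozen ranking)"))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Area under a cascade decay curve
#'
#' Summarizes how fast a global metric decays along a deletion trajectory:
#' the sum of the metric over all steps (a discrete area; smaller means a
#' faster, more damaging decay).
#'
#' @param traj a `deletion_trajectory`.
#' @param metric `"efficiency"`, `"entropy"`, or `"largest_component"`.
#' @return numeric scalar.
#' @export
decay_auc <- function(traj,
                      metric = c("efficiency", "entropy",
                                 "largest_component")) {
  metric <- match.arg(metric)
  sum(traj[[metric]])
}
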