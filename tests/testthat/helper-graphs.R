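# graph builders and independent oracles shared across the suite

k_n <- function(n, w = 1) weighted_graph(w * (matrix(1, n, n) - diag(n)))

path_graph <- function(n, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  weighted_graph(m)
}

cycle_graph <- function(n, w = 1) {
  g <- path_graph(n, w)
  m <- g$weights
  m[1, n] <- m[n, 1] <- w
  weighted_graph(m)
}

star_graph <- function(n_leaves, w = 1) {
  m <- matrix(0, n_leaves + 1, n_leaves + 1)
  m[1, -1] <- m[-1, 1] <- w
  weighted_graph(m)
}

# Erdos-Renyi-style random graph; unit or exponential weights
random_graph <- function(n, p_edge = 0.5, weights = c("unit", "exp")) {
  weights <- match.arg(weights)
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- up[runif(length(up)) < p_edge]
  m[on] <- if (weights == "unit") 1 else rexp(length(on))
  weighted_graph(m + t(m))
}

random_connected_graph <- function(n, p_edge = 0.5,
                                   weights = c("unit", "exp")) {
  repeat {
    g <- random_graph(n, p_edge, weights)
    if (largest_component_size(g) == n) return(g)
  }
}

# independent union-find oracle for component sizes
uf_largest_component <- function(g) {
  n <- n_nodes(g)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ed <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(ed))) {
    a <- find(ed[k, 1]); b <- find(ed[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(max(table(roots)))
}

# all simple paths between a and b, as lists of node indices
all_simple_paths_idx <- function(adj, a, b) {
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == b) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (nx in which(adj[cur, ] > 0))
      if (!nx %in% path) walk(c(path, nx))
    invisible()
  }
  walk(a)
  out
}

# exhaustive all-geodesic betweenness (unordered pairs, unnormalized)
brute_betweenness <- function(g, length_mode = "inverse_weight") {
  n <- n_nodes(g)
  w <- g$weights
  len <- function(path) {
    steps <- cbind(path[-length(path)], path[-1])
    if (length_mode == "hop") nrow(steps)
    else sum(1 / w[steps])
  }
  btw <- numeric(n)
  for (j in seq_len(n - 1)) for (k in seq(j + 1, n)) {
    paths <- all_simple_paths_idx(w, j, k)
    if (length(paths) == 0) next
    lens <- vapply(paths, len, numeric(1))
    geo <- paths[abs(lens - min(lens)) < 1e-12]
    for (i in setdiff(seq_len(n), c(j, k))) {
      through <- sum(vapply(geo, function(p) i %in% p, logical(1)))
      btw[i] <- btw[i] + through / length(geo)
    }
  }
  btw
}

# exhaustive shortest-path-length global efficiency
brute_efficiency <- function(g, length_mode = "hop") {
  n <- n_nodes(g)
  w <- g$weights
  len <- function(path) {
    steps <- cbind(path[-length(path)], path[-1])
    if (length_mode == "hop") nrow(steps) else sum(1 / w[steps])
  }
  acc <- 0
  for (j in seq_len(n - 1)) for (k in seq(j + 1, n)) {
    paths <- all_simple_paths_idx(w, j, k)
    if (length(paths) == 0) next
    acc <- acc + 2 / min(vapply(paths, len, numeric(1)))
  }
  acc / (n * (n - 1))
}

# random discrete measure with masses in units of 1/L
random_measure <- function(support, L) {
  a <- as.vector(rmultinom(1, L, runif(length(support))))
  discrete_measure(support, a / L)
}

# curvature of every edge via the brute-force transport oracle
oracle_edge_curvatures <- function(g) {
  D <- hop_distances(g)
  ed <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  ed <- ed[order(ed[, 1], ed[, 2]), , drop = FALSE] # match the edge-table order
  vapply(seq_len(nrow(ed)), function(k) {
    i <- ed[k, 1]; j <- ed[k, 2]
    px <- node_distribution(g, i)
    py <- node_distribution(g, j)
    # common denominator of the neighborhood masses (unit-weight graphs)
    degs <- c(length(px$support), length(py$support))
    L <- Reduce(function(a, b) a * b / gcd2(a, b), degs)
    si <- match(px$support, g$node_ids)
    sj <- match(py$support, g$node_ids)
    1 - emd_bruteforce(px, py, D[si, sj, drop = FALSE], L) / D[i, j]
  }, numeric(1))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
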