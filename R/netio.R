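#' Construct a weighted undirected graph from a connectivity matrix
#'
#' The universal substrate of the package: an undirected graph with
#' nonnegative symmetric edge weights (streamline counts or densities,
#' treated as dimensionless), zero diagonal, and stable node identifiers.
#' Adjacency is implied by positive weight: `y` is a neighbor of `x`
#' iff `w[x, y] > 0`.
#'
#' Inputs that are asymmetric within a relative tolerance of `1e-9` are
#' symmetrized by averaging the two triangles; relative asymmetry above
#' `1e-6` is treated as a corrupt matrix and rejected. A nonzero diagonal
#' is forced to zero with a warning.
#'
#' @param weights numeric N x N matrix of nonnegative weights.
#' @param node_ids character vector of N unique node identifiers
#'   (default `"n1" ... "nN"`, or the matrix dimnames if present).
#' @param labels optional per-node text labels.
#' @param metadata optional data.frame of per-node metadata (coordinates,
#'   community tags), N rows aligned to `node_ids`.
#' @return an object of class `weighted_graph`: a list with elements
#'   `weights`, `node_ids`, `labels`, `metadata`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2))
#' n_nodes(g)
#' @export
weighted_graph <- function(weights, node_ids = NULL, labels = NULL,
                           metadata = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square, got ", nrow(weights), " x ",
         ncol(weights), call. = FALSE)
  storage.mode(weights) <- "double"
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite weight at cell (%d, %d)", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  bad <- which(weights < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative weight %g at cell (%d, %d)",
                 weights[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]),
         call. = FALSE)

  n <- nrow(weights)
  if (n > 0) {
    scale <- max(abs(weights), 1e-300)
    asym <- max(abs(weights - t(weights))) / scale
    if (asym > 1e-6)
      stop(sprintf(
        "matrix asymmetry (relative %.3g) exceeds 1e-6; refusing to symmetrize",
        asym), call. = FALSE)
    if (asym > 0) {
      if (asym > 1e-9)
        warning(sprintf(
          "asymmetric input (relative %.3g); symmetrized by averaging", asym),
          call. = FALSE)
      weights <- (weights + t(weights)) / 2
    }
    if (any(diag(weights) != 0)) {
      warning("nonzero diagonal forced to 0 (self-loops are not allowed)",
              call. = FALSE)
      diag(weights) <- 0
    }
  }
  if (is.null(node_ids)) {
    node_ids <- rownames(weights)
    if (is.null(node_ids))
      node_ids <- paste0("n", seq_len(n), recycle0 = TRUE)
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length must equal node count")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  dimnames(weights) <- list(node_ids, node_ids)
  if (!is.null(metadata) && nrow(metadata) != n)
    stop("metadata must have one row per node")

  structure(list(weights = weights, node_ids = node_ids, labels = labels,
                 metadata = metadata),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  w <- x$weights
  n_edges <- sum(w[upper.tri(w)] > 0)
  cat(sprintf("weighted_graph: %d nodes, %d edges, density %.3f\n",
              nrow(w), n_edges,
              if (nrow(w) > 1) n_edges / choose(nrow(w), 2) else 0))
  invisible(x)
}

#' Number of nodes of a graph
#' @param g a `weighted_graph`.
#' @return integer node count.
#' @export
n_nodes <- function(g) nrow(g$weights)

#' Edge list of a graph
#' @param g a `weighted_graph`.
#' @return data.frame with columns `x`, `y` (node ids, x before y in node
#'   order) and `weight`, one row per unordered edge.
#' @export
graph_edges <- function(g) {
  idx <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(x = g$node_ids[idx[, 1]], y = g$node_ids[idx[, 2]],
             weight = g$weights[idx], stringsAsFactors = FALSE)
}

# igraph view of the weighted graph (weights attached as 'weight')
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

resolve_node <- function(g, x) {
  if (is.character(x)) {
    i <- match(x, g$node_ids)
    if (is.na(i)) stop("unknown node id: ", x, call. = FALSE)
    return(i)
  }
  x <- as.integer(x)
  if (x < 1 || x > n_nodes(g)) stop("node index out of range: ", x,
                                    call. = FALSE)
  x
}

#' Read a dense connectivity matrix from a delimited text file
#'
#' Accepts a plain numeric N x N table, optionally with a header row and a
#' leading label column (auto-detected). The delimiter is auto-detected
#' among tab, comma and whitespace unless given.
#'
#' @param path file path.
#' @param delimiter field delimiter; `NULL` (default) auto-detects.
#' @param has_header logical; `NA` (default) auto-detects a non-numeric
#'   first row/column of labels.
#' @return a [weighted_graph].
#' @export
load_matrix <- function(path, delimiter = NULL, has_header = NA) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
                 else ""
  }
  probe <- strsplit(trimws(first),
                    if (delimiter == "") "[[:space:]]+" else delimiter)[[1]]
  numeric_like <- !is.na(suppressWarnings(as.numeric(probe))) |
    toupper(probe) %in% c("NA", "NAN", "INF", "-INF")
  if (is.na(has_header)) has_header <- !all(numeric_like)
  raw <- read.delim(path, sep = delimiter, header = has_header,
                    check.names = FALSE, stringsAsFactors = FALSE)
  node_ids <- NULL
  if (!is.numeric(raw[[1]]) &&
      anyNA(suppressWarnings(as.numeric(raw[[1]])))) {
    node_ids <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  } else if (has_header) {
    node_ids <- colnames(raw)
  }
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric or missing entry at cell (%d, %d) of %s",
                 bad[1, 1], bad[1, 2], path), call. = FALSE)
  dimnames(m) <- NULL
  # file inputs follow the averaging rule: any asymmetry is reconciled by
  # the mean of the two triangles, with a warning when it is material
  if (nrow(m) == ncol(m) && nrow(m) > 0) {
    asym <- max(abs(m - t(m))) / max(abs(m), 1e-300)
    if (asym > 1e-9) {
      warning(sprintf(
        "asymmetric input (relative %.3g); symmetrized by averaging", asym),
        call. = FALSE)
      m <- (m + t(m)) / 2
    }
  }
  weighted_graph(m, node_ids = node_ids)
}

#' Read a node metadata table
#'
#' TSV with columns `node_id`, `label`, and optionally `x`, `y`, `z`,
#' `community`.
#'
#' @param path file path.
#' @return data.frame of metadata rows.
#' @export
load_node_metadata <- function(path) {
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"node_id" %in% names(md))
    stop("metadata table must have a node_id column", call. = FALSE)
  md
}

#' Hop-distance matrix
#'
#' Shortest-path length counting edges (the binarized graph's geodesic),
#' computed by breadth-first search from each source. This is the metric
#' used as the transport cost in the curvature definition. Disconnected
#' pairs are `Inf` — a documented sentinel, never a large finite stand-in.
#'
#' @param g a `weighted_graph`.
#' @return N x N numeric matrix; `d[x, x] = 0`, `Inf` between components.
#' @export
hop_distances <- function(g) {
  d <- igraph::distances(as_igraph(g), weights = NA, algorithm = "unweighted")
  dimnames(d) <- list(g$node_ids, g$node_ids)
  d
}

#' Size of the largest connected component
#'
#' @param g a `weighted_graph`.
#' @return integer; node count of the largest component of the binarized
#'   graph (0 for the empty graph).
#' @export
largest_component_size <- function(g) {
  if (n_nodes(g) == 0) return(0L)
  as.integer(max(igraph::components(as_igraph(g))$csize))
}

format_num <- function(x) {
  ifelse(is.finite(x), sprintf("%.12g", x), as.character(x))
}

write_tsv12 <- function(df, path, append = FALSE) {
  out <- df
  for (k in seq_along(out))
    if (is.double(out[[k]])) out[[k]] <- format_num(out[[k]])
  suppressWarnings(write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = append))
}

#' Write an analysis result to a tab-separated file
#'
#' One header line, values at 12 significant digits so that a write/read
#' cycle is lossless at that precision. Curvature tables are written as two
#' sections (edge rows, then node rows) separated by a blank line.
#'
#' @param obj a `node_measures`, `curvature_table`, `deletion_trajectory`,
#'   `group_comparison` object or plain data.frame.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
save_table <- function(obj, path) UseMethod("save_table")

#' @export
save_table.data.frame <- function(obj, path) {
  write_tsv12(obj, path)
  invisible(path)
}

#' @export
save_table.curvature_table <- function(obj, path) {
  write_tsv12(obj$edges, path)
  cat("\n", file = path, append = TRUE)
  write_tsv12(obj$nodes, path, append = TRUE)
  invisible(path)
}

#' Read back a table written by [save_table()]
#'
#' @param path file path.
#' @return a data.frame (for curvature tables, a list with `edges` and
#'   `nodes` data.frames).
#' @export
load_table <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")
  if (length(blank) > 0 && blank[1] < length(lines)) {
    con1 <- textConnection(lines[seq_len(blank[1] - 1)])
    con2 <- textConnection(lines[seq(blank[1] + 1, length(lines))])
    on.exit({ close(con1); close(con2) })
    return(list(edges = read.delim(con1, stringsAsFactors = FALSE),
                nodes = read.delim(con2, stringsAsFactors = FALSE)))
  }
  read.delim(path, stringsAsFactors = FALSE)
}

#' Construct a per-node measure vector
#'
#' A per-node measure aligned to the graph's node order: a data.frame with
#' columns `node_id` and `value` plus a `measure_name` attribute. All nodal
#' measures in the package are returned in this form.
#'
#' @param node_ids node identifiers.
#' @param values numeric values, one per node.
#' @param measure_name name of the measure (e.g. `"strength"`).
#' @return a `node_measures` object.
#' @export
node_measures <- function(node_ids, values, measure_name) {
  stopifnot(length(node_ids) == length(values))
  structure(data.frame(node_id = node_ids, value = as.double(values),
                       stringsAsFactors = FALSE),
            measure_name = measure_name,
            class = c("node_measures", "data.frame"))
}

#' @export
print.node_measures <- function(x, ...) {
  cat(sprintf("node measure '%s' over %d nodes\n",
              attr(x, "measure_name"), nrow(x)))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Values of a node measure as a named numeric vector
#' @param m a `node_measures` object.
#' @return named numeric vector aligned to the graph's node order.
#' @export
measure_values <- function(m) setNames(m$value, m$node_id)
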