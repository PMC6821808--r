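#' Specification for a synthetic connectome
#'
#' The generator emulates the statistical structure of parcellated
#' structural connectomes: a symmetric nonnegative matrix whose positive
#' weights are i.i.d. exponential (as streamline counts empirically are),
#' with edges placed by a modular block model so that curvature and the
#' classical measures are heterogeneous across nodes, as in real brains.
#'
#' @param n_nodes number of nodes (default 116, a common low-resolution
#'   parcellation size).
#' @param density fraction of possible edges in (0, 1] (default 0.3,
#'   typical of streamline-count connectomes at this scale).
#' @param weight_scale mean of the exponential weight law (default 50,
#'   dimensionless streamline-count scale; all curvature results are
#'   invariant to it).
#' @param n_modules number of modules >= 1 (default 4).
#' @param within_between_ratio relative edge probability inside vs between
#'   modules (default 4).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 116, density = 0.3, weight_scale = 50,
                           n_modules = 4, within_between_ratio = 4,
                           seed = 1L) {
  stopifnot(n_nodes >= 2, density > 0, density <= 1, weight_scale > 0,
            n_modules >= 1, within_between_ratio > 0)
  if (density * n_nodes * (n_nodes - 1) / 2 < n_nodes - 1)
    warning("expected edge count below n_nodes - 1; ",
            "generated graphs are unlikely to be connected", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), density = density,
                 weight_scale = weight_scale,
                 n_modules = as.integer(n_modules),
                 within_between_ratio = within_between_ratio,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# module assignment and per-pair edge probabilities for the block model
block_model_probs <- function(spec) {
  n <- spec$n_nodes
  modules <- sort(rep_len(seq_len(spec$n_modules), n))
  up <- which(upper.tri(matrix(0, n, n)))
  rowi <- ((up - 1) %% n) + 1
  colj <- ((up - 1) %/% n) + 1
  within <- modules[rowi] == modules[colj]
  f_w <- mean(within)
  r <- spec$within_between_ratio
  p_b <- spec$density / (f_w * r + (1 - f_w))
  p_w <- min(1, r * p_b)
  list(upper_idx = up, within = within, p = ifelse(within, p_w, p_b),
       modules = modules)
}

# weights for a given edge set (indices into the upper triangle)
fill_weights <- function(n, upper_idx, weights) {
  w <- matrix(0, n, n)
  w[upper_idx] <- weights
  w + t(w)
}

#' Generate one synthetic connectome
#'
#' Edges are sampled independently per node pair at the block-model
#' probability implied by the requested density and module structure;
#' positive weights are i.i.d. exponential with mean `weight_scale`.
#' Fully reproducible from the spec's seed.
#'
#' @param spec a [synthetic_spec].
#' @return a `weighted_graph` with module assignments in `$metadata`.
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bm <- block_model_probs(spec)
  on <- runif(length(bm$upper_idx)) < bm$p
  idx <- bm$upper_idx[on]
  w <- fill_weights(spec$n_nodes, idx,
                    rexp(length(idx), rate = 1 / spec$weight_scale))
  weighted_graph(w, metadata = data.frame(community = bm$modules))
}

#' Localized group-difference effect for synthetic cohorts
#'
#' Describes the group-B alteration injected by [generate_cohort()]: every
#' edge incident to a target node is either scaled down by a multiplicative
#' factor or removed outright. This is the stand-in for localized
#' connectivity differences between clinical or age groups.
#'
#' @param target_nodes integer indices (or node ids) of affected nodes.
#' @param effect_type `"weight_scale_down"` or `"edge_removal"`.
#' @param effect_size multiplicative factor in (0, 1\]; ignored for
#'   `"edge_removal"`.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(target_nodes,
                        effect_type = c("weight_scale_down", "edge_removal"),
                        effect_size = 0.3) {
  effect_type <- match.arg(effect_type)
  stopifnot(effect_size > 0, effect_size <= 1)
  structure(list(target_nodes = target_nodes, effect_type = effect_type,
                 effect_size = effect_size),
            class = "effect_spec")
}

apply_effect <- function(w, effect, node_ids) {
  targets <- effect$target_nodes
  if (is.character(targets)) targets <- match(targets, node_ids)
  if (anyNA(targets) || any(targets < 1) || any(targets > nrow(w)))
    stop("effect target nodes outside the node set", call. = FALSE)
  f <- if (effect$effect_type == "edge_removal") 0 else effect$effect_size
  w[targets, ] <- w[targets, ] * f
  w[, targets] <- t(w[targets, ])
  w
}

#' Subject cohort on a shared node set
#'
#' @param graphs list of `weighted_graph`s, one per subject, all with
#'   identical node ids in identical order.
#' @param groups optional factor (or character) of group labels, one per
#'   subject; at most 2 levels (two are required for group comparison).
#' @param subject_ids optional subject identifiers.
#' @return object of class `cohort`.
#' @export
cohort <- function(graphs, groups = NULL, subject_ids = NULL) {
  stopifnot(length(graphs) >= 1)
  ids <- graphs[[1]]$node_ids
  for (g in graphs)
    if (!identical(g$node_ids, ids))
      stop("all subjects must share identical node ids in identical order",
           call. = FALSE)
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%03d", seq_along(graphs))
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != length(graphs))
      stop("one group label per subject required")
    if (nlevels(groups) > 2)
      stop("at most 2 group levels are supported")
  }
  structure(list(graphs = graphs, groups = groups,
                 subject_ids = subject_ids, node_ids = ids),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d nodes%s\n", length(x$graphs),
              length(x$node_ids),
              if (is.null(x$groups)) "" else
                paste0(" (", paste(table(x$groups), collapse = " + "),
                       " by group)")))
  invisible(x)
}

#' Generate a two-group synthetic cohort
#'
#' Subjects share the edge backbone drawn from the master seed (emulating a
#' common anatomical scaffold) and redraw independent exponential weights
#' from per-subject seeds spawned deterministically from the master seed —
#' this is the within-group variability the t-tests operate on. Group B
#' additionally receives the `effect` alteration at its target nodes.
#'
#' @param spec a [synthetic_spec]; its `seed` is the cohort master seed.
#' @param n_per_group subjects per group.
#' @param effect an [effect_spec] or `NULL` (null cohort: the two groups
#'   are exchangeable draws).
#' @return a [cohort] with groups `"A"` and `"B"`.
#' @export
generate_cohort <- function(spec, n_per_group, effect = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), n_per_group >= 1)
  if (!is.null(effect)) stopifnot(inherits(effect, "effect_spec"))
  set.seed(spec$seed)
  bm <- block_model_probs(spec)
  idx <- bm$upper_idx[runif(length(bm$upper_idx)) < bm$p]
  n_sub <- 2L * n_per_group
  subject_seeds <- sample.int(.Machine$integer.max, n_sub)
  groups <- rep(c("A", "B"), each = n_per_group)
  graphs <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    set.seed(subject_seeds[s])
    w <- fill_weights(spec$n_nodes, idx,
                      rexp(length(idx), rate = 1 / spec$weight_scale))
    if (!is.null(effect) && groups[s] == "B")
      w <- apply_effect(w, effect, paste0("n", seq_len(spec$n_nodes)))
    graphs[[s]] <- weighted_graph(w)
  }
  cohort(graphs, groups = groups)
}

#' Write a cohort to per-subject matrix files with a manifest
#'
#' @param cohort a [cohort].
#' @param dir output directory (created if needed).
#' @return invisible path of the manifest TSV (columns `subject_id`,
#'   `group`, `file`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$graphs))
  for (s in seq_along(cohort$graphs)) {
    files[s] <- file.path(dir, paste0(cohort$subject_ids[s], ".tsv"))
    w <- cohort$graphs[[s]]$weights
    df <- data.frame(node_id = rownames(w), as.data.frame(w),
                     check.names = FALSE)
    write_tsv12(df, files[s])
  }
  manifest <- data.frame(
    subject_id = cohort$subject_ids,
    group = if (is.null(cohort$groups)) NA_character_
            else as.character(cohort$groups),
    file = basename(files), stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.tsv")
  write_tsv12(manifest, mp)
  invisible(mp)
}

#' Read a cohort from a directory of matrix files
#'
#' Reads either a `manifest.tsv` (as written by [write_cohort()]) or all
#' `*.tsv`/`*.csv` matrix files in the directory.
#'
#' @param dir directory of per-subject matrices.
#' @param group optional group label to attach to every subject (used when
#'   assembling a two-group cohort from two directories).
#' @return a [cohort].
#' @export
read_cohort <- function(dir, group = NULL) {
  mp <- file.path(dir, "manifest.tsv")
  if (file.exists(mp)) {
    man <- read.delim(mp, stringsAsFactors = FALSE)
    files <- file.path(dir, man$file)
    ids <- man$subject_id
    groups <- if (!is.null(group)) rep(group, nrow(man))
              else if (all(!is.na(man$group))) man$group else NULL
  } else {
    files <- list.files(dir, pattern = "\\.(tsv|csv|txt)$",
                        full.names = TRUE)
    if (length(files) == 0) stop("no matrix files found in ", dir,
                                 call. = FALSE)
    ids <- sub("\\.[^.]+$", "", basename(files))
    groups <- if (!is.null(group)) rep(group, length(files)) else NULL
  }
  cohort(lapply(files, load_matrix), groups = groups, subject_ids = ids)
}
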