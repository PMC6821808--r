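#' Per-subject nodal measure matrix of a cohort
#'
#' @param cohort a [cohort].
#' @param measure one of `"curvature"`, `"weighted_curvature"`,
#'   `"strength"`, `"betweenness"`, `"clustering"`.
#' @param length_mode betweenness edge-length convention.
#' @return numeric matrix, nodes x subjects, dimnames set.
#' @export
cohort_measure_matrix <- function(cohort,
                                  measure = c("curvature",
                                              "weighted_curvature",
                                              "strength", "betweenness",
                                              "clustering"),
                                  length_mode = c("inverse_weight", "hop")) {
  measure <- match.arg(measure)
  length_mode <- match.arg(length_mode)
  vals <- vapply(cohort$graphs, function(g) {
    switch(measure,
           curvature = node_curvature(g)$value,
           weighted_curvature = weighted_node_curvature(g)$value,
           strength = node_strength(g)$value,
           betweenness = node_betweenness(g, length_mode)$value,
           clustering = clustering_coefficient(g)$value)
  }, numeric(length(cohort$node_ids)))
  dimnames(vals) <- list(cohort$node_ids, cohort$subject_ids)
  vals
}

#' Per-node two-sample t-tests between cohort groups
#'
#' Unpaired two-sided t-test at every node, assuming equal group variances
#' (pooled variance; the homoscedasticity convention), with Welch's
#' unequal-variance form available behind `var_equal = FALSE`. Nodes with
#' zero pooled variance get `t = 0`, `p = 1` and a flag rather than a
#' division by zero.
#'
#' @param values nodes x subjects numeric matrix (see
#'   [cohort_measure_matrix()]).
#' @param groups two-level factor over the subject columns, both levels
#'   with at least 2 subjects.
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return data.frame with columns `node_id`, `mean_a`, `mean_b`,
#'   `t_statistic`, `p_value`, `zero_variance`.
#' @export
pernode_ttest <- function(values, groups, var_equal = TRUE) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, ncol(values) == length(groups))
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stop("both groups need at least 2 subjects")

  ma <- rowMeans(values[, ia, drop = FALSE])
  mb <- rowMeans(values[, ib, drop = FALSE])
  va <- apply(values[, ia, drop = FALSE], 1, var)
  vb <- apply(values[, ib, drop = FALSE], 1, var)

  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  zero_var <- se == 0 | !is.finite(se)
  tstat <- ifelse(zero_var, 0, (ma - mb) / se)
  p <- ifelse(zero_var, 1, 2 * pt(-abs(tstat), df))
  data.frame(node_id = if (is.null(rownames(values)))
               paste0("n", seq_len(nrow(values))) else rownames(values),
             mean_a = ma, mean_b = mb, t_statistic = tstat, p_value = p,
             zero_variance = zero_var, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Controls the family-wise error rate at level `alpha` over `m = length(p)`
#' tests. Sort the p-values ascending; the i-th smallest is rejected iff
#' every \eqn{j \le i} satisfies
#' \deqn{p_{(j)} \le 1 - (1 - \alpha)^{1/(m - j + 1)}.}
#' The rejection decisions are primary; Sidak-adjusted p-values
#' \eqn{1 - (1 - p_{(i)})^{m - i + 1}} (monotonized by running maximum) are
#' also returned for convenience.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param alpha FWER level in (0, 1), default 0.05.
#' @return list with `significant` (logical flags in the original order),
#'   `p_adjusted`, `alpha`, `m`.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1), alpha > 0, alpha < 1)
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  thresh <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  ok <- ps <= thresh
  n_rej <- if (all(ok)) m else which(!ok)[1] - 1L
  sig <- logical(m)
  sig[ord[seq_len(n_rej)]] <- TRUE

  padj_sorted <- cummax(1 - (1 - ps)^(m - seq_len(m) + 1))
  padj <- numeric(m)
  padj[ord] <- pmin(1, padj_sorted)
  list(significant = sig, p_adjusted = padj, alpha = alpha, m = m)
}

#' Two-group nodal comparison with family-wise error control
#'
#' Computes the chosen nodal measure for every subject, runs per-node
#' pooled-variance t-tests between the two groups, and applies the
#' Holm-Sidak step-down correction with `m` equal to the number of nodes.
#'
#' @param cohort a [cohort] with two group labels.
#' @param measure nodal measure name (see [cohort_measure_matrix()]).
#' @param alpha FWER level (default 0.05).
#' @param var_equal pooled-variance t-tests (default TRUE).
#' @param length_mode betweenness edge-length convention.
#' @return object of class `group_comparison`: data.frame with per-node
#'   `node_id`, `mean_a`, `mean_b`, `t_statistic`, `p_value`, `p_adjusted`,
#'   `significant`, `zero_variance`; attributes `alpha`, `m`,
#'   `measure_name`.
#' @export
group_compare <- function(cohort, measure = "curvature", alpha = 0.05,
                          var_equal = TRUE,
                          length_mode = c("inverse_weight", "hop")) {
  if (is.null(cohort$groups))
    stop("cohort has no group labels", call. = FALSE)
  vals <- cohort_measure_matrix(cohort, measure, length_mode)
  tt <- pernode_ttest(vals, cohort$groups, var_equal = var_equal)
  hs <- holm_sidak(tt$p_value, alpha)
  tt$p_adjusted <- hs$p_adjusted
  tt$significant <- hs$significant
  structure(tt, alpha = alpha, m = hs$m, measure_name = measure,
            class = c("group_comparison", "data.frame"))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group_comparison: measure '%s', %d nodes, %d significant at FWER %.3g\n",
    attr(x, "measure_name"), attr(x, "m"), sum(x$significant),
    attr(x, "alpha")))
  invisible(x)
}

#' Cross-subject consistency map of top-ranked nodes
#'
#' For each subject, mark its top `ceiling(top_fraction * N)` nodes by the
#' measure (ties broken by node index); return, per node, the number of
#' subjects in which it is marked. High counts identify nodes that rank
#' high consistently across the cohort.
#'
#' @param cohort a [cohort].
#' @param measure nodal measure name.
#' @param top_fraction fraction in (0, 1) of nodes to mark (default 0.25).
#' @param values optional precomputed nodes x subjects matrix (skips the
#'   measure computation).
#' @return integer vector of per-node counts, named by node id.
#' @export
consistency_map <- function(cohort, measure = "curvature",
                            top_fraction = 0.25, values = NULL) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  if (is.null(values)) values <- cohort_measure_matrix(cohort, measure)
  n <- nrow(values)
  k <- ceiling(top_fraction * n)
  counts <- integer(n)
  for (s in seq_len(ncol(values))) {
    top <- order(-values[, s], seq_len(n))[seq_len(k)]
    counts[top] <- counts[top] + 1L
  }
  setNames(counts, rownames(values))
}

#' Per-subject correlation between two nodal measures
#'
#' Pearson r across nodes, one per subject, with the across-subject mean
#' and variance — the ingredients of a cross-measure correlation histogram.
#' Subjects in which either measure is constant have no defined r and are
#' skipped with a flag.
#'
#' @param cohort a [cohort].
#' @param measure_a,measure_b nodal measure names.
#' @param values_a,values_b optional precomputed nodes x subjects matrices
#'   overriding the measure computation.
#' @return list with `r` (per-subject values, NA where skipped),
#'   `skipped` (logical), `mean`, `variance`.
#' @export
measure_correlation_histogram <- function(cohort, measure_a, measure_b,
                                          values_a = NULL, values_b = NULL) {
  va <- if (is.null(values_a)) cohort_measure_matrix(cohort, measure_a)
        else values_a
  vb <- if (is.null(values_b)) cohort_measure_matrix(cohort, measure_b)
        else values_b
  ns <- ncol(va)
  r <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    if (sd(va[, s]) == 0 || sd(vb[, s]) == 0) next
    r[s] <- cor(va[, s], vb[, s])
  }
  skipped <- is.na(r)
  ok <- r[!skipped]
  list(r = setNames(r, cohort$subject_ids), skipped = skipped,
       mean = if (length(ok)) mean(ok) else NA_real_,
       variance = if (length(ok) > 1) var(ok) else 0)
}
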