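#' Discrete probability measure on a node set
#'
#' A probability mass assignment over an ordered support of node ids, the
#' building block of the curvature computation (each node's neighborhood
#' measure is one of these).
#'
#' @param support character or integer vector of unique support ids.
#' @param masses nonnegative reals summing to 1 (within 1e-12).
#' @return object of class `discrete_measure` with fields `support`, `masses`.
#' @examples
#' discrete_measure(c("a", "b"), c(0.5, 0.5))
#' @export
discrete_measure <- function(support, masses) {
  if (length(support) != length(masses))
    stop("support and masses must have equal length")
  if (anyDuplicated(support)) stop("support ids must be unique")
  masses <- as.double(masses)
  if (any(masses < 0)) stop("masses must be nonnegative")
  if (abs(sum(masses) - 1) > 1e-12)
    stop(sprintf("masses must sum to 1 (got %.15g)", sum(masses)))
  structure(list(support = support, masses = masses),
            class = "discrete_measure")
}

#' @export
print.discrete_measure <- function(x, ...) {
  cat("discrete_measure on", length(x$support), "points\n")
  print(setNames(x$masses, x$support))
  invisible(x)
}

#' Earth mover's distance (Wasserstein-1) between discrete measures
#'
#' Solves the balanced transportation linear program
#' \deqn{W_1(p, q) = \min_\pi \sum_{ij} c_{ij} \pi_{ij}}
#' over plans \eqn{\pi \ge 0} whose row sums equal the masses of `p` and
#' whose column sums equal the masses of `q`. The solver is an exact
#' transportation simplex; the result contract is the optimal value within
#' 1e-9 together with a feasible plan attaining it (the optimal plan itself
#' need not be unique).
#'
#' Zero-mass support points are dropped before solving and restored as
#' zero rows/columns of the returned plan.
#'
#' @param p,q `discrete_measure` objects.
#' @param cost numeric matrix of nonnegative finite costs,
#'   `length(p$support)` x `length(q$support)` (typically hop distances).
#' @return list of class `transport_plan` with `dist` (the W1 value) and
#'   `plan` (the transference matrix, dimnames from the supports).
#' @examples
#' p <- discrete_measure(c("a"), 1)
#' q <- discrete_measure(c("b"), 1)
#' emd(p, q, matrix(1, 1, 1))$dist
#' @export
emd <- function(p, q, cost) {
  stopifnot(inherits(p, "discrete_measure"), inherits(q, "discrete_measure"))
  cost <- as.matrix(cost)
  if (nrow(cost) != length(p$support) || ncol(cost) != length(q$support))
    stop("cost dimensions must match the supports")
  if (any(!is.finite(cost)))
    stop("cost matrix contains non-finite entries")
  if (any(cost < 0)) stop("cost matrix must be nonnegative")

  ip <- which(p$masses > 0)
  iq <- which(q$masses > 0)
  res <- .emd_lp_cpp(p$masses[ip], q$masses[iq],
                     cost[ip, iq, drop = FALSE])
  plan <- matrix(0, length(p$support), length(q$support),
                 dimnames = list(p$support, q$support))
  plan[ip, iq] <- res$plan
  structure(list(dist = res$cost, plan = plan), class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("transport_plan: W1 = %.6g (%d x %d)\n", x$dist,
              nrow(x$plan), ncol(x$plan)))
  invisible(x)
}

#' Brute-force earth mover's distance by exhaustive enumeration
#'
#' Independent oracle for [emd()]: the masses are rounded to multiples of
#' `1/resolution` and the exact minimum over all integer transport plans in
#' those units is found by recursive enumeration (with exact
#' branch-and-bound pruning, which discards only provably suboptimal
#' branches). When `resolution` is a common denominator of the masses this
#' equals the LP optimum.
#'
#' Guarded to small supports (at most 6 points each) because the number of
#' integer plans grows combinatorially.
#'
#' @param p,q `discrete_measure` objects with supports of at most 6 points.
#' @param cost nonnegative cost matrix as in [emd()].
#' @param resolution integer L; masses are expressed in units of 1/L.
#' @return the minimal transport cost (numeric scalar).
#' @export
emd_bruteforce <- function(p, q, cost, resolution) {
  stopifnot(inherits(p, "discrete_measure"), inherits(q, "discrete_measure"))
  if (length(p$support) > 6 || length(q$support) > 6)
    stop("brute-force oracle is limited to supports of at most 6 points")
  L <- as.integer(resolution)
  stopifnot(L >= 1)
  a <- round(p$masses * L)
  b <- round(q$masses * L)
  if (max(abs(a - p$masses * L)) > 1e-6 || max(abs(b - q$masses * L)) > 1e-6)
    stop("masses are not multiples of 1/resolution")
  if (sum(a) != L || sum(b) != L)
    stop("rounded masses do not sum to resolution")
  cost <- as.matrix(cost)
  n <- length(a); m <- length(b)

  # cheapest achievable cost for each unit of remaining row mass
  row_min <- apply(cost, 1, min)
  best <- Inf
  rem <- b

  # assign row i's mass across columns, cell by cell
  recurse <- function(i, j, row_left, acc) {
    lb <- acc + row_left * row_min[i]
    if (i < n && n >= 1)
      lb <- lb + sum(a[seq.int(i + 1, length.out = n - i)] *
                       row_min[seq.int(i + 1, length.out = n - i)])
    if (lb >= best) return(invisible(NULL))
    if (row_left == 0) {
      if (i == n) { best <<- min(best, acc); return(invisible(NULL)) }
      recurse(i + 1, 1L, a[i + 1], acc)
      return(invisible(NULL))
    }
    if (j > m) return(invisible(NULL))
    if (j == m) {
      if (rem[j] >= row_left) {
        rem[j] <<- rem[j] - row_left
        recurse(i, j, 0L, acc + row_left * cost[i, j])
        rem[j] <<- rem[j] + row_left
      }
      return(invisible(NULL))
    }
    for (t in 0:min(row_left, rem[j])) {
      rem[j] <<- rem[j] - t
      recurse(i, j + 1L, row_left - t, acc + t * cost[i, j])
      rem[j] <<- rem[j] + t
    }
    invisible(NULL)
  }
  recurse(1L, 1L, a[1], 0)
  best / L
}
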