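#' Weighted PageRank on a learned gene network
#'
#' Iterates
#' \deqn{PR_i^{(k)} = (1-d)/n + d \sum_{j \in M_i} \frac{|G_{ij}|}{\sum_{t \in M_j} |G_{tj}|} PR_j^{(k-1)}}
#' from the uniform vector 1/n until the largest absolute per-gene change
#' falls below `tol`, where \eqn{M_i} is the neighbour set of gene i and
#' \eqn{|G_{ij}|} the learned edge weight. Nodes whose incident weights sum
#' to zero (dangling under the weighting) redistribute uniformly over all
#' genes, which keeps the iteration stochastic, so scores always sum to 1.
#'
#' @param G symmetric nonnegative weight matrix (magnitudes are taken, so a
#'   signed matrix is also accepted) with gene dimnames; zero diagonal.
#' @param d damping factor in (0,1); 0.85 by convention.
#' @param tol convergence threshold on `max |PR^k - PR^{k-1}|`; the
#'   published criterion is 0.005.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with a warning and `converged = FALSE`.
#' @return list with `scores` (named, sums to 1), `iterations`, `converged`.
#' @export
weighted_pagerank <- function(G, d = 0.85, tol = 0.005, max_iter = 1000L) {
  if (!is.matrix(G) || nrow(G) != ncol(G) || nrow(G) == 0L)
    stop_validation("G must be a nonempty square matrix")
  if (d <= 0 || d >= 1) stop_validation("damping d must be in (0,1)")
  if (tol <= 0) stop_validation("tol must be positive")
  G <- abs(G)
  n <- nrow(G)
  colsum <- colSums(G)
  dangling <- colsum == 0
  P <- G
  if (any(!dangling))
    P[, !dangling] <- sweep(G[, !dangling, drop = FALSE], 2,
                            colsum[!dangling], "/")
  pr <- rep(1 / n, n)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    new <- (1 - d) / n + d * as.vector(P %*% pr) +
      d * sum(pr[dangling]) / n
    if (max(abs(new - pr)) < tol) {
      pr <- new
      converged <- TRUE
      break
    }
    pr <- new
  }
  if (!converged)
    warning("PageRank did not reach tol = ", tol, " within ", max_iter,
            " iterations; returning last iterate")
  names(pr) <- rownames(G)
  list(scores = pr, iterations = it, converged = converged)
}

#' Stability selection over repeated scoring runs
#'
#' Given the top-gene sets of `t` repeated runs (each run re-learns the edge
#' weights from a fresh random initialization and re-scores by PageRank),
#' selects the genes appearing in at least `b` of the runs.
#'
#' @param run_tops list of character vectors, one top-N set per run.
#' @param b minimum appearance count, `1 <= b <= length(run_tops)`
#'   (inclusive: a gene appearing exactly `b` times is selected).
#' @return list with `selected` (sorted gene ids) and `counts` (named
#'   integer vector of appearance counts for every gene that appeared).
#' @examples
#' stability_select(list(c("a", "b"), c("a", "c"), c("a", "b")), b = 2)
#' @export
stability_select <- function(run_tops, b) {
  t_runs <- length(run_tops)
  if (!is.numeric(b) || length(b) != 1L || b < 1L)
    stop_validation("b must be a positive count")
  if (b > t_runs)
    stop_validation("b (", b, ") must not exceed the number of runs (",
                    t_runs, ")")
  counts <- table(unlist(lapply(run_tops, unique), use.names = FALSE))
  counts <- setNames(as.integer(counts), names(counts))
  list(selected = sort(names(counts)[counts >= b]), counts = counts)
}
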