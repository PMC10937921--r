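#' Wasserstein-1 distance between two distributions on a graph
#'
#' Optimal-transport cost between probability vectors `p_i` and `p_j` on a
#' common vertex set, with ground cost `dist_matrix` (in the curvature
#' pipeline, the shortest-path metric). The exact solver runs a
#' successive-shortest-path min-cost flow on the transportation problem and
#' is the reference; the Sinkhorn solver is an entropically regularized
#' alternative for large networks.
#'
#' Because the pipeline's ground cost is a metric (zero diagonal, triangle
#' inequality), mass shared between the two distributions can be left in
#' place and only the signed difference routed (`reduce = TRUE`); for an
#' arbitrary cost matrix set `reduce = FALSE`.
#'
#' @param p_i,p_j probability vectors over the same vertex set (masses must
#'   agree within 1e-6).
#' @param dist_matrix nonnegative ground-cost matrix.
#' @param method `"exact_lp"` or `"sinkhorn"`.
#' @param reduce transport only the signed difference (valid for metric
#'   costs; default `FALSE`).
#' @param trunc_delta cumulative small-mass truncation applied to each input
#'   before solving (default 0 = exact marginals).
#' @param want_plan also return the optimal coupling (exact solver only).
#' @param eps Sinkhorn entropic regularization, as a fraction of the maximum
#'   ground cost (default 0.01).
#' @param max_iter,tol Sinkhorn iteration cap and marginal tolerance.
#' @return The transport cost, or (with `want_plan = TRUE`) a list with
#'   `cost` and the coupling matrix `plan`.
#' @export
wasserstein1 <- function(p_i, p_j, dist_matrix,
                         method = c("exact_lp", "sinkhorn"),
                         reduce = FALSE, trunc_delta = 0,
                         want_plan = FALSE,
                         eps = 0.01, max_iter = 20000, tol = 1e-10) {
  method <- match.arg(method)
  p_i <- as.numeric(p_i)
  p_j <- as.numeric(p_j)
  if (length(p_i) != length(p_j) || length(p_i) != nrow(dist_matrix) ||
      nrow(dist_matrix) != ncol(dist_matrix)) {
    abort("p_i, p_j and dist_matrix must share one vertex set")
  }
  if (any(p_i < 0) || any(p_j < 0)) abort("negative mass in input distribution")
  if (abs(sum(p_i) - sum(p_j)) > 1e-6) {
    abort("marginal mass mismatch exceeds 1e-6")
  }
  if (any(!is.finite(dist_matrix))) abort("ground cost must be finite")
  if (trunc_delta > 0) {
    p_i <- truncate_mass(p_i, trunc_delta)
    p_j <- truncate_mass(p_j, trunc_delta)
  }
  if (method == "exact_lp") {
    res <- w1_exact_cpp(p_i, p_j, dist_matrix, reduce = reduce,
                        want_plan = want_plan)
    if (want_plan) {
      return(list(cost = res$cost, plan = res$plan))
    }
    return(res$cost)
  }
  sinkhorn_w1(p_i, p_j, dist_matrix, eps = eps, max_iter = max_iter, tol = tol)
}

truncate_mass <- function(p, delta) {
  ord <- order(p)
  cum <- cumsum(p[ord])
  drop <- ord[cum < delta & p[ord] > 0]
  p[drop] <- 0
  p / sum(p)
}

# Log-domain Sinkhorn; returns the *unregularized* cost of the entropic plan,
# which converges to W1 as eps -> 0.
sinkhorn_w1 <- function(p, q, C, eps = 0.01, max_iter = 20000, tol = 1e-10) {
  si <- which(p > 0)
  sj <- which(q > 0)
  a <- p[si] / sum(p[si])
  b <- q[sj] / sum(q[sj])
  M <- C[si, sj, drop = FALSE]
  reg <- eps * max(M, 1e-300)
  if (reg == 0) reg <- eps
  logsumexp_rows <- function(X) {
    m <- apply(X, 1, max)
    m + log(rowSums(exp(X - m)))
  }
  f <- rep(0, length(a))
  g <- rep(0, length(b))
  la <- log(a)
  lb <- log(b)
  for (it in seq_len(max_iter)) {
    f <- reg * (la - logsumexp_rows(sweep(-M, 2, g, "+") / reg))
    g <- reg * (lb - logsumexp_rows(t(sweep(-M, 1, f, "+")) / reg))
    if (it %% 20 == 0 || it == max_iter) {
      lg <- (outer(f, g, "+") - M) / reg
      gamma <- exp(lg)
      err <- max(abs(rowSums(gamma) - a), abs(colSums(gamma) - b))
      if (err < tol) break
    }
  }
  lg <- (outer(f, g, "+") - M) / reg
  gamma <- exp(lg)
  sum(gamma * M)
}
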