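#' Random-walk graph Laplacian of a gene network
#'
#' `L = I - K^{-1} C_N`, where `C_N` is the shifted-correlation adjacency
#' restricted to network edges (zero diagonal) and `K` the diagonal of its
#' row sums (weighted degrees). The similar symmetric matrix
#' `K^{-1/2} C_N K^{-1/2}` is eigendecomposed once so the heat kernel at any
#' scale is a cheap reconstruction.
#'
#' @param network a `gene_network` from [build_correlation_network()].
#' @return A `graph_laplacian` object.
#' @export
build_laplacian <- function(network) {
  A <- shifted_adjacency(network)
  K <- rowSums(A)
  if (any(K <= 0)) {
    abort(paste0("zero weighted degree at vertex: ",
                 names(K)[which(K <= 0)[1]]))
  }
  L <- diag(nrow(A)) - A / K
  dimnames(L) <- dimnames(A)
  s <- 1 / sqrt(K)
  S <- A * outer(s, s) # K^{-1/2} C_N K^{-1/2}, symmetric
  eig <- eigen(S, symmetric = TRUE)
  structure(
    list(L = L, K = K, vertices = rownames(A),
         eig_values = eig$values, eig_vectors = eig$vectors,
         sqrtK = sqrt(K), isqrtK = s),
    class = "graph_laplacian"
  )
}

#' @export
print.graph_laplacian <- function(x, ...) {
  cat("<graph_laplacian> ", length(x$vertices), " vertices\n", sep = "")
  invisible(x)
}

#' Heat-kernel diffusion at scale tau
#'
#' `D = exp(-tau L)`: row i is the probability distribution reached by
#' diffusing a delta at vertex i for pseudotime tau. Tiny negative entries
#' from the spectral reconstruction are clipped at zero and rows
#' renormalized, guarded by a 1e-8 mass-error check.
#'
#' @param laplacian a `graph_laplacian`.
#' @param tau nonnegative diffusion scale.
#' @return The row-stochastic diffusion matrix.
#' @export
diffuse <- function(laplacian, tau) {
  stopifnot(inherits(laplacian, "graph_laplacian"))
  if (tau < 0) abort("tau must be nonnegative")
  U <- laplacian$eig_vectors
  ex <- exp(-tau * (1 - laplacian$eig_values))
  # e^{-tau L} = K^{-1/2} U diag(ex) U' K^{1/2}
  D <- (laplacian$isqrtK * U) %*% (ex * t(U * laplacian$sqrtK))
  neg <- pmin(D, 0)
  if (max(abs(rowSums(neg))) > 1e-8) {
    abort("diffusion produced negative mass beyond tolerance")
  }
  D[D < 0] <- 0
  rs <- rowSums(D)
  if (max(abs(rs - 1)) > 1e-6) abort("diffusion rows lost probability mass")
  D <- D / rs
  dimnames(D) <- list(laplacian$vertices, laplacian$vertices)
  D
}

#' Default diffusion-scale grid
#'
#' `n` scales with log10(tau) equally spaced over `log10_range`
#' (101 points over \[-2, 2\] by default).
#'
#' @param n number of grid points.
#' @param log10_range length-2 range of log10(tau).
#' @return Numeric vector of tau values.
#' @export
default_tau_grid <- function(n = 101, log10_range = c(-2, 2)) {
  10^seq(log10_range[1], log10_range[2], length.out = n)
}

#' Per-edge curvature at one diffusion scale
#'
#' `kappa_ij = 1 - W1(p_i, p_j) / d_ij` for each network edge, where the
#' transport ground cost inside W1 is the shortest-path metric, while the
#' denominator `d_ij` is the *direct* edge cost `1 / rho_shifted`. With a
#' multi-hop path undercutting a direct edge, kappa at tau = 0 can therefore
#' exceed 0; nothing is clamped.
#'
#' @param network a `gene_network`.
#' @param distributions row-stochastic matrix from [diffuse()] (rows indexed
#'   by network vertices).
#' @param dist_matrix shortest-path matrix (defaults to the network's own).
#' @param trunc_delta cumulative small-mass truncation applied to each
#'   distribution before the transport solve (default 1e-4; 0 disables).
#' @return Numeric vector of per-edge kappa, aligned with `network$edges`.
#' @export
edge_curvature <- function(network, distributions, dist_matrix = network$dist,
                           trunc_delta = 1e-4) {
  stopifnot(inherits(network, "gene_network"))
  v <- network$vertices
  D <- distributions[v, v, drop = FALSE]
  dm <- dist_matrix[v, v, drop = FALSE]
  ei <- match(network$edges$gene_a, v) - 1L
  ej <- match(network$edges$gene_b, v) - 1L
  edge_kappa_cpp(D, dm, ei, ej, network$edges$cost, trunc_delta)
}

#' Sweep curvature over the diffusion-scale grid
#'
#' Computes the per-edge Ollivier-Ricci curvature trajectory across the full
#' tau grid, using the exact transport solver (or Sinkhorn).
#'
#' @param network a `gene_network`.
#' @param tau_grid diffusion scales (default [default_tau_grid()]).
#' @param method `"exact_lp"` (reference) or `"sinkhorn"`.
#' @param trunc_delta support-truncation threshold (see [edge_curvature()]).
#' @param sinkhorn_eps entropic regularization when `method = "sinkhorn"`.
#' @return A `curvature_field`: edges, `kappa` matrix (edges x scales),
#'   `tau_grid`, solver settings.
#' @export
curvature_sweep <- function(network, tau_grid = default_tau_grid(),
                            method = c("exact_lp", "sinkhorn"),
                            trunc_delta = 1e-4, sinkhorn_eps = 0.01) {
  method <- match.arg(method)
  lap <- build_laplacian(network)
  kappa <- matrix(NA_real_, nrow(network$edges), length(tau_grid))
  v <- network$vertices
  dm <- network$dist[v, v, drop = FALSE]
  ei <- match(network$edges$gene_a, v)
  ej <- match(network$edges$gene_b, v)
  if (method == "exact_lp") {
    # exact W1 as min-cost flow routed over the network's own edges
    # (equivalent to the dense transportation solve against the
    # shortest-path metric); the persistent solver warm-starts each edge's
    # dual potentials from the previous scale
    solver <- sweep_solver_new(length(v), ei - 1L, ej - 1L,
                               network$edges$cost, nrow(network$edges))
  }
  for (k in seq_along(tau_grid)) {
    D <- diffuse(lap, tau_grid[k])
    if (method == "exact_lp") {
      kappa[, k] <- edge_kappa_warm_cpp(solver, D, ei - 1L, ej - 1L,
                                        network$edges$cost, trunc_delta)
    } else {
      kappa[, k] <- vapply(seq_along(ei), function(e) {
        w <- wasserstein1(D[ei[e], ], D[ej[e], ], dm, method = "sinkhorn",
                          eps = sinkhorn_eps, trunc_delta = trunc_delta)
        1 - w / network$edges$cost[e]
      }, 0.0)
    }
  }
  structure(
    list(edges = network$edges[, c("gene_a", "gene_b", "cost")],
         kappa = kappa, tau_grid = tau_grid, method = method,
         trunc_delta = trunc_delta),
    class = "curvature_field"
  )
}

#' @export
print.curvature_field <- function(x, ...) {
  cat("<curvature_field> ", nrow(x$kappa), " edges x ", ncol(x$kappa),
      " scales (", x$method, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.curvature_field <- function(x, ...) {
  df <- as_tibble(x$kappa, .name_repair = ~ as.character(seq_along(.x)))
  names(df) <- as.character(x$tau_grid)
  dplyr::bind_cols(x$edges[, c("gene_a", "gene_b")], df) |>
    tidyr::pivot_longer(-c("gene_a", "gene_b"), names_to = "tau",
                        values_to = "kappa") |>
    mutate(tau = as.numeric(.data$tau))
}

#' @export
glance.curvature_field <- function(x, ...) {
  tibble(
    n_edges = nrow(x$kappa), n_scales = ncol(x$kappa),
    tau_min = min(x$tau_grid), tau_max = max(x$tau_grid),
    kappa_min = min(x$kappa), kappa_max = max(x$kappa),
    method = x$method
  )
}

#' Critical diffusion scale
#'
#' The smallest grid tau at which the upper `percentile` of all edge
#' curvatures (linear-interpolation percentile) reaches `kappa_threshold`.
#'
#' @param field a `curvature_field`.
#' @param percentile percentile of edge kappa values (default 99).
#' @param kappa_threshold curvature threshold (default 0.75).
#' @return The critical tau (a grid value).
#' @export
find_tau_crit <- function(field, percentile = 99, kappa_threshold = 0.75) {
  stopifnot(inherits(field, "curvature_field"))
  p99 <- apply(field$kappa, 2, quantile, probs = percentile / 100, type = 7)
  hit <- which(p99 >= kappa_threshold)
  if (length(hit) == 0) {
    abort(paste0("the ", percentile, "th percentile of kappa never reaches ",
                 kappa_threshold, "; extend the tau grid"))
  }
  field$tau_grid[hit[1]]
}

#' Integral-smoothed curvature up to the critical scale
#'
#' Per-edge trapezoidal integral of kappa over linear tau from 0 to
#' `tau_crit`, with the analytic point (tau = 0, kappa = 0) prepended to the
#' (log-spaced, hence unevenly partitioned) grid. Optionally normalized by
#' `tau_crit` to a mean curvature.
#'
#' @param field a `curvature_field`.
#' @param tau_crit a grid tau, typically from [find_tau_crit()].
#' @param normalize divide the integral by `tau_crit` (default `FALSE`,
#'   the literal integral).
#' @return Numeric vector of per-edge integrated curvature.
#' @export
integral_curvature <- function(field, tau_crit, normalize = FALSE) {
  stopifnot(inherits(field, "curvature_field"))
  idx <- which(abs(field$tau_grid - tau_crit) < 1e-12 * max(1, tau_crit))
  if (length(idx) != 1) abort("tau_crit must be a grid value")
  taus <- c(0, field$tau_grid[seq_len(idx)])
  K <- cbind(0, field$kappa[, seq_len(idx), drop = FALSE])
  dt <- diff(taus)
  mid <- (K[, -1, drop = FALSE] + K[, -ncol(K), drop = FALSE]) / 2
  out <- as.numeric(mid %*% dt)
  if (normalize) out <- out / tau_crit
  out
}

#' Summarize a curvature field at its critical scale
#'
#' Convenience wrapper: finds `tau_crit`, extracts per-edge `kappa_crit` (the
#' curvature at `tau_crit`) and `kappa_bar_crit` (the integral up to it), and
#' returns the edge table augmented with both.
#'
#' @param field a `curvature_field`.
#' @inheritParams find_tau_crit
#' @inheritParams integral_curvature
#' @return A list with `tau_crit` and an `edges` tibble carrying
#'   `kappa_crit`, `kappa_bar_crit`.
#' @export
critical_curvature <- function(field, percentile = 99, kappa_threshold = 0.75,
                               normalize = FALSE) {
  tau_crit <- find_tau_crit(field, percentile, kappa_threshold)
  idx <- which(field$tau_grid == tau_crit)
  edges <- field$edges |>
    mutate(
      kappa_crit = field$kappa[, idx],
      kappa_bar_crit = integral_curvature(field, tau_crit, normalize)
    )
  list(tau_crit = tau_crit, edges = edges)
}

#' Write a curvature field as TSVs
#'
#' A wide trajectory table (edge, then one column per grid tau) and, when
#' critical-scale summaries are supplied, a summary table.
#'
#' @param field a `curvature_field`.
#' @param path output path for the trajectory TSV.
#' @param summary optional result of [critical_curvature()].
#' @param summary_path output path for the summary TSV.
#' @export
write_curvature_tsv <- function(field, path, summary = NULL,
                                summary_path = NULL) {
  wide <- dplyr::bind_cols(
    field$edges[, c("gene_a", "gene_b")],
    as_tibble(field$kappa,
              .name_repair = ~ paste0("tau_", signif(field$tau_grid, 8)))
  )
  readr::write_tsv(wide, path)
  if (!is.null(summary) && !is.null(summary_path)) {
    readr::write_tsv(summary$edges, summary_path)
  }
  invisible(path)
}
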