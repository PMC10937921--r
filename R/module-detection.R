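#' Curvature-weighted Louvain gene modules
#'
#' Partitions the network by weighted-modularity Louvain clustering with the
#' integrated curvature `kappa_bar_crit` of each edge as its modularity
#' weight, so the partition maximizes integrated curvature within modules
#' and minimizes it between modules.
#'
#' Newman modularity assumes nonnegative weights; negative integrated
#' curvatures are clamped at 0 by default (a negative-curvature edge is then
#' maximally penalized as a within-module edge), with the clamped count
#' reported. `negative_weights = "passthrough"` forwards raw weights to the
#' underlying implementation for comparison.
#'
#' @param network a `gene_network`.
#' @param kappa_bar_weights per-edge weights aligned with `network$edges`
#'   (typically `kappa_bar_crit` from [critical_curvature()]).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed making the (randomized) Louvain sweep reproducible.
#' @param negative_weights `"clamp"` (default) or `"passthrough"`.
#' @param n_restarts best-modularity-of-k restarts (default 1).
#' @return A `module_assignment` tibble (`gene`, `module`) with modules
#'   numbered by descending size; attributes record modularity and sizes.
#' @export
louvain_modules <- function(network, kappa_bar_weights, resolution = 1,
                            seed = 0, negative_weights = c("clamp", "passthrough"),
                            n_restarts = 1) {
  stopifnot(inherits(network, "gene_network"))
  negative_weights <- match.arg(negative_weights)
  w <- as.numeric(kappa_bar_weights)
  if (length(w) != nrow(network$edges)) {
    abort("need one weight per network edge")
  }
  n_neg <- sum(w < 0)
  if (negative_weights == "clamp" && n_neg > 0) {
    inform(paste0("clamping ", n_neg, " negative modularity weight(s) at 0"))
    w <- pmax(w, 0)
  }
  g <- network$graph
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(max(1L, n_restarts))) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
    q <- igraph::modularity(g, igraph::membership(cl), weights = w,
                            resolution = resolution)
    if (q > best_q) {
      best_q <- q
      best <- cl
    }
  }
  memb <- igraph::membership(best)
  memb <- memb[network$vertices]
  # renumber by descending module size, ties by smallest member gene
  sizes <- table(memb)
  firsts <- vapply(names(sizes), function(m) min(names(memb)[memb == m]), "")
  ord <- names(sizes)[order(-as.integer(sizes), firsts)]
  relab <- setNames(seq_along(ord), ord)
  out <- tibble(gene = names(memb), module = unname(relab[as.character(memb)]))
  structure(out,
            class = c("module_assignment", class(out)),
            modularity = best_q,
            resolution = resolution,
            n_clamped = if (negative_weights == "clamp") n_neg else 0L,
            module_sizes = as.integer(table(out$module)))
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- attr(x, "module_sizes")
  cat("<module_assignment> ", nrow(x), " genes in ", length(sizes),
      " modules (sizes ", paste(sizes, collapse = "/"),
      "; modularity ", signif(attr(x, "modularity"), 4), ")\n", sep = "")
  invisible(x)
}

#' @export
glance.module_assignment <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_modules = length(attr(x, "module_sizes")),
    modularity = attr(x, "modularity"),
    resolution = attr(x, "resolution"),
    n_clamped = attr(x, "n_clamped")
  )
}

#' Within- versus between-module curvature summary
#'
#' Classifies every edge as within- or between-module under an assignment,
#' reports counts and mean weights for each class, and compares the classes
#' with an unpaired (Welch) two-sample t-test.
#'
#' @param assignment a `module_assignment`.
#' @param network a `gene_network` (defines the edges).
#' @param kappa_bar_weights per-edge weights aligned with `network$edges`.
#' @return A list: `summary` tibble (class, n_edges, mean_weight),
#'   `t_statistic`, `p_value`, and `test_skipped = TRUE` when either class
#'   has fewer than two edges (means are still reported).
#' @export
within_between_summary <- function(assignment, network, kappa_bar_weights) {
  mod <- setNames(assignment$module, assignment$gene)
  miss <- setdiff(network$vertices, names(mod))
  if (length(miss)) abort("assignment does not cover all edge endpoints")
  within <- mod[network$edges$gene_a] == mod[network$edges$gene_b]
  w <- as.numeric(kappa_bar_weights)
  summary <- tibble(
    class = c("within", "between"),
    n_edges = c(sum(within), sum(!within)),
    mean_weight = c(mean(w[within]), mean(w[!within]))
  )
  if (sum(within) < 2 || sum(!within) < 2) {
    return(list(summary = summary, t_statistic = NA_real_,
                p_value = NA_real_, test_skipped = TRUE))
  }
  tt <- t.test(w[within], w[!within])
  list(summary = summary, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, test_skipped = FALSE)
}

#' Per-patient module scores
#'
#' The score of a module for a patient is the mean scaled expression
#' difference over the module's genes: a signed summary of how the module
#' moved on treatment in that patient.
#'
#' @param assignment a `module_assignment`.
#' @param scaled_diff a scaled `diff_matrix`.
#' @return A wide tibble: `patient_id`, then one column `M<k>` per module.
#' @export
module_scores <- function(assignment, scaled_diff) {
  stopifnot(inherits(scaled_diff, "diff_matrix"))
  if (!isTRUE(scaled_diff$scaled)) abort("differences must be scaled first")
  miss <- setdiff(assignment$gene, scaled_diff$genes)
  if (length(miss)) {
    abort(paste0("module genes absent from the difference matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  mods <- sort(unique(assignment$module))
  scores <- vapply(mods, function(m) {
    genes <- assignment$gene[assignment$module == m]
    if (length(genes) == 0) abort("empty module")
    colMeans(scaled_diff$values[genes, , drop = FALSE])
  }, numeric(length(scaled_diff$patients)))
  colnames(scores) <- paste0("M", mods)
  dplyr::bind_cols(tibble(patient_id = scaled_diff$patients),
                   as_tibble(scores))
}
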