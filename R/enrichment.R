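#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a collection for over-representation in a module
#' gene list against a universe of analyzed genes. For a set with K members
#' in a universe of N, and a module of n genes overlapping the set in k, the
#' upper-tail p-value is P(X >= k) under the hypergeometric null; sets with
#' zero overlap get p = 1. P-values are Benjamini-Hochberg adjusted across
#' the collection.
#'
#' @param module_genes character vector of the module's genes (must lie in
#'   the universe).
#' @param collection named list of gene-symbol character vectors (e.g. from
#'   [read_gmt()]). Set members outside the universe are ignored.
#' @param universe character vector of background genes, typically the
#'   analyzed network's vertex set.
#' @return A tibble: `set`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, sorted by
#'   `p_value`.
#' @export
hypergeometric_ora <- function(module_genes, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  module_genes <- unique(module_genes)
  out <- setdiff(module_genes, universe)
  if (length(out)) {
    abort(paste0("module genes outside the universe: ",
                 paste(head(out, 5), collapse = ", ")))
  }
  if (length(collection) == 0) abort("empty gene-set collection")
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    abort("collection sets must be named")
  }
  N <- length(universe)
  n <- length(module_genes)
  res <- purrr::map_dfr(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, module_genes))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = nm, k = k, K = K, n = n, N = N, p_value = p)
  })
  res$fdr <- bh_adjust(res$p_value)
  arrange(res, .data$p_value, .data$set)
}

#' Read a GMT gene-set collection
#'
#' @param path path to a GMT file (set name, description, then members, tab
#'   separated).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#'
#' @param collection named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, nm, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
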