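#' PPI topology edge table
#'
#' Canonical undirected edge table: columns `gene_a`, `gene_b`, `score`
#' (STRING-style integer confidence, 0-1000). Self-loops are dropped with a
#' warning; duplicate unordered pairs are collapsed keeping the maximum
#' score.
#'
#' @param edges data frame whose first three columns are the two endpoint
#'   genes and the confidence score.
#' @return A tibble of class `ppi_topology`.
#' @export
ppi_topology <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) abort("edge table needs endpoint and score columns")
  out <- tibble(
    gene_a = as.character(edges[[1]]),
    gene_b = as.character(edges[[2]]),
    score = as.numeric(edges[[3]])
  )
  if (anyNA(out$score)) abort("non-numeric confidence score in edge table")
  loops <- out$gene_a == out$gene_b
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-loop(s)"))
    out <- out[!loops, , drop = FALSE]
  }
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]
  out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  out <- out |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$gene_a, .data$gene_b)
  class(out) <- c("ppi_topology", class(out))
  out
}

topology_vertices <- function(topology) {
  sort(unique(c(topology$gene_a, topology$gene_b)))
}

topology_igraph <- function(topology) {
  igraph::graph_from_data_frame(
    as.data.frame(topology[, c("gene_a", "gene_b", "score")]),
    directed = FALSE
  )
}

#' Read a STRING-style protein-links edge list
#'
#' Whitespace-separated `protein1 protein2 combined_score` lines; a header
#' line is tolerated. Identifiers are assumed pre-mapped to gene symbols.
#'
#' @param path path to the edge-list file.
#' @return A [ppi_topology()] tibble.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty PPI file")
  parts <- strsplit(trimws(lines), "\\s+")
  start <- 1L
  if (length(parts[[1]]) >= 3 && is.na(suppressWarnings(as.numeric(parts[[1]][3])))) {
    start <- 2L # header
  }
  if (start > length(parts)) abort("PPI file has a header but no edges")
  rows <- parts[start:length(parts)]
  bad <- which(vapply(rows, length, 1L) < 3)
  if (length(bad)) {
    abort(paste0("malformed PPI line ", bad[1] + start - 1L, ": '",
                 lines[bad[1] + start - 1L], "'"))
  }
  score <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3L)))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    abort(paste0("malformed PPI line ", bad + start - 1L,
                 ": non-numeric combined_score"))
  }
  ppi_topology(data.frame(
    gene_a = vapply(rows, `[`, "", 1L),
    gene_b = vapply(rows, `[`, "", 2L),
    score = score
  ))
}

#' Write a topology in STRING protein-links dialect
#' @param topology a [ppi_topology()].
#' @param path output path.
#' @export
write_ppi <- function(topology, path) {
  df <- data.frame(protein1 = topology$gene_a, protein2 = topology$gene_b,
                   combined_score = topology$score)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep edges at or above a confidence score
#'
#' Edges scoring below `min_score` are removed; vertices left without edges
#' disappear with them (the table is purely edge-based).
#'
#' @param topology a [ppi_topology()].
#' @param min_score minimum STRING combined score to keep (default 700,
#'   STRING "high confidence").
#' @return The filtered topology.
#' @export
filter_confidence <- function(topology, min_score = 700) {
  out <- topology[topology$score >= min_score, , drop = FALSE]
  class(out) <- class(topology)
  out
}

#' Optional compartment-aware edge sparsification
#'
#' Removes edges whose endpoints have disjoint cellular-compartment label
#' sets; genes absent from the annotation are treated as compatible with
#' everything (permissive). Off by default in the pipeline.
#'
#' @param topology a [ppi_topology()].
#' @param compartment_table data frame with columns `gene`, `compartment`
#'   (one row per gene-label pair).
#' @return The sparsified topology.
#' @export
compartment_sparsify <- function(topology, compartment_table) {
  ct <- as.data.frame(compartment_table)
  if (nrow(ct) == 0) return(topology)
  labs <- split(as.character(ct[[2]]), as.character(ct[[1]]))
  compatible <- function(a, b) {
    la <- labs[[a]]; lb <- labs[[b]]
    is.null(la) || is.null(lb) || length(intersect(la, lb)) > 0
  }
  keep <- mapply(compatible, topology$gene_a, topology$gene_b)
  out <- topology[keep, , drop = FALSE]
  class(out) <- class(topology)
  out
}

#' Remove low-degree vertices (single pass)
#'
#' Vertices whose degree in the *input* topology is below `min_degree` are
#' removed, together with their edges, in one pass; the rule is deliberately
#' not iterated to a k-core, so applying it twice can remove more vertices.
#'
#' @param topology a [ppi_topology()].
#' @param min_degree minimum initial degree to keep (default 5).
#' @return The filtered topology.
#' @export
filter_min_degree <- function(topology, min_degree = 5) {
  deg <- table(c(topology$gene_a, topology$gene_b))
  keep_v <- names(deg)[deg >= min_degree]
  keep <- topology$gene_a %in% keep_v & topology$gene_b %in% keep_v
  out <- topology[keep, , drop = FALSE]
  class(out) <- class(topology)
  out
}

#' Expand a core gene set to its PPI neighborhood
#'
#' Returns the core genes present in the topology together with every vertex
#' adjacent to a core gene.
#'
#' @param topology a [ppi_topology()].
#' @param core_genes character vector of core gene symbols.
#' @return Character vector of selected vertices (sorted).
#' @export
select_core_neighborhood <- function(topology, core_genes) {
  verts <- topology_vertices(topology)
  core_in <- intersect(core_genes, verts)
  if (length(core_in) == 0) abort("no core gene is present in the topology")
  nb_a <- topology$gene_b[topology$gene_a %in% core_in]
  nb_b <- topology$gene_a[topology$gene_b %in% core_in]
  sort(unique(c(core_in, nb_a, nb_b)))
}

#' Largest connected component of an induced subgraph
#'
#' Restricts the topology to `subset`, then keeps its largest connected
#' component; ties are broken toward the component whose sorted vertex set is
#' lexicographically smallest.
#'
#' @param topology a [ppi_topology()].
#' @param subset character vector of vertices (defaults to all).
#' @return The component's topology.
#' @export
largest_component <- function(topology, subset = NULL) {
  if (is.null(subset)) subset <- topology_vertices(topology)
  if (length(subset) == 0) abort("empty vertex subset")
  keep <- topology$gene_a %in% subset & topology$gene_b %in% subset
  sub <- topology[keep, , drop = FALSE]
  if (nrow(sub) == 0) abort("induced subgraph has no edges")
  g <- topology_igraph(sub)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, "")
    best <- best[order(firsts)][1]
  }
  verts <- igraph::V(g)$name[comp$membership == best]
  keep <- sub$gene_a %in% verts & sub$gene_b %in% verts
  out <- sub[keep, , drop = FALSE]
  class(out) <- class(topology)
  out
}

#' Build the weighted correlation network on a PPI topology
#'
#' For every PPI edge, the Pearson correlation rho of the two genes' scaled
#' expression changes across patients is computed and shifted to the
#' similarity `rho_shifted = (1 + rho) / 2`; the direct transport cost of the
#' edge is `1 / rho_shifted`, floored at `1 / eps` so anti-correlated edges
#' stay finite. All-pairs shortest-path distances over these costs define the
#' network's metric.
#'
#' @param topology a [ppi_topology()] whose vertices are all present in
#'   `scaled_diff`.
#' @param scaled_diff a scaled `diff_matrix` from [scale_differences()].
#' @param eps similarity floor when inverting to cost (default 1e-6).
#' @return A `gene_network`: vertices, edge tibble (`gene_a`, `gene_b`,
#'   `rho`, `rho_shifted`, `cost`), and the shortest-path matrix `dist`.
#' @export
build_correlation_network <- function(topology, scaled_diff, eps = 1e-6) {
  stopifnot(inherits(scaled_diff, "diff_matrix"))
  verts <- topology_vertices(topology)
  missing <- setdiff(verts, scaled_diff$genes)
  if (length(missing)) {
    abort(paste0("topology vertices absent from the difference matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (length(scaled_diff$patients) < 3) abort("need at least 3 patients")
  X <- scaled_diff$values[verts, , drop = FALSE]
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance gene(s) in the network: ",
                 paste(head(verts[sds == 0], 5), collapse = ", ")))
  }
  rho <- mapply(function(a, b) cor(X[a, ], X[b, ]),
                topology$gene_a, topology$gene_b)
  edges <- tibble(
    gene_a = topology$gene_a,
    gene_b = topology$gene_b,
    score = topology$score,
    rho = unname(rho),
    rho_shifted = (1 + unname(rho)) / 2,
    cost = 1 / pmax((1 + unname(rho)) / 2, eps)
  )
  net <- new_gene_network(verts, edges, eps = eps)
  net$dist <- all_pairs_shortest_paths(net)
  net
}

new_gene_network <- function(vertices, edges, eps) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = vertices)
  )
  structure(
    list(vertices = vertices, edges = edges, graph = g, eps = eps,
         dist = NULL),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$vertices), " genes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' @export
tidy.gene_network <- function(x, ...) x$edges

#' All-pairs shortest-path distances over edge costs
#'
#' Dijkstra over the network's direct edge costs. The network must be
#' connected (guaranteed by the upstream largest-component step).
#'
#' @param network a `gene_network`.
#' @return A symmetric distance matrix over network vertices.
#' @export
all_pairs_shortest_paths <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  d <- igraph::distances(network$graph, weights = igraph::E(network$graph)$cost,
                         algorithm = "dijkstra")
  if (any(!is.finite(d))) abort("network is disconnected; distances are infinite")
  d[network$vertices, network$vertices]
}

#' Adjacency matrix of shifted correlations
#'
#' The symmetric weighted adjacency C_N restricted to network edges, zero
#' diagonal.
#' @param network a `gene_network`.
#' @return A dense matrix over network vertices.
#' @export
shifted_adjacency <- function(network) {
  n <- length(network$vertices)
  A <- matrix(0, n, n, dimnames = list(network$vertices, network$vertices))
  ia <- match(network$edges$gene_a, network$vertices)
  ib <- match(network$edges$gene_b, network$vertices)
  A[cbind(ia, ib)] <- network$edges$rho_shifted
  A[cbind(ib, ia)] <- network$edges$rho_shifted
  A
}

#' Write a gene network to GraphML plus an edge-list TSV
#'
#' @param network a `gene_network`.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) readr::write_tsv(network$edges, edges_path)
  invisible(network)
}
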