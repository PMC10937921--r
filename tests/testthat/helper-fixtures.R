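# Fixture builders and independent oracles shared across the suite.

# Small paired study built in code: `n_genes` x (2 * n_patients + extras).
toy_study <- function(n_genes = 6, n_patients = 5, seed = 42,
                      extra_pre = 1, extra_on = 1) {
  set.seed(seed)
  pats <- paste0("P", seq_len(n_patients))
  upre <- if (extra_pre > 0) paste0("U", seq_len(extra_pre)) else character()
  uon <- if (extra_on > 0) paste0("V", seq_len(extra_on)) else character()
  ids <- c(paste0(pats, "_pre"), paste0(pats, "_on"),
           paste0(upre, "_pre"), paste0(uon, "_on"))
  genes <- paste0("g", seq_len(n_genes))
  norm <- matrix(rnorm(n_genes * length(ids), 6, 1), n_genes,
                 dimnames = list(genes, ids))
  counts <- round(2^norm)
  samples <- tibble::tibble(
    sample_id = ids,
    patient_id = c(pats, pats, upre, uon),
    timepoint = c(rep("pre", n_patients), rep("on", n_patients),
                  rep("pre", length(upre)), rep("on", length(uon)))
  )
  expression_study(counts, norm, samples)
}

# Fabricate a gene_network directly from an edge table with rho values,
# bypassing expression data (for geometry-only tests).
make_network <- function(edges_df, eps = 1e-6) {
  edges_df <- as.data.frame(edges_df)
  verts <- sort(unique(c(edges_df$gene_a, edges_df$gene_b)))
  edges <- tibble::tibble(
    gene_a = edges_df$gene_a, gene_b = edges_df$gene_b,
    score = if ("score" %in% names(edges_df)) edges_df$score else 900,
    rho = edges_df$rho,
    rho_shifted = (1 + edges_df$rho) / 2,
    cost = 1 / pmax((1 + edges_df$rho) / 2, eps)
  )
  net <- riccinet:::new_gene_network(verts, edges, eps = eps)
  net$dist <- all_pairs_shortest_paths(net)
  net
}

# Seven vertices: a 4-clique and a 3-clique joined by one weak bridge edge.
# Every direct edge is a shortest path (within-clique alternatives cost two
# hops; the bridge is the only clique-to-clique connection).
two_clique_network <- function(rho_in = 0.8, rho_bridge = 0.1) {
  cl1 <- t(utils::combn(c("A1", "A2", "A3", "A4"), 2))
  cl2 <- t(utils::combn(c("B1", "B2", "B3"), 2))
  edges <- data.frame(
    gene_a = c(cl1[, 1], cl2[, 1], "A1"),
    gene_b = c(cl1[, 2], cl2[, 2], "B1"),
    rho = c(rep(rho_in, nrow(cl1) + nrow(cl2)), rho_bridge)
  )
  make_network(edges)
}

# Exhaustive all-simple-paths shortest-path oracle (graphs <= 8 vertices).
brute_shortest_paths <- function(vertices, edges) {
  n <- length(vertices)
  idx <- setNames(seq_len(n), vertices)
  adj <- matrix(Inf, n, n)
  diag(adj) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- idx[[edges$gene_a[k]]]
    j <- idx[[edges$gene_b[k]]]
    adj[i, j] <- adj[j, i] <- min(adj[i, j], edges$cost[k])
  }
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t) {
        best_st <- Inf
        rec <- function(u, visited, len) {
          if (len >= best_st) return(invisible())
          if (u == t) { best_st <<- len; return(invisible()) }
          for (v in seq_len(n)) {
            if (is.finite(adj[u, v]) && u != v && !(v %in% visited)) {
              rec(v, c(visited, v), len + adj[u, v])
            }
          }
        }
        rec(s, s, 0)
        best[s, t] <- best_st
      }
    }
  }
  dimnames(best) <- list(vertices, vertices)
  best
}

# Independent transportation-LP oracle via boot::simplex on the full
# primal: minimize sum c_ij g_ij subject to marginal equalities, g >= 0.
lp_wasserstein <- function(p, q, C) {
  si <- which(p > 1e-15)
  sj <- which(q > 1e-15)
  m <- length(si)
  n <- length(sj)
  cost <- as.vector(t(C[si, sj, drop = FALSE])) # row-major g_ij
  A3 <- matrix(0, m + n, m * n)
  for (i in seq_len(m)) A3[i, ((i - 1) * n + 1):(i * n)] <- 1
  for (j in seq_len(n)) A3[m + j, seq(j, m * n, by = n)] <- 1
  b3 <- c(p[si], q[sj] * sum(p[si]) / sum(q[sj]))
  # the marginal equalities are rank-deficient by one (total mass appears on
  # both sides); drop the final row so the simplex basis stays nonsingular
  fit <- boot::simplex(a = cost, A3 = A3[-(m + n), , drop = FALSE],
                       b3 = b3[-(m + n)], maxi = FALSE)
  stopifnot(fit$solved == 1)
  unname(fit$value)
}

# Random connected graph with <= max_v vertices and positive edge costs.
random_small_graph <- function(max_v = 8, seed = 1) {
  set.seed(seed)
  n <- sample(4:max_v, 1)
  verts <- LETTERS[seq_len(n)]
  repeat {
    pairs <- t(utils::combn(verts, 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (sum(keep) >= n - 1) {
      edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                          rho = runif(sum(keep), -0.5, 0.95))
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = verts))
      if (igraph::is_connected(g)) return(make_network(edges))
    }
  }
}

# Weighted Newman modularity of a partition (independent of igraph).
hand_modularity <- function(membership, edges, weights, resolution = 1) {
  w <- weights
  m2 <- sum(w) * 2
  if (m2 == 0) return(0)
  verts <- sort(unique(c(edges$gene_a, edges$gene_b)))
  k <- setNames(numeric(length(verts)), verts)
  for (e in seq_len(nrow(edges))) {
    k[edges$gene_a[e]] <- k[edges$gene_a[e]] + w[e]
    k[edges$gene_b[e]] <- k[edges$gene_b[e]] + w[e]
  }
  q <- 0
  for (e in seq_len(nrow(edges))) {
    if (membership[edges$gene_a[e]] == membership[edges$gene_b[e]]) {
      q <- q + w[e] / (m2 / 2)
    }
  }
  same <- outer(membership[verts], membership[verts], "==")
  q - resolution * sum((k %o% k) * same) / (m2 * m2)
}

# All set partitions of a vector (Bell-number enumeration; keep inputs <= 8).
all_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- all_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(x[1], q[[k]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(x[1]), p)
  }
  out
}

# Synthetic bundle at reduced scale for fast pipeline tests.
small_pipeline_inputs <- function(seed = 5, n_genes = 36, n_modules = 3,
                                  n_patients = 20) {
  top <- generate_topology(n_genes = n_genes, n_modules = n_modules,
                           seed = seed)
  expr <- generate_expression(top$topology, top$truth,
                              n_patients = n_patients, seed = seed + 1)
  clin <- generate_clinical(expr$truth, seed = seed + 2)
  list(topology = top$topology, truth = clin$truth, study = expr$study,
       clinical = clin$clinical,
       core = synthetic_core_genes(expr$truth),
       sets = generate_gene_sets(clin$truth, seed = seed + 3))
}
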