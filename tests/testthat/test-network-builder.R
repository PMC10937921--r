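test_that("STRING-dialect parsing dedupes, drops self-loops, flags bad lines", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "links.txt")
  writeLines(c("protein1 protein2 combined_score",
               "A B 900", "B A 850", "B C 700"), f)
  expect_warning(topo <- NULL, NA)
  topo <- read_ppi(f)
  expect_equal(nrow(topo), 2)                     # A-B deduped
  expect_equal(topo$score[topo$gene_a == "A"], 900) # max kept
  writeLines(c("A A 500", "A B 700"), f)
  expect_warning(topo <- read_ppi(f), "self-loop")
  expect_equal(nrow(topo), 1)
  writeLines(c("A B 700", "C D"), f)
  expect_error(read_ppi(f), "line 2")
  # round trip through the writer
  topo <- ppi_topology(data.frame(a = c("A", "B"), b = c("B", "C"),
                                  s = c(700, 900)))
  write_ppi(topo, f)
  expect_equal(as.data.frame(read_ppi(f)), as.data.frame(topo))
})

test_that("confidence filter keeps scores >= cutoff and drops isolated vertices", {
  topo <- ppi_topology(data.frame(
    a = c("A", "A", "B", "C", "D"), b = c("B", "C", "C", "D", "E"),
    s = c(900, 650, 700, 400, 710)
  ))
  expect_equal(nrow(filter_confidence(topo, 0)), 5)
  expect_equal(nrow(filter_confidence(topo, 2000)), 0)
  kept <- filter_confidence(topo, 700)
  expect_setequal(paste(kept$gene_a, kept$gene_b),
                  c("A B", "B C", "D E"))
})

test_that("compartment sparsification removes disjoint-label edges, permissive on missing genes", {
  topo <- ppi_topology(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                                  s = 900))
  ct <- data.frame(
    gene = c("A", "A", "B", "C"),
    compartment = c("cytoplasm", "nucleus", "cytoplasm", "extracellular")
  )
  out <- compartment_sparsify(topo, ct)
  expect_true(any(out$gene_a == "A" & out$gene_b == "B"))  # share cytoplasm
  expect_false(any(out$gene_a == "B" & out$gene_b == "C")) # disjoint
  expect_true(any(out$gene_a == "C" & out$gene_b == "D"))  # D unannotated
  expect_equal(nrow(compartment_sparsify(topo, ct[0, ])), nrow(topo))
})

test_that("degree filter is a single pass on initial degrees, not a k-core", {
  star <- ppi_topology(data.frame(a = "HUB", b = paste0("L", 1:4), s = 900))
  expect_equal(nrow(filter_min_degree(star, 5)), 0) # center degree 4
  six <- t(utils::combn(paste0("V", 1:6), 2))
  clique <- ppi_topology(data.frame(a = six[, 1], b = six[, 2], s = 900))
  expect_equal(nrow(filter_min_degree(clique, 5)), 15) # all degrees 5
  # non-idempotence: path A-B-C-D at min_degree 2
  path <- ppi_topology(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                                  s = 900))
  once <- filter_min_degree(path, 2)
  expect_equal(nrow(once), 1) # B-C survives
  twice <- filter_min_degree(once, 2)
  expect_equal(nrow(twice), 0) # second pass removes more
})

test_that("core neighborhood is core plus direct PPI neighbors", {
  path <- ppi_topology(data.frame(a = c("A", "B"), b = c("B", "C"), s = 900))
  expect_equal(select_core_neighborhood(path, "A"), c("A", "B"))
  expect_equal(select_core_neighborhood(path, c("A", "B", "C")),
               c("A", "B", "C"))
  expect_error(select_core_neighborhood(path, "ZZZ"), "no core gene")
  # brute-force adjacency scan on a random 20-gene topology
  gen <- generate_topology(n_genes = 20, n_modules = 2, seed = 3)
  core <- names(gen$truth$modules)[c(1, 8, 15)]
  got <- select_core_neighborhood(gen$topology, core)
  adj <- unique(c(
    core,
    gen$topology$gene_b[gen$topology$gene_a %in% core],
    gen$topology$gene_a[gen$topology$gene_b %in% core]
  ))
  expect_setequal(got, intersect(adj, unique(c(gen$topology$gene_a,
                                               gen$topology$gene_b))))
})

test_that("largest component selection obeys size then lexicographic tie-break", {
  two <- ppi_topology(data.frame(
    a = c("A", "B", "C", "D", "E", "X", "Y"),
    b = c("B", "C", "D", "E", "A", "Y", "Z"),
    s = 900
  ))
  big <- largest_component(two)
  expect_setequal(unique(c(big$gene_a, big$gene_b)), c("A", "B", "C", "D", "E"))
  # tie: two 3-vertex components -> the one with the alphabetically first gene
  tie <- ppi_topology(data.frame(
    a = c("A", "B", "M", "N"), b = c("B", "C", "N", "O"), s = 900
  ))
  win <- largest_component(tie)
  expect_setequal(unique(c(win$gene_a, win$gene_b)), c("A", "B", "C"))
  expect_error(largest_component(two, character()), "empty")
})

test_that("correlation network carries exact shifted correlations and capped costs", {
  vals <- rbind(
    A = c(1, 2, 3, 4, 5),
    B = c(1, 2, 3, 4, 5),     # rho = 1 with A
    C = c(-1, -2, -3, -4, -5), # rho = -1 with A
    D = c(1, 2, 4, 3, 7)
  )
  colnames(vals) <- paste0("P", 1:5)
  sd_vals <- vals / apply(vals, 1, sd)
  d <- riccinet:::new_diff_matrix(sd_vals, scaled = TRUE)
  topo <- ppi_topology(data.frame(a = c("A", "A", "A"), b = c("B", "C", "D"),
                                  s = 900))
  net <- build_correlation_network(topo, d)
  e <- net$edges
  expect_equal(e$rho[e$gene_b == "B"], 1, tolerance = 1e-12)
  expect_equal(e$cost[e$gene_b == "B"], 1, tolerance = 1e-12)
  expect_equal(e$rho[e$gene_b == "C"], -1, tolerance = 1e-12)
  expect_equal(e$cost[e$gene_b == "C"], 1e6, tolerance = 1e-6) # 1/eps cap
  # hand Pearson for the D edge
  r <- cor(vals["A", ], vals["D", ])
  expect_equal(e$rho[e$gene_b == "D"], r, tolerance = 1e-12)
  expect_equal(e$rho_shifted[e$gene_b == "D"], (1 + r) / 2, tolerance = 1e-12)
  expect_equal(e$cost[e$gene_b == "D"], 2 / (1 + r), tolerance = 1e-12)
  # rho monotone => cost antitone
  ord <- order(e$rho)
  expect_true(all(diff(e$cost[ord]) <= 0))
  # zero-variance gene rejected
  zv <- sd_vals
  zv["D", ] <- 0
  expect_error(
    build_correlation_network(topo, riccinet:::new_diff_matrix(zv, TRUE)),
    "zero-variance"
  )
})

test_that("shortest paths match hand values and the exhaustive oracle", {
  path <- make_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                                  rho = c(1, 1/3))) # costs 1, 1.5
  expect_equal(path$dist["A", "C"], 2.5)
  # triangle with a heavy edge: go around it
  tri <- make_network(data.frame(gene_a = c("A", "A", "B"),
                                 gene_b = c("B", "C", "C"),
                                 rho = c(1, 1, -0.5))) # costs 1, 1, 4
  expect_equal(tri$dist["B", "C"], 2)
  # random <= 8-vertex graphs vs exhaustive path enumeration
  for (seed in 1:4) {
    net <- random_small_graph(8, seed = seed)
    oracle <- brute_shortest_paths(net$vertices, net$edges)
    expect_equal(net$dist, oracle[net$vertices, net$vertices],
                 tolerance = 1e-10)
    expect_equal(net$dist, t(net$dist))
    expect_true(all(diag(net$dist) == 0))
    # direct edge bounds the metric
    for (e in seq_len(nrow(net$edges))) {
      expect_lte(net$dist[net$edges$gene_a[e], net$edges$gene_b[e]],
                 net$edges$cost[e] + 1e-12)
    }
  }
})
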