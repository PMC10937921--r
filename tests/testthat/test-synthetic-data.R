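test_that("topology generation is a pure function of its seed", {
  a <- generate_topology(n_genes = 120, n_modules = 6, p_in = 0.3,
                         p_out = 0.01, seed = 7)
  b <- generate_topology(n_genes = 120, n_modules = 6, p_in = 0.3,
                         p_out = 0.01, seed = 7)
  expect_identical(as.data.frame(a$topology), as.data.frame(b$topology))
  expect_identical(a$truth$modules, b$truth$modules)
  c <- generate_topology(seed = 8)
  expect_false(identical(as.data.frame(a$topology), as.data.frame(c$topology)))
})

test_that("planted blocks have the prescribed edge densities and forced connectivity", {
  gen <- generate_topology(n_genes = 90, n_modules = 3, p_in = 0.4,
                           p_out = 0.05, seed = 2)
  topo <- gen$topology
  mod <- gen$truth$modules
  bridge_keys <- paste(gen$truth$bridges$gene_a, gen$truth$bridges$gene_b)
  non_bridge <- topo[!paste(topo$gene_a, topo$gene_b) %in% bridge_keys, ]
  same <- mod[non_bridge$gene_a] == mod[non_bridge$gene_b]
  n_within_pairs <- 3 * choose(30, 2)
  n_between_pairs <- choose(90, 2) - n_within_pairs
  expect_equal(sum(same) / n_within_pairs, 0.4, tolerance = 0.1)
  expect_equal(sum(!same) / n_between_pairs, 0.05, tolerance = 0.35)
  # graph is connected
  g <- igraph::graph_from_data_frame(as.data.frame(topo[, 1:2]),
                                     directed = FALSE)
  expect_true(igraph::is_connected(g))
  # p_out = 0: between-block edges are exactly the recorded bridges
  gen0 <- generate_topology(n_genes = 30, n_modules = 3, p_in = 0.5,
                            p_out = 0, seed = 5)
  t0 <- gen0$topology
  between <- t0[gen0$truth$modules[t0$gene_a] != gen0$truth$modules[t0$gene_b], ]
  expect_setequal(paste(between$gene_a, between$gene_b),
                  paste(gen0$truth$bridges$gene_a, gen0$truth$bridges$gene_b))
  # p_in = p_out: no community structure (uniform density across pair types)
  genu <- generate_topology(n_genes = 80, n_modules = 4, p_in = 0.2,
                            p_out = 0.199999, seed = 6)
  tu <- genu$topology
  bridge_u <- paste(genu$truth$bridges$gene_a, genu$truth$bridges$gene_b)
  tu <- tu[!paste(tu$gene_a, tu$gene_b) %in% bridge_u, ]
  same_u <- genu$truth$modules[tu$gene_a] == genu$truth$modules[tu$gene_b]
  n_w <- 4 * choose(20, 2)
  n_b <- choose(80, 2) - n_w
  tab <- rbind(c(sum(same_u), n_w - sum(same_u)),
               c(sum(!same_u), n_b - sum(!same_u)))
  expect_gt(chisq.test(tab)$p.value, 0.01)
  expect_error(generate_topology(p_in = 0.2, p_out = 0.5), "p_out < p_in")
})

test_that("expression signals follow the rank-one-block latent model", {
  gen <- generate_topology(n_genes = 30, n_modules = 3, seed = 3)
  # noiseless: within-module difference correlations are exactly 1
  ex0 <- generate_expression(gen$topology, gen$truth, n_patients = 12,
                             noise_sd = 0, seed = 3, n_low_genes = 0)
  d0 <- paired_difference(ex0$study)
  m1 <- names(gen$truth$modules)[gen$truth$modules == 1]
  cors <- cor(t(d0$values[m1, ]))
  expect_equal(unname(cors), matrix(1, length(m1), length(m1)),
               tolerance = 1e-10)
  # across modules, loadings are independent: mean |rho| small at larger n
  ex <- generate_expression(gen$topology, gen$truth, n_patients = 200,
                            noise_sd = 0.5, seed = 4, n_low_genes = 0)
  d <- paired_difference(ex$study)
  m2 <- names(gen$truth$modules)[gen$truth$modules == 2]
  cross <- cor(t(d$values[m1, ]), t(d$values[m2, ]))
  expect_lt(mean(abs(cross)), 0.12)
  # determinism
  exb <- generate_expression(gen$topology, gen$truth, n_patients = 12,
                             noise_sd = 0, seed = 3, n_low_genes = 0)
  expect_identical(ex0$study$norm, exb$study$norm)
  # counts are consistent with the log-scale values
  expect_equal(ex0$study$counts, round(2^ex0$study$norm))
  # the matched-patient count drives the difference matrix width
  expect_equal(length(d0$patients), 12)
  # low decoy genes fall to the low-expression filter
  ex_low <- generate_expression(gen$topology, gen$truth, n_patients = 12,
                                seed = 5, n_low_genes = 6)
  kept <- filter_low_expression(ex_low$study)
  expect_false(any(grepl("^LOW", kept$genes)))
  expect_true(all(names(gen$truth$modules) %in% kept$genes))
})

test_that("clinical generation encodes the protective-module survival model", {
  gen <- generate_topology(n_genes = 30, n_modules = 3, seed = 11)
  ex <- generate_expression(gen$topology, gen$truth, n_patients = 300,
                            seed = 11)
  # censor_rate = 0: everyone has an event
  cl0 <- generate_clinical(ex$truth, censor_rate = 0, seed = 1,
                           ne_patient = FALSE)
  expect_true(all(cl0$clinical$os_event == 1))
  # beta = 1, large n: Cox on the true loading recovers -beta
  fit <- survival::coxph(
    survival::Surv(os_time, os_event) ~ lam,
    data = data.frame(cl0$clinical,
                      lam = ex$truth$loadings[cl0$clinical$patient_id, 3])
  )
  ci <- confint(fit)
  expect_lt(abs(unname(coef(fit)) + 1), 3 * sqrt(vcov(fit)[1, 1]))
  expect_true(ci[1] < -1 && -1 < ci[2])
  # exactly one NE patient when requested
  cl1 <- generate_clinical(ex$truth, seed = 2)
  expect_equal(sum(cl1$clinical$response == "NE"), 1)
  # response is ordinal in the loading: CR/PR loadings exceed PD loadings
  lam <- ex$truth$loadings[cl1$clinical$patient_id, 3]
  grp <- cl1$clinical$response
  expect_gt(mean(lam[grp %in% c("CR", "PR")]), mean(lam[grp == "PD"]))
  # PD is the largest evaluated group on average
  tab <- table(factor(grp, levels = c("CR", "PR", "SD", "PD")))
  expect_equal(names(which.max(tab)), "PD")
  expect_error(generate_clinical(ex$truth, censor_rate = 1), "censor_rate")
  expect_error(generate_clinical(gen$truth), "loadings")
})

test_that("a null protective effect gives uniform log-rank p-values", {
  set.seed(19)
  gen <- generate_topology(n_genes = 12, n_modules = 2, seed = 19)
  ps <- vapply(1:150, function(r) {
    ex <- generate_expression(gen$topology, gen$truth, n_patients = 40,
                              seed = 1000 + r)
    cl <- generate_clinical(ex$truth, beta = 0, seed = 2000 + r,
                            ne_patient = FALSE)
    sc <- tibble::tibble(patient_id = cl$clinical$patient_id,
                         M1 = ex$truth$loadings[, 2])
    km_logrank(sc, cl$clinical, "M1")$p_value
  }, 0.0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("gene-set generation mirrors module sizes with decoys", {
  gen <- generate_topology(n_genes = 40, n_modules = 4, seed = 23)
  sets <- generate_gene_sets(gen$truth, n_decoy_sets = 6, seed = 23)
  expect_length(sets, 10)
  sizes <- as.integer(table(gen$truth$modules))
  expect_equal(unname(lengths(sets[paste0("MODULE_", 1:4)])), sizes)
  expect_equal(unname(lengths(sets[paste0("DECOY_", 1:4)])), sizes)
  # module sets are exact memberships
  expect_setequal(sets$MODULE_2,
                  names(gen$truth$modules)[gen$truth$modules == 2])
})
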