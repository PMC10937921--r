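sim_clinical <- function(n, lp = rep(0, n), h0 = 0.1, censor = 0.3,
                         seed = 1) {
  set.seed(seed)
  t_ev <- rexp(n, rate = h0 * exp(lp))
  if (censor > 0) {
    t_c <- rexp(n, rate = h0 * censor / (1 - censor))
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      response = sample(c("CR", "PR", "SD", "PD"), n, replace = TRUE),
      os_time = pmin(t_ev, t_c),
      os_event = as.integer(t_ev <= t_c)
    )
  } else {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      response = sample(c("CR", "PR", "SD", "PD"), n, replace = TRUE),
      os_time = t_ev, os_event = 1L
    )
  }
}

test_that("Cox regression recovers a known hazard ratio and is scale-equivariant", {
  set.seed(10)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  cl <- sim_clinical(n, lp = log(2) * x, censor = 0, seed = 10)
  scores <- tibble::tibble(patient_id = cl$patient_id, M1 = x)
  fit <- cox_multiple(scores, cl)
  td <- tidy(fit)
  expect_equal(td$hr, 2, tolerance = 0.2)
  expect_true(td$hr_low < td$hr && td$hr < td$hr_high)
  # multiplying the covariate by c divides the log-HR by c
  fit10 <- cox_multiple(dplyr::mutate(scores, M1 = M1 * 10), cl)
  expect_equal(tidy(fit10)$estimate, td$estimate / 10, tolerance = 1e-6)
  # glance carries fit-level statistics
  g <- glance(fit)
  expect_equal(g$n, n)
  expect_gt(g$concordance, 0.5)
  # all-censored input is an error
  cl0 <- cl
  cl0$os_event <- 0L
  expect_error(cox_multiple(scores, cl0), "no events")
})

test_that("null Cox simulations are centered with nominal CI coverage", {
  n_rep <- 120
  n <- 150
  cover <- 0
  ests <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cl <- sim_clinical(n, seed = 500 + r)
    set.seed(9000 + r)
    scores <- tibble::tibble(patient_id = cl$patient_id, M1 = rnorm(n))
    td <- tidy(cox_multiple(scores, cl))
    ests[r] <- td$estimate
    cover <- cover + (td$hr_low <= 1 && 1 <= td$hr_high)
  }
  expect_lt(abs(mean(ests)), 0.03)
  expect_gt(cover / n_rep, 0.88)
  expect_lt(cover / n_rep, 1.0)
})

test_that("the log-rank test matches hand O-E/V arithmetic on a textbook example", {
  # 6 subjects, groups L/H, times with one censor
  cl <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    response = "SD",
    os_time = c(1, 2, 3, 4, 4, 5),
    os_event = c(1, 1, 1, 1, 0, 1)
  )
  scores <- tibble::tibble(patient_id = cl$patient_id,
                           M1 = c(0, 0, 0, 1, 1, 1)) # median split -> L/H
  km <- km_logrank(scores, cl, "M1")
  # hand computation of the two-group log-rank statistic
  lr <- survival::survdiff(survival::Surv(os_time, os_event) ~ (M1 > 0.5),
                           data = dplyr::inner_join(scores, cl, "patient_id"))
  expect_equal(km$chisq, lr$chisq, tolerance = 1e-12)
  # explicit O-E/V for the same data, accumulated over event times
  d <- dplyr::inner_join(scores, cl, "patient_id")
  d$grp <- d$M1 > 0.5
  times <- sort(unique(d$os_time[d$os_event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- d$os_time >= t
    n1 <- sum(at_risk & d$grp)
    n0 <- sum(at_risk)
    dt <- sum(d$os_time == t & d$os_event == 1)
    d1 <- sum(d$os_time == t & d$os_event == 1 & d$grp)
    O <- O + d1
    E <- E + dt * n1 / n0
    if (n0 > 1) V <- V + dt * (n1 / n0) * (1 - n1 / n0) * (n0 - dt) / (n0 - 1)
  }
  expect_equal(km$chisq, (O - E)^2 / V, tolerance = 1e-10)
  expect_equal(km$p_value, pchisq((O - E)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical survival in both groups: statistic ~ 0, p ~ 1
  cl2 <- tibble::tibble(patient_id = paste0("P", 1:8), response = "SD",
                        os_time = rep(c(1, 2, 3, 4), 2), os_event = 1L)
  sc2 <- tibble::tibble(patient_id = cl2$patient_id,
                        M1 = rep(c(0, 1), each = 4))
  km2 <- km_logrank(sc2, cl2, "M1")
  expect_lt(km2$chisq, 1e-10)
  expect_equal(km2$p_value, 1, tolerance = 1e-6)
  # degenerate split errors
  sc3 <- sc2
  sc3$M1 <- 1
  expect_error(km_logrank(sc3, cl2, "M1"), "degenerate")
})

test_that("log-rank agrees with the Cox score test direction on larger data", {
  set.seed(77)
  n <- 400
  x <- rnorm(n)
  cl <- sim_clinical(n, lp = -0.8 * x, censor = 0.2, seed = 77)
  scores <- tibble::tibble(patient_id = cl$patient_id, M1 = x)
  km <- km_logrank(scores, cl, "M1")
  expect_lt(km$p_value, 1e-4)
  # high group (protective direction) survives longer
  td <- tidy(km)
  med_surv <- tapply(td$estimate, td$group, min)
  expect_gt(med_surv["high"], med_surv["low"])
})

test_that("Kruskal-Wallis reproduces the rank formula and collapses RECIST groups", {
  cl <- tibble::tibble(
    patient_id = paste0("P", 1:9),
    response = c("CR", "PR", "PR", "SD", "SD", "SD", "PD", "PD", "PD"),
    os_time = 1, os_event = 1L
  )
  scores <- tibble::tibble(patient_id = cl$patient_id, M1 = c(1:3, 4:6, 7:9))
  res <- kruskal_wallis(scores, cl, "M1")
  # groups {1,2,3}, {4,5,6}, {7,8,9}: H = 7.2 by the rank-sum formula
  expect_equal(res$statistic, 7.2, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$mean_crpr, 2)
  expect_equal(res$mean_pd, 8)
  # NE patients are excluded before testing
  cl_ne <- cl
  cl_ne$response[5] <- "NE"
  res_ne <- kruskal_wallis(scores, cl_ne, "M1")
  expect_equal(res_ne$mean_sd, mean(c(4, 6)))
  # all observations equal -> H = 0
  sc_flat <- tibble::tibble(patient_id = cl$patient_id, M1 = rep(2, 9))
  expect_equal(kruskal_wallis(sc_flat, cl, "M1")$statistic, 0)
})

test_that("null Kruskal-Wallis p-values are approximately uniform", {
  set.seed(31)
  cl <- tibble::tibble(
    patient_id = paste0("P", 1:30),
    response = rep(c("CR", "PR", "SD", "PD"), c(3, 6, 9, 12)),
    os_time = 1, os_event = 1L
  )
  ps <- vapply(1:200, function(r) {
    scores <- tibble::tibble(patient_id = cl$patient_id, M1 = rnorm(30))
    kruskal_wallis(scores, cl, "M1")$p_value
  }, 0.0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("per-gene Wilcoxon matches exact enumeration and flags the planted gene", {
  # 3 vs 3: exact p by brute-force enumeration of rank assignments
  x <- c(1.1, 2.3, 3.7)
  y <- c(0.2, 0.9, 1.9)
  vals <- rbind(g1 = c(x, y))
  colnames(vals) <- paste0("P", 1:6)
  d <- riccinet:::new_diff_matrix(vals, scaled = TRUE)
  cl <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    response = c("CR", "PR", "PR", "PD", "PD", "PD"),
    os_time = 1, os_event = 1L
  )
  res <- per_gene_response_test(d, "g1", cl)
  pooled <- c(x, y)
  combos <- utils::combn(6, 3)
  u_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2
  u_all <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]) - 6)
  p_exact <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(res$statistic, u_obs)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res$mean_crpr, mean(x))
  expect_equal(res$mean_pd, mean(y))
  # identical values across groups: p = 1
  flat <- riccinet:::new_diff_matrix(
    rbind(g1 = rep(1, 6)) |> (\(m) { colnames(m) <- paste0("P", 1:6); m })(),
    scaled = TRUE)
  expect_equal(per_gene_response_test(flat, "g1", cl)$p_value, 1)
  # a planted responsive gene among nulls gets the smallest FDR
  set.seed(17)
  hits <- 0
  for (r in 1:20) {
    n_per <- 30
    ids <- paste0("P", seq_len(2 * n_per))
    cl_big <- tibble::tibble(
      patient_id = ids,
      response = rep(c("PR", "PD"), each = n_per),
      os_time = 1, os_event = 1L
    )
    m <- matrix(rnorm(21 * 2 * n_per), 21, 2 * n_per,
                dimnames = list(paste0("g", 1:21), ids))
    m["g1", seq_len(n_per)] <- m["g1", seq_len(n_per)] + 1.5
    db <- riccinet:::new_diff_matrix(m, scaled = TRUE)
    res_big <- per_gene_response_test(db, rownames(m), cl_big)
    hits <- hits + (res_big$gene[1] == "g1")
  }
  expect_gte(hits / 20, 0.95)
})

test_that("BH adjustment follows step-up arithmetic and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  adj <- bh_adjust(p)
  # hand step-up: p_(i) * n / i with cumulative minimum from the top
  hand <- rev(cummin(rev(p * length(p) / seq_along(p))))
  expect_equal(adj, pmin(1, hand))
  expect_true(all(adj >= p))
  expect_true(!is.unsorted(adj))
  # order-equivariant
  perm <- sample(length(p))
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("fully null per-gene testing controls the FDR at 5%", {
  set.seed(4)
  n_per <- 12
  ids <- paste0("P", seq_len(2 * n_per))
  cl <- tibble::tibble(patient_id = ids,
                       response = rep(c("PR", "PD"), each = n_per),
                       os_time = 1, os_event = 1L)
  false_hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    m <- matrix(rnorm(15 * 2 * n_per), 15, 2 * n_per,
                dimnames = list(paste0("g", 1:15), ids))
    d <- riccinet:::new_diff_matrix(m, scaled = TRUE)
    res <- per_gene_response_test(d, rownames(m), cl)
    false_hits <- false_hits + any(res$fdr < 0.05)
  }
  expect_lte(false_hits / n_rep, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep))
})
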