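#' Planted-partition PPI topology
#'
#' Samples an undirected planted-partition graph over `n_genes` genes split
#' evenly into `n_modules` blocks: within-block edges appear with
#' probability `p_in`, between-block edges with `p_out`, and STRING-style
#' confidence scores are drawn uniformly from `confidence_range`. If the
#' graph is disconnected, bridge edges joining the components are added and
#' recorded in the truth object.
#'
#' @param n_genes number of genes (default 120).
#' @param n_modules number of planted blocks (default 6).
#' @param p_in,p_out within-/between-block edge probabilities (defaults
#'   0.5 / 0.05, matching the analyzed study network's density of ~0.12 at
#'   120-gene scale so the degree filter stays the light touch it is at
#'   full scale; `p_out < p_in` required).
#' @param confidence_range length-2 integer range of confidence scores
#'   (default c(700, 1000), emulating a high-confidence STRING export so the
#'   planted edge probabilities remain the effective topology under the
#'   pipeline's default confidence cutoff).
#' @param seed RNG seed; the generator is a pure function of it.
#' @return A list: `topology` ([ppi_topology()]) and `truth`
#'   (`synthetic_truth` with planted `modules`, recorded `bridges`, `seed`).
#' @export
generate_topology <- function(n_genes = 120, n_modules = 6, p_in = 0.5,
                              p_out = 0.05, confidence_range = c(700, 1000),
                              seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("need 0 <= p_out < p_in <= 1")
  }
  if (n_modules < 1) abort("need n_modules >= 1")
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  modules <- sort(rep(seq_len(n_modules), length.out = n_genes))
  names(modules) <- genes
  block <- n_genes / n_modules
  exp_deg <- (block - 1) * p_in + (n_genes - block) * p_out
  if (exp_deg < 1) warn("expected degree below 1; graph will be very sparse")
  pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  same <- modules[pairs[, 1]] == modules[pairs[, 2]]
  prob <- ifelse(same, p_in, p_out)
  keep <- rbinom(nrow(pairs), 1, prob) == 1
  ea <- genes[pairs[keep, 1]]
  eb <- genes[pairs[keep, 2]]
  score <- round(runif(sum(keep), confidence_range[1], confidence_range[2]))
  topo <- ppi_topology(data.frame(gene_a = ea, gene_b = eb, score = score))
  # connect components with recorded bridges
  g <- topology_igraph(topo)
  present <- igraph::V(g)$name
  isolated <- setdiff(genes, present)
  comp <- igraph::components(g)
  reps <- vapply(seq_len(comp$no), function(k) {
    min(igraph::V(g)$name[comp$membership == k])
  }, "")
  anchors <- sort(c(reps, isolated))
  bridges <- NULL
  if (length(anchors) > 1) {
    bridges <- tibble(
      gene_a = anchors[-length(anchors)],
      gene_b = anchors[-1],
      score = max(confidence_range)
    )
    topo <- ppi_topology(bind_rows(as_tibble(topo[, c("gene_a", "gene_b", "score")]),
                                   bridges))
  }
  truth <- structure(
    list(modules = modules,
         bridges = bridges %||% tibble(gene_a = character(), gene_b = character(),
                                       score = numeric()),
         n_modules = n_modules, seed = seed),
    class = "synthetic_truth"
  )
  list(topology = topo, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", length(x$modules), " genes in ", x$n_modules,
      " planted modules, ", nrow(x$bridges), " bridges (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Synthetic paired expression study with planted module signals
#'
#' Each patient p draws one latent loading per module,
#' `lambda[p, m] ~ N(0, 1)`; the on-minus-pre difference of gene g in module
#' m is `a_g * lambda[p, m] + N(0, noise_sd)` with gene amplitude
#' `a_g ~ U(0.5, 1.5)`, so genes of one module are correlated through their
#' shared loading and genes of different modules are independent.
#' Pre-treatment log-scale values sit on a per-gene baseline; on = pre +
#' difference; raw counts are reconstructed as `round(2^norm)` so the
#' low-expression filter is exercisable. Unmatched pre-only/on-only patients
#' and near-zero "low" decoy genes are added to exercise pairing and
#' filtering.
#'
#' @param topology a [ppi_topology()] from [generate_topology()].
#' @param truth the matching `synthetic_truth`.
#' @param n_patients matched patients (default 43).
#' @param noise_sd gene-level noise sd (default 0.5).
#' @param seed RNG seed.
#' @param n_unmatched_pre,n_unmatched_on extra single-timepoint patients
#'   (defaults 8 and 15, mirroring a 51-pre / 58-on cohort).
#' @param n_low_genes decoy genes below the count filter (default 8).
#' @param baseline_mean,baseline_sd per-gene baseline distribution of the
#'   log-scale values (defaults 7 and 1).
#' @return A list: `study` ([expression_study()]) and `truth` augmented with
#'   `loadings` (patient x module), `amplitudes`, `noise_sd`.
#' @export
generate_expression <- function(topology, truth, n_patients = 43,
                                noise_sd = 0.5, seed = 1,
                                n_unmatched_pre = 8, n_unmatched_on = 15,
                                n_low_genes = 8,
                                baseline_mean = 7, baseline_sd = 1) {
  if (n_patients < 4) abort("need n_patients >= 4")
  set.seed(seed)
  genes <- names(truth$modules)
  m <- truth$n_modules
  pats <- sprintf("P%02d", seq_len(n_patients))
  loadings <- matrix(rnorm(n_patients * m), n_patients, m,
                     dimnames = list(pats, paste0("M", seq_len(m))))
  amp <- setNames(runif(length(genes), 0.5, 1.5), genes)
  noise <- matrix(rnorm(length(genes) * n_patients, 0, noise_sd),
                  length(genes), n_patients)
  diff <- amp * t(loadings[, truth$modules[genes], drop = FALSE]) + noise
  dimnames(diff) <- list(genes, pats)

  mu <- setNames(rnorm(length(genes), baseline_mean, baseline_sd), genes)
  pre <- mu + matrix(rnorm(length(genes) * n_patients, 0, 0.3),
                     length(genes), n_patients)
  on <- pre + diff

  upre <- if (n_unmatched_pre > 0) sprintf("U%02d", seq_len(n_unmatched_pre)) else character()
  uon <- if (n_unmatched_on > 0) sprintf("V%02d", seq_len(n_unmatched_on)) else character()
  pre_extra <- mu + matrix(rnorm(length(genes) * length(upre), 0, 0.3),
                           length(genes), length(upre))
  on_extra <- mu + matrix(rnorm(length(genes) * length(uon), 0, 0.3),
                          length(genes), length(uon))

  low <- if (n_low_genes > 0) sprintf("LOW%02d", seq_len(n_low_genes)) else character()
  n_samp <- 2 * n_patients + length(upre) + length(uon)
  low_norm <- matrix(rnorm(length(low) * n_samp, 1, 0.3), length(low), n_samp)

  norm <- cbind(pre, on, pre_extra, on_extra)
  sample_ids <- c(paste0(pats, "_pre"), paste0(pats, "_on"),
                  paste0(upre, "_pre"), paste0(uon, "_on"))
  colnames(norm) <- sample_ids
  if (length(low)) {
    rownames(low_norm) <- low
    colnames(low_norm) <- sample_ids
    norm <- rbind(norm, low_norm)
  }
  counts <- round(2^norm)
  samples <- tibble(
    sample_id = sample_ids,
    patient_id = c(pats, pats, upre, uon),
    timepoint = c(rep("pre", n_patients), rep("on", n_patients),
                  rep("pre", length(upre)), rep("on", length(uon)))
  )
  study <- expression_study(counts, norm, samples)
  truth$loadings <- loadings
  truth$amplitudes <- amp
  truth$noise_sd <- noise_sd
  truth$diff_signal <- diff
  list(study = study, truth = truth)
}

#' Synthetic clinical outcomes driven by one module's loading
#'
#' Survival times are exponential with hazard
#' `h0 * exp(-beta * lambda[p, m*])` for the designated protective module
#' m*, so a positive `beta` makes a higher loading protective; independent
#' exponential censoring is calibrated so roughly `censor_rate` of patients
#' are censored. RECIST-like responses come from an ordinal model on the
#' same loading (latent `1.5 * lambda + logistic noise` against cutpoints
#' 3.5 / 2.0 / 0.0 for CR / PR / SD, PD below), making PD the largest group;
#' one patient is relabeled NE to exercise the removal rule.
#'
#' @param truth a `synthetic_truth` carrying `loadings`.
#' @param protective_module designated module index m* (default: the last).
#' @param beta protective log-hazard coefficient (default 1).
#' @param h0 baseline hazard (default 0.05).
#' @param censor_rate target censored fraction in \[0, 1) (default 0.3).
#' @param seed RNG seed.
#' @param ne_patient add one NE-labeled patient (default `TRUE`).
#' @return A list: `clinical` tibble (`patient_id`, `response`, `os_time`,
#'   `os_event`) and `truth` augmented with the survival/response model.
#' @export
generate_clinical <- function(truth, protective_module = NULL, beta = 1,
                              h0 = 0.05, censor_rate = 0.3, seed = 1,
                              ne_patient = TRUE) {
  if (is.null(truth$loadings)) abort("truth carries no loadings; run generate_expression first")
  if (!is.finite(beta)) abort("beta must be finite")
  if (censor_rate < 0 || censor_rate >= 1) abort("need 0 <= censor_rate < 1")
  set.seed(seed)
  mstar <- protective_module %||% truth$n_modules
  lam <- truth$loadings[, mstar]
  n <- length(lam)
  haz <- h0 * exp(-beta * lam)
  t_event <- rexp(n, rate = haz)
  if (censor_rate > 0) {
    c_rate <- h0 * censor_rate / (1 - censor_rate)
    t_cens <- rexp(n, rate = c_rate)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
  } else {
    os_time <- t_event
    os_event <- rep(1L, n)
  }
  latent <- 1.5 * lam + rlogis(n)
  response <- ifelse(latent > 3.5, "CR",
              ifelse(latent > 2.0, "PR",
              ifelse(latent > 0.0, "SD", "PD")))
  ne_idx <- NA_integer_
  if (ne_patient && n > 1) {
    ne_idx <- sample.int(n, 1)
    response[ne_idx] <- "NE"
  }
  clinical <- tibble(
    patient_id = rownames(truth$loadings),
    response = response, os_time = os_time, os_event = os_event
  )
  truth$protective_module <- mstar
  truth$beta <- beta
  truth$h0 <- h0
  truth$censor_rate <- censor_rate
  truth$ne_patient <- if (is.na(ne_idx)) NA_character_ else clinical$patient_id[ne_idx]
  list(clinical = clinical, truth = truth)
}

#' Synthetic gene-set collection with module-exact sets and decoys
#'
#' One set per planted module containing exactly its genes, plus
#' `n_decoy_sets` random sets whose sizes cycle through the module sizes.
#'
#' @param truth a `synthetic_truth`.
#' @param n_decoy_sets number of random decoy sets (default 10).
#' @param seed RNG seed.
#' @return A named list of character vectors (GMT-writable).
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 10, seed = 1) {
  set.seed(seed)
  genes <- names(truth$modules)
  sets <- lapply(seq_len(truth$n_modules), function(m) {
    genes[truth$modules == m]
  })
  names(sets) <- paste0("MODULE_", seq_len(truth$n_modules))
  sizes <- lengths(sets)
  if (n_decoy_sets > 0) {
    decoys <- lapply(seq_len(n_decoy_sets), function(k) {
      sample(genes, sizes[((k - 1) %% length(sizes)) + 1])
    })
    names(decoys) <- paste0("DECOY_", seq_len(n_decoy_sets))
    sets <- c(sets, decoys)
  }
  sets
}

#' Core-gene list for a synthetic study
#'
#' Picks the first `per_module` genes of each planted module as the "core"
#' set whose PPI neighborhood seeds the network, mirroring how a curated
#' core pathway set seeds the real analysis.
#'
#' @param truth a `synthetic_truth`.
#' @param per_module core genes per module (default 2).
#' @return Character vector of core genes.
#' @export
synthetic_core_genes <- function(truth, per_module = 2) {
  unlist(lapply(seq_len(truth$n_modules), function(m) {
    head(names(truth$modules)[truth$modules == m], per_module)
  }), use.names = FALSE)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every file the pipeline reads: counts and normalized TSVs, the
#' sample sheet, the clinical table, a STRING-dialect PPI edge list, the
#' core-gene list, and a GMT collection.
#'
#' @param dir output directory (created if absent).
#' @param n_genes,n_modules,p_in,p_out,n_patients,noise_sd,beta,censor_rate
#'   generator parameters (see the individual generators).
#' @param seed RNG seed for all stages.
#' @return Invisibly, a list of file paths plus the `truth` object.
#' @export
write_synthetic_bundle <- function(dir, n_genes = 120, n_modules = 6,
                                   p_in = 0.5, p_out = 0.05, n_patients = 43,
                                   noise_sd = 0.5, beta = 1,
                                   censor_rate = 0.3, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- generate_topology(n_genes, n_modules, p_in, p_out, seed = seed)
  expr <- generate_expression(top$topology, top$truth, n_patients = n_patients,
                              noise_sd = noise_sd, seed = seed + 1)
  clin <- generate_clinical(expr$truth, beta = beta,
                            censor_rate = censor_rate, seed = seed + 2)
  sets <- generate_gene_sets(clin$truth, seed = seed + 3)
  core <- synthetic_core_genes(clin$truth)

  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    norm = file.path(dir, "norm.tsv"),
    samples = file.path(dir, "samples.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    ppi = file.path(dir, "ppi_links.txt"),
    core = file.path(dir, "core_genes.txt"),
    gmt = file.path(dir, "gene_sets.gmt")
  )
  st <- expr$study
  readr::write_tsv(as_tibble(st$counts, rownames = "gene"), paths$counts)
  readr::write_tsv(as_tibble(st$norm, rownames = "gene"), paths$norm)
  readr::write_tsv(st$samples, paths$samples)
  readr::write_tsv(clin$clinical, paths$clinical)
  write_ppi(top$topology, paths$ppi)
  writeLines(core, paths$core)
  write_gmt(sets, paths$gmt)
  invisible(c(paths, list(truth = clin$truth)))
}
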