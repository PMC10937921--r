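#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end analysis. The
#' fixed defaults are the study conditions: 101 diffusion scales with
#' log10(tau) in \[-2, 2\], critical rule = first scale where the 99th
#' percentile of edge curvature reaches 0.75, Louvain resolution 1, STRING
#' confidence cutoff 700, minimum initial degree 5.
#'
#' @param counts_path,norm_path,sample_meta_path,clinical_path,ppi_path,core_path
#'   input file paths (`NULL` entries allowed when the corresponding object
#'   is passed directly to [run_pipeline()]).
#' @param gmt_path optional gene-set collection for enrichment.
#' @param min_score STRING confidence cutoff (default 700).
#' @param min_degree minimum initial PPI degree (default 5).
#' @param tau_n,tau_log10_range diffusion grid spec (defaults 101 and
#'   c(-2, 2)).
#' @param percentile,kappa_threshold critical-scale rule (defaults 99, 0.75).
#' @param ot_method `"exact_lp"` or `"sinkhorn"`.
#' @param trunc_delta transport support truncation (default 1e-4).
#' @param louvain_resolution,louvain_seed,negative_weights Louvain settings.
#' @param normalize_integral normalize kappa_bar by tau_crit (default FALSE).
#' @param quantile_normalize apply cross-sample quantile normalization
#'   (default TRUE).
#' @param compartment_path optional gene-compartment annotation for edge
#'   sparsification (off when `NULL`).
#' @param out_dir output directory (`NULL` = keep results in memory only).
#' @param seed pipeline seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, norm_path = NULL,
                            sample_meta_path = NULL, clinical_path = NULL,
                            ppi_path = NULL, core_path = NULL,
                            gmt_path = NULL,
                            min_score = 700, min_degree = 5,
                            tau_n = 101, tau_log10_range = c(-2, 2),
                            percentile = 99, kappa_threshold = 0.75,
                            ot_method = c("exact_lp", "sinkhorn"),
                            trunc_delta = 1e-4,
                            louvain_resolution = 1, louvain_seed = 0,
                            negative_weights = c("clamp", "passthrough"),
                            normalize_integral = FALSE,
                            quantile_normalize = TRUE,
                            compartment_path = NULL,
                            out_dir = NULL, seed = 1) {
  ot_method <- match.arg(ot_method)
  negative_weights <- match.arg(negative_weights)
  stopifnot(tau_n >= 1, length(tau_log10_range) == 2,
            percentile > 0, percentile <= 100,
            kappa_threshold > 0, kappa_threshold <= 1,
            min_degree >= 0, trunc_delta >= 0)
  cfg <- list(
    counts_path = counts_path, norm_path = norm_path,
    sample_meta_path = sample_meta_path, clinical_path = clinical_path,
    ppi_path = ppi_path, core_path = core_path, gmt_path = gmt_path,
    min_score = min_score, min_degree = min_degree,
    tau_n = tau_n, tau_log10_range = tau_log10_range,
    percentile = percentile, kappa_threshold = kappa_threshold,
    ot_method = ot_method, trunc_delta = trunc_delta,
    louvain_resolution = louvain_resolution, louvain_seed = louvain_seed,
    negative_weights = negative_weights,
    normalize_integral = normalize_integral,
    quantile_normalize = quantile_normalize,
    compartment_path = compartment_path,
    out_dir = out_dir, seed = seed
  )
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  key <- cfg[setdiff(names(cfg), "out_dir")]
  paste0(sum(utf8ToInt(paste(deparse(key), collapse = ""))
             * seq_along(utf8ToInt(paste(deparse(key), collapse = "")))) %% 1e9)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: expression loading/filtering/normalization, paired
#' differencing and scaling, PPI filtering and core-neighborhood network
#' construction, the dynamic-curvature sweep, critical-scale detection and
#' integral curvature, curvature-weighted Louvain modules, module scores,
#' survival and response statistics, and (when a collection is supplied)
#' per-module over-representation analysis. With `out_dir` set, all tables,
#' the GraphML network, and a JSON run manifest are written; the expensive
#' curvature sweep is cached there keyed by a config hash.
#'
#' @param config a [pipeline_config()].
#' @param study optional in-memory [expression_study()] (overrides paths).
#' @param clinical optional in-memory clinical tibble.
#' @param topology optional in-memory [ppi_topology()].
#' @param core_genes optional in-memory core-gene vector.
#' @param collection optional in-memory gene-set collection.
#' @return A `pipeline_result` list: `study`, `diff`, `network`, `field`,
#'   `tau_crit`, `critical` (edge table with kappa_crit / kappa_bar_crit),
#'   `assignment`, `scores`, `within_between`, `cox`, `km`, `kruskal`,
#'   `gene_tests`, `enrichment`, `manifest`. The Kaplan-Meier, response, and
#'   per-gene analyses target the module whose Cox p-value is smallest (the
#'   manifest's `focus_module`).
#' @export
run_pipeline <- function(config, study = NULL, clinical = NULL,
                         topology = NULL, core_genes = NULL,
                         collection = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  study <- stage("expression_io", {
    st <- study %||% read_expression(config$counts_path, config$norm_path,
                                     config$sample_meta_path)
    st <- filter_low_expression(st)
    if (config$quantile_normalize) st <- quantile_normalize(st)
    st
  })
  clinical <- stage("clinical_io", {
    validate_clinical(clinical %||% read_clinical(config$clinical_path))
  })
  diff <- stage("paired_difference", {
    scale_differences(paired_difference(study))
  })

  network <- stage("network_builder", {
    topo <- topology %||% read_ppi(config$ppi_path)
    core <- core_genes %||% readLines(config$core_path)
    topo <- filter_confidence(topo, config$min_score)
    if (!is.null(config$compartment_path)) {
      ct <- readr::read_tsv(config$compartment_path, show_col_types = FALSE)
      topo <- compartment_sparsify(topo, ct)
    }
    topo <- filter_min_degree(topo, config$min_degree)
    # restrict to genes with expression before correlating
    keep <- topo$gene_a %in% diff$genes & topo$gene_b %in% diff$genes
    topo <- topo[keep, , drop = FALSE]
    class(topo) <- c("ppi_topology", class(tibble()))
    subset <- select_core_neighborhood(topo, core)
    topo <- largest_component(topo, subset)
    build_correlation_network(topo, diff)
  })

  field <- NULL
  cache_path <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    cache_path <- file.path(config$out_dir,
                            paste0("curvature_cache_", config_hash(config), ".rds"))
    if (file.exists(cache_path)) field <- readRDS(cache_path)
  }
  if (is.null(field)) {
    field <- stage("dynamic_curvature", {
      curvature_sweep(
        network,
        tau_grid = default_tau_grid(config$tau_n, config$tau_log10_range),
        method = config$ot_method, trunc_delta = config$trunc_delta
      )
    })
    if (!is.null(cache_path)) saveRDS(field, cache_path)
  }
  crit <- stage("critical_scale", {
    critical_curvature(field, config$percentile, config$kappa_threshold,
                       config$normalize_integral)
  })

  assignment <- stage("module_detection", {
    louvain_modules(network, crit$edges$kappa_bar_crit,
                    resolution = config$louvain_resolution,
                    seed = config$louvain_seed,
                    negative_weights = config$negative_weights)
  })
  wb <- within_between_summary(assignment, network, crit$edges$kappa_bar_crit)
  scores <- module_scores(assignment, diff)

  cox <- stage("clinical_stats", cox_multiple(scores, clinical))
  # follow-up analyses target the module with the strongest survival signal
  cox_tab <- tidy(cox)
  focus <- cox_tab$module[which.min(cox_tab$p_value)]
  focus_idx <- as.integer(sub("^M", "", focus))
  km <- stage("km_logrank", km_logrank(scores, clinical, focus))
  # response analyses need populated responder/non-responder groups; a small
  # cohort may lack one, in which case these outputs are NULL
  groups <- table(response_groups(clinical)$response_group)
  kw <- NULL
  gene_tests <- NULL
  if (sum(groups > 0) >= 2) {
    kw <- stage("kruskal_wallis", kruskal_wallis(scores, clinical, focus))
  }
  if (groups[["CR/PR"]] > 0 && groups[["PD"]] > 0) {
    gene_tests <- stage("per_gene_response_test", {
      per_gene_response_test(diff,
                             assignment$gene[assignment$module == focus_idx],
                             clinical)
    })
  }

  enr <- NULL
  if (!is.null(collection) || !is.null(config$gmt_path)) {
    enr <- stage("enrichment", {
      coll <- collection %||% read_gmt(config$gmt_path)
      mods <- sort(unique(assignment$module))
      purrr::map_dfr(mods, function(m) {
        hypergeometric_ora(assignment$gene[assignment$module == m], coll,
                           universe = network$vertices) |>
          mutate(module = m, .before = 1)
      })
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("riccinet")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_genes = length(network$vertices),
    n_edges = nrow(network$edges),
    tau_crit = crit$tau_crit,
    focus_module = focus,
    n_modules = length(attr(assignment, "module_sizes")),
    module_sizes = attr(assignment, "module_sizes"),
    modularity = attr(assignment, "modularity")
  )

  result <- structure(
    list(study = study, diff = diff, network = network, field = field,
         tau_crit = crit$tau_crit, critical = crit$edges,
         assignment = assignment, scores = scores, within_between = wb,
         cox = cox, km = km, kruskal = kw, gene_tests = gene_tests,
         enrichment = enr, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result> ", m$n_genes, " genes / ", m$n_edges,
      " edges; tau_crit = ", signif(m$tau_crit, 4), "; ", m$n_modules,
      " modules (sizes ", paste(m$module_sizes, collapse = "/"), ")\n",
      sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$critical, file.path(out_dir, "edge_curvature.tsv"))
  readr::write_tsv(as_tibble(result$assignment),
                   file.path(out_dir, "module_assignment.tsv"))
  readr::write_tsv(result$scores, file.path(out_dir, "module_scores.tsv"))
  readr::write_tsv(tidy(result$cox), file.path(out_dir, "cox_modules.tsv"))
  if (!is.null(result$gene_tests)) {
    readr::write_tsv(result$gene_tests,
                     file.path(out_dir, "gene_response_tests.tsv"))
  }
  if (!is.null(result$enrichment)) {
    readr::write_tsv(result$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  write_network(result$network,
                graphml_path = file.path(out_dir, "network.graphml"),
                edges_path = file.path(out_dir, "network_edges.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
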