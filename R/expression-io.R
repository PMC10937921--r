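#' Expression study container
#'
#' Bundles a paired pre-/on-treatment expression experiment: raw counts and
#' normalized (log-scale) values over the same gene-by-sample grid, plus the
#' sample sheet linking each sample to a patient and a timepoint.
#'
#' @param counts gene x sample matrix of nonnegative raw counts, rownames =
#'   gene symbols, colnames = sample ids.
#' @param norm gene x sample matrix of normalized log-scale values with
#'   identical dimnames.
#' @param samples data frame with columns `sample_id`, `patient_id`,
#'   `timepoint` (one of `"pre"`, `"on"`).
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(counts, norm, samples) {
  counts <- as.matrix(counts)
  norm <- as.matrix(norm)
  samples <- as_tibble(samples)
  need <- c("sample_id", "patient_id", "timepoint")
  if (!all(need %in% names(samples))) {
    abort(paste0("sample sheet must have columns: ", paste(need, collapse = ", ")))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$patient_id <- as.character(samples$patient_id)
  samples$timepoint <- as.character(samples$timepoint)
  bad_tp <- setdiff(unique(samples$timepoint), c("pre", "on"))
  if (length(bad_tp) > 0) {
    abort(paste0("unknown timepoint label(s): ", paste(bad_tp, collapse = ", ")))
  }
  if (is.null(rownames(counts)) || is.null(rownames(norm))) {
    abort("count and normalized matrices must carry gene rownames")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene ids in counts")
  missing_in_norm <- setdiff(rownames(counts), rownames(norm))
  missing_in_counts <- setdiff(rownames(norm), rownames(counts))
  if (length(missing_in_norm) || length(missing_in_counts)) {
    abort(paste0(
      "gene sets differ between counts and normalized values; ",
      "missing in norm: [", paste(head(missing_in_norm, 5), collapse = ", "),
      "], missing in counts: [", paste(head(missing_in_counts, 5), collapse = ", "), "]"
    ))
  }
  norm <- norm[rownames(counts), , drop = FALSE]
  if (!setequal(colnames(counts), samples$sample_id) ||
      !setequal(colnames(norm), samples$sample_id)) {
    abort("matrix columns must match the sample sheet's sample_id set")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  norm <- norm[, samples$sample_id, drop = FALSE]
  if (anyDuplicated(samples[, c("patient_id", "timepoint")])) {
    abort("a patient may contribute at most one sample per timepoint")
  }
  structure(
    list(genes = rownames(counts), samples = samples,
         counts = counts, norm = norm),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  matched <- n_matched_patients(x)
  cat("<expression_study> ", length(x$genes), " genes x ", nrow(x$samples),
      " samples (", sum(x$samples$timepoint == "pre"), " pre / ",
      sum(x$samples$timepoint == "on"), " on; ", matched,
      " matched patients)\n", sep = "")
  invisible(x)
}

n_matched_patients <- function(study) {
  tp <- table(study$samples$patient_id, study$samples$timepoint)
  if (!all(c("pre", "on") %in% colnames(tp))) return(0L)
  sum(tp[, "pre"] > 0 & tp[, "on"] > 0)
}

#' @export
tidy.expression_study <- function(x, values = c("norm", "counts"), ...) {
  values <- match.arg(values)
  m <- x[[values]]
  as_tibble(m, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value") |>
    left_join(x$samples, by = "sample_id")
}

#' Read a paired expression study from TSV files
#'
#' Expects genes-as-rows tables with a leading gene-id column and a header of
#' sample ids, plus a sample sheet with columns `sample_id`, `patient_id`,
#' `timepoint`.
#'
#' @param counts_path,norm_path,sample_meta_path paths to tab-separated files.
#' @return An [expression_study()] object.
#' @export
read_expression <- function(counts_path, norm_path, sample_meta_path) {
  counts <- read_gene_matrix(counts_path)
  norm <- read_gene_matrix(norm_path)
  samples <- readr::read_tsv(sample_meta_path, show_col_types = FALSE)
  expression_study(counts, norm, samples)
}

read_gene_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a patient clinical table
#'
#' Columns: `patient_id`, `response` (RECIST v1.1: CR/PR/SD/PD/NE),
#' `os_time` (nonnegative, units as recorded), `os_event` (0/1).
#'
#' @param path path to a tab-separated clinical table.
#' @return A tibble.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE)
  validate_clinical(cl)
}

validate_clinical <- function(cl) {
  cl <- as_tibble(cl)
  need <- c("patient_id", "response", "os_time", "os_event")
  if (!all(need %in% names(cl))) {
    abort(paste0("clinical table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cl$patient_id)) abort("one row per patient required")
  bad <- setdiff(unique(cl$response), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad)) abort(paste0("unknown response label(s): ", paste(bad, collapse = ", ")))
  if (any(cl$os_time < 0)) abort("os_time must be nonnegative")
  if (!all(cl$os_event %in% c(0, 1))) abort("os_event must be 0/1")
  cl$patient_id <- as.character(cl$patient_id)
  cl
}

#' Drop lowly expressed genes
#'
#' A gene is removed when its raw count falls below `min_count` in strictly
#' more than `frac_threshold` of samples (e.g. with the defaults, fewer than
#' 10 counts in more than 90% of samples).
#'
#' @param study an [expression_study()].
#' @param min_count count threshold defining "low" (default 10).
#' @param frac_threshold strict fraction-of-samples threshold (default 0.90).
#' @return A filtered `expression_study` with gene order preserved.
#' @export
filter_low_expression <- function(study, min_count = 10, frac_threshold = 0.90) {
  stopifnot(inherits(study, "expression_study"))
  frac_low <- rowMeans(study$counts < min_count)
  keep <- frac_low <= frac_threshold
  if (!any(keep)) abort("low-expression filter removed every gene")
  subset_genes(study, study$genes[keep])
}

subset_genes <- function(study, genes) {
  structure(
    list(genes = genes, samples = study$samples,
         counts = study$counts[genes, , drop = FALSE],
         norm = study$norm[genes, , drop = FALSE]),
    class = "expression_study"
  )
}

#' Quantile-normalize the normalized-value matrix across samples
#'
#' Makes every sample column share the identical empirical distribution (the
#' per-rank mean across samples), preserving within-column ranks; ties within
#' a column receive the mean of the reference values across their rank span.
#'
#' @param study an [expression_study()].
#' @return The study with `norm` replaced by its quantile-normalized version.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$norm) < 2) {
    warn("single-sample study: quantile normalization is a no-op")
    return(study)
  }
  qn <- limma::normalizeQuantiles(study$norm, ties = TRUE)
  dimnames(qn) <- dimnames(study$norm)
  study$norm <- qn
  study
}

#' Rename genes through a two-column id mapping
#'
#' Genes without a mapping are dropped (with a message); when several source
#' ids map to one target symbol, the row with the highest mean raw count is
#' kept.
#'
#' @param study an [expression_study()].
#' @param mapping data frame whose first two columns are (source id, symbol).
#' @return The study with genes renamed to symbols.
#' @export
map_gene_ids <- function(study, mapping) {
  stopifnot(inherits(study, "expression_study"))
  mapping <- as.data.frame(mapping)
  if (nrow(mapping) == 0) abort("empty gene id mapping")
  src <- as.character(mapping[[1]])
  sym <- as.character(mapping[[2]])
  hit <- match(study$genes, src)
  unmapped <- sum(is.na(hit))
  if (unmapped > 0) {
    inform(paste0("dropping ", unmapped, " gene(s) without an id mapping"))
  }
  keep <- which(!is.na(hit))
  if (length(keep) == 0) abort("no gene mapped to a symbol")
  genes <- study$genes[keep]
  symbols <- sym[hit[keep]]
  mean_count <- rowMeans(study$counts[genes, , drop = FALSE])
  ord <- order(symbols, -mean_count, genes)
  dup <- duplicated(symbols[ord])
  if (any(dup)) {
    inform(paste0("resolving ", sum(dup),
                  " duplicate symbol(s) by highest mean raw count"))
  }
  sel <- ord[!dup]
  sel <- sel[order(match(genes[sel], study$genes))] # original order
  out <- subset_genes(study, genes[sel])
  rownames(out$counts) <- rownames(out$norm) <- symbols[sel]
  out$genes <- symbols[sel]
  out
}

#' Per-patient on-minus-pre expression differences
#'
#' For every patient with both a pre- and an on-treatment sample, the
#' difference of normalized values (on minus pre), one column per matched
#' patient.
#'
#' @param study an [expression_study()].
#' @return A `diff_matrix` object (`scaled = FALSE`).
#' @export
paired_difference <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  s <- study$samples
  pre <- s[s$timepoint == "pre", ]
  on <- s[s$timepoint == "on", ]
  patients <- intersect(pre$patient_id, on$patient_id)
  if (length(patients) == 0) abort("no patient has both pre and on samples")
  pre_id <- setNames(pre$sample_id, pre$patient_id)[patients]
  on_id <- setNames(on$sample_id, on$patient_id)[patients]
  values <- study$norm[, on_id, drop = FALSE] - study$norm[, pre_id, drop = FALSE]
  colnames(values) <- patients
  new_diff_matrix(values, scaled = FALSE)
}

new_diff_matrix <- function(values, scaled) {
  structure(
    list(genes = rownames(values), patients = colnames(values),
         values = values, scaled = scaled),
    class = "diff_matrix"
  )
}

#' @export
print.diff_matrix <- function(x, ...) {
  cat("<diff_matrix> ", length(x$genes), " genes x ", length(x$patients),
      " patients", if (x$scaled) " (scaled)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.diff_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "patient_id", values_to = "diff")
}

#' Scale expression differences by per-gene standard deviation
#'
#' Each gene row is divided by its cross-patient sample standard deviation
#' (n - 1 denominator) without mean-centering, so the sign of each change is
#' preserved. Zero-variance genes are set to 0 with a warning rather than
#' dropped, keeping the gene set aligned with the network.
#'
#' @param diff an unscaled `diff_matrix` from [paired_difference()].
#' @return The `diff_matrix` with `scaled = TRUE`.
#' @export
scale_differences <- function(diff) {
  stopifnot(inherits(diff, "diff_matrix"))
  if (isTRUE(diff$scaled)) abort("differences are already scaled")
  sds <- apply(diff$values, 1, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warn(paste0(sum(const), " zero-variance gene row(s) set to 0 after scaling"))
    sds[const] <- 1
  }
  values <- diff$values / sds
  values[const, ] <- 0
  new_diff_matrix(values, scaled = TRUE)
}

#' Write a difference matrix as TSV
#'
#' @param diff a `diff_matrix`.
#' @param path output path.
#' @export
write_diff_tsv <- function(diff, path) {
  df <- as_tibble(diff$values, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read GEO-style supplementary count/normalized tables
#'
#' Loader for series-supplementary tables whose first column is the gene id
#' and whose sample columns encode patient and timepoint as
#' `<patient>_Pre`/`<patient>_On`; the sample sheet is derived from the
#' header.
#'
#' @param counts_path,norm_path paths to comma- or tab-separated tables.
#' @return An [expression_study()].
#' @export
read_geo_supplementary <- function(counts_path, norm_path) {
  read_auto <- function(path) {
    df <- readr::read_delim(path, delim = NULL, show_col_types = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
  counts <- read_auto(counts_path)
  norm <- read_auto(norm_path)
  ids <- colnames(counts)
  tp <- ifelse(grepl("_pre$", ids, ignore.case = TRUE), "pre",
        ifelse(grepl("_on$", ids, ignore.case = TRUE), "on", NA))
  if (anyNA(tp)) {
    abort("cannot parse timepoint from sample column names (expect *_Pre / *_On)")
  }
  samples <- tibble(
    sample_id = ids,
    patient_id = sub("_(pre|on)$", "", ids, ignore.case = TRUE),
    timepoint = tp
  )
  expression_study(counts, norm, samples)
}
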