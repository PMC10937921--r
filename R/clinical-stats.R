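#' Multiple Cox regression of survival on module scores
#'
#' Fits one Cox proportional-hazards model with all module scores as joint
#' covariates (Efron tie handling), giving each module's hazard ratio
#' adjusted for the others.
#'
#' @param scores wide score tibble from [module_scores()].
#' @param clinical clinical tibble (`patient_id`, `os_time`, `os_event`, ...).
#' @return A `module_cox` object wrapping the `survival::coxph` fit; use
#'   [tidy()] for the per-module hazard-ratio table and [glance()] for global
#'   fit statistics.
#' @export
cox_multiple <- function(scores, clinical) {
  clinical <- validate_clinical(clinical)
  df <- inner_join(scores, clinical, by = "patient_id")
  if (nrow(df) == 0) abort("no patient overlaps between scores and clinical data")
  if (sum(df$os_event) == 0) abort("no events: all survival times censored")
  covs <- setdiff(names(scores), "patient_id")
  fml <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~",
    paste(sprintf("`%s`", covs), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) && isTRUE(grepl("did not converge", fit$info))) {
    abort("Cox fit did not converge")
  }
  structure(list(fit = fit, covariates = covs, n = nrow(df),
                 n_events = sum(df$os_event)),
            class = "module_cox")
}

#' @export
print.module_cox <- function(x, ...) {
  cat("<module_cox> ", length(x$covariates), " module scores, n = ", x$n,
      " (", x$n_events, " events)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.module_cox <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(
    module = rownames(co),
    estimate = co[, "coef"],
    hr = co[, "exp(coef)"],
    std_error = co[, "se(coef)"],
    hr_low = ci[, "lower .95"],
    hr_high = ci[, "upper .95"],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @export
glance.module_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n, n_events = x$n_events,
    concordance = unname(s$concordance[1]),
    logtest_stat = unname(s$logtest["test"]),
    logtest_p = unname(s$logtest["pvalue"])
  )
}

#' Kaplan-Meier analysis of a median-split module score
#'
#' Splits patients into low/high groups at the median of one module's score,
#' estimates Kaplan-Meier curves per group, and compares them with the
#' two-group log-rank test.
#'
#' @param scores wide score tibble from [module_scores()].
#' @param clinical clinical tibble.
#' @param module score column to split on (e.g. `"M6"`).
#' @param split `"median"` or a numeric cut value.
#' @return A `km_split` object: `fit` (survfit), `chisq`, `p_value`,
#'   `groups` tibble.
#' @export
km_logrank <- function(scores, clinical, module, split = "median") {
  clinical <- validate_clinical(clinical)
  if (!module %in% names(scores)) abort(paste0("no score column '", module, "'"))
  df <- inner_join(scores[, c("patient_id", module)], clinical,
                   by = "patient_id")
  x <- df[[module]]
  cut <- if (identical(split, "median")) median(x) else as.numeric(split)
  grp <- ifelse(x > cut, "high", "low")
  if (length(unique(grp)) < 2) {
    abort("degenerate split: all scores fall on one side of the cut")
  }
  df$group <- factor(grp, levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = df)
  p <- pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  structure(
    list(fit = fit, chisq = unname(lr$chisq), p_value = p,
         cut = cut, module = module,
         groups = df |> group_by(.data$group) |>
           summarise(n = n(), n_events = sum(.data$os_event), .groups = "drop")),
    class = "km_split"
  )
}

#' @export
print.km_split <- function(x, ...) {
  cat("<km_split> ", x$module, " median split: log-rank chisq = ",
      signif(x$chisq, 4), ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.km_split <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    group = sub("^group=", "", as.character(s$strata)),
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    estimate = s$surv, std_error = s$std.err,
    conf_low = s$lower, conf_high = s$upper
  )
}

#' @export
glance.km_split <- function(x, ...) {
  tibble(module = x$module, cut = x$cut, chisq = x$chisq, p_value = x$p_value)
}

#' Collapse RECIST responses for analysis
#'
#' Removes NE (not evaluated) patients and groups CR with PR into one
#' responder category, leaving groups CR/PR, SD, PD.
#'
#' @param clinical clinical tibble.
#' @return The clinical tibble with a `response_group` factor column.
#' @export
response_groups <- function(clinical) {
  clinical <- validate_clinical(clinical)
  out <- clinical[clinical$response != "NE", , drop = FALSE]
  out$response_group <- factor(
    ifelse(out$response %in% c("CR", "PR"), "CR/PR", out$response),
    levels = c("CR/PR", "SD", "PD")
  )
  out
}

#' Kruskal-Wallis test of a module score across response groups
#'
#' Nonparametric analysis of variance of one module's score over the
#' collapsed response groups (CR/PR, SD, PD; NE removed), with tie-corrected
#' H statistic and chi-square p-value.
#'
#' @param scores wide score tibble from [module_scores()].
#' @param clinical clinical tibble.
#' @param module score column to test.
#' @return A one-row tibble: group means, `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(scores, clinical, module) {
  cl <- response_groups(clinical)
  df <- inner_join(scores[, c("patient_id", module)], cl, by = "patient_id")
  df <- df[!is.na(df$response_group), ]
  groups <- droplevels(df$response_group)
  if (nlevels(groups) < 2) abort("need at least 2 response groups")
  if (length(unique(df[[module]])) == 1) {
    # fully tied scores carry no evidence; the tie-corrected H is 0/0
    kt <- list(statistic = 0, parameter = nlevels(groups) - 1, p.value = 1)
  } else {
    kt <- kruskal.test(df[[module]], groups)
  }
  means <- tapply(df[[module]], groups, mean)
  tibble(
    module = module,
    mean_crpr = unname(means["CR/PR"]),
    mean_sd = unname(means["SD"]),
    mean_pd = unname(means["PD"]),
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' Per-gene response tests within a module
#'
#' For each module gene, compares the scaled expression change between
#' responders (CR/PR) and non-responders (PD) with a two-sample Wilcoxon
#' rank-sum test (exact when the combined n is at most 20 and there are no
#' ties; continuity-corrected normal approximation otherwise), adjusting
#' p-values across the module's genes by Benjamini-Hochberg.
#'
#' @param scaled_diff a scaled `diff_matrix`.
#' @param module_genes character vector of the module's genes.
#' @param clinical clinical tibble.
#' @return A tibble: gene, group means, `statistic` (W), `p_value`, `fdr`,
#'   sorted by `fdr`.
#' @export
per_gene_response_test <- function(scaled_diff, module_genes, clinical) {
  stopifnot(inherits(scaled_diff, "diff_matrix"))
  cl <- response_groups(clinical)
  pats <- intersect(scaled_diff$patients, cl$patient_id)
  cl <- cl[match(pats, cl$patient_id), ]
  g1 <- pats[cl$response_group == "CR/PR"]
  g2 <- pats[cl$response_group == "PD"]
  if (length(g1) == 0 || length(g2) == 0) {
    abort("both CR/PR and PD groups must be nonempty")
  }
  miss <- setdiff(module_genes, scaled_diff$genes)
  if (length(miss)) abort("module genes missing from the difference matrix")
  res <- purrr::map_dfr(module_genes, function(g) {
    x <- scaled_diff$values[g, g1]
    y <- scaled_diff$values[g, g2]
    n <- length(x) + length(y)
    ties <- anyDuplicated(c(x, y)) > 0
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = (n <= 20 && !ties), correct = TRUE)
    )
    p <- wt$p.value
    if (is.na(p)) p <- 1 # fully tied data carries no evidence
    tibble(gene = g, mean_crpr = mean(x), mean_pd = mean(y),
           statistic = unname(wt$statistic), p_value = p)
  })
  res$fdr <- bh_adjust(res$p_value)
  arrange(res, .data$fdr, .data$p_value)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; validates that inputs are probabilities.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
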