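#' Plot curvature trajectories over the diffusion grid
#'
#' One line per edge, kappa against log10(tau), colored by the edge's
#' integrated curvature when a [critical_curvature()] summary is given.
#'
#' @param object a `curvature_field`.
#' @param critical optional result of [critical_curvature()] (adds the
#'   tau_crit line and kappa_bar coloring).
#' @param max_edges cap on plotted edges (sampled deterministically).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.curvature_field <- function(object, critical = NULL,
                                     max_edges = 500, ...) {
  df <- tidy(object)
  df$edge <- paste(df$gene_a, df$gene_b, sep = "--")
  edges <- unique(df$edge)
  if (length(edges) > max_edges) {
    keep <- edges[seq(1, length(edges), length.out = max_edges)]
    df <- df[df$edge %in% keep, ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$tau), y = .data$kappa,
                                        group = .data$edge))
  if (!is.null(critical)) {
    kb <- critical$edges |>
      mutate(edge = paste(.data$gene_a, .data$gene_b, sep = "--")) |>
      select("edge", "kappa_bar_crit")
    df <- left_join(df, kb, by = "edge")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$tau),
                                          y = .data$kappa,
                                          group = .data$edge,
                                          color = .data$kappa_bar_crit)) +
      ggplot2::geom_vline(xintercept = log10(critical$tau_crit),
                          linetype = "dashed") +
      ggplot2::scale_color_gradient2(low = "navy", mid = "grey85",
                                     high = "firebrick", midpoint = 0,
                                     name = "integrated\ncurvature")
  }
  p + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "log10(tau)", y = "edge curvature kappa") +
    ggplot2::theme_minimal()
}

#' Forest plot of module hazard ratios
#'
#' @param object a `module_cox` fit.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.module_cox <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = .data$module)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hr_low,
                                         xmax = .data$hr_high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a median-split module score
#'
#' @param object a `km_split` result.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.km_split <- function(object, ...) {
  df <- tidy(object)
  start <- df |> group_by(.data$group) |>
    summarise(time = 0, estimate = 1, .groups = "drop")
  df2 <- bind_rows(start, df[, c("group", "time", "estimate")]) |>
    arrange(.data$group, .data$time)
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$time, y = .data$estimate,
                                    color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "time", y = "survival probability",
      subtitle = paste0(object$module, " median split, log-rank p = ",
                        signif(object$p_value, 3))
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of one module's patient scores by response
#'
#' Patients ordered by score, bars colored by collapsed response group.
#'
#' @param scores wide score tibble from [module_scores()].
#' @param clinical clinical tibble.
#' @param module score column to plot.
#' @return A ggplot object.
#' @export
plot_score_waterfall <- function(scores, clinical, module) {
  cl <- response_groups(clinical)
  df <- inner_join(scores[, c("patient_id", module)], cl, by = "patient_id")
  df <- df[order(-df[[module]]), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data[[module]],
                                   fill = .data$response_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "patient (ranked)", y = paste(module, "score"),
                  fill = "response") +
    ggplot2::theme_minimal()
}
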