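#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline
#'   geom_vline geom_boxplot geom_jitter facet_wrap labs
#'   scale_colour_manual theme_minimal autoplot
NULL

volcano_colours <- c(cell_derived = "#2e7d32", ecm_enriched = "#6a1b9a",
                     uninformative = "grey65")

#' Volcano plot of the ECM-blank classification
#'
#' log2 fold change (biological over blank) against -log10 Welch p, one
#' panel per analytical mode; cell-derived features in green, ECM-enriched
#' in purple, uninformative in grey, with the fold-change and significance
#' cut-offs drawn.
#'
#' @param object A `blank_classification` tibble.
#' @param cfg A [pipeline_config()] supplying the cut-off lines.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot blank_classification
#' @export
autoplot.blank_classification <- function(object, cfg = pipeline_config(),
                                          ...) {
  df <- volcano_table(object)
  ggplot(df, aes(.data$log2_fc, .data$neg_log10_p,
                 colour = .data$label)) +
    geom_point(size = 0.8, alpha = 0.8) +
    geom_vline(xintercept = log2(c(cfg$fc_down, cfg$fc_up)),
               linetype = "dashed", colour = "grey40") +
    geom_hline(yintercept = -log10(cfg$alpha), linetype = "dashed",
               colour = "grey40") +
    scale_colour_manual(values = volcano_colours) +
    facet_wrap(~mode) +
    labs(x = "log2 fold change (organoid / ECM blank)",
         y = "-log10 Welch p", colour = NULL) +
    theme_minimal()
}

#' @rdname autoplot.blank_classification
#' @param classifications A `blank_classification` tibble.
#' @export
plot_volcano <- function(classifications, cfg = pipeline_config()) {
  autoplot.blank_classification(classifications, cfg)
}

#' QC drift diagnostic plot for selected features
#'
#' Peak area against injection order with QC injections highlighted and
#' the fitted correction trend overlaid, one panel per feature.
#'
#' @param table The table returned by [loess_correct()] (or the raw input
#'   table, in which case only the points are shown).
#' @param feature_ids Features to display.
#' @param raw_table Optional uncorrected table to plot points from.
#' @return A ggplot object.
#' @export
plot_drift <- function(table, feature_ids,
                       raw_table = table) {
  df <- as_tibble(raw_table) |>
    filter(.data$feature_id %in% feature_ids)
  p <- ggplot(df, aes(.data$injection_order, .data$abundance)) +
    geom_point(aes(colour = .data$role), size = 1.2) +
    facet_wrap(~feature_id, scales = "free_y") +
    labs(x = "injection order", y = "peak area", colour = NULL) +
    theme_minimal()
  dm <- drift_model(table)
  if (!is.null(dm)) {
    ref <- df |>
      filter(.data$role == "qc") |>
      group_by(.data$feature_id) |>
      summarise(ref = median(.data$abundance, na.rm = TRUE),
                .groups = "drop")
    trend <- dm$factors |>
      filter(.data$feature_id %in% feature_ids) |>
      left_join(distinct(df[c("sample_id", "injection_order")]),
                by = "sample_id") |>
      left_join(ref, by = "feature_id") |>
      mutate(trend = .data$factor * .data$ref)
    p <- p + geom_line(data = trend,
                       aes(.data$injection_order, .data$trend),
                       colour = "grey30", linewidth = 0.4)
  }
  p
}

#' Dose-response boxplots for selected features
#'
#' Control-scaled abundance per dose group, boxplots with overlaid
#' per-experiment points, one panel per feature — the standard way of
#' displaying dose-dependent metabolite regulation across experiments.
#'
#' @param tables A multi-experiment `ms_feature_table` or list of
#'   per-experiment tables.
#' @param feature_ids Features to display.
#' @param cfg A [pipeline_config()].
#' @param control_dose Control dose in uM.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(tables, feature_ids,
                               cfg = pipeline_config(), control_dose = 0) {
  if (inherits(tables, "ms_feature_table")) tables <- list(tables)
  df <- purrr::map_dfr(tables, function(tbl) {
    tbl <- exclude_low_outliers(tbl, cfg$outlier_fraction)
    as_tibble(control_scale(tbl, control_dose = control_dose))
  }) |>
    filter(.data$feature_id %in% feature_ids,
           .data$role == "biological")
  ggplot(df, aes(factor(.data$dose_uM), .data$abundance)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(aes(colour = .data$experiment_id), width = 0.15,
                size = 1, alpha = 0.8) +
    facet_wrap(~feature_id, scales = "free_y") +
    labs(x = "dose (µM)", y = "abundance relative to control mean",
         colour = NULL) +
    theme_minimal()
}
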