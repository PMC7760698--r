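#' Welch's t-test p-value on log2-transformed values
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, applied to log2-transformed peak areas. Values that are missing
#' or <= 0 are dropped before transformation (no pseudocount is added, so
#' fold changes computed on the raw scale stay undistorted).
#'
#' @param group_a,group_b Numeric vectors of raw peak areas.
#' @return Two-sided p-value, or `NA` when either group has fewer than two
#'   usable (positive) values. Zero variance in both groups gives p = 1 for
#'   equal means and p = 0 otherwise.
#' @export
welch_log2_p <- function(group_a, group_b) {
  a <- log2(group_a[!is.na(group_a) & group_a > 0])
  b <- log2(group_b[!is.na(group_b) & group_b > 0])
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Fold change of biological over blank abundance
#'
#' Ratio of a location statistic of the biological replicates to the same
#' statistic of the ECM-blank replicates, on the raw (untransformed) scale.
#' The mean is used for drug-response screening; the median for protocol
#' rating.
#'
#' @param bio,blank Numeric vectors of raw peak areas (`NA` = missing).
#' @param statistic `"mean"` or `"median"`.
#' @return The ratio, or `NA` when the blank statistic is zero or undefined.
#' @export
fold_change <- function(bio, blank, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  f <- if (statistic == "mean") mean else median
  denom <- f(blank, na.rm = TRUE)
  num <- f(bio, na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0 || !is.finite(num)) return(NA_real_)
  num / denom
}

#' Two-step ECM-blank classification of every feature
#'
#' Classifies each feature by comparing biological samples against ECM
#' blanks: `cell_derived` when the fold change exceeds `fc_up` with Welch
#' p < `alpha` (both strict), `ecm_enriched` when the fold change falls
#' below `fc_down` with p < `alpha`, `untestable` when the test or fold
#' change is undefined, and `uninformative` otherwise. p-values are used
#' unadjusted at this stage.
#'
#' @param table An `ms_feature_table` containing at least two biological
#'   and two blank samples.
#' @param cfg A [pipeline_config()].
#' @param statistic Fold-change statistic; defaults to the config preset's.
#' @return A `blank_classification` tibble with columns `feature_id`,
#'   `mode`, `fc`, `p_value`, `label`.
#' @export
classify_features <- function(table, cfg = pipeline_config(),
                              statistic = cfg$statistic) {
  smp <- ft_samples(table)
  if (!any(smp$role == "blank")) {
    abort("no blank samples in table", class = "ecmet_config_error")
  }
  out <- as_tibble(table) |>
    filter(.data$role %in% c("biological", "blank")) |>
    group_by(.data$feature_id, .data$mode) |>
    summarise(
      fc = fold_change(.data$abundance[.data$role == "biological"],
                       .data$abundance[.data$role == "blank"],
                       statistic = statistic),
      p_value = welch_log2_p(.data$abundance[.data$role == "biological"],
                             .data$abundance[.data$role == "blank"]),
      .groups = "drop"
    ) |>
    mutate(label = classification_label(.data$fc, .data$p_value, cfg))
  out <- out[match(unique(table$feature_id), out$feature_id), , drop = FALSE]
  structure(out, class = c("blank_classification", class(tibble())))
}

classification_label <- function(fc, p, cfg) {
  dplyr::case_when(
    is.na(p) | is.na(fc) ~ "untestable",
    fc > cfg$fc_up & p < cfg$alpha ~ "cell_derived",
    fc < cfg$fc_down & p < cfg$alpha ~ "ecm_enriched",
    TRUE ~ "uninformative"
  )
}

#' Subset a table to the cell-derived features
#'
#' Features classified `cell_derived` pass into further analysis; blank
#' background (uninformative, ECM-enriched, untestable) is dropped.
#'
#' @param table The `ms_feature_table` the classifications were computed on.
#' @param classifications A `blank_classification` tibble.
#' @return A feature table restricted to the retained features.
#' @export
retained_table <- function(table, classifications) {
  keep <- classifications$feature_id[classifications$label == "cell_derived"]
  ft_subset(table, features = keep)
}

#' @method glance blank_classification
#' @export
glance.blank_classification <- function(x, ...) {
  tibble(
    n_total = nrow(x),
    n_cell_derived = sum(x$label == "cell_derived"),
    n_ecm_enriched = sum(x$label == "ecm_enriched"),
    n_uninformative = sum(x$label == "uninformative"),
    n_untestable = sum(x$label == "untestable")
  )
}
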