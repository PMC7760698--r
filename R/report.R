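round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-mode classification summary with retained percentage
#'
#' Counts features per label within each analytical mode and reports the
#' percentage of features retained as cell-derived, to one decimal
#' (half-up). Untestable features are counted in the denominator together
#' with the uninformative ones (reported separately) unless
#' `drop_untestable = TRUE`.
#'
#' @param classifications A `blank_classification` tibble (from
#'   [classify_features()]), or any data frame with `mode` and `label`
#'   columns.
#' @param drop_untestable Exclude untestable features from the denominator.
#' @return Tibble with one row per mode: counts per label, `n_total`,
#'   `retained_pct`.
#' @export
classification_summary <- function(classifications,
                                   drop_untestable = FALSE) {
  stopifnot(nrow(classifications) > 0)
  as_tibble(classifications) |>
    group_by(.data$mode) |>
    summarise(
      n_cell_derived = sum(.data$label == "cell_derived"),
      n_ecm_enriched = sum(.data$label == "ecm_enriched"),
      n_uninformative = sum(.data$label == "uninformative"),
      n_untestable = sum(.data$label == "untestable"),
      .groups = "drop"
    ) |>
    mutate(
      n_total = .data$n_cell_derived + .data$n_ecm_enriched +
        .data$n_uninformative +
        if (drop_untestable) 0L else .data$n_untestable,
      retained_pct = round_half_up(100 * .data$n_cell_derived /
                                     .data$n_total, 1)
    )
}

#' Total count of blank-enriched features across modes
#'
#' @param summaries Output of [classification_summary()].
#' @return Sum of `n_ecm_enriched` over modes.
#' @export
blank_enriched_total <- function(summaries) {
  sum(summaries$n_ecm_enriched)
}

#' Protocol-comparison summary
#'
#' Rates extraction protocols by the number of metabolites detected
#' significantly above the ECM-blank background (median fold change > 1,
#' Welch p < 0.05 — the protocol-rating preset) and by the median
#' coefficient of variation (%) of exactly those metabolites across the
#' biological replicates.
#'
#' @param tables Named list of `ms_feature_table`s, one per
#'   protocol/mode dataset; names are used as protocol labels when the
#'   tables carry no `protocol` metadata.
#' @param cfg A [pipeline_config()]; defaults to the protocol-rating
#'   preset.
#' @return Tibble with `protocol`, `mode`, `n_significant`,
#'   `median_cv_pct`.
#' @export
protocol_summary <- function(tables,
                             cfg = pipeline_config("protocol_rating")) {
  if (inherits(tables, "ms_feature_table")) tables <- list(tables)
  labels <- names(tables) %||% as.character(seq_along(tables))
  purrr::map_dfr(seq_along(tables), function(i) {
    tbl <- tables[[i]]
    smp <- ft_samples(tbl)
    prot <- unique(smp$protocol[!is.na(smp$protocol)])
    prot <- if (length(prot) == 1L) prot else labels[i]
    cls <- classify_features(tbl, cfg)
    sig <- cls$feature_id[cls$label == "cell_derived"]
    med_cv <- if (length(sig) == 0L) NA_real_ else {
      as_tibble(tbl) |>
        filter(.data$feature_id %in% sig, .data$role == "biological") |>
        group_by(.data$feature_id) |>
        summarise(cv = cv(.data$abundance), .groups = "drop") |>
        dplyr::pull(.data$cv) |>
        median(na.rm = TRUE)
    }
    tibble(protocol = prot, mode = unique(cls$mode)[1],
           n_significant = length(sig),
           median_cv_pct = 100 * med_cv)
  })
}

#' Pairwise overlap of metabolite lists
#'
#' Jaccard overlap, `100 * |A intersect B| / |A union B|`, between every
#' pair of lists (switchable to the overlap coefficient,
#' `|A intersect B| / min(|A|, |B|)`), plus the size of the union of all
#' lists.
#'
#' @param lists Named list of identifier vectors (e.g. annotation names
#'   per protocol/mode).
#' @param method `"jaccard"` or `"min_size"`.
#' @return A list with `pairs` (tibble `set_a`, `set_b`, `overlap_pct`)
#'   and `union_count`.
#' @export
overlap_summary <- function(lists, method = c("jaccard", "min_size")) {
  method <- match.arg(method)
  stopifnot(length(lists) >= 1)
  nm <- names(lists) %||% as.character(seq_along(lists))
  combos <- utils::combn(seq_along(lists), 2, simplify = FALSE)
  pairs <- purrr::map_dfr(combos, function(ij) {
    a <- unique(lists[[ij[1]]])
    b <- unique(lists[[ij[2]]])
    inter <- length(intersect(a, b))
    denom <- if (method == "jaccard") length(union(a, b)) else
      min(length(a), length(b))
    tibble(set_a = nm[ij[1]], set_b = nm[ij[2]],
           overlap_pct = round_half_up(
             if (denom == 0) 0 else 100 * inter / denom, 1))
  })
  if (length(lists) == 1L) {
    pairs <- tibble(set_a = character(), set_b = character(),
                    overlap_pct = numeric())
  }
  list(pairs = pairs, union_count = length(unique(unlist(lists))))
}

#' Long-format volcano table
#'
#' One row per testable feature with `log2_fc`, `neg_log10_p` and its
#' classification label, ready for plotting. Untestable features are
#' omitted; their count is in the `"n_untestable"` attribute.
#'
#' @param classifications A `blank_classification` tibble.
#' @return Tibble `feature_id`, `mode`, `log2_fc`, `neg_log10_p`, `label`.
#' @export
volcano_table <- function(classifications) {
  df <- as_tibble(classifications)
  testable <- filter(df, .data$label != "untestable")
  out <- testable |>
    mutate(log2_fc = log2(.data$fc),
           neg_log10_p = -log10(.data$p_value)) |>
    select("feature_id", "mode", "log2_fc", "neg_log10_p", "label")
  attr(out, "n_untestable") <- sum(df$label == "untestable")
  out
}

#' Feature counts along the preprocessing chain
#'
#' Runs the stated stage order — LOESS drift correction, QC-CV filter,
#' ECM-blank filter, total-sum normalization — and records the feature
#' count after each stage.
#'
#' @param table A raw `ms_feature_table` for one experiment, with QC and
#'   blank samples.
#' @param cfg A [pipeline_config()].
#' @return A list with `table` (the fully preprocessed table),
#'   `classification`, `drift` (the [drift_model()]) and `stage_counts`
#'   (tibble `stage`, `n_features`).
#' @export
run_preprocessing <- function(table, cfg = pipeline_config()) {
  counts <- list(c(stage = "input", n = length(unique(table$feature_id))))
  corrected <- loess_correct(table, span = cfg$loess_span,
                             degree = cfg$loess_degree,
                             min_qc = cfg$min_qc)
  dm <- drift_model(corrected)
  counts <- c(counts, list(c(stage = "loess_corrected",
                             n = length(unique(corrected$feature_id)))))
  filtered <- qc_cv_filter(corrected, cfg$qc_cv_max)
  counts <- c(counts, list(c(stage = "qc_cv_filtered",
                             n = length(unique(filtered$feature_id)))))
  cls <- classify_features(filtered, cfg)
  retained <- retained_table(filtered, cls)
  counts <- c(counts, list(c(stage = "blank_filtered",
                             n = length(unique(retained$feature_id)))))
  normalized <- sum_normalize(retained)
  counts <- c(counts, list(c(stage = "sum_normalized",
                             n = length(unique(normalized$feature_id)))))
  stage_counts <- tibble(
    stage = vapply(counts, `[[`, "", "stage"),
    n_features = as.integer(vapply(counts, `[[`, "", "n"))
  )
  list(table = normalized, classification = cls, drift = dm,
       stage_counts = stage_counts)
}
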