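#' Exclude low-signal outlier values before dose-response testing
#'
#' Within each treatment group (same `experiment_id` and `dose_uM`, among
#' biological samples) of each feature, a measured value below
#' `outlier_fraction` (default 1%) of the group median is marked missing —
#' at most one value per group, the smallest when several qualify. Such
#' near-zero values reflect integration dropouts rather than biology. The
#' group median is computed over all values of the group, including the
#' candidate. Groups of size one are never touched (the median is the value
#' itself).
#'
#' @param table An `ms_feature_table`.
#' @param outlier_fraction Fraction of the group median below which a value
#'   is excluded.
#' @return The table with excluded values set to `NA`.
#' @export
exclude_low_outliers <- function(table, outlier_fraction = 0.01) {
  df <- as_tibble(table)
  df <- df |>
    group_by(.data$feature_id, .data$experiment_id, .data$dose_uM) |>
    mutate(abundance = exclude_one_low(
      .data$abundance,
      is_group = .data$role == "biological" & !is.na(.data$dose_uM),
      frac = outlier_fraction
    )) |>
    ungroup()
  as_feature_table(df)
}

exclude_one_low <- function(x, is_group, frac) {
  vals <- x[is_group]
  if (sum(!is.na(vals)) < 2L) return(x)
  med <- median(vals, na.rm = TRUE)
  low <- which(is_group & !is.na(x) & x < frac * med)
  if (length(low) == 0L) return(x)
  x[low[which.min(x[low])]] <- NA_real_
  x
}

#' Spearman rank correlation of a feature with dose
#'
#' Rank correlation with average ranks for ties (doses come in tied groups
#' of replicates) and a two-sided p-value from the t approximation. The
#' statistic is rank-based, so using raw doses in uM or their ordinal ranks
#' gives identical results.
#'
#' @param feature_values Numeric vector of (preprocessed) abundances.
#' @param doses Numeric vector of doses, same length.
#' @return A list with `rs` and `p_raw`; both `NA` when fewer than three
#'   complete pairs remain, fewer than two distinct doses are present, or
#'   the values are all identical.
#' @export
spearman_dose <- function(feature_values, doses) {
  ok <- !is.na(feature_values) & !is.na(doses)
  v <- feature_values[ok]
  d <- doses[ok]
  if (length(v) < 3L || length(unique(d)) < 2L ||
      length(unique(v)) < 2L) {
    return(list(rs = NA_real_, p_raw = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(v, d, method = "spearman", exact = FALSE)
  )
  list(rs = unname(ct$estimate), p_raw = ct$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1. The adjustment family is all tested features within one
#' analytical mode and one analysis run (per-experiment or joint); `NA`
#' entries are passed through unadjusted.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

dose_response_one <- function(df, cfg, analysis_id) {
  res <- df |>
    filter(.data$role == "biological") |>
    group_by(.data$feature_id, .data$mode, .data$neutral_mass, .data$rt,
             .data$annotation) |>
    summarise(
      sp = list(spearman_dose(.data$abundance, .data$dose_uM)),
      .groups = "drop"
    ) |>
    mutate(
      rs = purrr::map_dbl(.data$sp, "rs"),
      p_raw = purrr::map_dbl(.data$sp, "p_raw")
    ) |>
    select(-"sp")
  fam <- if (isTRUE(cfg$bh_per_mode)) "mode" else character(0)
  res <- res |>
    group_by(across(all_of(fam))) |>
    mutate(q_bh = bh_adjust(.data$p_raw)) |>
    ungroup() |>
    mutate(
      experiment_id = analysis_id,
      direction = ifelse(is.na(.data$rs), NA_character_,
                         ifelse(.data$rs > 0, "up", "down")),
      significant = !is.na(.data$rs) & !is.na(.data$q_bh) &
        abs(.data$rs) > cfg$rs_min & .data$q_bh < cfg$q_max
    )
  res[c("feature_id", "mode", "neutral_mass", "rt", "annotation",
        "experiment_id", "rs", "p_raw", "q_bh", "direction", "significant")]
}

#' Per-experiment dose-response screening
#'
#' For each experiment independently: low-outlier exclusion, Spearman
#' correlation of every feature with dose, Benjamini-Hochberg adjustment
#' within each analytical mode, and significance flagging at
#' `|rs| > rs_min` and `q < q_max`. Input tables are expected to be
#' preprocessed (drift-corrected, QC-CV and blank filtered,
#' sum-normalized).
#'
#' @param tables A single `ms_feature_table` (possibly spanning several
#'   experiments) or a list of per-experiment tables.
#' @param cfg A [pipeline_config()].
#' @return A `dose_response_result` tibble, one row per feature per
#'   experiment.
#' @export
per_experiment_hits <- function(tables, cfg = pipeline_config()) {
  if (inherits(tables, "ms_feature_table")) tables <- list(tables)
  rows <- purrr::map_dfr(tables, function(tbl) {
    tbl <- exclude_low_outliers(tbl, cfg$outlier_fraction)
    df <- as_tibble(tbl)
    purrr::map_dfr(split(df, df$experiment_id), function(d) {
      doses <- unique(d$dose_uM[d$role == "biological"])
      if (length(doses[!is.na(doses)]) < 2L) {
        warn(paste0("experiment ", d$experiment_id[1],
                    " has fewer than two dose levels; skipped"))
        return(NULL)
      }
      dose_response_one(d, cfg, analysis_id = d$experiment_id[1])
    })
  })
  structure(rows, class = c("dose_response_result", class(tibble())))
}

#' Joint dose-response analysis across experiments
#'
#' Each experiment is scaled to its own control-group mean (so experiments
#' share a common unit), low outliers are excluded per treatment group, and
#' the control-scaled values of all experiments are pooled before a single
#' Spearman + Benjamini-Hochberg pass per analytical mode. Features are
#' aligned across experiments by `feature_id`; only features present in
#' every experiment enter the pooled test.
#'
#' @param tables A single multi-experiment `ms_feature_table` or a list of
#'   per-experiment tables sharing a feature namespace.
#' @param cfg A [pipeline_config()].
#' @param control_dose Dose identifying the control group.
#' @return A `dose_response_result` tibble with `experiment_id = "joint"`.
#' @export
joint_analysis <- function(tables, cfg = pipeline_config(),
                           control_dose = 0) {
  if (inherits(tables, "ms_feature_table")) tables <- list(tables)
  parts <- purrr::map(tables, function(tbl) {
    tbl <- exclude_low_outliers(tbl, cfg$outlier_fraction)
    tbl <- control_scale(tbl, control_dose = control_dose)
    as_tibble(tbl)
  })
  pooled <- dplyr::bind_rows(parts)
  common <- pooled |>
    distinct(.data$feature_id, .data$experiment_id) |>
    dplyr::count(.data$feature_id) |>
    filter(.data$n == length(unique(pooled$experiment_id)))
  pooled <- pooled[pooled$feature_id %in% common$feature_id, , drop = FALSE]
  res <- dose_response_one(pooled, cfg, analysis_id = "joint")
  structure(res, class = c("dose_response_result", class(tibble())))
}

#' Consolidate per-experiment hits by cross-experiment feature matching
#'
#' Significant features from different experiments are matched by mass
#' (within `mass_tol_ppm`) and retention time (within `rt_tol_match`);
#' groups significant in at least `min_experiments` experiments with a
#' consistent regulation direction are reported, with the representative
#' mass and retention time as the mean over the matched features.
#' Direction-conflicting groups are dropped and recorded in the
#' `"direction_conflicts"` attribute. Many-to-many ambiguities resolve to
#' the nearest-mass candidate.
#'
#' @param per_experiment A `dose_response_result` from
#'   [per_experiment_hits()].
#' @param cfg A [pipeline_config()].
#' @return A `consolidated_hits` tibble with columns `mode`, `mean_mass`,
#'   `rt`, `direction`, `annotation`, `n_experiments_significant`,
#'   `feature_ids`.
#' @export
consolidate_hits <- function(per_experiment, cfg = pipeline_config()) {
  sig <- as_tibble(per_experiment) |>
    filter(.data$significant) |>
    arrange(.data$mode, .data$neutral_mass)
  if (nrow(sig) == 0L) {
    out <- tibble(mode = character(), mean_mass = numeric(),
                  rt = numeric(), direction = character(),
                  annotation = character(),
                  n_experiments_significant = integer(),
                  feature_ids = list())
    return(structure(out, class = c("consolidated_hits", class(tibble()))))
  }
  sig$group <- match_by_tolerance(sig$mode, sig$neutral_mass, sig$rt,
                                  cfg$mass_tol_ppm, cfg$rt_tol_match)
  grouped <- sig |>
    group_by(.data$group) |>
    summarise(
      mode = first(.data$mode),
      mean_mass = mean(.data$neutral_mass),
      rt = mean(.data$rt),
      n_experiments_significant =
        length(unique(.data$experiment_id)),
      n_directions = length(unique(.data$direction)),
      direction = first(.data$direction),
      annotation = if (all(is.na(.data$annotation))) NA_character_ else
        first(.data$annotation[!is.na(.data$annotation)]),
      feature_ids = list(unique(.data$feature_id)),
      .groups = "drop"
    )
  conflicts <- grouped |>
    filter(.data$n_directions > 1L,
           .data$n_experiments_significant >= cfg$min_experiments)
  keep <- grouped |>
    filter(.data$n_experiments_significant >= cfg$min_experiments)
  if (isTRUE(cfg$require_direction_consistency)) {
    keep <- filter(keep, .data$n_directions == 1L)
  }
  out <- keep |>
    arrange(.data$mode, .data$mean_mass) |>
    select("mode", "mean_mass", "rt", "direction", "annotation",
           "n_experiments_significant", "feature_ids")
  out <- structure(out, class = c("consolidated_hits", class(tibble())))
  attr(out, "direction_conflicts") <-
    conflicts[c("mode", "mean_mass", "rt", "n_experiments_significant")]
  out
}

# Greedy single-pass grouping of (mode, mass, rt) triples sorted by mass:
# a row joins the group whose running mean mass is within the ppm tolerance
# and mean rt within the rt tolerance (nearest mass wins on ties).
match_by_tolerance <- function(mode, mass, rt, tol_ppm, tol_rt) {
  n <- length(mass)
  group <- integer(n)
  ord <- order(mode, mass)
  means_mass <- numeric(0)
  means_rt <- numeric(0)
  modes <- character(0)
  sizes <- integer(0)
  next_id <- 0L
  for (i in ord) {
    cand <- which(modes == mode[i] &
                    abs(mass[i] - means_mass) / means_mass * 1e6 <= tol_ppm &
                    abs(rt[i] - means_rt) <= tol_rt)
    if (length(cand) == 0L) {
      next_id <- next_id + 1L
      group[i] <- next_id
      means_mass[next_id] <- mass[i]
      means_rt[next_id] <- rt[i]
      modes[next_id] <- mode[i]
      sizes[next_id] <- 1L
    } else {
      g <- cand[which.min(abs(mass[i] - means_mass[cand]))]
      group[i] <- g
      sizes[g] <- sizes[g] + 1L
      means_mass[g] <- means_mass[g] + (mass[i] - means_mass[g]) / sizes[g]
      means_rt[g] <- means_rt[g] + (rt[i] - means_rt[g]) / sizes[g]
    }
  }
  group
}

#' @method tidy dose_response_result
#' @export
tidy.dose_response_result <- function(x, ...) as_tibble(x)

#' @method glance dose_response_result
#' @export
glance.dose_response_result <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$experiment_id, .data$mode) |>
    summarise(n_tested = sum(!is.na(.data$rs)),
              n_significant = sum(.data$significant, na.rm = TRUE),
              .groups = "drop")
}
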