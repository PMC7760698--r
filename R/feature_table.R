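#' @importFrom rlang .data abort warn enquo quo_is_null eval_tidy %||%
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   left_join distinct bind_rows n across all_of any_of first row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd setNames
NULL

#' Analytical modes recognised by the pipeline
#'
#' Each chromatography x ionisation-polarity combination is processed as an
#' independent dataset throughout the pipeline.
#'
#' @format Character vector of the four mode tokens.
#' @export
MS_MODES <- c("HILIC+", "HILIC-", "RPLC+", "RPLC-")

#' Sample roles recognised by the pipeline
#' @format Character vector.
#' @export
MS_ROLES <- c("biological", "blank", "qc")

ft_columns <- c(
  "feature_id", "neutral_mass", "rt", "mode", "annotation", "msi_level",
  "sample_id", "role", "dose_uM", "experiment_id", "injection_order",
  "protocol", "abundance"
)

#' Build a feature table from components
#'
#' An `ms_feature_table` is a tidy (long) tibble with one row per
#' feature x sample pair: feature metadata (`feature_id`, `neutral_mass` in
#' Da, `rt` in minutes, `mode`, optional `annotation` and `msi_level`),
#' sample metadata (`sample_id`, `role`, `dose_uM`, `experiment_id`,
#' `injection_order`, optional `protocol`) and the peak-area `abundance`.
#' Missing measurements are `NA` (never imputed as zero: zero vs absent is
#' meaningful for the coefficient-of-variation and low-outlier rules).
#'
#' @param features Tibble with columns `feature_id`, `neutral_mass`, `rt`,
#'   `mode` and optionally `annotation`, `msi_level`.
#' @param samples Tibble with columns `sample_id`, `role`, `dose_uM`,
#'   `experiment_id`, `injection_order` and optionally `protocol`.
#' @param abundance Numeric matrix, features x samples, non-negative peak
#'   areas; `NA` marks a missing value.
#' @return A validated `ms_feature_table` tibble.
#' @export
feature_table <- function(features, samples, abundance) {
  features <- as_tibble(features)
  samples <- as_tibble(samples)
  abundance <- as.matrix(abundance)
  if (nrow(abundance) != nrow(features) || ncol(abundance) != nrow(samples)) {
    abort(sprintf(
      "abundance matrix is %d x %d but there are %d features and %d samples",
      nrow(abundance), ncol(abundance), nrow(features), nrow(samples)
    ), class = "ecmet_validation_error")
  }
  if (!"annotation" %in% names(features)) features$annotation <- NA_character_
  if (!"msi_level" %in% names(features)) features$msi_level <- NA_integer_
  if (!"protocol" %in% names(samples)) samples$protocol <- NA_character_
  if (!"dose_uM" %in% names(samples)) samples$dose_uM <- NA_real_

  long <- tidyr::expand_grid(
    .f = seq_len(nrow(features)),
    .s = seq_len(nrow(samples))
  )
  out <- dplyr::bind_cols(
    features[long$.f, c("feature_id", "neutral_mass", "rt", "mode",
                        "annotation", "msi_level")],
    samples[long$.s, c("sample_id", "role", "dose_uM", "experiment_id",
                       "injection_order", "protocol")]
  )
  out$abundance <- as.vector(t(abundance))
  as_feature_table(out)
}

#' Validate and class a long tibble as a feature table
#'
#' @param x Data frame in the long layout described in [feature_table()].
#' @return The validated `ms_feature_table`.
#' @export
as_feature_table <- function(x) {
  x <- as_tibble(x)
  if (!"annotation" %in% names(x)) x$annotation <- NA_character_
  if (!"msi_level" %in% names(x)) x$msi_level <- NA_integer_
  if (!"protocol" %in% names(x)) x$protocol <- NA_character_
  if (!"dose_uM" %in% names(x)) x$dose_uM <- NA_real_
  missing_cols <- setdiff(ft_columns, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "ecmet_format_error")
  }
  x <- x[c(ft_columns, setdiff(names(x), ft_columns))]
  validate_feature_table(x)
  class(x) <- c("ms_feature_table", class(tibble()))
  x
}

validate_feature_table <- function(x) {
  if (any(!is.na(x$abundance) & x$abundance < 0)) {
    abort("negative abundance values are not allowed",
          class = "ecmet_validation_error")
  }
  bad_mode <- setdiff(unique(x$mode), MS_MODES)
  if (length(bad_mode)) {
    abort(paste0("unknown analytical mode: ", paste(bad_mode, collapse = ", ")),
          class = "ecmet_validation_error")
  }
  bad_role <- setdiff(unique(x$role), MS_ROLES)
  if (length(bad_role)) {
    abort(paste0("unknown sample role: ", paste(bad_role, collapse = ", ")),
          class = "ecmet_validation_error")
  }
  if (any(!is.na(x$neutral_mass) & x$neutral_mass <= 0)) {
    abort("neutral_mass must be > 0", class = "ecmet_validation_error")
  }
  if (any(!is.na(x$rt) & x$rt < 0)) {
    abort("rt must be >= 0", class = "ecmet_validation_error")
  }
  smp <- distinct(as_tibble(x)[c("sample_id", "role", "dose_uM",
                                 "experiment_id", "injection_order")])
  if (anyDuplicated(smp$sample_id)) {
    abort("inconsistent metadata for at least one sample_id",
          class = "ecmet_validation_error")
  }
  dup <- smp |>
    dplyr::count(.data$experiment_id, .data$injection_order) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort("injection_order must be unique within an acquisition batch",
          class = "ecmet_validation_error")
  }
  if (any(smp$role != "biological" & !is.na(smp$dose_uM))) {
    abort("blank and qc samples must not carry a dose",
          class = "ecmet_validation_error")
  }
  # every feature x sample pair exactly once
  if (nrow(x) != length(unique(x$feature_id)) * nrow(smp)) {
    abort("table is not a complete feature x sample grid",
          class = "ecmet_validation_error")
  }
  invisible(x)
}

#' Feature metadata of a table
#' @param table An `ms_feature_table`.
#' @return Tibble with one row per feature, in table order.
#' @export
ft_features <- function(table) {
  distinct(as_tibble(table)[c("feature_id", "neutral_mass", "rt", "mode",
                              "annotation", "msi_level")])
}

#' Sample metadata of a table
#' @param table An `ms_feature_table`.
#' @return Tibble with one row per sample, in table order.
#' @export
ft_samples <- function(table) {
  distinct(as_tibble(table)[c("sample_id", "role", "dose_uM", "experiment_id",
                              "injection_order", "protocol")])
}

#' Abundance matrix of a table
#' @param table An `ms_feature_table`.
#' @return Numeric matrix, features x samples, with dimnames.
#' @export
ft_matrix <- function(table) {
  fid <- unique(table$feature_id)
  sid <- ft_samples(table)$sample_id
  m <- matrix(NA_real_, length(fid), length(sid),
              dimnames = list(fid, sid))
  m[cbind(match(table$feature_id, fid), match(table$sample_id, sid))] <-
    table$abundance
  m
}

#' Subset a feature table by samples and/or features
#'
#' @param table An `ms_feature_table`.
#' @param samples Optional logical expression on sample metadata columns
#'   (e.g. `role == "blank"`), evaluated per row.
#' @param features Optional character vector of `feature_id`s to keep; every
#'   id must exist in the table. An empty vector yields a zero-feature table.
#' @return A new `ms_feature_table`; invariants preserved.
#' @export
ft_subset <- function(table, samples = NULL, features = NULL) {
  out <- as_tibble(table)
  sq <- enquo(samples)
  if (!quo_is_null(sq)) {
    keep <- eval_tidy(sq, data = out)
    out <- out[keep, , drop = FALSE]
  }
  if (!is.null(features)) {
    unknown <- setdiff(features, unique(table$feature_id))
    if (length(unknown)) {
      abort(paste0("unknown feature_id: ", paste(unknown, collapse = ", ")),
            class = "ecmet_key_error")
    }
    out <- out[out$feature_id %in% features, , drop = FALSE]
  }
  class(out) <- c("ms_feature_table", class(tibble()))
  out
}

#' Read a feature table from matrix and sample-sheet CSV files
#'
#' The matrix CSV carries a feature-metadata block (`feature_id`,
#' `neutral_mass`, `rt`, `mode`, optionally `annotation`, `msi_level`)
#' followed by one column of peak areas per sample; empty cells are missing
#' values. The sample sheet has columns `sample_id`, `role`, `dose_uM`,
#' `experiment_id`, `injection_order` and optionally `protocol`. Sample
#' columns and sheet rows are matched by `sample_id`; the matrix column
#' order is preserved.
#'
#' @param matrix_path,sample_sheet_path Paths to the two CSV files.
#' @return A validated `ms_feature_table`.
#' @export
read_feature_table <- function(matrix_path, sample_sheet_path) {
  mat <- readr::read_csv(matrix_path, col_types = readr::cols(
    feature_id = readr::col_character(),
    neutral_mass = readr::col_double(),
    rt = readr::col_double(),
    mode = readr::col_character(),
    annotation = readr::col_character(),
    msi_level = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  sheet <- readr::read_csv(sample_sheet_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    role = readr::col_character(),
    dose_uM = readr::col_double(),
    experiment_id = readr::col_character(),
    injection_order = readr::col_integer(),
    protocol = readr::col_character()
  ), progress = FALSE)
  meta_cols <- intersect(
    c("feature_id", "neutral_mass", "rt", "mode", "annotation", "msi_level"),
    names(mat)
  )
  if (!all(c("feature_id", "neutral_mass", "rt", "mode") %in% meta_cols)) {
    abort("matrix CSV must start with feature_id, neutral_mass, rt, mode",
          class = "ecmet_format_error")
  }
  sample_cols <- setdiff(names(mat), meta_cols)
  if (anyDuplicated(sheet$sample_id)) {
    abort("duplicated sample_id in sample sheet",
          class = "ecmet_format_error")
  }
  not_in_sheet <- setdiff(sample_cols, sheet$sample_id)
  if (length(not_in_sheet)) {
    abort(paste0("matrix columns absent from sample sheet: ",
                 paste(not_in_sheet, collapse = ", ")),
          class = "ecmet_format_error")
  }
  not_in_matrix <- setdiff(sheet$sample_id, sample_cols)
  if (length(not_in_matrix)) {
    abort(paste0("sample-sheet rows absent from matrix: ",
                 paste(not_in_matrix, collapse = ", ")),
          class = "ecmet_format_error")
  }
  sheet <- sheet[match(sample_cols, sheet$sample_id), , drop = FALSE]
  feature_table(mat[meta_cols], sheet,
                as.matrix(mat[sample_cols]))
}

#' Write a feature table to matrix and sample-sheet CSV files
#'
#' Files written here are read back losslessly by [read_feature_table()]:
#' metadata bit-identical, abundances at full double precision, missing
#' values as empty cells.
#'
#' @param table An `ms_feature_table`.
#' @param matrix_path,sample_sheet_path Output CSV paths.
#' @return Invisibly, `table`.
#' @export
write_feature_table <- function(table, matrix_path, sample_sheet_path) {
  feats <- ft_features(table)
  smps <- ft_samples(table)
  m <- ft_matrix(table)
  wide <- dplyr::bind_cols(feats, as_tibble(m, .name_repair = "minimal"))
  readr::write_csv(wide, matrix_path, na = "", progress = FALSE)
  readr::write_csv(smps, sample_sheet_path, na = "", progress = FALSE)
  invisible(table)
}

#' Pipeline configuration
#'
#' Collects every threshold the pipeline uses. Defaults implement the
#' proof-of-concept rules: two-step blank filter at fold change > 1.2 /
#' < 0.8 with uncorrected Welch p < 0.05, QC CV filter at >= 20%, Spearman
#' screening at |rs| > 0.7 with Benjamini-Hochberg q < 0.05, annotation
#' tolerances of +/-15 ppm and +/-0.2 min (0.7 min for targeted extraction),
#' composite-score weights mass 100 / isotope abundance 60 / isotope
#' spacing 50 / retention time 20 with acceptance above 70%, low-outlier
#' exclusion below 1% of the treatment-group median, and consolidation over
#' at least 2 experiments.
#'
#' @param preset `"proof_of_concept"` (mean-based fold change, fc_up 1.2) or
#'   `"protocol_rating"` (median-based fold change, threshold > 1), the two
#'   filtering variants used for drug-response screening and for comparing
#'   extraction protocols respectively.
#' @param ... Named overrides of any field listed above, e.g. `alpha`,
#'   `fc_up`, `qc_cv_max`, `rs_min`, `q_max`, `mass_tol_ppm`, `loess_span`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("proof_of_concept", "protocol_rating"),
                            ...) {
  preset <- match.arg(preset)
  cfg <- list(
    fc_up = 1.2, fc_down = 0.8, alpha = 0.05,
    statistic = "mean",
    qc_cv_max = 0.20,
    rs_min = 0.7, q_max = 0.05,
    mass_tol_ppm = 15, rt_tol_match = 0.2, rt_tol_targeted = 0.7,
    score_weights = c(mass = 100, isotope_abundance = 60,
                      isotope_spacing = 50, rt = 20),
    score_min = 70,
    iso_abundance_tol = 0.25, iso_spacing_tol_mda = 5,
    outlier_fraction = 0.01, min_experiments = 2,
    require_direction_consistency = TRUE,
    loess_span = 0.75, loess_degree = 2, min_qc = 5,
    bh_per_mode = TRUE
  )
  if (preset == "protocol_rating") {
    cfg$statistic <- "median"
    cfg$fc_up <- 1
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config field: ", paste(unknown, collapse = ", ")),
          class = "ecmet_config_error")
  }
  cfg[names(over)] <- over
  stopifnot(cfg$fc_down > 0, cfg$fc_down < 1, cfg$fc_up >= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$rs_min > 0, cfg$rs_min <= 1,
            cfg$mass_tol_ppm > 0, cfg$rt_tol_match > 0)
  structure(cfg, class = "pipeline_config", preset = preset)
}

#' Read / write a pipeline configuration as flat key-value text
#'
#' @param path File path; plain `key: value` YAML mirroring the
#'   [pipeline_config()] fields.
#' @param cfg A `pipeline_config`.
#' @return `read_pipeline_config()` a `pipeline_config`;
#'   `write_pipeline_config()` invisibly `cfg`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  preset <- vals$preset %||% "proof_of_concept"
  vals$preset <- NULL
  if (!is.null(vals$score_weights)) {
    vals$score_weights <- unlist(vals$score_weights)
  }
  do.call(pipeline_config, c(list(preset = preset), vals))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$score_weights <- as.list(out$score_weights)
  out <- c(list(preset = attr(cfg, "preset")), out)
  yaml::write_yaml(out, path)
  invisible(cfg)
}
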