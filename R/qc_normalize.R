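#' Coefficient of variation
#'
#' Sample (n-1) standard deviation divided by the mean, on the raw scale,
#' over present values — the convention used both for replicate
#' repeatability and for the QC-based feature filter.
#'
#' @param x Numeric vector (`NA` = missing).
#' @return CV as a fraction, or `NA` with fewer than two present values.
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sd(x) / m
}

#' QC-anchored LOESS correction of injection-order signal drift
#'
#' For each feature (within each acquisition batch, i.e. `experiment_id`) a
#' LOESS curve is fitted to the pooled-QC peak areas against injection
#' order. Every sample value is divided by the fitted QC trend at its
#' injection position, relative to the per-feature QC median, so the QC
#' level is preserved while the drift is removed. Between QC positions the
#' trend is interpolated linearly; beyond the first/last QC it is held
#' constant. Features with fewer than `min_qc` usable QC values, or whose
#' fitted trend is not strictly positive, are left uncorrected and flagged.
#'
#' @param table An `ms_feature_table` whose samples all carry an
#'   `injection_order`.
#' @param span LOESS span (fraction of QC points per local fit).
#' @param degree Local polynomial degree.
#' @param min_qc Minimum number of usable QC values per feature.
#' @return The corrected `ms_feature_table`, with the fitted
#'   [drift_model()] attached as attribute `"drift_model"`.
#' @export
loess_correct <- function(table, span = 0.75, degree = 2, min_qc = 5) {
  if (any(is.na(table$injection_order))) {
    abort("all samples must carry an injection_order",
          class = "ecmet_config_error")
  }
  df <- as_tibble(table)
  fits <- df |>
    group_by(.data$feature_id, .data$experiment_id) |>
    dplyr::group_map(function(d, key) {
      qc <- d[d$role == "qc" & !is.na(d$abundance), ]
      res <- list(feature_id = key$feature_id,
                  experiment_id = key$experiment_id,
                  n_qc = nrow(qc), corrected = FALSE,
                  qc_cv_pre = cv(qc$abundance), qc_cv_post = NA_real_,
                  factors = tibble(sample_id = d$sample_id,
                                   factor = rep(1, nrow(d))))
      if (nrow(qc) < min_qc) return(res)
      ref <- median(qc$abundance)
      fit <- tryCatch(
        suppressWarnings(stats::loess(
          abundance ~ injection_order, data = qc,
          span = span, degree = degree, surface = "direct",
          family = "gaussian"
        )),
        error = function(e) NULL
      )
      if (is.null(fit)) return(res)
      at_qc <- stats::fitted(fit)
      if (any(!is.finite(at_qc)) || any(at_qc <= 0) || ref <= 0) return(res)
      trend <- stats::approx(qc$injection_order, at_qc,
                             xout = d$injection_order, rule = 2)$y
      fac <- trend / ref
      if (any(!is.finite(fac)) || any(fac <= 0)) return(res)
      res$corrected <- TRUE
      res$factors$factor <- fac
      res$qc_cv_post <- cv(qc$abundance /
                             fac[match(qc$sample_id, d$sample_id)])
      res
    })
  summary <- purrr::map_dfr(fits, function(r) {
    tibble(feature_id = r$feature_id, experiment_id = r$experiment_id,
           n_qc = r$n_qc, corrected = r$corrected,
           qc_cv_pre = r$qc_cv_pre, qc_cv_post = r$qc_cv_post)
  })
  factors <- purrr::map_dfr(fits, function(r) {
    mutate(r$factors, feature_id = r$feature_id,
           experiment_id = r$experiment_id)
  })
  out <- df |>
    left_join(factors, by = c("feature_id", "experiment_id", "sample_id")) |>
    mutate(abundance = .data$abundance / .data$factor) |>
    select(-"factor")
  out <- as_feature_table(out)
  attr(out, "drift_model") <- structure(
    list(summary = summary, factors = factors,
         span = span, degree = degree, min_qc = min_qc),
    class = "drift_model"
  )
  out
}

#' Extract the drift model fitted by [loess_correct()]
#' @param table The table returned by [loess_correct()].
#' @return A `drift_model` object, or `NULL` if absent.
#' @export
drift_model <- function(table) attr(table, "drift_model")

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf(
    "QC-LOESS drift model: %d feature/batch fits (%d corrected, %d flagged)\n",
    nrow(x$summary), sum(x$summary$corrected), sum(!x$summary$corrected)
  ))
  cat(sprintf("span = %.2f, degree = %d, min QC points = %d\n",
              x$span, x$degree, x$min_qc))
  invisible(x)
}

#' @method tidy drift_model
#' @export
tidy.drift_model <- function(x, ...) x$summary

#' @method glance drift_model
#' @export
glance.drift_model <- function(x, ...) {
  s <- x$summary
  tibble(
    n_fits = nrow(s),
    n_corrected = sum(s$corrected),
    n_flagged = sum(!s$corrected),
    median_qc_cv_pre = median(s$qc_cv_pre, na.rm = TRUE),
    median_qc_cv_post = median(
      ifelse(s$corrected, s$qc_cv_post, s$qc_cv_pre), na.rm = TRUE)
  )
}

#' Remove features with unstable QC signal
#'
#' Features whose coefficient of variation across the batch QC injections
#' is at or above `qc_cv_max` (default 20%, boundary removed) are dropped
#' after drift correction; repeated injections of the same pool should not
#' vary this much, so such features are unreliable.
#'
#' @param table An `ms_feature_table` with at least two QC samples.
#' @param qc_cv_max Removal threshold as a fraction.
#' @return The filtered `ms_feature_table`.
#' @export
qc_cv_filter <- function(table, qc_cv_max = 0.20) {
  df <- as_tibble(table)
  if (sum(ft_samples(table)$role == "qc") < 2L) {
    abort("qc_cv_filter needs at least two QC samples",
          class = "ecmet_config_error")
  }
  cvs <- df |>
    filter(.data$role == "qc") |>
    group_by(.data$feature_id) |>
    summarise(qc_cv = cv(.data$abundance), .groups = "drop")
  keep <- cvs$feature_id[!is.na(cvs$qc_cv) & cvs$qc_cv < qc_cv_max]
  ft_subset(table, features = keep)
}

#' Total-sum normalization
#'
#' Divides each feature's peak area by the sum of peak areas of all
#' features in the same sample, correcting for global intensity differences
#' between injections. Missing values stay missing and are excluded from
#' the totals.
#'
#' @param table An `ms_feature_table`; every sample must have a positive
#'   total over present values.
#' @return The normalized table; per-sample totals equal 1.
#' @export
sum_normalize <- function(table) {
  df <- as_tibble(table)
  totals <- df |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$abundance, na.rm = TRUE), .groups = "drop")
  bad <- totals$sample_id[!is.finite(totals$total) | totals$total <= 0]
  if (length(bad)) {
    abort(paste0("zero or undefined total peak area in sample: ",
                 paste(bad, collapse = ", ")),
          class = "ecmet_validation_error")
  }
  out <- df |>
    left_join(totals, by = "sample_id") |>
    mutate(abundance = .data$abundance / .data$total) |>
    select(-"total")
  as_feature_table(out)
}

#' Scale abundances to the control-group mean
#'
#' Within each experiment, each feature's values are divided by the mean of
#' that feature in the experiment's control group (biological samples at
#' `control_dose`), so the control mean maps to 1 and experiments become
#' comparable for pooled analysis. Features whose control mean is zero or
#' undefined in an experiment are left unscaled there and flagged in the
#' `"unscaled_features"` attribute.
#'
#' @param table An `ms_feature_table` with a non-empty control group per
#'   experiment.
#' @param control_dose Dose (in uM) identifying the control group.
#' @return The control-scaled table.
#' @export
control_scale <- function(table, control_dose = 0) {
  df <- as_tibble(table)
  ctrl <- df |>
    filter(.data$role == "biological", .data$dose_uM == control_dose) |>
    group_by(.data$feature_id, .data$experiment_id) |>
    summarise(ctrl_mean = mean(.data$abundance, na.rm = TRUE),
              .groups = "drop")
  if (nrow(ctrl) == 0L) {
    abort("no control-group samples found", class = "ecmet_config_error")
  }
  ctrl <- mutate(ctrl, usable = is.finite(.data$ctrl_mean) &
                   .data$ctrl_mean > 0)
  out <- df |>
    left_join(ctrl, by = c("feature_id", "experiment_id")) |>
    mutate(abundance = ifelse(!is.na(.data$usable) & .data$usable,
                              .data$abundance / .data$ctrl_mean,
                              .data$abundance)) |>
    select(-"ctrl_mean", -"usable")
  out <- as_feature_table(out)
  attr(out, "unscaled_features") <-
    ctrl[!ctrl$usable, c("feature_id", "experiment_id")]
  out
}
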