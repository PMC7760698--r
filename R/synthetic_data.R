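#' Simulation design for synthetic feature tables
#'
#' Describes the statistical structure of a simulated untargeted LC-MS
#' acquisition: ECM-embedded organoid replicates against ECM blanks, with
#' interleaved pooled-QC injections, multiplicative injection-order drift,
#' log-normal replicate noise, and (for dose experiments) planted
#' monotonically dose-responsive features. Defaults mirror the study
#' conditions the pipeline is built for: 5 biological replicates vs 3
#' blanks per mode, 4 dose groups (0/1/10/100 uM) x 5 replicates x 3
#' experiments, replicate CVs spanning 7-35%, and a majority of features
#' shared with the blanks.
#'
#' @param n_features Number of features to simulate.
#' @param frac_cell_derived,frac_ecm_enriched Fractions of features planted
#'   as cell-derived (biological/blank mean ratio at least 1.25x above the
#'   1.2 fold-change threshold) and ECM-enriched (at least 1.25x below the
#'   0.8 threshold); the remainder is background with ratio 1.
#' @param frac_responsive Fraction of cell-derived features planted with a
#'   monotone dose response (split evenly up/down).
#' @param n_bio Biological replicates per group (default 5).
#' @param n_blank ECM-blank replicates (default 3).
#' @param doses Dose levels in uM, ascending (default 0/1/10/100).
#' @param n_experiments Number of independent experiments (default 3).
#' @param replicate_cv Replicate coefficient of variation; a single value,
#'   or a range `c(lo, hi)` from which each feature's CV is drawn uniformly
#'   (default 0.07-0.35, the span observed across protocols and modes).
#' @param qc_cv Technical CV of repeated QC-pool injections (default 0.08;
#'   pooled-QC reinjections vary less than biological replicates).
#' @param drift_amplitude Fractional signal change over the batch (default
#'   0.3); the drift is a smooth multiplicative function of injection
#'   order, linear plus one sine term by default.
#' @param drift_shape `"linear_sine"` or `"linear"`.
#' @param dose_effect Multiplicative expected-abundance factors per dose
#'   for planted up-responsive features (reciprocal for down), default
#'   `c(1, 1.3, 1.8, 2.5)`.
#' @param dropout_rate Probability that a biological value is replaced by a
#'   near-zero dropout (below 1% of its group median), default 0.01.
#' @param qc_every One QC injection per this many analytical injections,
#'   plus bracketing QCs at batch start and end (default 5).
#' @param mode Analytical mode label for the simulated dataset.
#' @param seed Integer seed; fixes the full output.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_features = 1000,
                              frac_cell_derived = 0.25,
                              frac_ecm_enriched = 0.08,
                              frac_responsive = 0.05,
                              n_bio = 5, n_blank = 3,
                              doses = c(0, 1, 10, 100),
                              n_experiments = 3,
                              replicate_cv = c(0.07, 0.35),
                              qc_cv = 0.08,
                              drift_amplitude = 0.3,
                              drift_shape = c("linear_sine", "linear"),
                              dose_effect = c(1, 1.3, 1.8, 2.5),
                              dropout_rate = 0.01,
                              qc_every = 5,
                              mode = "HILIC+",
                              seed = 1L) {
  drift_shape <- match.arg(drift_shape)
  if (frac_cell_derived + frac_ecm_enriched > 1 ||
      frac_cell_derived < 0 || frac_ecm_enriched < 0) {
    abort("class fractions must be in [0,1] and sum to at most 1",
          class = "ecmet_design_error")
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    abort("doses must be sorted ascending", class = "ecmet_design_error")
  }
  if (length(dose_effect) != length(doses)) {
    abort("dose_effect must have one factor per dose",
          class = "ecmet_design_error")
  }
  structure(list(
    n_features = n_features,
    frac_cell_derived = frac_cell_derived,
    frac_ecm_enriched = frac_ecm_enriched,
    frac_responsive = frac_responsive,
    n_bio = n_bio, n_blank = n_blank, doses = doses,
    n_experiments = n_experiments,
    replicate_cv = replicate_cv, qc_cv = qc_cv,
    drift_amplitude = drift_amplitude, drift_shape = drift_shape,
    dose_effect = dose_effect, dropout_rate = dropout_rate,
    qc_every = qc_every, mode = mode, seed = as.integer(seed)
  ), class = "simulation_design")
}

# log-normal multiplier with unit mean and the requested CV
lnorm_noise <- function(n, cv) {
  if (all(cv == 0)) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

# Smooth multiplicative drift over injection positions 1..n_inj, anchored
# at 1 at the batch start and reaching 1 + amplitude at the end (linear
# part), with one superimposed sine period for the non-linear shape.
drift_curve <- function(order, n_inj, amplitude, shape) {
  u <- (order - 1) / max(1, n_inj - 1)
  d <- switch(shape,
    linear = 1 + amplitude * u,
    linear_sine = 1 + amplitude * (u + 0.25 * sin(2 * pi * u))
  )
  pmax(d, 0.05)
}

sim_feature_meta <- function(design) {
  n <- design$n_features
  n_cell <- round(design$frac_cell_derived * n)
  n_ecm <- round(design$frac_ecm_enriched * n)
  class <- c(rep("cell_derived", n_cell), rep("ecm_enriched", n_ecm),
             rep("background", n - n_cell - n_ecm))
  cvr <- design$replicate_cv
  tibble(
    feature_id = sprintf("F%04d", seq_len(n)),
    neutral_mass = sort(stats::runif(n, 80, 1200)),
    rt = round(stats::runif(n, 0.5, 12), 3),
    mode = design$mode,
    class = class,
    # planted biological/blank expected ratio: background sits at 1,
    # planted classes keep a 1.25x margin beyond the 1.2 / 0.8 thresholds
    # with an extra log-uniform spread up to 4x
    bio_ratio = dplyr::case_when(
      class == "cell_derived" ~
        1.2 * 1.25 * exp(stats::runif(n, 0, log(4))),
      class == "ecm_enriched" ~
        0.8 / 1.25 / exp(stats::runif(n, 0, log(4))),
      TRUE ~ 1
    ),
    cv = if (length(cvr) == 2L) stats::runif(n, cvr[1], cvr[2])
         else rep(cvr, n),
    base = stats::rlnorm(n, meanlog = 11, sdlog = 1.3)
  )
}

#' Generate a blank-filter experiment with known ground truth
#'
#' Simulates one acquisition of biological organoid replicates and ECM
#' blanks. Blank expected abundance is the feature baseline; biological
#' expected abundance is the baseline times the planted class ratio
#' (cell-derived above, ECM-enriched below, background at 1). Replicate
#' noise is multiplicative log-normal at the per-feature CV. Fixed seed
#' gives bit-identical output.
#'
#' @param design A [simulation_design()].
#' @return A list with `table` (an `ms_feature_table`) and `truth` (tibble
#'   of per-feature `class` and planted `bio_ratio`).
#' @export
generate_blank_experiment <- function(design = simulation_design()) {
  set.seed(design$seed)
  meta <- sim_feature_meta(design)
  n_s <- design$n_bio + design$n_blank
  samples <- tibble(
    sample_id = c(sprintf("BIO%02d", seq_len(design$n_bio)),
                  sprintf("BLK%02d", seq_len(design$n_blank))),
    role = c(rep("biological", design$n_bio),
             rep("blank", design$n_blank)),
    dose_uM = c(rep(0, design$n_bio), rep(NA_real_, design$n_blank)),
    experiment_id = "E1",
    injection_order = seq_len(n_s),
    protocol = NA_character_
  )
  mu <- outer(meta$base, rep(1, n_s))
  mu[, seq_len(design$n_bio)] <- mu[, seq_len(design$n_bio)] * meta$bio_ratio
  noise <- matrix(lnorm_noise(length(mu), rep(meta$cv, n_s)),
                  nrow = nrow(mu))
  tbl <- feature_table(meta[c("feature_id", "neutral_mass", "rt", "mode")],
                       samples, mu * noise)
  list(table = tbl,
       truth = meta[c("feature_id", "class", "bio_ratio", "cv")])
}

#' Generate a multi-experiment dose-response study with known ground truth
#'
#' Simulates `n_experiments` independent acquisitions, each with every dose
#' group in `doses` at `n_bio` replicates, `n_blank` ECM blanks, and
#' pooled-QC injections interleaved every `qc_every` analytical injections
#' (plus bracketing QCs). Expected abundance of a planted responsive
#' feature is multiplied by `dose_effect` (or its reciprocal for
#' down-regulated features) along the dose series; QC samples are noisy
#' copies of the mean over all biological and blank channels; every value
#' is scaled by the smooth drift function at its injection position;
#' dropouts (values pushed below 1% of the group median) are injected at
#' `dropout_rate` among biological samples.
#'
#' @param design A [simulation_design()].
#' @return A list with `tables` (list of per-experiment
#'   `ms_feature_table`s), `truth` (per-feature class and dose direction)
#'   and `drift` (per-experiment tibble of injection order vs true drift
#'   factor).
#' @export
generate_dose_experiment <- function(design = simulation_design()) {
  set.seed(design$seed)
  meta <- sim_feature_meta(design)
  cell_idx <- which(meta$class == "cell_derived")
  n_resp <- round(design$frac_responsive * length(cell_idx))
  resp_idx <- if (n_resp > 0) sample(cell_idx, n_resp) else integer(0)
  dir <- rep("none", design$n_features)
  if (n_resp > 0) {
    dir[resp_idx] <- rep_len(c("up", "down"), n_resp)
  }
  meta$dose_direction <- dir

  n_doses <- length(design$doses)
  n_analytical <- n_doses * design$n_bio + design$n_blank
  qc_after <- seq(0, n_analytical, by = design$qc_every)
  if (max(qc_after) < n_analytical) qc_after <- c(qc_after, n_analytical)
  n_qc <- length(qc_after)
  n_inj <- n_analytical + n_qc

  tables <- vector("list", design$n_experiments)
  drifts <- vector("list", design$n_experiments)
  for (e in seq_len(design$n_experiments)) {
    eid <- paste0("E", e)
    bio <- tidyr::expand_grid(dose_uM = design$doses,
                              rep = seq_len(design$n_bio))
    samples <- dplyr::bind_rows(
      tibble(sample_id = sprintf("%s_D%g_R%d", eid, bio$dose_uM, bio$rep),
             role = "biological", dose_uM = bio$dose_uM),
      tibble(sample_id = sprintf("%s_BLK%02d", eid,
                                 seq_len(design$n_blank)),
             role = "blank", dose_uM = NA_real_)
    )
    # interleave QCs: one after every qc_every analytical injections,
    # plus one before the first
    analytical_order <- order(stats::runif(nrow(samples)))
    inj_analytical <- integer(nrow(samples))
    pos <- 1L
    inj <- integer(0)
    qc_orders <- integer(0)
    slot <- 1L
    for (k in 0:n_analytical) {
      if (k %in% qc_after) {
        qc_orders <- c(qc_orders, slot)
        slot <- slot + 1L
      }
      if (k < n_analytical) {
        inj <- c(inj, slot)
        slot <- slot + 1L
      }
    }
    samples$injection_order <- inj[analytical_order]
    qc_samples <- tibble(
      sample_id = sprintf("%s_QC%02d", eid, seq_len(n_qc)),
      role = "qc", dose_uM = NA_real_,
      injection_order = qc_orders
    )
    samples <- dplyr::bind_rows(samples, qc_samples)
    samples$experiment_id <- eid
    samples$protocol <- NA_character_

    # expected abundance per feature x sample
    dose_factor <- matrix(1, design$n_features, nrow(samples))
    is_bio <- samples$role == "biological"
    for (j in which(is_bio)) {
      fct <- design$dose_effect[match(samples$dose_uM[j], design$doses)]
      dose_factor[dir == "up", j] <- fct
      dose_factor[dir == "down", j] <- 1 / fct
    }
    mu <- outer(meta$base, rep(1, nrow(samples))) * dose_factor
    mu[, is_bio] <- mu[, is_bio] * meta$bio_ratio
    # QC pool: mean over all biological and blank expected channels
    qc_cols <- samples$role == "qc"
    mu[, qc_cols] <- rowMeans(mu[, !qc_cols, drop = FALSE])

    cvm <- matrix(rep(meta$cv, nrow(samples)), ncol = nrow(samples))
    cvm[, qc_cols] <- design$qc_cv
    noise <- matrix(lnorm_noise(length(mu), as.vector(cvm)),
                    nrow = nrow(mu))
    d <- drift_curve(samples$injection_order, n_inj,
                     design$drift_amplitude, design$drift_shape)
    values <- mu * noise * matrix(rep(d, each = design$n_features),
                                  nrow = design$n_features)
    # dropouts: push a biological value below 1% of its group median
    if (design$dropout_rate > 0) {
      drop_mask <- matrix(FALSE, nrow(values), ncol(values))
      drop_mask[, is_bio] <-
        stats::runif(design$n_features * sum(is_bio)) < design$dropout_rate
      values[drop_mask] <- values[drop_mask] * 1e-4
    }
    tables[[e]] <- feature_table(
      meta[c("feature_id", "neutral_mass", "rt", "mode")],
      samples, values
    )
    drifts[[e]] <- tibble(experiment_id = eid,
                          injection_order = sort(samples$injection_order),
                          drift = drift_curve(sort(samples$injection_order),
                                              n_inj,
                                              design$drift_amplitude,
                                              design$drift_shape))
  }
  list(tables = tables,
       truth = meta[c("feature_id", "class", "bio_ratio", "cv",
                      "dose_direction")],
       drift = dplyr::bind_rows(drifts))
}
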