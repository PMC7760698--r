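# Monoisotopic masses of the most abundant isotope (CODATA/IUPAC values).
ISOTOPE_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637064864,
  Cl = 34.968852682, F = 18.9984031627, Se = 79.9165218, Si = 27.9769265347
)

#' Monoisotopic mass from an elemental formula
#'
#' Sums the masses of the most abundant isotope of each element, e.g.
#' `"C9H12N2O5"` (2'-deoxyuridine) gives 228.0746 Da.
#'
#' @param formula Elemental composition string such as `"C6H12O6"`;
#'   element symbols followed by optional counts.
#' @return Mass in Da; 0 for an empty formula.
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(0)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    if (sum(nchar(parts)) != nchar(f)) {
      abort(paste0("cannot parse formula: ", f),
            class = "ecmet_formula_error")
    }
    total <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      cnt <- sub("^[A-Za-z]+", "", p)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(ISOTOPE_MASS)) {
        abort(paste0("unknown element: ", el),
              class = "ecmet_formula_error")
      }
      total <- total + ISOTOPE_MASS[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Signed mass error in parts per million
#'
#' @param observed_mass,theoretical_mass Masses in Da;
#'   `theoretical_mass > 0`.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed_mass, theoretical_mass) {
  stopifnot(all(theoretical_mass > 0))
  1e6 * (observed_mass - theoretical_mass) / theoretical_mass
}

#' Build a reference-compound list
#'
#' @param df Data frame with columns `name` and at least one of `formula` /
#'   `monoisotopic_mass`, plus optional `expected_rt` (min) and
#'   `msi_evidence` (`"standard_rt_msms"` = MSI level 1,
#'   `"spectral_db_match"` = MSI level 2). Masses absent but derivable from
#'   the formula are filled in; a stated mass inconsistent with its formula
#'   by more than 1 mDa is an error.
#' @return A `reference_compounds` tibble with an `msi_level` column.
#' @export
reference_compounds <- function(df) {
  df <- as_tibble(df)
  if (!"monoisotopic_mass" %in% names(df)) df$monoisotopic_mass <- NA_real_
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  if (!"expected_rt" %in% names(df)) df$expected_rt <- NA_real_
  if (!"msi_evidence" %in% names(df)) df$msi_evidence <- NA_character_
  from_formula <- !is.na(df$formula) & nzchar(df$formula)
  calc <- ifelse(from_formula, monoisotopic_mass(df$formula), NA_real_)
  inconsistent <- !is.na(df$monoisotopic_mass) & !is.na(calc) &
    abs(df$monoisotopic_mass - calc) > 1e-3
  if (any(inconsistent)) {
    abort(paste0("mass inconsistent with formula for: ",
                 paste(df$name[inconsistent], collapse = ", ")),
          class = "ecmet_validation_error")
  }
  df$monoisotopic_mass <- ifelse(is.na(df$monoisotopic_mass), calc,
                                 df$monoisotopic_mass)
  if (any(is.na(df$monoisotopic_mass) | df$monoisotopic_mass <= 0)) {
    abort("every reference compound needs a positive monoisotopic mass",
          class = "ecmet_validation_error")
  }
  df$msi_level <- dplyr::case_when(
    df$msi_evidence == "standard_rt_msms" ~ 1L,
    df$msi_evidence == "spectral_db_match" ~ 2L,
    TRUE ~ NA_integer_
  )
  structure(df, class = c("reference_compounds", class(tibble())))
}

#' Read a reference-compound CSV
#'
#' Expected columns: `name`, `formula`, `monoisotopic_mass`,
#' `expected_rt`, `msi_evidence`.
#'
#' @param path CSV path.
#' @return A `reference_compounds` tibble.
#' @export
read_reference_compounds <- function(path) {
  reference_compounds(readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(),
    formula = readr::col_character(),
    monoisotopic_mass = readr::col_double(),
    expected_rt = readr::col_double(),
    msi_evidence = readr::col_character()
  ), progress = FALSE))
}

# linear tolerance-ramp component score: 100 at zero error, 0 at/beyond
# the tolerance
ramp_score <- function(err, tol) 100 * pmax(0, 1 - abs(err) / tol)

#' Weighted composite annotation match score
#'
#' Scores a feature against one reference compound. Each available
#' component gets a linear tolerance-ramp score (100 at zero error, 0 at
#' the tolerance): mass error against 15 ppm, retention-time error against
#' 0.2 min, mean relative isotope-abundance deviation against 25%, and
#' isotope-spacing deviation against 5 mDa. The composite is the
#' weight-normalized mean over the available components with weights mass
#' 100, isotope abundance 60, isotope spacing 50, retention time 20. A
#' match is accepted when at least two of three criteria hold: mass within
#' tolerance, retention time within tolerance, composite above
#' `score_min` (70%).
#'
#' @param observed_mass Observed neutral mass (Da); required.
#' @param ref A one-row [reference_compounds()] entry (or a list with
#'   `name`, `monoisotopic_mass`, `expected_rt`).
#' @param observed_rt Observed retention time (min), optional.
#' @param iso_abundance_dev Mean relative deviation of the observed isotope
#'   envelope abundances from theory (fraction), optional.
#' @param iso_spacing_dev_mda Deviation of observed isotope spacing from
#'   theory (mDa), optional.
#' @param cfg A [pipeline_config()].
#' @return One-row tibble with component scores, `composite`,
#'   `criteria_met` and `accepted`.
#' @export
composite_score <- function(observed_mass, ref, observed_rt = NA,
                            iso_abundance_dev = NA,
                            iso_spacing_dev_mda = NA,
                            cfg = pipeline_config()) {
  ppm <- ppm_error(observed_mass, ref$monoisotopic_mass)
  rt_err <- if (!is.na(observed_rt) && !is.null(ref$expected_rt) &&
                !is.na(ref$expected_rt)) observed_rt - ref$expected_rt
            else NA_real_
  w <- cfg$score_weights
  scores <- c(
    mass = ramp_score(ppm, cfg$mass_tol_ppm),
    isotope_abundance = if (is.na(iso_abundance_dev)) NA_real_ else
      ramp_score(iso_abundance_dev, cfg$iso_abundance_tol),
    isotope_spacing = if (is.na(iso_spacing_dev_mda)) NA_real_ else
      ramp_score(iso_spacing_dev_mda, cfg$iso_spacing_tol_mda),
    rt = if (is.na(rt_err)) NA_real_ else
      ramp_score(rt_err, cfg$rt_tol_match)
  )
  avail <- !is.na(scores)
  composite <- sum(w[avail] * scores[avail]) / sum(w[avail])
  criteria_met <- sum(
    abs(ppm) <= cfg$mass_tol_ppm,
    !is.na(rt_err) && abs(rt_err) <= cfg$rt_tol_match,
    composite > cfg$score_min
  )
  tibble(
    compound = ref$name %||% NA_character_,
    ppm_error = ppm,
    rt_error = rt_err,
    score_mass = scores[["mass"]],
    score_isotope_abundance = scores[["isotope_abundance"]],
    score_isotope_spacing = scores[["isotope_spacing"]],
    score_rt = scores[["rt"]],
    composite = composite,
    criteria_met = criteria_met,
    accepted = criteria_met >= 2L && composite > cfg$score_min
  )
}

#' Targeted matching of reference compounds against a feature table
#'
#' For each reference compound, finds the feature within the mass tolerance
#' (15 ppm) and the targeted retention-time window (0.7 min by default)
#' with the smallest absolute ppm error (ties broken by retention-time
#' error); at most one feature per reference. Unmatched references are
#' reported with `NA` feature columns.
#'
#' @param table An `ms_feature_table`.
#' @param refs A [reference_compounds()] tibble.
#' @param rt_window Retention-time tolerance in minutes.
#' @param cfg A [pipeline_config()].
#' @return Tibble with one row per reference: `name`, `feature_id`,
#'   `ppm_error`, `rt_error`, `matched`.
#' @export
targeted_match <- function(table, refs, rt_window = cfg$rt_tol_targeted,
                           cfg = pipeline_config()) {
  if (nrow(refs) == 0L) {
    abort("reference list is empty", class = "ecmet_config_error")
  }
  feats <- ft_features(table)
  purrr::map_dfr(seq_len(nrow(refs)), function(i) {
    r <- refs[i, ]
    ppm <- ppm_error(feats$neutral_mass, r$monoisotopic_mass)
    rt_err <- if (is.na(r$expected_rt)) rep(0, nrow(feats)) else
      feats$rt - r$expected_rt
    ok <- abs(ppm) <= cfg$mass_tol_ppm & abs(rt_err) <= rt_window
    if (!any(ok)) {
      return(tibble(name = r$name, feature_id = NA_character_,
                    ppm_error = NA_real_, rt_error = NA_real_,
                    matched = FALSE))
    }
    cand <- which(ok)
    best <- cand[order(abs(ppm[cand]), abs(rt_err[cand]))][1]
    tibble(name = r$name, feature_id = feats$feature_id[best],
           ppm_error = ppm[best],
           rt_error = if (is.na(r$expected_rt)) NA_real_ else rt_err[best],
           matched = TRUE)
  })
}

#' Annotate a feature table from a targeted match
#'
#' Copies compound names and MSI levels onto matched features.
#'
#' @param table An `ms_feature_table`.
#' @param refs A [reference_compounds()] tibble.
#' @param matches Result of [targeted_match()]; computed if missing.
#' @param cfg A [pipeline_config()].
#' @return The annotated table.
#' @export
annotate_features <- function(table, refs,
                              matches = targeted_match(table, refs,
                                                       cfg = cfg),
                              cfg = pipeline_config()) {
  hit <- matches |>
    filter(.data$matched) |>
    left_join(as_tibble(refs)[c("name", "msi_level")], by = "name")
  df <- as_tibble(table) |>
    left_join(hit[c("feature_id", "name", "msi_level")],
              by = "feature_id", suffix = c("", ".ref")) |>
    mutate(
      annotation = ifelse(is.na(.data$name), .data$annotation, .data$name),
      msi_level = dplyr::coalesce(.data$msi_level.ref, .data$msi_level)
    ) |>
    select(-"name", -"msi_level.ref")
  as_feature_table(df)
}
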