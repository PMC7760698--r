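test_that("low-outlier exclusion drops at most the single smallest value", {
  tbl <- dose_table(list(c(100, 102, 98, 0.5, 101),
                         c(100, 0.3, 0.4, 99, 101),
                         c(100, 101, 99, 98, 102),
                         c(50, 51, 49, 52, 50)))
  out <- tibble::as_tibble(exclude_low_outliers(tbl))
  g0 <- out$abundance[out$dose_uM == 0]
  expect_equal(sum(is.na(g0)), 1)
  expect_false(0.5 %in% g0)
  # several qualifying values: only the smallest goes
  g1 <- out$abundance[out$dose_uM == 1]
  expect_equal(sum(is.na(g1)), 1)
  expect_true(0.4 %in% g1)
  expect_false(0.3 %in% g1)
  # clean groups untouched
  expect_equal(sum(is.na(out$abundance[out$dose_uM %in% c(10, 100)])), 0)
})

test_that("exclusion is the identity on clean generated data", {
  d <- generate_dose_experiment(simulation_design(
    n_features = 100, dropout_rate = 0, seed = 14))
  tbl <- d$tables[[1]]
  out <- exclude_low_outliers(tbl)
  expect_equal(ft_matrix(out), ft_matrix(tbl))
})

test_that("exclusion removes at most one value per feature-group", {
  d <- generate_dose_experiment(simulation_design(
    n_features = 150, dropout_rate = 0.1, seed = 15))
  tbl <- d$tables[[1]]
  out <- tibble::as_tibble(exclude_low_outliers(tbl))
  na_counts <- out |>
    dplyr::filter(role == "biological") |>
    dplyr::group_by(feature_id, dose_uM) |>
    dplyr::summarise(n_na = sum(is.na(abundance)), .groups = "drop")
  expect_true(all(na_counts$n_na <= 1))
})

test_that("Spearman on a strictly monotone series is exactly 1", {
  # one untied observation per dose level: perfect rank agreement
  expect_equal(spearman_dose(c(0.4, 1.1, 2.5, 7), c(0, 1, 10, 100))$rs,
               1, tolerance = 1e-12)
  # tied doses cap |rs| below 1 even for strictly increasing values
  expect_lt(spearman_dose(1:20, rep(c(0, 1, 10, 100), each = 5))$rs, 1)
  expect_true(is.na(spearman_dose(rep(5, 12),
                                  rep(c(0, 1, 10), each = 4))$rs))
  expect_true(is.na(spearman_dose(c(1, 2), c(0, 1))$rs))
})

test_that("Spearman equals Pearson on midranks with the t approximation", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    v <- rnorm(n)
    d <- sample(c(0, 1, 10, 100), n, replace = TRUE)
    if (length(unique(d)) < 2) next
    got <- spearman_dose(v, d)
    want <- spearman_oracle(v, d)
    expect_equal(got$rs, want$rs, tolerance = 1e-12)
    expect_equal(got$p_raw, want$p, tolerance = 1e-10)
  }
})

test_that("Spearman is invariant to using dose ranks instead of doses", {
  set.seed(55)
  v <- rnorm(20)
  doses <- rep(c(0, 1, 10, 100), each = 5)
  expect_equal(spearman_dose(v, doses),
               spearman_dose(v, rep(1:4, each = 5)))
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(77)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    # permutation invariance up to reordering
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm],
                 tolerance = 1e-12)
  }
})

test_that("per-experiment screening flags planted responders and the
           significance flag is self-consistent", {
  d <- generate_dose_experiment(simulation_design(
    n_features = 150, frac_responsive = 0.15, replicate_cv = 0.1,
    drift_amplitude = 0, seed = 19))
  res <- tidy(per_experiment_hits(d$tables))
  expect_equal(res$significant,
               !is.na(res$rs) & abs(res$rs) > 0.7 & res$q_bh < 0.05)
  expect_true(all(res$q_bh >= res$p_raw - 1e-12, na.rm = TRUE))
  planted <- d$truth$feature_id[d$truth$dose_direction != "none"]
  hit_rate <- res |>
    dplyr::filter(feature_id %in% planted) |>
    dplyr::group_by(feature_id) |>
    dplyr::summarise(n_sig = sum(significant), .groups = "drop")
  expect_gte(mean(hit_rate$n_sig >= 2), 0.9)
  # planted directions are recovered
  dirs <- res |>
    dplyr::filter(significant) |>
    dplyr::left_join(d$truth, by = "feature_id")
  expect_true(all(dirs$direction == dirs$dose_direction))
})

test_that("nothing passes at the rs_min = 1 boundary under noise", {
  d <- generate_dose_experiment(simulation_design(
    n_features = 80, frac_responsive = 0.2, replicate_cv = 0.1,
    seed = 25))
  res <- per_experiment_hits(d$tables[[1]],
                             pipeline_config(rs_min = 1.0))
  expect_equal(sum(res$significant), 0)
})

test_that("consolidation honours the two-experiment and direction rules", {
  base <- tibble::tibble(
    feature_id = "F1", mode = "HILIC+", neutral_mass = 228.0731,
    rt = 2.12, annotation = NA_character_, rs = 0.9, p_raw = 1e-4,
    q_bh = 1e-3, direction = "up", significant = TRUE
  )
  res <- dplyr::bind_rows(
    dplyr::mutate(base, experiment_id = "E1"),
    dplyr::mutate(base, experiment_id = "E3",
                  neutral_mass = 228.0731 * (1 + 5e-6), rt = 2.15)
  )
  class(res) <- c("dose_response_result", class(tibble::tibble()))
  hits <- consolidate_hits(res)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_experiments_significant, 2)
  expect_equal(hits$mean_mass,
               mean(c(228.0731, 228.0731 * (1 + 5e-6))))

  # conflicting direction -> dropped and logged
  conflict <- dplyr::bind_rows(
    dplyr::mutate(base, experiment_id = "E1"),
    dplyr::mutate(base, experiment_id = "E2", direction = "down",
                  rs = -0.9)
  )
  class(conflict) <- c("dose_response_result", class(tibble::tibble()))
  hits2 <- consolidate_hits(conflict)
  expect_equal(nrow(hits2), 0)
  expect_equal(nrow(attr(hits2, "direction_conflicts")), 1)

  # out-of-tolerance masses stay separate
  apart <- dplyr::bind_rows(
    dplyr::mutate(base, experiment_id = "E1"),
    dplyr::mutate(base, experiment_id = "E2",
                  neutral_mass = 228.0731 * (1 + 50e-6))
  )
  class(apart) <- c("dose_response_result", class(tibble::tibble()))
  expect_equal(nrow(consolidate_hits(apart)), 0)
})

test_that("consolidation recovers features planted in all experiments", {
  d <- generate_dose_experiment(simulation_design(
    n_features = 150, frac_responsive = 0.15, replicate_cv = 0.1,
    drift_amplitude = 0, seed = 29))
  res <- per_experiment_hits(d$tables)
  hits <- consolidate_hits(res)
  planted <- d$truth$feature_id[d$truth$dose_direction != "none"]
  all_three <- tidy(res) |>
    dplyr::filter(feature_id %in% planted, significant) |>
    dplyr::count(feature_id) |>
    dplyr::filter(n == 3)
  recovered <- unlist(hits$feature_ids)
  expect_gte(mean(all_three$feature_id %in% recovered), 0.9)
})

test_that("joint analysis of a single experiment reduces to the
           per-experiment result", {
  d <- generate_dose_experiment(simulation_design(
    n_features = 60, n_experiments = 1, frac_responsive = 0.1,
    seed = 33))
  per <- tidy(per_experiment_hits(d$tables[[1]]))
  joint <- tidy(joint_analysis(d$tables[[1]]))
  expect_equal(joint$rs, per$rs, tolerance = 1e-12)
  expect_equal(joint$q_bh, per$q_bh, tolerance = 1e-12)
})

test_that("a shared dose effect gains evidence when experiments are
           pooled", {
  d <- generate_dose_experiment(simulation_design(
    n_features = 100, frac_responsive = 0.2, replicate_cv = 0.25,
    dose_effect = c(1, 1.15, 1.35, 1.6), drift_amplitude = 0,
    seed = 37))
  per <- tidy(per_experiment_hits(d$tables))
  joint <- tidy(joint_analysis(d$tables))
  planted <- d$truth$feature_id[d$truth$dose_direction != "none"]
  # tripling n sharpens the p-values for a consistent moderate effect
  mean_log_p_per <- per |>
    dplyr::filter(feature_id %in% planted) |>
    dplyr::pull(p_raw) |> log() |> mean()
  mean_log_p_joint <- joint |>
    dplyr::filter(feature_id %in% planted) |>
    dplyr::pull(p_raw) |> log() |> mean()
  expect_lt(mean_log_p_joint, mean_log_p_per)
})
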