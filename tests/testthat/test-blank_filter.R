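test_that("Welch p handles identical groups, degeneracy and scaling", {
  expect_equal(welch_log2_p(c(4, 8, 16), c(4, 8, 16)), 1)
  # textbook Welch-Satterthwaite computation
  a <- c(10.1, 10.3, 9.9, 10.2, 10.0)
  b <- c(10.1, 10.2, 9.9)
  expect_equal(welch_log2_p(a, b), welch_oracle_p(log2(a), log2(b)),
               tolerance = 1e-10)
  # multiplicative scaling is a location shift on the log scale
  expect_equal(welch_log2_p(a * 1000, b * 1000), welch_log2_p(a, b),
               tolerance = 1e-12)
  # fewer than two usable values -> untestable
  expect_true(is.na(welch_log2_p(c(5), b)))
  expect_true(is.na(welch_log2_p(c(5, 0, NA), b)))
  # zero variance, equal means
  expect_equal(welch_log2_p(c(4, 4, 4), c(4, 4)), 1)
  expect_equal(welch_log2_p(c(4, 4, 4), c(8, 8)), 0)
})

test_that("fold change is the plain ratio of location statistics", {
  expect_equal(fold_change(c(12, 12, 12), c(10, 10, 10), "mean"), 1.2)
  expect_equal(fold_change(c(7, 9, 11), c(7, 9, 11), "mean"), 1)
  expect_true(is.na(fold_change(c(1, 2), c(0, 0), "mean")))
  set.seed(42)
  for (i in 1:50) {
    bio <- runif(5, 1, 100)
    blank <- runif(3, 1, 100)
    expect_equal(fold_change(bio, blank, "mean"),
                 mean(bio) / mean(blank), tolerance = 1e-12)
    expect_equal(fold_change(bio, blank, "median"),
                 median(bio) / median(blank), tolerance = 1e-12)
  }
})

test_that("classification applies the strict two-step rule", {
  cfg <- pipeline_config()
  expect_equal(ecmet:::classification_label(1.5, 0.01, cfg), "cell_derived")
  expect_equal(ecmet:::classification_label(0.5, 0.01, cfg), "ecm_enriched")
  expect_equal(ecmet:::classification_label(1.5, 0.2, cfg), "uninformative")
  # boundary: fc exactly at the threshold fails the strict inequality
  expect_equal(ecmet:::classification_label(1.2, 0.001, cfg),
               "uninformative")
  expect_equal(ecmet:::classification_label(0.8, 0.001, cfg),
               "uninformative")
  expect_equal(ecmet:::classification_label(NA_real_, NA_real_, cfg),
               "untestable")
})

test_that("every feature gets exactly one label and counts partition", {
  g <- generate_blank_experiment(simulation_design(n_features = 400,
                                                   seed = 3))
  cls <- classify_features(g$table)
  expect_equal(nrow(cls), 400)
  expect_setequal(cls$feature_id, g$truth$feature_id)
  gl <- glance(cls)
  expect_equal(gl$n_cell_derived + gl$n_ecm_enriched +
                 gl$n_uninformative + gl$n_untestable, gl$n_total)
})

test_that("tightening thresholds never gains features", {
  g <- generate_blank_experiment(simulation_design(n_features = 400,
                                                   seed = 13))
  n_cell <- function(cfg) sum(classify_features(g$table, cfg)$label ==
                                "cell_derived")
  base <- pipeline_config()
  expect_lte(n_cell(pipeline_config(fc_up = 1.5)), n_cell(base))
  strict_alpha <- classify_features(g$table, pipeline_config(alpha = 0.01))
  loose <- classify_features(g$table, base)
  expect_lte(sum(strict_alpha$label == "cell_derived"),
             sum(loose$label == "cell_derived"))
  expect_lte(sum(strict_alpha$label == "ecm_enriched"),
             sum(loose$label == "ecm_enriched"))
})

test_that("classification equals the per-feature oracle path", {
  g <- generate_blank_experiment(simulation_design(n_features = 60,
                                                   seed = 17))
  cls <- classify_features(g$table)
  m <- ft_matrix(g$table)
  roles <- ft_samples(g$table)$role
  for (i in seq_len(nrow(m))) {
    bio <- m[i, roles == "biological"]
    blank <- m[i, roles == "blank"]
    expect_equal(cls$fc[i], mean(bio) / mean(blank), tolerance = 1e-12)
    expect_equal(cls$p_value[i],
                 welch_oracle_p(log2(bio), log2(blank)),
                 tolerance = 1e-10)
  }
})

test_that("retained_table keeps exactly the cell-derived set, idempotently", {
  g <- generate_blank_experiment(simulation_design(n_features = 200,
                                                   seed = 5))
  cls <- classify_features(g$table)
  kept <- retained_table(g$table, cls)
  expect_setequal(unique(kept$feature_id),
                  cls$feature_id[cls$label == "cell_derived"])
  # re-running on the output (blanks still present) changes nothing
  cls2 <- classify_features(kept)
  kept2 <- retained_table(kept, cls2)
  expect_equal(as.data.frame(kept2), as.data.frame(kept))

  # all uninformative -> zero features
  flat <- toy_table(abundance = matrix(rep(c(10, 10.1, 10, 10.05), 3),
                                       3, 4, byrow = TRUE),
                    roles = c("biological", "biological", "blank",
                              "blank"))
  cls3 <- classify_features(flat)
  expect_equal(nrow(ft_features(retained_table(flat, cls3))), 0)
})

test_that("classification recovers planted classes on simulated data", {
  g <- generate_blank_experiment(simulation_design(
    n_features = 1000, replicate_cv = 0.15, seed = 7))
  cls <- classify_features(g$table)
  tr <- dplyr::left_join(tibble::as_tibble(cls), g$truth,
                         by = "feature_id")
  sens <- mean(tr$label[tr$class == "cell_derived"] == "cell_derived")
  spec <- mean(tr$label[tr$class != "cell_derived"] != "cell_derived")
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("filtering can only lower the maximum replicate CV when noise
           concentrates in background features", {
  d <- simulation_design(n_features = 300, frac_cell_derived = 0.3,
                         frac_ecm_enriched = 0, seed = 23)
  g <- generate_blank_experiment(d)
  # push background features into a high-CV stratum by construction
  m <- ft_matrix(g$table)
  bg <- g$truth$class == "background"
  set.seed(23)
  m[bg, ] <- m[bg, ] * matrix(exp(rnorm(sum(bg) * ncol(m), 0, 1)),
                              sum(bg))
  tbl <- feature_table(ft_features(g$table), ft_samples(g$table), m)
  cls <- classify_features(tbl)
  kept <- retained_table(tbl, cls)
  feat_cv <- function(t) {
    mm <- ft_matrix(t)[, ft_samples(t)$role == "biological", drop = FALSE]
    apply(mm, 1, cv_oracle)
  }
  expect_lt(max(feat_cv(kept)), max(feat_cv(tbl)))
})
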