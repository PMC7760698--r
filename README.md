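# ecmet

Untargeted LC-MS metabolomics and lipidomics of 3D organoids is complicated
by the extracellular matrix (ECM) the organoids grow in: the protein-rich
hydrogel contributes hundreds of abundant background ions that swamp the
cell-derived signal of a few hundred cells per injection. `ecmet` implements
a feature-table preprocessing and screening pipeline built for exactly this
setting, for analysts working with peak-picked LC-MS feature tables
(features × samples peak areas) from ECM-embedded organoid experiments.

## What it does

Each chromatography × polarity combination (HILIC ±, RPLC ±) is processed
as an independent dataset, in this order:

1. **QC-anchored LOESS drift correction.** For every feature, a LOESS curve
   is fitted to the pooled-QC peak areas against injection order; each
   sample value is divided by the fitted trend at its injection position
   relative to the QC median.
2. **QC CV filter.** Features with a coefficient of variation
   CV = s/x̄ ≥ 20% across the QC injections are removed.
3. **Two-step ECM-blank filter.** For each feature, Welch's unequal-variance
   t-test on log2-transformed data compares biological samples against ECM
   blanks, and the fold change FC = x̄_bio / x̄_blank is computed on the raw
   scale. Features with FC > 1.2 and p < 0.05 are *cell-derived* and
   retained; FC < 0.8 with p < 0.05 flags *ECM-enriched* background;
   everything else is uninformative.
4. **Total-sum normalization** (each peak area divided by the sample's
   total), and, for cross-experiment work, scaling to the control-group
   mean.
5. **Dose–response screening.** After excluding low outliers (a value
   < 1% of its treatment-group median, at most one per group), each
   feature's abundance is correlated with dose by Spearman's r_s;
   Benjamini–Hochberg adjustment is applied per analytical mode, and
   features with |r_s| > 0.7 and q < 0.05 are flagged — per experiment,
   consolidated across experiments (significant in ≥ 2 with a consistent
   direction, matched by ±15 ppm / ±0.2 min), and in a pooled joint
   analysis.
6. **Annotation.** Reference compounds are matched by mass (±15 ppm) and
   retention time, with a weighted composite score (weights: mass 100,
   isotope abundance 60, isotope spacing 50, retention time 20; accepted
   above 70% with ≥ 2 criteria met) and MSI-level bookkeeping.

A synthetic-data generator (`generate_blank_experiment()`,
`generate_dose_experiment()`) produces feature tables with planted ground
truth — class labels, dose directions, and the true drift curve — so every
stage can be validated by parameter recovery.

## Worked example

```r
library(ecmet)

design <- simulation_design(n_features = 500, frac_responsive = 0.1, seed = 42)
study  <- generate_dose_experiment(design)   # 3 experiments, 0/1/10/100 µM

run_preprocessing(study$tables[[1]])$stage_counts
#>   stage           n_features
#> 1 input                  500
#> 2 loess_corrected        500
#> 3 qc_cv_filtered         500
#> 4 blank_filtered         103
#> 5 sum_normalized         103

prep <- lapply(study$tables, function(t) run_preprocessing(t)$table)
res  <- per_experiment_hits(prep)
glance(res)
#>   experiment_id mode   n_tested n_significant
#> 1 E1            HILIC+      103             9
#> 2 E2            HILIC+      115             9
#> 3 E3            HILIC+       99             7

consolidate_hits(res)
#> # A tibble: 9 × 7   (mode, mean_mass, rt, direction, …)
#> 1 HILIC+  101.  9.34 up    n_experiments_significant = 3
#> 2 HILIC+  136.  8.44 up    n_experiments_significant = 2
#> ...
```

The stage counts show the blank filter doing the heavy lifting: of 500
features, 103 are retained as cell-derived (the generator planted 25%
cell-derived features, of which these are the recovered subset plus a small
number of false positives). Nine features per experiment pass the
dose–response criteria, and nine distinct features are significant in at
least two of three experiments with consistent direction; the joint pooled
analysis confirms six of them at much sharper p-values. With
`plot_volcano()`, `plot_drift()` and `plot_dose_response()` the
corresponding diagnostic figures are one call away.

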