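---
title: "Preprocessing ECM-embedded organoid metabolomics data with ecmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing ECM-embedded organoid metabolomics data with ecmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmet)
library(dplyr)
```

## The problem

Organoids are grown embedded in an extracellular matrix (ECM), typically a
basement-membrane extract. When such cultures are profiled by untargeted
LC-MS, the matrix and the culture medium contribute a large background of
ion features — protein fragments, phospholipids, medium components — that
usually outnumber the cell-derived features. With fewer than a thousand
cells per injection, the biological signal is faint, and any downstream
statistics run on unfiltered tables are dominated by background variance.
`ecmet` operates on exported feature tables (peak areas for features ×
samples, plus per-feature mass/RT/mode and per-sample role/dose/injection
metadata) and removes this background with a *measured* reference: ECM
blank samples, prepared with matrix and medium but no cells.

## The model and the processing order

Every analytical mode (HILIC or RPLC crossed with ESI polarity) is an
independent dataset. The stages run in a fixed order, and
`run_preprocessing()` records the feature count after each one:

1. LOESS drift correction over QC samples,
2. QC CV filter (≥ 20% removed),
3. two-step ECM-blank filter (keep FC > 1.2 with Welch p < 0.05),
4. total-sum normalization.

The ordering matters: drift correction must precede any CV-based filter
(otherwise drift masquerades as irreproducibility), the blank filter runs
on drift-corrected but *not yet* sum-normalized data (sum normalization
would couple every feature's value to the background features about to be
removed), and normalization comes last so that the per-sample totals are
computed over the retained features only.

### The two-step blank filter

For feature $i$ with biological replicate values $x_{i1},\dots,x_{in}$ and
blank values $y_{i1},\dots,y_{im}$:

* Welch's unequal-variance $t$-test is applied to $\log_2$-transformed
  values, with Welch–Satterthwaite degrees of freedom, two-sided;
* the fold change $\mathrm{FC}_i = \bar x_i / \bar y_i$ is computed on the
  raw scale.

A feature is **cell-derived** iff $\mathrm{FC} > 1.2$ and $p < 0.05$
(both strict), **ECM-enriched** iff $\mathrm{FC} < 0.8$ and $p < 0.05$,
**untestable** if either quantity is undefined (fewer than two usable
values in a group, or a zero blank mean), and **uninformative** otherwise.
The intuition behind 1.2: if up to 20% variation is tolerated as
irreproducibility in the QC filter, then only a > 20% excess over the
blank level is *relevant* signal. p-values are deliberately unadjusted at
this stage — the filter is a screening device, not an inference, and
adjusting here would only let more background through.

Two presets exist: the screening variant above (mean-based FC, threshold
1.2) and a *protocol-rating* variant (median-based FC, threshold > 1) used
to count detectable metabolites when comparing extraction protocols; both
are `pipeline_config()` presets rather than hidden behaviour.

Zeros and missing values are never imputed. Values ≤ 0 are dropped before
the log2 transform (a pseudocount would distort both the test and the
fold change); the raw-scale FC tolerates zeros naturally. Whether a value
is absent or near-zero is meaningful for the CV and outlier rules, so the
distinction is preserved end to end.

### Drift correction

Instrument response drifts over an acquisition batch. Repeated injections
of one pooled QC sample measure that drift, and a LOESS curve (span 0.75,
degree 2 — standard QC-based regression-correction practice; the smoothing
parameters are config-exposed because no single setting suits all batch
lengths) fitted per feature to QC peak area vs injection order estimates
it. Every sample value is divided by the fitted trend at its injection
position relative to the per-feature QC *median* (more robust than
anchoring to the first QC). Between QC positions the trend is linearly
interpolated; beyond the first/last QC it is held constant rather than
extrapolated. Features with fewer than 5 usable QC values, or whose
fitted trend is non-positive anywhere, are left uncorrected and flagged —
kept, not dropped, so the QC CV filter can make the final call.

With few QC injections per batch a span-0.75 quadratic LOESS has nearly as
many effective parameters as points and approaches interpolation: QC
residuals, and hence post-correction QC CVs, become very small. This is a
known property of QC-anchored correction at low QC density, not evidence
that the biological samples are noise-free; the biological replicate CV is
the honest repeatability measure.

### Dose–response screening

Treatment groups are defined by (experiment, dose). Before testing, a
value below 1% of its treatment-group median is excluded — at most one
per group, the smallest when several qualify (a deterministic,
conservative tie-break) — to remove integration dropouts that would
otherwise destroy a monotone rank pattern. The group median is computed
over all values including the candidate; a singleton group can never lose
its value.

Each feature is then tested by Spearman rank correlation against dose
(two-sided, $t$ approximation; doses are heavily tied so an exact p-value
is unavailable, and because the statistic is rank-based, raw doses and
ordinal dose ranks give identical results). Benjamini–Hochberg adjustment
is applied *within one analytical mode and one analysis run* — modes are
separate datasets throughout, so they form separate adjustment families
(a single family across modes is one flag away). A feature is significant
at $|r_s| > 0.7$ and $q < 0.05$.

Three views are produced: per-experiment results; a consolidation that
matches significant features across experiments by mass (±15 ppm) and
retention time (±0.2 min) and keeps those significant in at least two
experiments *with a consistent direction* (a feature "up" in one
experiment and "down" in another is a disagreement, not a replication;
such conflicts are recorded, not reported); and a joint analysis that
scales each experiment to its control-group mean — so the experiments
share a unit and their control means map to 1 — pools all control-scaled
values and runs a single Spearman + BH pass. Note that pooling sharpens
p-values (three times the sample size) but does not inflate $|r_s|$
itself; with tied dose groups the attainable $|r_s|$ is in fact bounded
below 1 even for perfectly monotone data.

### Annotation scoring

A feature matches a reference compound through up to four components, each
scored by a linear tolerance ramp $100 \cdot \max(0, 1 - |e|/t)$: mass
error against 15 ppm, retention-time error against 0.2 min, mean relative
isotope-abundance deviation against 25%, and isotope-spacing deviation
against 5 mDa. The composite is the weight-normalized mean over the
*available* components with weights 100 (mass), 60 (isotope abundance),
50 (isotope spacing), 20 (RT). A match is accepted when at least two of
three criteria hold: mass within tolerance, RT within tolerance,
composite > 70%. The ramp shape and the isotope tolerances are this
package's own definitions (vendor scoring functions are not public); they
are the simplest monotone forms consistent with "score above 70%"
semantics, and all of them are config fields. MSI identification levels
are bookkeeping derived from the evidence type (level 1 for an authentic
standard with RT and MS/MS, level 2 for a spectral-library match), never
computed from spectra.

## The synthetic-data generator

No public raw dataset accompanies this kind of organoid experiment, so the
package ships a generator whose defaults encode the study design the
pipeline targets, and whose planted truth makes every stage testable:

* **Design**: 5 biological replicates vs 3 ECM blanks per mode for the
  blank-filter experiment; 4 dose groups (0/1/10/100 µM) × 5 replicates ×
  3 experiments plus blanks and interleaved QCs for the dose experiment.
* **Noise**: multiplicative log-normal with $\sigma$ chosen so the CV
  matches the target (peak areas are positive and right-skewed, and the
  log2 t-test presupposes approximate log-normality). Per-feature CVs are
  drawn uniformly from 0.07–0.35, the range seen across protocols and
  modes in this kind of data. QC injections use a lower technical CV
  (default 0.08): they are re-injections of one pool, so only instrument
  variance applies.
* **Classes**: cell-derived features get a biological/blank mean ratio at
  least 1.25× beyond the 1.2 threshold (ECM-enriched 1.25× below 0.8),
  with an additional log-uniform spread up to 4× — the margin keeps
  recovery well-posed at $n = 5$ vs $3$, and the spread makes the planted
  population heterogeneous rather than a point mass at the threshold.
* **Drift**: a smooth multiplicative function of injection order — linear
  plus one sine term by default (amplitude 0.3) — deliberately *not* a
  LOESS realization, so the correction is tested against a shape it did
  not assume. QCs are injected 1 per 5 analytical injections plus
  bracketing QCs at batch start and end.
* **Dose response**: a small fraction (default 5% of cell-derived
  features, split up/down) gets multiplicative expected-abundance factors
  (1, 1.3, 1.8, 2.5) along the dose series; down-regulated features use
  the reciprocal. Dropouts — values pushed below 1% of their group median
  — are injected at rate 0.01 to exercise the outlier rule.
* **QC composition**: the mean over all biological and blank expected
  channels, mirroring how a QC pool is made from leftover extract of all
  samples including blanks.

The generator emulates the *statistical* structure the analysis assumes:
log-normal replicate noise, multiplicative drift, planted mean ratios,
monotone dose effects. It does not emulate correlated features (adducts,
isotopologues, in-source fragments of one compound), retention-time
shifts between batches, heteroscedastic detector saturation, or missing
values from true absence. Tests passing on generated data therefore
demonstrate that the implementation does what the model says — not that
the model captures everything real data will do.

## Numerical choices and degenerate inputs

* Thresholds are strict where stated strictly: FC exactly 1.2 is not
  retained; QC CV exactly 20% *is* removed (the rule is "≥ 20%").
* A Welch test with zero variance in both groups returns p = 1 for equal
  means (no evidence of difference) and 0 otherwise; fewer than two
  usable values in either group makes a feature untestable rather than
  an error.
* BH adjustment uses the standard step-up with cumulative-minimum
  monotonicity, capped at 1; `NA` p-values pass through.
* CVs use the sample (n−1) standard deviation on the raw scale.
* Percentages in summaries are rounded half-up to one decimal.
* List overlaps are Jaccard ($100\,|A\cap B|/|A\cup B|$) by default,
  switchable to the overlap coefficient — the definition is stated
  because published overlap percentages rarely say which one they used.
* Cross-experiment feature matching is greedy in mass order against
  running group means (±15 ppm, ±0.2 min), with nearest-mass tie-break;
  deterministic and adequate at the hit-list sizes involved (tens of
  features), though not a globally optimal assignment.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at the design scale
of the emulated study or modestly below it: blank-filter recovery on
1000 features × (5 vs 3) replicates over 20 simulated batches; drift
correction on 300 features with 30% linear drift; null calibration of
the dose–response screen on 50 batches of 200 features; oracle
equivalence of every statistical primitive on 1000 random small
instances.

## Known limitations

* Single-batch correction only: no batch-to-batch anchoring or
  internal-standard normalization.
* The pipeline starts at exported feature tables; peak picking, adduct
  grouping and EIC curation are upstream concerns.
* MS/MS spectral matching against public libraries is out of scope; the
  composite score covers accurate mass, RT and isotope envelope only.
* Joint analysis aligns features by `feature_id` and so requires tables
  from one extraction batch (or pre-matched ids); only the consolidation
  step does tolerance-based cross-table matching.
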