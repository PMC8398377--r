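---
title: "Statistical methods behind radmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind radmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmetab)
```

# The problem

`radmetab` implements the complete statistical workflow for discovering
plasma metabolite biomarkers of abdominal radiation injury in a nonhuman
primate (NHP) study design: two cohorts, doses of 0 (sham), 8, 11, 12.5 and
14 Gy, and plasma sampled on days −5/−1 (timepoint group TP1,
pre-exposure), 9/10 (TP2), 28/29 (TP3) and 59/60 (TP4). Untargeted LC-MS
profiling of such a design yields a samples × metabolites intensity matrix
with left-censored missingness, a two-level pathway annotation
(subpathway nested in superpathway), and a metadata table of design
factors. Downstream questions are of two kinds: *within a dose arm, what
changed over time relative to baseline?* (TP1 vs TP2/TP3/TP4), and *at a
fixed timepoint, what differs between sham and irradiated animals?*
(0 Gy vs each dose).

Because female arms of the motivating design are small, all statistics
default to the male samples (`sex_filter = "M"`); the filter is applied
before any other computation.

# Preprocessing

The pipeline enforces one fixed order, each stage tagged on the matrix so
stages cannot be applied out of sequence:

1. **Volume normalization** — intensities divided by each sample's plasma
   volume. Units are relative; only between-sample ratios matter.
2. **Missingness filter** — metabolites not detected in *strictly more
   than* 20% of samples are removed (`max_missing_fraction = 0.20`;
   a metabolite missing in exactly 20% is retained). The denominator is
   all loaded samples, before any subsetting, so the background is filtered
   once per study.
3. **Log transformation** — natural log by default. The base shifts
   log-scale statistics by a constant and changes neither p-values nor VIP;
   it is recorded on the matrix and configurable.
4. **Minimum-value imputation** — each remaining missing entry is replaced
   by that metabolite's minimum observed (logged) value, the conventional
   stand-in for intensities below a detection limit. Imputation never
   invents a value outside the observed per-metabolite range.

# Univariate screen

For each contrast, per metabolite:

* **Fold change**: the ratio of the two group means. By default means are
  taken on the volume-normalized, unlogged scale (arithmetic means), which
  is recoverable exactly from the imputed matrix by inverting the recorded
  log base; a geometric-mean variant (`fc_scale = "log"`) is available.
  The threshold of 2 is applied two-sidedly: a metabolite passes when
  FC > 2 or FC < 0.5, i.e. |log2 FC| > 1.
* **Welch's two-sample t-test** (two-sided, Satterthwaite df) on the
  logged, imputed values. Degenerate inputs follow fixed conventions: two
  constant equal groups give t = 0, p = 1; two constant but different
  groups give p = 0 with a `degenerate` flag — no jitter is injected.
* **Benjamini–Hochberg adjustment** across metabolites within the
  contrast.

Imputed values participate in both the fold change and the test, matching
a workflow that imputes before analysis. Significance counts are reported
twice per contrast — FC with raw p, and FC with BH q — mirroring the
usual headline table of such studies. A one-way ANOVA across all timepoint
groups within a dose arm (`anova_timepoints()`) is provided as a secondary
screen; the pairwise Welch contrasts are the primary path because they are
the ones with fully stated parameters.

# Latent-variable models

**PCA** (`fit_pca()`) supports qualitative inspection of group separation.
Columns are mean-centered and unit-variance scaled by default
(autoscaling, the metabolomics norm — every metabolite contributes equally
regardless of intensity scale); component signs are fixed by making each
component's largest-magnitude loading positive, so results are
reproducible.

**OPLS-DA** (`fit_oplsda()`) is implemented from scratch as a NIPALS-style
orthogonal projection: for a two-class problem with centered 0/1 class
coding, components of X-variation *uncorrelated* with the class vector are
extracted and deflated one at a time, then a single predictive PLS
component is fit on the filtered matrix. With zero orthogonal components
the model reduces exactly to one-component PLS1-DA (this equivalence is a
test invariant at 1e-8). Orthogonal scores have zero sample covariance
with the class vector by construction.

* **Number of orthogonal components** is chosen by forward selection:
  start at 0, add components while cross-validated Q² improves by more
  than 0.01, cap at 3. A subtlety worth knowing: on noisy autoscaled data
  a single orthogonal component almost always buys a small genuine Q² gain
  by filtering the dominant finite-sample noise direction, so the selector
  returns 0 mainly when residual noise is small relative to the class
  signal.
* **Cross-validation**: stratified k-fold with centering/scaling refit on
  each training split. Q² = 1 − PRESS/TSS on the centered class vector.
  The fold rule: 10-fold when the smaller class has ≥ 10 members, 5-fold
  when it has ≥ 5, otherwise leave-one-out; a split that would leave a
  single-class training set falls back to leave-one-out with a warning.
  Folds are keyed to sample ids, so Q² is invariant to row order.
* **CV-ANOVA**: an F-test comparing cross-validated residuals to the
  intercept-only residuals, charging the model one degree of freedom per
  component (A = 1 + K): F = ((TSS − PRESS)/A)/(PRESS/(n − 1 − A)). When
  PRESS ≥ TSS the statistic is floored at 0 and p = 1; the test is
  therefore conservative under the null (much of the null mass sits at
  p = 1), which is the safe direction for a validation guard.
* **Permutation test**: class labels are permuted (default 100 times), the
  model refit and cross-validated per permutation, and add-one p-values
  reported for both R²Y and Q²: p = (1 + #{permuted ≥ observed})/(1 + n).
  The Q²-based p-value is the headline. A permutation that reproduces the
  original labels still counts toward the numerator.
* **Validation** (`validate_oplsda()`): a model is *validated* when the Q²
  permutation p < 0.05 and Q² > 0. Both thresholds are configurable; no
  standard definition exists, and these are deliberately mild guards
  against overfitting rather than quality scores.

**VIP** uses the predictive component only — the component that carries
class separation — so for one predictive component VIP_j reduces to
√M·|w_j|/‖w‖ and the squared VIPs average exactly 1. VIP > 1 marks
metabolites contributing more than an average variable.

# Subpathway enrichment

Given the significant set of a contrast (two-sided FC and Welch p) and the
background of retained metabolites, each subpathway with at least 5 tested
members gets exact hypergeometric tail probabilities: P(X ≥ k) for
over-enrichment and P(X ≤ k) for under-enrichment, both including the
point mass at k. A subpathway is significant when the smaller tail is
below 0.05. No correction across subpathways is applied by default (a BH
flag exists); the raw threshold matches the workflow the package
reproduces. Metabolites absent from the annotation are dropped with a
warning and reported in an unannotated bucket; subpathways below the size
threshold are listed separately rather than silently discarded.

# Composite selection and the confounder filter

A metabolite is a biomarker candidate for a contrast when it passes
*every* criterion: |log2 FC| > 1, Welch p < 0.05, VIP > 1 from the
contrast's validated OPLS-DA model, and membership in a subpathway with
≥ 5 tested metabolites and enrichment p < 0.05. Every rejected metabolite
carries the list of criteria that removed it. Unannotated metabolites can
never be selected.

Sham animals drift over time too, so a metabolite flagged in the 0 Gy arm
between TP1 and TPk reflects time, not radiation. The **confounder
filter** subtracts these sham markers (and analogously sham-enriched
subpathways) from the corresponding TP1-vs-TPk selection of each
irradiated arm. Two design choices here:

* The filter applies at *every* irradiated dose, not only the well-powered
  ones; the dose list follows the contrast grid.
* Sham markers are identified by the **univariate rule** (FC and Welch p)
  by default, not the full composite rule. The sham arm of this design has
  5–6 male samples per timepoint; requiring a permutation-validated
  supervised model on so few samples frequently empties the sham marker
  set and would silently disable the filter exactly when drift is present.
  "Differentially abundant in the sham arm" is the univariate notion, and
  it keeps the filter active. `sham_filter_basis = "composite"` restores
  the stricter behavior.

Dose-vs-sham contrasts at a fixed timepoint do not receive the filter: the
sham group is already the comparator. Filtering is idempotent, and
post-filter selections are always subsets of pre-filter selections. Venn
partitions of the post-filter sets are reported per axis (time contrasts
within each dose; dose contrasts within each timepoint), kept separate
rather than unioned across axes.

# The synthetic cohort generator

`simulate_cohort()` generates data with recoverable ground truth under the
motivating design, so every stage of the pipeline is testable without any
external data.

* **Design**: per-(dose, day, sex, cohort) sample counts default to the
  published sampling table — 200 plasma samples, 150 of them male, with
  days grouped into TP1..TP4. Subject ids follow the repeated-measures
  layout (the k-th sample per day within an arm belongs to subject k), and
  subject-level random intercepts (sd 0.15 on the log scale) are included,
  although the downstream tests deliberately ignore pairing, as the
  univariate screen does.
* **Baselines**: per-metabolite log-normal, log-mean drawn from
  N(10, 1) — right-skewed positive intensities typical of untargeted
  LC-MS.
* **Planted effects**: 50 of 696 metabolites carry a signed log2 fold
  change drawn from ±Uniform(1.3, 3), scaled multiplicatively on the log
  scale by a dose–response factor (0, 0.5, 0.8, 1, 1 for 0–14 Gy) and a
  time profile peaking at TP2 and decaying at TP3/TP4 (0, 1, 0.5, 0.25) —
  the qualitative pattern of a radiation response with partial recovery.
* **Sham drift**: 20 further metabolites shift with the time profile at
  *every* dose including sham (|log2 FC| 1.5 at the peak), giving the
  confounder filter a nontrivial known truth. Affected and drift sets are
  disjoint by construction.
* **Pathway coherence**: affected and drift metabolites are sampled as
  blocks of at least 5 members within subpathways (whole subpathways plus
  at most two partial blocks). Radiation dysregulates pathways coherently,
  and a generator that scattered single metabolites across subpathways
  would make the enrichment criterion of the composite rule unsatisfiable
  by construction rather than by evidence.
* **Missingness**: left-censoring at a per-metabolite empirical intensity
  quantile (detection-limit behavior, matching the minimum-value
  imputation downstream), not missing-completely-at-random; an MCAR
  mechanism exists behind a flag. By default 118 metabolites — drawn
  disjoint from the affected and drift sets, so the filter exercises
  no planted truth — are censored at the 0.25 quantile and the rest at
  0.05, so the 20% missingness filter removes approximately (and with the
  default panel, exactly) the near-detection-limit subset.
* **Noise**: i.i.d. log-scale noise with sd 0.4, a realistic biological
  CV for plasma metabolomics.

What the generator does *not* emulate: raw spectra, retention times, batch
or instrument drift beyond the cohort label, correlated metabolite
modules, and heavy-tailed or metabolite-specific noise. Passing tests on
synthetic data therefore demonstrate that the statistical machinery is
correct and that the workflow recovers planted truth under its stated
assumptions — not that those assumptions hold for any particular real
dataset.

# Numerical conventions

* Class coding 0/1, centered; class calls threshold predictions at 0.5.
* PCA/OPLS-DA component signs fixed by the largest-loading convention.
* Zero-variance metabolites are an error under autoscaling (they carry no
  information and cannot be scaled); constant-group degeneracies in the
  Welch test follow the exact conventions above.
* All randomness — design volumes, baselines, effects, fold assignment,
  permutations — is derived from explicit seeds; two runs of
  `run_full_pipeline()` with the same master seed produce byte-identical
  output files.

# Problem sizes in the test suite

The packaged tests run the full 200-sample, 696-metabolite pipeline once
(100 permutations per contrast, about half a minute) and use reduced
cohorts — two dose arms, 120–150 metabolites, 10–40 permutations — for the
remaining end-to-end properties. Null-calibration checks use 2,000 null
metabolites for the Welch screen and 200 replicate OPLS-DA fits at 50
permutations for the permutation-p calibration; these sizes give stable
Kolmogorov–Smirnov checks while keeping the suite quick.

# Known limitations

* No repeated-measures modelling: samples are treated as independent in
  all tests, as in the workflow the package reproduces; subject intercepts
  planted by the generator therefore act as (mild) extra noise.
* No batch correction across cohorts; the two-cohort label exists in the
  design only.
* The CV-ANOVA null distribution is conservative (see above); use the
  permutation test as the primary validation evidence.
* The sham arm's small size bounds the confounder filter's sensitivity:
  with 5–6 samples per timepoint a drift marker has a non-negligible
  chance of missing the sham fold-change cutoff, so a small fraction of
  drift can leak through the filter at any given seed.
* Enrichment assumes exactly one subpathway per metabolite; multi-mapped
  annotations must be resolved upstream.
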