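---
title: "Methods: the ditpqsar pipeline, its assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ditpqsar pipeline, its assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ditpqsar)
```

`ditpqsar` builds and audits binary QSAR classifiers for drug-induced
immune thrombocytopenia (DITP). This vignette explains the statistical
procedure, the parameters that matter, the synthetic data the tests rely
on, and the places where the design was genuinely open and a choice had to
be made.

## The modeling procedure and its assumptions

The pipeline treats toxicity prediction as supervised binary
classification on structure-derived features. Its core assumptions are the
standard QSAR ones: molecules with similar substructure/descriptor
profiles have similar toxicity; the labeled dataset is a representative
sample of the chemical space where predictions will be made (which is why
an explicit applicability domain is part of the pipeline rather than an
afterthought); and labels, derived from antibody assays, are trustworthy
but the dataset is small — hence repeated cross-validation and a
consensus option rather than a single split.

The stages are strictly ordered and each fits only on training data:

1. featurization (fingerprints, descriptors, imported tables),
2. descriptor streamlining + min–max normalization (fit on the training
   portion, applied to held-out data with clipping),
3. SMOTE rebalancing of the *training folds only*,
4. classifier fitting and scoring,
5. metric aggregation over 5 folds × 10 repeats,
6. applicability-domain fitting in the selected model's normalized feature
   space,
7. information-gain alert mining on a binary fragment block.

## Tunable parameters

| parameter | default | unit / range | rationale |
|---|---|---|---|
| `train_fraction` | 0.8 | fraction | the study design's 8:2 split |
| CV geometry | 5 folds × 10 repeats | — | small-dataset variance control |
| `corr_threshold` | 0.95 | abs. Pearson r | drop near-duplicate descriptors |
| `extreme_limit` | 1e8 | magnitude | operationalizes "extreme values" (no published threshold exists) |
| SMOTE `k_neighbors` | 5 | neighbors | canonical SMOTE setting |
| SMOTE `target_ratio` | 1.0 | minority/majority | full balance, standard usage |
| AD `percentile` | 0.95 | quantile | the conventional 95 % domain threshold |
| alert `min_occurrences` | 7 | count | "more than six occurrences", read strictly |
| hard-label threshold | 0.5 | score | no calibration is attempted |

Hyperparameter grids (overridable in `default_grids()`): SVM C ∈
{0.1, 1, 10, 100}; k-NN k ∈ {1, 3, 5, 7, 9}; random forest 50–500 trees ×
{sqrt, log2} feature sampling at depth 4; ANN hidden layer ∈ {50, 100,
200}; AdaBoost 50–500 estimators; XGBoost depth 3–6 × min child weight
{1, 3, 5}; naive Bayes at provider defaults. The published source of these
grids is an appendix that is not available, so the values above are
conventional mid-range grids; they are configuration, not constants.

## Feature providers and substitutions

Chemistry is served by OpenBabel (through ChemmineR/ChemmineOB and the
`obabel` CLI). Consequences worth knowing:

* **MACCS** comes from OpenBabel's MACCS SMARTS definitions, truncated
  from its padded 256-bit storage to the 166 published keys.
* **The 881-bit fingerprint** follows the public PubChem/CACTVS
  *sectioning* — element counts (bits 0–114), ring counts/types
  (115–262), bonded element pairs (263–326), substructure patterns
  (327–880). Sections 1–3 are computed structurally from the formula, SSSR
  ring statistics and the bond table. The pattern sections are driven by
  the SMARTS catalog shipped in `inst/extdata/pubchem_patterns.tsv`, which
  covers the commonly hit organic keys; bits without a catalog entry are
  deterministically 0, and a fuller (or official) bit-indexed catalog can
  be dropped in via `catalog_path`. Ring perception is SSSR, not the
  extended ESSSR of the original toolkit. The fingerprint is therefore
  layout-faithful and deterministic but **not bit-exact** against PubChem's
  own values — adequate for the pipeline's modeling and mining logic,
  which only assumes a fixed-width informative binary representation.
* **Descriptors.** The classic 13-descriptor set includes three quantities
  whose original provider is proprietary. Substitutes: aqueous solubility
  via the Delaney ESOL linear model (logS from logP, MW, rotatable bonds,
  aromatic proportion); logD7.4 by AlogP (deliberately collinear — the
  correlation filter then removes it, mirroring the known 13 → 10
  reduction); molecular surface area from van der Waals sphere areas with
  spherical-cap corrections at each bond — a coarse but deterministic
  3D-free estimate. The extended set is the open provider's full scalar
  list plus structural counts (46 columns); its width is recorded at run
  time rather than forced to any legacy provider's count.
* **Klekota–Roth, CDK, ExtFP, AP2D and bioactivity-signature blocks** are
  defined by external tools and enter via `load_feature_table()` (CSV) or
  `smarts_block()` (any SMARTS catalog); they are not reimplemented
  bit-exactly.
* **Hashed fingerprints** are OpenBabel FP2 linear-path 1024-bit vectors,
  OR-folded to a requested power-of-two width.

## Numerical choices, tie-breaks and degenerate inputs

* **Split arithmetic.** Per-class training counts follow the
  largest-remainder rule on `train_fraction * n_class`, with total seats
  fixed at the rounded overall training size. For a 93/132 dataset at 0.8
  this gives 74 + 106 = 180; the historical 75/105 allocation is *not*
  derivable from any standard rounding, so `per_class_counts` exists to
  reproduce published splits exactly.
* **Correlation filter tie-break:** of a pair with |r| > 0.95, the later
  column in block order is dropped (greedy scan in column order) — the
  choice is arbitrary but order-deterministic, so reruns are identical.
* **Min–max on held-out data** clips to [0, 1] and counts the clips;
  extrapolation outside the training range is never used.
* **Tanimoto of two all-zero fingerprints** is defined as 1 (absence of
  all features is maximal agreement); real data never hits this case.
* **MCC with a zero denominator factor** is reported as 0 with a
  `degenerate_mcc` flag; SE/SP are NA-with-flag when a class is absent.
* **AUC** uses the Mann–Whitney rank formulation with ties counted 0.5.
* **Entropy** is base-2 with 0·log 0 = 0; information gain is clipped at 0
  against floating-point cancellation (≈ −1e−16).
* **AD distances** are computed in the per-query difference form rather
  than the expanded quadratic form so that self-matches give exactly 0;
  training coverage is therefore exactly 100 % by construction. The
  boundary is inside (≤). A centroid-distance variant is available behind
  `method = "centroid"`.
* **SMOTE** reduces `k` with a warning when the minority class is smaller
  than `k + 1`, and refuses a minority class of one.
* **Single-heavy-atom molecules** (water, bare ions) have no usable SDF
  container representation; scalar properties for them come from the same
  OpenBabel engine via its CLI, and structural counts are 0 by definition.
* **AdaBoost** is authored in-package (discrete AdaBoost.M1 on depth-1
  rpart stumps, logistic link on the boosted margin) since no installed
  package provides it; the neural-network family uses nnet's quasi-Newton
  optimizer with the hidden-size grid (the optimizer differs from a plain
  SGD solver; the adapter contract deliberately fixes only the
  model family and its tuned capacity, not the optimizer brand).

## Design choices that were genuinely open

* **Where SMOTE and preprocessing are fit.** The strict reading — refit
  both inside every CV fold — is the default, because fitting them on the
  full training set before folding leaks held-out information into the CV
  estimate. A compatibility flag (`refit_per_fold = FALSE`) reproduces the
  looser protocol.
* **Alert-mining scope.** The occurrence filter (> 6) is applied over the
  full dataset by default (`scope = "full"`), matching how fragment
  statistics are normally quoted; `scope = "train"` restricts mining to
  the training set.
* **Whether streamlining touches fingerprint bits.** By default it does
  not (the filters target descriptor redundancy); `drop_constant_bits`
  optionally removes zero-variance bits.
* **Ranking ties** in model selection resolve by mean MCC, then mean ACC,
  then lexicographic model label — a total order, so `select_top()` is
  deterministic.

## The synthetic-data generator

`synthetic_spec()` defaults describe the study conditions: 225 molecules
at positive fraction 0.41 (the 93/225 imbalance, so the SMOTE path is
always exercised), a 200-bit fragment block with three planted alert bits
at presence probabilities 0.8 (toxicants) / 0.1 (non-toxicants) over a 0.1
background rate, and ten unit-variance Gaussian descriptors whose
toxicant-class means are shifted by 1.5 sd. The generator returns ground
truth (planted bit ids, their theoretical enrichment from the
fragment-frequency formula at expected counts, pre-noise labels) so
parameter-recovery tests are one-liners.

What it emulates: class imbalance, sparse informative binary features,
correlated-with-class continuous features, label noise. What it does not:
real substructure correlation between fragments (bits are independent
given the class), descriptor-descriptor correlation structure, and any
actual chemistry. Passing tests on synthetic data therefore demonstrate
that the machinery is correct and recovers known signal — not that the
fingerprints carry DITP information; that claim can only come from real
labeled data.

Problem sizes in the test-suite and acceptance script were chosen to keep
a full run in the tens-of-seconds range on one CPU: n = 300 molecules and
200 fragment bits for recovery checks, 100 seeded repetitions for the
alert-recovery rate, 1000 random columns for the entropy-oracle
comparison, 500 instances for the AUC oracle. These sizes are stated here
as the package's reference conditions; all of them scale up by argument.

## Known limitations

* The 881-bit fingerprint's pattern sections are as good as the bundled
  catalog; bits without entries never fire. Mining alerts on it will rank
  only covered substructures.
* The descriptor substitutes (ESOL solubility, AlogP-for-logD, vdW surface
  estimate) are open approximations; absolute values differ from
  proprietary providers even when rankings broadly agree.
* Euclidean AD treats all normalized features equally; with mixed
  binary+continuous blocks the binary bits dominate distances in high
  dimension. Fitting the AD in the model's own representation (the
  default) keeps this consistent with what the classifier sees.
* Fragment-frequency alert statistics ignore the spatial arrangement of
  fragments and interactions between co-occurring alerts.
* k-NN probability scores are vote fractions and therefore coarse; AUC on
  small external sets has correspondingly wide ties.
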