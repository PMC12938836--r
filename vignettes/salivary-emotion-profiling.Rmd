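---
title: "Salivary biomarker profiling of fragrance-induced emotions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salivary biomarker profiling of fragrance-induced emotions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivemo)
```

This vignette is the package's own account of the science it implements:
the measurement model, the statistical procedures, the synthetic cohort
that stands in for clinical data, and the numerical choices made where the
design was genuinely open. No empirical claim is made here beyond what the
package's tests and scripts themselves compute.

## The measurement model

Four salivary analytes are measured per sample: alpha-amylase activity
(sAA, U/mL), a fast surrogate of sympathetic activation; cortisol (CRT,
pg/mL), the end-product of HPA-axis activation; dehydroepiandrosterone
(DHEA, pg/mL), an adrenal steroid with anti-glucocorticoid,
resilience-linked effects; and oxytocin (OXT, pg/mL), a neuropeptide tied
to social and affiliative processing. Together they span arousal, stress,
resilience and affiliation — four axes along which emotional states that
share valence can still differ.

Saliva is collected at three points around an olfactory stimulation: S1
five minutes before, S2 five minutes after, and S3 twenty minutes after.
Baseline levels vary widely between people (the packaged defaults carry
the morning pre-stimulation means: sAA 176.1 U/mL, CRT 2076.2 pg/mL, DHEA
427.2 pg/mL, OXT 171.1 pg/mL, with their SEMs), so all downstream analysis
works on within-person post/pre ratios, S2/S1 and S3/S1. Ratios cancel the
individual baseline and the measurement unit; their logarithm treats up-
and down-regulation symmetrically, which is why clustering operates on
log2 ratios while the discretization below operates on the raw ratio
scale, where the published cut points live.

## Discretization and the 81-profile lattice

The assay noise floor — a mean coefficient of variation near 10 % — sets
the width of the indifference band: a ratio below 0.9 is *decreased*,
above 1.1 *increased*, and the closed interval [0.9, 1.1] is *stable*.
The boundary values themselves are deliberately mapped to *stable*
(a literal reading of the published band; the choice only matters on a
measure-zero set but must be fixed for reproducibility). An exposure's
four states form one of 3⁴ = 81 discrete profiles, encoded in base 3 with
decreased = 0, stable = 1, increased = 2 and sAA as the most significant
digit (`encode_profile()` / `decode_profile()` are exact inverses). Both
cut points are configurable (`discretization_thresholds()`).

## Clustering

Per fragrance, participants' log2 S2/S1 4-vectors are clustered. The
deterministic workhorse is `hkmeans_fit()`: Ward's minimum-variance
agglomeration on squared Euclidean distances, cut at *k*, whose cluster
means seed Lloyd iterations refined by Hartigan-style single-point
exchange passes (the exact, size-weighted within-SS move criterion) and,
for up to 64 points, pairwise-swap passes. Plain Lloyd converges to
Voronoi fixed points, but the globally optimal within-SS partition need
not be one — a point can sit nearer a neighbouring centroid and still be
optimally placed once the size correction n/(n±1) is accounted for — so
the exchange refinement is what lets small instances actually reach the
optimum. For very small groups (at most 20 points and at most 20,000
candidate partitions) `hkmeans_fit()` skips the heuristic entirely and
enumerates all partitions, guaranteeing the global optimum
deterministically. `kmeans_fit()` is the randomised counterpart (best of
`n_restarts` seeded starts) and is validated in the test suite against
exhaustive-partition enumeration on every instance with n ≤ 8, k ≤ 3.

The cluster count maximises the Calinski–Harabasz index
CH(k) = (B/(k−1)) / (W/(n−k)), with B the between- and W the
within-cluster sum of squares (B + W equals the total sum of squares, a
conservation the tests check to 1e−9). Ties resolve to the smaller k.
`recursive_subcluster()` reapplies selection and splitting inside each
cluster while a group keeps at least 2·`min_size` points and the depth
limit is not reached; degenerate groups (fewer than three distinct
points) become leaves. Defaults in the analysis scripts: `min_size` 5,
`max_depth` 2, `k_range` 2–6 — sized for ~59 participants per fragrance.

Cluster emotion responsiveness uses the reporting fraction with cuts at
one and two thirds: *low* below 1/3, *high* above 2/3, *moderate* in the
closed interval between. The published wording is ambiguous about the
boundary (strict in the text, inclusive in the figure caption); the
closed moderate interval was chosen and is asserted exactly in the tests.
"Reporting" an emotion means a valence of at least 1 on the 0–2 scale —
the scale calls 0 its lowest valence, so any positive report counts; the
cut is configurable (set 2 for strongly-felt-only analyses) and is shared
with the CART labels.

## CART over discrete states

`fit_cart()` grows a binary classification tree over the four 3-state
features by greedy Gini splits: at each node all three binary subset
partitions of each analyte's states are scored (categorical subsets, not
ordinal thresholds, so "decreased or increased vs stable" is
expressible), and the split maximising the impurity decrease wins. Ties
resolve by the fixed analyte order (sAA, CRT, DHEA, OXT), then the
lexicographically smallest left subset — determinism over elegance.
Growth stops at `min_split` 20, `min_bucket` 7, `max_depth` 30; the grown
tree is pruned by weakest-link cost-complexity pruning with the link
strength scaled by the root's misclassification risk and threshold
`cp` 0.01. These defaults mirror the conventional recursive-partitioning
tool the field uses, since no parameters are published; all are exposed.
Leaf class is the majority label with ties negative (a conservative
default: absent evidence, no emotion is claimed).

`extract_rules()` converts a fitted tree into the explicit subset of the
81 codes its positive leaves cover; the equivalence "code in rule set ⇔
tree predicts positive" holds exactly for every fitted tree and is
asserted over the full lattice in the tests. Metrics are resubstitution
(training-set) sensitivity/specificity — the reporting convention of the
original analysis; no held-out protocol is implied. Evaluation against
the generator's noise-free ground truth (rather than the noisy training
labels) is what the recovery tests use, since with symmetric label noise
at rate ε even a perfectly recovered rule scores only about 1−ε against
the noisy labels.

## Fragrance signatures, the IAT, and concordance

A fragrance's signature is, per emotion, the percentage of its exposed
participants whose discrete profile lies in that emotion's rule set —
exact set membership, no smoothing. The implicit association test is
scored from go/no-go records with three presentations per emotion:
Go-percent is 100·clicks/(3·participants); the strength of association is
the mean over go trials of 100·(window − latency)/window with a 1500 ms
window. **This strength formula is a package convention**: the published
scores come with no formula, so a transparent linear speed score was
chosen and flagged; any monotone transform of latency would preserve the
rank-based concordance analysis. Strength categories are percentiles
within a fragrance across its emotions (excellent > 80th, good > 50th,
else low), matching the per-fragrance colouring of the original figure;
the percentile is computed as 100·(rank−1)/(n−1).

Concordance between the molecular signature and each IAT measure is
Spearman's rank correlation; for up to 8 emotions the two-sided p-value
is exact by full permutation enumeration (valid under ties), beyond that
a t approximation is used. Valuation analysis groups ratings 1–2/3–4/5–6
into high/medium/low hedonic groups and compares per-analyte S2/S1 ratios
with Kruskal–Wallis and pairwise Wilcoxon tests (exact small-sample
distributions where the base implementations provide them), adjusted by
Benjamini–Hochberg step-up across the full analyte × comparison family.

## The synthetic cohort

No raw clinical data are distributable, so `generate_cohort()` simulates
cohorts with the statistical structure the analysis assumes; it is the
package's test bed, not a claim about any real population. Its defaults
are the main study's conditions: 59 participants × 4 fragrances (F2–F5),
morning sessions starting uniformly between 09:00 and 11:30, panels at
session start, +10 and +25 minutes (S1/S2/S3 around a stimulation at
+5 min).

* **Baselines** are log-normal per participant with the packaged means
  and SDs. The published "±" values are read as SEMs of the n = 30
  morning cohort, so the per-participant SD is SEM·√30 — ±6.5 U/mL on a
  mean of 176.1 would otherwise be an implausibly tight population SD
  for a quantity with broad inter-individual variability.
* **Circadian drift** follows geometric (log-linear) level curves
  anchored at 09:00: CRT and DHEA decline at 6 % per 30 min, OXT at 3 %
  (its diurnal effect is modest), and sAA is flat through the morning,
  rising at 6 % per 30 min after midday — the opposite diurnal pattern.
  Geometric rather than linear segments are used so the relative change
  over *any* interval of at most 30 minutes is bounded by the configured
  rate, not just intervals anchored at 09:00. Each session additionally
  scales its drift slope by a mean-one log-normal factor (sdlog 0.15),
  giving realistic between-person diurnal variability while preserving
  the ~6 % population-mean bound — the quantity `scripts/acceptance.R`
  recomputes.
* **Phenotypes.** Each exposure draws a latent response phenotype; the
  default palette mirrors the recurring cluster types: *happy_relaxed*
  (sAA/CRT/DHEA log2 shifts −0.35, OXT +0.40), *happy_dynamised*
  (sAA/CRT/DHEA −0.80, OXT −0.05), *comforted* (sAA −0.20, CRT +0.40,
  DHEA 0, OXT +0.40) and a *non_responder* (no shift). Shifts apply at
  S2 and, attenuated by 0.5, at S3 — the S3 magnitude is not published,
  so the attenuation is an explicit config knob, not a claim. Emotion
  valences (0–2) and 1–6 valuations are emitted from per-phenotype
  probability tables; phenotypes with decreased sAA and increased OXT
  lean toward poor ratings, emulating the observed valuation
  association.
* **Noise.** Every measurement is multiplied by mean-one log-normal
  noise with CV 0.10 (positivity and multiplicative error are what CV-
  characterised immunoassays motivate).
* **IAT.** Three presentations per emotion; whether an exposure "feels"
  an emotion is drawn from its phenotype's positive-valence probability;
  felt emotions click with probability 0.85 at log-normal latencies
  around 600 ms, unfelt with 0.20 around 950 ms (sdlog 0.25); latencies
  at or beyond the 1500 ms window become no-gos.

What the generator deliberately does **not** emulate: storage/stability
degradation, assay-kit differences, inter-day baseline drift within a
participant, missing data, and any correlation between phenotypes across
fragrances for the same participant (each exposure draws independently).
Passing recovery tests on this cohort therefore shows the pipeline
recovers structure of this known form at realistic noise — not that real
cohorts contain such structure.

## Determinism and numerics

Everything stochastic is seeded: the generator from `config$seed`, the
IAT from seed + 1, k-means restarts from seed + 2 in the pipeline.
Floating-point ties in the split search and CH selection are broken by
fixed documented orders. The B + W decomposition and the rule/tree
equivalence are asserted to 1e−9 and exactly, respectively. Problem sizes
in the tests and scripts — 1000 trajectories for the drift check, 100
random datasets for the CART oracle, the n ≤ 8 clustering battery, a
236-exposure recovery cohort — were chosen as the smallest sizes at which
the corresponding Monte-Carlo or enumeration argument is convincing.

## Known limitations

* The strength-of-association formula is a convention (see above); only
  rank-based comparisons of strengths should be interpreted.
* Resubstitution metrics overstate out-of-sample performance by design;
  use the exposed controls to run cross-validated variants if needed.
* The published cohort-dependent numbers (specific cluster memberships,
  per-emotion sensitivities, fragrance percentages, IAT scores) are not
  reproducible without the clinical dataset; the package reproduces the
  design arithmetic, the method's behaviour under controlled synthetic
  conditions, and the published bounds (profile count, drift bound).
* Four participants in the original design smelled only some fragrances;
  readers of partial datasets keep such exposures and
  `validate_design()` flags them, leaving exclusion to each stage.
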