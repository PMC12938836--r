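# salivemo

Decoding fragrance-induced emotions from salivary biomarker panels.

Olfactory stimuli trigger fast neuroendocrine responses that are measurable
in saliva. This package implements a complete analysis pipeline that turns
pre/post-stimulation measurements of four salivary analytes — alpha-amylase
(sAA, sympathetic arousal), cortisol (CRT, HPA axis), dehydroepiandrosterone
(DHEA, resilience) and oxytocin (OXT, social affiliation) — into molecular
emotional profiles, and validates them against self-report questionnaires and
an implicit association test (IAT). It is aimed at psychophysiology and
sensory-science researchers who collect saliva at a baseline (S1, −5 min) and
after stimulation (S2, +5 min; S3, +20 min) and want an objective,
rule-based readout of the emotional response.

## The method

1. **Ratio normalisation.** Each exposure's post-stimulation panel is
   expressed relative to its own baseline, `r_a = x_a(S2) / x_a(S1)` per
   analyte *a*, removing inter-individual level differences and units.
2. **Discretization.** Using the assay coefficient of variation (~10 %) as a
   noise band, each ratio becomes *decreased* (r < 0.9), *stable*
   (0.9 ≤ r ≤ 1.1) or *increased* (r > 1.1), so an exposure maps to one of
   3⁴ = 81 discrete biomarker profiles.
3. **Clustering.** Per fragrance, log2 ratio 4-vectors are grouped by
   hierarchical k-means (Ward seeding, Hartigan-refined Lloyd iterations)
   with the cluster count chosen by the Calinski–Harabasz index
   CH = (B/(k−1))/(W/(n−k)), applied recursively to subclusters. Cluster
   emotion responsiveness is graded low (<33 %), moderate (33–66 %) or high
   (>66 % reporting).
4. **CART.** Per emotion, a classification tree over the four discrete
   states (binary Gini splits over categorical state subsets, rpart-style
   stopping and cost-complexity pruning) predicts whether the emotion was
   felt; positive leaves are expanded into explicit profile-code rule sets
   and scored by sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP).
5. **Signatures and concordance.** Applying each emotion's rule set per
   fragrance yields its molecular emotional signature (percent of exposed
   participants matching); IAT Go-percent and strength-of-association are
   scored per emotion, and the two profile types are compared by Spearman
   rank correlation with exact permutation p-values.
6. **Valuation.** S2/S1 ratios are compared across hedonic rating groups
   (1–2 high, 3–4 medium, 5–6 low) with Kruskal–Wallis and pairwise
   Wilcoxon tests under Benjamini–Hochberg correction.

Because the underlying clinical dataset is not public, the package ships a
synthetic cohort generator (`generate_cohort()`) that reproduces the study
design — 59 participants × 4 fragrances × 3 timepoints = 708 panels over
236 exposures — with log-normal baselines, a circadian drift bounded at
~6 % per 30 morning minutes, latent emotion-linked phenotypes that shift
log2 ratios, and ~10 % multiplicative assay noise. Every stage is tested
against independent oracles (exhaustive partition enumeration for
clustering, exhaustive subset search for CART splits, brute-force
permutation nulls for the statistics).

## Worked example

```r
library(salivemo)

cfg <- generator_config(seed = 1)        # 59 participants, F2-F5
cohort <- generate_cohort(cfg)
validate_design(cohort$samples)
#> Saliva sampling design: 59 participants x 4 fragrances
#>   236 participant-fragrance combinations, 708 biomarker panels
#>   complete design (every exposure sampled at S1, S2, S3)

ratios <- compute_ratios(cohort$samples, "S2/S1")
profiles <- discretize_ratios(ratios)

lab <- emotion_labels(cohort$emotions, "dynamised")
dat <- dplyr::inner_join(profiles, lab, by = c("participant_id", "fragrance_id"))
tree <- fit_cart(dat, dat$label)
tree
#> CART over discrete biomarker states: n = 236, 4 leaves
#> dhea in {decreased}? (n = 236)
#>   oxt in {decreased,stable}? (n = 152)
#>     saa in {decreased}? (n = 65)
#>       * positive leaf: 42/53 positive (79%), coverage 22%
#>       * negative leaf: 3/12 positive (25%), coverage 5%
#>     * negative leaf: 33/87 positive (38%), coverage 37%
#>   * negative leaf: 16/84 positive (19%), coverage 36%
evaluate_cart(tree, dat, dat$label)
#> confusion: TP 42  FP 11  TN 131  FN 52
#> sensitivity 0.447  specificity 0.923  accuracy 0.733
```

The tree reads as an explicit physiological rule: exposures with decreased
DHEA, decreased or stable oxytocin and decreased sAA form the leaf in which
79 % of participants reported feeling dynamised (22 % of the cohort), while
non-decreased DHEA argues against the emotion. `extract_rules(tree)`
expands the positive leaves into the exact set of discrete profiles (here 6
of the 81) for downstream fragrance profiling.

The full analysis — simulation through signatures, concordance and
valuation — lives in `analysis/01_simulate.R` … `analysis/05_profile.R`;
each script is a thin narrative driver over the package functions and
writes its tables under `results/`. The same stages can be run in one call
with `run_pipeline(pipeline_config(generator = generator_config(seed = 1)))`.

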