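#!/usr/bin/env Rscript
# Stage 5 -- fragrance signatures, IAT scoring, concordance and valuation.
#
# The per-emotion CART rule sets are applied fragrance by fragrance to
# obtain molecular emotional signatures (percent of exposed participants
# matching each emotion's profile set); the implicit association test is
# scored (Go-percent and strength of association); the two profile types
# are compared by Spearman rank concordance; and S2/S1 ratios are
# analysed across the 1-6 valuation groups.

suppressPackageStartupMessages({
  library(salivemo)
  library(dplyr)
})

profiles <- readr::read_csv("results/profiles.csv", show_col_types = FALSE)
rules_tbl <- readr::read_csv("results/rules.csv", show_col_types = FALSE)
emotions <- read_emotions("results/data/emotions.csv")
iat <- read_iat("results/data/iat.csv")
valuation <- read_valuation("results/data/valuation.csv")
ratios <- readr::read_csv("results/ratios.csv", show_col_types = FALSE) |>
  filter(horizon == "S2/S1")

rules <- lapply(split(rules_tbl$code, rules_tbl$emotion), function(codes) {
  structure(list(codes = as.integer(codes)), class = "emotion_rule_set")
})

fragrances <- sort(unique(profiles$fragrance_id))
signatures <- purrr::map_dfr(fragrances,
                             function(f) fragrance_signature(rules, profiles, f))
iat_profiles <- purrr::map_dfr(fragrances, function(f) score_iat(iat, f))
conc <- purrr::map_dfr(fragrances, function(f) {
  concordance(filter(signatures, fragrance_id == f),
              filter(iat_profiles, fragrance_id == f))
})

readr::write_csv(signatures, "results/signatures.csv")
readr::write_csv(iat_profiles, "results/iat_profiles.csv")
readr::write_csv(conc, "results/concordance.csv")

cat("fragrance emotional signatures (% of participants matching rules):\n")
print(as.data.frame(tidyr::pivot_wider(signatures[, c("fragrance_id",
                                                      "emotion", "percent")],
                                       names_from = "emotion",
                                       values_from = "percent")))
cat("\nbiomarker-vs-IAT rank concordance (Spearman, exact permutation p):\n")
print(as.data.frame(conc))

va <- valuation_analysis(valuation, ratios)
readr::write_csv(va$summary, "results/valuation_summary.csv")
readr::write_csv(va$pairwise, "results/valuation_tests.csv")
cat("\nmean S2/S1 ratios by valuation group:\n")
print(as.data.frame(tidyr::pivot_wider(va$summary,
                                       names_from = "analyte",
                                       values_from = "mean_ratio",
                                       id_cols = "group")))
cat("\nKruskal-Wallis across valuation groups:\n")
print(as.data.frame(va$kruskal))
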