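#!/usr/bin/env Rscript
# Stage 3 -- per-fragrance clustering of log2 S2/S1 ratio profiles.
#
# For each fragrance, recursive hk-means (Ward-seeded k-means with
# Calinski-Harabasz model selection) groups participants by the shape of
# their biomarker response; each cluster's emotion responsiveness is then
# categorised as low (<33%), moderate (33-66%) or high (>66% reporting).

suppressPackageStartupMessages({
  library(salivemo)
  library(dplyr)
})

ratios <- readr::read_csv("results/ratios.csv", show_col_types = FALSE) |>
  filter(horizon == "S2/S1")
emotions <- read_emotions("results/data/emotions.csv")

assignments <- list(); profiles <- list()
for (f in sort(unique(ratios$fragrance_id))) {
  sub <- filter(ratios, fragrance_id == f)
  rs <- recursive_subcluster(sub[, paste0("log2_", ANALYTES)],
                             min_size = 5, max_depth = 2, k_range = 2:6)
  assignments[[f]] <- tibble::tibble(participant_id = sub$participant_id,
                                     fragrance_id = f,
                                     cluster = paste0(f, rs$leaf))
  profiles[[f]] <- profile_clusters(assignments[[f]], emotions)
  cat(sprintf("%s: %d clusters, sizes %s\n", f,
              n_distinct(rs$leaf),
              paste(sort(table(rs$leaf), decreasing = TRUE), collapse = ", ")))
}

clusters <- bind_rows(assignments)
cluster_profiles <- bind_rows(profiles)
readr::write_csv(clusters, "results/clusters.csv")
readr::write_csv(cluster_profiles, "results/cluster_profiles.csv")

cat("\nhigh-responsiveness cluster-emotion pairs:\n")
cluster_profiles |>
  filter(level == "high") |>
  arrange(desc(fraction)) |>
  as.data.frame() |>
  print()
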