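#!/usr/bin/env Rscript
# Stage 2 -- post/pre ratios and discrete biomarker profiles.
#
# Each exposure's S2 and S3 panels are expressed relative to its own S1
# baseline; S2/S1 ratios are discretized with the assay-CV band
# (<0.9 decreased, 0.9-1.1 stable, >1.1 increased) into one of the 81
# discrete biomarker profiles.

suppressPackageStartupMessages(library(salivemo))

samples <- read_samples("results/data/samples.csv")

ratios_s2 <- compute_ratios(samples, "S2/S1")
ratios_s3 <- compute_ratios(samples, "S3/S1")
readr::write_csv(dplyr::bind_rows(ratios_s2, ratios_s3), "results/ratios.csv")

profiles <- discretize_ratios(ratios_s2)
readr::write_csv(profiles, "results/profiles.csv")

cat(sprintf("computed %d S2/S1 and %d S3/S1 ratio profiles\n",
            nrow(ratios_s2), nrow(ratios_s3)))
cat(sprintf("distinct discrete profiles observed: %d of %d possible\n",
            dplyr::n_distinct(profiles$code), nrow(enumerate_profiles())))
cat("\nstate distribution per analyte (S2/S1):\n")
for (a in ANALYTES) {
  print(table(profiles[[paste0("state_", a)]]))
}
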