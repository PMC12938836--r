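#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# 59 participants each smell four fragrances (F2-F5) in morning sessions;
# saliva panels (sAA, cortisol, DHEA, oxytocin) are drawn 5 min before and
# 5 / 20 min after stimulation, with circadian drift, latent emotional
# phenotypes shifting the post/pre ratios, ~10% assay noise, questionnaire
# valences, 1-6 valuations, and a go/no-go implicit association test.

suppressPackageStartupMessages(library(salivemo))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = 1)
cohort <- generate_cohort(cfg)
iat <- generate_iat(cohort$latent, cfg)

write_samples(cohort$samples, file.path(out, "samples.csv"))
write_emotions(cohort$emotions, file.path(out, "emotions.csv"))
write_valuation(cohort$valuation, file.path(out, "valuation.csv"))
write_iat(iat, file.path(out, "iat.csv"))
readr::write_csv(cohort$latent, file.path(out, "latent_assignments.csv"))

design <- validate_design(cohort$samples)
print(design)
cat("\nlatent phenotype mix:\n")
print(table(cohort$latent$phenotype))
cat(sprintf("\n%d IAT records (%d exposures x %d emotions x 3 presentations)\n",
            nrow(iat), nrow(cohort$latent),
            length(unique(iat$emotion))))
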