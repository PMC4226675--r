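#!/usr/bin/env Rscript
# Build the synthetic study cohorts every later step consumes:
#  - a default cohort (100 tumors + 20 normals, anticorrelated AR/NF-kB
#    programs, GSK3 tracking AR, NF-kB-dependent hazard)
#  - the same cohort with two planted outlier chips for the QC step.
# Writes expression/metadata/truth under results/data/.

suppressPackageStartupMessages(library(arnfkb))

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

clean <- simulate_cohort(sim_config(seed = seed))
write_cohort(clean, "results/data/cohort_clean")

outliers <- data.frame(sample = c("T005", "N003"), shift = 2.0)
dirty <- simulate_cohort(sim_config(outlier_chips = outliers, seed = seed))
write_cohort(dirty, "results/data/cohort_outliers")

tr <- clean$truth$activity
cat(sprintf("cohort: %d genes x %d samples; latent AR/NF-kB correlation %.3f\n",
            nrow(clean$expression$values), ncol(clean$expression$values),
            cor(tr$ar, tr$nfkb)))
cat(sprintf("planted outlier chips: %s (shift +2.0 log2)\n",
            paste(dirty$truth$outlier_chips, collapse = ", ")))
cat("written to results/data/\n")
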