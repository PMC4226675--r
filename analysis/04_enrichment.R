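#!/usr/bin/env Rscript
# Gene-set enrichment with a phenotype-permutation null: is the NF-kB
# target program depleted in high-AR-signature tumors, and is the derived
# AR-repressed target set depleted in high-GSK3 tumors?
# Writes results/enrichment.tsv and results/derived_set.gmt.

suppressPackageStartupMessages(library(arnfkb))

seed <- 1L
md <- read_metadata_tsv("results/data/cohort_clean/metadata.tsv")
roles <- setNames(md$role, md$sample_id)
em <- read_expression_tsv("results/data/cohort_clean/expression.tsv", roles)
truth <- jsonlite::read_json("results/data/cohort_clean/truth.json",
                             simplifyVector = TRUE)

z <- zscore_vs_reference(em)
ar_labels <- stratify_extremes(
  summed_zscore(z, gene_set("AR_signature", truth$ar_genes)), 1 / 3)

nfkb <- gene_set("NFKB_targets", truth$nfkb_genes)
enr_ar <- permutation_test(em, ar_labels, nfkb, n_permutations = 1000,
                           seed = seed)
cat("NF-kB targets in high-vs-low AR tumors:\n")
print(enr_ar)

derived <- derive_repressed_targets(enr_ar,
                                    name = "AR_repressed_NFkB_targets")
cat(sprintf("derived set: %d genes, precision vs planted program %.2f\n",
            length(derived$genes),
            mean(derived$genes %in% truth$nfkb_genes)))
write_gmt(derived, "results/derived_set.gmt")

gsk3_labels <- classify_dual_threshold(z)
enr_gsk3 <- permutation_test(em, gsk3_labels, derived,
                             n_permutations = 1000, seed = seed + 1L)
cat("derived set in high-vs-low GSK3 tumors:\n")
print(enr_gsk3)

write.table(
  data.frame(contrast = c("high_vs_low_AR", "high_vs_low_GSK3"),
             set = c(nfkb$name, derived$name),
             es = c(enr_ar$es, enr_gsk3$es),
             nes = c(enr_ar$nes, enr_gsk3$nes),
             p_nominal = c(enr_ar$p_nominal, enr_gsk3$p_nominal),
             n_permutations = 1000,
             leading_edge = c(length(enr_ar$leading_edge$genes),
                              length(enr_gsk3$leading_edge$genes))),
  "results/enrichment.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("written results/enrichment.tsv, results/derived_set.gmt\n")
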