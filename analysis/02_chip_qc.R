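#!/usr/bin/env Rscript
# Chip quality control on the cohort with planted outlier arrays: RLE per
# chip, 1.5-IQR fences, and the discard decision. Expects 01_simulate.R to
# have run. Writes results/chip_qc.tsv.

suppressPackageStartupMessages(library(arnfkb))

md <- read_metadata_tsv("results/data/cohort_outliers/metadata.tsv")
roles <- setNames(md$role, md$sample_id)
em <- read_expression_tsv("results/data/cohort_outliers/expression.tsv",
                          roles)

rle <- compute_rle(em)
report <- iqr_flag(rle)
print(report)

truth <- jsonlite::read_json("results/data/cohort_outliers/truth.json",
                             simplifyVector = TRUE)
cat(sprintf("planted: %s | flagged: %s | exact match: %s\n",
            paste(truth$outlier_chips, collapse = ","),
            paste(report$flagged, collapse = ","),
            setequal(report$flagged, truth$outlier_chips)))

dir.create("results", showWarnings = FALSE)
write.table(
  data.frame(sample_id = names(rle), rle = rle,
             flagged = names(rle) %in% report$flagged),
  "results/chip_qc.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cleaned <- apply_qc(em, report)
cat(sprintf("kept %d of %d chips\n", ncol(cleaned$values), ncol(em$values)))
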