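#!/usr/bin/env Rscript
# Survival analysis: split tumors at the median of the derived-set summed
# Z-score and compare the groups with the log-rank test at the 100- and
# 220-month horizons. Writes results/survival.tsv and KM curves.

suppressPackageStartupMessages(library(arnfkb))

md <- read_metadata_tsv("results/data/cohort_clean/metadata.tsv")
roles <- setNames(md$role, md$sample_id)
em <- read_expression_tsv("results/data/cohort_clean/expression.tsv", roles)

derived <- read_gmt("results/derived_set.gmt")[[1]]
z <- zscore_vs_reference(em)
scores <- summed_zscore(z, derived)
grp <- group_by_signature(scores, "median")

rec <- data.frame(
  time = md$time_months[match(names(grp), md$sample_id)],
  event = md$event[match(names(grp), md$sample_id)],
  group = unname(grp))

rows <- lapply(c(100, 220), function(h) {
  lr <- logrank_test(rec, horizon_months = h)
  print(lr)
  data.frame(horizon_months = h, chi_square = lr$chi_square, df = lr$df,
             p_value = lr$p_value, n_events = lr$n_events)
})
write.table(do.call(rbind, rows), "results/survival.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

km_rows <- do.call(rbind, lapply(c("high", "low"), function(g) {
  km <- km_estimate(rec$time[rec$group == g], rec$event[rec$group == g])
  data.frame(group = g, time = km$time, surv = km$surv)
}))
write.table(km_rows, "results/km_curves.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("written results/survival.tsv, results/km_curves.tsv\n")
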