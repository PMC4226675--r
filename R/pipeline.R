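#' Configuration for the orchestrated analysis pipeline
#'
#' @param qc run chip QC (RLE + IQR fences) before anything else.
#' @param qc_k IQR fence multiplier.
#' @param reference_role role of the Z-score reference group.
#' @param stratify_fraction fraction of tumors per AR-signature extreme.
#' @param gsk3_hi,gsk3_lo dual-threshold cutoffs for the GSK3 classes.
#' @param weight enrichment running-sum exponent.
#' @param n_permutations phenotype permutations per enrichment test.
#' @param min_overlap minimum gene-set/list overlap.
#' @param survival_rule `"median"` or `"threshold"` split for survival
#'   groups.
#' @param survival_threshold cut point when `survival_rule = "threshold"`.
#' @param horizons log-rank truncation horizons in months.
#' @param use_packaged_set use the packaged 29-gene repressed-target set
#'   for the GSK3 contrast and survival instead of the set derived from
#'   this cohort's AR contrast.
#' @param seed integer seed for the permutation tests.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(qc = TRUE, qc_k = 1.5,
                            reference_role = "normal",
                            stratify_fraction = 1 / 3,
                            gsk3_hi = 0.5, gsk3_lo = -0.5,
                            weight = 1, n_permutations = 1000,
                            min_overlap = 5,
                            survival_rule = "median",
                            survival_threshold = 0,
                            horizons = c(100, 220),
                            use_packaged_set = FALSE,
                            seed = 1L) {
  structure(list(qc = qc, qc_k = qc_k, reference_role = reference_role,
                 stratify_fraction = stratify_fraction,
                 gsk3_hi = gsk3_hi, gsk3_lo = gsk3_lo, weight = weight,
                 n_permutations = n_permutations, min_overlap = min_overlap,
                 survival_rule = survival_rule,
                 survival_threshold = survival_threshold,
                 horizons = horizons, use_packaged_set = use_packaged_set,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full tumor-expression analysis chain
#'
#' QC -> reference Z-scores -> AR-signature stratification -> enrichment
#' of the NF-kB target set in high-vs-low-AR tumors -> derivation of the
#' AR-repressed NF-kB target set from the negative leading edge ->
#' enrichment of that derived set in high-vs-low-GSK3 tumors -> log-rank
#' survival comparison of tumors split by the derived-set summed Z-score,
#' at each configured horizon. A stage that cannot run aborts with its
#' name. Identical inputs, config and seed give an identical report.
#'
#' @param em an [expression_matrix()] (tumors plus reference normals).
#' @param metadata data.frame with sample_id, role, time_months, event
#'   (survival fields used for tumors only); `NULL` skips survival.
#' @param ar_set AR-signature [gene_set()].
#' @param nfkb_set NF-kB target [gene_set()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all artifacts (scores,
#'   labels, derived GMT, running sums, JSON report) are written there.
#' @return a `run_report` list with per-stage summaries; see details in
#'   the package vignette.
#' @export
run_pipeline <- function(em, metadata, ar_set, nfkb_set,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(em, "expr_mat"), inherits(config, "pipeline_config"),
            inherits(ar_set, "gene_set"), inherits(nfkb_set, "gene_set"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }
  report <- list(config = unclass(config), stages = list())

  # --- chip QC ---------------------------------------------------------
  if (isTRUE(config$qc)) {
    qc <- stage("chip_qc", iqr_flag(compute_rle(em), k = config$qc_k))
    em <- stage("chip_qc", suppressMessages(apply_qc(em, qc)))
    report$stages$chip_qc <- list(
      metric = qc$metric_name, k = qc$k,
      lower_fence = qc$lower_fence, upper_fence = qc$upper_fence,
      discarded = as.list(qc$flagged), n_discarded = length(qc$flagged))
  } else {
    report$stages$chip_qc <- list(skipped = TRUE)
  }

  # --- Z-scores and AR stratification ----------------------------------
  z <- stage("zscore", zscore_vs_reference(em, config$reference_role))
  ar_scores <- stage("ar_score", summed_zscore(z, ar_set))
  ar_labels <- stage("ar_stratify",
                     stratify_extremes(ar_scores, config$stratify_fraction))
  report$stages$ar_stratification <- list(
    signature = ar_set$name,
    n_genes_used = ar_scores$n_genes_used,
    missing_genes = as.list(ar_scores$missing_genes),
    rule = ar_labels$rule,
    group_sizes = as.list(table(ar_labels$per_sample_label)))

  # --- NF-kB enrichment in high-vs-low AR ------------------------------
  nfkb_enr <- stage("nfkb_enrichment", permutation_test(
    em, ar_labels, nfkb_set,
    n_permutations = config$n_permutations, weight = config$weight,
    seed = config$seed, min_overlap = config$min_overlap))
  report$stages$nfkb_enrichment <- enr_summary(nfkb_enr)

  # --- derived AR-repressed NF-kB target set ---------------------------
  derived <- stage("derive_repressed", {
    if (isTRUE(config$use_packaged_set)) {
      ar_repressed_nfkb_targets()
    } else {
      derive_repressed_targets(nfkb_enr, name = "AR_repressed_NFkB_targets")
    }
  })
  report$stages$derived_set <- list(
    name = derived$name, n_genes = length(derived$genes),
    source = if (isTRUE(config$use_packaged_set)) "packaged" else "derived",
    genes = as.list(derived$genes))

  # --- GSK3 contrast ---------------------------------------------------
  gsk3_labels <- stage("gsk3_classify", classify_dual_threshold(
    z, hi = config$gsk3_hi, lo = config$gsk3_lo))
  report$stages$gsk3_classification <- list(
    rule = gsk3_labels$rule,
    group_sizes = as.list(table(gsk3_labels$per_sample_label)))
  gsk3_enr <- stage("gsk3_enrichment", permutation_test(
    em, gsk3_labels, derived,
    n_permutations = config$n_permutations, weight = config$weight,
    seed = config$seed + 1L, min_overlap = config$min_overlap))
  report$stages$gsk3_enrichment <- enr_summary(gsk3_enr)

  # --- survival by derived-set score -----------------------------------
  if (!is.null(metadata)) {
    surv <- stage("survival", {
      dscore <- summed_zscore(z, derived)
      grp <- group_by_signature(dscore, rule = config$survival_rule,
                                threshold = config$survival_threshold)
      md <- metadata[match(names(grp), metadata$sample_id), ]
      rec <- data.frame(time = md$time_months, event = md$event,
                        group = unname(grp))
      rec <- rec[is.finite(rec$time), ]
      lapply(config$horizons, function(h) logrank_test(rec, h))
    })
    report$stages$survival <- lapply(surv, function(lr) list(
      horizon_months = lr$horizon_months,
      chi_square = lr$chi_square, df = lr$df, p_value = lr$p_value,
      group_sizes = as.list(lr$group_sizes), n_events = lr$n_events))
    names(report$stages$survival) <-
      paste0("horizon_", config$horizons, "m")
  } else {
    report$stages$survival <- list(skipped = TRUE)
  }

  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    write_run_artifacts(report, out_dir, ar_scores, ar_labels,
                        derived, nfkb_enr, gsk3_enr)
  }
  report
}

enr_summary <- function(x) {
  list(set_name = x$set_name, es = x$es, nes = x$nes,
       p_nominal = x$p_nominal, n_permutations = x$n_permutations,
       n_hits = x$n_hits, direction = x$direction, seed = x$seed,
       leading_edge_size = length(x$leading_edge$genes))
}

write_run_artifacts <- function(report, out_dir, ar_scores, ar_labels,
                                derived, nfkb_enr, gsk3_enr) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(sample_id = names(ar_scores$per_sample_score),
               summed_z = ar_scores$per_sample_score,
               label = ar_labels$per_sample_label[
                 names(ar_scores$per_sample_score)]),
    file.path(out_dir, "ar_signature_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(derived, file.path(out_dir, "derived_set.gmt"))
  utils::write.table(
    data.frame(position = seq_along(nfkb_enr$running_sum),
               running_sum = nfkb_enr$running_sum),
    file.path(out_dir, "nfkb_running_sum.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_report(report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Write a run report as JSON
#' @param report a `run_report` from [run_pipeline()].
#' @param path output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  s <- x$stages
  if (!is.null(s$chip_qc$n_discarded)) {
    cat(sprintf("  chip QC: %d discarded\n", s$chip_qc$n_discarded))
  }
  cat(sprintf("  AR stratification: high=%s low=%s\n",
              s$ar_stratification$group_sizes$high,
              s$ar_stratification$group_sizes$low))
  cat(sprintf("  NF-kB enrichment in high-vs-low AR: es=%.3f p=%.4g\n",
              s$nfkb_enrichment$es, s$nfkb_enrichment$p_nominal))
  cat(sprintf("  derived set (%s): %d genes\n",
              s$derived_set$source, s$derived_set$n_genes))
  cat(sprintf("  GSK3 contrast: es=%.3f p=%.4g\n",
              s$gsk3_enrichment$es, s$gsk3_enrichment$p_nominal))
  if (is.null(s$survival$skipped)) {
    for (h in s$survival) {
      cat(sprintf("  log-rank at %g months: chi-square=%.3f p=%.4g\n",
                  h$horizon_months, h$chi_square, h$p_value))
    }
  }
  invisible(x)
}
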