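#' Z-scores of tumor expression against a reference group
#'
#' For every gene, the tumor value is centred on the reference-group mean
#' and scaled by the reference standard deviation (denominator n - 1). The
#' reference defaults to samples with role `"normal"`; if the cohort has
#' none, the cohort-wide mean/sd is used with a loud warning. Genes with
#' zero reference sd are dropped with a warning.
#'
#' @param em an [expression_matrix()].
#' @param reference_role role providing the reference distribution.
#' @return numeric matrix, genes x tumors, of Z-scores.
#' @export
zscore_vs_reference <- function(em, reference_role = "normal") {
  stopifnot(inherits(em, "expr_mat"))
  ref_ids <- samples_of(em, reference_role)
  tum_ids <- samples_of(em, "tumor")
  if (length(ref_ids) == 0) {
    warning("no '", reference_role,
            "' samples: falling back to cohort-wide mean/sd reference")
    ref_ids <- colnames(em$values)
  }
  if (length(ref_ids) < 2) stop("need >= 2 reference samples")
  ref <- em$values[, ref_ids, drop = FALSE]
  m <- rowMeans(ref)
  s <- sqrt(rowSums((ref - m)^2) / (ncol(ref) - 1))
  ok <- s > 0
  if (!all(ok)) {
    warning(sprintf("dropped %d gene(s) with zero reference sd", sum(!ok)))
  }
  (em$values[ok, tum_ids, drop = FALSE] - m[ok]) / s[ok]
}

#' Summed Z-score of a gene signature per tumor
#'
#' The per-tumor sum of Z-scores over the signature genes present in the
#' matrix; absent genes are recorded, not imputed.
#'
#' @param z gene x tumor Z matrix from [zscore_vs_reference()].
#' @param signature a [gene_set()].
#' @return a `signature_scores` object: `signature` (name),
#'   `per_sample_score` (named numeric), `n_genes_used`, `missing_genes`.
#' @export
summed_zscore <- function(z, signature) {
  stopifnot(is.matrix(z), inherits(signature, "gene_set"))
  present <- intersect(signature$genes, rownames(z))
  if (length(present) == 0) {
    stop("no gene of signature '", signature$name, "' present in matrix")
  }
  score <- colSums(z[present, , drop = FALSE])
  structure(list(
    signature = signature$name,
    per_sample_score = score,
    n_genes_used = length(present),
    missing_genes = setdiff(signature$genes, present)
  ), class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("<signature_scores> %s: %d samples, %d/%d genes used\n",
              x$signature, length(x$per_sample_score), x$n_genes_used,
              x$n_genes_used + length(x$missing_genes)))
  invisible(x)
}

#' Stratify tumors by extreme summed Z-scores
#'
#' The top `ceiling(fraction * n)` tumors by score are labelled `high`, the
#' bottom as many `low`, the remainder `unclassified`. Ties at a cut are
#' broken by sample id order; if `2 * ceiling(fraction * n) > n` (odd n at
#' fraction 0.5) the low group is shrunk so the groups stay disjoint.
#'
#' @param scores a `signature_scores` object.
#' @param fraction fraction of tumors per extreme, in (0, 0.5].
#' @return a `strat_labels` object: `per_sample_label` (named character in
#'   high/low/unclassified) and `rule` (description).
#' @export
stratify_extremes <- function(scores, fraction = 1 / 3) {
  stopifnot(inherits(scores, "signature_scores"))
  if (!(fraction > 0 && fraction <= 0.5)) {
    stop("fraction must be in (0, 0.5]")
  }
  s <- scores$per_sample_score
  n <- length(s)
  if (n < 4) stop("need >= 4 scored tumors")
  k <- ceiling(fraction * n)
  k_low <- min(k, n - k)
  ids <- names(s)
  desc <- ids[order(-s, ids)]
  asc <- ids[order(s, ids)]
  lab <- stats::setNames(rep("unclassified", n), ids)
  lab[desc[seq_len(k)]] <- "high"
  lab[asc[seq_len(k_low)]] <- "low"
  structure(list(
    per_sample_label = lab,
    rule = sprintf("extremes of summed Z-score '%s', fraction=%.4g (high n=%d, low n=%d)",
                   scores$signature, fraction, k, k_low)
  ), class = "strat_labels")
}

#' Classify tumors by dual Z-score thresholds on two genes
#'
#' A tumor is `high` when both genes exceed `hi`, `low` when both fall
#' below `lo`, otherwise `unclassified`; inequalities are strict. Defaults
#' implement the GSK3 rule: both isoform Z-scores above 0.5 for high, both
#' below -0.5 for low.
#'
#' @param z gene x tumor Z matrix.
#' @param gene_a,gene_b the two gene symbols (default GSK3A, GSK3B).
#' @param hi,lo upper and lower thresholds.
#' @return a `strat_labels` object.
#' @export
classify_dual_threshold <- function(z, gene_a = "GSK3A", gene_b = "GSK3B",
                                    hi = 0.5, lo = -0.5) {
  stopifnot(is.matrix(z))
  gene_a <- toupper(gene_a); gene_b <- toupper(gene_b)
  miss <- setdiff(c(gene_a, gene_b), rownames(z))
  if (length(miss) > 0) {
    stop("gene(s) absent from Z matrix: ", paste(miss, collapse = ", "))
  }
  za <- z[gene_a, ]; zb <- z[gene_b, ]
  lab <- rep("unclassified", ncol(z))
  lab[za > hi & zb > hi] <- "high"
  lab[za < lo & zb < lo] <- "low"
  structure(list(
    per_sample_label = stats::setNames(lab, colnames(z)),
    rule = sprintf("dual threshold on %s & %s: high if both Z > %g, low if both Z < %g",
                   gene_a, gene_b, hi, lo)
  ), class = "strat_labels")
}

#' @export
print.strat_labels <- function(x, ...) {
  tab <- table(factor(x$per_sample_label,
                      levels = c("high", "low", "unclassified")))
  cat(sprintf("<strat_labels> high=%d low=%d unclassified=%d (%s)\n",
              tab["high"], tab["low"], tab["unclassified"], x$rule))
  invisible(x)
}
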