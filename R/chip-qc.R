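#' Relative log expression (RLE) per chip
#'
#' For each chip, the median over genes of the deviation of that chip's
#' log2 value from the gene-wise median across chips. Chips from a clean
#' batch sit near 0; a chip whose whole distribution is shifted shows an
#' RLE near its shift.
#'
#' @param em an [expression_matrix()] (log2 scale).
#' @return named numeric vector, one RLE value per chip.
#' @export
compute_rle <- function(em) {
  stopifnot(inherits(em, "expr_mat"))
  v <- em$values
  if (ncol(v) < 3) stop("RLE needs >= 3 chips")
  gene_med <- apply(v, 1, stats::median)
  apply(v - gene_med, 2, stats::median)
}

#' Flag outlier chips by 1.5-IQR fences
#'
#' Chips whose metric lies more than `k` interquartile ranges above the
#' upper quartile or below the lower quartile are flagged for discard.
#' Quartiles use linear interpolation between order statistics (R type 7);
#' values exactly on a fence are not flagged.
#'
#' @param metrics named numeric vector (e.g. from [compute_rle()]).
#' @param k fence multiplier, default 1.5.
#' @param metric_name label recorded in the report.
#' @return a `qc_report`: list with `per_chip_metric`, `lower_fence`,
#'   `upper_fence`, `flagged` (sample ids), `metric_name`, `k`.
#' @export
iqr_flag <- function(metrics, k = 1.5, metric_name = "RLE") {
  if (length(metrics) < 3) stop("need >= 3 chip metrics")
  if (is.null(names(metrics))) stop("metrics must be named by sample id")
  q <- stats::quantile(metrics, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  flagged <- names(metrics)[metrics < lower | metrics > upper]
  structure(list(
    per_chip_metric = metrics, lower_fence = lower, upper_fence = upper,
    flagged = flagged, metric_name = metric_name, k = k
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %s over %d chips; fences [%.3f, %.3f]; flagged: %s\n",
    x$metric_name, length(x$per_chip_metric), x$lower_fence, x$upper_fence,
    if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Discard flagged chips from an expression matrix
#'
#' @param em an [expression_matrix()].
#' @param report a `qc_report` from [iqr_flag()].
#' @return the matrix without flagged chips; discarded ids are messaged.
#' @export
apply_qc <- function(em, report) {
  stopifnot(inherits(em, "expr_mat"), inherits(report, "qc_report"))
  ids <- colnames(em$values)
  if (!all(report$flagged %in% ids)) {
    stop("flagged ids not present in matrix: ",
         paste(setdiff(report$flagged, ids), collapse = ", "))
  }
  keep <- setdiff(ids, report$flagged)
  roles_kept <- em$roles[keep]
  if (sum(roles_kept == "tumor") < 2) {
    stop("QC would leave fewer than 2 tumors")
  }
  if (any(em$roles == "normal") && !any(roles_kept == "normal")) {
    stop("QC would empty the reference (normal) group")
  }
  if (length(report$flagged) > 0) {
    message("QC discarded chips: ", paste(report$flagged, collapse = ", "))
  }
  expression_matrix(em$values[, keep, drop = FALSE], roles_kept)
}
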