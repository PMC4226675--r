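#' Construct a transcription-factor binding-array grid
#'
#' A membrane of spotted TF binding-site probes: an intensity matrix plus a
#' spot annotation table naming, for each (row, column) position, whether
#' the spot is a TF site (with its site name), a negative control, or a
#' positive control. Sites are usually spotted in duplicate.
#'
#' @param intensity numeric matrix of spot intensities (>= 0).
#' @param annotation data.frame with columns `row`, `col`,
#'   `type` (`"site"`, `"negative_control"`, `"positive_control"`) and
#'   `site` (site name; `NA` for controls).
#' @param membrane_id identifier.
#' @param condition condition label (e.g. `"control"`, `"shGSK3B"`).
#' @return object of class `tf_array_grid`.
#' @export
tf_array_grid <- function(intensity, annotation, membrane_id = "m1",
                          condition = "control") {
  stopifnot(is.matrix(intensity), is.data.frame(annotation))
  need <- c("row", "col", "type", "site")
  if (!all(need %in% names(annotation))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (any(annotation$row < 1 | annotation$row > nrow(intensity) |
          annotation$col < 1 | annotation$col > ncol(intensity))) {
    stop("annotation positions outside grid bounds")
  }
  if (sum(annotation$type == "negative_control") < 1 ||
      sum(annotation$type == "positive_control") < 2) {
    stop("need >= 1 negative and >= 2 positive control spots")
  }
  structure(list(intensity = intensity, annotation = annotation,
                 membrane_id = membrane_id, condition = condition),
            class = "tf_array_grid")
}

#' Normalized per-site signals from one membrane
#'
#' The mean of the negative-control spots is the blank; the mean of the
#' positive-control spots minus the blank is the membrane scale. Each site
#' signal is the average over its duplicate spots of
#' `max(raw - blank, 0) / scale`, so signals are non-negative and
#' comparable across membranes regardless of exposure.
#'
#' @param grid a [tf_array_grid()].
#' @param saturation_ceiling optional intensity ceiling; errors when more
#'   than 5 percent of spots reach it (a saturated exposure).
#' @return named numeric vector of normalized signals, one per site.
#' @export
quantify_membrane <- function(grid, saturation_ceiling = NULL) {
  stopifnot(inherits(grid, "tf_array_grid"))
  ann <- grid$annotation
  val <- grid$intensity[cbind(ann$row, ann$col)]
  if (!is.null(saturation_ceiling)) {
    if (mean(val >= saturation_ceiling) > 0.05) {
      stop("membrane ", grid$membrane_id,
           ": > 5% of spots at saturation ceiling; select another exposure")
    }
  }
  blank <- mean(val[ann$type == "negative_control"])
  scale <- mean(val[ann$type == "positive_control"]) - blank
  if (scale <= 0) {
    stop("membrane ", grid$membrane_id,
         ": non-positive positive-control scale (failed membrane)")
  }
  is_site <- ann$type == "site"
  norm <- pmax(val[is_site] - blank, 0) / scale
  sites <- unique(ann$site[is_site])
  vapply(sites, function(s) mean(norm[ann$site[is_site] == s]),
         numeric(1))
}

#' Compare per-site binding between conditions
#'
#' Takes per-membrane normalized signal vectors (from
#' [quantify_membrane()]) grouped by condition, and for every site reports
#' the ratio of each condition's mean to the control mean and a two-sample
#' Student t-test across membranes; sites with p < 0.05 are flagged. At
#' least 2 membranes per condition are required.
#'
#' @param signals named list: condition -> list of per-membrane named
#'   signal vectors.
#' @param control name of the control condition.
#' @return data.frame with columns `condition`, `site`, `mean_control`,
#'   `mean_condition`, `ratio`, `p_value`, `flagged`; `ratio` is `NA` where
#'   the control mean is 0.
#' @export
compare_conditions <- function(signals, control = "control") {
  stopifnot(is.list(signals), control %in% names(signals))
  n_mem <- vapply(signals, length, 1L)
  if (any(n_mem < 2)) {
    stop("need >= 2 membranes per condition; got: ",
         paste(sprintf("%s=%d", names(n_mem), n_mem), collapse = ", "))
  }
  to_mat <- function(lst) do.call(rbind, lst)  # membranes x sites
  ctrl <- to_mat(signals[[control]])
  out <- list()
  for (cond in setdiff(names(signals), control)) {
    m <- to_mat(signals[[cond]])
    sites <- intersect(colnames(ctrl), colnames(m))
    mc <- colMeans(ctrl[, sites, drop = FALSE])
    mt <- colMeans(m[, sites, drop = FALSE])
    pv <- vapply(sites, function(s) {
      x <- m[, s]; y <- ctrl[, s]
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      }
      stats::t.test(x, y, var.equal = TRUE)$p.value
    }, numeric(1))
    out[[cond]] <- data.frame(
      condition = cond, site = sites,
      mean_control = mc, mean_condition = mt,
      ratio = ifelse(mc > 0, mt / mc, NA_real_),
      p_value = pv, flagged = pv < 0.05,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Construct a qPCR Ct table
#'
#' Long-format replicate Ct values with a designated reference
#' (housekeeping) gene and control condition.
#'
#' @param data data.frame with columns `condition`, `gene`, `ct` (one row
#'   per replicate well).
#' @param reference_gene housekeeping gene (default `"36B4"`).
#' @param control_condition baseline condition label.
#' @return object of class `ct_table`.
#' @export
ct_table <- function(data, reference_gene = "36B4",
                     control_condition = "control") {
  stopifnot(is.data.frame(data),
            all(c("condition", "gene", "ct") %in% names(data)))
  reps <- table(data$condition, data$gene)
  if (any(reps > 0 & reps < 2)) {
    stop("need >= 2 replicates per (condition, gene)")
  }
  for (cond in unique(data$condition)) {
    if (!reference_gene %in% data$gene[data$condition == cond]) {
      stop("reference gene ", reference_gene,
           " missing for condition ", cond)
    }
  }
  if (!control_condition %in% data$condition) {
    stop("control condition '", control_condition, "' absent")
  }
  structure(list(data = data, reference_gene = reference_gene,
                 control_condition = control_condition),
            class = "ct_table")
}

#' Relative fold changes by the delta-delta-Ct method
#'
#' Per condition and gene: `dCt = mean(Ct_gene) - mean(Ct_ref)`;
#' `ddCt = dCt_condition - dCt_control`; `fold = 2^-ddCt`. The replicate
#' standard deviations propagate in quadrature,
#' `s_dCt = sqrt(s_gene^2 + s_ref^2)`, and the reported range is
#' `[2^-(ddCt + s), 2^-(ddCt - s)]` using the condition's own `s_dCt`.
#'
#' @param table a [ct_table()].
#' @return data.frame with columns `condition`, `gene`, `dct`, `sd_dct`,
#'   `ddct`, `fold`, `fold_lo`, `fold_hi`.
#' @export
ddct_fold_change <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  d <- table$data
  agg <- stats::aggregate(ct ~ condition + gene, data = d,
                          FUN = function(x) c(m = mean(x), s = stats::sd(x)))
  agg <- data.frame(condition = agg$condition, gene = agg$gene,
                    m = agg$ct[, "m"], s = agg$ct[, "s"],
                    stringsAsFactors = FALSE)
  ref <- agg[agg$gene == table$reference_gene, ]
  rownames(ref) <- ref$condition
  tgt <- agg[agg$gene != table$reference_gene, ]
  tgt$dct <- tgt$m - ref[tgt$condition, "m"]
  tgt$sd_dct <- sqrt(tgt$s^2 + ref[tgt$condition, "s"]^2)
  ctrl_dct <- stats::setNames(
    tgt$dct[tgt$condition == table$control_condition],
    tgt$gene[tgt$condition == table$control_condition])
  if (!all(tgt$gene %in% names(ctrl_dct))) {
    stop("gene(s) missing from the control condition: ",
         paste(setdiff(tgt$gene, names(ctrl_dct)), collapse = ", "))
  }
  tgt$ddct <- tgt$dct - ctrl_dct[tgt$gene]
  tgt$fold <- 2^(-tgt$ddct)
  tgt$fold_lo <- 2^(-(tgt$ddct + tgt$sd_dct))
  tgt$fold_hi <- 2^(-(tgt$ddct - tgt$sd_dct))
  rownames(tgt) <- NULL
  tgt[c("condition", "gene", "dct", "sd_dct", "ddct",
        "fold", "fold_lo", "fold_hi")]
}
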