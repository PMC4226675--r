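#' Rank genes by two-sample t statistic between stratified groups
#'
#' Pooled-variance Student t statistic per gene, group `high` minus group
#' `low`, ordered best-to-worst (descending t, ties broken alphabetically
#' by symbol). Genes with zero variance in both groups are dropped with a
#' warning.
#'
#' @param em an [expression_matrix()].
#' @param labels a `strat_labels` object; only samples labelled `high` or
#'   `low` enter the test.
#' @return a `ranked_list`: `genes` (ordered symbols), `metric` (named t
#'   values in that order), `group_sizes` (c(high, low)).
#' @export
rank_by_t <- function(em, labels) {
  stopifnot(inherits(em, "expr_mat"), inherits(labels, "strat_labels"))
  lab <- labels$per_sample_label
  hi <- names(lab)[lab == "high"]
  lo <- names(lab)[lab == "low"]
  hi <- intersect(hi, colnames(em$values))
  lo <- intersect(lo, colnames(em$values))
  if (length(hi) < 2 || length(lo) < 2) {
    stop("each group needs >= 2 samples (high=", length(hi),
         ", low=", length(lo), ")")
  }
  t_stat <- pooled_t(em$values[, hi, drop = FALSE],
                     em$values[, lo, drop = FALSE])
  bad <- !is.finite(t_stat)
  if (any(bad)) {
    warning(sprintf("dropped %d gene(s) with zero variance in both groups",
                    sum(bad)))
    t_stat <- t_stat[!bad]
  }
  ord <- order(-t_stat, names(t_stat))
  t_stat <- t_stat[ord]
  structure(list(genes = names(t_stat), metric = t_stat,
                 group_sizes = c(high = length(hi), low = length(lo))),
            class = "ranked_list")
}

# row-wise pooled-variance two-sample t, vectorised for permutation speed
pooled_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2)
  vb <- rowSums((b - mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Weighted running-sum enrichment score of a gene set in a ranked list
#'
#' Walking down the ranked list, the running sum increments by
#' `|metric|^weight / sum of hit weights` at set members ("hits") and
#' decrements by `1 / (N - Nh)` elsewhere. The enrichment score is the
#' signed maximum deviation; the leading edge holds the set members at or
#' before the extremum (positive score) or at or after it (negative).
#'
#' @param ranked a `ranked_list` from [rank_by_t()].
#' @param set a [gene_set()].
#' @param weight exponent on the ranking metric, default 1.
#' @param min_overlap minimum required overlap with the list, default 1.
#' @return an `enrichment_result` with `es`, `running_sum`, `leading_edge`
#'   (a gene_set), `direction`, `set_name`, `n_hits`.
#' @export
enrichment_score <- function(ranked, set, weight = 1, min_overlap = 1) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(set, "gene_set"))
  hits <- ranked$genes %in% set$genes
  nh <- sum(hits)
  if (nh < max(1, min_overlap)) {
    stop("gene-set overlap with ranked list (", nh, ") below minimum ",
         max(1, min_overlap))
  }
  if (nh >= length(ranked$genes)) {
    stop("gene set covers the whole ranked list")
  }
  rs <- running_sum(ranked$metric, hits, weight)
  i <- which.max(abs(rs))
  es <- rs[i]
  hit_pos <- which(hits)
  le_pos <- if (es >= 0) hit_pos[hit_pos <= i] else hit_pos[hit_pos >= i]
  structure(list(
    set_name = set$name,
    es = es,
    running_sum = rs,
    leading_edge = gene_set(
      paste0(set$name, "_leading_edge"), ranked$genes[le_pos],
      description = sprintf("leading edge (es=%.4f)", es)
    ),
    direction = sign(es),
    n_hits = nh
  ), class = "enrichment_result")
}

# core running-sum statistic; `hits` logical along the sorted list
running_sum <- function(metric, hits, weight) {
  n <- length(metric)
  nh <- sum(hits)
  w <- abs(metric[hits])^weight
  tot <- sum(w)
  step <- rep(-1 / (n - nh), n)
  # all-zero hit metrics: fall back to equal hit increments
  step[hits] <- if (tot > 0) w / tot else 1 / nh
  unname(cumsum(step))
}

#' Phenotype-permutation enrichment test
#'
#' Computes the observed enrichment score from the true high/low labels,
#' then a null distribution from label shuffles that preserve the group
#' sizes. The nominal p uses add-one smoothing over the same-sign null
#' scores; the normalized score (NES) divides by the mean magnitude of the
#' same-sign null scores.
#'
#' @param em an [expression_matrix()].
#' @param labels a `strat_labels` object.
#' @param set a [gene_set()].
#' @param n_permutations number of label shuffles, default 1000.
#' @param weight running-sum exponent, default 1.
#' @param seed integer seed for the shuffles.
#' @param min_overlap minimum set/list overlap, default 5.
#' @return an `enrichment_result` with `es`, `running_sum`, `leading_edge`,
#'   `p_nominal`, `nes`, `null_es`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(em, labels, set, n_permutations = 1000,
                             weight = 1, seed = 1L, min_overlap = 5) {
  stopifnot(n_permutations >= 1)
  obs_ranked <- rank_by_t(em, labels)
  obs <- enrichment_score(obs_ranked, set, weight, min_overlap)

  lab <- labels$per_sample_label
  ids <- c(names(lab)[lab == "high"], names(lab)[lab == "low"])
  ids <- intersect(ids, colnames(em$values))
  nh <- sum(lab[ids] == "high")
  sub <- em$values[, ids, drop = FALSE]
  # restrict to genes retained in the observed ranking so hit membership
  # is computed once
  sub <- sub[obs_ranked$genes, , drop = FALSE]
  in_set <- rownames(sub) %in% set$genes
  syms <- rownames(sub)

  set.seed(seed)
  null_es <- vapply(seq_len(n_permutations), function(p) {
    idx <- sample.int(ncol(sub))
    t_null <- pooled_t(sub[, idx[seq_len(nh)], drop = FALSE],
                       sub[, idx[-seq_len(nh)], drop = FALSE])
    t_null[!is.finite(t_null)] <- 0
    ord <- order(-t_null, syms)
    rs <- running_sum(t_null[ord], in_set[ord], weight)
    rs[which.max(abs(rs))]
  }, numeric(1))

  es <- obs$es
  same_sign <- if (es >= 0) null_es >= 0 else null_es <= 0
  n_ss <- sum(same_sign)
  if (n_ss == 0) {
    warning("degenerate null: no same-sign permutation scores")
    p <- 1 / (n_permutations + 1)
    nes <- NA_real_
  } else {
    p <- (1 + sum(same_sign & abs(null_es) >= abs(es))) / (1 + n_ss)
    nes <- es / mean(abs(null_es[same_sign]))
  }
  obs$p_nominal <- p
  obs$nes <- nes
  obs$null_es <- null_es
  obs$n_permutations <- n_permutations
  obs$seed <- seed
  obs
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: es=%.4f", x$set_name, x$es))
  if (!is.null(x$p_nominal)) {
    cat(sprintf(", nes=%.3f, p=%.4g (%d permutations)",
                x$nes, x$p_nominal, x$n_permutations))
  }
  cat(sprintf("; leading edge %d genes\n", length(x$leading_edge$genes)))
  invisible(x)
}

#' Derive a repressed-target gene set from a negative enrichment
#'
#' In a high-vs-low contrast, a negative enrichment score means the set's
#' genes pile up at the repressed end; its leading edge is returned as a
#' named gene set, ready for GMT export and survival grouping.
#'
#' @param result an `enrichment_result` with negative `es`.
#' @param name name for the derived set.
#' @return a [gene_set()].
#' @export
derive_repressed_targets <- function(result, name = "repressed_targets") {
  stopifnot(inherits(result, "enrichment_result"))
  if (result$es >= 0) {
    stop("enrichment score is non-negative; repressed targets come from ",
         "a negative enrichment - run the opposite contrast")
  }
  gene_set(name, result$leading_edge$genes,
           description = sprintf(
             "leading edge of negative enrichment of '%s' (es=%.4f)",
             result$set_name, result$es))
}
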