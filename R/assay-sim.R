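#' Simulate paired TF binding-array membranes
#'
#' Builds replicate membranes for each condition on a shared layout: sites
#' spotted in duplicate (adjacent columns), one full row of positive
#' controls at the membrane scale level, and a row of negative controls at
#' the blank level. Duplicate spots of a site share one true signal; every
#' spot gets Gaussian noise, and each membrane gets its own multiplicative
#' gain (exposure) that the downstream normalization must remove.
#'
#' @param true_signals named list: condition -> named numeric vector of
#'   per-site true normalized signals (on the scale of
#'   [quantify_membrane()] output: 0 = blank, 1 = positive-control level).
#' @param n_membranes membranes per condition.
#' @param blank_level blank intensity (negative-control mean).
#' @param positive_level positive-control intensity.
#' @param noise_sd per-spot additive intensity noise sd.
#' @param gain_sd sd of per-membrane log-normal exposure gain (0 = none).
#' @param n_cols spot columns per grid row.
#' @param seed integer seed.
#' @return named list: condition -> list of [tf_array_grid()] objects.
#' @export
simulate_tf_membranes <- function(true_signals, n_membranes = 2,
                                  blank_level = 50, positive_level = 350,
                                  noise_sd = 5, gain_sd = 0, n_cols = 10,
                                  seed = 1L) {
  stopifnot(is.list(true_signals), length(true_signals) >= 1)
  sites <- names(true_signals[[1]])
  if (is.null(sites)) stop("true_signals vectors must be named by site")
  for (ts in true_signals) {
    if (!identical(names(ts), sites)) {
      stop("all conditions must cover the same sites in the same order")
    }
  }
  set.seed(seed)

  # layout: duplicate spots per site row-major, then a negative-control
  # row, then the positive-control row
  n_site_rows <- ceiling(2 * length(sites) / n_cols)
  n_rows <- n_site_rows + 2L
  ann <- data.frame(row = integer(), col = integer(),
                    type = character(), site = character(),
                    stringsAsFactors = FALSE)
  pos <- 0L
  for (s in sites) {
    for (rep_i in 1:2) {
      ann <- rbind(ann, data.frame(
        row = pos %/% n_cols + 1L, col = pos %% n_cols + 1L,
        type = "site", site = s, stringsAsFactors = FALSE))
      pos <- pos + 1L
    }
  }
  neg_row <- n_site_rows + 1L
  pos_row <- n_site_rows + 2L
  ann <- rbind(
    ann,
    data.frame(row = neg_row, col = seq_len(n_cols),
               type = "negative_control", site = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(row = pos_row, col = seq_len(n_cols),
               type = "positive_control", site = NA_character_,
               stringsAsFactors = FALSE)
  )
  scale <- positive_level - blank_level

  out <- list()
  for (cond in names(true_signals)) {
    ts <- true_signals[[cond]]
    mems <- vector("list", n_membranes)
    for (m in seq_len(n_membranes)) {
      gain <- if (gain_sd > 0) exp(stats::rnorm(1, 0, gain_sd)) else 1
      grid <- matrix(0, n_rows, n_cols)
      true_spot <- numeric(nrow(ann))
      is_site <- ann$type == "site"
      true_spot[is_site] <- blank_level + scale * ts[ann$site[is_site]]
      true_spot[ann$type == "negative_control"] <- blank_level
      true_spot[ann$type == "positive_control"] <- positive_level
      spot <- gain * (true_spot + stats::rnorm(nrow(ann), 0, noise_sd))
      grid[cbind(ann$row, ann$col)] <- pmax(spot, 0)
      mems[[m]] <- tf_array_grid(grid, ann,
                                 membrane_id = sprintf("%s_m%d", cond, m),
                                 condition = cond)
    }
    out[[cond]] <- mems
  }
  out
}

#' Simulate a replicate qPCR Ct table with planted fold changes
#'
#' Treated-condition Ct values sit `log2(fold)` cycles below the control
#' baseline (one cycle = one doubling); the reference gene is generated
#' per condition at its own baseline. Replicate noise is Gaussian on the
#' Ct scale.
#'
#' @param true_folds named list: condition -> named numeric vector of true
#'   fold changes per target gene (control condition is generated with
#'   fold 1 automatically).
#' @param ct_baseline named numeric baseline Ct per target gene (recycled
#'   from a scalar).
#' @param ct_ref baseline Ct of the reference gene.
#' @param reference_gene housekeeping gene name.
#' @param replicate_sd Gaussian Ct noise sd.
#' @param n_reps replicates per (condition, gene); >= 2.
#' @param control_condition label of the generated baseline condition.
#' @param seed integer seed.
#' @return a [ct_table()].
#' @export
simulate_ct_table <- function(true_folds, ct_baseline = 24, ct_ref = 18,
                              reference_gene = "36B4", replicate_sd = 0.2,
                              n_reps = 3, control_condition = "control",
                              seed = 1L) {
  stopifnot(n_reps >= 2, is.list(true_folds))
  genes <- names(true_folds[[1]])
  if (is.null(genes)) stop("true_folds vectors must be named by gene")
  if (length(ct_baseline) == 1) {
    ct_baseline <- stats::setNames(rep(ct_baseline, length(genes)), genes)
  }
  set.seed(seed)
  conds <- c(stats::setNames(
    list(stats::setNames(rep(1, length(genes)), genes)), control_condition),
    true_folds)
  rows <- list()
  for (cond in names(conds)) {
    folds <- conds[[cond]]
    for (g in genes) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, gene = g,
        ct = ct_baseline[g] - log2(folds[g]) +
          stats::rnorm(n_reps, 0, replicate_sd),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, gene = reference_gene,
      ct = ct_ref + stats::rnorm(n_reps, 0, replicate_sd),
      stringsAsFactors = FALSE)
  }
  ct_table(do.call(rbind, rows), reference_gene = reference_gene,
           control_condition = control_condition)
}
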