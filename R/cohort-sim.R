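#' Configuration for the synthetic cohort generator
#'
#' Parameters of the generative model behind [simulate_cohort()]. Tumor
#' expression is built from two anticorrelated latent activities (an
#' androgen-receptor program and an NF-kB program); GSK3A/GSK3B track the
#' AR activity; survival hazard depends on the NF-kB signature; normal
#' samples carry neither program.
#'
#' @param n_tumors,n_normals sample counts.
#' @param n_genes total genes (includes GSK3A and GSK3B).
#' @param n_program_genes genes per program (AR and NF-kB, disjoint).
#' @param effect_size_beta log2-units expression shift per unit latent
#'   activity on program genes.
#' @param anticorrelation_rho strength in `[-1, 1]` of the inverse coupling
#'   between AR and NF-kB activities (`b = -rho * a + sqrt(1-rho^2) * eta`).
#' @param gsk3_coupling log2-units tying GSK3A/GSK3B to the AR activity.
#' @param baseline_mean,baseline_sd per-gene baseline log2 level
#'   distribution.
#' @param noise_sd residual sd (log2 units).
#' @param chip_offset_max half-width of the bounded per-chip offset
#'   (log2 units) representing residual mis-normalization left after
#'   between-array normalization; drawn uniform on
#'   `[-chip_offset_max, chip_offset_max]` per chip.
#' @param hazard_gamma log-hazard coefficient on the standardized NF-kB
#'   summed Z-score.
#' @param censor_rate fraction of tumors subject to early uniform
#'   censoring (all tumors are administratively censored at
#'   `max_followup`).
#' @param max_followup administrative follow-up horizon in months.
#' @param median_survival_months baseline median survival (sets the
#'   exponential baseline hazard).
#' @param outlier_chips optional data.frame with columns `sample` and
#'   `shift`: chips whose whole expression column is shifted (log2 units)
#'   after everything else, emulating failed arrays.
#' @param seed integer seed; same config + seed gives bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tumors = 100, n_normals = 20, n_genes = 2000,
                       n_program_genes = 30, effect_size_beta = 1.0,
                       anticorrelation_rho = 0.6, gsk3_coupling = 0.5,
                       baseline_mean = 7, baseline_sd = 1, noise_sd = 0.5,
                       chip_offset_max = 0.1,
                       hazard_gamma = 0.8, censor_rate = 0.3,
                       max_followup = 220, median_survival_months = 100,
                       outlier_chips = NULL, seed = 1L) {
  cfg <- list(n_tumors = n_tumors, n_normals = n_normals, n_genes = n_genes,
              n_program_genes = n_program_genes,
              effect_size_beta = effect_size_beta,
              anticorrelation_rho = anticorrelation_rho,
              gsk3_coupling = gsk3_coupling,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, chip_offset_max = chip_offset_max,
              hazard_gamma = hazard_gamma,
              censor_rate = censor_rate, max_followup = max_followup,
              median_survival_months = median_survival_months,
              outlier_chips = outlier_chips, seed = as.integer(seed))
  with(cfg, {
    if (n_tumors <= 0 || n_normals <= 0 || n_genes <= 0 ||
        n_program_genes <= 0) stop("all counts must be > 0")
    if (abs(anticorrelation_rho) > 1) stop("|rho| must be <= 1")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (2 * n_program_genes + 2 > n_genes) {
      stop("program genes (plus GSK3A/GSK3B) exceed n_genes")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a tumor/normal expression cohort with survival follow-up
#'
#' Expression is generated directly on the normalized log2 scale:
#' `x_gs = mu_g + beta * (a_s [g in AR set] + b_s [g in NFkB set])
#' + coupling * a_s [g in {GSK3A, GSK3B}] + eps`, with per-tumor latent AR
#' activity `a ~ N(0,1)` and NF-kB activity `b = -rho * a +
#' sqrt(1-rho^2) * eta`. Normals have `a = b = 0`. Tumor survival times
#' are exponential with log-hazard proportional to the standardized NF-kB
#' summed Z-score of the generated expression (scored against the normal
#' reference), censored administratively at `max_followup` and, for a
#' `censor_rate` fraction, by an early uniform censoring time. Outlier
#' chip shifts, if any, are added last.
#'
#' @param config a [sim_config()].
#' @return a `syn_cohort`: `expression` (an [expression_matrix()]),
#'   `metadata` (sample_id, role, time_months, event; survival `NA` for
#'   normals) and `truth` (latent activities, program gene lists, planted
#'   outlier ids).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)

  n_named <- cf$n_genes - 2L
  genes <- c(sprintf("G%05d", seq_len(n_named)), "GSK3A", "GSK3B")
  prog <- sample(genes[seq_len(n_named)], 2 * cf$n_program_genes)
  ar_genes <- sort(prog[seq_len(cf$n_program_genes)])
  nfkb_genes <- sort(prog[-seq_len(cf$n_program_genes)])

  tum_ids <- sprintf("T%03d", seq_len(cf$n_tumors))
  nor_ids <- sprintf("N%03d", seq_len(cf$n_normals))
  ids <- c(tum_ids, nor_ids)
  roles <- stats::setNames(
    c(rep("tumor", cf$n_tumors), rep("normal", cf$n_normals)), ids)

  a <- c(stats::rnorm(cf$n_tumors), rep(0, cf$n_normals))
  eta <- c(stats::rnorm(cf$n_tumors), rep(0, cf$n_normals))
  rho <- cf$anticorrelation_rho
  b <- -rho * a + sqrt(1 - rho^2) * eta

  mu <- stats::rnorm(cf$n_genes, cf$baseline_mean, cf$baseline_sd)
  x <- matrix(stats::rnorm(cf$n_genes * length(ids), 0, cf$noise_sd),
              nrow = cf$n_genes, dimnames = list(genes, ids)) + mu
  x[ar_genes, ] <- x[ar_genes, ] +
    cf$effect_size_beta * rep(a, each = length(ar_genes))
  x[nfkb_genes, ] <- x[nfkb_genes, ] +
    cf$effect_size_beta * rep(b, each = length(nfkb_genes))
  x[c("GSK3A", "GSK3B"), ] <- x[c("GSK3A", "GSK3B"), ] +
    cf$gsk3_coupling * rep(a, each = 2)
  if (cf$chip_offset_max > 0) {
    offsets <- stats::runif(length(ids), -cf$chip_offset_max,
                            cf$chip_offset_max)
    x <- x + rep(offsets, each = cf$n_genes)
  }

  em <- expression_matrix(x, roles)

  # hazard rides on the measured NF-kB summed Z (scored vs normals)
  z <- suppressWarnings(zscore_vs_reference(em))
  nf_score <- summed_zscore(z, gene_set("nfkb_truth", nfkb_genes))
  zs <- as.numeric(scale(nf_score$per_sample_score))
  lambda0 <- log(2) / cf$median_survival_months
  t_event <- stats::rexp(cf$n_tumors, rate = lambda0 * exp(cf$hazard_gamma * zs))
  cens <- rep(cf$max_followup, cf$n_tumors)
  early <- stats::runif(cf$n_tumors) < cf$censor_rate
  cens[early] <- pmin(cens[early],
                      stats::runif(sum(early), 0, cf$max_followup))
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)

  outlier_ids <- character()
  if (!is.null(cf$outlier_chips)) {
    oc <- cf$outlier_chips
    if (!all(oc$sample %in% ids)) stop("outlier chip id not in cohort")
    for (i in seq_len(nrow(oc))) {
      em$values[, oc$sample[i]] <- em$values[, oc$sample[i]] + oc$shift[i]
    }
    outlier_ids <- as.character(oc$sample)
  }

  metadata <- data.frame(
    sample_id = ids,
    role = unname(roles),
    time_months = c(time, rep(NA_real_, cf$n_normals)),
    event = c(event, rep(NA_integer_, cf$n_normals)),
    stringsAsFactors = FALSE
  )
  structure(list(
    expression = em,
    metadata = metadata,
    truth = list(
      activity = data.frame(sample_id = tum_ids,
                            ar = a[seq_len(cf$n_tumors)],
                            nfkb = b[seq_len(cf$n_tumors)]),
      ar_genes = ar_genes, nfkb_genes = nfkb_genes,
      outlier_chips = outlier_ids
    ),
    config = cf
  ), class = "syn_cohort")
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat(sprintf(
    "<syn_cohort> %d genes x (%d tumors + %d normals); rho=%.2f beta=%.2f seed=%d\n",
    x$config$n_genes, x$config$n_tumors, x$config$n_normals,
    x$config$anticorrelation_rho, x$config$effect_size_beta, x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Expression as TSV, metadata as TSV, truth as JSON; round-trips with
#' [read_expression_tsv()] and [read_metadata_tsv()].
#' @param cohort a `syn_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "syn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_metadata_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
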