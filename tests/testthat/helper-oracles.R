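# Independent oracles used across tests. Each recomputes its quantity the
# slow, obvious way and never calls the implementation it checks.

# brute-force running-sum enrichment: explicit position loop
oracle_es <- function(metric, genes, set_genes, weight = 1) {
  metric <- unname(metric)
  n <- length(genes)
  hits <- genes %in% set_genes
  nh <- sum(hits)
  w <- abs(metric)^weight
  sumw <- sum(w[hits])
  cur <- 0
  best <- 0
  rs <- numeric(n)
  for (i in seq_len(n)) {
    cur <- cur + if (hits[i]) w[i] / sumw else -1 / (n - nh)
    rs[i] <- cur
    if (abs(cur) > abs(best)) best <- cur
  }
  list(es = best, running_sum = rs)
}

# hand product-limit table
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# textbook observed-minus-expected log-rank chi-square (2 groups)
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# naive per-gene loops for Z-scores and pooled t
oracle_zscore <- function(values, ref_ids, tum_ids) {
  out <- matrix(NA_real_, nrow(values), length(tum_ids),
                dimnames = list(rownames(values), tum_ids))
  for (g in rownames(values)) {
    r <- values[g, ref_ids]
    for (s in tum_ids) out[g, s] <- (values[g, s] - mean(r)) / sd(r)
  }
  out
}

oracle_pooled_t <- function(values, hi_ids, lo_ids) {
  sapply(rownames(values), function(g) {
    x <- values[g, hi_ids]; y <- values[g, lo_ids]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  })
}

# small deterministic expression matrix for unit tests
toy_em <- function(n_genes = 20, n_tumors = 6, n_normals = 4, seed = 42,
                   genes = sprintf("G%03d", seq_len(n_genes))) {
  set.seed(seed)
  ids <- c(sprintf("T%02d", seq_len(n_tumors)),
           sprintf("N%02d", seq_len(n_normals)))
  v <- matrix(rnorm(n_genes * length(ids), 8, 1), n_genes,
              dimnames = list(genes, ids))
  roles <- setNames(c(rep("tumor", n_tumors), rep("normal", n_normals)), ids)
  expression_matrix(v, roles)
}

# ranked list built directly (bypasses rank_by_t) for enrichment units
toy_ranked <- function(metric) {
  ord <- order(-metric, names(metric))
  structure(list(genes = names(metric)[ord], metric = metric[ord],
                 group_sizes = c(high = 3, low = 3)),
            class = "ranked_list")
}

# planted-signal recovery runs at generator defaults, shared between the
# enrichment-direction and derived-set tests (memoised: computed once per
# test run)
.recovery_cache <- new.env(parent = emptyenv())
recovery_runs <- function(n_seeds = 50, n_permutations = 199) {
  key <- sprintf("r_%d_%d", n_seeds, n_permutations)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(s) {
    co <- simulate_cohort(sim_config(seed = s))
    z <- zscore_vs_reference(co$expression)
    ar <- summed_zscore(z, gene_set("AR_truth", co$truth$ar_genes))
    labels <- stratify_extremes(ar, 1 / 3)
    enr <- permutation_test(co$expression, labels,
                            gene_set("NFKB_truth", co$truth$nfkb_genes),
                            n_permutations = n_permutations, seed = s)
    precision <- if (enr$es < 0) {
      d <- derive_repressed_targets(enr)
      mean(d$genes %in% co$truth$nfkb_genes)
    } else NA_real_
    list(es = enr$es, p = enr$p_nominal, precision = precision)
  })
  .recovery_cache[[key]] <- runs
  runs
}
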