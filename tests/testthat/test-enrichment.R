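test_that("t ranking matches the textbook formula and is antisymmetric", {
  em <- toy_em(n_genes = 30, n_tumors = 10, n_normals = 2, seed = 21)
  ids <- samples_of(em, "tumor")
  lab <- structure(list(per_sample_label = setNames(
    rep(c("high", "low"), each = 5), ids), rule = "test"),
    class = "strat_labels")
  rl <- rank_by_t(em, lab)
  t_or <- oracle_pooled_t(em$values, ids[1:5], ids[6:10])
  expect_equal(rl$metric[names(t_or)][order(names(t_or))],
               t_or[order(names(t_or))], tolerance = 1e-10)
  expect_false(is.unsorted(rev(rl$metric)))

  swapped <- lab
  swapped$per_sample_label <- setNames(
    rep(c("low", "high"), each = 5), ids)
  rl2 <- rank_by_t(em, swapped)
  expect_equal(sort(rl2$metric), sort(-rl$metric), tolerance = 1e-10)

  # equal means and variances -> t = 0
  em$values[1, ids] <- rep(c(1, 2, 1, 2, 1), 2)
  rl3 <- rank_by_t(em, lab)
  expect_equal(unname(rl3$metric[rownames(em$values)[1]]), 0)

  lab_bad <- lab
  lab_bad$per_sample_label[ids[2:5]] <- "unclassified"
  expect_error(rank_by_t(em, lab_bad), ">= 2 samples")
})

test_that("enrichment score reproduces hand-enumerated running sums", {
  # singleton set at the top of the list
  m1 <- setNames(c(5, 4, 3, 2, 1), c("A", "B", "C", "D", "E"))
  r1 <- enrichment_score(toy_ranked(m1), gene_set("s", "A"))
  expect_equal(r1$es, 1)
  expect_identical(r1$leading_edge$genes, "A")

  # singleton set at the bottom, weight 0
  r2 <- enrichment_score(toy_ranked(m1), gene_set("s", "E"), weight = 0)
  expect_equal(r2$es, -1)
  expect_identical(r2$leading_edge$genes, "E")

  # the four-gene hand case
  m3 <- setNames(c(3, 2, 1, 1), c("A", "B", "C", "D"))
  r3 <- enrichment_score(toy_ranked(m3), gene_set("s", c("A", "C")))
  expect_equal(r3$running_sum, c(0.75, 0.25, 0.50, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(r3$es, 0.75)

  expect_error(enrichment_score(toy_ranked(m3), gene_set("s", "ZZ")),
               "overlap")
  expect_error(enrichment_score(toy_ranked(m3),
                                gene_set("s", c("A", "B", "C", "D"))),
               "whole ranked list")
})

test_that("enrichment score agrees with fgsea's statistic", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("G%03d", seq_len(n))
    sel <- sort(sample(n, sample(3:8, 1)))
    mine <- enrichment_score(toy_ranked(stats),
                             gene_set("s", names(stats)[sel]))$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = sel, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("enrichment score equals the brute-force loop on random cases", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    metric <- setNames(round(rnorm(n), 2), sprintf("G%03d", seq_len(n)))
    k <- sample(1:min(10, n - 1), 1)
    set_genes <- sample(names(metric), k)
    w <- sample(c(0, 1, 1.5), 1)
    rl <- toy_ranked(metric)
    mine <- enrichment_score(rl, gene_set("s", set_genes), weight = w)
    orc <- oracle_es(rl$metric, rl$genes, set_genes, weight = w)
    expect_equal(mine$es, orc$es, tolerance = 1e-12)
    expect_equal(unname(mine$running_sum), orc$running_sum,
                 tolerance = 1e-12)
    expect_lte(abs(mine$es), 1)
    expect_lt(abs(orc$running_sum[n]), 1e-9)
  }
})

test_that("permutation p-values are deterministic, bounded and stable", {
  co <- simulate_cohort(sim_config(n_tumors = 60, n_normals = 10,
                                   n_genes = 300, seed = 13))
  z <- zscore_vs_reference(co$expression)
  lab <- stratify_extremes(
    summed_zscore(z, gene_set("AR", co$truth$ar_genes)), 1 / 3)
  nf <- gene_set("NF", co$truth$nfkb_genes)
  r1 <- permutation_test(co$expression, lab, nf, n_permutations = 99,
                         seed = 5)
  r2 <- permutation_test(co$expression, lab, nf, n_permutations = 99,
                         seed = 5)
  expect_identical(r1$null_es, r2$null_es)
  expect_gte(r1$p_nominal, 1 / 100)
  expect_lte(r1$p_nominal, 1)
  # different shuffle seeds move p by no more than Monte-Carlo error
  r3 <- permutation_test(co$expression, lab, nf, n_permutations = 99,
                         seed = 6)
  expect_lt(abs(r1$p_nominal - r3$p_nominal), 0.15)
})

test_that("an observed score beyond every null gives the add-one p", {
  co <- simulate_cohort(sim_config(n_tumors = 60, n_normals = 10,
                                   n_genes = 300, anticorrelation_rho = 0.95,
                                   effect_size_beta = 2, seed = 17))
  z <- zscore_vs_reference(co$expression)
  lab <- stratify_extremes(
    summed_zscore(z, gene_set("AR", co$truth$ar_genes)), 1 / 3)
  r <- permutation_test(co$expression, lab,
                        gene_set("NF", co$truth$nfkb_genes),
                        n_permutations = 99, seed = 3)
  same_sign <- if (r$es >= 0) r$null_es >= 0 else r$null_es <= 0
  if (all(abs(r$null_es[same_sign]) < abs(r$es))) {
    expect_equal(r$p_nominal, 1 / (1 + sum(same_sign)))
  }
  expect_lt(r$es, 0)
})

test_that("repressed targets come from negative leading edges only", {
  m <- setNames(c(5, 4, 3, 2, 1), c("A", "B", "C", "D", "E"))
  neg <- enrichment_score(toy_ranked(m), gene_set("s", "E"))
  d <- derive_repressed_targets(neg, name = "derived")
  expect_identical(d$genes, "E")
  expect_identical(d$name, "derived")

  pos <- enrichment_score(toy_ranked(m), gene_set("s", "A"))
  expect_error(derive_repressed_targets(pos), "opposite contrast")
})

test_that("|NES| does not decrease with effect size", {
  # low-SNR regime (small programs, high noise) so the bounded enrichment
  # score is not saturated at the larger effect sizes
  mean_nes <- vapply(c(0, 0.5, 1.0), function(beta) {
    v <- vapply(1:25, function(s) {
      co <- simulate_cohort(sim_config(
        n_tumors = 40, n_normals = 10, n_genes = 300, n_program_genes = 10,
        effect_size_beta = beta, noise_sd = 1.5, seed = s))
      z <- suppressWarnings(zscore_vs_reference(co$expression))
      lab <- stratify_extremes(
        summed_zscore(z, gene_set("AR", co$truth$ar_genes)), 1 / 3)
      r <- permutation_test(co$expression, lab,
                            gene_set("NF", co$truth$nfkb_genes),
                            n_permutations = 99, seed = s)
      abs(r$nes)
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_nes) >= 0))
})
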