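test_that("Z-scores follow the reference mean/sd definition", {
  # reference {8, 12}: mean 10, sd (n-1) = 2.828...; tumor at 12.828 -> Z = 1
  v2 <- matrix(c(12.828427, 8, 12), nrow = 1,
               dimnames = list("GA", c("T1", "N1", "N2")))
  roles <- setNames(c("tumor", "normal", "normal"), colnames(v2))
  z <- zscore_vs_reference(expression_matrix(v2, roles))
  expect_equal(z["GA", "T1"], 1, tolerance = 1e-6)

  # tumor at the reference mean scores zero
  v3 <- matrix(c(10, 9, 11), nrow = 1,
               dimnames = list("GA", c("T1", "N1", "N2")))
  z3 <- zscore_vs_reference(expression_matrix(v3, roles))
  expect_equal(unname(z3["GA", "T1"]), 0)
})

test_that("Z-scores match a naive per-gene loop", {
  em <- toy_em(n_genes = 20, n_tumors = 6, n_normals = 4, seed = 31)
  z <- zscore_vs_reference(em)
  zo <- oracle_zscore(em$values, samples_of(em, "normal"),
                      samples_of(em, "tumor"))
  expect_equal(z, zo, tolerance = 1e-12)
})

test_that("degenerate references are handled as documented", {
  em <- toy_em(n_genes = 5, seed = 2)
  em$values[3, samples_of(em, "normal")] <- 7  # zero reference sd
  expect_warning(z <- zscore_vs_reference(em), "zero reference sd")
  expect_false(rownames(em$values)[3] %in% rownames(z))

  # tumor-only matrix falls back to cohort reference with a warning
  ids <- sprintf("T%02d", 1:5)
  v <- matrix(rnorm(50, 8), 10, 5,
              dimnames = list(sprintf("G%03d", 1:10), ids))
  em2 <- expression_matrix(v, setNames(rep("tumor", 5), ids))
  expect_warning(zscore_vs_reference(em2), "cohort-wide")
})

test_that("adding a constant to one gene everywhere leaves Z unchanged", {
  em <- toy_em(seed = 8)
  z1 <- zscore_vs_reference(em)
  em$values["G005", ] <- em$values["G005", ] + 3.7
  z2 <- zscore_vs_reference(em)
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("summed Z-scores sum present genes and record missing ones", {
  z <- matrix(c(1, -0.5, 0.5, 0, 0, 0), nrow = 3,
              dimnames = list(c("GA", "GB", "GC"), c("T1", "T2")))
  sc <- summed_zscore(z, gene_set("sig", c("GA", "GB", "GC")))
  expect_equal(unname(sc$per_sample_score), c(1, 0))

  sc2 <- summed_zscore(z, gene_set("sig", c("GA", "GB", "GC", "GX", "GY")))
  expect_equal(sc2$n_genes_used, 3)
  expect_setequal(sc2$missing_genes, c("GX", "GY"))
  expect_equal(sc2$per_sample_score, sc$per_sample_score)

  expect_error(summed_zscore(z, gene_set("none", c("GX", "GY"))),
               "no gene")
})

test_that("extreme-score stratification labels the stated order statistics", {
  sc <- structure(list(signature = "s",
                       per_sample_score = c(s1 = 3, s2 = 2, s3 = 1, s4 = 0),
                       n_genes_used = 1, missing_genes = character()),
                  class = "signature_scores")
  lab <- stratify_extremes(sc, 0.25)
  expect_identical(unname(lab$per_sample_label[c("s1", "s4")]),
                   c("high", "low"))
  expect_identical(unname(lab$per_sample_label[c("s2", "s3")]),
                   rep("unclassified", 2))

  all_lab <- stratify_extremes(sc, 0.5)
  expect_false(any(all_lab$per_sample_label == "unclassified"))

  expect_error(stratify_extremes(sc, 0.6), "fraction")
  expect_error(stratify_extremes(sc, 0), "fraction")
})

test_that("labels always partition the tumors", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    sc <- structure(list(signature = "s",
                         per_sample_score = setNames(
                           round(rnorm(n), 1), sprintf("t%03d", 1:n)),
                         n_genes_used = 1, missing_genes = character()),
                    class = "signature_scores")
    f <- runif(1, 0.05, 0.5)
    lab <- stratify_extremes(sc, f)$per_sample_label
    expect_length(lab, n)
    expect_true(all(lab %in% c("high", "low", "unclassified")))
    expect_length(intersect(names(lab)[lab == "high"],
                            names(lab)[lab == "low"]), 0)
  }
})

test_that("high-AR tumors carry higher true AR activity than low-AR tumors", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_tumors = 100, n_normals = 10,
                                     n_genes = 300, seed = s))
    z <- zscore_vs_reference(co$expression)
    lab <- stratify_extremes(
      summed_zscore(z, gene_set("AR", co$truth$ar_genes)),
      1 / 3)$per_sample_label
    tr <- setNames(co$truth$activity$ar, co$truth$activity$sample_id)
    mean(tr[names(lab)[lab == "high"]]) > mean(tr[names(lab)[lab == "low"]])
  }, logical(1))
  expect_true(all(hits))
})

test_that("summed-Z scoring recovers the latent AR activity", {
  good <- vapply(1:50, function(s) {
    co <- simulate_cohort(sim_config(seed = s))
    z <- zscore_vs_reference(co$expression)
    sc <- summed_zscore(z, gene_set("AR", co$truth$ar_genes))
    tr <- setNames(co$truth$activity$ar, co$truth$activity$sample_id)
    cor(sc$per_sample_score, tr[names(sc$per_sample_score)],
        method = "spearman") >= 0.8
  }, logical(1))
  expect_gte(mean(good), 0.95)
})

test_that("dual-threshold GSK3 classes follow the printed rule", {
  z <- matrix(c(0.6, 0.8,   -0.6, -0.7,   0.6, -0.7,   0.5, 0.5),
              nrow = 2,
              dimnames = list(c("GSK3A", "GSK3B"),
                              c("T1", "T2", "T3", "T4")))
  lab <- classify_dual_threshold(z)$per_sample_label
  expect_identical(unname(lab),
                   c("high", "low", "unclassified", "unclassified"))
  expect_error(classify_dual_threshold(z[1, , drop = FALSE]), "absent")
})
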