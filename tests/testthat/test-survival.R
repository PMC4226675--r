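test_that("signature grouping splits deterministically and validates", {
  sc <- structure(list(signature = "s",
                       per_sample_score = c(a = 1, b = 2, c = 3, d = 4),
                       n_genes_used = 1, missing_genes = character()),
                  class = "signature_scores")
  g <- group_by_signature(sc, "median")
  expect_identical(unname(g[c("a", "b")]), c("low", "low"))
  expect_identical(unname(g[c("c", "d")]), c("high", "high"))

  sc$per_sample_score <- c(a = 5, b = 5, c = 5, d = 5)
  expect_error(group_by_signature(sc, "median"), "degenerate")

  sc$per_sample_score <- c(a = -1, b = 1)
  expect_error(group_by_signature(sc, "threshold", threshold = 0),
               ">= 2 samples")
})

test_that("Kaplan-Meier estimates match the hand product-limit table", {
  # all censored -> flat at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km0$surv_fun(c(0, 3, 10)), c(1, 1, 1))

  # single event
  km1 <- km_estimate(5, 1)
  expect_equal(km1$surv_fun(c(0, 4.99, 5, 10)), c(1, 1, 0, 0))

  # the 5-record mixed case
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 0, 1, 1, 0)
  km <- km_estimate(time, event)
  orc <- oracle_km(time, event)
  expect_equal(km$surv_fun(orc$time), orc$surv, tolerance = 1e-12)
  expect_equal(orc$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM curves are monotone, bounded, and 1 before the first event", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    time <- round(rexp(n, 0.02) + 0.5, 1)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(time, event)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    first_event <- min(time[event == 1])
    expect_equal(km$surv_fun(first_event - 1e-9), 1)
  }
})

test_that("log-rank matches the observed-minus-expected oracle", {
  rec <- data.frame(time = c(1, 2, 3, 4),
                    event = 1,
                    group = c("A", "A", "B", "B"))
  lr <- logrank_test(rec)
  chi_orc <- oracle_logrank_chisq(rec$time, rec$event, rec$group)
  expect_equal(lr$chi_square, chi_orc, tolerance = 1e-10)
  expect_equal(lr$df, 1L)

  set.seed(44)
  for (i in 1:10) {
    n <- 30
    rec2 <- data.frame(
      time = round(rexp(n, 0.02) + 0.5, 1),
      event = rbinom(n, 1, 0.8),
      group = sample(rep(c("A", "B"), n / 2)))
    if (sum(rec2$event) == 0) rec2$event[1] <- 1
    lr2 <- logrank_test(rec2)
    expect_equal(lr2$chi_square,
                 oracle_logrank_chisq(rec2$time, rec2$event, rec2$group),
                 tolerance = 1e-10)
  }
})

test_that("identical groups give chi-square 0 and label swap changes nothing", {
  tv <- c(3, 6, 9, 12, 15)
  ev <- c(1, 0, 1, 1, 0)
  rec <- data.frame(time = rep(tv, 2), event = rep(ev, 2),
                    group = rep(c("A", "B"), each = 5))
  lr <- logrank_test(rec)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)

  rec2 <- data.frame(time = c(1, 4, 7, 2, 5, 9),
                     event = c(1, 1, 0, 1, 0, 1),
                     group = c("A", "A", "A", "B", "B", "B"))
  lr_a <- logrank_test(rec2)
  rec2$group <- ifelse(rec2$group == "A", "B", "A")
  lr_b <- logrank_test(rec2)
  expect_equal(lr_a$chi_square, lr_b$chi_square, tolerance = 1e-12)
  expect_equal(lr_a$p_value, lr_b$p_value, tolerance = 1e-12)
})

test_that("horizon truncation censors late follow-up and degenerates safely", {
  rec <- data.frame(time = c(50, 150, 80, 200),
                    event = c(1, 1, 1, 1),
                    group = c("A", "A", "B", "B"))
  lr <- logrank_test(rec, horizon_months = 100)
  expect_equal(lr$n_events, 2)  # events after 100 months become censored
  expect_equal(lr$horizon_months, 100)
  expect_error(logrank_test(rec, horizon_months = 10), "no events")
  expect_error(logrank_test(data.frame(time = 1, event = 1, group = "A")),
               "2 groups")
})

test_that("high derived-set scores mean worse survival when hazard is on", {
  worse <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_tumors = 100, n_normals = 10,
                                     n_genes = 300, hazard_gamma = 0.8,
                                     seed = s))
    z <- zscore_vs_reference(co$expression)
    sc <- summed_zscore(z, gene_set("NF", co$truth$nfkb_genes))
    grp <- group_by_signature(sc, "median")
    md <- co$metadata[match(names(grp), co$metadata$sample_id), ]
    km_hi <- km_estimate(md$time_months[grp == "high"],
                         md$event[grp == "high"])
    km_lo <- km_estimate(md$time_months[grp == "low"],
                         md$event[grp == "low"])
    t_med <- median(md$time_months)
    km_hi$surv_fun(t_med) < km_lo$surv_fun(t_med)
  }, logical(1))
  expect_gte(mean(worse), 0.9)
})
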