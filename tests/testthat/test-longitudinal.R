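test_that("burden table conserves effect classes and handles edge cohorts", {
  co <- make_cohort(n_patients = 8, cycles_per_patient = 3, seed = 50)
  br <- burden_by_cycle(co)
  expect_equal(br$burden$n_total,
               br$burden$n_nonsilent + br$burden$n_silent +
                 br$burden$n_noncoding)
  # strong decay: every pre mean above post mean across seeds
  for (s in 1:5) {
    cs <- make_cohort(n_patients = 30, cycles_per_patient = 3,
                      decay_sensitive = 0.3, decay_insensitive = 0.3,
                      seed = 60 + s)
    b <- burden_by_cycle(cs)$burden
    expect_gt(mean(b$n_total[b$timepoint == "pre"]),
              mean(b$n_total[b$timepoint == "post"]))
  }
  # single sample: one row, comparison not applicable
  one <- list(samples = co$samples[1, , drop = FALSE],
              variants = co$variants[co$samples$sample_id[1]])
  b1 <- burden_by_cycle(one)
  expect_equal(nrow(b1$burden), 1L)
  expect_null(b1$test_total)
  expect_equal(b1$note, "not-applicable")
  # a patient without baseline is dropped from the paired view only
  no_base <- list(samples = co$samples[co$samples$cycle_index > 0 |
                                         co$samples$patient_id != "P01", ],
                  variants = co$variants)
  expect_message(b2 <- burden_by_cycle(no_base), "without baseline")
  expect_false("P01" %in% b2$paired$patient_id)
  expect_true("P01" %in% b2$burden$patient_id)
})

test_that("pre/post burden comparison controls type I error under no decay", {
  # decay 1.0: the t-test should reject at ~alpha; over 100 seeds at least
  # 90% of runs stay non-significant
  ps <- vapply(1:100, function(s) {
    cs <- make_cohort(n_patients = 20, cycles_per_patient = 3,
                      decay_sensitive = 1, decay_insensitive = 1,
                      seed = 200 + s)
    burden_by_cycle(cs)$test_total$p.value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("Mann-Whitney comparisons match exact rank enumeration", {
  d <- data.frame(vaf = c(1, 2, 3, 4, 5, 6),
                  group = rep(c("a", "b"), each = 3))
  res <- group_compare_vaf(d, test = "mann-whitney", alternative = "less")
  expect_equal(res$p_value, 0.05)             # U = 0, exact one-sided 1/20
  expect_equal(res$statistic, 0)
  # exact enumeration oracle across random tie-free small samples
  set.seed(51)
  for (i in 1:8) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- round(rnorm(n1), 6); y <- round(rnorm(n2, 0.5), 6)
    d2 <- data.frame(vaf = c(x, y), group = rep(c("a", "b"), c(n1, n2)))
    for (alt in c("two.sided", "less", "greater")) {
      got <- group_compare_vaf(d2, test = "mann-whitney",
                               alternative = alt)$p_value
      expect_equal(got, mw_exact_oracle(x, y, alt), tolerance = 1e-12)
    }
  }
  # identical groups: two-sided p = 1
  d3 <- data.frame(vaf = c(1.2, 3.4, 5.6, 1.2, 3.4, 5.6),
                   group = rep(c("a", "b"), each = 3))
  expect_equal(group_compare_vaf(d3, test = "mann-whitney")$p_value, 1)
  # empty group is not evaluable, never a fabricated p-value
  d4 <- data.frame(vaf = 1:3, group = factor(rep("a", 3),
                                             levels = c("a", "b")))
  r4 <- group_compare_vaf(d4, test = "mann-whitney")
  expect_equal(r4$note, "not-evaluable")
  expect_true(is.na(r4$p_value))
})

test_that("per-key comparisons report BH-adjusted alongside raw p-values", {
  set.seed(52)
  d <- data.frame(key = rep(c("g1", "g2", "g3"), each = 20),
                  vaf = rnorm(60), group = rep(c("pre", "post"), 30))
  res <- group_compare_vaf(d, key_col = "key", test = "t")
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adj, p.adjust(res$p_value, "BH"))
})

test_that("Fisher matches hypergeometric sums; CMH matches direct formula", {
  tab <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  r <- contingency_tests(tab, "fisher")
  expect_equal(r$p_value, fisher_oracle(tab), tolerance = 1e-10)
  expect_lt(r$p_value, 1.1e-5)
  r2 <- contingency_tests(matrix(c(5, 5, 5, 5), 2), "fisher")
  expect_equal(r2$p_value, 1)
  expect_equal(r2$odds_ratio, 1, tolerance = 1e-6)
  set.seed(53)
  for (i in 1:6) {
    t2 <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(contingency_tests(t2, "fisher")$p_value, fisher_oracle(t2),
                 tolerance = 1e-10)
  }
  # stratified: CMH equals the direct observed-minus-expected formula, and
  # for identical strata approaches the pooled chi-square
  one <- matrix(c(12, 5, 7, 14), 2)
  strat <- array(c(one, one), dim = c(2, 2, 2))
  cmh <- contingency_tests(strat, "cmh")
  direct <- {
    num <- 0; v <- 0
    for (s in 1:2) {
      tt <- strat[, , s]
      n <- sum(tt)
      e <- sum(tt[1, ]) * sum(tt[, 1]) / n
      num <- num + tt[1, 1] - e
      v <- v + sum(tt[1, ]) * sum(tt[2, ]) * sum(tt[, 1]) * sum(tt[, 2]) /
        (n^2 * (n - 1))
    }
    num^2 / v
  }
  expect_equal(cmh$statistic, direct, tolerance = 1e-10)
  pooled <- suppressWarnings(stats::chisq.test(one + one, correct = FALSE))
  expect_equal(cmh$statistic, unname(pooled$statistic), tolerance = 0.05)
  # all-zero margin
  r0 <- contingency_tests(matrix(c(0, 0, 3, 4), 2, byrow = TRUE), "fisher")
  expect_equal(r0$note, "not-evaluable")
})

test_that("Kaplan-Meier and log-rank match hand-worked instances", {
  # product-limit steps for three uncensored deaths
  km <- km_logrank(c(1, 2, 3), c(1, 1, 1))
  expect_equal(summary(km$fit)$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # identical groups: statistic 0, p = 1
  r0 <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(r0$chisq, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # two-group instance with censoring vs the direct O-E accumulation
  time <- c(6, 7, 10, 15, 19, 25, 23, 21, 5, 9, 13, 17)
  event <- c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1, 0)
  group <- rep(c("ctl", "trt"), each = 6)
  r <- km_logrank(time, event, group)
  expect_equal(r$chisq, logrank_oracle(time, event, group), tolerance = 1e-10)
  expect_equal(r$p_value, pchisq(r$chisq, 1, lower.tail = FALSE))
  # a group with zero subjects is not evaluable
  rg <- km_logrank(c(1, 2), c(1, 1),
                   factor(c("a", "a"), levels = c("a", "b")))
  expect_equal(rg$note, "not-evaluable")
  expect_error(km_logrank(c(1, 2), c(0, 0)), class = "invalid_argument")
})

test_that("survival of simulated sensitive patients exceeds insensitive", {
  co <- make_cohort(n_patients = 120, cycles_per_patient = 1, seed = 54)
  s <- co$samples
  g <- response_group(s$response)
  r <- km_logrank(s$os_time, s$os_event, g)
  med <- summary(r$fit)$table[, "median"]
  expect_gt(med[["g=sensitive"]], med[["g=insensitive"]])
  expect_lt(r$p_value, 0.05)
})

test_that("concordance reports overlap and all three fraction conventions", {
  a <- sprintf("1:%d:C:T", 1:5)
  expect_equal(concordance(a, a)$fraction_union, 1)
  expect_equal(concordance(a, sprintf("2:%d:C:T", 1:5))$n_overlap, 0)
  # constructed overlap 27 of 101 pooled calls
  plasma <- sprintf("1:%d:C:T", 1:60)
  tissue <- sprintf("1:%d:C:T", 34:101)
  cc <- concordance(plasma, tissue)
  expect_equal(cc$n_overlap, 27)
  expect_equal(cc$n_union, 101)
  expect_equal(round(cc$fraction_union, 3), 0.267)
  # union fraction symmetric in set exchange
  expect_equal(cc$fraction_union, concordance(tissue, plasma)$fraction_union)
})

test_that("actionability join matches exactly with monotone gene fallback", {
  tab <- data.frame(gene = c("KRAS", "EGFR"),
                    protein_change = c("G12C", NA),
                    drugs = c("ARS-853", "EGFR-TKI"), stringsAsFactors = FALSE)
  v <- data.frame(patient_id = c("P1", "P1", "P2", "P3"),
                  timepoint = c("pre", "post", "pre", "post"),
                  gene = c("KRAS", "KRAS", "EGFR", "TP53"),
                  protein_change = c("G12C", "G12C", "L858R", "R175H"),
                  stringsAsFactors = FALSE)
  res <- actionability_join(v, tab)
  expect_equal(res$matches$drugs[res$matches$gene == "KRAS"],
               c("ARS-853", "ARS-853"))
  av <- res$patient_availability
  expect_equal(av$availability[av$patient_id == "P1"], "pre_and_post")
  expect_equal(av$availability[av$patient_id == "P2"], "pre_only")
  # gene fallback off removes (and never adds) matches
  res_off <- actionability_join(v, tab, gene_fallback = FALSE)
  expect_lte(nrow(res_off$matches), nrow(res$matches))
  expect_false("EGFR" %in% res_off$matches$gene)
  # empty table: empty report
  empty <- actionability_join(v, tab[0, , drop = FALSE])
  expect_equal(nrow(empty$matches), 0)
})

test_that("VAF series pool correctly to pathway level", {
  co <- make_cohort(n_patients = 10, cycles_per_patient = 2, seed = 55)
  pw <- list(MAPK = c("KRAS", "EGFR", "BRAF"))
  sg <- vaf_series(co, "gene")
  sp <- vaf_series(co, "pathway", pathway_sets = pw)
  expect_equal(nrow(sp), sum(sg$key %in% pw$MAPK))
  expect_true(all(sp$vaf >= 0 & sp$vaf <= 1))
  res <- group_compare_vaf(sp, group_col = "timepoint", key_col = "key")
  expect_equal(res$key, "MAPK")
})
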