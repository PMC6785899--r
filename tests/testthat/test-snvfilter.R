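test_that("detection power matches exhaustive enumeration and edge cases", {
  m <- power_model(min_alt_reads = 4L, min_per_strand = 1L)
  expect_equal(detection_power(0, m, assumed_vaf = 0.3), 0)
  expect_equal(detection_power(3, m, assumed_vaf = 0.9), 0)
  expect_equal(detection_power(30, m, assumed_vaf = 0.3),
               power_oracle(30, 0.3), tolerance = 1e-14)
  for (d in c(5, 17, 42)) {
    for (v in c(0.02, 0.1, 0.5)) {
      expect_equal(detection_power(d, m, assumed_vaf = v),
                   power_oracle(d, v), tolerance = 1e-13)
    }
  }
  # other strand/support thresholds
  m2 <- power_model(min_alt_reads = 6L, min_per_strand = 2L)
  expect_equal(detection_power(25, m2, assumed_vaf = 0.2),
               power_oracle(25, 0.2, 6L, 2L), tolerance = 1e-13)
  expect_error(detection_power(10, m, assumed_vaf = 0),
               class = "invalid_argument")
})

test_that("power is monotone in depth and assumed VAF", {
  m <- power_model()
  grid_v <- c(0.01, 0.05, 0.2, 0.6)
  for (v in grid_v) {
    p <- detection_power(0:80, m, assumed_vaf = v)
    expect_true(all(diff(p) >= -1e-12))
  }
  for (d in c(10, 40, 120)) {
    p <- vapply(seq(0.01, 0.99, by = 0.02), function(v)
      detection_power(d, m, assumed_vaf = v), numeric(1))
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("posterior follows the two-hypothesis Bayes rule", {
  pr <- recurrence_prior(baseline_prior = 0.5, pseudocount = 1)
  # no evidence: posterior stays at/below the baseline prior
  expect_lte(posterior_probability(0, 100, pr), 0.5)
  # hand-computed closed form: alt 20 / depth 40, error 1e-3, prior 0.5
  l1 <- dbinom(20, 40, 0.5); l0 <- dbinom(20, 40, 0.001)
  expect_equal(posterior_probability(20, 40, pr),
               0.5 * l1 / (0.5 * l1 + 0.5 * l0), tolerance = 1e-12)
  # monotone in recurrence at fixed evidence
  p_r <- vapply(c(0, 1, 5, 100), function(r)
    posterior_probability(4, 3000, pr, recurrence_count = r), numeric(1))
  expect_true(all(diff(p_r) > 0))
  # monotone in alt count at fixed depth (above the error rate)
  p_a <- vapply(2:30, function(a) posterior_probability(a, 200, pr),
                numeric(1))
  expect_true(all(diff(p_a) >= 0))
  expect_error(recurrence_prior(baseline_prior = 1.2),
               class = "invalid_argument")
})

test_that("condition 1 applies the support/normal/coverage/database rules", {
  # clean site passes all four checks
  v <- candidate_variant(alt_fwd = 3L, alt_rev = 1L, depth_tumor = 100L,
                         depth_normal = 100L)
  expect_true(!any(unlist(condition1_support(v))))
  # strand rule: 4 mutant reads all forward
  v2 <- candidate_variant(alt_fwd = 4L, alt_rev = 0L)
  expect_true(condition1_support(v2)$C1_support)
  # population-frequency removal: 1 normal read + ExAC-style AF 0.002
  v3 <- candidate_variant(alt_normal = 1L, population_af = 0.002)
  expect_true(condition1_support(v3)$C1_db)
  # hotspot membership rescues 2 supporting normal reads
  v4 <- candidate_variant(alt_normal = 2L, in_hotspot_db = TRUE,
                          depth_normal = 400L)
  expect_false(condition1_support(v4)$C1_db)
  v5 <- candidate_variant(alt_normal = 2L, in_hotspot_db = FALSE,
                          depth_normal = 400L)
  expect_true(condition1_support(v5)$C1_db)
  # zero depth: coverage failure, VAF defined as 0, no division error
  v6 <- candidate_variant(depth_tumor = 0L, alt_fwd = 0L, alt_rev = 0L)
  c1 <- condition1_support(v6)
  expect_true(c1$C1_coverage)
  expect_equal(v6$vaf_tumor, 0)
})

test_that("condition 2 window rules: outlier, indel, mismatch, context", {
  # clean window, strong support
  v <- candidate_variant(alt_fwd = 5L, alt_rev = 5L)
  c2 <- condition2_local_context(v)
  expect_false(any(c2$C2_outlier, c2$C2_indel, c2$C2_mismatch,
                   c2$insufficient_context))
  # 3 indels within 10 bp
  expect_true(condition2_local_context(
    candidate_variant(n_indel_10bp = 3L))$C2_indel)
  expect_false(condition2_local_context(
    candidate_variant(n_indel_10bp = 2L))$C2_indel)
  # site not an outlier against flanking counts of equal size
  # (mean + 3*SD of a constant vector is the constant itself)
  v5 <- candidate_variant(alt_fwd = 3L, alt_rev = 2L,
                          flank_mm = list(rep(5, 10)))
  expect_true(condition2_local_context(v5)$C2_outlier)
  # hand-computed mean + k*SD bound: flanks 0..9 have mean 4.5, sd ~3.028;
  # site count 14 exceeds 4.5 + 3*3.028 = 13.58, 13 does not
  fl <- list(as.numeric(0:9))
  expect_false(condition2_local_context(
    candidate_variant(alt_fwd = 7L, alt_rev = 7L, flank_mm = fl))$C2_outlier)
  expect_true(condition2_local_context(
    candidate_variant(alt_fwd = 7L, alt_rev = 6L, flank_mm = fl))$C2_outlier)
  # mismatch enrichment: a flanking position exceeding the site count
  v6 <- candidate_variant(alt_fwd = 2L, alt_rev = 2L,
                          flank_mm = list(c(40, rep(0, 9))))
  c2b <- condition2_local_context(v6)
  expect_true(c2b$C2_mismatch)
  # missing window: insufficient context, not a pass
  v7 <- candidate_variant(flank_mm = list(rep(0, 4)))
  expect_true(condition2_local_context(v7)$insufficient_context)
})

test_that("cascade verdicts name exactly the engineered failure", {
  fx <- engineered_candidates()
  res <- run_cascade(fx$cands)
  expect_equal(res$verdicts$failed_conditions, unname(fx$expect))
  expect_equal(sum(res$verdicts$passed), 1L)
  expect_equal(res$counts[["n_candidates"]],
               res$counts[["n_passed"]] + res$counts[["n_failed"]] +
                 res$counts[["n_unevaluable"]])
})

test_that("cascade conditions are order-independent and audit-complete", {
  fx <- engineered_candidates()
  cands <- fx$cands
  # a variant failing several conditions reports all of them
  multi <- candidate_variant(alt_fwd = 4L, alt_rev = 0L, depth_tumor = 30L,
                             depth_normal = 30L, alt_normal = 5L)
  res <- run_cascade(rbind(cands, multi))
  last <- res$verdicts$failed_conditions[nrow(res$verdicts)]
  expect_true(all(c("C1_support", "C1_normal", "C1_coverage") %in%
                    strsplit(last, ",")[[1]]))
  # verdict flags equal independently evaluated conditions (no ordering
  # effect, no short-circuit)
  c1 <- condition1_support(cands)
  c2 <- condition2_local_context(cands)
  res2 <- run_cascade(cands)
  for (col in names(c1)) expect_equal(res2$verdicts[[col]], c1[[col]])
  for (col in c("C2_outlier", "C2_indel", "C2_mismatch")) {
    expect_equal(res2$verdicts[[col]], c2[[col]])
  }
})

test_that("disabling power/posterior reduces the cascade to conditions 1-2", {
  fx <- engineered_candidates()
  res0 <- run_cascade(fx$cands, power_threshold = 0, posterior_threshold = 0)
  c1 <- condition1_support(fx$cands)
  c2 <- condition2_local_context(fx$cands)
  manual <- !(rowSums(cbind(c1, c2[c("C2_outlier", "C2_indel",
                                     "C2_mismatch")])) > 0) &
    !c2$insufficient_context
  expect_equal(res0$verdicts$passed, manual)
})

test_that("unevaluable candidates are excluded but counted", {
  v <- rbind(candidate_variant(),
             candidate_variant(pos = 200L, flank_mm = list(rep(0, 3))))
  res <- run_cascade(v)
  expect_equal(res$counts[["n_unevaluable"]], 1L)
  expect_equal(res$verdicts$failed_conditions[2], "insufficient_context")
  expect_equal(nrow(res$passed), 1L)
})

test_that("cascade recovers truth on a simulated tumor/normal pair", {
  ds <- filter_recovery_dataset(seed = 31L)
  res <- run_cascade(ds$cands)
  passed <- res$verdicts$passed
  expect_equal(sum(passed[ds$origin == "germline"]), 0L)
  somatic_keys <- paste(ds$truth$position[ds$truth$origin == "somatic"],
                        ds$truth$alt[ds$truth$origin == "somatic"])
  found <- paste(ds$cands$pos, ds$cands$alt)[passed]
  recall <- mean(somatic_keys %in% found)
  expect_gte(recall, 0.9)
  # error-only sites essentially never pass
  expect_lte(mean(passed[ds$origin == "error"]), 0.01)
})
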