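test_that("reference generation is deterministic, seed-sensitive and valid", {
  r <- make_reference(3, seed = 1)
  expect_equal(nchar(r$sequence), 3)
  expect_true(grepl("^[ACGT]+$", r$sequence))
  a <- make_reference(1000, seed = 7)
  b <- make_reference(1000, seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, make_reference(1000, seed = 8)$sequence))
  expect_setequal(unique(strsplit(a$sequence, "")[[1]]), c("A", "C", "G", "T"))
  expect_error(make_reference(2), class = "invalid_argument")
  # generators restore the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_reference(50, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("truth variants sit on the reference with consistent alleles", {
  ref <- make_reference(2000, seed = 2)
  tr <- make_truth_variants(ref, 10, 10, 5, seed = 3)
  expect_equal(nrow(tr), 25)
  expect_identical(tr$ref, ref_base(ref, tr$position))
  expect_true(all(tr$ref != tr$alt))
  expect_true(all(diff(sort(tr$position)) >= 25))
  expect_true(all(tr$true_vaf[tr$origin == "germline"] %in% c(0.5, 1.0)))
})

test_that("simulated reads honour tumor fraction, VAF and fragment peaks", {
  ref <- make_reference(3000, seed = 4)
  tr <- make_truth_variants(ref, 5, 0, 0, somatic_vaf_range = c(0.5, 0.5),
                            seed = 5)
  # tumor_fraction 0: no somatic alt beyond error background
  sim0 <- simulate_reads(ref, tr, tumor_fraction = 0, n_reads = 4000,
                         error_rate = 0, seed = 6)
  expect_equal(nrow(sim0$mismatches), 0)
  # tumor_fraction 1, error 0, VAF 0.5: observed alt fraction within a
  # 4-sigma binomial band at the realised coverage
  sim1 <- simulate_reads(ref, tr, tumor_fraction = 1, n_reads = 4000,
                         error_rate = 0, seed = 7)
  pu <- pileup_from_reads(sim1, ref)
  for (k in seq_len(nrow(tr))) {
    i <- match(tr$position[k], pu$sites$pos)
    d <- pu$sites$depth[i]
    a <- pu$alt[pu$alt$pos == tr$position[k] & pu$alt$base == tr$alt[k], ]
    alt_n <- if (nrow(a)) a$fwd + a$rev else 0L
    expect_lt(abs(alt_n / d - 0.5), 4 * sqrt(0.25 / d))
  }
  # fragment peaks: tumor-component inserts shorter on average
  simm <- simulate_reads(ref, NULL, tumor_fraction = 0.3, n_reads = 4000,
                         seed = 8)
  mt <- mean(simm$reads$insert_size[simm$reads$origin == "tumor"])
  mb <- mean(simm$reads$insert_size[simm$reads$origin == "background"])
  expect_lt(mt, mb)
  expect_lt(abs(mt - 133), 2)
  expect_lt(abs(mb - 167), 2)
  expect_error(simulate_reads(ref, tr, tumor_fraction = 1.5),
               class = "invalid_argument")
})

test_that("pileup counts match a brute-force recount and conserve depth", {
  ref <- make_reference(300, seed = 9)
  tr <- make_truth_variants(ref, 3, 2, 0, margin = 12, seed = 10)
  sim <- simulate_reads(ref, tr, tumor_fraction = 0.5, n_reads = 150,
                        frag = frag_model(spread = 10), error_rate = 0.002,
                        seed = 11)
  pu <- pileup_from_reads(sim, ref)
  oracle <- pileup_recount_oracle(sim, ref)
  expect_equal(pu$sites$depth, oracle$depth)
  # every observed alt allele count matches the recount, per strand
  for (i in seq_len(nrow(pu$alt))) {
    a <- pu$alt[i, ]
    expect_equal(a$fwd,
                 oracle$base_counts[[paste(a$pos, a$base, "+")]] %||% 0L)
    expect_equal(a$rev,
                 oracle$base_counts[[paste(a$pos, a$base, "-")]] %||% 0L)
  }
  # allele counts at a site sum to depth: non-ref counts = mm_total
  mmsum <- tapply(pu$alt$fwd + pu$alt$rev, pu$alt$pos, sum)
  expect_equal(as.vector(mmsum),
               pu$sites$mm_total[match(as.integer(names(mmsum)),
                                       pu$sites$pos)])
  # empty input
  empty <- sim; empty$reads <- empty$reads[0, ]; empty$mismatches <- empty$mismatches[0, ]
  expect_equal(nrow(pileup_from_reads(empty, ref)$sites), 0)
})

test_that("cohort burden decays at the configured per-cycle rate", {
  # decay 1.0: constant burden in expectation
  c1 <- make_cohort(n_patients = 200, cycles_per_patient = 3,
                    decay_sensitive = 1, decay_insensitive = 1, seed = 12)
  b1 <- burden_by_cycle(c1)$burden
  m_pre <- mean(b1$n_total[b1$cycle_index == 0])
  m_post <- mean(b1$n_total[b1$cycle_index == 2])
  expect_lt(abs(m_post / m_pre - 1), 0.05)
  # decay 0.5: successive-cycle ratio near 0.5
  c2 <- make_cohort(n_patients = 1000, cycles_per_patient = 3,
                    decay_sensitive = 0.5, decay_insensitive = 0.5, seed = 13)
  b2 <- burden_by_cycle(c2)$burden
  r01 <- mean(b2$n_total[b2$cycle_index == 1]) /
    mean(b2$n_total[b2$cycle_index == 0])
  r12 <- mean(b2$n_total[b2$cycle_index == 2]) /
    mean(b2$n_total[b2$cycle_index == 1])
  expect_lt(abs(r01 - 0.5), 0.03)
  expect_lt(abs(r12 - 0.5), 0.03)
  # response mix: about half the patients sensitive at fraction 0.5
  s <- c2$samples[c2$samples$cycle_index == 0, ]
  frac_sens <- mean(response_group(s$response) == "sensitive")
  expect_lt(abs(frac_sens - 0.5), 3 * sqrt(0.25 / 1000))
  # cycle 0 is exactly the pre timepoint
  expect_identical(c2$samples$timepoint == "pre", c2$samples$cycle_index == 0)
})

test_that("sampled catalogs follow the signature mixture", {
  S <- synthetic_signature_catalog()
  expect_equal(colSums(S), setNames(rep(1, 30), colnames(S)), tolerance = 1e-9)
  # one-hot: empirical profile close to the column
  cat1 <- sample_catalog(S, c(1, rep(0, 29)), 20000, seed = 14)
  expect_equal(cat1$total, 20000)
  expect_lt(max(abs(cat1$counts / cat1$total - S[, 1])), 0.02)
  # 0.7/0.3 mixture over two signatures
  w <- c(0.7, 0.3)
  S2 <- S[, c(4, 16)]
  cat2 <- sample_catalog(S2, w, 10000, seed = 15)
  mix <- as.vector(S2 %*% w)
  dev <- abs(cat2$counts / cat2$total - mix)
  expect_true(all(dev < 4 * sqrt(mix * (1 - mix) / 10000) + 1e-6))
  # n = 0: all-zero catalog
  expect_equal(sum(sample_catalog(S, c(1, rep(0, 29)), 0)$counts), 0)
  expect_error(sample_catalog(S, c(-0.1, 1.1, rep(0, 28)), 10),
               class = "invalid_argument")
})
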