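# Engineered candidate fixtures: each row is built to fail exactly one
# cascade condition; the clean row passes everything. Returns the candidate
# table plus the expected failure code per row.
engineered_candidates <- function() {
  rows <- list(
    clean = list(cand = candidate_variant(pos = 100L, alt_fwd = 10L,
                                          alt_rev = 10L, depth_tumor = 200L,
                                          depth_normal = 200L),
                 expect = ""),
    support = list(cand = candidate_variant(pos = 110L, alt_fwd = 10L,
                                            alt_rev = 0L, depth_tumor = 100L,
                                            depth_normal = 200L),
                   expect = "C1_support"),
    normal = list(cand = candidate_variant(pos = 120L, alt_fwd = 10L,
                                           alt_rev = 10L, depth_tumor = 400L,
                                           depth_normal = 400L,
                                           alt_normal = 3L,
                                           in_hotspot_db = TRUE),
                  expect = "C1_normal"),
    coverage = list(cand = candidate_variant(pos = 130L, alt_fwd = 5L,
                                             alt_rev = 5L, depth_tumor = 30L,
                                             depth_normal = 35L),
                    expect = "C1_coverage"),
    db = list(cand = candidate_variant(pos = 140L, alt_fwd = 10L,
                                       alt_rev = 10L, depth_tumor = 400L,
                                       depth_normal = 400L, alt_normal = 1L,
                                       population_af = 0.002),
              expect = "C1_db"),
    outlier = list(cand = candidate_variant(pos = 150L, alt_fwd = 5L,
                                            alt_rev = 5L, depth_tumor = 100L,
                                            depth_normal = 200L,
                                            flank_mm = list(rep(10, 10))),
                   expect = "C2_outlier"),
    indel = list(cand = candidate_variant(pos = 160L, alt_fwd = 10L,
                                          alt_rev = 10L, depth_tumor = 200L,
                                          depth_normal = 200L,
                                          n_indel_10bp = 3L),
                 expect = "C2_indel"),
    mismatch = list(cand = candidate_variant(pos = 170L, alt_fwd = 5L,
                                             alt_rev = 5L, depth_tumor = 200L,
                                             depth_normal = 200L,
                                             n_alt_extra_mm = 10L),
                    expect = "C2_mismatch"),
    power = list(cand = candidate_variant(pos = 180L, alt_fwd = 2L,
                                          alt_rev = 2L, depth_tumor = 40L,
                                          depth_normal = 200L),
                 expect = "C3_power"),
    posterior = list(cand = candidate_variant(pos = 190L, alt_fwd = 3L,
                                              alt_rev = 1L,
                                              depth_tumor = 3000L,
                                              depth_normal = 3000L),
                     expect = "C4_posterior"))
  cands <- do.call(rbind, lapply(rows, `[[`, "cand"))
  rownames(cands) <- NULL
  list(cands = cands, expect = vapply(rows, `[[`, "", "expect"))
}

# Truth-labelled synthetic cascade dataset matching the filter-recovery
# study conditions: somatic variants at VAF >= 0.05 and depth >= 200,
# germline heterozygotes, plus error-only sites at error rate 1e-3.
filter_recovery_dataset <- function(seed = 11L, n_somatic = 20L,
                                    n_germline = 20L, n_error_sites = 50L,
                                    n_reads = 9000L, ref_length = 3000L,
                                    error_rate = 1e-3) {
  ref <- make_reference(ref_length, seed = seed)
  truth <- make_truth_variants(ref, n_somatic = n_somatic,
                               n_germline = n_germline, n_artifact = 0L,
                               somatic_vaf_range = c(0.05, 0.4),
                               germline_hom_fraction = 0, margin = 250L,
                               seed = seed + 1L)
  tumor <- simulate_reads(ref, truth, tumor_fraction = 1,
                          n_reads = n_reads, error_rate = error_rate,
                          seed = seed + 2L)
  normal <- simulate_reads(ref, truth, tumor_fraction = 0,
                           n_reads = n_reads, error_rate = error_rate,
                           seed = seed + 3L)
  fixtures <- make_annotation_fixtures(ref, truth, seed = seed + 4L)
  tpu <- pileup_from_reads(tumor, ref)
  npu <- pileup_from_reads(normal, ref)
  cands <- annotate_candidates(make_candidates(tpu, npu, min_alt_reads = 1L),
                               fixtures, ref)
  key <- paste(cands$pos, cands$alt)
  tkey <- paste(truth$position, truth$alt)
  origin <- truth$origin[match(key, tkey)]
  origin[is.na(origin)] <- "error"
  # error-only evaluation set: candidate sites with no truth variant
  list(ref = ref, truth = truth, cands = cands, origin = origin,
       tumor_pileup = tpu, normal_pileup = npu, n_error_sites = n_error_sites)
}
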