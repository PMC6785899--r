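#' Pipeline configuration
#'
#' All thresholds of the filter cascade and the synthetic-data parameters in
#' one validated object. Defaults are the published cascade values: insert
#' threshold 150 bp, >= 4 mutant reads with >= 1 per strand, <= 2 mutant
#' reads and VAF < 0.01 in normal, 40-fold coverage, population AF cutoff
#' 0.001, 11-bp context window with indel radius 10 bp, power > 0.80 and
#' posterior > 0.8. The configuration round-trips through JSON unchanged.
#'
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param out_dir Output directory.
#' @param ref_length,n_reads,tumor_fraction,error_rate Simulation scale.
#' @param n_somatic,n_germline,n_artifact Truth-set composition.
#' @param insert_threshold Fragment-selection cutoff (bp).
#' @param min_alt_reads,min_per_strand,max_normal_alt,max_normal_vaf,min_coverage,min_population_af
#'   Condition-1 thresholds.
#' @param outlier_k,max_extra_mm_fraction Condition-2 tuning.
#' @param power_threshold,posterior_threshold Condition 3/4 cutoffs.
#' @param select_fragments Apply the short-fragment selection before calling
#'   (the remoulded path); `FALSE` calls on the original read set.
#' @param cohort_patients,cohort_cycles Longitudinal stage scale.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("ctdna_run_"),
                            ref_length = 4000L, n_reads = 30000L,
                            tumor_fraction = 0.2, error_rate = 1e-3,
                            n_somatic = 20L, n_germline = 20L,
                            n_artifact = 0L,
                            insert_threshold = 150L,
                            min_alt_reads = 4L, min_per_strand = 1L,
                            max_normal_alt = 2L, max_normal_vaf = 0.01,
                            min_coverage = 40L, min_population_af = 0.001,
                            outlier_k = 3, max_extra_mm_fraction = 0.2,
                            power_threshold = 0.80, posterior_threshold = 0.8,
                            select_fragments = TRUE,
                            cohort_patients = 32L, cohort_cycles = 3L) {
  cfg <- as.list(environment())
  checks <- c(tumor_fraction >= 0 && tumor_fraction <= 1,
              error_rate >= 0 && error_rate < 1,
              insert_threshold > 0, min_alt_reads >= 0, min_per_strand >= 0,
              max_normal_vaf >= 0 && max_normal_vaf <= 1,
              min_coverage >= 0, power_threshold >= 0 && power_threshold <= 1,
              posterior_threshold >= 0 && posterior_threshold <= 1,
              ref_length >= 100, n_reads >= 1)
  if (!all(checks)) stop_invalid("pipeline_config: threshold out of range")
  structure(cfg, class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @return `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in order: reference and truth simulation, paired
#' tumor/normal read simulation, short-fragment selection, pileup, candidate
#' generation and annotation, the five-condition filter cascade, spectrum
#' and signature fitting, and the longitudinal cohort statistics. All
#' outputs are plain text under `config$out_dir`; identical configurations
#' (including the seed) produce byte-identical outputs. The returned
#' manifest satisfies `n_candidates = n_passed + n_failed + n_unevaluable`.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_manifest`: per-stage record counts,
#'   file paths, and the configuration used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  seed <- as.integer(config$seed)

  ref <- make_reference(config$ref_length, seed = seed)
  truth <- make_truth_variants(ref, n_somatic = config$n_somatic,
                               n_germline = config$n_germline,
                               n_artifact = config$n_artifact,
                               seed = seed + 1L)
  fixtures <- make_annotation_fixtures(ref, truth, seed = seed + 2L)
  tumor <- simulate_reads(ref, truth, tumor_fraction = config$tumor_fraction,
                          n_reads = config$n_reads,
                          error_rate = config$error_rate, seed = seed + 3L)
  normal <- simulate_reads(ref, truth, tumor_fraction = 0,
                           n_reads = config$n_reads,
                           error_rate = config$error_rate, seed = seed + 4L)

  fs <- select_short_fragments(tumor, config$insert_threshold)
  call_reads <- if (config$select_fragments) fs$reads else tumor

  tpu <- pileup_from_reads(call_reads, ref)
  npu <- pileup_from_reads(normal, ref)
  cands <- make_candidates(tpu, npu)
  cands <- annotate_candidates(cands, fixtures, ref)

  model <- power_model(error_rate = max(config$error_rate, 1e-6),
                       min_alt_reads = config$min_alt_reads,
                       min_per_strand = config$min_per_strand)
  res <- run_cascade(cands, model = model,
                     power_threshold = config$power_threshold,
                     posterior_threshold = config$posterior_threshold,
                     outlier_k = config$outlier_k,
                     max_extra_mm_fraction = config$max_extra_mm_fraction)

  catalog <- build_catalog(res$passed, ref, sample_id = "pipeline")
  fit <- fit_signatures(catalog, fixtures$signature_catalog)

  cohort <- make_cohort(n_patients = config$cohort_patients,
                        cycles_per_patient = config$cohort_cycles,
                        seed = seed + 5L)
  burden <- burden_by_cycle(cohort)

  write_sam(tumor, ref, p("tumor_all.sam"))
  write_sam(fs$reads, ref, p("tumor_short.sam"))
  write.table(fs$report, p("fragselect_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_pileup_tsv(tpu, p("tumor_pileup.tsv"))
  write_candidate_vcf(cands, res$verdicts, p("candidates.vcf"))
  vd <- res$verdicts
  write.table(vd, p("verdicts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_catalog_tsv(catalog, p("catalog.tsv"))
  write.table(data.frame(signature = names(fit$weights),
                         weight = unname(fit$weights),
                         fraction = unname(fit$fractions)),
              p("signature_fit.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(burden$burden, p("burden.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_pipeline_config(config, p("config.json"))

  manifest <- list(
    seed = seed,
    counts = c(n_reads = nrow(tumor$reads),
               n_reads_short = nrow(fs$reads$reads),
               n_truth = nrow(truth),
               res$counts,
               n_catalog_mutations = catalog$total,
               n_cohort_samples = nrow(cohort$samples)),
    files = c(tumor_all = p("tumor_all.sam"),
              tumor_short = p("tumor_short.sam"),
              fragselect_report = p("fragselect_report.tsv"),
              truth = p("truth.tsv"), tumor_pileup = p("tumor_pileup.tsv"),
              candidates = p("candidates.vcf"),
              verdicts = p("verdicts.tsv"), catalog = p("catalog.tsv"),
              signature_fit = p("signature_fit.tsv"),
              burden = p("burden.tsv"), config = p("config.json")),
    config = unclass(config))
  jsonlite::write_json(manifest[c("seed", "counts")], p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(manifest, class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest>\n")
  print(x$counts)
  invisible(x)
}
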