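#' Select tumor-enriched short cfDNA fragments
#'
#' Reconstructs the "remoulded" read set: because ctDNA fragments peak near
#' 133 bp and background cfDNA near 167 bp, keeping fragments with insert
#' size strictly below a threshold (default 150 bp) enriches for
#' tumor-derived molecules. The absolute value of the insert/template-length
#' field is used (SAM encodes signed TLEN); records with insert size 0 or
#' missing carry no usable fragment length and are dropped and counted
#' separately.
#'
#' @param reads A `sim_reads` object (see [simulate_reads()]) or a data frame
#'   with an `insert_size` column.
#' @param threshold_bp Strict upper bound on |insert size| (bp); must be > 0.
#' @return List with `reads` (the retained subset, same class as the input)
#'   and `report`, a one-row data frame: `n_input_reads`, `n_retained`,
#'   `n_no_insert`, `retained_fraction`, `insert_threshold`,
#'   `mean_insert_before`, `mean_insert_after`.
#' @export
select_short_fragments <- function(reads, threshold_bp = 150L) {
  if (threshold_bp <= 0) stop_invalid("threshold_bp must be positive")
  is_sim <- inherits(reads, "sim_reads")
  rd <- if (is_sim) reads$reads else reads
  ins <- abs(rd$insert_size)
  usable <- !is.na(ins) & ins > 0
  keep <- usable & ins < threshold_bp
  report <- data.frame(
    n_input_reads = nrow(rd),
    n_retained = sum(keep),
    n_no_insert = sum(!usable),
    retained_fraction = if (nrow(rd)) sum(keep) / nrow(rd) else 0,
    insert_threshold = threshold_bp,
    mean_insert_before = if (any(usable)) mean(ins[usable]) else NA_real_,
    mean_insert_after = if (any(keep)) mean(ins[keep]) else NA_real_)
  if (is_sim) {
    kept_ids <- rd$read_id[keep]
    out <- structure(list(
      reads = rd[keep, , drop = FALSE],
      mismatches = reads$mismatches[reads$mismatches$read_id %in% kept_ids, ,
                                    drop = FALSE],
      contig = reads$contig), class = "sim_reads")
    rownames(out$reads) <- NULL
    rownames(out$mismatches) <- NULL
  } else {
    out <- rd[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  list(reads = out, report = report)
}
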