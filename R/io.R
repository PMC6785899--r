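# Plain-text interchange for simulated fragments and pileups. Fragments are
# written as minimal single-end SAM records (one line per fragment, fragment
# length in the TLEN field, mismatches materialised into SEQ); Rsamtools
# handles the binary BAM side of the format, these writers keep the
# text-only synthetic path self-contained.

#' Write simulated fragments as a SAM file
#'
#' One alignment line per fragment: FLAG 0/16 encodes strand, POS is 1-based,
#' CIGAR is `<len>M`, TLEN carries the signed fragment length and SEQ is the
#' reference substring with the fragment's mismatches applied.
#'
#' @param sim A `sim_reads` object.
#' @param ref The `ref_context` the reads came from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$contig, ref_length(ref))), con)
  rd <- sim$reads
  if (!nrow(rd)) return(invisible(path))
  mm <- split(sim$mismatches, sim$mismatches$read_id)
  seqs <- vapply(seq_len(nrow(rd)), function(i) {
    s <- substring(ref$sequence,
                   rd$start[i] - ref$origin_coordinate + 1L,
                   rd$start[i] - ref$origin_coordinate + rd$insert_size[i])
    m <- mm[[as.character(rd$read_id[i])]]
    if (!is.null(m)) {
      for (j in seq_len(nrow(m))) {
        substr(s, m$offset[j] + 1L, m$offset[j] + 1L) <- m$base[j]
      }
    }
    s
  }, character(1))
  flag <- ifelse(rd$strand == "+", 0L, 16L)
  tlen <- ifelse(rd$strand == "+", rd$insert_size, -rd$insert_size)
  lines <- sprintf("rd%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t%d\t%s\t*\tXO:Z:%s",
                   rd$read_id, flag, rd$contig,
                   rd$start - ref$origin_coordinate + 1L,
                   rd$insert_size, tlen, seqs, rd$origin)
  writeLines(lines, con)
  invisible(path)
}

#' Read fragments back from a SAM file written by [write_sam()]
#'
#' @param path SAM path.
#' @param ref The matching `ref_context` (used to recover mismatches from
#'   SEQ).
#' @return A `sim_reads` object.
#' @export
read_sam <- function(path, ref) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(structure(list(reads = data.frame(read_id = integer(0),
                                             contig = character(0),
                                             start = integer(0),
                                             insert_size = integer(0),
                                             strand = character(0),
                                             origin = character(0),
                                             stringsAsFactors = FALSE),
                          mismatches = data.frame(read_id = integer(0),
                                                  offset = integer(0),
                                                  base = character(0),
                                                  stringsAsFactors = FALSE),
                          contig = ref$contig), class = "sim_reads"))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(f)
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L +
    ref$origin_coordinate
  tlen <- vapply(f, function(x) as.integer(x[9]), integer(1))
  strand <- ifelse(bitwAnd(vapply(f, function(x) as.integer(x[2]), integer(1)),
                           16L) > 0L, "-", "+")
  origin <- vapply(f, function(x) {
    tag <- grep("^XO:Z:", x, value = TRUE)
    if (length(tag)) sub("^XO:Z:", "", tag[1]) else "unknown"
  }, character(1))
  seqs <- vapply(f, `[`, character(1), 10L)
  reads <- data.frame(read_id = seq_len(n), contig = ref$contig,
                      start = start, insert_size = abs(tlen), strand = strand,
                      origin = origin, stringsAsFactors = FALSE)
  mm_id <- integer(0); mm_off <- integer(0); mm_base <- character(0)
  for (i in seq_len(n)) {
    refseq <- substring(ref$sequence, start[i] - ref$origin_coordinate + 1L,
                        start[i] - ref$origin_coordinate + abs(tlen[i]))
    a <- strsplit(seqs[i], "")[[1]]
    b <- strsplit(refseq, "")[[1]]
    d <- which(a != b)
    if (length(d)) {
      mm_id <- c(mm_id, rep(i, length(d)))
      mm_off <- c(mm_off, d - 1L)
      mm_base <- c(mm_base, a[d])
    }
  }
  structure(list(reads = reads,
                 mismatches = data.frame(read_id = mm_id, offset = mm_off,
                                         base = mm_base,
                                         stringsAsFactors = FALSE),
                 contig = ref$contig), class = "sim_reads")
}

#' Write a pileup's site table as TSV
#' @param pileup A `pileup` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(pileup$sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write candidates and verdicts as a minimal VCF
#'
#' VCFv4.2 with the cascade verdict in FILTER (PASS or the comma-joined
#' failed condition codes) and power/posterior in INFO.
#'
#' @param cands A `candidates` data frame.
#' @param verdicts The matching verdict table from [run_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_vcf <- function(cands, verdicts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=PW,Number=1,Type=Float,Description=\"Detection power\">",
               "##INFO=<ID=PP,Number=1,Type=Float,Description=\"Somatic posterior probability\">",
               "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Tumor VAF\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(cands)) {
    filt <- ifelse(verdicts$passed, "PASS",
                   gsub(",", ";", verdicts$failed_conditions))
    filt[filt == ""] <- "PASS"
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tPW=%.6g;PP=%.6g;TVAF=%.6g",
                     cands$contig, cands$pos + 1L, cands$ref, cands$alt,
                     filt, verdicts$power, verdicts$posterior,
                     cands$vaf_tumor)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a mutation catalog as a channel-labelled TSV
#' @param catalog A `mutation_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- data.frame(channel = names(catalog$counts),
                   count = as.integer(catalog$counts))
  names(df)[2] <- catalog$sample_id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
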