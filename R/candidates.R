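#' Naive pileup-based candidate generation
#'
#' Turns paired tumor/normal pileups into a candidate variant table: every
#' non-reference allele with at least `min_alt_reads` supporting reads in the
#' tumor becomes a candidate, carrying the paired evidence the filter cascade
#' judges (strand-split tumor counts, normal counts, 11-bp window mismatch
#' profile, indel counts within 10 bp, extra-mismatch read counts). This is a
#' deliberately permissive generator for end-to-end synthetic runs; in a real
#' deployment candidates come from external callers and only the evidence
#' assembly here applies.
#'
#' @param tumor_pileup,normal_pileup `pileup` objects from
#'   [pileup_from_reads()], aligned to the same reference.
#' @param min_alt_reads Minimum tumor mutant reads to emit a candidate
#'   (default 2).
#' @param window_halfwidth Half-width of the context window (default 5, the
#'   11-bp window).
#' @param indel_radius Radius for the indel count (default 10 bp).
#' @return A `candidates` data frame (see [candidate_variant()]).
#' @export
make_candidates <- function(tumor_pileup, normal_pileup, min_alt_reads = 2L,
                            window_halfwidth = 5L, indel_radius = 10L) {
  ts <- tumor_pileup$sites
  ta <- tumor_pileup$alt
  ta <- ta[ta$fwd + ta$rev >= min_alt_reads, , drop = FALSE]
  # drop alleles equal to the reference base (can't happen from mismatches,
  # but guard anyway)
  ta <- ta[ta$base != ts$ref[match(ta$pos, ts$pos)], , drop = FALSE]
  if (!nrow(ta)) return(candidate_variant()[0, , drop = FALSE])
  ns <- normal_pileup$sites
  na <- normal_pileup$alt
  mm_at <- function(pos) {
    i <- match(pos, ts$pos)
    ifelse(is.na(i), NA_integer_, ts$mm_total[i])
  }
  indel_at <- function(pos) {
    i <- match(pos, ts$pos)
    ifelse(is.na(i), 0L, ts$indel_count[i])
  }
  rows <- lapply(seq_len(nrow(ta)), function(k) {
    p <- ta$pos[k]; b <- ta$base[k]
    it <- match(p, ts$pos); inm <- match(p, ns$pos)
    site_ref <- ts$ref[it]
    # flanking mismatch counts exclude the site itself; mismatches at the
    # site from other alt alleles still count toward nothing here (the site
    # column is the candidate's own support)
    offs <- setdiff(seq.int(-window_halfwidth, window_halfwidth), 0L)
    fl <- vapply(p + offs, mm_at, numeric(1))
    fl <- fl[!is.na(fl)]
    ind <- sum(vapply(seq.int(p - indel_radius, p + indel_radius), indel_at,
                      integer(1)))
    ia <- which(na$pos == p & na$base == b)
    alt_n <- if (length(ia)) na$fwd[ia] + na$rev[ia] else 0L
    dn <- if (!is.na(inm)) ns$depth[inm] else 0L
    candidate_variant(contig = ts$contig[it], pos = p, ref = site_ref,
                      alt = b, alt_fwd = ta$fwd[k], alt_rev = ta$rev[k],
                      depth_tumor = ts$depth[it], depth_normal = dn,
                      alt_normal = alt_n, flank_mm = list(fl),
                      n_indel_10bp = as.integer(ind),
                      n_alt_extra_mm = ta$n_extra_mm[k])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate candidates against fixture databases and a toy gene model
#'
#' Adds SNP-database membership, population allele frequency, hotspot
#' membership, the containing gene and a simplified effect class
#' (silent / nonsilent / noncoding) with a protein-change label, by
#' translating the affected codon of the toy gene model against the
#' reference.
#'
#' @param cands A `candidates` data frame.
#' @param fixtures An `annotation_fixtures` object
#'   ([make_annotation_fixtures()]).
#' @param ref The `ref_context`.
#' @return The input with annotation columns filled in.
#' @export
annotate_candidates <- function(cands, fixtures, ref) {
  if (!nrow(cands)) return(cands)
  key <- paste(cands$contig, cands$pos, cands$alt)
  skey <- with(fixtures$snp_sites, paste(contig, position, alt))
  hkey <- with(fixtures$hotspot_sites, paste(contig, position, alt))
  cands$in_snp_db <- key %in% skey
  cands$in_hotspot_db <- key %in% hkey
  pkey <- with(fixtures$population_af, paste(contig, position, alt))
  pidx <- match(key, pkey)
  cands$population_af <- ifelse(is.na(pidx), NA_real_,
                                fixtures$population_af$af[pidx])
  eff <- classify_effect(cands$pos, cands$alt, fixtures$gene_model, ref)
  cands$gene <- eff$gene
  cands$effect <- eff$effect
  cands$protein_change <- eff$protein_change
  cands
}

#' Classify coding effect against a toy gene model
#'
#' A substitution inside a coding interval is translated: if the altered
#' codon encodes the same amino acid the call is `silent`, otherwise
#' `nonsilent` (protein change like `"G12C"`); positions outside every
#' interval are `noncoding`. Intervals carry a `frame` offset (0-based
#' position of the first complete codon relative to `start`); minus-strand
#' intervals are translated from the reverse complement.
#'
#' @param pos 0-based positions.
#' @param alt Alternate alleles.
#' @param gene_model Data frame `gene`, `contig`, `start`, `end` (0-based,
#'   end-exclusive), `strand`, `frame`.
#' @param ref The `ref_context`.
#' @return Data frame `gene`, `effect`, `protein_change`.
#' @export
classify_effect <- function(pos, alt, gene_model, ref) {
  gc <- Biostrings::GENETIC_CODE
  n <- length(pos)
  gene <- rep(NA_character_, n)
  effect <- rep("noncoding", n)
  pchange <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- which(gene_model$start <= pos[i] & pos[i] < gene_model$end)
    if (!length(hit)) next
    gm <- gene_model[hit[1], ]
    gene[i] <- gm$gene
    if (gm$strand == "+") {
      cds_off <- pos[i] - gm$start - gm$frame
      if (cds_off < 0) next
      ci <- cds_off %/% 3L
      c0 <- gm$start + gm$frame + 3L * ci
      if (c0 + 2L >= gm$end) next
      codon <- paste(ref_base(ref, c0 + 0:2), collapse = "")
      within <- pos[i] - c0 + 1L
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt[i]
    } else {
      cds_off <- (gm$end - 1L - gm$frame) - pos[i]
      if (cds_off < 0) next
      ci <- cds_off %/% 3L
      c2 <- gm$end - 1L - gm$frame - 3L * ci   # codon's first base on - strand
      if (c2 - 2L < gm$start) next
      codon <- revcomp(paste(ref_base(ref, (c2 - 2L):c2), collapse = ""))
      within <- c2 - pos[i] + 1L
      alt_codon <- codon
      substr(alt_codon, within, within) <- chartr("ACGT", "TGCA", alt[i])
    }
    aa_ref <- unname(gc[codon]); aa_alt <- unname(gc[alt_codon])
    if (is.na(aa_ref) || is.na(aa_alt)) next
    if (aa_ref == aa_alt) {
      effect[i] <- "silent"
    } else {
      effect[i] <- "nonsilent"
      pchange[i] <- paste0(aa_ref, ci + 1L, aa_alt)
    }
  }
  data.frame(gene = gene, effect = effect, protein_change = pchange,
             stringsAsFactors = FALSE)
}
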