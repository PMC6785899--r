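#' Generate a random reference context
#'
#' Builds a single synthetic contig of i.i.d. A/C/G/T bases. Positions
#' throughout the package are 0-based; the contig starts at
#' `origin_coordinate` (default 0). Interior positions (1 .. length-2) have a
#' full trinucleotide context, which the 96-channel spectrum classifier
#' requires.
#'
#' @param length Number of bases; must be at least 3.
#' @param seed Integer seed; the result is a pure function of `(length, seed)`.
#' @param contig Contig name.
#' @param origin_coordinate 0-based coordinate of the first base.
#' @return An object of class `ref_context` with fields `contig`, `sequence`
#'   (a single upper-case string) and `origin_coordinate`.
#' @export
make_reference <- function(length, seed = 1L, contig = "sim1",
                           origin_coordinate = 0L) {
  if (length < 3) stop_invalid("reference length must be >= 3")
  seq <- with_seed(seed, paste(sample(BASES, length, replace = TRUE),
                               collapse = ""))
  structure(list(contig = contig, sequence = seq,
                 origin_coordinate = as.integer(origin_coordinate)),
            class = "ref_context")
}

#' @export
print.ref_context <- function(x, ...) {
  cat(sprintf("<ref_context> %s: %d bp starting at %d\n", x$contig,
              nchar(x$sequence), x$origin_coordinate))
  invisible(x)
}

ref_length <- function(ref) nchar(ref$sequence)

#' Look up reference bases at 0-based positions
#' @param ref A `ref_context`.
#' @param pos Integer vector of 0-based positions.
#' @return Character vector of bases ("N" outside the contig).
#' @export
ref_base <- function(ref, pos) {
  i <- pos - ref$origin_coordinate + 1L
  out <- rep("N", length(pos))
  ok <- i >= 1L & i <= ref_length(ref)
  out[ok] <- substring(ref$sequence, i[ok], i[ok])
  out
}

#' Trinucleotide context around 0-based positions
#' @inheritParams ref_base
#' @return Character vector of 3-mers centred on `pos`; `NA` at contig edges.
#' @export
ref_context3 <- function(ref, pos) {
  i <- pos - ref$origin_coordinate + 1L
  out <- rep(NA_character_, length(pos))
  ok <- i >= 2L & i <= ref_length(ref) - 1L
  if (any(ok)) out[ok] <- substring(ref$sequence, i[ok] - 1L, i[ok] + 1L)
  out
}

#' Place truth variants on a reference
#'
#' Draws distinct interior positions and assigns alt alleles, true VAFs and
#' origins. Somatic variants live only in the tumor read component; germline
#' variants are carried by every cell at VAF 0.5 or 1.0 (diploid
#' heterozygous/homozygous); artifact entries model low-level systematic
#' noise present on all reads.
#'
#' @param ref A `ref_context`.
#' @param n_somatic,n_germline,n_artifact Counts per origin class.
#' @param somatic_vaf_range Range the somatic true VAF is drawn from
#'   (uniform).
#' @param germline_hom_fraction Fraction of germline variants at VAF 1.0
#'   (the rest are 0.5).
#' @param artifact_vaf Per-read probability of the artifact allele.
#' @param margin Positions are kept at least this far from the contig ends so
#'   every variant has a full filter window.
#' @param min_spacing Minimum distance (bp) between truth variants, so one
#'   variant never sits inside another's 11-bp context window.
#' @param seed Integer seed.
#' @return Data frame with columns `contig`, `position` (0-based), `ref`,
#'   `alt`, `true_vaf`, `origin`.
#' @export
make_truth_variants <- function(ref, n_somatic = 20L, n_germline = 20L,
                                n_artifact = 0L,
                                somatic_vaf_range = c(0.05, 0.4),
                                germline_hom_fraction = 0.2,
                                artifact_vaf = 0.005,
                                margin = 10L, min_spacing = 25L, seed = 1L) {
  n <- n_somatic + n_germline + n_artifact
  L <- ref_length(ref)
  if (L < 2 * margin + n * min_spacing)
    stop_invalid("reference too short for requested truth set")
  with_seed(seed, {
    avail <- seq.int(margin, L - margin - 1L)
    pos <- integer(0)
    for (k in seq_len(n)) {
      if (!length(avail)) stop_invalid("could not place variants at min_spacing")
      p <- avail[sample.int(length(avail), 1L)]
      pos <- c(pos, p)
      avail <- avail[abs(avail - p) >= min_spacing]
    }
    pos <- sort(pos) + ref$origin_coordinate
    refb <- ref_base(ref, pos)
    alt <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), character(1))
    origin <- sample(rep(c("somatic", "germline", "artifact"),
                         c(n_somatic, n_germline, n_artifact)))
    vaf <- numeric(n)
    vaf[origin == "somatic"] <- runif(sum(origin == "somatic"),
                                      somatic_vaf_range[1], somatic_vaf_range[2])
    vaf[origin == "germline"] <- ifelse(
      runif(sum(origin == "germline")) < germline_hom_fraction, 1.0, 0.5)
    vaf[origin == "artifact"] <- artifact_vaf
    data.frame(contig = ref$contig, position = pos, ref = unname(refb),
               alt = unname(alt), true_vaf = vaf, origin = origin,
               stringsAsFactors = FALSE)
  })
}

#' Fragment-length model for cell-free DNA mixtures
#'
#' Plasma cfDNA fragments peak near 167 bp (chromatosome protection) while
#' tumor-derived ctDNA fragments peak near 133 bp; both components are
#' modelled as Normal distributions truncated at `min_insert`.
#'
#' @param cfdna_peak,ctdna_peak Mean fragment length (bp) of the background
#'   and tumor components.
#' @param spread Standard deviation (bp) shared by both components.
#' @param min_insert Lower truncation point (bp).
#' @return A list of class `frag_model`.
#' @export
frag_model <- function(cfdna_peak = 167, ctdna_peak = 133, spread = 15,
                       min_insert = 50) {
  if (spread <= 0 || cfdna_peak <= 0 || ctdna_peak <= 0)
    stop_invalid("fragment model parameters must be positive")
  structure(list(cfdna_peak = cfdna_peak, ctdna_peak = ctdna_peak,
                 spread = spread, min_insert = min_insert),
            class = "frag_model")
}

# Truncated-normal fragment lengths, by rejection so the draw is exact.
draw_inserts <- function(n, mean, sd, min_insert, max_insert) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < min_insert | out > max_insert)
  while (length(bad)) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < min_insert | out[bad] > max_insert]
  }
  as.integer(out)
}

#' Simulate fragment-level reads from a tumor/background mixture
#'
#' Each record is one sequenced cfDNA fragment: the insert size is the
#' fragment length and the fragment reports every base it covers. A fraction
#' `tumor_fraction` of fragments derive from tumor cells and draw their
#' length from the shorter ctDNA peak; the rest draw from the cfDNA peak.
#' Somatic alt alleles appear only on tumor-component fragments, with
#' probability `true_vaf`; germline alleles appear on all fragments at their
#' VAF; artifact alleles appear on all fragments at their (low) VAF.
#' Sequencing errors are injected uniformly per covered base at `error_rate`,
#' mutating to a random different base. Strand is assigned 50/50.
#'
#' @param ref A `ref_context`.
#' @param truth Data frame from [make_truth_variants()] (may be empty).
#' @param tumor_fraction Fraction of fragments of tumor origin, in [0,1].
#' @param n_reads Number of fragments.
#' @param frag A [frag_model()].
#' @param error_rate Per-base error probability in [0,1].
#' @param seed Integer seed.
#' @return Object of class `sim_reads`: a list with `reads` (data frame:
#'   `read_id`, `contig`, `start` 0-based, `insert_size`, `strand`,
#'   `origin` in {tumor, background}) and `mismatches` (data frame:
#'   `read_id`, `offset` 0-based within the fragment, `base`).
#' @export
simulate_reads <- function(ref, truth = NULL, tumor_fraction = 0.1,
                           n_reads = 1000L, frag = frag_model(),
                           error_rate = 1e-3, seed = 1L) {
  if (ref_length(ref) < 3) stop_invalid("empty or near-empty reference")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop_invalid("tumor_fraction must be in [0,1]")
  if (error_rate < 0 || error_rate > 1)
    stop_invalid("error_rate must be in [0,1]")
  L <- ref_length(ref)
  max_ins <- min(L, round(frag$cfdna_peak + 10 * frag$spread))
  with_seed(seed, {
    tumor <- runif(n_reads) < tumor_fraction
    ins <- integer(n_reads)
    ins[tumor] <- draw_inserts(sum(tumor), frag$ctdna_peak, frag$spread,
                               frag$min_insert, max_ins)
    ins[!tumor] <- draw_inserts(sum(!tumor), frag$cfdna_peak, frag$spread,
                                frag$min_insert, max_ins)
    start <- ref$origin_coordinate +
      as.integer(floor(runif(n_reads) * (L - ins + 1L)))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- data.frame(read_id = seq_len(n_reads), contig = ref$contig,
                        start = start, insert_size = ins, strand = strand,
                        origin = ifelse(tumor, "tumor", "background"),
                        stringsAsFactors = FALSE)

    mm_id <- integer(0); mm_off <- integer(0); mm_base <- character(0)
    if (!is.null(truth) && nrow(truth)) {
      for (k in seq_len(nrow(truth))) {
        tv <- truth[k, ]
        cov <- which(start <= tv$position & start + ins > tv$position)
        if (tv$origin == "somatic") cov <- cov[tumor[cov]]
        if (!length(cov)) next
        carrier <- cov[runif(length(cov)) < tv$true_vaf]
        if (!length(carrier)) next
        mm_id <- c(mm_id, carrier)
        mm_off <- c(mm_off, as.integer(tv$position - start[carrier]))
        mm_base <- c(mm_base, rep(tv$alt, length(carrier)))
      }
    }
    if (error_rate > 0) {
      nerr <- rbinom(n_reads, ins, error_rate)
      hit <- which(nerr > 0)
      for (r in hit) {
        off <- sample.int(ins[r], nerr[r]) - 1L
        pos <- start[r] + off
        rb <- ref_base(ref, pos)
        eb <- vapply(rb, function(b) sample(setdiff(BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
        mm_id <- c(mm_id, rep(r, nerr[r]))
        mm_off <- c(mm_off, off)
        mm_base <- c(mm_base, eb)
      }
    }
    mm <- data.frame(read_id = mm_id, offset = mm_off, base = mm_base,
                     stringsAsFactors = FALSE)
    # a truth allele takes precedence over an error at the same read/position
    mm <- mm[!duplicated(mm[c("read_id", "offset")]), , drop = FALSE]
    mm <- mm[order(mm$read_id, mm$offset), , drop = FALSE]
    rownames(mm) <- NULL
    structure(list(reads = reads, mismatches = mm, contig = ref$contig),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %d fragments on %s (%d mismatch records)\n",
              nrow(x$reads), x$contig, nrow(x$mismatches)))
  invisible(x)
}

#' Build a per-position pileup from simulated fragments
#'
#' Counts, for every reference position, the covering fragments (depth, by
#' strand) and the observed alleles (reference plus mismatch bases, split by
#' strand). Allele counts at a site always sum to its depth. For every
#' non-reference allele the pileup additionally records how many supporting
#' fragments carry at least one further mismatch within `extra_mm_radius`
#' bases of the site — the read-level signal the local-context filter
#' consumes.
#'
#' @param sim A `sim_reads` object.
#' @param ref The `ref_context` the reads were simulated from.
#' @param extra_mm_radius Radius (bp) for the extra-mismatch read count.
#' @return Object of class `pileup`: list with `sites` (data frame: `contig`,
#'   `pos`, `ref`, `depth`, `depth_fwd`, `depth_rev`, `mm_total`,
#'   `indel_count`) and `alt` (data frame: `pos`, `base`, `fwd`, `rev`,
#'   `n_extra_mm`). `indel_count` is zero here; indel window noise can be
#'   injected by tests/fixtures.
#' @export
pileup_from_reads <- function(sim, ref, extra_mm_radius = 5L) {
  L <- ref_length(ref)
  o <- ref$origin_coordinate
  empty_sites <- data.frame(contig = character(0), pos = integer(0),
                            ref = character(0), depth = integer(0),
                            depth_fwd = integer(0), depth_rev = integer(0),
                            mm_total = integer(0), indel_count = integer(0),
                            stringsAsFactors = FALSE)
  empty_alt <- data.frame(pos = integer(0), base = character(0),
                          fwd = integer(0), rev = integer(0),
                          n_extra_mm = integer(0), stringsAsFactors = FALSE)
  if (!nrow(sim$reads)) {
    return(structure(list(sites = empty_sites, alt = empty_alt,
                          contig = ref$contig), class = "pileup"))
  }
  rd <- sim$reads
  cov_counts <- function(idx) {
    if (!length(idx)) return(integer(L))
    inc <- tabulate(rd$start[idx] - o + 1L, nbins = L)
    dec <- tabulate(pmin(rd$start[idx] + rd$insert_size[idx] - o + 1L, L + 1L),
                    nbins = L + 1L)
    cumsum(inc - dec[seq_len(L)])
  }
  depth_fwd <- cov_counts(which(rd$strand == "+"))
  depth_rev <- cov_counts(which(rd$strand == "-"))
  depth <- depth_fwd + depth_rev

  mm <- sim$mismatches
  if (nrow(mm)) {
    ri <- match(mm$read_id, rd$read_id)
    mm$pos <- rd$start[ri] + mm$offset
    mm$strand <- rd$strand[ri]
    mm_tab <- aggregate(list(n = rep(1L, nrow(mm))),
                        by = list(pos = mm$pos, base = mm$base,
                                  strand = mm$strand), FUN = sum)
    # reads carrying >1 mismatch: flag pairs within the extra-mm radius
    mm$extra <- FALSE
    multi <- mm$read_id %in% mm$read_id[duplicated(mm$read_id)]
    if (any(multi)) {
      for (rid in unique(mm$read_id[multi])) {
        i <- which(mm$read_id == rid)
        p <- mm$pos[i]
        for (j in seq_along(i)) {
          if (any(abs(p[-j] - p[j]) <= extra_mm_radius))
            mm$extra[i[j]] <- TRUE
        }
      }
    }
    keys <- paste(mm$pos, mm$base)
    extra_tab <- tapply(mm$extra, keys, sum)
    fwd_tab <- with(mm_tab[mm_tab$strand == "+", ],
                    setNames(n, paste(pos, base)))
    rev_tab <- with(mm_tab[mm_tab$strand == "-", ],
                    setNames(n, paste(pos, base)))
    ak <- sort(unique(keys))
    sp <- strsplit(ak, " ")
    alt <- data.frame(pos = as.integer(vapply(sp, `[`, "", 1L)),
                      base = vapply(sp, `[`, "", 2L),
                      fwd = as.integer(ifelse(is.na(fwd_tab[ak]), 0L, fwd_tab[ak])),
                      rev = as.integer(ifelse(is.na(rev_tab[ak]), 0L, rev_tab[ak])),
                      n_extra_mm = as.integer(extra_tab[ak]),
                      stringsAsFactors = FALSE)
    alt <- alt[order(alt$pos, alt$base), , drop = FALSE]
    rownames(alt) <- NULL
    mm_per_pos <- tapply(rep(1L, nrow(mm)), mm$pos, sum)
  } else {
    alt <- empty_alt
    mm_per_pos <- integer(0)
  }
  pos <- seq.int(o, o + L - 1L)
  mm_total <- integer(L)
  if (length(mm_per_pos)) {
    idx <- as.integer(names(mm_per_pos)) - o + 1L
    mm_total[idx] <- as.integer(mm_per_pos)
  }
  sites <- data.frame(contig = ref$contig, pos = pos,
                      ref = ref_base(ref, pos), depth = depth,
                      depth_fwd = depth_fwd, depth_rev = depth_rev,
                      mm_total = mm_total, indel_count = 0L,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, alt = alt, contig = ref$contig),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d positions, %d alt alleles observed\n",
              x$contig, nrow(x$sites), nrow(x$alt)))
  invisible(x)
}

#' Synthetic 96-channel signature catalog
#'
#' A deterministic stand-in for a 30-signature reference catalog (real
#' catalogs are distributed by their curators and are not bundled). Columns
#' are probability profiles over the 96 pyrimidine-centred trinucleotide
#' channels, sparse like real mutational signatures, with a few columns given
#' recognisable etiologies used by the default labelling sets: column 1
#' (clock-like C>T at NpCpG), column 3 (flat, platinum/HRD-like), columns 4,
#' 16 and 29 (C>A- or T>C-heavy, smoking-like).
#'
#' @param K Number of signatures (>= 1; defaults to 30).
#' @return 96 x K numeric matrix, columns summing to 1, rownames the COSMIC
#'   channel labels (`A[C>A]A` ... `T[T>G]T`), colnames `Signature.1` ...
#' @export
synthetic_signature_catalog <- function(K = 30L) {
  if (K < 1) stop_invalid("K must be >= 1")
  ch <- sub_channels()
  with_seed(20190L, {
    S <- matrix(0, 96, K, dimnames = list(ch, paste0("Signature.", seq_len(K))))
    for (k in seq_len(K)) {
      w <- rexp(96)^2                      # sparse-ish random profile
      S[, k] <- w / sum(w)
    }
    cls <- substr(ch, 3, 5)
    shape_on <- function(k, sel, weight) {
      w <- rexp(96)^2 * (0.05 + weight * sel)
      S[, k] <<- w / sum(w)
    }
    if (K >= 1) shape_on(1L, cls == "C>T" & substr(ch, 7, 7) == "G", 20)
    if (K >= 3) S[, 3] <- rep(1 / 96, 96)  # flat profile
    if (K >= 4) shape_on(4L, cls == "C>A", 15)
    if (K >= 16) shape_on(16L, cls == "T>C", 15)
    if (K >= 29) shape_on(29L, cls == "C>A" & substr(ch, 1, 1) == "T", 15)
    S
  })
}

#' Sample a mutation catalog from a signature mixture
#'
#' Draws `n_mutations` channel assignments from the multinomial distribution
#' `signature_catalog %*% weights`.
#'
#' @param signature_catalog 96 x K non-negative matrix, columns summing to 1.
#' @param weights K non-negative mixture weights summing to 1 (within 1e-6).
#' @param n_mutations Total mutations to draw.
#' @param seed Integer seed.
#' @param sample_id Label stored on the catalog.
#' @return A `mutation_catalog` (see [mutation_catalog()]).
#' @export
sample_catalog <- function(signature_catalog, weights, n_mutations,
                           seed = 1L, sample_id = "sim") {
  if (any(weights < 0)) stop_invalid("signature weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-6) stop_invalid("weights must sum to 1")
  p <- as.vector(signature_catalog %*% weights)
  counts <- if (n_mutations == 0) integer(96) else
    with_seed(seed, as.integer(rmultinom(1, n_mutations, p)))
  mutation_catalog(counts, sample_id = sample_id)
}

#' Materialise variants realising a mutation catalog
#'
#' For every channel with a positive count, picks reference positions whose
#' trinucleotide context matches the channel (on either strand) and emits one
#' variant per count. Useful for round-trip tests: `build_catalog()` on the
#' result reproduces the input catalog exactly.
#'
#' @param catalog A `mutation_catalog`.
#' @param ref A `ref_context` long enough to contain every needed context.
#' @param seed Integer seed (position choice only).
#' @return Data frame with `contig`, `position`, `ref`, `alt`.
#' @export
variants_from_catalog <- function(catalog, ref, seed = 1L) {
  ch <- sub_channels()
  pos_all <- seq.int(ref$origin_coordinate + 1L,
                     ref$origin_coordinate + ref_length(ref) - 2L)
  ctx <- ref_context3(ref, pos_all)
  with_seed(seed, {
    out <- list()
    for (i in which(catalog$counts > 0)) {
      lab <- ch[i]
      pyr_ctx <- paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
      alt_pyr <- substr(lab, 5, 5)
      hit_f <- pos_all[!is.na(ctx) & ctx == pyr_ctx]
      hit_r <- pos_all[!is.na(ctx) & ctx == revcomp(pyr_ctx)]
      n <- catalog$counts[i]
      pool <- c(hit_f, hit_r)
      alt_pool <- c(rep(alt_pyr, length(hit_f)),
                    rep(chartr("ACGT", "TGCA", alt_pyr), length(hit_r)))
      if (!length(pool))
        stop_invalid("reference lacks context ", pyr_ctx, "; use a longer reference")
      pick <- sample.int(length(pool), n, replace = TRUE)
      out[[lab]] <- data.frame(contig = ref$contig, position = pool[pick],
                               ref = ref_base(ref, pool[pick]),
                               alt = alt_pool[pick], stringsAsFactors = FALSE)
    }
    if (!length(out)) {
      return(data.frame(contig = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Synthetic annotation fixtures
#'
#' Bundles the external knowledge the filter cascade and downstream joins
#' consume: SNP-database membership, population allele frequencies, somatic
#' hotspot membership, a signature catalog, a toy gene model with known
#' reading frames, pathway gene sets and an actionability table. All content
#' is synthetic; germline truth variants (if given) are entered into the SNP
#' and population tables so the normal-contamination filter has real targets.
#'
#' @param ref A `ref_context`.
#' @param truth Optional truth data frame; germline rows seed `snp_sites` and
#'   `population_af`, somatic rows seed `hotspot_sites` (with probability
#'   `hotspot_fraction`).
#' @param n_genes Number of toy genes tiled across the reference.
#' @param hotspot_fraction Fraction of somatic truth sites entered in the
#'   hotspot table.
#' @param seed Integer seed.
#' @return List of class `annotation_fixtures` with elements `snp_sites`,
#'   `population_af`, `hotspot_sites`, `signature_catalog`, `gene_model`,
#'   `pathway_sets`, `actionability`.
#' @export
make_annotation_fixtures <- function(ref, truth = NULL, n_genes = 8L,
                                     hotspot_fraction = 0.5, seed = 1L) {
  L <- ref_length(ref)
  with_seed(seed, {
    gl <- floor(L / n_genes)
    gene_names <- c("TP53", "KRAS", "EGFR", "ALK", "STK11", "SETD2", "ROBO2",
                    "BRAF", "MYC", "NOTCH1", "PIK3CA", "MTOR")
    gene_names <- gene_names[seq_len(min(n_genes, length(gene_names)))]
    starts <- ref$origin_coordinate + (seq_len(n_genes) - 1L) * gl
    width <- floor(gl * 2 / 3)
    width <- width - width %% 3L          # whole codons
    gene_model <- data.frame(gene = gene_names, contig = ref$contig,
                             start = starts, end = starts + width,
                             strand = "+", frame = 0L,
                             stringsAsFactors = FALSE)
    snp <- pop <- hot <- data.frame(contig = character(0), position = integer(0),
                                    alt = character(0), stringsAsFactors = FALSE)
    if (!is.null(truth) && nrow(truth)) {
      g <- truth[truth$origin == "germline", c("contig", "position", "alt")]
      snp <- g
      if (nrow(g)) {
        pop <- cbind(g, af = round(runif(nrow(g), 0.001, 0.5), 4))
      } else pop$af <- numeric(0)
      s <- truth[truth$origin == "somatic", c("contig", "position", "alt")]
      hot <- s[runif(nrow(s)) < hotspot_fraction, , drop = FALSE]
    } else pop$af <- numeric(0)
    pathway_sets <- list(
      MAPK = intersect(c("KRAS", "EGFR", "BRAF", "ALK", "MYC"), gene_names),
      PI3K_MTOR = intersect(c("PIK3CA", "MTOR", "STK11"), gene_names),
      NOTCH = intersect(c("NOTCH1"), gene_names))
    pathway_sets <- pathway_sets[vapply(pathway_sets, length, 1L) > 0]
    actionability <- data.frame(
      gene = c("KRAS", "EGFR", "EGFR", "ALK"),
      protein_change = c("G12C", "S768I", NA, NA),
      drugs = c("ARS-853;Selumetinib", "Erlotinib;Gefitinib",
                "EGFR-TKI", "Crizotinib"),
      stringsAsFactors = FALSE)
    structure(list(snp_sites = snp, population_af = pop, hotspot_sites = hot,
                   signature_catalog = synthetic_signature_catalog(),
                   gene_model = gene_model, pathway_sets = pathway_sets,
                   actionability = actionability),
              class = "annotation_fixtures")
  })
}

#' Simulate a multi-cycle plasma cohort with known burden dynamics
#'
#' Emulates a longitudinal chemotherapy cohort: each patient has a
#' pre-treatment baseline (cycle 0) and `cycles_per_patient - 1` on-treatment
#' samples. Baseline mutation counts are Poisson(`baseline_burden`); each
#' mutation independently survives a cycle with probability `decay` (thinning),
#' so the expected burden ratio between consecutive cycles equals `decay`.
#' Treatment-sensitive patients (labelled PR/SDa) use `decay_sensitive`,
#' insensitive patients (SD/SDb/PD) `decay_insensitive`. Overall and
#' progression-free survival are exponential with sensitivity-dependent means,
#' administratively censored.
#'
#' @param n_patients,cycles_per_patient Cohort dimensions (>= 1).
#' @param baseline_burden Mean mutation count per baseline sample.
#' @param decay_sensitive,decay_insensitive Per-cycle mutation survival
#'   probability by response group (in [0,1]).
#' @param sensitive_fraction Fraction of patients drawing a sensitive label.
#' @param smoker_fraction Fraction of smokers.
#' @param os_mean,pfs_mean Length-2 vectors (sensitive, insensitive): mean
#'   survival in months. Censoring at `os_censor`/`pfs_censor` months.
#' @param os_censor,pfs_censor Administrative censoring times (months).
#' @param tki_fraction Fraction receiving TKI therapy after chemotherapy.
#' @param seed Integer seed.
#' @return List of class `cohort`: `samples` (one row per plasma sample with
#'   patient/cycle/response/smoking/regimen/survival fields) and `variants`
#'   (named list of per-sample variant data frames with `key`, `gene`,
#'   `effect`, `vaf`, `protein_change`).
#' @export
make_cohort <- function(n_patients = 32L, cycles_per_patient = 3L,
                        baseline_burden = 16, decay_sensitive = 0.5,
                        decay_insensitive = 0.85, sensitive_fraction = 0.5,
                        smoker_fraction = 0.6,
                        os_mean = c(24, 12), pfs_mean = c(8, 4),
                        os_censor = 36, pfs_censor = 18,
                        tki_fraction = 0.375, seed = 1L) {
  if (n_patients < 1 || cycles_per_patient < 1)
    stop_invalid("n_patients and cycles_per_patient must be >= 1")
  gene_pool <- c("TP53", "KRAS", "EGFR", "ALK", "STK11", "SETD2", "ROBO2",
                 "BRAF", "MYC", "NOTCH1", "PIK3CA", "MTOR", "NSD1", "LRRK2",
                 "GNAS", "ATRX", "RPTOR", "CDK12", "HDAC4", "POLQ")
  effect_probs <- c(nonsilent = 0.409, silent = 0.168, noncoding = 0.423)
  hotspot_changes <- c(KRAS = "G12C", EGFR = "L858R", BRAF = "V600E")
  with_seed(seed, {
    sensitive <- runif(n_patients) < sensitive_fraction
    response <- ifelse(sensitive,
                       sample(c("PR", "SDa"), n_patients, replace = TRUE),
                       sample(c("SD", "SDb", "PD"), n_patients, replace = TRUE))
    smoking <- ifelse(runif(n_patients) < smoker_fraction, "smoker", "nonsmoker")
    regimen <- sample(c("pemetrexed+cisplatin", "pemetrexed+carboplatin", "other"),
                      n_patients, replace = TRUE, prob = c(0.53, 0.41, 0.06))
    os_raw <- rexp(n_patients, 1 / ifelse(sensitive, os_mean[1], os_mean[2]))
    pfs_raw <- rexp(n_patients, 1 / ifelse(sensitive, pfs_mean[1], pfs_mean[2]))
    samples <- list(); variants <- list()
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%02d", p)
      decay <- if (sensitive[p]) decay_sensitive else decay_insensitive
      n0 <- rpois(1, baseline_burden)
      if (n0 > 0) {
        eff <- sample(names(effect_probs), n0, replace = TRUE, prob = effect_probs)
        gene <- sample(gene_pool, n0, replace = TRUE)
        pc <- ifelse(eff == "nonsilent" & gene %in% names(hotspot_changes) &
                       runif(n0) < 0.5,
                     hotspot_changes[gene],
                     ifelse(eff == "nonsilent",
                            paste0(sample(LETTERS[c(1, 3:9)], n0, replace = TRUE),
                                   sample(600L, n0, replace = TRUE),
                                   sample(LETTERS[c(1, 3:9)], n0, replace = TRUE)),
                            NA))
        base_vars <- data.frame(
          key = sprintf("%s:%d:%s", pid, seq_len(n0),
                        sample(BASES, n0, replace = TRUE)),
          gene = gene, effect = eff, vaf = rbeta(n0, 2, 30),
          protein_change = unname(pc), stringsAsFactors = FALSE)
      } else {
        base_vars <- data.frame(key = character(0), gene = character(0),
                                effect = character(0), vaf = numeric(0),
                                protein_change = character(0),
                                stringsAsFactors = FALSE)
      }
      cur <- base_vars
      for (cy in seq.int(0L, cycles_per_patient - 1L)) {
        if (cy > 0 && nrow(cur)) {
          keep <- runif(nrow(cur)) < decay
          cur <- cur[keep, , drop = FALSE]
          if (nrow(cur)) cur$vaf <- pmin(1, cur$vaf * exp(rnorm(nrow(cur), 0, 0.2)))
        } else if (cy > 0) cur <- cur[0, , drop = FALSE]
        sid <- sprintf("%s_C%d", pid, cy)
        samples[[sid]] <- data.frame(
          sample_id = sid, patient_id = pid, cycle_index = cy,
          timepoint = if (cy == 0) "pre" else "post",
          response = response[p], smoking = smoking[p], regimen = regimen[p],
          os_time = min(os_raw[p], os_censor),
          os_event = as.integer(os_raw[p] <= os_censor),
          pfs_time = min(pfs_raw[p], pfs_censor),
          pfs_event = as.integer(pfs_raw[p] <= pfs_censor),
          tki_after = as.integer(runif(1) < tki_fraction),
          stringsAsFactors = FALSE)
        variants[[sid]] <- cur
      }
    }
    samples <- do.call(rbind, samples)
    rownames(samples) <- NULL
    # tki assignment is per patient, not per sample
    for (p in unique(samples$patient_id)) {
      i <- samples$patient_id == p
      samples$tki_after[i] <- samples$tki_after[which(i)[1]]
    }
    structure(list(samples = samples, variants = variants), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples from %d patients\n", nrow(x$samples),
              length(unique(x$samples$patient_id))))
  invisible(x)
}

#' Response label grouping: platinum sensitive vs insensitive
#'
#' Sensitive = PR or SDa; insensitive = SD, SDb or PD (CR, when present, is
#' grouped with sensitive).
#' @param response Character vector of RECIST-derived labels.
#' @return Character vector `"sensitive"`/`"insensitive"`.
#' @export
response_group <- function(response) {
  ifelse(response %in% c("CR", "PR", "SDa"), "sensitive", "insensitive")
}
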