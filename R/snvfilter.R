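#' Detection power model
#'
#' Parameters of the binomial detection-power criterion: the probability that
#' a true variant at `assumed_vaf` would yield at least `min_alt_reads`
#' supporting reads with at least `min_per_strand` on each strand at the
#' observed depth. When `assumed_vaf` is `NULL` the cascade substitutes
#' `max(observed tumor VAF, 0.01)` per variant (plasma variants are counted
#' from a mean VAF of about 1% upward).
#'
#' @param assumed_vaf Assumed true allele fraction in (0, 1], or `NULL`.
#' @param error_rate Per-base sequencing error rate (used by the posterior,
#'   carried here so one object parameterises the cascade).
#' @param min_alt_reads Minimum mutant reads (default 4).
#' @param min_per_strand Minimum mutant reads per strand (default 1).
#' @return List of class `power_model`.
#' @export
power_model <- function(assumed_vaf = NULL, error_rate = 1e-3,
                        min_alt_reads = 4L, min_per_strand = 1L) {
  if (!is.null(assumed_vaf) && (assumed_vaf <= 0 || assumed_vaf > 1))
    stop_invalid("assumed_vaf must be in (0,1]")
  if (min_alt_reads < 0 || min_per_strand < 0)
    stop_invalid("read thresholds must be non-negative")
  structure(list(assumed_vaf = assumed_vaf, error_rate = error_rate,
                 min_alt_reads = as.integer(min_alt_reads),
                 min_per_strand = as.integer(min_per_strand)),
            class = "power_model")
}

#' Binomial detection power at a site
#'
#' Probability that a variant truly present at `assumed_vaf` yields at least
#' `min_alt_reads` mutant reads with at least `min_per_strand` on each strand,
#' when the mutant read count is Binomial(depth, vaf) and each mutant read
#' falls on the forward strand independently with probability 1/2:
#' \deqn{\mathrm{power} = \sum_{a} \binom{d}{a} v^a (1-v)^{d-a}
#'   \; P(m \le F \le a - m \mid F \sim \mathrm{Bin}(a, 1/2))}
#' Power is monotone non-decreasing in depth and in the assumed VAF.
#'
#' @param depth Integer vector of sequencing depths (>= 0).
#' @param model A [power_model()]; its `assumed_vaf` must be set here.
#' @param assumed_vaf Optional override of the model's assumed VAF.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
detection_power <- function(depth, model = power_model(assumed_vaf = 0.05),
                            assumed_vaf = NULL) {
  v <- if (!is.null(assumed_vaf)) assumed_vaf else model$assumed_vaf
  if (is.null(v) || any(v <= 0) || any(v > 1))
    stop_invalid("assumed_vaf must be in (0,1]")
  if (any(depth < 0)) stop_invalid("depth must be >= 0")
  k <- model$min_alt_reads
  m <- model$min_per_strand
  if (length(v) == 1L) v <- rep(v, length(depth))
  vapply(seq_along(depth), function(i) {
    d <- depth[i]
    amin <- max(k, 2L * m)
    if (d < amin) return(0)
    a <- seq.int(amin, d)
    strand_ok <- if (m == 0L) rep(1, length(a)) else
      pbinom(a - m, a, 0.5) - pbinom(m - 1L, a, 0.5)
    sum(dbinom(a, d, v[i]) * strand_ok)
  }, numeric(1))
}

#' Recurrence-weighted somatic prior
#'
#' Encodes how often a site (or its gene) recurs in an external somatic
#' catalog. The prior probability that a candidate is a true somatic variant
#' is \deqn{\pi(r) = \frac{r + c}{r + c + 1/\pi_0 - 1}} where `r` is the
#' recurrence count, `c` the pseudocount and `pi_0` the baseline prior, so
#' that `pi(0) = pi_0` when `c = 1` and `pi` increases towards 1 with
#' recurrence.
#'
#' @param recurrence Named numeric vector of recurrence counts; names are
#'   either `"contig:position:alt"` site keys or gene symbols (site keys are
#'   looked up first, then the gene).
#' @param pseudocount Positive pseudocount (default 1).
#' @param baseline_prior Baseline somatic prior in (0, 1) (default 0.5).
#' @return List of class `recurrence_prior`.
#' @export
recurrence_prior <- function(recurrence = numeric(0), pseudocount = 1,
                             baseline_prior = 0.5) {
  if (pseudocount <= 0) stop_invalid("pseudocount must be positive")
  if (baseline_prior <= 0 || baseline_prior >= 1)
    stop_invalid("baseline_prior must be in (0,1)")
  if (any(recurrence < 0)) stop_invalid("recurrence counts must be >= 0")
  structure(list(recurrence = recurrence, pseudocount = pseudocount,
                 baseline_prior = baseline_prior), class = "recurrence_prior")
}

prior_weight <- function(prior, count) {
  c0 <- prior$pseudocount
  (count + c0) / (count + c0 + 1 / prior$baseline_prior - 1)
}

lookup_recurrence <- function(prior, contig, position, alt, gene) {
  key <- paste(contig, position, alt, sep = ":")
  r <- prior$recurrence[key]
  miss <- is.na(r)
  if (any(miss) && length(gene)) {
    g <- prior$recurrence[gene[miss]]
    r[miss] <- ifelse(is.na(g), 0, g)
  }
  r[is.na(r)] <- 0
  unname(r)
}

#' Posterior probability that a candidate is a true somatic variant
#'
#' Two-hypothesis Bayes rule: the observed mutant read count is compared
#' under a somatic hypothesis (binomial at the observed tumor VAF, floored at
#' the error rate) and an artifact hypothesis (binomial at the sequencing
#' error rate). Prior odds come from the recurrence-weighted prior:
#' \deqn{P(\mathrm{somatic} \mid a, d) = \frac{\pi L_1}{\pi L_1 + (1-\pi) L_0}}
#' with \eqn{L_1 = \mathrm{Bin}(a; d, \max(v, e))} and \eqn{L_0 =
#' \mathrm{Bin}(a; d, e)}. The posterior is monotone non-decreasing in the
#' recurrence count and, above the error rate, in the mutant read count at
#' fixed depth.
#'
#' @param alt_reads,depth Integer vectors: mutant reads and total depth in
#'   the tumor.
#' @param prior A [recurrence_prior()].
#' @param recurrence_count Recurrence counts (numeric vector, recycled); use
#'   [lookup_recurrence()] via [run_cascade()] to resolve from keys.
#' @param error_rate Per-base error rate in (0, 1).
#' @return Numeric vector of posterior probabilities.
#' @export
posterior_probability <- function(alt_reads, depth, prior = recurrence_prior(),
                                  recurrence_count = 0, error_rate = 1e-3) {
  if (error_rate <= 0 || error_rate >= 1)
    stop_invalid("error_rate must be in (0,1)")
  vaf <- ifelse(depth > 0, alt_reads / depth, 0)
  v1 <- pmax(vaf, error_rate)
  l1 <- dbinom(alt_reads, depth, v1)
  l0 <- dbinom(alt_reads, depth, error_rate)
  p <- prior_weight(prior, recurrence_count)
  num <- p * l1
  den <- num + (1 - p) * l0
  ifelse(den > 0, num / den, p)
}

#' Construct a candidate variant table
#'
#' Convenience constructor used by tests and examples to assemble the
#' columns [run_cascade()] expects without running the simulator. `flank_mm`
#' is the list of mismatch counts at the 10 non-site positions of the 11-bp
#' window.
#'
#' @param contig,pos,ref,alt Site and alleles.
#' @param alt_fwd,alt_rev Mutant reads on each strand (tumor).
#' @param depth_tumor,depth_normal Total depths.
#' @param alt_normal Mutant reads in the matched normal.
#' @param in_snp_db,in_hotspot_db Database membership flags.
#' @param population_af Population allele frequency (`NA` if absent).
#' @param gene,protein_change,effect Annotation labels.
#' @param flank_mm List column: numeric vector of 10 flanking mismatch
#'   counts (or fewer if the window is truncated at a contig edge).
#' @param n_indel_10bp Indel events within 10 bp.
#' @param n_alt_extra_mm Mutant-supporting reads carrying another mismatch in
#'   the 11-bp window.
#' @return Data frame of class `candidates`.
#' @export
candidate_variant <- function(contig = "sim1", pos = 100L, ref = "C",
                              alt = "T", alt_fwd = 10L, alt_rev = 10L,
                              depth_tumor = 200L, depth_normal = 200L,
                              alt_normal = 0L, in_snp_db = FALSE,
                              in_hotspot_db = FALSE, population_af = NA_real_,
                              gene = NA_character_,
                              protein_change = NA_character_,
                              effect = NA_character_,
                              flank_mm = list(rep(0, 10)),
                              n_indel_10bp = 0L, n_alt_extra_mm = 0L) {
  df <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                   alt_fwd = alt_fwd, alt_rev = alt_rev,
                   depth_tumor = depth_tumor, depth_normal = depth_normal,
                   alt_normal = alt_normal, in_snp_db = in_snp_db,
                   in_hotspot_db = in_hotspot_db,
                   population_af = population_af, gene = gene,
                   protein_change = protein_change, effect = effect,
                   n_indel_10bp = n_indel_10bp,
                   n_alt_extra_mm = n_alt_extra_mm, stringsAsFactors = FALSE)
  df$flank_mm <- flank_mm
  df$vaf_tumor <- ifelse(df$depth_tumor > 0,
                         (df$alt_fwd + df$alt_rev) / df$depth_tumor, 0)
  df$vaf_normal <- ifelse(df$depth_normal > 0,
                          df$alt_normal / df$depth_normal, 0)
  class(df) <- c("candidates", "data.frame")
  df
}

#' Condition 1: read support, normal contamination, coverage, databases
#'
#' The first filter condition of the cascade, split into four auditable
#' checks:
#' * `C1_support` — the tumor must show >= `min_alt_reads` mutant reads with
#'   >= `min_per_strand` on each strand.
#' * `C1_normal` — the matched normal may carry at most `max_normal_alt`
#'   mutant reads, with normal VAF < `max_normal_vaf`, and the site must not
#'   be a known SNP.
#' * `C1_coverage` — at least `min_coverage`-fold depth in both tumor and
#'   normal (VAF at zero depth is defined as 0, never a division error).
#' * `C1_db` — removed if (>= 1 mutant read in normal AND population AF >=
#'   `min_population_af`) OR (>= 2 mutant reads in normal AND not a known
#'   somatic hotspot).
#'
#' @param cands A `candidates` data frame ([candidate_variant()]).
#' @param min_alt_reads,min_per_strand,max_normal_alt,max_normal_vaf,min_coverage,min_population_af
#'   Thresholds; defaults are the published cascade values (4, 1, 2, 0.01,
#'   40, 0.001).
#' @return Data frame of logical failure flags `C1_support`, `C1_normal`,
#'   `C1_coverage`, `C1_db`.
#' @export
condition1_support <- function(cands, min_alt_reads = 4L, min_per_strand = 1L,
                               max_normal_alt = 2L, max_normal_vaf = 0.01,
                               min_coverage = 40L, min_population_af = 0.001) {
  alt_total <- cands$alt_fwd + cands$alt_rev
  pop <- ifelse(is.na(cands$population_af), 0, cands$population_af)
  data.frame(
    C1_support = !(alt_total >= min_alt_reads &
                     cands$alt_fwd >= min_per_strand &
                     cands$alt_rev >= min_per_strand),
    C1_normal = !(cands$alt_normal <= max_normal_alt &
                    cands$vaf_normal < max_normal_vaf & !cands$in_snp_db),
    C1_coverage = !(cands$depth_tumor >= min_coverage &
                      cands$depth_normal >= min_coverage),
    C1_db = (cands$alt_normal >= 1L & pop >= min_population_af) |
      (cands$alt_normal >= 2L & !cands$in_hotspot_db))
}

#' Condition 2: local sequence-context checks in an 11-bp window
#'
#' * `C2_outlier` — the mutant read count must be an outlier against the
#'   mismatch counts at the 10 other window positions: it must exceed their
#'   mean + `outlier_k` standard deviations.
#' * `C2_indel` — fails when `max_indel` (default 3) or more small
#'   insertion/deletion events fall within `indel_radius` (10 bp) of the
#'   site.
#' * `C2_mismatch` — mismatching bases must not be enriched around the site:
#'   no flanking position may exceed the site's mutant count, and the
#'   fraction of mutant-supporting reads that carry an additional mismatch
#'   inside the window must stay below `max_extra_mm_fraction` (with at
#'   least 2 such reads required to fail, so a single stray sequencing error
#'   on one supporting read does not veto a true variant).
#'
#' A window truncated below 10 flanking positions (contig edge, missing
#' pileup) is an insufficient-context state: the variant is marked
#' unevaluable rather than passed.
#'
#' @param cands A `candidates` data frame.
#' @param outlier_k Outlier multiplier (default 3).
#' @param max_indel Indel count at which `C2_indel` fails (default 3).
#' @param indel_radius Radius in bp for the indel count (default 10; the
#'   count itself is precomputed into `n_indel_10bp`).
#' @param max_extra_mm_fraction Maximum tolerated fraction of mutant reads
#'   with extra window mismatches (default 0.2).
#' @return Data frame of logical flags `C2_outlier`, `C2_indel`,
#'   `C2_mismatch`, `insufficient_context`.
#' @export
condition2_local_context <- function(cands, outlier_k = 3, max_indel = 3L,
                                     indel_radius = 10L,
                                     max_extra_mm_fraction = 0.2) {
  alt_total <- cands$alt_fwd + cands$alt_rev
  n <- nrow(cands)
  out <- data.frame(C2_outlier = logical(n), C2_indel = logical(n),
                    C2_mismatch = logical(n), insufficient_context = logical(n))
  for (i in seq_len(n)) {
    fl <- cands$flank_mm[[i]]
    if (is.null(fl) || length(fl) < 10 || anyNA(fl)) {
      out$insufficient_context[i] <- TRUE
      next
    }
    mu <- mean(fl); s <- sd(fl)
    out$C2_outlier[i] <- !(alt_total[i] > mu + outlier_k * s)
    out$C2_indel[i] <- cands$n_indel_10bp[i] >= max_indel
    frac <- if (alt_total[i] > 0) cands$n_alt_extra_mm[i] / alt_total[i] else 0
    out$C2_mismatch[i] <- any(fl > alt_total[i]) ||
      (cands$n_alt_extra_mm[i] >= 2L && frac > max_extra_mm_fraction)
  }
  out
}

#' Run the five-condition somatic SNV filter cascade
#'
#' Evaluates every condition for every candidate (no short-circuiting, so the
#' verdict lists all failed conditions and per-condition audit counts are
#' meaningful). A candidate passes when no condition fails, its detection
#' power exceeds `power_threshold` and its posterior probability exceeds
#' `posterior_threshold`. Candidates with unresolvable evidence (missing
#' counts, insufficient window context) are flagged unevaluable and excluded
#' from the passed set but counted separately, so
#' `candidates = passed + failed + unevaluable` always holds.
#'
#' @param cands A `candidates` data frame ([candidate_variant()] or
#'   [make_candidates()] + [annotate_candidates()]).
#' @param model A [power_model()].
#' @param prior A [recurrence_prior()].
#' @param power_threshold,posterior_threshold Strict lower bounds (defaults
#'   0.80 and 0.8).
#' @param outlier_k,max_extra_mm_fraction Condition-2 tuning, see
#'   [condition2_local_context()].
#' @return List with `passed` (subset of `cands`), `verdicts` (one row per
#'   candidate: failure flags, `power`, `posterior`, `failed_conditions`
#'   comma-joined, `passed`, `unevaluable`) and `counts` (named vector:
#'   n_candidates, n_passed, n_failed, n_unevaluable).
#' @export
run_cascade <- function(cands, model = power_model(),
                        prior = recurrence_prior(),
                        power_threshold = 0.80, posterior_threshold = 0.8,
                        outlier_k = 3, max_extra_mm_fraction = 0.2) {
  n <- nrow(cands)
  c1 <- condition1_support(cands, min_alt_reads = model$min_alt_reads,
                           min_per_strand = model$min_per_strand)
  c2 <- condition2_local_context(cands, outlier_k = outlier_k,
                                 max_extra_mm_fraction = max_extra_mm_fraction)
  alt_total <- cands$alt_fwd + cands$alt_rev
  assumed <- if (!is.null(model$assumed_vaf)) rep(model$assumed_vaf, n) else
    pmax(cands$vaf_tumor, 0.01)
  power <- numeric(n)
  ok_depth <- cands$depth_tumor > 0
  power[ok_depth] <- detection_power(cands$depth_tumor[ok_depth], model,
                                     assumed_vaf = assumed[ok_depth])
  rec <- lookup_recurrence(prior, cands$contig, cands$pos, cands$alt,
                           cands$gene)
  posterior <- posterior_probability(alt_total, cands$depth_tumor, prior,
                                     recurrence_count = rec,
                                     error_rate = model$error_rate)
  flags <- cbind(c1,
                 c2[c("C2_outlier", "C2_indel", "C2_mismatch")],
                 C3_power = !(power > power_threshold),
                 C4_posterior = !(posterior > posterior_threshold))
  unevaluable <- c2$insufficient_context |
    is.na(cands$depth_tumor) | is.na(cands$depth_normal) | is.na(alt_total)
  failed_any <- rowSums(flags) > 0
  passed <- !failed_any & !unevaluable
  failed_conditions <- apply(flags, 1, function(r)
    paste(colnames(flags)[r], collapse = ","))
  failed_conditions[unevaluable] <- "insufficient_context"
  verdicts <- cbind(
    data.frame(contig = cands$contig, pos = cands$pos, ref = cands$ref,
               alt = cands$alt, stringsAsFactors = FALSE),
    flags,
    data.frame(power = power, posterior = posterior,
               failed_conditions = failed_conditions, passed = passed,
               unevaluable = unevaluable, stringsAsFactors = FALSE))
  list(passed = cands[passed, , drop = FALSE],
       verdicts = verdicts,
       counts = c(n_candidates = n, n_passed = sum(passed),
                  n_failed = sum(failed_any & !unevaluable),
                  n_unevaluable = sum(unevaluable)))
}
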