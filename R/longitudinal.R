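#' Per-sample mutation burden with pre/post comparison
#'
#' Counts each sample's variants by effect class (total = nonsilent + silent
#' + noncoding) and compares pre- vs post-treatment burden with a two-sample
#' t-test, both per sample and as per-patient paired differences (baseline
#' vs mean of the patient's post-treatment samples). Patients without a
#' baseline are excluded from the paired view but retained in the group
#' view.
#'
#' @param cohort A `cohort` object ([make_cohort()]) or a list with
#'   `samples` and `variants` of the same shape.
#' @return List of class `burden_result`: `burden` (one row per sample:
#'   `sample_id`, `patient_id`, `cycle_index`, `timepoint`, `n_total`,
#'   `n_nonsilent`, `n_silent`, `n_noncoding`), `test_total` and
#'   `test_nonsilent` (`htest` objects, or `NULL` with `note`
#'   "not-applicable" when either group is empty or too small), `paired`
#'   (per-patient baseline and mean post burden), `n_excluded_no_baseline`.
#' @export
burden_by_cycle <- function(cohort) {
  s <- cohort$samples
  burden <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    v <- cohort$variants[[s$sample_id[i]]]
    eff <- if (!is.null(v) && nrow(v)) v$effect else character(0)
    data.frame(sample_id = s$sample_id[i], patient_id = s$patient_id[i],
               cycle_index = s$cycle_index[i], timepoint = s$timepoint[i],
               n_total = length(eff),
               n_nonsilent = sum(eff == "nonsilent"),
               n_silent = sum(eff == "silent"),
               n_noncoding = sum(eff == "noncoding"),
               stringsAsFactors = FALSE)
  }))
  rownames(burden) <- NULL
  pre <- burden[burden$timepoint == "pre", , drop = FALSE]
  post <- burden[burden$timepoint == "post", , drop = FALSE]
  run_t <- function(col) {
    if (nrow(pre) < 2 || nrow(post) < 2) return(NULL)
    t.test(pre[[col]], post[[col]])
  }
  test_total <- run_t("n_total")
  test_nonsilent <- run_t("n_nonsilent")
  pats <- unique(burden$patient_id)
  paired <- do.call(rbind, lapply(pats, function(p) {
    b <- burden[burden$patient_id == p, , drop = FALSE]
    has_base <- any(b$timepoint == "pre")
    has_post <- any(b$timepoint == "post")
    data.frame(patient_id = p,
               baseline = if (has_base) b$n_total[b$timepoint == "pre"][1] else NA,
               mean_post = if (has_post) mean(b$n_total[b$timepoint == "post"]) else NA,
               stringsAsFactors = FALSE)
  }))
  n_excl <- sum(is.na(paired$baseline))
  if (n_excl > 0)
    message(n_excl, " patient(s) without baseline excluded from paired view")
  paired_ok <- paired[!is.na(paired$baseline), , drop = FALSE]
  structure(list(burden = burden, test_total = test_total,
                 test_nonsilent = test_nonsilent, paired = paired_ok,
                 note = if (is.null(test_total)) "not-applicable" else NA,
                 n_excluded_no_baseline = n_excl), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result> %d samples; pre/post t-test p = %s\n",
              nrow(x$burden),
              if (is.null(x$test_total)) "not-applicable" else
                format.pval(x$test_total$p.value)))
  invisible(x)
}

#' Group comparison of VAF (or any value) series per key
#'
#' For each key (mutation, gene or pathway) compares the value distribution
#' between groups: Mann-Whitney U (exact for small tie-free samples, normal
#' approximation with tie correction otherwise), Student's t, or one-way
#' ANOVA for 3+ groups (the smoker/nonsmoker-by-cycle convention). An empty
#' group yields a "not-evaluable" row, never a fabricated p-value.
#' Benjamini-Hochberg adjusted p-values are reported alongside raw ones.
#'
#' @param data Data frame with at least the value and group columns.
#' @param value_col,group_col,key_col Column names (key optional: `NULL`
#'   compares the whole frame as one key).
#' @param test One of "mann-whitney", "t", "anova".
#' @param alternative Passed to the two-sample tests (default two-sided).
#' @return Data frame: `key`, `test`, `statistic`, `p_value`, `p_adj`,
#'   group sizes, `note`.
#' @export
group_compare_vaf <- function(data, value_col = "vaf", group_col = "group",
                              key_col = NULL,
                              test = c("mann-whitney", "t", "anova"),
                              alternative = "two.sided") {
  test <- match.arg(test)
  keys <- if (is.null(key_col)) list(all = data) else
    split(data, data[[key_col]])
  rows <- lapply(names(keys), function(k) {
    d <- keys[[k]]
    g <- factor(d[[group_col]])
    v <- d[[value_col]]
    sizes <- table(g)
    base <- data.frame(key = k, test = test, statistic = NA_real_,
                       p_value = NA_real_, n_groups = nlevels(g),
                       n_min = if (length(sizes)) min(sizes) else 0L,
                       note = NA_character_, stringsAsFactors = FALSE)
    if (nlevels(g) < 2 || any(sizes == 0)) {
      base$note <- "not-evaluable"
      return(base)
    }
    if (test == "anova") {
      fit <- aov(v ~ g)
      sm <- summary(fit)[[1]]
      base$statistic <- sm[["F value"]][1]
      base$p_value <- sm[["Pr(>F)"]][1]
      return(base)
    }
    if (nlevels(g) != 2) {
      base$note <- "not-evaluable"
      return(base)
    }
    x <- v[g == levels(g)[1]]; y <- v[g == levels(g)[2]]
    if (test == "mann-whitney") {
      exact <- length(x) <= 20 && length(y) <= 20 &&
        !any(duplicated(c(x, y)))
      ht <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                         correct = !exact,
                                         alternative = alternative))
    } else {
      ht <- t.test(x, y, alternative = alternative)
    }
    base$statistic <- unname(ht$statistic)
    base$p_value <- ht$p.value
    base
  })
  out <- do.call(rbind, rows)
  ok <- is.na(out$note)
  out$p_adj <- NA_real_
  out$p_adj[ok] <- p.adjust(out$p_value[ok], method = "BH")
  rownames(out) <- NULL
  out
}

#' Fisher's exact and Cochran-Mantel-Haenszel tests on 2x2(xS) tables
#'
#' Fisher's exact test (hypergeometric enumeration, via `fisher.test`) for a
#' single 2x2 table; the Cochran-Mantel-Haenszel chi-squared test (without
#' continuity correction, stated in the result) for a stratified 2x2xS
#' array. A table with an all-zero margin is reported "not-evaluable".
#'
#' @param tab 2x2 matrix (fisher) or 2x2xS array (cmh).
#' @param test "fisher" or "cmh".
#' @return List: `method`, `statistic` (CMH chi-squared, `NA` for Fisher),
#'   `odds_ratio`, `p_value`, `note`.
#' @export
contingency_tests <- function(tab, test = c("fisher", "cmh")) {
  test <- match.arg(test)
  flat <- if (length(dim(tab)) == 3) apply(tab, c(1, 2), sum) else tab
  if (any(rowSums(flat) == 0) || any(colSums(flat) == 0)) {
    return(list(method = test, statistic = NA_real_, odds_ratio = NA_real_,
                p_value = NA_real_, note = "not-evaluable"))
  }
  if (test == "fisher") {
    ht <- fisher.test(tab)
    list(method = "fisher", statistic = NA_real_,
         odds_ratio = unname(ht$estimate), p_value = ht$p.value, note = NA)
  } else {
    if (length(dim(tab)) != 3) stop_invalid("cmh requires a 2x2xS array")
    ht <- mantelhaen.test(tab, correct = FALSE)
    list(method = "cmh (no continuity correction)",
         statistic = unname(ht$statistic),
         odds_ratio = unname(ht$estimate), p_value = ht$p.value, note = NA)
  }
}

#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit survival estimates with right censoring and, for two or
#' more groups, the log-rank test (observed minus expected event counts over
#' the pooled event times, chi-squared with groups-1 df).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored); at least one
#'   event required.
#' @param group Group labels (optional: `NULL` fits a single curve and skips
#'   the test).
#' @return List of class `km_result`: `fit` (a `survfit` object), and when
#'   groups are compared `chisq`, `df`, `p_value`, `observed`, `expected`;
#'   `note` is "not-evaluable" when a group has no subjects.
#' @export
km_logrank <- function(time, event, group = NULL) {
  if (any(time < 0)) stop_invalid("times must be non-negative")
  if (sum(event) < 1) stop_invalid("at least one event is required")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    return(structure(list(fit = fit, chisq = NA_real_, df = NA_integer_,
                          p_value = NA_real_, note = "single-group"),
                     class = "km_result"))
  }
  g <- factor(group)
  if (any(table(g) == 0) || nlevels(g) < 2) {
    return(structure(list(fit = NULL, chisq = NA_real_, df = NA_integer_,
                          p_value = NA_real_, note = "not-evaluable"),
                     class = "km_result"))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd$n) - 1L
  structure(list(fit = fit, chisq = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = unname(sd$obs), expected = unname(sd$exp),
                 note = NA), class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  if (!is.na(x$chisq)) {
    cat(sprintf("<km_result> log-rank chisq = %.4g on %d df, p = %s\n",
                x$chisq, x$df, format.pval(x$p_value)))
  } else cat("<km_result>", x$note, "\n")
  invisible(x)
}

#' Plasma-tissue variant concordance
#'
#' Overlap between two variant call sets keyed by (contig, position, ref,
#' alt). Because the published convention for the denominator is ambiguous,
#' three fractions are reported and labelled: the union fraction
#' |A intersect B| / |A union B| (symmetric), and per-source fractions
#' |A intersect B| / |A| and / |B|.
#'
#' @param plasma_keys,tissue_keys Character vectors of variant keys
#'   (duplicates ignored).
#' @return List: `n_overlap`, `n_plasma`, `n_tissue`, `n_union`,
#'   `fraction_union`, `fraction_of_plasma`, `fraction_of_tissue`.
#' @export
concordance <- function(plasma_keys, tissue_keys) {
  a <- unique(plasma_keys); b <- unique(tissue_keys)
  ov <- length(intersect(a, b))
  un <- length(union(a, b))
  list(n_overlap = ov, n_plasma = length(a), n_tissue = length(b),
       n_union = un,
       fraction_union = if (un) ov / un else NA_real_,
       fraction_of_plasma = if (length(a)) ov / length(a) else NA_real_,
       fraction_of_tissue = if (length(b)) ov / length(b) else NA_real_)
}

#' Join passed variants against an actionability table
#'
#' Exact match on (gene, protein change); rows of the table with a missing
#' protein change act as gene-level entries matched when `gene_fallback` is
#' on. Patients are grouped by when a target was available: pre-treatment
#' only, pre & post, or post only.
#'
#' @param variants Data frame with `patient_id`, `timepoint` ("pre"/"post"),
#'   `gene`, `protein_change`.
#' @param table Data frame with `gene`, `protein_change` (NA = gene-level),
#'   `drugs`.
#' @param gene_fallback Also match gene-level table rows (default TRUE).
#'   Turning it on can only add matches.
#' @return List: `matches` (variant rows with matched `drugs`),
#'   `patient_availability` (data frame `patient_id`, `availability` in
#'   {pre_only, pre_and_post, post_only}).
#' @export
actionability_join <- function(variants, table, gene_fallback = TRUE) {
  if (!nrow(variants) || !nrow(table)) {
    return(list(matches = cbind(variants[0, , drop = FALSE],
                                drugs = character(0)),
                patient_availability = data.frame(patient_id = character(0),
                                                  availability = character(0),
                                                  stringsAsFactors = FALSE)))
  }
  exact <- table[!is.na(table$protein_change), , drop = FALSE]
  genelvl <- table[is.na(table$protein_change), , drop = FALSE]
  ekey <- paste(exact$gene, exact$protein_change)
  vkey <- paste(variants$gene, variants$protein_change)
  m <- match(vkey, ekey)
  drugs <- ifelse(is.na(m), NA_character_, exact$drugs[m])
  if (gene_fallback && nrow(genelvl)) {
    g <- match(variants$gene, genelvl$gene)
    use <- is.na(drugs) & !is.na(g)
    drugs[use] <- genelvl$drugs[g[use]]
  }
  hit <- !is.na(drugs)
  matches <- cbind(variants[hit, , drop = FALSE], drugs = drugs[hit])
  rownames(matches) <- NULL
  avail <- do.call(rbind, lapply(split(matches, matches$patient_id),
                                 function(d) {
    has_pre <- any(d$timepoint == "pre"); has_post <- any(d$timepoint == "post")
    data.frame(patient_id = d$patient_id[1],
               availability = if (has_pre && has_post) "pre_and_post"
                              else if (has_pre) "pre_only" else "post_only",
               stringsAsFactors = FALSE)
  }))
  if (is.null(avail)) {
    avail <- data.frame(patient_id = character(0), availability = character(0),
                        stringsAsFactors = FALSE)
  }
  rownames(avail) <- NULL
  list(matches = matches, patient_availability = avail)
}

#' Pool per-variant VAF observations to gene or pathway level
#'
#' Builds the long table [group_compare_vaf()] consumes: one row per variant
#' observation, keyed by gene or by pathway (a variant contributes to every
#' pathway whose gene set contains its gene).
#'
#' @param cohort A `cohort` object.
#' @param level "gene" or "pathway".
#' @param pathway_sets Named list of gene sets (required for pathway level).
#' @return Data frame `key`, `sample_id`, `patient_id`, `timepoint`,
#'   `response`, `smoking`, `cycle_index`, `vaf`.
#' @export
vaf_series <- function(cohort, level = c("gene", "pathway"),
                       pathway_sets = NULL) {
  level <- match.arg(level)
  if (level == "pathway" && is.null(pathway_sets))
    stop_invalid("pathway level requires pathway_sets")
  s <- cohort$samples
  rows <- lapply(seq_len(nrow(s)), function(i) {
    v <- cohort$variants[[s$sample_id[i]]]
    if (is.null(v) || !nrow(v)) return(NULL)
    if (level == "gene") {
      keys <- v$gene; vafs <- v$vaf
    } else {
      keys <- character(0); vafs <- numeric(0)
      for (pw in names(pathway_sets)) {
        inpw <- v$gene %in% pathway_sets[[pw]]
        keys <- c(keys, rep(pw, sum(inpw)))
        vafs <- c(vafs, v$vaf[inpw])
      }
    }
    if (!length(keys)) return(NULL)
    data.frame(key = keys, sample_id = s$sample_id[i],
               patient_id = s$patient_id[i], timepoint = s$timepoint[i],
               response = s$response[i], smoking = s$smoking[i],
               cycle_index = s$cycle_index[i], vaf = vafs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(key = character(0), sample_id = character(0),
                      patient_id = character(0), timepoint = character(0),
                      response = character(0), smoking = character(0),
                      cycle_index = integer(0), vaf = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
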