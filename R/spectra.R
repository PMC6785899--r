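SIX_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution channels
#'
#' Pyrimidine-centred channel labels in canonical catalog order: the six
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each crossed with the
#' 16 flanking-base combinations ordered alphabetically, giving
#' `A[C>A]A`, `A[C>A]C`, ..., `T[T>G]T`.
#'
#' @return Character vector of length 96.
#' @export
sub_channels <- function() {
  out <- character(0)
  for (cls in SIX_CLASSES) {
    for (five in BASES) for (three in BASES) {
      out <- c(out, paste0(five, "[", cls, "]", three))
    }
  }
  out
}

#' Classify a single-base substitution into class and channel
#'
#' Substitutions with a purine reference base (A or G) are reverse
#' complemented onto the pyrimidine strand, so every substitution maps to one
#' of the six classes and one of the 96 channels; the mapping over all
#' 6 x 16 pyrimidine-centred inputs is a bijection onto the channels.
#'
#' @param ref,alt Reference and alternate bases (vectors recycled to common
#'   length); `ref != alt`, both in A/C/G/T.
#' @param context 3-mer centred on the reference base.
#' @return Data frame with `class` (one of the six), `channel` (label) and
#'   `index` (1-96, position in [sub_channels()]).
#' @export
classify_substitution <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  if (!all(is_base(ref)) || !all(is_base(alt)))
    stop_invalid("ref and alt must be single bases in A/C/G/T")
  if (any(ref == alt)) stop_invalid("ref and alt must differ")
  if (any(nchar(context) != 3) ||
      !all(is_base(unlist(strsplit(context, "")))))
    stop_invalid("context must be 3-mers over A/C/G/T")
  if (any(substr(context, 2, 2) != ref))
    stop_invalid("context must be centred on the reference base")
  pur <- ref %in% c("A", "G")
  ref[pur] <- chartr("ACGT", "TGCA", ref[pur])
  alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  context[pur] <- revcomp(context[pur])
  cls <- paste0(ref, ">", alt)
  channel <- paste0(substr(context, 1, 1), "[", cls, "]",
                    substr(context, 3, 3))
  data.frame(class = cls, channel = channel,
             index = match(channel, sub_channels()), stringsAsFactors = FALSE)
}

#' Construct a 96-channel mutation catalog object
#'
#' @param counts Integer vector of length 96 (COSMIC channel order), named
#'   or unnamed.
#' @param sample_id Label.
#' @param n_uncontexted Variants that could not be assigned a full
#'   trinucleotide context (contig edges); excluded from `counts`.
#' @return List of class `mutation_catalog` with `sample_id`, `counts`
#'   (named), `total`, `n_uncontexted`.
#' @export
mutation_catalog <- function(counts, sample_id = "sample",
                             n_uncontexted = 0L) {
  if (length(counts) != 96) stop_invalid("counts must have length 96")
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  counts <- as.integer(counts)
  names(counts) <- sub_channels()
  structure(list(sample_id = sample_id, counts = counts,
                 total = sum(counts), n_uncontexted = as.integer(n_uncontexted)),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("<mutation_catalog> %s: %d mutations over 96 channels\n",
              x$sample_id, x$total))
  invisible(x)
}

#' Aggregate a 96-channel catalog to the six substitution classes
#' @param catalog A `mutation_catalog`.
#' @return Named integer vector over C>A, C>G, C>T, T>A, T>C, T>G.
#' @export
spectrum_six <- function(catalog) {
  cls <- substr(sub_channels(), 3, 5)
  vapply(SIX_CLASSES, function(k) sum(catalog$counts[cls == k]), integer(1))
}

#' Build a mutation catalog from passed variants
#'
#' Classifies each substitution by its trinucleotide context on the
#' reference. Variants at contig edges without a full context are counted in
#' an `n_uncontexted` bucket and excluded from the 96-vector, so the catalog
#' total always equals the number of contexted SNVs and the six-class
#' spectrum aggregates the channels 16-to-1.
#'
#' @param variants Data frame with `position` (0-based; or `pos`), `ref`,
#'   `alt`.
#' @param ref A `ref_context`.
#' @param sample_id Catalog label.
#' @return A `mutation_catalog`.
#' @export
build_catalog <- function(variants, ref, sample_id = "sample") {
  pos_col <- if ("position" %in% names(variants)) "position" else "pos"
  if (!nrow(variants)) return(mutation_catalog(integer(96), sample_id))
  ctx <- ref_context3(ref, variants[[pos_col]])
  ok <- !is.na(ctx)
  counts <- integer(96)
  if (any(ok)) {
    cl <- classify_substitution(variants$ref[ok], variants$alt[ok], ctx[ok])
    tab <- tabulate(cl$index, nbins = 96)
    counts <- as.integer(tab)
  }
  mutation_catalog(counts, sample_id = sample_id, n_uncontexted = sum(!ok))
}

#' Fit signature weights by non-negative least squares
#'
#' Decomposes a 96-channel catalog over a signature matrix by NNLS
#' (Lawson-Hanson, via `pracma::lsqnonneg`): weights minimise
#' \eqn{\lVert S w - y \rVert_2} subject to \eqn{w \ge 0}. Fitting is on raw
#' counts by default (weights are then attributed mutation counts);
#' `proportions = TRUE` fits the normalised profile instead.
#'
#' @param catalog A `mutation_catalog`.
#' @param signature_matrix 96 x K non-negative matrix, columns summing to 1.
#' @param proportions Fit the catalog as proportions instead of counts.
#' @return List of class `signature_fit`: `weights` (K, named), `fractions`
#'   (weights normalised to sum 1; all zero for an empty fit),
#'   `residual_norm`, `total`, `empty` (flag for a zero-mutation catalog).
#' @export
fit_signatures <- function(catalog, signature_matrix, proportions = FALSE) {
  K <- ncol(signature_matrix)
  nm <- colnames(signature_matrix)
  if (is.null(nm)) nm <- paste0("Signature.", seq_len(K))
  if (nrow(signature_matrix) != 96)
    stop_invalid("signature_matrix must have 96 rows")
  y <- as.numeric(catalog$counts)
  if (catalog$total == 0) {
    return(structure(list(weights = setNames(numeric(K), nm),
                          fractions = setNames(numeric(K), nm),
                          residual_norm = 0, total = 0L, empty = TRUE),
                     class = "signature_fit"))
  }
  if (proportions) y <- y / sum(y)
  w <- pracma::lsqnonneg(signature_matrix, y)$x
  w <- pmax(w, 0)
  res <- sqrt(sum((as.vector(signature_matrix %*% w) - y)^2))
  fr <- if (sum(w) > 0) w / sum(w) else w
  structure(list(weights = setNames(w, nm), fractions = setNames(fr, nm),
                 residual_norm = res, total = catalog$total, empty = FALSE),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  top <- sort(x$fractions, decreasing = TRUE)
  top <- top[top > 0.01]
  cat(sprintf("<signature_fit> %d mutations, residual %.3g\n", x$total,
              x$residual_norm))
  if (length(top)) {
    cat("  top weights:",
        paste(sprintf("%s=%.2f", names(top)[seq_len(min(5, length(top)))],
                      top[seq_len(min(5, length(top)))]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Label a sample's dominant mutational etiology
#'
#' A label is assigned when the summed weight fraction of its signature set
#' reaches `dominance_fraction`. Default sets follow the usual catalog
#' conventions for this tumor type: smoking-associated signatures {4, 16,
#' 29} and the platinum/HRD-associated signature {3}.
#'
#' @param fit A `signature_fit`.
#' @param smoking_set,platinum_set Integer indices (or names) of catalog
#'   columns in each etiology set.
#' @param dominance_fraction Threshold on the summed weight fraction
#'   (default 0.25).
#' @return Character vector: subset of `c("smoking", "platinum")` (may be
#'   empty).
#' @export
label_etiology <- function(fit, smoking_set = c(4L, 16L, 29L),
                           platinum_set = 3L, dominance_fraction = 0.25) {
  pick <- function(set) {
    idx <- if (is.character(set)) match(set, names(fit$fractions)) else set
    idx <- idx[!is.na(idx) & idx >= 1 & idx <= length(fit$fractions)]
    sum(fit$fractions[idx])
  }
  out <- character(0)
  if (pick(smoking_set) >= dominance_fraction) out <- c(out, "smoking")
  if (pick(platinum_set) >= dominance_fraction) out <- c(out, "platinum")
  out
}
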