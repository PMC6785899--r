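#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois rexp rbeta rmultinom dbinom
#'   pbinom wilcox.test t.test fisher.test mantelhaen.test aov p.adjust
#'   pchisq sd setNames aggregate format.pval
#' @importFrom utils write.table read.table head
NULL

BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators are pure functions of (seed,
# parameters).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

stop_invalid <- function(...) {
  stop(structure(class = c("invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_base <- function(x) x %in% BASES

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
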