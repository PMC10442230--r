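#' Derive a stage-specific RNG seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; each
#' stage perturbs it deterministically so that re-running one stage does not
#' depend on how many random draws earlier stages consumed.
#'
#' @param seed master integer seed.
#' @param stage character tag naming the consuming stage.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Classify chromosomes as X or autosome
#'
#' @param chromosome character vector of chromosome names.
#' @param x_aliases names recognized as the X chromosome.
#' @return factor with levels `c("autosome", "X")`.
#' @export
chromosome_class <- function(chromosome, x_aliases = c("X", "chrX")) {
  factor(ifelse(chromosome %in% x_aliases, "X", "autosome"),
         levels = c("autosome", "X"))
}

#' Geometric mean ignoring non-finite values
#' @param x positive numeric vector.
#' @return geometric mean; 0 if any value is 0.
#' @keywords internal
geom_mean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# stop() with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Benjamini-Hochberg adjustment of a named p-value vector
#'
#' Thin wrapper used so every reported p-value family is adjusted the same
#' way; keeps NA entries in place.
#' @param p named numeric vector of p-values.
#' @return adjusted p-values, same names.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
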