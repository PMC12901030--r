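#' False-discovery-rate correction
#'
#' Benjamini-Hochberg step-up adjusted p values with a rejection mask at
#' level `q`. Wraps the standard step-up procedure; adjusted values never fall
#' below the raw ones.
#'
#' @param p Numeric vector of p values in \[0, 1\] (`NA` allowed, kept `NA`).
#' @param q FDR level.
#' @return A list with `corrected` (adjusted p values) and `mask`
#'   (`corrected <= q`).
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (!length(p)) return(list(corrected = numeric(0), mask = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(corrected = adj, mask = !is.na(adj) & adj <= q)
}

#' Paired t test
#'
#' Classical paired t statistic of `a - b` against zero, one- or two-sided.
#' Identical inputs (all differences exactly zero) give a statistic of 0 with
#' a two-sided p of 1; a constant nonzero difference has no defensible
#' standard error and raises an error.
#'
#' @param a,b Numeric vectors of equal length (at least 2).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (of `a - b`).
#' @return A list with `statistic`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) < 1e-15) {
    if (all(abs(d) < 1e-15))
      return(list(statistic = 0, df = length(d) - 1L,
                  p = switch(alternative, two.sided = 1, 0.5),
                  mean_diff = 0))
    stop("zero variance of the paired differences")
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}
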