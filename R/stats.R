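#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric enumeration: the p-value is the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. Ties are included with a
#' `1 + 1e-7` relative tolerance, the convention of the widely used
#' implementations this matches. A table with an empty row or column
#' margin carries no information and returns `p = 1`.
#'
#' @param a,b,c,d Non-negative integer counts; rows are groups, columns
#'   outcomes. Alternatively `a` may be a 2x2 matrix.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty table")
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default (the field's default for
#' discovery lists); Bonferroni available as an option. Output order
#' matches input order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = if (method == "bh") "BH" else "bonferroni")
}
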