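#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact hypergeometric enumeration with the minimum-likelihood definition of
#' the two-sided p value: the sum of the probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table (a relative slack of 1e-7 absorbs floating-point ties, the same
#' convention as `stats::fisher.test`).
#'
#' @param a,b top row of the table (e.g. tumor alt / tumor ref reads).
#' @param c_,d_ bottom row (e.g. normal alt / normal ref reads).
#' @return the two-sided exact p value.
#' @examples
#' fisher_exact_p(3, 1, 1, 3) # 34/70
#' @export
fisher_exact_p <- function(a, b, c_, d_) {
  counts <- c(a, b, c_, d_)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  m <- a + b            # row-1 margin
  n <- c_ + d_          # row-2 margin
  k <- a + c_           # column-1 margin
  if (m + n == 0) stop("empty table", call. = FALSE)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}
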