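# Independent oracles used across test files. These re-derive expected
# values by direct enumeration / closed form, never by calling the code
# paths they check.

# Fisher two-sided p by direct factorial enumeration of all 2x2 tables with
# the observed margins (probability computed from choose(), not dhyper).
fisher_oracle <- function(a, b, c_, d_) {
  m <- a + b; n <- c_ + d_; k <- a + c_
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# lower-tail binomial by direct summation of the mass function
binom_lower_oracle <- function(k, n) {
  sum(vapply(0:k, function(x) choose(n, x) * 0.5^n, numeric(1)))
}

# empirical survival function (no censoring): fraction surviving past t
empirical_surv <- function(times, t) mean(times > t)

# a tiny deterministic variant table builder
make_variants <- function(tumor_alt, tumor_depth, normal_alt, normal_depth,
                          ...) {
  n <- length(tumor_alt)
  defaults <- list(chrom = rep("chr1", n), pos = seq_len(n),
                   ref = rep("A", n), alt = rep("T", n),
                   gene = sprintf("G%d", seq_len(n)),
                   effect = rep("nonsyn_damaging", n),
                   gene_role = rep("oncogene", n), pop_af = rep(0, n),
                   in_cosmic = rep(TRUE, n), pon_hits = rep(0L, n))
  extra <- list(...)
  for (nm in names(extra)) defaults[[nm]] <- rep_len(extra[[nm]], n)
  do.call(data.frame, c(defaults,
                        list(tumor_alt = tumor_alt, tumor_depth = tumor_depth,
                             normal_alt = normal_alt, normal_depth = normal_depth,
                             stringsAsFactors = FALSE)))
}
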