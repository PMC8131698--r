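# ChIP-qPCR fold-enrichment arithmetic: enrichment of an immunoprecipitated
# target over the IgG control, on the 2^-dCt scale.

#' qPCR fold enrichment
#'
#' Fold enrichment of an immunoprecipitation over its IgG control:
#' `2^-(ip_ct - igg_ct)`. One cycle of difference doubles (or halves) the
#' enrichment.
#'
#' @param ip_ct immunoprecipitation Ct (cycles), finite and positive.
#' @param igg_ct IgG control Ct (cycles), finite and positive.
#' @return fold enrichment (dimensionless); vectorized.
#' @examples
#' fold_enrichment(25, 28) # 8
#' @export
fold_enrichment <- function(ip_ct, igg_ct) {
  if (anyNA(ip_ct) || anyNA(igg_ct) ||
      !all(is.finite(ip_ct)) || !all(is.finite(igg_ct)) ||
      any(ip_ct <= 0) || any(igg_ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  2^(-(ip_ct - igg_ct))
}

#' Replicate summary of fold enrichments
#'
#' @param folds per-replicate fold values (at least 2).
#' @return list with `mean`, `sem` (sample SD / sqrt(n)), `n`.
#' @export
replicate_summary <- function(folds) {
  folds <- folds[!is.na(folds)]
  n <- length(folds)
  if (n < 2) stop("SEM undefined with fewer than 2 replicates", call. = FALSE)
  list(mean = mean(folds), sem = stats::sd(folds) / sqrt(n), n = n)
}

#' Per-sample fold-enrichment table from long-format qPCR data
#'
#' Replicate Cts are averaged per sample and antibody before the enrichment
#' arithmetic (`aggregate = "mean_ct"`, the default); alternatively each
#' replicate pair is converted to a fold first and the folds summarized
#' (`aggregate = "per_replicate"`, requires matching replicate ids).
#'
#' @param data data.frame with columns `sample`, `antibody` (values `IP` and
#'   `IgG`), `replicate`, `ct`.
#' @param aggregate `"mean_ct"` or `"per_replicate"`.
#' @return data.frame with one row per sample: `fold` (and `sem`, `n` for
#'   per-replicate aggregation).
#' @export
qpcr_fold_table <- function(data, aggregate = c("mean_ct", "per_replicate")) {
  aggregate <- match.arg(aggregate)
  need <- c("sample", "antibody", "replicate", "ct")
  if (!all(need %in% names(data))) {
    stop("need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(data$antibody %in% c("IP", "IgG"))) {
    stop("antibody must be 'IP' or 'IgG'", call. = FALSE)
  }
  out <- lapply(split(data, data$sample), function(d) {
    ip <- d[d$antibody == "IP", ]
    igg <- d[d$antibody == "IgG", ]
    if (nrow(ip) == 0 || nrow(igg) == 0) {
      stop("sample ", d$sample[1], " lacks IP or IgG measurements", call. = FALSE)
    }
    if (aggregate == "mean_ct") {
      data.frame(sample = d$sample[1],
                 fold = fold_enrichment(mean(ip$ct), mean(igg$ct)),
                 stringsAsFactors = FALSE)
    } else {
      m <- merge(ip[, c("replicate", "ct")], igg[, c("replicate", "ct")],
                 by = "replicate", suffixes = c("_ip", "_igg"))
      if (nrow(m) == 0) stop("no matching replicate ids for sample ",
                             d$sample[1], call. = FALSE)
      folds <- fold_enrichment(m$ct_ip, m$ct_igg)
      s <- replicate_summary(folds)
      data.frame(sample = d$sample[1], fold = s$mean, sem = s$sem, n = s$n,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
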