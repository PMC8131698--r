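# The variant-processing chain: read-support and VAF filter, population
# allele-frequency filter, panel-of-normals filter, exact-Fisher somatic
# classification against the contaminated normal, and driver annotation.
# Variants are rows of a data.frame; filters set monotone flag columns and
# never modify counts, so the chain is idempotent.

FLAG_COLS <- c("fail_support", "fail_pop_af", "fail_pon", "somatic",
               "germline_ambiguous", "putative_driver")

ensure_flags <- function(variants) {
  n <- nrow(variants)
  for (f in FLAG_COLS) {
    if (is.null(variants[[f]])) variants[[f]] <- rep(FALSE, n)
  }
  if (is.null(variants$somatic_p)) variants$somatic_p <- rep(NA_real_, n)
  variants
}

variant_id <- function(variants) {
  paste0(variants$chrom, ":", variants$pos, " ", variants$ref, ">", variants$alt)
}

#' Read-support and VAF filter
#'
#' Excludes alternative alleles with fewer than `min_reads` supporting reads
#' and/or a tumor VAF below `min_vaf`. Both thresholds are strict (`<`):
#' boundary values (5 reads, VAF 0.05) pass.
#'
#' @param variants data.frame with `tumor_alt`, `tumor_depth`.
#' @param min_reads minimum alt read count (default 5).
#' @param min_vaf minimum tumor VAF (default 0.05).
#' @return `variants` with the `fail_support` flag set.
#' @export
support_filter <- function(variants, min_reads = 5, min_vaf = 0.05) {
  variants <- ensure_flags(variants)
  if (any(variants$tumor_depth < 1)) {
    bad <- which(variants$tumor_depth < 1)[1]
    stop(sprintf("tumor depth 0 at %s: VAF undefined", variant_id(variants)[bad]),
         call. = FALSE)
  }
  if (any(variants$tumor_alt > variants$tumor_depth |
          variants$tumor_alt < 0)) {
    stop("tumor_alt must lie in [0, tumor_depth]", call. = FALSE)
  }
  vaf <- variants$tumor_alt / variants$tumor_depth
  variants$fail_support <- variants$fail_support |
    variants$tumor_alt < min_reads | vaf < min_vaf
  variants
}

#' Population allele-frequency filter
#'
#' Flags known polymorphisms: variants whose population allele frequency
#' (ExAC-style) is strictly above `af_cutoff`. Missing `pop_af` is treated as
#' 0 (novel variant) with a warning rather than silently dropping the record.
#'
#' @param variants data.frame with `pop_af`.
#' @param af_cutoff exclusion cutoff (default 0.001; "above" is strict).
#' @return `variants` with the `fail_pop_af` flag set.
#' @export
population_filter <- function(variants, af_cutoff = 0.001) {
  variants <- ensure_flags(variants)
  af <- variants$pop_af
  if (anyNA(af)) {
    warning(sprintf("%d variants with missing pop_af treated as 0", sum(is.na(af))),
            call. = FALSE)
    af[is.na(af)] <- 0
  }
  check_prob(af, "pop_af")
  variants$fail_pop_af <- variants$fail_pop_af | af > af_cutoff
  variants
}

#' Panel-of-normals filter
#'
#' Flags recurrent artifacts: variants observed in at least `min_hits` of the
#' panel-of-normals samples. A singleton PON hit is tolerated as a possible
#' artifact or contamination event.
#'
#' @param variants data.frame with `pon_hits`.
#' @param min_hits flag when `pon_hits >= min_hits` (default 2).
#' @return `variants` with the `fail_pon` flag set.
#' @export
pon_filter <- function(variants, min_hits = 2) {
  variants <- ensure_flags(variants)
  if (any(variants$pon_hits < 0)) stop_field("pon_hits", "must be >= 0")
  variants$fail_pon <- variants$fail_pon | variants$pon_hits >= min_hits
  variants
}

#' Fisher exact somatic classification against a contaminated normal
#'
#' Because the CD3-positive "normal" compartment can itself carry tumor
#' cells, somatic status cannot be called by simple subtraction. Instead the
#' tumor and normal allele counts are compared with a two-sided Fisher exact
#' test on the 2x2 table `[[tumor_alt, tumor_ref], [normal_alt, normal_ref]]`
#' (minimum-likelihood enumeration, see [fisher_exact_p()]); a variant is
#' classified somatic when p falls below `p_cutoff`, otherwise it remains
#' germline-ambiguous.
#'
#' @param tumor_alt,tumor_depth,normal_alt,normal_depth read counts
#'   (vectorized).
#' @param p_cutoff somatic call threshold (default 1e-4; "below" is strict).
#' @return data.frame with `p_value` and `classification` (`somatic` /
#'   `germline_ambiguous`).
#' @export
fisher_somatic_test <- function(tumor_alt, tumor_depth, normal_alt,
                                normal_depth, p_cutoff = 1e-4) {
  m <- length(tumor_alt)
  counts <- cbind(tumor_alt, tumor_depth, normal_alt, normal_depth)
  if (anyNA(counts) || any(counts < 0)) {
    stop("read counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(tumor_depth < 1) || any(normal_depth < 1)) {
    stop("zero depth: Fisher somatic test undefined", call. = FALSE)
  }
  if (any(tumor_alt > tumor_depth) || any(normal_alt > normal_depth)) {
    stop("alt count exceeds depth", call. = FALSE)
  }
  p <- vapply(seq_len(m), function(i) {
    fisher_exact_p(tumor_alt[i], tumor_depth[i] - tumor_alt[i],
                   normal_alt[i], normal_depth[i] - normal_alt[i])
  }, numeric(1))
  data.frame(
    p_value = p,
    classification = ifelse(p < p_cutoff, "somatic", "germline_ambiguous"),
    stringsAsFactors = FALSE
  )
}

#' Putative-driver annotation
#'
#' A variant is a putative driver if it is reported in COSMIC and, for tumor
#' suppressor genes, belongs to a damaging effect class: stop-gain,
#' frameshift indel, splice-site, or probably damaging nonsynonymous.
#' Oncogene (and unknown-role) variants need only the COSMIC report.
#'
#' @param variants data.frame with `in_cosmic`, `gene_role`, `effect`.
#' @return `variants` with the `putative_driver` flag set.
#' @export
annotate_driver <- function(variants) {
  variants <- ensure_flags(variants)
  damaging <- c("stop_gain", "frameshift_indel", "splice_site", "nonsyn_damaging")
  variants$putative_driver <- variants$in_cosmic &
    (variants$gene_role != "TSG" | variants$effect %in% damaging)
  variants
}

#' Run the full variant filter chain
#'
#' Applies the stages in order: read support -> population frequency ->
#' panel of normals -> Fisher somatic classification -> driver annotation.
#' Flags are monotone (never cleared by a later stage) and exclusions are
#' attributed to the first stage that removes a variant, so the chain is
#' idempotent and the per-stage counts sum to the number excluded.
#'
#' @param variants data.frame of variant calls (see
#'   [simulate_tumor_normal_counts()] for the column layout).
#' @param p_cutoff Fisher somatic threshold (default 1e-4).
#' @param af_cutoff population-frequency cutoff (default 0.001).
#' @param pon_min_hits panel-of-normals threshold (default 2).
#' @param min_reads,min_vaf read-support thresholds (defaults 5 and 0.05).
#' @return list of class `filter_report`: `variants` (all rows, flags set),
#'   `passed` (somatic survivors), and `report` (per-stage input/excluded
#'   counts).
#' @export
run_filter_chain <- function(variants, p_cutoff = 1e-4, af_cutoff = 0.001,
                             pon_min_hits = 2, min_reads = 5, min_vaf = 0.05) {
  variants <- ensure_flags(variants)
  n0 <- nrow(variants)
  if (n0 == 0) {
    report <- data.frame(
      stage = c("support", "pop_af", "pon", "fisher_somatic"),
      n_in = 0L, n_excluded = 0L, stringsAsFactors = FALSE
    )
    return(structure(list(variants = variants, passed = variants,
                          report = report),
                     class = "filter_report"))
  }

  variants <- support_filter(variants, min_reads = min_reads, min_vaf = min_vaf)
  alive <- !variants$fail_support
  n_support <- sum(!alive)

  variants <- population_filter(variants, af_cutoff = af_cutoff)
  excl_pop <- alive & variants$fail_pop_af
  alive <- alive & !variants$fail_pop_af

  variants <- pon_filter(variants, min_hits = pon_min_hits)
  excl_pon <- alive & variants$fail_pon
  alive <- alive & !variants$fail_pon

  ft <- fisher_somatic_test(variants$tumor_alt, variants$tumor_depth,
                            variants$normal_alt, variants$normal_depth,
                            p_cutoff = p_cutoff)
  variants$somatic_p <- ft$p_value
  variants$somatic <- ft$classification == "somatic"
  variants$germline_ambiguous <- !variants$somatic
  excl_fisher <- alive & !variants$somatic
  alive <- alive & variants$somatic

  variants <- annotate_driver(variants)

  report <- data.frame(
    stage = c("support", "pop_af", "pon", "fisher_somatic"),
    n_in = c(n0, n0 - n_support, n0 - n_support - sum(excl_pop),
             n0 - n_support - sum(excl_pop) - sum(excl_pon)),
    n_excluded = c(n_support, sum(excl_pop), sum(excl_pon), sum(excl_fisher)),
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants,
                 passed = variants[alive, , drop = FALSE],
                 report = report),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("clonarch filter chain:", nrow(x$variants), "variants in,",
      nrow(x$passed), "somatic survivors\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
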