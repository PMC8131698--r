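# Minimal VCF 4.2 serialization for variant-call tables: two samples (TUMOR,
# NORMAL) with allelic depths in FORMAT AD, annotations in INFO (GENE,
# EFFECT, ROLE, POPAF, COSMIC, PONHITS, and SOMATICP once classified),
# filter verdicts in FILTER. Reading goes through vcfR.

vcf_filter_string <- function(variants) {
  verdict <- rep("PASS", nrow(variants))
  pick <- function(flag, label) {
    hit <- !is.na(variants[[flag]]) & variants[[flag]]
    ifelse(hit & verdict == "PASS", label,
           ifelse(hit, paste(verdict, label, sep = ";"), verdict))
  }
  if (!is.null(variants$fail_support)) verdict <- pick("fail_support", "support")
  if (!is.null(variants$fail_pop_af)) verdict <- pick("fail_pop_af", "pop_af")
  if (!is.null(variants$fail_pon)) verdict <- pick("fail_pon", "pon")
  if (!is.null(variants$germline_ambiguous)) {
    verdict <- pick("germline_ambiguous", "germline")
  }
  verdict
}

#' Write a variant table as minimal VCF 4.2
#'
#' @param variants data.frame with coordinates, annotations and tumor/normal
#'   counts (layout of [simulate_tumor_normal_counts()]); flag columns, when
#'   present, populate FILTER and INFO/SOMATICP.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, seed = NA) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=clonarch %s", utils::packageVersion("clonarch")),
    sprintf("##clonarch_seed=%s", format(seed)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect class\">",
    "##INFO=<ID=ROLE,Number=1,Type=String,Description=\"Gene role (oncogene/TSG/unknown)\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=COSMIC,Number=0,Type=Flag,Description=\"Reported in COSMIC\">",
    "##INFO=<ID=PONHITS,Number=1,Type=Integer,Description=\"Panel-of-normals hits\">",
    "##INFO=<ID=SOMATICP,Number=1,Type=Float,Description=\"Fisher exact somatic p value\">",
    "##FILTER=<ID=support,Description=\"<5 alt reads and/or VAF <5%\">",
    "##FILTER=<ID=pop_af,Description=\"Population allele frequency above cutoff\">",
    "##FILTER=<ID=pon,Description=\"Recurrent in panel of normals\">",
    "##FILTER=<ID=germline,Description=\"Fisher test not below somatic cutoff\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  )
  if (nrow(variants)) {
    info <- sprintf("GENE=%s;EFFECT=%s;ROLE=%s;POPAF=%g;PONHITS=%d",
                    variants$gene, variants$effect, variants$gene_role,
                    variants$pop_af, as.integer(variants$pon_hits))
    info <- ifelse(variants$in_cosmic, paste0(info, ";COSMIC"), info)
    if (!is.null(variants$somatic_p) && any(!is.na(variants$somatic_p))) {
      info <- ifelse(is.na(variants$somatic_p), info,
                     sprintf("%s;SOMATICP=%g", info, variants$somatic_p))
    }
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tAD:DP\t%d,%d:%d\t%d,%d:%d",
      variants$chrom, as.integer(variants$pos), variants$ref, variants$alt,
      vcf_filter_string(variants), info,
      as.integer(variants$tumor_depth - variants$tumor_alt),
      as.integer(variants$tumor_alt), as.integer(variants$tumor_depth),
      as.integer(variants$normal_depth - variants$normal_alt),
      as.integer(variants$normal_alt), as.integer(variants$normal_depth)
    )
  } else body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF 4.2 variant file
#'
#' Parses a two-sample (TUMOR/NORMAL) VCF with FORMAT AD, as written by
#' [write_variant_vcf()], via `vcfR`.
#'
#' @param path VCF file path.
#' @return data.frame in the package's variant-call layout.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame())
  }
  info_field <- function(key, default = NA_character_) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    out <- rep(default, nrow(fix))
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  split_ad <- function(col, part) {
    as.integer(vapply(strsplit(ad[, col], ","), `[`, character(1), part))
  }
  tumor_ref <- split_ad("TUMOR", 1); tumor_alt <- split_ad("TUMOR", 2)
  normal_ref <- split_ad("NORMAL", 1); normal_alt <- split_ad("NORMAL", 2)
  somatic_p <- suppressWarnings(as.numeric(info_field("SOMATICP")))
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    gene = info_field("GENE"),
    effect = info_field("EFFECT"),
    gene_role = info_field("ROLE"),
    pop_af = as.numeric(info_field("POPAF", "0")),
    in_cosmic = grepl("(^|;)COSMIC(;|$)", fix$INFO),
    pon_hits = as.integer(info_field("PONHITS", "0")),
    tumor_alt = tumor_alt, tumor_depth = tumor_ref + tumor_alt,
    normal_alt = normal_alt, normal_depth = normal_ref + normal_alt,
    filter = fix$FILTER,
    somatic_p = somatic_p,
    stringsAsFactors = FALSE
  )
}
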