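# VAF-based clonality: max pathway VAF per patient, ROC against the
# pCMML/dCMML phenotype, threshold classification, phenotype associations.

RAS_PATHWAY_GENES <- c("NRAS", "KRAS", "CBL", "PTPN11")

#' Maximum pathway VAF for a patient
#'
#' When more than one mutation of the gene set is present, the maximal VAF is
#' used as the patient's score.
#'
#' @param vafs named numeric vector (or one-row data.frame of `VAF_*`
#'   columns) of per-gene VAFs; `NA` = gene not mutated.
#' @param genes gene set to maximize over (default the oncogenic RAS
#'   pathway: NRAS, KRAS, CBL, PTPN11).
#' @return the maximum VAF, or `NA` if no mutation in the set.
#' @export
max_pathway_vaf <- function(vafs, genes = RAS_PATHWAY_GENES) {
  if (is.data.frame(vafs)) {
    cols <- intersect(paste0("VAF_", genes), names(vafs))
    vafs <- stats::setNames(as.numeric(vafs[1, cols]),
                            sub("^VAF_", "", cols))
  }
  v <- vafs[intersect(genes, names(vafs))]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  max(v)
}

#' Per-patient maximum pathway VAF over a cohort table
#'
#' @param cohort data.frame with wide `VAF_<gene>` columns.
#' @param genes gene set (default RAS pathway).
#' @param wildtype_as_zero if `TRUE`, patients without any mutation in the
#'   set score 0 instead of `NA` (both conventions are defensible for ROC
#'   input; the default keeps wild-type patients out).
#' @return numeric vector, one score per row of `cohort`.
#' @export
cohort_pathway_vaf <- function(cohort, genes = RAS_PATHWAY_GENES,
                               wildtype_as_zero = FALSE) {
  cols <- intersect(paste0("VAF_", genes), names(cohort))
  if (!length(cols)) stop("no VAF_* columns for the requested genes", call. = FALSE)
  m <- as.matrix(cohort[, cols, drop = FALSE])
  score <- apply(m, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  if (wildtype_as_zero) score[is.na(score)] <- 0
  score
}

#' ROC curve, AUC, and optimal threshold
#'
#' Scores are binarized as positive when `score >= threshold`; candidate
#' thresholds are the observed scores. The AUC is the Mann-Whitney pair
#' statistic (ties count 1/2), computed from midranks. The reported optimal
#' threshold maximizes the chosen criterion -- Youden's J = TPR - FPR by
#' default, or accuracy -- with ties broken toward the smallest achieving
#' score.
#'
#' @param scores numeric scores (e.g. per-patient maximum RAS VAF).
#' @param labels binary labels (logical, or 0/1), `TRUE` = positive class
#'   (e.g. pCMML).
#' @param criterion `"youden"` (default) or `"accuracy"`.
#' @return list of class `clonarch_roc`: `points` (threshold, fpr, tpr),
#'   `auc`, `threshold`, `criterion`.
#' @export
roc_curve <- function(scores, labels, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be represented", call. = FALSE)
  }
  r <- rank(scores)                      # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  crit <- switch(criterion,
                 youden = tpr - fpr,
                 accuracy = (tpr * n1 + (1 - fpr) * n0) / (n1 + n0))
  best <- which(crit >= max(crit) - 1e-12)
  threshold <- thr[min(best)]            # smallest achieving score

  structure(list(
    points = data.frame(threshold = c(thr, Inf), fpr = c(fpr, 0), tpr = c(tpr, 0)),
    auc = auc, threshold = threshold, criterion = criterion,
    n_pos = n1, n_neg = n0
  ), class = "clonarch_roc")
}

#' @export
print.clonarch_roc <- function(x, ...) {
  cat(sprintf("ROC: %d positives vs %d negatives; AUC = %.4f; %s threshold = %.4g\n",
              x$n_pos, x$n_neg, x$auc, x$criterion, x$threshold))
  invisible(x)
}

#' Clonal vs subclonal classification from VAF
#'
#' A mutation is called clonal when its VAF reaches the threshold
#' (inclusive: `vaf >= threshold`, matching the cohort-derived rules
#' NRAS VAF >= 0.3 and oncogenic RAS VAF >= 0.19).
#'
#' @param vaf numeric VAF in [0, 1] (vectorized; `NA` passes through).
#' @param threshold clonality cutoff.
#' @return character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonal <- function(vaf, threshold) {
  check_prob(vaf[!is.na(vaf)], "vaf")
  ifelse(is.na(vaf), NA_character_,
         ifelse(vaf >= threshold, "clonal", "subclonal"))
}

#' Association between clonality grouping and a phenotype variable
#'
#' Categorical variables are tested with the exact Fisher test (native 2x2
#' enumeration, `stats::fisher.test` for larger tables); continuous variables
#' with the two-sided Mann-Whitney rank-sum test (exact enumeration when the
#' combined sample is at most 20 without ties, otherwise the normal
#' approximation with midrank tie correction).
#'
#' @param x phenotype values (factor/character/logical = categorical,
#'   numeric = continuous).
#' @param group two-level grouping (e.g. clonal vs subclonal).
#' @param exact_max combined sample size up to which the rank-sum test is
#'   exact (default 20).
#' @return list with `method`, `statistic` (rank-sum W or odds ratio NA for
#'   Fisher), and `p_value`.
#' @export
phenotype_association <- function(x, group, exact_max = 20) {
  keep <- !is.na(x) & !is.na(group)
  x <- x[keep]
  group <- as.factor(as.character(group[keep]))
  if (nlevels(group) != 2) stop("group must have exactly two levels", call. = FALSE)
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)

  if (is.numeric(x)) {
    g1 <- x[group == levels(group)[1]]
    g2 <- x[group == levels(group)[2]]
    n <- length(x)
    use_exact <- n <= exact_max && !anyDuplicated(x)
    wt <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = use_exact, correct = FALSE)
    )
    p <- wt$p.value
    if (!is.finite(p)) p <- 1  # zero-variance degenerate case (all values tied)
    list(method = "rank_sum", statistic = unname(wt$statistic),
         p_value = p)
  } else {
    tab <- table(factor(x), group)
    if (all(dim(tab) == c(2, 2))) {
      p <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    } else {
      p <- stats::fisher.test(tab)$p.value
    }
    list(method = "fisher_exact", statistic = NA_real_, p_value = p)
  }
}
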