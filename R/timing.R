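# Driver timing across paired chronic-phase (CP) / leukemic-transformation
# (LT) samples. Categories follow the set identities:
#   1d (primary)   = CP intersect LT
#   2d (secondary) = LT \ CP
#   3d (eliminated subclone) = CP \ LT

#' Categorize drivers across two timepoints
#'
#' @param cp_drivers character vector of variant keys at chronic phase.
#' @param lt_drivers character vector of variant keys at transformation.
#' @return data.frame with `key` and `label` in `1d`/`2d`/`3d`; every driver
#'   in the union appears exactly once.
#' @examples
#' categorize_drivers(c("TET2:a", "CBL:d"), c("TET2:a", "NRAS:c"))
#' @export
categorize_drivers <- function(cp_drivers, lt_drivers) {
  if (anyDuplicated(cp_drivers)) {
    stop("duplicate variant key at chronic phase: ",
         cp_drivers[duplicated(cp_drivers)][1], call. = FALSE)
  }
  if (anyDuplicated(lt_drivers)) {
    stop("duplicate variant key at transformation: ",
         lt_drivers[duplicated(lt_drivers)][1], call. = FALSE)
  }
  keys <- union(cp_drivers, lt_drivers)
  label <- ifelse(keys %in% cp_drivers & keys %in% lt_drivers, "1d",
                  ifelse(keys %in% lt_drivers, "2d", "3d"))
  data.frame(key = keys, label = label, stringsAsFactors = FALSE)
}

#' Label a long table of paired profiles
#'
#' @param profiles data.frame with `patient_id`, `timepoint` (`CP`/`LT`) and
#'   either `gene` alone (gene-level matching) or `gene` plus `key` columns
#'   forming the variant identity.
#' @param key_cols columns forming the variant key (default `"gene"`).
#' @return data.frame with `patient_id`, `key` and `label`.
#' @export
label_paired_profiles <- function(profiles, key_cols = "gene") {
  if (!all(c("patient_id", "timepoint") %in% names(profiles))) {
    stop("profiles need patient_id and timepoint columns", call. = FALSE)
  }
  if (!all(profiles$timepoint %in% c("CP", "LT"))) {
    stop("timepoint must be 'CP' or 'LT'", call. = FALSE)
  }
  key <- do.call(paste, c(profiles[key_cols], sep = ":"))
  out <- lapply(split(seq_len(nrow(profiles)), profiles$patient_id), function(i) {
    cp <- key[i][profiles$timepoint[i] == "CP"]
    lt <- key[i][profiles$timepoint[i] == "LT"]
    lab <- categorize_drivers(cp, lt)
    data.frame(patient_id = profiles$patient_id[i][1], lab,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-category means and per-gene category frequencies
#'
#' @param labels data.frame from [label_paired_profiles()] (`patient_id`,
#'   `key`, `label`); the key's leading field is taken as the gene.
#' @param n_patients number of patients over which to average; defaults to
#'   the number of distinct `patient_id` values present.
#' @return list with `means` (named 1d/2d/3d mean count per patient) and
#'   `per_gene` (gene x category count table as data.frame).
#' @export
category_summary <- function(labels, n_patients = NULL) {
  if (nrow(labels) == 0) stop("empty profile list", call. = FALSE)
  n_patients <- n_patients %||% length(unique(labels$patient_id))
  cats <- c("1d", "2d", "3d")
  counts <- vapply(cats, function(k) sum(labels$label == k), numeric(1))
  gene <- sub(":.*$", "", labels$key)
  tab <- table(gene, factor(labels$label, levels = cats))
  per_gene <- as.data.frame.matrix(tab)
  per_gene <- cbind(gene = rownames(per_gene), per_gene)
  rownames(per_gene) <- NULL
  list(means = counts / n_patients, per_gene = per_gene)
}

#' Eliminated- vs progressive-subclone binomial test
#'
#' Exact binomial test of whether eliminated subclones carry fewer driver
#' mutations than progressive subclones, under a null proportion of 1/2.
#' `less` gives the lower-tail probability of observing at most
#' `n_eliminated` of the total; `two_sided` sums all outcomes whose
#' probability does not exceed the observed one (minimum-likelihood).
#'
#' @param n_eliminated driver count in eliminated subclones.
#' @param n_progressive driver count in progressive subclones.
#' @param alternative `"less"` (default) or `"two_sided"`.
#' @return exact binomial p value.
#' @examples
#' eliminated_vs_progressive_test(19, 38) # ~0.008, rounds to 0.01
#' @export
eliminated_vs_progressive_test <- function(n_eliminated, n_progressive,
                                           alternative = c("less", "two_sided")) {
  alternative <- match.arg(alternative)
  k <- check_count(n_eliminated, "n_eliminated")
  m <- check_count(n_progressive, "n_progressive")
  n <- k + m
  if (n < 1) stop("both counts are zero", call. = FALSE)
  if (alternative == "less") {
    return(stats::pbinom(k, n, 0.5))
  }
  d <- stats::dbinom(0:n, n, 0.5)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}
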