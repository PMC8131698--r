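# Synthetic-data generators. Each generator seeds its own stream from the
# master seed with a fixed per-stage offset, so stages are individually and
# jointly reproducible (same config => byte-identical output).
SEED_OFFSET <- c(cohort = 0L, counts = 1L, paired = 2L, colonies = 3L)

rbeta_mean_conc <- function(n, mean, conc) {
  stats::rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Simulate a CMML cohort with known clonality ground truth
#'
#' Each patient receives a latent subtype (proliferative with probability
#' `p_pCMML`), a WBC count drawn from the subtype's log-normal, and a final
#' subtype label re-derived from the defining rule WBC >= 13e9/L -- so labels
#' are always consistent with the rule, and patients whose WBC crosses the
#' cutoff act as label noise relative to the latent draw. Per panel gene a
#' mutation is drawn with the subtype-specific probability; mutated
#' RAS-pathway genes are clonal with `p_clonal_given_<subtype>` and other
#' drivers with `p_clonal_other`, and the VAF comes from the corresponding
#' Beta component. Survival is exponential per subtype with independent
#' exponential censoring, for both the overall-survival and the
#' transformation clocks.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (one row per patient: subtype, wbc, platelets,
#'   pb_blasts, per-gene `VAF_*` columns, survival_time/event,
#'   lt_time/lt_event) and `truth` (list with `variants`: one row per
#'   simulated mutation incl. `true_clonal`; and `patients`: latent subtype
#'   per patient).
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + SEED_OFFSET[["cohort"]])
  n <- config$n_patients
  gp <- config$gene_panel

  latent <- ifelse(stats::runif(n) < config$p_pCMML, "pCMML", "dCMML")
  wbc <- stats::rlnorm(n, config$wbc_meanlog[latent], config$wbc_sdlog[latent])
  subtype <- ifelse(wbc >= 13, "pCMML", "dCMML")

  p_clonal_ras <- c(pCMML = config$p_clonal_given_pCMML,
                    dCMML = config$p_clonal_given_dCMML)

  vaf <- matrix(NA_real_, n, nrow(gp), dimnames = list(NULL, gp$gene))
  truth_rows <- vector("list", nrow(gp))
  for (j in seq_len(nrow(gp))) {
    p_mut <- ifelse(subtype == "pCMML", gp$p_pCMML[j], gp$p_dCMML[j])
    mutated <- stats::runif(n) < p_mut
    p_clonal <- if (gp$ras_pathway[j]) p_clonal_ras[subtype] else
      rep(config$p_clonal_other, n)
    clonal <- stats::runif(n) < p_clonal
    v <- ifelse(clonal,
                rbeta_mean_conc(n, config$clonal_vaf_mean, config$clonal_vaf_conc),
                rbeta_mean_conc(n, config$subclonal_vaf_mean, config$subclonal_vaf_conc))
    vaf[mutated, j] <- v[mutated]
    idx <- which(mutated)
    truth_rows[[j]] <- data.frame(
      patient_id = sprintf("P%04d", idx),
      gene = rep(gp$gene[j], length(idx)),
      true_clonal = clonal[idx], true_vaf = v[idx],
      stringsAsFactors = FALSE
    )
  }

  # mild phenotype coupling: clonal RAS pathway lowers platelets, raises blasts
  ras_genes <- gp$gene[gp$ras_pathway]
  ras_vaf <- if (length(ras_genes)) {
    apply(vaf[, ras_genes, drop = FALSE], 1, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  } else rep(NA_real_, n)
  clonal_ras <- !is.na(ras_vaf) & ras_vaf >= 0.19
  platelets <- stats::rlnorm(n, log(150) - 0.4 * clonal_ras, 0.3)
  pb_blasts <- round(stats::rlnorm(n, log(2) + 0.6 * clonal_ras, 0.7), 1)

  ev_os <- stats::rexp(n, config$hazard_os[subtype])
  ev_lt <- stats::rexp(n, config$hazard_lt[subtype])
  cens <- stats::rexp(n, config$censor_rate)
  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    subtype = subtype, wbc = wbc,
    platelets = platelets, pb_blasts = pb_blasts,
    survival_time = pmin(ev_os, cens), event = as.integer(ev_os <= cens),
    lt_time = pmin(ev_lt, cens), lt_event = as.integer(ev_lt <= cens),
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(vaf)[, , drop = FALSE])
  names(cohort)[seq(ncol(cohort) - nrow(gp) + 1, ncol(cohort))] <-
    paste0("VAF_", gp$gene)

  truth_variants <- do.call(rbind, truth_rows)
  truth_variants <- truth_variants[order(truth_variants$patient_id,
                                         truth_variants$gene), , drop = FALSE]
  rownames(truth_variants) <- NULL
  list(
    cohort = cohort,
    truth = list(
      variants = truth_variants,
      patients = data.frame(patient_id = cohort$patient_id,
                            latent_subtype = latent,
                            stringsAsFactors = FALSE)
    )
  )
}

#' Simulate tumor / contaminated-normal read counts
#'
#' The "normal" compartment is modeled as a rho-mixture of tumor and germline
#' cells. For a somatic variant with true cell-fraction VAF `v`, tumor alt
#' reads are Binomial(depth, v(1-eps) + (1-v)eps) and normal alt reads are
#' Binomial(depth, rho*v*(1-eps) + (1-rho*v)*eps); for a germline variant the
#' normal compartment carries the variant at the same allele fraction as the
#' tumor. Depths are Poisson around `mean_depth`, floored at 1.
#'
#' @param config a [sim_config()] (supplies depth, rho, eps and the seed).
#' @param true_vafs numeric vector of true allele fractions in [0, 1].
#' @param somatic logical vector (recycled): TRUE for somatic truth, FALSE
#'   for germline truth.
#' @param annotations optional data.frame of per-variant annotation columns
#'   (`gene`, `effect`, `gene_role`, `pop_af`, `in_cosmic`, `pon_hits`)
#'   overriding the defaults.
#' @return data.frame of variant calls: coordinates, annotations, tumor and
#'   normal alt/depth counts, plus truth columns `true_somatic`, `true_vaf`.
#' @export
simulate_tumor_normal_counts <- function(config, true_vafs, somatic = TRUE,
                                         annotations = NULL) {
  config <- validate_sim_config(config)
  if (anyNA(true_vafs) || any(true_vafs < 0) || any(true_vafs > 1)) {
    stop_field("true_vafs", "must lie in [0, 1]")
  }
  set.seed(config$seed + SEED_OFFSET[["counts"]])
  m <- length(true_vafs)
  somatic <- rep_len(as.logical(somatic), m)
  eps <- config$error_rate_eps
  rho <- config$contamination_rho

  tumor_depth <- pmax(1L, stats::rpois(m, config$mean_depth))
  normal_depth <- pmax(1L, stats::rpois(m, config$mean_depth))
  p_tumor <- true_vafs * (1 - eps) + (1 - true_vafs) * eps
  v_norm <- ifelse(somatic, rho * true_vafs, true_vafs)
  p_normal <- v_norm * (1 - eps) + (1 - v_norm) * eps
  tumor_alt <- stats::rbinom(m, tumor_depth, p_tumor)
  normal_alt <- stats::rbinom(m, normal_depth, p_normal)

  out <- data.frame(
    chrom = "chr1", pos = seq_len(m),
    ref = "A", alt = "T",
    gene = sprintf("G%04d", seq_len(m)),
    effect = "nonsyn_damaging", gene_role = "oncogene",
    pop_af = 0, in_cosmic = TRUE, pon_hits = 0L,
    tumor_alt = tumor_alt, tumor_depth = tumor_depth,
    normal_alt = normal_alt, normal_depth = normal_depth,
    true_somatic = somatic, true_vaf = true_vafs,
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    for (col in names(annotations)) out[[col]] <- annotations[[col]]
  }
  out
}

#' Simulate paired chronic-phase / transformation driver profiles
#'
#' Chronic-phase driver sets are drawn from the panel with subtype-specific
#' probabilities; each chronic-phase driver persists to transformation (1d)
#' with probability `1 - p_loss` and is lost (3d) with `p_loss`; every gene
#' not mutated at chronic phase is gained at transformation (2d) with
#' `p_gain`. Variant keys are gene-level.
#'
#' @param config a [sim_config()].
#' @return list with `profiles` (long data.frame: patient_id, timepoint in
#'   CP/LT, gene) and `truth` (data.frame: patient_id, gene, label in
#'   1d/2d/3d).
#' @export
simulate_paired_timepoints <- function(config) {
  config <- validate_sim_config(config)
  gp <- config$gene_panel
  if (nrow(gp) == 0) stop_field("gene_panel", "must be non-empty")
  set.seed(config$seed + SEED_OFFSET[["paired"]])
  n <- config$n_patients

  profiles <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    subtype <- if (stats::runif(1) < config$p_pCMML) "pCMML" else "dCMML"
    p_mut <- if (subtype == "pCMML") gp$p_pCMML else gp$p_dCMML
    cp <- gp$gene[stats::runif(nrow(gp)) < p_mut]
    lost <- cp[stats::runif(length(cp)) < config$p_loss]
    candidates <- setdiff(gp$gene, cp)
    gained <- candidates[stats::runif(length(candidates)) < config$p_gain]
    lt <- c(setdiff(cp, lost), gained)

    genes <- c(cp, gained)
    if (length(genes)) {
      label <- c(ifelse(cp %in% lost, "3d", "1d"), rep("2d", length(gained)))
      truth[[i]] <- data.frame(patient_id = rep(pid, length(genes)),
                               gene = genes, label = label,
                               stringsAsFactors = FALSE)
    }
    n_rows <- length(cp) + length(lt)
    profiles[[i]] <- data.frame(
      patient_id = rep(pid, n_rows),
      timepoint = c(rep("CP", length(cp)), rep("LT", length(lt))),
      gene = c(cp, lt), stringsAsFactors = FALSE
    )
  }
  list(profiles = do.call(rbind, profiles), truth = do.call(rbind, truth))
}

#' Simulate single-colony genotypes along a linear clonal trajectory
#'
#' Clones are the successive states of a linear acquisition order: the
#' ancestral (wild-type) clone carries no mutation, clone k carries the first
#' k mutations. Each colony is drawn from `clone_weights` (length
#' `length(clone_order) + 1`, ancestral first) and receives its clone's
#' genotype; `dropout` independently flips present calls to absent, emulating
#' failed Sanger calls.
#'
#' @param clone_order character vector: mutations in acquisition order.
#' @param n_colonies number of colonies (0 allowed: empty matrix).
#' @param clone_weights clone prevalences summing to 1 (tolerance 1e-9).
#' @param dropout per-call probability of a present->absent flip.
#' @param seed optional seed for this draw.
#' @return list with `genotypes` (binary colonies x mutations matrix) and
#'   `truth` (data.frame: colony, clone index 0 = ancestral, clone genotype
#'   string).
#' @export
simulate_colonies <- function(clone_order, n_colonies, clone_weights,
                              dropout = 0, seed = NULL) {
  if (anyDuplicated(clone_order)) {
    stop_field("clone_order", "duplicate mutation names")
  }
  k <- length(clone_order)
  if (length(clone_weights) != k + 1) {
    stop_field("clone_weights",
               sprintf("must have length %d (ancestral clone first)", k + 1))
  }
  check_prob(clone_weights, "clone_weights")
  if (abs(sum(clone_weights) - 1) > 1e-9) {
    stop_field("clone_weights", "must sum to 1 (tolerance 1e-9)")
  }
  check_prob(dropout, "colony_dropout")
  n_colonies <- check_count(n_colonies, "n_colonies", min = 0L)
  if (!is.null(seed)) set.seed(seed)

  geno <- matrix(0L, n_colonies, k,
                 dimnames = list(if (n_colonies) sprintf("colony%03d", seq_len(n_colonies)),
                                 clone_order))
  if (n_colonies == 0) {
    return(list(genotypes = geno,
                truth = data.frame(colony = character(), clone = integer(),
                                   stringsAsFactors = FALSE)))
  }
  clone <- sample.int(k + 1, n_colonies, replace = TRUE,
                      prob = clone_weights) - 1L
  for (i in seq_len(n_colonies)) {
    if (clone[i] > 0) geno[i, seq_len(clone[i])] <- 1L
  }
  if (dropout > 0 && k > 0) {
    flip <- matrix(stats::runif(n_colonies * k) < dropout, n_colonies, k)
    geno[flip & geno == 1L] <- 0L
  }
  list(genotypes = geno,
       truth = data.frame(colony = rownames(geno), clone = clone,
                          stringsAsFactors = FALSE))
}
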