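#' Default driver-gene panel
#'
#' Recurrently mutated CMML genes with their role (oncogene vs tumor
#' suppressor), per-subtype mutation probabilities, and whether they belong to
#' the oncogenic RAS pathway. The per-subtype probabilities follow the
#' mutation frequencies reported for proliferative (pCMML) versus dysplastic
#' (dCMML) disease: NRAS 30% vs 8%, ASXL1 60% vs 42%, TET2 43% vs 54%,
#' JAK2 12% vs 5%, with the remaining RAS-pathway genes (KRAS, CBL, PTPN11)
#' set so the combined pathway frequency lands near 46% vs 25%.
#'
#' @return data.frame with columns `gene`, `role`, `p_pCMML`, `p_dCMML`,
#'   `ras_pathway`.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("TET2", "ASXL1", "SRSF2", "NRAS", "KRAS", "CBL", "PTPN11",
             "JAK2", "RUNX1", "DNMT3A"),
    role = c("TSG", "TSG", "TSG", "oncogene", "oncogene", "oncogene",
             "oncogene", "oncogene", "TSG", "TSG"),
    p_pCMML = c(0.43, 0.60, 0.50, 0.30, 0.12, 0.15, 0.06, 0.12, 0.15, 0.05),
    p_dCMML = c(0.54, 0.42, 0.40, 0.08, 0.08, 0.12, 0.04, 0.05, 0.10, 0.05),
    ras_pathway = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                    FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every generative parameter of the synthetic-data module. Defaults
#' encode the study conditions the generator emulates: ~100x mean depth,
#' a Beta VAF mixture with clonal mean 0.40 and subclonal mean 0.10
#' (concentration 50) reproducing the observed bimodal RAS-pathway VAF
#' spectrum, WBC log-normals straddling the 13e9/L proliferative cutoff, and
#' exponential survival with subtype hazards matching median OS of 23 months
#' (pCMML) and 39.6 months (dCMML) and median AML-free survival of 18 and 32
#' months.
#'
#' @param seed master RNG seed; every generator derives its stream from it.
#' @param n_patients cohort size.
#' @param gene_panel data.frame as [default_gene_panel()].
#' @param clonal_vaf_mean,clonal_vaf_conc Beta mean/concentration of the
#'   clonal VAF component (shape1 = mean*conc, shape2 = (1-mean)*conc).
#' @param subclonal_vaf_mean,subclonal_vaf_conc subclonal component.
#' @param p_clonal_given_pCMML,p_clonal_given_dCMML probability that a
#'   RAS-pathway mutation is clonal given the subtype.
#' @param p_clonal_other probability that a non-RAS driver (TET2/SRSF2/ASXL1
#'   class, predominantly clonal founders) is clonal.
#' @param mean_depth Poisson mean sequencing depth (reads), floored at 1.
#' @param contamination_rho fraction of tumor cells in the "normal"
#'   (CD3-positive) compartment, in [0, 1].
#' @param error_rate_eps per-base sequencing error, in [0, 0.01].
#' @param wbc_meanlog,wbc_sdlog named length-2 vectors (pCMML, dCMML):
#'   log-normal WBC parameters, units 1e9/L.
#' @param hazard_os,hazard_lt named length-2 vectors: exponential event rates
#'   (1/month) for overall survival and AML transformation per subtype.
#' @param censor_rate exponential censoring rate (1/month).
#' @param p_gain,p_loss per-driver two-timepoint transition probabilities
#'   (gain of a new driver at transformation; loss of a chronic-phase driver).
#' @param n_colonies colonies per single-colony assay.
#' @param colony_dropout probability a truly present mutation is missed in a
#'   colony genotype call.
#' @param p_pCMML prior probability of the proliferative subtype.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 200L,
                       gene_panel = default_gene_panel(),
                       clonal_vaf_mean = 0.40, clonal_vaf_conc = 50,
                       subclonal_vaf_mean = 0.10, subclonal_vaf_conc = 50,
                       p_clonal_given_pCMML = 0.85,
                       p_clonal_given_dCMML = 0.15,
                       p_clonal_other = 0.95,
                       mean_depth = 100,
                       contamination_rho = 0.05,
                       error_rate_eps = 0.001,
                       wbc_meanlog = c(pCMML = log(30), dCMML = log(8)),
                       wbc_sdlog = c(pCMML = 0.40, dCMML = 0.40),
                       hazard_os = c(pCMML = log(2) / 23, dCMML = log(2) / 39.6),
                       hazard_lt = c(pCMML = log(2) / 18, dCMML = log(2) / 32),
                       censor_rate = 0.01,
                       p_gain = 0.10, p_loss = 0.05,
                       n_colonies = 60L,
                       colony_dropout = 0.02,
                       p_pCMML = 0.5) {
  cfg <- list(
    seed = seed, n_patients = n_patients, gene_panel = gene_panel,
    clonal_vaf_mean = clonal_vaf_mean, clonal_vaf_conc = clonal_vaf_conc,
    subclonal_vaf_mean = subclonal_vaf_mean,
    subclonal_vaf_conc = subclonal_vaf_conc,
    p_clonal_given_pCMML = p_clonal_given_pCMML,
    p_clonal_given_dCMML = p_clonal_given_dCMML,
    p_clonal_other = p_clonal_other,
    mean_depth = mean_depth, contamination_rho = contamination_rho,
    error_rate_eps = error_rate_eps,
    wbc_meanlog = wbc_meanlog, wbc_sdlog = wbc_sdlog,
    hazard_os = hazard_os, hazard_lt = hazard_lt, censor_rate = censor_rate,
    p_gain = p_gain, p_loss = p_loss,
    n_colonies = n_colonies, colony_dropout = colony_dropout,
    p_pCMML = p_pCMML
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Every violated constraint is reported with the offending field name.
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly usable (returned for chaining).
#' @export
validate_sim_config <- function(cfg) {
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  cfg$n_patients <- check_count(cfg$n_patients, "n_patients", min = 1L)
  gp <- cfg$gene_panel
  if (!is.data.frame(gp) || nrow(gp) == 0) {
    stop_field("gene_panel", "must be a non-empty data.frame")
  }
  need <- c("gene", "role", "p_pCMML", "p_dCMML", "ras_pathway")
  if (!all(need %in% names(gp))) {
    stop_field("gene_panel", paste("must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(gp$gene)) stop_field("gene_panel", "duplicate gene symbols")
  if (!all(gp$role %in% c("oncogene", "TSG"))) {
    stop_field("gene_panel", "role must be 'oncogene' or 'TSG'")
  }
  check_prob(gp$p_pCMML, "gene_panel$p_pCMML")
  check_prob(gp$p_dCMML, "gene_panel$p_dCMML")
  for (f in c("clonal_vaf_mean", "subclonal_vaf_mean", "p_clonal_given_pCMML",
              "p_clonal_given_dCMML", "p_clonal_other", "contamination_rho",
              "p_gain", "p_loss", "colony_dropout", "p_pCMML")) {
    check_prob(cfg[[f]], f)
  }
  check_positive(cfg$clonal_vaf_conc, "clonal_vaf_conc")
  check_positive(cfg$subclonal_vaf_conc, "subclonal_vaf_conc")
  if (!is.numeric(cfg$mean_depth) || cfg$mean_depth < 1) {
    stop_field("mean_depth", "must be >= 1")
  }
  if (!is.numeric(cfg$error_rate_eps) || cfg$error_rate_eps < 0 ||
      cfg$error_rate_eps > 0.01) {
    stop_field("error_rate_eps", "must lie in [0, 0.01]")
  }
  for (f in c("wbc_meanlog", "wbc_sdlog", "hazard_os", "hazard_lt")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || !all(c("pCMML", "dCMML") %in% names(v))) {
      stop_field(f, "must be numeric with names pCMML and dCMML")
    }
  }
  check_positive(unname(cfg$hazard_os), "hazard_os")
  check_positive(unname(cfg$hazard_lt), "hazard_lt")
  check_positive(cfg$censor_rate, "censor_rate")
  cfg$n_colonies <- check_count(cfg$n_colonies, "n_colonies", min = 0L)
  cfg
}

#' Read a simulation configuration from a flat YAML file
#'
#' Keys are the argument names of [sim_config()]; unknown keys are an error.
#' The per-subtype vectors are given as two-element maps
#' (`wbc_meanlog: {pCMML: 3.4, dCMML: 2.1}`) and the gene panel, if supplied,
#' as a list of records with the panel's column names.
#'
#' @param path YAML file path.
#' @param seed optional seed override.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_field(bad[1], "unknown configuration key")
  }
  if (!is.null(raw$gene_panel)) {
    raw$gene_panel <- do.call(rbind, lapply(raw$gene_panel, as.data.frame))
  }
  for (f in c("wbc_meanlog", "wbc_sdlog", "hazard_os", "hazard_lt")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}
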