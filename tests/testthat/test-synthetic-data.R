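test_that("identical seeds give identical outputs across all generators", {
  cfg <- sim_config(seed = 11, n_patients = 40)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_paired_timepoints(cfg), simulate_paired_timepoints(cfg))
  v <- runif(30, 0.05, 0.5)
  expect_identical(simulate_tumor_normal_counts(cfg, v),
                   simulate_tumor_normal_counts(cfg, v))
  expect_identical(
    simulate_colonies(c("a", "b"), 50, c(0.2, 0.4, 0.4), seed = 5),
    simulate_colonies(c("a", "b"), 50, c(0.2, 0.4, 0.4), seed = 5))
})

test_that("config validation names the offending field", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(contamination_rho = 1.5), "contamination_rho")
  expect_error(sim_config(error_rate_eps = 0.5), "error_rate_eps")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(hazard_os = c(pCMML = 0, dCMML = 0.1)), "hazard_os")
  expect_error(sim_config(gene_panel = data.frame()), "gene_panel")
})

test_that("subtype labels always satisfy the WBC >= 13 rule", {
  sim <- simulate_cohort(sim_config(seed = 2, n_patients = 300))
  expect_true(all((sim$cohort$wbc >= 13) == (sim$cohort$subtype == "pCMML")))
})

test_that("degenerate clonality mixture sends subtypes to pure Beta components", {
  cfg <- sim_config(seed = 3, n_patients = 400,
                    p_clonal_given_pCMML = 1, p_clonal_given_dCMML = 0)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth$variants
  ras <- cfg$gene_panel$gene[cfg$gene_panel$ras_pathway]
  sub <- sim$cohort$subtype[match(tr$patient_id, sim$cohort$patient_id)]
  expect_true(all(tr$true_clonal[tr$gene %in% ras & sub == "pCMML"]))
  expect_false(any(tr$true_clonal[tr$gene %in% ras & sub == "dCMML"]))
})

test_that("per-component VAF means match configured Beta means at large n", {
  cfg <- sim_config(seed = 4, n_patients = 2000)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth$variants
  expect_equal(mean(tr$true_vaf[tr$true_clonal]), 0.40, tolerance = 0.02)
  expect_equal(mean(tr$true_vaf[!tr$true_clonal]), 0.10, tolerance = 0.02)
})

test_that("truth tables are complete", {
  cfg <- sim_config(seed = 5, n_patients = 100)
  sim <- simulate_cohort(cfg)
  # every truth variant maps to a non-NA VAF cell and vice versa
  vaf_cols <- paste0("VAF_", cfg$gene_panel$gene)
  n_mutations <- sum(!is.na(as.matrix(sim$cohort[vaf_cols])))
  expect_identical(nrow(sim$truth$variants), n_mutations)
  expect_identical(anyDuplicated(sim$truth$variants[c("patient_id", "gene")]), 0L)

  pt <- simulate_paired_timepoints(cfg)
  union_keys <- unique(pt$profiles[c("patient_id", "gene")])
  expect_identical(nrow(pt$truth), nrow(union_keys))

  col <- simulate_colonies(c("a", "b", "c"), 80, c(0.25, 0.25, 0.25, 0.25),
                           seed = 1)
  expect_identical(col$truth$colony, rownames(col$genotypes))
})

test_that("contaminated-normal counts follow the stated binomial model", {
  # rho = 0, eps = 0: normals carry no alt reads at all
  cfg0 <- sim_config(seed = 6, contamination_rho = 0, error_rate_eps = 0)
  v0 <- simulate_tumor_normal_counts(cfg0, runif(200, 0.1, 0.6))
  expect_true(all(v0$normal_alt == 0))

  # rho = 1: expected normal VAF equals expected tumor VAF
  cfg1 <- sim_config(seed = 7, contamination_rho = 1, error_rate_eps = 0,
                     mean_depth = 200)
  v1 <- simulate_tumor_normal_counts(cfg1, rep(0.4, 2000))
  expect_equal(mean(v1$normal_alt / v1$normal_depth),
               mean(v1$tumor_alt / v1$tumor_depth), tolerance = 0.01)

  # rho = 0.3, v = 0.4 at high depth: mean normal VAF = 0.12 +- 0.01
  cfg3 <- sim_config(seed = 8, contamination_rho = 0.3, error_rate_eps = 0,
                     mean_depth = 10000)
  v3 <- simulate_tumor_normal_counts(cfg3, rep(0.4, 1000))
  expect_equal(mean(v3$normal_alt / v3$normal_depth), 0.12, tolerance = 0.01)

  expect_error(simulate_tumor_normal_counts(cfg0, c(0.5, 1.2)), "true_vafs")
})

test_that("normal VAF regresses on tumor VAF with slope rho", {
  rho <- 0.2
  cfg <- sim_config(seed = 9, contamination_rho = rho, error_rate_eps = 0,
                    mean_depth = 5000)
  v <- simulate_tumor_normal_counts(cfg, runif(1000, 0.05, 0.6))
  fit <- lm(I(normal_alt / normal_depth) ~ I(tumor_alt / tumor_depth), data = v)
  expect_equal(unname(coef(fit)[2]), rho, tolerance = 0.02)
})

test_that("paired-timepoint transitions follow p_gain / p_loss", {
  # no gain, no loss: everything is a primary (1d) driver
  cfg <- sim_config(seed = 10, n_patients = 100, p_gain = 0, p_loss = 0)
  pt <- simulate_paired_timepoints(cfg)
  expect_true(all(pt$truth$label == "1d"))

  # total loss: every chronic-phase driver is eliminated (3d)
  cfg_l <- sim_config(seed = 11, n_patients = 100, p_gain = 0, p_loss = 1)
  pt_l <- simulate_paired_timepoints(cfg_l)
  expect_true(all(pt_l$truth$label == "3d"))

  # mean 2d count per patient ~ Binomial expectation over candidate genes
  cfg_g <- sim_config(seed = 12, n_patients = 500, p_gain = 0.1, p_loss = 0,
                      gene_panel = within(default_gene_panel(), {
                        p_pCMML <- 0; p_dCMML <- 0
                      }))
  pt_g <- simulate_paired_timepoints(cfg_g)
  mean_2d <- sum(pt_g$truth$label == "2d") / 500
  expect_equal(mean_2d, 1.0, tolerance = 0.15)
})

test_that("colony simulation respects weights, dropout and nesting", {
  # all mass on the terminal clone, no dropout: every colony fully mutated
  col <- simulate_colonies(c("a", "b", "c"), 30, c(0, 0, 0, 1), seed = 1)
  expect_true(all(col$genotypes == 1))

  # zero colonies: empty matrix, no error
  col0 <- simulate_colonies(c("a", "b"), 0, c(0.5, 0.25, 0.25))
  expect_identical(dim(col0$genotypes), c(0L, 2L))

  # linear trajectory forces strictly nested column prevalences
  col_n <- simulate_colonies(c("TET2", "NRAS", "ASXL1"), 1000,
                             c(0.1, 0.3, 0.3, 0.3), dropout = 0, seed = 2)
  counts <- colSums(col_n$genotypes)
  expect_true(counts["TET2"] > counts["NRAS"] &&
              counts["NRAS"] > counts["ASXL1"])

  expect_error(simulate_colonies(c("a"), 10, c(0.6, 0.5)), "clone_weights")
  expect_error(simulate_colonies(c("a"), 10, c(0.5)), "clone_weights")
})
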