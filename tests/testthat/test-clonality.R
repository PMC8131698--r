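test_that("max pathway VAF takes the maximum over mutated genes only", {
  expect_equal(max_pathway_vaf(c(NRAS = 0.42, CBL = 0.12)), 0.42)
  expect_equal(max_pathway_vaf(c(KRAS = 0.19)), 0.19)
  expect_true(is.na(max_pathway_vaf(c(TET2 = 0.45))))   # outside the set
  expect_true(is.na(max_pathway_vaf(numeric(0))))
  # data.frame row input with VAF_ columns
  df <- data.frame(VAF_NRAS = 0.3, VAF_KRAS = NA, VAF_TET2 = 0.5)
  expect_equal(max_pathway_vaf(df), 0.3)
})

test_that("cohort scoring supports both wild-type conventions", {
  cohort <- data.frame(VAF_NRAS = c(0.4, NA), VAF_KRAS = c(NA, NA),
                       VAF_CBL = c(0.1, NA), VAF_PTPN11 = c(NA, NA))
  expect_equal(cohort_pathway_vaf(cohort), c(0.4, NA))
  expect_equal(cohort_pathway_vaf(cohort, wildtype_as_zero = TRUE), c(0.4, 0))
})

test_that("ROC handles perfect separation and hand-counted AUC", {
  r <- roc_curve(c(0.1, 0.2, 0.35, 0.4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1.0)
  expect_true(r$threshold > 0.2 && r$threshold <= 0.35)

  # positives {0.3, 0.15}, negatives {0.2, 0.1}: 3 of 4 pairs concordant
  r2 <- roc_curve(c(0.3, 0.15, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)

  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("AUC counts ties as half and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(15)
  scores <- round(runif(200), 2)  # many ties
  labels <- runif(200) < plogis(4 * scores - 2)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  r <- roc_curve(scores, labels)
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(16)
  scores <- runif(300)
  labels <- runif(300) < scores
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  a0 <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(qlogis(scores), labels)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_curve(scores^3, labels)$auc, a0, tolerance = 1e-12)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(17)
  r <- roc_curve(runif(2000), runif(2000) < 0.5)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
})

test_that("clonal classification is inclusive at the threshold and monotone", {
  expect_identical(classify_clonal(0.30, 0.30), "clonal")
  expect_identical(classify_clonal(0.19, 0.19), "clonal")
  expect_identical(classify_clonal(0.18, 0.19), "subclonal")
  calls <- classify_clonal(seq(0, 1, 0.01), 0.3)
  expect_true(all(diff(calls == "clonal") >= 0))
})

test_that("Youden threshold recovers the Beta density crossing on synthetic cohorts", {
  # degenerate mixture: pCMML RAS mutations all clonal, dCMML all subclonal;
  # NRAS mutated in every patient so each patient carries a score
  panel <- default_gene_panel()
  panel$p_pCMML[panel$ras_pathway] <- 0
  panel$p_dCMML[panel$ras_pathway] <- 0
  panel$p_pCMML[panel$gene == "NRAS"] <- 1
  panel$p_dCMML[panel$gene == "NRAS"] <- 1
  cfg <- sim_config(seed = 18, n_patients = 2000, gene_panel = panel,
                    p_clonal_given_pCMML = 0.97, p_clonal_given_dCMML = 0.03)
  sim <- simulate_cohort(cfg)
  score <- cohort_pathway_vaf(sim$cohort)
  r <- roc_curve(score, sim$cohort$subtype == "pCMML")
  # oracle: equal-density crossing of Beta(0.40, 50) and Beta(0.10, 50)
  crossing <- uniroot(function(x) dbeta(x, 20, 30) - dbeta(x, 5, 45),
                      c(0.11, 0.39), tol = 1e-10)$root
  expect_equal(r$threshold, crossing, tolerance = 0.05)
})

test_that("phenotype associations use the exact tests", {
  # shared Fisher enumeration: [[3,1],[1,3]]
  x <- rep(c("lo", "hi"), c(4, 4))
  g <- c("A", "A", "A", "B", "A", "B", "B", "B")
  res <- phenotype_association(x, g)
  expect_identical(res$method, "fisher_exact")
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)

  # identical continuous samples: two-sided midrank rank-sum p = 1
  res2 <- phenotype_association(c(1, 2, 3, 1, 2, 3),
                                rep(c("A", "B"), each = 3))
  expect_identical(res2$method, "rank_sum")
  expect_equal(res2$p_value, 1)

  # exact enumeration of all rank assignments: (1,2,3) vs (4,5,6)
  res3 <- phenotype_association(c(1, 2, 3, 4, 5, 6),
                                rep(c("A", "B"), each = 3))
  expect_equal(res3$p_value, 2 / 20, tolerance = 1e-12)

  expect_error(phenotype_association(1:4, rep("A", 4)), "two levels")
})
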