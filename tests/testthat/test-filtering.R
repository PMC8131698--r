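test_that("read-support filter uses strict 5-read / 5% thresholds", {
  v <- make_variants(tumor_alt = c(4, 5, 6, 5),
                     tumor_depth = c(100, 100, 200, 50),
                     normal_alt = 0, normal_depth = 100)
  out <- support_filter(v)
  # 4 reads: fail; 5 reads at VAF 0.05: boundary passes; VAF 0.03: fail;
  # 5 reads at VAF 0.10: pass
  expect_identical(out$fail_support, c(TRUE, FALSE, TRUE, FALSE))

  bad <- make_variants(1, 0, 0, 100)
  expect_error(support_filter(bad), "depth 0")
})

test_that("population filter is strict at the 0.001 cutoff and warns on NA", {
  v <- make_variants(rep(20, 3), rep(100, 3), rep(0, 3), rep(100, 3),
                     pop_af = c(0.0011, 0.001, 0))
  out <- population_filter(v)
  expect_identical(out$fail_pop_af, c(TRUE, FALSE, FALSE))

  v_na <- make_variants(20, 100, 0, 100, pop_af = NA_real_)
  expect_warning(out_na <- population_filter(v_na), "missing pop_af")
  expect_false(out_na$fail_pop_af)
})

test_that("panel-of-normals filter flags recurrent hits", {
  v <- make_variants(rep(20, 3), rep(100, 3), rep(0, 3), rep(100, 3),
                     pon_hits = c(0L, 2L, 50L))
  out <- pon_filter(v)
  expect_identical(out$fail_pon, c(FALSE, TRUE, TRUE))
  out1 <- pon_filter(v, min_hits = 1)
  expect_identical(out1$fail_pon, c(FALSE, TRUE, TRUE))
})

test_that("fisher somatic classification applies the strict 1e-4 rule", {
  res <- fisher_somatic_test(c(10, 40), c(100, 100), c(10, 2), c(100, 100))
  expect_equal(res$p_value[1], 1)
  expect_identical(res$classification[1], "germline_ambiguous")
  expect_lt(res$p_value[2], 1e-4)
  expect_identical(res$classification[2], "somatic")
  expect_error(fisher_somatic_test(1, 0, 0, 100), "depth")
  expect_error(fisher_somatic_test(-1, 10, 0, 100), "non-negative")
})

test_that("driver annotation combines COSMIC with TSG effect classes", {
  v <- make_variants(rep(20, 4), rep(100, 4), rep(0, 4), rep(100, 4),
                     gene_role = c("TSG", "TSG", "oncogene", "oncogene"),
                     effect = c("nonsyn_benign", "frameshift_indel",
                                "nonsyn_damaging", "nonsyn_benign"),
                     in_cosmic = c(TRUE, TRUE, FALSE, TRUE))
  out <- annotate_driver(v)
  expect_identical(out$putative_driver, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("filter chain attributes exclusions to the first failing stage", {
  v <- make_variants(tumor_alt = c(3, 20, 20, 20, 40),
                     tumor_depth = rep(100, 5),
                     normal_alt = c(0, 0, 0, 20, 1),
                     normal_depth = rep(100, 5),
                     pop_af = c(0, 0.01, 0, 0, 0),
                     pon_hits = c(0L, 5L, 5L, 0L, 0L))
  chain <- run_filter_chain(v)
  expect_identical(chain$report$n_excluded, c(1L, 1L, 1L, 1L))
  expect_identical(nrow(chain$passed), 1L)
  # flags are monotone and the chain is idempotent on its own output
  again <- run_filter_chain(chain$variants)
  expect_identical(again$variants[names(chain$variants)], chain$variants)
  expect_identical(nrow(again$passed), nrow(chain$passed))
})

test_that("empty input yields an empty report, not an error", {
  chain <- run_filter_chain(make_variants(integer(), integer(), integer(),
                                          integer()))
  expect_identical(nrow(chain$passed), 0L)
  expect_true(all(chain$report$n_excluded == 0))
})

test_that("somatic specificity is high on contaminated simulations", {
  for (rho in c(0, 0.05, 0.1)) {
    cfg <- sim_config(seed = 20 + round(rho * 100), contamination_rho = rho,
                      mean_depth = 100)
    v_som <- runif(250, 0.2, 0.6)
    v_germ <- rep(0.5, 250)
    v <- simulate_tumor_normal_counts(cfg, c(v_som, v_germ),
                                      somatic = rep(c(TRUE, FALSE), each = 250))
    chain <- run_filter_chain(v)
    germ <- chain$variants[!chain$variants$true_somatic, ]
    specificity <- mean(!germ$somatic)
    expect_gt(specificity, 0.99)
  }
})

test_that("a fully contaminated normal suppresses somatic calls", {
  cfg <- sim_config(seed = 30, contamination_rho = 1, mean_depth = 10000)
  v <- simulate_tumor_normal_counts(cfg, runif(200, 0.1, 0.6))
  chain <- run_filter_chain(v)
  expect_lt(mean(chain$variants$somatic), 0.01)
})
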