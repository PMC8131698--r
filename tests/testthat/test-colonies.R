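make_matrix <- function(rows, muts) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("c", seq_len(nrow(m))), muts)
  m
}

test_that("a single mutation yields the two-clone trajectory", {
  m <- make_matrix(list(1, 1, 1, 0, 0), "m1")
  tr <- infer_clone_order(m)
  expect_identical(nrow(tr$table), 2L)
  expect_equal(tr$table$prevalence, c(0.4, 0.6))
  expect_identical(tr$table$mutations, c("WT", "m1"))
})

test_that("hand-checked 5-colony example gives the known chain and prevalences", {
  m <- make_matrix(list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 1, 1),
                        c(1, 0, 0)), c("TET2", "NRAS", "ASXL1"))
  tr <- infer_clone_order(m)
  expect_true(tr$linear)
  expect_identical(tr$table$mutations,
                   c("WT", "TET2", "TET2+NRAS", "TET2+NRAS+ASXL1"))
  expect_equal(tr$table$prevalence, c(0, 0.4, 0.2, 0.4))
  expect_identical(nrow(tr$conflicts), 0L)
  # fishplot table mirrors the trajectory and sums to 1
  ft <- fishplot_table(tr)
  expect_identical(nrow(ft), 4L)
  expect_equal(sum(ft$prevalence), 1, tolerance = 1e-12)
})

test_that("incomparable disjoint colony sets become sibling branches", {
  m <- make_matrix(list(c(1, 1, 0), c(1, 0, 1)), c("TET2", "NRAS", "ASXL1"))
  tr <- infer_clone_order(m)
  expect_false(tr$linear)
  expect_identical(nrow(tr$conflicts), 0L)
  # TET2 is ancestral to both branches
  branch_parents <- tr$table$parent[tr$table$n_mutations == 2]
  expect_true(all(tr$table$mutations[branch_parents] == "TET2"))
})

test_that("overlapping incomparable sets are reported as conflicts", {
  # infinite-sites violation: the two mutations overlap but neither contains
  # the other
  m <- make_matrix(list(c(1, 0), c(1, 1), c(0, 1)), c("a", "b"))
  tr <- infer_clone_order(m)
  expect_identical(nrow(tr$conflicts), 1L)
  # raising the tolerance never increases the conflict count
  n_prev <- nrow(tr$conflicts)
  for (tol in c(0.2, 0.4, 0.6)) {
    n_tol <- nrow(infer_clone_order(m, tolerance = tol)$conflicts)
    expect_lte(n_tol, n_prev)
    n_prev <- n_tol
  }
})

test_that("identical colony sets merge into one acquisition step", {
  m <- make_matrix(list(c(1, 1, 0), c(1, 1, 0), c(1, 1, 1)),
                   c("TET2", "SRSF2", "NRAS"))
  tr <- infer_clone_order(m)
  expect_identical(nrow(tr$table), 3L)  # WT, TET2+SRSF2 step, +NRAS
  expect_true(any(grepl("TET2\\+SRSF2|SRSF2\\+TET2", tr$table$mutations)))
})

test_that("degenerate and invalid matrices are handled per contract", {
  # all-zero matrix: single wild-type clone at prevalence 1
  m0 <- make_matrix(list(c(0, 0), c(0, 0)), c("a", "b"))
  tr0 <- infer_clone_order(m0)
  expect_identical(nrow(tr0$table), 1L)
  expect_equal(tr0$table$prevalence, 1)

  expect_error(fishplot_table(list()), "not a valid")
  expect_error(infer_clone_order(make_matrix(list(c(1, 2)), c("a", "b"))),
               "binary")
  m_dup <- make_matrix(list(c(1, 0)), c("a", "b"))
  rownames(m_dup) <- NULL
  m_dup <- rbind(m_dup, m_dup)
  rownames(m_dup) <- c("c1", "c1")
  expect_error(infer_clone_order(m_dup), "duplicate")
})

test_that("inference recovers simulated linear orders exactly (round trip)", {
  set.seed(19)
  for (k in 1:6) {
    for (rep in 1:3) {
      order_true <- sample(paste0("M", 1:k))
      w <- rep(1 / (k + 1), k + 1)
      col <- simulate_colonies(order_true, n_colonies = 50 * (k + 1),
                               clone_weights = w, dropout = 0,
                               seed = 1000 * k + rep)
      tr <- infer_clone_order(col$genotypes)
      expect_true(tr$linear, label = sprintf("k=%d rep=%d linear", k, rep))
      terminal <- tr$table$mutations[nrow(tr$table)]
      expect_identical(terminal, paste(order_true, collapse = "+"),
                       label = sprintf("k=%d rep=%d order", k, rep))
      # clone prevalences match the simulation truth
      truth_counts <- tabulate(col$truth$clone + 1, nbins = k + 1)
      expect_equal(tr$table$count, truth_counts)
      expect_equal(sum(tr$table$prevalence), 1, tolerance = 1e-12)
    }
  }
})
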