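make_tables <- function(expr, psi, tissues = sprintf("t%02d", seq_along(expr)),
                        event = "EX1", gene = "SNCA") {
  psi_df <- data.frame(tissue = tissues)
  psi_df[[event]] <- psi
  expr_df <- data.frame(tissue = tissues)
  expr_df[[gene]] <- expr
  psi_expression_tables(psi_df, expr_df)
}

test_that("a single observation lands in its left-closed bin", {
  tabs <- make_tables(expr = 5, psi = 80)
  b <- bin_psi_by_expression(tabs, gene = "SNCA")
  populated <- b[!is.na(b$mean_psi), ]
  expect_identical(nrow(populated), 1L)
  expect_identical(populated$bin_lo, 0)
  expect_identical(populated$mean_psi, 80)
  expect_identical(sum(b$n_tissues), 1L)
})

test_that("tissues sharing a bin are averaged; boundaries are left-closed", {
  tabs <- make_tables(expr = c(12, 17, 20), psi = c(40, 60, 99))
  b <- bin_psi_by_expression(tabs, gene = "SNCA")
  expect_identical(b$mean_psi[b$bin_lo == 10], 50)
  # expression exactly 20 belongs to [20, 30), not [10, 20)
  expect_identical(b$mean_psi[b$bin_lo == 20], 99)
})

test_that("bin means match the grouping oracle and conserve the grand mean", {
  set.seed(23)
  for (i in 1:5) {
    n <- 50
    expr <- runif(n, 0, 210)  # some tissues overflow past 190
    psi <- runif(n, 0, 100)
    psi[sample(n, 5)] <- NA
    tabs <- make_tables(expr, psi)
    b <- bin_psi_by_expression(tabs, gene = "SNCA")
    oracle <- oracle_bin_means(expr, psi, edges = seq(0, 190, 10))
    expect_equal(b$mean_psi, oracle$means)
    expect_identical(b$n_tissues, oracle$counts)
    # count-weighted mean of bin means == global mean over included tissues
    ok <- b$n_tissues > 0
    expect_equal(sum(b$mean_psi[ok] * b$n_tissues[ok]) / sum(b$n_tissues[ok]),
                 mean(psi, na.rm = TRUE), tolerance = 1e-12)
  }
})

test_that("binning is invariant to tissue order and to dropping missing-PSI tissues", {
  set.seed(29)
  n <- 40
  expr <- runif(n, 0, 190)
  psi <- runif(n, 0, 100)
  psi[c(3, 11)] <- NA
  tabs <- make_tables(expr, psi)
  b1 <- bin_psi_by_expression(tabs, gene = "SNCA")
  perm <- sample(n)
  b2 <- bin_psi_by_expression(
    make_tables(expr[perm], psi[perm], tissues = sprintf("t%02d", perm)),
    gene = "SNCA")
  expect_equal(b1$mean_psi, b2$mean_psi)
  expect_identical(b1$n_tissues, b2$n_tissues)
  # removing a tissue whose PSI is missing changes nothing
  keep <- setdiff(seq_len(n), 3)
  b3 <- bin_psi_by_expression(
    make_tables(expr[keep], psi[keep], tissues = sprintf("t%02d", keep)),
    gene = "SNCA")
  expect_equal(b1$mean_psi, b3$mean_psi)
})

test_that("trend summaries handle monotone, constant and sparse bins", {
  tabs <- make_tables(expr = seq(5, 185, by = 10), psi = seq(5, 95, by = 5))
  tr <- psi_expression_trend(bin_psi_by_expression(tabs, gene = "SNCA"))
  expect_identical(tr$spearman_rho, 1)
  const <- make_tables(expr = seq(5, 185, by = 10), psi = rep(50, 19))
  tr2 <- psi_expression_trend(bin_psi_by_expression(const, gene = "SNCA"))
  expect_identical(tr2$spearman_rho, 0)
  sparse <- make_tables(expr = c(5, 15), psi = c(10, 20))
  tr3 <- psi_expression_trend(bin_psi_by_expression(sparse, gene = "SNCA"))
  expect_false(tr3$defined)
  expect_true(is.na(tr3$spearman_rho))
})

test_that("tables reject invalid PSI, expression, or disjoint tissues", {
  expect_error(make_tables(expr = 5, psi = 120), "\\[0, 100\\]")
  expect_error(make_tables(expr = -2, psi = 50), "nonnegative")
  expect_error(
    psi_expression_tables(data.frame(tissue = "a", EX1 = 50),
                          data.frame(tissue = "b", SNCA = 10)),
    "no shared tissues")
})

test_that("trend sign matches the generating direction in >= 95% of seeded tables", {
  hits <- vapply(1:200, function(s) {
    up <- s %% 2 == 0
    spec <- psi_tables_spec(n_tissues = 40,
                            trend = if (up) "increasing" else "decreasing",
                            outlier_frac = 0.05, noise_sd = 5, seed = s)
    tabs <- gen_psi_tables(spec)
    tr <- psi_expression_trend(bin_psi_by_expression(tabs, gene = "SNCA"))
    isTRUE(tr$defined) && sign(tr$spearman_rho) == (if (up) 1 else -1)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
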