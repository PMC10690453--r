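test_that("fold activation divides treated by basal, elementwise", {
  conc <- c(0, 0.5, 2, 8)
  basal <- titration_curve(conc, c(2, 2, 2, 2))
  treated <- titration_curve(conc, c(6, 6, 6, 6))
  fa <- compute_fold_activation(basal, treated)
  expect_equal(fa$activity, rep(3, 4))
  # identity
  same <- compute_fold_activation(basal, basal)
  expect_equal(same$activity, rep(1, 4))
  # randomized paired curves match direct division
  set.seed(5)
  b <- titration_curve(conc, runif(4, 1, 5))
  t <- titration_curve(conc, runif(4, 1, 5))
  expect_equal(compute_fold_activation(b, t)$activity,
               average_replicates(t)$activity / average_replicates(b)$activity)
})

test_that("nonpositive basal activity yields NA with a warning", {
  basal <- titration_curve(c(0, 1, 2, 3), c(0, 1, 2, 3))
  treated <- titration_curve(c(0, 1, 2, 3), c(1, 2, 4, 6))
  expect_warning(fa <- compute_fold_activation(basal, treated),
                 "nonpositive basal")
  expect_equal(nrow(fa), 3)  # undefined point dropped after warning
})

test_that("activation factor is 1 at zero, bounded, monotone, and closed-form", {
  m <- activation_model(beta = 6, k_half = 1)
  expect_identical(activation_factor(m, 0), 1)
  expect_equal(activation_factor(m, 1), 3.5)  # (1 + 6)/(1 + 1)
  expect_error(activation_factor(m, -1), "nonnegative")
  set.seed(8)
  for (i in 1:20) {
    beta <- runif(1, 0, 10); k <- 10^runif(1, -1, 1)
    mi <- activation_model(beta = beta, k_half = k)
    a <- sort(10^runif(20, -2, 3))
    fa <- activation_factor(mi, a)
    # independent symbolic evaluation
    expect_equal(fa, (1 + beta * a / k) / (1 + a / k), tolerance = 1e-14)
    expect_true(all(fa >= min(1, beta) - 1e-12 & fa <= max(1, beta) + 1e-12))
    mono <- diff(fa)
    if (beta > 1) expect_true(all(mono >= -1e-12)) else
      expect_true(all(mono <= 1e-12))
  }
})

test_that("noiseless activation curves are recovered to 1e-6 relative error", {
  spec <- activation_curve_spec(beta = 6, k_half = 1, noise_sd = 0, seed = 1)
  fit <- fit_activation(gen_activation_curve(spec))
  expect_true(fit$converged)
  expect_equal(fit$beta, 6, tolerance = 1e-6)
  expect_equal(fit$k_half, 1, tolerance = 1e-6)
})

test_that("flat fold curves flag beta as unidentifiable; negatives are rejected", {
  flat <- gen_activation_curve(activation_curve_spec(beta = 1, k_half = 1,
                                                     noise_sd = 0, seed = 2))
  fit <- fit_activation(flat)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_false(fit$converged)
  expect_error(
    fit_activation(titration_curve(c(0, 1, 2, 4), c(1, -0.2, 2, 3),
                                   ligand_name = "aSN")),
    "negative fold")
})

test_that("median beta error stays below 10% at 10% noise over 100 seeds", {
  betas <- vapply(1:100, function(s) {
    spec <- activation_curve_spec(beta = 6, k_half = 1, noise_sd = 0.1,
                                  replicates = 3, seed = s)
    fit_activation(gen_activation_curve(spec))$beta
  }, numeric(1))
  expect_lte(stats::median(abs(betas - 6) / 6), 0.10)
})

test_that("fit_activation accepts raw rates with a scalar basal", {
  spec <- activation_curve_spec(beta = 4, k_half = 2, noise_sd = 0, seed = 9)
  fold <- gen_activation_curve(spec)
  raw <- titration_curve(fold$conc_uM, fold$activity * 2.5,
                         ligand_name = "aSN")
  fit <- fit_activation(raw, basal = 2.5)
  expect_equal(fit$beta, 4, tolerance = 1e-6)
  expect_equal(fit$basal_rate, 2.5)
})
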