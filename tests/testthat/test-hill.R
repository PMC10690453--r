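test_that("titration curves validate their invariants", {
  expect_error(titration_curve(c(-1, 1), c(1, 2)), "nonnegative")
  expect_error(titration_curve(c(1, 2), c(1, NA)), "finite")
  expect_error(titration_curve(1:3, 1:2), "same length")
  tc <- titration_curve(c(0.1, 1), c(1, 2), replicate = c(1, 1),
                        sem = c(0.1, 0.2))
  expect_s3_class(tc, "titration_curve")
  expect_identical(attr(tc, "ligand_name"), "Ca2+_free")
})

test_that("titration curves survive a CSV/TSV round trip", {
  tc <- gen_hill_curve(hill_curve_spec(noise_sd = 0.05, replicates = 2,
                                       seed = 7))
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_titration(tc, path)
    back <- read_titration(path)
    expect_equal(back$conc_uM, tc$conc_uM, tolerance = 1e-12)
    expect_equal(back$activity, tc$activity, tolerance = 1e-12)
  }
})

test_that("noiseless Hill curves are recovered to 1e-6 relative error", {
  # broad sampled parameter range, fixed seed
  set.seed(11)
  cases <- data.frame(vmax = runif(6, 0.5, 20),
                      kd = 10^runif(6, -2, 0.5),
                      n = runif(6, 0.8, 3))
  for (i in seq_len(nrow(cases))) {
    spec <- hill_curve_spec(vmax = cases$vmax[i], kd = cases$kd[i],
                            n = cases$n[i], noise_sd = 0, n_points = 10,
                            conc_range = c(cases$kd[i] / 30,
                                           cases$kd[i] * 30),
                            seed = i)
    fit <- fit_hill(gen_hill_curve(spec))
    expect_true(fit$converged)
    expect_equal(fit$kd_app, cases$kd[i], tolerance = 1e-6)
    expect_equal(fit$vmax, cases$vmax[i], tolerance = 1e-6)
    expect_equal(fit$hill_n, cases$n[i], tolerance = 1e-6)
  }
})

test_that("fixing the Hill coefficient estimates only vmax and kd", {
  tc <- gen_hill_curve(hill_curve_spec(vmax = 5, kd = 0.3, n = 2,
                                       noise_sd = 0, seed = 3))
  fit <- fit_hill(tc, fix_n = 2)
  expect_identical(fit$hill_n, 2)
  expect_true(fit$fixed_n)
  expect_equal(fit$kd_app, 0.3, tolerance = 1e-8)
  expect_named(fit$standard_errors, c("vmax", "kd"))
})

test_that("degenerate inputs are rejected or flagged, never silent", {
  expect_error(fit_hill(titration_curve(c(1, 2, 3), c(1, 2, 3))),
               "at least 4 distinct")
  # constant activity: kd non-identifiable
  flat <- fit_hill(titration_curve(c(0.01, 0.1, 1, 10), rep(3, 4)))
  expect_false(flat$converged)
})

test_that("the fitter beats an exhaustive grid search on noisy data", {
  tc <- gen_hill_curve(hill_curve_spec(vmax = 5, kd = 0.56, n = 1.5,
                                       noise_sd = 0.05, replicates = 3,
                                       seed = 42))
  fit <- fit_hill(tc)
  grid <- oracle_hill_grid(tc$conc_uM, tc$activity,
                           vmax_range = c(3, 7), kd_range = c(0.1, 2),
                           n_range = c(0.5, 3))
  expect_lte(fit$residual_norm, grid$ssr + 1e-12)
  # grid resolution ~ a few percent in kd
  expect_equal(fit$kd_app, grid$kd, tolerance = 0.1)
})

test_that("median recovered kd over seeded noisy replicates sits within the reported SE", {
  res <- vapply(1:200, function(s) {
    spec <- hill_curve_spec(vmax = 5, kd = 0.56, n = 1.5, noise_sd = 0.05,
                            replicates = 3, seed = s)
    fit <- fit_hill(gen_hill_curve(spec))
    c(fit$kd_app, fit$standard_errors[["kd"]])
  }, numeric(2))
  med_kd <- stats::median(res[1, ], na.rm = TRUE)
  med_se <- stats::median(res[2, ], na.rm = TRUE)
  expect_lte(abs(med_kd - 0.56), med_se)
})
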