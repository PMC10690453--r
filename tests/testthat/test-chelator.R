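test_that("free Ca equals total Ca without chelators", {
  buf <- buffer_system(total_ca = 1.8)
  expect_identical(compute_free_ca(buf), 1.8)
})

test_that("single Ca/EGTA pair matches the closed-form quadratic root", {
  # Ca_t = Ca_f (1 + K E_f), E_t = E_f (1 + K Ca_f)  =>  quadratic in Ca_f:
  # K Ca_f^2 + (1 + K(E_t - Ca_t)) Ca_f - Ca_t = 0
  constants <- data.frame(species = "CaEGTA", logK_apparent = 6.91,
                          ph = 7.2, temperature_C = 37)
  K <- 10^6.91
  for (ca_t_uM in c(100, 500, 900)) {
    buf <- buffer_system(total_ca = ca_t_uM, total_egta = 1,
                         constants = constants)
    ca_t <- ca_t_uM * 1e-6; e_t <- 1e-3
    b <- 1 + K * (e_t - ca_t)
    root <- (-b + sqrt(b^2 + 4 * K * ca_t)) / (2 * K)
    expect_equal(compute_free_ca(buf), root * 1e6, tolerance = 1e-9)
  }
})

test_that("the full system matches a brute-force bisection oracle to 1e-9", {
  logK <- c(CaEGTA = 6.91, MgEGTA = 2.38, CaATP = 3.79, MgATP = 4.10)
  for (ca_t in c(50, 200, 600, 950)) {
    buf <- buffer_system(total_ca = ca_t, total_mg = 3, total_egta = 1,
                         total_atp = 3)
    got <- compute_free_ca(buf)
    want <- oracle_free_ca_bisect(ca_t, 3, 1, 3, logK)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("free Ca is monotone in total Ca and total EGTA, with conserved mass", {
  grid <- seq(50, 950, by = 100)
  free <- vapply(grid, function(ca_t) {
    res <- compute_free_ca(buffer_system(total_ca = ca_t, total_mg = 3,
                                         total_egta = 1, total_atp = 3),
                           full = TRUE)
    expect_lte(max(res$residuals), 1e-9)
    res$free_ca_uM
  }, numeric(1))
  expect_true(all(diff(free) > 0))
  more_egta <- vapply(c(0.5, 1, 2, 4), function(e) {
    compute_free_ca(buffer_system(total_ca = 400, total_mg = 3,
                                  total_egta = e, total_atp = 3))
  }, numeric(1))
  expect_true(all(diff(more_egta) < 0))
})

test_that("invert_free_ca round-trips the assay set-points to 0.1%", {
  base <- buffer_system(total_ca = 0, total_mg = 3, total_egta = 1,
                        total_atp = 3)
  for (target in c(0.06, 1.8)) {  # the low- and standard free-Ca set-points
    total <- invert_free_ca(base, target)
    check <- base; check$total_ca <- total
    expect_equal(compute_free_ca(check), target, tolerance = 1e-3)
  }
  # no chelators: identity
  expect_equal(invert_free_ca(buffer_system(total_ca = 0), 1.8), 1.8,
               tolerance = 1e-6)
})

test_that("round-trip closure holds over random chelator mixes", {
  set.seed(21)
  for (i in 1:10) {
    buf <- buffer_system(total_ca = 0, total_mg = runif(1, 0, 5),
                         total_egta = runif(1, 0.1, 3),
                         total_atp = runif(1, 0, 5))
    target <- 10^runif(1, -2, 1)
    total <- invert_free_ca(buf, target)
    buf$total_ca <- total
    expect_equal(compute_free_ca(buf), target, tolerance = 1e-3)
  }
})

test_that("missing constants and invalid totals are rejected", {
  constants <- data.frame(species = "CaEGTA", logK_apparent = 6.91,
                          ph = 7.2, temperature_C = 37)
  expect_error(buffer_system(total_ca = 100, total_mg = 3, total_egta = 1,
                             constants = constants),
               "MgEGTA")
  expect_error(buffer_system(total_ca = -1), "nonnegative")
})
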