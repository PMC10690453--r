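params <- model_parameters()

test_that("pmca_flux matches its closed form and limits", {
  expect_equal(pmca_flux(0.25, 0, params),
               params$pmca$v_max * 0.25^2 / (0.25^2 + 0.56^2),
               tolerance = 1e-12)
  # saturation in Ca approaches FA(asn) * Vmax
  fa <- activation_factor(params$pmca$activation, 7)
  expect_equal(pmca_flux(1e6, 7, params), fa * params$pmca$v_max,
               tolerance = 1e-6)
  # randomized grid against independent evaluation
  set.seed(13)
  for (i in 1:25) {
    ca <- 10^runif(1, -2, 2); asn <- 10^runif(1, -2, 2)
    th <- (asn / 1) / (1 + asn / 1)
    k <- 0.56 + th * (0.082 - 0.56)
    want <- (1 + 5 * asn) / (1 + asn) * params$pmca$v_max *
      ca^2 / (ca^2 + k^2)
    expect_equal(pmca_flux(ca, asn, params), want, tolerance = 1e-12)
  }
  expect_error(pmca_flux(-1, 0, params), "positive")
  expect_error(pmca_flux(1, -1, params), "nonnegative")
})

test_that("rest is a fixed point: unstimulated trajectories stay flat", {
  for (asn in c(0, 50)) {
    ss <- steady_state_ca(params, asn)
    sim <- simulate_presynapse(params, stimulus_protocol("none"),
                               asn_conc = asn, t_end = 200, dt_out = 1)
    late <- sim$ca_uM[sim$time_ms > 20]
    expect_lt(max(abs(late - ss)) / ss, 1e-3)
    expect_true(all(sim$ca_uM > 0))
  }
})

test_that("a single pulse elicits exactly one action potential and one Ca transient", {
  sim <- simulate_presynapse(params, stimulus_protocol("single_pulse"),
                             asn_conc = 10)
  expect_identical(count_action_potentials(sim), 1L)
  m <- peak_metrics(sim)
  expect_gt(m$peak_height, 2 * m$baseline)
  # Ca relaxes back toward baseline by the end of the trace
  expect_lt(abs(sim$ca_uM[nrow(sim)] - m$baseline), 0.1 * m$peak_height)
  expect_true(all(sim$ca_uM > 0))
})

test_that("a 20 Hz / 400 ms train gives 8 pulses, 8 APs and 8 Ca peaks", {
  prot <- stimulus_protocol("spike_train", train_frequency = 20,
                            train_duration = 400)
  expect_length(prot$pulse_starts, 8)
  sim <- simulate_presynapse(params, prot, asn_conc = 10)
  expect_identical(count_action_potentials(sim), 8L)
  # Ca oscillation peaks: local maxima above the resting level
  ca <- sim$ca_uM
  peaks <- which(diff(sign(diff(ca))) == -2) + 1
  peaks <- peaks[ca[peaks] > 2 * steady_state_ca(params, 10)]
  expect_identical(length(peaks), 8L)
})

test_that("steady states agree with a bisection oracle and balance fluxes", {
  set.seed(31)
  for (i in 1:8) {
    p <- model_parameters(
      asn_activation = activation_model(beta = runif(1, 2, 8),
                                        k_half = 10^runif(1, -0.5, 0.5)),
      ca_ss_basal = runif(1, 0.15, 0.4),
      ca_ss_activated = runif(1, 0.05, 0.12))
    asn <- 10^runif(1, -1, 2)
    got <- steady_state_ca(p, asn)
    v_rest <- resting_potential(p)
    s_rest <- 1 / (1 + exp(-(v_rest - p$vgcc$v_half) / p$vgcc$slope))
    influx <- p$flux_scale * p$vgcc$g_ca * s_rest *
      (p$vgcc$e_ca - v_rest) + p$leak_ca$influx
    net <- function(ca) influx - pmca_flux(ca, asn, p) -
      p$ncx$v_max * ca / (ca + p$ncx$k_half)
    expect_equal(got, oracle_steady_state_bisect(net), tolerance = 1e-8)
    efflux_at_ss <- influx - net(got)
    expect_lt(abs(net(got)), 1e-9 * efflux_at_ss)
  }
})

test_that("the algebraic steady state is confirmed by long integration", {
  expect_silent(ss <- steady_state_ca(params, 5, verify = TRUE))
  expect_gt(ss, 0)
})

test_that("halving solver tolerances leaves the settled Ca unchanged to 0.01%", {
  end_ca <- function(rtol, atol) {
    sim <- simulate_presynapse(params, stimulus_protocol("none"),
                               asn_conc = 3, t_end = 300, dt_out = 5,
                               rtol = rtol, atol = atol)
    sim$ca_uM[nrow(sim)]
  }
  expect_equal(end_ca(1e-8, 1e-10), end_ca(5e-9, 5e-11), tolerance = 1e-4)
})

test_that("transient size and duration shrink as PMCA Vmax grows", {
  scales <- seq(0.5, 3, length.out = 10)
  m <- vapply(scales, function(s) {
    p <- params
    p$pmca$v_max <- params$pmca$v_max * s
    pm <- peak_metrics(simulate_presynapse(p, stimulus_protocol("single_pulse"),
                                           asn_conc = 5))
    c(pm$peak_height, pm$pre_peak_width, pm$post_peak_width)
  }, numeric(3))
  for (j in 1:3) expect_true(all(diff(m[j, ]) <= 1e-9))
})

test_that("degenerate and invalid model setups fail loudly", {
  # no influx at rest: steady state collapses to the zero boundary
  p <- model_parameters(calibrate = FALSE, leak_ca = list(influx = 0),
                        vgcc = list(g_ca = 1e-12))
  expect_error(steady_state_ca(p, 0), "degenerate|no Ca influx")
  expect_error(model_parameters(ncx = list(v_max = -1)), "positive")
  expect_error(simulate_presynapse(params, stimulus_protocol("single_pulse"),
                                   asn_conc = 10, t_end = 10),
               "t_end")
  expect_error(asn_dose_response(params, c(5, 1)), "sorted")
})
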