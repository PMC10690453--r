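# Independent oracles used to cross-check package computations.
# Each is deliberately written as brute force / closed form, not by
# calling the implementation under test.

# Exhaustive grid search for the Hill-equation least-squares optimum.
oracle_hill_grid <- function(conc, act, vmax_range, kd_range, n_range,
                             n_grid = 40) {
  vmaxs <- seq(vmax_range[1], vmax_range[2], length.out = n_grid)
  kds <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = n_grid))
  ns <- seq(n_range[1], n_range[2], length.out = n_grid)
  best <- list(ssr = Inf)
  for (v in vmaxs) for (k in kds) {
    for (n in ns) {
      pred <- v * conc^n / (k^n + conc^n)
      ssr <- sum((act - pred)^2)
      if (ssr < best$ssr) best <- list(vmax = v, kd = k, n = n, ssr = ssr)
    }
  }
  best
}

# Brute-force bisection for the free-Ca equilibrium (inner bisection for
# free Mg), 200 halvings each: ~machine-precision bracketing.
oracle_free_ca_bisect <- function(total_ca_uM, total_mg_mM, total_egta_mM,
                                  total_atp_mM, logK) {
  k <- 10^logK  # named: CaEGTA, MgEGTA, CaATP, MgATP (M^-1)
  ca_t <- total_ca_uM * 1e-6; mg_t <- total_mg_mM * 1e-3
  e_t <- total_egta_mM * 1e-3; a_t <- total_atp_mM * 1e-3
  mg_free <- function(ca_f) {
    if (mg_t == 0) return(0)
    lo <- 0; hi <- mg_t
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      e_f <- e_t / (1 + k[["CaEGTA"]] * ca_f + k[["MgEGTA"]] * mid)
      a_f <- a_t / (1 + k[["CaATP"]] * ca_f + k[["MgATP"]] * mid)
      r <- mg_t - mid * (1 + k[["MgEGTA"]] * e_f + k[["MgATP"]] * a_f)
      if (r > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lo <- 0; hi <- ca_t
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    mg_f <- mg_free(mid)
    e_f <- e_t / (1 + k[["CaEGTA"]] * mid + k[["MgEGTA"]] * mg_f)
    a_f <- a_t / (1 + k[["CaATP"]] * mid + k[["MgATP"]] * mg_f)
    r <- ca_t - mid * (1 + k[["CaEGTA"]] * e_f + k[["CaATP"]] * a_f)
    if (r > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 * 1e6
}

# Exact integral of the piecewise-linear interpolant of (time, signal)
# over [t0, t1]; independent of compute_auc's clipping logic.
oracle_auc_piecewise <- function(time, signal, t0, t1) {
  f <- stats::approxfun(time, signal)
  total <- 0
  knots <- sort(unique(c(t0, t1, time[time > t0 & time < t1])))
  for (i in seq_len(length(knots) - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    total <- total + (b - a) * (f(a) + f(b)) / 2
  }
  total
}

# Per-tissue grouping oracle for PSI binning: explicit loop over tissues.
oracle_bin_means <- function(expr, psi, edges) {
  n_bins <- length(edges)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (i in seq_along(expr)) {
    if (is.na(expr[i]) || is.na(psi[i]) || expr[i] < edges[1]) next
    b <- max(which(edges <= expr[i]))
    sums[b] <- sums[b] + psi[i]
    counts[b] <- counts[b] + 1L
  }
  list(means = ifelse(counts > 0, sums / counts, NA_real_), counts = counts)
}

# Brute-force bisection for the resting Ca fixed point of a net-flux
# function (influx constant, efflux increasing).
oracle_steady_state_bisect <- function(net, lower = 1e-9, upper = 1e4) {
  lo <- lower; hi <- upper
  for (i in 1:200) {
    mid <- sqrt(lo * hi)  # geometric: Ca spans decades
    if (net(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
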