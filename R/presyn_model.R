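#' Default presynaptic model parameters
#'
#' Parameterizes a point model of a presynaptic terminal: classical
#' squid-axon Hodgkin-Huxley membrane (Na, K, leak), a voltage-gated Ca2+
#' channel (VGCC) with one Boltzmann activation gate, and a cytosolic Ca2+
#' balance with PMCA, NCX and constant-leak fluxes. The PMCA flux is scaled
#' by the alpha-synuclein activation factor and its apparent Ca affinity
#' interpolates between the basal and aSN-saturated dissociation constants
#' measured for PMCA1d in brain lipid extract (0.56 and 0.082 uM).
#'
#' By default the PMCA maximal flux and the Ca leak influx are calibrated
#' in closed form (see [calibrate_ca_fluxes()]) so that the unstimulated
#' steady-state Ca2+ is `ca_ss_basal` (0.25 uM) without aSN and
#' `ca_ss_activated` (0.1 uM) at saturating aSN.
#'
#' @param asn_activation an [activation_model()] giving the fold
#'   activation of PMCA by aSN; default beta = 5, k_half = 1 uM, a
#'   saturating activation with half-effect in the low-micromolar range so
#'   that the steady-state response is steepest below 10 uM aSN.
#' @param ca_ss_basal,ca_ss_activated calibration targets (uM) for the
#'   resting steady state at zero and saturating aSN.
#' @param calibrate if `TRUE` (default), solve for `pmca$v_max` and
#'   `leak_ca$influx` from the two steady-state targets; if `FALSE`, the
#'   values passed in `pmca`/`leak_ca` are used as-is.
#' @param membrane,vgcc,pmca,ncx,leak_ca,flux_scale overrides merged into
#'   the defaults (lists for the compartments, scalar for `flux_scale`,
#'   the factor converting membrane Ca current in uA/cm2 to cytosolic
#'   concentration change in uM/ms; it lumps surface-to-volume ratio,
#'   Faraday conversion and fast-buffer binding).
#' @return An object of class `model_parameters` (a named list).
#' @examples
#' p <- model_parameters()
#' steady_state_ca(p, asn_conc = 0)
#' @export
model_parameters <- function(asn_activation = activation_model(beta = 5,
                                                               k_half = 1),
                             ca_ss_basal = 0.25, ca_ss_activated = 0.10,
                             calibrate = TRUE,
                             membrane = list(), vgcc = list(), pmca = list(),
                             ncx = list(), leak_ca = list(),
                             flux_scale = 0.15) {
  p <- list(
    membrane = utils::modifyList(list(
      cm = 1, g_na = 120, g_k = 36, g_leak = 0.3,
      e_na = 50, e_k = -77, e_leak = -54.4), membrane),
    vgcc = utils::modifyList(list(
      g_ca = 0.1, v_half = -17, slope = 8, tau_ms = 1, e_ca = 125,
      driving = "ohmic", ca_out_uM = 2000), vgcc),
    pmca = utils::modifyList(list(
      v_max = 0.01, kd_basal = 0.56, kd_activated = 0.082, hill_n = 2,
      activation = asn_activation), pmca),
    ncx = utils::modifyList(list(v_max = 0.4, k_half = 1.8), ncx),
    leak_ca = utils::modifyList(list(influx = 0.05), leak_ca),
    flux_scale = flux_scale,
    ca_ss_basal = ca_ss_basal,
    ca_ss_activated = ca_ss_activated)
  validate_model_parameters(p)
  p <- structure(p, class = "model_parameters")
  if (calibrate) p <- calibrate_ca_fluxes(p)
  p
}

validate_model_parameters <- function(p) {
  pos <- c(p$membrane$cm, p$membrane$g_na, p$membrane$g_k, p$membrane$g_leak,
           p$vgcc$g_ca, p$vgcc$slope, p$vgcc$tau_ms,
           p$pmca$v_max, p$pmca$kd_basal, p$pmca$kd_activated, p$pmca$hill_n,
           p$ncx$v_max, p$ncx$k_half, p$flux_scale,
           p$ca_ss_basal, p$ca_ss_activated)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("conductances, fluxes, Kd values, time constants and calibration ",
         "targets must be strictly positive and finite")
  if (p$leak_ca$influx < 0) stop("leak influx must be nonnegative")
  if (!inherits(p$pmca$activation, "activation_model"))
    stop("pmca$activation must be an activation_model")
  invisible(TRUE)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Presynaptic Ca2+ model parameters\n")
  cat(sprintf("  PMCA: v_max = %.4g uM/ms, Kd %0.3g -> %0.3g uM (n = %g), beta = %g, k_half = %g uM\n",
              x$pmca$v_max, x$pmca$kd_basal, x$pmca$kd_activated,
              x$pmca$hill_n, x$pmca$activation$beta, x$pmca$activation$k_half))
  cat(sprintf("  NCX : v_max = %.4g uM/ms, K = %g uM\n",
              x$ncx$v_max, x$ncx$k_half))
  cat(sprintf("  leak influx = %.4g uM/ms; VGCC g_ca = %g mS/cm2 (%s)\n",
              x$leak_ca$influx, x$vgcc$g_ca, x$vgcc$driving))
  cat(sprintf("  steady-state targets: %g uM (aSN = 0), %g uM (aSN sat)\n",
              x$ca_ss_basal, x$ca_ss_activated))
  invisible(x)
}

#' Calibrate the PMCA maximum and leak influx from steady-state targets
#'
#' At rest the Ca balance reads
#' `leak + J_VGCC(V_rest) = FA * Vp * H(ca, K) + J_NCX(ca)`.
#' Imposing this at the two target concentrations — `ca_ss_basal` with
#' `FA = 1, K = Kd_basal` and `ca_ss_activated` with `FA = beta,
#' K = Kd_activated` — gives two equations linear in the PMCA maximal flux
#' `Vp` and the leak influx, solved here in closed form.
#'
#' @param params a `model_parameters` object.
#' @return The parameter set with `pmca$v_max` and `leak_ca$influx`
#'   replaced by the calibrated values.
#' @export
calibrate_ca_fluxes <- function(params) {
  p <- params
  h <- p$pmca$hill_n
  beta <- p$pmca$activation$beta
  ca0 <- p$ca_ss_basal
  ca1 <- p$ca_ss_activated
  a1 <- ca0^h / (ca0^h + p$pmca$kd_basal^h)
  a2 <- ca1^h / (ca1^h + p$pmca$kd_activated^h)
  b1 <- p$ncx$v_max * ca0 / (ca0 + p$ncx$k_half)
  b2 <- p$ncx$v_max * ca1 / (ca1 + p$ncx$k_half)
  if (beta * a2 - a1 <= 0)
    stop("calibration impossible: activated PMCA occupancy does not exceed basal")
  v_rest <- resting_potential(p)
  jv <- vgcc_ca_influx(v_rest, vgcc_gate_inf(v_rest, p), ca1, p)
  vp <- (b1 - b2) / (beta * a2 - a1)
  leak <- vp * a1 + b1 - jv
  if (vp <= 0 || leak < 0)
    stop("calibration yields nonpositive PMCA flux or negative leak; ",
         "adjust NCX/VGCC magnitudes")
  p$pmca$v_max <- vp
  p$leak_ca$influx <- leak
  p
}

## ---- Hodgkin-Huxley gating (classical squid-axon rates, V in mV) ----

# alpha/beta with removable singularities handled by their limits
hh_rates <- function(v) {
  am <- ifelse(abs(v + 40) < 1e-7, 1,
               0.1 * (v + 40) / (1 - exp(-(v + 40) / 10)))
  bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20)
  bh <- 1 / (1 + exp(-(v + 35) / 10))
  an <- ifelse(abs(v + 55) < 1e-7, 0.1,
               0.01 * (v + 55) / (1 - exp(-(v + 55) / 10)))
  bn <- 0.125 * exp(-(v + 65) / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

hh_gates_inf <- function(v) {
  r <- hh_rates(v)
  c(m = r$am / (r$am + r$bm),
    h = r$ah / (r$ah + r$bh),
    n = r$an / (r$an + r$bn))
}

vgcc_gate_inf <- function(v, params) {
  1 / (1 + exp(-(v - params$vgcc$v_half) / params$vgcc$slope))
}

# Ca influx through VGCC, uM/ms (positive inward). Ohmic driving force by
# default; "ghk" uses the Goldman-Hodgkin-Katz current normalized so the
# two conventions agree at the resting potential.
vgcc_ca_influx <- function(v, s, ca_uM, params) {
  g <- params$vgcc
  if (identical(g$driving, "ghk")) {
    u <- 2 * v / 26.7  # zFV/RT at 37 C, z = 2, RT/F ~ 26.7 mV
    u <- pmax(pmin(u, 500), -500)
    ghk <- ifelse(abs(u) < 1e-6,
                  (ca_uM - g$ca_out_uM) - u / 2 * (ca_uM + g$ca_out_uM),
                  u * (ca_uM - g$ca_out_uM * exp(-u)) / (1 - exp(-u)))
    # scale so that at v = e_ca the flux vanishes and magnitude tracks g_ca
    params$flux_scale * g$g_ca * (-ghk) / g$ca_out_uM * 26.7 / 2 * s
  } else {
    params$flux_scale * g$g_ca * s * (g$e_ca - v)
  }
}

#' PMCA-mediated Ca2+ efflux
#'
#' `J = FA(asn) * Vp * ca^h / (ca^h + K(asn)^h)` with the apparent
#' dissociation constant interpolated between the basal and aSN-saturated
#' values through the activation occupancy
#' `theta(asn) = (asn/k_half) / (1 + asn/k_half)`.
#'
#' @param ca cytosolic Ca2+ (uM), `> 0`.
#' @param asn_conc aSN concentration (uM), `>= 0`.
#' @param params a [model_parameters()] object.
#' @return efflux rate, uM/ms.
#' @export
pmca_flux <- function(ca, asn_conc, params) {
  if (any(ca <= 0)) stop("ca must be strictly positive")
  if (any(asn_conc < 0)) stop("asn_conc must be nonnegative")
  pm <- params$pmca
  fa <- activation_factor(pm$activation, asn_conc)
  theta <- (asn_conc / pm$activation$k_half) /
    (1 + asn_conc / pm$activation$k_half)
  k <- pm$kd_basal + theta * (pm$kd_activated - pm$kd_basal)
  fa * pm$v_max * ca^pm$hill_n / (ca^pm$hill_n + k^pm$hill_n)
}

ncx_flux <- function(ca, params) {
  params$ncx$v_max * ca / (ca + params$ncx$k_half)
}

#' Resting membrane potential of the model
#'
#' Root of the total ionic current with all gates at their steady-state
#' values (the Ca2+ concentration does not feed back on the ohmic VGCC
#' current, so the membrane fixed point is independent of Ca).
#'
#' @param params a [model_parameters()] object.
#' @return resting potential, mV.
#' @export
resting_potential <- function(params) {
  m <- params$membrane
  itot <- function(v) {
    g <- hh_gates_inf(v)
    s <- vgcc_gate_inf(v, params)
    m$g_na * g[["m"]]^3 * g[["h"]] * (v - m$e_na) +
      m$g_k * g[["n"]]^4 * (v - m$e_k) +
      m$g_leak * (v - m$e_leak) +
      params$vgcc$g_ca * s * (v - params$vgcc$e_ca)
  }
  stats::uniroot(itot, lower = -90, upper = -40, tol = 1e-12)$root
}

## ---- stimulus protocols ----

#' Define a stimulation protocol
#'
#' @param kind `"none"`, `"single_pulse"` or `"spike_train"`.
#' @param pulse_amplitude injected current, uA/cm2.
#' @param pulse_duration pulse width, ms.
#' @param train_frequency spike-train frequency, Hz (spike_train only).
#' @param train_duration spike-train duration, ms (spike_train only);
#'   the experiment of interest uses 20 Hz over 400 ms, i.e. 8 pulses.
#' @param onset time of the first pulse, ms.
#' @return An object of class `stimulus_protocol` carrying the pulse
#'   schedule (`pulse_starts`).
#' @export
stimulus_protocol <- function(kind = c("none", "single_pulse", "spike_train"),
                              pulse_amplitude = 10, pulse_duration = 2,
                              train_frequency = 20, train_duration = 400,
                              onset = 20) {
  kind <- match.arg(kind)
  starts <- switch(kind,
    none = numeric(0),
    single_pulse = onset,
    spike_train = {
      if (train_frequency <= 0 || train_duration <= 0)
        stop("spike_train needs positive frequency and duration")
      isi <- 1000 / train_frequency
      n <- floor(train_duration / isi)
      onset + isi * (seq_len(n) - 1)
    })
  structure(list(kind = kind, pulse_amplitude = pulse_amplitude,
                 pulse_duration = pulse_duration,
                 train_frequency = train_frequency,
                 train_duration = train_duration, onset = onset,
                 pulse_starts = starts),
            class = "stimulus_protocol")
}

## ---- integration ----

presyn_rhs <- function(t, y, parms) {
  p <- parms$params
  i_stim <- parms$i_stim
  v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]; s <- y[5]; ca <- y[6]
  mb <- p$membrane
  r <- hh_rates(v)
  i_na <- mb$g_na * m^3 * h * (v - mb$e_na)
  i_k <- mb$g_k * n^4 * (v - mb$e_k)
  i_l <- mb$g_leak * (v - mb$e_leak)
  i_ca <- p$vgcc$g_ca * s * (v - p$vgcc$e_ca)
  dv <- (i_stim - i_na - i_k - i_l - i_ca) / mb$cm
  dm <- r$am * (1 - m) - r$bm * m
  dh <- r$ah * (1 - h) - r$bh * h
  dn <- r$an * (1 - n) - r$bn * n
  ds <- (vgcc_gate_inf(v, p) - s) / p$vgcc$tau_ms
  j_in <- vgcc_ca_influx(v, s, ca, p) + p$leak_ca$influx
  j_out <- pmca_flux(max(ca, 1e-12), parms$asn, p) + ncx_flux(ca, p)
  list(c(dv, dm, dh, dn, ds, j_in - j_out))
}

#' Simulate presynaptic membrane potential and calcium
#'
#' Integrates the coupled system {V, m, h, n, VGCC gate, Ca} under a
#' stimulation protocol. Square current pulses are handled by integrating
#' piecewise between pulse edges, so the solver never steps across a
#' discontinuity. The initial state is the resting fixed point (membrane
#' at its resting potential, gates at steady state, Ca at the aSN-dependent
#' steady state), so a `"none"` protocol stays flat.
#'
#' @param params a [model_parameters()] object.
#' @param protocol a [stimulus_protocol()].
#' @param asn_conc aSN concentration, uM.
#' @param t_end end time, ms; defaults to cover the protocol plus 150 ms.
#' @param dt_out output sampling interval, ms.
#' @param rtol,atol solver tolerances (lsoda).
#' @return An object of class `presyn_sim`: a data frame with columns
#'   `time_ms`, `voltage_mV`, `m`, `h`, `n`, `s_vgcc`, `ca_uM`, with the
#'   aSN concentration, parameters, protocol and solver diagnostics as
#'   attributes. Integration aborts with an error if Ca becomes
#'   nonpositive.
#' @examples
#' \donttest{
#' p <- model_parameters()
#' sim <- simulate_presynapse(p, stimulus_protocol("single_pulse"), 10)
#' peak_metrics(sim)
#' }
#' @export
simulate_presynapse <- function(params, protocol = stimulus_protocol("none"),
                                asn_conc = 0, t_end = NULL, dt_out = 0.02,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(protocol, "stimulus_protocol"))
  if (asn_conc < 0) stop("asn_conc must be nonnegative")
  if (is.null(t_end)) {
    t_end <- if (length(protocol$pulse_starts))
      max(protocol$pulse_starts) + protocol$pulse_duration + 150 else 200
  }
  if (length(protocol$pulse_starts) &&
      t_end < max(protocol$pulse_starts) + protocol$pulse_duration)
    stop("t_end does not cover the stimulation protocol")

  v0 <- resting_potential(params)
  g0 <- hh_gates_inf(v0)
  y0 <- c(v = v0, m = g0[["m"]], h = g0[["h"]], n = g0[["n"]],
          s = vgcc_gate_inf(v0, params),
          ca = steady_state_ca(params, asn_conc))

  edges <- sort(unique(c(0, t_end,
                         protocol$pulse_starts,
                         protocol$pulse_starts + protocol$pulse_duration)))
  edges <- edges[edges >= 0 & edges <= t_end]
  out <- NULL
  y <- y0
  n_steps <- 0L
  for (i in seq_len(length(edges) - 1)) {
    t0 <- edges[i]; t1 <- edges[i + 1]
    in_pulse <- any(protocol$pulse_starts <= t0 + 1e-9 &
                    t0 + 1e-9 < protocol$pulse_starts + protocol$pulse_duration)
    i_stim <- if (in_pulse) protocol$pulse_amplitude else 0
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    seg <- deSolve::ode(y = y, times = times, func = presyn_rhs,
                        parms = list(params = params, asn = asn_conc,
                                     i_stim = i_stim),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(seg, "istate")[1] < 0)
      stop("ODE solver failed in [", t0, ", ", t1, "] ms; last state: ",
           paste(signif(y, 6), collapse = ", "))
    if (any(seg[, "ca"] <= 0))
      stop("nonpositive Ca encountered during integration; aborted at t = ",
           times[which(seg[, "ca"] <= 0)[1]], " ms")
    y <- seg[nrow(seg), -1]
    n_steps <- n_steps + nrow(seg)
    out <- rbind(out, if (i == 1) seg else seg[-1, , drop = FALSE])
  }
  df <- data.frame(time_ms = out[, "time"], voltage_mV = out[, "v"],
                   m = out[, "m"], h = out[, "h"], n = out[, "n"],
                   s_vgcc = out[, "s"], ca_uM = out[, "ca"])
  structure(df, asn_conc = asn_conc, params = params, protocol = protocol,
            diagnostics = list(rtol = rtol, atol = atol,
                               n_output = n_steps, v_rest = v0),
            class = c("presyn_sim", "data.frame"))
}

#' @export
print.presyn_sim <- function(x, ...) {
  cat(sprintf("Presynaptic simulation: %d points over %.4g ms, aSN = %g uM (%s)\n",
              nrow(x), max(x$time_ms), attr(x, "asn_conc"),
              attr(x, "protocol")$kind))
  cat(sprintf("  Ca range: %.4g - %.4g uM; V range: %.4g - %.4g mV\n",
              min(x$ca_uM), max(x$ca_uM), min(x$voltage_mV),
              max(x$voltage_mV)))
  invisible(x)
}

#' Count action potentials in a simulation
#'
#' Upward crossings of a voltage threshold.
#'
#' @param sim a `presyn_sim`.
#' @param threshold_mV crossing threshold, default 0 mV.
#' @return integer count.
#' @export
count_action_potentials <- function(sim, threshold_mV = 0) {
  above <- sim$voltage_mV > threshold_mV
  sum(diff(above) == 1L) + as.integer(above[1])
}

#' Unstimulated steady-state Ca2+ concentration
#'
#' Root of the net Ca flux at the resting membrane potential: the leak and
#' resting VGCC influx balanced against PMCA and NCX efflux. Because the
#' efflux is strictly increasing in Ca while the influx is constant, the
#' positive root is unique; it is found by bracketed Brent search.
#'
#' @param params a [model_parameters()] object.
#' @param asn_conc aSN concentration, uM.
#' @param verify if `TRUE`, additionally integrate the unstimulated model
#'   for 5 s and require agreement with the algebraic root to 0.1 percent.
#' @return steady-state Ca2+, uM.
#' @export
steady_state_ca <- function(params, asn_conc = 0, verify = FALSE) {
  stopifnot(inherits(params, "model_parameters"))
  if (asn_conc < 0) stop("asn_conc must be nonnegative")
  v_rest <- resting_potential(params)
  s_rest <- vgcc_gate_inf(v_rest, params)
  net <- function(ca) {
    vgcc_ca_influx(v_rest, s_rest, ca, params) + params$leak_ca$influx -
      pmca_flux(ca, asn_conc, params) - ncx_flux(ca, params)
  }
  influx <- vgcc_ca_influx(v_rest, s_rest, 1e-9, params) +
    params$leak_ca$influx
  if (influx <= 0 || net(1e-9) <= 0)
    stop("degenerate system: no effective Ca influx at rest, steady state ",
         "collapses to the zero boundary")
  upper <- 1
  while (net(upper) > 0 && upper < 1e6) upper <- upper * 10
  if (net(upper) > 0)
    stop("no positive steady state: influx exceeds maximal efflux capacity")
  ca_ss <- stats::uniroot(net, lower = 1e-9, upper = upper,
                          tol = 1e-14)$root
  if (verify) {
    sim <- simulate_presynapse(params, stimulus_protocol("none"),
                               asn_conc = asn_conc, t_end = 5000,
                               dt_out = 1)
    ca_end <- sim$ca_uM[nrow(sim)]
    if (abs(ca_end - ca_ss) > 1e-3 * ca_ss)
      stop("long integration (", format(ca_end),
           " uM) disagrees with algebraic steady state (",
           format(ca_ss), " uM) beyond 0.1%")
  }
  ca_ss
}

#' Steady-state Ca2+ across an aSN concentration grid
#'
#' @param params a [model_parameters()] object.
#' @param asn_grid nonnegative, sorted aSN concentrations (uM).
#' @return numeric vector of steady-state Ca (uM), one per grid point;
#'   non-increasing in aSN whenever the fitted activation beta exceeds 1.
#' @export
asn_dose_response <- function(params, asn_grid) {
  if (any(asn_grid < 0)) stop("asn_grid must be nonnegative")
  if (is.unsorted(asn_grid)) stop("asn_grid must be sorted increasing")
  vapply(asn_grid, function(a) steady_state_ca(params, a), numeric(1))
}
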