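#' Synthetic-data generator specifications
#'
#' Each generator is a pure function of its specification, seed included:
#' identical specs give identical output, and every generated object
#' carries its generating parameters (attribute `generating_parameters`)
#' for round-trip recovery tests. The four kinds emulate, in turn,
#' Ca2+-titration activity curves, saturating aSN fold-activation curves,
#' tissue PSI/expression tables with a monotone trend plus off-trend
#' outlier tissues, and indicator-style depolarization traces (baseline,
#' evoked rise, exponential clearance).
#'
#' @param vmax,kd,n Hill-curve generating parameters (rate, uM,
#'   dimensionless).
#' @param noise_sd noise scale: for Hill curves, Gaussian SD as a fraction
#'   of `vmax`; for activation curves, a fraction of the local fold value;
#'   for PSI tables, absolute PSI points; for traces, absolute signal.
#' @param n_points number of concentrations (log-spaced over `conc_range`).
#' @param replicates replicate observations per concentration.
#' @param conc_range concentration range, uM.
#' @param seed mandatory integer RNG seed.
#' @return A `generator_spec` object for the matching `gen_*` function.
#' @name generator_specs
NULL

new_generator_spec <- function(kind, true_parameters, noise_sd, seed, ...) {
  if (is.null(seed) || !is.finite(seed)) stop("a finite integer seed is mandatory")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(c(list(kind = kind, true_parameters = true_parameters,
                   noise_sd = noise_sd, seed = as.integer(seed)),
              list(...)),
            class = "generator_spec")
}

# run expr with a private, seeded RNG stream; global RNG state untouched
with_gen_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @rdname generator_specs
#' @export
hill_curve_spec <- function(vmax = 5, kd = 0.56, n = 1.5, noise_sd = 0.05,
                            n_points = 8, replicates = 1,
                            conc_range = c(0.01, 10), seed) {
  stopifnot(vmax > 0, kd > 0, n > 0, n_points >= 4, replicates >= 1,
            all(conc_range > 0), conc_range[2] > conc_range[1])
  new_generator_spec("hill_curve",
                     list(vmax = vmax, kd = kd, n = n),
                     noise_sd, seed,
                     n_points = n_points, replicates = replicates,
                     conc_range = conc_range)
}

#' Generate a synthetic Ca2+-titration activity curve
#'
#' Hill-equation activities over log-spaced free-Ca concentrations with
#' additive Gaussian noise (`SD = noise_sd * vmax`) and optional
#' replicates.
#'
#' @param spec a [hill_curve_spec()].
#' @return A [titration_curve()] tagged with its generating parameters.
#' @export
gen_hill_curve <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), spec$kind == "hill_curve")
  tp <- spec$true_parameters
  conc <- 10^seq(log10(spec$conc_range[1]), log10(spec$conc_range[2]),
                 length.out = spec$n_points)
  conc <- rep(conc, each = spec$replicates)
  repl <- rep(seq_len(spec$replicates), times = spec$n_points)
  act <- hill_equation(conc, tp$vmax, tp$kd, tp$n)
  act <- with_gen_seed(spec$seed,
    act + stats::rnorm(length(act), sd = spec$noise_sd * tp$vmax))
  out <- titration_curve(conc, act, ligand_name = "Ca2+_free",
                         replicate = repl)
  attr(out, "generating_parameters") <- tp
  out
}

#' @rdname generator_specs
#' @param beta,k_half activation-curve generating parameters.
#' @export
activation_curve_spec <- function(beta = 6, k_half = 1, noise_sd = 0.1,
                                  n_points = 10, replicates = 1,
                                  conc_range = c(0.05, 30), seed) {
  stopifnot(beta >= 0, k_half > 0, n_points >= 4, replicates >= 1,
            all(conc_range > 0), conc_range[2] > conc_range[1])
  new_generator_spec("activation_curve",
                     list(beta = beta, k_half = k_half),
                     noise_sd, seed,
                     n_points = n_points, replicates = replicates,
                     conc_range = conc_range)
}

#' Generate a synthetic aSN fold-activation curve
#'
#' Fold-activation values from the non-essential-activation hyperbola over
#' a zero point plus log-spaced aSN concentrations, with multiplicative
#' Gaussian noise (`SD = noise_sd * FA`); the value at zero activator is
#' centered on 1.
#'
#' @param spec an [activation_curve_spec()].
#' @return A [titration_curve()] of fold values, ligand `"aSN"`.
#' @export
gen_activation_curve <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), spec$kind == "activation_curve")
  tp <- spec$true_parameters
  conc <- c(0, 10^seq(log10(spec$conc_range[1]), log10(spec$conc_range[2]),
                      length.out = spec$n_points - 1))
  conc <- rep(conc, each = spec$replicates)
  repl <- rep(seq_len(spec$replicates), times = spec$n_points)
  fa <- fold_activation_curve(conc, tp$beta, tp$k_half)
  fa <- with_gen_seed(spec$seed,
    fa + stats::rnorm(length(fa), sd = spec$noise_sd * fa))
  fa <- pmax(fa, 0)
  out <- titration_curve(conc, fa, ligand_name = "aSN", replicate = repl)
  attr(out, "generating_parameters") <- tp
  out
}

#' @rdname generator_specs
#' @param n_tissues number of tissues.
#' @param trend direction of the PSI-expression relationship.
#' @param psi_range PSI asymptotes of the logistic trend (low, high).
#' @param expr_range expression range (cRPKM) tissues are drawn from.
#' @param outlier_frac fraction of tissues drawn off-trend
#'   (uniform PSI in \[0, 100\]).
#' @param events names of the splicing-event columns to generate.
#' @param gene name of the expression (binning) gene column.
#' @export
psi_tables_spec <- function(n_tissues = 60,
                            trend = c("increasing", "decreasing"),
                            psi_range = c(10, 90), expr_range = c(0, 190),
                            outlier_frac = 0.05, noise_sd = 5,
                            events = "EX1", gene = "SNCA", seed) {
  trend <- match.arg(trend)
  stopifnot(n_tissues >= 2, outlier_frac >= 0, outlier_frac < 1,
            psi_range[1] >= 0, psi_range[2] <= 100,
            expr_range[1] >= 0, expr_range[2] > expr_range[1])
  new_generator_spec("psi_tables",
                     list(trend = trend, psi_range = psi_range,
                          expr_range = expr_range,
                          outlier_frac = outlier_frac),
                     noise_sd, seed,
                     n_tissues = n_tissues, events = events, gene = gene)
}

# logistic PSI-expression trend used by the generator
psi_trend_function <- function(expr, trend, psi_range, expr_range) {
  mid <- mean(expr_range)
  scale <- diff(expr_range) / 8
  f <- stats::plogis((expr - mid) / scale)
  if (trend == "decreasing") f <- 1 - f
  psi_range[1] + diff(psi_range) * f
}

#' Generate synthetic tissue PSI/expression tables
#'
#' Tissues receive uniform expression levels over `expr_range`; each
#' event's PSI follows a logistic function of expression plus Gaussian
#' noise, clipped to \[0, 100\]. A designated fraction of tissues is drawn
#' off-trend (uniform PSI), emulating outlier tissues.
#'
#' @param spec a [psi_tables_spec()].
#' @return A [psi_expression_tables()] tagged with generating parameters
#'   and the outlier tissue indices.
#' @export
gen_psi_tables <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), spec$kind == "psi_tables")
  tp <- spec$true_parameters
  out <- with_gen_seed(spec$seed, {
    tissues <- sprintf("tissue_%02d", seq_len(spec$n_tissues))
    expr <- stats::runif(spec$n_tissues, tp$expr_range[1], tp$expr_range[2])
    n_out <- round(tp$outlier_frac * spec$n_tissues)
    outliers <- if (n_out > 0) sample(spec$n_tissues, n_out) else integer(0)
    psi <- data.frame(tissue = tissues)
    for (ev in spec$events) {
      v <- psi_trend_function(expr, tp$trend, tp$psi_range, tp$expr_range)
      v <- v + stats::rnorm(spec$n_tissues, sd = spec$noise_sd)
      if (length(outliers))
        v[outliers] <- stats::runif(length(outliers), 0, 100)
      psi[[ev]] <- pmin(pmax(v, 0), 100)
    }
    expression <- data.frame(tissue = tissues, expr)
    names(expression)[2] <- spec$gene
    list(tables = psi_expression_tables(psi, expression),
         outliers = outliers)
  })
  tabs <- out$tables
  attr(tabs, "generating_parameters") <- tp
  attr(tabs, "outlier_tissues") <- out$outliers
  tabs
}

#' @rdname generator_specs
#' @param baseline resting signal level.
#' @param amplitude evoked rise above baseline.
#' @param onset time of the evoked rise (min).
#' @param rise_time linear rise duration (min).
#' @param tau exponential clearance time constant (min).
#' @param t_max trace duration (min).
#' @param dt sampling interval (min).
#' @export
ca_trace_spec <- function(baseline = 0.1, amplitude = 1, onset = 2,
                          rise_time = 0.1, tau = 2, t_max = 14, dt = 0.005,
                          noise_sd = 0, seed) {
  stopifnot(baseline >= 0, amplitude > 0, onset >= 0, rise_time >= 0,
            tau > 0, t_max > onset + rise_time, dt > 0)
  new_generator_spec("ca_trace",
                     list(baseline = baseline, amplitude = amplitude,
                          onset = onset, rise_time = rise_time, tau = tau),
                     noise_sd, seed, t_max = t_max, dt = dt)
}

# continuous noiseless trace: baseline, linear rise, exponential decay
ca_trace_function <- function(t, tp) {
  ifelse(t < tp$onset, tp$baseline,
    ifelse(t < tp$onset + tp$rise_time,
           tp$baseline + tp$amplitude * (t - tp$onset) /
             max(tp$rise_time, .Machine$double.xmin),
           tp$baseline + tp$amplitude *
             exp(-(t - tp$onset - tp$rise_time) / tp$tau)))
}

#' Closed-form area under the noiseless generated trace
#'
#' Exact integral of the continuous baseline/rise/decay trace of
#' [gen_ca_trace()] over an arbitrary window, from the piecewise
#' antiderivative.
#'
#' @param spec a [ca_trace_spec()].
#' @param t_start,t_end integration window (min).
#' @return the exact integral.
#' @export
analytic_trace_auc <- function(spec, t_start = 2, t_end = 12) {
  stopifnot(inherits(spec, "generator_spec"), spec$kind == "ca_trace",
            t_end > t_start)
  tp <- spec$true_parameters
  t1 <- tp$onset; t2 <- tp$onset + tp$rise_time
  seg <- function(a, b, f) if (b > a) f(a, b) else 0
  auc <- tp$baseline * (t_end - t_start)  # baseline under every segment
  # rise above baseline: linear from 0 to amplitude over [t1, t2]
  auc <- auc + seg(max(t_start, t1), min(t_end, t2), function(a, b) {
    r <- tp$rise_time
    tp$amplitude / r * ((b - t1)^2 - (a - t1)^2) / 2
  })
  # decay above baseline: amplitude * exp(-(t - t2)/tau) on [t2, Inf)
  auc + seg(max(t_start, t2), t_end, function(a, b) {
    tp$amplitude * tp$tau * (exp(-(a - t2) / tp$tau) - exp(-(b - t2) / tp$tau))
  })
}

#' Generate a synthetic indicator trace
#'
#' Flat baseline, linear evoked rise at `onset`, exponential clearance
#' with time constant `tau`, sampled at `dt` with optional additive
#' Gaussian noise. The exact area of the noiseless continuous trace over
#' the default 2-12 min window is stored in attribute `analytic_auc`.
#'
#' @param spec a [ca_trace_spec()].
#' @return A [ca_trace()] in minutes.
#' @export
gen_ca_trace <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), spec$kind == "ca_trace")
  tp <- spec$true_parameters
  t <- seq(0, spec$t_max, by = spec$dt)
  sig <- ca_trace_function(t, tp)
  if (spec$noise_sd > 0)
    sig <- with_gen_seed(spec$seed,
                         sig + stats::rnorm(length(sig), sd = spec$noise_sd))
  out <- ca_trace(t, sig, time_unit = "min")
  attr(out, "generating_parameters") <- tp
  attr(out, "analytic_auc") <- analytic_trace_auc(spec)
  out
}
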