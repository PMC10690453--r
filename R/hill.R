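#' Evaluate the Hill equation
#'
#' `v = vmax * C^n / (kd^n + C^n)`, the standard cooperative dose-response
#' form used for the Ca2+ dependence of PMCA ATPase activity.
#'
#' @param conc concentration(s), uM.
#' @param vmax maximal rate.
#' @param kd apparent dissociation constant (uM).
#' @param n Hill coefficient.
#' @return rate(s) on the scale of `vmax`.
#' @export
hill_equation <- function(conc, vmax, kd, n) {
  vmax * conc^n / (kd^n + conc^n)
}

#' Fit the Hill equation to a Ca2+ titration curve
#'
#' Unweighted nonlinear least squares on replicate-level observations
#' (Levenberg-Marquardt via [minpack.lm::nlsLM()]). Starting values are
#' taken from the data (vmax from the maximal activity, kd from the
#' abscissa of half-maximal activity, n = 1); on failure, five jittered
#' restarts are attempted with a fixed internal seed.
#'
#' @param curve a [titration_curve()] with at least 4 distinct
#'   concentrations; activities are assumed background-subtracted.
#' @param fix_n optionally hold the Hill coefficient at this value and
#'   estimate only `vmax` and `kd`.
#' @param weights optional per-observation weights (e.g. `1/sem^2`);
#'   default unweighted.
#' @return An object of class `hill_fit` with elements `vmax`, `kd_app`,
#'   `hill_n`, `standard_errors` (named vector), `residual_norm` (sum of
#'   squared residuals), `converged`, `fixed_n` and `fit` (the underlying
#'   `nls` object, or `NULL` when all starts failed). A fit is flagged
#'   non-converged when the optimizer fails, a parameter leaves its
#'   admissible region, or the kd standard error exceeds 10 times the
#'   estimate (non-identifiable plateau data).
#' @examples
#' tc <- gen_hill_curve(hill_curve_spec(vmax = 5, kd = 0.56, n = 1.5,
#'                                      noise_sd = 0, seed = 1))
#' fit_hill(tc)
#' @export
fit_hill <- function(curve, fix_n = NULL, weights = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  if (length(unique(curve$conc_uM)) < 4)
    stop("at least 4 distinct concentrations are required to fit the Hill equation")
  df <- data.frame(conc = curve$conc_uM, act = curve$activity)

  start <- hill_start(df$conc, df$act)
  lower <- c(vmax = 1e-12, kd = 1e-9, n = 1e-3)
  upper <- c(vmax = Inf, kd = Inf, n = 50)
  if (!is.null(fix_n)) {
    stopifnot(is.numeric(fix_n), fix_n > 0)
    form <- act ~ vmax * conc^fix_n / (kd^fix_n + conc^fix_n)
    start <- start[c("vmax", "kd")]
    lower <- lower[c("vmax", "kd")]
    upper <- upper[c("vmax", "kd")]
  } else {
    form <- act ~ vmax * conc^n / (kd^n + conc^n)
  }

  fit <- try_nls_multistart(form, df, start, lower, upper, weights)
  new_hill_fit(fit, fix_n)
}

hill_start <- function(conc, act) {
  vmax0 <- max(act)
  pos <- conc > 0
  half <- vmax0 / 2
  kd0 <- if (any(pos & act >= half)) {
    min(conc[pos & act >= half])
  } else {
    stats::median(conc[pos])
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- 1
  if (vmax0 <= 0) vmax0 <- 1
  c(vmax = vmax0, kd = kd0, n = 1)
}

# Levenberg-Marquardt with jittered restarts on failure; returns the nls
# object or NULL.
try_nls_multistart <- function(form, df, start, lower, upper,
                               weights = NULL, n_restart = 5) {
  args <- list(form, data = df,
               lower = lower, upper = upper,
               control = minpack.lm::nls.lm.control(maxiter = 500,
                                                    ftol = 1e-15,
                                                    ptol = 1e-15))
  if (!is.null(weights)) args$weights <- weights
  do_fit <- function(st) {
    tryCatch(
      suppressWarnings(do.call(minpack.lm::nlsLM,
                               c(args, list(start = as.list(st))))),
      error = function(e) NULL)
  }
  fit <- do_fit(start)
  if (is.null(fit)) {
    jit <- local({
      set.seed(20260101L)  # internal restart jitter only
      lapply(seq_len(n_restart), function(i)
        start * exp(stats::rnorm(length(start), sd = 0.5)))
    })
    for (st in jit) {
      fit <- do_fit(pmin(pmax(st, lower * 1.01 + 1e-12), 1e6))
      if (!is.null(fit)) break
    }
  }
  fit
}

new_hill_fit <- function(fit, fix_n) {
  if (is.null(fit)) {
    return(structure(list(vmax = NA_real_, kd_app = NA_real_,
                          hill_n = if (is.null(fix_n)) NA_real_ else fix_n,
                          standard_errors = NULL, residual_norm = NA_real_,
                          converged = FALSE, fixed_n = !is.null(fix_n),
                          fit = NULL, message = "all optimizer starts failed"),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, length(cf)), names(cf))
  })
  kd <- unname(cf["kd"])
  converged <- is.finite(kd) && kd > 0 && unname(cf["vmax"]) > 0 &&
    all(is.finite(se)) && se[["kd"]] <= 10 * abs(kd)
  structure(list(
    vmax = unname(cf["vmax"]),
    kd_app = kd,
    hill_n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
    standard_errors = se,
    residual_norm = sum(stats::residuals(fit)^2),
    converged = converged,
    fixed_n = !is.null(fix_n),
    fit = fit,
    message = if (converged) "converged" else "flagged: unstable or non-identifiable fit"
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  vmax   = %.6g\n  Kd_app = %.6g uM\n  n      = %.6g%s\n",
              x$vmax, x$kd_app, x$hill_n, if (x$fixed_n) " (fixed)" else ""))
  if (!is.null(x$standard_errors))
    cat("  SE:", paste(sprintf("%s=%.3g", names(x$standard_errors),
                               x$standard_errors), collapse = ", "), "\n")
  cat(sprintf("  SSR = %.6g\n", x$residual_norm))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(vmax = object$vmax, kd_app = object$kd_app, hill_n = object$hill_n)
}
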