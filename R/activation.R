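#' Fold activation of one titration curve relative to another
#'
#' Divides the (replicate-averaged) treated activity by the basal activity
#' at matched concentrations, as used to express aSN titrations as fold
#' activation of PMCA. Points where the basal activity is not strictly
#' positive give `NA` with a warning.
#'
#' @param basal,treated [titration_curve()] objects on the same
#'   concentration grid (after replicate averaging).
#' @return A [titration_curve()] of dimensionless fold values.
#' @export
compute_fold_activation <- function(basal, treated) {
  stopifnot(inherits(basal, "titration_curve"),
            inherits(treated, "titration_curve"))
  b <- average_replicates(basal)
  t <- average_replicates(treated)
  if (nrow(b) != nrow(t) || any(abs(b$conc_uM - t$conc_uM) >
                                1e-9 * pmax(1, abs(b$conc_uM))))
    stop("basal and treated curves must share the same concentration grid")
  bad <- b$activity <= 0
  ratio <- ifelse(bad, NA_real_, t$activity / b$activity)
  if (any(bad))
    warning(sum(bad), " point(s) with nonpositive basal activity; ",
            "fold activation undefined there (NA)")
  ratio[!is.finite(ratio) & !is.na(ratio)] <- NA_real_
  out <- data.frame(conc_uM = b$conc_uM, activity = ratio)
  out <- out[!is.na(out$activity) | TRUE, , drop = FALSE]
  titration_curve(out$conc_uM[!is.na(out$activity)],
                  out$activity[!is.na(out$activity)],
                  ligand_name = attr(treated, "ligand_name"))
}

#' Non-essential-activation fold-activation curve
#'
#' The general modifier mechanism for a non-essential activator, evaluated
#' at the fixed substrate concentration of the assay, reduces to the
#' two-parameter hyperbola
#' `FA(A) = (1 + beta * A / k_half) / (1 + A / k_half)`,
#' which is exactly 1 at `A = 0` and saturates at `beta`.
#'
#' @param asn_conc activator concentration(s), uM, nonnegative.
#' @param beta maximal fold activation (dimensionless).
#' @param k_half activator concentration of half-maximal effect (uM).
#' @return fold-activation value(s).
#' @export
fold_activation_curve <- function(asn_conc, beta, k_half) {
  (1 + beta * asn_conc / k_half) / (1 + asn_conc / k_half)
}

#' Construct a non-essential activation model
#'
#' @param beta maximal fold activation, `>= 0`.
#' @param k_half half-effect activator concentration (uM), `> 0`.
#' @param basal_rate rate at zero activator (optional; `NA` for
#'   fold-activation-only models).
#' @param standard_errors,residual_norm,converged fit diagnostics
#'   (populated by [fit_activation()]).
#' @return An object of class `activation_model`.
#' @export
activation_model <- function(beta, k_half, basal_rate = NA_real_,
                             standard_errors = NULL,
                             residual_norm = NA_real_, converged = TRUE) {
  stopifnot(is.numeric(beta), beta >= 0, is.numeric(k_half), k_half > 0)
  structure(list(beta = beta, k_half = k_half, basal_rate = basal_rate,
                 standard_errors = standard_errors,
                 residual_norm = residual_norm, converged = converged),
            class = "activation_model")
}

#' @export
print.activation_model <- function(x, ...) {
  cat("Non-essential activation model",
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  beta (max fold) = %.6g\n  k_half          = %.6g uM\n",
              x$beta, x$k_half))
  if (!is.null(x$standard_errors))
    cat("  SE:", paste(sprintf("%s=%.3g", names(x$standard_errors),
                               x$standard_errors), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the non-essential activation model to an aSN titration
#'
#' Fits `FA(A) = (1 + beta*A/k_half) / (1 + A/k_half)` by nonlinear least
#' squares. The input may be a fold-activation curve directly, or a raw
#' activity curve with `basal` supplied, in which case fold activation is
#' computed first. `FA(0) = 1` holds structurally, so no intercept is
#' estimated.
#'
#' @param fold_curve a [titration_curve()] whose abscissa is aSN
#'   concentration (uM) and ordinate is fold activation (dimensionless),
#'   or raw rates if `basal` is given.
#' @param basal optional scalar basal rate, or basal [titration_curve()]
#'   on the same grid, used to convert raw rates to fold activation.
#' @return An [activation_model()] with fit diagnostics. A flat curve
#'   (all fold values within noise of 1) is flagged non-converged because
#'   `k_half` is then unidentifiable.
#' @examples
#' tc <- gen_activation_curve(activation_curve_spec(beta = 6, k_half = 1,
#'                                                  noise_sd = 0, seed = 1))
#' fit_activation(tc)
#' @export
fit_activation <- function(fold_curve, basal = NULL) {
  stopifnot(inherits(fold_curve, "titration_curve"))
  basal_rate <- NA_real_
  if (!is.null(basal)) {
    if (inherits(basal, "titration_curve")) {
      fold_curve <- compute_fold_activation(basal, fold_curve)
    } else {
      stopifnot(is.numeric(basal), basal > 0)
      basal_rate <- basal
      fold_curve <- titration_curve(fold_curve$conc_uM,
                                    fold_curve$activity / basal,
                                    ligand_name = attr(fold_curve, "ligand_name"))
    }
  }
  if (any(fold_curve$activity < 0))
    stop("negative fold-activation values are not admissible")
  df <- data.frame(conc = fold_curve$conc_uM, fa = fold_curve$activity)

  beta0 <- max(df$fa)
  rise <- df$fa > 1 + (beta0 - 1) / 2
  k0 <- if (beta0 > 1 && any(rise & df$conc > 0)) {
    min(df$conc[rise & df$conc > 0])
  } else {
    stats::median(df$conc[df$conc > 0])
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- 1
  start <- c(beta = max(beta0, 1.001), k_half = k0)

  fit <- try_nls_multistart(
    fa ~ (1 + beta * conc / k_half) / (1 + conc / k_half),
    df, start,
    lower = c(beta = 0, k_half = 1e-9),
    upper = c(beta = Inf, k_half = Inf))

  if (is.null(fit)) {
    m <- activation_model(beta = 1, k_half = 1, basal_rate = basal_rate,
                          converged = FALSE)
    m$message <- "all optimizer starts failed"
    return(m)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  # flat curves: beta ~ 1 leaves k_half unidentifiable
  flat <- abs(cf[["beta"]] - 1) < 1e-6 ||
    (is.finite(se[["k_half"]]) && se[["k_half"]] > 10 * cf[["k_half"]]) ||
    any(!is.finite(se))
  activation_model(beta = unname(cf["beta"]), k_half = unname(cf["k_half"]),
                   basal_rate = basal_rate, standard_errors = se,
                   residual_norm = sum(stats::residuals(fit)^2),
                   converged = !flat)
}

#' Evaluate the activation factor of a fitted model
#'
#' @param model an [activation_model()].
#' @param asn_conc aSN concentration(s), uM, nonnegative.
#' @return `FA(asn_conc)`; exactly 1 at zero, approaching `beta` at
#'   saturating concentrations.
#' @export
activation_factor <- function(model, asn_conc) {
  stopifnot(inherits(model, "activation_model"))
  if (any(asn_conc < 0)) stop("asn_conc must be nonnegative")
  fold_activation_curve(asn_conc, model$beta, model$k_half)
}
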