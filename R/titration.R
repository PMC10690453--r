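#' Construct a titration curve
#'
#' A titration curve holds ATPase activity observations as a function of
#' ligand concentration (free Ca2+ or alpha-synuclein, both in uM), with
#' optional replicate structure and per-point SEM. It is the common input to
#' [fit_hill()], [fit_activation()] and [compute_fold_activation()].
#'
#' @param concentrations numeric vector of ligand concentrations (uM),
#'   nonnegative, one per observation.
#' @param activities numeric vector of rates (nmol Pi/ug/min) or, for
#'   fold-activation curves, dimensionless fold values; same length as
#'   `concentrations`.
#' @param ligand_name label for the titrated species, e.g. `"Ca2+_free"`
#'   or `"aSN"`.
#' @param replicate optional replicate identifier per observation.
#' @param sem optional standard error of the mean per observation.
#' @return An object of class `titration_curve`: a data frame with columns
#'   `conc_uM`, `activity` and optionally `replicate`, `sem`, plus a
#'   `ligand_name` attribute.
#' @examples
#' tc <- titration_curve(c(0.1, 0.3, 1, 3), c(1.2, 2.8, 4.1, 4.8))
#' @export
titration_curve <- function(concentrations, activities,
                            ligand_name = "Ca2+_free",
                            replicate = NULL, sem = NULL) {
  concentrations <- as.numeric(concentrations)
  activities <- as.numeric(activities)
  if (length(concentrations) != length(activities))
    stop("`concentrations` and `activities` must have the same length")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and nonnegative")
  if (any(!is.finite(activities)))
    stop("activities must be finite")
  df <- data.frame(conc_uM = concentrations, activity = activities)
  if (!is.null(replicate)) {
    if (length(replicate) != nrow(df))
      stop("`replicate` must match the number of observations")
    df$replicate <- replicate
  }
  if (!is.null(sem)) {
    if (length(sem) != nrow(df))
      stop("`sem` must match the number of observations")
    df$sem <- as.numeric(sem)
  }
  structure(df,
            ligand_name = as.character(ligand_name)[1],
            class = c("titration_curve", "data.frame"))
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("Titration curve:", attr(x, "ligand_name"),
      sprintf("(%d observations, %d distinct concentrations)\n",
              nrow(x), length(unique(x$conc_uM))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a titration curve from a delimited file
#'
#' Expects header columns `conc_uM` and `activity`, with optional
#' `replicate` and `sem` columns. The delimiter is sniffed from the file
#' extension (`.csv` -> comma, otherwise tab).
#'
#' @param path file path.
#' @param ligand_name label for the titrated species.
#' @return A [titration_curve()].
#' @export
read_titration <- function(path, ligand_name = "Ca2+_free") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("conc_uM", "activity") %in% names(df)))
    stop("input must have `conc_uM` and `activity` columns: ", path)
  titration_curve(df$conc_uM, df$activity, ligand_name = ligand_name,
                  replicate = df$replicate, sem = df$sem)
}

#' Write a titration curve to a delimited file
#'
#' @param curve a [titration_curve()].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_titration <- function(curve, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(curve), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# average replicates onto the distinct concentration grid
average_replicates <- function(curve) {
  agg <- stats::aggregate(activity ~ conc_uM, data = as.data.frame(curve),
                          FUN = mean)
  agg[order(agg$conc_uM), , drop = FALSE]
}
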