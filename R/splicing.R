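#' Tissue-level PSI and expression tables
#'
#' Pairs a tissue x splicing-event table of percent-spliced-in (PSI)
#' values with a tissue x gene expression table (cRPKM), as exported from
#' VastDB-style resources. Tissues are matched by the shared `tissue`
#' column; PSI values may be missing (event not covered in a tissue).
#'
#' @param psi data frame with a `tissue` column and one numeric column per
#'   splicing event (PSI, 0-100, `NA` allowed).
#' @param expression data frame with a `tissue` column and one numeric
#'   column per gene (cRPKM, nonnegative).
#' @return An object of class `psi_expression_tables` restricted to the
#'   shared tissues.
#' @export
psi_expression_tables <- function(psi, expression) {
  for (tab in list(psi, expression))
    if (!is.data.frame(tab) || !"tissue" %in% names(tab))
      stop("both tables need a `tissue` column")
  shared <- intersect(psi$tissue, expression$tissue)
  if (!length(shared)) stop("no shared tissues between the two tables")
  psi <- psi[match(shared, psi$tissue), , drop = FALSE]
  expression <- expression[match(shared, expression$tissue), , drop = FALSE]
  pv <- as.matrix(psi[setdiff(names(psi), "tissue")])
  if (any(pv < 0 | pv > 100, na.rm = TRUE))
    stop("PSI values must lie in [0, 100]")
  ev <- as.matrix(expression[setdiff(names(expression), "tissue")])
  if (any(ev < 0, na.rm = TRUE)) stop("expression values must be nonnegative")
  structure(list(psi = psi, expression = expression, tissues = shared),
            class = "psi_expression_tables")
}

#' Read a flattened PSI/expression export
#'
#' One TSV with tissues as rows: a `tissue` column, PSI columns for the
#' named events and cRPKM columns for the named genes.
#'
#' @param path TSV path.
#' @param events character vector of event column names.
#' @param genes character vector of gene column names.
#' @return A [psi_expression_tables()].
#' @export
read_psi_expression <- function(path, events, genes) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("tissue", events, genes), names(df))
  if (length(missing))
    stop("columns missing from ", path, ": ", paste(missing, collapse = ", "))
  psi_expression_tables(df[c("tissue", events)], df[c("tissue", genes)])
}

#' Mean PSI per expression interval
#'
#' Assigns each tissue to an expression interval of the chosen gene and
#' averages each event's non-missing PSI within every interval — the mean
#' exon inclusion as a function of expression level. Intervals are
#' left-closed/right-open `[a, a + w)`; tissues at or above the last edge
#' fall into a separately flagged overflow bin.
#'
#' @param tables a [psi_expression_tables()].
#' @param gene gene column (in the expression table) defining the binning
#'   axis.
#' @param events event columns (in the PSI table) to summarise; default
#'   all.
#' @param edges strictly increasing interval boundaries; default
#'   `seq(0, 190, 10)`, i.e. intervals of width 10 from 0 to 190.
#' @return An object of class `binned_psi`: a data frame with columns
#'   `event`, `bin_lo`, `bin_hi`, `bin_mid`, `mean_psi`, `n_tissues`,
#'   `overflow`; empty bins have `NA` mean and count 0.
#' @examples
#' tabs <- gen_psi_tables(psi_tables_spec(seed = 1))
#' head(bin_psi_by_expression(tabs, gene = "SNCA"))
#' @export
bin_psi_by_expression <- function(tables, gene, events = NULL,
                                  edges = seq(0, 190, by = 10)) {
  stopifnot(inherits(tables, "psi_expression_tables"))
  if (!gene %in% names(tables$expression))
    stop("gene `", gene, "` not in the expression table")
  if (is.null(events)) events <- setdiff(names(tables$psi), "tissue")
  missing <- setdiff(events, names(tables$psi))
  if (length(missing))
    stop("events not in the PSI table: ", paste(missing, collapse = ", "))
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")

  expr <- tables$expression[[gene]]
  keep <- !is.na(expr) & expr >= edges[1]
  expr <- expr[keep]
  # findInterval with left-closed bins; index length(edges) = overflow
  bin <- findInterval(expr, edges)

  n_bins <- length(edges)  # last index is the overflow bin [max(edges), Inf)
  rows <- lapply(events, function(ev) {
    psi <- tables$psi[[ev]][keep]
    ok <- !is.na(psi)
    if (!any(ok))
      warning("event `", ev, "` has no non-missing PSI values")
    means <- rep(NA_real_, n_bins)
    counts <- integer(n_bins)
    if (any(ok)) {
      agg <- tapply(psi[ok], bin[ok], mean)
      cnt <- table(bin[ok])
      idx <- as.integer(names(agg))
      means[idx] <- as.numeric(agg)
      counts[idx] <- as.integer(cnt)
    }
    data.frame(event = ev,
               bin_lo = edges,
               bin_hi = c(edges[-1], Inf),
               bin_mid = c((edges[-1] + edges[-n_bins]) / 2, edges[n_bins]),
               mean_psi = means,
               n_tissues = counts,
               overflow = c(rep(FALSE, n_bins - 1), TRUE))
  })
  structure(do.call(rbind, rows), edges = edges, gene = gene,
            class = c("binned_psi", "data.frame"))
}

#' Rank-correlation trend of binned PSI versus expression
#'
#' Spearman rank correlation between interval midpoint and mean PSI across
#' populated (non-overflow) intervals, one summary per event; quantifies
#' whether exon inclusion rises or falls with expression of the binning
#' gene.
#'
#' @param binned a [bin_psi_by_expression()] result.
#' @return Data frame with columns `event`, `spearman_rho`, `n_bins`,
#'   `defined`. Events with fewer than 3 populated bins get `NA` rho and
#'   `defined = FALSE`; constant bin means give rho 0.
#' @export
psi_expression_trend <- function(binned) {
  stopifnot(inherits(binned, "binned_psi"))
  events <- unique(binned$event)
  out <- lapply(events, function(ev) {
    d <- binned[binned$event == ev & !binned$overflow &
                  !is.na(binned$mean_psi), , drop = FALSE]
    n <- nrow(d)
    rho <- if (n < 3) {
      NA_real_
    } else if (stats::sd(d$mean_psi) == 0) {
      0  # all-tied means carry no trend
    } else {
      stats::cor(d$bin_mid, d$mean_psi, method = "spearman")
    }
    data.frame(event = ev, spearman_rho = rho, n_bins = n, defined = n >= 3)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
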