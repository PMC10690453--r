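#' Construct a chelator buffer system
#'
#' Describes the composition of an ATPase assay buffer whose free Ca2+
#' concentration is set by EGTA/ATP/Mg equilibria (the situation handled by
#' Maxchelator-style calculators): total Ca, Mg, EGTA and ATP together with
#' a table of apparent association constants at the assay pH and
#' temperature.
#'
#' @param total_ca total calcium, uM.
#' @param total_mg total magnesium, mM.
#' @param total_egta total EGTA, mM.
#' @param total_atp total ATP, mM.
#' @param ph assay pH (metadata; constants must already be apparent
#'   constants at this pH).
#' @param temperature_C assay temperature (metadata, as for `ph`).
#' @param constants data frame with columns `species` (one of `CaEGTA`,
#'   `MgEGTA`, `CaATP`, `MgATP`), `logK_apparent` (log10 of the apparent
#'   association constant, M^-1), `ph`, `temperature_C`. Defaults to the
#'   packaged table for pH 7.2, 37 C.
#' @return An object of class `buffer_system`.
#' @examples
#' buf <- buffer_system(total_ca = 900, total_mg = 3, total_egta = 1,
#'                      total_atp = 3)
#' compute_free_ca(buf)
#' @export
buffer_system <- function(total_ca, total_mg = 0, total_egta = 0,
                          total_atp = 0, ph = 7.2, temperature_C = 37,
                          constants = default_chelator_constants()) {
  tot <- c(total_ca, total_mg, total_egta, total_atp)
  if (any(!is.finite(tot)) || any(tot < 0))
    stop("all totals must be finite and nonnegative")
  validate_constants(constants, total_mg > 0, total_egta > 0, total_atp > 0)
  structure(list(total_ca = total_ca, total_mg = total_mg,
                 total_egta = total_egta, total_atp = total_atp,
                 ph = ph, temperature_C = temperature_C,
                 constants = constants),
            class = "buffer_system")
}

validate_constants <- function(constants, need_mg, need_egta, need_atp) {
  req <- c("species", "logK_apparent")
  if (!is.data.frame(constants) || !all(req %in% names(constants)))
    stop("`constants` must be a data frame with columns species, logK_apparent")
  if (any(!is.finite(constants$logK_apparent)))
    stop("association constants must be finite")
  need <- character(0)
  if (need_egta) need <- c(need, "CaEGTA")
  if (need_egta && need_mg) need <- c(need, "MgEGTA")
  if (need_atp) need <- c(need, "CaATP")
  if (need_atp && need_mg) need <- c(need, "MgATP")
  missing <- setdiff(need, constants$species)
  if (length(missing))
    stop("missing association constants for: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Packaged apparent association constants
#'
#' Apparent (pH- and temperature-corrected) log10 association constants for
#' the Ca/Mg/EGTA/ATP system at pH 7.2 and 37 C, of the magnitudes used by
#' Maxchelator-style free-calcium calculators built on critically reviewed
#' stability constants. Constants are data, not code: supply your own table
#' to [buffer_system()] for other conditions.
#'
#' @return Data frame with columns `species`, `logK_apparent`, `ph`,
#'   `temperature_C`.
#' @export
default_chelator_constants <- function() {
  path <- system.file("extdata", "chelator_constants.csv",
                      package = "pmcasyn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# association constants (M^-1) keyed by species; absent species -> 0
constants_lookup <- function(buffer) {
  k <- stats::setNames(rep(0, 4), c("CaEGTA", "MgEGTA", "CaATP", "MgATP"))
  tab <- buffer$constants
  for (sp in intersect(names(k), tab$species))
    k[sp] <- 10^tab$logK_apparent[match(sp, tab$species)]
  k
}

# Free ligand concentrations (M) given free metals (M); explicit because
# each ligand binds independently of the other.
free_ligands <- function(ca_f, mg_f, totals, k) {
  list(egta = totals$egta / (1 + k["CaEGTA"] * ca_f + k["MgEGTA"] * mg_f),
       atp  = totals$atp  / (1 + k["CaATP"] * ca_f + k["MgATP"] * mg_f))
}

# free Mg (M) given free Ca (M): 1-D root of the Mg mass balance,
# monotone in mg_f
solve_free_mg <- function(ca_f, totals, k) {
  if (totals$mg <= 0) return(0)
  bal <- function(mg_f) {
    lf <- free_ligands(ca_f, mg_f, totals, k)
    totals$mg - mg_f * (1 + k["MgEGTA"] * lf$egta + k["MgATP"] * lf$atp)
  }
  if (bal(totals$mg) >= 0) return(totals$mg)  # nothing bound
  r <- stats::uniroot(function(lg) bal(10^lg),
                      lower = log10(totals$mg) - 15,
                      upper = log10(totals$mg),
                      tol = 1e-13)
  10^r$root
}

#' Free calcium concentration of a buffer system
#'
#' Solves the coupled mass-action equilibria Ca-EGTA, Mg-EGTA, Ca-ATP and
#' Mg-ATP under total-mass conservation of Ca, Mg, EGTA and ATP, and
#' returns the free Ca2+ concentration. Because each ligand's free
#' concentration is an explicit function of the two free metals, the
#' system reduces to nested one-dimensional root searches (Brent's method
#' in log space), which are monotone and hence globally convergent.
#'
#' @param buffer a [buffer_system()].
#' @param full if `TRUE`, return all species concentrations and the
#'   mass-balance residuals instead of just free Ca.
#' @return Free Ca2+ in uM, or (with `full = TRUE`) a list with free
#'   species (uM for Ca, mM otherwise) and relative mass-balance
#'   residuals. Relative residuals are checked to be below 1e-9.
#' @export
compute_free_ca <- function(buffer, full = FALSE) {
  stopifnot(inherits(buffer, "buffer_system"))
  totals <- list(ca = buffer$total_ca * 1e-6, mg = buffer$total_mg * 1e-3,
                 egta = buffer$total_egta * 1e-3, atp = buffer$total_atp * 1e-3)
  k <- constants_lookup(buffer)

  if (totals$ca == 0 || (totals$egta == 0 && totals$atp == 0)) {
    # nothing binds Ca: free equals total, exactly
    free <- buffer$total_ca
    if (!full) return(free)
    mg_f <- solve_free_mg(free * 1e-6, totals, k)
    lf <- free_ligands(free * 1e-6, mg_f, totals, k)
    return(list(free_ca_uM = free, free_mg_mM = mg_f * 1e3,
                free_egta_mM = lf$egta * 1e3, free_atp_mM = lf$atp * 1e3,
                bound = list(ca_egta_mM = 0, mg_egta_mM = 0,
                             ca_atp_mM = 0, mg_atp_mM = 0),
                residuals = c(ca = 0, mg = 0, egta = 0, atp = 0)))
  } else {
    bal <- function(ca_f) {
      mg_f <- solve_free_mg(ca_f, totals, k)
      lf <- free_ligands(ca_f, mg_f, totals, k)
      totals$ca - ca_f * (1 + k["CaEGTA"] * lf$egta + k["CaATP"] * lf$atp)
    }
    r <- stats::uniroot(function(lg) bal(10^lg),
                        lower = log10(totals$ca) - 15,
                        upper = log10(totals$ca),
                        tol = 1e-13, maxiter = 200)
    ca_f <- 10^r$root
    if (!is.finite(ca_f) || ca_f <= 0)
      stop("free-Ca root search failed to converge; bracketing [",
           format(totals$ca * 1e-15), ", ", format(totals$ca), "] M")
  }

  mg_f <- solve_free_mg(ca_f, totals, k)
  lf <- free_ligands(ca_f, mg_f, totals, k)
  res <- mass_balance_residuals(ca_f, mg_f, lf, totals, k)
  if (max(res) > 1e-9)
    stop("mass-balance residual above tolerance: ", format(max(res)))
  if (!full) return(ca_f * 1e6)
  list(free_ca_uM = ca_f * 1e6, free_mg_mM = mg_f * 1e3,
       free_egta_mM = lf$egta * 1e3, free_atp_mM = lf$atp * 1e3,
       bound = list(ca_egta_mM = k["CaEGTA"] * ca_f * lf$egta * 1e3,
                    mg_egta_mM = k["MgEGTA"] * mg_f * lf$egta * 1e3,
                    ca_atp_mM = k["CaATP"] * ca_f * lf$atp * 1e3,
                    mg_atp_mM = k["MgATP"] * mg_f * lf$atp * 1e3),
       residuals = res)
}

# relative conservation errors for each species with nonzero total
mass_balance_residuals <- function(ca_f, mg_f, lf, totals, k) {
  rel <- function(total, recon) if (total > 0) abs(total - recon) / total else 0
  c(ca = rel(totals$ca,
             ca_f * (1 + k["CaEGTA"] * lf$egta + k["CaATP"] * lf$atp)),
    mg = rel(totals$mg,
             mg_f * (1 + k["MgEGTA"] * lf$egta + k["MgATP"] * lf$atp)),
    egta = rel(totals$egta,
               lf$egta * (1 + k["CaEGTA"] * ca_f + k["MgEGTA"] * mg_f)),
    atp = rel(totals$atp,
              lf$atp * (1 + k["CaATP"] * ca_f + k["MgATP"] * mg_f)))
}

#' Total calcium needed for a target free concentration
#'
#' Inverts [compute_free_ca()]: given a buffer composition without its
#' calcium ("CaCl2 to be added"), finds the total Ca giving the desired
#' free Ca2+ — the quantity pipetted when setting assay free-calcium
#' set-points such as 60 nM or 1.8 uM.
#'
#' @param buffer_without_ca a [buffer_system()]; its `total_ca` is ignored.
#' @param target_free_ca desired free Ca2+, uM, `> 0`.
#' @return Total Ca (uM) whose forward solution reproduces the target to
#'   within 0.1 percent relative.
#' @export
invert_free_ca <- function(buffer_without_ca, target_free_ca) {
  stopifnot(inherits(buffer_without_ca, "buffer_system"),
            is.numeric(target_free_ca), target_free_ca > 0)
  b <- buffer_without_ca
  # upper bound: target free plus every chelator molecule Ca-loaded
  upper <- target_free_ca + (b$total_egta + b$total_atp) * 1e3 + 1
  f <- function(total_ca) {
    b$total_ca <- total_ca
    compute_free_ca(b) - target_free_ca
  }
  r <- stats::uniroot(f, lower = target_free_ca * (1 - 1e-12), upper = upper,
                      tol = target_free_ca * 1e-8, extendInt = "upX",
                      maxiter = 200)
  total <- r$root
  b$total_ca <- total
  achieved <- compute_free_ca(b)
  if (abs(achieved - target_free_ca) > 1e-3 * target_free_ca)
    stop("target free Ca unattainable to 0.1%: achieved ",
         format(achieved), " uM for target ", format(target_free_ca), " uM")
  total
}
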