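#' Cooperativity of tandem phosphosites from site and tandem energies
#'
#' For a doubly phosphorylated (tandem) peptide, compares the Gibbs
#' energy of the high-affinity tandem binding event with the sum of the
#' two single-site energies:
#' `ddG = dG_tandem - (dG_siteA + dG_siteB)`. Under strict additivity
#' `ddG = 0`; `ddG > tol` means the tandem interaction is less than
#' additive (negatively cooperative), `ddG < -tol` more than additive
#' (positively cooperative). All energies must be in kJ/mol at the same
#' temperature.
#'
#' @param dG_A,dG_B Single-site Gibbs energies (kJ/mol).
#' @param dG_AB Tandem-peptide Gibbs energy (kJ/mol).
#' @param tol Additivity tolerance in kJ/mol (default 1.0, roughly the
#'   fit-error scale of calorimetric energies here).
#' @return An object of class `"coop_summary"`: the three energies,
#'   `ddG_coop`, `tol` and `classification` (one of
#'   `"positively cooperative"`, `"additive"`,
#'   `"negatively cooperative (less than additive)"`).
#' @examples
#' cooperativity(-26.7, -34.6, -44.7)  # ddG = +16.6, less than additive
#' @export
cooperativity <- function(dG_A, dG_B, dG_AB, tol = 1.0) {
  stopifnot(is.finite(dG_A), is.finite(dG_B), is.finite(dG_AB), tol >= 0)
  ddG <- dG_AB - (dG_A + dG_B)
  classification <- if (ddG < -tol) {
    "positively cooperative"
  } else if (ddG > tol) {
    "negatively cooperative (less than additive)"
  } else {
    "additive"
  }
  structure(
    list(dG_siteA = dG_A, dG_siteB = dG_B, dG_tandem = dG_AB,
         ddG_coop = ddG, tol = tol, classification = classification),
    class = "coop_summary"
  )
}

#' @export
print.coop_summary <- function(x, ...) {
  cat(sprintf(
    "<coop_summary> ddG = %+.1f kJ/mol (tandem %.1f vs sum %.1f): %s\n",
    x$ddG_coop, x$dG_tandem, x$dG_siteA + x$dG_siteB, x$classification))
  invisible(x)
}

#' Fold enhancement in affinity between two dissociation constants
#'
#' Ratio `Kd_reference / Kd_enhanced`; a value above 1 means the
#' "enhanced" interaction is tighter. Optionally rounded to a number of
#' significant figures for reporting (e.g. a 204-fold enhancement
#' reported as ~200-fold at one significant figure).
#'
#' @param Kd_reference,Kd_enhanced Dissociation constants (molar,
#'   positive).
#' @param sig_figs Optional significant figures for rounding.
#' @return The (optionally rounded) fold ratio.
#' @examples
#' fold_enhancement(10.2e-6, 5.0e-8, sig_figs = 1)  # 200
#' @export
fold_enhancement <- function(Kd_reference, Kd_enhanced, sig_figs = NULL) {
  stopifnot(Kd_reference > 0, Kd_enhanced > 0)
  ratio <- Kd_reference / Kd_enhanced
  if (!is.null(sig_figs)) ratio <- signif(ratio, sig_figs)
  ratio
}

#' Cross-technique concordance table of dissociation constants
#'
#' Collects per-peptide affinities measured by different techniques (FA,
#' ITC, SPR, ...) into one row per peptide, flags lower-bound-only
#' entries (non-saturating titrations, reported as "> value"), and
#' computes the maximum pairwise fold-difference among the available
#' point estimates. The fold-difference is reported, not judged: it
#' quantifies how far the orthogonal techniques agree.
#'
#' @param fits Data frame with columns `peptide_id`, `technique`, `Kd`
#'   (molar) and optionally `lower_bound` (logical; `TRUE` marks a
#'   "Kd greater than" entry).
#' @return A data frame with one row per peptide: one `Kd_<technique>`
#'   column per technique present (NA when not measured), a matching
#'   `bound_<technique>` flag column, and `max_fold_diff` (NA when fewer
#'   than two point estimates exist).
#' @export
concordance_table <- function(fits) {
  need <- c("peptide_id", "technique", "Kd")
  if (!all(need %in% names(fits))) {
    stop("fits must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(fits$lower_bound)) fits$lower_bound <- FALSE
  techniques <- unique(fits$technique)
  rows <- lapply(split(fits, fits$peptide_id), function(df) {
    row <- data.frame(peptide_id = df$peptide_id[1],
                      stringsAsFactors = FALSE)
    for (tech in techniques) {
      sel <- df$technique == tech
      row[[paste0("Kd_", tech)]] <-
        if (any(sel)) df$Kd[sel][1] else NA_real_
      row[[paste0("bound_", tech)]] <-
        if (any(sel)) isTRUE(df$lower_bound[sel][1]) else NA
    }
    pts <- df$Kd[!df$lower_bound & is.finite(df$Kd)]
    row$max_fold_diff <-
      if (length(pts) >= 2) max(pts) / min(pts) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gibbs-energy table from a set of dissociation constants
#'
#' Applies [delta_g()] to every entry of a named `Kd` map, carrying
#' lower-bound flags through: a "Kd greater than" entry yields a
#' "dG greater than" (i.e. weaker-than) bound. Energies are reported in
#' kJ/mol; the printed table shows one decimal place.
#'
#' @param kd Named numeric vector of dissociation constants (molar), or a
#'   data frame with columns `peptide_id`, `Kd` and optionally
#'   `lower_bound`.
#' @param T Temperature (kelvin, default 298.15).
#' @return A data frame of class `"delta_g_table"` with `peptide_id`,
#'   `Kd_M`, `dG_kJmol` and `lower_bound`.
#' @examples
#' delta_g_table(c(pSer367 = 870e-9, pSer342 = 21e-6))
#' @export
delta_g_table <- function(kd, T = 298.15) {
  if (is.data.frame(kd)) {
    df <- data.frame(peptide_id = kd$peptide_id, Kd_M = kd$Kd,
                     lower_bound = isTRUE_vec(kd$lower_bound, nrow(kd)),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      peptide_id = if (is.null(names(kd))) as.character(seq_along(kd))
                   else names(kd),
      Kd_M = as.numeric(kd), lower_bound = FALSE,
      stringsAsFactors = FALSE)
  }
  df$dG_kJmol <- delta_g(df$Kd_M, T = T)
  class(df) <- c("delta_g_table", "data.frame")
  df[, c("peptide_id", "Kd_M", "dG_kJmol", "lower_bound")]
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(FALSE, n) else as.logical(x)
}

#' @export
print.delta_g_table <- function(x, ...) {
  shown <- data.frame(
    peptide_id = x$peptide_id,
    Kd = sprintf("%s%.3g M", ifelse(x$lower_bound, "> ", ""), x$Kd_M),
    dG = sprintf("%s%.1f kJ/mol", ifelse(x$lower_bound, "> ", ""),
                 x$dG_kJmol),
    stringsAsFactors = FALSE
  )
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
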