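#' Describe an ITC experiment (schedule, concentrations, heats)
#'
#' Container for a peptide-into-protein titration on a single-cell
#' calorimeter. Heats may be left `NULL` at construction (the forward
#' model fills them in) or supplied as integrated per-injection heats in
#' microjoules (`"uJ"`) or microcalories (`"ucal"`).
#'
#' @param cell_volume Working cell volume V0 in litres.
#' @param cell_conc Protein concentration in the cell (molar, monomer
#'   convention).
#' @param syringe_conc Peptide concentration in the syringe (molar); must
#'   exceed `cell_conc`.
#' @param injection_volumes Injection volumes in litres (>= 10
#'   injections).
#' @param heats Optional integrated injection heats (same length as
#'   `injection_volumes`).
#' @param T Temperature (kelvin, default 298.15).
#' @param heat_unit `"uJ"` (default) or `"ucal"`.
#' @return An object of class `"itc_experiment"`.
#' @export
itc_experiment <- function(cell_volume, cell_conc, syringe_conc,
                           injection_volumes, heats = NULL, T = 298.15,
                           heat_unit = c("uJ", "ucal")) {
  heat_unit <- match.arg(heat_unit)
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > cell_conc,
            length(injection_volumes) >= 10L, all(injection_volumes > 0),
            T > 0)
  if (!is.null(heats) && length(heats) != length(injection_volumes)) {
    stop("heats must have one entry per injection")
  }
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = injection_volumes, heats = heats, T = T,
         heat_unit = heat_unit),
    class = "itc_experiment"
  )
}

# per-injection cell concentrations after the perfusion (constant-volume)
# dilution bookkeeping: each injection of volume dV displaces dV of mixed
# cell content, diluting everything already present by (1 - dV/V0)
.itc_cell_conc <- function(exp) {
  V0 <- exp$cell_volume
  nI <- length(exp$injection_volumes)
  P <- numeric(nI)
  L <- numeric(nI)
  p <- exp$cell_conc
  l <- 0
  for (i in seq_len(nI)) {
    f <- 1 - exp$injection_volumes[i] / V0
    p <- p * f
    l <- l * f + exp$syringe_conc * exp$injection_volumes[i] / V0
    P[i] <- p
    L[i] <- l
  }
  list(P = P, L = L)
}

# cumulative molar ratio of peptide to protein in the cell
.itc_molar_ratio <- function(exp) {
  cc <- .itc_cell_conc(exp)
  cc$L / cc$P
}

# heat conversion factors to/from the experiment's unit (internal unit J)
.heat_to_J <- c(uJ = 1e-6, ucal = 4.184e-6)

#' One-set-of-sites ITC forward model
#'
#' Predicts per-injection heats for a single class of identical binding
#' sites. For each injection the cell protein and accumulated peptide are
#' diluted by the constant-volume displacement factor `(1 - dV/V0)`, the
#' new peptide from the syringe is added, the bound-complex concentration
#' is computed exactly via [bound_ligand_quadratic()] with site
#' concentration `n * [protein]`, and the heat is `dH` times the moles of
#' complex formed during the injection, including the material expelled
#' with the displaced volume (mean-concentration convention:
#' `formed_i = V0 (B_i - B_{i-1}) + dV_i (B_i + B_{i-1})/2`).
#'
#' @param params List with `Kd` (molar), `dH` (kJ per mol of peptide
#'   bound) and `n` (sites per cell protein molecule).
#' @param exp An [itc_experiment()].
#' @return Predicted heats per injection, in the experiment's heat unit.
#' @export
itc_forward <- function(params, exp) {
  stopifnot(inherits(exp, "itc_experiment"))
  Kd <- params$Kd; dH <- params$dH; n <- params$n
  stopifnot(Kd > 0, is.finite(dH), n > 0)
  V0 <- exp$cell_volume
  cc <- .itc_cell_conc(exp)
  nI <- length(exp$injection_volumes)
  q <- numeric(nI)
  B_prev <- 0
  for (i in seq_len(nI)) {
    X <- n * cc$P[i]
    L <- cc$L[i]
    B <- if (L <= 0 || X <= 0) 0 else bound_ligand_quadratic(Kd, X, L)
    dV <- exp$injection_volumes[i]
    formed <- V0 * (B - B_prev) + dV * (B + B_prev) / 2
    q[i] <- dH * 1000 * formed   # kJ/mol * mol -> J
    B_prev <- B
  }
  q / .heat_to_J[[exp$heat_unit]]
}

#' Fit the one-set-of-sites model to ITC injection heats
#'
#' Levenberg-Marquardt least squares with `log10(Kd)`, `dH` and `n` free,
#' followed by the thermodynamic decomposition `dG = RT ln(Kd)` and
#' `-TdS = dG - dH` (an exact identity of the fit, not an independent
#' measurement). The Wiseman `c`-value `n * [cell] / Kd` controls how well
#' the affinity is determined; a classed warning
#' (`"phosphofit_c_value_warning"`) is raised outside the reliable window
#' `[1, 1000]`.
#'
#' @param exp An [itc_experiment()] with heats.
#' @param discard_first Drop the first injection before fitting (common
#'   practice when the first injection is anomalous; default `FALSE`).
#' @return An object of class `"itc_fit"`: `Kd` (molar) with `Kd_se`,
#'   `dH` (kJ/mol) with `dH_se`, `n` with `n_se`, derived `dG` and
#'   `minus_TdS` (kJ/mol), `c_value`, and `residual_sd` (heat units).
#' @export
fit_itc <- function(exp, discard_first = FALSE) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (is.null(exp$heats)) stop("experiment carries no heats to fit")
  keep <- seq_along(exp$heats)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 10L) stop("need at least 10 informative injections")
  q_obs <- exp$heats[keep]

  mol_inj1 <- exp$syringe_conc * exp$injection_volumes[keep[1]]
  dH0 <- (q_obs[1] * .heat_to_J[[exp$heat_unit]]) / mol_inj1 / 1000
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -10
  start <- list(logKd = log10(exp$cell_conc / 10), dH = dH0, n = 1)

  model <- function(logKd, dH, n) {
    itc_forward(list(Kd = 10^logKd, dH = dH, n = n), exp)[keep]
  }
  fit <- minpack.lm::nlsLM(
    q_obs ~ model(logKd, dH, n), start = start,
    lower = c(logKd = -12, dH = -Inf, n = 1e-3),
    upper = c(logKd = 0, dH = Inf, n = 10),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  Kd <- 10^cf[["logKd"]]
  c_value <- cf[["n"]] * exp$cell_conc / Kd
  if (c_value < 1 || c_value > 1000) {
    .warn_classed("phosphofit_c_value_warning", sprintf(
      "c-value %.3g outside [1, 1000]: Kd poorly determined", c_value))
  }
  dG <- delta_g(Kd, T = exp$T)
  structure(
    list(Kd = Kd, Kd_se = Kd * log(10) * sqrt(vc[1, 1]),
         dH = cf[["dH"]], dH_se = sqrt(vc[2, 2]),
         n = cf[["n"]], n_se = sqrt(vc[3, 3]),
         dG = dG, minus_TdS = entropic_term(dG, cf[["dH"]]),
         c_value = c_value, T = exp$T,
         residual_sd = stats::sigma(fit)),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "<itc_fit> Kd = %.4g M, dH = %.3g kJ/mol, n = %.3f (c = %.3g)\n",
    x$Kd, x$dH, x$n, x$c_value))
  cat(sprintf("  dG = %.1f, dH = %.1f, -TdS = %.1f kJ/mol at %.2f K\n",
              x$dG, x$dH, x$minus_TdS, x$T))
  invisible(x)
}
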