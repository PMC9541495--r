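# expects the long sensorgram layout produced by gen_spr(): columns
# cycle, conc_M, time_s (0 = injection start), response_RU, phase
.check_sensorgrams <- function(sgr) {
  need <- c("cycle", "conc_M", "time_s", "response_RU", "phase")
  if (!all(need %in% names(sgr))) {
    stop("sensorgram table must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(sgr$conc_M)) < 5) {
    stop("need at least 5 analyte concentrations")
  }
  invisible(sgr)
}

# end-of-injection time per cycle (attribute or max association time)
.injection_end <- function(sgr) {
  te <- attr(sgr, "t_inject_end")
  if (is.null(te)) te <- max(sgr$time_s[sgr$phase == "association"])
  te
}

# mean response over the last `window` fraction of the association phase
.end_of_injection_response <- function(sgr, window = 0.05) {
  te <- .injection_end(sgr)
  out <- lapply(split(sgr, sgr$cycle), function(df) {
    a <- df[df$phase == "association", ]
    sel <- a$time_s >= te * (1 - window)
    data.frame(conc_M = a$conc_M[1], Req = mean(a$response_RU[sel]))
  })
  do.call(rbind, out)
}

#' Global 1:1 Langmuir kinetic fit of a multicycle sensorgram set
#'
#' Fits all cycles simultaneously with shared parameters `kon`, `koff`
#' and `Rmax` (a single immobilized surface serves every cycle):
#' association phases follow [langmuir_association()], dissociation
#' phases follow [langmuir_dissociation()] from the model's
#' end-of-injection response. Rates are fitted on a log scale. The
#' equilibrium constant `Kd_kinetic = koff/kon` is reported alongside the
#' rates; note that it need not coincide with a separately fitted
#' steady-state `Kd` on real data.
#'
#' When every curve is already at equilibrium by the first sample after
#' injection start, the exchange kinetics are unresolvable at the
#' sampling rate and a classed error (`"phosphofit_kinetics_too_fast"`)
#' is raised; for such analytes only a steady-state affinity can be
#' reported.
#'
#' @param sgr Long sensorgram table (see [gen_spr()]): columns `cycle`,
#'   `conc_M`, `time_s`, `response_RU`, `phase`; optional attribute
#'   `t_inject_end`.
#' @return An object of class `"kinetic_fit"`: `kon` (1/(M s)), `koff`
#'   (1/s), `Rmax` (RU), their standard errors, `Kd_kinetic` (molar) and
#'   `residual_sd`.
#' @export
fit_kinetic <- function(sgr) {
  .check_sensorgrams(sgr)
  te <- .injection_end(sgr)

  # resolvability check: is there curvature left at the sampling interval?
  eq <- .end_of_injection_response(sgr)
  first_frac <- vapply(split(sgr, sgr$cycle), function(df) {
    a <- df[df$phase == "association" & df$time_s > 0, ]
    plateau <- eq$Req[match(a$conc_M[1], eq$conc_M)]
    if (plateau <= 0) return(0)
    a$response_RU[1] / plateau
  }, numeric(1))
  if (min(first_frac) > 0.95) {
    .stop_classed("phosphofit_kinetics_too_fast", paste0(
      "association reaches equilibrium within one sampling interval for ",
      "every concentration; only a steady-state affinity is determinable"))
  }

  C <- sgr$conc_M
  t <- sgr$time_s
  assoc <- sgr$phase == "association"
  model <- function(logkon, logkoff, Rmax) {
    kon <- 10^logkon; koff <- 10^logkoff
    R <- numeric(length(t))
    R[assoc] <- langmuir_association(t[assoc], kon, koff, Rmax, C[assoc])
    R0 <- langmuir_association(te, kon, koff, Rmax, C[!assoc])
    R[!assoc] <- R0 * exp(-koff * (t[!assoc] - te))
    R
  }
  # starts: koff from the tail of the top-concentration dissociation,
  # kon from a mid-series half-time guess
  top <- sgr[sgr$cycle == sgr$cycle[which.max(sgr$conc_M)] &
               sgr$phase == "dissociation", ]
  koff0 <- {
    pos <- top$response_RU > 0
    if (sum(pos) > 3) {
      f <- stats::lm(log(top$response_RU[pos]) ~ top$time_s[pos])
      max(1e-5, -stats::coef(f)[2])
    } else 0.1
  }
  kon0 <- koff0 / stats::median(unique(sgr$conc_M))
  fit <- minpack.lm::nlsLM(
    response_RU ~ model(logkon, logkoff, Rmax),
    data = list(response_RU = sgr$response_RU),
    start = list(logkon = log10(kon0), logkoff = log10(koff0),
                 Rmax = max(sgr$response_RU)),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  kon <- 10^cf[["logkon"]]; koff <- 10^cf[["logkoff"]]
  structure(
    list(kon = kon, kon_se = kon * log(10) * sqrt(vc[1, 1]),
         koff = koff, koff_se = koff * log(10) * sqrt(vc[2, 2]),
         Rmax = cf[["Rmax"]], Rmax_se = sqrt(vc[3, 3]),
         Kd_kinetic = koff / kon,
         residual_sd = stats::sigma(fit)),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> kon = %.3g 1/(M s), koff = %.3g 1/s, Rmax = %.3g RU\n",
    x$kon, x$koff, x$Rmax))
  cat(sprintf("  Kd (kinetic, koff/kon) = %.3g M\n", x$Kd_kinetic))
  invisible(x)
}

#' Steady-state affinity fit of end-of-injection responses
#'
#' Extracts the equilibrium response per cycle as the mean of the final
#' fraction (`window`, default 5%) of association-phase samples and fits
#' the hyperbola [steady_state_response()] for `Kd` and `Rmax`. A classed
#' warning (`"phosphofit_saturation_warning"`) is raised when the top
#' concentration is below twice the fitted `Kd`; when the series does not
#' even reach the fitted `Kd`, the result is flagged `lower_bound` and
#' the affinity should be read as "weaker than the top concentration".
#'
#' @param sgr Long sensorgram table (see [fit_kinetic()]).
#' @param window Fraction of the association phase averaged for the
#'   end-of-injection response (default 0.05).
#' @return An object of class `"steady_state_fit"`: `Kd` (molar),
#'   `Kd_se`, `Rmax`, `lower_bound` (`NA` or the top concentration), and
#'   the `responses` table used.
#' @export
fit_steady_state <- function(sgr, window = 0.05) {
  .check_sensorgrams(sgr)
  eq <- .end_of_injection_response(sgr, window = window)
  fit <- minpack.lm::nlsLM(
    Req ~ Rmax * conc_M / (10^logKd + conc_M),
    data = eq,
    start = list(logKd = log10(stats::median(eq$conc_M)),
                 Rmax = 1.2 * max(eq$Req)),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  Kd <- 10^cf[["logKd"]]
  top <- max(eq$conc_M)
  lower_bound <- NA_real_
  if (top < Kd) {
    lower_bound <- top
  } else if (top < 2 * Kd) {
    .warn_classed("phosphofit_saturation_warning", sprintf(
      "top concentration %.3g M below 2 x fitted Kd (%.3g M)", top, Kd))
  }
  structure(
    list(Kd = Kd, Kd_se = Kd * log(10) * sqrt(vc[1, 1]),
         Rmax = cf[["Rmax"]], lower_bound = lower_bound, responses = eq,
         residual_sd = stats::sigma(fit)),
    class = "steady_state_fit"
  )
}

#' @export
print.steady_state_fit <- function(x, ...) {
  if (is.finite(x$lower_bound)) {
    cat(sprintf("<steady_state_fit> Kd > %.3g M (non-saturating series)\n",
                x$lower_bound))
  } else {
    cat(sprintf("<steady_state_fit> Kd = %.4g M, Rmax = %.3g RU\n",
                x$Kd, x$Rmax))
  }
  invisible(x)
}
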