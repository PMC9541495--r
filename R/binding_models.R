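#' Bound-ligand concentration for a 1:1 interaction with ligand depletion
#'
#' Exact solution of the 1:1 binding equilibrium when the labelled ligand
#' (tracer) is not in vast excess over its own dissociation constant, i.e.
#' the "tight-binding" regime of a direct fluorescence-anisotropy titration.
#' The bound concentration is the physically meaningful (smaller) root of
#'
#' \deqn{B = \frac{(K + X + FL) - \sqrt{(K + X + FL)^2 - 4\,X\,FL}}{2}}
#'
#' evaluated in the numerically stable form \eqn{2 X FL / (b + \sqrt{b^2 -
#' 4 X FL})} with \eqn{b = K + X + FL}, which avoids catastrophic
#' cancellation when \eqn{K} is large.
#'
#' @param K Dissociation constant (molar). Non-negative; vectorised.
#' @param X Total binding-site concentration (molar, 14-3-3 monomer
#'   convention). Non-negative; vectorised.
#' @param FL Total tracer (fluorescent ligand) concentration (molar),
#'   strictly positive.
#' @return Bound-tracer concentration in molar, guaranteed to lie in
#'   `[0, min(X, FL)]`.
#' @examples
#' bound_ligand_quadratic(K = 1e-7, X = 2e-7, FL = 5e-8)
#' # infinitely tight limit: all tracer bound
#' bound_ligand_quadratic(K = 0, X = 1e-6, FL = 5e-8)
#' @export
bound_ligand_quadratic <- function(K, X, FL) {
  if (any(K < 0)) stop("K must be non-negative")
  if (any(FL <= 0)) stop("FL must be strictly positive")
  if (any(X < 0)) stop("X must be non-negative")
  b <- K + X + FL
  disc <- b^2 - 4 * X * FL
  # floating-point guard: disc is mathematically (K + |X - FL|)^2 + cross
  # terms >= 0, so any negative value here is rounding noise
  bad <- disc < 0
  if (any(bad & disc < -1e-9 * b^2)) {
    stop("internal consistency error: negative discriminant in quadratic")
  }
  disc[bad] <- 0
  bound <- 2 * X * FL / (b + sqrt(disc))
  pmin(bound, pmin(X, FL))
}

#' Fraction of tracer bound along a titration series
#'
#' Evaluates [bound_ligand_quadratic()] along a series of total protein
#' concentrations and divides by the tracer concentration. The result is
#' monotone non-decreasing in `X_series` and approaches 1 at saturating
#' protein.
#'
#' @param K Dissociation constant (molar).
#' @param FL Total tracer concentration (molar).
#' @param X_series Non-negative total binding-site concentrations (molar).
#' @return Numeric vector of fractions bound, one per concentration.
#' @export
fraction_bound_curve <- function(K, FL, X_series) {
  if (any(X_series < 0)) stop("X_series must be non-negative")
  bound_ligand_quadratic(K, X_series, FL) / FL
}

#' Describe a coupled monomer-dimer binding mechanism
#'
#' Parameter container for the mass-action equilibrium solved by
#' [solve_mass_action()]. 14-3-3 proteins dimerize; each protomer carries
#' one amphipathic phosphopeptide groove. A bivalent (doubly phosphorylated)
#' peptide already engaged through one phosphosite can engage the second
#' groove of the same dimer intramolecularly; the strength of that step is
#' parameterized by an effective molarity `alpha_bridge`, so the
#' intramolecular equilibrium constant is the dimensionless ratio
#' `alpha_bridge / Kd_site`.
#'
#' @param Kdim Monomer-monomer dimerization dissociation constant (molar),
#'   `Kdim = [M]^2 / [D]`.
#' @param Kd_site Per-groove peptide dissociation constant (molar).
#' @param alpha_bridge Effective molarity (molar) for the intramolecular
#'   engagement of the second phosphosite; only meaningful for `valency = 2`.
#' @param valency 1 for singly phosphorylated peptides, 2 for tandem
#'   (doubly phosphorylated) peptides.
#' @return An object of class `"coupled_mechanism"`.
#' @export
coupled_mechanism <- function(Kdim, Kd_site, alpha_bridge = 0, valency = 1) {
  stopifnot(Kdim > 0, Kd_site > 0, alpha_bridge >= 0, valency %in% c(1, 2))
  structure(
    list(Kdim = Kdim, Kd_site = Kd_site,
         alpha_bridge = alpha_bridge, valency = as.integer(valency)),
    class = "coupled_mechanism"
  )
}

#' Solve the coupled monomer/dimer/peptide mass-action equilibrium
#'
#' Numeric root finder for the species distribution of a 14-3-3
#' monomer-dimer system binding a mono- or bivalent phosphopeptide. Species:
#' free monomer `M`, free dimer `D`, free peptide `L`, monomer-peptide `ML`,
#' dimer with one occupied groove `DL`, dimer with both grooves occupied by
#' two peptides `DL2`, and (valency 2 only) the bridged complex `Dbr` in
#' which one peptide spans both grooves of a dimer.
#'
#' The two conservation equations (total monomer units, total peptide) are
#' solved by damped Newton iteration on log-concentrations of the free
#' species, which preserves positivity and is scale-free; an analytic
#' Jacobian is used. Convergence requires conservation residuals below
#' `1e-10` times the respective totals (or an absolute floor for zero
#' totals).
#'
#' @param mechanism A [coupled_mechanism()].
#' @param totals Named list or vector with `monomer_total` and
#'   `peptide_total` (molar, non-negative).
#' @param tol Relative conservation tolerance (default `1e-10`).
#' @param max_iter Maximum Newton iterations.
#' @return Named list of species concentrations (`M`, `D`, `L`, `ML`, `DL`,
#'   `DL2`, `Dbr`) plus `peptide_bound` (total peptide in any complex) and
#'   `residual` (worst scaled conservation residual).
#' @export
solve_mass_action <- function(mechanism, totals, tol = 1e-10,
                              max_iter = 200L) {
  stopifnot(inherits(mechanism, "coupled_mechanism"))
  totals <- as.list(totals)
  Pt <- totals$monomer_total
  Lt <- totals$peptide_total
  if (is.null(Pt) || is.null(Lt) || Pt < 0 || Lt < 0) {
    stop("totals must supply non-negative monomer_total and peptide_total")
  }
  Kdim <- mechanism$Kdim
  Kd <- mechanism$Kd_site
  br <- if (mechanism$valency == 2L) mechanism$alpha_bridge / Kd else 0

  species <- function(m, l) {
    d <- m^2 / Kdim
    list(M = m, D = d, L = l,
         ML = m * l / Kd,
         DL = 2 * d * l / Kd,
         DL2 = d * l^2 / Kd^2,
         Dbr = br * 2 * d * l / Kd)
  }
  conserv <- function(s) {
    c(P = s$M + 2 * s$D + s$ML + 2 * (s$DL + s$DL2 + s$Dbr),
      L = s$L + s$ML + s$DL + 2 * s$DL2 + s$Dbr)
  }
  scaleP <- max(Pt, .Machine$double.xmin)
  scaleL <- max(Lt, .Machine$double.xmin)

  # degenerate edges solved in closed form
  if (Pt == 0) {
    s <- species(0, Lt)
    return(c(s, list(peptide_bound = 0, residual = 0)))
  }
  if (Lt == 0) {
    # m + 2 m^2/Kdim = Pt
    m <- (-Kdim + sqrt(Kdim^2 + 8 * Kdim * Pt)) / 4
    s <- species(m, 0)
    return(c(s, list(peptide_bound = 0,
                     residual = abs(conserv(s)[["P"]] - Pt) / scaleP)))
  }

  resid <- function(u, v) {
    s <- species(exp(u), exp(v))
    cs <- conserv(s)
    c((cs[["P"]] - Pt) / scaleP, (cs[["L"]] - Lt) / scaleL)
  }
  # each species is c * m^a * l^b, so d(species)/d(log m) = a * species etc.
  jac <- function(u, v) {
    s <- species(exp(u), exp(v))
    dPu <- s$M + 4 * s$D + s$ML + 4 * s$DL + 4 * s$DL2 + 4 * s$Dbr
    dPv <- s$ML + 2 * s$DL + 4 * s$DL2 + 2 * s$Dbr
    dLu <- s$ML + 2 * s$DL + 4 * s$DL2 + 2 * s$Dbr
    dLv <- s$L + s$ML + s$DL + 4 * s$DL2 + s$Dbr
    matrix(c(dPu / scaleP, dLu / scaleL, dPv / scaleP, dLv / scaleL), 2, 2)
  }

  newton <- function(u, v) {
    r <- resid(u, v)
    for (it in seq_len(max_iter)) {
      if (max(abs(r)) < tol) break
      J <- jac(u, v)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        step <- -r * 0.1
      }
      step <- pmin(pmax(step, -2), 2)  # trust region in log space
      lambda <- 1
      repeat {
        r_new <- resid(u + lambda * step[1], v + lambda * step[2])
        ok <- all(is.finite(r_new)) && max(abs(r_new)) < max(abs(r))
        if (ok || lambda < 1e-8) break
        lambda <- lambda / 2
      }
      if (!all(is.finite(r_new))) break
      u <- u + lambda * step[1]
      v <- v + lambda * step[2]
      r <- r_new
    }
    list(u = u, v = v, r = r)
  }

  sol <- newton(log(min(Pt, Kdim + Pt) / 2), log(Lt / 2))
  if (max(abs(sol$r)) >= tol) {
    # restart Newton from a nested-bisection point: the conservation
    # equations are monotone in each free concentration, so bisection
    # cannot diverge where Newton can (extreme effective molarities)
    inner_m <- function(l) {
      f <- function(lm) {
        s <- species(exp(lm), l)
        s$M + 2 * s$D + s$ML + 2 * (s$DL + s$DL2 + s$Dbr) - Pt
      }
      exp(stats::uniroot(f, c(log(Pt) - 80, log(Pt)), tol = 1e-14)$root)
    }
    outer_l <- function(ll) {
      l <- exp(ll)
      s <- species(inner_m(l), l)
      s$L + s$ML + s$DL + 2 * s$DL2 + s$Dbr - Lt
    }
    ll <- stats::uniroot(outer_l, c(log(Lt) - 80, log(Lt)), tol = 1e-14)$root
    sol <- newton(log(inner_m(exp(ll))), ll)
  }
  if (max(abs(sol$r)) >= tol) {
    stop(sprintf(paste0("mass-action solver did not converge: scaled ",
                        "residuals (%.3e, %.3e)"), sol$r[1], sol$r[2]))
  }
  u <- sol$u; v <- sol$v; r <- sol$r
  s <- species(exp(u), exp(v))
  bound <- s$ML + s$DL + 2 * s$DL2 + s$Dbr
  c(s, list(peptide_bound = bound, residual = max(abs(r))))
}

#' Langmuir 1:1 association-phase response
#'
#' Closed-form response of a 1:1 surface interaction during analyte
#' injection: \eqn{R(t) = R_{eq} (1 - e^{-(k_{on} C + k_{off}) t})} with
#' \eqn{R_{eq} = R_{max} C / (C + k_{off}/k_{on})}.
#'
#' @param t Time since injection start (seconds, non-negative).
#' @param kon Association rate constant (1/(M s)).
#' @param koff Dissociation rate constant (1/s).
#' @param Rmax Saturating response (RU).
#' @param C Analyte concentration (molar).
#' @return Response in RU at each time point.
#' @export
langmuir_association <- function(t, kon, koff, Rmax, C) {
  stopifnot(all(t >= 0), kon > 0, koff > 0, Rmax > 0, C >= 0)
  Req <- Rmax * C / (C + koff / kon)
  Req * (1 - exp(-(kon * C + koff) * t))
}

#' Langmuir 1:1 dissociation-phase response
#'
#' @param t Time since end of injection (seconds, non-negative).
#' @param koff Dissociation rate constant (1/s).
#' @param R0 Response at end of injection (RU).
#' @return `R0 * exp(-koff * t)`.
#' @export
langmuir_dissociation <- function(t, koff, R0) {
  stopifnot(all(t >= 0), koff > 0)
  R0 * exp(-koff * t)
}

#' Steady-state (equilibrium) SPR response
#'
#' Hyperbolic dose-response of the end-of-injection response against
#' analyte concentration: \eqn{R_{eq} = R_{max} C / (K_d + C)}.
#'
#' @param C_series Analyte concentrations (molar, non-negative).
#' @param Kd Dissociation constant (molar).
#' @param Rmax Saturating response (RU).
#' @return Equilibrium responses in RU.
#' @export
steady_state_response <- function(C_series, Kd, Rmax) {
  stopifnot(all(C_series >= 0), Kd > 0)
  Rmax * C_series / (Kd + C_series)
}

#' Standard Gibbs energy of binding from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln K_d} with the 1 M standard state, reported in
#' kJ/mol. Assays here are run at 25 degrees C, hence the 298.15 K default.
#'
#' @param Kd Dissociation constant (molar, strictly positive); vectorised.
#' @param T Temperature in kelvin (default 298.15).
#' @param R Gas constant in J/(mol K) (default 8.314).
#' @return Gibbs energy in kJ/mol (negative for sub-molar `Kd`).
#' @examples
#' delta_g(870e-9)  # -34.6 kJ/mol
#' @export
delta_g <- function(Kd, T = 298.15, R = 8.314) {
  if (any(Kd <= 0)) stop("Kd must be strictly positive")
  stopifnot(T > 0)
  R * T * log(Kd) / 1000
}

#' Entropic term of the thermodynamic signature
#'
#' The calorimetric decomposition \eqn{\Delta G = \Delta H - T \Delta S}
#' rearranged for the entropic term: \eqn{-T\Delta S = \Delta G - \Delta H}.
#' Both inputs must be in kJ/mol at the same temperature.
#'
#' @param delta_g_val Gibbs energy (kJ/mol).
#' @param delta_h Enthalpy (kJ/mol).
#' @return `-TdS` in kJ/mol.
#' @export
entropic_term <- function(delta_g_val, delta_h) {
  delta_g_val - delta_h
}
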