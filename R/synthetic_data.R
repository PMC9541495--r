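#' Design of a direct fluorescence-anisotropy titration plate
#'
#' Describes the layout and optical parameters of a direct FA titration:
#' a fixed concentration of FAM-labelled tracer peptide is read against a
#' serial dilution of 14-3-3 protein (given as monomer concentration),
#' in replicate wells, on a two-channel (parallel S / perpendicular P)
#' polarization reader.
#'
#' @param tracer_conc Tracer concentration in molar (default 50 nM).
#' @param top_conc Highest protein concentration in molar (default 100 uM,
#'   spanning the nanomolar-to-high-micromolar affinities of these
#'   peptides).
#' @param dilution_factor Serial dilution factor (default 2, a half-fold
#'   series).
#' @param n_points Number of concentrations (default 24).
#' @param replicates Wells per concentration (default 3).
#' @param G Grating factor applied to the perpendicular channel (default 1).
#' @param r_free Anisotropy of the free tracer.
#' @param r_bound_event1 Anisotropy plateau after the first binding event.
#' @param r_bound_event2 Anisotropy plateau after the second binding event
#'   (two-event curves only; must exceed `r_bound_event1`).
#' @param intensity_scale Total fluorescence intensity per well in
#'   arbitrary units.
#' @param noise_sd Fractional Gaussian noise applied independently to each
#'   channel of each well (0 = noiseless).
#' @param lambda Bound/free tracer intensity ratio; 1 means binding does
#'   not change total intensity (the default, matching fluorescein tracers
#'   in this system). Values other than 1 are a stress-test option and are
#'   supported for single-site mechanisms only.
#' @param seed Integer RNG seed making the plate reproducible.
#' @return An object of class `"fa_design"`.
#' @export
fa_design <- function(tracer_conc = 50e-9, top_conc = 100e-6,
                      dilution_factor = 2, n_points = 24L, replicates = 3L,
                      G = 1, r_free = 0.05, r_bound_event1 = 0.20,
                      r_bound_event2 = 0.30, intensity_scale = 1e6,
                      noise_sd = 0, lambda = 1, seed = 1L) {
  stopifnot(tracer_conc > 0, top_conc > 0, dilution_factor > 1,
            n_points >= 6L, replicates >= 1L, G > 0, noise_sd >= 0,
            lambda > 0, r_bound_event1 > r_free,
            r_bound_event2 >= r_bound_event1)
  structure(
    list(tracer_conc = tracer_conc, top_conc = top_conc,
         dilution_factor = dilution_factor, n_points = as.integer(n_points),
         replicates = as.integer(replicates), G = G, r_free = r_free,
         r_bound_event1 = r_bound_event1, r_bound_event2 = r_bound_event2,
         intensity_scale = intensity_scale, noise_sd = noise_sd,
         lambda = lambda, seed = as.integer(seed)),
    class = "fa_design"
  )
}

# true anisotropy and event-wise fractions bound for a mechanism
.fa_truth <- function(design, mechanism, conc) {
  FL <- design$tracer_conc
  if (inherits(mechanism, "coupled_mechanism")) {
    fb <- vapply(conc, function(ct) {
      solve_mass_action(mechanism,
                        list(monomer_total = ct, peptide_total = FL)
      )$peptide_bound / FL
    }, numeric(1))
    r <- design$r_free + (design$r_bound_event1 - design$r_free) * fb
    list(r = r, fb_total = fb)
  } else if (identical(mechanism$type, "single_site")) {
    fb <- fraction_bound_curve(mechanism$Kd, FL, conc)
    r <- design$r_free + (design$r_bound_event1 - design$r_free) * fb
    list(r = r, fb_total = fb)
  } else if (identical(mechanism$type, "two_event")) {
    stopifnot(mechanism$Kd1 < mechanism$Kd2)
    fb1 <- fraction_bound_curve(mechanism$Kd1, FL, conc)
    fb2 <- fraction_bound_curve(mechanism$Kd2, FL, conc)
    r <- design$r_free +
      (design$r_bound_event1 - design$r_free) * fb1 +
      (design$r_bound_event2 - design$r_bound_event1) * fb2
    list(r = r, fb_total = (fb1 + fb2) / 2)
  } else {
    stop("mechanism must be a coupled_mechanism, or a list with type ",
         "'single_site' (Kd) or 'two_event' (Kd1 < Kd2)")
  }
}

#' Generate a raw FA titration plate with known ground truth
#'
#' Computes the true fraction(s) of tracer bound under the requested
#' binding mechanism, composes the true anisotropy
#' `r(c) = r_free + sum(dr_event * fb_event(c))`, inverts the two-channel
#' relations `I = 2PG + S`, `r = (S - PG)/I` to per-well parallel (S) and
#' perpendicular (P) intensities, and adds independent Gaussian channel
#' noise. Each replicate receives distinct noise draws; reruns with the
#' same design are identical.
#'
#' @param design An [fa_design()].
#' @param mechanism One of: a [coupled_mechanism()]; `list(type =
#'   "single_site", Kd = ...)`; or `list(type = "two_event", Kd1 = ...,
#'   Kd2 = ...)` with `Kd1 < Kd2`.
#' @return A data frame with columns `peptide_id`, `concentration_M`,
#'   `replicate`, `S`, `P` (one row per well), carrying the design and the
#'   true per-concentration anisotropy in attribute `"truth"`.
#' @export
gen_fa_titration <- function(design, mechanism) {
  stopifnot(inherits(design, "fa_design"))
  if (design$lambda != 1 && !identical(mechanism$type, "single_site")) {
    stop("lambda != 1 generation is supported for single_site mechanisms only")
  }
  conc <- design$top_conc / design$dilution_factor^(seq_len(design$n_points) - 1)
  truth <- .fa_truth(design, mechanism, conc)
  r <- truth$r
  I <- design$intensity_scale * (1 + (design$lambda - 1) * truth$fb_total)
  S_true <- I * (1 + 2 * r) / 3
  P_true <- I * (1 - r) / (3 * design$G)

  .with_seed(design$seed, {
    rows <- lapply(seq_len(design$replicates), function(rep_i) {
      S <- S_true * (1 + stats::rnorm(length(conc), sd = design$noise_sd))
      P <- P_true * (1 + stats::rnorm(length(conc), sd = design$noise_sd))
      data.frame(peptide_id = "synthetic", concentration_M = conc,
                 replicate = rep_i, S = S, P = P,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(design = design, mechanism = mechanism,
                               concentration_M = conc, r_true = r)
    out
  })
}

#' Design of a synthetic ITC titration
#'
#' Describes a one-cell isothermal titration calorimetry experiment in
#' which peptide (syringe) is titrated into 14-3-3 protein (cell). The
#' instrument geometry defaults to a 200 uL cell with 20 x 2 uL
#' injections. Cell/syringe concentrations default to 20 uM protein and
#' 200 uM peptide; the concentrations printed for such experiments in
#' units of "m" are read as mM here, since molar values would be
#' physically implausible for a protein cell.
#'
#' @param cell_volume Cell volume in litres (default 200 uL).
#' @param cell_conc Protein concentration in the cell, molar (monomer
#'   convention; default 20 uM).
#' @param syringe_conc Peptide concentration in the syringe, molar
#'   (default 200 uM).
#' @param injection_volumes Injection volumes in litres (default 20 x 2 uL).
#' @param T Temperature in kelvin (default 298.15).
#' @param true_Kd Ground-truth dissociation constant (molar).
#' @param true_dH Ground-truth binding enthalpy (kJ/mol of peptide bound).
#' @param mechanism `"monovalent"` (one peptide per 14-3-3 monomer) or
#'   `"bivalent"` (one peptide simultaneously occupies both protomers of a
#'   dimer, halving the binding-site concentration).
#' @param heat_noise_sd Gaussian noise as a fraction of the largest
#'   absolute injection heat (0 = noiseless).
#' @param seed Integer RNG seed.
#' @return An object of class `"itc_design"`.
#' @export
itc_design <- function(cell_volume = 200e-6, cell_conc = 20e-6,
                       syringe_conc = 200e-6,
                       injection_volumes = rep(2e-6, 20L), T = 298.15,
                       true_Kd, true_dH,
                       mechanism = c("monovalent", "bivalent"),
                       heat_noise_sd = 0, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > cell_conc,
            length(injection_volumes) >= 10L, all(injection_volumes > 0),
            T > 0, true_Kd > 0, is.finite(true_dH), heat_noise_sd >= 0)
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = injection_volumes, T = T,
         true_Kd = true_Kd, true_dH = true_dH, mechanism = mechanism,
         heat_noise_sd = heat_noise_sd, seed = as.integer(seed)),
    class = "itc_design"
  )
}

#' Generate a synthetic ITC injection table
#'
#' Forward-simulates the one-set-of-sites isotherm through
#' [itc_forward()]. Under the `"monovalent"` mechanism the binding-site
#' concentration equals the cell (monomer) concentration; under
#' `"bivalent"` each peptide occupies both protomers of a 14-3-3 dimer,
#' so the site concentration is half the monomer concentration and a
#' standard monovalent fit of the resulting isotherm returns an apparent
#' stoichiometry near 0.5.
#'
#' @param design An [itc_design()].
#' @return An [itc_experiment()] whose `heats` are filled in (uJ), with
#'   the design stored in attribute `"truth"`. A classed warning
#'   (`"phosphofit_design_warning"`) is raised when the schedule cannot
#'   reach a site molar ratio of 2 by the final injection.
#' @export
gen_itc <- function(design) {
  stopifnot(inherits(design, "itc_design"))
  n_true <- if (design$mechanism == "bivalent") 0.5 else 1
  exp0 <- itc_experiment(
    cell_volume = design$cell_volume, cell_conc = design$cell_conc,
    syringe_conc = design$syringe_conc,
    injection_volumes = design$injection_volumes, T = design$T,
    heat_unit = "uJ"
  )
  # molar ratio of injected peptide to available sites at the end
  ratio_end <- .itc_molar_ratio(exp0)[length(design$injection_volumes)] / n_true
  if (ratio_end < 2) {
    .warn_classed("phosphofit_design_warning", sprintf(
      "syringe concentration too low: final site molar ratio %.2f < 2",
      ratio_end))
  }
  q <- itc_forward(list(Kd = design$true_Kd, dH = design$true_dH,
                        n = n_true), exp0)
  .with_seed(design$seed, {
    if (design$heat_noise_sd > 0) {
      q <- q + stats::rnorm(length(q), sd = design$heat_noise_sd * max(abs(q)))
    }
    exp0$heats <- q
    attr(exp0, "truth") <- design
    exp0
  })
}

#' Design of a multicycle SPR kinetic titration
#'
#' Describes a multicycle surface plasmon resonance experiment: each
#' cycle injects one analyte concentration over an immobilized 14-3-3
#' surface (1 min association), followed by buffer flow (4 min
#' dissociation/regeneration), with complete regeneration between cycles.
#' The default concentration series is an 11-point two-fold serial
#' dilution from 10x the equilibrium `Kd` implied by the rate constants.
#'
#' @param true_kon Ground-truth association rate (1/(M s)).
#' @param true_koff Ground-truth dissociation rate (1/s).
#' @param Rmax Saturating surface response (RU, default 100).
#' @param conc_series Analyte concentrations (molar, descending). Default
#'   `10 * koff/kon / 2^(0:10)`.
#' @param association_s Injection length in seconds (default 60).
#' @param dissociation_s Dissociation window in seconds (default 240).
#' @param sampling_hz Detector sampling rate (default 2 Hz).
#' @param noise_sd Gaussian response noise as a fraction of `Rmax`.
#' @param seed Integer RNG seed.
#' @return An object of class `"spr_design"`.
#' @export
spr_design <- function(true_kon, true_koff, Rmax = 100,
                       conc_series = NULL, association_s = 60,
                       dissociation_s = 240, sampling_hz = 2,
                       noise_sd = 0, seed = 1L) {
  stopifnot(true_kon > 0, true_koff > 0, Rmax > 0, association_s > 0,
            dissociation_s > 0, sampling_hz > 0, noise_sd >= 0)
  if (is.null(conc_series)) {
    conc_series <- 10 * (true_koff / true_kon) / 2^(0:10)
  }
  stopifnot(all(conc_series > 0), all(diff(conc_series) < 0))
  structure(
    list(true_kon = true_kon, true_koff = true_koff, Rmax = Rmax,
         conc_series = conc_series, association_s = association_s,
         dissociation_s = dissociation_s, sampling_hz = sampling_hz,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "spr_design"
  )
}

#' Generate a synthetic multicycle SPR sensorgram set
#'
#' Association phases follow [langmuir_association()]; dissociation
#' phases follow [langmuir_dissociation()] starting from the
#' end-of-injection response. Every cycle starts from a zero baseline
#' (complete regeneration). Gaussian noise is added independently per
#' time point.
#'
#' @param design An [spr_design()].
#' @return A long data frame with columns `cycle`, `conc_M`, `time_s`
#'   (0 = injection start), `response_RU` and `phase`
#'   (`"association"`/`"dissociation"`), plus attributes `"truth"` (the
#'   design) and `"t_inject_end"`.
#' @export
gen_spr <- function(design) {
  stopifnot(inherits(design, "spr_design"))
  dt <- 1 / design$sampling_hz
  t_assoc <- seq(0, design$association_s, by = dt)
  t_diss <- seq(dt, design$dissociation_s, by = dt)
  .with_seed(design$seed, {
    rows <- lapply(seq_along(design$conc_series), function(i) {
      C <- design$conc_series[i]
      Ra <- langmuir_association(t_assoc, design$true_kon, design$true_koff,
                                 design$Rmax, C)
      R0 <- Ra[length(Ra)]
      Rd <- langmuir_dissociation(t_diss, design$true_koff, R0)
      df <- data.frame(
        cycle = i, conc_M = C,
        time_s = c(t_assoc, design$association_s + t_diss),
        response_RU = c(Ra, Rd),
        phase = rep(c("association", "dissociation"),
                    c(length(t_assoc), length(t_diss))),
        stringsAsFactors = FALSE
      )
      if (design$noise_sd > 0) {
        df$response_RU <- df$response_RU +
          stats::rnorm(nrow(df), sd = design$noise_sd * design$Rmax)
      }
      df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- design
    attr(out, "t_inject_end") <- design$association_s
    out
  })
}
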