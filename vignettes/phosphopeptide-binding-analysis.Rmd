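---
title: "Quantifying 14-3-3 phosphopeptide binding: models, fits and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 14-3-3 phosphopeptide binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphofit)
```

## The system and the measurement problem

14-3-3 proteins are dimeric adaptors; each protomer carries one
amphipathic groove that recognizes phosphorylated Ser/Thr motifs in
client proteins. For clients such as the p53 regulators hDMX and hDM2,
the biologically interesting quantities are per-phosphosite
dissociation constants, the gain conferred by tandem phosphosites
spaced ~20-25 residues apart, and the thermodynamic character of that
gain. Three orthogonal techniques measure it: fluorescence anisotropy
(FA) titrations of a fluorescent tracer peptide, isothermal titration
calorimetry (ITC), and surface plasmon resonance (SPR). This package
implements the complete analysis chain for all three plus the
synthetic-data generators needed to validate every stage with known
ground truth.

## Fluorescence anisotropy

A direct titration holds the FAM-labelled tracer peptide at a fixed low
concentration `FL` (default 50 nM) while the protein is serially
diluted (half-fold, 24 points, triplicate). Each well yields parallel
(`S`) and perpendicular (`P`) intensities; with grating factor `G`,

    I = 2 P G + S,    r = (S - P G) / I.

`compute_anisotropy()` aggregates wells to a mean +/- SD per
concentration. Fits operate on replicate means; replicate SDs are
reported but not used as weights (no weighting scheme is implied by the
instrument model, and unweighted means keep the estimate invariant to
duplicated rows).

**Window fit.** `fit_logistic()` fits
`r(x) = rmin + (rmax - rmin)/(1 + 10^(h (logx0 - x)))` on
`x = log10(c)`. Two conventions deserve note. First, the sigmoid is
written in its *increasing* orientation: titrating protein into tracer
can only raise `r`, so a decreasing parameterization would be a sign
slip. Second, the Hill-type slope `h` is left free (start 1, bounds
0.2-5): when `Kd` is comparable to `FL`, ligand depletion makes the
true transition steeper than a slope-1 sigmoid, and pinning `h = 1`
biases the plateau estimates by several percent. Only the plateaus are
consumed downstream.

**Fraction bound and the tight-binding quadratic.**
`to_fraction_bound()` applies
`Lb = (r - rmin)/(lambda (rmax - r) + r - rmin)`, with
`lambda = I_bound/I_free` defaulting to 1 (fluorescein tracers in this
system show no intensity change on binding; the generator can produce
`lambda != 1` data as a stress test). `fit_single_site()` then fits the
exact 1:1 bound-ligand solution with `log10(Kd)` free. The quadratic is
evaluated in the cancellation-safe form `2 X FL/(b + sqrt(b^2 - 4 X FL))`.

**Self-consistent window refinement.** An empirical sigmoid is only an
approximation to the binding curve, and on noiseless synthetic data the
plain chain leaves a ~4% bias in `Kd` for tight binders. `fa_fit()`
therefore polishes the window: given the current `Kd`, the model
fraction bound is computed, the plateaus are re-estimated by linear
least squares (for any `lambda`, `r` is linear in `rmin` and `rmax`
given `Lb`), and `Kd` is refitted; four rounds suffice. This makes the
noiseless round trip exact to ~1e-4 relative while changing nothing
about the underlying model.

**Saturation failures.** Weak binders may never approach their upper
plateau within the sampled range. `fit_logistic()` signals a classed
error when (a) the curve span is below 3x the median replicate SD (no
transition) or (b) the observed top anisotropy stays below 85% of the
fitted window or the fitted midpoint lies beyond the data. The 85%
threshold separates a titration that is merely weak (a `Kd` at ~1/10 of
the top concentration still reaches ~90% of its window) from one that
is genuinely unbounded (a `Kd` at ~1/3 of the top concentration reaches
only ~76%). `fa_fit()` converts the error into a lower-bound-only
result (`Kd > c_top`), mirroring how such titrations must be reported.

**Biphasic curves.** Doubly phosphorylated peptides show two
transitions in FA: a high-affinity event and a second, micromolar
event. `fit_biphasic()` splits the curve at the flattest interior point
of a smoothed `dr/d(log c)` (cubic smoothing spline, df <= 8, valley
between the two dominant derivative maxima; a user-supplied `split`
overrides detection) and fits each event separately through the same
1:1 chain with event-local plateaus. Because each event's tail leaks
into the other's window, the stepwise estimates are then used to start
a joint refit of the two-component composite
`r0 + dr1 fb(Kd1) + dr2 fb(Kd2)` — each component still the exact 1:1
solution. The stepwise values are retained in the result. The two
events are modelled with *independent* plateau parameters (whether the
second event's baseline equals the first's ceiling is not constrained;
the joint composite enforces continuity by construction). If only one
transition is detected the function falls back to a single-site fit
with a classed warning.

## ITC

`itc_forward()` implements the one-set-of-sites isotherm with
constant-volume displacement bookkeeping: injection `i` of volume `dV`
dilutes everything in the cell by `(1 - dV/V0)` and adds
`syringe_conc * dV/V0` of peptide; the bound complex is the exact
quadratic solution with site concentration `n * [protein]`; the
injection heat is `dH` times the moles of complex formed, counting
material expelled during the injection at the mean of the pre- and
post-injection bound concentrations. `fit_itc()` frees `log10(Kd)`,
`dH` and `n`, then reports `dG = RT ln Kd` and `-TdS = dG - dH` (an
identity of the decomposition, not an independent measurement). The
Wiseman `c = n [cell]/Kd` is checked against the reliable window
[1, 1000] with a classed warning outside it, and `discard_first = TRUE`
drops a (commonly anomalous) first injection.

Stoichiometry is the mechanistic diagnostic: a bivalent binding mode in
which one peptide occupies both protomers of a dimer halves the
available site concentration, so the monovalent fit of such an isotherm
returns `n` near 0.5, whereas one-peptide-per-protomer binding returns
`n` near 1. The generator supports both mechanisms; published cell
concentrations printed in ambiguous "m" units are read as mM (20 or
100 uM cells), the only physically plausible reading for a protein
sample.

## SPR

`fit_kinetic()` fits all cycles of a multicycle titration globally with
shared `kon`, `koff`, `Rmax` — one immobilized surface serves every
cycle, and complete regeneration between cycles is assumed (no
decaying-surface correction). Association follows
`Req (1 - exp(-(kon C + koff) t))`, dissociation decays exponentially
from the model's end-of-injection response. Rates are fitted on log
scale; starting values come from a log-linear regression of the
top-concentration dissociation tail. When every curve reaches >95% of
its equilibrium response by the first sample after injection start, the
exchange is unresolvable at the sampling rate and a classed error says
so — for such analytes only the steady-state route is available.
`fit_steady_state()` takes the mean of the final 5% (configurable) of
association samples per cycle and fits the hyperbola; it warns when the
top concentration is below `2 Kd` and flags a lower-bound-only outcome
when the series does not even reach the fitted `Kd`. On real data the
kinetic ratio `koff/kon` and the steady-state `Kd` need not agree; the
package reports both and never substitutes one for the other.

## Coupled mass-action equilibria

`solve_mass_action()` solves the monomer/dimer/peptide network: species
`M`, `D`, `L`, `ML`, singly and doubly occupied dimers, and — for
bivalent peptides — a bridged complex spanning both grooves,
parameterized by an effective molarity `alpha_bridge` (intramolecular
step constant `alpha_bridge/Kd_site`, dimensionless). The two
conservation equations are solved by damped Newton iteration on
log-concentrations (positivity-preserving and scale-free) with an
analytic Jacobian, scaled residual tolerance 1e-10 and a trust region
of 2 log units per step; if Newton stalls (extreme effective
molarities), the solver restarts from a nested-bisection point, which
is guaranteed to bracket because both conservation functions are
monotone in each free concentration. Degenerate totals (no protein, no
peptide) are handled in closed form. The all-dimer valency-1 limit
reproduces the tight-binding quadratic to better than 1e-9 relative,
which the test suite exercises on 1000 random parameter draws.

The mechanism container deliberately does not commit to what the second
FA binding event *is* — statistical rebinding, a secondary surface
site, or dimerization-linked exchange are all compatible with the data
this package targets. The generators expose a phenomenological
two-event mode and a mechanistic monomer-dimer mode; choosing between
the physical hypotheses is left to experiments, not defaults.

## Motif classification

`scan_modes()` tests each phosphosite against the canonical recognition
sequences: mode I (`R` at -3 and `P` at +2), mode II (`R` at -5, `Y/F`
at -3, `P` at +2) and mode III (phosphosite penultimate with a
free-acid C terminus). Three conventions: modes I/II require the whole
anchor window inside the sequence (no wrap or imputation); synthetic
amidated peptides can never be mode III, because mode III is defined on
the protein C terminus; and when several definitions hold, one label is
reported with priority II > I > III (mode II being the more specific
superset of the mode I anchors). Individually satisfied anchors are
always reported, even without a full-mode match, so a site that has the
-3 arginine but lacks the +2 proline is distinguishable from one with
no anchor at all. The scanner is strict by design: it does not soften
the definitions to match looser usage of "mode I" for sites that only
partially satisfy the pattern, and it does not attempt
predictor-style scoring.

## What the generators emulate — and what they do not

`gen_fa_titration()` inverts the anisotropy equations to per-well S/P
channels at a given total intensity, then adds independent Gaussian
noise proportional to each channel (the simplest model consistent with
replicate SD error bars). `gen_itc()` runs the forward isotherm;
`gen_spr()` composes Langmuir phases per cycle from a zero baseline.
All three take an explicit integer seed and are byte-identical on
rerun; replicates receive distinct draws.

Defaults encode the study conditions: 50 nM tracer, half-fold series
over 24 points in triplicate, `lambda = 1`, 200 uL cell with 20 x 2 uL
injections and 10x-concentrated syringe, 1 min association / 4 min
dissociation multicycle SPR with an 11-point series from 10x `Kd`, all
at 298.15 K. The top FA concentration defaults to 100 uM, spanning the
nanomolar-to-high-micromolar affinities of these peptides. Anisotropy
plateaus default to 0.05 (free) to 0.20/0.30 (bound), typical
fluorescein-tracer values.

Not modelled: instrument drift and baseline artefacts, photobleaching,
plate-read time dependence, vendor raw-file formats,
mass-transport-limited SPR kinetics, and isoform-dependent maximum
anisotropy as a mechanism (it is emulated phenomenologically by the
plateau knobs). Passing round-trip tests therefore demonstrates that
the estimators are correct for data generated by the stated physical
models with well-behaved noise — not that real instrument pathologies
are handled.

## Verification strategy and problem sizes

The test suite validates along three axes, with all seeds fixed in the
test code:

- *Independent oracles.* The quadratic is checked against a brute-force
  `uniroot` solution of the mass-action polynomial; the ITC forward
  model against a per-injection oracle; the Langmuir closed form
  against numerical ODE integration (`deSolve`); the mass-action
  solver against its closed-form limits.
- *Round trips at zero noise.* Generate-then-fit recovers FA `Kd`, ITC
  `{Kd, dH, n}`, and SPR `{kon, koff}` to well within 0.5%, and the
  biphasic pair to well within 1%.
- *Recovery under noise.* Monte-Carlo runs at instrument-realistic
  noise (1% FA channel noise, 100 seeds; 0.5% SPR response noise, 50
  seeds) bound the mean recovery error: within 5% for single-site FA,
  10%/15% for the biphasic pair, 2% for the SPR rates. Per-seed scatter
  at 1% channel noise is naturally of the same order as these bands;
  the bounds are on the bias, and the per-seed spread is visible in the
  test objects for anyone who wants it.

These sizes (24 x 3 wells per plate, 20 injections, 11 x ~600
timepoints per SPR set) match the defaults above, so the whole suite
doubles as a worked example of the intended experimental scale.

## Thermodynamic reporting

`delta_g()` uses `dG = RT ln Kd` at 298.15 K (8.314 J/mol/K), reported
in kJ/mol to one decimal in printed tables; lower-bound affinities
propagate as lower-bound (weaker-than) energies. `cooperativity()`
classifies `ddG = dG_tandem - (dG_A + dG_B)` against a 1.0 kJ/mol
additivity tolerance, the scale of typical calorimetric fit errors;
the classification is symmetric in the two sites by construction.
Cross-technique `concordance_table()` rows report the maximum pairwise
fold-difference among point estimates without judging it. One caveat
carried in the documentation rather than the code: published
FA-derived energy columns can be internally inconsistent with their
own affinity tables (a factor-of-10 concentration slip produces a
~5.7 kJ/mol offset); this package recomputes energies only from
explicit `Kd` inputs and makes no attempt to reproduce such columns.

## Known limitations

- Two phosphosites per peptide at most; no heterodimeric 14-3-3
  species; no temperature dependence of `dH` (single-temperature
  assays, no van 't Hoff analysis).
- The biphasic split detector assumes two separated transitions; for
  midpoints closer than ~1.5 decades the joint refit still works but
  split detection may need the manual override.
- ITC fitting assumes integrated per-injection heats; baseline
  integration of raw power traces is out of scope.
- Standard errors are asymptotic (delta method on log-parameters) and
  will understate uncertainty for poorly determined windows.
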