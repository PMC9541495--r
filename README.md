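# phosphofit

Quantitative analysis of 14-3-3 / phosphopeptide binding from three
orthogonal biophysical readouts. The package is written for
protein–peptide interaction studies in which phosphorylated client
sequences (here the p53 regulators hDMX and hDM2) are titrated against
14-3-3 adaptor proteins, and the questions are: how tight is each
phosphosite, what do tandem (doubly phosphorylated) peptides gain, and
is that gain additive, cooperative, or less than additive?

## What it computes

**Fluorescence anisotropy (FA).** Direct titrations of a FAM-labelled
tracer peptide (fixed, typically 50 nM) with 14-3-3 (half-fold serial
dilution, monomer concentration convention). Per-well two-channel reads
are converted with

    I = 2 P G + S        r = (S - P G) / I

a logistic window fit supplies the anisotropy plateaus `r_min`/`r_max`,
the fraction bound follows from

    Lb = (r - rmin) / (lambda (rmax - r) + r - rmin)

and the dissociation constant is obtained from the exact 1:1
tight-binding (ligand-depletion) quadratic

    B = ((K + X + FL) - sqrt((K + X + FL)^2 - 4 X FL)) / 2

which stays unbiased when `Kd` approaches the tracer concentration.
Biphasic (two-event) dose-response curves of doubly phosphorylated
peptides are decomposed into stepwise `Kd1 < Kd2` by fitting each event
separately to a 1:1 model, then polishing with a joint two-component
refit. Titrations that never reach saturation are reported as lower
bounds (`Kd > top concentration`), not point estimates.

**ITC.** A one-set-of-sites forward model with per-injection
constant-volume displacement bookkeeping, fitted for `Kd`, `dH` and the
stoichiometry `n`, with the thermodynamic signature `dG = RT ln Kd`,
`-TdS = dG - dH`. Fitting a bivalent isotherm (one peptide spanning
both protomers of a 14-3-3 dimer) with the monovalent model returns the
diagnostic apparent `n = 0.5`.

**SPR.** Multicycle sensorgrams fitted globally (shared `kon`, `koff`,
`Rmax`) with the 1:1 Langmuir model, plus the steady-state affinity fit
`Req = Rmax C / (Kd + C)` of end-of-injection responses. Analytes that
equilibrate within one sampling interval raise a "kinetics too fast"
error, leaving the steady-state route.

**Thermodynamics and motifs.** `delta_g_table()`, tandem-site
cooperativity `ddG = dG_tandem - (dG_A + dG_B)` with classification,
fold-enhancement ratios, cross-technique concordance tables, and a
scanner classifying phosphosites into the canonical 14-3-3 recognition
modes I (`RXXpS/pTXP`), II (`RX(Y/F)XpSXP`) and III (C-terminal
`XXpSX-COOH`).

**Synthetic data.** Because the raw instrument data behind such studies
are rarely deposited, `gen_fa_titration()`, `gen_itc()` and `gen_spr()`
forward-simulate all three instruments with known ground truth
(including a coupled monomer–dimer mass-action mechanism with an
effective-molarity bridging knob), so every pipeline stage is testable
end to end.

## Worked example

```r
library(phosphofit)

rec <- parse_phosphopeptide("Ac-DCRRTIpSAPVVRPK-NH2",
                            id = "hDMX_361-374", protein_offset = 361)
scan_modes(rec)[, c("protein_position", "residue", "mode")]
#>   protein_position residue mode
#> 1              367       S    I

design <- fa_design(tracer_conc = 50e-9, top_conc = 10e-6,
                    noise_sd = 0.01, seed = 42)
plate <- gen_fa_titration(design, list(type = "single_site", Kd = 98.8e-9))
fa_fit(plate, tracer_conc = design$tracer_conc)
#> <single_site_fit> Kd = 9.033e-08 M (se 3.2e-09 M)

delta_g_table(c(pSer342 = 21e-6, pSer367 = 870e-9, tandem = 14e-9))
#>  peptide_id        Kd           dG
#>     pSer342 2.1e-05 M -26.7 kJ/mol
#>     pSer367 8.7e-07 M -34.6 kJ/mol
#>      tandem 1.4e-08 M -44.8 kJ/mol

cooperativity(delta_g(21e-6), delta_g(870e-9), delta_g(14e-9))
#> <coop_summary> ddG = +16.5 kJ/mol (tandem -44.8 vs sum -61.3):
#>   negatively cooperative (less than additive)
```

Reading: the pSer367 site is a canonical mode I sequence and the
titration recovers its dissociation constant (truth 98.8 nM) within the
noise of a triplicate 1%-channel-noise plate. The tandem peptide binds
far tighter than either site alone, but by ~16 kJ/mol less than the sum
of the two site energies — the avidity gain is real yet negatively
cooperative.

## Layout

- `R/` — motif scanner, binding models and mass-action solver,
  synthetic-data generators, FA/ITC/SPR fitting pipelines, thermodynamic
  reporting.
- `tests/testthat/` — unit, property and round-trip/recovery tests.
- `vignettes/phosphopeptide-binding-analysis.Rmd` — models, assumptions,
  numerical choices and limitations.
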