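Package: phosphofit
Title: Binding Affinity and Cooperativity Analysis for 14-3-3 Phosphopeptide
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying protein-phosphopeptide interactions of the
    14-3-3 adaptor family. Implements fluorescence-anisotropy titration
    processing with tight-binding (ligand-depletion) quadratic fits and
    stepwise biphasic decomposition of two-event dose-response curves, a
    one-set-of-sites isothermal titration calorimetry model with stoichiometry
    estimation, 1:1 Langmuir kinetic and steady-state fits for multicycle
    surface plasmon resonance, thermodynamic (Gibbs energy, enthalpy/entropy
    decomposition) and tandem-phosphosite cooperativity summaries, a coupled
    monomer-dimer mass-action equilibrium solver, classification of candidate
    14-3-3 binding sites into the canonical mode I/II/III recognition
    sequences, and synthetic-data generators for all three instrument types
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve
Config/testthat/edition: 3
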