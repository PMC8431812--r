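Package: eecfold
Title: Entropy-Enthalpy-Compensation Analysis of Protein Folding
Version: 0.1.0
Authors@R:
    person("Maintainer", "eecfold", email = "eecfold@example.org",
           role = c("aut", "cre"))
Description: Rule-based tools for studying protein folding through
    entropy-enthalpy compensation. Classifies amino-acid side-chains by
    their hydrophobic portions and derives a pairwise lateral
    hydrophobic-attraction table; predicts per-residue secondary
    structure (strand/helix/turn/coil) from sequence using
    interval-attraction and turn-blocking rules; scores predictions
    against reference annotations with segment-level coverage and
    success-rate statistics; performs the hydrogen-bond-swap enthalpy
    and hydration-shell entropy bookkeeping behind the compensation
    argument; evaluates a conformational Gibbs free-energy functional
    on union-of-balls molecular models with a force decomposition and a
    toy relaxer; and predicts dimer docking placements from labeled 2D
    surface-patch projections by hydrophobic-overlap maximization under
    a donor-acceptor contact constraint. Ships a synthetic-fixture
    generator so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
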