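Package: cspbind
Title: NMR Chemical Shift Perturbation Interface Mapping and Equilibrium
    Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping protein-protein interfaces from NMR chemical
    shift perturbation (CSP) titrations and for quantifying the underlying
    equilibria. Computes per-residue CSPs from paired free/bound amide peak
    lists with nitrogen scaling and broadening caps, calls active interface
    residues by combining CSPs with relative solvent accessibility
    (Shrake-Rupley SASA), emits ambiguous interaction restraints in CNS/HADDOCK
    tbl dialect, scores candidate complex poses and two-body centre-of-mass
    geometry, and fits one-site ITC isotherms and hyperbolic SPR saturation
    series with full thermodynamic bookkeeping (Kd, dH, dG, -TdS, N).
    Includes seeded synthetic-data generators (planted-interface titrations,
    toy structures with closed-form geometry, binding curves) so every stage
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
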