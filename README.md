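# cspbind

Interface mapping from NMR chemical shift perturbations, and equilibrium
binding analysis, for protein–ubiquitin interaction studies.

## The problem

Small ubiquitin-binding domains (CUE, UBA, UIM, …) are routinely
characterised by the same trio of experiments: a ¹H–¹⁵N HSQC titration
locates the binding surface, isothermal titration calorimetry (ITC) and
surface plasmon resonance (SPR) quantify the equilibria, and the combined
evidence constrains a structural model of the complex. The arithmetic
between the raw observables and the published numbers — per-residue CSPs
with broadening caps, exposure-filtered active-residue calls, ambiguous
interaction restraints, buried surface areas, centre-of-mass geometry, and
one-site binding fits with ΔG/−TΔS bookkeeping — is usually scattered
across ad-hoc scripts. cspbind packages it, with seeded synthetic-data
generators so every stage is testable against known ground truth.

The core quantities:

- **CSP**: Δδ = √((δ<sup>H</sup><sub>bound</sub>−δ<sup>H</sup><sub>free</sub>)² + ((δ<sup>N</sup><sub>bound</sub>−δ<sup>N</sup><sub>free</sub>)/a)²), with
  a = (δ<sup>N</sup><sub>max</sub>−δ<sup>N</sup><sub>min</sub>)/(δ<sup>H</sup><sub>max</sub>−δ<sup>H</sup><sub>min</sub>); broadened signals are set to a
  per-molecule cap (0.3 ppm for ubiquitin, 0.5 ppm for the CUE domain).
- **Active residues**: CSP above the per-molecule mean *and* relative SASA
  (Shrake–Rupley, Tien reference maxima) above 30%.
- **SPR**: R = R<sub>max</sub>·C/(K<sub>D</sub>+C) on plateau responses.
- **ITC**: one-site isotherm with displacement dilution,
  q<sub>i</sub> = V₀·ΔH·([ML]<sub>i</sub> − [ML]<sub>i−1</sub>(1−v/V₀)), fitted for (K<sub>D</sub>, ΔH, N);
  ΔG = RT·ln K<sub>D</sub>, −TΔS = ΔG − ΔH.

## Worked example

Plant a five-residue interface in a 40-residue synthetic titration and
recover it, then refit published-style binding parameters from noiseless
forward-model data:

```r
library(cspbind)

tt <- make_titration(40, interface_residues = c(5, 6, 7, 24, 38),
                     interface_csp_mean = 0.4, background_csp_sd = 0.01,
                     seed = 11)
prof <- compute_csp(tt$pairs, cap = 0.5)
prof
#> <csp_profile> 40 residues (0 broadened/capped, 0 missing)
#>   a = 7.851, cap = 0.5 ppm, mean CSP = 0.0574 ppm, 5 above mean
csp_above_mean(prof)
#> [1]  5  6  7 24 38
```

The scaling factor (7.85) is the ratio of ¹⁵N to ¹H dispersion; the mean
CSP (0.057 ppm) is the interface threshold, and exactly the five planted
residues exceed it.

```r
C <- c(0.05, 0.15, 0.5, 1.5, 5, 15, 30, 50) * 1e-6   # molar
fit_spr(C, spr_response(C, 0.43e-6, 100))
#> <binding_fit> SPR saturation (hyperbolic) at 298.15 K
#>   K_D = 0.43 uM (+/- 1.6e-16)
#>   R_max = 100 RU, dG = -8.69 kcal/mol

expt <- simulate_itc(27.5e-6, -5.2, 0.915,
                     cell_conc = 100e-6, syringe_conc = 1e-3)
fit_itc(expt)
#> <binding_fit> ITC one-site isotherm at 293.00 K
#>   K_D = 27.5 uM (+/- 2.4e-13)
#>   dH = -5.2 kcal/mol, N = 0.915, dG = -6.11, -TdS = -0.914 kcal/mol

fold_change(28.1, 0.43)
#> [1] 65.34884
```

Both fitters recover their generating parameters to machine precision on
noiseless data; the fold change is the ~65-fold affinity gain of the
dimerising tandem construct over the isolated domain for M1-linked diUb.

A thin command-line wrapper over the same functions ships in
`inst/scripts/cspbind.R` (subcommands `csp`, `sasa`, `fit-spr`, `fit-itc`,
`simulate`, `dimer-check`, `run`), and `run_pipeline()` chains
peak lists → CSP → SASA → active/passive calls → restraints → optional
pose scoring from a single JSON config.

See `vignettes/interface-mapping-methods.Rmd` for the model assumptions,
parameter defaults and design choices.

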