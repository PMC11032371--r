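---
title: "From NMR titrations to binding models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From NMR titrations to binding models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspbind)
```

cspbind implements the quantitative backbone of a common structural-biology
campaign: characterising how a small ubiquitin-binding domain (here, the
C-terminal CUE domain of N4BP1 and its tandem RNase–CUE construct) engages
mono- and di-ubiquitin. The wet-lab observables are HSQC titrations, ITC
isotherms and SPR plateau series; the computational steps between them —
chemical shift perturbation (CSP) mapping, solvent-accessibility filtering,
ambiguous-restraint generation, geometric model checking and equilibrium
fitting — are what this package provides, each testable on synthetic data
with known ground truth.

## Chemical shift perturbation mapping

A ¹H–¹⁵N HSQC titration gives, per backbone amide, a free-state and a
bound-state peak position. The combined perturbation is

$$\Delta\delta \;=\; \sqrt{(\delta^H_\mathrm{bound}-\delta^H_\mathrm{free})^2
 + \left(\frac{\delta^N_\mathrm{bound}-\delta^N_\mathrm{free}}{a}\right)^2},
 \qquad
 a = \frac{\delta^N_{\max}-\delta^N_{\min}}{\delta^H_{\max}-\delta^H_{\min}},$$

where the scaling factor $a$ compresses the much wider ¹⁵N dispersion onto
the ¹H scale. Design choices that the formula alone does not fix:

* **Pooling for $a$.** The extrema are taken over free *and* bound states of
  the titrated molecule. This is the most inclusive reading and is stable as
  peaks move; in practice the amide envelope barely changes, so $a$ lands
  near its physical value of ~7 for well-dispersed proteins.
* **Capping.** Signals broadened beyond detection in the bound state have
  moved at least as far as anything measurable, so they are *set to* a cap
  (0.3 ppm when the titrated molecule is ubiquitin, 0.5 ppm for the CUE
  domain — the conventional per-molecule maxima for these spectra); large
  measured CSPs are clipped to the same cap and flagged. Capped residues
  enter the per-molecule mean at their cap: they are maximal perturbations,
  and excluding them would bias the interface threshold downward.
* **Thresholding.** The interface candidate set is every residue with
  $\Delta\delta$ strictly greater than the arithmetic mean over the
  molecule's non-missing residues. Strict inequality makes the all-equal
  case return the empty set rather than everything. The mean is computed
  after capping, consistent with including capped residues at their cap.
* **Missing vs broadened.** A residue observed free but not bound is
  broadened (gets the cap); a residue observed in neither state is missing
  and excluded from the mean.

`assignment_completeness()` reports the fraction of potential backbone and
side-chain resonances assigned. What counts as "potential" is a bookkeeping
convention with no single standard, so the inventory is table-driven and
exposed: the default backbone inventory is {N, H, Cα, Cβ, C′} with no Cβ
for glycine and no amide H for proline, and the side-chain table counts
carbons, their attached proton groups (one per methyl, two per
diastereotopic methylene) and protonated side-chain nitrogens, excluding
hydroxyl/thiol protons. Completeness statistics quoted elsewhere may use a
different inventory; pass your own tables to reproduce them.

## Solvent accessibility and interface geometry

SASA uses the Shrake–Rupley sphere-point method: each atom's van der Waals
sphere is inflated by the probe radius (1.4 Å ≈ water), sampled with a
deterministic golden-section spiral of `n_points` quasi-uniform points
(default 960), and the exposed fraction of points sets the atom's area.
Determinism was chosen over random sampling so results are bit-stable;
the cost is that the quadrature error at a fixed orientation oscillates
with `n_points` rather than shrinking smoothly, which is why the test suite
measures convergence as orientation-averaged error against the two-sphere
closed form. At 960 points an isolated sphere is accurate to well under 1%.

Radii are a Bondi-style element table. Structures without hydrogens
automatically switch to a united-atom variant (C 1.90, N 1.65, O 1.55,
S 1.90 Å) that absorbs the implicit protons; deposited models come both
ways, so `radii = "auto"` inspects the structure.

Relative accessibility divides each residue's SASA by a per-type reference
maximum (the theoretical Gly-X-Gly maxima of Tien et al. 2013, shipped as a
swappable table). The 30% exposure rule used for active-residue calling
depends on this scale; making the table explicit keeps the rule auditable.

Buried surface area is the three-call identity
$\mathrm{BSA} = \mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB)$,
reported both as the total (both faces) and per side; published interface
areas are quoted in either convention, and for this system the ~830 Å²
CUE–Ub interface is consistent with the total-area reading.

## Active residues, passive residues, ambiguous restraints

A residue drives docking restraints only if it is both strongly perturbed
(CSP above the molecule's mean) and solvent exposed (relative SASA > 30%):
buried residues with large CSPs respond to indirect conformational strain
and are reported separately as "buried responders" rather than silently
dropped. Passive residues are the exposed neighbours of the active set
(any atom within 6.5 Å, the common docking convention, since no tighter
definition is standard).

Each active residue contributes one ambiguous interaction restraint (AIR)
against the union of the partner's active and passive residues, serialised
in the CNS/HADDOCK `tbl` dialect with bounds [0, `d_max`], `d_max` = 2 Å by
default (the upstream docking default). When scoring a pose, the effective
distance of a restraint is the *minimum* atom-pair distance to the target
group — deliberately simpler than the r⁻⁶ sum-averaging used by docking
engines. The minimum is monotone under rigid separation and ranks poses
identically in the regimes that matter here; the divergence is documented
rather than hidden. Violations contribute quadratically
($\sum \max(0, d_\mathrm{eff}-d_\mathrm{max})^2$), and model ranking is
lexicographic: satisfaction, then violation energy, then buried surface
area, then input order (stable).

The dimer geometry check asks whether two ubiquitin-binding domains could
engage both moieties of M1-linked diUb simultaneously: their centres of
mass must sit near 31 Å apart. The paper-scale figure is approximate, so
the tolerance is explicit (default ±2 Å) and the COM selection (all atoms
vs backbone, author residue ranges per protomer) is user-configurable,
since deposited dimer models vary in chain naming and hydrogen content.

## Equilibrium binding

**SPR.** When kinetics are too fast to resolve, plateau responses follow
the hyperbolic saturation law $R = R_\mathrm{max} C / (K_D + C)$, fitted by
nonlinear least squares. A series whose top response stays below 60% of
the fitted $R_\mathrm{max}$ is flagged non-saturating.

**ITC.** Injection heats follow the standard single-site model with
displacement dilution: each 2 µl injection into the 200 µl cell scales all
prior cell concentrations by $(1 - v/V_0)$, the bound complex solves the
one-site quadratic, and the heat credits complex lost to displacement:

$$q_i = V_0\,\Delta H\,\big([ML]_i - [ML]_{i-1}(1 - v/V_0)\big).$$

The default schedule mirrors common microcalorimeter practice (20 × 2 µl,
cell 50–100 µM, syringe ten-fold, 293 K). The cell volume (200 µl) is a
typical value for this instrument class; recovery tests are
volume-consistent by construction, so the choice affects realism, not
correctness. The first injection is kept by default — discarding it is a
common convention, so it is a flag, not silent behaviour. Fits run on a
log-parameterisation of $K_D$ and $N$ (both positive by construction) via
Levenberg–Marquardt; starting values come from the first-injection
enthalpy, the heat midpoint (stoichiometry) and the cell concentration.
Fits with a Wiseman c-value ($N M_0 / K_D$) outside [0.1, 1000] are
flagged: below, the isotherm has no curvature; above, it is a step and the
curvature at the equivalence point no longer encodes $K_D$.

Bookkeeping uses $\Delta G = RT\ln K_D$ with $R = 1.9872\times10^{-3}$
kcal/(mol K), $-T\Delta S = \Delta G - \Delta H$, at 293 K for ITC and
298.15 K for SPR. `thermo_table()` also accepts transcribed literature
rows and reports the rounding residual $|\Delta H + (-T\Delta S) - \Delta G|$
instead of asserting it — published tables are rounded and occasionally
internally inconsistent. "No binding detected" is an explicit outcome, not
a failed fit: all-zero SPR responses, or total ITC heat under ~1 µcal,
raise it directly.

Affinity comparisons are plain ratios of $K_D$s (`fold_change()`); for this
system the tandem RNase–CUE construct against M1-diUb versus the isolated
CUE domain gives 28.1/0.43 ≈ 65.

## The synthetic-data generators

The generators define the regime in which the package is validated:

* `make_titration()` draws free peaks uniformly in the amide region (¹H
  6.5–10.5 ppm, ¹⁵N 103–133 ppm) and displaces bound peaks so the planted
  CSPs are *exactly* recoverable: displacement directions are chosen inward
  at the spectral extremes, so the pooled extrema — and hence the scaling
  factor — are fixed by the free state. Defaults (interface CSP 0.4 ppm,
  background 0.02 ppm) mirror a clear mid-exchange titration; the generator
  refuses plants whose mean is within 3 background standard deviations, so
  "noiseless-limit recovery" tests are meaningful by construction.
* `make_toy_structure()` builds bodies with closed-form geometry (isolated
  spheres, far pairs, a 100°-per-residue helix whose COM sits exactly on
  the axis, burial cages) so SASA and COM have analytic oracles.
* `make_binding_data()` front-ends the two forward models and writes the
  exact TSV dialects the fitters read, with a JSON truth sidecar.

All generators are pure functions of (spec, seed), restore the caller's
RNG state, and are bit-reproducible.

What the synthetic data do *not* emulate: peak overlap and assignment
errors, intermediate-exchange line-shape distortion, correlated ITC
baseline drift and dilution heats, SPR mass-transport limitation, or
physically realistic protein packing. Passing tests therefore demonstrate
the correctness of the computations, not robustness to every experimental
pathology.

## Problem sizes and numerical choices

The bundled tests run titrations of 20–50 residues, toy structures of up
to ~70 atoms, SASA quadratures of 250–16 000 points, and 20-injection
isotherms; the noisy recovery study uses 20 seeded parameter triples at 1%
heat noise. These sizes make every oracle brute-forceable while leaving the
algorithms' scaling behaviour unexercised — SASA on full proteins (hundreds
of atoms) works but takes seconds, not milliseconds, in the pure-R
implementation.

Ties and degenerate inputs are handled explicitly: altloc ties keep the
first-seen conformer; zero ¹⁵N dispersion degrades the CSP to |ΔδH| with a
warning, zero ¹H dispersion is an error; the all-equal CSP profile selects
nothing; `rank_models()` preserves input order on exact ties; empty
selections are errors everywhere a mean or COM would be undefined.

## Known limitations

* The NMR-STAR reader handles only the `Atom_chem_shift` loop — enough for
  completeness statistics, not a general STAR parser.
* Restraint satisfaction uses minimum-distance effective distances, so
  absolute violation energies are not comparable with docking-engine
  energies; only the ordering is.
* The ITC model is strictly 1:1 single-site; competitive, sequential or
  multi-site isotherms are out of scope.
* Relative SASA above 1 is possible (extended termini) and intentionally
  not clipped.
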