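---
title: "Ligand-modified trafficking and activation of VEGF receptors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-modified trafficking and activation of VEGF receptors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`vegftraffic` implements a mechanistic, compartmental model of the three
VEGF receptors expressed on human endothelial cells — the receptor tyrosine
kinases VEGFR1 and VEGFR2 and the non-kinase co-receptor Neuropilin-1
(NRP1) — together with four bivalent ligand isoforms: VEGF165a and VEGF121a
(which bind VEGFR1 and VEGFR2) and PLGF1 and PLGF2 (which bind VEGFR1 only).
The heparin-binding isoforms VEGF165a and PLGF2 additionally engage NRP1 or
extracellular-matrix sites through a separate domain.

The cell is reduced to three well-mixed compartments — the plasma membrane
facing the culture medium, Rab4a/5a early endosomes, and Rab11a recycling
endosomes — plus a cumulative degradation pool that absorbs, but never
returns, receptor mass. Receptor monomers are synthesized into the surface
at constant rates; every species is transported between compartments as a
unit by first-order processes (internalization `kint`, fast recycling
`krec4`, transfer `k4to11`, slow recycling `krec11`, degradation `kdeg`
out of the early endosome). Binding and coupling occur in every compartment
where the partners coexist. State variables are molecule counts per cell,
which makes first-order trafficking natural and forces two unit
adjustments: volumetric association constants (M^-1 s^-1) are divided by
N_A x V of the local fluid volume, and membrane coupling constants
((#/um^2)^-1 s^-1) by the local membrane area. An endosome concentrates the
same number of molecules into ~1e6-fold less fluid than the medium, which is
the mechanical origin of the *reservoir effect* analyzed below.

### The reaction network

Complexes are site-typed bond graphs: receptors carry one ligand site,
VEGFR1 and VEGFR2 one homodimerization site, VEGFR1 and NRP1 one mutual
coupling site, ligands two symmetric receptor sites and (heparin-binding
isoforms) one NRP1/matrix site. Exclusion rules encode the biology: NRP1
coupled to VEGFR1 admits no ligand on either partner interface for the
NRP1-binding isoforms; VEGF165a bridges NRP1 and VEGFR2 but cannot engage
NRP1 and matrix simultaneously; VEGFR1–VEGFR2 heterocomplexes are excluded.
`enumerate_complexes()` closes the rule set exhaustively (deduplicated by an
isomorphism-invariant canonical key), `instantiate_species()` places the
templates into compartments, and `generate_reactions()` emits every
association, dissociation, ring closure/opening, transport and synthesis
reaction mechanically from the graphs.

Under the default rules the counted inventory is exactly 281 species. The
accounting conventions that reproduce that count — receptor dimers may carry
one ligand on each ligand site; open (uncoupled) ligand-bridged triads are
distinct species from the delta-closed conformation; matrix-tethered
ligands may engage VEGFR1 or VEGFR2 but matrix complexes are enumerated to
single-ligand depth; the degradation pool is tracked per receptor kind —
were fixed by requiring the full rule set to land on the published total,
and are asserted by the test suite. Matrix-containing species exist only at
the surface and are held at zero concentration in all standard simulations;
four extra uncounted accumulators track degraded ligand for conservation
audits.

### Dimerization kinetics

Measured binding constants describe a 1:1 interaction; the network is
dimerization-explicit. The base association constant is one quarter of the
measured value and symmetry-equivalent bond choices are merged with integer
multiplicities, which restores the 2x (ligand to receptor monomer) and 4x
(ligand to unliganded dimer) statistical on-rates. The base dissociation
constant is sqrt(koff/2), reflecting the two unbinding events needed for
full release. Three derived constants complete the scheme: the in-membrane
capture of a second receptor monomer `kon_LR`, the intramolecular capture of
a dimer partner `kdelta_LR = 1 - koff_LR` (s^-1), and the coupling of two
receptors already bridged by one ligand,
`kdelta_RR = kdelta_LR (kon_RR / kon_LR)`. The available presentation of these
relations is typographically ambiguous, so `derive_coupling_constants()`
exposes them as a pluggable formula. The package default,
`kon_LR = 2 kdelta_LR / Rtot`, is the unique choice that (i) preserves the
printed identity `kdelta_RR / kdelta_LR = kon_RR / kon_LR`, (ii) restores
detailed balance around the monomer-capture / pre-dimerization cycle under
the package's per-bond dissociation counting, and (iii) collapses both
pathways onto the measured 1:1 affinity — which is what makes the simulated
Scatchard line of the full model agree with the classic 1:1 line (the
package reproduces that agreement to within ~3% in slope and ~6% in
intercept on a standard 0.3x–30x KD titration; the acceptance suite asserts
10%).

## Parameters

The parameter set (`default_parameters()`, serialized with explicit units in
`inst/extdata/params_default.json`) is a documented reconstruction: directly
reported values fix the compartment volumes (15 fL of endosomes split 3:1;
1e7 fL of medium per cell), the ligand molecular weights and the dose
conversion factors f1, and the single ligand-induced trafficking change
(3x internalization of ligand-bound VEGFR2); everything else had to be
chosen. The choices, made once and calibrated only against independently
stated facts about the system:

* **Surface receptor baselines** 1800 VEGFR1, 4900 VEGFR2, 68000 NRP1 per
  cell — literature quantitative flow cytometry for HUVEC. Production rates
  are calibrated (`calibrate_production()`) so the pre-simulated steady
  state reproduces these surface levels.
* **Trafficking constants** (s^-1) are set so the no-ligand steady state
  honors the stated localization and stability facts: VEGFR1 fast-cycling
  and degradation-dominant (kint 3.5e-3, kdeg 4e-4; about 10% on the
  surface, ~1 h turnover — the least stable receptor), VEGFR2 slow and
  recycling-poor (kint = kdeg = 2e-4; about half surface, half internal),
  NRP1 recycling-dominant and majority-surface.
* **1:1 binding kinetics**: literature-typical picomolar constants
  (VEGF165a: 33 pM to VEGFR1, 100 pM to VEGFR2, 312 pM to NRP1; PLGF ~170 pM
  to VEGFR1), with koff 1e-3 s^-1 throughout.
* **Receptor-receptor coupling**: koff 1e-2 s^-1; kon chosen per pair to
  give ~40% homodimers of an isolated receptor at its baseline surface
  density (upper half of the stated 30–40% pre-dimerization window) and
  ~35% of surface VEGFR1 coupled to NRP1.
* **Geometry**: 1000 um^2 of plasma membrane; 225 um^2 of endosomal
  membrane from vesicle arithmetic (15 fL enclosed at area/volume = 3/r
  with r ~ 0.2 um), split 3:1.
* **Free endosomal ligand** degrades at 1e-3 s^-1 from the early endosome;
  dissociated intracellular ligand is not resecreted (no washout), matching
  the stated first-order degradation of internalized ligand. Both choices
  are exposed as configuration.

Knockdowns map siRNA targets to rate constants: Rab4a scales both exits
from the early endosome toward recycling (`krec4`, `k4to11`), Rab11a scales
`krec11`; the default efficiency in examples is 90% depletion. Receptor
deletions zero production and are applied before pre-simulation, so
comparisons are always between self-consistent steady states.
Compartment-wise kon/koff multipliers provide the endosomal-pH hooks
(default 1).

## Numerical methods

The mass-action system (285 state variables, ~1700 reactions) is stiff: the
fastest processes (intramolecular closure, ~1 s^-1) and the slowest
(Rab11a exit of VEGFR2, 1e-5 s^-1) span five orders of magnitude. No ODE
solver package being available in the target environment, the package
carries its own: a 4-stage Kaps–Rentrop Rosenbrock method (Shampine
coefficients, embedded 3rd-order error estimate, L-stable) in compiled
code, with the analytic Jacobian assembled from the stoichiometry. Defaults
are rtol 1e-8 and atol 1e-3 molecules/cell; negative excursions are clipped
only below the absolute tolerance, larger ones fail the step. Events
(ligand steps, knockdowns) terminate an integration leg exactly at the
event time; a ligand step at t = 0 is part of the reported t = 0 state.
Pre-simulation integrates 48 h without ligand and then polishes the root
with full Newton steps on the analytic Jacobian (structurally absent
species are excluded to keep it nonsingular), demanding a relative
derivative below 1e-8 per hour; monomer conservation along trajectories
holds to ~1e-10 relative.

## The synthetic-data generator

The measurements being emulated are western-blot band intensities normalized to a
loading control and then to the no-ligand condition: strictly positive,
unit-centered ratios with high replicate scatter, three replicates, at 0,
15, 30, 60, 120 and 240 minutes, under 50 ng/mL of VEGF165a or PLGF1.
`generate_blot_dataset()` emulates exactly that structure: true ratios from
a simulated trajectory times multiplicative lognormal noise of unit mean,
CV 0.2 by default (replicate variability is reported as high, without a noise model),
independent across time points and replicates. It does not emulate
within-blot correlation, loading-control error, saturation of the
chemiluminescent signal, or band-quantification artifacts — so a green
recovery test establishes identifiability under idealized noise, not
robustness to systematic blot error. `recovery_fixture()` seals a true
internalization multiplier with a noisy dataset; the scan recovers a truth
of 3 in at least 95% of seeds at CV 0.15, and recovery degrades
monotonically as the CV grows.

## Analyses and design decisions

* **Internalization-multiplier scan** (`internalization_multiplier_scan()`):
  simulates the VEGF165a treatment with the ligated-VEGFR2 `kint` at 1, 2,
  3, 4 and 8 times the unligated value and minimizes the summed squared
  residual against the normalized surface/internal/whole-cell ratios, all
  localizations weighted equally, measured time points only. The 3x
  override applies to every complex containing ligand-bound VEGFR2
  (including NRP1-bridged ones). With it, surface VEGFR2 falls to ~34% by
  4 h while internal VEGFR2 rises transiently and returns near baseline —
  the production/degradation balance, not a degradation change, restores
  the internal level. Degradation or recycling overrides fail this pattern
  (no surface decline; persistent internal loss), which is the
  model-selection argument for the single-mechanism explanation.
* **Decoy metric** (`decoy_effect()`): percent change in active
  (receptor–ligand–receptor) complexes of a target receptor when a
  competing receptor is deleted, both scenarios independently
  pre-simulated. Active complexes count one per bridging ligand, delta
  closure not required. The evaluation time defaults to 4 h (the published
  curves span 4 h without printing an anchor; competition uses the printed
  2 h anchor).
* **Competition grids** (`competition_grid()`): co-administration over a
  dose grid with zero rows/columns as single-ligand references, readouts
  resolved per bridging ligand, percent reduction relative to the matching
  reference.
* **Sensitivity** (`local_sensitivity()`): normalized local sensitivity
  (percent output change over percent parameter change), one-sided
  five-fold increases by default, with a symmetric option. Fold-stability
  holds for near-linear outputs (e.g. receptor totals against production
  rates, sensitivity exactly 1); strongly saturating outputs are
  fold-dependent by nature, so robustness checks should shrink the fold
  rather than expect invariance.
* **Scatchard comparison** (`scatchard()`): equilibrium titration with
  transport off under three representations — single-step 1:1 binding to
  pre-dimerized receptors (Rtot/2 sites in ligand units, the closed-form
  comparator), ligand-induced dimerization only, and the full scheme.
  Bound ligand counts molecules, as a radioligand assay would.

## Known limitations, and one honest disagreement

With the reconstructed parameter set the package reproduces the reference
unit conversions, species inventory, baseline localization and stability
asymmetries, the 3x-internalization mechanism and its alternatives'
failure, the intracellular bias of active complexes, the NRP1
dose-dependent enhancement of receptor activation, and the high-dose
ligand-competition percentages. Two reference quantities disagree, and the
acceptance suite reports them red rather than loosened:

* **Low-dose competition** between VEGF165a and PLGF1 is stronger here
  (13%/29% at 5 ng/mL against the reference 3.7%/15%): with picomolar
  literature affinities, 5 ng/mL (~114 pM) already saturates VEGFR1
  substantially. The original binding-constant table, which is not available for
  transcription, presumably differs.
* **The full-model decoy sign.** Deleting VEGFR1 here *reduces* active
  VEGFR2 (~-16 to -19% at 2.5-5 ng/mL) instead of increasing it. Two real
  mechanisms compete: VEGFR1 removes ligand (the decoy role), but it also
  ferries ligand into endosomes and, through direct NRP1 coupling, drags
  NRP1 into its fast degradative itinerary — so removing VEGFR1 both cuts
  the endosomal ligand supply and raises the NRP1 level, and with this
  parameter set those effects win. In an NRP1-null configuration the
  package shows the published signature exactly: essentially no decoy
  effect at the surface and a large intracellular effect (+50% at
  5 ng/mL) that shrinks with dose — the reservoir effect in its pure form,
  asserted green in the test suite. The sign of the full-model effect
  therefore hinges on the NRP1 coupling/trafficking balance in the
  unavailable original parameter tables, not on the competition machinery.

Other limitations: no autocrine ligand secretion, no VEGFR1–VEGFR2
heterodimers, no downstream phosphorylation or phosphatases, matrix sites
present but empty, deterministic continuum kinetics only, and replicate
noise independent across time points.
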