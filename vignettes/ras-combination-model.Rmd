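---
title: "Modeling combined KRAS G12C and EGFR inhibition with rascycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling combined KRAS G12C and EGFR inhibition with rascycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rascycle)
```

## The biological question

Cancers driven by KRAS G12C respond better to a covalent G12C inhibitor
combined with an EGFR inhibitor than to either drug alone, and the
combination suppresses not only mutant but also wild-type RAS-GTP. The
hypothesis encoded here is that the shared GAP, NF1, mediates the
crosstalk: codon-12 mutant RAS is insensitive to GAP catalysis yet
still binds NF1, so a mutant pool held in its GTP state sequesters NF1
and de-represses the wild-type pools. Covalently removing the mutant
frees NF1 onto wild-type RAS, while EGFR inhibition removes the GEF
drive — two mechanistically independent hits on the same wild-type
signal, which is where synergy can arise.

## Model structure and assumptions

The model is a mass-action reaction network over competing RAS pools
(isoform x genotype) sharing one GEF, one GAP and one effector, built
by `build_network()` from `ras_pool()` and `base_parameters()`.

Assumptions worth making explicit:

* **Explicit enzyme complexes, not Michaelis–Menten.** NF1
  sequestration *is* the mechanism of interest, so a bound-GAP species
  must exist; quasi-steady-state kinetics would erase it. GEF and
  effector get the same explicit treatment for consistency.
* **Lumped nucleotide exchange.** GDP release, the nucleotide-free
  intermediate and GTP loading are collapsed into a single GDP→GTP
  conversion, justified by the large cellular GTP excess. No observable
  used here distinguishes the two formulations, and the lumping saves
  one species per pool.
* **Protein turnover for RAS only.** Every RAS-containing species is
  produced into the GDP state and degrades first-order with a 24 h
  half-life; degradation of a complex returns the enzyme intact. GEF,
  GAP and effector are not themselves turned over.
* **Intrinsic hydrolysis continues inside the GAP complex.** A
  GAP-bound mutant that GAP cannot catalyse still hydrolyses GTP at its
  own (reduced) rate, releasing free GAP — without this, mutant-bound
  NF1 would only recycle by dissociation and degradation.
* **Genotype profiles.** Codon-12 mutants: intrinsic GTPase at 72% of
  wild type, GAP kcat = 0, effector dissociation ×1.2. G12C adds a
  ten-fold weaker NF1 interaction (Km,GAP ×10) and is the only
  drug-accessible genotype; G12V shares the codon-12 defaults but keeps
  wild-type NF1 binding and is never drugged. The Km,GAP scaling is
  realised by dividing the association rate by 10 (dissociation and
  catalysis untouched), reading the weakened interaction as a binding
  defect.

## Pharmacology

* **Covalent G12C inhibition** uses the composite second-order constant
  kinact/Ki (9900 M⁻¹s⁻¹ for AMG-510, 76 M⁻¹s⁻¹ for ARS-853) times a
  clamped intracellular dose: drug depletion, efflux and the reversible
  pre-equilibrium are not modeled. Only *free* GDP-bound G12C is
  accessible (not GEF-bound), the simplest mechanism consistent with
  GDP-state selectivity. The adduct is inert — it binds neither GEF,
  GAP nor effector — and degrades at the normal RAS rate (assumed equal
  for lack of evidence either way).
* **EGFR inhibition** scales GEF association *and* catalysis by
  `1 − f`: receptor-level inhibition removes GEF recruitment, i.e.
  reduces the effective active GEF concentration, which affects
  engagement and turnover alike. Extracellular doses map to `f` through
  a Hill link (`egfr_inhibition()`); the intracellular coupling is not
  a measured constant, so the link's midpoint is declared
  configuration. The shipped default (ic50 = 0.2 µg/ml, hill = 1,
  max inhibition = 1) places the 1 µg/ml working dose at ~83% GEF
  inhibition, consistent with that dose producing strong but
  saturable pathway suppression.
* **Knockdowns** act on what siRNA actually perturbs: NF1 knockdown
  scales the conserved GAP total, KRAS knockdown scales KRAS *production*
  (mutant and wild-type KRAS pools alike), letting pre-existing protein
  decay at the 24 h half-life. Knockdown phenotypes are therefore
  steady-state (≥48 h) quantities.

## Baseline parameters

The wild-type reference constants are configuration, not measurements;
they are pinned in `inst/extdata/default_model.yaml` so every result is
reproducible from one declared file. The regime constraints that guided
them:

| parameter | default | why |
|---|---|---|
| `k_act_intrinsic`, `k_hyd_intrinsic` | 1e-4, 3.5e-4 s⁻¹ | intrinsic cycling slow; enzymes dominate |
| GEF kon/koff/kcat | 1e7 M⁻¹s⁻¹, 1, 1 s⁻¹ | Km ≈ 0.2 µM, comparable to RAS levels |
| GAP kon/koff/kcat | 1e7 M⁻¹s⁻¹, 0.1, 10 s⁻¹ | efficient catalysis; wild-type RAS-GTP held to a few percent at vehicle |
| totals GEF/GAP/EFF | 20, 100, 40 nM | effector ≪ RAS total (400 nM); GAP sub-stoichiometric so sequestration matters |
| `t_half` | 86400 s | 24 h RAS protein half-life |

With these defaults the all-wild-type network sits at ~5% GTP-bound at
vehicle, and the heterozygous G12C network sequesters roughly a third
of NF1 — enough for the mutant→wild-type crosstalk to be visible
without dominating.

The heterozygous cell model splits KRAS production 50/50 between G12C
and wild type, with total production divided KRAS:NRAS:HRAS = 2:1:1
(configurable); the homozygous model makes all KRAS production mutant.

## Numerics

Steady states are found by stiff integration (deSolve's `lsoda`,
rtol 1e-9, atol 1e-12 M) in doubling horizons until the relative state
change over a one-hour window falls below 1e-9, polished by a damped
Newton iteration with the analytic mass-action Jacobian. Two details
matter:

* The conservation laws (free + complexed GEF/GAP/EFF constant) make
  the raw Jacobian exactly singular, so the free-species rows of the
  Newton system are replaced by the conservation constraints — this
  simultaneously regularises the solve and pins the conserved totals.
* Newton steps are limited fraction-to-the-boundary so no concentration
  goes negative; after each integration chunk a Newton attempt is made,
  and whichever of integrator/Newton has the lower residual wins.
  Convergence means max |dx/dt| ≤ 1e-9 × max concentration; failure is
  flagged on the result, never raised, so grids can report partial
  results.

Treatments are applied to a pre-equilibrated cell: treated solves start
from the vehicle steady state (a timecourse mode exists to check that
48 h endpoints are near-stationary, which they are with a 24 h
half-life). Dose-grid cells all start from the same vehicle state, so
cells are independent and execution order cannot change results. A
knocked-down GAP total is imposed by rescaling the GAP-containing
species of the starting state onto the new conserved total.

Degenerate inputs: pools may use explicit production rates instead of
abundance fractions (including zero production); enzyme totals of zero
drop the corresponding species and reactions entirely, which is how the
closed-form single-pool test cases are built.

## Synergy scoring

Readouts (or viability values) are converted to fraction affected,
`fA = 1 − value/vehicle`, clamped to [0, 1] — the same transform for
model RAS-GTP and viability so both travel one code path; for noisy
viability data the clamp count is recorded on the effect matrix.
`eob_matrix()` uses row/column margins as the monotherapies and scores
interior cells with `(fA_combo − [fA_A + fA_B − fA_A·fA_B]) × 100`;
margins are defined as EOB = 0. Matrices are oriented rows = EGFRi
dose, columns = G12Ci dose, vehicle at (1,1), and serialised with their
axes so no orientation ambiguity survives in files. Replicate EOB
matrices are computed per replicate and then averaged
(`aggregate_replicates()`); averaging effects first is available by
composing the same functions in the other order.

A scoring caveat that the model makes visible: when one monotherapy
margin approaches complete effect (fA → 1), the Bliss expectation
approaches the combination ceiling and EOB necessarily compresses
toward zero — at the extreme high-dose corner of the default grids the
wild-type readout's EOB even dips marginally below zero, because at
near-total GEF inhibition the EGFR inhibitor alone has already freed
most of the NF1. Synergy claims should therefore be read from the
sub-saturating interior of the grid, where all three readouts (total,
mutant, wild-type RAS-GTP) score clearly positive.

## Synthetic data: what it emulates and what it does not

`generate_viability_plate()` emulates an MTT drug-combination grid: a
noise-free surface `floor + (1 − floor) · m^gamma` of the
vehicle-normalised total RAS-GTP `m`, times i.i.d. multiplicative
lognormal noise per replicate (sigma 0.1 by default, keeping
OD-like values positive). The power-law link with a floor is a declared
emulation device — the experiments measure viability and RAS-GTP
separately and provide no link — and the generating truth is stored
beside every dataset. `generate_pulldown()` emulates four-arm RBD
pulldown quantifications per isoform, each replicate normalised to its
own vehicle replicate as blots are normalised per experiment, plus a
phenomenological pERK proxy (a Hill function of total RAS-GTP standing
in for the MAPK cascade, which is deliberately not modeled).

Not emulated: plate edge effects, western-blot loading-control errors,
imaging saturation, biological (non-lognormal) replicate structure, and
any viability effect not mediated by total RAS-GTP. Passing pipeline
tests therefore show internal consistency of the analysis chain, not
fidelity of these generators to real assay noise.

Generators are pure functions of (configuration, seed), restore the
caller's RNG state, and refuse unconverged grids.

## Parameter recovery

`recover_link_parameters()` refits (gamma, floor, ic50) from a plate by
least squares against the mechanistic surface. Because the EGFRi dose
enters only through the GEF-inhibition fraction `f`, the steady-state
surface is precomputed on an `f`-grid per G12Ci dose (13 nodes,
monotone Hyman splines) and interpolated during the Nelder-Mead search
over (log ic50, log gamma), with the baseline solved in closed form at
each step; a grid of nine starts guards against local basins. For
noise-free plates a final polish re-evaluates the objective with exact
warm-started Newton solves, so recovery is limited by arithmetic, not
interpolation. For noisy plates the spline objective is used throughout
— its interpolation error is orders of magnitude below the noise floor.
A deliberately mismatched candidate network (e.g. G12V in place of
G12C) leaves a large residual, which is the package's model
discrimination check.

## Problem sizes

The shipped analyses use 8 × 8 dose grids (two-fold ladders bracketing
the 250 nM and 1 µg/ml working doses), 24-species networks, triplicate
synthetic replicates at sigma 0.05–0.1, and 20-seed Monte-Carlo
recovery runs; the steady-state oracle comparisons integrate ten
protein half-lives. These sizes resolve every qualitative claim while
keeping a full run on one CPU in the minutes range.

## Known limitations

* No downstream MAPK/ERK dynamics, negative feedback, receptor-level
  signaling, RAS dimerisation, membrane compartments, or
  isoform-specific effector preferences; pERK appears only as a
  phenomenological readout proxy in the synthetic data.
* Wild-type reference rate constants are declared, not fitted to data;
  conclusions should be read as structural (orderings, signs, synergy
  patterns) rather than quantitative predictions.
* Drug exposure is clamped; no PK, efflux or inhibitor decay.
* Bliss is the only synergy framework implemented (no Loewe, HSA, ZIP
  or combination-index scores).
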