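# rascycle

Mechanistic modeling of why combining a covalent KRAS G12C inhibitor
(e.g. sotorasib/AMG-510) with an EGFR inhibitor (e.g. cetuximab)
suppresses **both mutant and wild-type** RAS-GTP synergistically.

## The problem

Oncogenic KRAS G12C can be drugged covalently in its GDP-bound state,
yet G12C-mutant colorectal cancers respond poorly to monotherapy, and
the combination with EGFR inhibition works better than either drug
alone. One proposed mechanism runs through the shared negative
regulator NF1 (a RAS GAP): mutant RAS-GTP is GAP-insensitive but still
*binds* NF1, sequestering it away from the wild-type RAS pools and
elevating wild-type RAS-GTP. Drugging the mutant frees NF1, which then
suppresses wild-type RAS; EGFR inhibition removes the GEF drive on what
remains. `rascycle` implements this hypothesis as a mass-action ODE
model and scores the resulting dose grids for synergy, so the claim is
reproducible and testable in silico.

## The model

Competing RAS pools (indexed by isoform and genotype) share one GEF,
one GAP (NF1) and one effector. Per pool `i`, with free species
`R_i·GDP` and `R_i·GTP` and explicit enzyme complexes:

* turnover: `∅ → R_i·GDP` at rate `s_i`; every RAS-containing species
  degrades at `d = ln 2 / t_half` (t_half = 24 h), complexes releasing
  their partner intact;
* exchange: `R_i·GDP → R_i·GTP` intrinsically (`k_act`) and via
  `GEF + R·GDP ⇌ GEF:R·GDP → GEF + R·GTP`;
* hydrolysis: `R_i·GTP → R_i·GDP` intrinsically (`k_hyd,i`) and via
  `GAP + R·GTP ⇌ GAP:R·GTP → GAP + R·GDP` (`k_cat,i`); intrinsic
  hydrolysis continues inside the GAP complex;
* effector binding: `EFF + R·GTP ⇌ EFF:R·GTP`.

Codon-12 mutants use the measured defects: `k_hyd × 0.72`,
GAP `k_cat = 0` (hence NF1 sequestration), effector `k_d × 1.2`; G12C
additionally has `K_m,GAP × 10` and is the only genotype reachable by
the covalent inhibitor, which converts free `R·GDP` to an inert adduct
at the pseudo-first-order rate `(k_inact/K_i) · [drug]`
(9900 M⁻¹s⁻¹ for AMG-510, 76 M⁻¹s⁻¹ for ARS-853). EGFR inhibition
scales GEF association and catalysis by `1 − f`, with `f` either given
directly or through a Hill link from an extracellular dose.

Steady states over 2-D dose grids are converted to fraction affected,
`fA = 1 − readout/vehicle`, and scored with excess over Bliss:

    EOB = ( fA_combo − [fA_A + fA_B − fA_A·fA_B] ) × 100 .

A synthetic-data module emulates the corresponding wet-lab experiments
(MTT viability grids with lognormal replicate noise, four-arm RBD
pulldown intensities) for pipeline tests and parameter recovery.

## Worked example

```r
library(rascycle)

net <- build_network(heterozygous_g12c_pools(), base_parameters())
vehicle <- find_steady_state(net)
vehicle
#> <ras_steady_state> converged (residual 4.34e-24 M/s)
#>   RAS-GTP: total 1.229e-07 M (mutant 9.944e-08, wild-type 2.346e-08)
#>   free GAP 6.431e-08 M; adduct fraction 0; effector occupancy 0.386

combo <- find_steady_state(
  net,
  treatment(g12ci = amg510(250),                       # 250 nM
            egfri = egfr_inhibition(dose = 1, ic50 = 0.2)),  # 1 ug/ml
  init = vehicle$state
)
combo
#> <ras_steady_state> converged (residual 1.31e-22 M/s)
#>   RAS-GTP: total 6.29e-09 M (mutant 4.74e-09, wild-type 1.55e-09)
#>   free GAP 9.789e-08 M; adduct fraction 0.949; effector occupancy 0.0269
```

At vehicle, the GAP-insensitive mutant keeps most of its pool GTP-bound
and sequesters ~36% of NF1, elevating wild-type RAS-GTP. The
combination engages 95% of the mutant, frees NF1 (free GAP rises from
64% to 98% of total), and drops wild-type RAS-GTP 15-fold — the
co-suppression phenotype. The full in-silico combination experiment:

```r
res <- run_synergy_grid_scenario(default_model_config(), out_dir = "out")
res$synergy$total_ras_gtp
#> <ras_synergy_matrix> 8 x 8, source = model_total_ras_gtp
#>   interior EOB: min 3.12, mean 22.88, max 48.40 points
```

Positive interior EOB (synergy) appears for total, mutant *and*
wild-type RAS-GTP readouts on the G12C network, and vanishes
(|EOB| < 1e-6) on all-wild-type or G12V control networks, where the
covalent drug is a structural no-op.

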