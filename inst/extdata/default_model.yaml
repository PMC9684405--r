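# Pinned default configuration of the RAS cycling model.
#
# The wild-type reference constants are configuration, not measured
# ground truth; they are chosen so that (i) intrinsic exchange and
# hydrolysis are slow (~1e-4 /s) and enzymes dominate cycling, (ii) the
# GAP keeps wild-type RAS-GTP low (a few percent of total RAS at
# vehicle), (iii) the effector total is small relative to total RAS,
# and (iv) RAS turnover follows a 24 h protein half-life.
# Units: M, s. Doses carry explicit unit suffixes and are converted
# internally.

base_parameters:
  k_hyd_intrinsic: 3.5e-4     # 1/s, wild-type intrinsic GTP hydrolysis
  k_act_intrinsic: 1.0e-4     # 1/s, intrinsic GDP->GTP exchange (GTP excess lumped)
  gef_kon: 1.0e+7              # 1/(M s)
  gef_koff: 1.0               # 1/s
  gef_kcat: 1.0               # 1/s
  gap_kon: 1.0e+7              # 1/(M s); wild-type Km,GAP = (koff+kcat)/kon
  gap_koff: 0.1               # 1/s
  gap_kcat: 10.0              # 1/s
  eff_kon: 1.0e+7              # 1/(M s)
  eff_koff: 1.0               # 1/s, wild-type effector dissociation
  gef_total: 2.0e-8           # M
  gap_total: 1.0e-7           # M (NF1)
  eff_total: 4.0e-8           # M, << total RAS
  ras_total: 4.0e-7           # M, sets production = ras_total * log(2)/t_half
  t_half: 86400               # s, RAS protein half-life (24 h)

# KRAS G12C heterozygous cell model: KRAS production split 50/50
# mutant/wild-type, total RAS production KRAS:NRAS:HRAS = 2:1:1.
pools:
  - {name: KRAS_G12C, isoform: KRAS, genotype: G12C, abundance_fraction: 0.25}
  - {name: KRAS_WT,   isoform: KRAS, genotype: WT,   abundance_fraction: 0.25}
  - {name: NRAS_WT,   isoform: NRAS, genotype: WT,   abundance_fraction: 0.25}
  - {name: HRAS_WT,   isoform: HRAS, genotype: WT,   abundance_fraction: 0.25}

# Hill link mapping extracellular EGFR-inhibitor dose (ug/ml) to the
# fractional loss of GEF activity. The intracellular coupling is not a
# measured constant; the midpoint is placed below the 1 ug/ml working
# dose so that dose produces strong (~83%) GEF inhibition.
egfri_link:
  ic50_ug_per_ml: 0.2
  hill: 1
  max_inhibition: 1

# Default 8 x 8 dose grids (vehicle first), log-ish spacing bracketing
# the 1 ug/ml and 250 nM working doses.
doses:
  g12ci_nM: [0, 15.625, 31.25, 62.5, 125, 250, 500, 1000]
  egfri_ug_per_ml: [0, 0.0625, 0.125, 0.25, 0.5, 1, 2, 4]

# Working single doses used by the four-arm comparisons.
treatment:
  g12ci: {name: AMG-510, dose_nM: 250}
  egfri: {dose_ug_per_ml: 1}

# Synthetic-data defaults: multiplicative lognormal noise on positive
# intensities, power-law viability link with a baseline floor.
synthetic:
  sigma: 0.1
  n_replicates: 3
  link: {gamma: 1, floor: 0.1}
  perk: {hill: 2, k_half_rel: 0.5}
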