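#' Baseline (wild-type) kinetic parameters for the RAS cycling model
#'
#' Collects the wild-type reference rate constants that every RAS pool
#' modifies through its genotype multipliers, together with the shared
#' enzyme/effector totals and RAS turnover. All concentrations are molar
#' and all times are seconds.
#'
#' The exchange step is lumped: GDP release, nucleotide-free RAS and GTP
#' loading are folded into a single GDP -> GTP conversion (intrinsic at
#' `k_act_intrinsic`, GEF-catalysed through an explicit GEF:RAS-GDP
#' complex), justified by the large cellular excess of GTP over GDP.
#' GAP action is likewise explicit (association, dissociation, catalysis)
#' rather than quasi-steady-state Michaelis-Menten, because sequestration
#' of the GAP (NF1) by mutant RAS-GTP is a mechanism of interest and
#' requires a real bound-GAP species.
#'
#' RAS turnover: `ras_degradation = log(2) / t_half` with a default
#' half-life of 24 h, and total zeroth-order production
#' `ras_production_total` defaulting to `ras_total * ras_degradation` so
#' that total RAS at steady state equals `ras_total`.
#'
#' @param k_hyd_intrinsic intrinsic GTP hydrolysis rate of wild-type RAS
#'   (1/s).
#' @param k_act_intrinsic intrinsic (GEF-independent) GDP -> GTP exchange
#'   rate (1/s).
#' @param gef_kon,gef_koff,gef_kcat GEF association (1/(M s)),
#'   dissociation (1/s) and catalytic (1/s) constants.
#' @param gap_kon,gap_koff,gap_kcat GAP (NF1) association, dissociation
#'   and catalytic constants; wild-type Km,GAP is
#'   `(gap_koff + gap_kcat) / gap_kon`.
#' @param eff_kon,eff_koff effector association/dissociation constants for
#'   wild-type RAS-GTP.
#' @param gef_total,gap_total,eff_total conserved totals of the shared
#'   GEF, GAP and effector (M).
#' @param ras_total target steady-state total RAS concentration (M); used
#'   only to derive the default production rate.
#' @param ras_production_total total zeroth-order RAS production rate
#'   (M/s), split across pools by their abundance fractions.
#' @param t_half RAS protein half-life (s); degradation is first order at
#'   `log(2)/t_half` for every RAS-containing species.
#'
#' @return An object of class `ras_base_parameters` (a validated list).
#' @examples
#' base <- base_parameters()
#' base$ras_degradation # ~8.02e-6 /s for a 24 h half-life
#' @export
base_parameters <- function(k_hyd_intrinsic = 3.5e-4,
                            k_act_intrinsic = 1e-4,
                            gef_kon = 1e7,
                            gef_koff = 1,
                            gef_kcat = 1,
                            gap_kon = 1e7,
                            gap_koff = 0.1,
                            gap_kcat = 10,
                            eff_kon = 1e7,
                            eff_koff = 1,
                            gef_total = 2e-8,
                            gap_total = 1e-7,
                            eff_total = 4e-8,
                            ras_total = 4e-7,
                            ras_production_total = NULL,
                            t_half = 24 * 3600) {
  ras_degradation <- log(2) / t_half
  if (is.null(ras_production_total)) {
    ras_production_total <- ras_total * ras_degradation
  }
  base <- list(
    k_hyd_intrinsic = k_hyd_intrinsic,
    k_act_intrinsic = k_act_intrinsic,
    gef_kon = gef_kon, gef_koff = gef_koff, gef_kcat = gef_kcat,
    gap_kon = gap_kon, gap_koff = gap_koff, gap_kcat = gap_kcat,
    eff_kon = eff_kon, eff_koff = eff_koff,
    gef_total = gef_total, gap_total = gap_total, eff_total = eff_total,
    ras_production_total = ras_production_total,
    ras_degradation = ras_degradation,
    t_half = t_half
  )
  rates <- unlist(base[c(
    "k_hyd_intrinsic", "k_act_intrinsic",
    "gef_kon", "gef_koff", "gef_kcat",
    "gap_kon", "gap_koff", "gap_kcat",
    "eff_kon", "eff_koff",
    "ras_production_total", "ras_degradation"
  )])
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all base rate constants must be finite and strictly positive")
  }
  totals <- unlist(base[c("gef_total", "gap_total", "eff_total")])
  if (any(!is.finite(totals)) || any(totals < 0)) {
    stop("enzyme/effector totals must be finite and non-negative")
  }
  structure(base, class = "ras_base_parameters")
}

#' Wild-type Michaelis constant of the GAP reaction
#'
#' @param base a [base_parameters()] object.
#' @return Km,GAP in M: `(gap_koff + gap_kcat) / gap_kon`.
#' @export
gap_km <- function(base) {
  (base$gap_koff + base$gap_kcat) / base$gap_kon
}

.genotypes <- c("WT", "G12C", "G12V")

#' Genotype-specific rate multipliers
#'
#' Codon-12 oncogenic mutants share the measured biochemical defects:
#' intrinsic GTPase reduced to 72% of wild type, complete insensitivity
#' to GAP catalysis (kcat = 0, while intrinsic hydrolysis continues even
#' in the GAP-bound state), and 20% faster dissociation from effectors.
#' G12C additionally binds the GAP (NF1) ten-fold more weakly
#' (Km,GAP x 10, realised as a ten-fold slower association rate) and is
#' the only genotype accessible to covalent G12C inhibitors.
#'
#' @param genotype one of `"WT"`, `"G12C"`, `"G12V"`.
#' @return A list with `gtpase_mult`, `gap_kcat_mult`, `gap_km_mult`,
#'   `effector_kdiss_mult`, `drug_targetable`.
#' @export
mutant_multipliers <- function(genotype) {
  genotype <- match.arg(genotype, .genotypes)
  switch(genotype,
    WT = list(
      gtpase_mult = 1, gap_kcat_mult = 1, gap_km_mult = 1,
      effector_kdiss_mult = 1, drug_targetable = FALSE
    ),
    G12C = list(
      gtpase_mult = 0.72, gap_kcat_mult = 0, gap_km_mult = 10,
      effector_kdiss_mult = 1.2, drug_targetable = TRUE
    ),
    G12V = list(
      gtpase_mult = 0.72, gap_kcat_mult = 0, gap_km_mult = 1,
      effector_kdiss_mult = 1.2, drug_targetable = FALSE
    )
  )
}

#' Apply a genotype's multipliers to the wild-type reference constants
#'
#' @param base a [base_parameters()] object.
#' @param genotype one of `"WT"`, `"G12C"`, `"G12V"`.
#' @param multipliers optionally, a multiplier list overriding
#'   [mutant_multipliers()] for the genotype (`drug_targetable` stays
#'   tied to the genotype and cannot be overridden).
#'
#' @return A list of pool-level rate constants: `k_hyd`, `k_act`,
#'   `gap_kon`, `gap_koff`, `gap_kcat`, `eff_kon`, `eff_koff`, plus the
#'   multipliers and `drug_targetable`. The Km,GAP scaling acts on the
#'   association rate only (`gap_kon / gap_km_mult`), reflecting impaired
#'   binding rather than altered catalysis or release.
#' @examples
#' base <- base_parameters()
#' g12c <- apply_mutant_profile(base, "G12C")
#' g12c$k_hyd / base$k_hyd_intrinsic # 0.72
#' @export
apply_mutant_profile <- function(base, genotype, multipliers = NULL) {
  stopifnot(inherits(base, "ras_base_parameters"))
  if (!is.character(genotype) || length(genotype) != 1L ||
      !(genotype %in% .genotypes)) {
    stop("unknown genotype '", paste(genotype, collapse = ","),
         "'; must be one of ", paste(.genotypes, collapse = ", "))
  }
  mult <- mutant_multipliers(genotype)
  if (!is.null(multipliers)) {
    for (nm in intersect(names(multipliers), setdiff(names(mult), "drug_targetable"))) {
      mult[[nm]] <- multipliers[[nm]]
    }
  }
  num <- unlist(mult[c("gtpase_mult", "gap_km_mult", "effector_kdiss_mult")])
  if (any(num <= 0) || mult$gap_kcat_mult < 0) {
    stop("multipliers must be positive (gap_kcat_mult may be exactly 0)")
  }
  list(
    genotype = genotype,
    k_hyd = base$k_hyd_intrinsic * mult$gtpase_mult,
    k_act = base$k_act_intrinsic,
    gap_kon = base$gap_kon / mult$gap_km_mult,
    gap_koff = base$gap_koff,
    gap_kcat = base$gap_kcat * mult$gap_kcat_mult,
    eff_kon = base$eff_kon,
    eff_koff = base$eff_koff * mult$effector_kdiss_mult,
    multipliers = mult,
    drug_targetable = mult$drug_targetable
  )
}

#' Specify one RAS pool (isoform x genotype population)
#'
#' A pool is a homogeneous population of RAS molecules sharing an isoform,
#' a genotype and a production share. Its rate constants are the wild-type
#' reference set modified by the genotype multipliers.
#'
#' @param name pool label, unique within a network.
#' @param isoform `"KRAS"`, `"NRAS"` or `"HRAS"`.
#' @param genotype `"WT"`, `"G12C"` or `"G12V"`.
#' @param abundance_fraction share of total RAS production assigned to
#'   this pool (the fractions over a network's pools must sum to 1).
#' @param production_rate absolute zeroth-order production rate (M/s);
#'   alternative to `abundance_fraction`.
#' @param multipliers optional override of the genotype multipliers (see
#'   [apply_mutant_profile()]).
#' @return An object of class `ras_pool`.
#' @export
ras_pool <- function(name, isoform, genotype,
                     abundance_fraction = NULL,
                     production_rate = NULL,
                     multipliers = NULL) {
  isoform <- match.arg(isoform, c("KRAS", "NRAS", "HRAS"))
  genotype <- match.arg(genotype, .genotypes)
  if (is.null(abundance_fraction) && is.null(production_rate)) {
    stop("one of abundance_fraction or production_rate is required")
  }
  if (!is.null(abundance_fraction) &&
      (abundance_fraction < 0 || abundance_fraction > 1)) {
    stop("abundance_fraction must lie in [0, 1]")
  }
  if (!is.null(production_rate) && production_rate < 0) {
    stop("production_rate must be non-negative")
  }
  structure(list(
    name = as.character(name),
    isoform = isoform,
    genotype = genotype,
    abundance_fraction = abundance_fraction,
    production_rate = production_rate,
    multipliers = multipliers
  ), class = "ras_pool")
}

#' @export
print.ras_pool <- function(x, ...) {
  cat(sprintf(
    "<ras_pool> %s: %s %s, %s\n", x$name, x$isoform, x$genotype,
    if (!is.null(x$abundance_fraction)) {
      sprintf("%.3g of total production", x$abundance_fraction)
    } else {
      sprintf("production %.3g M/s", x$production_rate)
    }
  ))
  invisible(x)
}

#' Standard pool compositions
#'
#' Convenience pool sets for the cell models studied with this network:
#' `heterozygous_g12c_pools()` splits KRAS production 50/50 between G12C
#' and wild type, with total RAS production divided KRAS:NRAS:HRAS =
#' 2:1:1; `homozygous_g12c_pools()` makes all KRAS production mutant;
#' `all_wt_pools()` is the wild-type control; `heterozygous_g12v_pools()`
#' swaps the mutant genotype to the drug-inaccessible G12V.
#'
#' @param kras_split fraction of KRAS production carried by the mutant
#'   pool in the heterozygous sets.
#' @return A list of [ras_pool()] objects.
#' @export
heterozygous_g12c_pools <- function(kras_split = 0.5) {
  stopifnot(kras_split >= 0, kras_split <= 1)
  list(
    ras_pool("KRAS_G12C", "KRAS", "G12C", abundance_fraction = 0.5 * kras_split),
    ras_pool("KRAS_WT", "KRAS", "WT", abundance_fraction = 0.5 * (1 - kras_split)),
    ras_pool("NRAS_WT", "NRAS", "WT", abundance_fraction = 0.25),
    ras_pool("HRAS_WT", "HRAS", "WT", abundance_fraction = 0.25)
  )
}

#' @rdname heterozygous_g12c_pools
#' @export
homozygous_g12c_pools <- function() {
  list(
    ras_pool("KRAS_G12C", "KRAS", "G12C", abundance_fraction = 0.5),
    ras_pool("NRAS_WT", "NRAS", "WT", abundance_fraction = 0.25),
    ras_pool("HRAS_WT", "HRAS", "WT", abundance_fraction = 0.25)
  )
}

#' @rdname heterozygous_g12c_pools
#' @export
all_wt_pools <- function() {
  list(
    ras_pool("KRAS_WT", "KRAS", "WT", abundance_fraction = 0.5),
    ras_pool("NRAS_WT", "NRAS", "WT", abundance_fraction = 0.25),
    ras_pool("HRAS_WT", "HRAS", "WT", abundance_fraction = 0.25)
  )
}

#' @rdname heterozygous_g12c_pools
#' @export
heterozygous_g12v_pools <- function(kras_split = 0.5) {
  stopifnot(kras_split >= 0, kras_split <= 1)
  list(
    ras_pool("KRAS_G12V", "KRAS", "G12V", abundance_fraction = 0.5 * kras_split),
    ras_pool("KRAS_WT", "KRAS", "WT", abundance_fraction = 0.5 * (1 - kras_split)),
    ras_pool("NRAS_WT", "NRAS", "WT", abundance_fraction = 0.25),
    ras_pool("HRAS_WT", "HRAS", "WT", abundance_fraction = 0.25)
  )
}
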