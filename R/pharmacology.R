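#' Covalent KRAS G12C inhibitor
#'
#' A covalent inhibitor is characterised by its composite second-order
#' efficiency constant kinact/Ki (1/(M s)). At a clamped intracellular
#' dose (assumed in constant excess, no depletion) the pseudo-first-order
#' inactivation rate of free, GDP-bound G12C RAS is
#' `kinact_over_ki * dose`.
#'
#' @param name inhibitor label.
#' @param kinact_over_ki composite second-order constant (1/(M s)).
#' @param dose clamped concentration (M).
#' @return An object of class `covalent_inhibitor`.
#' @seealso [amg510()], [ars853()] for the shipped parameterisations.
#' @export
covalent_inhibitor <- function(name, kinact_over_ki, dose = 0) {
  if (!is.numeric(kinact_over_ki) || kinact_over_ki <= 0) {
    stop("kinact_over_ki must be strictly positive")
  }
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("dose must be a single non-negative concentration (M)")
  }
  structure(list(
    name = as.character(name),
    kinact_over_ki = kinact_over_ki,
    dose = dose
  ), class = "covalent_inhibitor")
}

#' @export
print.covalent_inhibitor <- function(x, ...) {
  cat(sprintf("<covalent_inhibitor> %s: kinact/Ki = %.4g /(M s), dose = %.4g M\n",
              x$name, x$kinact_over_ki, x$dose))
  invisible(x)
}

#' Shipped covalent inhibitor parameterisations
#'
#' Sotorasib (AMG-510) engages GDP-bound KRAS G12C with kinact/Ki =
#' 9900 /(M s); the earlier tool compound ARS-853 with 76 /(M s).
#'
#' @param dose_nM dose in nanomolar (converted to M internally).
#' @return A [covalent_inhibitor()].
#' @export
amg510 <- function(dose_nM = 250) {
  covalent_inhibitor("AMG-510", 9900, dose = dose_nM * 1e-9)
}

#' @rdname amg510
#' @export
ars853 <- function(dose_nM = 250) {
  covalent_inhibitor("ARS-853", 76, dose = dose_nM * 1e-9)
}

#' Pseudo-first-order covalent engagement rate
#'
#' @param inhibitor a [covalent_inhibitor()].
#' @return Rate in 1/s: `kinact_over_ki * dose`. This drives the
#'   irreversible reaction RAS-GDP (G12C) -> RAS-GDP-drug, consistent
#'   with the inhibitors' selectivity for the GDP-bound, inactive state.
#' @examples
#' covalent_binding_rate(amg510(250)) # 9900 * 250e-9 = 2.475e-3 /s
#' @export
covalent_binding_rate <- function(inhibitor) {
  stopifnot(inherits(inhibitor, "covalent_inhibitor"))
  inhibitor$kinact_over_ki * inhibitor$dose
}

#' EGFR inhibition as fractional loss of GEF activity
#'
#' EGFR drives RAS activation by recruiting GEFs (SOS1/2) to the
#' receptor; EGFR inhibition is modeled as a fractional reduction of
#' GEF-mediated activation. Two modes: a verbatim inhibition fraction,
#' or a Hill dose-response link
#' `max_inhibition * dose^hill / (dose^hill + ic50^hill)` mapping an
#' extracellular dose (e.g. cetuximab in ug/ml) to that fraction. The
#' intracellular coupling constant (ic50) is configuration, not a
#' measured quantity.
#'
#' @param fraction direct GEF inhibition fraction in \[0, 1\]
#'   (mode `"fraction"`).
#' @param dose drug dose in its native units (mode `"dose_response"`).
#' @param ic50 dose of half-maximal inhibition, same units as `dose`.
#' @param hill Hill coefficient (dimensionless).
#' @param max_inhibition maximal attainable inhibition fraction.
#' @return An object of class `egfr_inhibition`.
#' @export
egfr_inhibition <- function(fraction = NULL, dose = NULL, ic50 = 0.2,
                            hill = 1, max_inhibition = 1) {
  if (is.null(fraction) == is.null(dose)) {
    stop("exactly one of `fraction` or `dose` must be given")
  }
  if (!is.null(fraction)) {
    if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
    obj <- list(mode = "fraction", fraction = fraction)
  } else {
    if (dose < 0) stop("dose must be non-negative")
    if (ic50 <= 0 || hill <= 0) stop("ic50 and hill must be positive")
    if (max_inhibition < 0 || max_inhibition > 1) {
      stop("max_inhibition must lie in [0, 1]")
    }
    obj <- list(mode = "dose_response", dose = dose, ic50 = ic50,
                hill = hill, max_inhibition = max_inhibition)
  }
  structure(obj, class = "egfr_inhibition")
}

#' @export
print.egfr_inhibition <- function(x, ...) {
  if (x$mode == "fraction") {
    cat(sprintf("<egfr_inhibition> fraction = %.3g\n", x$fraction))
  } else {
    cat(sprintf(
      "<egfr_inhibition> dose = %.3g (ic50 = %.3g, hill = %.3g, max = %.3g) -> fraction %.3g\n",
      x$dose, x$ic50, x$hill, x$max_inhibition, gef_inhibition_fraction(x)
    ))
  }
  invisible(x)
}

#' Fraction of GEF activity removed by an EGFR inhibitor exposure
#'
#' @param egfri an [egfr_inhibition()] object (or `NULL`, giving 0).
#' @return Dimensionless fraction in \[0, 1\].
#' @examples
#' gef_inhibition_fraction(egfr_inhibition(dose = 0.2, ic50 = 0.2)) # 0.5
#' @export
gef_inhibition_fraction <- function(egfri) {
  if (is.null(egfri)) return(0)
  stopifnot(inherits(egfri, "egfr_inhibition"))
  if (egfri$mode == "fraction") return(egfri$fraction)
  if (egfri$dose == 0) return(0)
  dh <- egfri$dose^egfri$hill
  egfri$max_inhibition * dh / (dh + egfri$ic50^egfri$hill)
}

#' Genetic perturbations (siRNA-style knockdowns)
#'
#' `nf1_knockdown` scales the conserved GAP (NF1) total by
#' `1 - nf1_knockdown`; `kras_knockdown` scales the production rate of
#' every KRAS pool (mutant and wild type) by `1 - kras_knockdown`.
#' Knockdown of production lets pre-existing protein decay at the RAS
#' half-life, so knockdown phenotypes are steady-state (or >= 48 h)
#' quantities.
#'
#' @param nf1_knockdown,kras_knockdown fractions in \[0, 1\].
#' @return An object of class `ras_perturbation`.
#' @export
perturbation <- function(nf1_knockdown = 0, kras_knockdown = 0) {
  if (nf1_knockdown < 0 || nf1_knockdown > 1 ||
      kras_knockdown < 0 || kras_knockdown > 1) {
    stop("knockdown fractions must lie in [0, 1]")
  }
  structure(list(
    nf1_knockdown = nf1_knockdown,
    kras_knockdown = kras_knockdown
  ), class = "ras_perturbation")
}

#' Compose a treatment from drug exposures and perturbations
#'
#' Absent components are identity transformations, so treatments compose:
#' applying two treatments that touch disjoint components equals applying
#' their union.
#'
#' @param g12ci a [covalent_inhibitor()] or `NULL`.
#' @param egfri an [egfr_inhibition()] or `NULL`.
#' @param perturb a [perturbation()] or `NULL`.
#' @return An object of class `ras_treatment`.
#' @export
treatment <- function(g12ci = NULL, egfri = NULL, perturb = NULL) {
  if (!is.null(g12ci)) stopifnot(inherits(g12ci, "covalent_inhibitor"))
  if (!is.null(egfri)) stopifnot(inherits(egfri, "egfr_inhibition"))
  if (!is.null(perturb)) stopifnot(inherits(perturb, "ras_perturbation"))
  structure(list(g12ci = g12ci, egfri = egfri, perturb = perturb),
            class = "ras_treatment")
}

#' @export
print.ras_treatment <- function(x, ...) {
  cat("<ras_treatment>\n")
  if (is.null(x$g12ci) && is.null(x$egfri) && is.null(x$perturb)) {
    cat("  vehicle (no components)\n")
  }
  if (!is.null(x$g12ci)) {
    cat(sprintf("  G12C inhibitor: %s at %.4g M\n", x$g12ci$name, x$g12ci$dose))
  }
  if (!is.null(x$egfri)) {
    cat(sprintf("  EGFR inhibition fraction: %.3g\n",
                gef_inhibition_fraction(x$egfri)))
  }
  if (!is.null(x$perturb)) {
    cat(sprintf("  knockdowns: NF1 %.2g, KRAS %.2g\n",
                x$perturb$nf1_knockdown, x$perturb$kras_knockdown))
  }
  invisible(x)
}

.is_empty_treatment <- function(tr) {
  is.null(tr) ||
    (is.null(tr$g12ci) || tr$g12ci$dose == 0) &&
    (is.null(tr$egfri) || gef_inhibition_fraction(tr$egfri) == 0) &&
    (is.null(tr$perturb) ||
       (tr$perturb$nf1_knockdown == 0 && tr$perturb$kras_knockdown == 0))
}

#' Apply a treatment to a reaction network
#'
#' Returns a new network in which:
#'
#' 1. the covalent engagement reaction RAS-GDP -> RAS-GDP-drug is added
#'    for every drug-targetable pool at rate [covalent_binding_rate()]
#'    (only free RAS-GDP is drug accessible; the adduct is inert apart
#'    from degradation, which the untreated network already carries);
#' 2. GEF association and catalysis rate constants are scaled by
#'    `1 - gef_inhibition_fraction(egfri)` — inhibition removes GEF
#'    recruitment, i.e. reduces the effective active GEF, which scales
#'    engagement and turnover alike (GEF dissociation is untouched);
#' 3. the conserved GAP total is scaled by `1 - nf1_knockdown`;
#' 4. production of KRAS-isoform pools is scaled by `1 - kras_knockdown`.
#'
#' A G12C inhibitor applied to a network with no targetable pool is legal
#' and leaves the reaction set unchanged. An empty treatment returns the
#' network unchanged (structural equality).
#'
#' @param network a `ras_network`.
#' @param tr a [treatment()] (or `NULL` for vehicle).
#' @return A `ras_network` with the treatment folded into its rates and
#'   totals; `network$treatment` records the applied spec.
#' @export
apply_treatment <- function(network, tr) {
  stopifnot(inherits(network, "ras_network"))
  if (.is_empty_treatment(tr)) return(network)
  stopifnot(inherits(tr, "ras_treatment"))
  net <- network

  if (!is.null(tr$g12ci) && tr$g12ci$dose > 0) {
    rate <- covalent_binding_rate(tr$g12ci)
    for (i in seq_along(net$pools)) {
      if (!net$profiles[[i]]$drug_targetable) next
      p <- net$pools[[i]]
      gdp <- paste0(p$name, ".GDP")
      adduct <- paste0(p$name, ".GDP.drug")
      col <- numeric(nrow(net$species))
      gi <- match(gdp, net$species$name)
      ai <- match(adduct, net$species$name)
      col[gi] <- -1
      col[ai] <- 1
      net$stoich <- cbind(net$stoich, col)
      colnames(net$stoich)[ncol(net$stoich)] <- paste0("drug_", p$name)
      net$reactions <- rbind(net$reactions, data.frame(
        name = paste0("drug_", p$name), kind = "covalent_engagement",
        pool = p$name, rate = rate, stringsAsFactors = FALSE
      ))
      net$reactants[[length(net$reactants) + 1L]] <- gi
    }
  }

  f <- gef_inhibition_fraction(tr$egfri)
  if (f > 0) {
    sel <- net$reactions$kind %in% c("gef_bind", "gef_cat")
    net$reactions$rate[sel] <- net$reactions$rate[sel] * (1 - f)
  }

  if (!is.null(tr$perturb)) {
    if (tr$perturb$nf1_knockdown > 0 && !is.null(net$conserved_totals$gap)) {
      net$conserved_totals$gap <-
        net$conserved_totals$gap * (1 - tr$perturb$nf1_knockdown)
    }
    if (tr$perturb$kras_knockdown > 0) {
      kras_pools <- vapply(net$pools, function(p) p$isoform == "KRAS",
                           logical(1))
      knames <- vapply(net$pools[kras_pools], `[[`, character(1), "name")
      sel <- net$reactions$kind == "production" & net$reactions$pool %in% knames
      net$reactions$rate[sel] <-
        net$reactions$rate[sel] * (1 - tr$perturb$kras_knockdown)
      net$production[knames] <-
        net$production[knames] * (1 - tr$perturb$kras_knockdown)
    }
  }

  net$treatment <- tr
  net
}
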