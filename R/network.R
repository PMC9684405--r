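#' Build the mass-action reaction network for a set of RAS pools
#'
#' Constructs the full species list, stoichiometry matrix and elementary
#' mass-action reaction set for competing RAS pools that share one GEF,
#' one GAP (NF1) and one effector. Per pool the network contains:
#'
#' * zeroth-order production into RAS-GDP and first-order degradation of
#'   every RAS-containing species (a degrading complex releases its
#'   enzyme/effector partner intact; GEF, GAP and effector themselves are
#'   not turned over);
#' * intrinsic GDP -> GTP exchange and intrinsic GTP hydrolysis, the
#'   latter also inside the GAP complex (a GAP-bound mutant that GAP
#'   cannot catalyse still hydrolyses GTP at its own rate, releasing
#'   free GAP and RAS-GDP);
#' * GEF catalysis via an explicit complex:
#'   GEF + RAS-GDP <-> GEF:RAS-GDP -> GEF + RAS-GTP;
#' * GAP catalysis via an explicit complex:
#'   GAP + RAS-GTP <-> GAP:RAS-GTP -> GAP + RAS-GDP (kcat = 0 for
#'   codon-12 mutants, which therefore sequester GAP);
#' * reversible effector binding: EFF + RAS-GTP <-> EFF:RAS-GTP.
#'
#' Pools whose genotype is accessible to covalent G12C inhibitors also
#' carry a drug-adduct species (RAS-GDP-drug). The adduct is chemically
#' inert — its only reaction is first-order degradation — and the covalent
#' conversion itself is added by [apply_treatment()], so that treated and
#' untreated networks share one species layout.
#'
#' Shared enzyme/effector species are included only when their configured
#' total is positive, so a degenerate enzyme-free single-pool network
#' reduces to two species and five reactions.
#'
#' @param pools list of [ras_pool()] objects; abundance fractions, when
#'   used, must sum to 1 (tolerance 1e-12).
#' @param base a [base_parameters()] object.
#' @return An object of class `ras_network` with elements `species`
#'   (data.frame: name, pool, isoform, genotype, role), `stoich` (species
#'   x reactions matrix), `reactions` (data.frame: name, kind, pool,
#'   rate), `reactants` (list of species-index vectors per reaction),
#'   `conserved_totals`, `pools`, `base`, `treatment`.
#' @export
build_network <- function(pools, base) {
  stopifnot(inherits(base, "ras_base_parameters"))
  if (inherits(pools, "ras_pool")) pools <- list(pools)
  if (length(pools) < 1L) stop("at least one RAS pool is required")
  if (!all(vapply(pools, inherits, logical(1), "ras_pool"))) {
    stop("pools must be a list of ras_pool objects")
  }
  nms <- vapply(pools, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("pool names must be unique")

  fractions <- vapply(pools, function(p) {
    if (is.null(p$abundance_fraction)) NA_real_ else p$abundance_fraction
  }, numeric(1))
  use_fraction <- !is.na(fractions)
  if (any(use_fraction) && !all(use_fraction)) {
    stop("pools must use abundance fractions or production rates consistently")
  }
  if (all(use_fraction) && abs(sum(fractions) - 1) > 1e-12) {
    stop("pool abundance fractions must sum to 1 (tolerance 1e-12)")
  }
  production <- if (all(use_fraction)) {
    fractions * base$ras_production_total
  } else {
    vapply(pools, `[[`, numeric(1), "production_rate")
  }

  has_gef <- base$gef_total > 0
  has_gap <- base$gap_total > 0
  has_eff <- base$eff_total > 0

  profiles <- lapply(pools, function(p) {
    apply_mutant_profile(base, p$genotype, p$multipliers)
  })

  # -- species table ----------------------------------------------------
  sp <- list()
  add_species <- function(name, pool, isoform, genotype, role) {
    sp[[length(sp) + 1L]] <<- data.frame(
      name = name, pool = pool, isoform = isoform, genotype = genotype,
      role = role, stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(pools)) {
    p <- pools[[i]]
    add_species(paste0(p$name, ".GDP"), p$name, p$isoform, p$genotype, "gdp")
    add_species(paste0(p$name, ".GTP"), p$name, p$isoform, p$genotype, "gtp")
    if (has_gef) {
      add_species(paste0("GEF:", p$name, ".GDP"), p$name, p$isoform,
                  p$genotype, "gef_gdp")
    }
    if (has_gap) {
      add_species(paste0("GAP:", p$name, ".GTP"), p$name, p$isoform,
                  p$genotype, "gap_gtp")
    }
    if (has_eff) {
      add_species(paste0("EFF:", p$name, ".GTP"), p$name, p$isoform,
                  p$genotype, "eff_gtp")
    }
    if (profiles[[i]]$drug_targetable) {
      add_species(paste0(p$name, ".GDP.drug"), p$name, p$isoform,
                  p$genotype, "adduct")
    }
  }
  if (has_gef) add_species("GEF", NA, NA, NA, "free_gef")
  if (has_gap) add_species("GAP", NA, NA, NA, "free_gap")
  if (has_eff) add_species("EFF", NA, NA, NA, "free_eff")
  species <- do.call(rbind, sp)
  rownames(species) <- NULL
  n_sp <- nrow(species)
  idx <- function(name) match(name, species$name)

  # -- reactions --------------------------------------------------------
  rx_name <- character(0)
  rx_kind <- character(0)
  rx_pool <- character(0)
  rx_rate <- numeric(0)
  reactants <- list()
  stoich_cols <- list()
  add_reaction <- function(name, kind, pool, rate, from, to) {
    # `from` are consumed species names, `to` produced; zeroth order has
    # an empty `from`.
    if (!is.finite(rate) || rate < 0) {
      stop("reaction '", name, "' has a non-finite or negative rate constant")
    }
    col <- numeric(n_sp)
    ri <- integer(0)
    for (s in from) {
      k <- idx(s)
      col[k] <- col[k] - 1
      ri <- c(ri, k)
    }
    for (s in to) {
      k <- idx(s)
      col[k] <- col[k] + 1
    }
    rx_name[length(rx_name) + 1L] <<- name
    rx_kind[length(rx_kind) + 1L] <<- kind
    rx_pool[length(rx_pool) + 1L] <<- if (is.null(pool)) NA_character_ else pool
    rx_rate[length(rx_rate) + 1L] <<- rate
    reactants[[length(reactants) + 1L]] <<- ri
    stoich_cols[[length(stoich_cols) + 1L]] <<- col
  }

  d <- base$ras_degradation
  for (i in seq_along(pools)) {
    p <- pools[[i]]
    pr <- profiles[[i]]
    gdp <- paste0(p$name, ".GDP")
    gtp <- paste0(p$name, ".GTP")
    add_reaction(paste0("prod_", p$name), "production", p$name,
                 production[i], character(0), gdp)
    add_reaction(paste0("deg_", gdp), "degradation", p$name, d, gdp, character(0))
    add_reaction(paste0("deg_", gtp), "degradation", p$name, d, gtp, character(0))
    add_reaction(paste0("act_", p$name), "intrinsic_activation", p$name,
                 pr$k_act, gdp, gtp)
    add_reaction(paste0("hyd_", p$name), "intrinsic_hydrolysis", p$name,
                 pr$k_hyd, gtp, gdp)
    if (has_gef) {
      cx <- paste0("GEF:", gdp)
      add_reaction(paste0("gef_bind_", p$name), "gef_bind", p$name,
                   base$gef_kon, c("GEF", gdp), cx)
      add_reaction(paste0("gef_unbind_", p$name), "gef_unbind", p$name,
                   base$gef_koff, cx, c("GEF", gdp))
      add_reaction(paste0("gef_cat_", p$name), "gef_cat", p$name,
                   base$gef_kcat, cx, c("GEF", gtp))
      add_reaction(paste0("deg_", cx), "degradation", p$name, d, cx, "GEF")
    }
    if (has_gap) {
      cx <- paste0("GAP:", gtp)
      add_reaction(paste0("gap_bind_", p$name), "gap_bind", p$name,
                   pr$gap_kon, c("GAP", gtp), cx)
      add_reaction(paste0("gap_unbind_", p$name), "gap_unbind", p$name,
                   pr$gap_koff, cx, c("GAP", gtp))
      if (pr$gap_kcat > 0) {
        add_reaction(paste0("gap_cat_", p$name), "gap_cat", p$name,
                     pr$gap_kcat, cx, c("GAP", gdp))
      }
      # GAP-bound RAS-GTP retains intrinsic hydrolysis (relevant for
      # GAP-insensitive mutants): complex -> free GAP + RAS-GDP.
      add_reaction(paste0("hyd_in_gap_", p$name), "hydrolysis_in_gap",
                   p$name, pr$k_hyd, cx, c("GAP", gdp))
      add_reaction(paste0("deg_", cx), "degradation", p$name, d, cx, "GAP")
    }
    if (has_eff) {
      cx <- paste0("EFF:", gtp)
      add_reaction(paste0("eff_bind_", p$name), "eff_bind", p$name,
                   pr$eff_kon, c("EFF", gtp), cx)
      add_reaction(paste0("eff_unbind_", p$name), "eff_unbind", p$name,
                   pr$eff_koff, cx, c("EFF", gtp))
      add_reaction(paste0("deg_", cx), "degradation", p$name, d, cx, "EFF")
    }
    if (pr$drug_targetable) {
      ad <- paste0(gdp, ".drug")
      add_reaction(paste0("deg_", ad), "degradation", p$name, d, ad, character(0))
    }
  }

  stoich <- do.call(cbind, stoich_cols)
  dimnames(stoich) <- list(species$name, rx_name)
  conserved <- list()
  if (has_gef) conserved$gef <- base$gef_total
  if (has_gap) conserved$gap <- base$gap_total
  if (has_eff) conserved$eff <- base$eff_total

  net <- structure(list(
    species = species,
    stoich = stoich,
    reactions = data.frame(
      name = rx_name, kind = rx_kind, pool = rx_pool, rate = rx_rate,
      stringsAsFactors = FALSE
    ),
    reactants = reactants,
    conserved_totals = conserved,
    pools = pools,
    profiles = profiles,
    production = stats::setNames(production, nms),
    base = base,
    treatment = NULL
  ), class = "ras_network")
  net
}

#' @export
print.ras_network <- function(x, ...) {
  cat(sprintf(
    "<ras_network> %d pool(s), %d species, %d reactions\n",
    length(x$pools), nrow(x$species), nrow(x$reactions)
  ))
  for (p in x$pools) {
    cat(sprintf("  pool %-10s %s %-5s production %.3g M/s\n",
                p$name, p$isoform, p$genotype,
                x$production[[p$name]]))
  }
  ct <- x$conserved_totals
  if (length(ct)) {
    cat("  conserved totals:",
        paste(sprintf("%s = %.3g M", names(ct), unlist(ct)), collapse = ", "),
        "\n")
  }
  if (!is.null(x$treatment)) cat("  treatment applied\n")
  invisible(x)
}

#' Number of species / reactions in a network
#' @param network a `ras_network`.
#' @return integer count.
#' @export
n_species <- function(network) nrow(network$species)

#' @rdname n_species
#' @export
n_reactions <- function(network) nrow(network$reactions)

#' Mass-action reaction fluxes for a state vector
#'
#' @param state numeric vector of concentrations (M) aligned to
#'   `network$species`.
#' @param network a `ras_network`.
#' @return numeric vector of reaction rates (M/s), one per reaction.
#' @keywords internal
.reaction_fluxes <- function(state, network) {
  k <- network$reactions$rate
  v <- k
  ri <- network$reactants
  for (j in seq_along(ri)) {
    for (s in ri[[j]]) v[j] <- v[j] * state[s]
  }
  v
}

#' Time derivative of a network state (mass-action right-hand side)
#'
#' The user-facing right-hand side: validates alignment and
#' non-negativity, then returns the stoichiometry-weighted sum of
#' elementary mass-action fluxes. Enzyme/effector conservation holds by
#' construction: the derivative of free + complexed GEF (resp. GAP, EFF)
#' is exactly zero.
#'
#' @param state numeric vector of concentrations (M) aligned to
#'   `network$species`.
#' @param network a `ras_network`.
#' @return Named numeric vector of derivatives (M/s).
#' @export
network_rhs <- function(state, network) {
  stopifnot(inherits(network, "ras_network"))
  if (length(state) != nrow(network$species)) {
    stop("state length does not match network species")
  }
  if (any(state < 0)) stop("negative concentrations are not allowed")
  dx <- drop(network$stoich %*% .reaction_fluxes(state, network))
  names(dx) <- network$species$name
  dx
}

# Unchecked rhs for solver internals: tolerant of tiny negative
# excursions from the integrator (clamped to zero before evaluation).
.rhs_raw <- function(state, network) {
  drop(network$stoich %*% .reaction_fluxes(pmax(state, 0), network))
}

# Analytic Jacobian of the mass-action rhs.
.rhs_jacobian <- function(state, network) {
  n <- nrow(network$species)
  m <- nrow(network$reactions)
  k <- network$reactions$rate
  dv <- matrix(0, m, n)
  ri <- network$reactants
  for (j in seq_len(m)) {
    r <- ri[[j]]
    if (length(r) == 1L) {
      dv[j, r] <- k[j]
    } else if (length(r) == 2L) {
      dv[j, r[1L]] <- k[j] * state[r[2L]]
      dv[j, r[2L]] <- k[j] * state[r[1L]]
    }
  }
  network$stoich %*% dv
}

#' Default initial state for a network
#'
#' All RAS mass starts as free RAS-GDP at the pool's steady-state total
#' (production / degradation), enzymes and effector start free. Per-pool
#' RAS totals are then invariant along the trajectory (production and
#' degradation balance exactly), so only the fast internal redistribution
#' has to relax.
#'
#' @param network a `ras_network`.
#' @return Named numeric state vector.
#' @export
initial_state <- function(network) {
  sp <- network$species
  x <- numeric(nrow(sp))
  names(x) <- sp$name
  d <- network$base$ras_degradation
  for (p in network$pools) {
    x[paste0(p$name, ".GDP")] <- network$production[[p$name]] / d
  }
  ct <- network$conserved_totals
  if (!is.null(ct$gef)) x["GEF"] <- ct$gef
  if (!is.null(ct$gap)) x["GAP"] <- ct$gap
  if (!is.null(ct$eff)) x["EFF"] <- ct$eff
  x
}

#' Conserved enzyme/effector totals implied by a state
#'
#' @param state state vector aligned to the network.
#' @param network a `ras_network`.
#' @return Named numeric vector (gef/gap/eff as present): free +
#'   complexed totals.
#' @export
conservation_totals <- function(state, network) {
  sp <- network$species
  out <- numeric(0)
  ct <- network$conserved_totals
  if (!is.null(ct$gef)) {
    out["gef"] <- state[sp$role == "free_gef"] + sum(state[sp$role == "gef_gdp"])
  }
  if (!is.null(ct$gap)) {
    out["gap"] <- state[sp$role == "free_gap"] + sum(state[sp$role == "gap_gtp"])
  }
  if (!is.null(ct$eff)) {
    out["eff"] <- state[sp$role == "free_eff"] + sum(state[sp$role == "eff_gtp"])
  }
  out
}

# Species-role masks used by readouts.
.gtp_roles <- c("gtp", "gap_gtp", "eff_gtp")

#' Derived readouts from a network state
#'
#' GTP-bound RAS is summed over free, GAP-bound and effector-bound GTP
#' states. `total_ras_gtp` is computed directly from the GTP-state mask;
#' `mutant_ras_gtp` and `wt_ras_gtp` are accumulated pool by pool from
#' the genotype labels, an intentionally separate code path.
#'
#' @param state state vector aligned to the network.
#' @param network a `ras_network`.
#' @return Named list: `mutant_ras_gtp`, `wt_ras_gtp`, `total_ras_gtp`,
#'   `free_gap`, `free_gef`, `adduct_fraction` (share of drug-targetable
#'   pools' RAS carrying the covalent adduct; `NA` when the network has
#'   no targetable pool), `effector_occupancy`, `pool_totals`,
#'   `pool_gtp`, and `isoform_gtp`.
#' @export
state_readouts <- function(state, network) {
  sp <- network$species
  gtp_mask <- sp$role %in% .gtp_roles
  total <- sum(state[gtp_mask])

  mutant <- 0
  wt <- 0
  pool_gtp <- numeric(0)
  pool_tot <- numeric(0)
  for (p in network$pools) {
    in_pool <- !is.na(sp$pool) & sp$pool == p$name
    g <- sum(state[in_pool & sp$role %in% .gtp_roles])
    pool_gtp[p$name] <- g
    pool_tot[p$name] <- sum(state[in_pool])
    if (p$genotype == "WT") wt <- wt + g else mutant <- mutant + g
  }
  iso_gtp <- vapply(c(KRAS = "KRAS", NRAS = "NRAS", HRAS = "HRAS"),
                    function(iso) {
                      sum(state[!is.na(sp$isoform) & sp$isoform == iso &
                                  sp$role %in% .gtp_roles])
                    }, numeric(1))

  targetable <- vapply(network$profiles, `[[`, logical(1), "drug_targetable")
  if (any(targetable)) {
    tnames <- vapply(network$pools[targetable], `[[`, character(1), "name")
    t_mask <- !is.na(sp$pool) & sp$pool %in% tnames
    t_total <- sum(state[t_mask])
    adduct <- sum(state[t_mask & sp$role == "adduct"])
    adduct_fraction <- if (t_total > 0) adduct / t_total else 0
  } else {
    adduct_fraction <- NA_real_
  }

  ct <- network$conserved_totals
  list(
    mutant_ras_gtp = mutant,
    wt_ras_gtp = wt,
    total_ras_gtp = total,
    free_gap = if (is.null(ct$gap)) 0 else unname(state[sp$role == "free_gap"]),
    free_gef = if (is.null(ct$gef)) 0 else unname(state[sp$role == "free_gef"]),
    adduct_fraction = adduct_fraction,
    effector_occupancy = if (is.null(ct$eff)) {
      NA_real_
    } else {
      sum(state[sp$role == "eff_gtp"]) / ct$eff
    },
    pool_totals = pool_tot,
    pool_gtp = pool_gtp,
    isoform_gtp = iso_gtp
  )
}
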