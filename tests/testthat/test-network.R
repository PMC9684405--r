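test_that("degenerate enzyme-free single pool reduces to 2 species, 5 reactions", {
  base <- base_parameters(gef_total = 0, gap_total = 0, eff_total = 0)
  net <- build_network(
    list(ras_pool("R", "KRAS", "WT", abundance_fraction = 1)), base
  )
  expect_identical(n_species(net), 2L)
  expect_identical(n_reactions(net), 5L)
  expect_setequal(net$reactions$kind,
                  c("production", "degradation", "intrinsic_activation",
                    "intrinsic_hydrolysis"))
  expect_length(net$conserved_totals, 0)
})

test_that("heterozygous network has one drug-targetable pool and one adduct species", {
  net <- het_network()
  targetable <- vapply(net$profiles, `[[`, logical(1), "drug_targetable")
  expect_identical(sum(targetable), 1L)
  expect_identical(sum(net$species$role == "adduct"), 1L)
  expect_identical(net$species$pool[net$species$role == "adduct"], "KRAS_G12C")
})

test_that("G12V pools carry no drug-adduct species", {
  net <- g12v_network()
  expect_false(any(net$species$role == "adduct"))
  expect_false(any(vapply(net$profiles, `[[`, logical(1), "drug_targetable")))
})

test_that("every reaction conserves GEF, GAP and EFF element counts", {
  for (net in list(het_network(), hom_network(), wt_network())) {
    sp <- net$species
    for (grp in list(c("free_gef", "gef_gdp"), c("free_gap", "gap_gtp"),
                     c("free_eff", "eff_gtp"))) {
      mask <- sp$role %in% grp
      col_sums <- colSums(net$stoich[mask, , drop = FALSE])
      expect_true(all(col_sums == 0))
    }
  }
})

test_that("rhs on an all-zero state is pure production into RAS-GDP", {
  net <- het_network()
  dx <- network_rhs(numeric(n_species(net)), net)
  gdp <- net$species$role == "gdp"
  expect_equal(unname(dx[gdp]), unname(net$production))
  expect_true(all(dx[!gdp] == 0))
})

test_that("rhs rejects misaligned and negative states", {
  net <- het_network()
  expect_error(network_rhs(numeric(3), net), "does not match")
  x <- numeric(n_species(net))
  x[1] <- -1e-12
  expect_error(network_rhs(x, net), "negative")
})

test_that("mass-action homogeneity: rate and concentration doubling", {
  net <- het_network()
  x <- initial_state(net) + 1e-9
  v1 <- rascycle:::.reaction_fluxes(x, net)
  net2 <- net
  net2$reactions$rate <- net2$reactions$rate * 2
  v2 <- rascycle:::.reaction_fluxes(2 * x, net2)
  order <- lengths(net$reactants)
  expect_equal(v2[order == 2], 8 * v1[order == 2])
  expect_equal(v2[order == 1], 4 * v1[order == 1])
  expect_equal(v2[order == 0], 2 * v1[order == 0])
})

test_that("rhs vanishes at the converged steady state", {
  ss <- het_vehicle()
  dx <- network_rhs(ss$state, ss$network)
  expect_lt(max(abs(dx)) / max(ss$state), 1e-9)
})

test_that("enzyme totals are conserved at steady state", {
  ss <- het_vehicle()
  tot <- conservation_totals(ss$state, ss$network)
  expect_equal(unname(tot["gef"]), 2e-8, tolerance = 1e-9)
  expect_equal(unname(tot["gap"]), 1e-7, tolerance = 1e-9)
  expect_equal(unname(tot["eff"]), 4e-8, tolerance = 1e-9)
})

test_that("mutant RAS elevates wild-type RAS-GTP over the all-WT network", {
  # same enzyme totals, same total production; only the KRAS genotype
  # composition differs -> GAP sequestration frees wild-type pools
  het_wt_gtp <- het_vehicle()$readouts$wt_ras_gtp
  wt_total_gtp <- wt_vehicle()$readouts$total_ras_gtp
  expect_gt(het_wt_gtp, wt_total_gtp)
})
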