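test_that("covalent engagement rate is kinact/Ki times dose", {
  expect_equal(covalent_binding_rate(amg510(250)), 9900 * 250e-9)
  expect_equal(covalent_binding_rate(ars853(250)), 76 * 250e-9)
  expect_identical(covalent_binding_rate(amg510(0)), 0)
  expect_error(covalent_inhibitor("x", 100, dose = -1), "non-negative")
  expect_error(covalent_inhibitor("x", 0), "positive")
})

test_that("GEF inhibition fraction covers both modes", {
  expect_identical(gef_inhibition_fraction(NULL), 0)
  expect_identical(gef_inhibition_fraction(egfr_inhibition(dose = 0)), 0)
  expect_equal(
    gef_inhibition_fraction(egfr_inhibition(dose = 0.2, ic50 = 0.2, hill = 1)),
    0.5
  )
  expect_identical(gef_inhibition_fraction(egfr_inhibition(fraction = 0.8)), 0.8)
  half <- gef_inhibition_fraction(
    egfr_inhibition(dose = 3, ic50 = 3, hill = 2.5, max_inhibition = 0.9)
  )
  expect_equal(half, 0.45)
  expect_error(egfr_inhibition(fraction = 1.2), "\\[0, 1\\]")
  expect_error(egfr_inhibition(), "exactly one")
})

test_that("a G12C inhibitor is a structural no-op on non-targetable networks", {
  net <- g12v_network()
  treated <- apply_treatment(net, treatment(g12ci = amg510(1000)))
  expect_identical(treated$reactions, net$reactions)
  expect_identical(treated$stoich, net$stoich)
})

test_that("treatments modify rates and totals as specified", {
  net <- het_network()
  tr <- treatment(g12ci = amg510(250), egfri = egfr_inhibition(fraction = 0.5),
                  perturb = perturbation(nf1_knockdown = 1,
                                         kras_knockdown = 0.9))
  treated <- apply_treatment(net, tr)

  drug_rx <- treated$reactions[treated$reactions$kind == "covalent_engagement", ]
  expect_identical(nrow(drug_rx), 1L)
  expect_equal(drug_rx$rate, 9900 * 250e-9)

  gef_sel <- net$reactions$kind %in% c("gef_bind", "gef_cat")
  expect_equal(treated$reactions$rate[gef_sel], net$reactions$rate[gef_sel] * 0.5)
  koff_sel <- net$reactions$kind == "gef_unbind"
  expect_equal(treated$reactions$rate[koff_sel], net$reactions$rate[koff_sel])

  expect_identical(treated$conserved_totals$gap, 0)

  kras_prod <- treated$reactions$kind == "production" &
    treated$reactions$pool %in% c("KRAS_G12C", "KRAS_WT")
  expect_equal(treated$reactions$rate[kras_prod],
               net$reactions$rate[net$reactions$kind == "production" &
                                    net$reactions$pool %in%
                                      c("KRAS_G12C", "KRAS_WT")] * 0.1)
  nras_prod <- treated$reactions$kind == "production" &
    treated$reactions$pool == "NRAS_WT"
  expect_equal(treated$reactions$rate[nras_prod],
               net$reactions$rate[nras_prod])
})

test_that("an empty treatment is the identity transformation", {
  net <- het_network()
  expect_identical(apply_treatment(net, treatment()), net)
  expect_identical(apply_treatment(net, NULL), net)
  expect_identical(apply_treatment(net, treatment(g12ci = amg510(0))), net)
})

test_that("treatments touching disjoint components compose", {
  net <- het_network()
  a <- treatment(g12ci = amg510(250))
  b <- treatment(perturb = perturbation(nf1_knockdown = 0.9))
  ab <- treatment(g12ci = amg510(250),
                  perturb = perturbation(nf1_knockdown = 0.9))
  seq_applied <- apply_treatment(apply_treatment(net, a), b)
  joint <- apply_treatment(net, ab)
  expect_identical(seq_applied$reactions, joint$reactions)
  expect_identical(seq_applied$stoich, joint$stoich)
  expect_identical(seq_applied$conserved_totals, joint$conserved_totals)
})

test_that("the drug adduct is inert: only degradation consumes it", {
  treated <- apply_treatment(het_network(), treatment(g12ci = amg510(250)))
  adduct_row <- which(treated$species$role == "adduct")
  consuming <- which(treated$stoich[adduct_row, ] < 0)
  expect_identical(treated$reactions$kind[consuming], "degradation")
  # and nothing but the covalent step produces it
  producing <- which(treated$stoich[adduct_row, ] > 0)
  expect_identical(treated$reactions$kind[producing], "covalent_engagement")
})
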