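test_that("the vehicle steady state is a fixed point of the dynamics", {
  ss <- het_vehicle()
  tc <- simulate_timecourse(het_network(), NULL, t_end = 24 * 3600,
                            times = c(0, 12 * 3600, 24 * 3600),
                            init = ss$state)
  # relative at the state scale: tiny species are held to the solver's
  # absolute tolerance, not to machine-relative constancy
  floor_scale <- 1e-6 * max(ss$state)
  for (i in seq_along(tc$times)) {
    expect_lt(max(abs(tc$states[i, ] - ss$state) /
                    pmax(abs(ss$state), floor_scale)), 1e-6)
  }
})

test_that("with production off, total RAS decays as exp(-d t)", {
  base <- base_parameters(gef_total = 0, gap_total = 0, eff_total = 0)
  net <- build_network(
    list(ras_pool("R", "KRAS", "WT", production_rate = 0)), base
  )
  d <- base$ras_degradation
  init <- c(2e-7, 1e-7)
  names(init) <- net$species$name
  tt <- c(0, 6, 24, 48) * 3600
  tc <- simulate_timecourse(net, NULL, t_end = 48 * 3600, times = tt,
                            init = init)
  total <- rowSums(tc$states)
  expect_equal(total, 3e-7 * exp(-d * tt), tolerance = 1e-6)
})

test_that("covalent adduct accumulation is monotone along the trajectory", {
  tc <- simulate_timecourse(hom_network(), treatment(g12ci = amg510(250)),
                            t_end = 48 * 3600,
                            init = hom_vehicle()$state)
  af <- tc$readouts$adduct_fraction
  expect_true(all(diff(af) >= -1e-10))
  expect_gt(af[length(af)], af[1])
})

test_that("degenerate single-pool steady state matches the closed form", {
  # birth-death nucleotide cycle: R-GTP = a T / (a + h + d), T = s / d
  base <- base_parameters(gef_total = 0, gap_total = 0, eff_total = 0)
  for (genotype in c("WT", "G12C")) {
    net <- build_network(
      list(ras_pool("R", "KRAS", genotype, abundance_fraction = 1)), base
    )
    prof <- apply_mutant_profile(base, genotype)
    a <- prof$k_act
    h <- prof$k_hyd
    d <- base$ras_degradation
    s <- base$ras_production_total
    ss <- find_steady_state(net)
    expect_true(ss$converged)
    expect_equal(unname(ss$state[paste0("R.GTP")]),
                 a * (s / d) / (a + h + d), tolerance = 1e-6)
    expect_equal(sum(ss$state), s / d, tolerance = 1e-6)
  }
})

test_that("per-pool RAS totals equal production/degradation at steady state", {
  for (ss in list(het_vehicle(),
                  find_steady_state(het_network(),
                                    treatment(g12ci = amg510(250),
                                              egfri = egfr_inhibition(fraction = 0.8)),
                                    init = het_vehicle()$state))) {
    for (p in ss$network$pools) {
      expect_equal(unname(ss$readouts$pool_totals[p$name]),
                   expected_pool_total(ss$network, p$name),
                   tolerance = 1e-6)
    }
  }
})

test_that("saturating covalent dose drives mutant RAS-GTP to zero", {
  ss <- find_steady_state(hom_network(), treatment(g12ci = amg510(1e6)),
                          init = hom_vehicle()$state)
  expect_true(ss$converged)
  expect_gt(ss$readouts$adduct_fraction, 0.999)
  expect_lt(ss$readouts$mutant_ras_gtp,
            1e-3 * hom_vehicle()$readouts$mutant_ras_gtp)
})

test_that("enzyme conservation holds along treated trajectories", {
  tc <- simulate_timecourse(het_network(),
                            treatment(g12ci = amg510(250),
                                      egfri = egfr_inhibition(fraction = 0.8)),
                            t_end = 48 * 3600,
                            init = het_vehicle()$state)
  net <- tc$network
  for (i in seq(1, nrow(tc$states), by = 20)) {
    tot <- conservation_totals(pmax(tc$states[i, ], 0), net)
    expect_lt(max(abs(tot - c(2e-8, 1e-7, 4e-8)) / c(2e-8, 1e-7, 4e-8)), 1e-9)
  }
})

test_that("mutant + wild-type RAS-GTP equals total, computed independently", {
  ss <- find_steady_state(het_network(),
                          treatment(g12ci = amg510(250)),
                          init = het_vehicle()$state)
  r <- ss$readouts
  # independent summation over the species table, not via state_readouts
  sp <- ss$network$species
  total_independent <- sum(ss$state[sp$role %in% c("gtp", "gap_gtp", "eff_gtp")])
  expect_equal(r$mutant_ras_gtp + r$wt_ras_gtp, total_independent,
               tolerance = 1e-12)
  expect_equal(r$total_ras_gtp, total_independent, tolerance = 1e-12)
})

test_that("Newton steady states match long-horizon integration (random draws)", {
  set.seed(101)
  for (k in 1:5) {
    jitter <- function(x) x * 10^stats::runif(1, -0.3, 0.3)
    base <- base_parameters(
      k_hyd_intrinsic = jitter(3.5e-4), k_act_intrinsic = jitter(1e-4),
      gef_kon = jitter(1e7), gef_koff = jitter(1), gef_kcat = jitter(1),
      gap_kon = jitter(1e7), gap_koff = jitter(0.1), gap_kcat = jitter(10),
      eff_kon = jitter(1e7), eff_koff = jitter(1),
      gef_total = jitter(2e-8), gap_total = jitter(1e-7),
      eff_total = jitter(4e-8), ras_total = jitter(4e-7)
    )
    net <- build_network(heterozygous_g12c_pools(), base)
    ss <- find_steady_state(net)
    expect_true(ss$converged)
    oracle <- deSolve::ode(
      y = initial_state(net), times = c(0, 10 * base$t_half),
      func = function(t, y, p) list(rascycle:::.rhs_raw(y, net)),
      method = "lsoda", rtol = 1e-11, atol = 1e-16
    )
    x_oracle <- pmax(oracle[2, -1], 0)
    expect_lt(max(abs(ss$state - x_oracle) / pmax(abs(x_oracle), 1e-15)), 1e-6)
  }
})

test_that("non-convergence is flagged, not raised", {
  net <- het_network()
  opts <- solver_options(max_time = 60, newton_maxit = 1, window_tol = 0)
  ss <- find_steady_state(net, treatment(g12ci = amg510(250)),
                          init = initial_state(net), options = opts)
  expect_s3_class(ss, "ras_steady_state")
  expect_false(ss$converged)
})
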