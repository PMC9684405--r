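test_that("fraction affected, Bliss expectation and EOB arithmetic are exact", {
  expect_identical(fraction_affected(1, 1), 0)
  expect_identical(fraction_affected(0, 1), 1)
  expect_identical(fraction_affected(0.25, 1), 0.75)
  expect_identical(fraction_affected(1.5, 1), 0)  # clamped
  expect_error(fraction_affected(0.5, 0), "positive")

  expect_identical(bliss_expected(0.5, 0.5), 0.75)
  expect_identical(bliss_expected(0, 0.37), 0.37)
  expect_identical(bliss_expected(1, 0.37), 1)
  expect_identical(bliss_expected(0.3, 0.7), bliss_expected(0.7, 0.3))
  expect_error(bliss_expected(1.1, 0.5), "\\[0, 1\\]")

  expect_equal(excess_over_bliss(0.9, 0.5, 0.5), 15)
  expect_identical(excess_over_bliss(bliss_expected(0.3, 0.6), 0.3, 0.6), 0)
  expect_equal(excess_over_bliss(0.4, 0.5, 0), -10)
})

test_that("a Bliss-independent surface yields an all-zero EOB matrix", {
  fa_a <- c(0, 0.2, 0.5, 0.8)
  fa_b <- c(0, 0.1, 0.4, 0.9)
  fa <- outer(fa_a, fa_b, bliss_expected)
  eff <- effect_matrix(fa, egfri_doses = c(0, 1, 2, 3),
                       g12ci_doses = c(0, 1, 2, 3), source = "viability")
  syn <- eob_matrix(eff)
  expect_true(all(syn$eob == 0))
})

test_that("EOB is invariant under relabeling the two drugs", {
  set.seed(7)
  for (k in 1:5) {
    fa <- matrix(stats::runif(16), 4, 4)
    fa[1, 1] <- 0
    eff <- effect_matrix(fa, c(0, 1, 2, 3), c(0, 4, 5, 6), "viability")
    eff_t <- effect_matrix(t(fa), c(0, 4, 5, 6), c(0, 1, 2, 3), "viability")
    expect_equal(unname(eob_matrix(eff_t)$eob), unname(t(eob_matrix(eff)$eob)))
  }
})

test_that("EOB margins are zero and missing margins are rejected", {
  fa <- matrix(c(0, 0.3, 0.2, 0.8), 2, 2)
  syn <- eob_matrix(effect_matrix(fa, c(0, 1), c(0, 1), "viability"))
  expect_identical(syn$eob[1, ], c(`0` = 0, `1` = 0))
  expect_identical(syn$eob[, 1], c(`0` = 0, `1` = 0))
  expect_error(eob_matrix(effect_matrix(matrix(0, 1, 1), 0, 0, "viability")),
               "margins")
})

test_that("viability-derived effects clamp noisy cells and count them", {
  v <- matrix(c(1, 0.9, 1.08, 0.4), 2, 2)  # one cell above vehicle
  eff <- effect_from_viability(v, c(0, 1), c(0, 1))
  expect_identical(eff$clamp_count, 1L)
  expect_identical(eff$fa[1, 2], 0)  # clamped to zero, not negative
})

test_that("replicate aggregation returns elementwise mean and SD", {
  f1 <- effect_matrix(matrix(c(0, 0.5, 0.5, 0.2), 2), c(0, 1), c(0, 1),
                      "viability")
  f2 <- effect_matrix(matrix(c(0, 0.5, 0.5, 0.4), 2), c(0, 1), c(0, 1),
                      "viability")
  agg <- aggregate_replicates(list(f1, f2))
  expect_equal(agg$mean$fa[2, 2], 0.3)
  expect_equal(agg$sd[2, 2], stats::sd(c(0.2, 0.4)))
  expect_equal(agg$sd[1, 2], 0)
  agg_same <- aggregate_replicates(list(f1, f1, f1))
  expect_equal(agg_same$mean$fa, f1$fa)
  expect_true(all(agg_same$sd == 0))

  f3 <- effect_matrix(matrix(c(0, 0.5, 0.5, 0.4), 2), c(0, 2), c(0, 1),
                      "viability")
  expect_error(aggregate_replicates(list(f1, f3)), "identical dose axes")
  expect_error(aggregate_replicates(list(f1)), "at least two")
})

test_that("model grids satisfy the algebraic EOB lower bound", {
  grid <- small_het_grid()
  eff <- effect_from_grid(grid, "total_ras_gtp")
  expect_identical(eff$clamp_count, 0L)  # clamping never fires on model grids
  fa <- eff$fa
  combo_dominates <- all(fa >= outer(fa[, 1], fa[1, ], pmax) - 1e-12)
  expect_true(combo_dominates)
  syn <- eob_matrix(eff)
  bound <- -outer(fa[, 1], fa[1, ]) * 100
  expect_true(all(syn$eob >= bound - 1e-9))
})
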