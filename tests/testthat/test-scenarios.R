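# Scenario configs trimmed to 3 x 3 grids keep these end-to-end tests fast.
small_scenario_config <- function() {
  cfg <- default_model_config()
  cfg$doses$g12ci_nM <- c(0, 250, 1000)
  cfg$doses$egfri_ug_per_ml <- c(0, 1, 4)
  cfg
}

test_that("steady-state scenario writes coherent readout files", {
  out <- withr::local_tempdir()
  ss <- run_steady_state_scenario(default_model_config(), out_dir = out)
  r <- jsonlite::read_json(file.path(out, "readouts.json"))
  expect_true(r$converged)
  expect_equal(r$readouts$mutant_ras_gtp + r$readouts$wt_ras_gtp,
               r$readouts$total_ras_gtp, tolerance = 1e-9)
  expect_match(r$config_hash, "^[0-9a-f]{32}$")
  species <- utils::read.csv(file.path(out, "species.csv"))
  expect_identical(nrow(species), 24L)
  # the combo working doses suppress wild-type RAS-GTP below vehicle
  vehicle <- find_steady_state(network_from_config(default_model_config()))
  expect_lt(r$readouts$wt_ras_gtp, vehicle$readouts$wt_ras_gtp)
})

test_that("synergy-grid scenario reproduces its files byte-identically", {
  cfg <- small_scenario_config()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res1 <- run_synergy_grid_scenario(cfg, out_dir = out1, write_plots = FALSE)
  res2 <- run_synergy_grid_scenario(cfg, out_dir = out2, write_plots = FALSE)
  for (f in c("dose_grid.csv", "eob_total_ras_gtp.csv",
              "eob_mutant_ras_gtp.csv", "eob_wt_ras_gtp.csv")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_true(all(res1$grid$converged))
  # interior synergy is positive at the working-dose cell for all readouts
  for (nm in names(res1$synergy)) {
    expect_gt(res1$synergy[[nm]]$eob[2, 2], 0)
  }
})

test_that("knockdown panel reports the NF1-dependent orderings", {
  panel <- run_knockdown_panel_scenario(small_scenario_config(),
                                        nf1_kd = 0.9, kras_kd = 0.9)
  expect_true(all(panel$converged))
  row <- function(iv, nf1) {
    panel$wt_normalized[panel$intervention == iv & panel$nf1 == nf1]
  }
  expect_equal(row("none", "intact"), 1.0, tolerance = 1e-9)
  # the G12C inhibitor and the KRAS knockdown both lower WT RAS-GTP ...
  expect_lt(row("g12ci", "intact"), 1)
  expect_lt(row("kras_kd", "intact"), 1)
  # ... and NF1 knockdown attenuates the drop (rescue), comparing each
  # arm to its own NF1 baseline
  rel_drop <- function(iv, nf1) 1 - row(iv, nf1) / row("none", nf1)
  expect_lt(rel_drop("g12ci", "knockdown"), rel_drop("g12ci", "intact"))
  expect_lt(rel_drop("kras_kd", "knockdown"), rel_drop("kras_kd", "intact"))
})

test_that("panel output files carry the config hash", {
  out <- withr::local_tempdir()
  run_knockdown_panel_scenario(small_scenario_config(), out_dir = out)
  expect_true(file.exists(file.path(out, "knockdown_panel.csv")))
  meta <- jsonlite::read_json(file.path(out, "knockdown_panel_meta.json"))
  expect_match(meta$config_hash, "^[0-9a-f]{32}$")
})
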