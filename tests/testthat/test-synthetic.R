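test_that("plate generation is a pure function of its seed", {
  grid <- small_het_grid()
  p1 <- generate_viability_plate(grid, viability_link(1.2, 0.1),
                                 sigma = 0.1, n_replicates = 3, seed = 11)
  p2 <- generate_viability_plate(grid, viability_link(1.2, 0.1),
                                 sigma = 0.1, n_replicates = 3, seed = 11)
  p3 <- generate_viability_plate(grid, viability_link(1.2, 0.1),
                                 sigma = 0.1, n_replicates = 3, seed = 12)
  expect_identical(p1$replicates, p2$replicates)
  expect_false(identical(p1$replicates, p3$replicates))
  # the generator must not disturb the caller's RNG stream
  set.seed(5)
  expected_draw <- stats::runif(1)
  set.seed(5)
  invisible(generate_viability_plate(grid, viability_link(), seed = 99))
  expect_identical(stats::runif(1), expected_draw)
})

test_that("noise-free identity link reproduces the normalised model surface", {
  grid <- small_het_grid()
  plate <- generate_viability_plate(grid, viability_link(gamma = 1, floor = 0),
                                    sigma = 0, n_replicates = 1, seed = 1)
  total <- grid$readouts$total_ras_gtp
  expect_equal(unname(plate$replicates[[1]]), unname(total / total[1, 1]))
  expect_identical(plate$truth[1, 1], 1)  # vehicle cell normalises to 1
})

test_that("replicate log-intensity spread is consistent with sigma", {
  grid <- small_het_grid()
  sigma <- 0.1
  n_seeds <- 120
  # pooled unbiased SD of log replicates across many seeds, one cell
  devs <- unlist(lapply(seq_len(n_seeds), function(s) {
    p <- generate_viability_plate(grid, viability_link(), sigma = sigma,
                                  n_replicates = 3, seed = s)
    vals <- log(vapply(p$replicates, function(m) m[3, 3], numeric(1)))
    vals - mean(vals)
  }))
  df <- n_seeds * 2  # 3 replicates centred per seed
  sd_hat <- sqrt(sum(devs^2) / df)
  se <- sigma / sqrt(2 * df)
  expect_lt(abs(sd_hat - sigma), 3 * se)
})

test_that("generation refuses unconverged grids", {
  grid <- small_het_grid()
  bad <- grid
  bad$converged[2, 2] <- FALSE
  expect_error(generate_viability_plate(bad, viability_link()), "unconverged")
})

test_that("pulldown emulation: normalisation, determinism, arm ordering", {
  net <- het_network()
  pd <- generate_pulldown(net, sigma = 0.1, n_replicates = 3, seed = 21)
  veh <- pd$data[pd$data$arm == "vehicle", ]
  expect_true(all(veh$normalized == 1))

  pd0 <- generate_pulldown(net, sigma = 0, n_replicates = 3, seed = 21)
  by_cell <- split(pd0$data$intensity, paste(pd0$data$arm, pd0$data$isoform))
  expect_true(all(vapply(by_cell, function(v) length(unique(v)) == 1L,
                         logical(1))))

  # combo suppresses wild-type RAS-GTP below both monotherapies: check
  # the noise-free model ordering first, then the drawn replicate means
  wt_free <- pd$noise_free[, "NRAS"] + pd$noise_free[, "HRAS"]
  expect_lt(wt_free[["combo"]], wt_free[["egfri"]])
  expect_lt(wt_free[["combo"]], wt_free[["g12ci"]])
  wt_rows <- pd$data$isoform %in% c("NRAS", "HRAS")
  arm_means <- tapply(pd$data$normalized[wt_rows], pd$data$arm[wt_rows], mean)
  expect_lt(arm_means[["combo"]], arm_means[["egfri"]])
  expect_lt(arm_means[["combo"]], arm_means[["g12ci"]])

  # pERK proxy falls under combination treatment
  perk_means <- tapply(pd$perk$normalized, pd$perk$arm, mean)
  expect_lt(perk_means[["combo"]], perk_means[["vehicle"]])
})

test_that("synthetic plates round-trip through the EOB pipeline", {
  grid <- small_het_grid()
  link <- viability_link(gamma = 1, floor = 0.1)
  noise_free <- generate_viability_plate(grid, link, sigma = 0,
                                         n_replicates = 1, seed = 1)
  eob_true <- eob_matrix(effect_from_viability(
    noise_free$replicates[[1]], grid$egfri_doses, grid$g12ci_doses
  ))$eob

  plate <- generate_viability_plate(grid, link, sigma = 0.05,
                                    n_replicates = 3, seed = 31)
  reps <- lapply(plate$replicates, function(m) {
    eob_matrix(effect_from_viability(m, grid$egfri_doses, grid$g12ci_doses))
  })
  agg <- aggregate_replicates(reps)
  # mean-of-replicates EOB sits within a few noise SDs of the truth
  expect_lt(max(abs(agg$mean$eob - eob_true)), 100 * 0.05 * 3)
})

test_that("tidy serialisation of synthetic data carries the truth sidecar", {
  grid <- small_het_grid()
  plate <- generate_viability_plate(grid, viability_link(1.3, 0.15),
                                    sigma = 0.05, n_replicates = 2, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_synthetic_csv(plate, csv, json)
  df <- utils::read.csv(csv)
  expect_identical(nrow(df), 2L * length(plate$truth))
  meta <- jsonlite::read_json(json)
  expect_equal(meta$link$gamma, 1.3)
  expect_equal(meta$seed, 3)
  expect_equal(meta$sigma, 0.05)
})

test_that("link recovery finds the generating basin and discriminates models", {
  grid <- small_het_grid()
  link <- viability_link(gamma = 1.3, floor = 0.15)
  plate <- generate_viability_plate(grid, link, sigma = 0,
                                    n_replicates = 1, seed = 1)
  fit <- recover_link_parameters(plate, het_network(), refine = "spline")
  expect_lt(abs(fit$gamma - 1.3) / 1.3, 0.01)
  expect_lt(abs(fit$floor - 0.15) / 0.15, 0.01)
  expect_lt(abs(fit$ic50 - 0.2) / 0.2, 0.01)

  fit_wrong <- recover_link_parameters(plate, g12v_network(),
                                       refine = "spline")
  expect_gt(fit_wrong$residual_norm, 10 * max(fit$residual_norm, 1e-9))
})
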