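# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are pure functions of
# (config, seed).
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Viability link from normalized RAS-GTP
#'
#' The synthetic viability surface is a declared emulation device (the
#' experiments measure viability and RAS-GTP separately, without a stated
#' link): viability = `floor + (1 - floor) * m^gamma` where `m` is
#' vehicle-normalised total RAS-GTP, `gamma` a power-law exponent and
#' `floor` the RAS-independent baseline viability.
#'
#' @param gamma power-law exponent, > 0.
#' @param floor baseline viability in \[0, 1).
#' @return An object of class `viability_link`.
#' @export
viability_link <- function(gamma = 1, floor = 0.1) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.numeric(floor) || floor < 0 || floor >= 1) {
    stop("floor must lie in [0, 1)")
  }
  structure(list(gamma = gamma, floor = floor), class = "viability_link")
}

.apply_link <- function(m, link) link$floor + (1 - link$floor) * m^link$gamma

#' Generate a synthetic MTT-style viability plate from a model grid
#'
#' Emulates a 2-D drug-combination viability experiment: the noise-free
#' surface is the [viability_link()] applied to the vehicle-normalised
#' total RAS-GTP surface of a converged [dose_response_grid()]; each
#' replicate multiplies the surface by i.i.d. lognormal noise
#' (`exp(rnorm(0, sigma))`), keeping optical-density-like values
#' positive. Regeneration with the same seed is bit-identical.
#'
#' @param grid a fully converged `ras_dose_grid`.
#' @param link a [viability_link()].
#' @param sigma lognormal noise scale (SD of log intensities).
#' @param n_replicates replicate plates to draw.
#' @param seed integer seed; the generator is a pure function of
#'   (grid, link, sigma, n_replicates, seed).
#' @return An object of class `viability_plate`: `replicates` (list of
#'   matrices), `truth` (noise-free surface), axes, `link`, `sigma`,
#'   `seed`, and the grid's inhibitor templates (the truth sidecar for
#'   recovery tests).
#' @export
generate_viability_plate <- function(grid, link = viability_link(),
                                     sigma = 0.1, n_replicates = 3,
                                     seed = 1) {
  stopifnot(inherits(grid, "ras_dose_grid"), inherits(link, "viability_link"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!all(grid$converged)) {
    stop("refusing to generate data from a grid with unconverged cells")
  }
  total <- grid$readouts$total_ras_gtp
  m <- total / total[1, 1]
  truth <- .apply_link(m, link)
  dimnames(truth) <- dimnames(total)
  replicates <- .with_seed(seed, function() {
    lapply(seq_len(n_replicates), function(r) {
      noise <- matrix(stats::rnorm(length(truth), 0, sigma),
                      nrow(truth), ncol(truth))
      truth * exp(noise)
    })
  })
  structure(list(
    replicates = replicates,
    truth = truth,
    egfri_doses = grid$egfri_doses,
    g12ci_doses = grid$g12ci_doses,
    link = link,
    sigma = sigma,
    seed = seed,
    g12ci_template = grid$g12ci_template,
    egfri_template = grid$egfri_template
  ), class = "viability_plate")
}

#' @export
print.viability_plate <- function(x, ...) {
  cat(sprintf(
    "<viability_plate> %d x %d, %d replicate(s), sigma = %.3g, seed = %d\n",
    nrow(x$truth), ncol(x$truth), length(x$replicates), x$sigma, x$seed
  ))
  invisible(x)
}

#' Tidy data.frame view of a viability plate
#' @param x a `viability_plate`.
#' @param ... unused.
#' @return data.frame with `egfri_dose`, `g12ci_dose`, `replicate`,
#'   `value`.
#' @export
as.data.frame.viability_plate <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$replicates), function(r) {
    m <- x$replicates[[r]]
    data.frame(
      egfri_dose = rep(x$egfri_doses, times = ncol(m)),
      g12ci_dose = rep(x$g12ci_doses, each = nrow(m)),
      replicate = r,
      value = as.vector(m)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset as tidy CSV with a JSON truth sidecar
#'
#' @param x a `viability_plate` or `pulldown_dataset`.
#' @param csv_path output CSV path.
#' @param json_path output JSON sidecar (seed, noise, generating truth).
#' @return `csv_path`, invisibly.
#' @export
write_synthetic_csv <- function(x, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(x), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    meta <- if (inherits(x, "viability_plate")) {
      list(kind = "viability_plate", seed = x$seed, sigma = x$sigma,
           link = unclass(x$link),
           egfri_link = if (!is.null(x$egfri_template)) {
             unclass(x$egfri_template)
           },
           n_replicates = length(x$replicates))
    } else {
      list(kind = "pulldown_dataset", seed = x$seed, sigma = x$sigma,
           n_replicates = x$n_replicates)
    }
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(csv_path)
}

#' Default four-arm treatment set for pulldown emulation
#'
#' Vehicle, EGFR inhibitor alone, covalent G12C inhibitor alone, and the
#' combination, at the working doses of 1 ug/ml (EGFRi, through the
#' configured Hill link) and 250 nM (G12Ci).
#'
#' @param egfri_dose EGFR-inhibitor dose (native units, default 1).
#' @param g12ci_dose_nM G12C-inhibitor dose in nM (default 250).
#' @param ic50 EGFRi Hill link midpoint.
#' @return Named list of [treatment()] objects.
#' @export
pulldown_arms <- function(egfri_dose = 1, g12ci_dose_nM = 250, ic50 = 0.2) {
  egfri <- egfr_inhibition(dose = egfri_dose, ic50 = ic50)
  g12ci <- amg510(g12ci_dose_nM)
  list(
    vehicle = treatment(),
    egfri = treatment(egfri = egfri),
    g12ci = treatment(g12ci = g12ci),
    combo = treatment(g12ci = g12ci, egfri = egfri)
  )
}

#' Generate a synthetic RBD-pulldown style dataset
#'
#' Emulates active-RAS pulldown quantifications: per treatment arm and
#' isoform, the steady-state GTP-bound RAS of the model is multiplied by
#' i.i.d. lognormal band-intensity noise per replicate. A phenomenological
#' pERK proxy — a Hill function of total RAS-GTP, standing in for the
#' downstream MAPK readout without modeling the cascade — is generated
#' alongside. Mirroring per-blot normalisation, each replicate is
#' normalised to its own vehicle replicate, so vehicle-normalised values
#' are exactly 1 in the vehicle arm.
#'
#' @param network an untreated `ras_network`.
#' @param arms named list of [treatment()] objects; must contain
#'   `vehicle`.
#' @param sigma lognormal noise scale.
#' @param n_replicates replicates per arm (3 by default, as in triplicate
#'   pulldown experiments).
#' @param seed integer seed.
#' @param perk_hill Hill coefficient of the pERK proxy.
#' @param perk_khalf_rel half-maximal total RAS-GTP of the pERK proxy,
#'   relative to the vehicle level.
#' @param options a [solver_options()].
#' @return An object of class `pulldown_dataset`: `data` (tidy
#'   data.frame: arm, isoform, replicate, intensity, normalized), `perk`
#'   (arm, replicate, value, normalized), `noise_free` (arm x isoform
#'   matrix of model GTP readouts), `seed`, `sigma`.
#' @export
generate_pulldown <- function(network, arms = pulldown_arms(),
                              sigma = 0.1, n_replicates = 3, seed = 1,
                              perk_hill = 2, perk_khalf_rel = 0.5,
                              options = solver_options()) {
  stopifnot(inherits(network, "ras_network"))
  if (!("vehicle" %in% names(arms))) stop("arms must include 'vehicle'")
  if (sigma < 0) stop("sigma must be non-negative")

  vehicle_ss <- find_steady_state(network, arms$vehicle, options = options)
  if (!vehicle_ss$converged) stop("vehicle steady state did not converge")
  states <- lapply(arms, function(tr) {
    if (.is_empty_treatment(tr)) {
      vehicle_ss
    } else {
      find_steady_state(network, tr, init = vehicle_ss$state,
                        options = options)
    }
  })
  if (!all(vapply(states, `[[`, logical(1), "converged"))) {
    stop("refusing to generate data from unconverged steady states")
  }

  isoforms <- c("KRAS", "NRAS", "HRAS")
  noise_free <- t(vapply(states, function(s) s$readouts$isoform_gtp,
                         numeric(3)))
  colnames(noise_free) <- isoforms
  total_vehicle <- states$vehicle$readouts$total_ras_gtp
  k_half <- perk_khalf_rel * total_vehicle
  perk_free <- vapply(states, function(s) {
    t <- s$readouts$total_ras_gtp
    t^perk_hill / (t^perk_hill + k_half^perk_hill)
  }, numeric(1))

  drawn <- .with_seed(seed, function() {
    band <- array(
      stats::rnorm(length(arms) * 3 * n_replicates, 0, sigma),
      dim = c(length(arms), 3, n_replicates)
    )
    perk_noise <- matrix(stats::rnorm(length(arms) * n_replicates, 0, sigma),
                         length(arms), n_replicates)
    list(band = band, perk = perk_noise)
  })

  rows <- list()
  vi <- which(names(arms) == "vehicle")
  for (a in seq_along(arms)) {
    for (iso in seq_along(isoforms)) {
      for (r in seq_len(n_replicates)) {
        intensity <- noise_free[a, iso] * exp(drawn$band[a, iso, r])
        vehicle_intensity <- noise_free[vi, iso] * exp(drawn$band[vi, iso, r])
        rows[[length(rows) + 1L]] <- data.frame(
          arm = names(arms)[a], isoform = isoforms[iso], replicate = r,
          intensity = intensity,
          normalized = intensity / vehicle_intensity
        )
      }
    }
  }
  data <- do.call(rbind, rows)

  perk_rows <- list()
  for (a in seq_along(arms)) {
    for (r in seq_len(n_replicates)) {
      v <- perk_free[a] * exp(drawn$perk[a, r])
      v0 <- perk_free[vi] * exp(drawn$perk[vi, r])
      perk_rows[[length(perk_rows) + 1L]] <- data.frame(
        arm = names(arms)[a], replicate = r, value = v,
        normalized = v / v0
      )
    }
  }

  structure(list(
    data = data,
    perk = do.call(rbind, perk_rows),
    noise_free = noise_free,
    arms = arms,
    seed = seed,
    sigma = sigma,
    n_replicates = n_replicates
  ), class = "pulldown_dataset")
}

#' @export
print.pulldown_dataset <- function(x, ...) {
  cat(sprintf(
    "<pulldown_dataset> %d arm(s) x 3 isoforms x %d replicate(s), sigma = %.3g\n",
    length(x$arms), x$n_replicates, x$sigma
  ))
  agg <- stats::aggregate(normalized ~ arm + isoform, x$data, mean)
  print(utils::head(agg, 12))
  invisible(x)
}

#' @export
as.data.frame.pulldown_dataset <- function(x, ...) x$data
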