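#' Two-dimensional dose-response grid of steady-state readouts
#'
#' Solves one steady state per (EGFR-inhibitor dose, G12C-inhibitor dose)
#' cell. Rows index the EGFR inhibitor, columns the G12C inhibitor; both
#' dose vectors must start with 0, so cell (1,1) is the vehicle steady
#' state. Every cell starts from the same vehicle steady state
#' (treatments act on pre-equilibrated cells), making cells independent:
#' execution order cannot affect results.
#'
#' @param network an untreated `ras_network`.
#' @param g12ci_doses vector of covalent-inhibitor doses (M), first
#'   element 0.
#' @param egfri_doses vector of EGFR-inhibitor doses in the native units
#'   of `egfri_template` (or inhibition fractions when the template is
#'   `NULL`), first element 0.
#' @param g12ci_template a [covalent_inhibitor()] whose dose is replaced
#'   cell by cell (default AMG-510 kinetics).
#' @param egfri_template an [egfr_inhibition()] in dose-response mode
#'   whose dose is replaced cell by cell; `NULL` interprets `egfri_doses`
#'   as direct inhibition fractions.
#' @param perturb a [perturbation()] applied uniformly to all cells, or
#'   `NULL`.
#' @param options a [solver_options()]. Grid cells warm-start Newton from
#'   the vehicle steady state with the integrate-then-polish path as
#'   fallback.
#' @return An object of class `ras_dose_grid`: `g12ci_doses`,
#'   `egfri_doses`, `readouts` (list of matrices: `total_ras_gtp`,
#'   `mutant_ras_gtp`, `wt_ras_gtp`, `free_gap`, `adduct_fraction`),
#'   `converged` (logical matrix), `vehicle` (the vehicle
#'   `ras_steady_state`), plus the templates.
#' @export
dose_response_grid <- function(network, g12ci_doses, egfri_doses,
                               g12ci_template = amg510(0),
                               egfri_template = egfr_inhibition(dose = 0),
                               perturb = NULL,
                               options = solver_options()) {
  stopifnot(inherits(network, "ras_network"))
  if (length(g12ci_doses) < 1L || g12ci_doses[1] != 0) {
    stop("g12ci_doses must start with 0 (vehicle column)")
  }
  if (length(egfri_doses) < 1L || egfri_doses[1] != 0) {
    stop("egfri_doses must start with 0 (vehicle row)")
  }
  nr <- length(egfri_doses)
  nc <- length(g12ci_doses)

  vehicle <- find_steady_state(network, options = options)
  cell_options <- options
  cell_options$newton_first <- TRUE

  readout_names <- c("total_ras_gtp", "mutant_ras_gtp", "wt_ras_gtp",
                     "free_gap", "adduct_fraction")
  readouts <- lapply(readout_names, function(nm) {
    matrix(NA_real_, nr, nc,
           dimnames = list(egfri = egfri_doses, g12ci = g12ci_doses))
  })
  names(readouts) <- readout_names
  converged <- matrix(NA, nr, nc,
                      dimnames = list(egfri = egfri_doses, g12ci = g12ci_doses))

  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      tr <- .grid_cell_treatment(g12ci_doses[j], egfri_doses[i],
                                 g12ci_template, egfri_template, perturb)
      ss <- if (.is_empty_treatment(tr)) {
        vehicle
      } else {
        find_steady_state(network, tr, init = vehicle$state,
                          options = cell_options)
      }
      converged[i, j] <- ss$converged
      for (nm in readout_names) readouts[[nm]][i, j] <- ss$readouts[[nm]]
    }
  }

  structure(list(
    g12ci_doses = g12ci_doses,
    egfri_doses = egfri_doses,
    readouts = readouts,
    converged = converged,
    vehicle = vehicle,
    network = network,
    g12ci_template = g12ci_template,
    egfri_template = egfri_template,
    perturb = perturb,
    options = options
  ), class = "ras_dose_grid")
}

.grid_cell_treatment <- function(g12ci_dose, egfri_dose,
                                 g12ci_template, egfri_template, perturb) {
  g12ci <- if (g12ci_dose > 0) {
    covalent_inhibitor(g12ci_template$name, g12ci_template$kinact_over_ki,
                       dose = g12ci_dose)
  }
  egfri <- if (egfri_dose > 0) {
    if (is.null(egfri_template)) {
      egfr_inhibition(fraction = egfri_dose)
    } else {
      egfr_inhibition(dose = egfri_dose, ic50 = egfri_template$ic50,
                      hill = egfri_template$hill,
                      max_inhibition = egfri_template$max_inhibition)
    }
  }
  treatment(g12ci = g12ci, egfri = egfri, perturb = perturb)
}

#' @export
print.ras_dose_grid <- function(x, ...) {
  cat(sprintf(
    "<ras_dose_grid> %d x %d (EGFRi x G12Ci), %d/%d cells converged\n",
    length(x$egfri_doses), length(x$g12ci_doses),
    sum(x$converged), length(x$converged)
  ))
  cat("  total RAS-GTP, vehicle-normalised:\n")
  m <- x$readouts$total_ras_gtp / x$readouts$total_ras_gtp[1, 1]
  print(round(m, 3))
  invisible(x)
}

#' Tidy data.frame view of a dose grid
#'
#' @param x a `ras_dose_grid`.
#' @param ... unused.
#' @return data.frame with columns `egfri_dose`, `g12ci_dose`, `readout`,
#'   `value`, `converged`.
#' @export
as.data.frame.ras_dose_grid <- function(x, ...) {
  rows <- list()
  for (nm in names(x$readouts)) {
    m <- x$readouts[[nm]]
    rows[[nm]] <- data.frame(
      egfri_dose = rep(x$egfri_doses, times = ncol(m)),
      g12ci_dose = rep(x$g12ci_doses, each = nrow(m)),
      readout = nm,
      value = as.vector(m),
      converged = as.vector(x$converged),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a dose grid as tidy CSV plus a JSON metadata sidecar
#'
#' @param grid a `ras_dose_grid`.
#' @param csv_path output CSV path (columns `egfri_dose`, `g12ci_dose`,
#'   `readout`, `value`, `converged`).
#' @param json_path optional metadata JSON path (doses, solver options,
#'   convergence flags, package version, optional config hash).
#' @param config_hash optional content hash recorded in the metadata.
#' @return `csv_path`, invisibly.
#' @export
write_grid_csv <- function(grid, csv_path, json_path = NULL,
                           config_hash = NULL) {
  stopifnot(inherits(grid, "ras_dose_grid"))
  utils::write.csv(as.data.frame(grid), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    meta <- list(
      package = "rascycle",
      version = as.character(utils::packageVersion("rascycle")),
      config_hash = config_hash,
      g12ci = grid$g12ci_template$name,
      g12ci_doses_M = grid$g12ci_doses,
      egfri_doses = grid$egfri_doses,
      solver = unclass(grid$options),
      n_unconverged = sum(!grid$converged)
    )
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(csv_path)
}
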