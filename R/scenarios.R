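#' Run a single steady-state scenario from a configuration
#'
#' Builds the configured network, applies the configured treatment,
#' solves the steady state, and (optionally) writes `readouts.json` and
#' `species.csv` to an output directory. Outputs embed the configuration
#' hash so every file traces back to its exact resolved configuration.
#'
#' @param cfg a [read_model_config()] configuration (default: the
#'   shipped default model).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param options a [solver_options()].
#' @return The `ras_steady_state`, invisibly when writing.
#' @export
run_steady_state_scenario <- function(cfg = default_model_config(),
                                      out_dir = NULL,
                                      options = solver_options()) {
  network <- network_from_config(cfg)
  tr <- treatment_from_config(cfg$treatment, cfg)
  ss <- find_steady_state(network, tr, options = options)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    r <- ss$readouts
    jsonlite::write_json(list(
      package = "rascycle",
      version = as.character(utils::packageVersion("rascycle")),
      config_hash = attr(cfg, "hash"),
      converged = ss$converged,
      residual = ss$residual,
      readouts = list(
        mutant_ras_gtp = r$mutant_ras_gtp,
        wt_ras_gtp = r$wt_ras_gtp,
        total_ras_gtp = r$total_ras_gtp,
        free_gap = r$free_gap,
        adduct_fraction = r$adduct_fraction,
        effector_occupancy = r$effector_occupancy
      )
    ), file.path(out_dir, "readouts.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
    utils::write.csv(
      data.frame(species = names(ss$state), concentration_M = unname(ss$state)),
      file.path(out_dir, "species.csv"), row.names = FALSE
    )
    return(invisible(ss))
  }
  ss
}

#' Run the in-silico combination dose-grid experiment
#'
#' Computes the 2-D EGFRi x G12Ci steady-state dose grid on the
#' configured network and derives excess-over-Bliss synergy matrices for
#' the total, mutant and wild-type RAS-GTP readouts. With an output
#' directory, writes the tidy grid CSV, one EOB CSV per readout, heatmap
#' images, and a JSON metadata sidecar.
#'
#' @param cfg a configuration with a `doses` block.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param options a [solver_options()].
#' @param write_plots write PNG heatmaps (requires `out_dir`).
#' @return List with `grid` (`ras_dose_grid`) and `synergy` (named list
#'   of `ras_synergy_matrix`).
#' @export
run_synergy_grid_scenario <- function(cfg = default_model_config(),
                                      out_dir = NULL,
                                      options = solver_options(),
                                      write_plots = TRUE) {
  network <- network_from_config(cfg)
  link <- cfg$egfri_link %||% list()
  egfri_template <- egfr_inhibition(
    dose = 0, ic50 = link$ic50_ug_per_ml %||% 0.2,
    hill = link$hill %||% 1, max_inhibition = link$max_inhibition %||% 1
  )
  g12ci_name <- (cfg$treatment$g12ci$name) %||% "AMG-510"
  g12ci_template <- covalent_inhibitor(
    g12ci_name,
    cfg$treatment$g12ci$kinact_over_ki %||% .known_inhibitors[[g12ci_name]],
    dose = 0
  )
  grid <- dose_response_grid(
    network,
    g12ci_doses = cfg$doses$g12ci_nM * 1e-9,
    egfri_doses = cfg$doses$egfri_ug_per_ml,
    g12ci_template = g12ci_template,
    egfri_template = egfri_template,
    options = options
  )
  readouts <- c("total_ras_gtp", "mutant_ras_gtp", "wt_ras_gtp")
  synergy <- lapply(readouts, function(nm) eob_matrix(effect_from_grid(grid, nm)))
  names(synergy) <- readouts

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_grid_csv(grid, file.path(out_dir, "dose_grid.csv"),
                   json_path = file.path(out_dir, "dose_grid_meta.json"),
                   config_hash = attr(cfg, "hash"))
    for (nm in readouts) {
      m <- synergy[[nm]]$eob
      df <- data.frame(
        egfri_dose = rep(grid$egfri_doses, times = ncol(m)),
        g12ci_dose = rep(grid$g12ci_doses, each = nrow(m)),
        eob = as.vector(m)
      )
      utils::write.csv(df, file.path(out_dir, paste0("eob_", nm, ".csv")),
                       row.names = FALSE)
      if (write_plots) {
        p <- plot_eob_heatmap(synergy[[nm]])
        ggplot2::ggsave(file.path(out_dir, paste0("eob_", nm, ".png")),
                        p, width = 5, height = 4, dpi = 150)
      }
    }
  }
  list(grid = grid, synergy = synergy)
}

#' Run the knockdown/drug factorial panel
#'
#' The in-silico analog of the NF1-dependence experiments: a factorial
#' of intervention (none, covalent G12C inhibitor, KRAS production
#' knockdown) by NF1 status (intact, 90% knockdown), optionally crossed
#' with EGFR inhibition, reporting wild-type RAS-GTP normalised to the
#' untreated NF1-intact arm.
#'
#' @param cfg a configuration; the `treatment` block supplies working
#'   doses.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param nf1_kd NF1 knockdown fraction for the knockdown arms.
#' @param kras_kd KRAS production knockdown fraction for the siRNA arms.
#' @param with_egfri also cross every arm with the configured EGFR
#'   inhibitor dose.
#' @param pools pool composition for the panel. The default is the
#'   homozygous G12C cell model: there the KRAS knockdown removes only
#'   mutant production, so the rescue factorial isolates the
#'   NF1-mediated crosstalk (in a heterozygous model the knockdown also
#'   depletes wild-type KRAS protein directly, confounding the readout).
#' @param options a [solver_options()].
#' @return data.frame with columns `intervention`, `nf1`, `egfri`,
#'   `wt_ras_gtp`, `mutant_ras_gtp`, `wt_normalized`.
#' @export
run_knockdown_panel_scenario <- function(cfg = default_model_config(),
                                         out_dir = NULL,
                                         nf1_kd = 0.9, kras_kd = 0.9,
                                         with_egfri = FALSE,
                                         pools = homozygous_g12c_pools(),
                                         options = solver_options()) {
  network <- build_network(pools, do.call(base_parameters,
                                          cfg$base_parameters))
  base_tr <- treatment_from_config(cfg$treatment, cfg)
  g12ci <- base_tr$g12ci %||% amg510(250)
  egfri <- base_tr$egfri %||% egfr_inhibition(fraction = 0.8)

  vehicle <- find_steady_state(network, options = options)
  interventions <- list(none = NULL, g12ci = g12ci, kras_kd = kras_kd)
  egfri_levels <- if (with_egfri) c(FALSE, TRUE) else FALSE

  rows <- list()
  for (iv in names(interventions)) {
    for (nf1 in c(FALSE, TRUE)) {
      for (eg in egfri_levels) {
        tr <- treatment(
          g12ci = if (iv == "g12ci") g12ci,
          egfri = if (eg) egfri,
          perturb = perturbation(
            nf1_knockdown = if (nf1) nf1_kd else 0,
            kras_knockdown = if (iv == "kras_kd") kras_kd else 0
          )
        )
        ss <- if (.is_empty_treatment(tr)) {
          vehicle
        } else {
          find_steady_state(network, tr, init = vehicle$state,
                            options = options)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          intervention = iv,
          nf1 = if (nf1) "knockdown" else "intact",
          egfri = eg,
          converged = ss$converged,
          wt_ras_gtp = ss$readouts$wt_ras_gtp,
          mutant_ras_gtp = ss$readouts$mutant_ras_gtp,
          total_ras_gtp = ss$readouts$total_ras_gtp
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  ref <- out$wt_ras_gtp[out$intervention == "none" & out$nf1 == "intact" &
                          !out$egfri]
  out$wt_normalized <- out$wt_ras_gtp / ref

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "knockdown_panel.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      package = "rascycle",
      version = as.character(utils::packageVersion("rascycle")),
      config_hash = attr(cfg, "hash"),
      nf1_kd = nf1_kd, kras_kd = kras_kd, with_egfri = with_egfri
    ), file.path(out_dir, "knockdown_panel_meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
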