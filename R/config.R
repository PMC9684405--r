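#' Path to the shipped default model configuration
#'
#' The pinned default parameter file: wild-type reference rate constants,
#' pool compositions, the EGFR-inhibitor Hill link, default dose grids
#' and synthetic-data settings. Shipping these as configuration keeps
#' every simulation reproducible from one declared file.
#'
#' @return File path of `default_model.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_model.yaml", package = "rascycle",
              mustWork = TRUE)
}

#' Read and validate a model/scenario configuration
#'
#' Configurations are YAML or JSON documents with the structure described
#' by the shipped schema (`inst/extdata/config_schema.json`). Validation
#' is structural: required blocks, types, ranges, unit suffixes, and pool
#' fraction sums are checked before any computation.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return The validated configuration list, class `ras_config`, with a
#'   `hash` attribute (MD5 of the canonicalised content).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML sequences mixing integers and reals parse as lists; flatten
  if (!is.null(cfg$doses)) {
    cfg$doses <- lapply(cfg$doses, function(v) as.numeric(unlist(v)))
  }
  validate_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- c("ras_config", class(cfg))
  cfg
}

#' @rdname read_model_config
#' @export
default_model_config <- function() read_model_config(default_config_path())

#' Validate a configuration list against the shipped schema contract
#'
#' @param cfg configuration list.
#' @return `TRUE` invisibly; errors describe the first violated
#'   constraint.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  if (!is.list(cfg)) fail("configuration must be a mapping")
  if (is.null(cfg$pools)) fail("missing required block 'pools'")
  if (is.null(cfg$base_parameters)) fail("missing required block 'base_parameters'")

  bp <- cfg$base_parameters
  allowed_bp <- names(formals(base_parameters))
  extra <- setdiff(names(bp), allowed_bp)
  if (length(extra)) fail("unknown base_parameters field(s): ",
                          paste(extra, collapse = ", "))
  for (nm in names(bp)) {
    if (!is.numeric(bp[[nm]]) || length(bp[[nm]]) != 1L || bp[[nm]] < 0) {
      fail("base_parameters$", nm, " must be a single non-negative number")
    }
  }

  pools <- cfg$pools
  if (is.data.frame(pools)) pools <- split(pools, seq_len(nrow(pools)))
  if (length(pools) < 1L) fail("at least one pool is required")
  fr <- 0
  for (p in pools) {
    if (is.null(p$name) || is.null(p$isoform) || is.null(p$genotype)) {
      fail("every pool needs name, isoform and genotype")
    }
    if (!p$isoform %in% c("KRAS", "NRAS", "HRAS")) {
      fail("pool '", p$name, "': unknown isoform '", p$isoform, "'")
    }
    if (!p$genotype %in% c("WT", "G12C", "G12V")) {
      fail("pool '", p$name, "': unknown genotype '", p$genotype, "'")
    }
    if (is.null(p$abundance_fraction)) {
      fail("pool '", p$name, "': abundance_fraction is required")
    }
    if (p$abundance_fraction < 0 || p$abundance_fraction > 1) {
      fail("pool '", p$name, "': abundance_fraction out of [0, 1]")
    }
    fr <- fr + p$abundance_fraction
  }
  if (abs(fr - 1) > 1e-12) fail("pool abundance fractions must sum to 1")

  if (!is.null(cfg$egfri_link)) {
    el <- cfg$egfri_link
    if (!is.null(el$ic50_ug_per_ml) && el$ic50_ug_per_ml <= 0) {
      fail("egfri_link$ic50_ug_per_ml must be positive")
    }
    if (!is.null(el$hill) && el$hill <= 0) fail("egfri_link$hill must be positive")
    if (!is.null(el$max_inhibition) &&
        (el$max_inhibition < 0 || el$max_inhibition > 1)) {
      fail("egfri_link$max_inhibition must lie in [0, 1]")
    }
  }
  if (!is.null(cfg$treatment)) .validate_treatment_block(cfg$treatment, fail)
  if (!is.null(cfg$doses)) {
    dl <- cfg$doses
    for (nm in c("g12ci_nM", "egfri_ug_per_ml")) {
      if (!is.null(dl[[nm]])) {
        v <- dl[[nm]]
        if (any(v < 0)) fail("doses$", nm, " must be non-negative")
        if (v[1] != 0) fail("doses$", nm, " must start with 0 (vehicle)")
      }
    }
  }
  if (!is.null(cfg$synthetic)) {
    sy <- cfg$synthetic
    if (!is.null(sy$sigma) && sy$sigma < 0) fail("synthetic$sigma must be >= 0")
    if (!is.null(sy$link)) {
      if (!is.null(sy$link$gamma) && sy$link$gamma <= 0) {
        fail("synthetic$link$gamma must be positive")
      }
      if (!is.null(sy$link$floor) &&
          (sy$link$floor < 0 || sy$link$floor >= 1)) {
        fail("synthetic$link$floor must lie in [0, 1)")
      }
    }
  }
  invisible(TRUE)
}

.validate_treatment_block <- function(tb, fail) {
  if (!is.null(tb$g12ci)) {
    if (is.null(tb$g12ci$dose_nM)) fail("treatment$g12ci needs dose_nM")
    if (tb$g12ci$dose_nM < 0) fail("treatment$g12ci$dose_nM must be >= 0")
  }
  if (!is.null(tb$egfri)) {
    has_dose <- !is.null(tb$egfri$dose_ug_per_ml)
    has_fraction <- !is.null(tb$egfri$fraction)
    if (has_dose == has_fraction) {
      fail("treatment$egfri needs exactly one of dose_ug_per_ml or fraction")
    }
    if (has_fraction && (tb$egfri$fraction < 0 || tb$egfri$fraction > 1)) {
      fail("treatment$egfri$fraction must lie in [0, 1]")
    }
    if (has_dose && tb$egfri$dose_ug_per_ml < 0) {
      fail("treatment$egfri$dose_ug_per_ml must be >= 0")
    }
  }
  if (!is.null(tb$perturbation)) {
    for (nm in c("nf1_kd", "kras_kd")) {
      v <- tb$perturbation[[nm]]
      if (!is.null(v) && (v < 0 || v > 1)) {
        fail("treatment$perturbation$", nm, " must lie in [0, 1]")
      }
    }
  }
  invisible(TRUE)
}

#' Content hash of a configuration
#'
#' MD5 of the canonicalised (JSON-serialised) configuration; embedded in
#' scenario outputs so any result traces back to the exact resolved
#' configuration.
#'
#' @param cfg configuration list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  attributes(cfg) <- attributes(cfg)["names"]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

#' Build a reaction network from a configuration
#'
#' @param cfg a configuration list from [read_model_config()].
#' @return A `ras_network`.
#' @export
network_from_config <- function(cfg) {
  base <- do.call(base_parameters, cfg$base_parameters)
  pools <- cfg$pools
  if (is.data.frame(pools)) pools <- split(pools, seq_len(nrow(pools)))
  pools <- lapply(pools, function(p) {
    ras_pool(p$name, p$isoform, p$genotype,
             abundance_fraction = p$abundance_fraction)
  })
  build_network(pools, base)
}

.known_inhibitors <- list("AMG-510" = 9900, "ARS-853" = 76)

#' Build a treatment from a configuration block
#'
#' Doses carry explicit unit suffixes (`dose_nM`, `dose_ug_per_ml`) and
#' are converted to SI internally. The G12C inhibitor's kinact/Ki is
#' looked up by name (AMG-510, ARS-853) unless given explicitly as
#' `kinact_over_ki`.
#'
#' @param tb the `treatment` block of a configuration.
#' @param cfg the full configuration (for the EGFRi Hill link defaults).
#' @return A [treatment()].
#' @export
treatment_from_config <- function(tb, cfg = NULL) {
  if (is.null(tb)) return(treatment())
  g12ci <- NULL
  if (!is.null(tb$g12ci)) {
    name <- tb$g12ci$name %||% "AMG-510"
    kk <- tb$g12ci$kinact_over_ki %||% .known_inhibitors[[name]]
    if (is.null(kk)) {
      stop("unknown G12C inhibitor '", name,
           "'; give kinact_over_ki explicitly")
    }
    g12ci <- covalent_inhibitor(name, kk, dose = tb$g12ci$dose_nM * 1e-9)
  }
  egfri <- NULL
  if (!is.null(tb$egfri)) {
    if (!is.null(tb$egfri$fraction)) {
      egfri <- egfr_inhibition(fraction = tb$egfri$fraction)
    } else {
      link <- cfg$egfri_link %||% list()
      egfri <- egfr_inhibition(
        dose = tb$egfri$dose_ug_per_ml,
        ic50 = link$ic50_ug_per_ml %||% 0.2,
        hill = link$hill %||% 1,
        max_inhibition = link$max_inhibition %||% 1
      )
    }
  }
  perturb <- NULL
  if (!is.null(tb$perturbation)) {
    perturb <- perturbation(
      nf1_knockdown = tb$perturbation$nf1_kd %||% 0,
      kras_knockdown = tb$perturbation$kras_kd %||% 0
    )
  }
  treatment(g12ci = g12ci, egfri = egfri, perturb = perturb)
}
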