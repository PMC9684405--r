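#' Fraction affected
#'
#' Converts a treated readout to the fraction-affected scale:
#' `1 - treated/vehicle`, clamped to \[0, 1\]. The same transform serves
#' viability fractions (where it is "1 minus percent viable") and model
#' RAS-GTP readouts (where synergy is scored on predicted RAS-GTP).
#'
#' @param treated numeric vector/matrix of treated values.
#' @param vehicle scalar vehicle (untreated) value, > 0.
#' @return Values on the fraction-affected scale, clamped to \[0, 1\].
#' @examples
#' fraction_affected(0.25, 1) # 0.75
#' @export
fraction_affected <- function(treated, vehicle) {
  if (!is.numeric(vehicle) || length(vehicle) != 1L || is.na(vehicle) ||
      vehicle <= 0) {
    stop("vehicle value must be a single positive number")
  }
  pmin(pmax(1 - treated / vehicle, 0), 1)
}

#' Bliss-independence expected fraction affected
#'
#' Under Bliss independence two non-interacting drugs with single-agent
#' fractions affected `fa_a` and `fa_b` combine to
#' `fa_a + fa_b - fa_a * fa_b` (symmetric in its arguments).
#'
#' @param fa_a,fa_b fractions affected in \[0, 1\] (vectorised).
#' @return Expected combination fraction affected.
#' @examples
#' bliss_expected(0.5, 0.5) # 0.75
#' @export
bliss_expected <- function(fa_a, fa_b) {
  if (any(fa_a < 0 | fa_a > 1, na.rm = TRUE) ||
      any(fa_b < 0 | fa_b > 1, na.rm = TRUE)) {
    stop("fractions affected must lie in [0, 1]")
  }
  fa_a + fa_b - fa_a * fa_b
}

#' Excess over Bliss
#'
#' `(fa_combo - bliss_expected(fa_a, fa_b)) * 100`, in percentage points.
#' Positive values indicate synergy, zero independence, negative
#' antagonism.
#'
#' @param fa_combo observed combination fraction affected.
#' @param fa_a,fa_b single-agent fractions affected.
#' @return Excess over Bliss in percentage points.
#' @examples
#' excess_over_bliss(0.9, 0.5, 0.5) # 15
#' @export
excess_over_bliss <- function(fa_combo, fa_a, fa_b) {
  if (any(fa_combo < 0 | fa_combo > 1, na.rm = TRUE)) {
    stop("fractions affected must lie in [0, 1]")
  }
  (fa_combo - bliss_expected(fa_a, fa_b)) * 100
}

#' Fraction-affected effect matrix
#'
#' A matrix of fraction-affected values over a 2-D dose grid, oriented
#' rows = EGFR-inhibitor dose, columns = G12C-inhibitor dose, with cell
#' (1,1) the vehicle. Row 1 and column 1 are the monotherapy margins.
#'
#' @param fa numeric matrix of fractions affected in \[0, 1\].
#' @param egfri_doses,g12ci_doses axis dose vectors (first element 0).
#' @param source provenance label: `"viability"`,
#'   `"model_total_ras_gtp"`, `"model_mutant_ras_gtp"` or
#'   `"model_wt_ras_gtp"`.
#' @param clamp_count number of cells clamped into \[0, 1\] during
#'   construction (bookkeeping for noisy viability data).
#' @return An object of class `ras_effect_matrix`.
#' @export
effect_matrix <- function(fa, egfri_doses, g12ci_doses,
                          source = c("viability", "model_total_ras_gtp",
                                     "model_mutant_ras_gtp",
                                     "model_wt_ras_gtp"),
                          clamp_count = 0L) {
  source <- match.arg(source)
  fa <- as.matrix(fa)
  stopifnot(nrow(fa) == length(egfri_doses), ncol(fa) == length(g12ci_doses))
  if (any(fa < 0 | fa > 1)) stop("fa values must lie in [0, 1]")
  if (egfri_doses[1] != 0 || g12ci_doses[1] != 0) {
    stop("dose axes must start at 0 (vehicle margins)")
  }
  dimnames(fa) <- list(egfri = egfri_doses, g12ci = g12ci_doses)
  structure(list(
    fa = fa, egfri_doses = egfri_doses, g12ci_doses = g12ci_doses,
    source = source, clamp_count = as.integer(clamp_count)
  ), class = "ras_effect_matrix")
}

#' @export
print.ras_effect_matrix <- function(x, ...) {
  cat(sprintf("<ras_effect_matrix> %d x %d, source = %s (%d clamped)\n",
              nrow(x$fa), ncol(x$fa), x$source, x$clamp_count))
  print(round(x$fa, 3))
  invisible(x)
}

#' Effect matrix from a model dose grid
#'
#' @param grid a [dose_response_grid()] result.
#' @param readout which readout to score: total, mutant or wild-type
#'   RAS-GTP.
#' @return A [effect_matrix()] with the matching `model_*` source.
#' @export
effect_from_grid <- function(grid,
                             readout = c("total_ras_gtp",
                                         "mutant_ras_gtp",
                                         "wt_ras_gtp")) {
  stopifnot(inherits(grid, "ras_dose_grid"))
  readout <- match.arg(readout)
  values <- grid$readouts[[readout]]
  vehicle <- values[1, 1]
  raw <- 1 - values / vehicle
  clamped <- sum(raw < 0 | raw > 1)
  effect_matrix(
    fraction_affected(values, vehicle),
    grid$egfri_doses, grid$g12ci_doses,
    source = paste0("model_", sub("_ras_gtp", "", readout), "_ras_gtp"),
    clamp_count = clamped
  )
}

#' Effect matrix from a viability matrix (vehicle cell at \[1,1\])
#'
#' Viability values above the vehicle (possible under replicate noise)
#' give negative fractions affected and are clamped to 0; the clamp
#' count is recorded on the returned object.
#'
#' @param viability matrix of viability fractions, vehicle at cell (1,1).
#' @param egfri_doses,g12ci_doses axis dose vectors.
#' @return A [effect_matrix()] with source `"viability"`.
#' @export
effect_from_viability <- function(viability, egfri_doses, g12ci_doses) {
  viability <- as.matrix(viability)
  vehicle <- viability[1, 1]
  raw <- 1 - viability / vehicle
  clamped <- sum(raw < 0 | raw > 1)
  effect_matrix(fraction_affected(viability, vehicle),
                egfri_doses, g12ci_doses,
                source = "viability", clamp_count = clamped)
}

#' Excess-over-Bliss synergy matrix from an effect matrix
#'
#' Uses row 1 (EGFR inhibitor alone) and column 1 (G12C inhibitor alone)
#' as the monotherapy margins: for an interior cell (i, j) the expected
#' fraction affected is `bliss_expected(fa[i,1], fa[1,j])` and
#' EOB(i, j) = `(fa[i,j] - expected) * 100`. Margin cells are defined as
#' EOB = 0.
#'
#' @param effect a [effect_matrix()] with margins present.
#' @return An object of class `ras_synergy_matrix`: `eob` (percentage
#'   points), `expected` (Bliss-expected fa), axes, `source`.
#' @export
eob_matrix <- function(effect) {
  stopifnot(inherits(effect, "ras_effect_matrix"))
  fa <- effect$fa
  if (nrow(fa) < 2L || ncol(fa) < 2L) {
    stop("effect matrix must contain both monotherapy margins")
  }
  fa_a <- fa[, 1]            # EGFRi alone, one per row
  fa_b <- fa[1, ]            # G12Ci alone, one per column
  expected <- outer(fa_a, fa_b, bliss_expected)
  eob <- (fa - expected) * 100
  eob[1, ] <- 0
  eob[, 1] <- 0
  structure(list(
    eob = eob, expected = expected,
    egfri_doses = effect$egfri_doses, g12ci_doses = effect$g12ci_doses,
    source = effect$source
  ), class = "ras_synergy_matrix")
}

#' @export
print.ras_synergy_matrix <- function(x, ...) {
  cat(sprintf("<ras_synergy_matrix> %d x %d, source = %s\n",
              nrow(x$eob), ncol(x$eob), x$source))
  cat(sprintf("  interior EOB: min %.2f, mean %.2f, max %.2f points\n",
              min(x$eob[-1, -1]), mean(x$eob[-1, -1]), max(x$eob[-1, -1])))
  invisible(x)
}

#' Aggregate replicate effect or synergy matrices
#'
#' Elementwise mean and sample standard deviation across replicates with
#' identical axes. Replicate-level EOB matrices averaged here correspond
#' to computing EOB per experiment and then averaging (the default
#' analysis order); averaging effect matrices first and then applying
#' [eob_matrix()] gives the alternative order.
#'
#' @param matrices list (length >= 2) of `ras_effect_matrix` or
#'   `ras_synergy_matrix` objects with identical axes.
#' @return A list with `mean` (an object of the input class), `sd`
#'   (numeric matrix), `n` (replicate count).
#' @export
aggregate_replicates <- function(matrices) {
  if (length(matrices) < 2L) stop("at least two replicate matrices required")
  cls <- class(matrices[[1]])[1]
  if (!cls %in% c("ras_effect_matrix", "ras_synergy_matrix")) {
    stop("matrices must be effect or synergy matrices")
  }
  if (!all(vapply(matrices, function(m) identical(class(m)[1], cls), logical(1)))) {
    stop("all replicates must share one class")
  }
  ax_ok <- vapply(matrices, function(m) {
    isTRUE(all.equal(m$egfri_doses, matrices[[1]]$egfri_doses)) &&
      isTRUE(all.equal(m$g12ci_doses, matrices[[1]]$g12ci_doses))
  }, logical(1))
  if (!all(ax_ok)) stop("replicate matrices must share identical dose axes")

  field <- if (cls == "ras_effect_matrix") "fa" else "eob"
  arr <- simplify2array(lapply(matrices, `[[`, field))
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- apply(arr, c(1, 2), stats::sd)

  mean_obj <- matrices[[1]]
  mean_obj[[field]] <- mean_m
  if (cls == "ras_synergy_matrix") {
    exp_arr <- simplify2array(lapply(matrices, `[[`, "expected"))
    mean_obj$expected <- apply(exp_arr, c(1, 2), mean)
  }
  list(mean = mean_obj, sd = sd_m, n = length(matrices))
}

#' Heatmap of an excess-over-Bliss matrix
#'
#' Diverging fill centred at EOB = 0 (blue antagonism, red synergy),
#' doses shown as ordered categories.
#'
#' @param synergy a [eob_matrix()] result.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_eob_heatmap <- function(synergy, title = NULL) {
  stopifnot(inherits(synergy, "ras_synergy_matrix"))
  df <- data.frame(
    egfri = factor(rep(synergy$egfri_doses, times = ncol(synergy$eob))),
    g12ci = factor(rep(synergy$g12ci_doses, each = nrow(synergy$eob))),
    eob = as.vector(synergy$eob)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g12ci, y = .data$egfri,
                                   fill = .data$eob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = "EOB") +
    ggplot2::labs(x = "G12C inhibitor dose (M)",
                  y = "EGFR inhibitor dose",
                  title = title %||% paste("Excess over Bliss:", synergy$source)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
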