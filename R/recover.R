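#' Recover viability-link and EGFR-inhibition parameters from a plate
#'
#' Least-squares fit of the generating parameters of a synthetic
#' viability plate against the mechanistic model: the link exponent
#' `gamma`, baseline `floor`, and the EGFR-inhibitor Hill midpoint
#' `ic50` that maps doses to GEF-inhibition fractions. The Hill slope
#' and maximal inhibition are taken from the plate's EGFRi template
#' (they are configuration, not fitted).
#'
#' The model surface enters through the steady-state total RAS-GTP at
#' GEF-inhibition fraction `f` and each G12C-inhibitor dose. Because the
#' EGFRi dose acts only through `f`, the surface is precomputed on an
#' `f`-grid per G12Ci dose and interpolated with a monotone cubic spline
#' during optimisation; for noise-free plates a final polish re-evaluates
#' the objective with exact steady-state solves so the minimiser is not
#' limited by interpolation error.
#'
#' For fixed (`ic50`, `gamma`) the baseline is linear in the residual and
#' is solved in closed form, leaving a two-parameter search over
#' (log ic50, log gamma) by Nelder-Mead from a small grid of starts.
#'
#' @param plate a [generate_viability_plate()] result.
#' @param network the untreated `ras_network` the plate was generated
#'   from (or a candidate network, for model discrimination).
#' @param n_f_nodes number of GEF-inhibition-fraction nodes for the
#'   interpolated surface.
#' @param refine `"auto"` (exact polish for noise-free plates),
#'   `"exact"`, or `"spline"`.
#' @param options a [solver_options()].
#' @return A list with `gamma`, `floor`, `ic50`, `residual_norm` (RMS of
#'   the fitted residuals), `converged`, and `fit` diagnostics.
#' @export
recover_link_parameters <- function(plate, network,
                                    n_f_nodes = 13,
                                    refine = c("auto", "exact", "spline"),
                                    options = solver_options()) {
  stopifnot(inherits(plate, "viability_plate"),
            inherits(network, "ras_network"))
  refine <- match.arg(refine)
  if (is.null(plate$egfri_template)) {
    stop("plate carries no EGFRi dose-response template; ic50 is undefined")
  }
  hill <- plate$egfri_template$hill
  max_inh <- plate$egfri_template$max_inhibition
  egfri_doses <- plate$egfri_doses
  g12ci_doses <- plate$g12ci_doses
  ybar <- Reduce(`+`, plate$replicates) / length(plate$replicates)

  cell_options <- options
  cell_options$newton_first <- TRUE
  vehicle <- find_steady_state(network, options = options)

  # One treated network per G12Ci dose (drug reaction folded in); a
  # candidate EGFRi fraction then only rescales the GEF rate constants,
  # so each steady-state evaluation is a bare warm-started Newton solve.
  n_g <- length(g12ci_doses)
  nets_j <- lapply(g12ci_doses, function(dg) {
    tr <- treatment(g12ci = if (dg > 0) {
      covalent_inhibitor(plate$g12ci_template$name,
                         plate$g12ci_template$kinact_over_ki, dose = dg)
    })
    apply_treatment(network, tr)
  })
  gef_sel <- lapply(nets_j, function(n) {
    n$reactions$kind %in% c("gef_bind", "gef_cat")
  })
  gtp_mask <- network$species$role %in% .gtp_roles

  solve_cell <- function(f, j, init) {
    net_f <- nets_j[[j]]
    if (f > 0) {
      net_f$reactions$rate[gef_sel[[j]]] <-
        net_f$reactions$rate[gef_sel[[j]]] * (1 - f)
    }
    np <- .newton_polish(net_f, init, cell_options)
    if (np$res > cell_options$newton_tol * max(np$x, 1e-30)) {
      # robust fallback for a cell Newton cannot reach from this start
      return(find_steady_state(net_f, init = init, options = options)$state)
    }
    np$x
  }

  # surface of total RAS-GTP over (f, g12ci dose), continuation in f
  f_nodes <- seq(0, 1, length.out = n_f_nodes)
  surf <- matrix(NA_real_, n_f_nodes, n_g)
  cache <- vector("list", n_g)
  for (j in seq_len(n_g)) {
    init <- vehicle$state
    states <- vector("list", n_f_nodes)
    for (i in seq_len(n_f_nodes)) {
      x <- solve_cell(f_nodes[i], j, init)
      surf[i, j] <- sum(x[gtp_mask])
      states[[i]] <- x
      init <- x
    }
    cache[[j]] <- states
  }
  m0 <- surf[1, 1]
  norm_surf <- surf / m0
  splines <- lapply(seq_len(n_g), function(j) {
    stats::splinefun(f_nodes, norm_surf[, j], method = "hyman")
  })

  f_of_dose <- function(ic50) {
    ifelse(egfri_doses == 0, 0,
           max_inh * egfri_doses^hill / (egfri_doses^hill + ic50^hill))
  }

  m_spline <- function(ic50) {
    f <- f_of_dose(ic50)
    vapply(seq_len(n_g), function(j) splines[[j]](f), numeric(length(f)))
  }

  m_exact <- function(ic50) {
    f <- f_of_dose(ic50)
    out <- matrix(NA_real_, length(f), n_g)
    for (j in seq_len(n_g)) {
      for (i in seq_along(f)) {
        near <- which.min(abs(f_nodes - f[i]))
        x <- solve_cell(f[i], j, cache[[j]][[near]])
        out[i, j] <- sum(x[gtp_mask]) / m0
      }
    }
    out
  }

  # closed-form baseline for fixed (ic50, gamma):
  # v = u + floor * (1 - u) with u = m^gamma
  sse_fun <- function(theta, m_fun) {
    ic50 <- exp(theta[1])
    gamma <- exp(theta[2])
    m <- m_fun(ic50)
    u <- m^gamma
    w <- 1 - u
    denom <- sum(w^2)
    fl <- if (denom > 0) sum((ybar - u) * w) / denom else 0
    fl <- min(max(fl, 0), 0.999)
    sum((ybar - (u + fl * w))^2)
  }

  starts <- expand.grid(
    log_ic50 = log(stats::quantile(egfri_doses[egfri_doses > 0],
                                   c(0.15, 0.5, 0.85), names = FALSE)),
    log_gamma = log(c(0.5, 1, 2))
  )
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[s, ]), sse_fun, m_fun = m_spline,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  do_exact <- refine == "exact" || (refine == "auto" && plate$sigma == 0)
  if (do_exact) {
    best <- stats::optim(best$par, sse_fun, m_fun = m_exact,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 400))
  }

  ic50 <- exp(best$par[1])
  gamma <- exp(best$par[2])
  m <- if (do_exact) m_exact(ic50) else m_spline(ic50)
  u <- m^gamma
  w <- 1 - u
  fl <- if (sum(w^2) > 0) sum((ybar - u) * w) / sum(w^2) else 0
  fl <- min(max(fl, 0), 0.999)
  resid <- ybar - (u + fl * w)

  list(
    gamma = gamma,
    floor = fl,
    ic50 = ic50,
    residual_norm = sqrt(mean(resid^2)),
    converged = best$convergence == 0,
    fit = list(sse = best$value, exact_polish = do_exact,
               optim_convergence = best$convergence)
  )
}
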