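#' Numerical options for the simulation engine
#'
#' All solver tolerances live in one options object. Integration uses a
#' stiff-capable method from \pkg{deSolve} (`lsoda`); steady states are
#' found by integrating until the relative state change over a one-hour
#' model-time window falls below `window_tol`, then polishing with a
#' damped Newton iteration on the right-hand side using the analytic
#' mass-action Jacobian.
#'
#' @param rtol,atol relative / absolute integration tolerances (absolute
#'   in M).
#' @param method deSolve integration method.
#' @param window model-time window (s) over which steady-state approach
#'   is measured.
#' @param window_tol relative change over `window` below which
#'   integration hands over to Newton.
#' @param max_time integration horizon cap (s) for the steady-state
#'   search.
#' @param newton_tol relative residual tolerance: converged when
#'   `max|dx/dt| <= newton_tol * max(state)`.
#' @param newton_maxit maximum Newton iterations.
#' @param newton_first try Newton directly from the initial state before
#'   integrating (used for warm-started continuation, e.g. along dose
#'   grids); on failure the integrate-then-polish path runs as usual.
#' @return An object of class `ras_solver_options`.
#' @export
solver_options <- function(rtol = 1e-9, atol = 1e-12, method = "lsoda",
                           window = 3600, window_tol = 1e-9,
                           max_time = 1.5e7,
                           newton_tol = 1e-9, newton_maxit = 60,
                           newton_first = FALSE) {
  structure(list(
    rtol = rtol, atol = atol, method = method,
    window = window, window_tol = window_tol, max_time = max_time,
    newton_tol = newton_tol, newton_maxit = newton_maxit,
    newton_first = newton_first
  ), class = "ras_solver_options")
}

# Rescale free + complexed enzyme/effector groups of a state so they
# match the network's conserved totals (needed when a treatment changes
# a total, e.g. NF1 knockdown, and the start state predates it).
.project_conserved <- function(state, network) {
  sp <- network$species
  ct <- network$conserved_totals
  groups <- list(
    gef = c("free_gef", "gef_gdp"),
    gap = c("free_gap", "gap_gtp"),
    eff = c("free_eff", "eff_gtp")
  )
  for (nm in names(groups)) {
    if (is.null(ct[[nm]])) next
    mask <- sp$role %in% groups[[nm]]
    cur <- sum(state[mask])
    target <- ct[[nm]]
    if (cur <= 0) {
      state[sp$role == groups[[nm]][1]] <- target
    } else if (abs(cur - target) > 1e-12 * max(cur, target)) {
      state[mask] <- state[mask] * (target / cur)
    }
  }
  state
}

.integrate <- function(network, init, times, options) {
  rhs_fun <- function(t, y, parms) list(.rhs_raw(y, network))
  jac_fun <- function(t, y, parms) .rhs_jacobian(pmax(y, 0), network)
  out <- deSolve::ode(
    y = init, times = times, func = rhs_fun, parms = NULL,
    method = options$method, rtol = options$rtol, atol = options$atol,
    jacfunc = jac_fun, jactype = "fullusr"
  )
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0) {
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         ") at t = ", max(out[, 1]), " s; try loosening tolerances")
  }
  out
}

#' Simulate a treated time course from the vehicle steady state
#'
#' Treatments are applied to a pre-equilibrated cell: unless `init` is
#' supplied, the vehicle (untreated) steady state of `network` is found
#' first and used as the starting point, mirroring drug addition to
#' growing cells.
#'
#' @param network a `ras_network` (untreated).
#' @param tr a [treatment()] or `NULL`.
#' @param t_end end time (s), > 0.
#' @param times optional explicit output time grid (s); defaults to 201
#'   evenly spaced points from 0 to `t_end`.
#' @param init optional initial state vector (aligned to the treated
#'   network's species).
#' @param options a [solver_options()].
#' @return An object of class `ras_trajectory`: list with `times`,
#'   `states` (matrix, rows = times), `network` (the treated network),
#'   `readouts` (data.frame of [state_readouts()] scalars per time).
#' @export
simulate_timecourse <- function(network, tr = NULL, t_end,
                                times = NULL, init = NULL,
                                options = solver_options()) {
  stopifnot(inherits(network, "ras_network"), t_end > 0)
  treated <- apply_treatment(network, tr)
  if (is.null(init)) {
    vehicle <- find_steady_state(network, options = options)
    init <- vehicle$state
  }
  init <- .project_conserved(init, treated)
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  out <- .integrate(treated, init, times, options)
  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- treated$species$name
  scalars <- c("mutant_ras_gtp", "wt_ras_gtp", "total_ras_gtp",
               "free_gap", "free_gef", "adduct_fraction",
               "effector_occupancy")
  readouts <- do.call(rbind, lapply(seq_len(nrow(states)), function(i) {
    r <- state_readouts(pmax(states[i, ], 0), treated)
    as.data.frame(r[scalars])
  }))
  readouts$time <- out[, 1]
  structure(list(
    times = out[, 1], states = states, network = treated,
    readouts = readouts
  ), class = "ras_trajectory")
}

#' @export
print.ras_trajectory <- function(x, ...) {
  cat(sprintf("<ras_trajectory> %d time points over %.3g s, %d species\n",
              length(x$times), max(x$times), ncol(x$states)))
  invisible(x)
}

# One damped Newton solve of rhs(x) = 0 on the non-negative orthant,
# with a fraction-to-the-boundary step limit so concentrations cannot
# be driven negative (which would put mass-action rates out of domain).
# The enzyme/effector conservation laws make the raw Jacobian exactly
# rank-deficient; the free-species rows are therefore replaced by the
# conservation constraints (scaled to rate units), which both regularises
# the Newton system and pins the conserved totals exactly.
.newton_polish <- function(network, x0, options) {
  sp <- network$species
  ct <- network$conserved_totals
  cons <- list()
  if (!is.null(ct$gef)) {
    cons$gef <- list(free = which(sp$role == "free_gef"),
                     group = which(sp$role %in% c("free_gef", "gef_gdp")),
                     total = ct$gef)
  }
  if (!is.null(ct$gap)) {
    cons$gap <- list(free = which(sp$role == "free_gap"),
                     group = which(sp$role %in% c("free_gap", "gap_gtp")),
                     total = ct$gap)
  }
  if (!is.null(ct$eff)) {
    cons$eff <- list(free = which(sp$role == "free_eff"),
                     group = which(sp$role %in% c("free_eff", "eff_gtp")),
                     total = ct$eff)
  }
  srate <- network$base$ras_degradation
  augment <- function(f, x, J = NULL) {
    for (cc in cons) {
      f[cc$free] <- (sum(x[cc$group]) - cc$total) * srate
      if (!is.null(J)) {
        J[cc$free, ] <- 0
        J[cc$free, cc$group] <- srate
      }
    }
    if (is.null(J)) f else list(f = f, J = J)
  }

  x <- pmax(x0, 0)
  f <- augment(.rhs_raw(x, network), x)
  best <- list(x = x, res = max(abs(.rhs_raw(x, network))))
  for (it in seq_len(options$newton_maxit)) {
    aug <- augment(.rhs_raw(x, network), x, .rhs_jacobian(x, network))
    f <- aug$f
    step <- tryCatch(solve(aug$J, -f), error = function(e) NULL)
    if (is.null(step)) break
    # species already at zero may not move further down
    step[x <= 0 & step < 0] <- 0
    if (all(step == 0)) break
    dec <- step < 0
    lam_max <- if (any(dec)) {
      min(1, 0.999 * min(x[dec] / -step[dec]))
    } else {
      1
    }
    lambda <- lam_max
    improved <- FALSE
    for (k in 1:30) {
      xn <- pmax(x + lambda * step, 0)
      fn <- augment(.rhs_raw(xn, network), xn)
      if (max(abs(fn)) < max(abs(f))) {
        x <- xn
        f <- fn
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    res_true <- max(abs(.rhs_raw(x, network)))
    if (res_true < best$res) best <- list(x = x, res = res_true)
    # polish well past the acceptance tolerance, down to numerical noise
    scale <- max(x, 1e-30)
    if (max(abs(f)) <= options$newton_tol * scale * 1e-4) break
  }
  best
}

#' Find the steady state of a (possibly treated) network
#'
#' Integrates from the initial state until the relative state change over
#' a one-hour window drops below `options$window_tol` (or the horizon cap
#' is hit), then polishes with damped Newton using the analytic Jacobian.
#' The lower-residual iterate of the two wins. Non-convergence is
#' flagged, not raised, so dose grids can report partial results.
#'
#' @param network a `ras_network` (untreated; `tr` is applied here).
#' @param tr a [treatment()] or `NULL`.
#' @param init optional starting state. Default: for vehicle solves, the
#'   analytic per-pool totals with all RAS in the GDP state
#'   ([initial_state()]); for treated solves, the vehicle steady state
#'   (computed internally), since treatments act on pre-equilibrated
#'   cells.
#' @param options a [solver_options()].
#' @return An object of class `ras_steady_state`: `state`, `time`
#'   (model time integrated), `converged`, `residual` (max |dx/dt|,
#'   M/s), `readouts` ([state_readouts()]), `network` (treated network).
#' @export
find_steady_state <- function(network, tr = NULL, init = NULL,
                              options = solver_options()) {
  stopifnot(inherits(network, "ras_network"))
  treated <- apply_treatment(network, tr)
  if (is.null(init)) {
    init <- if (.is_empty_treatment(tr)) {
      initial_state(treated)
    } else {
      find_steady_state(network, options = options)$state
    }
  }
  init <- .project_conserved(pmax(init, 0), treated)

  scale_of <- function(x) max(x, 1e-30)
  total_time <- 0
  x <- init

  if (options$newton_first) {
    np <- .newton_polish(treated, x, options)
    if (np$res <= options$newton_tol * scale_of(max(np$x))) {
      return(.steady_state_result(np$x, total_time, TRUE, np$res, treated))
    }
  }

  # integrate in doubling horizons until the 1-h window criterion holds,
  # attempting a Newton polish after each chunk (the polish is cheap and
  # usually lands once the transient has relaxed into its basin)
  horizon <- 48 * 3600
  repeat {
    t_hi <- min(horizon, options$max_time - total_time)
    if (t_hi <= 0) break
    times <- if (t_hi > options$window) {
      c(0, t_hi - options$window, t_hi)
    } else {
      c(0, t_hi / 2, t_hi)
    }
    out <- tryCatch(.integrate(treated, x, times, options),
                    error = function(e) NULL)
    if (is.null(out)) break
    x_prev <- pmax(out[2, -1], 0)
    x <- pmax(out[3, -1], 0)
    total_time <- total_time + t_hi
    np_try <- .newton_polish(treated, x, options)
    if (np_try$res <= options$newton_tol * scale_of(max(np_try$x))) {
      return(.steady_state_result(np_try$x, total_time, TRUE, np_try$res,
                                  treated))
    }
    delta <- max(abs(x - x_prev)) / scale_of(max(x))
    if (delta < options$window_tol || total_time >= options$max_time) break
    horizon <- horizon * 4
  }

  np <- .newton_polish(treated, x, options)
  res_int <- max(abs(.rhs_raw(x, treated)))
  if (np$res <= res_int) {
    x <- np$x
    res <- np$res
  } else {
    res <- res_int
  }
  converged <- res <= options$newton_tol * scale_of(max(x))
  .steady_state_result(x, total_time, converged, res, treated)
}

.steady_state_result <- function(state, time, converged, residual, network) {
  names(state) <- network$species$name
  structure(list(
    state = state, time = time, converged = converged,
    residual = residual, readouts = state_readouts(state, network),
    network = network
  ), class = "ras_steady_state")
}

#' @export
print.ras_steady_state <- function(x, ...) {
  r <- x$readouts
  cat(sprintf(
    "<ras_steady_state> %s (residual %.3g M/s)\n",
    if (x$converged) "converged" else "NOT converged", x$residual
  ))
  cat(sprintf("  RAS-GTP: total %.4g M (mutant %.4g, wild-type %.4g)\n",
              r$total_ras_gtp, r$mutant_ras_gtp, r$wt_ras_gtp))
  cat(sprintf("  free GAP %.4g M; adduct fraction %s; effector occupancy %.3g\n",
              r$free_gap,
              ifelse(is.na(r$adduct_fraction), "n/a",
                     sprintf("%.3g", r$adduct_fraction)),
              r$effector_occupancy))
  invisible(x)
}
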