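#' Monod reproduction rate profile
#'
#' The local per-capita division rate `rho(x) = r F(x) / (k + F(x))`,
#' saturating at `r` for abundant food and half-maximal at `F = k`.
#'
#' @param F Food concentration profile (mM), elementwise non-negative.
#' @param params A [gut_parameters()] object.
#' @return Numeric vector of rates (1/h), bounded in `[0, r)`.
#' @export
reproduction_rate <- function(F, params) {
  stopifnot(inherits(params, "gut_params"))
  if (any(F < 0))
    stop("food concentrations must be non-negative", call. = FALSE)
  params$r * F / (params$k + F)
}

#' Construct a field state
#'
#' A snapshot of the three concentration fields on a grid: food `F` (mM),
#' wild-type bacteria `B` and mutants `M` (bacteria/cm^3), at time `t`.
#'
#' @param F,B,M Numeric vectors of equal length (one value per grid cell),
#'   elementwise non-negative.
#' @param t Time (h).
#' @return Object of class `gut_field_state`.
#' @export
field_state <- function(F, B, M = rep(0, length(F)), t = 0) {
  if (length(B) != length(F) || length(M) != length(F))
    stop("F, B, M must have equal length", call. = FALSE)
  if (any(F < 0) || any(B < 0) || any(M < 0))
    stop("concentration fields must be non-negative", call. = FALSE)
  structure(list(t = t, F = as.numeric(F), B = as.numeric(B),
                 M = as.numeric(M)),
            class = "gut_field_state")
}

#' @export
print.gut_field_state <- function(x, ...) {
  cat(sprintf(
    "Field state at t = %g h on %d cells: max F = %.4g mM, max B = %.4g, max M = %.4g cm^-3\n",
    x$t, length(x$F), max(x$F), max(x$B), max(x$M)))
  invisible(x)
}

# pack/unpack between a field state and the flat solver vector c(F, B, M)
pack_state <- function(state) c(state$F, state$B, state$M)
unpack_state <- function(y, n, t) {
  field_state(F = pmax(y[seq_len(n)], 0),
              B = pmax(y[n + seq_len(n)], 0),
              M = pmax(y[2 * n + seq_len(n)], 0), t = t)
}

#' Time derivative of the field state
#'
#' Evaluates the conservative finite-volume semi-discretisation of the
#' coupled transport-reaction system:
#' `dF/dt = D F'' - v F' - (r/alpha)(B+M) F/(k+F)`,
#' `dB/dt = D B'' - v B' + rho B`, and the analogous mutant equation.
#' Advection is first-order upwind and diffusion central; the inlet face
#' carries total flux `vFin` for food and 0 for bacteria, the outlet face
#' zero diffusive flux with free advective outflow.
#'
#' This is the reference R implementation; the integrator uses an
#' identical compiled kernel (their agreement is asserted in the tests).
#'
#' @param state A [field_state()].
#' @param params A [gut_parameters()] object.
#' @param grid A [build_grid()] grid matching the state.
#' @return List with components `dF`, `dB`, `dM` (per-cell derivatives).
#' @export
gut_rhs <- function(state, params, grid) {
  stopifnot(inherits(state, "gut_field_state"), inherits(grid, "gut_grid"))
  n <- grid$n_cells
  if (length(state$F) != n)
    stop("state and grid sizes differ", call. = FALSE)
  dx <- grid$dx
  v <- params$v; D <- params$D
  transport <- function(c, inflow_flux) {
    interior <- v * c[-n] - D * diff(c) / dx
    flux <- c(inflow_flux, interior, v * c[n])
    -diff(flux) / dx
  }
  mono <- pmax(state$F, 0) / (params$k + pmax(state$F, 0))
  list(
    dF = transport(state$F, params$vFin) -
      (params$r / params$alpha) * (state$B + state$M) * mono,
    dB = transport(state$B, 0) + params$r * mono * state$B,
    dM = transport(state$M, 0) + params$r * mono * state$M)
}

# deSolve-facing derivative function (compiled kernel)
derivs_desolve <- function(t, y, p) {
  list(gut_rhs_cpp(y, p$n, p$dx, p$v, p$D, p$r, p$k, p$vFin, p$alpha))
}

solver_parms <- function(params, grid) {
  list(n = grid$n_cells, dx = grid$dx, v = params$v, D = params$D,
       r = params$r, k = params$k, vFin = params$vFin,
       alpha = params$alpha)
}

#' Advance the fields in time
#'
#' Integrates the semi-discrete system with a stiff, adaptive solver
#' (`deSolve::lsodes`); positivity is preserved up to solver tolerance
#' (tiny negative round-off is clipped on output).
#'
#' @param state Initial [field_state()].
#' @param params A [gut_parameters()] object.
#' @param grid A [build_grid()] grid.
#' @param t_end Final time (h), greater than `state$t`.
#' @param rtol,atol_frac Relative tolerance and the fraction of the
#'   natural concentration scale (`Fin`, `alpha*Fin`) used as absolute
#'   tolerance.
#' @param times Optional vector of output times (h); overrides `t_end`
#'   and returns the full trajectory.
#' @return If `times` is `NULL`, the [field_state()] at `t_end`.
#'   Otherwise a list of field states, one per output time.
#' @export
integrate_fields <- function(state, params, grid, t_end,
                             rtol = 1e-8, atol_frac = 1e-12, times = NULL) {
  stopifnot(inherits(state, "gut_field_state"), inherits(grid, "gut_grid"))
  n <- grid$n_cells
  Fin <- food_inflow_conc(params)
  atol <- c(rep(Fin * atol_frac, n), rep(params$alpha * Fin * atol_frac, 2 * n))
  tt <- if (is.null(times)) c(state$t, t_end) else times
  if (tt[length(tt)] <= state$t)
    stop("t_end must exceed the current state time", call. = FALSE)
  sol <- deSolve::ode(y = pack_state(state), times = tt,
                      func = derivs_desolve,
                      parms = solver_parms(params, grid),
                      method = "lsodes", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("time integration failed (stiff solver did not complete); ",
         "diagnostics: istate = ", attr(sol, "istate")[1], call. = FALSE)
  if (is.null(times)) {
    unpack_state(sol[nrow(sol), -1], n, t_end)
  } else {
    lapply(seq_len(nrow(sol)),
           function(i) unpack_state(sol[i, -1], n, sol[i, 1]))
  }
}

# max over cells of |dc/dt| / (|c| + eps*scale), per species scales
state_residual <- function(state, params, grid, eps = 1e-6) {
  d <- gut_rhs(state, params, grid)
  Fin <- food_inflow_conc(params)
  sB <- params$alpha * Fin
  max(abs(d$dF) / (abs(state$F) + eps * Fin),
      abs(d$dB) / (abs(state$B) + eps * sB),
      abs(d$dM) / (abs(state$M) + eps * sB))
}

#' Solve for the mutant-free steady state
#'
#' Integrates from a uniform food profile with a small uniform bacterial
#' seed until the state stops changing (max relative time derivative below
#' `tol`) or until `t_max`.  In washout regimes the bacterial field decays
#' towards zero and the (near-)zero state is returned.  The steady state
#' is independent of the seed in persistent regimes.
#'
#' @param params A [gut_parameters()] object.
#' @param grid A [build_grid()] grid (default 100 cells/cm).
#' @param t_max Integration horizon (h).
#' @param tol Steady-state tolerance on
#'   `max |dc/dt| / (|c| + 1e-6 * scale)` (1/h).
#' @param seed_frac Initial uniform bacterial seed as a fraction of
#'   `alpha * Fin`.
#' @param init Optional initial [field_state()] (overrides the default).
#' @param chunk Time between convergence checks (h).
#' @return Object of class `gut_steady`: fields `state`, `residual`,
#'   `converged`, `t_elapsed`, `washout`, plus the `params` and `grid`
#'   used.
#' @export
solve_steady_state <- function(params, grid = build_grid(params),
                               t_max = 6000, tol = 1e-8, seed_frac = 1e-3,
                               init = NULL, chunk = 100) {
  stopifnot(inherits(params, "gut_params"), inherits(grid, "gut_grid"))
  Fin <- food_inflow_conc(params)
  state <- if (is.null(init)) {
    field_state(F = rep(Fin, grid$n_cells),
                B = rep(seed_frac * params$alpha * Fin, grid$n_cells))
  } else init
  t0 <- state$t
  repeat {
    t_next <- min(state$t + chunk, t0 + t_max)
    state <- integrate_fields(state, params, grid, t_next)
    res <- state_residual(state, params, grid)
    if (res <= tol || state$t >= t0 + t_max) break
  }
  out <- list(state = state, residual = res, converged = res <= tol,
              t_elapsed = state$t - t0,
              washout = max(state$B) < 1e-6 * params$alpha * Fin,
              params = params, grid = grid)
  class(out) <- "gut_steady"
  out
}

#' @export
print.gut_steady <- function(x, ...) {
  cat(sprintf(
    "Steady state after %g h: residual %.3g 1/h (%s)%s\n",
    x$t_elapsed, x$residual,
    if (x$converged) "converged" else "NOT converged",
    if (x$washout) " -- washout (no bacteria persist)" else ""))
  invisible(x)
}

# Boundary values of a field consistent with the flux discretisation:
# at x = 0 the face value solves  v*c0 - D*(c_1 - c0)/(dx/2) = total_flux;
# at x = L zero diffusive flux gives c(L) = c_n.
boundary_values <- function(c, params, grid, inflow_flux) {
  dx <- grid$dx
  c0 <- (inflow_flux + 2 * params$D * c[1] / dx) /
    (params$v + 2 * params$D / dx)
  c(c0, c[grid$n_cells])
}

#' Spatial dependence of the food profile
#'
#' The dimensionless gradient strength `(F(0) - F(L)) / Fin` used to
#' distinguish well-mixed-like profiles (near 0) from strongly spatial
#' ones (near 1).  Boundary values are extrapolated consistently with the
#' imposed face fluxes, not taken from the first/last cell centres.
#'
#' @param steady A `gut_steady` object from [solve_steady_state()].
#' @param params Parameters (defaults to those stored in `steady`).
#' @return Numeric scalar in `[0, 1]` for monotone food profiles.
#' @export
spatial_dependence <- function(steady, params = steady$params) {
  stopifnot(inherits(steady, "gut_steady"))
  if (!steady$converged)
    warning("steady state did not converge; spatial dependence computed anyway")
  bv <- boundary_values(steady$state$F, params, steady$grid, params$vFin)
  (bv[1] - bv[2]) / food_inflow_conc(params)
}

#' Analytic washout thresholds
#'
#' The two washout limits in the (v, D) plane, evaluated with
#' `Fin = vFin/v`: diffusive washout for `D < d_crit` with
#' `d_crit = v^2 (k/Fin + 1) / (4 r)` (the flow outruns the
#' Fisher-like front that diffusion plus growth can sustain), and
#' convective washout for `v > v_crit` with `v_crit = r L / (k/Fin + 1)`
#' (transit faster than a division time).  Both are asymptotic limits.
#'
#' @param params A [gut_parameters()] object.
#' @return Named list `d_crit` (cm^2/h), `v_crit` (cm/h).
#' @export
washout_thresholds <- function(params) {
  stopifnot(inherits(params, "gut_params"))
  Fin <- food_inflow_conc(params)
  list(d_crit = params$v^2 * (params$k / Fin + 1) / (4 * params$r),
       v_crit = params$r * params$L / (params$k / Fin + 1))
}

#' Classify the flow regime
#'
#' Labels a parameter set as washout (diffusive or convective, from the
#' analytic thresholds) or persistent; persistent regimes are further
#' split into `persistent_spatial` vs `persistent_mixed` by thresholding
#' the spatial-dependence metric (default 0.9, the filter used for the
#' active-population analysis).
#'
#' @param params A [gut_parameters()] object.
#' @param steady Optional precomputed `gut_steady`; if `NULL` and the
#'   regime is persistent, the steady state is solved internally (which
#'   takes a few seconds).
#' @param threshold Spatial-dependence cutoff between the two persistent
#'   labels.
#' @param ... Passed to [solve_steady_state()] when solving internally.
#' @return Object of class `gut_regime` with fields `label`,
#'   `spatial_dependence` (NA when washed out), `d_crit`, `v_crit`.
#' @export
classify_regime <- function(params, steady = NULL, threshold = 0.9, ...) {
  th <- washout_thresholds(params)
  if (params$D < th$d_crit) {
    label <- "washout_diffusive"; dep <- NA_real_
  } else if (params$v > th$v_crit) {
    label <- "washout_convective"; dep <- NA_real_
  } else {
    if (is.null(steady)) steady <- solve_steady_state(params, ...)
    dep <- spatial_dependence(steady, params)
    label <- if (dep > threshold) "persistent_spatial" else "persistent_mixed"
  }
  structure(list(label = label, spatial_dependence = dep,
                 d_crit = th$d_crit, v_crit = th$v_crit),
            class = "gut_regime")
}

#' @export
print.gut_regime <- function(x, ...) {
  cat(sprintf("Regime: %s (d_crit = %.4g cm^2/h, v_crit = %.4g cm/h",
              x$label, x$d_crit, x$v_crit))
  if (!is.na(x$spatial_dependence))
    cat(sprintf(", spatial dependence = %.3f", x$spatial_dependence))
  cat(")\n")
  invisible(x)
}

#' Check grid convergence of the steady state
#'
#' Solves the steady state at the given resolution and at double the
#' resolution and reports the sup-norm relative change of each field
#' (normalised by its maximum).
#'
#' @param params A [gut_parameters()] object.
#' @param n_cells Base resolution.
#' @param ... Passed to [solve_steady_state()].
#' @return Named numeric vector with components `F`, `B` (relative
#'   sup-norm differences, coarse cells compared at matching positions).
#' @export
check_grid_convergence <- function(params, n_cells = round(100 * params$L),
                                   ...) {
  g1 <- build_grid(params, n_cells)
  g2 <- build_grid(params, 2 * n_cells)
  s1 <- solve_steady_state(params, g1, ...)
  s2 <- solve_steady_state(params, g2, ...)
  cmp <- function(c1, c2) {
    fine <- stats::approx(g2$cell_centers, c2, xout = g1$cell_centers,
                          rule = 2)$y
    max(abs(c1 - fine)) / max(abs(fine), .Machine$double.eps)
  }
  c(F = cmp(s1$state$F, s2$state$F), B = cmp(s1$state$B, s2$state$B))
}
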