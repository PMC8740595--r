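#' Specify a localised mutant introduction
#'
#' Neutral mutants are introduced as a narrow pulse at position `xM`: a
#' total of `NM` mutants spread over a width `dx_pulse` (by default one
#' grid cell, matching the numerical discretisation step; results are
#' independent of the width while it stays small compared with the scale
#' of concentration variation).
#'
#' @param xM Introduction position (cm), strictly inside `(0, L)`.
#' @param NM Total number of mutants introduced (> 0; may be fractional,
#'   since the deterministic dynamics is linear in the dilute limit).
#' @param dx_pulse Pulse width (cm); `NULL` means one grid cell.
#' @return Object of class `gut_pulse`.
#' @export
mutant_pulse <- function(xM, NM = 1, dx_pulse = NULL) {
  if (!is.numeric(xM) || length(xM) != 1 || !is.finite(xM))
    stop("xM must be a single finite number", call. = FALSE)
  if (!is.numeric(NM) || length(NM) != 1 || NM <= 0)
    stop("NM must be a single positive number", call. = FALSE)
  structure(list(xM = xM, NM = NM, dx_pulse = dx_pulse),
            class = "gut_pulse")
}

#' Introduce a mutant pulse into a steady state
#'
#' Returns a field state with food and wild type at their mutant-free
#' steady values and the mutant field set to `NM / (S * dx_pulse)` on the
#' cell(s) covering `xM`, so that `S * integral(M dx) = NM` exactly.  The
#' pulse must be dilute: the local mutant concentration has to be far
#' below the resident wild-type concentration (`M0 < 1e-3 * B(xM)`), as
#' the fixation analysis describes single mutants against a large
#' background.
#'
#' @param steady A converged `gut_steady` from [solve_steady_state()].
#' @param pulse A [mutant_pulse()].
#' @param grid Grid (defaults to the steady state's grid).
#' @return A [field_state()] ready for [mutant_steady_ratio()].
#' @export
introduce_mutant <- function(steady, pulse, grid = steady$grid) {
  stopifnot(inherits(steady, "gut_steady"), inherits(pulse, "gut_pulse"))
  if (!steady$converged)
    stop("steady state has not converged; refusing to introduce mutants",
         call. = FALSE)
  L <- grid$L
  if (pulse$xM <= 0 || pulse$xM >= L)
    stop("introduction position xM must lie strictly inside (0, L)",
         call. = FALSE)
  S <- steady$params$S
  width <- if (is.null(pulse$dx_pulse)) grid$dx else pulse$dx_pulse
  lo <- pulse$xM - width / 2
  hi <- pulse$xM + width / 2
  edges <- seq(0, L, by = grid$dx)
  # overlap of [lo, hi] with each cell
  overlap <- pmax(0, pmin(hi, edges[-1]) - pmax(lo, edges[-length(edges)]))
  if (sum(overlap) <= 0)
    stop("pulse does not overlap the grid", call. = FALSE)
  M0 <- pulse$NM / (S * width)
  M <- M0 * overlap / grid$dx   # per-cell concentration; S*sum(M)*dx == NM
  M <- M * pulse$NM / (S * sum(M) * grid$dx)  # exact count, clipped pulses too
  icell <- which.max(overlap)
  if (max(M) >= 1e-3 * steady$state$B[icell])
    stop("pulse concentration is not dilute relative to B(xM); ",
         "reduce NM or widen the pulse", call. = FALSE)
  field_state(F = steady$state$F, B = steady$state$B, M = M,
              t = steady$state$t)
}

#' Deterministic fate of an introduced mutant: the steady M/B ratio
#'
#' Integrates the full nonlinear system from a pulsed initial condition
#' until the fields are steady again.  Because mutants are neutral, the
#' mutant profile relaxes to a rescaled copy of the wild-type profile,
#' `M(x)/B(x) = C` independent of position; `C` is returned and equals
#' the fixation probability of that introduction (the conserved expected
#' mutant fraction).  Constancy of the ratio is verified over cells with
#' appreciable `B` (coefficient of variation below `cv_tol`).
#'
#' Convergence is judged on the ratio itself (its coefficient of
#' variation across cells and the drift of its mean between checks), not
#' on the absolute residual: the mutant field is many orders of magnitude
#' below the wild type, so absolute-scale residuals say nothing about it.
#'
#' @param initial A pulsed [field_state()] from [introduce_mutant()].
#' @param params,grid Model parameters and grid.
#' @param t_max Integration horizon (h).
#' @param cv_tol Maximum allowed coefficient of variation of `M/B`; the
#'   mean ratio must also drift by less than `cv_tol` (relative) over the
#'   last check interval.
#' @param chunk Time between convergence checks (h).
#' @return Scalar `C`, with attributes `cv` and `t_elapsed`.
#' @export
mutant_steady_ratio <- function(initial, params, grid, t_max = 6000,
                                cv_tol = 1e-3, chunk = 200) {
  stopifnot(inherits(initial, "gut_field_state"))
  Fin <- food_inflow_conc(params)
  state <- initial
  t0 <- state$t
  prev_mean <- NA_real_
  repeat {
    state <- integrate_fields(state, params, grid,
                              min(state$t + chunk, t0 + t_max))
    keep <- state$B > 1e-6 * params$alpha * Fin
    if (!any(keep))
      stop("no cells with appreciable wild-type concentration (washout?)",
           call. = FALSE)
    ratio <- state$M[keep] / state$B[keep]
    m <- mean(ratio)
    cv <- stats::sd(ratio) / m
    drift <- if (is.na(prev_mean)) Inf else abs(m - prev_mean) / m
    if (is.finite(cv) && cv < cv_tol && drift < cv_tol) break
    if (state$t >= t0 + t_max)
      stop(sprintf(
        "M/B did not become constant by t_max (CV = %.3g, drift = %.3g); increase t_max or resolution",
        cv, drift), call. = FALSE)
    prev_mean <- m
  }
  structure(m, cv = cv, t_elapsed = state$t - t0)
}

# Discrete linear operator of the mutant dynamics with food frozen at F*:
# dM/dt = A M, A tridiagonal (upwind transport + Monod growth diagonal).
mutant_operator <- function(steady, params = steady$params,
                            grid = steady$grid) {
  n <- grid$n_cells
  dx <- grid$dx
  v <- params$v; D <- params$D
  rho <- reproduction_rate(steady$state$F, params)
  a <- (v + D / dx) / dx          # sub-diagonal coefficient (from M_{i-1})
  b_up <- (D / dx) / dx           # super-diagonal coefficient (from M_{i+1})
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    outflux <- if (i > 1 && i < n) (v + 2 * D / dx) / dx
               else (v + D / dx) / dx
    A[i, i] <- -outflux + rho[i]
    if (i > 1) A[i, i - 1] <- a
    if (i < n) A[i, i + 1] <- b_up
  }
  A
}

#' Fixation probability curve from the adjoint zero mode
#'
#' With food frozen at its steady profile the mutant dynamics is linear,
#' `dM/dt = A M`, and the steady wild-type profile `B*` spans the null
#' space of `A`.  The left null vector `phi` (the adjoint zero mode)
#' defines a conserved quantity `sum(phi * M)`, which immediately gives
#' the long-time mutant fraction for a pulse at any position without time
#' integration:
#' `C(xM) = NM * phi(xM) / (S * dx * sum(phi * B*))`.
#'
#' Because the operator is tridiagonal, `phi` is computed by the
#' backward three-term recurrence of `t(A) phi = 0` starting from the
#' outlet (the stable direction: the mode grows monotonically upstream
#' and can span tens of orders of magnitude, far beyond what a dense
#' eigensolver resolves).  The first recurrence row is left over as a
#' residual; it vanishes exactly when 0 is an eigenvalue, and its
#' relative size is the accuracy check.  Positivity of `phi` is
#' guaranteed for an irreducible operator (Perron mode) and asserted.
#'
#' `C` is reported at cell centres; a pulse straddling two cells has
#' fixation probability `sum(phi * M0) / sum(phi * B*)`, the same linear
#' functional applied to its actual initial profile.
#'
#' @param steady Converged `gut_steady` in a persistent regime.
#' @param params,grid Model parameters and grid.
#' @param NM Total introduced mutant count.
#' @return Numeric vector `C(x)` over cell centres, with attributes
#'   `phi` (the adjoint mode, normalised to `phi[1] = 1`) and
#'   `residual` (relative size of the leftover recurrence row).
#' @export
fixation_curve_adjoint <- function(steady, params = steady$params,
                                   grid = steady$grid, NM = 1) {
  stopifnot(inherits(steady, "gut_steady"))
  if (!steady$converged)
    stop("steady state has not converged", call. = FALSE)
  if (steady$washout)
    stop("washout regime: no resident population, fixation undefined",
         call. = FALSE)
  A <- mutant_operator(steady, params, grid)
  n <- grid$n_cells
  d <- diag(A)
  sub <- A[2, 1]        # coupling to the upstream neighbour
  sup <- A[1, 2]        # coupling to the downstream neighbour
  phi <- numeric(n)
  phi[n] <- 1
  phi[n - 1] <- -d[n] * phi[n] / sup
  for (i in (n - 1):2)
    phi[i - 1] <- -(d[i] * phi[i] + sub * phi[i + 1]) / sup
  res <- abs(d[1] * phi[1] + sub * phi[2]) /
    (abs(d[1] * phi[1]) + abs(sub * phi[2]))
  if (!is.finite(res) || res > 1e-6)
    stop(sprintf(
      "adjoint zero mode is inaccurate (leftover residual %.2g); the null space may not be one-dimensional numerically -- refine the grid or tighten the steady state",
      res), call. = FALSE)
  if (any(phi <= 0))
    stop("adjoint mode is not positive; inconsistent operator", call. = FALSE)
  phi <- phi / phi[1]
  C <- NM * phi / (params$S * grid$dx * sum(phi * steady$state$B))
  attr(C, "phi") <- phi
  attr(C, "residual") <- res
  C
}

#' Local density of reproduction events
#'
#' `R(x) = B(x) * rho(x)`: reproductions per unit volume and time.
#' New mutants arising from replication errors appear proportionally to
#' this density, which is small both near the exit (food exhausted) and,
#' in the strongly spatial regime, near the entrance (few bacteria), with
#' a maximum in between.
#'
#' @param steady A `gut_steady` object.
#' @param params Parameters (defaults to those stored in `steady`).
#' @return Numeric vector (bacteria cm^-3 h^-1) over cell centres.
#' @export
reproduction_density <- function(steady, params = steady$params) {
  stopifnot(inherits(steady, "gut_steady"))
  steady$state$B * reproduction_rate(steady$state$F, params)
}

#' Overall fixation probability of spontaneously arising mutants
#'
#' Averages the per-position fixation probability `C(xM)` over the
#' distribution of mutant origins, which is proportional to the local
#' reproduction density `R(xM)`:
#' `F = integral(R C dx) / integral(R dx)` (finite-volume quadrature).
#'
#' @param ratio_curve `C(x)` from [fixation_curve_adjoint()] (or the
#'   direct method), per cell.
#' @param R_curve `R(x)` from [reproduction_density()], per cell.
#' @param grid The shared grid.
#' @return Scalar fixation probability.
#' @export
overall_fixation_probability <- function(ratio_curve, R_curve, grid) {
  stopifnot(inherits(grid, "gut_grid"))
  if (length(ratio_curve) != grid$n_cells ||
      length(R_curve) != grid$n_cells)
    stop("curves must live on the given grid", call. = FALSE)
  tot <- sum(R_curve) * grid$dx
  if (tot <= 0)
    stop("total reproduction rate is zero (washout); fixation undefined",
         call. = FALSE)
  sum(R_curve * ratio_curve) * grid$dx / tot
}

#' Total population size
#'
#' `NT = S * integral((B + M) dx)` over the whole segment; for a
#' mutant-free steady state this is `S * integral(B dx)`.
#'
#' @param steady A `gut_steady` object.
#' @param params Parameters (defaults to those stored in `steady`).
#' @return Scalar count of bacteria.
#' @export
total_population <- function(steady, params = steady$params) {
  stopifnot(inherits(steady, "gut_steady"))
  params$S * sum(steady$state$B + steady$state$M) * steady$grid$dx
}

#' Active population and the active-zone boundary
#'
#' The active population is the bacteria located upstream of `x*`, the
#' point where the (monotone decreasing) food profile falls to the Monod
#' constant, `F(x*) = k`; downstream of `x*` food is scarce and division
#' slow.  At that point the steady state satisfies
#' `B(x*) = alpha * Fin * (1 - k/Fin)`.  `x*` is found by linear
#' interpolation between the bracketing cell centres, and
#' `NA = S * integral_0^x* B dx`.  When the food profile never crosses
#' `k` there is no distinguished boundary and the whole population is
#' active (`x* = L`, `NA = NT`): either food is plentiful everywhere, or
#' the profile is flat and food-poor so that every bacterium divides at
#' the same (slow) rate -- in both cases drift acts on the entire
#' population, which is the well-mixed limit.
#'
#' @param steady A converged `gut_steady`.
#' @param params,grid Parameters and grid (default from `steady`).
#' @return List with `NA_pop` (count), `x_star` (cm) and `B_at_x_star`
#'   (interpolated, bacteria/cm^3).
#' @export
active_population <- function(steady, params = steady$params,
                              grid = steady$grid) {
  stopifnot(inherits(steady, "gut_steady"))
  F <- steady$state$F
  B <- steady$state$B
  Fin <- food_inflow_conc(params)
  if (any(diff(F) > 1e-8 * Fin))
    stop("food profile is not monotone decreasing; inconsistent steady state",
         call. = FALSE)
  k <- params$k
  x <- grid$cell_centers
  if (all(F > k) || F[1] <= k) {
    # no interior crossing: the whole population is active
    return(list(NA_pop = total_population(steady, params), x_star = grid$L,
                B_at_x_star = B[grid$n_cells]))
  }
  i <- which(F <= k)[1]            # first cell at or below k
  # linear interpolation of F between centres i-1 and i
  x_star <- x[i - 1] + (F[i - 1] - k) / (F[i - 1] - F[i]) * grid$dx
  B_star <- stats::approx(x, B, xout = x_star)$y
  # piecewise-constant integral of B over [0, x_star]
  edges <- seq(0, grid$L, by = grid$dx)
  frac <- pmax(0, pmin(x_star, edges[-1]) - edges[-length(edges)])
  NA_pop <- params$S * sum(B * frac)
  list(NA_pop = NA_pop, x_star = x_star, B_at_x_star = B_star)
}

#' Total reproduction rate of the population
#'
#' `NR = S * integral(B rho dx)`: the number of division events per unit
#' time in the whole segment.  At steady state this balances the net food
#' conversion, `NR ~ alpha * v * (Fin - F(L))`, and in the strongly
#' spatial regime it is approximately `r * NA` (divisions happen at near
#' maximal rate inside the active zone).
#'
#' @param steady A `gut_steady` object.
#' @param params Parameters (defaults to those stored in `steady`).
#' @return Scalar rate (bacteria/h).
#' @export
reproductions_per_time <- function(steady, params = steady$params) {
  stopifnot(inherits(steady, "gut_steady"))
  params$S * sum(reproduction_density(steady, params)) * steady$grid$dx
}

#' Well-mixed fixation prediction from the active population
#'
#' The neutral fixation probability of `NM` mutants in an effective
#' well-mixed population of size `NA`: `NM / NA`.  With `NA = NT` this is
#' the classic well-mixed expectation.
#'
#' @param NM Introduced mutant count.
#' @param NA_pop Active population size (> 0).
#' @return Scalar probability.
#' @export
predicted_fixation <- function(NM, NA_pop) {
  if (!is.numeric(NA_pop) || NA_pop <= 0)
    stop("active population must be positive (washout?)", call. = FALSE)
  NM / NA_pop
}

#' Full mutant-fate report at one parameter set
#'
#' Convenience wrapper running the whole deterministic pipeline: steady
#' state (if not supplied), adjoint fixation curve, reproduction density,
#' overall fixation probability, population sizes and regime label.
#'
#' @param params A [gut_parameters()] object.
#' @param NM Introduced mutant count.
#' @param steady Optional precomputed `gut_steady`.
#' @param grid Optional grid (used when solving internally).
#' @param ... Passed to [solve_steady_state()].
#' @return Object of class `gut_fixation_report` with fields
#'   `ratio_curve`, `R_curve`, `overall_fixation`, `NT`, `NA_pop`,
#'   `x_star`, `NR`, `spatial_dependence`, `regime`, `params`, `grid`.
#' @export
fixation_report <- function(params, NM = 1, steady = NULL,
                            grid = build_grid(params), ...) {
  if (is.null(steady)) steady <- solve_steady_state(params, grid, ...)
  grid <- steady$grid
  if (steady$washout)
    stop("washout regime: no fixation report available", call. = FALSE)
  dep <- spatial_dependence(steady, params)
  # label from the realised solution: the analytic washout thresholds are
  # asymptotic limits and can misclassify near the critical lines
  regime_label <- if (dep > 0.9) "persistent_spatial" else "persistent_mixed"
  C <- fixation_curve_adjoint(steady, params, grid, NM = NM)
  R <- reproduction_density(steady, params)
  act <- active_population(steady, params, grid)
  out <- list(
    ratio_curve = C, R_curve = R,
    overall_fixation = overall_fixation_probability(C, R, grid),
    NT = total_population(steady, params),
    NA_pop = act$NA_pop, x_star = act$x_star,
    NR = reproductions_per_time(steady, params),
    spatial_dependence = dep, regime = regime_label,
    params = params, grid = grid, steady = steady, NM = NM)
  class(out) <- "gut_fixation_report"
  out
}

#' @export
print.gut_fixation_report <- function(x, ...) {
  cat("Mutant fate report\n")
  cat(sprintf("  regime: %s (spatial dependence %.3f)\n",
              x$regime, x$spatial_dependence))
  cat(sprintf("  NT = %.4g, NA = %.4g, x* = %.3g cm, NR = %.4g /h\n",
              x$NT, x$NA_pop, x$x_star, x$NR))
  cat(sprintf("  overall fixation probability (NM = %g): %.4g\n",
              x$NM, x$overall_fixation))
  cat(sprintf("  well-mixed expectation NM/NT = %.4g, active NM/NA = %.4g\n",
              x$NM / x$NT, predicted_fixation(x$NM, x$NA_pop)))
  invisible(x)
}

#' Sweep fixation probability against population size
#'
#' For each flow velocity (and optionally several diffusion
#' coefficients), holding the food inflow rate `vFin` constant, solves
#' the steady state and computes the overall fixation probability, total
#' and active population sizes and the spatial-dependence metric.
#' Washout points are flagged rather than dropped.
#'
#' @param params_base A [gut_parameters()] object; its `v` and `D` are
#'   overridden point by point.
#' @param D_values Diffusion coefficients to sweep (cm^2/h).
#' @param v_values Velocities to sweep (cm/h): either a numeric vector
#'   applied to every `D`, or a list of vectors, one per `D`.
#' @param NM Introduced mutant count.
#' @param n_cells Grid resolution.
#' @param ... Passed to [solve_steady_state()].
#' @return A data.frame with one row per (v, D) point: `v, D, Fin,
#'   washout, converged, spatial_dependence, NT, NA_pop, x_star,
#'   fixation, NR, well_mixed, active_pred`.
#' @export
sweep_fixation_vs_population <- function(params_base, D_values, v_values,
                                         NM = 1,
                                         n_cells = round(100 * params_base$L),
                                         ...) {
  stopifnot(inherits(params_base, "gut_params"))
  if (!is.list(v_values)) v_values <- rep(list(v_values), length(D_values))
  if (length(v_values) != length(D_values))
    stop("need one vector of velocities per diffusion coefficient",
         call. = FALSE)
  rows <- list()
  for (j in seq_along(D_values)) {
    for (v in v_values[[j]]) {
      p <- params_base
      p$v <- v
      p$D <- D_values[j]
      grid <- build_grid(p, n_cells)
      st <- solve_steady_state(p, grid, ...)
      row <- data.frame(v = v, D = D_values[j], Fin = food_inflow_conc(p),
                        washout = st$washout, converged = st$converged,
                        spatial_dependence = NA_real_, NT = NA_real_,
                        NA_pop = NA_real_, x_star = NA_real_,
                        fixation = NA_real_, NR = NA_real_,
                        well_mixed = NA_real_, active_pred = NA_real_)
      if (!st$washout) {
        rep_ <- fixation_report(p, NM = NM, steady = st)
        row$spatial_dependence <- rep_$spatial_dependence
        row$NT <- rep_$NT
        row$NA_pop <- rep_$NA_pop
        row$x_star <- rep_$x_star
        row$fixation <- rep_$overall_fixation
        row$NR <- rep_$NR
        row$well_mixed <- NM / rep_$NT
        row$active_pred <- predicted_fixation(NM, rep_$NA_pop)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
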