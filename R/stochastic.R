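#' Configuration for the stochastic compartment simulator
#'
#' The stochastic counterpart of the deterministic model tracks integer
#' bacteria on a chain of compartments.  Individuals divide with the
#' local Monod rate, hop right at rate `D/dx^2 + v/dx` and left at rate
#' `D/dx^2` (the biased-hopping master equation whose mean field is
#' exactly the upwind finite-volume scheme), and leave the system by
#' hopping out of the last compartment at the advective rate.  Food is by
#' default a deterministic per-compartment field whose consumption is
#' tied to realised divisions.
#'
#' Population scale is set by the reduced yield `alpha_scaled`: the three
#' dimensionless groups (Peclet, growth number, saturation) do not
#' involve `alpha`, so scaling it down shrinks the population (making
#' demographic noise testable at desk scale) while leaving the shape of
#' the stationary state, and hence the deterministic fixation curve up to
#' the `1/alpha` factor, unchanged.
#'
#' @param n_compartments Number of compartments (the stochastic grid).
#' @param alpha_scaled Reduced yield (bacteria cm^-3 / mM); the expected
#'   steady population should land between 1e2 and 1e6.
#' @param n_replicates Replicates per estimate (at least 100).
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @param t_max Horizon per replicate (h); `NULL` picks three flow
#'   transit times `3 L / v` at simulation time.
#' @param dt Time step (h); `NULL` picks `0.05 / max_event_rate`.
#' @param food_treatment `"deterministic_field"` (default) or
#'   `"frozen"` (food held fixed at its initial profile).
#' @return Object of class `gut_stoch_config`.
#' @export
stochastic_config <- function(n_compartments = 60, alpha_scaled = 150,
                              n_replicates = 1000, seed = 1,
                              t_max = NULL, dt = NULL,
                              food_treatment = c("deterministic_field",
                                                 "frozen")) {
  if (n_replicates < 100)
    stop("at least 100 replicates are required for a fixation estimate",
         call. = FALSE)
  structure(list(n_compartments = as.integer(n_compartments),
                 alpha_scaled = alpha_scaled,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), t_max = t_max, dt = dt,
                 food_treatment = match.arg(food_treatment)),
            class = "gut_stoch_config")
}

# reduced-alpha copy of a parameter set (dimensionless groups preserved)
scale_population <- function(params, alpha_scaled) {
  p <- params
  p$alpha <- alpha_scaled
  p
}

#' Stochastic replicate simulation of mutant fate
#'
#' Runs `n_replicates` independent realisations of the individual-based
#' compartment model from the (reduced-`alpha`) deterministic steady
#' state with `NM` mutant individuals added at the introduction position.
#' A replicate ends when the mutant lineage is extinct (all descendants
#' washed out) or at the horizon; surviving lineages have then settled on
#' their coexistence plateau (the horizon covers several flow transit
#' times).  The per-replicate mutant fraction `M/(M+B)` at termination is
#' an unbiased estimator of the deterministic fixation probability `C`,
#' because the expected mutant fraction is conserved by the (linear)
#' dilute dynamics; its replicate mean and standard error are returned.
#'
#' @param params A [gut_parameters()] object (full-scale `alpha` is
#'   replaced by `config$alpha_scaled`).
#' @param config A [stochastic_config()].
#' @param pulse A [mutant_pulse()]; `NM` is rounded to an integer number
#'   of individuals (>= 1).
#' @return Object of class `gut_stoch_result`: `estimate`, `se`,
#'   `established_fraction`, `outcomes` (data.frame with one row per
#'   replicate: `fixed`, `extinct`, `final_ratio`, `t_final`),
#'   `deterministic` (the matched deterministic steady state and C
#'   curve), `params_scaled`, `config`, `pulse`.
#' @export
run_stochastic <- function(params, config, pulse) {
  stopifnot(inherits(params, "gut_params"),
            inherits(config, "gut_stoch_config"),
            inherits(pulse, "gut_pulse"))
  p <- scale_population(params, config$alpha_scaled)
  grid <- build_grid(p, config$n_compartments)
  steady <- solve_steady_state(p, grid)
  if (steady$washout || !steady$converged)
    stop("parameters are not in a persistent regime at the scaled yield",
         call. = FALSE)
  NT <- total_population(steady, p)
  if (NT < 1e2 || NT > 1e6)
    stop(sprintf(
      "expected steady population %.3g outside the tractable window [1e2, 1e6]; adjust alpha_scaled",
      NT), call. = FALSE)
  NM <- max(1L, as.integer(round(pulse$NM)))
  icell <- findInterval(pulse$xM, seq(0, grid$L, by = grid$dx),
                        all.inside = TRUE)
  B0 <- as.integer(round(steady$state$B * p$S * grid$dx))
  M0 <- integer(grid$n_cells)
  M0[icell] <- NM
  v <- p$v; D <- p$D; dx <- grid$dx
  max_rate <- p$r + 2 * D / dx^2 + v / dx
  dt <- if (is.null(config$dt)) 0.05 / max_rate else config$dt
  t_max <- if (is.null(config$t_max)) 3 * grid$L / v else config$t_max

  C_det <- fixation_curve_adjoint(steady, p, grid, NM = NM)

  outcomes <- vector("list", config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    set.seed(config$seed + i)
    rep_i <- stochastic_replicate_cpp(
      B_init = B0, M_init = M0, F_init = steady$state$F,
      dx = dx, v = v, D = D, r = p$r, k = p$k, vFin = p$vFin,
      alpha = p$alpha, S = p$S, dt = dt, t_final = t_max,
      closed = FALSE,
      fixed_food = config$food_treatment == "frozen",
      pop_cap = 50)
    outcomes[[i]] <- data.frame(fixed = !rep_i$extinct,
                                extinct = rep_i$extinct,
                                final_ratio = rep_i$final_ratio,
                                t_final = rep_i$t_final)
  }
  outcomes <- do.call(rbind, outcomes)
  est <- mean(outcomes$final_ratio)
  se <- stats::sd(outcomes$final_ratio) / sqrt(nrow(outcomes))
  out <- list(estimate = est, se = se,
              established_fraction = mean(outcomes$fixed),
              outcomes = outcomes,
              deterministic = list(steady = steady, C_curve = C_det,
                                   C_at_xM = C_det[icell], cell = icell),
              params_scaled = p, config = config, pulse = pulse,
              dt = dt, t_max = t_max)
  class(out) <- "gut_stoch_result"
  out
}

#' @export
print.gut_stoch_result <- function(x, ...) {
  cat(sprintf(
    "Stochastic fixation estimate at xM = %g cm (%d replicates):\n",
    x$pulse$xM, nrow(x$outcomes)))
  cat(sprintf("  estimate %.4g +- %.2g (SE); established fraction %.3g\n",
              x$estimate, x$se, x$established_fraction))
  cat(sprintf("  deterministic C at xM: %.4g (z = %.2f)\n",
              x$deterministic$C_at_xM,
              (x$estimate - x$deterministic$C_at_xM) / x$se))
  invisible(x)
}

#' Compare stochastic fixation estimates with the deterministic curve
#'
#' Tabulates, per introduction position, the replicate estimate, its
#' standard error, the deterministic fixation probability at the matched
#' (scaled) parameters, and the z-score; a position passes when the two
#' agree within `z_max` standard errors.
#'
#' @param stoch_results List of `gut_stoch_result` objects (one per
#'   introduction position) from [run_stochastic()].
#' @param z_max Agreement threshold in standard errors.
#' @return data.frame with columns `xM, estimate, se, deterministic, z,
#'   pass`.
#' @export
compare_to_deterministic <- function(stoch_results, z_max = 3) {
  if (inherits(stoch_results, "gut_stoch_result"))
    stoch_results <- list(stoch_results)
  groups <- unique(lapply(stoch_results,
                          function(r) nondimensionalize(r$params_scaled)))
  if (length(groups) > 1)
    stop("stochastic results come from mismatched parameter sets",
         call. = FALSE)
  rows <- lapply(stoch_results, function(r) {
    z <- (r$estimate - r$deterministic$C_at_xM) / r$se
    data.frame(xM = r$pulse$xM, estimate = r$estimate, se = r$se,
               deterministic = r$deterministic$C_at_xM, z = z,
               pass = abs(z) < z_max)
  })
  do.call(rbind, rows)
}

#' Replicate-averaged occupancy of the stochastic model
#'
#' Runs short mutant-free replicates and averages the bacterial counts
#' per compartment at the horizon; used to check convergence of the
#' stochastic model to the deterministic mean field as the population
#' scale (`alpha`) grows.
#'
#' @param params A [gut_parameters()] object (its `alpha` is used as-is).
#' @param n_compartments Compartments.
#' @param n_replicates Replicates to average.
#' @param t_final Horizon (h).
#' @param seed RNG seed.
#' @param init Optional initial `gut_steady` (default: deterministic
#'   steady state at these parameters).
#' @return List with `mean_B` (average counts per compartment),
#'   `deterministic_B` (PDE counts per compartment at `t_final`), `grid`.
#' @export
stochastic_mean_occupancy <- function(params, n_compartments = 30,
                                      n_replicates = 100, t_final = 5,
                                      seed = 1, init = NULL) {
  grid <- build_grid(params, n_compartments)
  steady <- if (is.null(init)) solve_steady_state(params, grid) else init
  B0 <- as.integer(round(steady$state$B * params$S * grid$dx))
  dx <- grid$dx
  max_rate <- params$r + 2 * params$D / dx^2 + params$v / dx
  dt <- 0.05 / max_rate
  acc <- numeric(n_compartments)
  for (i in seq_len(n_replicates)) {
    set.seed(seed + i)
    rep_i <- stochastic_replicate_cpp(
      B_init = B0, M_init = integer(n_compartments),
      F_init = steady$state$F, dx = dx, v = params$v, D = params$D,
      r = params$r, k = params$k, vFin = params$vFin,
      alpha = params$alpha, S = params$S, dt = dt, t_final = t_final,
      closed = FALSE, fixed_food = FALSE, pop_cap = 50)
    acc <- acc + rep_i$B
  }
  det <- integrate_fields(steady$state, params, grid,
                          t_end = steady$state$t + t_final)
  list(mean_B = acc / n_replicates,
       deterministic_B = det$B * params$S * grid$dx, grid = grid)
}
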