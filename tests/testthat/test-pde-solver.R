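test_that("compiled and pure-R right-hand sides agree to round-off", {
  p <- gut_parameters()
  g <- build_grid(p, 80)
  set.seed(42)
  Fin <- food_inflow_conc(p)
  st <- field_state(F = Fin * runif(80), B = p$alpha * Fin * runif(80),
                    M = p$alpha * Fin * runif(80) * 1e-4)
  r_ref <- gut_rhs(st, p, g)
  y <- c(st$F, st$B, st$M)
  r_cpp <- gutfix:::gut_rhs_cpp(y, g$n_cells, g$dx, p$v, p$D, p$r, p$k,
                                p$vFin, p$alpha)
  scale <- max(abs(unlist(r_ref)))
  expect_lt(max(abs(c(r_ref$dF, r_ref$dB, r_ref$dM) - r_cpp)) / scale,
            1e-12)
})

test_that("spatial discretisation conserves the advective-diffusive flux budget", {
  # For any state, the sum of dF/dt over cells must equal (inflow flux -
  # outflow flux - consumption) / dx exactly: the scheme is conservative.
  p <- gut_parameters()
  g <- build_grid(p, 60)
  set.seed(7)
  Fin <- food_inflow_conc(p)
  st <- field_state(F = Fin * runif(60), B = p$alpha * Fin * runif(60))
  d <- gut_rhs(st, p, g)
  consumption <- p$r * st$F / (p$k + st$F) * st$B / p$alpha
  outflow <- p$v * st$F[60]
  expect_equal(sum(d$dF) * g$dx, p$vFin - outflow - sum(consumption) * g$dx,
               tolerance = 1e-12)
  # Bacteria: zero inflow, advective outflow, growth source.
  growth <- p$r * st$F / (p$k + st$F) * st$B
  expect_equal(sum(d$dB) * g$dx, -p$v * st$B[60] + sum(growth) * g$dx,
               tolerance = 1e-12)
})

test_that("the steady solver converges from independent initial seeds to the same state", {
  p <- gut_parameters()
  g <- build_grid(p, 200)
  s1 <- solve_steady_state(p, g, seed_frac = 1e-3)
  s2 <- solve_steady_state(p, g, seed_frac = 1e-1)
  expect_true(s1$converged)
  expect_true(s2$converged)
  expect_false(s1$washout)
  expect_lt(max(abs(s1$state$B - s2$state$B)) / max(s1$state$B), 1e-5)
  expect_lt(max(abs(s1$state$F - s2$state$F)) / food_inflow_conc(p), 1e-5)
})

test_that("steady profiles: food decreases downstream, bacteria peak behind the front", {
  st <- ref_steady(600)
  expect_true(st$converged)
  expect_true(all(diff(st$state$F) <= 1e-12))
  expect_gt(spatial_dependence(st), 0.9)  # strong-gradient reference regime
  expect_true(all(st$state$B >= 0))
  expect_gt(max(st$state$B), 0.5 * st$params$alpha *
              food_inflow_conc(st$params))
})

test_that("steady profiles converge at first order under grid refinement", {
  # Upwind advection is first-order accurate; the sup-norm error is
  # dominated by the steep bacterial front and must halve per refinement.
  p <- gut_parameters()
  c300 <- check_grid_convergence(p, n_cells = 300)
  c600 <- check_grid_convergence(p, n_cells = 600)
  for (fld in c("F", "B")) {
    ratio <- c600[[fld]] / c300[[fld]]
    expect_gt(ratio, 0.35)
    expect_lt(ratio, 0.75)
  }
  expect_lt(c600[["F"]], 0.03)
  expect_lt(c600[["B"]], 0.03)
})

test_that("washout thresholds reproduce the analytic critical lines", {
  p <- gut_parameters()
  th <- washout_thresholds(p)
  Fin <- food_inflow_conc(p)
  expect_equal(th$d_crit, p$v^2 * (p$k / Fin + 1) / (4 * p$r))
  expect_equal(th$v_crit, p$r * p$L / (p$k / Fin + 1))
})

test_that("a strongly advective regime washes out numerically and analytically", {
  p <- gut_parameters(v = 2.4)
  th <- washout_thresholds(p)
  expect_gt(p$v, th$v_crit)
  g <- build_grid(p, 150)
  st <- solve_steady_state(p, g, t_max = 2000)
  expect_true(st$washout)
})

test_that("regime classification labels flat and gradient profiles consistently", {
  flat <- gut_parameters(D = 20, v = 0.1)
  st_flat <- solve_steady_state(flat, build_grid(flat, 200))
  cls <- classify_regime(flat, steady = st_flat)
  expect_identical(cls$label, "persistent_mixed")
  expect_lt(cls$spatial_dependence, 0.05)
  grad <- spatial_params()
  st_grad <- spatial_steady(600)
  cls2 <- classify_regime(grad, steady = st_grad)
  expect_identical(cls2$label, "persistent_spatial")
  expect_gt(cls2$spatial_dependence, 0.9)
})

test_that("a growth-free pulse is advected at the flow speed", {
  p <- gut_parameters(); p$r <- 0
  g <- build_grid(p, 300)
  ic <- which.min(abs(g$cell_centers - 1.01))
  M <- rep(0, g$n_cells); M[ic] <- 100 / (p$S * g$dx)
  st <- field_state(F = rep(food_inflow_conc(p), g$n_cells),
                    B = rep(1, g$n_cells), M = M)
  p1 <- p; p1$D <- 1e-3
  times <- seq(0, 4, by = 1)
  sol <- integrate_fields(st, p1, g, times = times)
  cen <- vapply(sol, function(s) sum(g$cell_centers * s$M) / sum(s$M),
                numeric(1))
  slope <- stats::coef(stats::lm(cen ~ times))[[2]]
  expect_lt(abs(slope - p1$v) / p1$v, 0.01)
})
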