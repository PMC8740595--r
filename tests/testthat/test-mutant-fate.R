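test_that("mutant pulses are validated and introduced with an exact count", {
  expect_error(mutant_pulse("a"), "xM")
  expect_error(mutant_pulse(1, NM = -2), "NM")
  st <- ref_steady(600)
  p <- ref_params()
  g <- st$grid
  init <- introduce_mutant(st, mutant_pulse(xM = 1.505, NM = 1))
  expect_equal(p$S * sum(init$M) * g$dx, 1)
  expect_equal(init$B, st$state$B)
  expect_error(introduce_mutant(st, mutant_pulse(xM = -1)), "inside")
  expect_error(introduce_mutant(st, mutant_pulse(xM = 99)), "inside")
  # A pulse comparable to the local wild-type concentration is rejected:
  huge <- mutant_pulse(xM = 1.505, NM = 1e10)
  expect_error(introduce_mutant(st, huge), "dilute")
})

test_that("a neutral pulse relaxes to a position-independent M/B ratio", {
  st <- ref_steady(600)
  init <- introduce_mutant(st, mutant_pulse(xM = 2.005, NM = 1))
  C <- mutant_steady_ratio(init, ref_params(), st$grid)
  expect_gt(as.numeric(C), 0)
  expect_lt(attr(C, "cv"), 1e-3)
})

test_that("the adjoint zero mode matches direct integration at an interior position", {
  st <- ref_steady_tight(600)
  p <- ref_params()
  g <- st$grid
  Ccurve <- fixation_curve_adjoint(st, p, g, NM = 1)
  init <- introduce_mutant(st, mutant_pulse(xM = 1.505, NM = 1))
  Cdir <- as.numeric(mutant_steady_ratio(init, p, g))
  i <- which.min(abs(g$cell_centers - 1.505))
  expect_lt(abs(Ccurve[i] - Cdir) / Cdir, 0.02)
})

test_that("fixation decreases downstream and integrates to the overall probability", {
  st <- ref_steady(600)
  p <- ref_params()
  g <- st$grid
  C <- fixation_curve_adjoint(st, p, g)
  expect_true(all(C > 0))
  expect_true(all(diff(C) < 0))  # downstream introductions are worse off
  R <- reproduction_density(st, p)
  overall <- overall_fixation_probability(C, R, g)
  expect_gt(overall, min(C))
  expect_lt(overall, max(C))
  # overall = reproduction-weighted mean of C
  expect_equal(overall, sum(R * C) / sum(R), tolerance = 1e-12)
})

test_that("fixation from the adjoint is exactly linear in the introduced count", {
  st <- ref_steady(600)
  C1 <- fixation_curve_adjoint(st, NM = 1)
  C10 <- fixation_curve_adjoint(st, NM = 10)
  expect_equal(C10, 10 * C1, tolerance = 1e-12)
})

test_that("active population: food crosses the Monod constant at an interior point", {
  st <- spatial_steady(600)
  p <- spatial_params()
  ap <- active_population(st, p, st$grid)
  expect_gt(ap$x_star, 0)
  expect_lt(ap$x_star, p$L)
  expect_gt(ap$NA_pop, 0)
  expect_lt(ap$NA_pop, total_population(st, p))
  # B at the crossing matches the theoretical value alpha*Fin*(1 - k/Fin).
  Fin <- food_inflow_conc(p)
  B_star <- stats::approx(st$grid$cell_centers, st$state$B,
                          xout = ap$x_star)$y
  expect_lt(abs(B_star - p$alpha * Fin * (1 - p$k / Fin)) /
              (p$alpha * Fin * (1 - p$k / Fin)), 0.05)
})

test_that("flat profiles have no interior crossing and the whole population is active", {
  p <- gut_parameters(D = 20, v = 0.1)
  st <- solve_steady_state(p, build_grid(p, 200))
  ap <- active_population(st, p, st$grid)
  expect_equal(ap$x_star, p$L)
  expect_equal(ap$NA_pop, total_population(st, p))
})

test_that("reproduction and outflow balance at steady state", {
  st <- ref_steady(600)
  p <- ref_params()
  NR <- reproductions_per_time(st, p)
  # All reproduction is balanced by the advective outflow of bacteria:
  outflow <- p$S * p$v * (p$alpha * (food_inflow_conc(p) - st$state$F[600]) )
  expect_lt(abs(NR - outflow) / NR, 1e-3)
})

test_that("the fixation report assembles consistent pieces", {
  st <- ref_steady(600)
  p <- ref_params()
  rep_ <- fixation_report(p, NM = 1, steady = st)
  expect_s3_class(rep_, "gut_fixation_report")
  expect_equal(rep_$NT, total_population(st, p))
  expect_equal(rep_$overall_fixation,
               overall_fixation_probability(rep_$ratio_curve, rep_$R_curve,
                                            st$grid))
  expect_gt(rep_$NA_pop, 0)
  expect_identical(rep_$regime, "persistent_spatial")
  # washed-out parameters are refused
  pw <- gut_parameters(v = 2.4)
  stw <- solve_steady_state(pw, build_grid(pw, 120), t_max = 2000)
  expect_error(fixation_report(pw, steady = stw), "washout")
})

test_that("predicted fixation is the reciprocal active population per mutant", {
  expect_equal(predicted_fixation(1, 100), 0.01)
  expect_equal(predicted_fixation(5, 100), 0.05)
  expect_error(predicted_fixation(1, 0), "positive")
})
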