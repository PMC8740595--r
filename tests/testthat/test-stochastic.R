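test_that("stochastic configuration is validated", {
  expect_s3_class(stochastic_config(), "gut_stoch_config")
  expect_error(stochastic_config(n_replicates = 10), "replicates")
})

test_that("replicates are reproducible by seed and differ across seeds", {
  p <- spatial_params()
  cfg <- stochastic_config(n_compartments = 30, alpha_scaled = 60,
                           n_replicates = 100, seed = 3, t_max = 20)
  pulse <- mutant_pulse(xM = 0.55, NM = 2)
  r1 <- run_stochastic(p, cfg, pulse)
  r2 <- run_stochastic(p, cfg, pulse)
  expect_identical(r1$outcomes, r2$outcomes)
  cfg2 <- stochastic_config(n_compartments = 30, alpha_scaled = 60,
                            n_replicates = 100, seed = 4, t_max = 20)
  r3 <- run_stochastic(p, cfg2, pulse)
  expect_false(identical(r1$outcomes$final_ratio, r3$outcomes$final_ratio))
})

test_that("the result object carries the matched deterministic fixation value", {
  p <- spatial_params()
  cfg <- stochastic_config(n_compartments = 30, alpha_scaled = 60,
                           n_replicates = 100, seed = 5, t_max = 20)
  res <- run_stochastic(p, cfg, mutant_pulse(xM = 0.55, NM = 2))
  expect_s3_class(res, "gut_stoch_result")
  expect_equal(nrow(res$outcomes), 100)
  expect_gte(res$estimate, 0)
  expect_gt(res$deterministic$C_at_xM, 0)
  expect_equal(res$params_scaled$alpha, 60)
  tab <- compare_to_deterministic(res, z_max = 3)
  expect_identical(names(tab),
                   c("xM", "estimate", "se", "deterministic", "z", "pass"))
  expect_type(tab$pass, "logical")
})

test_that("population scales outside the tractable window are refused", {
  p <- spatial_params()
  cfg <- stochastic_config(alpha_scaled = 6.13e8, n_replicates = 100)
  expect_error(run_stochastic(p, cfg, mutant_pulse(0.55, 2)), "window")
})

test_that("washed-out parameters are refused by the stochastic driver", {
  p <- gut_parameters(v = 2.4)
  cfg <- stochastic_config(n_compartments = 30, alpha_scaled = 60,
                           n_replicates = 100)
  expect_error(run_stochastic(p, cfg, mutant_pulse(0.55, 2)), "persistent")
})

test_that("in a closed system the expected mutant fraction is conserved", {
  # Growing Yule-type population with no spatial escape: the mutant share
  # is a martingale, so the replicate-mean final fraction must equal the
  # initial fraction M0/(B0+M0).
  n <- 5
  B0 <- rep(10L, n)
  M0 <- c(0L, 0L, 5L, 0L, 0L)
  F0 <- rep(2, n)
  frac0 <- sum(M0) / (sum(B0) + sum(M0))
  reps <- 400
  ratios <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(1000 + i)
    out <- gutfix:::stochastic_replicate_cpp(
      B_init = B0, M_init = M0, F_init = F0, dx = 1.2, v = 0.5, D = 0.2,
      r = 0.42, k = 0.1, vFin = 1, alpha = 100, S = 1, dt = 0.5,
      t_final = 5, closed = TRUE, fixed_food = TRUE, pop_cap = 100)
    ratios[i] <- out$final_ratio
  }
  se <- stats::sd(ratios) / sqrt(reps)
  expect_gt(se, 0)
  expect_lt(abs(mean(ratios) - frac0), 4 * se)
})

test_that("the stochastic mean field converges to the PDE as the yield grows", {
  p_small <- gut_parameters(v = 0.5, D = 0.2, alpha = 5)
  p_large <- gut_parameters(v = 0.5, D = 0.2, alpha = 100)
  occ_small <- stochastic_mean_occupancy(p_small, n_compartments = 20,
                                         n_replicates = 60, t_final = 3,
                                         seed = 2)
  occ_large <- stochastic_mean_occupancy(p_large, n_compartments = 20,
                                         n_replicates = 60, t_final = 3,
                                         seed = 2)
  err <- function(occ) {
    sqrt(sum((occ$mean_B - occ$deterministic_B)^2)) /
      sqrt(sum(occ$deterministic_B^2))
  }
  expect_lt(err(occ_large), err(occ_small))
  expect_lt(err(occ_large), 0.05)
})

test_that("oversized time steps are rejected by the kernel", {
  expect_error(
    gutfix:::stochastic_replicate_cpp(
      B_init = rep(1L, 5), M_init = rep(0L, 5), F_init = rep(1, 5),
      dx = 0.1, v = 0.5, D = 0.2, r = 0.42, k = 0.1, vFin = 1,
      alpha = 100, S = 1, dt = 10, t_final = 20, closed = FALSE,
      fixed_food = FALSE, pop_cap = 50),
    "dt")
})
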