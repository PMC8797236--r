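## Engine-level behavior: determinism, density-mass bookkeeping, rest
## stability, noise statistics, single-population runner.

short_cfg <- function(duration_s = 2, ...) {
  ictal_config("control", duration_s = duration_s, nx = 16,
               tstar_max_ms = 30, trace_stride_ms = 10,
               field_stride_ms = 200, ...)
}

test_that("identical seeds give identical recordings, different seeds differ", {
  cfg <- short_cfg()
  a <- run_scenario(cfg, seed = 11)
  b <- run_scenario(cfg, seed = 11)
  expect_identical(a$traces, b$traces)
  expect_identical(a$fields$K_o, b$fields$K_o)
  c <- run_scenario(cfg, seed = 12)
  expect_false(identical(a$traces$U_I_S1, c$traces$U_I_S1))
})

test_that("density mass is conserved to machine precision over thousands of
           steps", {
  rec <- run_scenario(short_cfg(duration_s = 3), seed = 2)
  expect_lt(rec$diagnostics$mass_dev_max, 1e-9)
})

test_that("with noise off the coupled system stays at rest", {
  p <- ictal_params(I_noise_pA = 0)
  cfg <- ictal_config("control", duration_s = 10, nx = 16,
                      tstar_max_ms = 30, params = p)
  rec <- run_scenario(cfg, seed = 1)
  expect_lt(max(rec$traces$nu_E_S1), 1e-3)   # Hz
  expect_lt(max(rec$traces$nu_I_S1), 1e-3)
  ## membrane potentials hold the nominal resting level
  expect_lt(max(abs(rec$traces$U_E_S1 + 70)), 1.5)
  expect_lt(max(abs(rec$traces$U_I_S1 + 70)), 1.5)
  ## anchored ionic baseline: potassium stays near the bath level
  expect_lt(max(abs(rec$traces$K_o_S1 - 3.5)), 0.5)
})

test_that("OU noise reaches its stationary variance and is reproducible", {
  x <- cpp_ou_trace(1e6, 0.5, 4, 25, 123, 0)
  expect_equal(sd(x), 25, tolerance = 0.02)
  expect_lt(abs(mean(x)), 0.25)
  ## same seed/stream: bit-identical; different stream: different
  expect_identical(x[1:100], cpp_ou_trace(100, 0.5, 4, 25, 123, 0))
  expect_false(identical(x[1:100], cpp_ou_trace(100, 0.5, 4, 25, 123, 1)))
  ## R-level exact update gives the same stationary law
  set.seed(1)
  y <- Reduce(function(z, i) ou_noise_step(z, 0.5, 4, 25, rnorm(1)),
              1:20000, accumulate = TRUE)
  expect_equal(sd(y), 25, tolerance = 0.05)
})

test_that("single-population runner is quiescent below threshold and
           bursts then blocks above it", {
  sub <- cbrd_population_rate(duration_ms = 400, dt = 0.1, I_step = 0,
                              pop = "E")
  expect_lt(max(sub$rate_Hz), 0.5)
  sup <- cbrd_population_rate(duration_ms = 600, dt = 0.1, I_step = 1.5,
                              t_on = 100, pop = "E")
  ## silent before onset, a strong population discharge after it
  expect_lt(max(sup$rate_Hz[sup$t_ms < 100]), 0.5)
  expect_gt(max(sup$rate_Hz[sup$t_ms >= 100]), 20)
  ## sustained depolarization engages the dynamic-threshold block: the
  ## rate collapses again once the threshold has tracked the voltage
  expect_lt(mean(sup$rate_Hz[sup$t_ms > 400]), 2)
  ## density mass conserved throughout
  expect_lt(max(abs(attr(sup, "mass") - 1)), 1e-9)
})

test_that("holding-current observable separates GABA and glutamate polarity", {
  ## pure GABA event with reversal below -27 mV: positive (outward)
  expect_gt(holding_current(0, 0, 0.3, V_GABA = -60), 0)
  ## pure glutamatergic event: negative
  expect_lt(holding_current(0.2, 0.1, 0, V_GABA = -60), 0)
  expect_equal(holding_current(0, 0, 0, V_GABA = -60), 0)
})
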