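## Synaptic kinetics: Mg block, second-order kernel, peak normalization,
## Tsodyks-Markram depression.

test_that("NMDA magnesium block has the printed form and limits", {
  expect_equal(nmda_block(-80, Mg = 0), 1)
  expect_equal(nmda_block(200, Mg = 1), 1, tolerance = 1e-4)
  expect_equal(nmda_block(0, Mg = 0.25), 1 / (1 + 0.25 / 3.57),
               tolerance = 1e-12)
  expect_error(nmda_block(0, Mg = -1), "nonnegative")
})

test_that("synapse timescale has the equal-constant limit tau_r * e", {
  expect_equal(synapse_timescale(5, 5), 5 * exp(1))
  ## tau_d -> tau_r limit of the general formula approaches tau_r * e
  lims <- sapply(c(1e-3, 1e-4, 1e-5), function(eps)
    synapse_timescale(5, 5 * (1 + eps)))
  expect_true(all(abs(lims - 5 * exp(1)) < c(1e-2, 1e-3, 1e-4)))
})

test_that("impulse peak conductance is invariant to the time-constant pair", {
  ## drive each kernel with the same short rate pulse and compare peaks
  peak_for <- function(tau_r, tau_d) {
    m <- 0; dm <- 0; dt <- 0.02
    peak <- 0
    for (i in 1:20000) {
      phi <- if (i * dt <= 1) 0.05 else 0   # 1-ms pulse
      s <- advance_synapse(m, dm, phi, tau_r, tau_d, dt)
      m <- s$m; dm <- s$dm
      peak <- max(peak, m)
    }
    peak
  }
  pairs <- list(c(1.7, 8.3), c(0.5, 20), c(6.7, 100), c(3, 3.0001))
  peaks <- vapply(pairs, function(p) peak_for(p[1], p[2]), numeric(1))
  expect_lt(diff(range(peaks)) / mean(peaks), 0.03)
})

test_that("synapse kernel is quiescent without input and nonnegative", {
  s <- advance_synapse(0, 0, 0, 1.7, 8.3, 0.5)
  expect_equal(s$m, 0)
  expect_equal(s$dm, 0)
})

test_that("depression recovers, saturates and matches its fixed point", {
  ## no input at full resource: fixed point
  expect_equal(advance_depression(1, 0, 0.2, 500, 50), 1)
  ## recovery toward 1 with tau = 500 ms as printed
  x <- advance_depression(0.4, 0, 0.2, 500, 500)
  expect_equal(x, 1 + (0.4 - 1) * exp(-1), tolerance = 1e-12)
  ## constant rate: analytic fixed point 1/(1 + u tau phi)
  phi <- 0.02; u <- 0.2; tau <- 500
  x <- 1
  for (i in 1:4000) x <- advance_depression(x, phi, u, tau, 5)
  expect_equal(x, 1 / (1 + u * tau * phi), tolerance = 1e-6)
  expect_true(x >= 0 && x <= 1)
})

test_that("conductances assemble with depression and Mg block", {
  g <- synaptic_conductances(m_AMPA = 0.5, m_NMDA = 0.4, m_GABA = 0.3,
                             x_glu = 0, x_GABA = 1, V_post = -60,
                             g_AMPA_max = 0.3, g_NMDA_max = 0.6,
                             g_GABA_max = 1)
  expect_equal(g$g_AMPA, 0)          # full glutamatergic depression
  expect_equal(g$g_NMDA, 0)
  expect_equal(g$g_GABA, 0.3)
  g2 <- synaptic_conductances(0, 0, 0, 1, 1, -60, 0.3, 0.6, 1)
  expect_equal(unlist(g2), c(g_AMPA = 0, g_NMDA = 0, g_GABA = 0))
  ## printed GABA ceilings appear as configured maxima
  g3 <- synaptic_conductances(1, 0, 1, 1, 1, -60, 0.3, 0.6,
                              g_GABA_max = pp$g_GABA_E)
  expect_equal(g3$g_GABA, 1)
})
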