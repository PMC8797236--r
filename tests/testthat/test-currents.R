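## Gating kinetics, removable singularities, voltage update, representative
## neuron.

test_that("gating rates are finite and continuous across singular voltages", {
  U <- seq(-120, 60, by = 0.01)
  for (g in c("DR", "M", "m", "h")) {
    r <- gating_rates(g, U)
    expect_true(all(is.finite(r$alpha)), info = g)
    expect_true(all(is.finite(r$beta)), info = g)
    expect_true(all(r$alpha >= 0), info = g)
    expect_true(all(r$beta >= 0), info = g)
    ## no jumps: neighbouring samples differ smoothly
    expect_lt(max(abs(diff(r$alpha))), 0.05)
  }
  ## analytic limit at the DR singularity matches a series-expansion value
  lim <- gating_rates("DR", -48)$alpha
  eps <- 1e-7
  series <- -0.032 * ((-eps) / (exp(eps / 5) - 1) +
                        (eps) / (exp(-eps / 5) - 1)) / 2
  expect_equal(lim, series, tolerance = 1e-8)
  ## Na activation/inactivation singular points
  expect_true(is.finite(gating_rates("m", -50)$alpha))
  expect_true(is.finite(gating_rates("m", -23)$beta))
})

test_that("voltage-gated currents vanish without driving force or gating", {
  cur <- voltage_gated_currents(U = -90, n_DR = 0.5, n_M = 0.5, n_KCa = 0.5,
                                V_K = -90)
  expect_equal(unlist(cur), c(I_DR = 0, I_M = 0, I_KCa = 0))
  cur2 <- voltage_gated_currents(U = -50, n_DR = 0, n_M = 0.2, n_KCa = 0.2,
                                 V_K = -90)
  expect_equal(cur2$I_DR, 0)
})

test_that("gating update stays in [0,1] and matches the analytic solution", {
  ## fixed point is invariant
  r <- gating_rates("DR", -55)
  ninf <- r$alpha / (r$alpha + r$beta)
  expect_equal(advance_gating(ninf, r$alpha, r$beta, 5), ninf)
  ## alpha = 0: exponential decay at rate beta
  expect_equal(advance_gating(0.8, 0, 0.1, 7), 0.8 * exp(-0.7),
               tolerance = 1e-12)
  ## constant-U trajectory matches closed form over many steps
  n <- 0.1; dt <- 0.2
  for (i in 1:50) n <- advance_gating(n, r$alpha, r$beta, dt)
  closed <- ninf + (0.1 - ninf) * exp(-(r$alpha + r$beta) * 50 * dt)
  expect_equal(n, closed, tolerance = 1e-10)
  expect_true(n >= 0 && n <= 1)
})

test_that("population voltage step matches a high-accuracy ODE solution", {
  g <- list(g_K_leak = 0.02, g_Cl_leak = 0.02, g_Na_leak = 0.007,
            g_shunt = 0, g_DR_eff = 0.001, g_M_eff = 0.0005,
            g_KCa_eff = 0, g_AMPA = 0.05, g_NMDA_eff = 0.02, g_GABA = 0.1)
  E <- list(V_K = -95, V_Cl = -85, V_Na = 54, V_shunt = -70,
            V_GABA = -60, V_AMPA = 0, V_NMDA = 0)
  U0 <- -70; dt <- 0.5; I_ext <- 0.3
  out <- advance_population_voltage(U0, g, E, I_ext, dt)
  rhs <- function(t, y, p) {
    dU <- g$g_K_leak * (E$V_K - y) + g$g_Cl_leak * (E$V_Cl - y) +
      g$g_Na_leak * (E$V_Na - y) + g$g_DR_eff * (E$V_K - y) +
      g$g_M_eff * (E$V_K - y) + g$g_AMPA * (E$V_AMPA - y) +
      g$g_NMDA_eff * (E$V_NMDA - y) + g$g_GABA * (E$V_GABA - y) + I_ext
    list(dU)
  }
  ref <- deSolve::ode(y = U0, times = c(0, dt), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-12)
  expect_equal(out$U, unname(ref[2, 2]), tolerance = 1e-10)
  ## rest fixed point: only leak, U at the leak reversal
  g0 <- modifyList(g, list(g_DR_eff = 0, g_M_eff = 0, g_AMPA = 0,
                           g_NMDA_eff = 0, g_GABA = 0))
  VL <- (0.02 * -95 + 0.02 * -85 + 0.007 * 54) / 0.047
  expect_equal(advance_population_voltage(VL, g0, E, 0, 10)$U, VL,
               tolerance = 1e-12)
})

test_that("representative neuron rests quietly and spikes to strong input", {
  g0 <- list(g_K_leak = 0.02, g_Cl_leak = 0.02, g_Na_leak = 0.007,
             g_shunt = 0, g_AMPA = 0, g_NMDA_eff = 0, g_GABA = 0)
  E <- list(V_K = -95.9, V_Cl = -86.7, V_Na = 54.1, V_shunt = -70,
            V_GABA = -72, V_AMPA = 0, V_NMDA = 0)
  r <- gating_rates("m", -70); rh <- gating_rates("h", -70)
  rd <- gating_rates("DR", -70); rm <- gating_rates("M", -70)
  st <- list(V = -70, m = r$alpha / (r$alpha + r$beta),
             h = rh$alpha / (rh$alpha + rh$beta),
             n_DR = rd$alpha / (rd$alpha + rd$beta),
             n_M = rm$alpha / (rm$alpha + rm$beta), n_KCa = 0)
  ## 1 s at rest: no spikes
  vmax <- -100
  s <- st
  for (i in 1:200) {
    s <- representative_neuron_step(s, g0, E, dt = 5, params = pp)
    vmax <- max(vmax, s$V)
  }
  expect_lt(vmax, -50)
  ## strong step current: V crosses 0 mV (a genuine Na spike)
  s <- st; vmax <- -100
  for (i in 1:100) {
    s <- representative_neuron_step(s, g0, E, I_ext = 20, dt = 1,
                                    params = pp)
    vmax <- max(vmax, s$V)
  }
  expect_gt(vmax, 0)
})
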