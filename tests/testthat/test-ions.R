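## Ionic dynamics: Nernst reversals, transporters, pump, calcium, glia,
## volume.

test_that("Nernst potentials have the printed forms and invariances", {
  r <- nernst_potentials(129, 3.5, 5, 130, 17, 130)
  expect_equal(r$V_K, 26.6 * log(3.5 / 129), tolerance = 1e-12)
  expect_equal(r$V_Cl, 26.6 * log(5 / 130), tolerance = 1e-12)
  expect_equal(r$V_GABA, 26.6 * log((4 * 5 + 16) / (4 * 130 + 24)),
               tolerance = 1e-12)
  ## equal concentrations: zero potential
  r0 <- nernst_potentials(10, 10, 10, 10, 10, 10)
  expect_equal(unlist(r0)[1:3], c(V_K = 0, V_Cl = 0, V_Na = 0))
  ## chloride ratio invariance
  r2 <- nernst_potentials(129, 3.5, 10, 260, 17, 130)
  expect_equal(r2$V_Cl, r$V_Cl)
  expect_error(nernst_potentials(0, 3.5, 5, 130, 17, 130), "positive")
})

test_that("GABA reversal sits above the chloride reversal with printed HCO3", {
  for (cl_i in c(5, 9, 15, 25)) {
    r <- nernst_potentials(129, 3.5, cl_i, 130, 17, 130)
    expect_gt(r$V_GABA, r$V_Cl)
  }
})

test_that("transporter zero-crossing identities hold", {
  ## V_K = V_Cl: KCC2 flux vanishes (both forms)
  for (f in c("literal", "saturating")) {
    tc <- transporter_currents(-80, -80, 50, 3.5, 17, kcc2_form = f)
    expect_equal(tc$I_KCC2, 0)
  }
  ## V_Na + V_K = 2 V_Cl: NKCC1 flux vanishes
  tc <- transporter_currents(-90, -20, 50, 3.5, 17)
  expect_equal(tc$I_NKCC1, 0)
  ## simple pump at both sigmoid midpoints: I_max / 4
  tc2 <- transporter_currents(-90, -80, 50, K_o = 3.5, Na_i = 25,
                              I_pump_max = 0.8)
  expect_equal(tc2$I_pump_sigmoid, 0.8 / 4, tolerance = 1e-12)
})

test_that("kinetic pump is monotone in its substrates and matches a second
           independent transcription at rest", {
  ## monotone increasing in intracellular Na over the physiological range
  na <- seq(5, 40, by = 1)
  ip <- sapply(na, function(z) pump_current_kinetic(-70, 129, 3.5, z, 130))
  expect_true(all(diff(ip) > 0))
  ## monotone increasing in extracellular K over 1..15 mM
  ko <- seq(1, 15, by = 0.5)
  ip2 <- sapply(ko, function(z) pump_current_kinetic(-70, 129, z, 17, 130))
  expect_true(all(diff(ip2) > 0))
  ## independent symbolic-style transcription of the cycle at rest
  U <- -0.070
  Nai <- 17 / (2.49 * exp(-0.386 * U)); Nae <- 130 / (15.5 * exp(12.1 * U))
  Ki <- 129 / 0.5; Ke <- 3.5 / 0.213; Hp <- 1e-4; MgATP <- 3.904
  Pi <- 4.2 / (1 + 129 / 292 + Hp / 6.77 + 17 / 224)
  di <- (1 + Nai)^3 + (1 + Ki)^2 - 1
  de <- (1 + Nae)^3 + (1 + Ke)^2 - 1
  ap <- c(1050 * Nai^3 / di, 481, 2000 * Ke^2 / de, 320 * MgATP / (1 + MgATP))
  am <- c(8.605, 40 * Nae^3 / de, 79300 * Pi * Hp / (1 + MgATP),
          40 * Ki^2 / di)
  S <- ap[1]*ap[2]*ap[3] + ap[1]*ap[2]*ap[4] + ap[3]*ap[2]*ap[4] +
    ap[2]*ap[3]*ap[4] + am[1]*am[3]*am[4] + am[1]*am[2]*am[4] +
    am[2]*am[3]*am[4] + am[1]*am[2]*am[3] + ap[4]*am[2]*am[1] +
    ap[4]*am[2]*ap[1] + am[4]*ap[2]*ap[3] + am[4]*ap[2]*am[3] +
    ap[1]*ap[2]*am[3] + ap[1]*am[2]*am[3] + am[1]*am[4]*ap[3] +
    am[1]*ap[3]*ap[4]
  ref <- 0.8 * (prod(ap) - prod(am)) / (16.8 * S)
  expect_equal(pump_current_kinetic(-70, 129, 3.5, 17, 130), ref,
               tolerance = 1e-12)
})

test_that("calcium relaxes with tau_Ca and reaches its analytic fixed point", {
  ## no NMDA drive: exponential decay with tau = 200 ms as printed
  ca <- advance_calcium(0.4, g_NMDA = 0, U_E = -60, dt = 200, params = pp)
  expect_equal(ca, 0.4 * exp(-1), tolerance = 1e-12)
  ## U at the calcium reversal: pure decay
  ca2 <- advance_calcium(0.4, g_NMDA = 0.5, U_E = pp$V_Ca, dt = 200,
                         params = pp)
  expect_equal(ca2, 0.4 * exp(-1), tolerance = 1e-12)
  ## constant drive: fixed point tau_Ca * chi * g * (V_Ca - U)
  ca3 <- 0
  for (i in 1:300) ca3 <- advance_calcium(ca3, 0.05, -60, 10, pp)
  expect_equal(ca3, pp$tau_Ca * pp$chi_Ca * 0.05 * (pp$V_Ca + 60),
               tolerance = 1e-4)
  expect_gte(ca3, 0)
})

test_that("glial buffer follows the printed kinetics and is inert when off", {
  off <- glial_buffer_step(100, 20, 1, pp, enabled = FALSE)
  expect_equal(off$G, 0)
  expect_equal(off$B, 100)
  ## low K: k2 ~ 0, B relaxes toward B_max, uptake from the ECS (G < 0)
  lo <- glial_buffer_step(100, 3.5, 1, pp, enabled = TRUE)
  k2 <- pp$k1_glia / (1 + exp(-(3.5 - 15) / 1.15))
  dB <- pp$k1_glia * (pp$B_max - 100) - k2 * 100
  expect_equal(lo$B, 100 + dB, tolerance = 1e-12)
  expect_equal(lo$G, -dB, tolerance = 1e-12)
  expect_lt(lo$G, 0)
  ## saturation: at B = B_max with k2 -> 0, dB/dt <= 0
  sat <- glial_buffer_step(pp$B_max, 1, 1, pp, enabled = TRUE)
  expect_lte(sat$B, pp$B_max + 1e-9)
})

test_that("volume relaxes to the printed equilibrium and pins when fixed", {
  ## zero imbalance: rest fixed point 1
  v <- 1.4
  for (i in 1:30) v <- advance_volume(v, 0, 100, pp)
  expect_equal(v, 1, tolerance = 1e-4)
  ## constant imbalance: analytic fixed point
  dpi <- -10
  vinf <- 1 + pp$v_gain * pp$beta0_v * (exp(dpi / pp$pi_scale) - 1)
  v <- 1
  for (i in 1:50) v <- advance_volume(v, dpi, 100, pp)
  expect_equal(v, vinf, tolerance = 1e-4)
  expect_lt(vinf, 1)  # osmolyte gain inside cells shrinks the ECS
  ## fixed-volume mode
  expect_identical(advance_volume(0.7, -30, 10, pp, dynamic = FALSE), 1)
})

test_that("osmolarity imbalance is zero at baseline and tracks exchange", {
  intra0 <- list(K_i_E = 129, Cl_i_E = 5, Na_i_E = 17,
                 K_i_I = 129, Cl_i_I = 9, Na_i_I = 17)
  extra0 <- list(K_o = 3.5, Cl_o = 130, Na_o = 130)
  expect_equal(osmolarity_imbalance(intra0, extra0, intra0, extra0), 0)
  ## intracellular gain with matched extracellular loss: negative imbalance
  intra <- modifyList(intra0, list(Na_i_E = 27))
  extra <- modifyList(extra0, list(Na_o = 130 - 10 * 0.75 * 10))
  dpi <- osmolarity_imbalance(intra, extra, intra0, extra0)
  expect_equal(dpi, -75 - 7.5)
})

test_that("intra/extracellular balance equations preserve the printed
           bookkeeping structure", {
  I0 <- list(I_K_leak = 0, I_K_active = 0, I_K_glu = 0, I_pump = 0,
             I_KCC2 = 0, I_NKCC1 = 0, I_Cl_leak = 0, I_GABA = 0,
             I_Na_leak = 0, I_Na_glu = 0, I_NCX = 0)
  z <- intracellular_rates(I0, nu = 0, params = pp)
  expect_equal(unlist(z), c(dK_i = 0, dCl_i = 0, dNa_i = 0))
  ## per-spike sodium load alone: linear growth at gamma * 1000 * q_Na * nu
  z2 <- intracellular_rates(I0, nu = 0.01, params = pp)
  expect_equal(z2$dNa_i, pp$gamma_ion * 1000 * pp$q_Na * 0.01)
  ## pump stoichiometry: 2 K in / 3 Na out
  Ip <- modifyList(I0, list(I_pump = 0.3))
  z3 <- intracellular_rates(Ip, 0, pp)
  expect_equal(z3$dK_i / z3$dNa_i, -2 / 3, tolerance = 1e-12)
  ## ECS side mirrors the intracellular change scaled by -beta (closure)
  ex <- extracellular_rates(z3, z3, K_o = pp$K_bath, G = 0, lap_K = 0,
                            params = pp)
  expect_equal(ex$dvK_o, -pp$beta_vol * z3$dK_i)
  expect_equal(ex$dvNa_o, -pp$beta_vol * z3$dNa_i)
})
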