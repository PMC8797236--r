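## CBRD core: hazard function, density transport, firing-rate boundary,
## spike resets, dynamic threshold.

test_that("hazard vanishes far below threshold and clamps drift term", {
  gL <- 0.047
  ## T >> 1: deep subthreshold, no drift
  H <- hazard_rate(U = -120, g_tot = gL, dT_dt = 0, g_syn = 0, g_L = gL,
                   V_th = -50)
  expect_lt(H, 1e-10)
  ## nonnegative drift never contributes to B
  H0 <- hazard_rate(U = -60, g_tot = gL, dT_dt = 0, g_syn = 0, g_L = gL,
                    V_th = -50)
  Hpos <- hazard_rate(U = -60, g_tot = gL, dT_dt = 0.5, g_syn = 0, g_L = gL,
                      V_th = -50)
  expect_identical(Hpos, H0)
  ## negative drift adds a strictly positive flux term
  Hneg <- hazard_rate(U = -60, g_tot = gL, dT_dt = -0.5, g_syn = 0,
                      g_L = gL, V_th = -50)
  expect_gt(Hneg, H0)
})

test_that("hazard noise term matches a direct evaluation of its printed form", {
  gL <- 0.047
  tau_Noise <- 4
  for (gtot in c(gL, 2 * gL, 10 * gL)) {
    tau_m <- 1 / gtot
    ## choose U so that T lands at several values incl. 0
    for (Ttarget in c(0, 0.8, 2.5)) {
      sigma_V <- 3
      U <- -50 - Ttarget * sqrt(2) * sigma_V
      H <- hazard_rate(U = U, g_tot = gtot, dT_dt = 0, g_syn = 0, g_L = gL,
                       V_th = -50, sigma_V0 = sigma_V, tau_Noise = tau_Noise)
      expect_equal(H, hazard_A_direct(Ttarget, tau_m, tau_Noise),
                   tolerance = 1e-10)
    }
  }
})

test_that("hazard input validation rejects invalid states", {
  expect_error(hazard_rate(U = NaN, g_tot = 0.05, g_L = 0.05, V_th = -50),
               "non-finite")
  expect_error(hazard_rate(U = -60, g_tot = 0, g_L = 0.05, V_th = -50),
               "positive")
})

test_that("density transport conserves mass and removes the hazard sink", {
  n <- 50; dt <- 0.5
  rho <- rep(1 / (n * dt), n)
  ## H = 0: pure shift, mass unchanged to machine precision
  out <- advance_density(rho, rep(0, n), dt)
  expect_equal(sum(out$rho) * dt, 1, tolerance = 1e-14)
  expect_equal(out$removed_mass, 0)
  ## zero density stays zero
  out0 <- advance_density(rep(0, n), rep(0.3, n), dt)
  expect_true(all(out0$rho == 0))
  ## uniform rho, constant H: removed mass approaches int rho H dt* dt
  ## as dt -> 0 (Richardson-style refinement against the analytic limit)
  H0 <- 0.2
  err <- sapply(c(0.5, 0.25, 0.125), function(h) {
    r <- rep(1 / (n * h), n)
    rem <- advance_density(r, rep(H0, n), h)$removed_mass
    abs(rem - sum(r * H0) * h * h)
  })
  expect_true(all(diff(err) < 0))             # decreasing with dt
  expect_lt(err[3], (H0 * 0.125)^2)           # O(dt^2) bound
})

test_that("firing rate is the density-weighted hazard integral", {
  n <- 40; dt <- 0.5
  rho <- rep(1 / (n * dt), n)
  expect_identical(firing_rate(rep(0, n), rep(0.5, n), dt), 0)
  expect_identical(firing_rate(rho, rep(0, n), dt), 0)
  H <- seq(0, 0.1, length.out = n)
  expect_equal(firing_rate(rho, H, dt), sum(rho * H) * dt)
})

test_that("spike boundary injects rate and applies printed reset values", {
  n <- 40; dt <- 0.5
  st <- list(rho = rep(1 / (n * dt), n), U = rep(-60, n),
             n_DR = rep(0.1, n), n_M = rep(0.05, n),
             n_KCa = seq(0, 0.4, length.out = n))
  H <- rep(0, n); H[17] <- 1   # unimodal release peak at bin 17
  st2 <- apply_spike_boundary(st, nu = 0.02, H = H, dt = dt, params = pp)
  expect_equal(st2$rho[1], 0.02)
  froz <- seq_len(floor(pp$dt_AP / dt) + 1L)
  expect_true(all(st2$U[froz] == -40))          # V_reset as printed
  expect_true(all(st2$n_DR[froz] == 0.5))       # n(t, dt_AP) = 0.5
  ## slow gate reset taken at the argmax of rho*H (brute-force check)
  jp <- which.max(st$rho * H)
  expect_equal(st2$n_KCa[1], st$n_KCa[jp])
  ## zero rate: no mass enters at t* = 0
  st3 <- apply_spike_boundary(st, nu = 0, H = H, dt = dt, params = pp)
  expect_equal(st3$rho[1], 0)
})

test_that("dynamic threshold follows the printed sigmoid", {
  ## U_inf at the block voltage: half shift
  r <- update_dynamic_threshold(U_inf = -40, U = -40, dt = 0, V_th0 = -50,
                                params = pp)
  expect_equal(r$V_th, -50 + 50)
  ## far hyperpolarized: threshold at base
  r2 <- update_dynamic_threshold(U_inf = -300, U = -300, dt = 0,
                                 V_th0 = -50, params = pp)
  expect_equal(r2$V_th, -50, tolerance = 1e-10)
  ## direct evaluation of the sigmoid at an intermediate point
  r3 <- update_dynamic_threshold(U_inf = -33, U = -33, dt = 0, V_th0 = -50,
                                 params = pp)
  expect_equal(r3$V_th, -50 + 100 / (1 + exp(-(-33 + 40) / 7)),
               tolerance = 1e-12)
  ## relaxation of the filtered voltage toward U with tau = 100 ms
  r4 <- update_dynamic_threshold(U_inf = -70, U = -50, dt = 100,
                                 V_th0 = -50, params = pp)
  expect_equal(r4$U_inf, -50 + (-70 + 50) * exp(-1), tolerance = 1e-12)
})
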