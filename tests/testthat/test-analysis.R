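## Measurement procedures: electrode calibration, ID detection, the two
## wavefront-speed estimators, summary statistics.

test_that("electrode transform has the printed constants and inverts", {
  expect_equal(electrode_k(0), 2.5)
  expect_equal(electrode_k(1 / 0.044), 2.5 * exp(1), tolerance = 1e-12)
  V <- seq(-5, 40, by = 0.5)
  expect_equal(electrode_voltage(electrode_k(V)), V, tolerance = 1e-12)
  ## synthetic electrode trace generator is the exact inverse
  K <- c(3.5, 6, 12, 4)
  expect_equal(electrode_k(synthetic_electrode_trace(K)), K,
               tolerance = 1e-12)
})

test_that("ID detection finds sustained transients and rejects blips", {
  t <- seq(0, 120, by = 0.1)
  k <- rep(3.5, length(t))
  k[t >= 30 & t <= 50] <- 12            # a 20-s discharge
  k[t >= 80 & t <= 80.5] <- 12          # a half-second blip
  ev <- detect_ids(k, t)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 30, tolerance = 0.2)
  expect_equal(ev$peak_mM, 12)
  expect_gt(ev$offset_s, 50)
  ## flat trace: nothing
  expect_equal(nrow(detect_ids(rep(3.5, length(t)), t)), 0L)
})

test_that("delay-based speed recovers a constructed shift and guards", {
  t <- seq(0, 100, by = 0.1)
  bump <- function(on) 3.5 + 10 / (1 + exp(-(t - on) / 1)) /
    (1 + exp((t - on - 20) / 2))
  k1 <- bump(30); k2 <- bump(34)        # 4-s shift
  out <- speed_from_delay(k1, k2, t, distance_mm = 2)
  expect_equal(out$status, "ok")
  expect_equal(out$speed_mm_s, 0.5, tolerance = 0.02)
  ## zero lag flagged as unresolved, not a number
  out0 <- speed_from_delay(k1, k1, t, distance_mm = 2)
  expect_true(out0$status %in% c("zero_lag"))
  expect_true(is.na(out0$speed_mm_s))
  ## event missing at one site: failed to propagate
  out2 <- speed_from_delay(k1, rep(3.5, length(t)), t, distance_mm = 2)
  expect_equal(out2$status, "failed_to_propagate")
})

test_that("slope-based speed recovers constant and piecewise fronts", {
  ## constant-speed synthetic front: exact recovery
  w <- synthetic_wave(0.3, duration_s = 40, dt_s = 0.05, onset_s = 5)
  sp <- speed_from_slope(w$field, w$time_s, w$x_mm)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$speed_mm_s, 0.3, tolerance = 0.01)
  ## piecewise (fast then slow): the slow segment's speed is returned
  w2 <- synthetic_wave(c(2, 0.25), duration_s = 40, dt_s = 0.05,
                       onset_s = 5, x_break_mm = 1.25)
  sp2 <- speed_from_slope(w2$field, w2$time_s, w2$x_mm)
  expect_equal(sp2$speed_mm_s, 0.25, tolerance = 0.02)
  ## spatially simultaneous onset: no finite minimum below the cutoff
  f <- matrix(3.5, 200, 32)
  f[100:200, ] <- 12
  sp3 <- speed_from_slope(f, seq(0, 19.9, by = 0.1), seq(0, 2.5,
                                                         length.out = 32))
  expect_true(is.na(sp3$speed_mm_s))
})

test_that("both speed estimators are invariant to affine trace rescaling", {
  w <- synthetic_wave(0.4, duration_s = 40, dt_s = 0.05, onset_s = 5)
  i1 <- 16; i2 <- 48
  d <- w$x_mm[i2] - w$x_mm[i1]
  s_raw <- speed_from_delay(w$field[, i1], w$field[, i2], w$time_s, d)
  resc <- function(k) 2.2 * k - 1.1
  ## the delay method normalizes each rise to its own peak; rescale both
  ## traces and the baseline consistently
  s_res <- speed_from_delay(resc(w$field[, i1]), resc(w$field[, i2]),
                            w$time_s, d, baseline = resc(3.5),
                            thr_on = 2.2 * 3, thr_off = 2.2 * 1)
  expect_equal(s_res$speed_mm_s, s_raw$speed_mm_s, tolerance = 1e-6)
})

test_that("speed recovery tolerates additive noise across many seeds", {
  errs <- sapply(1:25, function(sd) {
    w <- synthetic_wave(0.3, duration_s = 40, dt_s = 0.1, onset_s = 5,
                        noise_sd = 0.5, seed = sd)
    i1 <- 16; i2 <- 48
    out <- speed_from_delay(w$field[, i1], w$field[, i2], w$time_s,
                            w$x_mm[i2] - w$x_mm[i1])
    abs(out$speed_mm_s[out$status == "ok"][1] - 0.3) / 0.3
  })
  expect_lt(stats::median(errs, na.rm = TRUE), 0.05)
  expect_gt(mean(is.finite(errs)), 0.9)
})

test_that("ID statistics exclude the first event and match sort-based
           quantiles", {
  ev <- data.frame(onset_s = c(50, 150, 240, 330),
                   offset_s = c(70, 170, 260, 350),
                   peak_mM = c(9, 11, 12, 10),
                   peak_time_s = c(55, 155, 245, 335))
  st <- id_statistics(list(ev))
  ## 4 IDs -> 3 usable after first-ID exclusion
  expect_equal(length(st$peak_mM), 3L)
  expect_equal(st$peak_mM, c(11, 12, 10))
  ## frequency = reciprocal inter-onset interval
  expect_equal(sort(st$freq_per_s), sort(1 / diff(ev$onset_s)))
  ## brute-force quantile cross-check
  z <- st$peak_mM
  sz <- sort(z)
  expect_equal(st$summary["peak_K_mM", "median"], sz[2])
  ## single-value set: degenerate quartiles
  one <- id_statistics(list(ev[1:1, ]), exclude_first = FALSE)
  expect_equal(one$summary["peak_K_mM", "median"], 9)
  expect_equal(one$summary["peak_K_mM", "q25"], 9)
  expect_equal(one$summary["peak_K_mM", "q75"], 9)
})
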