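## Spatial coupling: kernel normalization, all-to-all mixing, diffusion,
## AMPA gradient.

test_that("kernel rows are normalized for all lambdas and positions", {
  x <- seq(0, 2500, length.out = 48)
  for (lam in c(10, 50, 250, 1000)) {
    K <- connection_kernel(x, lam)
    expect_equal(rowSums(K), rep(1, length(x)), tolerance = 1e-12)
  }
  expect_identical(connection_kernel(x, 0), diag(length(x)))
})

test_that("rate-field convolution matches the brute-force double sum", {
  x <- seq(0, 2500, length.out = 40)
  nu <- numeric(40); nu[13] <- 2   # delta-like source
  for (lam in c(50, 250)) {
    expect_equal(presynaptic_rate_field(nu, lam, x),
                 kernel_direct(nu, x, lam), tolerance = 1e-12)
  }
  ## uniform field passes through unchanged; lambda = 0 is the identity
  u <- rep(0.3, 40)
  expect_equal(presynaptic_rate_field(u, 50, x), u, tolerance = 1e-12)
  expect_equal(presynaptic_rate_field(nu, 0, x), nu)
})

test_that("all-to-all mixing interpolates toward the domain mean", {
  phi <- c(1, 0, 0, 0)
  nu <- c(1, 0, 0, 0)
  expect_equal(mix_long_range(phi, nu, 0), phi)
  expect_equal(mix_long_range(phi, nu, 1), rep(0.25, 4))
  u <- rep(0.4, 6)
  expect_equal(mix_long_range(u, u, 0.37), u)
  m <- mix_long_range(phi, nu, 0.2)
  expect_equal(m, 0.8 * phi + 0.2 * 0.25)
})

test_that("diffusion operator conserves mass and matches the heat kernel", {
  x <- seq(0, 2500, length.out = 64)
  dx <- x[2] - x[1]
  ## uniform field: zero rate
  expect_equal(diffusion_operator(rep(5, 64), 0.39, dx), rep(0, 64))
  ## linear ramp: interior zero
  ramp <- seq(1, 10, length.out = 64)
  lap <- diffusion_operator(ramp, 0.39, dx)
  expect_equal(lap[2:63], rep(0, 62), tolerance = 1e-12)
  ## conservation to machine precision under Neumann ends
  f <- 5 + exp(-(x - 1200)^2 / 200^2)
  expect_lt(abs(sum(diffusion_operator(f, 390, dx))), 1e-12)
  ## Gaussian bump decays per the closed-form heat-kernel variance growth
  ## (short horizon so the Neumann boundaries stay unreached)
  D <- 390; dt <- 0.25; s0 <- 200
  f <- exp(-(x - 1250)^2 / (2 * s0^2))
  for (i in 1:200) f <- f + dt * diffusion_operator(f, D, dx)
  t_tot <- 200 * dt
  s_t <- sqrt(s0^2 + 2 * D * t_tot)
  ref <- (s0 / s_t) * exp(-(x - 1250)^2 / (2 * s_t^2))
  expect_equal(f, ref, tolerance = 5e-3)
})

test_that("AMPA gradient is linear from zero to the maximum", {
  x <- seq(0, 2500, length.out = 11)
  g <- ampa_gradient_profile(x, 0.3, 2500)
  expect_equal(g[1], 0)
  expect_equal(g[11], 0.3)
  expect_equal(g[6], 0.15)
})
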