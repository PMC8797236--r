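## shared fixtures and brute-force helpers, built in code at test time

## acceptance blocks may fail honestly without silencing later contexts
options(testthat.progress.max_fails = 1000)

## direct high-precision evaluation of the printed hazard noise-term
## expression (independent of the production code path)
hazard_A_direct <- function(T, tau_m, tau_Noise) {
  k <- tau_m / tau_Noise
  poly <- 0.0061 - 1.12 * T - 0.257 * T^2 - 0.072 * T^3 - 0.0117 * T^4
  (1 / tau_m) * exp(poly) * (1 - (1 + k)^(-0.71 + 0.0825 * (T + 3)))
}

## O(n^2) direct-sum evaluation of the normalized Gaussian convolution
kernel_direct <- function(nu, x, lambda) {
  sapply(seq_along(x), function(i) {
    w <- exp(-(x[i] - x)^2 / lambda^2)
    sum(w * nu) / sum(w)
  })
}

## small default parameter set shared across tests
pp <- ictal_params()
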