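## CBRD core: hazard function, density transport, firing-rate boundary,
## spike resets, depolarization block.

erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

## exp(-T^2) / (1 + erf(T)), stable for very negative T where both terms
## underflow: there the ratio tends to -T*sqrt(pi) (Mills-type asymptotic).
hazard_b_shape <- function(T) {
  out <- numeric(length(T))
  lo <- T <= -5
  if (any(lo)) {
    xx <- -T[lo]
    out[lo] <- xx * sqrt(pi) / (1 - 1 / (2 * xx^2) + 3 / (4 * xx^4))
  }
  if (any(!lo)) out[!lo] <- exp(-T[!lo]^2) / (1 + erf(T[!lo]))
  out
}

#' Scaled distance to threshold used by the hazard function
#'
#' \code{T = (V_th - U) / (sqrt(2) sigma_V)}, where the voltage-noise
#' amplitude grows with the synaptic conductance, by default as
#' \code{sigma_V = sigma_V0 * sqrt(1 + g_syn / g_L)} (a linear variant is
#' available). The conductance state enters the hazard only through
#' sigma_V and through the membrane time constant.
#'
#' @param U membrane voltage (mV), vector.
#' @param g_tot total membrane conductance (mS/cm2).
#' @param g_syn synaptic part of the conductance (mS/cm2).
#' @param g_L resting (leak) conductance (mS/cm2).
#' @param V_th spike threshold (mV).
#' @param sigma_V0 resting noise amplitude (mV).
#' @param form \code{"sqrt"} or \code{"linear"} scaling of sigma_V.
#' @return dimensionless threshold distance, same length as \code{U}.
#' @export
threshold_distance <- function(U, g_tot, g_syn = 0, g_L, V_th,
                               sigma_V0 = 3, form = c("sqrt", "linear")) {
  form <- match.arg(form)
  sigma_V <- if (form == "sqrt") sigma_V0 * sqrt(1 + g_syn / g_L)
             else sigma_V0 * (1 + g_syn / g_L)
  (V_th - U) / (sqrt(2) * sigma_V)
}

#' Hazard rate of spike emission
#'
#' Instantaneous probability rate (1/ms) for a neuron at scaled threshold
#' distance \code{T} to fire, as the sum of a noise-crossing term \code{A}
#' (self-exciting escape over threshold, approximated by an
#' exponential-polynomial in \code{T} with a correction in
#' \code{k = tau_m / tau_Noise}) and a drift term \code{B} equal to the
#' probability flux of the advected Gaussian voltage density through
#' threshold; \code{B} uses only the negative part of \code{dT/dt}.
#'
#' @param U membrane voltage (mV), vector over time-since-spike bins.
#' @param g_tot total conductance (mS/cm2), vector or scalar, must be > 0.
#' @param dT_dt rate of change of the scaled threshold distance (1/ms).
#' @param g_syn synaptic conductance (mS/cm2).
#' @param g_L resting conductance (mS/cm2).
#' @param V_th spike threshold (mV), vector or scalar.
#' @param C membrane capacitance (uF/cm2).
#' @param sigma_V0 resting noise amplitude (mV).
#' @param tau_Noise noise correlation time (ms).
#' @param form noise-scaling form, see \code{\link{threshold_distance}}.
#' @return hazard rate per bin (1/ms), nonnegative.
#' @export
hazard_rate <- function(U, g_tot, dT_dt = 0, g_syn = 0, g_L, V_th,
                        C = 1, sigma_V0 = 3, tau_Noise = 4,
                        form = c("sqrt", "linear")) {
  form <- match.arg(form)
  if (any(!is.finite(U))) stop("non-finite membrane voltage")
  if (any(!is.finite(g_tot)) || any(g_tot <= 0))
    stop("total conductance must be finite and positive")
  T <- threshold_distance(U, g_tot, g_syn, g_L, V_th, sigma_V0, form)
  tau_m <- C / g_tot
  k <- tau_m / tau_Noise
  ## the A approximation is a fit over moderate |T|; clamp outside
  Tc <- pmin(pmax(T, -3), 6)
  A <- (1 / tau_m) *
    exp(0.0061 - 1.12 * Tc - 0.257 * Tc^2 - 0.072 * Tc^3 - 0.0117 * Tc^4) *
    (1 - (1 + k)^(-0.71 + 0.0825 * (Tc + 3)))
  A <- pmax(A, 0)
  B <- (2 / sqrt(pi)) * pmax(-dT_dt, 0) * hazard_b_shape(T)
  A + B
}

#' Advance the neuronal density one step along time-since-spike
#'
#' Method-of-characteristics transport: the density is shifted one bin along
#' t* (the bin width equals \code{dt}) with a multiplicative sink
#' \code{exp(-H dt)}; the last bin absorbs all older neurons. The removed
#' mass equals the mass to be injected at t* = 0 by
#' \code{\link{apply_spike_boundary}}, so total mass is conserved.
#'
#' @param rho density over t* bins (1/ms).
#' @param H hazard per bin (1/ms).
#' @param dt time step = t* bin width (ms).
#' @return list with \code{rho} (shifted, bin 1 zeroed) and
#'   \code{removed_mass} (dimensionless probability mass).
#' @export
advance_density <- function(rho, H, dt) {
  stopifnot(length(rho) == length(H), dt > 0)
  n <- length(rho)
  dec <- rho * exp(-H * dt)
  removed <- sum(rho - dec) * dt
  out <- c(0, dec[-n])
  out[n] <- out[n] + dec[n]      # absorbing last bin
  list(rho = out, removed_mass = removed)
}

#' Population firing rate from density and hazard
#'
#' \code{nu = integral of rho H dt*}; the value is re-injected as the
#' density at t* = 0. The discrete form used here matches the sink of
#' \code{\link{advance_density}} to first order in dt.
#'
#' @inheritParams advance_density
#' @return firing rate (1/ms).
#' @export
firing_rate <- function(rho, H, dt) {
  stopifnot(length(rho) == length(H))
  sum(rho * H) * dt
}

#' Apply the spike boundary condition at t* = 0
#'
#' Injects the firing rate as density at t* = 0 and holds the state within
#' the spike window 0 < t* < dt_AP at reset values: voltage at
#' \code{V_reset}, the delayed-rectifier gate at 0.5, fast gates at their
#' precomputed spike-peak values, and the slow Ca-dependent K gate at its
#' value at the peak of the spike-release distribution \code{rho H}.
#'
#' @param state list with vectors \code{rho}, \code{U}, \code{n_DR},
#'   \code{n_M}, \code{n_KCa} over t* bins.
#' @param nu firing rate to inject (1/ms).
#' @param H hazard per bin (1/ms), used to locate the release peak.
#' @param dt bin width (ms).
#' @param params an \code{\link{ictal_params}} object.
#' @param n_M_reset precomputed fast-gate reset value for the M gate.
#' @return the updated state list.
#' @export
apply_spike_boundary <- function(state, nu, H, dt, params = ictal_params(),
                                 n_M_reset = 0) {
  stopifnot(nu >= 0)
  n <- length(state$rho)
  release <- state$rho * H
  tp <- if (any(release > 0)) which.max(release) else n
  frozen <- seq_len(min(n, floor(params$dt_AP / dt) + 1L))
  state$rho[1] <- nu
  state$U[frozen] <- params$V_reset
  state$n_DR[frozen] <- params$n_DR_reset
  if (!is.null(state$n_M)) state$n_M[frozen] <- n_M_reset
  if (!is.null(state$n_KCa)) state$n_KCa[1] <- state$n_KCa[tp]
  state
}

#' Dynamic spike threshold implementing depolarization block
#'
#' The threshold rises sigmoidally by up to 100 mV when the low-pass
#' filtered voltage \code{U_inf} approaches the block voltage
#' \code{V_DB = -40 mV} (slope 7 mV); \code{U_inf} relaxes toward the
#' instantaneous voltage with a 100 ms time constant.
#'
#' @param U_inf filtered voltage (mV).
#' @param U instantaneous voltage (mV).
#' @param dt time step (ms); 0 returns the threshold without relaxing.
#' @param V_th0 base threshold (mV).
#' @param params an \code{\link{ictal_params}} object.
#' @return list with \code{V_th} and updated \code{U_inf}.
#' @export
update_dynamic_threshold <- function(U_inf, U, dt, V_th0,
                                     params = ictal_params()) {
  if (dt > 0)
    U_inf <- U + (U_inf - U) * exp(-dt / params$tau_Uinf)
  V_th <- V_th0 + params$DB_amp /
    (1 + exp(-(U_inf - params$V_DB) / params$DB_slope))
  list(V_th = V_th, U_inf = U_inf)
}
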