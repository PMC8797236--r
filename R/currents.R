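## Voltage-gated currents and gating kinetics for the population voltage
## equation and the representative single neuron.

## x / (exp(x/s) - 1) with the removable singularity at x = 0 handled by a
## 3-term Taylor expansion (s - x/2 + x^2/(12 s)) near the singular point.
expdiv <- function(x, s) {
  out <- numeric(length(x))
  near <- abs(x) < 1e-3
  out[near] <- s - x[near] / 2 + x[near]^2 / (12 * s)
  out[!near] <- x[!near] / (expm1(x[!near] / s))
  out
}

#' Gating rate functions alpha(U), beta(U)
#'
#' Opening/closing rates (1/ms) for the model's voltage-dependent gates:
#' the delayed-rectifier K gate (\code{"DR"}), the M-type K gate
#' (\code{"M"}), and the representative neuron's Na activation (\code{"m"})
#' and inactivation (\code{"h"}). Removable singularities are evaluated by
#' their analytic limits.
#'
#' @param gate one of \code{"DR"}, \code{"M"}, \code{"m"}, \code{"h"}.
#' @param U membrane voltage (mV), vector.
#' @return list with vectors \code{alpha} and \code{beta} (1/ms).
#' @examples
#' gating_rates("DR", -48)$alpha  # analytic limit at the singular voltage
#' @export
gating_rates <- function(gate = c("DR", "M", "m", "h"), U) {
  gate <- match.arg(gate)
  switch(gate,
    DR = list(alpha = -0.032 * expdiv(U + 48, -5),
              beta  = 0.5 * exp(-(U + 53) / 40)),
    M  = list(alpha = -0.0001 * expdiv(U + 30, -9),
              beta  = 0.0001 * expdiv(U + 30, 9)),
    m  = list(alpha = -0.32 * expdiv(U + 50, -4),
              beta  = 0.28 * expdiv(U + 23, 5)),
    h  = list(alpha = 0.128 * exp(-(U + 46) / 18),
              beta  = 4 / (1 + exp(-(U + 23) / 5))))
}

#' Voltage-gated potassium currents
#'
#' \code{I_DR = g_DR n^4 (U - V_K)}, \code{I_M = g_M n_M (U - V_K)},
#' \code{I_KCa = g_KCa n_KCa^2 (U - V_K)} (uA/cm2). Interneurons have no
#' M- or K-Ca currents (their maximal conductances are zero).
#'
#' @param U membrane voltage (mV).
#' @param n_DR,n_M,n_KCa gating variables in [0, 1].
#' @param V_K potassium reversal potential (mV).
#' @param g_DR,g_M,g_KCa maximal conductances (mS/cm2).
#' @return list with \code{I_DR}, \code{I_M}, \code{I_KCa} (uA/cm2).
#' @export
voltage_gated_currents <- function(U, n_DR, n_M, n_KCa, V_K,
                                   g_DR = 0.004, g_M = 0.0007, g_KCa = 0.0004) {
  list(I_DR  = g_DR  * n_DR^4  * (U - V_K),
       I_M   = g_M   * n_M     * (U - V_K),
       I_KCa = g_KCa * n_KCa^2 * (U - V_K))
}

#' Advance a gating variable by exponential Euler
#'
#' Relaxation toward \code{alpha/(alpha+beta)} at rate \code{alpha+beta};
#' the result stays in [0, 1] for inputs in [0, 1].
#'
#' @param n gating variable.
#' @param alpha,beta rates (1/ms).
#' @param dt time step (ms).
#' @return updated gating variable.
#' @export
advance_gating <- function(n, alpha, beta, dt) {
  r <- alpha + beta
  ninf <- ifelse(r > 0, alpha / r, n)
  ninf + (n - ninf) * exp(-r * dt)
}

#' Rate constants of the Ca-dependent K gate
#'
#' The K-Ca gate opens at rate \code{alpha_KCa [Ca]^2} and closes at the
#' constant rate \code{beta_KCa}.
#'
#' @param Ca_i intracellular calcium (mM).
#' @param params an \code{\link{ictal_params}} object.
#' @return list with \code{alpha} and \code{beta} (1/ms).
#' @export
kca_rates <- function(Ca_i, params = ictal_params()) {
  list(alpha = params$alpha_KCa * Ca_i^2, beta = params$beta_KCa)
}

#' One exponential-Euler step of the population voltage equation
#'
#' \code{C dU/dt = -I_leak - I_DR - I_M - I_KCa + I_noise + g_GABA (V_GABA
#' - U) + g_AMPA (V_AMPA - U) + g_NMDA (V_NMDA - U)}, where the leak is the
#' sum of the K, Cl and Na ionic leak currents with Nernst reversals (plus,
#' for interneurons, a passive shunt). All conductance-shaped terms are
#' collected into a total conductance and an equilibrium voltage, and U is
#' relaxed exactly for frozen coefficients.
#'
#' @param U membrane voltage (mV), vector over bins.
#' @param g list of conductances (mS/cm2): \code{g_K_leak}, \code{g_Cl_leak},
#'   \code{g_Na_leak}, \code{g_shunt}, \code{g_DR_eff}, \code{g_M_eff},
#'   \code{g_KCa_eff} (already multiplied by their gate powers),
#'   \code{g_AMPA}, \code{g_NMDA_eff}, \code{g_GABA}.
#' @param E list of reversals (mV): \code{V_K}, \code{V_Cl}, \code{V_Na},
#'   \code{V_shunt}, \code{V_GABA}, \code{V_AMPA}, \code{V_NMDA}.
#' @param I_ext additive current (uA/cm2), e.g. noise.
#' @param dt time step (ms).
#' @param C capacitance (uF/cm2).
#' @return list with updated \code{U}, the total conductance \code{g_tot}
#'   and the equilibrium voltage \code{U_eq}.
#' @export
advance_population_voltage <- function(U, g, E, I_ext = 0, dt, C = 1) {
  g_tot <- g$g_K_leak + g$g_Cl_leak + g$g_Na_leak + g$g_shunt +
    g$g_DR_eff + g$g_M_eff + g$g_KCa_eff + g$g_AMPA + g$g_NMDA_eff + g$g_GABA
  num <- g$g_K_leak * E$V_K + g$g_Cl_leak * E$V_Cl + g$g_Na_leak * E$V_Na +
    g$g_shunt * E$V_shunt +
    (g$g_DR_eff + g$g_M_eff + g$g_KCa_eff) * E$V_K +
    g$g_AMPA * E$V_AMPA + g$g_NMDA_eff * E$V_NMDA + g$g_GABA * E$V_GABA +
    I_ext
  U_eq <- num / g_tot
  U_new <- U_eq + (U - U_eq) * exp(-g_tot * dt / C)
  if (any(!is.finite(U_new))) stop("non-finite voltage after update")
  list(U = U_new, g_tot = g_tot, U_eq = U_eq)
}

#' One step of the representative single neuron
#'
#' The representative neuron follows the basic single-neuron model: the
#' population voltage equation with the total time derivative and an
#' explicit transient sodium current \code{I_Na = g_Na m^3 h (V - V_Na)}.
#' It receives the same synaptic conductances as its population at the
#' node, observes spikes as genuine Na-driven action potentials, and does
#' not feed back into the population dynamics. The step is integrated with
#' internal substeps of at most 0.05 ms for spike fidelity.
#'
#' @param state list with \code{V}, \code{m}, \code{h}, \code{n_DR},
#'   \code{n_M}, \code{n_KCa}.
#' @param g,E conductances and reversals as in
#'   \code{\link{advance_population_voltage}}.
#' @param Ca_i intracellular calcium (mM) driving the K-Ca gate.
#' @param I_ext additive current (uA/cm2).
#' @param dt outer time step (ms).
#' @param params an \code{\link{ictal_params}} object.
#' @param pop \code{"E"} or \code{"I"} (interneurons lack M and K-Ca).
#' @return updated state list.
#' @export
representative_neuron_step <- function(state, g, E, Ca_i = 0, I_ext = 0, dt,
                                       params = ictal_params(), pop = "E") {
  nsub <- max(1L, ceiling(dt / 0.05))
  h <- dt / nsub
  gM <- if (pop == "E") params$g_M_E else params$g_M_I
  gKCa <- if (pop == "E") params$g_KCa_E else params$g_KCa_I
  kca <- kca_rates(Ca_i, params)
  for (i in seq_len(nsub)) {
    rm_ <- gating_rates("m", state$V); rh <- gating_rates("h", state$V)
    rDR <- gating_rates("DR", state$V); rM <- gating_rates("M", state$V)
    state$m <- advance_gating(state$m, rm_$alpha, rm_$beta, h)
    state$h <- advance_gating(state$h, rh$alpha, rh$beta, h)
    state$n_DR <- advance_gating(state$n_DR, rDR$alpha, rDR$beta, h)
    if (pop == "E") {
      state$n_M <- advance_gating(state$n_M, rM$alpha, rM$beta, h)
      state$n_KCa <- advance_gating(state$n_KCa, kca$alpha, kca$beta, h)
    }
    gg <- g
    gg$g_DR_eff <- params$g_DR_rep * state$n_DR^4
    gg$g_M_eff <- gM * state$n_M
    gg$g_KCa_eff <- gKCa * state$n_KCa^2
    g_Na <- params$g_Na_rep * state$m^3 * state$h
    gtot <- gg$g_K_leak + gg$g_Cl_leak + gg$g_Na_leak + gg$g_shunt +
      gg$g_DR_eff + gg$g_M_eff + gg$g_KCa_eff +
      gg$g_AMPA + gg$g_NMDA_eff + gg$g_GABA + g_Na
    num <- gg$g_K_leak * E$V_K + gg$g_Cl_leak * E$V_Cl +
      gg$g_Na_leak * E$V_Na + gg$g_shunt * E$V_shunt +
      (gg$g_DR_eff + gg$g_M_eff + gg$g_KCa_eff) * E$V_K +
      gg$g_AMPA * E$V_AMPA + gg$g_NMDA_eff * E$V_NMDA +
      gg$g_GABA * E$V_GABA + g_Na * params$V_Na_rep + I_ext
    Ueq <- num / gtot
    state$V <- Ueq + (state$V - Ueq) * exp(-gtot * h / params$C)
  }
  state
}
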