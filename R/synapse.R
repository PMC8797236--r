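## AMPA/NMDA/GABA conductance kinetics with magnesium block and
## Tsodyks-Markram short-term depression.

#' NMDA magnesium-block factor
#'
#' \code{f_NMDA(V) = 1 / (1 + (Mg / 3.57) exp(-0.062 V))}, in (0, 1].
#'
#' @param V postsynaptic voltage (mV).
#' @param Mg magnesium concentration (mM), nonnegative.
#' @return unblocked fraction.
#' @examples
#' nmda_block(0, 0.25)
#' nmda_block(-70, 0)   # no Mg -> fully unblocked
#' @export
nmda_block <- function(V, Mg = 0.25) {
  if (any(Mg < 0)) stop("Mg must be nonnegative")
  1 / (1 + (Mg / 3.57) * exp(-0.062 * V))
}

#' Normalizing time scale of the second-order synapse filter
#'
#' Chosen so that the peak conductance evoked by a short presynaptic pulse
#' is independent of the rise/decay time-constant pair: for distinct
#' constants \code{tau_s = (tau_r - tau_d) / ((tau_d/tau_r)^(tau_d/(tau_r -
#' tau_d)) - (tau_d/tau_r)^(tau_r/(tau_r - tau_d)))}; in the equal-constant
#' limit \code{tau_s = tau_r * e}.
#'
#' @param tau_r,tau_d rise and decay time constants (ms), positive.
#' @return normalizing time scale (ms).
#' @export
synapse_timescale <- function(tau_r, tau_d) {
  stopifnot(tau_r > 0, tau_d > 0)
  if (abs(tau_r - tau_d) < 1e-9 * tau_r) return(tau_r * exp(1))
  q <- tau_d / tau_r
  (tau_r - tau_d) / (q^(tau_d / (tau_r - tau_d)) - q^(tau_r / (tau_r - tau_d)))
}

#' Advance a synaptic conductance kernel one step
#'
#' The dimensionless conductance m obeys the second-order ODE
#' \code{tau_r tau_d m'' + (tau_r + tau_d) m' + m = tau_s (1 - m) phi},
#' integrated as two first-order equations (midpoint rule with internal
#' substeps when the step is coarse relative to tau_r).
#'
#' @param m conductance activation (dimensionless, >= 0).
#' @param dm its time derivative (1/ms).
#' @param phi presynaptic firing rate (1/ms), nonnegative.
#' @param tau_r,tau_d rise and decay time constants (ms).
#' @param dt time step (ms).
#' @return list with updated \code{m} and \code{dm}.
#' @export
advance_synapse <- function(m, dm, phi, tau_r, tau_d, dt) {
  stopifnot(phi >= 0)
  tau_s <- synapse_timescale(tau_r, tau_d)
  a <- tau_r * tau_d; b <- tau_r + tau_d
  nsub <- max(1L, ceiling(dt / (0.5 * min(tau_r, tau_d))))
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    f1m <- dm
    f1d <- (tau_s * (1 - m) * phi - b * dm - m) / a
    mh <- m + 0.5 * h * f1m; dh <- dm + 0.5 * h * f1d
    f2m <- dh
    f2d <- (tau_s * (1 - mh) * phi - b * dh - mh) / a
    m <- m + h * f2m; dm <- dm + h * f2d
  }
  if (m < 0) { m <- 0; dm <- max(dm, 0) }
  list(m = m, dm = dm)
}

#' Synaptic conductances from kernel states and depression resources
#'
#' \code{g_AMPA = gmax m x_glu}; \code{g_NMDA = gmax f_NMDA(V) m x_glu};
#' \code{g_GABA = gmax m x_GABA} (mS/cm2).
#'
#' @param m_AMPA,m_NMDA,m_GABA kernel activations.
#' @param x_glu,x_GABA depression resources in [0, 1].
#' @param V_post postsynaptic voltage (mV) for the Mg block.
#' @param g_AMPA_max,g_NMDA_max,g_GABA_max maximal conductances (mS/cm2).
#' @param Mg magnesium concentration (mM).
#' @return list with \code{g_AMPA}, \code{g_NMDA}, \code{g_GABA}.
#' @export
synaptic_conductances <- function(m_AMPA, m_NMDA, m_GABA, x_glu, x_GABA,
                                  V_post, g_AMPA_max, g_NMDA_max, g_GABA_max,
                                  Mg = 0.25) {
  list(g_AMPA = g_AMPA_max * m_AMPA * x_glu,
       g_NMDA = g_NMDA_max * nmda_block(V_post, Mg) * m_NMDA * x_glu,
       g_GABA = g_GABA_max * m_GABA * x_GABA)
}

#' Advance a short-term depression resource
#'
#' Tsodyks-Markram depression: \code{dx/dt = (1 - x)/tau - u x phi}.
#' Integrated exactly for the step (the equation is linear in x for frozen
#' phi); x stays in [0, 1] for nonnegative inputs.
#'
#' @param x available resource fraction in [0, 1].
#' @param phi presynaptic rate (1/ms), nonnegative.
#' @param u utilization per spike.
#' @param tau recovery time constant (ms).
#' @param dt time step (ms).
#' @return updated resource fraction.
#' @export
advance_depression <- function(x, phi, u, tau, dt) {
  stopifnot(all(phi >= 0))
  r <- 1 / tau + u * phi
  xinf <- (1 / tau) / r
  xinf + (x - xinf) * exp(-r * dt)
}
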