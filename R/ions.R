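## Ionic concentration balances: Nernst reversals, KCC2/NKCC1 cotransport,
## Na/K-ATPase (kinetic cycle and double-sigmoid forms), calcium, glial
## buffer and ECS volume dynamics.

#' Nernst reversal potentials and the GABA-A mixed reversal
#'
#' \code{V_X = 26.6 mV ln(out/in)} for cations, \code{ln(in/out)} for
#' chloride; the GABA-A reversal uses a 4:1 chloride:bicarbonate
#' permeability mixture:
#' \code{V_GABA = 26.6 ln((4[Cl]_i + [HCO3]_i) / (4[Cl]_o + [HCO3]_o))}.
#'
#' @param K_i,K_o,Cl_i,Cl_o,Na_i,Na_o ion concentrations (mM), positive.
#' @param HCO3_i,HCO3_o fixed bicarbonate concentrations (mM).
#' @param nernst_mV thermal voltage scale (mV).
#' @return list with \code{V_K}, \code{V_Cl}, \code{V_Na}, \code{V_GABA}
#'   (mV).
#' @examples
#' nernst_potentials(129, 3.5, 5, 130, 17, 130)$V_K
#' @export
nernst_potentials <- function(K_i, K_o, Cl_i, Cl_o, Na_i, Na_o,
                              HCO3_i = 16, HCO3_o = 24, nernst_mV = 26.6) {
  conc <- c(K_i, K_o, Cl_i, Cl_o, Na_i, Na_o, HCO3_i, HCO3_o)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("ion concentrations must be finite and positive")
  list(V_K  = nernst_mV * log(K_o / K_i),
       V_Cl = nernst_mV * log(Cl_i / Cl_o),
       V_Na = nernst_mV * log(Na_o / Na_i),
       V_GABA = nernst_mV *
         log((4 * Cl_i + HCO3_i) / (4 * Cl_o + HCO3_o)))
}

#' Cotransporter currents and the double-sigmoid pump approximation
#'
#' KCC2 flux (default, printed form):
#' \code{I_KCC2 = I_KCC2_max (V_K - V_Cl) / (V_K - V_Cl - 40 mV)}, with the
#' denominator clamped away from its pole. This transporter is impaired /
#' reversed relative to healthy tissue: positive (K and Cl import -- the
#' interictal chloride-accumulation ramp) at rest where
#' \code{V_K < V_Cl}, and negative (export, chloride recovery) while
#' extracellular potassium is elevated after a discharge. A saturating odd
#' variant \code{(V_K - V_Cl)/(|V_K - V_Cl| + 40)} describing a healthy
#' extruding KCC2 is available for comparison.
#' \code{I_NKCC1 = I_NKCC1_max (V_Na + V_K - 2 V_Cl) / 26.6 mV} (applied to
#' the I-population only in the full model); the simple pump is
#' \code{I_pump_max / ((1 + exp(3.5 - [K]_o)) (1 + exp((25 - [Na]_i)/3)))}.
#'
#' @param V_K,V_Cl,V_Na reversal potentials (mV).
#' @param K_o extracellular potassium (mM).
#' @param Na_i intracellular sodium (mM).
#' @param I_KCC2_max,I_NKCC1_max,I_pump_max amplitudes (uA/cm2).
#' @param nernst_mV thermal voltage scale (mV).
#' @param kcc2_form \code{"literal"} (default) or \code{"saturating"}.
#' @return list with \code{I_KCC2}, \code{I_NKCC1}, \code{I_pump_sigmoid}
#'   (uA/cm2).
#' @export
transporter_currents <- function(V_K, V_Cl, V_Na, K_o, Na_i,
                                 I_KCC2_max = 1, I_NKCC1_max = 0.1,
                                 I_pump_max = 0.8, nernst_mV = 26.6,
                                 kcc2_form = c("literal", "saturating")) {
  kcc2_form <- match.arg(kcc2_form)
  u <- V_K - V_Cl
  kcc2 <- if (kcc2_form == "saturating") {
    I_KCC2_max * u / (abs(u) + 40)
  } else {
    den <- ifelse(abs(u - 40) < 1e-6, -1e-6, u - 40)
    I_KCC2_max * u / den
  }
  list(
    I_KCC2 = kcc2,
    I_NKCC1 = I_NKCC1_max * (V_Na + V_K - 2 * V_Cl) / nernst_mV,
    I_pump_sigmoid = I_pump_max /
      ((1 + exp(3.5 - K_o)) * (1 + exp((25 - Na_i) / 3))))
}

## forward/backward rate constants of the 4-state ATPase cycle;
## U in volts, concentrations in mM.
pump_cycle_rates <- function(U, K_i, K_o, Na_i, Na_o) {
  Nai <- Na_i / (2.49 * exp(-0.386 * U))
  Nae <- Na_o / (15.5 * exp(12.1 * U))
  Ki  <- K_i / 0.5
  Ke  <- K_o / 0.213
  Hp  <- 1e-4
  MgATP <- 3.904
  Pi <- 4.2 / (1 + K_i / 292 + Hp / 6.77 + Na_i / 224)
  den_i <- (1 + Nai)^3 + (1 + Ki)^2 - 1
  den_e <- (1 + Nae)^3 + (1 + Ke)^2 - 1
  list(
    a1p = 1050 * Nai^3 / den_i,
    a2p = 481,
    a3p = 2000 * Ke^2 / den_e,
    a4p = 320 * MgATP / (1 + MgATP),
    a1m = 8.605,
    a2m = 40 * Nae^3 / den_e,
    a3m = 79300 * Pi * Hp / (1 + MgATP),
    a4m = 40 * Ki^2 / den_i)
}

#' Na+/K+-ATPase current from the kinetic-cycle model
#'
#' Net steady-state flux of a four-state pump cycle (King-Altman form):
#' the forward rate product minus the backward product, divided by the sum
#' of spanning-tree terms, normalized by 16.8 and scaled by
#' \code{I_pump_max}. The voltage enters the Na binding steps (in volts).
#' The 3 Na out / 2 K in stoichiometry is applied in the balance equations
#' (3 I_pump in the sodium, 2 I_pump in the potassium balance).
#'
#' @param U membrane voltage (mV).
#' @param K_i,K_o,Na_i,Na_o ion concentrations (mM).
#' @param I_pump_max pump amplitude (uA/cm2).
#' @return pump current (uA/cm2).
#' @export
pump_current_kinetic <- function(U, K_i, K_o, Na_i, Na_o, I_pump_max = 0.8) {
  r <- pump_cycle_rates(U / 1000, K_i, K_o, Na_i, Na_o)
  fwd <- r$a1p * r$a2p * r$a3p * r$a4p
  bwd <- r$a1m * r$a2m * r$a3m * r$a4m
  S <- with(r,
    a1p * a2p * a3p + a1p * a2p * a4p + a3p * a2p * a4p + a2p * a3p * a4p +
    a1m * a3m * a4m + a1m * a2m * a4m + a2m * a3m * a4m + a1m * a2m * a3m +
    a4p * a2m * a1m + a4p * a2m * a1p + a4m * a2p * a3p + a4m * a2p * a3m +
    a1p * a2p * a3m + a1p * a2m * a3m + a1m * a4m * a3p + a1m * a3p * a4p)
  I_pump_max * (fwd - bwd) / (16.8 * S)
}

#' Advance intracellular calcium (E-cells)
#'
#' \code{d[Ca]/dt = -[Ca]/tau_Ca + chi g_NMDA (V_Ca - U)}: NMDA-mediated
#' influx (inward calcium current, positive for U below the calcium
#' reversal) and relaxation by the Na/Ca exchanger. Integrated exactly for
#' frozen drive and clamped nonnegative.
#'
#' @param Ca_i calcium concentration (mM), nonnegative.
#' @param g_NMDA NMDA conductance (mS/cm2).
#' @param U_E mean E-cell voltage (mV).
#' @param dt time step (ms).
#' @param params an \code{\link{ictal_params}} object.
#' @return updated calcium concentration (mM).
#' @export
advance_calcium <- function(Ca_i, g_NMDA, U_E, dt, params = ictal_params()) {
  stopifnot(Ca_i >= 0)
  drive <- params$chi_Ca * g_NMDA * (params$V_Ca - U_E)
  Cainf <- params$tau_Ca * drive
  out <- Cainf + (Ca_i - Cainf) * exp(-dt / params$tau_Ca)
  pmax(out, 0)
}

#' One step of the glial potassium buffer
#'
#' \code{dB/dt = k1 (B_max - B) - k2 B} with
#' \code{k2 = k1 / (1 + exp(-([K]_o - 15)/1.15))}. The extracellular
#' source term is \code{G = -dB/dt}: potassium bound by the buffer leaves
#' the ECS. With glia disabled, \code{G = 0} and B is unchanged.
#'
#' @param B bound buffer (mM).
#' @param K_o extracellular potassium (mM).
#' @param dt time step (ms).
#' @param params an \code{\link{ictal_params}} object.
#' @param enabled logical; the buffer acts only in the glial scenario.
#' @return list with updated \code{B} and source \code{G} (mM/ms).
#' @export
glial_buffer_step <- function(B, K_o, dt, params = ictal_params(),
                              enabled = TRUE) {
  if (!enabled) return(list(B = B, G = 0))
  k1 <- params$k1_glia
  k2 <- k1 / (1 + exp(-(K_o - params$K_half_glia) / params$K_slope_glia))
  dB <- k1 * (params$B_max - B) - k2 * B
  list(B = B + dt * dB, G = -dB)
}

#' Osmolarity imbalance driving ECS volume change
#'
#' Change of the extracellular minus (population-weighted) intracellular
#' osmolarity relative to the initial state; zero at rest, negative when
#' neurons gain osmolytes (cells swell, the ECS shrinks). Bicarbonate is
#' constant and drops out. With this sign the volume relaxation is
#' self-stabilizing: ECS shrinkage concentrates the extracellular solutes,
#' which pushes the equilibrium volume back up.
#'
#' @param intra named list/vector with \code{K_i_E, Cl_i_E, Na_i_E, K_i_I,
#'   Cl_i_I, Na_i_I} (mM).
#' @param extra named list/vector with \code{K_o, Cl_o, Na_o} (mM).
#' @param intra0,extra0 the same quantities at the initial state.
#' @param alpha_I interneuron fraction weighting the intracellular sum.
#' @return osmolarity imbalance (mM).
#' @export
osmolarity_imbalance <- function(intra, extra, intra0, extra0,
                                 alpha_I = 0.25) {
  s <- function(z) {
    (1 - alpha_I) * (z$K_i_E + z$Cl_i_E + z$Na_i_E) +
      alpha_I * (z$K_i_I + z$Cl_i_I + z$Na_i_I)
  }
  so <- function(z) z$K_o + z$Cl_o + z$Na_o
  (so(extra) - so(extra0)) - (s(intra) - s(intra0))
}

#' Advance the ECS volume ratio
#'
#' \code{dv/dt = (1 + 0.1029 beta0 (exp(dpi/20) - 1) - v) / tau_v};
#' the fixed-volume mode holds \code{v = 1}.
#'
#' @param v ECS volume ratio (initial 1).
#' @param dpi osmolarity imbalance (mM), see
#'   \code{\link{osmolarity_imbalance}}.
#' @param dt time step (ms).
#' @param params an \code{\link{ictal_params}} object.
#' @param dynamic logical; FALSE returns 1.
#' @return updated volume ratio.
#' @export
advance_volume <- function(v, dpi, dt, params = ictal_params(),
                           dynamic = TRUE) {
  if (!dynamic) return(1)
  vinf <- 1 + params$v_gain * params$beta0_v * (exp(dpi / params$pi_scale) - 1)
  vinf + (v - vinf) * exp(-dt / params$tau_v)
}

#' Intracellular balance right-hand sides for one population
#'
#' Composes the printed balance equations (rates in mM/ms):
#' \code{d[K]_i/dt = gamma (-I_K_leak - I_K_active - I_K_glu + 2 I_pump +
#' I_KCC2 + I_NKCC1)}; \code{d[Cl]_i/dt = gamma (I_Cl_leak + I_GABA +
#' I_KCC2 + 2 I_NKCC1)}; \code{d[Na]_i/dt = gamma (-I_Na_leak - I_Na_glu +
#' q_Na nu - 3 I_pump + I_NKCC1 + I_NCX)}. The per-spike sodium load is
#' \code{q_Na nu} with nu in 1/ms (charge rate in uA/cm2 after the 1000x
#' uC-to-uA-per-ms conversion).
#'
#' @param I named list of currents (uA/cm2): \code{I_K_leak},
#'   \code{I_K_active}, \code{I_K_glu}, \code{I_pump}, \code{I_KCC2},
#'   \code{I_NKCC1}, \code{I_Cl_leak}, \code{I_GABA}, \code{I_Na_leak},
#'   \code{I_Na_glu}, \code{I_NCX}.
#' @param nu population firing rate (1/ms).
#' @param params an \code{\link{ictal_params}} object.
#' @return list with \code{dK_i}, \code{dCl_i}, \code{dNa_i} (mM/ms).
#' @export
intracellular_rates <- function(I, nu, params = ictal_params()) {
  g <- params$gamma_ion
  list(
    dK_i = g * (-I$I_K_leak - I$I_K_active - I$I_K_glu + 2 * I$I_pump +
                  I$I_KCC2 + I$I_NKCC1),
    dCl_i = g * (I$I_Cl_leak + I$I_GABA + I$I_KCC2 + 2 * I$I_NKCC1),
    dNa_i = g * (-I$I_Na_leak - I$I_Na_glu + 1000 * params$q_Na * nu -
                   3 * I$I_pump + I$I_NKCC1 + I$I_NCX))
}

#' Extracellular balance right-hand sides
#'
#' The conserved quantities are the volume-weighted products \code{v [X]_o}:
#' \code{d(v[K]_o)/dt = -beta ((1-alpha_I) d[K]_i^E/dt + alpha_I
#' d[K]_i^I/dt) + G + D_bath ([K]_bath - [K]_o) + D1d lap([K]_o)}; chloride
#' and sodium have only the exchange term.
#'
#' @param dI_E,dI_I intracellular rates for E and I populations, as
#'   returned by \code{\link{intracellular_rates}}.
#' @param K_o extracellular potassium (mM).
#' @param G glial source (mM/ms).
#' @param lap_K diffusion operator applied to the K field (mM/um2),
#'   already including D1d (mM/ms).
#' @param params an \code{\link{ictal_params}} object.
#' @return list with \code{dvK_o}, \code{dvCl_o}, \code{dvNa_o} (mM/ms).
#' @export
extracellular_rates <- function(dI_E, dI_I, K_o, G = 0, lap_K = 0,
                                params = ictal_params()) {
  b <- params$beta_vol; aI <- params$alpha_I
  mix <- function(e, i) -b * ((1 - aI) * e + aI * i)
  list(
    dvK_o = mix(dI_E$dK_i, dI_I$dK_i) + G +
      params$D_bath * (params$K_bath - K_o) + lap_K,
    dvCl_o = mix(dI_E$dCl_i, dI_I$dCl_i),
    dvNa_o = mix(dI_E$dNa_i, dI_I$dNa_i))
}
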