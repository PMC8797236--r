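#' Physical parameters of the ictal-discharge model
#'
#' Returns the complete set of biophysical constants used by the model, at
#' their default values. Units are mV, ms, mM, mS/cm2 (conductances),
#' uA/cm2 (currents) and um (space) throughout. Any entry can be overridden
#' via \code{...}; unknown names are rejected.
#'
#' The defaults describe a 4-AP-like hyperexcitable cortical slice:
#' regular-spiking pyramidal cells (E) with spike-frequency adaptation
#' (M-type and Ca-dependent K currents) and fast-spiking interneurons (I)
#' without adaptation, coupled through AMPA/NMDA/GABA-A conductances with
#' Tsodyks-Markram short-term depression, and embedded in ionic mass
#' balances for K+, Cl- and Na+ with KCC2/NKCC1 cotransport, an
#' electrogenic Na+/K+-ATPase, bath exchange, optional glial buffering and
#' dynamic extracellular-space (ECS) volume.
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of parameters, class \code{"ictal_params"}.
#' @examples
#' p <- ictal_params()
#' p$V_reset
#' ictal_params(Mg = 0)$Mg
#' @export
ictal_params <- function(...) {
  p <- list(
    ## membrane (capacitance uF/cm2; conductances mS/cm2)
    C        = 1,
    g_DR     = 0.004,   # delayed-rectifier K, both populations
    g_M_E    = 0.0007,  # M-type K, E-cells only
    g_M_I    = 0,
    g_KCa_E  = 0.0004,  # Ca-dependent K, E-cells only
    g_KCa_I  = 0,
    g_Na_rep = 7,       # transient Na, representative neurons only
    g_DR_rep = 4,
    V_Na_rep = 50,

    ## voltage-equation leak: fixed reversal; the leak conductance of each
    ## population is C/tau_m0 minus the resting voltage-gated conductance.
    ## The potassium share of the leak (g_KL/g_L, scaled by
    ## k_leak_coupling) carries a Nernst reversal, coupling [K+]o
    ## elevations to membrane depolarization
    V_L      = -70,
    tau_m0_E = 28,
    tau_m0_I = 9,
    k_leak_coupling = 1,

    ## ionic leak conductances (ion bookkeeping only; Nernst reversals)
    g_KL   = 0.020,
    g_ClL  = 0.020,
    g_NaL  = 0.007,

    ## spike mechanics
    V_reset   = -40,
    dt_AP     = 1.5,
    V_th0_E   = -50,
    V_th0_I   = -45,
    n_DR_reset = 0.5,

    ## depolarization block (dynamic threshold)
    V_DB        = -40,
    DB_slope    = 7,      # mV, sigmoid slope
    DB_amp      = 100,    # mV, maximal threshold shift
    tau_Uinf    = 100,    # ms, low-pass filter of voltage

    ## hazard-function noise model
    sigma_V0   = 3,      # mV, resting voltage-noise amplitude
    tau_Noise  = 4,      # ms, noise correlation time

    ## Ornstein-Uhlenbeck background drive (interneurons only)
    I_noise_pA   = 25,     # pA, stationary SD
    noise_gain   = 1,      # calibrates the interictal IPSC rate (~1/s)
    tau_OU       = 4,      # ms
    area_cm2     = 3e-5,   # membrane area, converts pA to uA/cm2

    ## synaptic kinetics (maximal conductances mS/cm2, times ms)
    g_AMPA_E = 0.3,    # spatial maximum; linearly graded 0 at x=0 -> max at x=L
    g_AMPA_I = 0.4,
    g_NMDA_E = 0.6,
    g_NMDA_I = 0.9,
    g_GABA_E = 1,
    g_GABA_I = 2,
    V_AMPA   = 0,
    V_NMDA   = 0,
    Mg       = 0.25,   # mM
    tau_r_AMPA = 1.7,  tau_d_AMPA = 8.3,
    tau_r_NMDA = 6.7,  tau_d_NMDA = 100,
    tau_r_GABA = 0.5,  tau_d_GABA = 20,

    ## short-term depression (Tsodyks-Markram)
    tau_glu  = 500, tau_GABA = 500,
    u_glu    = 0.2, u_GABA   = 0.1,

    ## ionic dynamics
    gamma_ion   = 1e-3,   # (mM/ms)/(uA/cm2)
    beta_vol    = 10,     # intra/extracellular volume ratio
    alpha_I     = 0.25,   # interneuron fraction
    I_pump_max  = 0.8,    # uA/cm2
    I_KCC2_max  = 1,      # uA/cm2 (both populations)
    I_NKCC1_max_E = 0,
    I_NKCC1_max_I = 0.1,  # uA/cm2 (I-population only)
    q_Na        = 0.1,    # uC/cm2 Na charge per spike
    frac_K_glu  = 0.2,    # K fraction of glutamatergic conductance
    frac_Na_glu = 0.4,    # Na fraction
    D_bath      = 2.5e-4, # 1/ms (0.25 1/s) bath exchange of K+
    K_bath      = 3.5,    # mM
    D1d         = 0.39,   # um2/ms, extracellular K+ diffusion
    nernst_mV   = 26.6,

    ## initial concentrations (mM)
    K_o0 = 3.5, Cl_o0 = 130, Na_o0 = 130,
    K_i0 = 129, Na_i0 = 17,
    Cl_iE0 = 5, Cl_iI0 = 9,
    HCO3_o = 24, HCO3_i = 16,

    ## calcium (E-cells)
    tau_Ca   = 200,    # ms
    chi_Ca   = 0.001,  # (mM/ms)/(uA/cm2)
    V_Ca     = 20,     # mV
    alpha_KCa = 2000,  # 1/(mM^2 ms)
    beta_KCa  = 0.002, # 1/ms

    ## glial buffer (enabled only in the glial-buffer scenario)
    k1_glia  = 2e-5,  # 1/ms (0.02 1/s)
    B_max    = 500,   # mM
    K_half_glia = 15, # mM, k2 sigmoid midpoint
    K_slope_glia = 1.15, # mM

    ## ECS volume
    tau_v    = 250,    # ms
    beta0_v  = 10,
    v_gain   = 0.1029,
    pi_scale = 20      # mM, osmolarity scale in exp(dpi/20)
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  structure(p, class = "ictal_params")
}
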