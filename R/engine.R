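## Simulation orchestration: noise, holding-current observable and the
## scenario runner wrapping the compiled core.

#' Exact Ornstein-Uhlenbeck update
#'
#' One step of an OU process with correlation time \code{tau} and
#' stationary standard deviation \code{sd}:
#' \code{x' = x e^(-dt/tau) + sd sqrt(1 - e^(-2 dt/tau)) xi}. This is the
#' update used for the interneuron background drive (amplitude 25 pA,
#' correlation time 4 ms, converted to current density by the membrane
#' area).
#'
#' @param x current value.
#' @param dt time step (ms).
#' @param tau correlation time (ms).
#' @param sd stationary standard deviation.
#' @param xi standard-normal increment(s).
#' @return updated value(s).
#' @export
ou_noise_step <- function(x, dt, tau, sd, xi) {
  a <- exp(-dt / tau)
  x * a + sd * sqrt(1 - a^2) * xi
}

#' Synaptic current at a holding voltage
#'
#' Voltage-clamp observable: the synaptic-only current at \code{V_hold}
#' (default -27 mV), \code{I = g_GABA (V_hold - V_GABA) + g_AMPA (V_hold -
#' V_AMPA) + g_NMDA f_NMDA(V_hold) (V_hold - V_NMDA)} (uA/cm2, outward
#' positive). With the GABA reversal below -27 mV, GABAergic events give
#' positive deflections and glutamatergic events negative ones.
#'
#' @param g_AMPA,g_NMDA,g_GABA conductances (mS/cm2); \code{g_NMDA} is the
#'   unblocked maximum times kernel and resource (the Mg block at
#'   \code{V_hold} is applied here).
#' @param V_GABA GABA-A reversal (mV).
#' @param V_hold holding voltage (mV).
#' @param V_AMPA,V_NMDA glutamatergic reversals (mV).
#' @param Mg magnesium concentration (mM).
#' @return clamp current (uA/cm2).
#' @export
holding_current <- function(g_AMPA, g_NMDA, g_GABA, V_GABA, V_hold = -27,
                            V_AMPA = 0, V_NMDA = 0, Mg = 0.25) {
  g_GABA * (V_hold - V_GABA) + g_AMPA * (V_hold - V_AMPA) +
    g_NMDA * nmda_block(V_hold, Mg) * (V_hold - V_NMDA)
}

#' Run an ictal-discharge scenario
#'
#' Integrates the full coupled system: Ornstein-Uhlenbeck noise, spatial
#' convolution of firing rates, synaptic kinetics with depression, CBRD
#' density transport with hazard-function spiking, representative neurons,
#' ionic balances, glial buffer and ECS volume, in that operator order.
#' Deterministic for a fixed seed.
#'
#' @param config an \code{\link{ictal_config}}.
#' @param seed integer RNG seed; defaults to the one stored in the config.
#' @return An object of class \code{"ictal_recording"}: a list with
#'   \code{traces} (data.frame of site observables at S1/S2, including
#'   \code{K_o}, mean voltages, firing rates in Hz, representative-neuron
#'   voltages, the -27 mV holding current and GABA reversals),
#'   \code{fields} (list of space-time matrices: \code{U_E}, \code{K_o},
#'   \code{Cl_iE}, \code{Na_iE}, \code{vol}, \code{nu_E}, \code{nu_I}),
#'   time bases, the spatial grid, diagnostics and the resolved config.
#' @examples
#' \donttest{
#' cfg <- ictal_config("control", duration_s = 5)
#' rec <- run_scenario(cfg, seed = 1)
#' summary(rec)
#' }
#' @export
run_scenario <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ictal_config"))
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  grid <- spatial_grid(config)
  nb <- as.integer(round(config$tstar_max_ms / config$dt_ms))
  nsteps <- as.integer(round(config$duration_s * 1000 / config$dt_ms))
  use_kernel <- config$lambda_um > 0
  kern <- if (use_kernel) connection_kernel(grid$x_um, config$lambda_um)
          else diag(config$nx)
  cfg <- list(
    params = unclass(config$params),
    dt_ms = config$dt_ms,
    nx = config$nx,
    D1d_um2_ms = config$D1d_um2_ms,
    dx_um = grid$dx_um,
    all_to_all_fraction = config$all_to_all_fraction,
    sigma_V_form = config$sigma_V_form,
    pump_model = config$pump_model,
    kcc2_form = config$kcc2_form,
    anchor_baseline = config$anchor_baseline,
    gaba_reversal_literal = config$gaba_reversal_literal,
    glia_on = config$glia_on,
    volume_dynamic = config$volume_dynamic,
    nb = nb,
    nsteps = nsteps,
    trace_stride = as.integer(round(config$trace_stride_ms / config$dt_ms)),
    field_stride = as.integer(round(config$field_stride_ms / config$dt_ms)),
    s1 = grid$s1, s2 = grid$s2,
    seed = as.double(seed),
    kernel = kern,
    use_kernel = use_kernel,
    g_AMPA_E_profile = ampa_gradient_profile(grid$x_um,
                                             config$params$g_AMPA_E,
                                             config$L_um)
  )
  raw <- cpp_run_scenario(cfg)
  if (isTRUE(raw$blown))
    stop(sprintf(
      "numerical blow-up at step %d (t = %.2f s); last valid state dumped",
      raw$blow_step, raw$blow_step * config$dt_ms / 1000))
  traces <- as.data.frame(raw$traces)
  names(traces) <- as.character(raw$trace_names)
  traces <- cbind(time_s = as.numeric(raw$trace_time_s), traces)
  rec <- list(
    traces = traces,
    fields = list(U_E = raw$U_E, K_o = raw$K_o, Cl_iE = raw$Cl_iE,
                  Na_iE = raw$Na_iE, vol = raw$vol, nu_E = raw$nu_E,
                  nu_I = raw$nu_I),
    field_time_s = as.numeric(raw$field_time_s),
    x_mm = grid$x_um / 1000,
    s1 = grid$s1, s2 = grid$s2,
    diagnostics = list(mass_dev_max = raw$mass_dev_max,
                       floor_warnings = raw$floor_warnings,
                       nM_reset = raw$nM_reset,
                       J0 = raw$J0,
                       U_rest_E = raw$U0_E, U_rest_I = raw$U0_I),
    seed = seed,
    config = config
  )
  class(rec) <- "ictal_recording"
  rec
}
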