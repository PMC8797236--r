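#' Scenario configuration for an ictal-discharge simulation
#'
#' Builds a validated configuration describing one in-silico experiment.
#' A scenario preset fixes the spatial-coupling switches; every numeric
#' choice can still be overridden explicitly.
#'
#' Scenario presets:
#' \describe{
#'   \item{control}{Gaussian connections, \code{lambda = 50} um; K+ diffusion
#'     on (\code{D1d = 0.39} um2/ms); dynamic ECS volume; no glia.}
#'   \item{no_diffusion}{control with \code{D1d = 0}.}
#'   \item{local_only}{\code{lambda = 0}: presynaptic rate equals the local
#'     somatic rate.}
#'   \item{high_diffusion}{\code{lambda = 0} and \code{D1d = 390} um2/ms.}
#'   \item{long_connections}{\code{lambda = 250} um.}
#'   \item{all_to_all}{control plus a 0.2 fraction of the presynaptic rate
#'     taken from the domain-mean firing rate.}
#'   \item{fixed_volume}{ECS volume held at 1.}
#'   \item{glial_buffer}{glial K+ buffer enabled.}
#' }
#'
#' @param scenario preset name, see Details.
#' @param duration_s simulated time in seconds.
#' @param dt_ms time step (equal to the time-since-spike bin width).
#' @param nx number of spatial nodes over the domain.
#' @param L_um domain length in micrometers.
#' @param lambda_um Gaussian connection length; \code{NULL} = preset value.
#' @param D1d_um2_ms extracellular K+ diffusion coefficient; \code{NULL} =
#'   preset value.
#' @param all_to_all_fraction fraction of presynaptic rate drawn from the
#'   domain mean; \code{NULL} = preset value.
#' @param volume_dynamic logical; \code{NULL} = preset value.
#' @param glia_on logical; \code{NULL} = preset value.
#' @param tstar_max_ms extent of the time-since-spike grid; the last bin
#'   absorbs all older neurons and is treated as quasi-stationary.
#' @param electrode_frac positions of the two virtual electrodes S1, S2 as
#'   fractions of the domain length.
#' @param trace_stride_ms output stride for site traces.
#' @param field_stride_ms output stride for space-time fields.
#' @param sigma_V_form \code{"sqrt"} (default) or \code{"linear"} scaling of
#'   the hazard noise amplitude with synaptic conductance.
#' @param pump_model \code{"sigmoid"} (double-sigmoid in extracellular K
#'   and intracellular Na, default) or \code{"kinetic"} (full ATPase
#'   cycle).
#' @param kcc2_form \code{"saturating"} (odd saturating flux, default:
#'   K+Cl extrusion at rest, import under pathological [K+]o) or
#'   \code{"literal"} (printed rational form).
#' @param anchor_baseline if TRUE (default), constant correction fluxes
#'   computed once at initialization make the nominal initial state an
#'   exact potassium/sodium flux equilibrium, so the interictal baseline
#'   sits at the nominal concentrations. Chloride is never corrected: its
#'   activity-driven loading is the ignition clock.
#' @param gaba_reversal_literal if TRUE, use the potassium reversal as the
#'   GABA driving force in the population voltage equation (audit mode).
#' @param seed default RNG seed used when \code{\link{run_scenario}} is
#'   called without one.
#' @param params an \code{\link{ictal_params}} object with the biophysical
#'   constants.
#' @return A list of class \code{"ictal_config"}.
#' @examples
#' cfg <- ictal_config("long_connections", duration_s = 10)
#' cfg$lambda_um
#' @export
ictal_config <- function(scenario = c("control", "no_diffusion", "local_only",
                                      "high_diffusion", "long_connections",
                                      "all_to_all", "fixed_volume",
                                      "glial_buffer"),
                         duration_s = 400,
                         dt_ms = 0.5,
                         nx = 64,
                         L_um = 2500,
                         lambda_um = NULL,
                         D1d_um2_ms = NULL,
                         all_to_all_fraction = NULL,
                         volume_dynamic = NULL,
                         glia_on = NULL,
                         tstar_max_ms = 60,
                         electrode_frac = c(0.25, 0.75),
                         trace_stride_ms = 10,
                         field_stride_ms = 100,
                         sigma_V_form = c("sqrt", "linear"),
                         pump_model = c("sigmoid", "kinetic"),
                         kcc2_form = c("saturating", "literal"),
                         anchor_baseline = TRUE,
                         gaba_reversal_literal = FALSE,
                         seed = 1L,
                         params = ictal_params()) {
  scenario <- match.arg(scenario)
  sigma_V_form <- match.arg(sigma_V_form)
  pump_model <- match.arg(pump_model)
  kcc2_form <- match.arg(kcc2_form)
  stopifnot(inherits(params, "ictal_params"))

  preset <- switch(scenario,
    control          = list(lambda = 50,  D1d = params$D1d, frac = 0,
                            vol = TRUE,  glia = FALSE),
    no_diffusion     = list(lambda = 50,  D1d = 0,          frac = 0,
                            vol = TRUE,  glia = FALSE),
    local_only       = list(lambda = 0,   D1d = params$D1d, frac = 0,
                            vol = TRUE,  glia = FALSE),
    high_diffusion   = list(lambda = 0,   D1d = 390,        frac = 0,
                            vol = TRUE,  glia = FALSE),
    long_connections = list(lambda = 250, D1d = params$D1d, frac = 0,
                            vol = TRUE,  glia = FALSE),
    all_to_all       = list(lambda = 50,  D1d = params$D1d, frac = 0.2,
                            vol = TRUE,  glia = FALSE),
    fixed_volume     = list(lambda = 50,  D1d = params$D1d, frac = 0,
                            vol = FALSE, glia = FALSE),
    glial_buffer     = list(lambda = 50,  D1d = params$D1d, frac = 0,
                            vol = TRUE,  glia = TRUE))

  cfg <- list(
    scenario = scenario,
    duration_s = duration_s,
    dt_ms = dt_ms,
    nx = as.integer(nx),
    L_um = L_um,
    lambda_um = if (is.null(lambda_um)) preset$lambda else lambda_um,
    D1d_um2_ms = if (is.null(D1d_um2_ms)) preset$D1d else D1d_um2_ms,
    all_to_all_fraction = if (is.null(all_to_all_fraction)) preset$frac
                          else all_to_all_fraction,
    volume_dynamic = if (is.null(volume_dynamic)) preset$vol
                     else volume_dynamic,
    glia_on = if (is.null(glia_on)) preset$glia else glia_on,
    tstar_max_ms = tstar_max_ms,
    electrode_frac = electrode_frac,
    trace_stride_ms = trace_stride_ms,
    field_stride_ms = field_stride_ms,
    sigma_V_form = sigma_V_form,
    pump_model = pump_model,
    kcc2_form = kcc2_form,
    anchor_baseline = isTRUE(anchor_baseline),
    gaba_reversal_literal = isTRUE(gaba_reversal_literal),
    seed = as.integer(seed),
    params = params
  )
  class(cfg) <- "ictal_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$params
  if (!is.numeric(cfg$dt_ms) || cfg$dt_ms <= 0)
    stop("dt_ms must be positive")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  if (cfg$nx < 8L) stop("nx must be at least 8")
  if (cfg$lambda_um < 0) stop("lambda_um must be nonnegative")
  if (cfg$D1d_um2_ms < 0) stop("D1d_um2_ms must be nonnegative")
  if (cfg$all_to_all_fraction < 0 || cfg$all_to_all_fraction > 1)
    stop("all_to_all_fraction must be in [0, 1]")
  if (cfg$tstar_max_ms < 4 * p$dt_AP)
    stop("tstar_max_ms too small relative to the spike duration")
  dx <- cfg$L_um / (cfg$nx - 1)
  if (cfg$D1d_um2_ms * cfg$dt_ms / dx^2 > 0.5)
    stop(sprintf(
      "diffusion CFL violation: D*dt/dx^2 = %.3f > 0.5 (dx = %.1f um)",
      cfg$D1d_um2_ms * cfg$dt_ms / dx^2, dx))
  ef <- cfg$electrode_frac
  if (length(ef) != 2L || any(ef < 0) || any(ef > 1) || ef[1] == ef[2])
    stop("electrode_frac must be two distinct fractions in [0, 1]")
  if (cfg$trace_stride_ms < cfg$dt_ms || cfg$field_stride_ms < cfg$dt_ms)
    stop("output strides must be at least dt_ms")
  invisible(cfg)
}

#' Spatial grid of a configuration
#'
#' @param cfg an \code{ictal_config}.
#' @return list with node positions \code{x_um}, spacing \code{dx_um} and
#'   electrode node indices \code{s1}, \code{s2} (1-based).
#' @export
spatial_grid <- function(cfg) {
  x <- seq(0, cfg$L_um, length.out = cfg$nx)
  idx <- function(f) which.min(abs(x - f * cfg$L_um))
  s1 <- idx(cfg$electrode_frac[1]); s2 <- idx(cfg$electrode_frac[2])
  list(x_um = x, dx_um = x[2] - x[1], s1 = s1, s2 = s2)
}

#' Load a scenario configuration from a YAML file
#'
#' The file may contain any argument of \code{\link{ictal_config}} plus a
#' \code{params:} block with \code{\link{ictal_params}} overrides. Unknown
#' keys are rejected.
#'
#' @param path path to a YAML file.
#' @return An \code{ictal_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  par_ov <- y$params
  y$params <- NULL
  allowed <- setdiff(names(formals(ictal_config)), "params")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  params <- do.call(ictal_params, as.list(par_ov))
  do.call(ictal_config, c(y, list(params = params)))
}

#' @export
print.ictal_config <- function(x, ...) {
  cat("Ictal-discharge scenario configuration\n")
  cat(sprintf("  scenario: %s   duration: %g s   dt: %g ms\n",
              x$scenario, x$duration_s, x$dt_ms))
  cat(sprintf("  grid: %d nodes over %g mm (dx = %.1f um), t* grid to %g ms\n",
              x$nx, x$L_um / 1000, x$L_um / (x$nx - 1), x$tstar_max_ms))
  cat(sprintf("  lambda = %g um, D1d = %g um2/ms, all-to-all fraction = %g\n",
              x$lambda_um, x$D1d_um2_ms, x$all_to_all_fraction))
  cat(sprintf("  volume %s, glia %s, pump = %s, sigma_V = %s form\n",
              if (x$volume_dynamic) "dynamic" else "fixed",
              if (x$glia_on) "on" else "off", x$pump_model, x$sigma_V_form))
  invisible(x)
}
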