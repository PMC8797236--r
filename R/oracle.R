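## Brute-force references: Monte-Carlo ensemble of individual neurons for
## validating the density approximation, and synthetic fixture generators
## for the analysis layer.

#' Monte-Carlo ensemble firing rate
#'
#' Simulates \code{N} individual neurons with the population's membrane
#' equations and reset convention, each receiving the shared step current
#' and an independent colored voltage noise matching the hazard model's
#' assumptions (correlation time \code{tau_Noise}, quasi-static amplitude
#' shunted by the total conductance). Ion concentrations are frozen at
#' rest, so the comparison with the density model isolates the CBRD
#' approximation itself.
#'
#' @param N ensemble size (>= 1000 recommended for rate comparisons).
#' @param duration_ms simulated time (ms).
#' @param dt time step (ms).
#' @param I_step step-current amplitude (uA/cm2).
#' @param t_on step onset (ms).
#' @param pop \code{"E"} or \code{"I"}.
#' @param seed RNG seed.
#' @param bin_ms width of the rate-counting bins (ms).
#' @param params an \code{\link{ictal_params}} object.
#' @param sigma_V0 optional override of the noise amplitude (mV).
#' @return data.frame with \code{t_ms} (bin centers) and \code{rate_Hz}.
#' @export
monte_carlo_population <- function(N = 4000, duration_ms = 1000, dt = 0.1,
                                   I_step = 1.5, t_on = 200, pop = "E",
                                   seed = 1, bin_ms = 5,
                                   params = ictal_params(),
                                   sigma_V0 = NULL) {
  stopifnot(N >= 1)
  out <- cpp_mc_population(unclass(params), as.integer(N), duration_ms, dt,
                           I_step, t_on, pop == "E", as.double(seed), bin_ms,
                           if (is.null(sigma_V0)) -1 else sigma_V0)
  data.frame(t_ms = as.numeric(out$t_ms), rate_Hz = as.numeric(out$rate_Hz))
}

#' Single-population CBRD rate for a step input
#'
#' Runs one uncoupled CBRD population with frozen ionic concentrations and
#' a shared step current -- the density-model counterpart of
#' \code{\link{monte_carlo_population}}.
#'
#' @inheritParams monte_carlo_population
#' @param tstar_max_ms extent of the time-since-spike grid (ms).
#' @return data.frame with \code{t_ms} and \code{rate_Hz}, plus the
#'   density-mass trace as attribute \code{"mass"}.
#' @export
cbrd_population_rate <- function(duration_ms = 1000, dt = 0.1,
                                 I_step = 1.5, t_on = 200, pop = "E",
                                 tstar_max_ms = 200,
                                 params = ictal_params(),
                                 sigma_V0 = NULL) {
  out <- cpp_cbrd_single(unclass(params), duration_ms, dt, tstar_max_ms,
                         I_step, t_on, pop == "E",
                         if (is.null(sigma_V0)) -1 else sigma_V0)
  df <- data.frame(t_ms = seq_len(length(out$nu_Hz)) * dt,
                   rate_Hz = as.numeric(out$nu_Hz))
  attr(df, "mass") <- as.numeric(out$mass)
  attr(df, "U0") <- out$U0
  df
}

#' Compare two firing-rate traces
#'
#' @param rate_a,rate_b rate traces on a common time base (Hz).
#' @param t_ms common time base (ms).
#' @param transient_cut_ms initial interval excluded from the error norm.
#' @return list with \code{rel_l2} (relative L2 error of b against a),
#'   \code{peak_ratio} and \code{onset_latency_ms} (difference of first
#'   crossings of half the joint peak).
#' @export
compare_rates <- function(rate_a, rate_b, t_ms, transient_cut_ms = 0) {
  stopifnot(length(rate_a) == length(rate_b), length(rate_a) == length(t_ms))
  keep <- t_ms >= transient_cut_ms
  a <- rate_a[keep]; b <- rate_b[keep]
  rel_l2 <- sqrt(sum((a - b)^2)) / sqrt(sum(a^2))
  half <- 0.5 * max(c(rate_a, rate_b))
  on_a <- t_ms[which(rate_a >= half)[1]]
  on_b <- t_ms[which(rate_b >= half)[1]]
  list(rel_l2 = rel_l2,
       peak_ratio = max(b) / max(a),
       onset_latency_ms = if (length(on_a) && length(on_b)) on_b - on_a
                          else NA_real_)
}

#' Synthetic traveling-wave potassium field with known speed
#'
#' Generates a \code{[K]_o}-like space-time field whose sigmoidal front
#' translates at a prescribed speed, optionally followed by a recovery
#' phase and corrupted by additive Gaussian noise. Ground truth is stored
#' in attributes; used to validate the analysis layer.
#'
#' @param speed_mm_s front speed (mm/s), positive. May be a length-2
#'   vector \code{c(v1, v2)}: the front then travels at \code{v1} up to
#'   \code{x_break_mm} and at \code{v2} beyond (piecewise front).
#' @param duration_s,dt_s time extent and sampling.
#' @param L_mm,nx spatial extent and nodes.
#' @param onset_s time the front passes x = 0.
#' @param baseline,amplitude resting level and transient size (mM).
#' @param rise_s 10-90 rise scale of the front (s).
#' @param event_dur_s plateau duration before recovery (s).
#' @param noise_sd additive noise SD (mM).
#' @param seed RNG seed for the noise.
#' @param x_break_mm breakpoint for a piecewise front.
#' @return list with \code{field} (time x nodes), \code{time_s},
#'   \code{x_mm}; attributes carry the ground-truth speed.
#' @export
synthetic_wave <- function(speed_mm_s, duration_s = 60, dt_s = 0.1,
                           L_mm = 2.5, nx = 64, onset_s = 10,
                           baseline = 3.5, amplitude = 10, rise_s = 1,
                           event_dur_s = 25, noise_sd = 0, seed = 1,
                           x_break_mm = L_mm / 2) {
  stopifnot(all(speed_mm_s > 0))
  time_s <- seq(0, duration_s, by = dt_s)
  x_mm <- seq(0, L_mm, length.out = nx)
  arrival <- if (length(speed_mm_s) == 1L) {
    onset_s + x_mm / speed_mm_s
  } else {
    t_break <- onset_s + x_break_mm / speed_mm_s[1]
    ifelse(x_mm <= x_break_mm,
           onset_s + x_mm / speed_mm_s[1],
           t_break + (x_mm - x_break_mm) / speed_mm_s[2])
  }
  field <- matrix(baseline, length(time_s), nx)
  for (j in seq_len(nx)) {
    up <- 1 / (1 + exp(-(time_s - arrival[j]) / (rise_s / 4)))
    down <- 1 / (1 + exp(-(time_s - arrival[j] - event_dur_s) / (rise_s)))
    field[, j] <- baseline + amplitude * up * (1 - down)
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    field <- field + matrix(rnorm(length(field), 0, noise_sd),
                            nrow(field), ncol(field))
    .Random.seed_restore(old)
  }
  out <- list(field = field, time_s = time_s, x_mm = x_mm)
  attr(out, "speed_mm_s") <- speed_mm_s
  attr(out, "arrival_s") <- arrival
  out
}

## preserve the caller's RNG state around fixture generation
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic ion-sensitive electrode voltage trace
#'
#' Inverse of the calibration transform applied to a known potassium
#' trace: \code{V = ln(K / 2.5) / S}; used to test
#' \code{\link{electrode_k}} round-tripping.
#'
#' @param K potassium trace (mM).
#' @param S electrode sensitivity (1/mV).
#' @return voltage trace (mV).
#' @export
synthetic_electrode_trace <- function(K, S = 0.044) {
  electrode_voltage(K, S)
}
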