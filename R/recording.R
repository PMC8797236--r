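## S3 methods for simulation recordings.

#' @export
print.ictal_recording <- function(x, ...) {
  cat("Ictal-discharge simulation recording\n")
  cat(sprintf("  scenario: %s, %g s simulated, seed %d\n",
              x$config$scenario, x$config$duration_s, x$seed))
  cat(sprintf("  %d trace samples at S1/S2, %d field frames over %d nodes\n",
              nrow(x$traces), length(x$field_time_s), length(x$x_mm)))
  cat(sprintf("  max |density mass - 1| = %.2e\n",
              x$diagnostics$mass_dev_max))
  invisible(x)
}

#' Summarize a recording: detected IDs and their characteristics
#'
#' Detects ictal discharges in the S1 potassium trace and reports their
#' onsets, peak \code{[K]_o}, inter-discharge statistics and the minimal
#' ECS volume.
#'
#' @param object an \code{ictal_recording}.
#' @param ... passed to \code{\link{detect_ids}}.
#' @return list with \code{events}, \code{stats}, \code{peak_K_mM} (field
#'   maximum), \code{min_volume}, invisibly printed.
#' @export
summary.ictal_recording <- function(object, ...) {
  ev <- detect_ids(object$traces$K_o_S1, object$traces$time_s, ...)
  st <- id_statistics(list(ev))
  out <- list(events = ev, stats = st$summary,
              peak_K_mM = max(object$fields$K_o),
              min_volume = min(object$fields$vol),
              n_events = nrow(ev))
  cat(sprintf("%d ID(s) detected at S1; field peak [K+]o = %.1f mM; min v = %.2f\n",
              nrow(ev), out$peak_K_mM, out$min_volume))
  if (nrow(ev)) print(ev, row.names = FALSE)
  invisible(out)
}

#' Plot a recording
#'
#' Base-graphics panel: the space-time potassium field and the S1/S2
#' potassium and firing-rate traces.
#'
#' @param x an \code{ictal_recording}.
#' @param ... ignored.
#' @export
plot.ictal_recording <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x$field_time_s, x$x_mm, x$fields$K_o,
                  xlab = "time (s)", ylab = "x (mm)",
                  main = "[K+]o space-time field (mM)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  tr <- x$traces
  graphics::plot(tr$time_s, tr$K_o_S1, type = "l", col = "blue",
                 xlab = "time (s)", ylab = "[K+]o (mM)", main = "S1/S2")
  graphics::lines(tr$time_s, tr$K_o_S2, col = "black")
  graphics::plot(tr$time_s, tr$nu_E_S1, type = "l", col = "red",
                 xlab = "time (s)", ylab = "rate (Hz)",
                 main = "firing rates at S1")
  graphics::lines(tr$time_s, tr$nu_I_S1, col = "darkgreen")
  invisible(x)
}
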