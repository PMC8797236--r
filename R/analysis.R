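## Measurement procedures: electrode calibration, ID detection, wavefront
## speed estimation (half-maximum delay and slowest-fragment slope),
## inter-discharge statistics.

#' Ion-sensitive electrode calibration transform
#'
#' Converts an electrode voltage trace to extracellular potassium
#' concentration, \code{[K]_o = 2.5 exp(S V)}, with sensitivity \code{S}
#' (1/mV). \code{electrode_voltage} is the exact inverse.
#'
#' @param V electrode voltage (mV).
#' @param S sensitivity (1/mV), positive.
#' @return potassium concentration (mM).
#' @examples
#' electrode_k(0)            # 2.5 mM at zero voltage
#' electrode_k(1 / 0.044)    # 2.5 * e
#' @export
electrode_k <- function(V, S = 0.044) {
  stopifnot(S > 0)
  2.5 * exp(S * V)
}

#' @rdname electrode_k
#' @param K potassium concentration (mM), positive.
#' @export
electrode_voltage <- function(K, S = 0.044) {
  stopifnot(S > 0, all(K > 0))
  log(K / 2.5) / S
}

#' Detect ictal discharges in a potassium trace
#'
#' An ID onset is marked when \code{[K]_o} exceeds \code{baseline + thr_on}
#' for at least \code{min_on_s}; the event ends when the trace stays below
#' \code{baseline + thr_off} for at least \code{min_off_s}. The thresholds
#' separate IDs (potassium transients of ~10 mM) from brief interictal
#' events.
#'
#' @param k potassium trace (mM).
#' @param time_s time base (s), monotone.
#' @param baseline resting potassium level (mM).
#' @param thr_on onset threshold above baseline (mM).
#' @param thr_off offset threshold above baseline (mM).
#' @param min_on_s minimum suprathreshold duration to call an onset (s).
#' @param min_off_s minimum subthreshold duration to close an event (s).
#' @return data.frame with one row per ID: \code{onset_s}, \code{offset_s},
#'   \code{peak_mM}, \code{peak_time_s}.
#' @export
detect_ids <- function(k, time_s, baseline = 3.5, thr_on = 3, thr_off = 1,
                       min_on_s = 2, min_off_s = 5) {
  stopifnot(length(k) == length(time_s), !is.unsorted(time_s))
  hi <- k > baseline + thr_on
  lo <- k < baseline + thr_off
  n <- length(k)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (hi[i]) {
      j <- i
      while (j < n && !isTRUE(time_s[j] - time_s[i] >= min_on_s && all(hi[i:j])))
        if (hi[j + 1L]) j <- j + 1L else break
      sustained <- (time_s[j] - time_s[i] >= min_on_s) && all(hi[i:j])
      if (sustained) {
        ## find offset: first index after j from which lo holds for min_off_s
        off <- NA_integer_
        m <- j
        while (m < n) {
          m <- m + 1L
          if (lo[m]) {
            e <- m
            while (e < n && lo[e + 1L] &&
                   time_s[e + 1L] - time_s[m] <= min_off_s + 1e-9)
              e <- e + 1L
            if (time_s[e] - time_s[m] >= min_off_s ||
                (e == n && all(lo[m:n]))) { off <- m; break }
            m <- e
          }
        }
        if (is.na(off)) off <- n
        seg <- i:off
        pk <- seg[which.max(k[seg])]
        events[[length(events) + 1L]] <-
          data.frame(onset_s = time_s[i], offset_s = time_s[off],
                     peak_mM = k[pk], peak_time_s = time_s[pk])
        i <- off + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (!length(events))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_mM = numeric(0), peak_time_s = numeric(0)))
  do.call(rbind, events)
}

## first crossing of half-maximum on the rising phase of one event
half_max_time <- function(k, time_s, onset_s, peak_time_s, baseline) {
  sel <- time_s <= peak_time_s & time_s >= onset_s - 10
  tt <- time_s[sel]; kk <- k[sel]
  peak <- kk[which.max(kk)]
  half <- baseline + 0.5 * (peak - baseline)
  idx <- which(kk >= half)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(tt[1L])
  ## linear interpolation between the bracketing samples
  t0 <- tt[i - 1L]; t1 <- tt[i]
  k0 <- kk[i - 1L]; k1 <- kk[i]
  if (k1 == k0) return(t1)
  t0 + (half - k0) / (k1 - k0) * (t1 - t0)
}

#' Propagation speed from the half-maximum delay between two sites
#'
#' For each ID detected at both sites, the rise of \code{[K]_o} is
#' normalized to its event peak, the first half-maximum crossing is found
#' at each site, and the speed is the electrode separation divided by the
#' time lag. Events with non-positive or unresolved lag are flagged rather
#' than converted to a speed.
#'
#' @param k1,k2 potassium traces at the two sites (mM).
#' @param time_s common time base (s).
#' @param distance_mm electrode separation (mm), positive.
#' @param baseline resting potassium (mM).
#' @param max_pair_gap_s maximum onset difference for pairing events
#'   across sites (s).
#' @param ... further arguments passed to \code{\link{detect_ids}}.
#' @return data.frame with one row per paired event: \code{t_half_1},
#'   \code{t_half_2}, \code{lag_s}, \code{speed_mm_s} (NA when
#'   unresolved), \code{status} (\code{"ok"}, \code{"zero_lag"} or
#'   \code{"failed_to_propagate"} for events missing at one site).
#' @export
speed_from_delay <- function(k1, k2, time_s, distance_mm, baseline = 3.5,
                             max_pair_gap_s = 30, ...) {
  stopifnot(distance_mm > 0)
  e1 <- detect_ids(k1, time_s, baseline = baseline, ...)
  e2 <- detect_ids(k2, time_s, baseline = baseline, ...)
  out <- list()
  used2 <- rep(FALSE, nrow(e2))
  for (i in seq_len(nrow(e1))) {
    d <- abs(e2$onset_s - e1$onset_s[i])
    d[used2] <- Inf
    j <- if (nrow(e2)) which.min(d) else integer(0)
    if (!length(j) || d[j] > max_pair_gap_s) {
      out[[length(out) + 1L]] <- data.frame(
        t_half_1 = NA_real_, t_half_2 = NA_real_, lag_s = NA_real_,
        speed_mm_s = NA_real_, status = "failed_to_propagate")
      next
    }
    used2[j] <- TRUE
    th1 <- half_max_time(k1, time_s, e1$onset_s[i], e1$peak_time_s[i],
                         baseline)
    th2 <- half_max_time(k2, time_s, e2$onset_s[j], e2$peak_time_s[j],
                         baseline)
    lag <- abs(th2 - th1)
    if (!is.finite(lag) || lag <= 0) {
      out[[length(out) + 1L]] <- data.frame(
        t_half_1 = th1, t_half_2 = th2, lag_s = lag,
        speed_mm_s = NA_real_, status = "zero_lag")
    } else {
      out[[length(out) + 1L]] <- data.frame(
        t_half_1 = th1, t_half_2 = th2, lag_s = lag,
        speed_mm_s = distance_mm / lag, status = "ok")
    }
  }
  if (!length(out))
    return(data.frame(t_half_1 = numeric(0), t_half_2 = numeric(0),
                      lag_s = numeric(0), speed_mm_s = numeric(0),
                      status = character(0)))
  do.call(rbind, out)
}

#' Wavefront speed from the slowest fragment of the space-time front
#'
#' The front position during each ID episode is the per-node first
#' crossing time of a fixed \code{[K]_o} threshold. Local front speeds are
#' obtained from linear fits of crossing time against position over a
#' sliding window of nodes; near-simultaneous (apparent-speed) segments
#' above \code{max_speed} are excluded, and the episode speed is the
#' minimum remaining |dx/dt|.
#'
#' @param field space-time potassium field, time in rows, nodes in columns
#'   (mM).
#' @param time_s row time base (s).
#' @param x_mm node positions (mm).
#' @param threshold front-crossing level (mM).
#' @param max_speed apparent-speed cutoff (mm/s).
#' @param window nodes per local fit (>= 3).
#' @param min_gap_s minimum quiet time between episodes (s).
#' @return data.frame with one row per episode: \code{t_start_s},
#'   \code{t_end_s}, \code{speed_mm_s} (NA when no resolvable fragment).
#' @export
speed_from_slope <- function(field, time_s, x_mm, threshold = 6,
                             max_speed = 10, window = 5L, min_gap_s = 5) {
  stopifnot(nrow(field) == length(time_s), ncol(field) == length(x_mm),
            window >= 3L)
  active <- apply(field, 1L, max) > threshold
  if (!any(active))
    return(data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                      speed_mm_s = numeric(0)))
  ## split active samples into episodes separated by >= min_gap_s
  idx <- which(active)
  brk <- which(diff(time_s[idx]) > min_gap_s)
  starts <- c(idx[1L], idx[brk + 1L])
  ends <- c(idx[brk], idx[length(idx)])
  out <- lapply(seq_along(starts), function(e) {
    rows <- starts[e]:ends[e]
    tcross <- vapply(seq_along(x_mm), function(j) {
      above <- field[rows, j] > threshold
      if (!any(above)) return(NA_real_)
      i <- rows[which(above)[1L]]
      if (i == rows[1L]) return(time_s[i])
      k0 <- field[i - 1L, j]; k1 <- field[i, j]
      if (k1 == k0) return(time_s[i])
      time_s[i - 1L] + (threshold - k0) / (k1 - k0) *
        (time_s[i] - time_s[i - 1L])
    }, numeric(1))
    ok <- which(is.finite(tcross))
    speed <- NA_real_
    if (length(ok) >= window) {
      sp <- c()
      for (s in seq_len(length(ok) - window + 1L)) {
        w <- ok[s:(s + window - 1L)]
        ft <- tcross[w]; fx <- x_mm[w]
        if (stats::var(ft) == 0) next   # simultaneous onset
        slope <- stats::cov(fx, ft) / stats::var(ft)   # dx/dt, mm/s
        v <- abs(slope)
        if (is.finite(v) && v <= max_speed) sp <- c(sp, v)
      }
      if (length(sp)) speed <- min(sp)
    }
    data.frame(t_start_s = time_s[starts[e]], t_end_s = time_s[ends[e]],
               speed_mm_s = speed)
  })
  do.call(rbind, out)
}

#' Summary statistics of ictal-discharge characteristics
#'
#' Pools per-run ID events, excluding the first ID of each run, and
#' reports the median and 25-75\% interquartile range of the peak
#' \code{[K]_o} and of the inter-discharge frequency (reciprocal interval
#' between successive onsets at one site).
#'
#' @param events_list list of per-run event data.frames from
#'   \code{\link{detect_ids}}.
#' @param exclude_first drop the first ID of each run (the start-up
#'   transient).
#' @return list with data.frame \code{summary} (one row per
#'   characteristic: median, q25, q75, n) and the pooled vectors
#'   \code{peak_mM}, \code{freq_per_s}, \code{freq_per_min}.
#' @export
id_statistics <- function(events_list, exclude_first = TRUE) {
  if (inherits(events_list, "data.frame")) events_list <- list(events_list)
  peaks <- c(); freqs <- c()
  for (ev in events_list) {
    if (!nrow(ev)) next
    iv <- diff(ev$onset_s)           # interval attributed to later event
    keep <- if (exclude_first && nrow(ev) > 1L) 2L:nrow(ev)
            else seq_len(nrow(ev))
    peaks <- c(peaks, ev$peak_mM[keep])
    if (length(iv)) {
      ivkeep <- if (exclude_first) seq_along(iv) else seq_along(iv)
      freqs <- c(freqs, 1 / iv[ivkeep])
    }
  }
  qs <- function(z) {
    if (!length(z)) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(stats::median(z), stats::quantile(z, 0.25, names = FALSE),
      stats::quantile(z, 0.75, names = FALSE), length(z))
  }
  s <- rbind(peak_K_mM = qs(peaks), freq_per_s = qs(freqs),
             freq_per_min = qs(freqs * 60))
  colnames(s) <- c("median", "q25", "q75", "n")
  list(summary = as.data.frame(s), peak_mM = peaks,
       freq_per_s = freqs, freq_per_min = freqs * 60)
}
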