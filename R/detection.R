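# Band-pass filtering, adaptive-threshold spike detection, active electrodes.

#' Detection parameters
#'
#' Parameters of the acquisition-side analysis: band-pass edges, detection
#' threshold in multiples of the local noise RMS, cutout windows around the
#' spike trough, the rolling window of the noise estimator, the detector dead
#' time, and the activity criterion for electrodes.
#'
#' The cutout is 0.84 ms before and 2.16 ms after the trough; at 12.5 kHz
#' that is 11 pre-trough and 27 post-trough samples (38 samples total, trough
#' at sample 12; the pre window rounds 0.84 ms up to whole samples).
#'
#' @param band Band-pass edges in Hz (default `c(200, 3000)`).
#' @param threshold Detection threshold in multiples of local RMS (default 6).
#' @param pre_ms,post_ms Cutout window before/after the trough (ms).
#' @param rms_window Length of the rolling robust-RMS window in seconds
#'   (default 0.1).
#' @param dead_time_ms Minimum separation of detected events (ms); closer
#'   events are collapsed to the larger-amplitude one.
#' @param active_min_rate Minimum firing rate (spikes/min) for an electrode
#'   to count as active (default 2, inclusive).
#' @param filter_order Butterworth section order per band edge (default 2;
#'   applied forward and backward, giving a 4th-order zero-phase response).
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(band = c(200, 3000), threshold = 6,
                             pre_ms = 0.84, post_ms = 2.16,
                             rms_window = 0.1, dead_time_ms = 1,
                             active_min_rate = 2, filter_order = 2) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop_config("band must be c(low, high) with 0 < low < high")
  check_number(threshold, "threshold", 0, strict_lower = TRUE)
  check_number(pre_ms, "pre_ms", 0, strict_lower = TRUE)
  check_number(post_ms, "post_ms", 0, strict_lower = TRUE)
  check_number(rms_window, "rms_window", 0, strict_lower = TRUE)
  check_number(dead_time_ms, "dead_time_ms", 0, strict_lower = TRUE)
  structure(list(band = band, threshold = threshold, pre_ms = pre_ms,
                 post_ms = post_ms, rms_window = rms_window,
                 dead_time_ms = dead_time_ms,
                 active_min_rate = active_min_rate,
                 filter_order = filter_order),
            class = "detection_params")
}

# Edge pre-warp: a Butterworth band-pass applied forward and backward has its
# combined -3 dB points inside the design band.  Solve (digital-domain, via
# the exact transfer function) for design edges that put the combined -3 dB
# points on the requested band.  Cached per (band, fs, order).
.filter_cache <- new.env(parent = emptyenv())

design_bandpass <- function(sampling_rate, band, order = 2) {
  key <- paste(sampling_rate, band[1], band[2], order, sep = "_")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  if (band[2] >= sampling_rate / 2)
    stop_config("band upper edge must be below the Nyquist frequency")
  gain2 <- function(bf, f) {     # squared magnitude = forward+backward gain
    z <- exp(1i * 2 * pi * f / sampling_rate)
    Mod(sum(bf$b * z^-(seq_along(bf$b) - 1)) /
          sum(bf$a * z^-(seq_along(bf$a) - 1)))^2
  }
  mk <- function(cl, ch) {
    hi <- min(band[2] * ch, 0.999 * sampling_rate / 2)
    signal::butter(order, c(band[1] * cl, hi) / (sampling_rate / 2),
                   type = "pass")
  }
  cl <- stats::uniroot(function(cl) gain2(mk(cl, 1.25), band[1]) - 1 / sqrt(2),
                       c(0.5, 1), tol = 1e-6)$root
  ch <- stats::uniroot(function(ch) gain2(mk(cl, ch), band[2]) - 1 / sqrt(2),
                       c(1, 2), tol = 1e-6)$root
  bf <- mk(cl, ch)
  .filter_cache[[key]] <- bf
  bf
}

#' Zero-phase band-pass filter
#'
#' Filters a voltage trace with a Butterworth band-pass applied forward and
#' backward (zero phase, so spike trough times are not biased).  The design
#' edges are pre-warped so that the combined -3 dB points fall on the
#' requested band edges.
#'
#' @param trace Numeric voltage trace.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Band edges in Hz.
#' @param order Butterworth section order (default 2).
#' @return Filtered trace, same length as the input.
#' @export
bandpass_filter <- function(trace, sampling_rate, band = c(200, 3000),
                            order = 2) {
  bf <- design_bandpass(sampling_rate, band, order)
  # filtfilt needs enough samples for its edge padding (3x filter length)
  if (length(trace) <= 3 * (length(bf$b) + 1))
    stop_config("trace too short to band-pass filter (", length(trace),
                " samples)")
  signal::filtfilt(bf, trace)
}

#' Rolling robust noise RMS estimate
#'
#' Estimates the local noise RMS of a filtered trace per sample as the
#' rolling median absolute value over `rms_window` seconds, scaled by
#' 1/0.6745 to its Gaussian RMS equivalent.  The median is insensitive to
#' the spikes themselves, so the threshold adapts to slow changes in the
#' noise floor without being inflated by neural activity.
#'
#' @param trace Filtered voltage trace.
#' @param sampling_rate Sampling rate in Hz.
#' @param rms_window Window length in seconds (default 0.1).
#' @return Numeric vector of per-sample RMS estimates (all zero for an
#'   all-zero trace).
#' @export
estimate_noise_rms <- function(trace, sampling_rate, rms_window = 0.1) {
  k <- round(rms_window * sampling_rate)
  k <- max(3L, k + (k %% 2 == 0))   # odd window
  if (k >= length(trace)) return(rep(stats::median(abs(trace)) / 0.6745,
                                     length(trace)))
  as.numeric(stats::runmed(abs(trace), k, endrule = "constant")) / 0.6745
}

#' Detect spikes on one electrode trace
#'
#' Adaptive-threshold detection: the band-passed trace is compared against
#' `-threshold x local RMS`; each negative-going crossing is aligned to the
#' local trough within the following dead time, events closer than the dead
#' time are collapsed to the larger-amplitude one, and a fixed cutout window
#' (11 pre + 27 post samples at 12.5 kHz) is extracted around each trough.
#' Cutouts that would overlap a trace edge are discarded.
#'
#' @param trace Raw voltage trace (filtering is applied internally).
#' @param sampling_rate Sampling rate in Hz.
#' @param params A [detection_params()].
#' @param well,electrode,phase Labels attached to the output rows.
#' @param filtered Set `TRUE` if `trace` is already band-passed.
#' @return A `spike_table`: data frame with columns `well`, `electrode`,
#'   `phase`, `time_s` (trough-aligned, seconds from trace start), and
#'   `amplitude` (trough depth, positive), with the waveform cutout matrix in
#'   `attr(, "waveforms")` (one row per event).
#' @export
detect_spikes <- function(trace, sampling_rate, params = detection_params(),
                          well = NA_integer_, electrode = NA_integer_,
                          phase = NA_character_, filtered = FALSE) {
  x <- if (filtered) trace
  else bandpass_filter(trace, sampling_rate, params$band, params$filter_order)
  sigma <- estimate_noise_rms(x, sampling_rate, params$rms_window)
  thr <- params$threshold * sigma
  n <- length(x)
  # pre window rounds up (0.84 ms -> 11 samples); the post window (2.16 ms ->
  # 27 samples) includes the trough sample, so cutouts have pre + post samples
  pre <- ceiling(params$pre_ms * sampling_rate / 1000)
  post <- round(params$post_ms * sampling_rate / 1000)
  dead <- max(1L, round(params$dead_time_ms * sampling_rate / 1000))
  below <- x < -thr & thr > 0
  onsets <- which(below & !c(FALSE, below[-n]))
  troughs <- integer(0)
  amps <- numeric(0)
  for (o in onsets) {
    hi <- min(n, o + dead)
    tr <- o + which.min(x[o:hi]) - 1L
    a <- -x[tr]
    if (length(troughs) && tr - troughs[length(troughs)] < dead) {
      # within dead time of the last kept event: keep the larger
      if (a > amps[length(amps)]) {
        troughs[length(troughs)] <- tr
        amps[length(amps)] <- a
      }
    } else {
      troughs <- c(troughs, tr)
      amps <- c(amps, a)
    }
  }
  keep <- troughs - pre >= 1 & troughs + post - 1 <= n
  troughs <- troughs[keep]
  amps <- amps[keep]
  wf <- if (length(troughs))
    t(vapply(troughs, function(tr) x[(tr - pre):(tr + post - 1L)],
             numeric(pre + post)))
  else matrix(numeric(0), 0, pre + post)
  k <- length(troughs)
  spike_table(
    data.frame(well = rep(well, k), electrode = rep(electrode, k),
               phase = rep(phase, k),
               time_s = (troughs - 1) / sampling_rate, amplitude = amps,
               stringsAsFactors = FALSE),
    waveforms = wf
  )
}

#' Construct a spike table
#'
#' A spike table is a data frame with columns `well`, `electrode`, `phase`,
#' `time_s`, `amplitude` (and optionally `unit_id`), with an aligned waveform
#' cutout matrix carried in `attr(, "waveforms")`.
#'
#' @param df Data frame of events.
#' @param waveforms Optional matrix, one row per event.
#' @return Object of class `spike_table`.
#' @export
spike_table <- function(df, waveforms = NULL) {
  rownames(df) <- NULL
  if (!is.null(waveforms)) {
    if (nrow(waveforms) != nrow(df))
      stop_schema("waveform matrix rows (", nrow(waveforms),
                  ") do not match events (", nrow(df), ")")
    attr(df, "waveforms") <- waveforms
  }
  class(df) <- unique(c("spike_table", class(df)))
  df
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf("spike_table: %d events", nrow(x)))
  if (!is.null(attr(x, "waveforms")))
    cat(sprintf(" (+ %d-sample cutouts)", ncol(attr(x, "waveforms"))))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# rbind spike tables preserving the waveform sidecar
bind_spike_tables <- function(tables) {
  tables <- Filter(function(t) !is.null(t), tables)
  if (!length(tables)) return(spike_table(data.frame(
    well = integer(0), electrode = integer(0), phase = character(0),
    time_s = numeric(0), amplitude = numeric(0))))
  wfs <- lapply(tables, attr, "waveforms")
  df <- do.call(rbind, lapply(tables, as.data.frame))
  wf <- if (all(!vapply(wfs, is.null, TRUE))) {
    wfs <- wfs[vapply(wfs, nrow, 1L) > 0]
    if (length(wfs)) do.call(rbind, wfs)
    else matrix(numeric(0), 0, 0)
  } else NULL
  spike_table(df, wf)
}

#' Detect spikes across a whole recording
#'
#' Runs [detect_spikes()] on every trace of an [render_voltage_traces()]
#' recording and binds the results.
#'
#' @param recording An `mea_recording`.
#' @param params A [detection_params()].
#' @return A `spike_table` covering all electrodes and phases.
#' @export
detect_recording <- function(recording, params = detection_params()) {
  stopifnot(inherits(recording, "mea_recording"))
  out <- list()
  for (ph in names(recording$traces)) {
    for (key in names(recording$traces[[ph]])) {
      we <- as.integer(strsplit(sub("^w", "", key), "e")[[1]])
      out[[paste(ph, key)]] <- detect_spikes(
        recording$traces[[ph]][[key]], recording$sampling_rate, params,
        well = we[1], electrode = we[2], phase = ph)
    }
  }
  bind_spike_tables(out)
}

#' Active-electrode criterion
#'
#' An electrode is active when it fires at least `min_rate` spikes per minute
#' (inclusive) during the phase.
#'
#' @param spikes A `spike_table` (one phase).
#' @param duration Phase duration in seconds.
#' @param electrodes Optional data frame of all `well`, `electrode` pairs to
#'   report (electrodes without spikes are then included as inactive).
#' @param min_rate Activity threshold in spikes/min (default 2).
#' @return Data frame `well`, `electrode`, `n_spikes`, `rate_per_min`,
#'   `active`.
#' @export
active_electrodes <- function(spikes, duration, electrodes = NULL,
                              min_rate = 2) {
  if (duration <= 0) stop_config("duration must be positive")
  counts <- stats::aggregate(
    list(n_spikes = rep(1L, nrow(spikes))),
    by = list(well = spikes$well, electrode = spikes$electrode), FUN = sum)
  if (!is.null(electrodes)) {
    counts <- merge(electrodes[, c("well", "electrode")], counts,
                    by = c("well", "electrode"), all.x = TRUE)
    counts$n_spikes[is.na(counts$n_spikes)] <- 0L
  }
  counts <- counts[order(counts$well, counts$electrode), , drop = FALSE]
  counts$rate_per_min <- counts$n_spikes / (duration / 60)
  counts$active <- counts$rate_per_min >= min_rate
  rownames(counts) <- NULL
  counts
}
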