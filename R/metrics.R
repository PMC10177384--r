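# Well-level activity and synchrony metrics: bursts, wMFR, network bursts.

#' Burst-detection parameters (ISI threshold method)
#'
#' @param max_isi_ms Maximum inter-spike interval inside a burst (default
#'   100 ms).
#' @param min_spikes Minimum number of contributing spikes (default 5).
#' @return Object of class `burst_params`.
#' @export
burst_params <- function(max_isi_ms = 100, min_spikes = 5) {
  check_number(max_isi_ms, "max_isi_ms", 0, strict_lower = TRUE)
  check_number(min_spikes, "min_spikes", 2)
  structure(list(max_isi_ms = max_isi_ms,
                 min_spikes = as.integer(min_spikes)),
            class = "burst_params")
}

#' Detect bursts on one electrode (ISI threshold)
#'
#' A burst is a maximal run of consecutive spikes whose inter-spike intervals
#' are all at most `max_isi_ms` and which contains at least `min_spikes`
#' spikes.  Runs are greedy-maximal: a run ends at the first interval above
#' the threshold.
#'
#' @param times Sorted spike times in seconds.
#' @param params A [burst_params()].
#' @return Data frame `start`, `end` (times of the first/last spike),
#'   `n_spikes`; zero rows when no burst is found.
#' @export
detect_bursts <- function(times, params = burst_params()) {
  if (is.unsorted(times)) stop_schema("spike times must be sorted ascending")
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  n <- length(times)
  if (n < params$min_spikes) return(empty)
  ok <- diff(times) <= params$max_isi_ms / 1000
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= params$min_spikes - 1L
  if (!any(sel)) return(empty)
  i0 <- starts[sel]              # index of first ISI in run
  i1 <- ends[sel] + 1L           # index of last spike in run
  data.frame(start = times[i0], end = times[i1],
             n_spikes = i1 - i0 + 1L)
}

#' Weighted mean firing rate of a well
#'
#' The weighted mean firing rate (wMFR) is the total number of spikes on
#' active electrodes divided by the phase duration and the number of active
#' electrodes, i.e. the mean firing rate of the well's active electrodes.
#' Zero when no electrode is active.
#'
#' @param spikes A `spike_table` restricted to one well and phase.
#' @param active Data frame from [active_electrodes()] for the same well and
#'   phase.
#' @param duration Phase duration in seconds.
#' @return wMFR in Hz.
#' @export
wmfr <- function(spikes, active, duration) {
  act <- active[active$active, , drop = FALSE]
  if (nrow(act) == 0) return(0)
  on_active <- interaction(spikes$well, spikes$electrode) %in%
    interaction(act$well, act$electrode)
  sum(on_active) / (duration * nrow(act))
}

#' Network-burst detection parameters (envelope method)
#'
#' The four headline parameters (threshold factor, minimum inter-burst
#' interval, minimum participating-electrode fraction, burst-inclusion
#' fraction) plus the internals of the envelope construction, which are
#' exposed so runs are fully reproducible: histogram bin width, Gaussian
#' smoothing width, and the per-electrode burst parameters used for the
#' participation rule.
#'
#' @param threshold_factor Envelope threshold as a multiple of the phase-mean
#'   envelope (default 1.25).
#' @param min_ibi_ms Candidate bursts separated by less than this are merged
#'   (default 100 ms).
#' @param min_participation Minimum fraction of the well's electrodes that
#'   must burst during the network burst (default 0.35; the denominator is
#'   all electrodes in the well).
#' @param burst_inclusion Fraction of the candidate's spikes retained when
#'   tightening boundaries (default 0.75; trimmed equally from both tails).
#' @param bin_width_ms Envelope histogram bin width (default 25 ms).
#' @param smoothing_sigma Gaussian smoothing width in bins (default 1).
#' @param burst A [burst_params()] for the per-electrode bursts that define
#'   participation.
#' @return Object of class `network_burst_params`.
#' @export
network_burst_params <- function(threshold_factor = 1.25, min_ibi_ms = 100,
                                 min_participation = 0.35,
                                 burst_inclusion = 0.75, bin_width_ms = 25,
                                 smoothing_sigma = 1,
                                 burst = burst_params()) {
  check_number(threshold_factor, "threshold_factor", 0, strict_lower = TRUE)
  check_number(min_participation, "min_participation", 0, 1,
               strict_lower = TRUE)
  check_number(burst_inclusion, "burst_inclusion", 0, 1, strict_lower = TRUE)
  structure(list(threshold_factor = threshold_factor,
                 min_ibi_ms = min_ibi_ms,
                 min_participation = min_participation,
                 burst_inclusion = burst_inclusion,
                 bin_width_ms = bin_width_ms,
                 smoothing_sigma = smoothing_sigma, burst = burst),
            class = "network_burst_params")
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Detect network bursts in one well (envelope method)
#'
#' Builds the well's population-rate envelope (all spikes binned at
#' `bin_width_ms` and smoothed with a discrete Gaussian), thresholds it at
#' `threshold_factor` times the phase-mean envelope, and treats contiguous
#' supra-threshold intervals as candidates.  A candidate is kept when the
#' electrodes with an ISI burst overlapping it make up at least
#' `min_participation` of the well's electrodes (network bursts are episodes
#' of simultaneous bursting, so participation is defined by bursting
#' electrodes, not stray single spikes).  Kept candidates separated by less
#' than `min_ibi_ms` are merged, boundaries are tightened to the smallest
#' interval holding `burst_inclusion` of the candidate's spikes (trimming
#' equally from both tails), and participation is re-checked on the
#' tightened interval.
#'
#' @param spikes A `spike_table` restricted to one well and phase.
#' @param n_electrodes Number of electrodes in the well (participation
#'   denominator).
#' @param duration Phase duration in seconds.
#' @param params A [network_burst_params()].
#' @return Data frame `start`, `end`, `n_spikes`, `n_electrodes`
#'   (participating), zero rows if none.
#' @export
detect_network_bursts <- function(spikes, n_electrodes, duration,
                                  params = network_burst_params()) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0))
  if (nrow(spikes) == 0) return(empty)
  bw <- params$bin_width_ms / 1000
  edges <- seq(0, duration + bw, by = bw)
  counts <- graphics::hist(spikes$time_s, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  kern <- gaussian_kernel(params$smoothing_sigma)
  r <- (length(kern) - 1L) / 2L
  padded <- c(numeric(r), counts, numeric(r))
  env <- stats::convolve(padded, rev(kern), type = "filter")
  thr <- params$threshold_factor * mean(env)
  supra <- env > thr
  if (!any(supra)) return(empty)
  rl <- rle(supra)
  hi <- cumsum(rl$lengths)
  lo <- hi - rl$lengths + 1L
  cand <- cbind(start = (lo[rl$values] - 1) * bw, end = hi[rl$values] * bw)
  # per-electrode bursts for the participation rule
  key <- paste(spikes$well, spikes$electrode)
  ebursts <- lapply(split(spikes$time_s, key),
                    function(tt) detect_bursts(sort(tt), params$burst))
  participation <- function(s, e) {
    sum(vapply(ebursts, function(b)
      any(b$start <= e & b$end >= s), logical(1)))
  }
  np <- vapply(seq_len(nrow(cand)),
               function(i) participation(cand[i, 1], cand[i, 2]), numeric(1))
  keep <- np / n_electrodes >= params$min_participation
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # merge kept candidates separated by < min_ibi
  merged <- list(cand[1, ])
  for (i in seq_len(nrow(cand))[-1]) {
    last <- merged[[length(merged)]]
    if (cand[i, 1] - last[2] < params$min_ibi_ms / 1000)
      merged[[length(merged)]] <- c(last[1], cand[i, 2])
    else merged[[length(merged) + 1L]] <- cand[i, ]
  }
  out <- empty
  tt_all <- sort(spikes$time_s)
  for (iv in merged) {
    tt <- tt_all[tt_all >= iv[1] & tt_all < iv[2]]
    n <- length(tt)
    if (n == 0) next
    m <- ceiling(params$burst_inclusion * n)
    left <- (n - m) %/% 2L
    kept <- tt[(left + 1L):(left + m)]
    s <- kept[1]; e <- kept[m]
    np <- participation(s, e)
    if (np / n_electrodes < params$min_participation) next
    ns <- sum(spikes$time_s >= s & spikes$time_s <= e)
    out <- rbind(out, data.frame(start = s, end = e, n_spikes = ns,
                                 n_electrodes = np))
  }
  rownames(out) <- NULL
  out
}

#' Summarize one well and phase
#'
#' Combines detection, burst, and network-burst output into the standard
#' well-level metric row: active-electrode count, weighted mean firing rate,
#' burst frequency (bursts on active electrodes per second of recording),
#' network-burst frequency, and the network-burst percentage (share of the
#' well's spikes that fall inside network bursts).
#'
#' @param spikes `spike_table` for the well and phase.
#' @param active [active_electrodes()] output for the same well/phase.
#' @param bursts Data frame of all electrode bursts in the well (needs an
#'   `electrode` column if bursts from inactive electrodes are present).
#' @param network_bursts [detect_network_bursts()] output.
#' @param duration Phase duration in seconds.
#' @return One-row data frame with the metric columns; when the well has no
#'   spikes the percentage is 0 and `no_spikes` is `TRUE`.
#' @export
summarize_well <- function(spikes, active, bursts, network_bursts, duration) {
  n_active <- sum(active$active)
  in_nb <- if (nrow(network_bursts) && nrow(spikes))
    vapply(spikes$time_s, function(t)
      any(t >= network_bursts$start & t <= network_bursts$end), logical(1))
  else logical(nrow(spikes))
  data.frame(
    active_electrodes = n_active,
    wmfr = wmfr(spikes, active, duration),
    burst_frequency = nrow(bursts) / duration,
    network_burst_frequency = nrow(network_bursts) / duration,
    network_burst_percentage =
      if (nrow(spikes)) 100 * sum(in_nb) / nrow(spikes) else 0,
    no_spikes = nrow(spikes) == 0
  )
}

#' Well-level metrics for every well and phase
#'
#' Convenience wrapper running the active-electrode rule, burst detection on
#' active electrodes, network-burst detection, and [summarize_well()] for
#' every well and phase of a spike table.
#'
#' @param spikes A `spike_table` (any number of wells/phases).
#' @param plate A [plate_config()] (electrode denominator per well).
#' @param plan A [phase_plan()] (phase durations).
#' @param params A [detection_params()] (activity rule).
#' @param bparams A [burst_params()].
#' @param nparams A [network_burst_params()].
#' @return Data frame, one row per well and phase, with the columns of
#'   [summarize_well()] plus `well` and `phase`.
#' @export
well_metrics <- function(spikes, plate, plan,
                         params = detection_params(),
                         bparams = burst_params(),
                         nparams = network_burst_params()) {
  out <- list()
  for (ph in plan$phase) {
    dur <- phase_duration(plan, ph)
    for (w in sort(unique(spikes$well))) {
      ws <- spikes[spikes$well == w & spikes$phase == ph, , drop = FALSE]
      all_e <- data.frame(well = w,
                          electrode = seq_len(plate$electrodes_per_well))
      act <- active_electrodes(ws, dur, electrodes = all_e,
                               min_rate = params$active_min_rate)
      act_keys <- paste(act$well, act$electrode)[act$active]
      bl <- lapply(split(ws$time_s, paste(ws$well, ws$electrode)),
                   function(tt) detect_bursts(sort(tt), bparams))
      bl <- bl[names(bl) %in% act_keys]
      bursts <- if (length(bl)) do.call(rbind, bl)
    else data.frame(start = numeric(0), end = numeric(0),
                    n_spikes = integer(0))
      nb <- detect_network_bursts(ws, plate$electrodes_per_well, dur,
                                  nparams)
      row <- summarize_well(ws, act, bursts, nb, dur)
      out[[paste(ph, w)]] <- cbind(data.frame(well = w, phase = ph), row)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
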