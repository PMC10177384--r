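# Shared fixture builders and independent oracles.

# Brute-force maximal-run burst oracle: linear scan, one spike at a time.
# Independent of the rle-based implementation in the package.
oracle_bursts <- function(times, max_isi_s = 0.1, min_spikes = 5) {
  res <- data.frame(start = numeric(0), end = numeric(0),
                    n_spikes = integer(0))
  n <- length(times)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1] - times[j] <= max_isi_s) j <- j + 1L
    if (j - i + 1L >= min_spikes)
      res <- rbind(res, data.frame(start = times[i], end = times[j],
                                   n_spikes = j - i + 1L))
    i <- j + 1L
  }
  res
}

# Random spike train mixing Poisson background with occasional dense runs.
random_train <- function(n_spikes, duration = 60, p_dense = 0.3) {
  tt <- sort(runif(n_spikes, 0, duration))
  if (runif(1) < p_dense && n_spikes >= 10) {
    k <- sample(5:min(30, n_spikes), 1)
    t0 <- runif(1, 0, duration * 0.8)
    tt <- sort(c(tt, t0 + cumsum(runif(k, 0.005, 0.08))))
  }
  tt
}

# Synchronous volley fixture: `n_electrodes` electrodes fire `spikes_per`
# spikes over `width` seconds, every `period` seconds, on silent background.
volley_spikes <- function(duration = 60, period = 2, n_electrodes = 8,
                          spikes_per = 20, width = 0.05, well = 1,
                          t0 = 1) {
  centers <- seq(t0, duration - period / 2, by = period)
  rows <- list()
  for (v in centers) for (e in seq_len(n_electrodes)) {
    tt <- v + seq(0, width, length.out = spikes_per)
    rows[[paste(v, e)]] <- data.frame(well = well, electrode = e,
                                      phase = "baseline1", time_s = tt)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$time_s, df$electrode), ]
  rownames(df) <- NULL
  list(spikes = spike_table(df), n_volleys = length(centers))
}

# Homogeneous Poisson well: `n_electrodes` independent electrodes at `rate`
# Hz each.
poisson_well_spikes <- function(duration = 300, n_electrodes = 8, rate = 2,
                                well = 1) {
  rows <- lapply(seq_len(n_electrodes), function(e) {
    n <- rpois(1, rate * duration)
    data.frame(well = well, electrode = e, phase = "baseline1",
               time_s = sort(runif(n, 0, duration)))
  })
  spike_table(do.call(rbind, rows))
}

# Three distinguishable unit shapes for waveform-level sorting fixtures.
shape_units <- function(k, amplitude = c(9, 10.5, 12)) {
  shapes <- data.frame(trough_width_ms = c(0.24, 0.48, 0.34),
                       peak_ratio = c(0.30, 0.65, 0.50))
  out <- shapes[seq_len(k), , drop = FALSE]
  out$amplitude <- amplitude[seq_len(k)]
  out
}

# Loglik trace monotone within segments (pruning/consolidation restarts
# excluded).
loglik_monotone <- function(fit, slack = 1e-8) {
  ll <- fit$loglik
  if (length(ll) < 2) return(TRUE)
  d <- diff(ll)
  bad <- which(d < -slack * (abs(ll[-length(ll)]) + 1))
  all(bad %in% fit$restarted_at)
}
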