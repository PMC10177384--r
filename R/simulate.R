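# Ground-truth simulator: spike trains, waveform templates, voltage traces.

#' Biphasic extracellular spike waveform template
#'
#' Generates a canonical extracellular action-potential shape: a narrow
#' negative trough followed by a broader positive overshoot, with ~3 ms
#' support.  Templates are parameterized by the trough width and the
#' peak/trough amplitude ratio so that distinct units on one electrode can be
#' given distinguishable shapes.  The template is normalized so the trough
#' equals -1; multiplying by a positive amplitude expresses the spike height
#' in multiples of the noise RMS.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param trough_width_ms Full width at half maximum of the negative trough
#'   (milliseconds).
#' @param peak_ratio Amplitude of the positive overshoot relative to the
#'   trough depth (0..1).
#' @param duration_ms Template support in milliseconds (default 3).
#' @param trough_at_ms Position of the trough within the template (default 1).
#' @return Numeric vector of template samples with `min(template) == -1`.
#' @examples
#' w <- spike_template(12500, trough_width_ms = 0.3, peak_ratio = 0.5)
#' min(w)  # -1
#' @export
spike_template <- function(sampling_rate, trough_width_ms = 0.3,
                           peak_ratio = 0.5, duration_ms = 3,
                           trough_at_ms = 1) {
  check_number(trough_width_ms, "trough_width_ms", 0, strict_lower = TRUE)
  check_number(peak_ratio, "peak_ratio", 0, 1)
  t_ms <- (seq_len(round(duration_ms * sampling_rate / 1000)) - 1) /
    sampling_rate * 1000
  sd_t <- trough_width_ms / 2.355          # FWHM -> gaussian sd
  t_peak <- trough_at_ms + 1.6 * trough_width_ms
  sd_p <- 2 * sd_t
  w <- -exp(-(t_ms - trough_at_ms)^2 / (2 * sd_t^2)) +
    peak_ratio * exp(-(t_ms - t_peak)^2 / (2 * sd_p^2))
  w / abs(min(w))
}

# Distinct (trough width, peak ratio) pairs assigned to successive units on
# one electrode; spacing chosen so waveform clusters are separable in feature
# space at the amplitudes the simulator uses.
unit_shape_defaults <- function(i) {
  shapes <- list(c(0.24, 0.30), c(0.48, 0.65), c(0.34, 0.50),
                 c(0.60, 0.40), c(0.20, 0.55))
  shapes[[((i - 1) %% length(shapes)) + 1]]
}

#' Generate a ground-truth unit population for a plate
#'
#' Draws a population of simulated units (putative neurons) across the wells
#' and electrodes of a plate.  Each unit carries a neuronal subtype (which
#' determines its pharmacological response via a [modulation_table()]), a
#' baseline firing rate, two-state burstiness parameters, a waveform shape,
#' and an amplitude in multiples of the noise RMS.
#'
#' @param plate A [plate_config()].
#' @param units_per_electrode Number of units per electrode (recycled or a
#'   range `c(min, max)` sampled per electrode).
#' @param subtype_probs Named probability vector over subtypes
#'   (`glutamatergic`, `GABAergic_mature`, `GABAergic_immature`,
#'   `dopaminergic`, `serotonergic`, `cholinergic`, `nonresponsive`).
#' @param base_rate_range Range of baseline firing rates in Hz, sampled
#'   log-uniformly (default 0.5 to 3 Hz, typical of hiPSC-derived cultures).
#' @param amplitude_range Range of spike amplitudes in multiples of noise RMS.
#' @param p_burst Probability that a tonic spike initiates a burst epoch.
#' @param burst_mean Mean number of extra spikes per burst epoch.
#' @param seed Integer seed.
#' @return A data frame of class `ground_truth_units`, one row per unit, with
#'   columns `unit_id`, `well`, `electrode`, `subtype`, `base_rate`,
#'   `amplitude`, `p_burst`, `burst_mean`, `trough_width_ms`, `peak_ratio`.
#' @export
generate_units <- function(plate, units_per_electrode = 2,
                           subtype_probs = c(glutamatergic = 0.3,
                                             GABAergic_mature = 0.2,
                                             GABAergic_immature = 0.2,
                                             dopaminergic = 0.1,
                                             serotonergic = 0.1,
                                             cholinergic = 0.05,
                                             nonresponsive = 0.05),
                           base_rate_range = c(0.5, 3),
                           amplitude_range = c(8, 12),
                           p_burst = 0.1, burst_mean = 5,
                           seed = 1) {
  stopifnot(inherits(plate, "plate_config"))
  if (any(subtype_probs < 0) || sum(subtype_probs) <= 0)
    stop_config("subtype_probs must be non-negative with positive sum")
  subtype_probs <- subtype_probs / sum(subtype_probs)
  with_local_seed(seed, {
    rows <- list()
    uid <- 0L
    for (w in seq_len(plate$n_wells)) {
      for (e in seq_len(plate$electrodes_per_well)) {
        k <- if (length(units_per_electrode) == 2)
          sample(units_per_electrode[1]:units_per_electrode[2], 1)
        else units_per_electrode
        for (i in seq_len(k)) {
          uid <- uid + 1L
          shape <- unit_shape_defaults(i)
          rows[[uid]] <- data.frame(
            unit_id = uid, well = w, electrode = e,
            subtype = sample(names(subtype_probs), 1, prob = subtype_probs),
            base_rate = exp(runif(1, log(base_rate_range[1]),
                                  log(base_rate_range[2]))),
            amplitude = runif(1, amplitude_range[1], amplitude_range[2]),
            p_burst = p_burst, burst_mean = burst_mean,
            trough_width_ms = shape[1] * runif(1, 0.95, 1.05),
            peak_ratio = shape[2] * runif(1, 0.95, 1.05),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("ground_truth_units", "data.frame")
    out
  })
}

#' Subtype-by-agent rate modulation table
#'
#' Maps (subtype, agent) pairs to multiplicative firing-rate factors applied
#' during the corresponding phases of a simulation.  A multiplier of 1 leaves
#' the unit unaffected.  Optionally a `concentration` column restricts an
#' entry to one cumulative concentration; entries with `NA` concentration
#' apply to all concentrations of that agent.
#'
#' @param subtype,agent,multiplier Vectors defining the mapping.
#' @param concentration Optional concentration-specific entries (uM).
#' @return Data frame of class `modulation_table`.
#' @seealso [default_modulation_table()]
#' @export
modulation_table <- function(subtype, agent, multiplier,
                             concentration = NA_real_) {
  df <- data.frame(subtype = as.character(subtype),
                   agent = as.character(agent),
                   concentration = as.numeric(concentration),
                   multiplier = as.numeric(multiplier),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$multiplier)) || any(df$multiplier <= 0))
    stop_config("multipliers must be positive and finite")
  if (any(df$subtype == "nonresponsive" & df$multiplier != 1))
    stop_config("nonresponsive units must have multiplier 1")
  structure(df, class = c("modulation_table", "data.frame"))
}

#' Default pharmacological modulation table
#'
#' Encodes the expected direction of each identification agent on its target
#' subtype: glutamate excites glutamatergic units while the NMDA/AMPA
#' antagonist mix AP5/NBQX suppresses them; GABA suppresses mature (post
#' GABA-switch) GABAergic units and excites immature ones, with the GABA-A
#' antagonists bicuculline and picrotoxin acting in the opposite directions;
#' the D2 antagonist haloperidol disinhibits dopaminergic-input units; the
#' 5-HT1A agonist buspirone suppresses serotonergic units; carbaryl
#' suppresses cholinergic units (net nicotinic-receptor effect).  Test
#' compounds: TMT (a glutamate-release enhancer) excites glutamatergic units;
#' the GABA-receptor agonist emamectin suppresses GABAergic units.
#'
#' @param strength Fold strength of "up" responses (default 2); "down"
#'   responses use `1/strength` scaled to 0.3/0.5 per agent below.
#' @return A [modulation_table()].
#' @export
default_modulation_table <- function(strength = 2) {
  modulation_table(
    subtype = c("glutamatergic", "glutamatergic",
                "GABAergic_mature", "GABAergic_mature", "GABAergic_mature",
                "GABAergic_immature", "GABAergic_immature",
                "GABAergic_immature",
                "dopaminergic", "serotonergic", "cholinergic",
                "glutamatergic", "GABAergic_mature", "GABAergic_immature"),
    agent = c("glutamate", "AP5/NBQX",
              "GABA", "bicuculline", "picrotoxin",
              "GABA", "bicuculline", "picrotoxin",
              "haloperidol", "buspirone", "carbaryl",
              "TMT", "emamectin", "emamectin"),
    multiplier = c(strength, 0.3,
                   0.5, strength, strength,
                   strength, 0.5, 0.5,
                   strength, 0.5, 0.5,
                   strength, 0.4, 0.4)
  )
}

# Multiplier lookup with the documented fall-through: exact
# (subtype, agent, concentration) entry, then (subtype, agent, NA), then 1 if
# the agent is known to the table for some other subtype; an agent absent from
# the table entirely is a configuration error.
modulation_multiplier <- function(modulation, subtype, agent, concentration) {
  if (is.na(agent)) return(1)
  rows <- modulation$agent == agent
  if (!any(rows))
    stop_config("agent '", agent, "' has no modulation entry; add it to the ",
                "modulation table (multiplier 1 for no effect)")
  m <- modulation[rows & modulation$subtype == subtype, , drop = FALSE]
  if (nrow(m) == 0) return(1)
  exact <- m[!is.na(m$concentration) & m$concentration == concentration, ,
             drop = FALSE]
  if (nrow(exact) > 0) return(exact$multiplier[1])
  any_c <- m[is.na(m$concentration), , drop = FALSE]
  if (nrow(any_c) > 0) return(any_c$multiplier[1])
  1
}

# Two-state renewal spike train: tonic inter-spike intervals are a 2 ms
# refractory floor plus an exponential tail; each tonic spike initiates, with
# probability p_burst, a burst epoch of Poisson(burst_mean) extra spikes at
# 10-30 ms intervals.  The tonic mean interval is solved so the overall mean
# rate equals `rate`.
simulate_train <- function(rate, duration, p_burst = 0.1, burst_mean = 5,
                           refractory = 0.002,
                           burst_isi_range = c(0.01, 0.03)) {
  if (rate <= 0) stop_config("rate must be positive")
  if (duration <= 0) stop_config("duration must be positive")
  mean_burst_isi <- mean(burst_isi_range)
  spikes_per_motif <- 1 + p_burst * burst_mean
  motif_time <- spikes_per_motif / rate
  tonic_mean <- motif_time - p_burst * burst_mean * mean_burst_isi
  if (tonic_mean <= refractory)
    stop_config("rate ", rate, " Hz is unattainably high for the requested ",
                "burstiness and 2 ms refractory period")
  times <- numeric(0)
  t <- 0
  n_guess <- max(16L, ceiling(duration / motif_time * 1.5))
  while (t < duration) {
    isi <- refractory + stats::rexp(n_guess, 1 / (tonic_mean - refractory))
    nb <- if (p_burst > 0) stats::rpois(n_guess, burst_mean) *
      (stats::runif(n_guess) < p_burst) else integer(n_guess)
    for (j in seq_len(n_guess)) {
      t <- t + isi[j]
      if (t >= duration) break
      times <- c(times, t)
      if (nb[j] > 0) {
        bisi <- stats::runif(nb[j], burst_isi_range[1], burst_isi_range[2])
        bt <- t + cumsum(bisi)
        bt <- bt[bt < duration]
        times <- c(times, bt)
        if (length(bt)) t <- bt[length(bt)]
      }
    }
  }
  times
}

#' Simulate ground-truth spike trains for a plate
#'
#' Draws one spike train per unit per phase from the unit's two-state firing
#' model, with the rate scaled by the modulation multiplier of the unit's
#' subtype under the phase's agent and concentration.  A 2 ms refractory
#' period is enforced by construction.  Reproducible: each unit-phase stream
#' derives its own seed from `seed`.
#'
#' @param plate A [plate_config()].
#' @param units A `ground_truth_units` data frame ([generate_units()]).
#' @param phases A [phase_plan()].
#' @param modulation A [modulation_table()] (default
#'   [default_modulation_table()]).
#' @param seed Integer seed.
#' @return An object of class `mea_ground_truth`: a list with elements
#'   `units`, `spikes` (data frame `unit_id`, `well`, `electrode`, `phase`,
#'   `time_s`), `plate`, `phases`, `modulation`, `seed`.
#' @export
simulate_spike_trains <- function(plate, units, phases,
                                  modulation = default_modulation_table(),
                                  seed = 1) {
  stopifnot(inherits(plate, "plate_config"), inherits(phases, "phase_plan"))
  if (any(units$well > plate$n_wells) ||
      any(units$electrode > plate$electrodes_per_well))
    stop_config("units reference wells/electrodes outside the plate")
  if (any(units$base_rate <= 0)) stop_config("base_rate must be positive")
  if (any(units$amplitude <= 0)) stop_config("amplitude must be positive")
  out <- vector("list", nrow(units) * nrow(phases))
  n <- 0L
  for (ui in seq_len(nrow(units))) {
    u <- units[ui, ]
    for (pi in seq_len(nrow(phases))) {
      ph <- phases[pi, ]
      mult <- modulation_multiplier(modulation, u$subtype, ph$agent,
                                    ph$concentration)
      tt <- with_local_seed(
        derive_seed(seed, ui, pi),
        simulate_train(u$base_rate * mult, ph$duration,
                       p_burst = u$p_burst, burst_mean = u$burst_mean)
      )
      n <- n + 1L
      out[[n]] <- data.frame(unit_id = u$unit_id, well = u$well,
                             electrode = u$electrode, phase = ph$phase,
                             time_s = tt, stringsAsFactors = FALSE)
    }
  }
  spikes <- do.call(rbind, out[seq_len(n)])
  rownames(spikes) <- NULL
  structure(list(units = units, spikes = spikes, plate = plate,
                 phases = phases, modulation = modulation, seed = seed),
            class = "mea_ground_truth")
}

#' @export
print.mea_ground_truth <- function(x, ...) {
  cat("MEA ground truth\n")
  cat(sprintf("  %d units on %d wells x %d electrodes; %d phases\n",
              nrow(x$units), x$plate$n_wells, x$plate$electrodes_per_well,
              nrow(x$phases)))
  cat(sprintf("  %d spikes total (seed %d)\n", nrow(x$spikes), x$seed))
  invisible(x)
}

#' Render the voltage trace of one electrode for one phase
#'
#' Sums the amplitude-scaled waveform templates of every unit on the
#' electrode at its ground-truth spike times (trough-aligned, overlaps summed
#' linearly) and adds band-limited noise: white noise band-pass filtered to
#' 200-3000 Hz and rescaled so its RMS equals `noise_rms` exactly.  The noise
#' stream of an electrode-phase depends only on (`seed`, well, electrode,
#' phase index), so a rendering of a subset of units plus the same seed
#' reproduces the same noise realization (superposition).
#'
#' @param truth An `mea_ground_truth` from [simulate_spike_trains()].
#' @param well,electrode,phase Identify the trace to render.
#' @param noise_rms Target noise RMS (same units as the template amplitudes,
#'   i.e. 1.0 makes unit amplitudes read as multiples of noise RMS).
#' @param seed Integer seed for the noise streams.
#' @return Numeric vector of `duration * sampling_rate` samples.
#' @export
render_electrode_trace <- function(truth, well, electrode, phase,
                                   noise_rms = 1, seed = 1) {
  if (noise_rms <= 0) stop_config("noise_rms must be positive")
  fs <- truth$plate$sampling_rate
  pi_ <- match(phase, truth$phases$phase)
  if (is.na(pi_)) stop_config("unknown phase: ", phase)
  dur <- truth$phases$duration[pi_]
  n <- round(dur * fs)
  noise <- with_local_seed(derive_seed(seed, well, electrode, pi_), {
    x <- bandpass_filter(stats::rnorm(n), fs, band = c(200, 3000))
    # scale so the noise RMS *after the detection-side band-pass* hits the
    # target: a second pass trims transition-band energy by a few percent
    x / sqrt(mean(bandpass_filter(x, fs, band = c(200, 3000))^2))
  })
  trace <- noise * noise_rms
  uu <- truth$units[truth$units$well == well &
                      truth$units$electrode == electrode, , drop = FALSE]
  for (ui in seq_len(nrow(uu))) {
    u <- uu[ui, ]
    tmpl <- spike_template(fs, u$trough_width_ms, u$peak_ratio) * u$amplitude
    trough_off <- which.min(tmpl) - 1L
    st <- truth$spikes$time_s[truth$spikes$unit_id == u$unit_id &
                                truth$spikes$phase == phase]
    idx0 <- round(st * fs) + 1L - trough_off
    for (s in idx0) {
      lo <- max(1L, s)
      hi <- min(n, s + length(tmpl) - 1L)
      if (lo <= hi)
        trace[lo:hi] <- trace[lo:hi] + tmpl[(lo - s + 1L):(hi - s + 1L)]
    }
  }
  trace
}

#' Render voltage traces for a recording
#'
#' Renders every (well, electrode) trace of the requested phases into an
#' in-memory recording object.  Memory grows as
#' `wells x electrodes x duration x sampling_rate` doubles; for large plates
#' render and process one electrode at a time with
#' [render_electrode_trace()].
#'
#' @inheritParams render_electrode_trace
#' @param wells,electrodes,phases Subsets to render (defaults: all).
#' @return An object of class `mea_recording`: list with `traces` (nested
#'   list `traces[[phase]][[\"w<well>e<electrode>\"]]`), `sampling_rate`,
#'   `phases`, `plate`.
#' @export
render_voltage_traces <- function(truth, noise_rms = 1, seed = 1,
                                  wells = NULL, electrodes = NULL,
                                  phases = NULL) {
  wells <- wells %||% seq_len(truth$plate$n_wells)
  electrodes <- electrodes %||% seq_len(truth$plate$electrodes_per_well)
  phases <- phases %||% truth$phases$phase
  traces <- list()
  for (ph in phases) {
    traces[[ph]] <- list()
    for (w in wells) for (e in electrodes) {
      traces[[ph]][[trace_key(w, e)]] <-
        render_electrode_trace(truth, w, e, ph, noise_rms, seed)
    }
  }
  structure(list(traces = traces, sampling_rate = truth$plate$sampling_rate,
                 phases = truth$phases[truth$phases$phase %in% phases, ,
                                       drop = FALSE],
                 plate = truth$plate, noise_rms = noise_rms, seed = seed),
            class = "mea_recording")
}

trace_key <- function(well, electrode) sprintf("w%de%d", well, electrode)

#' @export
print.mea_recording <- function(x, ...) {
  nt <- sum(vapply(x$traces, length, 1L))
  cat(sprintf("MEA recording: %d traces, %g Hz, %d phase(s)\n",
              nt, x$sampling_rate, length(x$traces)))
  invisible(x)
}

#' Simulate waveform cutouts for sorting tests
#'
#' Generates aligned waveform cutouts (template plus white noise of unit
#' standard deviation) directly, bypassing voltage rendering and detection.
#' Useful for exercising the feature-extraction and clustering stages with
#' known labels.
#'
#' @param units Data frame with columns `amplitude`, `trough_width_ms`,
#'   `peak_ratio` (one row per unit on the electrode).
#' @param n_spikes Integer vector of cutouts per unit.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_samples Cutout length in samples (default 38, i.e. 11 pre + 27
#'   post at 12.5 kHz).
#' @param noise_sd Per-sample noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return List with `waveforms` (matrix, one row per cutout) and `label`
#'   (true unit index per row).
#' @export
simulate_waveform_cutouts <- function(units, n_spikes, sampling_rate = 12500,
                                      n_samples = 38, noise_sd = 1,
                                      seed = 1) {
  stopifnot(nrow(units) == length(n_spikes))
  with_local_seed(seed, {
    rows <- sum(n_spikes)
    wf <- matrix(stats::rnorm(rows * n_samples, sd = noise_sd), rows)
    lab <- rep(seq_len(nrow(units)), n_spikes)
    for (i in seq_len(nrow(units))) {
      tmpl <- spike_template(sampling_rate, units$trough_width_ms[i],
                             units$peak_ratio[i]) * units$amplitude[i]
      # align template trough to cutout sample 12 (11 pre-trough samples)
      v <- numeric(n_samples)
      off <- 12L - which.min(tmpl)
      src <- seq_along(tmpl)
      dst <- src + off
      ok <- dst >= 1 & dst <= n_samples
      v[dst[ok]] <- tmpl[src[ok]]
      wf[lab == i, ] <- sweep(wf[lab == i, , drop = FALSE], 2, v, "+")
    }
    list(waveforms = wf, label = lab)
  })
}
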