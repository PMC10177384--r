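# End-to-end pipeline: simulate -> detect -> sort -> metrics -> assay.

#' Demonstration pipeline configuration
#'
#' A small configuration exercising the whole pipeline: 2 wells of 8
#' electrodes, 2 units per electrode, the standard hMNR phase plan at a
#' reduced per-phase duration so the demo completes in minutes.
#'
#' @param duration Per-phase recording duration in seconds (default 120 for
#'   the demo; production recordings use 900).
#' @param noise_rms Noise RMS of the rendered traces (default 1).
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(duration = 120, noise_rms = 1) {
  list(
    plate = list(n_wells = 2, electrodes_per_well = 8,
                 sampling_rate = 12500, phase_duration = duration),
    units = list(units_per_electrode = 2),
    phases = list(type = "hmnr", duration = duration),
    noise_rms = noise_rms
  )
}

build_phase_plan <- function(cfg) {
  type <- cfg$type %||% "hmnr"
  dur <- cfg$duration %||% 900
  if (type == "hmnr") {
    args <- cfg[setdiff(names(cfg), c("type", "duration"))]
    do.call(hmnr_phase_plan, c(args, list(duration = dur)))
  } else if (type == "characterization") {
    characterization_phase_plan(cfg$agent, cfg$concentrations, dur)
  } else stop_config("unknown phase plan type: ", type)
}

#' Run the full MEA analysis pipeline
#'
#' Executes simulate, detect, sort, metrics, and assay in order on a
#' configuration (a nested list, or the path of a YAML file with the same
#' structure).  Traces are rendered and detected one electrode at a time so
#' memory stays bounded.  All randomness derives from the single `seed`;
#' per-stage streams are independent, so rerunning with the same
#' configuration and seed reproduces every output exactly.  When `out_dir`
#' is given, each stage writes its tables (CSV) and a JSON run manifest.
#'
#' @param config Configuration list or YAML path with sections `plate`,
#'   `units`, `phases`, and optional `noise_rms`, `modulation`, `detection`,
#'   `sorting`, `assay` overrides.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param skip_render When `TRUE`, detection is skipped and sorting runs on
#'   waveforms simulated directly from the ground truth (faster; used when
#'   trace-level realism is not needed).
#' @return Object of class `hmnr_run`: list with `truth`, `spikes`,
#'   `sorted`, `activity`, `metrics`, `responses`, `subtypes`,
#'   `concentration_response`, `config`, `seed`.
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL,
                         skip_render = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  plate <- do.call(plate_config, config$plate %||% list())
  plan <- build_phase_plan(config$phases %||% list())
  dpar <- do.call(detection_params, config$detection %||% list())
  spar <- do.call(sorting_params, config$sorting %||% list())
  apar <- do.call(assay_params, config$assay %||% list())
  noise_rms <- config$noise_rms %||% 1
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(name, obj) {
    if (!is.null(out_dir))
      utils::write.csv(as.data.frame(obj), file.path(out_dir, name),
                       row.names = FALSE)
  }
  manifest <- function(stage, params, outputs) {
    if (!is.null(out_dir))
      write_manifest(stage, params, outputs = outputs, seed = seed,
                     path = file.path(out_dir,
                                      paste0("manifest_", stage, ".json")))
  }

  ucfg <- config$units %||% list()
  units <- do.call(generate_units,
                   c(list(plate = plate), ucfg,
                     list(seed = derive_seed(seed, 1))))
  truth <- simulate_spike_trains(plate, units, plan,
                                 modulation = config$modulation %||%
                                   default_modulation_table(),
                                 seed = derive_seed(seed, 2))
  if (!is.null(out_dir))
    write_spike_table(truth$spikes[order(truth$spikes$well,
                                         truth$spikes$electrode,
                                         match(truth$spikes$phase,
                                               plan$phase),
                                         truth$spikes$time_s), ],
                      file.path(out_dir, "ground_truth.csv"))
  manifest("simulate", list(plate = plate, units = ucfg,
                            noise_rms = noise_rms),
           "ground_truth.csv")

  if (skip_render) {
    spikes <- ground_truth_cutout_table(truth,
                                        seed = derive_seed(seed, 3))
  } else {
    per_e <- list()
    for (w in seq_len(plate$n_wells))
      for (e in seq_len(plate$electrodes_per_well))
        for (ph in plan$phase) {
          tr <- render_electrode_trace(truth, w, e, ph, noise_rms,
                                       seed = derive_seed(seed, 3))
          per_e[[paste(w, e, ph)]] <-
            detect_spikes(tr, plate$sampling_rate, dpar,
                          well = w, electrode = e, phase = ph)
        }
    spikes <- bind_spike_tables(per_e)
  }
  if (!is.null(out_dir))
    write_spike_table(spikes, file.path(out_dir, "spikes.csv"),
                      file.path(out_dir, "waveforms.csv"))
  manifest("detect", dpar, c("spikes.csv", "waveforms.csv"))

  pooled <- concatenate_phases(spikes, phase_order = plan$phase)
  sorted <- sort_spikes(pooled, spar)
  emit("units.csv", sorted$spikes)
  manifest("sort", spar, "units.csv")

  metrics <- well_metrics(spikes, plate, plan, dpar)
  emit("well_metrics.csv", metrics)
  manifest("metrics", list(), "well_metrics.csv")

  activity <- unit_rates(sorted, plan, min_rate = apar$activity_min_rate)
  responses <- fold_changes(activity, plan, apar)
  subtypes <- classify_subtypes(responses, apar)
  cr <- concentration_response(responses, subtypes, plan)
  emit("unit_responses.csv", responses)
  emit("subtypes.csv", subtypes)
  emit("concentration_response.csv", cr)
  manifest("assay", apar, c("unit_responses.csv", "subtypes.csv",
                            "concentration_response.csv"))

  structure(list(truth = truth, spikes = spikes, sorted = sorted,
                 activity = activity, metrics = metrics,
                 responses = responses, subtypes = subtypes,
                 concentration_response = cr, config = config, seed = seed),
            class = "hmnr_run")
}

#' @export
print.hmnr_run <- function(x, ...) {
  cat("hMNR pipeline run\n")
  cat(sprintf("  %d ground-truth units, %d detected spikes, %d sorted units\n",
              nrow(x$truth$units), nrow(x$spikes), nrow(x$sorted$units)))
  cat(sprintf("  %d unit(s) with subtype labels\n",
              length(unique(x$subtypes$unit))))
  invisible(x)
}

# Spike table with simulated cutouts taken directly from the ground truth
# (template + unit-variance noise), bypassing trace rendering; spike times
# and well/electrode/phase tags come from the true trains.
ground_truth_cutout_table <- function(truth, seed = 1) {
  sp <- truth$spikes
  o <- order(sp$well, sp$electrode, match(sp$phase, truth$phases$phase),
             sp$time_s)
  sp <- sp[o, , drop = FALSE]
  fs <- truth$plate$sampling_rate
  wf <- matrix(0, nrow(sp), 38L)
  with_local_seed(seed, {
    wf[] <- stats::rnorm(length(wf))
    for (ui in seq_len(nrow(truth$units))) {
      u <- truth$units[ui, ]
      tmpl <- spike_template(fs, u$trough_width_ms, u$peak_ratio) *
        u$amplitude
      v <- numeric(38L)
      off <- 12L - which.min(tmpl)
      src <- seq_along(tmpl)
      dst <- src + off
      ok <- dst >= 1 & dst <= 38L
      v[dst[ok]] <- tmpl[src[ok]]
      rows <- sp$unit_id == u$unit_id
      wf[rows, ] <- sweep(wf[rows, , drop = FALSE], 2, v, "+")
    }
  })
  df <- data.frame(well = sp$well, electrode = sp$electrode,
                   phase = sp$phase, time_s = sp$time_s,
                   amplitude = rep(NA_real_, nrow(sp)),
                   true_unit = sp$unit_id, stringsAsFactors = FALSE)
  spike_table(df, wf)
}
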