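#' Plate configuration for a multi-well MEA recording
#'
#' Describes the geometry and acquisition settings of a multi-well
#' microelectrode array plate: number of wells, electrodes per well, sampling
#' rate, and the duration of each recorded phase.  The defaults mirror a
#' 96-well plate format with 8 recording electrodes per well, 12.5 kHz
#' sampling, and 15-minute recordings per phase.
#'
#' @param n_wells Number of wells on the plate (>= 1).
#' @param electrodes_per_well Recording electrodes per well (default 8).
#' @param sampling_rate Acquisition sampling rate in Hz (default 12500).
#'   Must exceed twice the upper band-pass edge used for detection (3000 Hz).
#' @param phase_duration Default duration of one recorded phase in seconds
#'   (default 900, i.e. 15 min).
#' @return An object of class `plate_config`.
#' @examples
#' plate_config(n_wells = 2)
#' @export
plate_config <- function(n_wells = 96, electrodes_per_well = 8,
                         sampling_rate = 12500, phase_duration = 900) {
  check_number(n_wells, "n_wells", lower = 1)
  check_number(electrodes_per_well, "electrodes_per_well", lower = 1)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(phase_duration, "phase_duration", lower = 0, strict_lower = TRUE)
  if (sampling_rate <= 2 * 3000)
    stop_config("sampling_rate must exceed twice the upper filter edge ",
                "(2 x 3000 Hz); got ", sampling_rate)
  structure(
    list(n_wells = as.integer(n_wells),
         electrodes_per_well = as.integer(electrodes_per_well),
         sampling_rate = sampling_rate,
         phase_duration = phase_duration),
    class = "plate_config"
  )
}

#' @export
print.plate_config <- function(x, ...) {
  cat("MEA plate configuration\n")
  cat(sprintf("  wells: %d, electrodes/well: %d\n",
              x$n_wells, x$electrodes_per_well))
  cat(sprintf("  sampling rate: %g Hz, phase duration: %g s\n",
              x$sampling_rate, x$phase_duration))
  invisible(x)
}

new_phase_plan <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("phase_plan", "data.frame"))
}

#' Construct a phase plan
#'
#' A phase plan is an ordered table of recorded phases.  Each phase has a
#' label, the pharmacological agent applied (or `NA` for untreated baselines),
#' the cumulative bath concentration in micromolar, the recording duration in
#' seconds, and the label of the baseline phase that fold changes for this
#' phase are referenced to (`NA` for baselines themselves).
#'
#' @param phase Character vector of unique phase labels, in recording order.
#' @param agent Agent applied during each phase (`NA` for baselines).
#' @param concentration Cumulative concentration (micromolar) of the agent.
#' @param duration Recording duration per phase in seconds.
#' @param reference For each phase, the label of its reference baseline
#'   (`NA` for baseline phases).
#' @return An object of class `phase_plan` (a data frame).
#' @seealso [hmnr_phase_plan()], [characterization_phase_plan()]
#' @export
phase_plan <- function(phase, agent = NA_character_, concentration = NA_real_,
                       duration = 900, reference = NA_character_) {
  df <- data.frame(phase = as.character(phase),
                   agent = as.character(agent),
                   concentration = as.numeric(concentration),
                   duration = as.numeric(duration),
                   reference = as.character(reference),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$phase))
    stop_config("phase labels must be unique")
  if (any(df$duration <= 0))
    stop_config("phase durations must be positive")
  bad <- !is.na(df$reference) & !(df$reference %in% df$phase)
  if (any(bad))
    stop_config("reference phase not in plan: ", df$reference[which(bad)[1]])
  for (i in seq_len(nrow(df))) {
    r <- df$reference[i]
    if (!is.na(r) && match(r, df$phase) >= i)
      stop_config("reference baseline '", r, "' must precede phase '",
                  df$phase[i], "'")
  }
  new_phase_plan(df)
}

#' Standard hMNR assay phase plan
#'
#' Builds the phase plan of the human multi-neurotransmitter receptor (hMNR)
#' workflow: a first untreated baseline, acute neurotransmitter application,
#' addition of the corresponding antagonist, a washout/recovery period with no
#' recording, a second untreated baseline, and cumulative additions of a test
#' compound.  Identification phases (neurotransmitter, antagonist) are
#' referenced to the first baseline; test-compound phases to the second.
#'
#' Test-compound concentrations are cumulative: each entry is the running
#' total bath concentration after the corresponding addition.
#'
#' @param neurotransmitter Identification neurotransmitter (default
#'   `"glutamate"`; the GABAergic variant uses `"GABA"`).
#' @param antagonist Corresponding antagonist (default `"AP5/NBQX"`;
#'   the GABAergic variant uses `"bicuculline"`).
#' @param nt_concentration,antagonist_concentration Concentrations (uM).
#' @param test_compound Name of the test compound (default `"TMT"`).
#' @param test_concentrations Cumulative test concentrations (uM), increasing.
#' @param duration Recording duration per phase in seconds (default 900).
#' @return A `phase_plan`.
#' @examples
#' hmnr_phase_plan()
#' @export
hmnr_phase_plan <- function(neurotransmitter = "glutamate",
                            antagonist = "AP5/NBQX",
                            nt_concentration = 50,
                            antagonist_concentration = 50,
                            test_compound = "TMT",
                            test_concentrations = c(0.22, 0.67, 2.22, 6.7, 20),
                            duration = 900) {
  if (is.unsorted(test_concentrations, strictly = TRUE))
    stop_config("test_concentrations must be strictly increasing (cumulative)")
  n <- length(test_concentrations)
  phase_plan(
    phase = c("baseline1", "neurotransmitter", "antagonist", "baseline2",
              paste0("test", seq_len(n))),
    agent = c(NA, neurotransmitter, antagonist, NA, rep(test_compound, n)),
    concentration = c(NA, nt_concentration, antagonist_concentration, NA,
                      test_concentrations),
    duration = duration,
    reference = c(NA, "baseline1", "baseline1", NA, rep("baseline2", n))
  )
}

#' Single-agent subtype characterization phase plan
#'
#' Builds a plan with one untreated baseline followed by cumulative
#' concentrations of a single identification agent (e.g. bicuculline,
#' picrotoxin, haloperidol, buspirone, carbaryl), every treated phase
#' referenced to the baseline.
#'
#' @param agent Agent name.
#' @param concentrations Cumulative concentrations (uM), increasing.
#' @param duration Recording duration per phase in seconds.
#' @return A `phase_plan`.
#' @export
characterization_phase_plan <- function(agent, concentrations,
                                        duration = 900) {
  if (is.unsorted(concentrations, strictly = TRUE))
    stop_config("concentrations must be strictly increasing (cumulative)")
  n <- length(concentrations)
  phase_plan(
    phase = c("baseline1", paste0(agent, "_", seq_len(n))),
    agent = c(NA, rep(agent, n)),
    concentration = c(NA, concentrations),
    duration = duration,
    reference = c(NA, rep("baseline1", n))
  )
}

phase_duration <- function(plan, phase) {
  i <- match(phase, plan$phase)
  if (anyNA(i)) stop_config("unknown phase label: ",
                            paste(phase[is.na(i)], collapse = ", "))
  plan$duration[i]
}
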