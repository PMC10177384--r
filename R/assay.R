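# hMNR assay: per-unit fold changes, responder and subtype classification,
# concentration-response aggregation.

#' Assay parameters
#'
#' @param response_threshold Fold-change margin defining a responding unit
#'   (default 0.25): a unit responds when its treated-to-baseline rate ratio
#'   is at least `1 + threshold` (increase) or at most `1 - threshold`
#'   (decrease), both inclusive.
#' @param activity_min_rate Minimum baseline rate (spikes/min) for a unit to
#'   enter the analysis (default 2).
#' @param subtype_rules Classification rules; see [default_subtype_rules()].
#' @return Object of class `assay_params`.
#' @export
assay_params <- function(response_threshold = 0.25, activity_min_rate = 2,
                         subtype_rules = default_subtype_rules()) {
  check_number(response_threshold, "response_threshold", 0, 1,
               strict_lower = TRUE)
  if (response_threshold >= 1)
    stop_config("response_threshold must be in (0, 1)")
  structure(list(response_threshold = response_threshold,
                 activity_min_rate = activity_min_rate,
                 subtype_rules = subtype_rules),
            class = "assay_params")
}

#' Default subtype-classification rules
#'
#' Each rule is a list of clauses `(agent, direction)` that must all hold for
#' the unit to receive the label; `direction` is `"increase"`, `"decrease"`,
#' or `"any"` (responder in either direction).  The defaults follow the
#' pharmacology of the identification agents: glutamatergic units are excited
#' by glutamate and suppressed by the NMDA/AMPA antagonists AP5/NBQX; mature
#' (post GABA-switch) GABAergic units are suppressed by GABA and disinhibited
#' by bicuculline, immature ones respond in the opposite directions;
#' dopaminergic, serotonergic, and cholinergic units respond (either
#' direction) to haloperidol, buspirone, and carbaryl respectively.  Units
#' may satisfy several rules and then carry all matching labels.
#'
#' @return Named list of rules.
#' @export
default_subtype_rules <- function() {
  list(
    glutamatergic = list(list(agent = "glutamate", direction = "increase"),
                         list(agent = "AP5/NBQX", direction = "decrease")),
    GABAergic_mature = list(list(agent = "GABA", direction = "decrease"),
                            list(agent = "bicuculline",
                                 direction = "increase")),
    GABAergic_immature = list(list(agent = "GABA", direction = "increase"),
                              list(agent = "bicuculline",
                                   direction = "decrease")),
    dopaminergic = list(list(agent = "haloperidol", direction = "any")),
    serotonergic = list(list(agent = "buspirone", direction = "any")),
    cholinergic = list(list(agent = "carbaryl", direction = "any"))
  )
}

#' Per-unit fold changes and responder labels
#'
#' For every unit and treated phase, the fold change is the unit's firing
#' rate in that phase divided by its rate in the phase's reference baseline
#' (identification phases reference the first baseline, test-compound phases
#' the second; see [phase_plan()]).  Units whose reference-baseline rate is
#' below `activity_min_rate` are excluded from that comparison.  Labels:
#' `increase` when the fold change is at least `1 + response_threshold`,
#' `decrease` when at most `1 - response_threshold` (both inclusive), else
#' `none`.
#'
#' @param activity Output of [unit_rates()].
#' @param plan The [phase_plan()].
#' @param params An [assay_params()].
#' @return Data frame of class `unit_responses`: `unit`, `well`, `electrode`,
#'   `unit_id`, `phase`, `agent`, `concentration`, `fold_change`, `response`.
#'   One row per unit and treated phase; excluded comparisons carry `NA`
#'   fold change and response.
#' @export
fold_changes <- function(activity, plan, params = assay_params()) {
  treated <- plan[!is.na(plan$reference), , drop = FALSE]
  out <- list()
  rate_of <- function(unit, phase) {
    r <- activity$rate_per_min[activity$unit == unit &
                                 activity$phase == phase]
    if (length(r)) r[1] else 0
  }
  units <- unique(activity[, c("unit", "well", "electrode", "unit_id")])
  for (i in seq_len(nrow(treated))) {
    ph <- treated[i, ]
    for (j in seq_len(nrow(units))) {
      u <- units[j, ]
      ref <- rate_of(u$unit, ph$reference)
      fc <- if (ref >= params$activity_min_rate)
        rate_of(u$unit, ph$phase) / ref else NA_real_
      resp <- if (is.na(fc)) NA_character_
      else if (fc >= 1 + params$response_threshold) "increase"
      else if (fc <= 1 - params$response_threshold) "decrease"
      else "none"
      out[[length(out) + 1L]] <- data.frame(
        unit = u$unit, well = u$well, electrode = u$electrode,
        unit_id = u$unit_id, phase = ph$phase, agent = ph$agent,
        concentration = ph$concentration, fold_change = fc,
        response = resp, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("unit_responses", "data.frame")
  res
}

#' Classify units into neuronal subtypes
#'
#' Applies the subtype rules to each unit's responder labels.  A clause
#' `(agent, direction)` holds when the unit responded in that direction in
#' any phase of that agent (for agents applied as a concentration series).
#' Rules whose agents are not all present in the responses are skipped when
#' using the default rule set; a user-supplied rule referencing an agent
#' absent from the plan is a configuration error.
#'
#' @param responses [fold_changes()] output.
#' @param params An [assay_params()]; `subtype_rules` is used.
#' @param strict `TRUE` when `subtype_rules` were supplied explicitly: a rule
#'   agent missing from the responses then raises an error instead of
#'   skipping the rule.
#' @return Data frame `unit`, `subtype` (long format; units matching several
#'   rules appear once per label, units matching none are absent).
#' @export
classify_subtypes <- function(responses, params = assay_params(),
                              strict = FALSE) {
  agents <- unique(responses$agent)
  labels <- list()
  for (subtype in names(params$subtype_rules)) {
    rule <- params$subtype_rules[[subtype]]
    rule_agents <- vapply(rule, function(cl) cl$agent, character(1))
    missing <- setdiff(rule_agents, agents)
    if (length(missing)) {
      if (strict)
        stop_config("rule '", subtype, "' references agent(s) absent from ",
                    "the plan: ", paste(missing, collapse = ", "))
      next
    }
    for (u in unique(responses$unit)) {
      ru <- responses[responses$unit == u, , drop = FALSE]
      ok <- vapply(rule, function(cl) {
        resp <- ru$response[ru$agent == cl$agent]
        resp <- resp[!is.na(resp)]
        if (!length(resp)) return(FALSE)
        if (cl$direction == "any") any(resp != "none")
        else any(resp == cl$direction)
      }, logical(1))
      if (all(ok))
        labels[[length(labels) + 1L]] <- data.frame(
          unit = u, subtype = subtype, stringsAsFactors = FALSE)
    }
  }
  if (!length(labels))
    return(data.frame(unit = character(0), subtype = character(0)))
  res <- do.call(rbind, labels)
  rownames(res) <- NULL
  res
}

#' Concentration-response aggregation
#'
#' For each test-compound concentration and unit group (`unsorted` = all
#' analyzable units, plus one group per subtype label), reports the number
#' of units, the mean fold change with its standard error over units,
#' responder counts in each direction, and the percentage of responding
#' units.  Concentrations are cumulative (each phase's value is the running
#' total).  Groups with no units are absent from the table.
#'
#' @param responses [fold_changes()] output.
#' @param subtypes [classify_subtypes()] output.
#' @param plan The [phase_plan()].
#' @param phases Which phases to aggregate (default: phases referencing
#'   `baseline2`, i.e. the test-compound phases; falls back to all treated
#'   phases when no phase references `baseline2`).
#' @return Data frame of class `assay_result`: `phase`, `agent`,
#'   `concentration`, `group`, `n_units`, `mean_fc`, `sem_fc`, `n_increase`,
#'   `n_decrease`, `pct_responding`.
#' @export
concentration_response <- function(responses, subtypes, plan,
                                   phases = NULL) {
  if (is.null(phases)) {
    phases <- plan$phase[!is.na(plan$reference) &
                           plan$reference == "baseline2"]
    if (!length(phases)) phases <- plan$phase[!is.na(plan$reference)]
  }
  groups <- c(list(unsorted = unique(responses$unit)),
              split(subtypes$unit, subtypes$subtype))
  out <- list()
  for (ph in phases) {
    rp <- responses[responses$phase == ph & !is.na(responses$fold_change), ,
                    drop = FALSE]
    for (g in names(groups)) {
      rg <- rp[rp$unit %in% groups[[g]], , drop = FALSE]
      n <- nrow(rg)
      if (n == 0) next
      fc <- rg$fold_change
      out[[paste(ph, g)]] <- data.frame(
        phase = ph, agent = rp$agent[1], concentration = rp$concentration[1],
        group = g, n_units = n, mean_fc = mean(fc),
        sem_fc = if (n > 1) stats::sd(fc) / sqrt(n) else 0,
        n_increase = sum(rg$response == "increase"),
        n_decrease = sum(rg$response == "decrease"),
        pct_responding = 100 * mean(rg$response != "none"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("assay_result", "data.frame")
  res
}
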