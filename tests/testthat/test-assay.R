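# Fold changes, responder labels, subtype classification, aggregation.

mk_activity <- function(rates, plan) {
  # rates: named list unit -> named vector phase -> spikes/min
  rows <- list()
  for (u in names(rates)) for (ph in names(rates[[u]])) {
    rows[[paste(u, ph)]] <- data.frame(
      unit = u, well = 1L, electrode = 1L,
      unit_id = match(u, names(rates)), phase = ph,
      n_spikes = rates[[u]][[ph]] * 15, rate_per_min = rates[[u]][[ph]],
      active_in_baseline = rates[[u]][["baseline1"]] >= 2)
  }
  do.call(rbind, rows)
}

two_phase_plan <- function(agent = "glutamate") {
  phase_plan(c("baseline1", "t"), agent = c(NA, agent),
             concentration = c(NA, 50), duration = 900,
             reference = c(NA, "baseline1"))
}

test_that("fold-change labels follow the inclusive +/-0.25 rule", {
  plan <- two_phase_plan()
  act <- mk_activity(list(a = c(baseline1 = 120, t = 156),
                          b = c(baseline1 = 120, t = 96),
                          c = c(baseline1 = 120, t = 90)), plan)
  fc <- fold_changes(act, plan)
  fc <- fc[order(fc$unit), ]
  expect_equal(fc$fold_change, c(1.30, 0.80, 0.75))
  expect_equal(fc$response, c("increase", "none", "decrease"))
})

test_that("units inactive in the reference baseline are excluded", {
  plan <- two_phase_plan()
  act <- mk_activity(list(a = c(baseline1 = 1.9, t = 10)), plan)
  fc <- fold_changes(act, plan)
  expect_true(is.na(fc$fold_change))
  expect_true(is.na(fc$response))
})

test_that("identification and test phases use their own baselines", {
  plan <- hmnr_phase_plan(test_concentrations = c(1, 3))
  act <- mk_activity(list(a = c(baseline1 = 100, neurotransmitter = 200,
                                antagonist = 30, baseline2 = 50,
                                test1 = 50, test2 = 25)), plan)
  fc <- fold_changes(act, plan)
  expect_equal(fc$fold_change[fc$phase == "neurotransmitter"], 2)
  expect_equal(fc$fold_change[fc$phase == "antagonist"], 0.3)
  # test phases reference baseline2 (50/min), not baseline1
  expect_equal(fc$fold_change[fc$phase == "test1"], 1)
  expect_equal(fc$fold_change[fc$phase == "test2"], 0.5)
})

test_that("the two-clause glutamatergic rule needs both directions", {
  plan <- phase_plan(c("baseline1", "glu", "ant"),
                     agent = c(NA, "glutamate", "AP5/NBQX"),
                     concentration = c(NA, 50, 50), duration = 900,
                     reference = c(NA, "baseline1", "baseline1"))
  act <- mk_activity(list(yes = c(baseline1 = 100, glu = 300, ant = 20),
                          no = c(baseline1 = 100, glu = 300, ant = 100)),
                     plan)
  fc <- fold_changes(act, plan)
  lab <- classify_subtypes(fc)
  expect_equal(lab$unit[lab$subtype == "glutamatergic"], "yes")
  # explicit rule naming an absent agent errors
  pp <- assay_params(subtype_rules = list(
    x = list(list(agent = "nicotine", direction = "any"))))
  expect_error(classify_subtypes(fc, pp, strict = TRUE),
               class = "hmnr_config_error")
})

test_that("GABAergic maturity is read from the response directions", {
  plan <- phase_plan(c("baseline1", "g", "b"),
                     agent = c(NA, "GABA", "bicuculline"),
                     concentration = c(NA, 10, 10), duration = 900,
                     reference = c(NA, "baseline1", "baseline1"))
  act <- mk_activity(list(mat = c(baseline1 = 100, g = 40, b = 200),
                          imm = c(baseline1 = 100, g = 200, b = 40),
                          non = c(baseline1 = 100, g = 100, b = 100)),
                     plan)
  lab <- classify_subtypes(fold_changes(act, plan))
  expect_equal(lab$unit[lab$subtype == "GABAergic_mature"], "mat")
  expect_equal(lab$unit[lab$subtype == "GABAergic_immature"], "imm")
  expect_false("non" %in% lab$unit)
})

test_that("classification is invariant to unit order", {
  plan <- two_phase_plan()
  act <- mk_activity(list(a = c(baseline1 = 100, t = 200),
                          b = c(baseline1 = 100, t = 100),
                          c = c(baseline1 = 100, t = 260)), plan)
  fc <- fold_changes(act, plan)
  lab1 <- classify_subtypes(fc)
  fc_rev <- fc[rev(seq_len(nrow(fc))), ]
  lab2 <- classify_subtypes(fc_rev)
  expect_equal(sort(paste(lab1$unit, lab1$subtype)),
               sort(paste(lab2$unit, lab2$subtype)))
})

test_that("responder counts partition the analyzable units", {
  plan <- two_phase_plan()
  set.seed(3)
  rates <- setNames(lapply(1:40, function(i) {
    b <- runif(1, 60, 300)
    c(baseline1 = b, t = b * exp(rnorm(1, 0, 0.4)))
  }), paste0("u", 1:40))
  fc <- fold_changes(mk_activity(rates, plan), plan)
  tab <- table(fc$response)
  expect_equal(sum(tab), 40L)
})

test_that("concentration-response aggregation is plain unit arithmetic", {
  plan <- hmnr_phase_plan(test_concentrations = c(1, 3))
  act <- mk_activity(list(
    a = c(baseline1 = 100, neurotransmitter = 250, antagonist = 20,
          baseline2 = 100, test1 = 50, test2 = 50),
    b = c(baseline1 = 100, neurotransmitter = 250, antagonist = 20,
          baseline2 = 100, test1 = 150, test2 = 100)), plan)
  fc <- fold_changes(act, plan)
  lab <- classify_subtypes(fc)
  cr <- concentration_response(fc, lab, plan)
  t1 <- cr[cr$phase == "test1" & cr$group == "unsorted", ]
  expect_equal(t1$mean_fc, 1)                      # (0.5 + 1.5) / 2
  expect_equal(t1$sem_fc, 0.5)
  expect_equal(t1$n_units, 2L)
  t2 <- cr[cr$phase == "test2" & cr$group == "unsorted", ]
  expect_equal(t2$mean_fc, 0.75)
  expect_equal(t2$sem_fc, 0.25)
  # both units are glutamatergic; subtype group present, others absent
  expect_true("glutamatergic" %in% cr$group)
  expect_false(any(cr$group == "serotonergic"))
  # all-equal fold changes give SEM 0
  actc <- mk_activity(list(a = c(baseline1 = 100, neurotransmitter = 100,
                                 antagonist = 100, baseline2 = 100,
                                 test1 = 100, test2 = 100)), plan)
  crc <- concentration_response(fold_changes(actc, plan),
                                classify_subtypes(fold_changes(actc, plan)),
                                plan)
  expect_true(all(crc$mean_fc == 1 & crc$sem_fc == 0))
})

test_that("a suppressive agent drags the target group below unsorted", {
  plate <- plate_config(n_wells = 4, electrodes_per_well = 4,
                        phase_duration = 900)
  plan <- hmnr_phase_plan(neurotransmitter = "GABA",
                          antagonist = "bicuculline",
                          test_compound = "emamectin",
                          test_concentrations = c(0.01, 0.03))
  units <- generate_units(plate, 2,
                          subtype_probs = c(GABAergic_mature = 0.5,
                                            nonresponsive = 0.5),
                          seed = 31)
  truth <- simulate_spike_trains(plate, units, plan, seed = 32)
  act <- unit_rates(truth$spikes, plan)
  fc <- fold_changes(act, plan)
  lab <- classify_subtypes(fc)
  cr <- concentration_response(fc, lab, plan)
  for (ph in c("test1", "test2")) {
    g <- cr[cr$phase == ph & cr$group == "GABAergic_mature", "mean_fc"]
    u <- cr[cr$phase == ph & cr$group == "unsorted", "mean_fc"]
    expect_lt(g, u)
  }
})
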