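# Ground-truth simulator: rates, refractoriness, determinism, rendering.

test_that("simulated spike counts match the target rate (Poisson bound)", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 1,
                        phase_duration = 900)
  plan <- phase_plan("baseline1", duration = 900)
  units <- data.frame(unit_id = 1L, well = 1L, electrode = 1L,
                      subtype = "nonresponsive", base_rate = 5,
                      amplitude = 10, p_burst = 0, burst_mean = 0,
                      trough_width_ms = 0.3, peak_ratio = 0.5)
  fails <- 0L
  for (s in 1:30) {
    truth <- simulate_spike_trains(plate, units, plan, seed = s)
    n <- nrow(truth$spikes)
    if (abs(n - 4500) > 3 * sqrt(4500)) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("identity modulation leaves per-phase rates indistinguishable", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 1,
                        phase_duration = 600)
  plan <- phase_plan(c("baseline1", "p2", "p3"), duration = 600)
  units <- data.frame(unit_id = 1L, well = 1L, electrode = 1L,
                      subtype = "nonresponsive", base_rate = 3,
                      amplitude = 10, p_burst = 0.1, burst_mean = 5,
                      trough_width_ms = 0.3, peak_ratio = 0.5)
  truth <- simulate_spike_trains(plate, units, plan, seed = 11)
  rates <- tapply(truth$spikes$time_s, truth$spikes$phase, length) / 600
  expect_true(all(abs(rates / 3 - 1) < 0.15))
})

test_that("a 0.5 multiplier halves the phase rate", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 1,
                        phase_duration = 900)
  plan <- phase_plan(c("baseline1", "drug"), agent = c(NA, "agentX"),
                     concentration = c(NA, 10), duration = 900,
                     reference = c(NA, "baseline1"))
  units <- data.frame(unit_id = 1L, well = 1L, electrode = 1L,
                      subtype = "glutamatergic", base_rate = 4,
                      amplitude = 10, p_burst = 0, burst_mean = 0,
                      trough_width_ms = 0.3, peak_ratio = 0.5)
  mod <- modulation_table("glutamatergic", "agentX", 0.5)
  truth <- simulate_spike_trains(plate, units, plan, mod, seed = 21)
  n_base <- sum(truth$spikes$phase == "baseline1")
  n_drug <- sum(truth$spikes$phase == "drug")
  expect_lt(abs(n_drug / n_base - 0.5), 0.05)
})

test_that("refractory period holds in every unit-phase train", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 2,
                        phase_duration = 120)
  plan <- phase_plan(c("baseline1", "p2"), duration = 120)
  units <- generate_units(plate, units_per_electrode = 2,
                          base_rate_range = c(2, 20), seed = 5)
  truth <- simulate_spike_trains(plate, units, plan, seed = 6)
  for (u in unique(truth$spikes$unit_id)) for (ph in plan$phase) {
    tt <- truth$spikes$time_s[truth$spikes$unit_id == u &
                                truth$spikes$phase == ph]
    expect_true(all(diff(tt) >= 0.002 - 1e-12))
    expect_true(all(tt >= 0 & tt < 120))
    expect_false(is.unsorted(tt, strictly = TRUE))
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 2,
                        phase_duration = 60)
  plan <- hmnr_phase_plan(duration = 60)
  units <- generate_units(plate, 2, seed = 2)
  t1 <- simulate_spike_trains(plate, units, plan, seed = 7)
  t2 <- simulate_spike_trains(plate, units, plan, seed = 7)
  t3 <- simulate_spike_trains(plate, units, plan, seed = 8)
  expect_identical(t1$spikes, t2$spikes)
  expect_false(identical(t1$spikes, t3$spikes))
  tr1 <- render_electrode_trace(t1, 1, 1, "baseline1", seed = 3)
  tr2 <- render_electrode_trace(t2, 1, 1, "baseline1", seed = 3)
  expect_identical(tr1, tr2)
})

test_that("unknown agent in the phase plan is a configuration error", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 1,
                        phase_duration = 10)
  plan <- phase_plan(c("baseline1", "drug"), agent = c(NA, "mystery"),
                     concentration = c(NA, 1), duration = 10,
                     reference = c(NA, "baseline1"))
  units <- generate_units(plate, 1, seed = 1)
  expect_error(simulate_spike_trains(plate, units, plan, seed = 1),
               class = "hmnr_config_error")
})

test_that("noise-only traces hit the requested RMS after band-passing", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 1,
                        phase_duration = 20)
  plan <- phase_plan("baseline1", duration = 20)
  units <- data.frame(unit_id = integer(0), well = integer(0),
                      electrode = integer(0), subtype = character(0),
                      base_rate = numeric(0), amplitude = numeric(0),
                      p_burst = numeric(0), burst_mean = numeric(0),
                      trough_width_ms = numeric(0), peak_ratio = numeric(0))
  truth <- structure(list(units = units,
                          spikes = data.frame(unit_id = integer(0),
                                              well = integer(0),
                                              electrode = integer(0),
                                              phase = character(0),
                                              time_s = numeric(0)),
                          plate = plate,
                          phases = plan, seed = 1),
                     class = "mea_ground_truth")
  for (r in c(0.5, 2)) {
    tr <- render_electrode_trace(truth, 1, 1, "baseline1", noise_rms = r,
                                 seed = 4)
    post <- bandpass_filter(tr, plate$sampling_rate)
    expect_lt(abs(sqrt(mean(post^2)) / r - 1), 0.05)
    expect_equal(length(tr), 20 * 12500)
  }
  expect_error(render_electrode_trace(truth, 1, 1, "baseline1",
                                      noise_rms = 0),
               class = "hmnr_config_error")
})

test_that("superposition: a two-unit trace is the unit traces plus one noise", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 1,
                        phase_duration = 5)
  plan <- phase_plan("baseline1", duration = 5)
  units <- generate_units(plate, 2, base_rate_range = c(3, 5), seed = 9)
  truth <- simulate_spike_trains(plate, units, plan, seed = 10)
  sub <- function(ids) {
    t2 <- truth
    t2$units <- truth$units[truth$units$unit_id %in% ids, , drop = FALSE]
    t2$spikes <- truth$spikes[truth$spikes$unit_id %in% ids, , drop = FALSE]
    t2
  }
  tr_ab <- render_electrode_trace(truth, 1, 1, "baseline1", seed = 3)
  tr_a <- render_electrode_trace(sub(1), 1, 1, "baseline1", seed = 3)
  tr_b <- render_electrode_trace(sub(2), 1, 1, "baseline1", seed = 3)
  noise <- render_electrode_trace(sub(integer(0)), 1, 1, "baseline1",
                                  seed = 3)
  expect_equal(tr_ab, tr_a + tr_b - noise, tolerance = 1e-12)
})

test_that("the noiseless limit reproduces template extrema at spike times", {
  plate <- plate_config(n_wells = 1, electrodes_per_well = 1,
                        phase_duration = 2)
  plan <- phase_plan("baseline1", duration = 2)
  amp <- 9
  units <- data.frame(unit_id = 1L, well = 1L, electrode = 1L,
                      subtype = "nonresponsive", base_rate = 2,
                      amplitude = amp, p_burst = 0, burst_mean = 0,
                      trough_width_ms = 0.3, peak_ratio = 0.5)
  truth <- simulate_spike_trains(plate, units, plan, seed = 30)
  tr <- render_electrode_trace(truth, 1, 1, "baseline1",
                               noise_rms = 1e-9, seed = 2)
  gt <- truth$spikes$time_s
  for (t0 in gt) {
    i <- round(t0 * 12500) + 1
    expect_equal(tr[i], -amp, tolerance = 1e-3)
  }
})
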