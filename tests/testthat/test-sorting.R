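# Phase concatenation, PCA features, t-mixture EM, unit assignment.

mk_table <- function(n, phase, electrode = 1L, wf_len = 38) {
  spike_table(data.frame(well = rep(1L, n), electrode = rep(electrode, n),
                         phase = rep(phase, n),
                         time_s = sort(runif(n, 0, 60)),
                         amplitude = rep(1, n)),
              waveforms = matrix(rnorm(n * wf_len), n))
}

test_that("phase concatenation conserves counts, tags, and order", {
  set.seed(1)
  a <- mk_table(100, "baseline1")
  b <- mk_table(150, "drug")
  pooled <- concatenate_phases(list(a, b), c("baseline1", "drug"))
  expect_equal(nrow(pooled), 250L)
  expect_equal(table(pooled$phase)[["baseline1"]], 100L)
  expect_equal(nrow(attr(pooled, "waveforms")), 250L)
  expect_false(is.unsorted(match(pooled$phase, c("baseline1", "drug"))))
  expect_false(is.unsorted(pooled$time_s[pooled$phase == "drug"]))
  # single phase: identity
  one <- concatenate_phases(list(a))
  expect_equal(as.data.frame(one), as.data.frame(a))
  # empty phase contributes nothing
  empty <- mk_table(0, "washout")
  expect_equal(nrow(concatenate_phases(list(a, empty))), 100L)
  # mismatched cutout geometry is a format error
  expect_error(concatenate_phases(list(a, mk_table(5, "x", wf_len = 20))),
               class = "hmnr_schema_error")
})

test_that("feature extraction is deterministic and separates templates", {
  # exact duplicates map to two zero-radius points
  w1 <- sin(seq(0, 3, length.out = 38))
  w2 <- cos(seq(0, 6, length.out = 38))
  wf <- rbind(w1, w1, w1, w2, w2, w2)
  f <- extract_features(wf, 2)
  expect_lt(max(abs(f[1:3, 1] - f[1, 1])), 1e-10)
  expect_lt(max(abs(f[4:6, 1] - f[4, 1])), 1e-10)
  expect_gt(abs(f[1, 1] - f[4, 1]), 1e-3)
  # mirrored copies give a cloud symmetric about the origin
  set.seed(2)
  base <- matrix(rnorm(20 * 38), 20)
  base <- sweep(base, 2, colMeans(base))
  fsym <- extract_features(rbind(base, -base), 3)
  expect_lt(max(abs(colMeans(fsym))), 1e-10)
  # two templates at SNR ~8: between-template distance > 4x within spread
  u <- shape_units(2)
  sim <- simulate_waveform_cutouts(u, c(300, 300), seed = 3)
  fs2 <- extract_features(sim$waveforms, 3)
  centers <- apply(fs2, 2, function(col) tapply(col, sim$label, mean))
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  within <- sqrt(mean(unlist(lapply(split(as.data.frame(fs2), sim$label),
                                    function(g) apply(g, 2, var)))))
  expect_gt(between, 4 * within)
  expect_error(extract_features(matrix(rnorm(3 * 38), 3), 3),
               class = "hmnr_config_error")
})

test_that("EM collapses an over-specified start on single-cluster data", {
  u <- shape_units(1)
  sim <- simulate_waveform_cutouts(u, 1200, seed = 4)
  f <- extract_features(sim$waveforms)
  fit <- fit_t_mixture(f, sorting_params(seed = 5))
  expect_gte(max(fit$weights), 0.99)
  expect_true(loglik_monotone(fit))
})

test_that("EM recovers three well-separated clusters", {
  u <- shape_units(3)
  sim <- simulate_waveform_cutouts(u, c(700, 500, 400), seed = 6)
  f <- extract_features(sim$waveforms)
  fit <- fit_t_mixture(f, sorting_params(seed = 7))
  expect_gte(mclust::adjustedRandIndex(fit$cluster, sim$label), 0.95)
  expect_true(loglik_monotone(fit))
  # determinism
  fit2 <- fit_t_mixture(f, sorting_params(seed = 7))
  expect_identical(fit$cluster, fit2$cluster)
})

test_that("shuffling input order changes labels only up to relabeling", {
  u <- shape_units(2)
  sim <- simulate_waveform_cutouts(u, c(400, 300), seed = 8)
  f <- extract_features(sim$waveforms)
  fit <- fit_t_mixture(f, sorting_params(seed = 9))
  set.seed(10)
  perm <- sample(nrow(f))
  fitp <- fit_t_mixture(extract_features(sim$waveforms[perm, ]),
                        sorting_params(seed = 9))
  expect_equal(mclust::adjustedRandIndex(fit$cluster[perm], fitp$cluster), 1)
})

test_that("unit assignment conserves spikes and dissolves tiny clusters", {
  u <- shape_units(2)
  sim <- simulate_waveform_cutouts(u, c(500, 5), seed = 11)
  set.seed(11)
  tab <- spike_table(
    data.frame(well = 1L, electrode = 1L,
               phase = rep(c("baseline1", "drug"), length.out = 505),
               time_s = sort(runif(505, 0, 60)), amplitude = 1),
    waveforms = sim$waveforms)
  fit <- fit_t_mixture(extract_features(sim$waveforms),
                       sorting_params(seed = 12))
  out <- assign_units(fit, tab, min_unit_spikes = 10)
  # conservation: every spike is a unit spike or an outlier
  expect_equal(sum(!is.na(out$unit_id)) + sum(is.na(out$unit_id)), 505L)
  # the 5-spike cluster lands in the outlier pool
  if (length(fit$weights) > 1) {
    expect_equal(sort(unique(out$unit_id[!is.na(out$unit_id)])), 1L)
    expect_equal(sum(is.na(out$unit_id)), 5L)
  }
  # all spikes from one component -> one unit with every spike
  fit1 <- fit_t_mixture(extract_features(sim$waveforms[1:500, ]),
                        sorting_params(seed = 12))
  out1 <- assign_units(fit1, tab[1:500, ], min_unit_spikes = 10)
  expect_true(all(out1$unit_id == 1L))
})

test_that("sort_spikes keeps sparse electrodes as one unsorted unit", {
  set.seed(13)
  tiny <- mk_table(3, "baseline1", electrode = 2L)
  big <- spike_table(
    data.frame(well = 1L, electrode = 1L, phase = "baseline1",
               time_s = sort(runif(400, 0, 60)), amplitude = 1),
    waveforms = simulate_waveform_cutouts(shape_units(1), 400,
                                          seed = 14)$waveforms)
  pooled <- concatenate_phases(list(big, tiny))
  expect_warning(sorted <- sort_spikes(pooled, sorting_params(seed = 15)),
                 "unsorted")
  expect_true(all(sorted$spikes$unit_id[sorted$spikes$electrode == 2] == 1L))
  expect_false(sorted$diagnostics[["1 2"]]$sorted)
})

test_that("per-unit rates follow the inclusive 2 spikes/min baseline rule", {
  plan <- phase_plan(c("baseline1", "drug"), duration = 900,
                     agent = c(NA, "x"), concentration = c(NA, 1),
                     reference = c(NA, "baseline1"))
  mk <- function(n_base, n_drug, uid) data.frame(
    well = 1L, electrode = 1L, unit_id = uid,
    phase = rep(c("baseline1", "drug"), c(n_base, n_drug)),
    time_s = c(seq_len(n_base), seq_len(n_drug)))
  df <- rbind(mk(45, 10, 1L), mk(29, 10, 2L), mk(30, 10, 3L))
  act <- unit_rates(df, plan)
  r <- act[act$phase == "baseline1", ]
  r <- r[order(r$unit_id), ]
  expect_equal(r$rate_per_min, c(3, 29 / 15, 2))
  expect_equal(r$active_in_baseline, c(TRUE, FALSE, TRUE))
})

test_that("end-to-end sorting recovers a per-unit rate modulation", {
  # two units on one electrode; unit 2 is tripled in phase 2
  u <- shape_units(2)
  n1 <- c(300, 300)          # unit 1: flat
  n2 <- c(150, 450)          # unit 2: x3
  sims <- lapply(1:2, function(ph) {
    simulate_waveform_cutouts(u, c(n1[ph], n2[ph]), seed = 20 + ph)
  })
  tabs <- lapply(1:2, function(ph) {
    n <- sum(c(n1[ph], n2[ph]))
    set.seed(30 + ph)
    spike_table(data.frame(well = 1L, electrode = 1L,
                           phase = c("baseline1", "drug")[ph],
                           time_s = sort(runif(n, 0, 900)), amplitude = 1),
                waveforms = sims[[ph]]$waveforms[order(runif(n)), ])
  })
  pooled <- concatenate_phases(tabs, c("baseline1", "drug"))
  sorted <- sort_spikes(pooled, sorting_params(seed = 40))
  counts <- table(sorted$spikes$unit_id, sorted$spikes$phase)
  expect_equal(nrow(counts), 2L)
  ratios <- counts[, "drug"] / counts[, "baseline1"]
  expect_lt(abs(sort(ratios)[1] - 1), 0.2)
  expect_lt(abs(sort(ratios)[2] / 3 - 1), 0.2)
})
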