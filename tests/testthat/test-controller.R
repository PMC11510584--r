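test_that("ramp arithmetic and plan ordering follow the protocol", {
  tg <- data.frame(target_id = 1:4,
                   x = c(1, 0, 1, 0) * 1e-3, y = c(1, 1, 0, 0) * 1e-3, z = 0)
  plan <- sonication_plan(tg)
  # raster order: posterior (smallest y) left-most (smallest x) first
  expect_equal(plan$targets$target_id, c(4, 3, 2, 1))
  expect_equal(ramp_pressure(1, plan), 0.15e6)
  expect_equal(ramp_pressure(24, plan), 0.495e6)
  expect_equal(ramp_pressure(10, plan) - ramp_pressure(9, plan), 15e3)
  expect_error(sonication_plan(tg, target_level = 0))
  expect_error(sonication_plan(tg, ramp_step = -1))
})

test_that("deterministic noiseless calibration stops at the threshold crossing", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(16)
  sub <- point_subject(c(0, 0, 0), pthr = 0.495e6, constants = sc)
  plan <- sonication_plan(sub, burst_length = 1e-3, target_level = 50,
                          n_tx_bursts = 2, brf = 0.2, max_output = 0.6e6)
  base <- run_baseline_ramps(plan, sub, geom, seed = 31, constants = sc)
  expect_equal(nrow(base$records), 31)  # (0.6 - 0.15) / 0.015 + 1 steps
  cal <- run_calibration_phase(plan, sub, geom, base, seed = 32,
                               constants = sc)
  st <- cal$states
  expect_true(st$detected)
  expect_equal(st$detection_step, 24L)
  expect_equal(st$calibration_pnp, 0.495e6)
  expect_equal(st$stop_reason, "pci")
  # the detection burst is the 24th, at t = 115 s under the 0.2 Hz schedule
  det_rec <- cal$log$records[cal$log$records$step == 24, ]
  expect_equal(det_rec$timestamp, 115)
  # Tx phase runs at target level x calibration pressure
  tx <- run_tx_phase(plan, st, sub, geom, seed = 33, constants = sc)
  expect_equal(nrow(tx$records), 2)
  expect_equal(unique(tx$records$applied_pnp), 0.5 * 0.495e6)
})

test_that("a threshold below the ramp start is detected on the first burst", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(16)
  # admissible thresholds sit one step above the minimum output, so a
  # below-ramp-start threshold is realized with a raised starting pressure
  sub <- point_subject(c(0, 0, 0), pthr = 0.17e6, constants = sc)
  plan <- sonication_plan(sub, burst_length = 1e-3, ramp_start = 0.18e6,
                          max_output = 0.33e6, n_tx_bursts = 0)
  base <- run_baseline_ramps(plan, sub, geom, seed = 41, constants = sc)
  cal <- run_calibration_phase(plan, sub, geom, base, seed = 42,
                               constants = sc)
  expect_equal(cal$states$detection_step, 1L)
  expect_equal(cal$states$calibration_pnp, 0.18e6)
})

test_that("an undetectable target reaches maximum output and is excluded from Tx", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(16)
  sub <- point_subject(c(0, 0, 0), pthr = 5e6, constants = sc)  # unreachable
  plan <- sonication_plan(sub, burst_length = 1e-3, max_output = 0.3e6,
                          n_tx_bursts = 3)
  base <- run_baseline_ramps(plan, sub, geom, seed = 51, constants = sc)
  expect_warning(
    cal <- run_calibration_phase(plan, sub, geom, base, seed = 52,
                                 constants = sc),
    "uncalibrated")
  expect_false(cal$states$detected)
  expect_equal(cal$states$stop_reason, "max_output_reached")
  tx <- run_tx_phase(plan, cal$states, sub, geom, seed = 53, constants = sc)
  expect_equal(nrow(tx$records), 0)
})

test_that("burst scheduling spaces consecutive bursts at a target by 1/BRF", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(4)
  sub <- sample_virtual_subject(3, seed = 61, emission = det_emission(),
                                constants = sc, pthr_mean = 0.2e6,
                                pthr_sd = 0)
  plan <- sonication_plan(sub, burst_length = 1e-3, brf = 0.2,
                          n_tx_bursts = 4, max_output = 0.25e6)
  base <- run_baseline_ramps(plan, sub, geom, seed = 62, constants = sc)
  for (id in plan$targets$target_id) {
    ts <- base$records$timestamp[base$records$target_id == id]
    expect_equal(diff(ts), rep(5, length(ts) - 1))
  }
  # conservation: every scheduled burst appears exactly once
  expect_equal(nrow(base$records),
               sonocal:::n_ramp_steps(plan) * nrow(plan$targets))
})

test_that("calibration conservation: one burst per target per round until all stop", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(16)
  sub <- sample_virtual_subject(2, seed = 71, emission = det_emission(),
                                constants = sc, pthr_mean = 0.3e6,
                                pthr_sd = 0.05e6)
  plan <- sonication_plan(sub, burst_length = 1e-3, n_tx_bursts = 0,
                          max_output = 0.6e6)
  base <- run_baseline_ramps(plan, sub, geom, seed = 72, constants = sc)
  cal <- run_calibration_phase(plan, sub, geom, base, seed = 73,
                               constants = sc)
  rounds <- max(cal$states$detection_step)
  expect_equal(nrow(cal$log$records), rounds * 2)
  # after a target stops, its remaining bursts run at minimum output
  for (i in 1:2) {
    recs <- cal$log$records[cal$log$records$target_id ==
                              cal$states$target_id[i], ]
    post <- recs[recs$step > cal$states$detection_step[i], ]
    expect_true(all(post$min_output))
    expect_true(all(post$applied_pnp == sc$min_output_pressure))
  }
})

test_that("exclusion rules reproduce the constructed effective-level example", {
  # retrospective activity at 0.45 MPa with Tx PNP 0.38 MPa and intended 75%
  # gives an effective level of 84.4% -> rule 1
  fx <- exclusion_fixture(n_targets = 2, rule1_ids = integer(0),
                          rule2_ids = integer(0), rule3_ids = integer(0),
                          rule4_ids = integer(0))
  rec <- fx$log$records
  # craft target 1: detection at step 24 (0.495 MPa; Tx = 0.371 MPa), with a
  # retrospectively-visible burst at 0.45 MPa (step 21)
  pre <- rec$target_id == 1 & rec$phase == "calibration" & rec$step == 15
  rec$step[pre] <- 21L
  rec$applied_pnp[pre] <- 0.45e6
  rec$pslr[pre] <- 85
  fx$log$records <- rec
  out <- apply_exclusion_rules(fx$log, fx$states, fx$plan)
  eff <- 100 * (0.75 * 0.495e6) / 0.45e6
  expect_equal(out$effective_target_level[1], eff)
  expect_true(out$rule1_effective_tl_exceeded[1])
  expect_false(out$rule1_effective_tl_exceeded[2])
  expect_false(any(out$excluded[2]))
})

test_that("overlapping rule hits exclude 51 of 288 targets from 58 hits", {
  # 9 + 32 + 4 + 13 = 58 rule hits; 7 targets carry two rules
  rule1 <- 1:9
  rule2 <- 10:41
  rule3 <- 42:45
  rule4 <- c(35:41, 46:51)   # 7 overlap rule 2, 6 fresh
  fx <- exclusion_fixture(288, rule1, rule2, rule3, rule4)
  out <- apply_exclusion_rules(fx$log, fx$states, fx$plan,
                               anatomy_flags = fx$anatomy)
  expect_equal(sum(out$rule1_effective_tl_exceeded), 9)
  expect_equal(sum(out$rule2_tx_coherent_activity), 32)
  expect_equal(sum(out$rule3_false_positive_calibration), 4)
  expect_equal(sum(out$rule4_anatomy_confound), 13)
  n_hits <- sum(out$rule1_effective_tl_exceeded) +
    sum(out$rule2_tx_coherent_activity) +
    sum(out$rule3_false_positive_calibration) +
    sum(out$rule4_anatomy_confound)
  expect_equal(n_hits, 58)
  expect_equal(sum(out$excluded), 51)
  # excluded is the OR of the four rules
  expect_equal(out$excluded,
               out$rule1_effective_tl_exceeded | out$rule2_tx_coherent_activity |
                 out$rule3_false_positive_calibration | out$rule4_anatomy_confound)
})

test_that("clean logs produce no exclusions", {
  fx <- exclusion_fixture(6, integer(0), integer(0), integer(0), integer(0))
  out <- apply_exclusion_rules(fx$log, fx$states, fx$plan,
                               anatomy_flags = fx$anatomy)
  expect_false(any(out$excluded))
})

test_that("treatment-phase drift produces retrospective coherent activity", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(16)
  em <- det_emission(drift_rate = 0.04)
  sub <- point_subject(c(0, 0, 0), pthr = 0.4e6, emission = em,
                       constants = sc)
  states <- data.frame(target_id = 1, detected = TRUE, detection_step = 17L,
                       calibration_pnp = 0.39e6, stop_reason = "pci",
                       completed = TRUE)
  plan <- sonication_plan(sub, burst_length = 1e-3, target_level = 75,
                          n_tx_bursts = 12, max_output = 0.6e6)
  tx <- run_tx_phase(plan, states, sub, geom, seed = 91, constants = sc)
  # Tx PNP = 0.2925 MPa; effective threshold decays by 4%/burst from 0.4 MPa
  # and falls below the Tx pressure at burst ~8, after which bursts activate
  expect_true(any(tx$records$pci_detected))
  expect_false(any(tx$records$pci_detected[1:5]))
})
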