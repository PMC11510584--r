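# shared fixtures: geometries are cached per (seed, n_modules) because
# placement is deterministic and moderately expensive

.geom_cache <- new.env(parent = emptyenv())

test_geom <- function(n_modules = 8, seed = 7) {
  key <- paste0(seed, "_", n_modules)
  if (is.null(.geom_cache[[key]])) {
    .geom_cache[[key]] <- build_array_geometry(seed, n_modules = n_modules)
  }
  .geom_cache[[key]]
}

# short-capture constants for burst-level tests (10 MS/s study rate)
test_constants <- function(capture_length = 3e-3, sampling_rate = 10e6) {
  system_constants(sampling_rate = sampling_rate,
                   capture_length = capture_length)
}

# noiseless deterministic emission prototype: activation is a hard step at
# the threshold pressure, no channel noise, no clutter
det_emission <- function(...) {
  emission_model(noise_floor = 0, sigmoid_slope = Inf, clutter_n = 0, ...)
}

# single-target subject at an arbitrary position
point_subject <- function(pos, seed = 5, emission = det_emission(),
                          constants = test_constants(), pthr = NULL, ...) {
  if (is.null(pthr)) {
    sample_virtual_subject(1, seed, positions = matrix(pos, 1),
                           emission = emission, constants = constants, ...)
  } else {
    sample_virtual_subject(1, seed, positions = matrix(pos, 1),
                           emission = emission, constants = constants,
                           pthr_mean = pthr, pthr_sd = 0, ...)
  }
}

# constructed session-log fixture reproducing the retrospective-exclusion
# bookkeeping: n targets, with engineered rule hits (rule ids 1-4) possibly
# overlapping on the same target
exclusion_fixture <- function(n_targets = 288,
                              rule1_ids, rule2_ids, rule3_ids, rule4_ids) {
  tg <- data.frame(target_id = seq_len(n_targets),
                   x = rep(seq_len(18), length.out = n_targets) * 1e-3,
                   y = rep(seq_len(16), each = 18)[seq_len(n_targets)] * 1e-3,
                   z = 0)
  plan <- sonication_plan(tg, burst_length = 5e-3, target_level = 75,
                          n_tx_bursts = 60)
  det_step <- 24L  # calibration PNP 0.495 MPa
  rows <- list()
  states <- data.frame(target_id = tg$target_id, detected = TRUE,
                       detection_step = det_step,
                       calibration_pnp = ramp_pressure(det_step, plan),
                       stop_reason = "pci", completed = TRUE)
  good <- list(metrics = list(spta = 10, pslr = 40,
                              positional_error_lateral = 0.5e-3,
                              positional_error_axial = 1e-3),
               detected = TRUE)
  for (i in seq_len(n_targets)) {
    # pre-detection record: retrospectively suspicious only for rule-1 targets
    pre <- good
    pre$detected <- FALSE
    if (i %in% rule1_ids) {
      pre$metrics$pslr <- 85   # fails online gate, passes relaxed review
    } else {
      pre$metrics$pslr <- 99   # fails both
    }
    rows[[length(rows) + 1]] <- data.frame(
      timestamp = i, target_id = i, phase = "calibration", step = 15L,
      applied_pnp = ramp_pressure(15L, plan), burst_length = 5e-3,
      spta = pre$metrics$spta, pslr = pre$metrics$pslr,
      lateral_err = pre$metrics$positional_error_lateral,
      axial_err = pre$metrics$positional_error_axial,
      pci_detected = FALSE, icd_ratio = NA_real_, icd_flagged = FALSE,
      min_output = FALSE, activated = NA)
    # detection record: rule-3 targets fail the stricter retrospective set
    det <- good
    det$metrics$pslr <- if (i %in% rule3_ids) 65 else 30
    rows[[length(rows) + 1]] <- data.frame(
      timestamp = i + 0.1, target_id = i, phase = "calibration",
      step = det_step, applied_pnp = ramp_pressure(det_step, plan),
      burst_length = 5e-3, spta = det$metrics$spta, pslr = det$metrics$pslr,
      lateral_err = det$metrics$positional_error_lateral,
      axial_err = det$metrics$positional_error_axial,
      pci_detected = TRUE, icd_ratio = NA_real_, icd_flagged = FALSE,
      min_output = FALSE, activated = TRUE)
    # one Tx record; coherent activity for rule-2 targets
    rows[[length(rows) + 1]] <- data.frame(
      timestamp = i + 0.2, target_id = i, phase = "tx", step = 1L,
      applied_pnp = 0.75 * states$calibration_pnp[i], burst_length = 5e-3,
      spta = 5, pslr = if (i %in% rule2_ids) 35 else 95,
      lateral_err = 0.5e-3, axial_err = 1e-3,
      pci_detected = i %in% rule2_ids, icd_ratio = NA_real_,
      icd_flagged = FALSE, min_output = FALSE, activated = NA)
  }
  log <- structure(list(records = do.call(rbind, rows), plan = plan, seed = 1L),
                   class = "session_log")
  anatomy <- seq_len(n_targets) %in% rule4_ids
  list(log = log, states = states, plan = plan, anatomy = anatomy)
}

grid_coords_for_test <- function(grid) {
  as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
}
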