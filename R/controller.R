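# Closed-loop exposure protocol: microbubble-free baseline pressure ramps,
# the calibration-phase ramp with dual PCI/ICD stopping, the fixed-pressure
# treatment (Tx) phase, and the retrospective quality-control exclusion
# rules. Targets are interleaved in raster order (posterior-left first) at
# the target-wise burst repetition frequency.

#' PCI detection thresholds
#'
#' @param pslr_max Maximum PSLR, percent.
#' @param lateral_max Maximum lateral positional error, m.
#' @param axial_max Maximum axial positional error, m.
#' @return Named list of thresholds.
#' @export
pci_thresholds <- function(pslr_max = 70, lateral_max = 2e-3, axial_max = 4e-3) {
  list(pslr_max = pslr_max, lateral_max = lateral_max, axial_max = axial_max)
}

#' Sonication plan for one session
#'
#' Orders the subject's targets in a raster pattern starting at the
#' posterior-left-most target (ascending y, then ascending x) and fixes the
#' exposure parameters shared by all targets of the session.
#'
#' @param subject A `virtual_subject` (or a data frame with `target_id`,
#'   `x`, `y`, `z`).
#' @param burst_length Burst length, s (1, 5 or 10 ms in the protocol).
#' @param target_level Treatment pressure as a percentage of the calibration
#'   pressure (50-90).
#' @param n_tx_bursts Number of treatment-phase bursts (0, 60, 120 or 240).
#' @param brf Target-wise burst repetition frequency, Hz (0.2 or 1.0).
#' @param ramp_start Calibration ramp starting PNP, Pa.
#' @param ramp_step Calibration ramp step, Pa.
#' @param max_output Maximum system output PNP, Pa.
#' @return Object of class `sonication_plan`.
#' @export
sonication_plan <- function(subject, burst_length = 5e-3, target_level = 75,
                            n_tx_bursts = 120, brf = 0.2,
                            ramp_start = 0.15e6, ramp_step = 15e3,
                            max_output = 1.0e6) {
  stopifnot(target_level > 0, target_level <= 100, ramp_step > 0,
            brf > 0, n_tx_bursts >= 0, max_output > ramp_start)
  tg <- if (inherits(subject, "virtual_subject")) subject$targets else subject
  ord <- order(tg$y, tg$x)
  structure(list(targets = tg[ord, c("target_id", "x", "y", "z")],
                 burst_length = burst_length,
                 target_level = target_level,
                 n_tx_bursts = n_tx_bursts,
                 brf = brf,
                 ramp_start = ramp_start,
                 ramp_step = ramp_step,
                 max_output = max_output),
            class = "sonication_plan")
}

#' @export
print.sonication_plan <- function(x, ...) {
  cat(sprintf("sonication_plan: %d targets | %g ms bursts | %g%% target level | %d Tx bursts | BRF %g Hz\n",
              nrow(x$targets), x$burst_length * 1e3, x$target_level,
              x$n_tx_bursts, x$brf))
  invisible(x)
}

#' Applied PNP at a calibration ramp step
#'
#' @param step Step index (1-based).
#' @param plan A `sonication_plan`.
#' @return PNP in Pa: `ramp_start + (step - 1) * ramp_step`.
#' @export
ramp_pressure <- function(step, plan) {
  plan$ramp_start + (step - 1) * plan$ramp_step
}

n_ramp_steps <- function(plan) {
  floor((plan$max_output - plan$ramp_start) / plan$ramp_step) + 1L
}

# shared per-burst processing: filter -> beamform -> metrics -> detect
process_burst <- function(capture, geometry, grid, thresholds, fd_min,
                          sound_speed) {
  vol <- beamform_volume(capture, geometry, grid, fd_min = fd_min,
                         bandpass = TRUE, sound_speed = sound_speed)
  met <- compute_quality_metrics(vol, target = grid$centre)
  det <- pci_detect(met, thresholds$pslr_max, thresholds$lateral_max,
                    thresholds$axial_max)
  list(volume = vol, metrics = met, detected = det,
       icd = icd_integrals(capture))
}

empty_log_records <- function() {
  data.frame(timestamp = numeric(0), target_id = integer(0),
             phase = character(0), step = integer(0), applied_pnp = numeric(0),
             burst_length = numeric(0), spta = numeric(0), pslr = numeric(0),
             lateral_err = numeric(0), axial_err = numeric(0),
             pci_detected = logical(0), icd_ratio = numeric(0),
             icd_flagged = logical(0), min_output = logical(0),
             activated = logical(0))
}

log_row <- function(timestamp, target_id, phase, step, pnp, bl, proc,
                    icd_ratio = NA_real_, icd_flagged = FALSE,
                    min_output = FALSE, activated = NA) {
  data.frame(timestamp = timestamp, target_id = target_id, phase = phase,
             step = step, applied_pnp = pnp, burst_length = bl,
             spta = proc$metrics$spta, pslr = proc$metrics$pslr,
             lateral_err = proc$metrics$positional_error_lateral,
             axial_err = proc$metrics$positional_error_axial,
             pci_detected = proc$detected, icd_ratio = icd_ratio,
             icd_flagged = icd_flagged, min_output = min_output,
             activated = activated)
}

#' Baseline pressure ramps without microbubbles
#'
#' Runs the full pressure ramp at every target with `mb_present = FALSE`,
#' recording per-step PCI metrics (for false-positive-rate evaluation) and
#' per-step, per-channel ICD band integrals (the denominators of the
#' calibration-phase ICD ratio statistic).
#'
#' @param plan A [sonication_plan()].
#' @param subject A `virtual_subject`.
#' @param geometry An `array_geometry`.
#' @param seed Integer seed.
#' @param constants A [system_constants()] object.
#' @param thresholds [pci_thresholds()].
#' @param fd_min Narrowband beamformer decimated-envelope rate floor, Hz.
#' @param pci_metrics Beamform every baseline burst and record its PCI
#'   metrics (needed for false-positive-rate evaluation)? `FALSE` records
#'   only the ICD band integrals, which is all the calibration-phase ratio
#'   statistic requires.
#' @return Object of class `session_log` with a `baseline_icd` element
#'   (targets x steps x channels array of band integrals).
#' @export
run_baseline_ramps <- function(plan, subject, geometry, seed,
                               constants = system_constants(),
                               thresholds = pci_thresholds(),
                               fd_min = 150e3, pci_metrics = TRUE) {
  ns <- n_ramp_steps(plan)
  tg <- plan$targets
  nt <- nrow(tg)
  seeds <- child_seeds(seed, ns * nt)
  grids <- lapply(seq_len(nt), function(j) {
    beamform_grid(as.numeric(tg[j, c("x", "y", "z")]))
  })
  bicd <- array(NA_real_, c(nt, ns, nrow(geometry$icd_receiver_positions)))
  rows <- vector("list", ns * nt)
  b <- 0L
  for (k in seq_len(ns)) {
    pnp <- ramp_pressure(k, plan)
    for (j in seq_len(nt)) {
      b <- b + 1L
      ts <- (k - 1) / plan$brf + (j - 1) / (plan$brf * nt)
      cap <- simulate_burst(geometry, subject, tg$target_id[j], pnp,
                            plan$burst_length, mb_present = FALSE,
                            seed = seeds[b], constants = constants,
                            phase_tag = "baseline", timestamp = ts)
      proc <- if (pci_metrics) {
        process_burst(cap, geometry, grids[[j]], thresholds,
                      fd_min, constants$sound_speed)
      } else {
        list(metrics = list(spta = NA_real_, pslr = NA_real_,
                            positional_error_lateral = NA_real_,
                            positional_error_axial = NA_real_),
             detected = FALSE, icd = icd_integrals(cap))
      }
      bicd[j, k, ] <- proc$icd
      rows[[b]] <- log_row(ts, tg$target_id[j], "baseline", k, pnp,
                           plan$burst_length, proc, activated = cap$activated)
    }
  }
  structure(list(records = do.call(rbind, rows), plan = plan,
                 seed = as.integer(seed), baseline_icd = bicd),
            class = "session_log")
}

#' Calibration-phase pressure ramp with dual PCI/ICD stopping
#'
#' Increases the PNP by one step after each burst at a target until either
#' coherent microbubble activity is detected on PCI or the ICD ratio series
#' is flagged; the detection burst's PNP becomes that target's calibration
#' pressure and the output drops to the minimum system output for its
#' remaining calibration-phase bursts. Targets are interleaved in raster
#' order; the phase ends when every target has stopped (or reached maximum
#' output undetected, in which case it is marked uncalibrated).
#'
#' @inheritParams run_baseline_ramps
#' @param baseline The [run_baseline_ramps()] log (ICD denominators).
#' @param icd_n_ref,icd_k ICD flag reference-window length and SD multiplier.
#' @param icd_latency Bursts of operator latency between the ICD flag and the
#'   ramp actually stopping (0 = automatic stop on the flagged burst).
#' @param process_min_output Simulate and beamform the minimum-output bursts
#'   delivered after a target's detection (protocol-faithful)? `FALSE` logs
#'   them with NA metrics without simulating, which changes nothing about
#'   detection since the ramp at that target has already stopped.
#' @return List with `log` (a `session_log`) and `states` (a data frame with
#'   `target_id`, `detected`, `detection_step`, `calibration_pnp`,
#'   `stop_reason`, `completed`).
#' @export
run_calibration_phase <- function(plan, subject, geometry, baseline, seed,
                                  constants = system_constants(),
                                  thresholds = pci_thresholds(),
                                  fd_min = 150e3, icd_n_ref = 10L,
                                  icd_k = 5, icd_latency = 0L,
                                  process_min_output = TRUE) {
  ns <- n_ramp_steps(plan)
  if (dim(baseline$baseline_icd)[2] < ns) {
    stop("baseline ramp does not cover the calibration pressure steps")
  }
  tg <- plan$targets
  nt <- nrow(tg)
  seeds <- child_seeds(seed, (ns + 4L) * nt)
  grids <- lapply(seq_len(nt), function(j) {
    beamform_grid(as.numeric(tg[j, c("x", "y", "z")]))
  })
  active <- rep(TRUE, nt)
  det_step <- rep(NA_integer_, nt)
  cal_pnp <- rep(NA_real_, nt)
  reason <- rep(NA_character_, nt)
  flag_pending <- rep(NA_integer_, nt)  # rounds remaining before latency stop
  flag_step <- rep(NA_integer_, nt)
  ratios <- vector("list", nt)
  rows <- list()
  b <- 0L
  k <- 0L
  while (any(active)) {
    k <- k + 1L
    for (j in seq_len(nt)) {
      b <- b + 1L
      ts <- (k - 1) / plan$brf + (j - 1) / (plan$brf * nt)
      is_min <- !active[j]
      pnp <- if (is_min) constants$min_output_pressure else ramp_pressure(k, plan)
      if (is_min && !process_min_output) {
        rows[[b]] <- data.frame(timestamp = ts, target_id = tg$target_id[j],
                                phase = "calibration", step = k,
                                applied_pnp = pnp,
                                burst_length = plan$burst_length,
                                spta = NA_real_, pslr = NA_real_,
                                lateral_err = NA_real_, axial_err = NA_real_,
                                pci_detected = FALSE, icd_ratio = NA_real_,
                                icd_flagged = FALSE, min_output = TRUE,
                                activated = NA)
        next
      }
      cap <- simulate_burst(geometry, subject, tg$target_id[j], pnp,
                            plan$burst_length, mb_present = TRUE,
                            seed = seeds[((b - 1L) %% length(seeds)) + 1L],
                            constants = constants, phase_tag = "calibration",
                            timestamp = ts)
      proc <- process_burst(cap, geometry, grids[[j]], thresholds,
                            fd_min, constants$sound_speed)
      ratio <- NA_real_
      flagged <- FALSE
      if (!is_min) {
        base_int <- baseline$baseline_icd[j, k, ]
        guarded <- base_int < 1e-12
        ratio <- mean(proc$icd / pmax(base_int, 1e-12))
        if (all(guarded)) ratio <- NA_real_
        ratios[[j]] <- c(ratios[[j]], ratio)
        if (!anyNA(ratios[[j]])) {
          f <- suppressWarnings(icd_flag(ratios[[j]], icd_n_ref, icd_k))
          flagged <- !is.na(f) && f == k
        }
        pci_hit <- proc$detected
        icd_hit <- flagged && icd_latency == 0L
        if (flagged && icd_latency > 0L && is.na(flag_pending[j])) {
          flag_pending[j] <- icd_latency
          flag_step[j] <- k
        } else if (!is.na(flag_pending[j])) {
          flag_pending[j] <- flag_pending[j] - 1L
          if (flag_pending[j] <= 0L) icd_hit <- TRUE
        }
        if (pci_hit || icd_hit) {
          active[j] <- FALSE
          det_step[j] <- if (icd_hit && !is.na(flag_step[j])) flag_step[j] else k
          cal_pnp[j] <- ramp_pressure(det_step[j], plan)
          reason[j] <- if (pci_hit && icd_hit) "both"
                       else if (pci_hit) "pci" else "icd"
        } else if (k >= ns) {
          active[j] <- FALSE
          reason[j] <- "max_output_reached"
        }
      }
      rows[[b]] <- log_row(ts, tg$target_id[j], "calibration", k, pnp,
                           plan$burst_length, proc, icd_ratio = ratio,
                           icd_flagged = flagged, min_output = is_min,
                           activated = cap$activated)
    }
  }
  if (any(reason == "max_output_reached", na.rm = TRUE)) {
    warning("uncalibrated target(s) reached maximum output without detection; excluded from Tx phase")
  }
  states <- data.frame(target_id = tg$target_id,
                       detected = !is.na(det_step),
                       detection_step = det_step,
                       calibration_pnp = cal_pnp,
                       stop_reason = reason,
                       completed = TRUE)
  log <- structure(list(records = do.call(rbind, rows), plan = plan,
                        seed = as.integer(seed),
                        baseline_icd = baseline$baseline_icd),
                   class = "session_log")
  list(log = log, states = states)
}

#' Treatment (Tx) phase at a fixed fraction of the calibration pressure
#'
#' Delivers `n_tx_bursts` bursts per calibrated target at
#' `target_level/100 x calibration PNP`, in raster order at the target-wise
#' burst repetition frequency. PCI monitoring continues and detections are
#' logged but not acted upon (the protocol's Tx phase is open-loop). A
#' positive emission-model `drift_rate` lowers the effective activation
#' threshold burst by burst, producing the retrospective coherent-activity
#' events the exclusion rules screen for.
#'
#' @inheritParams run_baseline_ramps
#' @param states Calibration states from [run_calibration_phase()].
#' @param t_offset Session time at which the phase starts, s.
#' @return A `session_log`.
#' @export
run_tx_phase <- function(plan, states, subject, geometry, seed,
                         constants = system_constants(),
                         thresholds = pci_thresholds(),
                         fd_min = 150e3, t_offset = 0) {
  tg <- plan$targets
  nt <- nrow(tg)
  included <- states$detected[match(tg$target_id, states$target_id)]
  if (plan$n_tx_bursts == 0 || !any(included)) {
    return(structure(list(records = empty_log_records(), plan = plan,
                          seed = as.integer(seed)),
                     class = "session_log"))
  }
  seeds <- child_seeds(seed, plan$n_tx_bursts * nt)
  grids <- lapply(seq_len(nt), function(j) {
    beamform_grid(as.numeric(tg[j, c("x", "y", "z")]))
  })
  rows <- list()
  b <- 0L
  for (k in seq_len(plan$n_tx_bursts)) {
    for (j in seq_len(nt)) {
      if (!included[j]) next
      b <- b + 1L
      ts <- t_offset + (k - 1) / plan$brf + (j - 1) / (plan$brf * nt)
      st <- states[states$target_id == tg$target_id[j], ]
      pnp <- plan$target_level / 100 * st$calibration_pnp
      row_s <- match(tg$target_id[j], subject$targets$target_id)
      em <- subject$emission[[row_s]]
      pov <- if (em$drift_rate > 0) {
        em$threshold_pressure * (1 - em$drift_rate * (k - 1))
      } else NULL
      cap <- simulate_burst(geometry, subject, tg$target_id[j], pnp,
                            plan$burst_length, mb_present = TRUE,
                            seed = seeds[b], constants = constants,
                            phase_tag = "tx", timestamp = ts,
                            pthr_override = pov)
      proc <- process_burst(cap, geometry, grids[[j]], thresholds,
                            fd_min, constants$sound_speed)
      rows[[b]] <- log_row(ts, tg$target_id[j], "tx", k, pnp,
                           plan$burst_length, proc,
                           activated = cap$activated)
    }
  }
  structure(list(records = do.call(rbind, rows), plan = plan,
                 seed = as.integer(seed)),
            class = "session_log")
}

#' Merge session logs (baseline + calibration + Tx)
#'
#' @param ... `session_log` objects sharing a plan.
#' @return A `session_log` with row-bound records.
#' @export
merge_session_logs <- function(...) {
  logs <- list(...)
  structure(list(records = do.call(rbind, lapply(logs, `[[`, "records")),
                 plan = logs[[1]]$plan, seed = logs[[1]]$seed),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  ph <- table(x$records$phase)
  cat(sprintf("session_log: %d bursts (%s)\n", nrow(x$records),
              paste(sprintf("%s %d", names(ph), ph), collapse = ", ")))
  invisible(x)
}

#' Retrospective quality-control exclusion rules
#'
#' Flags targets for exclusion from analysis:
#' \enumerate{
#'   \item the effective target level exceeded the intended level by more
#'     than 5 percentage points, judged by re-screening calibration-phase
#'     bursts before the detection burst with relaxed (retrospective) PCI
#'     thresholds;
#'   \item coherent microbubble activity was observed during the Tx phase;
#'   \item the calibration detection fails a stricter retrospective
#'     threshold set (a stand-in for manual re-classification of the
#'     detection projections as a false positive);
#'   \item target-wise quantification is confounded by anatomy (ventricles,
#'     subarachnoid cisterns) -- supplied as an input flag.
#' }
#'
#' @param log A merged `session_log` covering calibration and Tx phases.
#' @param states Calibration states.
#' @param plan The session's `sonication_plan`.
#' @param anatomy_flags Logical per target (rule 4); default all `FALSE`.
#' @param retrospective Relaxed threshold list (rule 1), as
#'   [pci_thresholds()].
#' @param strict Stricter threshold list (rule 3).
#' @return Data frame: `target_id`, `rule1_effective_tl_exceeded`,
#'   `rule2_tx_coherent_activity`, `rule3_false_positive_calibration`,
#'   `rule4_anatomy_confound`, `effective_target_level`, `excluded`.
#' @export
apply_exclusion_rules <- function(log, states, plan, anatomy_flags = NULL,
                                  retrospective = pci_thresholds(90, 3e-3, 6e-3),
                                  strict = pci_thresholds(60, 1.2e-3, 3e-3)) {
  rec <- log$records
  ids <- states$target_id
  nt <- length(ids)
  if (is.null(anatomy_flags)) anatomy_flags <- rep(FALSE, nt)
  stopifnot(length(anatomy_flags) == nt)
  r1 <- r2 <- r3 <- rep(FALSE, nt)
  eff_tl <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    st <- states[i, ]
    cal <- rec[rec$target_id == ids[i] & rec$phase == "calibration" &
                 !rec$min_output, , drop = FALSE]
    if (st$detected) {
      tx_pnp <- plan$target_level / 100 * st$calibration_pnp
      pre <- cal[cal$step < st$detection_step, , drop = FALSE]
      retro_hit <- pre$pslr <= retrospective$pslr_max &
        pre$lateral_err <= retrospective$lateral_max &
        pre$axial_err <= retrospective$axial_max
      if (any(retro_hit)) {
        s_first <- min(pre$step[retro_hit])
        eff_tl[i] <- 100 * tx_pnp / ramp_pressure(s_first, plan)
        r1[i] <- eff_tl[i] > plan$target_level + 5
      }
      det <- cal[cal$step == st$detection_step, , drop = FALSE]
      if (nrow(det) == 1 && st$stop_reason %in% c("pci", "both")) {
        r3[i] <- !(det$pslr <= strict$pslr_max &
                     det$lateral_err <= strict$lateral_max &
                     det$axial_err <= strict$axial_max)
      }
    }
    txr <- rec[rec$target_id == ids[i] & rec$phase == "tx", , drop = FALSE]
    r2[i] <- nrow(txr) > 0 && any(txr$pci_detected)
  }
  data.frame(target_id = ids,
             rule1_effective_tl_exceeded = r1,
             rule2_tx_coherent_activity = r2,
             rule3_false_positive_calibration = r3,
             rule4_anatomy_confound = as.logical(anatomy_flags),
             effective_target_level = eff_tl,
             excluded = r1 | r2 | r3 | as.logical(anatomy_flags))
}

#' Write a session log as JSON-lines
#'
#' One JSON object per burst record, preceded by nothing; a separate header
#' JSON carries the plan and seed.
#'
#' @param log A `session_log`.
#' @param path Records file path (`.jsonl`).
#' @param header_path Optional header JSON path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path, header_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log$records))) {
    writeLines(jsonlite::toJSON(as.list(log$records[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  if (!is.null(header_path)) {
    jsonlite::write_json(list(plan = unclass(log$plan), seed = log$seed),
                         header_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
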