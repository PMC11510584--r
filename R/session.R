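# End-to-end session orchestration: a single master seed fans out into
# stage-specific child seeds (geometry, subject, baseline, calibration, Tx,
# outcomes, imaging, quantification), so a full run is reproducible
# end-to-end and every stage is independently reproducible from its recorded
# child seed.

# Table-1 parameter combinations of the study protocol, by preset name
preset_table <- function() {
  c2 <- expand.grid(burst_length_ms = c(1, 5, 10), target_level = c(50, 75),
                    n_tx_bursts = c(0, 60, 120, 240))
  c2 <- c2[!(c2$burst_length_ms == 1 & c2$target_level == 50), ]  # 1 ms run at 75% only
  c2$brf <- 0.2
  c2$cohort <- 2
  c1 <- rbind(
    data.frame(burst_length_ms = 5, target_level = 75,
               n_tx_bursts = c(0, 60, 120, 240), brf = 1.0, cohort = 1),
    data.frame(burst_length_ms = 5, target_level = c(50, 70, 80, 90),
               n_tx_bursts = 120, brf = 1.0, cohort = 1))
  rbind(c1, c2)
}

#' Named sonication-parameter preset
#'
#' Resolves a preset name of the form `cohort2_5ms_75TL_120` (cohort, burst
#' length, target level, Tx bursts) to the corresponding parameter
#' combination of the study protocol; unknown combinations are rejected.
#'
#' @param name Preset name string.
#' @return List: `burst_length` (s), `target_level`, `n_tx_bursts`, `brf`.
#' @examples
#' plan_preset("cohort2_5ms_75TL_240")
#' @export
plan_preset <- function(name) {
  m <- regmatches(name, regexec("^cohort([12])_([0-9]+)ms_([0-9]+)TL_([0-9]+)$", name))[[1]]
  if (length(m) != 5) stop("preset name must look like 'cohort2_5ms_75TL_120'")
  cohort <- as.integer(m[2])
  bl <- as.numeric(m[3])
  tl <- as.numeric(m[4])
  nb <- as.integer(m[5])
  tab <- preset_table()
  hit <- tab$cohort == cohort & tab$burst_length_ms == bl &
    tab$target_level == tl & tab$n_tx_bursts == nb
  if (!any(hit)) stop(sprintf("'%s' is not a protocol parameter combination", name))
  list(burst_length = bl * 1e-3, target_level = tl, n_tx_bursts = nb,
       brf = tab$brf[which(hit)[1]])
}

#' Session configuration
#'
#' @param master_seed Master seed; all stage seeds derive from it.
#' @param preset Preset name (see [plan_preset()]); overridden by any of
#'   `burst_length`, `target_level`, `n_tx_bursts`, `brf` given explicitly.
#' @param n_targets Targets per session.
#' @param n_modules Array modules to simulate (64 = full array; smaller
#'   values give a reduced-channel-count array for fast runs).
#' @param constants A [system_constants()] object (override e.g.
#'   `capture_length` to scale simulations).
#' @param emission Prototype [emission_model()].
#' @param imaging_noise_sd T1w voxel noise SD (fraction).
#' @param max_output Calibration ramp ceiling, Pa.
#' @param anatomy_flags Optional per-target anatomy-confound flags (rule 4).
#' @param fd_min Narrowband beamformer decimated-envelope rate floor, Hz.
#' @param ... Explicit plan parameter overrides (`burst_length`,
#'   `target_level`, `n_tx_bursts`, `brf`).
#' @return Object of class `session_config`.
#' @export
session_config <- function(master_seed, preset = "cohort2_5ms_75TL_120",
                           n_targets = 16, n_modules = 64,
                           constants = system_constants(),
                           emission = emission_model(),
                           imaging_noise_sd = 0.02,
                           max_output = 1.0e6,
                           anatomy_flags = NULL,
                           fd_min = 150e3, ...) {
  p <- plan_preset(preset)
  dots <- list(...)
  for (f in c("burst_length", "target_level", "n_tx_bursts", "brf")) {
    if (!is.null(dots[[f]])) p[[f]] <- dots[[f]]
  }
  structure(list(master_seed = as.integer(master_seed), preset = preset,
                 plan_params = p, n_targets = n_targets,
                 n_modules = n_modules, constants = constants,
                 emission = emission, imaging_noise_sd = imaging_noise_sd,
                 max_output = max_output, anatomy_flags = anatomy_flags,
                 fd_min = fd_min),
            class = "session_config")
}

#' Run a full simulated session end-to-end
#'
#' Baseline ramps, calibration phase, Tx phase, synthetic post-sonication
#' imaging, ROI quantification, exclusion rules and the assembled outcome
#' table, all driven by the configuration's master seed. Reruns with the
#' same configuration are identical.
#'
#' @param config A [session_config()].
#' @return Object of class `session_bundle`: `geometry`, `subject`, `plan`,
#'   `log` (merged `session_log`), `states`, `outcomes` (generator table),
#'   `t1w` volume, `quant` (recovered enhancement), `exclusions`,
#'   `outcome_table` (per-target assembled CSV-ready table), `qc` summary,
#'   `seeds` (the stage child seeds).
#' @export
run_full_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  sds <- child_seeds(config$master_seed, 8)
  names(sds) <- c("geometry", "subject", "baseline", "calibration", "tx",
                  "outcomes", "imaging", "quant")
  geometry <- build_array_geometry(sds["geometry"], n_modules = config$n_modules,
                                   constants = config$constants)
  subject <- sample_virtual_subject(config$n_targets, sds["subject"],
                                    emission = config$emission,
                                    constants = config$constants)
  pp <- config$plan_params
  plan <- sonication_plan(subject, burst_length = pp$burst_length,
                          target_level = pp$target_level,
                          n_tx_bursts = pp$n_tx_bursts, brf = pp$brf,
                          max_output = config$max_output)
  baseline <- run_baseline_ramps(plan, subject, geometry, sds["baseline"],
                                 constants = config$constants,
                                 fd_min = config$fd_min)
  cal <- run_calibration_phase(plan, subject, geometry, baseline,
                               sds["calibration"],
                               constants = config$constants,
                               fd_min = config$fd_min)
  t_off <- max(cal$log$records$timestamp) + 1 / plan$brf
  tx <- run_tx_phase(plan, cal$states, subject, geometry, sds["tx"],
                     constants = config$constants,
                     fd_min = config$fd_min, t_offset = t_off)
  log <- merge_session_logs(baseline, cal$log, tx)

  outcomes <- generate_outcome_table(subject, plan, sds["outcomes"])
  t1w <- simulate_t1w_volume(subject, outcomes$gd_true,
                             noise_sd = config$imaging_noise_sd,
                             seed = sds["imaging"])
  quant <- relative_gd_enhancement(t1w, subject, seed = sds["quant"])
  excl <- apply_exclusion_rules(merge_session_logs(cal$log, tx), cal$states,
                                plan, anatomy_flags = config$anatomy_flags)

  tab <- merge(merge(quant, outcomes, by = "target_id"),
               excl[, c("target_id", "excluded")], by = "target_id")
  tab <- merge(tab, cal$states[, c("target_id", "calibration_pnp", "stop_reason")],
               by = "target_id")
  qc <- list(n_targets = config$n_targets,
             n_calibrated = sum(cal$states$detected),
             stop_reasons = table(cal$states$stop_reason),
             n_excluded = sum(excl$excluded),
             n_bursts = nrow(log$records))
  structure(list(geometry = geometry, subject = subject, plan = plan,
                 log = log, states = cal$states, outcomes = outcomes,
                 t1w = t1w, quant = quant, exclusions = excl,
                 outcome_table = tab, qc = qc, seeds = sds,
                 config = config),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("session_bundle: %d targets, %d calibrated, %d excluded, %d bursts logged\n",
              x$qc$n_targets, x$qc$n_calibrated, x$qc$n_excluded, x$qc$n_bursts))
  invisible(x)
}

#' Write the artifacts of a session bundle to a directory
#'
#' JSON-lines burst log plus header, outcome table CSV, geometry JSON and
#' the T1w volume as NIfTI.
#'
#' @param bundle A `session_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_session_log(bundle$log, file.path(dir, "bursts.jsonl"),
                    file.path(dir, "session.json"))
  utils::write.csv(bundle$outcome_table, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  write_geometry_json(bundle$geometry, file.path(dir, "geometry.json"))
  write_volume_nifti(bundle$t1w, file.path(dir, "t1w.nii"))
  jsonlite::write_json(list(master_seed = bundle$config$master_seed,
                            stage_seeds = as.list(bundle$seeds),
                            qc = list(n_targets = bundle$qc$n_targets,
                                      n_calibrated = bundle$qc$n_calibrated,
                                      n_excluded = bundle$qc$n_excluded,
                                      n_bursts = bundle$qc$n_bursts)),
                       file.path(dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
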