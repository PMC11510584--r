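#' System constants for the clinical-prototype hemispherical FUS array
#'
#' Bundles the fixed acoustic and acquisition parameters of the transmit/receive
#' system: a 258 kHz lateral-mode drive, receivers tuned to the first
#' ultraharmonic (387 kHz) for passive cavitation imaging (PCI) and to the
#' subharmonic (129 kHz) for inertial cavitation detection (ICD), a 25.1 cm
#' diameter hemispherical scaffold, 10 MS/s digitisation and a 13.1 ms capture
#' window per burst. The minimum system output (0.55 Vpp) corresponds to
#' approximately 0.15 MPa peak negative pressure (PNP), defining a linear
#' voltage-to-pressure map.
#'
#' @param transmit_freq Drive frequency in Hz.
#' @param sampling_rate Receive digitisation rate in samples/s.
#' @param capture_length RF capture window per burst in seconds.
#' @param hemisphere_diameter Scaffold diameter in metres.
#' @param min_output_pressure Free-field PNP at the minimum system output, Pa.
#' @param min_output_vpp Peak-to-peak drive voltage at minimum output, V.
#' @param sound_speed Uniform medium sound speed in m/s (degassed water).
#'
#' @return An object of class `system_constants`: a list with the arguments
#'   above plus `ultraharmonic_freq` (1.5x drive), `subharmonic_freq`
#'   (0.5x drive) and `pressure_per_volt` (Pa per Vpp).
#' @examples
#' sc <- system_constants()
#' sc$ultraharmonic_freq / sc$transmit_freq  # 1.5
#' @export
system_constants <- function(transmit_freq = 258e3,
                             sampling_rate = 10e6,
                             capture_length = 13.1e-3,
                             hemisphere_diameter = 0.251,
                             min_output_pressure = 0.15e6,
                             min_output_vpp = 0.55,
                             sound_speed = 1482) {
  stopifnot(transmit_freq > 0, sampling_rate > 0, capture_length > 0,
            hemisphere_diameter > 0, min_output_pressure > 0, sound_speed > 0)
  uh <- 1.5 * transmit_freq
  sh <- 0.5 * transmit_freq
  if (sampling_rate <= 2 * (uh + 13e3)) {
    stop("sampling_rate must exceed twice the upper edge of the ultraharmonic band")
  }
  structure(list(
    transmit_freq = transmit_freq,
    ultraharmonic_freq = uh,
    subharmonic_freq = sh,
    sampling_rate = sampling_rate,
    capture_length = capture_length,
    hemisphere_diameter = hemisphere_diameter,
    min_output_pressure = min_output_pressure,
    min_output_vpp = min_output_vpp,
    pressure_per_volt = min_output_pressure / min_output_vpp,
    sound_speed = sound_speed
  ), class = "system_constants")
}

#' Convert drive voltage to free-field pressure
#'
#' Linear map anchored so the minimum system output (0.55 Vpp) maps to
#' approximately 0.15 MPa PNP.
#'
#' @param vpp Peak-to-peak drive voltage(s), V.
#' @param constants A [system_constants()] object.
#' @return PNP in Pa.
#' @export
vpp_to_pressure <- function(vpp, constants = system_constants()) {
  stopifnot(all(vpp >= 0))
  vpp * constants$pressure_per_volt
}

#' @rdname vpp_to_pressure
#' @param pnp Peak negative pressure(s), Pa.
#' @export
pressure_to_vpp <- function(pnp, constants = system_constants()) {
  stopifnot(all(pnp >= 0))
  pnp / constants$pressure_per_volt
}

#' @export
print.system_constants <- function(x, ...) {
  cat("FUS system constants\n")
  cat(sprintf("  drive %g kHz | ultraharmonic %g kHz | subharmonic %g kHz\n",
              x$transmit_freq / 1e3, x$ultraharmonic_freq / 1e3,
              x$subharmonic_freq / 1e3))
  cat(sprintf("  fs %g MS/s, capture %g ms, hemisphere %g cm, c %g m/s\n",
              x$sampling_rate / 1e6, x$capture_length * 1e3,
              x$hemisphere_diameter * 1e2, x$sound_speed))
  invisible(x)
}
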