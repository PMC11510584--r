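# Spectral reductions for exposure control: the ultraharmonic PCI band
# filter, burst-gated magnitude spectra, and the ICD band-integration ratio
# statistic computed against microbubble-free baseline ramps.

#' Zero-phase ultraharmonic bandpass filter
#'
#' 8-pole Butterworth bandpass (380-400 kHz) applied forward-backward
#' (zero phase). Works on a vector or column-wise on a samples x channels
#' matrix.
#'
#' @param rf Numeric vector or matrix (samples x channels).
#' @param fs Sampling rate, samples/s.
#' @param band Passband edges, Hz.
#' @param order Total filter order (number of poles); must be even.
#' @return Filtered signal, same shape as `rf`.
#' @export
bandpass_ultraharmonic <- function(rf, fs = 10e6, band = c(380e3, 400e3),
                                   order = 8) {
  stopifnot(order %% 2 == 0, band[1] < band[2])
  if (band[2] >= fs / 2) stop("passband edge at or above Nyquist frequency")
  bf <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  if (is.matrix(rf)) {
    out <- rf
    for (ch in seq_len(ncol(rf))) out[, ch] <- signal::filtfilt(bf, rf[, ch])
    out
  } else {
    signal::filtfilt(bf, rf)
  }
}

#' Burst-gated magnitude spectrum of one channel
#'
#' Hann-tapered FFT magnitude over a sample window, with the frequency grid.
#'
#' @param rf Single-channel samples.
#' @param fs Sampling rate, samples/s.
#' @param window Integer sample indices to gate (default: all samples).
#' @return List `freqs` (Hz), `magnitude`, `df` (bin width, Hz).
#' @export
spectral_summary <- function(rf, fs, window = seq_along(rf)) {
  x <- rf[window]
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- stats::fft(x * w)
  nk <- floor(n / 2) + 1
  list(freqs = (seq_len(nk) - 1) * fs / n,
       magnitude = Mod(X[seq_len(nk)]),
       df = fs / n)
}

#' ICD band integral of one wideband-receiver channel
#'
#' Integrated magnitude spectrum over 119-139 kHz excluding a 10 kHz notch
#' centred on the subharmonic (129 kHz), i.e. over 119-124 and 134-139 kHz. The FFT is gated to the burst window (with a guard interval) and
#' Hann-tapered, so subharmonic tone leakage into the integration band is
#' suppressed.
#'
#' @param rf Single ICD channel samples.
#' @param fs Sampling rate, samples/s.
#' @param window Integer sample indices covering the burst.
#' @param band Integration band edges, Hz.
#' @param notch Excluded notch edges, Hz.
#' @return Scalar band integral (magnitude x Hz).
#' @export
icd_band_integral <- function(rf, fs = 10e6, window = seq_along(rf),
                              band = c(119e3, 139e3), notch = c(124e3, 134e3)) {
  sp <- spectral_summary(rf, fs, window)
  sel <- sp$freqs >= band[1] & sp$freqs <= band[2] &
    !(sp$freqs > notch[1] & sp$freqs < notch[2])
  sum(sp$magnitude[sel]) * sp$df
}

# sample window covering the burst arrival on the ICD receivers
burst_window <- function(capture, guard = 0.5e-3, constants = NULL) {
  fs <- capture$fs
  tau <- capture$emission_onset
  i0 <- max(1L, floor(tau * fs))
  i1 <- min(nrow(capture$icd_rf),
            ceiling((tau + capture$burst_length + guard) * fs) +
              ceiling(1e-4 * fs))  # allow for propagation to the far receivers
  i0:i1
}

# per-channel ICD band integrals for one capture
icd_integrals <- function(capture, guard = 0.5e-3) {
  w <- burst_window(capture, guard)
  vapply(seq_len(ncol(capture$icd_rf)),
         function(ch) icd_band_integral(capture$icd_rf[, ch], capture$fs, w),
         numeric(1))
}

#' Per-step channel-mean ICD ratio series
#'
#' Ratio of the calibration-phase band integral to the baseline (no
#' microbubbles) band integral at each pressure step, averaged across the
#' ICD receivers.
#'
#' @param calibration Either a list of `burst_capture`s (one per pressure
#'   step) or a steps x channels matrix of band integrals.
#' @param baseline The matched baseline captures or integral matrix (same
#'   number of steps and channels).
#' @param eps Floor applied to baseline integrals to guard division by zero;
#'   guarded steps are flagged in the `"guarded"` attribute.
#' @return Numeric vector of per-step channel-mean ratios.
#' @export
icd_ratio_series <- function(calibration, baseline, eps = 1e-12) {
  as_int <- function(x) {
    if (is.matrix(x)) return(x)
    t(vapply(x, icd_integrals, numeric(ncol(x[[1]]$icd_rf))))
  }
  ci <- as_int(calibration)
  bi <- as_int(baseline)
  if (!all(dim(ci) == dim(bi))) {
    stop("calibration and baseline step lists have mismatched dimensions")
  }
  guarded <- bi < eps
  bi[guarded] <- eps
  ratios <- rowMeans(ci / bi)
  attr(ratios, "guarded") <- apply(guarded, 1, any)
  ratios
}

#' First ICD-flagged pressure step
#'
#' A step is flagged when its channel-mean ratio exceeds the mean of the
#' first `n_ref` steps by more than `k` standard deviations (SD with the
#' n-1 denominator; strictly-greater comparison, so a degenerate zero-SD
#' reference never flags on ties).
#'
#' @param ratios Per-step channel-mean ratio series.
#' @param n_ref Number of initial reference steps (10 in the study protocol).
#' @param k SD multiplier (5 in the study protocol).
#' @return Integer index of the first flagged step, or `NA` if none (with a
#'   warning when fewer than `n_ref` steps are available).
#' @export
icd_flag <- function(ratios, n_ref = 10, k = 5) {
  ratios <- as.numeric(ratios)
  if (length(ratios) < n_ref) {
    warning("fewer steps than the reference window; no ICD flag possible")
    return(NA_integer_)
  }
  ref <- ratios[seq_len(n_ref)]
  thr <- mean(ref) + k * stats::sd(ref)
  later <- which(ratios > thr)
  later <- later[later > n_ref]
  if (length(later) == 0) NA_integer_ else later[1]
}
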