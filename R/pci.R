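# 3D passive cavitation image formation: delay, sum and integrate
# beamforming of the bandpassed ultraharmonic receiver signals over a small
# target-centred grid, plus the image-quality metrics used for detection.
#
# Two interchangeable backends:
#  (a) a reference time-domain implementation (nearest-sample delays at the
#      full sampling rate) intended for small instances and used as the
#      correctness oracle, and
#  (b) the default fast narrowband backend: complex demodulation at the
#      passband centre, boxcar decimation, envelope alignment by
#      nearest-decimated-sample shifts and phase-accurate carrier rotation,
#      with the inner sum in compiled code.

#' Target-centred beamforming grid
#'
#' @param centre Grid centre (the targeted coordinate), m.
#' @param extent Field-of-view edge lengths `c(x, y, z)`, m
#'   (11 x 11 x 21 mm in the study protocol).
#' @param voxel Isotropic voxel size, m.
#' @return Object of class `beamform_grid`: voxel-centre offset vectors and
#'   dimensions.
#' @export
beamform_grid <- function(centre = c(0, 0, 0),
                          extent = c(11e-3, 11e-3, 21e-3),
                          voxel = 1e-3) {
  half_n <- floor(extent / voxel / 2)
  offs <- lapply(half_n, function(h) seq(-h, h) * voxel)
  structure(list(centre = centre,
                 x = centre[1] + offs[[1]],
                 y = centre[2] + offs[[2]],
                 z = centre[3] + offs[[3]],
                 dims = vapply(offs, length, integer(1)),
                 voxel = voxel),
            class = "beamform_grid")
}

# voxel-centre world coordinates, scan order = x fastest then y then z
grid_coords <- function(grid) {
  as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
}

#' Delay-sum-integrate beamforming of one burst capture
#'
#' Forms the temporal-average beamformed power at every voxel of `grid`
#' from the (already bandpass-filtered) PCI receiver signals. The
#' integration window starts at the capture's emission onset and spans
#' `integration_time` (the entire burst length by default).
#'
#' @param capture A `burst_capture` whose `pci_rf` has been filtered with
#'   [bandpass_ultraharmonic()].
#' @param geometry An `array_geometry`.
#' @param grid A [beamform_grid()]; a warning is issued if it extends beyond
#'   the array interior.
#' @param integration_time Integration time, s (default: burst length).
#' @param backend `"narrowband"` (default, compiled) or `"time"` (reference
#'   time-domain; intended for small instances).
#' @param fd_min Minimum decimated envelope sampling rate of the narrowband
#'   backend, Hz; the actual rate is the next power-of-two fraction of the
#'   FFT grid at or above this.
#' @param demod_freq Demodulation frequency, Hz (passband centre).
#' @param sound_speed Sound speed used for the beamforming delays, m/s.
#' @param window_start Integration window start within the capture, s.
#' @param bandpass Apply the zero-phase ultraharmonic bandpass inside the
#'   backend (for raw captures)? Set `FALSE` when the capture was already
#'   filtered with [bandpass_ultraharmonic()].
#' @param band Passband edges used when `bandpass = TRUE`, Hz.
#' @param time_interp Delay handling of the time backend:
#'   `"nearest"` (reference definition) or `"linear"` interpolation.
#' @return Object of class `pci_volume`: `intensities` (3D array in grid
#'   scan order), `spta` (max intensity), `spta_vox` / `spta_loc` (voxel
#'   index and world coordinate of the max), `grid`, `integration_time`,
#'   `target_id` and burst metadata.
#' @export
beamform_volume <- function(capture, geometry, grid,
                            integration_time = NULL,
                            backend = c("narrowband", "time"),
                            fd_min = 150e3,
                            demod_freq = 390e3,
                            sound_speed = 1482,
                            window_start = NULL,
                            bandpass = FALSE,
                            band = c(380e3, 400e3),
                            time_interp = c("nearest", "linear")) {
  backend <- match.arg(backend)
  time_interp <- match.arg(time_interp)
  if (is.null(integration_time)) integration_time <- capture$burst_length
  if (integration_time > capture$burst_length + 1e-12) {
    integration_time <- min(integration_time,
                            nrow(capture$pci_rf) / capture$fs - capture$emission_onset)
  }
  if (is.null(window_start)) window_start <- capture$emission_onset
  vox <- grid_coords(grid)
  if (max(sqrt(rowSums(vox^2))) > geometry$radius) {
    warning("beamforming grid extends beyond the array interior")
  }
  recv <- geometry$pci_receiver_positions
  tau <- matrix(0, nrow(vox), nrow(recv))
  for (ch in seq_len(nrow(recv))) {
    tau[, ch] <- sqrt(colSums((t(vox) - recv[ch, ])^2)) / sound_speed
  }

  fs <- capture$fs
  intens <- if (backend == "narrowband") {
    bf_narrowband(capture$pci_rf, fs, tau, demod_freq, fd_min,
                  window_start, integration_time, bandpass, band)
  } else {
    rf <- capture$pci_rf
    if (bandpass) rf <- bandpass_ultraharmonic(rf, fs, band)
    bf_timedomain(rf, fs, tau, window_start, integration_time, time_interp)
  }
  arr <- array(intens, dim = grid$dims)
  imax <- which.max(arr)
  loc <- arrayInd(imax, grid$dims)
  structure(list(intensities = arr,
                 spta = arr[imax],
                 spta_vox = as.integer(loc),
                 spta_loc = c(grid$x[loc[1]], grid$y[loc[2]], grid$z[loc[3]]),
                 grid = grid,
                 integration_time = integration_time,
                 target_id = capture$target_id,
                 applied_pnp = capture$applied_pnp,
                 phase_tag = capture$phase_tag,
                 backend = backend),
            class = "pci_volume")
}

# fast narrowband backend, fused in the spectral domain: trim the capture to
# the integration window (plus delays and a guard), zero-pad to a power of
# two, take one FFT per channel, keep only the bins around the passband
# (optionally weighted by the zero-phase |H|^2 Butterworth response), and
# inverse-FFT those bins into a short complex baseband record -- i.e. exact
# (sinc) decimation of the analytic signal demodulated at the bin-aligned
# carrier. The compiled kernel then applies per-voxel nearest-sample envelope
# shifts with phase-accurate carrier rotation, sums channels, and averages
# |.|^2 over the window.
bf_narrowband <- function(rf, fs, tau, demod_freq, fd_min, window_start,
                          integration_time, bandpass = FALSE,
                          band = c(380e3, 400e3)) {
  n <- nrow(rf)
  nch <- ncol(rf)
  max_tau <- max(tau)
  guard <- 2000L
  i0 <- max(1L, floor(window_start * fs) - guard)
  i1 <- min(n, ceiling((window_start + integration_time + max_tau) * fs) + guard)
  rf <- rf[i0:i1, , drop = FALSE]
  nt <- nrow(rf)
  n2 <- stats::nextn(nt, 2)
  df <- fs / n2
  kd <- round(demod_freq / df)           # carrier bin (0-based)
  f_demod <- kd * df
  nd <- 2^ceiling(log2(max(8, fd_min * n2 / fs)))
  fd <- fs * nd / n2
  kk <- (kd - nd / 2):(kd + nd / 2 - 1)  # kept positive-frequency bins
  if (kk[1] < 1 || kk[length(kk)] > n2 / 2 - 1) {
    stop("decimated band extends beyond the positive-frequency range")
  }
  gain <- rep(2, nd)                     # analytic-signal doubling
  if (bandpass) {
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    e <- exp(-1i * 2 * pi * kk / n2)
    num <- Reduce(function(acc, j) acc * e + bf$b[j], seq_along(bf$b)[-1],
                  init = rep(bf$b[1] + 0i, length(e)))
    den <- Reduce(function(acc, j) acc * e + bf$a[j], seq_along(bf$a)[-1],
                  init = rep(bf$a[1] + 0i, length(e)))
    gain <- gain * Mod(num / den)^2      # forward-backward magnitude response
  }
  sidx <- ifelse(kk - kd >= 0, kk - kd + 1, kk - kd + nd + 1)
  Z <- matrix(0i, nd, nch)
  for (ch in seq_len(nch)) {
    X <- stats::fft(c(rf[, ch], numeric(n2 - nt)))
    s <- complex(nd)
    s[sidx] <- X[kk + 1] * gain
    Z[, ch] <- stats::fft(s, inverse = TRUE) / n2
  }
  t0_trim <- i0 / fs
  shift <- matrix(as.integer(round(tau * fd)), nrow(tau), ncol(tau))
  phase <- exp(2i * pi * f_demod * tau)
  w0 <- as.integer(round((window_start - t0_trim) * fd))
  w1 <- as.integer(min(nd, w0 + max(1, round(integration_time * fd))))
  beamform_nb_kernel(Z, shift, phase, w0, w1) / 2
}

# reference time-domain backend (nearest-sample or linear-interpolated
# delays); O(voxels x channels x window) in plain R -- small instances only
bf_timedomain <- function(rf, fs, tau, window_start, integration_time,
                          interp = "nearest") {
  n <- nrow(rf)
  j0 <- max(1L, floor(window_start * fs) + 1L)
  j1 <- min(n, j0 + max(1L, round(integration_time * fs)) - 1L)
  win <- j0:j1
  nv <- nrow(tau)
  out <- numeric(nv)
  for (v in seq_len(nv)) {
    s <- numeric(length(win))
    for (ch in seq_len(ncol(tau))) {
      if (interp == "nearest") {
        idx <- win + as.integer(round(tau[v, ch] * fs))
        ok <- idx >= 1 & idx <= n
        s[ok] <- s[ok] + rf[idx[ok], ch]
      } else {
        pos <- win + tau[v, ch] * fs
        lo <- floor(pos)
        fr <- pos - lo
        ok <- lo >= 1 & lo + 1 <= n
        s[ok] <- s[ok] + (1 - fr[ok]) * rf[lo[ok], ch] + fr[ok] * rf[lo[ok] + 1, ch]
      }
    }
    out[v] <- mean(s^2)
  }
  out
}

#' @export
print.pci_volume <- function(x, ...) {
  cat(sprintf("pci_volume: %s voxels, SPTA %.3g at (%s) mm [%s backend]\n",
              paste(dim(x$intensities), collapse = " x "), x$spta,
              paste(sprintf("%.1f", x$spta_loc * 1e3), collapse = ", "),
              x$backend))
  invisible(x)
}

#' Write a PCI volume to NIfTI
#'
#' @param volume A `pci_volume`.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_pci_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities,
                         pixdim = rep(volume$grid$voxel * 1e3, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 26-connected component of `mask` containing seed voxel (matrix coords)
connected_region <- function(mask, seed) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  visited <- array(FALSE, dims)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, 1)
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      sweep(frontier, 2, offs[k, ], `+`)
    }))
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- cand[, 1] + dims[1] * (cand[, 2] - 1) + dims[1] * dims[2] * (cand[, 3] - 1)
    keep <- !visited[lin] & mask[lin]
    lin <- unique(lin[keep])
    if (length(lin) == 0) break
    visited[lin] <- TRUE
    frontier <- cbind((lin - 1) %% dims[1] + 1,
                      ((lin - 1) %/% dims[1]) %% dims[2] + 1,
                      (lin - 1) %/% (dims[1] * dims[2]) + 1)
  }
  visited
}

# trilinear upsampling of a 3D array by an integer factor (separable)
upsample_array <- function(a, factor) {
  if (factor <= 1) return(a)
  up1 <- function(m, f) {
    # interpolate along rows of a matrix (dim 1), preserving end points
    n <- nrow(m)
    if (n == 1) return(m[rep(1, 1), , drop = FALSE])
    xin <- seq_len(n)
    xout <- seq(1, n, by = 1 / f)
    apply(m, 2, function(col) stats::approx(xin, col, xout)$y)
  }
  d <- dim(a)
  # axis 1
  a <- array(up1(matrix(a, d[1]), factor), dim = c((d[1] - 1) * factor + 1, d[2], d[3]))
  d <- dim(a)
  a <- aperm(array(up1(matrix(aperm(a, c(2, 1, 3)), d[2]), factor),
                   dim = c((d[2] - 1) * factor + 1, d[1], d[3])), c(2, 1, 3))
  d <- dim(a)
  a <- aperm(array(up1(matrix(aperm(a, c(3, 1, 2)), d[3]), factor),
                   dim = c((d[3] - 1) * factor + 1, d[1], d[2])), c(2, 3, 1))
  a
}

#' PCI image-quality metrics
#'
#' Computes the peak side-lobe ratio (PSLR), the lateral and axial positional
#' errors of the spatial-peak temporal-average (SPTA) intensity voxel with
#' respect to the intended target, and the full lengths of the shortest and
#' longest principal axes of a 3D ellipsoidal fit to the -3 dB intensity
#' isosurface.
#'
#' The main lobe is the 26-connected region of voxels at or above 50% of the
#' maximum that contains the maximum; PSLR is the largest intensity outside
#' it, as a percentage of the maximum. The -3 dB ellipsoid is fit by
#' intensity-weighted second moments of the above-half-maximum region on a
#' trilinearly upsampled grid, with a Gaussian-equivalence factor scaling the
#' principal standard deviations to -3 dB full lengths.
#'
#' @param volume A `pci_volume`.
#' @param target Intended target coordinate, m (default: grid centre).
#' @param threshold_frac Main-lobe threshold as a fraction of the maximum.
#' @param upsample Integer upsampling factor for the ellipsoid fit.
#' @return Object of class `pci_quality_metrics`: list with `pslr` (%),
#'   `positional_error_lateral` / `positional_error_axial` (m),
#'   `main_lobe_short_axis` / `main_lobe_long_axis` (m), `spta`,
#'   `axes_reliable` (FALSE when the main lobe touches the grid boundary)
#'   and `tied_max`.
#' @export
compute_quality_metrics <- function(volume, target = volume$grid$centre,
                                    threshold_frac = 0.5, upsample = 4L) {
  arr <- volume$intensities
  dims <- dim(arr)
  mx <- max(arr)
  if (!is.finite(mx) || mx <= 0) {
    # degenerate (e.g. all-zero noiseless) volume: no dominant peak
    return(structure(list(pslr = 100,
                          positional_error_lateral = Inf,
                          positional_error_axial = Inf,
                          main_lobe_short_axis = NA_real_,
                          main_lobe_long_axis = NA_real_,
                          spta = mx, axes_reliable = FALSE, tied_max = TRUE),
                     class = "pci_quality_metrics"))
  }
  tied <- sum(arr == mx) > 1
  seed <- volume$spta_vox
  lobe <- connected_region(arr >= threshold_frac * mx, seed)
  outside <- arr
  outside[lobe] <- -Inf
  pslr <- if (all(!is.finite(outside))) 0 else 100 * max(0, max(outside)) / mx

  derr <- volume$spta_loc - target
  lat <- sqrt(sum(derr[1:2]^2))
  ax <- abs(derr[3])

  lobe_idx <- which(lobe, arr.ind = TRUE)
  touches <- any(lobe_idx == 1) ||
    any(sweep(lobe_idx, 2, dims, `-`) == 0)

  # the -3 dB ellipsoid is fit to the full above-half-maximum isosurface
  # interior (sidelobe structure above the threshold included, as for an
  # isosurface of the whole volume), on a trilinearly upsampled grid
  up <- upsample_array(arr, upsample)
  mxu <- max(up)
  lobeu <- up >= threshold_frac * mxu
  h <- volume$grid$voxel / upsample
  idx <- which(lobeu, arr.ind = TRUE)
  w <- up[lobeu]
  pts <- sweep(idx, 2, (dim(up) + 1) / 2) * h
  mu <- colSums(pts * w) / sum(w)
  ctr <- sweep(pts, 2, mu)
  S <- crossprod(ctr * w, ctr) / sum(w)
  ev <- sort(pmax(0, eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  # Gaussian equivalence: for a half-maximum-truncated Gaussian intensity
  # profile the weighted SD is 0.50472 x the profile sigma, and the -3 dB
  # full length is 2*sqrt(2*log(2)) x sigma
  scale <- 2 * sqrt(2 * log(2)) / 0.5047194
  axes <- scale * sqrt(ev)

  structure(list(pslr = pslr,
                 positional_error_lateral = lat,
                 positional_error_axial = ax,
                 main_lobe_short_axis = axes[1],
                 main_lobe_long_axis = axes[3],
                 spta = mx,
                 axes_reliable = !touches,
                 tied_max = tied),
            class = "pci_quality_metrics")
}

#' @export
print.pci_quality_metrics <- function(x, ...) {
  cat(sprintf("PSLR %.1f%% | pos err lat %.2f mm ax %.2f mm | -3 dB axes %.2f / %.2f mm%s\n",
              x$pslr, x$positional_error_lateral * 1e3,
              x$positional_error_axial * 1e3,
              x$main_lobe_short_axis * 1e3, x$main_lobe_long_axis * 1e3,
              if (x$axes_reliable) "" else " (axes unreliable)"))
  invisible(x)
}

#' Coherent microbubble activity detection gate
#'
#' TRUE when the PSLR and both positional errors are within the exposure
#' control thresholds (all comparisons inclusive).
#'
#' @param metrics A `pci_quality_metrics`.
#' @param pslr_max Maximum PSLR, percent.
#' @param lateral_max Maximum lateral positional error, m.
#' @param axial_max Maximum axial positional error, m.
#' @return Logical.
#' @export
pci_detect <- function(metrics, pslr_max = 70, lateral_max = 2e-3,
                       axial_max = 4e-3) {
  stopifnot(is.finite(metrics$pslr))
  metrics$pslr <= pslr_max &&
    metrics$positional_error_lateral <= lateral_max &&
    metrics$positional_error_axial <= axial_max
}

#' Maximum intensity projections of a PCI volume
#'
#' @param volume A `pci_volume` (or a 3D array).
#' @return List of three matrices: `xy`, `xz`, `yz`.
#' @export
max_intensity_projection <- function(volume) {
  arr <- if (inherits(volume, "pci_volume")) volume$intensities else volume
  list(xy = apply(arr, c(1, 2), max),
       xz = apply(arr, c(1, 3), max),
       yz = apply(arr, c(2, 3), max))
}
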