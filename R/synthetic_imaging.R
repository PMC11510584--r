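# Synthetic post-sonication image volumes and target-wise outcome tables.
#
# T1w volumes emulate the post-exposure contrast-enhanced acquisition
# (100 mm field of view, 256 x 256 matrix -> 0.39 mm in-plane, 1.5 mm
# slices): a uniform baseline with multiplicative Gaussian enhancement
# lesions centred on the targets. Lesion amplitude is calibrated so the ROI
# quantification stage (circular ROI, slice-wise normalization, max across
# planes, two jittered rater placements) returns the requested enhancement
# ratio in expectation -- the generator encodes outcomes, the quantifier
# recovers them.

#' In-memory image volume
#'
#' @param data 3D numeric array (x, y, z).
#' @param voxel Voxel dimensions `c(dx, dy, dz)` in metres.
#' @param origin World coordinate of the centre of voxel `[1, 1, 1]`, m.
#' @return Object of class `image_volume`.
#' @export
image_volume <- function(data, voxel, origin = NULL) {
  stopifnot(length(dim(data)) == 3, length(voxel) == 3)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxel
  structure(list(data = data, voxel = voxel, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels, %.3g x %.3g x %.3g mm\n",
              paste(dim(x$data), collapse = " x "),
              x$voxel[1] * 1e3, x$voxel[2] * 1e3, x$voxel[3] * 1e3))
  invisible(x)
}

# world coordinate -> (fractional) voxel index
world_to_vox <- function(volume, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(sweep(xyz, 2, volume$origin), 2, volume$voxel, `/`) + 1
}

#' Write an image volume to NIfTI
#'
#' @param volume An `image_volume`.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$data, pixdim = volume$voxel * 1e3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into an `image_volume`
#'
#' @param path NIfTI file path.
#' @return An `image_volume` (voxel sizes taken from the header, mm -> m).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))  # drop header attributes
  image_volume(data, voxel = RNifti::pixdim(img)[1:3] * 1e-3)
}

# in-plane circular ROI disc offsets (voxel units) for a given pixel size
roi_disc_offsets <- function(diameter, dx) {
  r <- round(diameter / dx / 2)
  g <- expand.grid(i = -r:r, j = -r:r)
  g[g$i^2 + g$j^2 <= r^2, , drop = FALSE]
}

# mean lesion profile over the ROI disc, averaged over the rater jitter
# offsets, used to calibrate lesion amplitude so quantification is unbiased
roi_gaussian_factor <- function(diameter, dx, sigma_xy, jitter = 1) {
  disc <- roi_disc_offsets(diameter, dx)
  offs <- expand.grid(oi = -jitter:jitter, oj = -jitter:jitter)
  f <- 0
  for (k in seq_len(nrow(offs))) {
    xi <- (disc$i + offs$oi[k]) * dx
    yj <- (disc$j + offs$oj[k]) * dx
    f <- f + mean(exp(-(xi^2 + yj^2) / (2 * sigma_xy^2)))
  }
  f / nrow(offs)
}

# cross-response matrix: F[i, j] = expected ROI mean at target i of a
# unit-amplitude Gaussian lesion centred at target j (jitter-averaged own
# response on the diagonal, tail cross-talk off it). Solving F a = E - 1
# makes the ROI quantification recover the encoded enhancements even with
# overlapping neighbour lesions on the 3.5 mm grid.
roi_response_matrix <- function(tg, diameter, dx, sigma_xy, sigma_z, jitter) {
  n <- nrow(tg)
  disc <- roi_disc_offsets(diameter, dx)
  fdiag <- roi_gaussian_factor(diameter, dx, sigma_xy, jitter)
  Fm <- diag(fdiag, n)
  if (n > 1) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      xi <- disc$i * dx + tg[i, 1] - tg[j, 1]
      yj <- disc$j * dx + tg[i, 2] - tg[j, 2]
      zf <- exp(-(tg[i, 3] - tg[j, 3])^2 / (2 * sigma_z^2))
      Fm[i, j] <- zf * mean(exp(-(xi^2 + yj^2) / (2 * sigma_xy^2)))
    }
  }
  Fm
}

#' Simulate a post-sonication T1w volume with encoded enhancement
#'
#' @param subject A `virtual_subject` (target coordinates), or an n x 3
#'   matrix of target coordinates.
#' @param enhancement Per-target true relative Gd contrast enhancement
#'   (ratios, each >= 1).
#' @param noise_sd Multiplicative voxel noise SD (fraction of signal).
#' @param seed Integer seed.
#' @param matrix_size In-plane matrix (256 -> 0.39 mm at 100 mm FOV).
#' @param fov In-plane field of view, m.
#' @param n_slices Number of 1.5 mm slices (odd, so a slice centre lies on the
#'   target plane).
#' @param slice_thickness Slice thickness, m.
#' @param lesion_fwhm In-plane lesion full width at half maximum, m.
#' @param lesion_fwhm_z Through-slice FWHM, m.
#' @param baseline Baseline tissue intensity (arbitrary units).
#' @param roi ROI specification used to calibrate the lesion amplitude; must
#'   match the one used at quantification for an unbiased round trip.
#' @return An `image_volume`.
#' @export
simulate_t1w_volume <- function(subject, enhancement, noise_sd = 0.02, seed = 1L,
                                matrix_size = 256, fov = 100e-3, n_slices = 21,
                                slice_thickness = 1.5e-3, lesion_fwhm = 2.5e-3,
                                lesion_fwhm_z = 3e-3, baseline = 100,
                                roi = roi_spec()) {
  tg <- if (inherits(subject, "virtual_subject")) {
    as.matrix(subject$targets[, c("x", "y", "z")])
  } else matrix(subject, ncol = 3)
  stopifnot(length(enhancement) == nrow(tg))
  if (any(enhancement < 1)) stop("enhancement ratios must be >= 1")
  dx <- fov / matrix_size
  vox <- c(dx, dx, slice_thickness)
  dims <- c(matrix_size, matrix_size, n_slices)
  origin <- -(dims - 1) / 2 * vox
  idx <- sweep(sweep(tg, 2, origin), 2, vox, `/`) + 1
  if (any(idx < 1 | idx > matrix(dims, nrow(tg), 3, byrow = TRUE))) {
    stop("target outside the imaging field of view")
  }

  sig_xy <- lesion_fwhm / (2 * sqrt(2 * log(2)))
  sig_z <- lesion_fwhm_z / (2 * sqrt(2 * log(2)))
  Fm <- roi_response_matrix(tg, roi$diameter, dx, sig_xy, sig_z, roi$jitter)
  amps <- solve(Fm, enhancement - 1)

  xs <- origin[1] + (seq_len(dims[1]) - 1) * dx
  ys <- origin[2] + (seq_len(dims[2]) - 1) * dx
  zs <- origin[3] + (seq_len(dims[3]) - 1) * slice_thickness
  lesion <- array(0, dims)
  for (t in seq_len(nrow(tg))) {
    amp <- amps[t]
    if (amp == 0) next
    gx <- exp(-(xs - tg[t, 1])^2 / (2 * sig_xy^2))
    gy <- exp(-(ys - tg[t, 2])^2 / (2 * sig_xy^2))
    gz <- exp(-(zs - tg[t, 3])^2 / (2 * sig_z^2))
    lesion <- lesion + amp * outer(outer(gx, gy), gz)
  }
  vol <- baseline * (1 + lesion)
  if (noise_sd > 0) {
    vol <- withr_seed(seed, vol * (1 + array(stats::rnorm(prod(dims), 0, noise_sd), dims)))
  }
  image_volume(vol, vox, origin)
}

#' Simulate a T2*w volume with optional hypointense (microhemorrhage) lesions
#'
#' @inheritParams simulate_t1w_volume
#' @param hypointense Logical per target: inject a dark lesion?
#' @param depth Fractional signal drop at the lesion centre (0..1).
#' @return An `image_volume`.
#' @export
simulate_t2star_volume <- function(subject, hypointense, depth = 0.5,
                                   noise_sd = 0.02, seed = 1L,
                                   matrix_size = 256, fov = 100e-3,
                                   n_slices = 21, slice_thickness = 1.5e-3,
                                   lesion_fwhm = 1.5e-3, baseline = 100) {
  tg <- if (inherits(subject, "virtual_subject")) {
    as.matrix(subject$targets[, c("x", "y", "z")])
  } else matrix(subject, ncol = 3)
  stopifnot(length(hypointense) == nrow(tg), depth >= 0, depth <= 1)
  dx <- fov / matrix_size
  vox <- c(dx, dx, slice_thickness)
  dims <- c(matrix_size, matrix_size, n_slices)
  origin <- -(dims - 1) / 2 * vox
  sig <- lesion_fwhm / (2 * sqrt(2 * log(2)))
  xs <- origin[1] + (seq_len(dims[1]) - 1) * dx
  ys <- origin[2] + (seq_len(dims[2]) - 1) * dx
  zs <- origin[3] + (seq_len(dims[3]) - 1) * slice_thickness
  les <- array(0, dims)
  for (t in which(hypointense)) {
    gx <- exp(-(xs - tg[t, 1])^2 / (2 * sig^2))
    gy <- exp(-(ys - tg[t, 2])^2 / (2 * sig^2))
    gz <- exp(-(zs - tg[t, 3])^2 / (2 * sig^2))
    les <- les + depth * outer(outer(gx, gy), gz)
  }
  vol <- baseline * pmax(0, 1 - les)
  if (noise_sd > 0) {
    vol <- withr_seed(seed, vol * (1 + array(stats::rnorm(prod(dims), 0, noise_sd), dims)))
  }
  image_volume(vol, vox, origin)
}

#' Simulate an immunofluorescence section with encoded relative intensities
#'
#' 2D analogue of [simulate_t1w_volume()]: a uniform background with Gaussian
#' fluorescence lesions at the in-plane target positions, calibrated so ROI
#' quantification recovers the encoded relative intensity.
#'
#' @param targets n x 2 (or n x 3; z ignored) matrix of target coordinates, m.
#' @param rel_intensity Per-target true relative signal intensity (>= 1).
#' @param pixel_size Section pixel size, m.
#' @param size Section matrix size (square).
#' @param noise_sd Multiplicative pixel noise SD.
#' @param seed Integer seed.
#' @param lesion_fwhm Lesion FWHM, m.
#' @param background Background intensity.
#' @param roi ROI specification (for amplitude calibration).
#' @return Matrix with attributes `pixel_size` and `background`.
#' @export
simulate_if_section <- function(targets, rel_intensity, pixel_size = 50e-6,
                                size = 512, noise_sd = 0.02, seed = 1L,
                                lesion_fwhm = 2.5e-3, background = 100,
                                roi = roi_spec()) {
  tg <- matrix(targets, ncol = ncol(as.matrix(targets)))[, 1:2, drop = FALSE]
  stopifnot(length(rel_intensity) == nrow(tg), all(rel_intensity >= 1))
  sig <- lesion_fwhm / (2 * sqrt(2 * log(2)))
  tg3 <- cbind(tg, 0)
  Fm <- roi_response_matrix(tg3, roi$diameter, pixel_size, sig, 1, roi$jitter)
  amps <- solve(Fm, rel_intensity - 1)
  orig <- -(size - 1) / 2 * pixel_size
  xs <- orig + (seq_len(size) - 1) * pixel_size
  img <- matrix(0, size, size)
  for (t in seq_len(nrow(tg))) {
    gx <- exp(-(xs - tg[t, 1])^2 / (2 * sig^2))
    gy <- exp(-(xs - tg[t, 2])^2 / (2 * sig^2))
    img <- img + amps[t] * outer(gx, gy)
  }
  img <- background * (1 + img)
  if (noise_sd > 0) {
    img <- withr_seed(seed, img * (1 + matrix(stats::rnorm(size^2, 0, noise_sd), size)))
  }
  attr(img, "pixel_size") <- pixel_size
  attr(img, "background") <- background
  img
}

#' Generate a target-wise outcome table from a sonication plan
#'
#' Draws the true relative Gd contrast enhancement of each target from the
#' subject's dose-response preset for its (target level, Tx bursts)
#' condition, then derives albumin and IgG relative immunofluorescence
#' intensities as linear functions of Gd enhancement plus Gaussian noise, and
#' red-blood-cell extravasation area as a linear function of Gd enhancement
#' with burst-length-specific intercepts plus half-normal noise, floored at
#' zero.
#'
#' @param subject A `virtual_subject`.
#' @param plan A [sonication_plan()] (burst length, target level, Tx bursts).
#' @param seed Integer seed.
#' @return Data frame: `target_id`, `target_level`, `n_tx_bursts`,
#'   `burst_length_ms`, `gd_true`, `albumin`, `igg`, `rbc_area_mm2`.
#' @export
generate_outcome_table <- function(subject, plan, seed = 1L) {
  n <- nrow(subject$targets)
  tl <- rep_len(plan$target_level, n)
  nb <- rep_len(plan$n_tx_bursts, n)
  bl_ms <- round(rep_len(plan$burst_length, n) * 1e3)
  pl <- subject$protein_link
  rl <- subject$rbc_link
  withr_seed(seed, {
    dr <- t(vapply(seq_len(n), function(i) subject$dose_response(tl[i], nb[i]),
                   numeric(2)))
    gd <- pmax(1, stats::rnorm(n, dr[, 1], dr[, 2]))
    alb <- pl$albumin$intercept + pl$albumin$slope * gd +
      stats::rnorm(n, 0, pl$albumin$noise_sd)
    igg <- pl$igg$intercept + pl$igg$slope * gd +
      stats::rnorm(n, 0, pl$igg$noise_sd)
    ic <- rl$intercepts[as.character(bl_ms)]
    ns <- rl$noise_sd[as.character(bl_ms)]
    if (anyNA(ic)) stop("rbc_link has no intercept for this burst length")
    rbc <- pmax(0, ic + rl$slope * (gd - rl$gd_centre) -
                  ns * sqrt(2 / pi) + abs(stats::rnorm(n, 0, ns)))
    data.frame(target_id = subject$targets$target_id,
               target_level = tl, n_tx_bursts = nb, burst_length_ms = bl_ms,
               gd_true = gd, albumin = alb, igg = igg, rbc_area_mm2 = rbc)
  })
}
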