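test_that("beamform grid has the protocol dimensions centred on the target", {
  g <- beamform_grid(c(1e-3, 2e-3, 3e-3))
  expect_equal(g$dims, c(11L, 11L, 21L))
  expect_equal(prod(g$dims), 2541)
  expect_equal(g$x[6], 1e-3)
  expect_equal(g$z[11], 3e-3)
})

test_that("a noiseless source at the grid centre peaks at the centre voxel", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(4)
  src <- c(2e-3, -1e-3, 0)
  sub <- point_subject(src, constants = sc)
  cap <- simulate_burst(geom, sub, 1, sub$targets$pthr + 1e3, 1e-3,
                        seed = 3, constants = sc)
  vol <- beamform_volume(cap, geom, beamform_grid(src), bandpass = TRUE)
  expect_equal(vol$spta_vox, c(6L, 6L, 11L))
  expect_equal(vol$spta_loc, src)
})

test_that("narrowband and time-domain backends agree on a toy instance", {
  # fine toy sampling so the reference's nearest-sample delay quantization
  # sits below the comparison tolerance
  sc <- test_constants(1.5e-3, sampling_rate = 8e7)
  geom <- build_array_geometry(11, n_modules = 2)
  src <- c(1e-3, -2e-3, 3e-3)
  sub <- point_subject(src, constants = sc)
  cap <- simulate_burst(geom, sub, 1, sub$targets$pthr + 1e3, 1e-3,
                        seed = 3, constants = sc, emission_onset = 0.2e-3)
  grid <- beamform_grid(src, extent = c(4e-3, 4e-3, 8e-3))
  vt <- beamform_volume(cap, geom, grid, backend = "time",
                        integration_time = 0.5e-3)
  vn <- beamform_volume(cap, geom, grid, backend = "narrowband",
                        fd_min = 6e5, integration_time = 0.5e-3)
  expect_lt(max(abs(vn$intensities - vt$intensities)) / max(vt$intensities),
            0.01)
  expect_equal(vn$spta_vox, vt$spta_vox)
})

test_that("narrowband backend matches an exact-fractional-delay spectral oracle", {
  sc <- test_constants(2e-3)
  geom <- test_geom(2)
  src <- c(1e-3, -2e-3, 3e-3)
  sub <- point_subject(src, constants = sc)
  cap <- simulate_burst(geom, sub, 1, sub$targets$pthr + 1e3, 1e-3,
                        seed = 5, constants = sc, emission_onset = 0.3e-3)
  fs <- sc$sampling_rate
  tau <- propagation_delay(src, geom$pci_receiver_positions, 1482)
  n <- nrow(cap$pci_rf)
  win <- (floor(0.3e-3 * fs) + 1):(floor(0.3e-3 * fs) + round(1e-3 * fs))
  s <- numeric(length(win))
  for (ch in seq_along(tau)) {
    X <- stats::fft(cap$pci_rf[, ch])
    k <- 0:(n - 1)
    fr <- ifelse(k <= n / 2, k, k - n) * fs / n
    xs <- Re(stats::fft(X * exp(2i * pi * fr * tau[ch]), inverse = TRUE)) / n
    s <- s + xs[win]
  }
  oracle <- mean(s^2)
  g1 <- beamform_grid(src, extent = c(1e-9, 1e-9, 1e-9))
  vn <- beamform_volume(cap, geom, g1, fd_min = 6e5)
  expect_equal(as.numeric(vn$intensities), oracle, tolerance = 1e-3)
})

test_that("shifting the source by one voxel shifts the SPTA voxel with it", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(4)
  base <- c(0, 0, 0)
  grid <- beamform_grid(base)
  for (dvec in list(c(1e-3, 0, 0), c(0, 0, 1e-3))) {
    sub <- point_subject(base + dvec, constants = sc)
    cap <- simulate_burst(geom, sub, 1, sub$targets$pthr + 1e3, 1e-3,
                          seed = 11, constants = sc)
    vol <- beamform_volume(cap, geom, grid, bandpass = TRUE)
    expect_equal(vol$spta_loc, base + dvec)
  }
})

test_that("point-source -3 dB width is near the half-wavelength limit", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(64, seed = 7)
  src <- c(0, 0, 0)
  sub <- point_subject(src, constants = sc)
  cap <- simulate_burst(geom, sub, 1, sub$targets$pthr + 1e3, 1e-3,
                        seed = 13, constants = sc)
  vol <- beamform_volume(cap, geom, beamform_grid(src), bandpass = TRUE)
  met <- compute_quality_metrics(vol)
  lambda_half <- 1482 / 387e3 / 2  # ~1.9 mm
  expect_lt(met$main_lobe_short_axis, 1.5 * lambda_half)
  expect_gt(met$main_lobe_short_axis, lambda_half / 1.5)
  expect_gt(met$main_lobe_long_axis, met$main_lobe_short_axis)
})

test_that("quality metrics handle a delta volume and constructed phantoms", {
  grid <- beamform_grid(c(0, 0, 0))
  arr <- array(0, grid$dims)
  arr[6, 6, 11] <- 1
  vol <- structure(list(intensities = arr, spta = 1, spta_vox = c(6L, 6L, 11L),
                        spta_loc = c(0, 0, 0), grid = grid),
                   class = "pci_volume")
  met <- compute_quality_metrics(vol)
  expect_equal(met$pslr, 0)
  expect_equal(met$positional_error_lateral, 0)
  expect_equal(met$positional_error_axial, 0)
  expect_lte(met$main_lobe_long_axis, 1e-3)

  # two-Gaussian phantom: secondary peak 0.6 x primary, 6 mm away -> PSLR 60
  co <- grid_coords_for_test(grid)
  g1 <- exp(-rowSums(sweep(co, 2, c(0, 0, -3e-3))^2) / (2 * (0.7e-3)^2))
  g2 <- 0.6 * exp(-rowSums(sweep(co, 2, c(0, 0, 3e-3))^2) / (2 * (0.7e-3)^2))
  arr2 <- array(g1 + g2, grid$dims)
  imax <- which.max(arr2)
  vol2 <- structure(list(intensities = arr2, spta = max(arr2),
                         spta_vox = as.integer(arrayInd(imax, grid$dims)),
                         spta_loc = c(0, 0, -3e-3), grid = grid),
                    class = "pci_volume")
  met2 <- compute_quality_metrics(vol2)
  expect_equal(met2$pslr, 60, tolerance = 1)

  # peak offset (1, 1, 2) voxels from the target
  arr3 <- array(0, grid$dims)
  arr3[7, 7, 13] <- 1
  vol3 <- structure(list(intensities = arr3, spta = 1, spta_vox = c(7L, 7L, 13L),
                         spta_loc = c(1e-3, 1e-3, 2e-3), grid = grid),
                    class = "pci_volume")
  met3 <- compute_quality_metrics(vol3, target = c(0, 0, 0))
  expect_equal(met3$positional_error_lateral, sqrt(2) * 1e-3, tolerance = 1e-9)
  expect_equal(met3$positional_error_axial, 2e-3)
})

test_that("detection gate thresholds are inclusive and independent", {
  m <- function(pslr, lat, ax) {
    structure(list(pslr = pslr, positional_error_lateral = lat,
                   positional_error_axial = ax), class = "pci_quality_metrics")
  }
  expect_true(pci_detect(m(49, 2.0e-3, 4.0e-3)))
  expect_true(pci_detect(m(70, 0, 0)))
  expect_false(pci_detect(m(71, 0, 0)))
  expect_false(pci_detect(m(0, 2.1e-3, 0)))
  expect_false(pci_detect(m(0, 0, 4.1e-3)))
})

test_that("maximum intensity projections commute with the volume maximum", {
  set.seed(21)
  arr <- array(runif(11 * 11 * 21), c(11, 11, 21))
  grid <- beamform_grid(c(0, 0, 0))
  vol <- structure(list(intensities = arr, spta = max(arr),
                        spta_vox = as.integer(arrayInd(which.max(arr), dim(arr))),
                        spta_loc = c(0, 0, 0), grid = grid),
                   class = "pci_volume")
  mip <- max_intensity_projection(vol)
  expect_equal(max(mip$xy), max(arr))
  expect_equal(max(mip$xz), max(arr))
  expect_equal(max(mip$yz), max(arr))
  expect_equal(dim(mip$xy), c(11L, 11L))
  expect_equal(dim(mip$xz), c(11L, 21L))
  # constant volume projects to constants; delta volume to single bright pixel
  volc <- vol; volc$intensities <- array(3, dim(arr))
  expect_true(all(max_intensity_projection(volc)$xy == 3))
  vold <- vol; vold$intensities <- array(0, dim(arr))
  vold$intensities[2, 3, 4] <- 1
  expect_equal(sum(max_intensity_projection(vold)$xy > 0), 1)
})
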